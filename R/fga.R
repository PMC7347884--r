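#' Lower weighted median
#'
#' Returns the smallest value (in sorted order) whose cumulative weight
#' reaches half the total weight. No interpolation: the estimator is a step
#' function of the weights, which keeps downstream alteration calls
#' deterministic.
#'
#' @param values numeric vector.
#' @param weights positive numeric vector, same length as \code{values}.
#' @return the lower weighted median, a single number.
#' @export
weighted_median <- function(values, weights) {
  if (length(values) == 0L) stop("weighted_median of empty input")
  if (length(values) != length(weights))
    stop("values and weights differ in length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  v[which(cumsum(w) >= sum(w) / 2)[1L]]
}

#' Fraction of genome altered for one sample
#'
#' FGA is the length-weighted fraction of segments whose mean log R ratio
#' deviates from the sample baseline by more than a threshold T. The baseline
#' WM is the weighted median of segment means by segment length; a segment i
#' with mean CN_i is altered when CN_i > WM + T or CN_i < WM - T (strict).
#' Segment length is end - start + 1 (1-based inclusive coordinates).
#'
#' @param segs data.frame of segments for a single sample (columns chrom,
#'   start, end, seg_mean; a sample column, if present, must hold one sample).
#' @param T alteration threshold on the segment mean (log R ratio units);
#'   0.1 is used for SNP6 tumor profiles, 0.2 for cell lines.
#' @return list with fields sample, fga, weighted_median, threshold,
#'   altered_length, total_length.
#' @export
compute_fga <- function(segs, T = 0.1) {
  if (nrow(segs) == 0L) stop("compute_fga: no segments")
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if ("sample" %in% names(segs) && length(unique(segs$sample)) > 1L)
    stop("compute_fga expects segments of a single sample")
  if (any(segs$end < segs$start)) stop("segment end < start")
  len <- as.numeric(segs$end - segs$start + 1)
  cn <- segs$seg_mean
  if (any(!is.finite(cn))) stop("non-finite segment mean")
  wm <- weighted_median(cn, len)
  altered <- cn > wm + T | cn < wm - T
  total <- sum(len)
  list(sample = if ("sample" %in% names(segs)) segs$sample[1L] else NA_character_,
       fga = sum(len[altered]) / total,
       weighted_median = wm,
       threshold = T,
       altered_length = sum(len[altered]),
       total_length = total)
}

#' Fraction of genome altered for a cohort
#'
#' Applies \code{\link{compute_fga}} per sample. The default threshold T
#' follows the platform mode: 0.1 for tumor SNP-array profiles, 0.2 for cell
#' lines. Per-sample failures are collected and reported; remaining samples
#' are still computed.
#'
#' @param segs data.frame of segments with a \code{sample} column.
#' @param mode "tumor" or "cellline"; sets the default T.
#' @param T override threshold; if NULL the mode default is used.
#' @return data.frame with one row per sample (sample, fga, weighted_median,
#'   threshold, altered_length, total_length); failed samples are listed in
#'   attribute \code{"failures"}.
#' @export
fga_cohort <- function(segs, mode = c("tumor", "cellline"), T = NULL) {
  mode <- match.arg(mode)
  if (is.null(T)) T <- if (mode == "tumor") 0.1 else 0.2
  if (!"sample" %in% names(segs)) stop("segment table needs a sample column")
  samples <- unique(segs$sample)
  rows <- list(); failures <- character(0)
  for (s in samples) {
    res <- tryCatch(compute_fga(segs[segs$sample == s, , drop = FALSE], T),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[s] <- conditionMessage(res)
    } else {
      rows[[s]] <- as.data.frame(res, stringsAsFactors = FALSE)
    }
  }
  if (length(failures) > 0L)
    warning("FGA failed for ", length(failures), " sample(s): ",
            paste(names(failures), collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
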