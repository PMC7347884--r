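#' Select a purity threshold equalizing contamination between groups
#'
#' Scans candidate purity thresholds t on a grid; at each t, samples with
#' purity > t are retained and a two-sided Wilcoxon rank-sum test compares the
#' purity of claudin-low vs non-claudin-low retained samples. The returned
#' threshold is the smallest t at which the two retained groups are no longer
#' statistically different (p >= alpha) with at least \code{min_group} samples
#' retained per group, i.e. the least stringent gate at which the degree of
#' normal-cell contamination is comparable between groups.
#'
#' @param purity numeric vector of tumor purities in (0, 1].
#' @param is_claudin_low logical vector, same length.
#' @param alpha significance level for the rank-sum test (default 0.05).
#' @param grid_step spacing of candidate thresholds (default 0.01).
#' @param min_group minimum retained samples per group (default 5).
#' @return list with fields threshold, p_value_at_threshold,
#'   n_retained_per_group, and grid (data.frame of all candidates with
#'   p-values and retained counts).
#' @export
select_purity_threshold <- function(purity, is_claudin_low, alpha = 0.05,
                                    grid_step = 0.01, min_group = 5L) {
  if (length(purity) != length(is_claudin_low))
    stop("purity and labels differ in length")
  keep <- !is.na(purity)
  purity <- purity[keep]; is_claudin_low <- is_claudin_low[keep]
  if (!any(is_claudin_low) || !any(!is_claudin_low))
    stop("both groups must be non-empty")
  lo <- floor(min(purity) / grid_step) * grid_step
  hi <- max(purity)
  grid <- seq(lo, hi, by = grid_step)
  pvals <- rep(NA_real_, length(grid))
  n_cl <- n_other <- integer(length(grid))
  for (i in seq_along(grid)) {
    sel <- purity > grid[i]
    a <- purity[sel & is_claudin_low]
    b <- purity[sel & !is_claudin_low]
    n_cl[i] <- length(a); n_other[i] <- length(b)
    if (length(a) >= min_group && length(b) >= min_group)
      pvals[i] <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           correct = TRUE)$p.value)
  }
  ok <- !is.na(pvals) & pvals >= alpha
  grid_df <- data.frame(threshold = grid, p_value = pvals,
                        n_claudin_low = n_cl, n_other = n_other)
  if (!any(ok)) {
    stop("no threshold equalizes purity at alpha = ", alpha, "; grid p-values: ",
         paste(sprintf("%.2f:%.3g", grid, pvals), collapse = " "))
  }
  j <- which(ok)[1L]
  list(threshold = grid[j],
       p_value_at_threshold = pvals[j],
       n_retained_per_group = c(claudin_low = n_cl[j], other = n_other[j]),
       grid = grid_df)
}

#' Find deletion segments by log R ratio cutoff
#'
#' @param segs data.frame of segments (chrom, start, end, seg_mean; optional
#'   sample).
#' @param lrr_cut negative segment-mean cutoff; segments with
#'   seg_mean < lrr_cut are returned (default -0.4).
#' @return the filtered data.frame (possibly empty).
#' @export
find_deletion_segments <- function(segs, lrr_cut = -0.4) {
  if (!is.numeric(lrr_cut) || lrr_cut >= 0) stop("lrr_cut must be negative")
  segs[segs$seg_mean < lrr_cut, , drop = FALSE]
}

#' Assess BAF band separation over deletion segments
#'
#' Within each deletion segment, a hemizygous single-copy loss splits the
#' heterozygous-SNP B allele frequencies into two bands at (1-p)/(2-p) and
#' 1/(2-p) for tumor purity p. Germline-homozygous SNPs are removed by
#' trimming BAF < 0.03 or > 0.97; remaining SNPs are split into a lower and
#' an upper cluster at BAF 0.5. The segment passes when the lower cluster
#' mean is <= \code{low_cut} and the upper cluster mean is >= \code{high_cut}
#' — bands pulled inside (low_cut, high_cut) are the signature of normal-cell
#' contamination. Segments with fewer than \code{min_snps} informative SNPs
#' are flagged uninformative rather than failed.
#'
#' @param snps data.frame with columns sample, chrom, position, baf.
#' @param segments data.frame of deletion segments (from
#'   \code{\link{find_deletion_segments}}).
#' @param low_cut upper bound for the lower band mean (default 0.2).
#' @param high_cut lower bound for the upper band mean (default 0.8).
#' @param min_snps minimum informative SNPs per segment (default 4).
#' @return data.frame, one row per segment: chrom, start, end, seg_mean,
#'   n_snps, lower_cluster_mean, upper_cluster_mean, informative,
#'   separation_pass.
#' @export
assess_baf_separation <- function(snps, segments, low_cut = 0.2,
                                  high_cut = 0.8, min_snps = 4L) {
  if (min_snps < 4L) stop("min_snps must be >= 4")
  n <- nrow(segments)
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    seg_mean = numeric(n), n_snps = integer(n),
                    lower_cluster_mean = NA_real_,
                    upper_cluster_mean = NA_real_,
                    informative = logical(n), separation_pass = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seg <- segments[i, ]
    sel <- snps$chrom == seg$chrom & snps$position >= seg$start &
      snps$position <= seg$end
    if ("sample" %in% names(segments) && "sample" %in% names(snps))
      sel <- sel & snps$sample == seg$sample
    baf <- snps$baf[sel]
    baf <- baf[baf > 0.03 & baf < 0.97]  # drop germline-homozygous bands
    lower <- baf[baf < 0.5]; upper <- baf[baf >= 0.5]
    out$chrom[i] <- as.character(seg$chrom)
    out$start[i] <- seg$start; out$end[i] <- seg$end
    out$seg_mean[i] <- seg$seg_mean
    out$n_snps[i] <- length(baf)
    informative <- length(baf) >= min_snps && length(lower) > 0L &&
      length(upper) > 0L
    out$informative[i] <- informative
    if (informative) {
      out$lower_cluster_mean[i] <- mean(lower)
      out$upper_cluster_mean[i] <- mean(upper)
      out$separation_pass[i] <- mean(lower) <= low_cut &&
        mean(upper) >= high_cut
    }
  }
  out
}

#' Count mutations with clonal-level VAF support
#'
#' Counts exonic non-silent mutations with variant allele frequency above
#' \code{vaf_cut}. A clonal heterozygous mutation in a diploid tumor of
#' purity p has expected VAF p/2, so VAF > 0.4 implies high purity.
#'
#' @param muts data.frame with columns vaf and annotation.
#' @param vaf_cut VAF threshold in (0, 1) (default 0.4).
#' @return list with fields n_pass (count) and pass (TRUE when n_pass >= 1).
#' @export
check_vaf_support <- function(muts, vaf_cut = 0.4) {
  if (vaf_cut <= 0 || vaf_cut >= 1) stop("vaf_cut must be in (0, 1)")
  sel <- muts$annotation == "exonic_nonsilent" & muts$vaf > vaf_cut
  n <- sum(sel, na.rm = TRUE)
  list(n_pass = n, pass = n >= 1L)
}

#' Focal-loss verification report for one sample
#'
#' Combines the deletion-segment scan, BAF band separation and VAF support
#' into a per-sample report answering whether a CNA-devoid profile
#' (FGA below \code{fga_devoid}) nevertheless shows genuine focal somatic
#' alterations — evidence that the flat landscape is real tumor, not
#' normal-cell contamination.
#'
#' @param segs segments of one sample.
#' @param snps SNP BAF/LRR profile of the sample.
#' @param muts mutation table of the sample (may be empty).
#' @param fga the sample's fraction of genome altered.
#' @param lrr_cut,low_cut,high_cut,min_snps,vaf_cut see the component
#'   functions.
#' @param fga_devoid FGA below which a profile counts as CNA-devoid
#'   (default 0.01).
#' @return list with fields sample, deletion_segments, baf (per-segment
#'   table), n_mutations_vaf_pass, cna_devoid, focal_evidence,
#'   cna_devoid_but_pure.
#' @export
focal_loss_report <- function(segs, snps, muts, fga, lrr_cut = -0.4,
                              low_cut = 0.2, high_cut = 0.8, min_snps = 4L,
                              vaf_cut = 0.4, fga_devoid = 0.01) {
  dels <- find_deletion_segments(segs, lrr_cut)
  baf <- assess_baf_separation(snps, dels, low_cut, high_cut, min_snps)
  vaf <- check_vaf_support(muts, vaf_cut)
  evidence <- any(baf$separation_pass) || vaf$pass
  list(sample = if ("sample" %in% names(segs) && nrow(segs) > 0L)
         segs$sample[1L] else NA_character_,
       deletion_segments = dels,
       baf = baf,
       n_mutations_vaf_pass = vaf$n_pass,
       cna_devoid = fga < fga_devoid,
       focal_evidence = evidence,
       cna_devoid_but_pure = fga < fga_devoid && evidence)
}
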