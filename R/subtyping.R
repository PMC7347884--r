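#' Call claudin-low status by nearest centroid
#'
#' Computes, for each sample, the Euclidean distance between its standardized
#' expression profile and each class centroid over the genes shared between
#' the matrix and the centroid model, and assigns the nearest centroid. Ties
#' are resolved conservatively: a sample exactly equidistant between the
#' claudin-low and another centroid is called the other class.
#'
#' @param m gene-by-sample z-scored expression matrix.
#' @param centroids gene-by-class numeric matrix (classes typically
#'   \code{claudin_low} and \code{other}; any k classes are allowed).
#' @param min_coverage minimum fraction of centroid genes that must be
#'   present in \code{m} (default 0.5).
#' @return data.frame with sample, label, and one distance column per class.
#' @export
call_claudin_low <- function(m, centroids, min_coverage = 0.5) {
  shared <- intersect(rownames(m), rownames(centroids))
  coverage <- length(shared) / nrow(centroids)
  if (coverage < min_coverage)
    stop(nrow(centroids) - length(shared), " of ", nrow(centroids),
         " centroid genes missing from the expression matrix (coverage ",
         sprintf("%.2f", coverage), " < ", min_coverage, ")")
  cls <- colnames(centroids)
  # evaluate claudin_low last so which.min's first-on-tie rule prefers others
  ord <- order(cls == "claudin_low")
  cls <- cls[ord]
  cen <- centroids[shared, cls, drop = FALSE]
  mm <- m[shared, , drop = FALSE]
  d <- vapply(cls, function(cl)
    sqrt(colSums((mm - cen[, cl])^2)), numeric(ncol(mm)))
  d <- matrix(d, nrow = ncol(mm), dimnames = list(colnames(mm), cls))
  labels <- cls[apply(d, 1L, which.min)]
  out <- data.frame(sample = colnames(mm), label = labels,
                    stringsAsFactors = FALSE)
  dist_df <- as.data.frame(d)
  names(dist_df) <- paste0("dist_", cls)
  cbind(out, dist_df)
}

#' Resolve a consensus intrinsic subtype across algorithms
#'
#' A sample's subtype is considered final when at least three algorithms
#' agree; otherwise the fallback algorithm's call (PAM50 in the published
#' procedure) is used.
#'
#' @param calls named character vector (or one-row data.frame) of per-algorithm
#'   labels for one sample, or a data.frame with one row per sample and one
#'   column per algorithm.
#' @param fallback name of the fallback algorithm.
#' @param min_agree agreement required for a direct call (default 3).
#' @return a single consensus label, or a character vector (one per row) when
#'   \code{calls} is a multi-row data.frame.
#' @export
consensus_subtype <- function(calls, fallback = "PAM50", min_agree = 3L) {
  if (is.data.frame(calls) && nrow(calls) > 1L) {
    return(vapply(seq_len(nrow(calls)), function(i)
      consensus_subtype(unlist(calls[i, , drop = TRUE]), fallback, min_agree),
      character(1)))
  }
  v <- unlist(calls)
  if (length(v) < 1L) stop("no algorithm calls supplied")
  tab <- sort(table(v), decreasing = TRUE)
  if (tab[1L] >= min_agree) return(names(tab)[1L])
  if (!fallback %in% names(v))
    stop("divergent calls and fallback algorithm '", fallback, "' absent")
  unname(v[[fallback]])
}

#' Derive triple-negative status from expression and ERBB2 copy state
#'
#' ER and PR negativity are called from the cohort distribution of ESR1 and
#' PGR expression: a two-component Gaussian mixture is fitted across samples
#' and a sample is negative when its posterior for the lower component
#' exceeds 0.5. If the cohort is unimodal (BIC prefers one component), a
#' fixed z-score cutoff of -0.5 is used instead, with a warning. HER2 is
#' negative when the ERBB2 copy-number state is below amplification
#' (state <= 1, i.e. at most gain). A sample is TN iff all three are
#' negative; samples with any missing input are "unknown".
#'
#' @param esr1_expr,pgr_expr numeric per-sample expression (z-scores).
#' @param erbb2_cn_state integer per-sample copy state (-2 deep loss, -1
#'   loss, 0 neutral, 1 gain, 2 amplification).
#' @param seed seed for the mixture fits.
#' @return character vector of "TN", "non-TN", "unknown" per sample.
#' @export
call_tn_status <- function(esr1_expr, pgr_expr, erbb2_cn_state, seed = 1L) {
  n <- length(esr1_expr)
  if (length(pgr_expr) != n || length(erbb2_cn_state) != n)
    stop("inputs differ in length")
  neg_call <- function(x, seed) {
    ok <- is.finite(x)
    neg <- rep(NA, length(x))
    fit <- tryCatch(select_model(x[ok], k_max = 2L, seed = seed),
                    error = function(e) NULL)
    if (is.null(fit) || fit$k < 2L) {
      warning("receptor expression looks unimodal; using z-score cutoff -0.5")
      neg[ok] <- x[ok] < -0.5
    } else {
      post <- .posterior_matrix(fit, x[ok])
      neg[ok] <- post[, 1L] > 0.5
    }
    neg
  }
  er_neg <- neg_call(esr1_expr, seed)
  pr_neg <- neg_call(pgr_expr, seed + 1L)
  her2_neg <- erbb2_cn_state <= 1L
  status <- rep("unknown", n)
  known <- !is.na(er_neg) & !is.na(pr_neg) & !is.na(her2_neg)
  status[known] <- ifelse(er_neg[known] & pr_neg[known] & her2_neg[known],
                          "TN", "non-TN")
  status
}
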