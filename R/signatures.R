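#' Signal2Noise ranking statistic
#'
#' For every gene, (mu_A - mu_B) / (sigma_A + sigma_B), with each group
#' standard deviation floored at max(0.2 |mu|, 1e-8) of its own group, the
#' convention of the original GSEA desktop implementation. Genes are
#' returned ranked by the statistic descending, ties broken by gene
#' identifier ascending so the ordering is deterministic.
#'
#' @param X gene-by-sample matrix.
#' @param groupA,groupB sample identifiers (or column indices) of the two
#'   groups; each must contain at least 3 samples.
#' @return data.frame (gene, statistic) ordered for preranked GSEA.
#' @export
signal2noise <- function(X, groupA, groupB) {
  X <- as.matrix(X)
  a <- X[, groupA, drop = FALSE]
  b <- X[, groupB, drop = FALSE]
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("each group needs >= 3 samples")
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  sd_a <- apply(a, 1L, stats::sd); sd_b <- apply(b, 1L, stats::sd)
  sd_a <- pmax(sd_a, 0.2 * abs(mu_a), 1e-8)
  sd_b <- pmax(sd_b, 0.2 * abs(mu_b), 1e-8)
  stat <- (mu_a - mu_b) / (sd_a + sd_b)
  ord <- order(-stat, rownames(X))
  data.frame(gene = rownames(X)[ord], statistic = stat[ord],
             stringsAsFactors = FALSE)
}

.es_weighted_ks <- function(stat_ranked, hit, p = 1) {
  # stat_ranked: statistic values in ranked order; hit: logical, same order
  n <- length(stat_ranked)
  nh <- sum(hit)
  w <- abs(stat_ranked)^p
  nr <- sum(w[hit])
  if (nr == 0) return(list(es = 0, running = numeric(n)))
  step_hit <- ifelse(hit, w / nr, 0)
  step_miss <- ifelse(hit, 0, 1 / (n - nh))
  running <- cumsum(step_hit - step_miss)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: walking down the ranked
#' list, the running sum rises by |statistic|^p (normalized over the set's
#' members) at set genes and falls by 1/(N - Nh) elsewhere; ES is the
#' maximum-magnitude deviation. The null is built by permuting gene labels
#' (sampling random same-size sets); NES divides ES by the mean |null ES| of
#' the same sign, and the nominal p-value counts same-sign null ES at least
#' as extreme. BH FDR is applied across sets.
#'
#' @param ranked data.frame (gene, statistic) from
#'   \code{\link{signal2noise}}, ordered descending.
#' @param sets named list of gene vectors (see \code{\link{read_gmt}}).
#' @param weight_p exponent on |statistic| for hit increments (default 1).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed permutation seed.
#' @param min_size minimum overlap between set and ranked genes (default 5);
#'   undersized sets are skipped with a warning.
#' @return data.frame: set, size, es, nes, p_value, fdr, leading_edge
#'   (semicolon-joined genes).
#' @export
gsea_preranked <- function(ranked, sets, weight_p = 1, n_perm = 1000L,
                           seed = 1L, min_size = 5L) {
  genes <- ranked$gene
  stat <- ranked$statistic
  n <- length(genes)
  sizes <- vapply(sets, function(s) sum(s %in% genes), integer(1))
  small <- sizes < min_size
  if (any(small)) {
    warning(sum(small), " set(s) below min_size skipped: ",
            paste(utils::head(names(sets)[small], 5L), collapse = ", "))
    sets <- sets[!small]; sizes <- sizes[!small]
  }
  if (length(sets) == 0L) stop("no gene set meets min_size")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  # one shared null per distinct set size
  null_by_size <- list()
  for (sz in unique(sizes)) {
    null_es <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      hit <- logical(n)
      hit[sample.int(n, sz)] <- TRUE
      null_es[b] <- .es_weighted_ks(stat, hit, weight_p)$es
    }
    null_by_size[[as.character(sz)]] <- null_es
  }
  rows <- lapply(names(sets), function(nm) {
    hit <- genes %in% sets[[nm]]
    r <- .es_weighted_ks(stat, hit, weight_p)
    es <- r$es
    null_es <- null_by_size[[as.character(sum(hit))]]
    same <- null_es[sign(null_es) == sign(es)]
    if (length(same) == 0L) same <- abs(null_es)
    nes <- es / mean(abs(same))
    pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    peak <- which.max(abs(r$running))
    le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
          else genes[peak:n][hit[peak:n]]
    data.frame(set = nm, size = sum(hit), es = es, nes = nes, p_value = pval,
               leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(-abs(out$nes)), c("set", "size", "es", "nes", "p_value", "fdr",
                              "leading_edge")]
}

.ssgsea_sample <- function(expr, sets, alpha) {
  # expr: named numeric vector for one sample
  n <- length(expr)
  # rank 1 = lowest expression; walk the list from highest rank down
  rk <- rank(expr, ties.method = "average")
  ord <- order(rk, decreasing = TRUE)
  rk_sorted <- rk[ord]
  genes_sorted <- names(expr)[ord]
  w <- rk_sorted^alpha
  vapply(sets, function(members) {
    hit <- genes_sorted %in% members
    nh <- sum(hit)
    if (nh == 0L || nh == n) return(0)   # empty in- or out-set: score 0
    ecdf_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    ecdf_out <- cumsum(!hit) / (n - nh)
    sum(ecdf_in - ecdf_out)
  }, numeric(1))
}

#' Single-sample GSEA scores
#'
#' For each sample independently, genes are ranked by expression and each
#' set's score is the integrated difference between the rank-weighted
#' in-set empirical CDF (weight rank^alpha) and the unweighted out-set
#' ECDF, summed over all positions in the ranking. Scores depend on the
#' ranking only, so they are invariant under any strictly monotone
#' transformation of a sample's expression values. With
#' \code{normalize = TRUE} the score matrix is divided by its overall range
#' (max - min).
#'
#' @param X gene-by-sample expression matrix.
#' @param sets named list of gene vectors.
#' @param alpha rank-weight exponent (default 0.25, the classic value).
#' @param normalize divide the whole matrix by its range (default TRUE).
#' @return set-by-sample numeric matrix of scores.
#' @export
ssgsea <- function(X, sets, alpha = 0.25, normalize = TRUE) {
  X <- as.matrix(X)
  keep <- vapply(sets, function(s) any(s %in% rownames(X)), logical(1))
  if (any(!keep))
    warning(sum(!keep), " set(s) with no genes in the matrix skipped")
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene set overlaps the expression matrix")
  scores <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]; names(v) <- rownames(X)
    .ssgsea_sample(v, sets, alpha)
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), colnames(X)))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Derive cell-type signatures from sorted subpopulations
#'
#' One-vs-rest differential expression (Welch t-test per gene) for each
#' subpopulation of a sorted-cell expression matrix; genes passing BH FDR <
#' \code{fdr_cut} are ranked by FDR, then p-value, then gene identifier, and
#' the top \code{top_n} form that subpopulation's signature.
#'
#' @param X gene-by-sample expression matrix of sorted normal subpopulations.
#' @param labels subpopulation label per sample (e.g. MaSC, LP, mL); each
#'   needs >= 2 samples.
#' @param top_n signature size cap (default 500).
#' @param fdr_cut BH FDR threshold (default 0.05).
#' @return named list of gene vectors (a gene-set collection), one per
#'   subpopulation; the per-gene statistics are attached as attribute
#'   \code{"tables"}.
#' @export
derive_cell_signatures <- function(X, labels, top_n = 500L, fdr_cut = 0.05) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  nk <- table(factor(labels, levels = classes))
  if (any(nk < 2L)) stop("every subpopulation needs >= 2 samples")
  sigs <- list(); tabs <- list()
  for (cl in classes) {
    in_cl <- labels == cl
    pv <- apply(X, 1L, function(v) {
      if (stats::sd(v[in_cl]) == 0 && stats::sd(v[!in_cl]) == 0)
        return(NA_real_)  # degenerate gene: skipped
      tryCatch(stats::t.test(v[in_cl], v[!in_cl])$p.value,
               error = function(e) NA_real_)
    })
    ok <- !is.na(pv)
    fdr <- rep(NA_real_, length(pv))
    fdr[ok] <- stats::p.adjust(pv[ok], method = "BH")
    tab <- data.frame(gene = rownames(X), p_value = pv, fdr = fdr,
                      stringsAsFactors = FALSE)
    hit <- tab[ok & fdr < fdr_cut, , drop = FALSE]
    hit <- hit[order(hit$fdr, hit$p_value, hit$gene), , drop = FALSE]
    sigs[[cl]] <- utils::head(hit$gene, top_n)
    tabs[[cl]] <- tab
  }
  attr(sigs, "tables") <- tabs
  attr(sigs, "description") <- stats::setNames(
    rep(paste("top", top_n, "one-vs-rest genes at FDR <", fdr_cut),
        length(classes)), classes)
  sigs
}
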