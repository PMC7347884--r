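#' Filter genes whose methylation anti-correlates with expression
#'
#' For every gene shared between the methylation beta-value matrix and the
#' expression matrix, Spearman's rho is computed across the shared samples;
#' genes with rho < 0 and BH FDR < \code{fdr_cut} are retained — the genes
#' for which promoter methylation plausibly represses expression.
#'
#' @param meth gene-by-sample beta-value matrix (values in [0, 1]).
#' @param expr gene-by-sample expression matrix.
#' @param fdr_cut BH FDR threshold (default 0.05).
#' @param min_samples minimum shared samples (default 10).
#' @return list with fields \code{genes} (retained identifiers) and
#'   \code{table} (gene, rho, p_value, fdr, skipped).
#' @export
filter_expression_correlated <- function(meth, expr, fdr_cut = 0.05,
                                         min_samples = 10L) {
  genes <- intersect(rownames(meth), rownames(expr))
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(genes) < 1L) stop("no shared genes")
  if (length(samples) < min_samples)
    stop("need >= ", min_samples, " shared samples, found ", length(samples))
  rho <- p <- rep(NA_real_, length(genes))
  skipped <- logical(length(genes))
  for (i in seq_along(genes)) {
    b <- meth[genes[i], samples]
    e <- expr[genes[i], samples]
    if (stats::sd(b) == 0 || stats::sd(e) == 0) {
      skipped[i] <- TRUE
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(b, e, method = "spearman", exact = FALSE))
    rho[i] <- ct$estimate
    p[i] <- ct$p.value
  }
  fdr <- rep(NA_real_, length(genes))
  fdr[!skipped] <- stats::p.adjust(p[!skipped], method = "BH")
  keep <- !skipped & rho < 0 & fdr < fdr_cut
  list(genes = genes[keep],
       table = data.frame(gene = genes, rho = rho, p_value = p, fdr = fdr,
                          skipped = skipped, stringsAsFactors = FALSE))
}

#' One-vs-rest differential methylation per subgroup
#'
#' For each subgroup and each gene, a two-sided Wilcoxon rank-sum test
#' compares beta-values of the subgroup against all other samples; BH FDR is
#' applied per contrast. A gene is significant when FDR < \code{fdr_cut} and
#' the median beta difference exceeds \code{min_delta} in magnitude;
#' direction is hyper for positive delta, hypo for negative.
#'
#' @param meth gene-by-sample beta matrix (ideally restricted to
#'   expression-anticorrelated genes).
#' @param subgroups subgroup label per sample (each >= 3 samples).
#' @param fdr_cut BH FDR threshold (default 0.05).
#' @param min_delta minimum |median beta difference| (default 0.1).
#' @return data.frame: gene, subgroup, delta_beta, p_value, fdr, significant,
#'   direction.
#' @export
differential_methylation <- function(meth, subgroups, fdr_cut = 0.05,
                                     min_delta = 0.1) {
  meth <- as.matrix(meth)
  subgroups <- as.character(subgroups)
  if (ncol(meth) != length(subgroups))
    stop("one subgroup label per sample required")
  classes <- sort(unique(subgroups))
  nk <- table(factor(subgroups, levels = classes))
  if (any(nk < 3L))
    stop("subgroup(s) with fewer than 3 samples: ",
         paste(classes[nk < 3L], collapse = ", "))
  rows <- list()
  for (cl in classes) {
    sel <- subgroups == cl
    delta <- apply(meth, 1L, function(v)
      stats::median(v[sel]) - stats::median(v[!sel]))
    pv <- apply(meth, 1L, function(v) {
      if (stats::sd(v) == 0) return(1)
      suppressWarnings(stats::wilcox.test(v[sel], v[!sel])$p.value)
    })
    fdr <- stats::p.adjust(pv, method = "BH")
    rows[[cl]] <- data.frame(
      gene = rownames(meth), subgroup = cl, delta_beta = delta,
      p_value = pv, fdr = fdr,
      significant = fdr < fdr_cut & abs(delta) >= min_delta,
      direction = ifelse(delta >= 0, "hyper", "hypo"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each set, within a stated gene universe; BH FDR across sets. A query
#' disjoint from a set has p = 1 under the upper-tail convention.
#'
#' @param query character vector of genes (must be a subset of
#'   \code{universe}).
#' @param universe character vector of all testable genes.
#' @param sets named list of gene vectors.
#' @return data.frame: set, overlap, set_size (within universe),
#'   universe_size, query_size, p_value, fdr.
#' @export
enrich_gene_sets <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    ov <- length(intersect(query, set_u))
    p <- stats::phyper(ov - 1, length(set_u),
                       length(universe) - length(set_u),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set_u),
               universe_size = length(universe), query_size = length(query),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}
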