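#' Convert FPKM/RPKM abundances to TPM
#'
#' Rescales each sample (column) of a gene-by-sample abundance matrix so the
#' column sums to one million: TPM(g,s) = abundance(g,s) / sum_i abundance(i,s)
#' * 1e6. FPKM and RPKM are already length-normalized, so the within-sample
#' proportion is all that changes.
#'
#' @param m numeric gene-by-sample matrix of FPKM or RPKM values (rownames =
#'   genes, colnames = samples). All values must be non-negative and every
#'   sample must have at least one positive value.
#' @return a matrix of the same shape with each column summing to 1e6, with
#'   attribute \code{unit_state = "tpm"}.
#' @examples
#' m <- matrix(c(5, 5, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
#' tpm_from_abundance(m)
#' @export
tpm_from_abundance <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("abundance matrix must be numeric")
  if (anyNA(m)) stop("abundance matrix contains missing values")
  if (any(m < 0)) stop("abundance values must be non-negative")
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    bad <- colnames(m)[zero]
    if (is.null(bad)) bad <- which(zero)
    stop("all-zero abundance column(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(m, 2, cs, "/") * 1e6
  attr(out, "unit_state") <- "tpm"
  out
}

#' Combine expression batches by per-gene median Z-scores
#'
#' Each batch is standardized independently: for every gene, values are
#' median-centered and divided by the within-batch standard deviation
#' (denominator n - 1). Batches are then column-concatenated over the
#' intersection of their gene universes. Genes with zero standard deviation in
#' any batch cannot be standardized and are dropped with a warning; the drop
#' log is attached as attribute \code{"dropped"}.
#'
#' @param batches a list of numeric gene-by-sample matrices with rownames.
#' @return combined matrix with attribute \code{unit_state = "zscore"} and
#'   attribute \code{dropped} listing genes removed for zero dispersion.
#' @export
zscore_combine <- function(batches) {
  if (!is.list(batches) || length(batches) < 1L)
    stop("batches must be a non-empty list of matrices")
  batches <- lapply(batches, as.matrix)
  if (any(vapply(batches, function(b) is.null(rownames(b)), logical(1))))
    stop("every batch must have gene rownames")
  genes <- Reduce(intersect, lapply(batches, rownames))
  if (length(genes) == 0L) stop("batches share no genes")
  std <- lapply(batches, function(b) {
    b <- b[genes, , drop = FALSE]
    med <- apply(b, 1L, stats::median)
    sds <- apply(b, 1L, stats::sd)
    list(values = (b - med) / sds, zero_sd = genes[!is.na(sds) & sds == 0])
  })
  dropped <- unique(unlist(lapply(std, `[[`, "zero_sd")))
  keep <- setdiff(genes, dropped)
  if (length(dropped) > 0L)
    warning(length(dropped), " gene(s) dropped for zero within-batch sd: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  if (length(keep) == 0L) stop("no genes left after dropping zero-sd genes")
  out <- do.call(cbind, lapply(std, function(s) s$values[keep, , drop = FALSE]))
  attr(out, "unit_state") <- "zscore"
  attr(out, "dropped") <- dropped
  out
}

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to the same gene are averaged (unweighted mean) per sample;
#' probes absent from the map are dropped.
#'
#' @param m numeric probe-by-sample matrix with probe rownames.
#' @param probe_map named character vector mapping probe id -> gene id.
#' @return gene-by-sample matrix, one row per mapped gene.
#' @export
collapse_probes <- function(m, probe_map) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("matrix must have probe rownames")
  if (is.null(names(probe_map))) stop("probe_map must be a named vector")
  shared <- intersect(rownames(m), names(probe_map))
  if (length(shared) == 0L)
    stop("no probes of the matrix are covered by probe_map")
  sub <- m[shared, , drop = FALSE]
  grp <- factor(probe_map[shared])
  sums <- rowsum(sub, grp)
  counts <- as.vector(table(grp))
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}
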