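## Readers/writers for the tab-separated formats the pipeline consumes:
## SEG segment tables, GMT gene-set collections, gene-by-sample matrices,
## MAF-like mutation tables, SNP BAF/LRR profiles, sample annotations and
## centroid tables. All are strict: malformed lines fail fast with a line
## number, matrices may not contain missing cells.

.valid_chroms <- c(as.character(1:22), "X", "Y",
                   paste0("chr", c(1:22, "X", "Y")))

.check_chrom <- function(chrom, file) {
  bad <- !chrom %in% .valid_chroms
  if (any(bad))
    stop("unknown chromosome token(s) in ", file, ": ",
         paste(unique(chrom[bad]), collapse = ", "))
}

.read_tsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Read a SEG segment table
#'
#' Expects the common SEG dialect: tab-separated columns Sample, Chromosome,
#' Start, End, Num_Probes (optional), Segment_Mean; coordinates 1-based
#' inclusive.
#'
#' @param path path to a SEG file.
#' @return data.frame with columns sample, chrom, start, end, num_probes,
#'   seg_mean.
#' @export
read_seg <- function(path) {
  df <- .read_tsv(path, "SEG")
  cols <- tolower(names(df))
  need <- c("sample", "chromosome", "start", "end", "segment_mean")
  miss <- setdiff(need, cols)
  if (length(miss) > 0L)
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample = as.character(df[[which(cols == "sample")]]),
    chrom = as.character(df[[which(cols == "chromosome")]]),
    start = df[[which(cols == "start")]],
    end = df[[which(cols == "end")]],
    num_probes = if ("num_probes" %in% cols)
      df[[which(cols == "num_probes")]] else NA_integer_,
    seg_mean = df[[which(cols == "segment_mean")]],
    stringsAsFactors = FALSE)
  .check_chrom(out$chrom, path)
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$seg_mean) |
                 out$end < out$start | !is.finite(out$seg_mean))
  if (length(bad) > 0L)
    stop("malformed SEG record at data line ", bad[1L], " of ", path)
  out
}

#' Write a SEG segment table
#' @param segs data.frame as returned by \code{\link{read_seg}}.
#' @param path output path.
#' @export
write_seg <- function(segs, path) {
  df <- data.frame(Sample = segs$sample, Chromosome = segs$chrom,
                   Start = segs$start, End = segs$end,
                   Num_Probes = segs$num_probes,
                   Segment_Mean = segs$seg_mean)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (the members), with a named
#'   character vector of descriptions attached as attribute
#'   \code{"description"}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           " (need name, description, >=1 member)")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("empty gene set at GMT line ", i, " in ", path)
    sets[[f[1L]]] <- members
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors; optional attribute
#'   \code{"description"}.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample numeric matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample each.
#' Missing cells are an error (readers fail fast rather than impute).
#'
#' @param path path to a TSV matrix.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path, "matrix")
  if (ncol(df) < 2L) stop("matrix TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in matrix ", path)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("missing cell at data line ", bad, " of ", path)
  }
  rownames(m) <- genes
  m
}

#' Write a gene-by-sample matrix to TSV
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the gene-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF-like somatic mutation table
#'
#' Tab-separated with named columns sample, gene, chromosome, position,
#' ref_allele, alt_allele, annotation, and either a precomputed \code{vaf}
#' column or the pair \code{t_alt_count}/\code{t_ref_count} from which VAF is
#' derived as alt / (alt + ref).
#'
#' @param path path to the mutation TSV.
#' @return data.frame with a numeric \code{vaf} column in [0, 1].
#' @export
read_mutations <- function(path) {
  df <- .read_tsv(path, "mutation")
  cols <- tolower(names(df))
  names(df) <- cols
  need <- c("sample", "gene", "chromosome", "position")
  miss <- setdiff(need, cols)
  if (length(miss) > 0L)
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"vaf" %in% cols) {
    if (!all(c("t_alt_count", "t_ref_count") %in% cols))
      stop("mutation table needs a vaf column or t_alt_count/t_ref_count")
    df$vaf <- df$t_alt_count / (df$t_alt_count + df$t_ref_count)
  }
  if (!"annotation" %in% cols) df$annotation <- "other"
  bad <- which(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1)
  if (length(bad) > 0L)
    stop("invalid VAF at data line ", bad[1L], " of ", path)
  .check_chrom(as.character(df$chromosome), path)
  df
}

#' Write a mutation table
#' @param muts data.frame as returned by \code{\link{read_mutations}}.
#' @param path output path.
#' @export
write_mutations <- function(muts, path) {
  utils::write.table(muts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP BAF/LRR profile
#'
#' Tab-separated columns sample, chromosome, position, baf, lrr. BAF must lie
#' in [0, 1]; positions must be strictly increasing within each
#' sample-chromosome block.
#'
#' @param path path to the SNP TSV.
#' @return data.frame with columns sample, chrom, position, baf, lrr.
#' @export
read_snp_profile <- function(path) {
  df <- .read_tsv(path, "SNP profile")
  names(df) <- tolower(names(df))
  need <- c("sample", "chromosome", "position", "baf", "lrr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("SNP profile missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample = as.character(df$sample),
                    chrom = as.character(df$chromosome),
                    position = df$position, baf = df$baf, lrr = df$lrr,
                    stringsAsFactors = FALSE)
  .check_chrom(out$chrom, path)
  if (any(is.na(out$baf) | out$baf < 0 | out$baf > 1))
    stop("BAF outside [0, 1] in ", path)
  inc <- unsplit(lapply(split(out$position,
                              paste(out$sample, out$chrom, sep = "\r")),
                        function(p) c(TRUE, diff(p) > 0)),
                 paste(out$sample, out$chrom, sep = "\r"))
  if (!all(inc))
    stop("positions not strictly increasing within a chromosome in ", path)
  out
}

#' Write a per-SNP BAF/LRR profile
#' @param snps data.frame as returned by \code{\link{read_snp_profile}}.
#' @param path output path.
#' @export
write_snp_profile <- function(snps, path) {
  df <- data.frame(sample = snps$sample, chromosome = snps$chrom,
                   position = snps$position, baf = snps$baf, lrr = snps$lrr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated with a \code{sample} column; optional \code{purity} (in
#' (0, 1]), \code{ploidy}, receptor status columns and per-algorithm subtype
#' call columns.
#'
#' @param path path to the annotation TSV.
#' @return data.frame keyed by sample.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path, "annotation")
  names(df) <- tolower(names(df))
  if (!"sample" %in% names(df)) stop("annotation table needs a sample column")
  if ("purity" %in% names(df)) {
    p <- df$purity
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      stop("purity outside (0, 1] in ", path)
  }
  df$sample <- as.character(df$sample)
  df
}

#' Write a sample annotation table
#' @param ann data.frame with a sample column.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a centroid table
#'
#' TSV with a gene column followed by one numeric column per class
#' (e.g. claudin_low, other).
#'
#' @param path path to the centroid TSV.
#' @return numeric gene-by-class matrix.
#' @export
read_centroids <- function(path) {
  m <- read_matrix_tsv(path)
  if (ncol(m) < 2L) stop("centroid table needs >=2 classes")
  m
}

#' Write a centroid table
#' @param centroids gene-by-class numeric matrix.
#' @param path output path.
#' @export
write_centroids <- function(centroids, path) {
  write_matrix_tsv(centroids, path, id_col = "gene")
}
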