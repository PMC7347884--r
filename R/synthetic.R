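## Synthetic multi-omic cohort with the statistical structure the pipeline
## assumes: a trimodal FGA distribution over claudin-low tumors, planted
## claudin-low and subgroup expression centroids, purity-dependent BAF bands
## at hemizygous deletions, clonal VAF near purity/2, and methylation
## beta-values anti-correlated with expression. Truth labels are emitted so
## every stage can be scored against ground truth.

# hg19 autosome lengths (bp), scaled down 10x for speed
.genome_model <- function(scale = 10) {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  data.frame(chrom = as.character(1:22), length = round(len / scale))
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions: 45 claudin-low tumors split
#' 10/17/18 into CL1/CL2/CL3 with FGA drawn from component means
#' 0.05/0.20/0.40 (sds 0.02/0.05/0.05), alteration threshold physics
#' compatible with T = 0.1, sequencing depth 60 for allelic sampling, and a
#' 22-autosome genome with hg19-like lengths scaled down 10x.
#'
#' @param seed master seed for the generator.
#' @param n_cl named counts per claudin-low subgroup.
#' @param n_other number of non-claudin-low samples.
#' @param n_genes expression genes simulated.
#' @param fga_means,fga_sds per-subgroup FGA component parameters.
#' @param clow_effect centroid shift of claudin-low discriminant genes.
#' @param n_clow_genes claudin-low discriminant genes planted.
#' @param subgroup_effect centroid shift (in noise sds) of subgroup genes.
#' @param n_subgroup_genes planted subgroup-discriminant genes per subgroup.
#' @param purity_range uniform purity range for all samples.
#' @param depth binomial sampling depth for BAF and VAF.
#' @param meth_coupling strength c of beta = inv-logit(-c * expression + eps).
#' @param n_meth_genes methylation genes (first \code{n_meth_coupled} are
#'   expression-coupled).
#' @param n_meth_coupled expression-coupled methylation genes.
#' @param n_mutations clonal mutations per claudin-low sample.
#' @param n_snps_per_deletion heterozygous SNPs simulated per planted
#'   deletion.
#' @param genome_scale divisor applied to hg19 autosome lengths.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(seed = 1L,
                          n_cl = c(CL1 = 10L, CL2 = 17L, CL3 = 18L),
                          n_other = 30L,
                          n_genes = 1000L,
                          fga_means = c(0.05, 0.20, 0.40),
                          fga_sds = c(0.02, 0.05, 0.05),
                          clow_effect = 1.0,
                          n_clow_genes = 200L,
                          subgroup_effect = 1.5,
                          n_subgroup_genes = 20L,
                          purity_range = c(0.45, 0.95),
                          depth = 60L,
                          meth_coupling = 2,
                          n_meth_genes = 400L,
                          n_meth_coupled = 300L,
                          n_mutations = 5L,
                          n_snps_per_deletion = 40L,
                          genome_scale = 10) {
  stopifnot(all(n_cl > 0), n_other >= 0, n_genes > 0,
            length(fga_means) == length(n_cl),
            length(fga_sds) == length(n_cl))
  structure(as.list(environment()), class = "cohort_config")
}

.make_sample_seg <- function(sample_id, fga, genome, focal_frac = 0.002,
                             bg_sd = 0.02, bg_max = 0.049) {
  L <- sum(genome$length)
  A <- round(min(max(fga, 0), 0.48) * L)
  rows <- list()
  remaining <- A
  focal_len <- min(A, round(focal_frac * L))
  chroms <- sample(nrow(genome))
  first <- TRUE
  for (ci in chroms) {
    chrom <- genome$chrom[ci]; clen <- genome$length[ci]
    alt_len <- 0
    if (remaining > 0) {
      alt_len <- if (first) focal_len else min(remaining, round(0.7 * clen))
      alt_len <- min(alt_len, clen - 2L)
      mean_alt <- if (first) -0.6 else sample(c(-0.5, 0.5), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, chrom = chrom, start = 1,
        end = alt_len, num_probes = max(10L, round(alt_len / 5e4)),
        seg_mean = mean_alt + stats::rnorm(1, 0, 0.02),
        focal = first, stringsAsFactors = FALSE)
      remaining <- remaining - alt_len
      first <- FALSE
    }
    # background remainder, split in two segments
    bg_start <- alt_len + 1
    mid <- bg_start + floor((clen - bg_start) / 2)
    for (iv in list(c(bg_start, mid), c(mid + 1, clen))) {
      if (iv[2] < iv[1]) next
      m <- stats::rnorm(1, 0, bg_sd)
      m <- max(min(m, bg_max), -bg_max)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, chrom = chrom, start = iv[1], end = iv[2],
        num_probes = max(10L, round((iv[2] - iv[1] + 1) / 5e4)),
        seg_mean = m, focal = FALSE, stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, rows)
  seg[order(match(seg$chrom, genome$chrom), seg$start), ]
}

#' Generate a synthetic multi-omic cohort
#'
#' Emits, in memory, every input the pipeline consumes plus truth labels:
#' segmented copy number whose realized FGA matches each sample's drawn FGA,
#' z-scored expression with planted claudin-low and subgroup centroids, SNP
#' BAF/LRR profiles at planted hemizygous deletions with band means
#' (1-p)/(2-p) and 1/(2-p), clonal mutations with VAF ~
#' Binomial(depth, p/2)/depth, expression-coupled methylation beta-values,
#' sample annotations, and a claudin-low/other centroid fixture.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return list of class \code{synthetic_cohort} with elements truth,
#'   expression, seg, snps, mutations, methylation, annotations, centroids,
#'   signature_sets, genome.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  genome <- .genome_model(cfg$genome_scale)
  subgroups <- rep(names(cfg$n_cl), cfg$n_cl)
  n_cl_tot <- length(subgroups)
  samples_cl <- sprintf("CLOW%03d", seq_len(n_cl_tot))
  samples_ot <- if (cfg$n_other > 0) sprintf("OTHR%03d", seq_len(cfg$n_other))
                else character(0)
  samples <- c(samples_cl, samples_ot)
  is_cl <- c(rep(TRUE, n_cl_tot), rep(FALSE, cfg$n_other))

  # truth-level draws
  sub_idx <- match(subgroups, names(cfg$n_cl))
  fga_cl <- stats::rnorm(n_cl_tot, cfg$fga_means[sub_idx], cfg$fga_sds[sub_idx])
  fga_cl <- pmin(pmax(fga_cl, 0.004), 0.48)
  fga_ot <- stats::runif(cfg$n_other, 0.05, 0.45)
  fga <- c(fga_cl, fga_ot)
  purity <- stats::runif(length(samples), cfg$purity_range[1],
                         cfg$purity_range[2])
  truth <- data.frame(sample = samples, claudin_low = is_cl,
                      subgroup = c(subgroups, rep(NA_character_, cfg$n_other)),
                      purity = purity, fga_drawn = fga,
                      stringsAsFactors = FALSE)

  # expression: z-scores with planted centroids
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  expr <- matrix(stats::rnorm(cfg$n_genes * length(samples)),
                 nrow = cfg$n_genes, dimnames = list(genes, samples))
  clow_genes <- genes[seq_len(cfg$n_clow_genes)]
  expr[clow_genes, is_cl] <- expr[clow_genes, is_cl] + cfg$clow_effect
  sub_genes <- list()
  offset <- cfg$n_clow_genes
  for (i in seq_along(cfg$n_cl)) {
    gs <- genes[offset + seq_len(cfg$n_subgroup_genes)]
    offset <- offset + cfg$n_subgroup_genes
    sub_genes[[names(cfg$n_cl)[i]]] <- gs
    in_sub <- c(subgroups == names(cfg$n_cl)[i], rep(FALSE, cfg$n_other))
    expr[gs, in_sub] <- expr[gs, in_sub] + cfg$subgroup_effect
  }
  attr(expr, "unit_state") <- "zscore"

  # segmented copy number (+ record of the planted focal deletion)
  seg_list <- lapply(seq_along(samples), function(i)
    .make_sample_seg(samples[i], fga[i], genome))
  seg <- do.call(rbind, seg_list)
  focal <- seg[seg$focal, c("sample", "chrom", "start", "end", "seg_mean")]
  seg$focal <- NULL
  rownames(seg) <- NULL

  # SNP BAF/LRR profiles over each planted deletion (claudin-low samples)
  snp_rows <- list()
  for (s in samples_cl) {
    f <- focal[focal$sample == s, ]
    if (nrow(f) == 0L) next
    p <- purity[match(s, samples)]
    band_lo <- (1 - p) / (2 - p)
    band_hi <- 1 / (2 - p)
    nsnp <- cfg$n_snps_per_deletion
    pos <- sort(sample(seq(f$start[1], f$end[1]), nsnp))
    band <- rep(c(band_lo, band_hi), length.out = nsnp)
    baf <- stats::rbinom(nsnp, cfg$depth, band) / cfg$depth
    snp_rows[[s]] <- data.frame(
      sample = s, chrom = f$chrom[1], position = pos, baf = baf,
      lrr = f$seg_mean[1] + stats::rnorm(nsnp, 0, 0.05),
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  rownames(snps) <- NULL

  # clonal somatic mutations, VAF ~ Binomial(depth, purity/2)/depth
  mut_rows <- list()
  for (s in samples_cl) {
    p <- purity[match(s, samples)]
    nm <- cfg$n_mutations
    mut_rows[[s]] <- data.frame(
      sample = s, gene = sample(genes, nm),
      chromosome = "1",
      position = sort(sample.int(genome$length[1], nm)),
      ref_allele = sample(c("A", "C", "G", "T"), nm, replace = TRUE),
      alt_allele = sample(c("A", "C", "G", "T"), nm, replace = TRUE),
      vaf = stats::rbinom(nm, cfg$depth, p / 2) / cfg$depth,
      annotation = "exonic_nonsilent", stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, mut_rows)
  rownames(mutations) <- NULL

  # methylation: beta anti-correlated with expression for coupled genes
  meth_genes <- genes[seq_len(cfg$n_meth_genes)]
  coupled <- meth_genes[seq_len(cfg$n_meth_coupled)]
  eps <- matrix(stats::rnorm(cfg$n_meth_genes * n_cl_tot, 0, 1),
                nrow = cfg$n_meth_genes)
  lin <- eps
  lin[match(coupled, meth_genes), ] <-
    -cfg$meth_coupling * expr[coupled, samples_cl] +
    eps[match(coupled, meth_genes), ]
  beta <- stats::plogis(lin)
  dimnames(beta) <- list(meth_genes, samples_cl)

  annotations <- data.frame(sample = samples, purity = purity,
                            stringsAsFactors = FALSE)

  truth$focal_chrom <- focal$chrom[match(truth$sample, focal$sample)]
  truth$focal_start <- focal$start[match(truth$sample, focal$sample)]
  truth$focal_end <- focal$end[match(truth$sample, focal$sample)]

  structure(list(
    truth = truth, expression = expr, seg = seg, snps = snps,
    mutations = mutations, methylation = beta, annotations = annotations,
    centroids = make_centroid_fixture(cfg),
    planted = list(clow_genes = clow_genes, subgroup_genes = sub_genes,
                   meth_coupled = coupled),
    genome = genome, config = cfg), class = "synthetic_cohort")
}

#' Claudin-low/other centroid fixture
#'
#' A synthetic stand-in for a published tumor-derived claudin-low centroid
#' table: the planted discriminant genes carry the configured claudin-low
#' shift, the non-claudin-low centroid sits at the z-score origin.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return gene-by-class matrix with columns claudin_low and other.
#' @export
make_centroid_fixture <- function(cfg = cohort_config()) {
  genes <- sprintf("g%04d", seq_len(cfg$n_clow_genes))
  m <- cbind(claudin_low = rep(cfg$clow_effect, cfg$n_clow_genes),
             other = rep(0, cfg$n_clow_genes))
  rownames(m) <- genes
  m
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the file formats the readers consume: expression.tsv, copy number
#' SEG, snps.tsv, mutations.tsv, methylation.tsv, annotations.tsv,
#' centroids.tsv and truth.tsv.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = write_matrix_tsv(cohort$expression,
                                  file.path(dir, "expression.tsv")),
    seg = write_seg(cohort$seg, file.path(dir, "copy_number.seg")),
    snps = write_snp_profile(cohort$snps, file.path(dir, "snps.tsv")),
    mutations = write_mutations(cohort$mutations,
                                file.path(dir, "mutations.tsv")),
    methylation = write_matrix_tsv(cohort$methylation,
                                   file.path(dir, "methylation.tsv")),
    annotations = write_annotations(cohort$annotations,
                                    file.path(dir, "annotations.tsv")),
    centroids = write_centroids(cohort$centroids,
                                file.path(dir, "centroids.tsv")),
    truth = {
      p <- file.path(dir, "truth.tsv")
      utils::write.table(cohort$truth, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    })
  paths
}
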