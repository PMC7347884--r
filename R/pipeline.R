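#' Pipeline configuration
#'
#' Collects input paths and per-stage parameters for
#' \code{\link{run_pipeline}}. Only \code{expression} and \code{seg} are
#' required; stages whose inputs are absent are skipped with a warning.
#' Parameter defaults are the published operating points: alteration
#' threshold T = 0.1 (tumor mode), deletion LRR cutoff -0.4, BAF band bounds
#' 0.2/0.8, VAF cutoff 0.4, purity-gate alpha 0.05, mixture k_max 5, FDR
#' 0.05 throughout.
#'
#' @param expression,seg,snps,mutations,methylation,annotations,centroids,gmt
#'   input file paths (NULL where unavailable).
#' @param out_dir output directory for stage TSVs, or NULL for in-memory
#'   results only.
#' @param seed master seed; each stage derives child seed
#'   \code{seed * 100 + stage_index} so adding a stage never perturbs
#'   earlier stages.
#' @param params named list overriding stage parameters: fga_T, fga_mode,
#'   lrr_cut, baf_low, baf_high, vaf_cut, purity_alpha, purity_grid_step,
#'   k_max, k_fixed (fix the mixture component count instead of selecting
#'   it by BIC), nsc_delta (NULL = choose by cross-validation), nsc_folds,
#'   fdr_cut, min_delta_beta, ssgsea_alpha.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression, seg, snps = NULL, mutations = NULL,
                            methylation = NULL, annotations = NULL,
                            centroids = NULL, gmt = NULL, out_dir = NULL,
                            seed = 1L, params = list()) {
  defaults <- list(fga_T = NULL, fga_mode = "tumor", lrr_cut = -0.4,
                   baf_low = 0.2, baf_high = 0.8, vaf_cut = 0.4,
                   purity_alpha = 0.05, purity_grid_step = 0.01,
                   k_max = 5L, k_fixed = NULL, nsc_delta = NULL,
                   nsc_folds = 10L,
                   fdr_cut = 0.05, min_delta_beta = 0.1, ssgsea_alpha = 0.25)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(paths = list(expression = expression, seg = seg,
                              snps = snps, mutations = mutations,
                              methylation = methylation,
                              annotations = annotations,
                              centroids = centroids, gmt = gmt),
                 out_dir = out_dir, seed = as.integer(seed),
                 params = defaults),
            class = "pipeline_config")
}

.stage_seed <- function(cfg, idx) cfg$seed * 100L + idx

#' Run the claudin-low stratification pipeline
#'
#' Executes the stages in order: expression loading, claudin-low calling
#' (nearest centroid), purity gating, FGA computation, Gaussian-mixture
#' stratification of pure claudin-low FGA into CL1..CLk, nearest shrunken
#' centroid classification, focal-loss verification of CNA-devoid samples,
#' ssGSEA scoring, and methylation filtering plus differential methylation.
#' Stages whose inputs are absent are skipped with a warning; a stage error
#' aborts the run naming the stage. Outputs are pure functions of (inputs,
#' config, seed).
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return list of class \code{pipeline_result} with one element per
#'   completed stage plus a run \code{manifest} (seeds, input checksums,
#'   stages completed/skipped, warnings).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  p <- cfg$params
  res <- list()
  skipped <- character(0)
  warnings_log <- character(0)
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    warning(msg, call. = FALSE)
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " [completed: ", paste(names(res), collapse = ", "), "]",
           call. = FALSE))
  }

  # 1 expression
  expr <- run_stage("expression", function()
    read_matrix_tsv(cfg$paths$expression))
  res$expression <- list(n_genes = nrow(expr), n_samples = ncol(expr))

  # 2 claudin-low call
  clow_labels <- NULL
  if (!is.null(cfg$paths$centroids)) {
    calls <- run_stage("claudin_low_call", function() {
      cen <- read_centroids(cfg$paths$centroids)
      call_claudin_low(expr, cen)
    })
    clow_labels <- stats::setNames(calls$label == "claudin_low", calls$sample)
    res$claudin_low_call <- calls
  } else {
    skipped <- c(skipped, "claudin_low_call")
    note("no centroid table: claudin-low calling skipped")
  }

  # 3 purity gate
  ann <- NULL
  pure_samples <- colnames(expr)
  if (!is.null(cfg$paths$annotations) && !is.null(clow_labels)) {
    gate <- run_stage("purity_gate", function() {
      ann <<- read_annotations(cfg$paths$annotations)
      idx <- match(ann$sample, names(clow_labels))
      select_purity_threshold(ann$purity[!is.na(idx)],
                              clow_labels[ann$sample[!is.na(idx)]],
                              alpha = p$purity_alpha,
                              grid_step = p$purity_grid_step)
    })
    pure_samples <- ann$sample[!is.na(ann$purity) &
                                 ann$purity > gate$threshold]
    res$purity_gate <- gate
  } else {
    skipped <- c(skipped, "purity_gate")
    note("no annotations or no claudin-low labels: purity gate skipped")
  }

  # 4 FGA
  seg <- run_stage("fga", function() read_seg(cfg$paths$seg))
  fga <- run_stage("fga", function()
    fga_cohort(seg, mode = p$fga_mode, T = p$fga_T))
  res$fga <- fga

  # 5 stratification on pure claudin-low FGA
  strat_samples <- fga$sample
  if (!is.null(clow_labels))
    strat_samples <- intersect(strat_samples,
                               names(clow_labels)[clow_labels])
  strat_samples <- intersect(strat_samples, pure_samples)
  strat <- run_stage("stratification", function() {
    v <- fga$fga[match(strat_samples, fga$sample)]
    fit <- if (is.null(p$k_fixed))
      select_model(v, k_max = p$k_max, seed = .stage_seed(cfg, 5L))
    else
      select_model(v, k_max = p$k_fixed, k_min = p$k_fixed,
                   seed = .stage_seed(cfg, 5L))
    assignments <- assign_subgroups(fit, v, samples = strat_samples)
    list(fit = fit, assignments = assignments,
         boundaries = attr(assignments, "boundaries"))
  })
  res$stratification <- strat
  subgroup <- stats::setNames(strat$assignments$subgroup,
                              strat$assignments$sample)

  # 6 NSC classifier on stratified samples
  nsc <- run_stage("nsc_classifier", function() {
    Xs <- expr[, names(subgroup), drop = FALSE]
    if (is.null(p$nsc_delta)) {
      cv <- cross_validate_nsc(Xs, subgroup, n_folds = p$nsc_folds,
                               seed = .stage_seed(cfg, 6L))
      delta <- cv$chosen_delta
    } else {
      cv <- NULL
      delta <- p$nsc_delta
    }
    model <- train_nsc(Xs, subgroup, delta = delta)
    pred <- predict_nsc(model, Xs)
    list(model = model, cv = cv, delta = delta, predictions = pred,
         training_accuracy = evaluate_accuracy(
           stats::setNames(pred$label, pred$sample), subgroup))
  })
  res$nsc_classifier <- nsc

  # 7 focal-loss verification of CNA-devoid samples
  if (!is.null(cfg$paths$snps)) {
    res$focal_check <- run_stage("focal_check", function() {
      snps <- read_snp_profile(cfg$paths$snps)
      muts <- if (!is.null(cfg$paths$mutations))
        read_mutations(cfg$paths$mutations)
      else data.frame(vaf = numeric(0), annotation = character(0))
      lapply(stats::setNames(nm = names(subgroup)), function(s) {
        focal_loss_report(
          seg[seg$sample == s, , drop = FALSE],
          snps[snps$sample == s, , drop = FALSE],
          muts[muts$sample == s, , drop = FALSE],
          fga = fga$fga[match(s, fga$sample)],
          lrr_cut = p$lrr_cut, low_cut = p$baf_low, high_cut = p$baf_high,
          vaf_cut = p$vaf_cut)
      })
    })
  } else {
    skipped <- c(skipped, "focal_check")
    note("no SNP profiles: focal check skipped")
  }

  # 8 ssGSEA
  if (!is.null(cfg$paths$gmt)) {
    res$ssgsea <- run_stage("ssgsea", function()
      ssgsea(expr, read_gmt(cfg$paths$gmt), alpha = p$ssgsea_alpha))
  } else {
    skipped <- c(skipped, "ssgsea")
    note("no GMT collection: ssGSEA skipped")
  }

  # 9 methylation
  if (!is.null(cfg$paths$methylation)) {
    res$methylation <- run_stage("methylation", function() {
      beta <- read_matrix_tsv(cfg$paths$methylation)
      filt <- filter_expression_correlated(beta, expr,
                                           fdr_cut = p$fdr_cut)
      shared <- intersect(colnames(beta), names(subgroup))
      dm <- if (length(filt$genes) > 0L && length(shared) >= 9L)
        differential_methylation(
          beta[filt$genes, shared, drop = FALSE], subgroup[shared],
          fdr_cut = p$fdr_cut, min_delta = p$min_delta_beta)
      else NULL
      list(filter = filt, dm = dm)
    })
  } else {
    skipped <- c(skipped, "methylation")
    note("no methylation matrix: methylation stage skipped")
  }

  paths <- Filter(Negate(is.null), cfg$paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("claudinlow")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(cfg$seed * 100L + c(5L, 6L),
                                  c("stratification", "nsc_classifier")),
    input_checksums = vapply(paths, function(f)
      unname(tools::md5sum(f)), character(1)),
    stages_completed = names(res),
    stages_skipped = skipped,
    warnings = warnings_log)
  res$manifest <- manifest

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(strat$assignments,
                       file.path(cfg$out_dir, "subgroups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fga, file.path(cfg$out_dir, "fga.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nsc$predictions,
                       file.path(cfg$out_dir, "nsc_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(res, class = "pipeline_result")
}
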