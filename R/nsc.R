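## Nearest shrunken centroid classifier: class centroids standardized by the
## pooled within-class dispersion are soft-thresholded toward the overall
## centroid by an amount Delta; genes whose standardized deviations shrink to
## zero in every class drop out of the discriminant, giving an embedded gene
## selection. Prediction uses the diagonal discriminant score with a class
## prior term.

#' Train a nearest shrunken centroid model
#'
#' For gene j and class k, the standardized centroid deviation is
#' d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0)) with
#' m_k = sqrt(1/n_k - 1/n), pooled within-class sd s_j and fudge factor
#' s0 = median_j(s_j). Deviations are soft-thresholded:
#' d'_kj = sign(d_kj) max(|d_kj| - Delta, 0), and shrunken centroids are
#' xbar'_kj = xbar_j + m_k (s_j + s0) d'_kj.
#'
#' @param X gene-by-sample expression matrix.
#' @param y class labels, one per sample (each class needs >= 2 samples).
#' @param delta shrinkage threshold Delta >= 0.
#' @param priors "empirical" (class frequencies, the default) or "uniform".
#' @param mk_variant "minus" uses m_k = sqrt(1/n_k - 1/n) (the original
#'   derivation); "plus" uses sqrt(1/n_k + 1/n), matching some
#'   implementations.
#' @return object of class \code{nsc_model}.
#' @export
train_nsc <- function(X, y, delta = 0, priors = c("empirical", "uniform"),
                      mk_variant = c("minus", "plus")) {
  priors <- match.arg(priors)
  mk_variant <- match.arg(mk_variant)
  X <- as.matrix(X)
  y <- as.character(y)
  if (ncol(X) != length(y)) stop("ncol(X) must equal length(y)")
  if (delta < 0) stop("delta must be >= 0")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes")
  nk <- table(factor(y, levels = classes))
  if (any(nk < 2L))
    stop("class(es) with fewer than 2 samples: ",
         paste(classes[nk < 2L], collapse = ", "))
  n <- ncol(X)
  K <- length(classes)
  overall <- rowMeans(X)
  cen <- vapply(classes, function(cl)
    rowMeans(X[, y == cl, drop = FALSE]), numeric(nrow(X)))
  # pooled within-class sd, denominator n - K
  ss <- 0
  for (cl in classes) {
    sub <- X[, y == cl, drop = FALSE]
    ss <- ss + rowSums((sub - cen[, cl])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  if (all(s + s0 == 0)) stop("zero pooled dispersion for all genes")
  mk <- if (mk_variant == "minus") sqrt(1 / as.numeric(nk) - 1 / n)
        else sqrt(1 / as.numeric(nk) + 1 / n)
  names(mk) <- classes
  d <- sweep(cen - overall, 2, mk, "/") / (s + s0)
  dshr <- sign(d) * pmax(abs(d) - delta, 0)
  cen_shr <- overall + sweep(dshr, 2, mk, "*") * (s + s0)
  pri <- if (priors == "uniform") rep(1 / K, K) else as.numeric(nk) / n
  names(pri) <- classes
  structure(list(genes = rownames(X), classes = classes,
                 overall_centroid = overall, class_centroids = cen,
                 shrunken_centroids = cen_shr, s = s, s0 = s0, mk = mk,
                 priors = pri, delta = delta,
                 deviations = d, shrunken_deviations = dshr,
                 selected = rowSums(abs(dshr) > 0) > 0,
                 mk_variant = mk_variant),
            class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("Nearest shrunken centroid model\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  delta =", x$delta, "; genes selected:", sum(x$selected), "of",
      length(x$genes), "\n")
  invisible(x)
}

#' Predict with a nearest shrunken centroid model
#'
#' Discriminant score for class k:
#' delta_k(x) = sum_j (x_j - xbar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k,
#' summed over the selected genes (all genes when shrinkage removed none or
#' all). The predicted class minimizes the score; posteriors are
#' proportional to exp(-delta_k / 2).
#'
#' @param model an \code{nsc_model}.
#' @param X gene-by-sample matrix of samples to classify (gene overlap with
#'   the model must be >= \code{min_coverage}).
#' @param min_coverage minimum fraction of model genes required (default 0.5).
#' @return data.frame with sample, label, per-class score columns and
#'   per-class posterior columns.
#' @export
predict_nsc <- function(model, X, min_coverage = 0.5) {
  X <- as.matrix(X)
  use_genes <- if (any(model$selected))
    model$genes[model$selected] else model$genes
  shared <- intersect(rownames(X), use_genes)
  if (length(shared) / length(use_genes) < min_coverage)
    stop("only ", length(shared), " of ", length(use_genes),
         " model genes present (coverage below ", min_coverage, ")")
  idx <- match(shared, model$genes)
  sc <- vapply(model$classes, function(cl) {
    diff <- X[shared, , drop = FALSE] - model$shrunken_centroids[idx, cl]
    colSums(diff^2 / (model$s[idx] + model$s0)^2) -
      2 * log(model$priors[[cl]])
  }, numeric(ncol(X)))
  sc <- matrix(sc, nrow = ncol(X),
               dimnames = list(colnames(X), model$classes))
  labels <- model$classes[apply(sc, 1L, which.min)]
  lp <- -sc / 2
  post <- exp(lp - apply(lp, 1L, max))
  post <- post / rowSums(post)
  out <- data.frame(sample = colnames(X), label = labels,
                    stringsAsFactors = FALSE)
  sc_df <- as.data.frame(sc); names(sc_df) <- paste0("score_", model$classes)
  po_df <- as.data.frame(post)
  names(po_df) <- paste0("posterior_", model$classes)
  cbind(out, sc_df, po_df)
}

#' Cross-validate the shrinkage threshold
#'
#' Stratified k-fold cross-validation of the misclassification error across a
#' grid of shrinkage values. The chosen Delta follows the one-standard-error
#' rule: the largest Delta whose CV error does not exceed the minimum error
#' plus one standard error of that minimum (larger Delta means fewer genes).
#'
#' @param X gene-by-sample matrix.
#' @param y class labels.
#' @param delta_grid increasing vector of shrinkage values; if NULL, 30
#'   values from 0 to the largest |d_kj| at Delta = 0.
#' @param n_folds folds (default 10; reduced with a warning if a class is
#'   too small to appear in every training fold).
#' @param seed fold-assignment seed.
#' @param ... passed to \code{\link{train_nsc}}.
#' @return list of class \code{nsc_cv}: delta_grid, cv_error, cv_se,
#'   n_genes, chosen_delta, min_error, folds, seed.
#' @export
cross_validate_nsc <- function(X, y, delta_grid = NULL, n_folds = 10L,
                               seed = 1L, ...) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  nk <- table(factor(y, levels = classes))
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (min(nk) < n_folds) {
    n_folds <- max(2L, min(nk))
    warning("smallest class has ", min(nk),
            " samples; folds reduced to ", n_folds)
  }
  if (is.null(delta_grid)) {
    full <- train_nsc(X, y, delta = 0, ...)
    delta_grid <- seq(0, max(abs(full$deviations)), length.out = 30L)
  }
  delta_grid <- sort(delta_grid)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  err <- matrix(NA_real_, nrow = n_folds, ncol = length(delta_grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    for (j in seq_along(delta_grid)) {
      fit <- train_nsc(X[, tr, drop = FALSE], y[tr],
                       delta = delta_grid[j], ...)
      pred <- predict_nsc(fit, X[, !tr, drop = FALSE])
      err[f, j] <- mean(pred$label != y[!tr])
    }
  }
  cv_error <- colMeans(err)
  cv_se <- apply(err, 2L, stats::sd) / sqrt(n_folds)
  n_genes <- vapply(delta_grid, function(d)
    sum(train_nsc(X, y, delta = d, ...)$selected), integer(1))
  jmin <- which.min(cv_error)
  ok <- cv_error <= cv_error[jmin] + cv_se[jmin]
  chosen <- max(delta_grid[ok])
  structure(list(delta_grid = delta_grid, cv_error = cv_error, cv_se = cv_se,
                 n_genes = n_genes, chosen_delta = chosen,
                 min_error = cv_error[jmin], folds = folds, seed = seed),
            class = "nsc_cv")
}

#' Classification accuracy
#'
#' Fraction of samples whose predicted label equals the reference label.
#'
#' @param pred named character vector of predictions, or unnamed vector
#'   aligned with \code{ref}.
#' @param ref reference labels.
#' @return fraction of exact matches in [0, 1].
#' @export
evaluate_accuracy <- function(pred, ref) {
  if (!is.null(names(pred)) && !is.null(names(ref))) {
    if (!setequal(names(pred), names(ref)))
      stop("prediction and reference sample sets differ")
    ref <- ref[names(pred)]
  } else if (length(pred) != length(ref)) {
    stop("prediction and reference differ in length")
  }
  mean(pred == ref)
}
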