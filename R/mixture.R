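## Univariate Gaussian finite mixtures fitted by EM, BIC model selection,
## and posterior-based subgroup assignment of FGA values into CL1..CLk.

.logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

.log_comp_dens <- function(x, k, w, mu, v) {
  n <- length(x)
  M <- matrix(x, n, k) - matrix(mu, n, k, byrow = TRUE)
  -M * M / matrix(2 * v, n, k, byrow = TRUE) +
    matrix(log(w) - 0.5 * log(2 * pi * v), n, k, byrow = TRUE)
}

.em_once <- function(x, k, model, mu0, tol, max_iter, var_floor) {
  n <- length(x)
  mu <- mu0
  w <- rep(1 / k, k)
  v <- rep(stats::var(x), k)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step (log domain)
    lp <- .log_comp_dens(x, k, w, mu, v)
    lse <- .logsumexp_rows(lp)
    ll <- sum(lse)
    resp <- exp(lp - lse)
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(NULL)        # empty component: restart
    w <- nk / n
    sumx <- colSums(resp * x)
    sumx2 <- colSums(resp * x * x)
    mu <- sumx / nk
    wss <- sumx2 - mu * mu * nk        # sum_i resp_ik (x_i - mu_k)^2
    if (model == "equal_variance") {
      v[] <- sum(wss) / n
    } else {
      v <- wss / nk
    }
    v <- pmax(v, var_floor)   # constrained M step: point masses hit the floor
    stopifnot(ll >= ll_old - 1e-8 * (abs(ll_old) + 1))  # EM monotonicity
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final log-likelihood at current parameters
  ll <- sum(.logsumexp_rows(.log_comp_dens(x, k, w, mu, v)))
  list(weights = w, means = mu, variances = v, log_likelihood = ll,
       n_iterations = iter, converged = converged)
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximization with multiple restarts. Initial means come from
#' k-means runs seeded at quantile-spaced centers with jitter; the best
#' restart by final log-likelihood is kept. Components are relabeled in
#' ascending order of mean. Variances are floored at
#' \code{1e-6 * var(values)} to prevent spurious singleton components.
#'
#' @param values numeric vector (n >= 3k).
#' @param k number of components.
#' @param model "free_variance" (default) or "equal_variance".
#' @param seed integer seed making the restarts reproducible.
#' @param n_starts number of restarts (default 25).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per start (default 1000).
#' @return object of class \code{mixture_fit}: k, model, weights, means,
#'   variances, log_likelihood, bic, n_iterations, converged, seed.
#' @export
fit_mixture <- function(values, k, model = c("free_variance", "equal_variance"),
                        seed = 1L, n_starts = 25L, tol = 1e-8,
                        max_iter = 1000L) {
  model <- match.arg(model)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 3L * k) stop("need n >= 3k observations (n = ", n, ", k = ", k, ")")
  var_floor <- 1e-6 * max(stats::var(x), .Machine$double.eps)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  starts <- list(qs)
  if (k > 1L) {
    for (s in seq_len(n_starts - 1L)) {
      km <- tryCatch(stats::kmeans(x, centers = jitter_centers(qs, x)),
                     error = function(e) NULL)
      starts[[s + 1L]] <- if (is.null(km))
        qs + stats::rnorm(k, 0, stats::sd(x) / 4)
      else sort(as.vector(km$centers))
    }
  }
  # distinct starts converge to distinct optima; duplicates add nothing
  starts <- starts[!duplicated(lapply(starts, function(m) round(m, 8)))]
  for (mu0 in starts) {
    fit <- .em_once(x, k, model, mu0, tol, max_iter, var_floor)
    if (!is.null(fit) &&
        (is.null(best) || fit$log_likelihood > best$log_likelihood))
      best <- fit
  }
  if (is.null(best))
    stop("every EM start produced an empty component; data may be degenerate")
  ord <- order(best$means)
  p <- (k - 1) + k + if (model == "equal_variance") 1L else k
  structure(list(k = k, model = model,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 variances = if (model == "equal_variance")
                   rep(best$variances[1L], k)[seq_len(k)]
                 else best$variances[ord],
                 log_likelihood = best$log_likelihood,
                 bic = -2 * best$log_likelihood + p * log(n),
                 n_parameters = p,
                 n_iterations = best$n_iterations,
                 converged = best$converged,
                 n = n, seed = seed),
            class = "mixture_fit")
}

jitter_centers <- function(qs, x) {
  cen <- qs + stats::rnorm(length(qs), 0, stats::sd(x) / 4)
  # kmeans needs distinct centers
  while (anyDuplicated(cen)) cen <- cen + stats::rnorm(length(cen), 0, 1e-8)
  matrix(sort(cen))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit: k =", x$k, "(", x$model, ")\n")
  cat("  weights: ", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("  means:   ", paste(sprintf("%.4f", x$means), collapse = " "), "\n")
  cat("  sds:     ", paste(sprintf("%.4f", sqrt(x$variances)), collapse = " "),
      "\n")
  cat("  loglik = ", sprintf("%.3f", x$log_likelihood),
      ", BIC = ", sprintf("%.3f", x$bic),
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Select a mixture model by BIC
#'
#' Fits every (k, model) combination over \code{1..k_max} and both variance
#' families, and returns the fit minimizing BIC =
#' -2 loglik + n_parameters * log(n).
#'
#' @param values numeric vector.
#' @param k_max largest component count to try (default 5).
#' @param models character vector of variance families to try.
#' @param seed,n_starts,tol,max_iter passed to \code{\link{fit_mixture}}.
#' @param k_min smallest component count to try (default 1; set
#'   \code{k_min = k_max} to fix the component count, as when the subgroup
#'   structure is known a priori).
#' @return the minimal-BIC \code{mixture_fit}, with the full BIC table
#'   attached as attribute \code{"bic_table"}.
#' @export
select_model <- function(values, k_max = 5L,
                         models = c("equal_variance", "free_variance"),
                         seed = 1L, n_starts = 25L, tol = 1e-8,
                         max_iter = 1000L, k_min = 1L) {
  if (k_max < 1L || k_min < 1L || k_min > k_max)
    stop("need 1 <= k_min <= k_max")
  fits <- list(); tab <- list()
  for (k in seq.int(k_min, k_max)) {
    if (length(values) < 3L * k) next
    for (m in models) {
      fit <- tryCatch(
        fit_mixture(values, k, model = m, seed = seed, n_starts = n_starts,
                    tol = tol, max_iter = max_iter),
        error = function(e) NULL)
      if (is.null(fit)) next
      key <- paste(m, k, sep = ":")
      fits[[key]] <- fit
      tab[[key]] <- data.frame(k = k, model = m, bic = fit$bic,
                               log_likelihood = fit$log_likelihood)
    }
  }
  if (length(fits) == 0L) stop("no mixture model could be fitted")
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  attr(best, "bic_table") <- tab
  best
}

.posterior_matrix <- function(fit, x) {
  lp <- .log_comp_dens(x, fit$k, fit$weights, fit$means, fit$variances)
  exp(lp - .logsumexp_rows(lp))
}

#' Assign samples to mixture subgroups
#'
#' Computes component posteriors for each value and assigns the
#' maximum-posterior component; components are labeled CL1..CLk in ascending
#' order of mean. Boundaries between adjacent components are the
#' posterior-equality crossings, located by bisection between the adjacent
#' component means.
#'
#' @param fit a converged \code{mixture_fit}.
#' @param values numeric vector to assign.
#' @param samples optional sample identifiers.
#' @return data.frame (sample, value, subgroup, posterior columns per
#'   component) with attribute \code{"boundaries"} (k - 1 crossings).
#' @export
assign_subgroups <- function(fit, values, samples = NULL) {
  if (!inherits(fit, "mixture_fit")) stop("fit must be a mixture_fit")
  if (!fit$converged) stop("mixture fit did not converge")
  x <- as.numeric(values)
  post <- .posterior_matrix(fit, x)
  grp <- max.col(post, ties.method = "first")
  labels <- paste0("CL", seq_len(fit$k))
  boundaries <- numeric(0)
  if (fit$k > 1L) {
    for (j in seq_len(fit$k - 1L)) {
      f <- function(v) {
        p <- .posterior_matrix(fit, v)
        p[, j] - p[, j + 1L]
      }
      lo <- fit$means[j]; hi <- fit$means[j + 1L]
      b <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
                    error = function(e) NA_real_)
      if (is.na(b)) {   # no sign change between means: dense-grid fallback
        g <- seq(lo, hi, length.out = 2001L)
        d <- f(g)
        cross <- which(diff(sign(d)) != 0)
        b <- if (length(cross) > 0L) g[cross[1L]] else (lo + hi) / 2
      }
      boundaries[j] <- b
    }
  }
  out <- data.frame(
    sample = if (is.null(samples)) paste0("s", seq_along(x)) else samples,
    value = x,
    subgroup = labels[grp],
    stringsAsFactors = FALSE)
  colnames(post) <- paste0("posterior_", labels)
  out <- cbind(out, as.data.frame(post))
  attr(out, "boundaries") <- boundaries
  out
}
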