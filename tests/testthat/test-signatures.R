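test_that("Signal2Noise matches the floored-sigma formula", {
  set.seed(1)
  X <- matrix(rnorm(100 * 8), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:8)))
  # plant a gene with a large mean so the 0.2|mu| sigma floor engages
  X["g001", ] <- rnorm(8, mean = 50, sd = 0.1)
  gA <- paste0("s", 1:4); gB <- paste0("s", 5:8)
  r <- signal2noise(X, gA, gB)
  oracle <- apply(X, 1, function(v) {
    a <- v[1:4]; b <- v[5:8]
    sa <- max(sd(a), 0.2 * abs(mean(a)), 1e-8)
    sb <- max(sd(b), 0.2 * abs(mean(b)), 1e-8)
    (mean(a) - mean(b)) / (sa + sb)
  })
  expect_equal(r$statistic, unname(oracle[r$gene]))
  expect_true(all(diff(r$statistic) <= 0))
  # identical groups score zero
  Xs <- X; Xs[, gB] <- Xs[, gA]
  expect_true(all(abs(signal2noise(Xs, gA, gB)$statistic) < 1e-12))
  expect_error(signal2noise(X, gA[1:2], gB), ">= 3")
})

test_that("preranked ES equals a hand-computed running sum on a toy", {
  ranked <- data.frame(gene = letters[1:10],
                       statistic = seq(2, -2.5, length.out = 10))
  set <- c("a", "c", "h")
  hit <- ranked$gene %in% set
  w <- abs(ranked$statistic)
  run <- cumsum(ifelse(hit, w / sum(w[hit]), -1 / 7))
  es_oracle <- run[which.max(abs(run))]
  r <- gsea_preranked(ranked, list(toy = set), n_perm = 50, seed = 1,
                      min_size = 3)
  expect_equal(r$es, es_oracle, tolerance = 1e-12)
})

test_that("preranked ES matches fgsea's statistic on random lists", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  stats <- sort(rnorm(200), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", 1:200)
  ranked <- data.frame(gene = names(stats), statistic = unname(stats))
  for (i in 1:10) {
    members <- sample(names(stats), sample(5:30, 1))
    mine <- gsea_preranked(ranked, list(s = members), n_perm = 10, seed = 1)
    oracle <- fgsea::calcGseaStat(stats, which(names(stats) %in% members),
                                  gseaParam = 1)
    expect_equal(mine$es, oracle, tolerance = 1e-10)
  }
})

test_that("a set of the top-ranked genes maximizes ES among its size", {
  set.seed(3)
  ranked <- data.frame(gene = sprintf("g%02d", 1:50),
                       statistic = sort(rnorm(50), decreasing = TRUE))
  top <- ranked$gene[1:8]
  r_top <- gsea_preranked(ranked, list(top = top), n_perm = 50, seed = 1)
  expect_gt(r_top$es, 0)
  for (i in 1:20) {
    rnd <- sample(ranked$gene, 8)
    r_rnd <- gsea_preranked(ranked, list(r = rnd), n_perm = 10, seed = 1)
    expect_lte(r_rnd$es, r_top$es + 1e-12)
  }
})

test_that("random sets are calibrated against their permutation null", {
  set.seed(5)
  ranked <- data.frame(gene = sprintf("g%03d", 1:300),
                       statistic = sort(rnorm(300), decreasing = TRUE))
  es <- vapply(1:200, function(i) {
    hit <- ranked$gene %in% sample(ranked$gene, 20)
    claudinlow:::.es_weighted_ks(ranked$statistic, hit, 1)$es
  }, numeric(1))
  set.seed(99)
  null_es <- vapply(1:200, function(i) {
    hit <- logical(300); hit[sample.int(300, 20)] <- TRUE
    claudinlow:::.es_weighted_ks(ranked$statistic, hit, 1)$es
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(es, null_es)$p.value), 0.01)
})

test_that("unweighted ES is antisymmetric between a set and its complement", {
  set.seed(6)
  stat <- sort(rnorm(40), decreasing = TRUE)
  hit <- rep(FALSE, 40); hit[sample.int(40, 15)] <- TRUE
  es1 <- claudinlow:::.es_weighted_ks(stat, hit, 0)
  es2 <- claudinlow:::.es_weighted_ks(stat, !hit, 0)
  expect_equal(max(es1$running), -min(es2$running), tolerance = 1e-12)
})

test_that("ssGSEA equals a step-by-step oracle and is rank-invariant", {
  set.seed(7)
  X <- matrix(rnorm(20 * 2), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2")))
  sets <- list(A = c("g01", "g05", "g09", "g13"), B = sprintf("g%02d", 1:20))
  sc <- ssgsea(X, sets, alpha = 0.25, normalize = FALSE)
  # independent running-sum oracle for one sample
  oracle_score <- function(v, members, alpha = 0.25) {
    rk <- rank(v)
    ord <- order(rk, decreasing = TRUE)
    hit <- names(v)[ord] %in% members
    w <- rk[ord]^alpha
    if (!any(!hit)) return(0)
    sum(cumsum(ifelse(hit, w, 0)) / sum(w[hit]) -
          cumsum(!hit) / sum(!hit))
  }
  v1 <- X[, 1]; names(v1) <- rownames(X)
  expect_equal(sc["A", "s1"], oracle_score(v1, sets$A), tolerance = 1e-12)
  # whole-matrix set degenerates to the empty-out-set convention: score 0
  expect_equal(unname(sc["B", ]), c(0, 0))
  # strictly monotone transform leaves scores unchanged
  sc_exp <- ssgsea(exp(X), sets, alpha = 0.25, normalize = FALSE)
  expect_equal(sc, sc_exp, tolerance = 1e-12)
  # normalization divides by the matrix range
  scn <- ssgsea(X, sets["A"], normalize = TRUE)
  sc0 <- ssgsea(X, sets["A"], normalize = FALSE)
  expect_equal(scn, sc0 / (max(sc0) - min(sc0)), tolerance = 1e-12)
})

test_that("cell signatures recover planted subpopulation genes", {
  set.seed(8)
  n_genes <- 800; per <- 6
  labels <- rep(c("MaSC", "LP", "mL"), each = per)
  X <- matrix(rnorm(n_genes * length(labels)), nrow = n_genes,
              dimnames = list(sprintf("g%04d", 1:n_genes), NULL))
  planted <- sprintf("g%04d", 1:600)
  X[planted, labels == "MaSC"] <- X[planted, labels == "MaSC"] + 2
  sigs <- derive_cell_signatures(X, labels, top_n = 500)
  expect_lte(length(sigs$MaSC), 500)
  expect_gte(mean(sigs$MaSC %in% planted), 0.9)
})

test_that("cell signatures stay near-empty under the null", {
  set.seed(9)
  X <- matrix(rnorm(400 * 18), nrow = 400,
              dimnames = list(sprintf("g%03d", 1:400), NULL))
  labels <- rep(c("MaSC", "LP", "mL"), each = 6)
  sigs <- derive_cell_signatures(X, labels)
  expect_lte(length(sigs$MaSC), 20)
  expect_lte(length(sigs$LP), 20)
})
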