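shared_names <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

test_that("perfect anticorrelation is kept, independence excluded", {
  set.seed(1)
  samples <- shared_names(20, "s")
  expr <- matrix(rnorm(40 * 20), nrow = 40,
                 dimnames = list(shared_names(40, "g"), samples))
  beta <- matrix(runif(40 * 20), nrow = 40,
                 dimnames = list(shared_names(40, "g"), samples))
  # gene g001: beta is a decreasing function of expression -> rho = -1
  beta["g001", ] <- plogis(-expr["g001", ])
  r <- filter_expression_correlated(beta, expr)
  expect_true("g001" %in% r$genes)
  expect_equal(r$table$rho[r$table$gene == "g001"], -1)

  # independent genes: exclusion rate >= 0.95 over replicates
  set.seed(2)
  excl <- replicate(20, {
    b2 <- matrix(runif(30 * 20), nrow = 30,
                 dimnames = list(shared_names(30, "g"), samples))
    e2 <- matrix(rnorm(30 * 20), nrow = 30,
                 dimnames = list(shared_names(30, "g"), samples))
    length(filter_expression_correlated(b2, e2)$genes) / 30
  })
  expect_gte(mean(1 - excl), 0.95)
})

test_that("Spearman rho and p equal a rank-then-Pearson oracle", {
  set.seed(3)
  samples <- shared_names(25, "s")
  expr <- matrix(rnorm(10 * 25), nrow = 10,
                 dimnames = list(shared_names(10, "g"), samples))
  beta <- matrix(runif(10 * 25), nrow = 10,
                 dimnames = list(shared_names(10, "g"), samples))
  beta[2, ] <- round(beta[2, ], 1)  # force ties
  r <- filter_expression_correlated(beta, expr)
  for (i in 1:10) {
    rho_oracle <- cor(rank(beta[i, ]), rank(expr[i, ]))
    expect_equal(r$table$rho[i], rho_oracle, tolerance = 1e-12)
  }
})

test_that("the filter is invariant to monotone transforms", {
  set.seed(4)
  samples <- shared_names(15, "s")
  expr <- matrix(rnorm(20 * 15), nrow = 20,
                 dimnames = list(shared_names(20, "g"), samples))
  beta <- matrix(runif(20 * 15), nrow = 20,
                 dimnames = list(shared_names(20, "g"), samples))
  r1 <- filter_expression_correlated(beta, expr)
  r2 <- filter_expression_correlated(beta^3, exp(expr))
  expect_equal(r1$table$rho, r2$table$rho, tolerance = 1e-12)
  expect_equal(r1$genes, r2$genes)
})

test_that("constant genes are skipped with a note, not an error", {
  samples <- shared_names(12, "s")
  expr <- matrix(rnorm(3 * 12), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), samples))
  beta <- matrix(runif(3 * 12), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), samples))
  beta["g2", ] <- 0.5
  r <- filter_expression_correlated(beta, expr)
  expect_true(r$table$skipped[r$table$gene == "g2"])
  expect_false("g2" %in% r$genes)
})

make_dm_cohort <- function(seed = 5, n_genes = 200, shift = -0.3) {
  set.seed(seed)
  labels <- rep(c("CL1", "CL2", "CL3"), c(10, 17, 18))
  beta <- matrix(runif(n_genes * length(labels), 0.3, 0.7),
                 nrow = n_genes,
                 dimnames = list(shared_names(n_genes, "g"),
                                 shared_names(length(labels), "s")))
  planted <- shared_names(min(50, n_genes %/% 2), "g")
  beta[planted, labels == "CL1"] <-
    pmax(beta[planted, labels == "CL1"] + shift, 0.01)
  list(beta = beta, labels = labels, planted = planted)
}

test_that("planted hypomethylation is recovered with direction labels", {
  d <- make_dm_cohort()
  dm <- differential_methylation(d$beta, d$labels)
  hit <- dm[dm$subgroup == "CL1" & dm$significant & dm$direction == "hypo", ]
  expect_gte(mean(d$planted %in% hit$gene), 0.9)
  stopifnot(length(d$planted) == 50)
  # direction is antisymmetric in the sign of the beta shift
  d_up <- make_dm_cohort(shift = +0.3)
  dm_up <- differential_methylation(d_up$beta, d_up$labels)
  hit_up <- dm_up[dm_up$subgroup == "CL1" & dm_up$significant, ]
  expect_true(all(hit_up$direction[hit_up$gene %in% d_up$planted] == "hyper"))
})

test_that("label permutation keeps significant counts in the null band", {
  d <- make_dm_cohort()
  set.seed(11)
  dm <- differential_methylation(d$beta, sample(d$labels))
  expect_lte(sum(dm$significant), 0.05 * nrow(dm) + 10)
})

test_that("flat genes are never significant and small groups error", {
  d <- make_dm_cohort(n_genes = 20)
  d$beta[1, ] <- 0.4
  dm <- differential_methylation(d$beta, d$labels)
  expect_false(any(dm$significant[dm$gene == "g001"]))
  expect_error(differential_methylation(d$beta, rep(c("A", "B"), c(2, 43))),
               "fewer than 3")
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- shared_names(40, "g")
  set <- universe[1:20]
  query <- set  # query equals the full set; universe is twice the set
  r <- enrich_gene_sets(query, universe, list(S = set))
  oracle <- sum(choose(20, 20:20) * choose(20, 0)) / choose(40, 20)
  expect_equal(r$p_value, phyper(19, 20, 20, 20, lower.tail = FALSE))
  expect_equal(r$p_value, oracle, tolerance = 1e-12)
  expect_equal(r$overlap, 20)

  # disjoint query: overlap 0, p = 1 under the upper-tail convention
  r0 <- enrich_gene_sets(universe[21:30], universe, list(S = set[1:10]))
  expect_equal(r0$overlap, 0)
  expect_equal(r0$p_value, 1)
  expect_error(enrich_gene_sets(c("zz"), universe, list(S = set)),
               "outside the universe")
})

test_that("overlap counts equal a brute-force intersection", {
  set.seed(12)
  universe <- shared_names(100, "g")
  sets <- list(a = sample(universe, 30), b = sample(universe, 10))
  query <- sample(universe, 25)
  r <- enrich_gene_sets(query, universe, sets)
  for (nm in names(sets)) {
    expect_equal(r$overlap[r$set == nm],
                 length(intersect(query, sets[[nm]])))
  }
})
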