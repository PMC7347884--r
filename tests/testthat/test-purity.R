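test_that("purity threshold scan matches an exhaustive grid oracle", {
  # claudin-low tumors carry an extra low-purity contamination tail; above
  # some threshold the retained distributions coincide
  set.seed(101)
  purity <- c(runif(200, 0.2, 0.9), runif(200, 0.4, 0.9))
  is_cl <- rep(c(TRUE, FALSE), each = 200)
  res <- select_purity_threshold(purity, is_cl, alpha = 0.05,
                                 grid_step = 0.01)
  # independent scan: smallest grid value with rank-sum p >= 0.05 and both
  # groups of size >= 5
  grid <- seq(floor(min(purity) / 0.01) * 0.01, max(purity), by = 0.01)
  oracle <- NA_real_
  for (t in grid) {
    a <- purity[purity > t & is_cl]; b <- purity[purity > t & !is_cl]
    if (length(a) >= 5 && length(b) >= 5 &&
        suppressWarnings(wilcox.test(a, b)$p.value) >= 0.05) {
      oracle <- t; break
    }
  }
  expect_equal(res$threshold, oracle)
  expect_gte(res$p_value_at_threshold, 0.05)
  expect_true(res$threshold %in% res$grid$threshold)
})

test_that("identical purity distributions return the minimal grid value", {
  set.seed(7)
  purity <- runif(400, 0.3, 0.9)
  is_cl <- rep(c(TRUE, FALSE), 200)
  res <- select_purity_threshold(purity, is_cl)
  expect_equal(res$threshold, min(res$grid$threshold))
})

test_that("raising alpha never lowers the selected threshold", {
  set.seed(55)
  purity <- c(runif(150, 0.25, 0.95), runif(150, 0.45, 0.95))
  is_cl <- rep(c(TRUE, FALSE), each = 150)
  t1 <- select_purity_threshold(purity, is_cl, alpha = 0.01)$threshold
  t2 <- select_purity_threshold(purity, is_cl, alpha = 0.05)$threshold
  t3 <- select_purity_threshold(purity, is_cl, alpha = 0.20)$threshold
  expect_true(t1 <= t2 && t2 <= t3)
})

test_that("irreconcilable purity distributions raise the error contract", {
  set.seed(66)
  purity <- c(runif(100, 0.2, 0.5), runif(100, 0.6, 0.9))
  is_cl <- rep(c(TRUE, FALSE), each = 100)
  expect_error(select_purity_threshold(purity, is_cl), "no threshold")
})

test_that("deletion segments are filtered by the LRR cutoff", {
  segs <- data.frame(sample = "s", chrom = "1", start = c(1, 101, 201),
                     end = c(100, 200, 300),
                     seg_mean = c(-0.5, -0.3, 0.2),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(find_deletion_segments(segs)), 1)
  expect_equal(find_deletion_segments(segs)$seg_mean, -0.5)
  segs$seg_mean <- abs(segs$seg_mean)
  expect_equal(nrow(find_deletion_segments(segs)), 0)
  expect_equal(eval(formals(find_deletion_segments)$lrr_cut), -0.4)
  expect_error(find_deletion_segments(segs, lrr_cut = 0.4), "negative")
})

simulate_deletion_snps <- function(p, n_snps = 400, depth = 60, seed = 1) {
  set.seed(seed)
  band <- rep(c((1 - p) / (2 - p), 1 / (2 - p)), length.out = n_snps)
  data.frame(sample = "s", chrom = "5", position = seq_len(n_snps) * 100,
             baf = rbinom(n_snps, depth, band) / depth,
             lrr = -0.6, stringsAsFactors = FALSE)
}

del_segment <- function(n_snps = 400) {
  data.frame(sample = "s", chrom = "5", start = 1, end = n_snps * 100 + 1,
             seg_mean = -0.6, stringsAsFactors = FALSE)
}

test_that("BAF cluster means track the hemizygous-loss closed form", {
  depth <- 60
  for (p in c(0.3, 0.5, 0.8, 1.0)) {
    snps <- simulate_deletion_snps(p, n_snps = 400, depth = depth, seed = 17)
    rep <- assess_baf_separation(snps, del_segment())
    lo <- (1 - p) / (2 - p); hi <- 1 / (2 - p)
    se_lo <- sqrt(lo * (1 - lo) / depth) / sqrt(200)
    se_hi <- sqrt(hi * (1 - hi) / depth) / sqrt(200)
    if (p == 1) {
      # pure-tumor bands sit at 0 and 1; they fall in the trimmed homozygous
      # range, matching the limit where separation is maximal
      expect_true(rep$separation_pass || rep$n_snps < 4)
    } else {
      expect_lt(abs(rep$lower_cluster_mean - lo), 3 * se_lo + 1e-3)
      expect_gt(rep$upper_cluster_mean, hi - 3 * se_hi - 1e-3)
    }
  }
})

test_that("separation passes at high purity and fails under contamination", {
  pass <- assess_baf_separation(simulate_deletion_snps(0.9, seed = 2),
                                del_segment())
  fail <- assess_baf_separation(simulate_deletion_snps(0.5, seed = 2),
                                del_segment())
  expect_true(pass$separation_pass)
  expect_false(fail$separation_pass)
  # expected band means at p = 0.8: ~0.167 / ~0.833
  mid <- assess_baf_separation(simulate_deletion_snps(0.8, seed = 3),
                               del_segment())
  expect_true(mid$separation_pass)
})

test_that("segments with too few informative SNPs are flagged, not failed", {
  snps <- simulate_deletion_snps(0.9, n_snps = 2, seed = 4)
  rep <- assess_baf_separation(snps, del_segment(2))
  expect_false(rep$informative)
  expect_false(rep$separation_pass)
})

test_that("VAF support counts clonal-level mutations", {
  muts <- data.frame(vaf = c(0.45, 0.1),
                     annotation = c("exonic_nonsilent", "exonic_nonsilent"))
  r <- check_vaf_support(muts)
  expect_equal(r$n_pass, 1)
  expect_true(r$pass)
  expect_equal(formals(check_vaf_support)$vaf_cut, 0.4)

  # clonal heterozygous mutations at purity 0.9 have expected VAF 0.45
  set.seed(6)
  vafs <- rbinom(50, 60, 0.45) / 60
  r2 <- check_vaf_support(data.frame(vaf = vafs,
                                     annotation = "exonic_nonsilent"))
  expect_true(r2$pass)
  # non-exonic mutations never count
  r3 <- check_vaf_support(data.frame(vaf = 0.5, annotation = "other"))
  expect_false(r3$pass)
})

test_that("a CNA-devoid pure sample is flagged, a contaminated one is not", {
  seg_pure <- rbind(del_segment(),
                    data.frame(sample = "s", chrom = "1", start = 1,
                               end = 1e7, seg_mean = 0.01,
                               stringsAsFactors = FALSE))
  make_report <- function(p, seed) {
    snps <- simulate_deletion_snps(p, seed = seed)
    muts <- data.frame(vaf = rbinom(5, 60, p / 2) / 60,
                       annotation = "exonic_nonsilent")
    focal_loss_report(seg_pure, snps, muts, fga = 0.004)
  }
  expect_true(make_report(0.95, 10)$cna_devoid_but_pure)
  expect_false(make_report(0.30, 10)$cna_devoid_but_pure)
})
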