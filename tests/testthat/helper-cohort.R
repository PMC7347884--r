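# One default synthetic cohort shared by tests that need full inputs;
# generated once per test run under a fixed seed.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_config(seed = 42L))
    cache
  }
})

# FGA values drawn from the trimodal claudin-low structure (10/17/18 samples
# with component means 0.05/0.20/0.40, sds 0.02/0.05/0.05).
draw_trimodal_fga <- function(seed, n = c(10L, 17L, 18L)) {
  set.seed(seed)
  pmax(c(stats::rnorm(n[1], 0.05, 0.02),
         stats::rnorm(n[2], 0.20, 0.05),
         stats::rnorm(n[3], 0.40, 0.05)), 0.001)
}

# Random segment table for one sample: k segments on one chromosome,
# contiguous, integer bp coordinates.
random_segments <- function(k, sample_id = "s1", chrom = "1") {
  len <- sample(1e4:1e6, k, replace = TRUE)
  end <- cumsum(len)
  data.frame(sample = sample_id, chrom = chrom,
             start = c(1, utils::head(end, -1) + 1), end = end,
             num_probes = NA_integer_,
             seg_mean = stats::rnorm(k, 0, 0.3),
             stringsAsFactors = FALSE)
}

# Independent brute-force FGA: sorts (value, weight) pairs, scans cumulative
# weights for the lower weighted median, then sums altered lengths directly.
fga_bruteforce <- function(segs, T) {
  len <- as.numeric(segs$end - segs$start + 1)
  cn <- segs$seg_mean
  ord <- order(cn)
  cum <- cumsum(len[ord])
  wm <- cn[ord][which(cum >= sum(len) / 2)[1]]
  sum(len[cn > wm + T | cn < wm - T]) / sum(len)
}
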