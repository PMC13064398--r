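test_that("single-window band at B = 1000 selects depth 26 with coverage 0.95", {
  set.seed(101)
  D <- matrix(rnorm(1000), ncol = 1)
  band <- scs_rank_band(D, alpha = 0.05)
  # closed-form count: (B - 2k + 2)/B >= 0.95 maximized at k = 26
  expect_identical(band$k, 26L)
  expect_equal(band$achieved_coverage, 0.95)
  expect_equal(band$lower, sort(D[, 1])[26])
  expect_equal(band$upper, sort(D[, 1])[975])
})

test_that("identical bootstrap rows give a zero-width band with full coverage", {
  D <- matrix(rep(c(0.2, -0.1, 0.4), each = 100), nrow = 100)
  band <- scs_rank_band(D, alpha = 0.05)
  expect_equal(band$lower, band$upper)
  expect_equal(band$achieved_coverage, 1)
  expect_identical(band$k, 50L)  # floor((B+1)/2)
})

test_that("simultaneity over many windows forces a smaller depth than one window", {
  set.seed(102)
  D <- matrix(rnorm(1000 * 50), ncol = 50)
  band <- scs_rank_band(D, alpha = 0.05)
  expect_lt(band$k, 26L)
  expect_gte(band$achieved_coverage, 0.95)
})

test_that("selected depth maximizes k under the coverage constraint (exhaustive scan)", {
  set.seed(103)
  for (case in 1:4) {
    B <- sample(c(60, 100, 150), 1)
    W <- sample(1:6, 1)
    D <- matrix(rnorm(B * W), ncol = W)
    if (case == 4) D[, 1] <- round(D[, 1], 1)  # ties
    band <- scs_rank_band(D, alpha = 0.05)
    oracle <- brute_band_scan(D, 0.05)
    expect_identical(band$k, as.integer(oracle$k))
    expect_equal(band$achieved_coverage, oracle$coverage[band$k])
    # coverage is non-increasing in k
    expect_true(all(diff(oracle$coverage) <= 1e-12))
  }
})

test_that("bands widen monotonically as alpha decreases", {
  set.seed(104)
  D <- matrix(rnorm(500 * 10), ncol = 10)
  b05 <- scs_rank_band(D, alpha = 0.05)
  b01 <- scs_rank_band(D, alpha = 0.01)
  expect_true(all(b01$lower <= b05$lower + 1e-15))
  expect_true(all(b01$upper >= b05$upper - 1e-15))
})

sim_small <- function(seed, n_per_group = 30, sweeps = list()) {
  simulate_panel(sim_config(n_chromosomes = 1, chrom_length_bp = 3e6,
                            snps_per_mb = 100,
                            n_samples_per_group = c(a = n_per_group,
                                                    b = n_per_group),
                            missing_rate = 0.02, sweeps = sweeps,
                            seed = seed))
}

test_that("bootstrap deviations are seeded and degenerate panels collapse", {
  sim <- sim_small(1)
  w <- make_snp_windows(sim$map, 50, 10)
  b1 <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 20, seed = 9)
  b2 <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 20, seed = 9)
  expect_identical(b1$dev, b2$dev)
  b3 <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 20, seed = 10)
  expect_false(identical(b1$dev, b3$dev))
  # panel of identical samples: resampling changes nothing
  d <- matrix(rep(c(0L, 1L, 2L, 4L), each = 25), nrow = 25)
  colnames(d) <- paste0("L", 1:4)
  ident <- dosage_panel(d, ploidy = 4)
  mapi <- snp_map(colnames(d), "Chr1", c(1L, 2L, 3L, 4L) * 1000L)
  wi <- data.frame(chrom = "Chr1", first = c(1L, 3L), last = c(2L, 4L),
                   start_bp = c(1000, 3000), end_bp = c(2000, 4000),
                   n_loci = 2L, mid_bp = c(1500, 3500))
  bi <- bootstrap_deviations(ident, mapi, wi, "He", B = 15, seed = 2)
  expect_equal(max(apply(bi$dev, 2, sd)), 0)
  expect_error(bootstrap_deviations(ident, mapi, wi, "bogus", B = 10,
                                    seed = 1), "unknown metric")
})

test_that("bootstrap means concentrate on the point estimate", {
  sim <- sim_small(3, n_per_group = 100)
  w <- make_snp_windows(sim$map, 50, 25)
  st <- diversity_stats(sim$panel)
  tr <- windowize(st$Ho, sim$map, w, "Ho")
  bt <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 400, seed = 5)
  bmean <- colMeans(bt$dev)
  bsd <- apply(bt$dev, 2, sd)
  expect_true(all(abs(bmean - tr$deviation) <= 4 * bsd / sqrt(400) + 1e-4))
})

test_that("stratified resampling preserves group sizes in expectation", {
  sim <- sim_small(7)
  w <- make_snp_windows(sim$map, 50, 25)
  bs <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 30, seed = 4,
                             stratify_by_group = TRUE)
  bu <- bootstrap_deviations(sim$panel, sim$map, w, "Ho", B = 30, seed = 4)
  expect_false(identical(bs$dev, bu$dev))
  expect_equal(dim(bs$dev), dim(bu$dev))
})

test_that("per-chromosome bands rarely exclude an independent data half under the null", {
  exits <- vapply(1:12, function(s) {
    sim <- simulate_panel(sim_config(n_chromosomes = 1,
                                     chrom_length_bp = 2e6,
                                     snps_per_mb = 100,
                                     n_samples_per_group = c(a = 80),
                                     missing_rate = 0, seed = 500 + s))
    n <- nrow(sim$panel$dosages)
    half1 <- dosage_panel(sim$panel$dosages[1:(n / 2), , drop = FALSE],
                          ploidy = 4)
    half2 <- dosage_panel(sim$panel$dosages[(n / 2 + 1):n, , drop = FALSE],
                          ploidy = 4)
    w <- make_snp_windows(sim$map, 40, 10)
    bt <- bootstrap_deviations(half1, sim$map, w, "He", B = 200, seed = s)
    band <- scs_rank_band(bt, alpha = 0.05)
    st2 <- diversity_stats(half2)
    tr2 <- windowize(st2$He, sim$map, w, "He")
    any(tr2$deviation < band$lower | tr2$deviation > band$upper)
  }, logical(1))
  # a simultaneous (not pointwise) band: exits must stay far below W * alpha
  expect_lt(mean(exits), 0.5)
})
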