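test_that("local minima match the printed examples and edge rules", {
  expect_identical(find_local_minima(c(-1, -3, -2, -1, -5, -2), 2),
                   c(2L, 5L))
  # strictly increasing: only the first entry
  expect_identical(find_local_minima(1:6, 2), 1L)
  # constant: leftmost of the tied run only
  expect_identical(find_local_minima(rep(0.3, 5), 2), 1L)
  # non-finite entries are skipped as candidates and comparators
  expect_identical(find_local_minima(c(NA, -2, -1, NA, -3), 1),
                   c(2L, 5L))
})

test_that("local minima agree with the brute-force double loop on random tracks", {
  set.seed(202)
  for (rep in 1:300) {
    n <- sample(3:40, 1)
    v <- rnorm(n)
    if (rep %% 3 == 0) v <- round(v, 1)          # force ties
    if (rep %% 5 == 0) v[sample(n, 2)] <- NA     # missing windows
    for (nb in 1:2)
      expect_identical(find_local_minima(v, nb), brute_minima(v, nb))
  }
})

test_that("merging unions overlaps, preserves coverage, and is idempotent", {
  r <- function(s, e, name = "x", metric = "Ho")
    data.frame(name = name, chrom = "Chr1", start_bp = s, end_bp = e,
               peak_mid_bp = (s + e) / 2, metrics = metric,
               direction = "reduced_in_all", provenance = "within_group",
               band_significant = NA)
  m <- merge_regions(rbind(r(1e6, 3e6, "p1"), r(2e6, 5e6, "p2", "pi")))
  expect_equal(nrow(m), 1)
  expect_equal(m$start_bp, 1e6)
  expect_equal(m$end_bp, 5e6)
  expect_identical(m$metrics, "Ho,pi")
  # disjoint regions unchanged
  d <- merge_regions(rbind(r(1e6, 2e6), r(4e6, 5e6)))
  expect_equal(nrow(d), 2)
  # idempotent and order-invariant
  x <- rbind(r(1e6, 3e6, "p1"), r(2e6, 5e6, "p2"), r(7e6, 8e6, "p3"))
  m1 <- merge_regions(x)
  expect_equal(merge_regions(m1)[, c("chrom", "start_bp", "end_bp")],
               m1[, c("chrom", "start_bp", "end_bp")])
  m2 <- merge_regions(x[c(3, 1, 2), ])
  expect_equal(m1[, c("chrom", "start_bp", "end_bp", "metrics")],
               m2[, c("chrom", "start_bp", "end_bp", "metrics")])
})

test_that("all-nonnegative deviation tracks yield no regions", {
  tr <- toy_track(abs(rnorm(50)) + 0.01)
  tr$deviation <- tr$window_mean  # all positive
  expect_equal(nrow(call_sweeps(tr)), 0)
})

test_that("a single deep dip becomes one region extended by 1 Mb", {
  # 40 windows over 8 Mb; 20 shallow negative windows plus one deep dip,
  # so the chromosome's 5% quantile of negative deviations isolates the dip
  dev <- rep(c(0.01, -0.001), 20)
  dev[24] <- -0.5
  tr <- toy_track(dev, spacing_bp = 2e5)
  tr$deviation <- dev
  tr$windows$mid_bp[24] <- 5e6
  regs <- call_sweeps(tr, quantile = 0.05, neighborhood = 2,
                      extend_bp = 1e6,
                      chrom_lengths = c(Chr1 = 2e7))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start_bp, 4e6)
  expect_equal(regs$end_bp, 6e6)
  expect_equal(regs$peak_mid_bp, 5e6)
  expect_identical(regs$direction, "reduced_in_all")
})

test_that("raising the caller quantile can only enlarge the call set", {
  set.seed(33)
  dev <- rnorm(200, sd = 0.05) - 0.01
  tr <- toy_track(dev)
  tr$deviation <- dev
  r1 <- call_sweeps(tr, quantile = 0.02)
  r2 <- call_sweeps(tr, quantile = 0.10)
  expect_gte(nrow(r2), nrow(r1))
  expect_true(all(r1$peak_mid_bp %in% r2$peak_mid_bp))
})

test_that("consensus keeps only regions supported by enough metrics", {
  r <- function(s, e) data.frame(
    name = "x", chrom = "Chr1", start_bp = s, end_bp = e,
    peak_mid_bp = (s + e) / 2, metrics = "raw",
    direction = "reduced_in_all", provenance = "within_group",
    band_significant = NA)
  # identical region from Ho and pi: retained with both metrics
  cons <- consensus_regions(list(Ho = r(1e6, 3e6), pi = r(1e6, 3e6)))
  expect_equal(nrow(cons), 1)
  expect_identical(cons$metrics, "Ho,pi")
  # region found by Ho only is dropped at min_metrics = 2
  cons2 <- consensus_regions(list(Ho = r(1e6, 3e6), pi = r(8e6, 9e6)),
                             min_metrics = 2)
  expect_equal(nrow(cons2), 0)
  expect_equal(nrow(consensus_regions(list(Ho = r(1e6, 3e6)),
                                      min_metrics = 1)), 1)
  # partial overlap: retained as the union interval
  cons3 <- consensus_regions(list(Ho = r(1e6, 3e6), pi = r(2.5e6, 4.5e6)))
  expect_equal(nrow(cons3), 1)
  expect_equal(cons3$start_bp, 1e6)
  expect_equal(cons3$end_bp, 4.5e6)
})

test_that("hand-built comparative tracks trigger a polarized call", {
  base_F <- rep(0.05, 100); base_D <- rep(0, 100); base_P <- rep(1, 100)
  base_F[50] <- 0.9      # Fst top 1%
  base_D[50] <- -0.5     # delta_Ho bottom 1%
  tracks <- list(Fst = toy_track(base_F, "Fst"),
                 delta_Ho = toy_track(base_D, "delta_Ho"),
                 pi_ratio = toy_track(base_P, "pi_ratio"))
  regs <- call_comparative_sweeps(tracks, quantile = 0.01,
                                  neighborhood = 1, min_metrics = 2)
  expect_equal(nrow(regs), 1)
  expect_identical(regs$direction, "reduced_in_A")
  expect_setequal(strsplit(regs$metrics, ",")[[1]], c("Fst", "delta_Ho"))
  expect_equal(regs$peak_mid_bp, tracks$Fst$windows$mid_bp[50])
  # extremum in one metric only: no region at min_metrics = 2
  only_f <- list(Fst = toy_track(base_F, "Fst"),
                 delta_Ho = toy_track(rep(0, 100), "delta_Ho"),
                 pi_ratio = toy_track(base_P, "pi_ratio"))
  expect_equal(nrow(call_comparative_sweeps(only_f)), 0)
  # mismatched windows rejected
  short <- list(Fst = toy_track(base_F[1:50], "Fst"),
                delta_Ho = toy_track(base_D, "delta_Ho"))
  expect_error(call_comparative_sweeps(short), "mismatched")
})

test_that("called regions stay within the padded chromosome span", {
  set.seed(44)
  sim <- simulate_panel(sim_config(
    n_chromosomes = 2, chrom_length_bp = 4e6, snps_per_mb = 80,
    n_samples_per_group = c(a = 40, b = 40),
    sweeps = list(truth_sweep("Chr1", 1, 1.5e6, "all", 1)), seed = 44))
  sc <- sweep_scan(sim$panel, sim$map, B = 0, seed = 1,
                   chrom_lengths = sim$chrom_lengths)
  regs <- sc$consensus
  expect_true(all(regs$start_bp >= 1))
  for (i in seq_len(nrow(regs)))
    expect_lte(regs$end_bp[i], sim$chrom_lengths[[regs$chrom[i]]])
  expect_true(all(regs$start_bp <= regs$peak_mid_bp &
                    regs$peak_mid_bp <= regs$end_bp))
})

test_that("canonical peak names rank by position within chromosome", {
  r <- data.frame(name = c("a", "b", "c"), chrom = c("Chr2", "Chr1", "Chr2"),
                  start_bp = c(5e6, 1e6, 1e6), end_bp = c(6e6, 2e6, 2e6),
                  peak_mid_bp = c(5.5e6, 1.5e6, 1.5e6),
                  metrics = "Ho", direction = "reduced_in_all",
                  provenance = c("within_group", "within_group",
                                 "comparative"),
                  band_significant = NA)
  named <- name_regions(r)
  expect_identical(named$name,
                   c("Peak 1.1", "Peak C2.1", "Peak 2.1"))
})
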