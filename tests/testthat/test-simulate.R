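test_that("identical configuration and seed reproduce the panel exactly", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                    snps_per_mb = 50,
                    n_samples_per_group = c(a = 15, b = 25), seed = 42)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$dosages, s2$panel$dosages)
  expect_identical(s1$map, s2$map)
  expect_identical(s1$truth_freqs, s2$truth_freqs)
})

test_that("panel dimensions, dosage range and position ordering hold", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 10e6,
                    snps_per_mb = 100,
                    n_samples_per_group = c(a = 50, b = 50), seed = 7)
  sim <- simulate_panel(cfg)
  expect_equal(dim(sim$panel$dosages), c(100, 2000))
  d <- sim$panel$dosages
  expect_true(all(d[!is.na(d)] %in% 0:4))
  for (ch in unique(sim$map$chrom))
    expect_true(all(diff(sim$map$pos[sim$map$chrom == ch]) > 0))
})

test_that("a full-intensity sweep fixes every locus in the interval", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6,
                    snps_per_mb = 60,
                    n_samples_per_group = c(a = 30, b = 30),
                    missing_rate = 0,
                    sweeps = list(truth_sweep("Chr1", 1e6, 3e6, "all", 1)),
                    seed = 3)
  sim <- simulate_panel(cfg)
  inside <- sim$map$chrom == "Chr1" & sim$map$pos >= 1e6 & sim$map$pos <= 3e6
  expect_gt(sum(inside), 50)
  expect_true(all(sim$truth_freqs[inside, ] %in% c(0, 1)))
  st <- diversity_stats(sim$panel)
  expect_true(all(st$He[inside] == 0))
  expect_true(all(st$pi[inside] == 0))
  expect_true(any(st$He[!inside] > 0))
})

test_that("sweep intensity 0.8 depresses expected heterozygosity versus background", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 10e6,
                    snps_per_mb = 100,
                    n_samples_per_group = c(a = 50, b = 50),
                    sweeps = list(truth_sweep("Chr1", 2e6, 6e6, "all", 0.8)),
                    seed = 11)
  sim <- simulate_panel(cfg)
  # oracle: He recomputed directly from the generator's truth frequencies
  he_truth <- 2 * sim$truth_freqs * (1 - sim$truth_freqs)
  inside <- sim$map$chrom == "Chr1" & sim$map$pos >= 2e6 & sim$map$pos <= 6e6
  expect_lt(mean(he_truth[inside, ]), mean(he_truth[!inside, ]))
  # and the realized dosage-based He agrees with the truth-based contrast
  st <- diversity_stats(sim$panel)
  expect_lt(mean(st$He[inside]), mean(st$He[!inside]))
})

test_that("missingness is placed at the configured rate", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6,
                    snps_per_mb = 80,
                    n_samples_per_group = c(a = 60), missing_rate = 0.08,
                    seed = 5)
  sim <- simulate_panel(cfg)
  n_cells <- length(sim$panel$dosages)
  se <- sqrt(0.08 * 0.92 / n_cells)
  expect_lt(abs(mean(is.na(sim$panel$dosages)) - 0.08), 3 * se)
})

test_that("empirical allele frequencies converge to the stored truth", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 100e6,
                    snps_per_mb = 100,
                    n_samples_per_group = c(a = 200), missing_rate = 0,
                    group_divergence = 0, seed = 9)
  sim <- simulate_panel(cfg)  # 10,000 check loci
  st <- diversity_stats(sim$panel)
  p <- sim$truth_freqs[, "a"]
  bound <- 4 * sqrt(p * (1 - p) / (4 * 200))
  viol <- sum(abs(st$p - p) > bound)
  # ~6e-5 two-sided tail per locus: a handful of exceedances at most
  expect_lte(viol, 10)
  expect_lt(mean(abs(st$p - p)), mean(bound) / 3)
})

test_that("sweeps referencing unknown chromosomes or groups are rejected", {
  expect_error(sim_config(n_chromosomes = 2,
                          n_samples_per_group = c(a = 5, b = 5),
                          sweeps = list(truth_sweep("Chr9", 1, 100))),
               "unknown chromosome")
  expect_error(sim_config(n_chromosomes = 2,
                          n_samples_per_group = c(a = 5, b = 5),
                          sweeps = list(truth_sweep("Chr1", 1, 100,
                                                    groups = "nope"))),
               "unknown group")
  expect_error(truth_sweep("Chr1", 100, 1), "start_bp <= end_bp")
  expect_error(truth_sweep("Chr1", 1, 100, intensity = 0))
})

test_that("without sweeps the windowed He track is stationary", {
  exceed <- vapply(1:5, function(s) {
    cfg <- sim_config(n_chromosomes = 3, chrom_length_bp = 4e6,
                      snps_per_mb = 100,
                      n_samples_per_group = c(a = 40, b = 40),
                      missing_rate = 0, seed = 100 + s)
    sim <- simulate_panel(cfg)
    st <- diversity_stats(sim$panel)
    w <- make_snp_windows(sim$map, size = 50, step = 10)
    tr <- windowize(st$He, sim$map, w, "He")
    wsd <- stats::sd(tr$window_mean, na.rm = TRUE)
    max(abs(tr$deviation), na.rm = TRUE) > 5 * wsd
  }, logical(1))
  expect_lte(sum(exceed), 1)
})

test_that("gene annotation simulator is seeded and validates inputs", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
                    snps_per_mb = 50, n_samples_per_group = c(a = 5),
                    seed = 2)
  map <- simulate_panel(cfg)$map
  expect_error(simulate_gene_annotations(map, n_genes = 0, n_terms = 5))
  a1 <- simulate_gene_annotations(map, 50, 10, seed = 4)
  a2 <- simulate_gene_annotations(map, 50, 10, seed = 4)
  expect_identical(a1, a2)
  expect_true(all(a1$genes$start_bp <= a1$genes$end_bp))
  expect_true(all(a1$gene2term$gene_id %in% a1$genes$gene_id))
})
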