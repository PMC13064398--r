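# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized code paths: plain loops and closed forms.

# per-locus stats by direct looping over genotypes
naive_locus_stats <- function(d, ploidy) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) return(list(p = NA, Ho = NA, He = NA, pi = NA, n = 0))
  p <- sum(d) / (ploidy * n)
  q <- 1 - p
  n_het <- sum(d >= 1 & d <= ploidy - 1)
  He <- 1 - (p^2 + q^2)
  pi <- if (n >= 2) n / (n - 1) * 2 * p * (1 - p) else NA
  list(p = p, Ho = n_het / n, He = He, pi = pi, n = n, n_het = n_het)
}

# local minima by exhaustive double loop (strict left / weak right rule,
# the normative tie convention: leftmost of a tied run qualifies)
brute_minima <- function(v, nb) {
  res <- integer(0)
  for (i in seq_along(v)) {
    if (!is.finite(v[i])) next
    good <- TRUE
    lo <- max(1, i - nb)
    hi <- min(length(v), i + nb)
    for (j in lo:hi) {
      if (j == i || !is.finite(v[j])) next
      if (j < i && !(v[i] < v[j])) good <- FALSE
      if (j > i && !(v[i] <= v[j])) good <- FALSE
    }
    if (good) res <- c(res, i)
  }
  res
}

# window means by a naive per-window loop
brute_window_means <- function(values, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    v <- values[windows$first[i]:windows$last[i]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

# one-sided over-representation p by direct hypergeometric summation
hyper_tail_p <- function(k, K, m, M) {
  i <- k:min(K, m)
  sum(choose(m, i) * choose(M - m, K - i)) / choose(M, K)
}

# exhaustive scan over the symmetric rank depth k: for each k, count the
# rows inside the closed band in every window, and return the largest k
# whose joint coverage is >= 1 - alpha
brute_band_scan <- function(D, alpha) {
  B <- nrow(D)
  kmax <- (B + 1) %/% 2
  cov <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lo <- apply(D, 2, function(col) sort(col)[k])
    hi <- apply(D, 2, function(col) sort(col)[B + 1 - k])
    inside <- vapply(seq_len(B), function(i)
      all(D[i, ] >= lo & D[i, ] <= hi), logical(1))
    cov[k] <- mean(inside)
  }
  ok <- which(cov >= 1 - alpha)
  list(k = if (length(ok)) max(ok) else 1L, coverage = cov)
}

# small deterministic panel: two groups with prescribed per-group dosage
# columns (list of list(a = vec, b = vec))
toy_two_group_panel <- function(cols, ploidy = 4) {
  a <- do.call(cbind, lapply(cols, `[[`, "a"))
  b <- do.call(cbind, lapply(cols, `[[`, "b"))
  d <- rbind(a, b)
  rownames(d) <- c(paste0("a", seq_len(nrow(a))), paste0("b", seq_len(nrow(b))))
  colnames(d) <- paste0("L", seq_along(cols))
  dosage_panel(d, ploidy = ploidy,
               groups = setNames(rep(c("A", "B"), c(nrow(a), nrow(b))),
                                 rownames(d)))
}

# hand-made window track over a single chromosome
toy_track <- function(values, metric = "Ho", group = "all",
                      chrom = "Chr1", spacing_bp = 1e5) {
  W <- length(values)
  windows <- data.frame(chrom = chrom, first = seq_len(W), last = seq_len(W),
                        start_bp = spacing_bp * (seq_len(W) - 1) + 1,
                        end_bp = spacing_bp * seq_len(W),
                        n_loci = 1L,
                        mid_bp = floor(spacing_bp * (seq_len(W) - 0.5)),
                        stringsAsFactors = FALSE)
  structure(list(windows = windows, window_mean = values,
                 genome_mean = mean(values, na.rm = TRUE),
                 deviation = values - mean(values, na.rm = TRUE),
                 metric = metric, group = group),
            class = "window_track")
}
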