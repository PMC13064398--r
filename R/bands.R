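#' Accession-level bootstrap of windowed deviation tracks
#'
#' Resamples accessions (rows of the dosage matrix) with replacement and,
#' in every replicate, recomputes the per-locus metric, the window means,
#' the genome-wide mean, and the deviations of window means from the
#' genome mean. Resampling whole accessions preserves the linkage
#' disequilibrium between loci that the windowed statistics depend on;
#' resampling loci would destroy it.
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param map matching \code{\link{snp_map}}
#' @param windows window data.frame built from \code{map}
#' @param metric one of \code{"Ho"}, \code{"He"}, \code{"pi"}
#' @param B number of bootstrap replicates (default 1000)
#' @param seed integer seed; identical seed gives an identical matrix
#' @param group restrict the metric and the resampling to one group
#' @param stratify_by_group resample within each group, preserving group
#'   sizes (used when group tracks are compared); default resamples the
#'   whole accession list
#' @param center \code{"recomputed"} (default) recenters every replicate
#'   by its own genome mean, mirroring the full recomputation of the point
#'   estimate; \code{"point"} subtracts the point-estimate genome mean
#'   instead
#' @return object of class \code{bootstrap_track}: list with \code{dev}
#'   (B x W deviation matrix), \code{B}, \code{windows}, \code{metric},
#'   \code{group}, \code{seed}, \code{center}
#' @export
bootstrap_deviations <- function(panel, map, windows, metric = "Ho",
                                 B = 1000, seed = 1, group = NULL,
                                 stratify_by_group = FALSE,
                                 center = c("recomputed", "point")) {
  res <- bootstrap_deviations_multi(panel, map, windows, metrics = metric,
                                    B = B, seed = seed, group = group,
                                    stratify_by_group = stratify_by_group,
                                    center = center)
  res[[metric]]
}

# shared-resample bootstrap for several metrics at once; each replicate is
# a multiplicity vector w and all per-locus counts are matrix-vector
# products against precomputed matrices
bootstrap_deviations_multi <- function(panel, map, windows,
                                       metrics = c("Ho", "He", "pi"),
                                       B = 1000, seed = 1, group = NULL,
                                       stratify_by_group = FALSE,
                                       center = c("recomputed", "point")) {
  center <- match.arg(center)
  stopifnot(B >= 2, nrow(windows) >= 1)
  bad <- setdiff(metrics, c("Ho", "He", "pi"))
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  check_aligned(panel, map)
  X <- panel$dosages
  grp <- panel$groups
  if (!is.null(group)) {
    keep <- grp == group
    if (!any(keep)) stop("unknown group label: ", group)
    X <- X[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  n <- nrow(X)
  pre <- precompute_stats(X, panel$ploidy)
  point <- stats_from_weights(pre, rep(1, n))
  strata <- if (stratify_by_group) split(seq_len(n), grp)
            else list(seq_len(n))

  set.seed(seed)
  dev <- lapply(metrics, function(m)
    matrix(NA_real_, nrow = B, ncol = nrow(windows)))
  names(dev) <- metrics
  for (b in seq_len(B)) {
    idx <- unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]),
      use.names = FALSE)
    w <- tabulate(idx, nbins = n)
    st <- stats_from_weights(pre, w)
    for (m in metrics) {
      v <- st[[m]]
      wm <- window_means(v, windows$first, windows$last)
      gm <- if (center == "recomputed") mean(v, na.rm = TRUE)
            else mean(point[[m]], na.rm = TRUE)
      dev[[m]][b, ] <- wm - gm
    }
  }
  lapply(setNames(metrics, metrics), function(m)
    structure(list(dev = dev[[m]], B = B, windows = windows, metric = m,
                   group = if (is.null(group)) "all" else group,
                   seed = seed, center = center),
              class = "bootstrap_track"))
}

#' Rank-based simultaneous confidence band
#'
#' Builds a multiplicity-corrected band for a windowed deviation profile
#' from its bootstrap matrix. For each window the B bootstrap deviations
#' are ordered, \eqn{t_{(1)} \le \dots \le t_{(B)}}; the band at symmetric
#' rank depth k is \eqn{[t_{(k)}, t_{(B+1-k)}]} per window. The selected k
#' is the largest depth for which the fraction of bootstrap replicates
#' lying inside the band at every window simultaneously is at least
#' \eqn{1 - \alpha}. Being rank based, the construction makes no
#' distributional assumption, and selecting k jointly over all windows of
#' the chromosome is what corrects for the multiplicity of (dependent)
#' windows: with more windows a smaller k — a wider band — is needed to
#' keep joint coverage.
#'
#' Ties are resolved by closed comparisons (\eqn{\le}/\eqn{\ge}), which can
#' only raise coverage. If even k = 1 fails the coverage constraint a
#' warning signals that B is too small for this alpha.
#'
#' @param track a \code{bootstrap_track} from
#'   \code{\link{bootstrap_deviations}}, or a bare B x W matrix; columns
#'   should belong to a single chromosome
#' @param alpha joint miscoverage level (default 0.05)
#' @return object of class \code{scs_band}: list with per-window
#'   \code{lower}/\code{upper}, \code{k}, \code{achieved_coverage},
#'   \code{alpha}, \code{B}
#' @export
scs_rank_band <- function(track, alpha = 0.05) {
  D <- if (inherits(track, "bootstrap_track")) track$dev else as.matrix(track)
  B <- nrow(D)
  W <- ncol(D)
  stopifnot(W >= 1, alpha > 0, alpha < 1, B >= ceiling(2 / alpha))
  if (!all(is.finite(D)))
    stop("non-finite bootstrap deviations; drop all-missing windows first")
  sorted <- apply(D, 2, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = B)
  # depth of row i: largest k at which the row is still inside the
  # depth-k band in every window
  depth <- rep(Inf, B)
  for (w in seq_len(W)) {
    sc <- sorted[, w]
    L <- findInterval(D[, w], sc)                      # #{t <= x}
    U <- B - findInterval(D[, w], sc, left.open = TRUE) # #{t >= x}
    depth <- pmin(depth, pmin(L, U))
  }
  k_max <- (B + 1L) %/% 2L
  cov_k <- vapply(seq_len(k_max), function(k) mean(depth >= k), numeric(1))
  ok <- which(cov_k >= 1 - alpha)
  k <- if (length(ok)) max(ok) else 1L
  achieved <- cov_k[k]
  if (k == 1L && achieved < 1 - alpha)
    warning(sprintf(
      "joint coverage %.3f < %.3f even at depth k = 1; increase B",
      achieved, 1 - alpha))
  structure(list(lower = sorted[k, ], upper = sorted[B + 1L - k, ],
                 k = as.integer(k), achieved_coverage = achieved,
                 alpha = alpha, B = B,
                 windows = if (inherits(track, "bootstrap_track"))
                   track$windows else NULL,
                 coverage_by_k = cov_k),
            class = "scs_band")
}

#' @export
print.scs_band <- function(x, ...) {
  cat(sprintf(
    "Simultaneous rank band: %d windows, B = %d, alpha = %.3g\n",
    length(x$lower), x$B, x$alpha))
  cat(sprintf("selected depth k = %d, achieved joint coverage %.4f\n",
              x$k, x$achieved_coverage))
  invisible(x)
}

#' Per-chromosome simultaneous bands for a bootstrap track
#'
#' Applies \code{\link{scs_rank_band}} separately to the windows of each
#' chromosome (the multiplicity adjustment is per chromosome). Windows
#' with any non-finite bootstrap deviation are excluded from the depth
#' selection and get NA limits.
#'
#' @param track a \code{bootstrap_track} spanning one or more chromosomes
#' @param alpha joint miscoverage level per chromosome
#' @return data.frame aligned with \code{track$windows}: chrom, lower,
#'   upper, k, achieved_coverage
#' @export
scs_bands_by_chrom <- function(track, alpha = 0.05) {
  stopifnot(inherits(track, "bootstrap_track"))
  w <- track$windows
  out <- data.frame(chrom = w$chrom, lower = NA_real_, upper = NA_real_,
                    k = NA_integer_, achieved_coverage = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(w$chrom)) {
    cols <- which(w$chrom == ch)
    fin <- cols[colSums(!is.finite(track$dev[, cols, drop = FALSE])) == 0]
    if (!length(fin)) next
    band <- scs_rank_band(track$dev[, fin, drop = FALSE], alpha = alpha)
    out$lower[fin] <- band$lower
    out$upper[fin] <- band$upper
    out$k[cols] <- band$k
    out$achieved_coverage[cols] <- band$achieved_coverage
  }
  out
}
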