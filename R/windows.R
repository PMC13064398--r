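#' Sliding windows of a fixed SNP count
#'
#' Per chromosome, windows cover \code{size} consecutive loci and start at
#' locus indices 1, 1+step, 1+2*step, ...; only complete windows (exactly
#' \code{size} member loci) are emitted, so trailing partial windows are
#' dropped and per-window variances stay comparable. Window bp bounds are
#' the first and last member positions.
#'
#' @param map a \code{\link{snp_map}}
#' @param size window size in SNPs (default 100)
#' @param step shift in SNPs (default 10)
#' @return data.frame of windows: chrom, first, last (row indices into the
#'   map), start_bp, end_bp, mid_bp, n_loci
#' @export
make_snp_windows <- function(map, size = 100, step = 10) {
  stopifnot(size >= 2, step >= 1, step <= size)
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    if (n < size) return(NULL)
    starts <- seq(1L, n - size + 1L, by = step)
    first <- idx[starts]
    last <- idx[starts + size - 1L]
    data.frame(chrom = ch, first = first, last = last,
               start_bp = map$pos[first], end_bp = map$pos[last],
               n_loci = size, stringsAsFactors = FALSE)
  })
  finish_windows(do.call(rbind, out))
}

#' Sliding windows of fixed physical width
#'
#' Windows are anchored at bp 1, 1+step_bp, ... up to the last mapped SNP
#' of each chromosome and span \code{width_bp} (1-based inclusive).
#' Windows holding fewer than \code{min_loci} SNPs are dropped (and
#' counted in a message): sparse windows produce wild means that the
#' rank bands would have to absorb.
#'
#' @param map a \code{\link{snp_map}}
#' @param width_bp window width (default 1 Mb)
#' @param step_bp shift (default 500 kb)
#' @param min_loci minimum SNPs per retained window (default 10)
#' @return data.frame of windows as in \code{\link{make_snp_windows}}
#' @export
make_physical_windows <- function(map, width_bp = 1e6, step_bp = 5e5,
                                  min_loci = 10) {
  stopifnot(step_bp >= 1, step_bp <= width_bp, min_loci >= 1)
  dropped <- 0L
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    if (!length(pos)) return(NULL)
    anchors <- seq(1, max(pos), by = step_bp)
    ends <- anchors + width_bp - 1
    # member loci form a contiguous index range in the sorted map
    first_rel <- findInterval(anchors - 1, pos) + 1L
    last_rel <- findInterval(ends, pos)
    n_loci <- pmax(0L, last_rel - first_rel + 1L)
    keep <- n_loci >= min_loci
    dropped <<- dropped + sum(!keep)
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, first = idx[first_rel[keep]],
               last = idx[last_rel[keep]],
               start_bp = anchors[keep], end_bp = ends[keep],
               n_loci = n_loci[keep], stringsAsFactors = FALSE)
  })
  if (dropped > 0)
    message(dropped, " window(s) dropped for holding < ", min_loci, " loci")
  finish_windows(do.call(rbind, out))
}

finish_windows <- function(w) {
  if (is.null(w) || nrow(w) == 0)
    return(data.frame(chrom = character(), first = integer(),
                      last = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_loci = integer(),
                      mid_bp = numeric(), stringsAsFactors = FALSE))
  w$mid_bp <- floor((w$start_bp + w$end_bp) / 2)
  rownames(w) <- NULL
  w
}

# window means via cumulative sums over the map-ordered value vector;
# windows index contiguous locus ranges so each mean is two lookups
window_means <- function(values, first, last) {
  ok <- !is.na(values)
  cs <- c(0, cumsum(ifelse(ok, values, 0)))
  cn <- c(0, cumsum(ok))
  s <- cs[last + 1L] - cs[first]
  k <- cn[last + 1L] - cn[first]
  ifelse(k > 0, s / k, NA_real_)
}

#' Summarize a per-locus metric into a window track
#'
#' A window track records, for each window, the arithmetic mean of the
#' metric over its non-missing member loci, plus the deviation of that
#' mean from the genome-wide mean. The genome-wide mean is taken over all
#' non-missing loci (not over windows), so overlapping windows do not
#' multiply-count loci in the baseline. Windows whose members are all
#' missing get a missing mean and are excluded downstream.
#'
#' @param values numeric vector aligned with the map rows
#' @param map the \code{\link{snp_map}} the windows were built from
#' @param windows window data.frame from \code{\link{make_snp_windows}} or
#'   \code{\link{make_physical_windows}}
#' @param metric metric name carried in the track (for reports)
#' @param group group context label (default "all")
#' @return object of class \code{window_track}: list with \code{windows},
#'   \code{window_mean}, \code{genome_mean}, \code{deviation},
#'   \code{metric}, \code{group}
#' @export
windowize <- function(values, map, windows, metric = "metric",
                      group = "all") {
  if (length(values) != nrow(map))
    stop("'values' must align with the map (", nrow(map), " loci)")
  if (nrow(windows) && max(windows$last) > nrow(map))
    stop("windows reference loci beyond the map; rebuild windows")
  wm <- if (nrow(windows)) window_means(values, windows$first, windows$last)
        else numeric(0)
  gm <- mean(values, na.rm = TRUE)
  structure(list(windows = windows, window_mean = wm, genome_mean = gm,
                 deviation = wm - gm, metric = metric, group = group),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("Window track '%s' (group %s): %d windows on %d chromosome(s)\n",
              x$metric, x$group, nrow(x$windows),
              length(unique(x$windows$chrom))))
  cat(sprintf("genome mean %.4g; deviation range [%.4g, %.4g]\n",
              x$genome_mean, suppressWarnings(min(x$deviation, na.rm = TRUE)),
              suppressWarnings(max(x$deviation, na.rm = TRUE))))
  invisible(x)
}

#' Linkage-disequilibrium decay from dosages
#'
#' Pairwise r-squared is the squared Pearson correlation of the two dosage
#' vectors over samples non-missing at both loci (the additive model for
#' unphased dosages). Pairs on different chromosomes, farther apart than
#' \code{max_dist_bp}, with fewer than 3 shared samples, or with zero
#' variance are skipped. Results are averaged in physical-distance bins.
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param map matching \code{\link{snp_map}}
#' @param max_dist_bp maximum pair distance considered
#' @param bin_bp distance bin width (default 10 kb)
#' @return data.frame: bin_midpoint, mean_r2, n_pairs
#' @export
ld_decay <- function(panel, map, max_dist_bp, bin_bp = 1e4) {
  check_aligned(panel, map)
  X <- panel$dosages
  dists <- numeric(0)
  r2s <- numeric(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    pos <- map$pos[idx]
    for (jj in 2:length(idx)) {
      ii <- which(pos[jj] - pos >= 0 & pos[jj] - pos <= max_dist_bp &
                    seq_along(pos) < jj)
      if (!length(ii)) next
      y <- X[, idx[jj]]
      shared <- colSums(!is.na(X[, idx[ii], drop = FALSE]) & !is.na(y))
      r <- suppressWarnings(
        stats::cor(X[, idx[ii], drop = FALSE], y,
                   use = "pairwise.complete.obs"))[, 1]
      keep <- shared >= 3 & !is.na(r)
      if (!any(keep)) next
      dists <- c(dists, (pos[jj] - pos[ii])[keep])
      r2s <- c(r2s, r[keep]^2)
    }
  }
  if (!length(dists))
    return(data.frame(bin_midpoint = numeric(), mean_r2 = numeric(),
                      n_pairs = integer()))
  bin <- pmax(1, ceiling(dists / bin_bp))
  agg <- tapply(r2s, bin, mean)
  cnt <- tapply(r2s, bin, length)
  b <- as.integer(names(agg))
  data.frame(bin_midpoint = (b - 0.5) * bin_bp,
             mean_r2 = as.numeric(agg), n_pairs = as.integer(cnt))
}
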