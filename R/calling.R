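#' Local minima of a deviation sequence
#'
#' Index i is a local minimum within a neighborhood of
#' \code{± neighborhood} entries iff \code{values[i]} is finite, strictly
#' smaller than every finite neighbor to its left, and no greater than
#' every finite neighbor to its right. The asymmetric tie rule makes the
#' leftmost entry of a tied run the only qualifying one (a constant
#' sequence has a single minimum, at its first entry). Sequence edges use
#' the truncated neighborhood; non-finite entries are skipped both as
#' candidates and as comparators.
#'
#' @param values numeric vector (a per-chromosome deviation track)
#' @param neighborhood half-width in windows (default 2)
#' @return integer vector of 1-based minima indices
#' @examples
#' find_local_minima(c(-1, -3, -2, -1, -5, -2), neighborhood = 2)  # 2, 5
#' @export
find_local_minima <- function(values, neighborhood = 2) {
  stopifnot(neighborhood >= 1)
  n <- length(values)
  out <- integer(0)
  for (i in seq_len(n)) {
    vi <- values[i]
    if (!is.finite(vi)) next
    lo <- max(1L, i - neighborhood)
    hi <- min(n, i + neighborhood)
    ok <- TRUE
    for (j in lo:hi) {
      if (j == i) next
      vj <- values[j]
      if (!is.finite(vj)) next
      if (if (j < i) vi >= vj else vi > vj) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# mirrored rule for maxima: leftmost of a tied run of maxima qualifies
find_local_maxima <- function(values, neighborhood = 2)
  find_local_minima(-values, neighborhood)

#' Within-group sweep caller
#'
#' Implements the local-minimum / lower-quantile rule on a windowed
#' deviation track, chromosome by chromosome: only windows with negative
#' deviation are eligible; candidate sweep centers are the local minima of
#' the deviation profile (\code{± neighborhood} windows); a candidate is
#' retained when its deviation falls at or below the \code{quantile}
#' quantile of all negative deviations of that chromosome and metric; each
#' retained minimum becomes the interval
#' \code{[mid_bp - extend_bp, mid_bp + extend_bp]}, clipped to the
#' chromosome. When a simultaneous band is supplied, each call is
#' annotated with \code{band_significant} (the band's upper limit at the
#' minimum lies below zero); with \code{require_band = TRUE} that
#' annotation becomes an additional filter.
#'
#' Overlapping calls are not merged here; see \code{\link{merge_regions}}
#' and \code{\link{consensus_regions}}.
#'
#' @param track a \code{\link{windowize}} track of deviations
#' @param band optional per-window band table from
#'   \code{\link{scs_bands_by_chrom}} (aligned with the track's windows)
#' @param quantile lower quantile of negative deviations (default 0.05)
#' @param neighborhood minima neighborhood in windows (default 2)
#' @param extend_bp extension on each side of a minimum (default 1 Mb)
#' @param require_band require the simultaneous upper limit below zero
#' @param chrom_lengths optional named vector for right-clipping
#' @return sweep-region data.frame (possibly empty)
#' @export
call_sweeps <- function(track, band = NULL, quantile = 0.05,
                        neighborhood = 2, extend_bp = 1e6,
                        require_band = FALSE, chrom_lengths = NULL) {
  stopifnot(inherits(track, "window_track"), quantile > 0, quantile < 1)
  w <- track$windows
  if (!is.null(band) && nrow(band) != nrow(w))
    stop("band and track are over different windows")
  rows <- list()
  for (ch in unique(w$chrom)) {
    sel <- which(w$chrom == ch)
    d <- track$deviation[sel]
    neg <- d[is.finite(d) & d < 0]
    if (!length(neg)) next
    thr <- stats::quantile(neg, quantile, names = FALSE)
    mins <- find_local_minima(d, neighborhood)
    mins <- mins[d[mins] < 0 & d[mins] <= thr]
    if (!is.null(band)) {
      up <- band$upper[sel]
      sig <- !is.na(up[mins]) & up[mins] < 0
    } else {
      sig <- rep(NA, length(mins))
    }
    if (require_band) {
      if (is.null(band)) stop("require_band = TRUE but no band supplied")
      keep <- !is.na(sig) & sig
      mins <- mins[keep]
      sig <- sig[keep]
    }
    if (!length(mins)) next
    mid <- w$mid_bp[sel][mins]
    lim <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else Inf
    rows[[ch]] <- data.frame(
      name = sprintf("peak_%s_%d", ch, seq_along(mins)),
      chrom = ch,
      start_bp = pmax(1, mid - extend_bp),
      end_bp = pmin(lim, mid + extend_bp),
      peak_mid_bp = mid,
      metrics = track$metric,
      direction = if (identical(track$group, "all")) "reduced_in_all"
                  else paste0("reduced_in_", track$group),
      provenance = "within_group",
      band_significant = sig,
      stringsAsFactors = FALSE)
  }
  as_regions(do.call(rbind, rows))
}

#' Merge overlapping sweep regions
#'
#' Overlapping (or abutting) regions on the same chromosome are merged
#' into continuous intervals; supporting metric sets and peak positions
#' are unioned, the covered base pairs are preserved, and the result is
#' deterministically ordered by (chromosome, start). Idempotent and
#' invariant to input order.
#'
#' @param regions sweep-region data.frame
#' @return merged sweep-region data.frame
#' @export
merge_regions <- function(regions) {
  regions <- as_regions(regions)
  if (!nrow(regions)) return(regions)
  peaks_of <- function(r) {
    p <- unlist(lapply(seq_len(nrow(r)), function(i) {
      extra <- r$peaks[i]
      c(r$peak_mid_bp[i],
        if (!is.null(extra) && !is.na(extra) && nzchar(extra))
          as.numeric(strsplit(extra, ",")[[1]]))
    }))
    sort(unique(p[is.finite(p)]))
  }
  if (is.null(regions$peaks)) regions$peaks <- ""
  out <- lapply(split(regions, regions$chrom), function(r) {
    ir <- IRanges::IRanges(start = r$start_bp, end = r$end_bp)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    rv <- S4Vectors::mcols(red)$revmap
    do.call(rbind, lapply(seq_along(red), function(i) {
      mem <- r[rv[[i]], , drop = FALSE]
      pk <- peaks_of(mem)
      data.frame(
        name = paste(sort(unique(mem$name)), collapse = "+"),
        chrom = mem$chrom[1],
        start_bp = IRanges::start(red)[i],
        end_bp = IRanges::end(red)[i],
        peak_mid_bp = pk[1],
        metrics = paste(sort(unique(unlist(
          strsplit(mem$metrics, ",")))), collapse = ","),
        direction = paste(sort(unique(mem$direction)), collapse = "+"),
        provenance = paste(sort(unique(mem$provenance)), collapse = "+"),
        band_significant = if (all(is.na(mem$band_significant))) NA
                           else any(mem$band_significant, na.rm = TRUE),
        peaks = paste(pk, collapse = ","),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out$peaks_keep <- out$peaks
  res <- as_regions(out)
  res$peaks <- out$peaks_keep
  res
}

#' Cross-metric consensus of sweep regions
#'
#' Pools the (per metric, already merged) region sets, forms connected
#' overlap components per chromosome, and retains a component iff its
#' member regions come from at least \code{min_metrics} distinct metrics.
#' Retained components are unioned into single intervals with unioned
#' metric sets and peak lists.
#'
#' @param per_metric named list metric -> sweep-region data.frame
#' @param min_metrics minimum distinct supporting metrics (default 2)
#' @return consensus sweep-region data.frame
#' @export
consensus_regions <- function(per_metric, min_metrics = 2) {
  stopifnot(length(per_metric) >= 1)
  pool <- do.call(rbind, lapply(names(per_metric), function(m) {
    r <- as_regions(per_metric[[m]])
    if (nrow(r)) r$metrics <- m
    r
  }))
  pool <- pool[!is.na(pool$start_bp), , drop = FALSE]
  if (is.null(pool) || !nrow(pool)) return(as_regions(NULL))
  merged <- merge_regions(pool)
  n_support <- vapply(strsplit(merged$metrics, ","), function(x)
    length(unique(x)), integer(1))
  out <- merged[n_support >= min_metrics, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group comparative sweep caller
#'
#' Flags regions of elevated differentiation between two groups from
#' windowed tracks of Fst, the observed-heterozygosity difference
#' delta_Ho (A minus B) and the nucleotide-diversity ratio pi_ratio
#' (A over B). Per chromosome and metric, extreme windows are those in the
#' designated 1 percent tail(s): Fst upper tail only; delta_Ho and
#' pi_ratio both tails. Among extreme windows only local extrema
#' (\code{± neighborhood} windows; minima for the low tail, maxima for the
#' high tail, leftmost-of-ties rule) are kept. Extrema from different
#' metrics whose windows are adjacent (index distance <= 1) or physically
#' overlapping are chained into clusters; a cluster supported by at least
#' \code{min_metrics} distinct metrics becomes a region of
#' \code{± extend_bp} around the cluster center (the mean of member
#' window midpoints). The direction is polarized by the tails involved:
#' low delta_Ho / low pi_ratio vote for reduced diversity in group A, the
#' high tails for group B, and a pure-Fst or balanced cluster is reported
#' as elevated differentiation.
#'
#' @param tracks named list of \code{window_track}s over identical
#'   windows; names among \code{"Fst"}, \code{"delta_Ho"},
#'   \code{"pi_ratio"} (a \code{"delta_He"} track is accepted and treated
#'   like delta_Ho)
#' @param quantile tail mass per side (default 0.01)
#' @param neighborhood extremum neighborhood in windows (default 1)
#' @param min_metrics minimum distinct supporting metrics (default 2)
#' @param extend_bp extension around the cluster center (default 1 Mb)
#' @param chrom_lengths optional named vector for right-clipping
#' @param tail_scope quantile thresholds computed from the metric's full
#'   genome-wide window distribution (\code{"genome"}, default) or per
#'   chromosome (\code{"chromosome"}). Local extrema are always evaluated
#'   per chromosome. The genome-wide scope is the more conservative
#'   multiplicity control: a chromosome-wise 1 percent tail flags its
#'   own most extreme windows on every chromosome by construction.
#' @return sweep-region data.frame
#' @export
call_comparative_sweeps <- function(tracks, quantile = 0.01,
                                    neighborhood = 1, min_metrics = 2,
                                    extend_bp = 1e6,
                                    chrom_lengths = NULL,
                                    tail_scope = c("genome", "chromosome")) {
  tail_scope <- match.arg(tail_scope)
  stopifnot(length(tracks) >= 1)
  known_tails <- list(Fst = "high",
                      delta_Ho = c("low", "high"),
                      delta_He = c("low", "high"),
                      pi_ratio = c("low", "high"))
  bad <- setdiff(names(tracks), names(known_tails))
  if (length(bad)) stop("unknown comparative metric(s): ",
                        paste(bad, collapse = ", "))
  w0 <- tracks[[1]]$windows
  for (tr in tracks)
    if (!identical(tr$windows[, c("chrom", "first", "last")],
                   w0[, c("chrom", "first", "last")]))
      stop("comparative tracks are on mismatched windows")

  cand <- list()
  for (m in names(tracks)) {
    tr <- tracks[[m]]
    for (ch in unique(w0$chrom)) {
      sel <- which(w0$chrom == ch)
      v <- tr$window_mean[sel]
      if (all(!is.finite(v))) next
      vq <- if (tail_scope == "genome") tr$window_mean else v
      med <- stats::median(vq, na.rm = TRUE)
      for (tail in known_tails[[m]]) {
        # a tail threshold that does not separate from the bulk (possible
        # for flat or heavily tied tracks) flags nothing
        if (tail == "low") {
          thr <- stats::quantile(vq, quantile, na.rm = TRUE, names = FALSE)
          if (!(thr < med)) next
          ext <- find_local_minima(v, neighborhood)
          ext <- ext[v[ext] <= thr]
        } else {
          thr <- stats::quantile(vq, 1 - quantile, na.rm = TRUE,
                                 names = FALSE)
          if (!(thr > med)) next
          ext <- find_local_maxima(v, neighborhood)
          ext <- ext[v[ext] >= thr]
        }
        if (length(ext))
          cand[[length(cand) + 1L]] <- data.frame(
            metric = m, tail = tail, chrom = ch, widx = ext,
            mid_bp = w0$mid_bp[sel][ext],
            start_bp = w0$start_bp[sel][ext],
            end_bp = w0$end_bp[sel][ext], stringsAsFactors = FALSE)
      }
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(as_regions(NULL))

  rows <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$widx, cc$metric, cc$tail), , drop = FALSE]
    # single-linkage chaining: adjacent window indices or bp overlap
    cluster_id <- integer(nrow(cc))
    cid <- 0L
    for (i in seq_len(nrow(cc))) {
      if (i == 1L) {
        cid <- 1L
      } else {
        prev <- cc[i - 1L, ]
        linked <- (cc$widx[i] - prev$widx) <= 1L ||
          cc$start_bp[i] <= max(cc$end_bp[cluster_id == cid])
        if (!linked) cid <- cid + 1L
      }
      cluster_id[i] <- cid
    }
    for (k in unique(cluster_id)) {
      mem <- cc[cluster_id == k, , drop = FALSE]
      if (length(unique(mem$metric)) < min_metrics) next
      center <- mean(unique(mem$mid_bp))
      a_votes <- sum(mem$metric %in% c("delta_Ho", "delta_He", "pi_ratio") &
                       mem$tail == "low")
      b_votes <- sum(mem$metric %in% c("delta_Ho", "delta_He", "pi_ratio") &
                       mem$tail == "high")
      dir <- if (a_votes > b_votes) "reduced_in_A"
             else if (b_votes > a_votes) "reduced_in_B"
             else "elevated_differentiation"
      lim <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
        chrom_lengths[[ch]] else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("cluster_%s_%d", ch, length(rows) + 1L),
        chrom = ch,
        start_bp = max(1, center - extend_bp),
        end_bp = min(lim, center + extend_bp),
        peak_mid_bp = center,
        metrics = paste(sort(unique(mem$metric)), collapse = ","),
        direction = dir,
        provenance = "comparative",
        band_significant = NA,
        stringsAsFactors = FALSE)
    }
  }
  as_regions(do.call(rbind, rows))
}

#' Assign canonical peak names to regions
#'
#' Names regions \code{Peak <chrom>.<rank>} (within-group provenance) or
#' \code{Peak C<chrom>.<rank>} (comparative), ranking by ascending start
#' position within each chromosome. A leading "Chr"/"chr" prefix on the
#' chromosome id is dropped in the label.
#'
#' @param regions sweep-region data.frame
#' @return the regions with the \code{name} column rewritten
#' @export
name_regions <- function(regions) {
  regions <- regions[order(regions$chrom, regions$start_bp), , drop = FALSE]
  if (!nrow(regions)) return(regions)
  short <- sub("^[Cc]hr", "", regions$chrom)
  pre <- ifelse(grepl("comparative", regions$provenance), "Peak C", "Peak ")
  rank <- stats::ave(seq_len(nrow(regions)),
                     paste(pre, regions$chrom), FUN = seq_along)
  regions$name <- sprintf("%s%s.%d", pre, short, rank)
  rownames(regions) <- NULL
  regions
}
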