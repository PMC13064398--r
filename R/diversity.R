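#' Per-locus diversity statistics from one dosage column
#'
#' For a biallelic locus scored as allele dosage in \code{0..ploidy}:
#' \itemize{
#'   \item \code{p}: alternative-allele frequency, the mean dosage divided
#'     by the ploidy, over non-missing genotypes;
#'   \item \code{Ho}: observed heterozygosity, the fraction of genotypes in
#'     the non-homozygous dosage classes \code{1..ploidy-1};
#'   \item \code{He}: expected heterozygosity \eqn{1 - (p^2 + q^2) = 2pq};
#'   \item \code{pi}: unbiased per-site nucleotide diversity
#'     \eqn{\frac{n}{n-1} 2p(1-p)}, with \code{n} the non-missing genotype
#'     count (undefined for n < 2).
#' }
#' Missing genotypes are excluded from every count. An all-missing column
#' yields an all-NA row that propagates as missing through window means.
#'
#' @param dosages integer vector of dosages (NA allowed)
#' @param ploidy ploidy level (>= 2)
#' @return one-row data.frame with columns p, n, n_het, Ho, He, pi
#' @examples
#' locus_stats(c(0, 4, 0, 4), ploidy = 4)  # Ho 0, He 0.5, pi 2/3
#' @export
locus_stats <- function(dosages, ploidy = 4) {
  stopifnot(ploidy >= 2)
  st <- stats_from_weights(precompute_stats(matrix(dosages, ncol = 1),
                                            ploidy),
                           rep(1, length(dosages)))
  data.frame(p = st$p, n = st$n, n_het = st$n_het, Ho = st$Ho,
             He = st$He, pi = st$pi)
}

# Precompute reusable matrices for weighted column statistics. The
# bootstrap reuses these across replicates: a resample is a vector of
# per-sample multiplicities w, and every per-locus count is then a single
# matrix-vector product.
precompute_stats <- function(X, ploidy) {
  nam <- is.na(X)
  X0 <- X
  X0[nam] <- 0L
  storage.mode(X0) <- "double"
  het <- (X >= 1L & X <= ploidy - 1L)
  het[nam] <- FALSE
  storage.mode(het) <- "double"
  namd <- nam
  storage.mode(namd) <- "double"
  list(X0 = X0, NAm = namd, HET = het, ploidy = ploidy)
}

# Per-locus p/n/Ho/He/pi for a weighting w of the samples (w = 1 gives the
# point estimate; w = resample multiplicities gives a bootstrap replicate).
stats_from_weights <- function(pre, w) {
  wm <- matrix(w, nrow = 1)
  s <- drop(wm %*% pre$X0)
  miss <- drop(wm %*% pre$NAm)
  n <- sum(w) - miss
  n_het <- drop(wm %*% pre$HET)
  p <- ifelse(n > 0, s / (pre$ploidy * n), NA_real_)
  He <- 2 * p * (1 - p)
  Ho <- ifelse(n > 0, n_het / n, NA_real_)
  pi <- ifelse(n >= 2, n / (n - 1) * He, NA_real_)
  list(p = p, n = n, n_het = n_het, Ho = Ho, He = He, pi = pi)
}

#' Per-locus diversity statistics for a panel
#'
#' Vectorized \code{\link{locus_stats}} over all loci, optionally
#' restricted to one sample group (frequencies are always re-estimated
#' within the sample set used).
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param group optional group label; default uses all samples
#' @return data.frame with one row per locus: p, n, n_het, Ho, He, pi
#' @export
diversity_stats <- function(panel, group = NULL) {
  stopifnot(inherits(panel, "dosage_panel"))
  X <- panel$dosages
  if (!is.null(group)) {
    keep <- panel$groups == group
    if (!any(keep)) stop("unknown group label: ", group)
    X <- X[keep, , drop = FALSE]
  }
  st <- stats_from_weights(precompute_stats(X, panel$ploidy),
                           rep(1, nrow(X)))
  out <- data.frame(p = st$p, n = st$n, n_het = st$n_het, Ho = st$Ho,
                    He = st$He, pi = st$pi)
  rownames(out) <- colnames(panel$dosages)
  out
}

#' Between-group comparative metrics per locus
#'
#' For two sample groups A and B computes, per locus, the group-specific
#' frequencies and diversity values plus:
#' \itemize{
#'   \item \code{pi_ratio} \eqn{= \pi_A / \pi_B} (undefined when
#'     \eqn{\pi_B = 0} or missing — never imputed as 0, which would
#'     fabricate extreme ratios);
#'   \item \code{delta_Ho} \eqn{= Ho_A - Ho_B} and \code{delta_He}
#'     \eqn{= He_A - He_B};
#'   \item \code{Fst} \eqn{= (H_T - H_S)/H_T} with
#'     \eqn{H_T = 2\bar p(1-\bar p)}, \eqn{\bar p} the unweighted mean of
#'     the two group frequencies, and \eqn{H_S} the average within-group
#'     expected heterozygosity (unweighted by default). Undefined when
#'     \eqn{H_T = 0} (monomorphic across both groups).
#' }
#'
#' @param panel a \code{\link{dosage_panel}} with at least groups A and B
#' @param group_a,group_b group labels (A is the numerator/first group)
#' @param weighted_hs use sample-size-weighted means for \eqn{\bar p} and
#'   \eqn{H_S} instead of the default unweighted two-group average
#' @return data.frame, one row per locus
#' @examples
#' # two fixed groups: p_A = 0.2, p_B = 0.8 gives Fst = 0.36
#' @export
group_comparison <- function(panel, group_a, group_b, weighted_hs = FALSE) {
  stopifnot(inherits(panel, "dosage_panel"))
  for (g in c(group_a, group_b))
    if (!any(panel$groups == g)) stop("unknown group label: ", g)
  a <- diversity_stats(panel, group_a)
  b <- diversity_stats(panel, group_b)
  if (weighted_hs) {
    wtot <- a$n + b$n
    p_bar <- (a$n * a$p + b$n * b$p) / wtot
    H_S <- (a$n * a$He + b$n * b$He) / wtot
  } else {
    p_bar <- (a$p + b$p) / 2
    H_S <- (a$He + b$He) / 2
  }
  H_T <- 2 * p_bar * (1 - p_bar)
  Fst <- ifelse(!is.na(H_T) & H_T > 0, (H_T - H_S) / H_T, NA_real_)
  pi_ratio <- ifelse(!is.na(b$pi) & b$pi > 0, a$pi / b$pi, NA_real_)
  out <- data.frame(p_A = a$p, p_B = b$p, n_A = a$n, n_B = b$n,
                    Ho_A = a$Ho, Ho_B = b$Ho, He_A = a$He, He_B = b$He,
                    pi_A = a$pi, pi_B = b$pi,
                    pi_ratio = pi_ratio,
                    delta_Ho = a$Ho - b$Ho,
                    delta_He = a$He - b$He,
                    p_bar = p_bar, H_T = H_T, H_S = H_S, Fst = Fst)
  rownames(out) <- colnames(panel$dosages)
  out
}
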