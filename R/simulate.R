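#' Simulation configuration for synthetic tetraploid panels
#'
#' Defines the genome layout, sampling design and ground-truth sweeps of a
#' synthetic dosage panel. Defaults emulate a commercial tetraploid rose
#' panel genotyped on a dense SNP array: seven chromosomes, about 87 SNPs
#' per Mb, two groups of 95 and 190 accessions, and a per-call missing rate
#' just under the conventional 10 percent per-locus filter so the filter is
#' actually exercised.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal)
#' @param snps_per_mb SNP density per Mb
#' @param n_samples_per_group named integer vector, group label -> sample
#'   count
#' @param ploidy ploidy level (default 4)
#' @param base_freq_range ancestral alternative-allele frequencies are
#'   drawn uniformly on this interval
#' @param missing_rate independent per-call missing probability in [0, 0.5)
#' @param sweeps list of \code{\link{truth_sweep}} ground-truth regions
#' @param group_divergence standard deviation of the truncated-normal
#'   jitter added per locus to each group's frequency (kept inside
#'   [0.01, 0.99]); produces nonzero background Fst as in real panels
#' @param seed integer seed; identical seed gives bit-identical output
#' @return list of class \code{sim_config}
#' @seealso \code{\link{simulate_panel}}
#' @export
sim_config <- function(n_chromosomes = 7,
                       chrom_length_bp = 10e6,
                       snps_per_mb = 87,
                       n_samples_per_group = c(cut = 95, garden = 190),
                       ploidy = 4,
                       base_freq_range = c(0.05, 0.95),
                       missing_rate = 0.08,
                       sweeps = list(),
                       group_divergence = 0.05,
                       seed = 1) {
  stopifnot(n_chromosomes >= 1, chrom_length_bp >= 1, snps_per_mb > 0,
            all(n_samples_per_group >= 1), ploidy >= 2,
            length(base_freq_range) == 2,
            base_freq_range[1] > 0, base_freq_range[2] < 1,
            base_freq_range[1] <= base_freq_range[2],
            missing_rate >= 0, missing_rate < 0.5,
            group_divergence >= 0)
  if (is.null(names(n_samples_per_group)))
    names(n_samples_per_group) <- paste0("G", seq_along(n_samples_per_group))
  chroms <- paste0("Chr", seq_len(n_chromosomes))
  for (sw in sweeps) {
    stopifnot(inherits(sw, "truth_sweep"))
    if (!sw$chrom %in% chroms)
      stop("sweep references unknown chromosome: ", sw$chrom)
    if (sw$end_bp > chrom_length_bp)
      stop("sweep ", sw$chrom, ":", sw$start_bp, "-", sw$end_bp,
           " exceeds chromosome length ", chrom_length_bp)
    if (!identical(sw$groups, "all")) {
      unk <- setdiff(sw$groups, names(n_samples_per_group))
      if (length(unk))
        stop("sweep references unknown group(s): ", paste(unk, collapse = ", "))
    }
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 snps_per_mb = snps_per_mb,
                 n_samples_per_group = n_samples_per_group,
                 ploidy = as.integer(ploidy),
                 base_freq_range = base_freq_range,
                 missing_rate = missing_rate,
                 sweeps = sweeps,
                 group_divergence = group_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth sweep specification
#'
#' A sweep is injected by pushing the generating allele frequency of every
#' locus inside the interval toward its nearer boundary (0 or 1) by
#' \code{intensity}: \code{p <- p * (1 - intensity)} for p < 0.5, and
#' symmetrically toward 1 otherwise. Intensity 1 fixes the interval
#' (monomorphic, zero heterozygosity) — the idealized end state of a hard
#' sweep; intermediate intensities model partial sweeps.
#'
#' @param chrom chromosome id (e.g. \code{"Chr3"})
#' @param start_bp,end_bp 1-based inclusive interval bounds
#' @param groups character vector of affected group labels, or \code{"all"}
#' @param intensity fraction in (0, 1]
#' @return list of class \code{truth_sweep}
#' @export
truth_sweep <- function(chrom, start_bp, end_bp, groups = "all",
                        intensity = 0.8) {
  stopifnot(start_bp >= 1, start_bp <= end_bp,
            intensity > 0, intensity <= 1)
  structure(list(chrom = as.character(chrom),
                 start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp),
                 groups = as.character(groups),
                 intensity = intensity),
            class = "truth_sweep")
}

# push a frequency toward a boundary by `intensity`; the boundary is
# chosen from `anchor` (default p itself) so that a sweep shared by
# several groups fixes the same allele in all of them, as a shared
# haplotype sweep would
squeeze_freq <- function(p, intensity, anchor = p) {
  ifelse(anchor < 0.5, p * (1 - intensity), 1 - (1 - p) * (1 - intensity))
}

#' Simulate a tetraploid dosage panel with known sweeps
#'
#' Generates locus positions uniformly per chromosome, draws a base
#' alternative-allele frequency per locus, derives per-group frequencies by
#' adding truncated-normal jitter (scale \code{group_divergence}), applies
#' the ground-truth sweeps to the affected groups' frequencies, and then
#' draws each sample's dosage as Binomial(ploidy, group frequency) — the
#' random-bivalent-pairing idealization appropriate for unphased
#' autotetraploid array calls. Missing calls are placed independently at
#' \code{missing_rate}. Everything is driven by \code{config$seed}, so the
#' same configuration reproduces the identical panel bit for bit.
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{panel} (\code{\link{dosage_panel}}),
#'   \code{map} (\code{\link{snp_map}}), \code{truth} (list of
#'   \code{truth_sweep}), \code{truth_freqs} (loci x groups matrix of the
#'   generating frequencies — the analytic oracle for expected diversity),
#'   and \code{chrom_lengths} (named vector).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
#'                   n_samples_per_group = c(a = 20, b = 20), seed = 7)
#' sim <- simulate_panel(cfg)
#' dim(sim$panel$dosages)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("Chr", seq_len(config$n_chromosomes))
  n_per_chr <- max(2L, round(config$snps_per_mb *
                               config$chrom_length_bp / 1e6))

  pos_list <- lapply(chroms, function(ch) {
    p <- sort(as.integer(ceiling(runif(n_per_chr, 0, config$chrom_length_bp))))
    # resolve collisions by +1 shifts; keeps positions strictly increasing
    while (any(d <- duplicated(p))) p[d] <- p[d] + 1L
    sort(p)
  })
  map <- snp_map(locus_id = unlist(lapply(seq_along(chroms), function(i)
                   sprintf("%s_M%05d", chroms[i], seq_along(pos_list[[i]])))),
                 chrom = rep(chroms, lengths(pos_list)),
                 pos = unlist(pos_list), sort = FALSE)
  M <- nrow(map)
  groups <- names(config$n_samples_per_group)

  base_f <- runif(M, config$base_freq_range[1], config$base_freq_range[2])
  freqs <- matrix(NA_real_, nrow = M, ncol = length(groups),
                  dimnames = list(map$locus_id, groups))
  for (g in groups) {
    jit <- stats::rnorm(M, 0, config$group_divergence)
    freqs[, g] <- pmin(0.99, pmax(0.01, base_f + jit))
  }
  for (sw in config$sweeps) {
    in_sw <- map$chrom == sw$chrom & map$pos >= sw$start_bp &
      map$pos <= sw$end_bp
    gs <- if (identical(sw$groups, "all")) groups else sw$groups
    for (g in gs)
      freqs[in_sw, g] <- squeeze_freq(freqs[in_sw, g], sw$intensity,
                                      anchor = base_f[in_sw])
  }

  n_total <- sum(config$n_samples_per_group)
  dos <- matrix(NA_integer_, nrow = n_total, ncol = M)
  sample_ids <- character(n_total)
  grp_of <- character(n_total)
  row0 <- 0L
  for (g in groups) {
    ng <- config$n_samples_per_group[[g]]
    # column-major fill: rep(f, each = ng) aligns frequency with locus column
    dos[row0 + seq_len(ng), ] <-
      matrix(stats::rbinom(ng * M, size = config$ploidy,
                           prob = rep(freqs[, g], each = ng)),
             nrow = ng)
    sample_ids[row0 + seq_len(ng)] <- sprintf("%s_%03d", g, seq_len(ng))
    grp_of[row0 + seq_len(ng)] <- g
    row0 <- row0 + ng
  }
  if (config$missing_rate > 0)
    dos[stats::runif(length(dos)) < config$missing_rate] <- NA_integer_
  dimnames(dos) <- list(sample_ids, map$locus_id)

  panel <- dosage_panel(dos, ploidy = config$ploidy,
                        groups = setNames(grp_of, sample_ids))
  list(panel = panel, map = map, truth = config$sweeps,
       truth_freqs = freqs,
       chrom_lengths = setNames(rep(config$chrom_length_bp,
                                    length(chroms)), chroms))
}

#' Simulate a gene annotation table and gene-to-term map
#'
#' Places genes uniformly over the chromosomes covered by a SNP map (gene
#' lengths drawn uniformly between 1 and 10 kb, clipped to the chromosome)
#' and assigns each gene a Poisson number of functional terms drawn from a
#' term universe. Intended as a fixture for the region-annotation and
#' enrichment stages.
#'
#' @param map a \code{\link{snp_map}}; chromosome extents are taken from
#'   the span of mapped SNPs
#' @param n_genes number of genes (>= 1)
#' @param n_terms size of the term universe (>= 1)
#' @param seed integer seed
#' @param mean_terms_per_gene Poisson mean of terms per gene
#' @return list with \code{genes} (data.frame: gene_id, chrom, start_bp,
#'   end_bp) and \code{gene2term} (data.frame: gene_id, term_id)
#' @export
simulate_gene_annotations <- function(map, n_genes, n_terms, seed = 1,
                                      mean_terms_per_gene = 2) {
  stopifnot(n_genes >= 1, n_terms >= 1)
  set.seed(seed)
  spans <- do.call(rbind, lapply(split(map$pos, map$chrom), range))
  chroms <- rownames(spans)
  ch <- sample(chroms, n_genes, replace = TRUE)
  start <- floor(stats::runif(n_genes, spans[ch, 1], spans[ch, 2]))
  len <- pmax(1, floor(stats::runif(n_genes, 1e3, 1e4)))
  end <- pmin(start + len, spans[ch, 2])
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                      chrom = ch, start_bp = as.numeric(start),
                      end_bp = as.numeric(end), stringsAsFactors = FALSE)
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  k <- pmin(stats::rpois(n_genes, mean_terms_per_gene), n_terms)
  g2t <- data.frame(
    gene_id = rep(genes$gene_id, k),
    term_id = unlist(lapply(k, function(ki)
      if (ki == 0) character(0) else sample(terms, ki))),
    stringsAsFactors = FALSE)
  rownames(g2t) <- NULL
  list(genes = genes, gene2term = g2t)
}
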