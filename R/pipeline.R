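#' Genome-wide sweep scan of a dosage panel
#'
#' Runs the full within-group scan and, when two group labels are given,
#' the two-group comparative scan, on one window scheme: missingness
#' filter, per-locus diversity metrics, window tracks of deviations from
#' the genome-wide mean, optional accession bootstrap with per-chromosome
#' simultaneous rank bands, the local-minimum/quantile sweep caller per
#' metric, merging, and the cross-metric consensus.
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param map matching \code{\link{snp_map}}
#' @param metrics within-group metrics to scan (subset of Ho, He, pi)
#' @param scheme \code{"snp"} (100-SNP windows stepped by 10) or
#'   \code{"physical"} (1 Mb stepped by 500 kb)
#' @param snp_size,snp_step SNP-window parameters
#' @param width_bp,step_bp,min_loci physical-window parameters
#' @param max_missing per-locus missing-fraction filter (default 0.10)
#' @param B bootstrap replicates; \code{B = 0} skips the bootstrap stage
#' @param alpha joint miscoverage of the simultaneous bands
#' @param seed seed for the bootstrap resampling
#' @param quantile,neighborhood,extend_bp,min_metrics,require_band
#'   within-group caller parameters (see \code{\link{call_sweeps}} and
#'   \code{\link{consensus_regions}})
#' @param compare_groups optional character vector of two group labels
#'   (A, B) for the comparative caller; \code{NULL} skips it
#' @param comp_quantile,comp_neighborhood,comp_min_metrics comparative
#'   caller parameters (see \code{\link{call_comparative_sweeps}})
#' @param chrom_lengths optional named chromosome lengths for clipping
#' @return object of class \code{sweep_scan}; see Details
#' @details The returned object contains \code{tracks}, \code{bands} and
#'   merged \code{regions_by_metric} per metric, the \code{consensus}
#'   region set, and (when requested) \code{comparative} tracks and
#'   regions. \code{print}, \code{summary} and \code{plot} methods are
#'   provided.
#' @export
sweep_scan <- function(panel, map,
                       metrics = c("Ho", "He", "pi"),
                       scheme = c("snp", "physical"),
                       snp_size = 100, snp_step = 10,
                       width_bp = 1e6, step_bp = 5e5, min_loci = 10,
                       max_missing = 0.10,
                       B = 1000, alpha = 0.05, seed = 1,
                       quantile = 0.05, neighborhood = 2,
                       extend_bp = 1e6, min_metrics = 2,
                       require_band = FALSE,
                       compare_groups = NULL,
                       comp_quantile = 0.01, comp_neighborhood = 1,
                       comp_min_metrics = 2,
                       chrom_lengths = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(all(metrics %in% c("Ho", "He", "pi")))
  flt <- filter_missingness(panel, map, max_missing = max_missing)
  panel <- flt$panel
  map <- flt$map
  windows <- if (scheme == "snp")
    make_snp_windows(map, size = snp_size, step = snp_step)
  else
    make_physical_windows(map, width_bp = width_bp, step_bp = step_bp,
                          min_loci = min_loci)
  if (!nrow(windows))
    stop("window stage: no windows could be built from ", nrow(map),
         " loci")

  stats <- diversity_stats(panel)
  tracks <- lapply(setNames(metrics, metrics), function(m)
    windowize(stats[[m]], map, windows, metric = m, group = "all"))

  bands <- NULL
  if (B > 0) {
    btr <- bootstrap_deviations_multi(panel, map, windows,
                                      metrics = metrics, B = B,
                                      seed = seed)
    bands <- lapply(btr, scs_bands_by_chrom, alpha = alpha)
  }

  regions_by_metric <- lapply(setNames(metrics, metrics), function(m)
    merge_regions(call_sweeps(tracks[[m]], band = bands[[m]],
                              quantile = quantile,
                              neighborhood = neighborhood,
                              extend_bp = extend_bp,
                              require_band = require_band,
                              chrom_lengths = chrom_lengths)))
  consensus <- name_regions(consensus_regions(regions_by_metric,
                                              min_metrics = min_metrics))

  comparative <- NULL
  if (!is.null(compare_groups)) {
    stopifnot(length(compare_groups) == 2)
    gc <- group_comparison(panel, compare_groups[1], compare_groups[2])
    ctracks <- lapply(setNames(c("Fst", "delta_Ho", "pi_ratio"),
                               c("Fst", "delta_Ho", "pi_ratio")),
                      function(m)
                        windowize(gc[[m]], map, windows, metric = m,
                                  group = paste(compare_groups,
                                                collapse = "_vs_")))
    cregions <- name_regions(merge_regions(
      call_comparative_sweeps(ctracks, quantile = comp_quantile,
                              neighborhood = comp_neighborhood,
                              min_metrics = comp_min_metrics,
                              extend_bp = extend_bp,
                              chrom_lengths = chrom_lengths)))
    comparative <- list(groups = compare_groups, per_locus = gc,
                        tracks = ctracks, regions = cregions)
  }

  structure(list(
    n_samples = nrow(panel$dosages), n_loci = nrow(map),
    n_loci_removed = flt$n_removed, scheme = scheme, windows = windows,
    map = map, tracks = tracks, bands = bands,
    regions_by_metric = regions_by_metric, consensus = consensus,
    comparative = comparative,
    params = list(metrics = metrics, snp_size = snp_size,
                  snp_step = snp_step, width_bp = width_bp,
                  step_bp = step_bp, min_loci = min_loci,
                  max_missing = max_missing, B = B, alpha = alpha,
                  seed = seed, quantile = quantile,
                  neighborhood = neighborhood, extend_bp = extend_bp,
                  min_metrics = min_metrics, require_band = require_band,
                  comp_quantile = comp_quantile,
                  comp_neighborhood = comp_neighborhood,
                  comp_min_metrics = comp_min_metrics)),
    class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("Sweep scan (%s windows): %d samples, %d loci (%d removed by missingness filter)\n",
              x$scheme, x$n_samples, x$n_loci, x$n_loci_removed))
  cat(sprintf("%d windows on %d chromosome(s); metrics: %s\n",
              nrow(x$windows), length(unique(x$windows$chrom)),
              paste(x$params$metrics, collapse = ", ")))
  if (!is.null(x$bands))
    cat(sprintf("simultaneous bands: B = %d, alpha = %.3g\n",
                x$params$B, x$params$alpha))
  cat(sprintf("consensus sweep regions (>= %d metrics): %d\n",
              x$params$min_metrics, nrow(x$consensus)))
  if (!is.null(x$comparative))
    cat(sprintf("comparative regions (%s vs %s): %d\n",
                x$comparative$groups[1], x$comparative$groups[2],
                nrow(x$comparative$regions)))
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  print(object)
  if (nrow(object$consensus)) {
    cat("\nConsensus regions:\n")
    print(object$consensus[, c("name", "chrom", "start_bp", "end_bp",
                               "peak_mid_bp", "metrics",
                               "band_significant")])
  }
  if (!is.null(object$comparative) && nrow(object$comparative$regions)) {
    cat("\nComparative regions:\n")
    print(object$comparative$regions[, c("name", "chrom", "start_bp",
                                         "end_bp", "metrics",
                                         "direction")])
  }
  invisible(object)
}

#' Plot a deviation track with its band and called regions
#'
#' Base-graphics view of one metric on one chromosome: the windowed
#' deviation from the genome-wide mean (line), the simultaneous band
#' (shaded), the zero line, and the consensus sweep regions (shaded
#' vertical strips).
#'
#' @param x a \code{sweep_scan}
#' @param metric metric to show (default first scanned)
#' @param chromosome chromosome id (default first)
#' @param ... passed to \code{plot}
#' @export
plot.sweep_scan <- function(x, metric = x$params$metrics[1],
                            chromosome = x$windows$chrom[1], ...) {
  tr <- x$tracks[[metric]]
  sel <- which(tr$windows$chrom == chromosome)
  if (!length(sel)) stop("no windows on chromosome ", chromosome)
  mb <- tr$windows$mid_bp[sel] / 1e6
  d <- tr$deviation[sel]
  band <- if (!is.null(x$bands)) x$bands[[metric]][sel, ] else NULL
  ylim <- range(c(d, band$lower, band$upper), na.rm = TRUE)
  plot(mb, d, type = "n", xlab = sprintf("%s position (Mb)", chromosome),
       ylab = sprintf("deviation of window mean %s", metric),
       ylim = ylim, ...)
  reg <- x$consensus[x$consensus$chrom == chromosome, , drop = FALSE]
  if (nrow(reg))
    graphics::rect(reg$start_bp / 1e6, ylim[1], reg$end_bp / 1e6, ylim[2],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  if (!is.null(band)) {
    ok <- stats::complete.cases(band[, c("lower", "upper")])
    graphics::polygon(c(mb[ok], rev(mb[ok])),
                      c(band$lower[ok], rev(band$upper[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::abline(h = 0, lty = 2)
  graphics::lines(mb, d, lwd = 1.5)
  invisible(x)
}

#' Config-driven full pipeline run
#'
#' Executes the stages filter, metrics, windows, bootstrap/bands, callers,
#' consensus and annotation in order, from either simulated or on-disk
#' inputs, and writes region tables (TSV + BED), window-track and band
#' tables, the resolved configuration, and a stage log into the output
#' directory. Reruns with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config a named list or path to a YAML file. Recognized blocks:
#'   \code{input} (dosage_tsv, groups_tsv, gene_table, gene2term),
#'   \code{simulate} (arguments of \code{\link{sim_config}}, plus a
#'   \code{sweeps} list of truth_sweep argument lists), \code{schemes}
#'   (subset of "snp", "physical"), plus the scalar parameters of
#'   \code{\link{sweep_scan}} (seed, B, alpha, quantile, ...).
#' @param outdir output directory (created if needed); \code{NULL} skips
#'   file output
#' @return named list of \code{\link{sweep_scan}} objects, one per window
#'   scheme, with an \code{annotation} attribute when gene data were given
#' @export
run_scan <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  logf <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[polysweep] ", msg)
    logf <<- c(logf, msg)
  }

  seed <- config$seed
  if (is.null(seed) && !is.null(config$simulate$seed))
    seed <- config$simulate$seed
  if (is.null(seed)) stop("config stage: 'seed' is mandatory")

  genes <- NULL; g2t <- NULL; chrom_lengths <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sweeps <- lapply(sim_args$sweeps, function(s) do.call(truth_sweep, s))
    sim_args$sweeps <- sweeps
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    if (!is.null(sim_args$n_samples_per_group))
      sim_args$n_samples_per_group <- unlist(sim_args$n_samples_per_group)
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_panel(cfg)
    panel <- sim$panel; map <- sim$map
    chrom_lengths <- sim$chrom_lengths; truth <- sim$truth
    say("simulate: %d samples x %d loci on %d chromosomes",
        nrow(panel$dosages), nrow(map), cfg$n_chromosomes)
    if (isTRUE(config$simulate_annotations)) {
      ann <- simulate_gene_annotations(map,
                                       n_genes = config$n_genes %||% 500,
                                       n_terms = config$n_terms %||% 50,
                                       seed = seed)
      genes <- ann$genes; g2t <- ann$gene2term
    }
  } else if (!is.null(config$input)) {
    io <- read_dosage_tsv(config$input$dosage_tsv,
                          ploidy = config$input$ploidy)
    panel <- io$panel; map <- io$map
    if (!is.null(config$input$groups_tsv)) {
      panel <- set_groups(panel, read_groups_tsv(config$input$groups_tsv))
    } else {
      say("no groups file: all samples in one group, comparative stage will be skipped")
    }
    if (!is.null(config$input$gene_table))
      genes <- read_gene_table(config$input$gene_table)
    if (!is.null(config$input$gene2term))
      g2t <- read_gene2term_tsv(config$input$gene2term)
    say("input: %d samples x %d loci", nrow(panel$dosages), nrow(map))
  } else stop("config stage: need an 'input' or 'simulate' block")

  grps <- unique(panel$groups)
  compare_groups <- config$compare_groups
  if (is.null(compare_groups) && length(grps) == 2) compare_groups <- grps
  if (!is.null(compare_groups)) compare_groups <- unlist(compare_groups)
  if (length(grps) < 2) {
    say("fewer than two groups: comparative stage skipped")
    compare_groups <- NULL
  }

  schemes <- config$schemes %||% c("snp", "physical")
  arg <- function(name, default)
    if (!is.null(config[[name]])) config[[name]] else default
  results <- lapply(setNames(schemes, schemes), function(sc) {
    res <- sweep_scan(panel, map, scheme = sc,
                      metrics = unlist(arg("metrics", c("Ho", "He", "pi"))),
                      snp_size = arg("snp_size", 100),
                      snp_step = arg("snp_step", 10),
                      width_bp = arg("width_bp", 1e6),
                      step_bp = arg("step_bp", 5e5),
                      min_loci = arg("min_loci", 10),
                      max_missing = arg("max_missing", 0.10),
                      B = arg("B", 1000), alpha = arg("alpha", 0.05),
                      seed = seed,
                      quantile = arg("quantile", 0.05),
                      neighborhood = arg("neighborhood", 2),
                      extend_bp = arg("extend_bp", 1e6),
                      min_metrics = arg("min_metrics", 2),
                      require_band = isTRUE(config$require_band),
                      compare_groups = compare_groups,
                      comp_quantile = arg("comp_quantile", 0.01),
                      comp_neighborhood = arg("comp_neighborhood", 1),
                      comp_min_metrics = arg("comp_min_metrics", 2),
                      chrom_lengths = chrom_lengths)
    say("%s windows: %d loci removed, %d windows, %d consensus region(s)%s",
        sc, res$n_loci_removed, nrow(res$windows), nrow(res$consensus),
        if (!is.null(res$comparative))
          sprintf(", %d comparative region(s)",
                  nrow(res$comparative$regions)) else "")
    res
  })

  annotation <- NULL
  if (!is.null(genes) && !is.null(g2t)) {
    annotation <- lapply(results, function(res) {
      regs <- rbind(res$consensus,
                    if (!is.null(res$comparative)) res$comparative$regions)
      annotate_regions(as_regions(regs), genes, g2t)
    })
    say("annotation: %d genes, %d terms", nrow(genes),
        length(unique(g2t$term_id)))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (sc in names(results)) {
      res <- results[[sc]]
      write_regions(res$consensus,
                    file.path(outdir, paste0("regions_", sc, ".tsv")))
      write_regions(res$consensus,
                    file.path(outdir, paste0("regions_", sc, ".bed")),
                    dialect = "bed")
      if (!is.null(res$comparative))
        write_regions(res$comparative$regions,
                      file.path(outdir,
                                paste0("regions_comparative_", sc, ".tsv")))
      for (m in names(res$tracks)) {
        tr <- res$tracks[[m]]
        tab <- cbind(tr$windows,
                     window_mean = tr$window_mean,
                     genome_mean = tr$genome_mean,
                     deviation = tr$deviation)
        if (!is.null(res$bands))
          tab <- cbind(tab, lower = res$bands[[m]]$lower,
                       upper = res$bands[[m]]$upper)
        utils::write.table(tab,
                           file.path(outdir,
                                     sprintf("track_%s_%s.tsv", m, sc)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    cfg_out <- config
    cfg_out$seed <- seed
    cfg_out$version <- as.character(utils::packageVersion("polysweep"))
    yaml::write_yaml(cfg_out, file.path(outdir, "resolved_config.yaml"))
    writeLines(logf, file.path(outdir, "run.log"))
    say("outputs written to %s", outdir)
  }

  attr(results, "annotation") <- annotation
  attr(results, "truth") <- truth
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a
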