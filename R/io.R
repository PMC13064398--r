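#' Read a dosage TSV
#'
#' The interchange format is a tab-separated file with header
#' \code{marker_id chrom pos <sample1> ... <sampleN>}; one row per locus,
#' dosage cells integer or the literal \code{NA}. Loci are sorted by
#' (chromosome, position) on read; unsorted input is accepted with a
#' message.
#'
#' @param path file path
#' @param ploidy ploidy override; default infers the maximum observed
#'   dosage (at least 2)
#' @return list with \code{panel} (a \code{\link{dosage_panel}} with all
#'   samples in group \code{"all"}) and \code{map} (a \code{\link{snp_map}})
#' @export
read_dosage_tsv <- function(path, ploidy = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("marker_id", "chrom", "pos")
  if (!identical(colnames(df)[1:3], need))
    stop("dosage TSV must start with columns: ", paste(need, collapse = ", "))
  if (ncol(df) < 4) stop("dosage TSV has no sample columns")
  if (anyDuplicated(df$marker_id))
    stop("duplicated marker_id: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]),
               collapse = ", "))
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) stop("non-integer position in 'pos' column")
  samples <- colnames(df)[-(1:3)]
  cells <- as.matrix(df[, -(1:3), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & cells != "NA")
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(cells))
    stop(sprintf("non-integer dosage '%s' at marker '%s', sample '%s'",
                 cells[bad[1L]], df$marker_id[idx[1L]], samples[idx[2L]]))
  }
  if (any(num[!is.na(num)] != round(num[!is.na(num)]))) {
    bad <- which(!is.na(num) & num != round(num))
    idx <- arrayInd(bad[1L], dim(cells))
    stop(sprintf("non-integer dosage '%s' at marker '%s', sample '%s'",
                 cells[bad[1L]], df$marker_id[idx[1L]], samples[idx[2L]]))
  }
  ord <- order(df$chrom, pos)
  if (!identical(ord, seq_len(nrow(df))))
    message("input loci not sorted by (chrom, pos); sorting")
  dos <- t(num[ord, , drop = FALSE])
  dimnames(dos) <- list(samples, df$marker_id[ord])
  map <- snp_map(df$marker_id[ord], df$chrom[ord], pos[ord], sort = FALSE)
  panel <- dosage_panel(dos, ploidy = ploidy)
  list(panel = panel, map = map)
}

#' Write a dosage TSV
#'
#' Inverse of \code{\link{read_dosage_tsv}}; missing dosages are written as
#' the literal \code{NA}.
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param map matching \code{\link{snp_map}}
#' @param path output path
#' @export
write_dosage_tsv <- function(panel, map, path) {
  check_aligned(panel, map)
  df <- data.frame(marker_id = map$locus_id, chrom = map$chrom,
                   pos = map$pos, t(panel$dosages),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group table
#'
#' Two-column TSV \code{sample_id<TAB>group}, with or without a header
#' line. Samples in the panel but absent from the file raise an error.
#'
#' @param path file path
#' @return named character vector sample id -> group
#' @export
read_groups_tsv <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("groups TSV needs two columns: sample_id, group")
  if (identical(tolower(df[1, 1]), "sample_id")) df <- df[-1, , drop = FALSE]
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Attach group labels to a panel
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param groups named character vector as from \code{\link{read_groups_tsv}}
#' @return the panel with groups replaced
#' @export
set_groups <- function(panel, groups) {
  dosage_panel(panel$dosages, ploidy = panel$ploidy, groups = groups)
}

#' Drop loci exceeding a missing-data threshold
#'
#' Removes loci whose missing fraction is strictly greater than
#' \code{max_missing} (so a locus missing in exactly 10 percent of samples
#' survives the default threshold). The sample set is unchanged and the
#' operation is idempotent.
#'
#' @param panel a \code{\link{dosage_panel}}
#' @param map matching \code{\link{snp_map}}
#' @param max_missing maximum tolerated missing fraction (default 0.10)
#' @param per_group if TRUE, a locus is removed when its missing fraction
#'   exceeds the threshold in any single group rather than panel-wide
#' @return list with filtered \code{panel}, \code{map}, and
#'   \code{n_removed}
#' @export
filter_missingness <- function(panel, map, max_missing = 0.10,
                               per_group = FALSE) {
  stopifnot(max_missing >= 0, max_missing < 1)
  check_aligned(panel, map)
  na_mat <- is.na(panel$dosages)
  if (per_group) {
    fracs <- do.call(rbind, lapply(unique(panel$groups), function(g)
      colMeans(na_mat[panel$groups == g, , drop = FALSE])))
    frac <- apply(fracs, 2, max)
  } else {
    frac <- colMeans(na_mat)
  }
  keep <- frac <= max_missing
  list(panel = dosage_panel(panel$dosages[, keep, drop = FALSE],
                            ploidy = panel$ploidy,
                            groups = setNames(panel$groups,
                                              rownames(panel$dosages))),
       map = {
         m <- map[keep, , drop = FALSE]
         rownames(m) <- NULL
         m
       },
       n_removed = sum(!keep))
}

#' Write sweep regions to BED or TSV
#'
#' The TSV dialect keeps the internal 1-based inclusive coordinates plus
#' peak position, supporting metrics, direction and provenance, and
#' round-trips losslessly via \code{\link{read_regions_tsv}}. The BED
#' dialect converts to 0-based half-open coordinates
#' (\code{start_bp - 1}, \code{end_bp}) at the write boundary.
#'
#' @param regions a sweep-region data.frame as produced by the callers
#' @param path output path
#' @param dialect \code{"tsv"} (default) or \code{"bed"}
#' @export
write_regions <- function(regions, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  regions <- as_regions(regions)
  if (dialect == "bed") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("track name=sweep_regions description=",
                      "\"1-based inclusive converted to BED half-open\""),
               con)
    if (nrow(regions))
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.",
                         regions$chrom,
                         as.integer(regions$start_bp) - 1L,
                         as.integer(regions$end_bp),
                         regions$name), con)
  } else {
    utils::write.table(regions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a sweep-region TSV written by \code{\link{write_regions}}
#'
#' @param path file path
#' @return sweep-region data.frame
#' @export
read_regions_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_regions(df)
}

# canonical sweep-region data.frame: fixed column set + types
region_cols <- c("name", "chrom", "start_bp", "end_bp", "peak_mid_bp",
                 "metrics", "direction", "provenance", "band_significant")

as_regions <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    df <- data.frame(name = character(), chrom = character(),
                     start_bp = numeric(), end_bp = numeric(),
                     peak_mid_bp = numeric(), metrics = character(),
                     direction = character(), provenance = character(),
                     band_significant = logical(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in region_cols)
    if (is.null(df[[col]]))
      df[[col]] <- switch(col,
                          name = sprintf("region_%d", seq_len(nrow(df))),
                          metrics = "", direction = "unknown",
                          provenance = "unknown",
                          band_significant = NA, NA)
  df <- df[, region_cols]
  df$start_bp <- as.numeric(df$start_bp)
  df$end_bp <- as.numeric(df$end_bp)
  df$peak_mid_bp <- as.numeric(df$peak_mid_bp)
  df$band_significant <- as.logical(df$band_significant)
  stopifnot(all(df$start_bp <= df$end_bp))
  rownames(df) <- NULL
  df
}

#' Read a gene table from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive coordinates on read; GFF3 input keeps only \code{gene}
#' features. Both go through \pkg{rtracklayer}.
#'
#' @param path file path ending in .bed, .gff, .gff3 or .gff.gz etc.
#' @param format override the format guess ("bed" or "gff3")
#' @return data.frame with columns gene_id, chrom, start_bp, end_bp
#' @export
read_gene_table <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3" && "type" %in% colnames(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = as.numeric(GenomicRanges::start(gr)),
             end_bp = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-term map
#'
#' Two-column TSV \code{gene_id<TAB>term_id}, one association per line,
#' optional header.
#'
#' @param path file path
#' @return data.frame with columns gene_id, term_id
#' @export
read_gene2term_tsv <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene2term TSV needs two columns: gene_id, term_id")
  if (identical(tolower(df[1, 1]), "gene_id")) df <- df[-1, , drop = FALSE]
  data.frame(gene_id = as.character(df[[1]]),
             term_id = as.character(df[[2]]), stringsAsFactors = FALSE)
}

#' Read dosages from a VCF
#'
#' Optional ingest path: uses FORMAT/DS (posterior dosage, rounded to the
#' nearest integer) when present, otherwise counts alternative alleles in
#' GT. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file
#' @param ploidy ploidy override (default inferred)
#' @return list with \code{panel} and \code{map} as
#'   \code{\link{read_dosage_tsv}}
#' @export
read_dosage_vcf <- function(path, ploidy = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- round(ds)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == ".")) return(NA_real_)
      sum(a != "0")
    })
  }
  ids <- v@fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids <- sprintf("%s_%s", v@fix[, "CHROM"], v@fix[, "POS"])
  rownames(dos) <- ids
  map <- snp_map(ids, v@fix[, "CHROM"], as.integer(v@fix[, "POS"]))
  dos <- t(dos)[, map$locus_id, drop = FALSE]
  list(panel = dosage_panel(dos, ploidy = ploidy), map = map)
}
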