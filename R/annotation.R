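#' Genes overlapping sweep regions
#'
#' A gene is assigned to a region iff their 1-based inclusive intervals
#' overlap by at least one bp (a gene ending exactly where a region starts
#' is inside). A gene may hit several regions. Chromosomes present in the
#' regions but absent from the gene table produce a warning and empty hit
#' lists.
#'
#' @param genes gene table data.frame (gene_id, chrom, start_bp, end_bp)
#' @param regions sweep-region data.frame
#' @return named list region name -> character vector of gene ids
#' @export
genes_in_regions <- function(genes, regions) {
  regions <- as_regions(regions)
  out <- setNames(rep(list(character(0)), nrow(regions)), regions$name)
  if (!nrow(regions)) return(out)
  missing_ch <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_ch))
    warning("chromosome(s) in regions but not in gene table: ",
            paste(missing_ch, collapse = ", "))
  if (!nrow(genes)) return(out)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start_bp, genes$end_bp))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start_bp, regions$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_reg, gr_genes))
  for (i in unique(S4Vectors::queryHits(hits)))
    out[[i]] <- genes$gene_id[
      S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
  out
}

#' Term over-representation in a sweep gene set
#'
#' One-sided Fisher exact test (over-representation) of each term among
#' the sweep genes against the genome-wide background, with
#' Benjamini-Hochberg correction across the terms tested for the region.
#' Terms with no sweep-gene member are skipped. Fold enrichment is
#' \code{(k/K)/(m/M)} with k/K the term count and size of the sweep set
#' and m/M the same for the background.
#'
#' @param sweep_genes character vector of gene ids in the region(s); must
#'   be a subset of the background
#' @param background_genes character vector of all gene ids considered
#' @param gene2term data.frame (gene_id, term_id)
#' @return data.frame sorted by adjusted p: term_id, k, K, m, M,
#'   fold_enrichment, p_value, p_adjusted
#' @export
fisher_enrichment <- function(sweep_genes, background_genes, gene2term) {
  background_genes <- unique(background_genes)
  sweep_genes <- unique(sweep_genes)
  if (!length(background_genes)) stop("empty background gene set")
  extra <- setdiff(sweep_genes, background_genes)
  if (length(extra))
    stop("sweep genes not in background: ", paste(extra, collapse = ", "))
  g2t <- unique(gene2term[gene2term$gene_id %in% background_genes,
                          c("gene_id", "term_id")])
  K <- length(sweep_genes)
  M <- length(background_genes)
  empty <- data.frame(term_id = character(), k = integer(), K = integer(),
                      m = integer(), M = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE)
  if (!nrow(g2t) || K == 0) return(empty)
  m_all <- table(g2t$term_id)
  k_all <- table(g2t$term_id[g2t$gene_id %in% sweep_genes])
  terms <- names(k_all)[k_all > 0]
  if (!length(terms)) return(empty)
  res <- do.call(rbind, lapply(terms, function(t) {
    k <- as.integer(k_all[[t]])
    m <- as.integer(m_all[[t]])
    p <- stats::fisher.test(
      matrix(c(k, K - k, m - k, (M - K) - (m - k)), nrow = 2),
      alternative = "greater")$p.value
    data.frame(term_id = t, k = k, K = K, m = m, M = M,
               fold_enrichment = (k / K) / (m / M), p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_adjusted, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate sweep regions with genes and term enrichment
#'
#' Convenience wrapper: finds the genes in each region and runs the
#' enrichment test per region (BH correction within each region's tested
#' terms, as the per-region dotplots imply).
#'
#' @param regions sweep-region data.frame
#' @param genes gene table
#' @param gene2term gene-to-term map
#' @return list with \code{genes_by_region} and \code{enrichment} (named
#'   list of per-region result tables)
#' @export
annotate_regions <- function(regions, genes, gene2term) {
  gby <- genes_in_regions(genes, regions)
  enr <- lapply(gby, function(g)
    if (length(g)) fisher_enrichment(g, genes$gene_id, gene2term)
    else NULL)
  list(genes_by_region = gby, enrichment = enr)
}
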