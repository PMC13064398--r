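#' Construct a dosage panel
#'
#' A dosage panel holds integer allele-dosage calls for a set of accessions
#' (samples) at biallelic loci, together with the ploidy and a group label
#' per sample. Dosages count copies of the alternative allele, so they lie
#' in \code{0..ploidy}; \code{NA} marks a failed call and is distinct from
#' dosage 0 throughout the package.
#'
#' @param dosages integer matrix, samples in rows and loci in columns;
#'   rownames are sample ids, colnames are locus ids. \code{NA} allowed.
#' @param ploidy integer ploidy level (4 for autotetraploids). If
#'   \code{NULL}, inferred as the maximum observed dosage (at least 2).
#' @param groups named character vector mapping sample id to group label;
#'   \code{NULL} assigns every sample to group \code{"all"}.
#' @return object of class \code{dosage_panel}: a list with elements
#'   \code{dosages}, \code{ploidy}, \code{groups}.
#' @examples
#' d <- matrix(c(0L, 4L, 2L, 1L, NA, 3L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
#' p <- dosage_panel(d, ploidy = 4)
#' p$ploidy
#' @export
dosage_panel <- function(dosages, ploidy = NULL, groups = NULL) {
  if (!is.matrix(dosages)) stop("'dosages' must be a matrix")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("L", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]),
               collapse = ", "))
  storage.mode(dosages) <- "integer"
  if (is.null(ploidy)) ploidy <- max(2L, max(dosages, na.rm = TRUE))
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L) stop("'ploidy' must be >= 2")
  bad <- which(!is.na(dosages) & (dosages < 0L | dosages > ploidy))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(dosages))
    stop(sprintf(
      "dosage %d outside 0..%d at sample '%s', locus '%s'",
      dosages[bad[1L]], ploidy, rownames(dosages)[i[1L]],
      colnames(dosages)[i[2L]]))
  }
  if (is.null(groups)) {
    groups <- setNames(rep("all", nrow(dosages)), rownames(dosages))
  } else {
    if (is.null(names(groups))) stop("'groups' must be named by sample id")
    missing_g <- setdiff(rownames(dosages), names(groups))
    if (length(missing_g))
      stop("samples without a group label: ",
           paste(missing_g, collapse = ", "))
    groups <- groups[rownames(dosages)]
  }
  structure(list(dosages = dosages, ploidy = ploidy,
                 groups = as.character(setNames(groups, rownames(dosages)))),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("Dosage panel: %d samples x %d loci, ploidy %d\n",
              nrow(x$dosages), ncol(x$dosages), x$ploidy))
  tab <- table(x$groups)
  cat("Groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("Missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

#' Subset a panel to one sample group
#'
#' @param panel a \code{dosage_panel}
#' @param group group label present in \code{panel$groups}
#' @return a \code{dosage_panel} containing only that group's samples
#' @export
subset_group <- function(panel, group) {
  stopifnot(inherits(panel, "dosage_panel"))
  keep <- panel$groups == group
  if (!any(keep)) stop("unknown group label: ", group)
  dosage_panel(panel$dosages[keep, , drop = FALSE], ploidy = panel$ploidy,
               groups = setNames(panel$groups[keep],
                                 rownames(panel$dosages)[keep]))
}

#' Construct / validate a SNP map
#'
#' The SNP map gives, for each locus column of a panel, its chromosome and
#' 1-based physical position. Loci must be sorted by (chromosome, position)
#' with strictly increasing positions within a chromosome; window
#' construction relies on this ordering.
#'
#' @param locus_id character vector of unique locus ids
#' @param chrom chromosome identifier per locus
#' @param pos 1-based bp position per locus
#' @param sort sort loci by (chromosome, position) first (default TRUE)
#' @return data.frame of class \code{snp_map} with columns
#'   \code{locus_id}, \code{chrom}, \code{pos}
#' @export
snp_map <- function(locus_id, chrom, pos, sort = TRUE) {
  map <- data.frame(locus_id = as.character(locus_id),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$locus_id))
    stop("duplicate locus ids: ",
         paste(unique(map$locus_id[duplicated(map$locus_id)]), collapse = ", "))
  if (sort) map <- map[order(map$chrom, map$pos), , drop = FALSE]
  rownames(map) <- NULL
  by_chr <- split(map$pos, map$chrom)
  for (ch in names(by_chr)) {
    if (any(diff(by_chr[[ch]]) <= 0L))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  class(map) <- c("snp_map", "data.frame")
  map
}

# internal: check panel columns and map rows line up
check_aligned <- function(panel, map) {
  if (ncol(panel$dosages) != nrow(map))
    stop("panel has ", ncol(panel$dosages), " loci but map has ",
         nrow(map), " rows")
  if (!identical(colnames(panel$dosages), map$locus_id))
    stop("panel locus ids and map locus ids differ")
  invisible(TRUE)
}
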