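#' Paired site-by-cell allele count matrices
#'
#' The central data container of the pipeline: a table of biallelic SNV sites
#' together with two parallel non-negative integer matrices holding, for every
#' site (row) and cell (column), the number of reads supporting the reference
#' and the alternate allele. A site-cell element with zero reads in both
#' matrices is a dropout: the site was simply not observed in that cell.
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based), and the
#'   single-base columns `ref_allele`, `alt_allele`; an optional `annotation`
#'   column is carried along. Sites must be unique by (chrom, pos).
#' @param cells Character vector of unique cell barcodes.
#' @param ref Integer matrix, `nrow(sites)` x `length(cells)`, reference reads.
#' @param alt Integer matrix of the same shape, alternate reads.
#'
#' @return An object of class `cell_counts`: a list with elements `sites`
#'   (tibble), `cells`, `ref`, `alt`. Matrix dimnames are set to site ids
#'   (`"chrom:pos"`) and barcodes.
#' @export
#' @examples
#' sites <- data.frame(chrom = "1", pos = c(100, 200),
#'                     ref_allele = "A", alt_allele = "G")
#' cc <- cell_counts(sites, c("c1", "c2"),
#'                   ref = matrix(c(3, 0, 1, 2), 2, 2),
#'                   alt = matrix(0L, 2, 2))
#' cc
cell_counts <- function(sites, cells, ref, alt) {
  sites <- validate_sites(sites)
  cells <- as.character(cells)
  if (anyDuplicated(cells))
    stop("duplicate cell barcodes: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  storage.mode(ref) <- "double"
  storage.mode(alt) <- "double"
  if (!all(dim(ref) == c(nrow(sites), length(cells))) ||
      !all(dim(alt) == c(nrow(sites), length(cells))))
    stop("count matrices must be |sites| x |cells| (",
         nrow(sites), " x ", length(cells), ")")
  if (anyNA(ref) || anyNA(alt) || any(ref < 0) || any(alt < 0))
    stop("allele counts must be non-negative and non-missing")
  ids <- site_ids(sites)
  dimnames(ref) <- dimnames(alt) <- list(ids, cells)
  structure(list(sites = sites, cells = cells, ref = ref, alt = alt),
            class = "cell_counts")
}

validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"annotation" %in% names(sites)) sites$annotation <- NA_character_
  sites <- sites[c(need, "annotation")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("site positions must be >= 1 (1-based)")
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref_allele %in% bases) || !all(sites$alt_allele %in% bases))
    stop("alleles must be single bases A/C/G/T (biallelic SNVs only)")
  bad <- sites$ref_allele == sites$alt_allele
  if (any(bad))
    stop("ref and alt allele identical at ", site_ids(sites)[bad][1])
  dup <- duplicated(sites[c("chrom", "pos")])
  if (any(dup))
    stop("duplicated site(s): ", paste(site_ids(sites)[dup], collapse = ", "))
  sites
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("<cell_counts> ", nrow(x$sites), " sites x ", length(x$cells),
      " cells; sparsity ", sprintf("%.1f%%", 100 * sparsity(x)), "\n", sep = "")
  invisible(x)
}

#' Site identifiers
#'
#' @param x A `cell_counts` object or a site table.
#' @return Character vector `"chrom:pos"`.
#' @export
site_ids <- function(x) {
  s <- if (inherits(x, "cell_counts")) x$sites else x
  paste0(s$chrom, ":", s$pos)
}

#' Total reads per element, and matrix sparsity
#'
#' `total_reads()` returns the element-wise sum of reference and alternate
#' reads; `sparsity()` the fraction of elements with zero reads (dropout).
#'
#' @param x A `cell_counts` object.
#' @return A matrix, or a single number in \[0, 1\].
#' @export
total_reads <- function(x) {
  stopifnot(inherits(x, "cell_counts"))
  x$ref + x$alt
}

#' @rdname total_reads
#' @export
sparsity <- function(x) {
  tot <- total_reads(x)
  mean(tot == 0)
}

#' Subset a count container by site and/or cell
#'
#' @param x A `cell_counts` object.
#' @param sites,cells Logical, integer or character index into sites / cells.
#' @return A `cell_counts` with the selected rows/columns.
#' @export
subset_counts <- function(x, sites = NULL, cells = NULL) {
  stopifnot(inherits(x, "cell_counts"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  if (is.character(si)) si <- match(si, site_ids(x))
  ci <- if (is.null(cells)) seq_along(x$cells) else cells
  if (is.character(ci)) ci <- match(ci, x$cells)
  cell_counts(x$sites[si, , drop = FALSE], x$cells[ci],
              x$ref[si, ci, drop = FALSE], x$alt[si, ci, drop = FALSE])
}

#' Long-format view of a count container
#'
#' @param x A `cell_counts` object.
#' @param drop_zero Drop dropout elements (the default keeps the table small).
#' @param ... Unused.
#' @return A tibble with columns chrom, pos, cell, ref_count, alt_count.
#' @export
tidy.cell_counts <- function(x, drop_zero = TRUE, ...) {
  tot <- total_reads(x)
  keep <- if (drop_zero) which(tot > 0) else seq_along(tot)
  idx <- arrayInd(keep, dim(tot))
  tibble::tibble(
    chrom = x$sites$chrom[idx[, 1]],
    pos = x$sites$pos[idx[, 1]],
    cell = x$cells[idx[, 2]],
    ref_count = x$ref[keep],
    alt_count = x$alt[keep]
  )
}
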