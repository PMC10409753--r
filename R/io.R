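#' Read biallelic SNV sites from a VCF file
#'
#' Adapter for the upstream pseudobulk variant-calling step: variant sites are
#' discovered externally (e.g. with the GATK RNA-Seq pipeline on a pooled
#' pseudobulk sample) and consumed here as a VCF. Only biallelic single
#' nucleotide variants are retained; indels and multi-allelic records are
#' skipped with a message reporting how many were dropped.
#'
#' @param path Path to a VCF 4.x file (uncompressed or bgzipped).
#' @return A tibble of sites with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `annotation` (the VCF ID field where present), in file
#'   order.
#' @export
read_variant_sites <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(validate_sites(tibble::tibble(
      chrom = character(), pos = integer(),
      ref_allele = character(), alt_allele = character())))
  bases <- c("A", "C", "G", "T")
  snv <- fix$REF %in% bases & fix$ALT %in% bases
  n_skip <- sum(!snv)
  if (n_skip > 0)
    message("read_variant_sites: skipped ", n_skip,
            " non-SNV/multi-allelic record(s)")
  fix <- fix[snv, , drop = FALSE]
  bad <- which(fix$REF == fix$ALT)
  if (length(bad))
    stop("VCF record with REF == ALT at ", fix$CHROM[bad[1]], ":",
         fix$POS[bad[1]])
  validate_sites(tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    annotation = ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)
  ))
}

#' Read allele counts from a long-format TSV
#'
#' One row per observed (site, cell) element with columns
#' `chrom`, `pos`, `cell`, `ref_count`, `alt_count` (optionally also
#' `ref_allele`/`alt_allele`). Elements absent from the file are dropout and
#' become 0/0. Site alleles come either from the file's allele columns or
#' from a site table (e.g. [read_variant_sites()]).
#'
#' @param path Path to the TSV.
#' @param sites Optional site table giving alleles and the site universe; when
#'   supplied, rows of the TSV at unlisted sites are an error.
#' @param cells Optional barcode vector fixing the cell universe and order.
#' @return A [cell_counts] object.
#' @export
read_counts_long <- function(path, sites = NULL, cells = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c", cell = "c"))
  need <- c("chrom", "pos", "cell", "ref_count", "alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("long-format counts lack column(s): ", paste(miss, collapse = ", "))
  if (any(tab$ref_count < 0 | tab$alt_count < 0))
    stop("negative read count in ", path)
  key <- paste0(tab$chrom, ":", tab$pos)
  dup <- duplicated(paste(key, tab$cell, sep = "@"))
  if (any(dup))
    stop("duplicate row for (", key[dup][1], ", ", tab$cell[dup][1], ")")
  if (is.null(sites)) {
    if (!all(c("ref_allele", "alt_allele") %in% names(tab)))
      stop("supply `sites` or include ref_allele/alt_allele columns")
    sites <- tab[!duplicated(key), c("chrom", "pos", "ref_allele", "alt_allele")]
    sites <- sites[order(match(unique(key), key)), ]
  }
  sites <- validate_sites(sites)
  ids <- site_ids(sites)
  if (!all(key %in% ids))
    stop("counts reference site(s) absent from the site table: ",
         paste(utils::head(setdiff(key, ids), 3), collapse = ", "))
  if (is.null(cells)) cells <- sort(unique(tab$cell))
  if (!all(tab$cell %in% cells))
    stop("counts reference unknown cell barcode(s)")
  ref <- matrix(0, nrow(sites), length(cells), dimnames = list(ids, cells))
  alt <- ref
  i <- cbind(match(key, ids), match(tab$cell, cells))
  ref[i] <- tab$ref_count
  alt[i] <- tab$alt_count
  cell_counts(sites, cells, ref, alt)
}

#' Write allele counts as a long-format TSV
#'
#' @param x A [cell_counts] object.
#' @param path Output path.
#' @param drop_zero Omit dropout elements (default).
#' @return `path`, invisibly.
#' @export
write_counts_long <- function(x, path, drop_zero = TRUE) {
  tab <- tidy(x, drop_zero = drop_zero)
  al <- x$sites[match(paste0(tab$chrom, ":", tab$pos), site_ids(x)), ]
  tab$ref_allele <- al$ref_allele
  tab$alt_allele <- al$alt_allele
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read / write allele counts in sparse-triplet form
#'
#' The triplet layout of a directory `dir` is the scRNA-seq convention of two
#' MatrixMarket files plus sidecar tables: `ref.mtx` and `alt.mtx` (sites x
#' cells), `sites.tsv` (chrom, pos, ref_allele, alt_allele) and
#' `barcodes.tsv` (one barcode per line).
#'
#' @param dir Directory holding (or to hold) the four files.
#' @param x A [cell_counts] object (writer only).
#' @return `read_counts_triplet()` a [cell_counts]; `write_counts_triplet()`
#'   `dir`, invisibly.
#' @export
read_counts_triplet <- function(dir) {
  ref <- as.matrix(Matrix::readMM(file.path(dir, "ref.mtx")))
  alt <- as.matrix(Matrix::readMM(file.path(dir, "alt.mtx")))
  sites <- readr::read_tsv(file.path(dir, "sites.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(chrom = "c"))
  cells <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  cell_counts(sites, cells, ref, alt)
}

#' @rdname read_counts_triplet
#' @export
write_counts_triplet <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$ref, sparse = TRUE),
                  file.path(dir, "ref.mtx"))
  Matrix::writeMM(Matrix::Matrix(x$alt, sparse = TRUE),
                  file.path(dir, "alt.mtx"))
  readr::write_tsv(x$sites, file.path(dir, "sites.tsv"))
  readr::write_lines(x$cells, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read and write rooted trees in Newick format
#'
#' Thin wrappers around \pkg{ape} that enforce the invariants downstream
#' statistics rely on: a single rooted tree, labelled tips, and non-negative
#' branch lengths.
#'
#' @param path Newick file path.
#' @param tree An \pkg{ape} `phylo` object.
#' @return `read_tree()` a `phylo`; `write_tree()` `path`, invisibly.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tree)) stop("could not parse a tree from ", path)
  check_tree(tree)
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  check_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("tree has unlabeled tip(s)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels")
  if (is.null(tree$edge.length))
    stop("tree lacks branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)")
  invisible(tree)
}

#' Read per-cell traits or group labels from a TSV
#'
#' @param path TSV with a `cell` column plus one column per trait.
#' @return A tibble; duplicate barcodes are an error, numeric traits must be
#'   finite.
#' @export
read_traits <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(cell = "c"))
  if (!"cell" %in% names(tab)) stop("trait table lacks a `cell` column")
  if (anyDuplicated(tab$cell))
    stop("duplicate cell barcode(s) in trait table")
  num <- vapply(tab, is.numeric, logical(1))
  for (j in names(tab)[num])
    if (any(!is.finite(tab[[j]])))
      stop("non-finite values in numeric trait `", j, "`")
  tab
}

#' Write genotype calls as a long TSV
#'
#' @param calls A genotype call matrix (see [call_genotypes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(calls, path) {
  tab <- tibble::tibble(
    site = rep(rownames(calls), times = ncol(calls)),
    cell = rep(colnames(calls), each = nrow(calls)),
    call = as.vector(calls)
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
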