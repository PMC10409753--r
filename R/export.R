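#' Encode genotype calls as nucleotide sequences
#'
#' Converts a sites x cells genotype call matrix into one sequence per cell,
#' one column per site: `R` becomes the site's reference allele, `A` the
#' alternate allele, and `H` a surrogate base distinct from both, so the
#' three genotype states stay distinguishable to a nucleotide substitution
#' model. The surrogate is the first base in the fixed order A, C, G, T that
#' is neither the reference nor the alternate, which makes the encoding
#' deterministic and reproducible. `MISSING` encodes as `N`.
#'
#' @param calls Character matrix over R/H/A/MISSING (sites x cells).
#' @param sites Site table aligned with the rows of `calls`.
#' @return A named character vector of equal-length sequences, one per cell.
#' @export
#' @examples
#' sites <- data.frame(chrom = "1", pos = 1:2,
#'                     ref_allele = c("A", "C"), alt_allele = c("G", "A"))
#' calls <- matrix(c("R", "H", "A", "MISSING"), 2, 2,
#'                 dimnames = list(NULL, c("c1", "c2")))
#' encode_alignment(calls, sites)
encode_alignment <- function(calls, sites) {
  sites <- validate_sites(sites)
  if (nrow(calls) != nrow(sites))
    stop("calls (", nrow(calls), " rows) do not match sites (",
         nrow(sites), ")")
  het <- surrogate_base(sites$ref_allele, sites$alt_allele)
  enc <- matrix(NA_character_, nrow(calls), ncol(calls))
  enc[calls == "R"] <- sites$ref_allele[row(calls)[calls == "R"]]
  enc[calls == "A"] <- sites$alt_allele[row(calls)[calls == "A"]]
  enc[calls == "H"] <- het[row(calls)[calls == "H"]]
  enc[calls == "MISSING"] <- "N"
  if (anyNA(enc)) stop("calls contain states other than R/H/A/MISSING")
  seqs <- apply(enc, 2, paste, collapse = "")
  names(seqs) <- colnames(calls)
  seqs
}

# first base in fixed A < C < G < T order not used by the site
surrogate_base <- function(ref, alt) {
  vapply(seq_along(ref), function(i)
    setdiff(c("A", "C", "G", "T"), c(ref[i], alt[i]))[1], character(1))
}

#' Write an encoded alignment to FASTA or NEXUS
#'
#' @param alignment Named character vector from [encode_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  check_alignment(alignment)
  x <- Biostrings::DNAStringSet(alignment)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_nexus <- function(alignment, path) {
  check_alignment(alignment)
  mat <- t(vapply(alignment, function(s) strsplit(s, "")[[1]],
                  character(nchar(alignment[1]))))
  ape::write.nexus.data(mat, file = path, interleaved = FALSE)
  invisible(path)
}

check_alignment <- function(alignment) {
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment records must carry unique cell barcodes")
  if (length(unique(nchar(alignment))) > 1)
    stop("alignment sequences differ in length")
  invisible(alignment)
}

#' Read an alignment back from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Pairwise Hamming distances between encoded cells
#'
#' The distance between two sequences is the fraction of differing columns
#' among the columns where neither sequence is `N`. A pair with no
#' comparable columns gets `NA` with a warning.
#'
#' @param alignment Named character vector from [encode_alignment()].
#' @return Symmetric cells x cells numeric matrix with zero diagonal.
#' @export
hamming_distance_matrix <- function(alignment) {
  check_alignment(alignment)
  n <- length(alignment)
  L <- nchar(alignment[1])
  chars <- matrix(unlist(strsplit(alignment, "")), nrow = L)
  colnames(chars) <- names(alignment)
  ok <- chars != "N"
  storage.mode(ok) <- "double"
  comparable <- crossprod(ok)
  same <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- chars == b
    storage.mode(ind) <- "double"
    same <- same + crossprod(ind)
  }
  d <- 1 - same / comparable
  d[comparable == 0] <- NA_real_
  if (anyNA(d))
    warning("some cell pairs share no comparable (non-N) columns; ",
            "their distances are undefined (NA)")
  diag(d) <- 0
  dimnames(d) <- list(names(alignment), names(alignment))
  d
}

#' Neighbour-joining fallback tree
#'
#' Builds a rooted tree from a distance matrix by neighbour joining, clamping
#' any negative branch lengths to zero and rooting at the midpoint. This is a
#' deterministic desk-scale stand-in for Bayesian tree inference: it lets the
#' whole pipeline and its downstream statistics run self-contained, but it is
#' not a posterior summary and its branch lengths are not calibrated
#' evolutionary times.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal (at
#'   least 3 taxa).
#' @return A rooted \pkg{ape} `phylo` with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour joining needs at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree <- phangorn::midpoint(tree)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Record the intended Bayesian model settings for an exported alignment
#'
#' External tree inference consumes the FASTA/NEXUS written by this package;
#' this sidecar JSON documents the model configuration those runs are
#' expected to use (relaxed log-normal clock, GTR site model, Yule tree
#' prior, long MCMC chain), plus the seed and the package version, so the
#' provenance of any downstream tree is recoverable.
#'
#' @param path Output JSON path.
#' @param n_cells,n_sites Alignment dimensions.
#' @param seed RNG seed used upstream.
#' @param chain_length Recorded MCMC chain length (default 1e8).
#' @return `path`, invisibly.
#' @export
write_model_sidecar <- function(path, n_cells, n_sites, seed = NA,
                                chain_length = 1e8) {
  info <- list(
    clock_model = "relaxed log-normal",
    site_model = "GTR",
    tree_prior = "Yule",
    chain_length = chain_length,
    n_cells = n_cells,
    n_sites = n_sites,
    seed = seed,
    package = as.character(utils::packageVersion("cellphylo"))
  )
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
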