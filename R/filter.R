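#' Filtering parameter bundles
#'
#' Returns the threshold set used by the site/cell filters. Three presets are
#' provided: `"default"`; `"lenient"` for poorly covered data (per-site read
#' floor 5 instead of 10, monomorphic cut 0.80 instead of 0.90); and
#' `"subclone"` for detecting small subpopulations (monomorphic cut 0.95, so
#' sites fixed in up to 95% of cells survive).
#'
#' @param preset One of `"default"`, `"lenient"`, `"subclone"`.
#' @param ... Named overrides of individual thresholds.
#' @return A list with elements `min_cell_reads` (reads per cell, 10000),
#'   `min_pseudobulk_reads` (20), `min_alt_reads` (5), `min_vaf` (0.05),
#'   `min_site_reads` (total reads per site across cells, 10),
#'   `monomorphic_frac` (0.90), `allowed_chroms` (autosomes 1-22),
#'   `min_spacing_nt` (5), `max_sites` (1000).
#' @export
filter_params <- function(preset = c("default", "lenient", "subclone"), ...) {
  preset <- match.arg(preset)
  p <- list(
    min_cell_reads = 10000,
    min_pseudobulk_reads = 20,
    min_alt_reads = 5,
    min_vaf = 0.05,
    min_site_reads = 10,
    monomorphic_frac = 0.90,
    allowed_chroms = as.character(1:22),
    min_spacing_nt = 5,
    max_sites = 1000
  )
  if (preset == "lenient") {
    p$min_site_reads <- 5
    p$monomorphic_frac <- 0.80
  } else if (preset == "subclone") {
    p$monomorphic_frac <- 0.95
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown filter parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$monomorphic_frac > 0, p$monomorphic_frac < 1, p$max_sites >= 1)
  p
}

#' Remove low-coverage cells
#'
#' Cells whose total reads (reference + alternate, summed over all sites)
#' fall below `min_cell_reads` are discarded; the site list is unchanged.
#' The boundary is literal "less than": a cell with exactly the threshold is
#' kept.
#'
#' @param counts A [cell_counts] object.
#' @param min_cell_reads Minimum total reads per cell (default 10000).
#' @return A filtered [cell_counts].
#' @export
filter_cells <- function(counts, min_cell_reads = 10000) {
  stopifnot(inherits(counts, "cell_counts"))
  keep <- colSums(total_reads(counts)) >= min_cell_reads
  if (!any(keep))
    stop("all cells fall below min_cell_reads = ", min_cell_reads,
         "; review the threshold for this data set")
  subset_counts(counts, cells = which(keep))
}

#' Candidate-variant support filter on pseudobulk totals
#'
#' Applied to the pooled (pseudobulk) read counts per site: a site is a
#' credible variant only if it is supported by at least
#' `min_pseudobulk_reads` total reads across all cells, with at least
#' `min_alt_reads` alternate reads making up at least `min_vaf` of the total.
#'
#' @param counts A [cell_counts] object.
#' @param params A [filter_params()] list (or individual values via `...`).
#' @param ... Overrides passed to [filter_params()] when `params` is missing.
#' @return A filtered [cell_counts].
#' @export
filter_candidate_variants <- function(counts, params = filter_params(), ...) {
  if (length(list(...))) params <- filter_params(...)
  tot <- rowSums(total_reads(counts))
  alt <- rowSums(counts$alt)
  keep <- tot >= params$min_pseudobulk_reads &
    alt >= params$min_alt_reads &
    alt >= params$min_vaf * tot
  subset_counts(counts, sites = which(keep))
}

#' Coarse site-quality filters
#'
#' Removes, in order: (1) sites with fewer than `min_site_reads` total reads
#' across cells; (2) monomorphic sites, where strictly more than
#' `monomorphic_frac` of the covered cells share one called genotype
#' (dropout cells are excluded from both numerator and denominator);
#' (3) sites outside the allowed chromosomes (autosomes 1-22 by default;
#' "chr"-prefixed names are normalized); (4) every member of any pair of
#' sites on the same chromosome within `min_spacing_nt` nucleotides of each
#' other.
#'
#' @param counts A [cell_counts] object.
#' @param calls Unsmoothed genotype calls on the same counts
#'   ([call_unsmoothed()]); smoothing happens after this filter.
#' @param params A [filter_params()] list.
#' @return A filtered [cell_counts]. Erroring when nothing survives.
#' @export
coarse_filter_sites <- function(counts, calls = call_unsmoothed(counts),
                                params = filter_params()) {
  stopifnot(inherits(counts, "cell_counts"))
  if (!all(dim(calls) == dim(counts$ref)))
    stop("`calls` does not match `counts` in shape")
  keep <- rowSums(total_reads(counts)) >= params$min_site_reads
  keep <- keep & !monomorphic_sites(calls, params$monomorphic_frac)
  keep <- keep & normalize_chrom(counts$sites$chrom) %in%
    normalize_chrom(params$allowed_chroms)
  keep <- keep & !proximal_sites(counts$sites, params$min_spacing_nt)
  if (!any(keep))
    stop("no sites survive the coarse filters; review thresholds")
  subset_counts(counts, sites = which(keep))
}

# TRUE for sites where > frac of covered cells share one called genotype
monomorphic_sites <- function(calls, frac) {
  counts_by_g <- vapply(GENOTYPES, function(g) rowSums(calls == g),
                        numeric(nrow(calls)))
  counts_by_g <- matrix(counts_by_g, nrow = nrow(calls))
  covered <- rowSums(counts_by_g)
  top <- apply(counts_by_g, 1, max)
  covered > 0 & top > frac * covered
}

# strip an optional "chr" prefix so "chr1" and "1" compare equal
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

# TRUE for every site within `spacing` nt of another site on the same chrom
proximal_sites <- function(sites, spacing) {
  out <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    if (length(i) < 2) next
    pos <- sort(sites$pos[i])
    close_next <- diff(pos) <= spacing
    flag <- c(close_next, FALSE) | c(FALSE, close_next)
    out[i] <- flag[match(sites$pos[i], pos)]
  }
  out
}

#' Keep the best-covered sites
#'
#' Ranks sites by total reads across cells (descending) and keeps the top
#' `max_sites`; ties at the boundary are resolved by ascending (chrom, pos).
#'
#' @param counts A [cell_counts] object.
#' @param max_sites Site cap (default 1000).
#' @return A [cell_counts] with at most `max_sites` sites, in rank order.
#' @export
select_top_sites <- function(counts, max_sites = 1000) {
  stopifnot(inherits(counts, "cell_counts"), max_sites >= 1)
  tot <- rowSums(total_reads(counts))
  ord <- order(-tot, chrom_rank(counts$sites$chrom), counts$sites$pos)
  keep <- ord[seq_len(min(max_sites, length(ord)))]
  subset_counts(counts, sites = keep)
}

# numeric-aware chromosome ordering: 1 < 2 < ... < 22 < X < Y < other
chrom_rank <- function(chrom) {
  ch <- normalize_chrom(chrom)
  num <- suppressWarnings(as.numeric(ch))
  rank <- ifelse(!is.na(num), num, 100 + as.integer(factor(ch)))
  rank
}

#' Run the published filtering and smoothing order end-to-end
#'
#' Composes the stages in their canonical order: candidate-variant support
#' filter on pseudobulk totals, low-coverage cell removal, coarse site
#' filters on unsmoothed calls, kNN smoothing, and finally the top-N site
#' selection by coverage.
#'
#' @param counts A [cell_counts] object.
#' @param params A [filter_params()] list.
#' @param theta,k,delta,n_samplings,seed Passed to [smooth_genotypes()].
#' @param apply_cell_filter Set `FALSE` to skip the per-cell read floor
#'   (useful for simulated data scaled below real sequencing depth).
#' @return A list with `counts` (filtered), `smoothed` (the
#'   [smooth_genotypes()] result on the coarse-filtered site set), `calls`
#'   (smoothed calls restricted to the selected sites), `sites` (final site
#'   table), and `log` (per-stage dimensions).
#' @export
run_pipeline <- function(counts, params = filter_params(), theta = 0.3,
                         k = 10, delta = k / (k + 1), n_samplings = 100,
                         seed = 1L, apply_cell_filter = TRUE) {
  log <- list(input = dim(counts$ref))
  x <- filter_candidate_variants(counts, params)
  log$candidate <- dim(x$ref)
  if (apply_cell_filter) {
    x <- filter_cells(x, params$min_cell_reads)
    log$cells <- dim(x$ref)
  }
  x <- coarse_filter_sites(x, call_unsmoothed(x, theta), params)
  log$coarse <- dim(x$ref)
  sm <- smooth_genotypes(x, theta = theta, k = k, delta = delta,
                         n_samplings = n_samplings, seed = seed)
  top <- select_top_sites(x, params$max_sites)
  log$top <- dim(top$ref)
  sel <- match(site_ids(top), site_ids(x))
  list(counts = top,
       smoothed = sm,
       calls = sm$calls[sel, , drop = FALSE],
       sites = top$sites,
       log = log)
}
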