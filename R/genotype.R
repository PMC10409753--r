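#' Beta-binomial genotype probabilities
#'
#' For a site-cell element with `r` reference and `a` alternate reads, the
#' alternate-allele frequency p is modelled as Beta(a + 1, r + 1) — the
#' posterior under a uniform prior with the alternate reads as Bernoulli
#' successes. The three genotypes partition the frequency axis with a noise
#' threshold `theta`: reads from a homozygous-reference genotype have
#' alternate-allele frequency below `theta`, a homozygous-alternate genotype
#' above `1 - theta`, and a heterozygous genotype in between. So
#' \deqn{P(R) = I_\theta(a+1, r+1), \quad P(A) = 1 - I_{1-\theta}(a+1, r+1),}
#' with the remaining mass on H, where I is the regularized incomplete beta
#' function. A dropout element (0/0 reads) has the uniform Beta(1,1) density,
#' giving the prior (theta, 1 - 2 theta, theta).
#'
#' @param counts A [cell_counts] object.
#' @param theta Noise threshold in (0, 0.5); default 0.3.
#' @return A `genotype_probs` object: a sites x cells x 3 array with genotype
#'   slices `"R"`, `"H"`, `"A"`; every triple sums to 1.
#' @export
#' @examples
#' cc <- cell_counts(data.frame(chrom = "1", pos = 1,
#'                              ref_allele = "A", alt_allele = "G"),
#'                   c("c1", "c2"), ref = matrix(c(0, 5), 1), alt = matrix(c(1, 5), 1))
#' genotype_probabilities(cc)[1, , ]
genotype_probabilities <- function(counts, theta = 0.3) {
  stopifnot(inherits(counts, "cell_counts"))
  check_theta(theta)
  p <- element_probs(counts$ref, counts$alt, theta)
  structure(p, class = "genotype_probs", theta = theta, sites = counts$sites)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) ||
      theta <= 0 || theta >= 0.5)
    stop("theta must lie strictly between 0 and 0.5")
  invisible(theta)
}

# r, a: equally shaped matrices of ref / alt read counts
element_probs <- function(r, a, theta) {
  stopifnot(is.matrix(r), is.matrix(a))
  pR <- stats::pbeta(theta, a + 1, r + 1)
  pA <- stats::pbeta(1 - theta, a + 1, r + 1, lower.tail = FALSE)
  pH <- pmax(1 - pR - pA, 0)
  dn <- dimnames(r)
  if (is.null(dn)) dn <- list(NULL, NULL)
  array(c(pR, pH, pA), dim = c(dim(r), 3L),
        dimnames = c(dn, list(genotype = GENOTYPES)))
}

GENOTYPES <- c("R", "H", "A")

#' @export
print.genotype_probs <- function(x, ...) {
  cat("<genotype_probs> ", dim(x)[1], " sites x ", dim(x)[2],
      " cells (theta = ", attr(x, "theta"), ")\n", sep = "")
  invisible(x)
}

#' Long-format view of genotype probabilities
#'
#' @param x A `genotype_probs` object.
#' @param ... Unused.
#' @return A tibble with columns site, cell, p_ref, p_het, p_alt.
#' @export
tidy.genotype_probs <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    site = rep(dimnames(x)[[1]], times = d[2]),
    cell = rep(dimnames(x)[[2]], each = d[1]),
    p_ref = as.vector(x[, , "R"]),
    p_het = as.vector(x[, , "H"]),
    p_alt = as.vector(x[, , "A"])
  )
}

#' Call discrete genotypes from genotype probabilities
#'
#' Each element is assigned the genotype with the highest probability. Exact
#' ties are broken by the fixed precedence H > R > A: a tie means the reads
#' cannot separate the states, and the heterozygous call is the conservative
#' middle ground.
#'
#' @param probs A `genotype_probs` object (or sites x cells x 3 array).
#' @return A character matrix (sites x cells) over `"R"`, `"H"`, `"A"`.
#' @export
call_genotypes <- function(probs) {
  pr <- unclass(probs)
  pR <- prob_slice(pr, "R")
  pH <- prob_slice(pr, "H")
  pA <- prob_slice(pr, "A")
  # precedence H > R > A on exact ties: a later state must strictly beat the
  # incumbent to displace it
  call <- matrix("H", nrow(pR), ncol(pR), dimnames = dimnames(pR))
  best <- pH
  idx <- pR > best
  call[idx] <- "R"
  best[idx] <- pR[idx]
  call[pA > best] <- "A"
  call
}

prob_slice <- function(pr, g) {
  matrix(pr[, , g], dim(pr)[1], dim(pr)[2], dimnames = dimnames(pr)[1:2])
}

#' Unsmoothed genotype calls with explicit dropout
#'
#' The baseline mode: elements with zero total reads are reported as
#' `"MISSING"` rather than being called from the uniform prior; all covered
#' elements are called exactly as [call_genotypes()] on
#' [genotype_probabilities()].
#'
#' @inheritParams genotype_probabilities
#' @return A character matrix over `"R"`, `"H"`, `"A"`, `"MISSING"`.
#' @export
call_unsmoothed <- function(counts, theta = 0.3) {
  calls <- call_genotypes(genotype_probabilities(counts, theta))
  calls[total_reads(counts) == 0] <- "MISSING"
  calls
}

#' Tabulate genotype changes by coverage bin
#'
#' Mirrors the standard diagnostic for smoothing: elements are stratified by
#' their total read count, and within each stratum the before-to-after
#' genotype transitions are tabulated as percentages of each "before" column.
#'
#' @param before,after Genotype call matrices of identical shape.
#' @param counts The [cell_counts] the calls were derived from (supplies the
#'   per-element total read counts).
#' @param breaks Lower edges of the coverage bins; the default
#'   `c(0, 1, 2, 5)` gives the bins 0 (dropout), 1 (low), 2-4 (medium),
#'   >= 5 (high) reads.
#' @return A tibble with columns `bin`, `before`, `after`, `n`, `pct`; within
#'   every (bin, before) group the `pct` values sum to 100.
#' @export
tabulate_genotype_changes <- function(before, after, counts,
                                      breaks = c(0, 1, 2, 5)) {
  if (!all(dim(before) == dim(after)))
    stop("`before` and `after` call matrices differ in shape")
  if (!all(dim(before) == dim(total_reads(counts))))
    stop("call matrices do not match `counts` in shape")
  tot <- as.vector(total_reads(counts))
  labs <- bin_labels(breaks)
  bin <- labs[findInterval(tot, breaks)]
  tab <- tibble::tibble(
    bin = factor(bin, levels = labs),
    before = as.vector(before),
    after = as.vector(after)
  )
  tab <- dplyr::count(tab, .data$bin, .data$before, .data$after)
  tab |>
    dplyr::group_by(.data$bin, .data$before) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

bin_labels <- function(breaks) {
  up <- c(breaks[-1] - 1, Inf)
  ifelse(breaks == up, as.character(breaks),
         ifelse(is.infinite(up), paste0(breaks, "+"),
                paste0(breaks, "-", up)))
}

#' Fraction of elements whose call changed, by coverage bin
#'
#' @inheritParams tabulate_genotype_changes
#' @return A tibble with columns `bin`, `n`, `changed`, `frac_changed`.
#' @export
genotype_change_rates <- function(before, after, counts,
                                  breaks = c(0, 1, 2, 5)) {
  tab <- tabulate_genotype_changes(before, after, counts, breaks)
  dplyr::summarise(dplyr::group_by(tab, .data$bin),
                   changed = sum(.data$n[.data$before != .data$after]),
                   n = sum(.data$n),
                   frac_changed = changed / n,
                   .groups = "drop")
}
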