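#' Simulation configuration
#'
#' Defaults emulate a well-characterised two-lineage cell-culture setting:
#' 400 cells in two equal clades across 500 candidate sites, with
#' expression-driven uneven coverage and ~65% dropout — the regime of a
#' typical droplet scRNA-seq genotyping matrix after site discovery.
#'
#' @param n_cells,n_sites Matrix dimensions (default 400 x 500).
#' @param n_clades Number of clades (default 2).
#' @param clade_proportions Clade size fractions summing to 1 (default
#'   equal).
#' @param frac_informative_sites Fraction of sites carrying a subclonal
#'   mutation, i.e. whose true genotype differs between clades (default
#'   0.1); the rest are shared germline genotypes.
#' @param mean_coverage Mean reads per site-cell element before sparsity
#'   calibration (default 1).
#' @param coverage_dispersion Negative-binomial size parameter; smaller is
#'   more overdispersed (default 0.5).
#' @param site_sdlog Log-normal sd of per-site mean coverage, emulating
#'   expression-driven variation across sites (default 1).
#' @param seq_error_rate Per-read sequencing error `eps` in \[0, 0.2\]
#'   (default 0.05): a homozygous-reference element yields alternate reads
#'   with probability `eps`, heterozygous with 0.5, homozygous-alternate
#'   with `1 - eps`.
#' @param target_sparsity Desired fraction of zero-read elements (default
#'   0.65); per-site means are rescaled so the expected sparsity matches.
#'   `NA` skips the calibration and uses `mean_coverage` directly (useful
#'   for high-coverage limiting cases, where near-zero sparsity follows).
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 400, n_sites = 500, n_clades = 2,
                       clade_proportions = rep(1 / n_clades, n_clades),
                       frac_informative_sites = 0.1,
                       mean_coverage = 1, coverage_dispersion = 0.5,
                       site_sdlog = 1, seq_error_rate = 0.05,
                       target_sparsity = 0.65, seed = 1L) {
  stopifnot(n_cells >= 2, n_sites >= 1, n_clades >= 1,
            length(clade_proportions) == n_clades)
  if (abs(sum(clade_proportions) - 1) > 1e-9)
    stop("clade_proportions must sum to 1")
  if (frac_informative_sites < 0 || frac_informative_sites > 1)
    stop("frac_informative_sites must lie in [0, 1]")
  if (seq_error_rate < 0 || seq_error_rate > 0.2)
    stop("seq_error_rate must lie in [0, 0.2]")
  if (!is.na(target_sparsity) &&
      (target_sparsity < 0 || target_sparsity >= 1))
    stop("target_sparsity must lie in [0, 1) or be NA")
  structure(list(n_cells = n_cells, n_sites = n_sites, n_clades = n_clades,
                 clade_proportions = clade_proportions,
                 frac_informative_sites = frac_informative_sites,
                 mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 site_sdlog = site_sdlog,
                 seq_error_rate = seq_error_rate,
                 target_sparsity = target_sparsity, seed = seed),
            class = "sim_config")
}

#' Simulate a clade-structured allele count matrix with ground truth
#'
#' Cells are assigned to clades in the configured proportions. Informative
#' sites carry clade-specific genotypes (two distinct genotypes split across
#' the clades); the remaining sites share one genotype in all cells. Total
#' reads per element are negative-binomial with per-site log-normal means
#' (expression-driven uneven coverage), rescaled so the expected zero
#' fraction hits `target_sparsity` — dropout arises from low coverage, not a
#' separate zero-inflation knob. Alternate reads are binomial with success
#' probability `eps`, 0.5, or `1 - eps` for true R/H/A genotypes.
#'
#' The true tree is a balanced clade tree: each clade is a star of its cells
#' (tip branches 1) joined to the root by unit internal branches.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [cell_counts]) and `truth` (list with
#'   `clades` named by cell, `genotypes` sites x cells over R/H/A, `tree`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_cells
  m <- cfg$n_sites
  cells <- sprintf("cell%03d", seq_len(n))
  # deterministic clade sizes in the configured proportions
  cuts <- round(cumsum(cfg$clade_proportions) * n)
  sizes <- diff(c(0, cuts))
  if (any(sizes < 1)) stop("a clade received no cells; enlarge n_cells")
  clades <- rep(paste0("clade", seq_len(cfg$n_clades)), times = sizes)
  names(clades) <- cells

  sites <- tibble::tibble(
    chrom = as.character(sample(1:22, m, replace = TRUE)),
    pos = sample(seq(1e4, 5e7, by = 7), m),
    ref_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE)
  )
  sites$alt_allele <- vapply(sites$ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  sites <- sites[order(chrom_rank(sites$chrom), sites$pos), ]

  # Informative sites model subclonal point mutations: the carrier clade(s)
  # are heterozygous, everyone else homozygous reference. A single read
  # cannot distinguish H from R/A, so clade structure is invisible in
  # unsmoothed calls at low coverage, as in real droplet data.
  informative <- stats::runif(m) < cfg$frac_informative_sites
  geno <- matrix("", m, n, dimnames = list(site_ids(sites), cells))
  shared <- sample(GENOTYPES, m, replace = TRUE, prob = c(0.55, 0.25, 0.20))
  clade_idx <- match(clades, unique(clades))
  for (s in seq_len(m)) {
    if (informative[s] && cfg$n_clades > 1) {
      carrier <- sample(c(TRUE, FALSE), cfg$n_clades, replace = TRUE)
      if (all(carrier) || all(!carrier)) carrier[sample(cfg$n_clades, 1)] <- !carrier[1]
      geno[s, ] <- ifelse(carrier[clade_idx], "H", "R")
    } else {
      geno[s, ] <- shared[s]
    }
  }

  # per-site log-normal means, rescaled so expected sparsity hits the target
  mu_site <- stats::rlnorm(m, meanlog = log(cfg$mean_coverage) -
                             cfg$site_sdlog^2 / 2, sdlog = cfg$site_sdlog)
  size <- cfg$coverage_dispersion
  expected_zero <- function(scale)
    mean((size / (size + scale * mu_site))^size)
  if (is.na(cfg$target_sparsity)) {
    scale <- 1
  } else {
    lo <- 1e-6; hi <- 1e6
    if (cfg$target_sparsity < expected_zero(hi) ||
        cfg$target_sparsity > expected_zero(lo))
      stop(sprintf(
        "target_sparsity %.2f unreachable; achievable range (%.3f, %.3f)",
        cfg$target_sparsity, expected_zero(hi), expected_zero(lo)))
    scale <- stats::uniroot(
      function(s) expected_zero(s) - cfg$target_sparsity,
      c(lo, hi), tol = 1e-10)$root
  }
  mu <- matrix(scale * mu_site, m, n)
  tot <- matrix(stats::rnbinom(m * n, size = size, mu = mu), m, n)

  vaf <- matrix(0.5, m, n)
  vaf[geno == "R"] <- cfg$seq_error_rate
  vaf[geno == "A"] <- 1 - cfg$seq_error_rate
  alt <- matrix(stats::rbinom(m * n, size = tot, prob = vaf), m, n)
  ref <- tot - alt

  counts <- cell_counts(sites, cells, ref, alt)
  tree <- clade_tree(clades)
  list(counts = counts,
       truth = list(clades = clades, genotypes = geno, tree = tree,
                    informative = informative))
}

# balanced clade tree: star subtrees per clade joined at the root
clade_tree <- function(clades) {
  groups <- split(names(clades), clades)
  sub <- vapply(groups, function(tips)
    paste0("(", paste0(tips, ":1", collapse = ","), "):1"), character(1))
  if (length(sub) == 1) {
    nwk <- paste0(sub, ";")
  } else {
    nwk <- paste0("(", paste(sub, collapse = ","), ");")
  }
  ape::read.tree(text = nwk)
}

#' Increase the dropout rate of a count matrix
#'
#' Zeroes uniformly random non-zero elements (jointly in both matrices)
#' until the requested fraction of elements has zero reads — the standard
#' stress test for robustness to sparsity.
#'
#' @param counts A [cell_counts].
#' @param target_sparsity Desired zero fraction; must be at least the
#'   current sparsity.
#' @param seed Integer RNG seed.
#' @return A [cell_counts] with realized sparsity within one element of the
#'   target.
#' @export
degrade_sparsity <- function(counts, target_sparsity, seed = 1L) {
  stopifnot(inherits(counts, "cell_counts"))
  tot <- total_reads(counts)
  cur <- mean(tot == 0)
  if (target_sparsity < cur)
    stop(sprintf("target sparsity %.3f below current %.3f", target_sparsity,
                 cur))
  n_zero_target <- round(target_sparsity * length(tot))
  n_add <- n_zero_target - sum(tot == 0)
  if (n_add <= 0) return(counts)
  nz <- which(tot > 0)
  drop <- withr::with_seed(seed, sample(nz, n_add))
  counts$ref[drop] <- 0
  counts$alt[drop] <- 0
  counts
}

#' Randomly corrupt a fraction of genotype calls
#'
#' Reassigns a uniformly random set of `floor(fraction * n)` elements to a
#' uniformly random *different* genotype — the stress test for robustness to
#' wrong calls.
#'
#' @param calls Genotype call matrix over R/H/A (no MISSING).
#' @param fraction Fraction of elements to flip, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A call matrix of the same shape.
#' @export
flip_genotype_calls <- function(calls, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_flip <- floor(fraction * length(calls))
  if (n_flip == 0) return(calls)
  withr::with_seed(seed, {
    idx <- sample(length(calls), n_flip)
    calls[idx] <- vapply(calls[idx], function(g)
      sample(setdiff(GENOTYPES, g), 1), character(1))
  })
  calls
}

#' Inject genotype errors upstream of smoothing
#'
#' Corrupts a fraction of site-cell elements at the probability level: for
#' each selected element the probability mass of its most likely genotype is
#' swapped with that of a uniformly random different genotype, so the
#' element's call flips while its confidence profile is preserved. Because
#' the corruption happens before the similarity/smoothing stage, moderate
#' error rates can be absorbed by the neighbourhood averaging while severe
#' ones degrade the neighbour graph itself.
#'
#' @param probs A `genotype_probs` object.
#' @param fraction Fraction of elements to corrupt, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A `genotype_probs` of the same shape.
#' @export
flip_probabilities <- function(probs, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  arr <- unclass(probs)
  nelem <- prod(dim(arr)[1:2])
  n_flip <- floor(fraction * nelem)
  if (n_flip == 0) return(probs)
  flat <- matrix(arr, nelem, 3)
  withr::with_seed(seed, {
    idx <- sample(nelem, n_flip)
    amax <- max.col(flat[idx, , drop = FALSE], ties.method = "first")
    other <- vapply(amax, function(g) sample(setdiff(1:3, g), 1), integer(1))
  })
  tmp <- flat[cbind(idx, amax)]
  flat[cbind(idx, amax)] <- flat[cbind(idx, other)]
  flat[cbind(idx, other)] <- tmp
  structure(array(flat, dim = dim(arr), dimnames = dimnames(arr)),
            class = "genotype_probs", theta = attr(probs, "theta"),
            sites = attr(probs, "sites"))
}

#' Mix a minor subclone into a major population
#'
#' Draws `floor(minor_fraction * total_cells)` cells from the minor pool and
#' fills the remainder from the major pool, preserving total cell count —
#' the construction used to probe subclone detectability at varying
#' frequency.
#'
#' @param major,minor [cell_counts] objects sharing the same site table.
#' @param minor_fraction Fraction of the mixture taken from `minor`.
#' @param total_cells Number of cells in the mixture.
#' @param seed Integer RNG seed.
#' @return A list with `counts` (the mixture) and `labels` (named
#'   `"major"`/`"minor"` per cell).
#' @export
spike_subclone <- function(major, minor, minor_fraction, total_cells,
                           seed = 1L) {
  stopifnot(inherits(major, "cell_counts"), inherits(minor, "cell_counts"))
  if (!identical(site_ids(major), site_ids(minor)))
    stop("major and minor pools must share the same site table")
  n_minor <- floor(minor_fraction * total_cells)
  n_major <- total_cells - n_minor
  if (n_minor > length(minor$cells) || n_major > length(major$cells))
    stop("insufficient cells in a pool for the requested mixture")
  withr::with_seed(seed, {
    pick_minor <- sample(length(minor$cells), n_minor)
    pick_major <- sample(length(major$cells), n_major)
  })
  a <- subset_counts(major, cells = pick_major)
  b <- subset_counts(minor, cells = pick_minor)
  counts <- cell_counts(major$sites, c(a$cells, b$cells),
                        cbind(a$ref, b$ref), cbind(a$alt, b$alt))
  labels <- stats::setNames(rep(c("major", "minor"), c(n_major, n_minor)),
                            counts$cells)
  list(counts = counts, labels = labels)
}
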