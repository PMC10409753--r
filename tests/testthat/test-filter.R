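test_that("cell filter applies the literal less-than boundary", {
  ref <- cbind(c(4999, 5000), c(5000, 5000), c(100, 100))
  alt <- cbind(c(0, 0), c(0, 0), c(0, 0))
  cc <- make_counts(ref, alt)            # totals: 9999, 10000, 200
  out <- filter_cells(cc, 10000)
  expect_equal(out$cells, "c02")

  # identity when everyone qualifies
  out2 <- filter_cells(cc, 100)
  expect_equal(out2$cells, cc$cells)

  expect_error(filter_cells(cc, 1e9), "threshold")
})

test_that("surviving cells equal an independent per-cell summation", {
  sim <- simulate_dataset(sim_config(n_cells = 50, n_sites = 80, seed = 31))
  thr <- 60
  out <- filter_cells(sim$counts, thr)
  sums <- vapply(seq_along(sim$counts$cells), function(j)
    sum(sim$counts$ref[, j]) + sum(sim$counts$alt[, j]), numeric(1))
  expect_equal(out$cells, sim$counts$cells[sums >= thr])
})

test_that("candidate-variant filter enforces support, depth and VAF", {
  # per-site pseudobulk (total, alt): (19,10) (100,4) (100,5) (200,5) (40,30)
  ref <- rbind(c(9, 0), c(96, 0), c(95, 0), c(195, 0), c(10, 0))
  alt <- rbind(c(5, 5), c(2, 2), c(3, 2), c(3, 2), c(20, 10))
  cc <- make_counts(ref, alt)
  out <- filter_candidate_variants(cc)
  kept <- site_ids(out)
  expect_false(site_ids(cc)[1] %in% kept)   # total 19 < 20
  expect_false(site_ids(cc)[2] %in% kept)   # alt 4 < 5
  expect_true(site_ids(cc)[3] %in% kept)    # 5 alt, exactly 5%
  expect_false(site_ids(cc)[4] %in% kept)   # 5 alt but 2.5% VAF
  expect_true(site_ids(cc)[5] %in% kept)
})

test_that("monomorphic filter uses the strict more-than boundary on covered cells", {
  n_cells <- 400
  # site 1: 365/400 covered cells called R (91.25% > 90%) -> removed
  # site 2: 360/400 exactly 90% -> kept
  ref1 <- c(rep(5, 365), rep(0, 35))
  alt1 <- c(rep(0, 365), rep(5, 35))
  ref2 <- c(rep(5, 360), rep(0, 40))
  alt2 <- c(rep(0, 360), rep(5, 40))
  cc <- make_counts(rbind(ref1, ref2), rbind(alt1, alt2))
  out <- coarse_filter_sites(cc, call_unsmoothed(cc),
                             filter_params(min_site_reads = 1))
  expect_equal(site_ids(out), site_ids(cc)[2])
})

test_that("dropout cells are excluded from the monomorphic denominator", {
  # 10 covered cells all R among 40 cells: 100% of covered -> removed even
  # though only 25% of all cells
  ref <- matrix(c(rep(4, 10), rep(0, 30)), 1)
  alt <- matrix(0, 1, 40)
  ref2 <- matrix(rep(c(4, 0), 20), 1)      # site 2 keeps the output non-empty
  alt2 <- matrix(rep(c(0, 4), 20), 1)
  cc <- make_counts(rbind(ref, ref2), rbind(alt, alt2))
  out <- coarse_filter_sites(cc, call_unsmoothed(cc),
                             filter_params(min_site_reads = 1))
  expect_equal(site_ids(out), site_ids(cc)[2])
})

test_that("proximity filter removes whole clusters within 5 nt", {
  sites <- tibble::tibble(chrom = c("1", "1", "1", "1"),
                          pos = c(100L, 104L, 200L, 206L),
                          ref_allele = "A", alt_allele = "G")
  # alternate R/A cells so no site is monomorphic
  ref <- matrix(rep(c(5, 0), length.out = 30), 4, 30, byrow = TRUE)
  alt <- matrix(rep(c(0, 5), length.out = 30), 4, 30, byrow = TRUE)
  cc <- cell_counts(sites, sprintf("c%02d", 1:30), ref, alt)
  out <- coarse_filter_sites(cc, call_unsmoothed(cc), filter_params())
  # 100 and 104 are within 5 nt (both removed); 200 and 206 are not
  expect_equal(out$sites$pos, c(200L, 206L))
})

test_that("sites outside autosomes 1-22 are removed, chr prefixes normalised", {
  sites <- tibble::tibble(chrom = c("1", "chr2", "X", "chrM"),
                          pos = c(100L, 200L, 300L, 400L),
                          ref_allele = "A", alt_allele = "G")
  ref <- matrix(rep(c(5, 0), length.out = 30), 4, 30, byrow = TRUE)
  alt <- matrix(rep(c(0, 5), length.out = 30), 4, 30, byrow = TRUE)
  cc <- cell_counts(sites, sprintf("c%02d", 1:30), ref, alt)
  out <- coarse_filter_sites(cc, call_unsmoothed(cc), filter_params())
  expect_equal(out$sites$chrom, c("1", "chr2"))
})

test_that("low-coverage sites fall to the per-site read floor", {
  ref <- rbind(rep(0, 10), rep(1, 10))
  alt <- rbind(c(9, rep(0, 9)), c(rep(1, 5), rep(0, 5)))
  cc <- make_counts(ref, alt)              # site totals: 9 and 15
  out <- coarse_filter_sites(cc, call_unsmoothed(cc),
                             filter_params(monomorphic_frac = 0.99))
  expect_equal(site_ids(out), site_ids(cc)[2])
})

test_that("coarse filters are idempotent", {
  sim <- simulate_dataset(sim_config(n_cells = 60, n_sites = 120, seed = 13))
  p <- filter_params("lenient")
  once <- coarse_filter_sites(sim$counts, call_unsmoothed(sim$counts), p)
  twice <- coarse_filter_sites(once, call_unsmoothed(once), p)
  expect_equal(site_ids(twice), site_ids(once))

  cand_once <- filter_candidate_variants(sim$counts)
  cand_twice <- filter_candidate_variants(cand_once)
  expect_equal(site_ids(cand_twice), site_ids(cand_once))
})

test_that("top-site selection caps, ranks and breaks ties deterministically", {
  sim <- simulate_dataset(sim_config(n_cells = 30, n_sites = 150, seed = 17))
  out <- select_top_sites(sim$counts, 40)
  expect_equal(nrow(out$sites), 40)
  totals <- rowSums(total_reads(out))
  expect_true(all(diff(totals) <= 0))
  # brute-force oracle: the kept totals are the 40 largest
  all_tot <- sort(rowSums(total_reads(sim$counts)), decreasing = TRUE)
  expect_equal(unname(sort(totals, decreasing = TRUE)),
               unname(all_tot[1:40]))

  # cap not binding -> identity
  out2 <- select_top_sites(sim$counts, 1000)
  expect_equal(nrow(out2$sites), 150)

  # tie at the boundary resolved by ascending (chrom, pos)
  sites <- tibble::tibble(chrom = c("2", "1"), pos = c(50L, 900L),
                          ref_allele = "A", alt_allele = "G")
  cc <- cell_counts(sites, c("x", "y"), matrix(3, 2, 2), matrix(0, 2, 2))
  kept <- select_top_sites(cc, 1)
  expect_equal(kept$sites$chrom, "1")
})

test_that("preset bundles carry the documented thresholds", {
  expect_equal(filter_params()$monomorphic_frac, 0.90)
  len <- filter_params("lenient")
  expect_equal(len$min_site_reads, 5)
  expect_equal(len$monomorphic_frac, 0.80)
  expect_equal(filter_params("subclone")$monomorphic_frac, 0.95)
  expect_error(filter_params(nonsense = 1), "unknown")
})
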