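# Synthetic STR generators: serial-founder expansion and Balding-Nichols.

test_that("serial-founder simulator honors its degenerate limits", {
  # no mutation, no bottleneck, one generation: everything stays ancestral
  p0 <- sim_params(n_demes = 4, N = 30, founder_size = 30,
                   generations_between_foundings = 1, mu = 0,
                   n_loci = 5, sample_size = 10, burn_in = 1, seed = 1)
  s <- simulate_serial_founder(p0)
  expect_true(all(s$genotypes$allele1 == 10))
  expect_true(all(s$genotypes$allele2 == 10))
  d <- diversity_table(s$genotypes)
  expect_true(all(d$per_population$He == 0))
  # mu = 0 conserves the ancestral allele set even with bottlenecks
  p1 <- sim_params(n_demes = 3, N = 20, founder_size = 4,
                   generations_between_foundings = 5, mu = 0,
                   n_loci = 3, sample_size = 8, burn_in = 10, seed = 2)
  s1 <- simulate_serial_founder(p1)
  expect_true(all(c(s1$genotypes$allele1, s1$genotypes$allele2) == 10))
})

test_that("serial-founder output is bit-identical for a fixed seed", {
  p <- sim_params(n_demes = 3, N = 30, founder_size = 6,
                  generations_between_foundings = 5, mu = 5e-3,
                  n_loci = 5, sample_size = 10, burn_in = 30, seed = 7)
  s1 <- simulate_serial_founder(p)
  s2 <- simulate_serial_founder(p)
  expect_identical(s1$genotypes$allele1, s2$genotypes$allele1)
  expect_identical(s1$genotypes$allele2, s2$genotypes$allele2)
  expect_identical(s1$metadata, s2$metadata)
  # metadata geometry: equal spacing along the equator
  dists <- haversine_km(cbind(s1$metadata$lat[-3], s1$metadata$lon[-3]),
                        cbind(s1$metadata$lat[-1], s1$metadata$lon[-1]))
  expect_equal(dists, rep(p$km_per_deme, 2), tolerance = 1e-6)
})

test_that("repeat values never drop below the floor", {
  p <- sim_params(n_demes = 2, N = 20, founder_size = 5,
                  generations_between_foundings = 10, mu = 0.4,
                  n_loci = 4, sample_size = 10, burn_in = 50,
                  ancestral_repeat = 2, seed = 3)
  s <- simulate_serial_founder(p)
  expect_true(all(c(s$genotypes$allele1, s$genotypes$allele2) >= 1))
})

test_that("Balding-Nichols limits behave analytically", {
  anc <- list(L1 = stats::setNames(c(0.3, 0.7), c(9, 10)))
  # F -> 0: population frequencies collapse to the ancestral spectrum
  low <- simulate_balding_nichols(
    bn_params(n_pops = 6, F = 1e-6, ancestral = anc, n_copies = 20000,
              seed = 4))
  f9 <- low$frequency[low$allele == 9]
  expect_equal(f9, rep(0.3, 6), tolerance = 0.02)
  # F near 1: populations are near-fixed for single alleles
  hi <- simulate_balding_nichols(
    bn_params(n_pops = 40, F = 0.99, ancestral = anc, n_copies = 200,
              seed = 5))
  maxf <- tapply(hi$frequency, hi$population, max)
  expect_gt(mean(maxf > 0.95), 0.8)
  # and the fixed allele follows the ancestral probabilities
  fixed9 <- mean(vapply(split(hi, hi$population), function(cell) {
    cell$allele[which.max(cell$frequency)] == 9
  }, TRUE))
  expect_equal(fixed9, 0.3, tolerance = 0.2)
})

test_that("Balding-Nichols expected heterozygosity is (1-F) x ancestral", {
  Fv <- 0.15
  anc <- lapply(1:300, function(l) stats::setNames(rep(0.25, 4), 8:11))
  ft <- simulate_balding_nichols(
    bn_params(n_pops = 4, F = Fv, ancestral = anc, n_copies = 400,
              seed = 6))
  he_anc <- 0.75
  d <- diversity_table(ft)
  expect_equal(mean(d$per_locus$He), (1 - Fv) * he_anc, tolerance = 0.02)
})

test_that("pooled-panel heterozygosity ranks loci stably", {
  g <- do.call(rbind, list(
    data.frame(individual = sprintf("A%d", 1:6), population = "A",
               locus = "mono", allele1 = 9, allele2 = 9),
    data.frame(individual = sprintf("A%d", 1:6), population = "A",
               locus = "quad", allele1 = c(8, 8, 9, 9, 10, 10),
               allele2 = c(11, 10, 8, 11, 9, 11))))
  gt <- genotype_table(g)
  he <- build_ascertainment_pool(gt, "A")
  expect_equal(unname(he["mono"]), 0)
  # 12 copies uniform over 4 alleles: unbiased He = (12/11)(1 - 4/16)
  expect_equal(unname(he["quad"]), 12 / 11 * 0.75, tolerance = 1e-12)
  expect_error(build_ascertainment_pool(gt, character()), "empty")

  set.seed(9)
  cp <- lapply(stats::setNames(1:4, paste0("p", 1:4)),
               function(.) sample(7:13, 12, replace = TRUE))
  pool <- gt_from_copies(cp)
  h1 <- build_ascertainment_pool(pool, c("p1", "p3"))
  h2 <- build_ascertainment_pool(pool, c("p3", "p1"))
  expect_equal(h1, h2)  # panel order is irrelevant
})
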