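# AMOVA variance components, permutation inference and derived matrices.

test_that("two-level AMOVA reproduces limiting cases", {
  fixed <- ft_from_counts(list(A = c("10" = 20), B = c("12" = 20)))
  r <- two_level_amova(fixed, "stepwise")
  expect_equal(r$strata$SSD[r$strata$stratum == "within_pops"], 0)
  expect_equal(unname(r$indices["RST"]), 1)

  same <- ft_from_counts(list(A = c("8" = 10, "10" = 10),
                              B = c("8" = 10, "10" = 10)))
  r2 <- two_level_amova(same, "stepwise")
  expect_lte(unname(r2$indices["RST"]), 0)
  expect_lte(r2$sigma2[["among_pops"]], 0)  # reported as computed
})

test_that("hand fixture matches the brute-force distance-matrix oracle", {
  copies <- c(10, 10, 11, 11, 12, 12, 13, 13)
  pop <- rep(c("A", "B"), each = 4)
  for (model in c("stepwise", "identity")) {
    ft <- ft_from_counts(list(A = table(copies[1:4]),
                              B = table(copies[5:8])))
    r <- two_level_amova(ft, model)
    expect_equal(unname(r$sigma2),
                 unname(oracle_amova(copies, pop, model)),
                 tolerance = 1e-12)
  }
})

test_that("AMOVA satisfies its accounting invariants on random data", {
  set.seed(20)
  for (i in 1:10) {
    fx <- random_fixture()
    ft <- ft_from_fixture(fx)
    r <- two_level_amova(ft, "stepwise")
    expect_equal(sum(r$strata$df), length(fx$copies) - 1)
    expect_equal(sum(r$percent), 100, tolerance = 1e-9)
    if (!is.null(fx$grp)) {
      r3 <- three_level_amova(ft, "stepwise",
                              hierarchy_config(fx$pops,
                                               unname(fx$grp[fx$pops])))
      expect_equal(sum(r3$strata$df), length(fx$copies) - 1)
      expect_equal(sum(r3$sigma2),
                   sum(r3$sigma2[1:3]), tolerance = 1e-9)
      expect_equal(sum(r3$percent), 100, tolerance = 1e-9)
    }
  }
})

test_that("collapsing the hierarchy to one group reduces to two levels", {
  set.seed(21)
  fx <- random_fixture()
  lc <- strpopgen:::.locus_counts(ft_from_fixture(fx), "L1")
  r2 <- strpopgen:::.amova2_counts(lc$counts, lc$alleles, "stepwise")
  r3 <- strpopgen:::.amova3_counts(lc$counts, lc$alleles, "stepwise",
                                   rep("all", length(lc$pops)))
  expect_equal(r3$sigma2[["among_groups"]], 0)
  expect_equal(r3$sigma2[["among_pops_within_groups"]],
               r2$sigma2[["among_pops"]], tolerance = 1e-9)
  expect_equal(r3$sigma2[["within_pops"]], r2$sigma2[["within_pops"]],
               tolerance = 1e-9)
  expect_equal(unname(r3$indices["RST"]), unname(r2$indices["RST"]),
               tolerance = 1e-9)
})

test_that("one population per group flags the degenerate stratum", {
  ft <- ft_from_counts(list(A = c("8" = 6, "9" = 2),
                            B = c("9" = 4, "10" = 4)))
  r <- three_level_amova(ft, "stepwise",
                         hierarchy_config(c("A", "B"), c("g1", "g2")))
  expect_true(r$degenerate)
  expect_equal(r$strata$df[2], 0)
  expect_true(is.na(r$indices[["RSC"]]))
})

test_that("multi-locus combination is an identity for duplicated loci", {
  set.seed(22)
  fx <- random_fixture()
  ft1 <- ft_from_fixture(fx, "L1")
  single <- two_level_amova(ft1, "stepwise")
  expect_equal(multilocus_combine(list(single))$indices, single$indices)
  copies13 <- multilocus_combine(rep(list(single), 13))
  expect_equal(copies13$indices, single$indices, tolerance = 1e-12)
  expect_equal(copies13$sigma2, 13 * single$sigma2, tolerance = 1e-12)
})

test_that("identity and stepwise indices coincide on unit-spaced diallelic loci", {
  set.seed(23)
  for (i in 1:5) {
    cnt <- lapply(stats::setNames(1:3, c("A", "B", "C")), function(.) {
      c("9" = sample(2:10, 1), "10" = sample(2:10, 1))
    })
    ft <- ft_from_counts(cnt)
    rs <- two_level_amova(ft, "stepwise")
    ri <- two_level_amova(ft, "identity")
    expect_equal(unname(rs$indices["RST"]), unname(ri$indices["FST"]),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values hit the floor for extreme structure", {
  ft <- ft_from_counts(list(A = c("8" = 20), B = c("14" = 20)))
  pt <- permutation_test(ft, "stepwise", "RST", n_perm = 99, seed = 1)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 1 / 100)
  # reproducible under a fixed seed
  pt2 <- permutation_test(ft, "stepwise", "RST", n_perm = 99, seed = 1)
  expect_identical(pt$perm_stats, pt2$perm_stats)
})

test_that("sampled permutation statistics live in the exhaustive set", {
  # 4 copies in 2 populations: all 4!/(2!2!) = 6 assignments enumerable
  copies <- c(8, 9, 11, 14)
  enum <- apply(utils::combn(4, 2), 2, function(sel) {
    pop <- rep("B", 4); pop[sel] <- "A"
    o <- oracle_amova(copies, pop, "stepwise")
    o[["among_pops"]] / sum(o)
  })
  ft <- ft_from_counts(list(A = table(copies[1:2]),
                            B = table(copies[3:4])))
  pt <- permutation_test(ft, "stepwise", "RST", n_perm = 200, seed = 5)
  expect_true(all(vapply(pt$perm_stats, function(s)
    any(abs(s - enum) < 1e-9), TRUE)))
})

test_that("Fisher combination matches chi-square closed forms", {
  f1 <- fisher_combine(rep(1, 5))
  expect_equal(f1$chi2, 0); expect_equal(f1$p, 1)
  expect_equal(fisher_combine(0.037)$p, 0.037, tolerance = 1e-12)
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$chi2, -4 * log(0.5), tolerance = 1e-12)
  expect_equal(f$df, 4L)
  expect_equal(f$p, 0.5966, tolerance = 1e-4)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pairwise matrices agree with direct pair runs", {
  set.seed(24)
  cp <- lapply(stats::setNames(1:4, paste0("p", 1:4)),
               function(.) sample(8:13, 10, replace = TRUE))
  g <- gt_from_copies(cp)
  pw <- pairwise_matrix(g, "stepwise", n_perm = 49, seed = 9)
  expect_equal(pw$index, t(pw$index))
  expect_equal(unname(diag(pw$index)), rep(0, 4))
  for (pair in list(c(1, 2), c(2, 4))) {
    direct <- two_level_amova(g, "stepwise",
                              pops = paste0("p", pair))
    expect_equal(pw$index[pair[1], pair[2]],
                 unname(direct$indices["RST"]), tolerance = 1e-12)
  }
  expect_true(all(pw$p[upper.tri(pw$p)] >= 1 / 50))

  ident <- ft_from_counts(list(A = c("8" = 10, "10" = 10),
                               B = c("8" = 10, "10" = 10)))
  expect_lte(max(pairwise_matrix(ident, "stepwise")$index), 0)
})

test_that("Reynolds transform clamps and maps closed forms", {
  expect_equal(reynolds_transform(0), 0)
  expect_equal(reynolds_transform(0.5), log(2), tolerance = 1e-12)
  expect_equal(reynolds_transform(-0.2), 0)  # negative index -> 0
  expect_true(is.finite(reynolds_transform(1)))
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  rm <- reynolds_transform(m)
  expect_equal(diag(rm), c(0, 0))
  expect_equal(rm[1, 2], log(2), tolerance = 1e-12)
})
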