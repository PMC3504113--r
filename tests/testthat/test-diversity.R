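# Diversity indices, group comparisons and Hardy-Weinberg testing.

test_that("unbiased He matches the closed form and its limits", {
  expect_equal(expected_heterozygosity(1, 10), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), 100),
               (100 / 99) * 0.5, tolerance = 1e-12)
  expect_equal(expected_heterozygosity(rep(0.25, 4), 1e9), 0.75,
               tolerance = 1e-6)
  expect_error(expected_heterozygosity(c(0.5, 0.5), 1), "n_copies")
  # invariant to allele relabeling (frequencies only matter)
  expect_equal(expected_heterozygosity(c(0.2, 0.3, 0.5), 40),
               expected_heterozygosity(c(0.5, 0.2, 0.3), 40))
})

test_that("Vp agrees between copy and frequency paths", {
  copies <- c(8, 8, 10, 10)
  expect_equal(repeat_variance(copies), 4 / 3)
  expect_equal(repeat_variance(c(9, 9, 9)), 0)
  freq_path <- repeat_variance(stats::setNames(c(0.5, 0.5), c(8, 10)),
                               n_copies = 4)
  expect_equal(freq_path, 4 / 3, tolerance = 1e-12)
  # shift invariance
  expect_equal(repeat_variance(copies + 7), repeat_variance(copies))
  # random agreement sweep
  set.seed(3)
  for (i in 1:10) {
    cp <- sample(6:13, 12, replace = TRUE)
    f <- table(cp) / length(cp)
    expect_equal(repeat_variance(stats::setNames(as.vector(f), names(f)),
                                 length(cp)),
                 repeat_variance(cp), tolerance = 1e-12)
  }
})

test_that("diversity from genotypes equals diversity from frequencies", {
  set.seed(4)
  cp <- lapply(stats::setNames(1:4, paste0("p", 1:4)),
               function(.) sample(c(7:12, 9.3), 16, replace = TRUE))
  g <- gt_from_copies(cp)
  dg <- diversity_table(g)
  df <- diversity_table(frequencies_from_genotypes(g))
  expect_equal(dg$per_locus$He, df$per_locus$He, tolerance = 1e-12)
  expect_equal(dg$per_locus$Vp, df$per_locus$Vp, tolerance = 1e-12)
})

test_that("group summaries respect ordering and degenerate groups", {
  cp <- list(p1 = c(8, 8, 9, 10), p2 = c(8, 9, 9, 10),
             p3 = c(10, 11, 11, 12))
  d <- diversity_table(gt_from_copies(cp))
  h <- hierarchy_config(names(cp), c("W", "W", "E"))
  gs <- group_summary(d, h, "He", group_order = c("E", "W"))
  expect_identical(gs$group, c("E", "W"))
  expect_true(is.na(gs$sd[gs$group == "E"]))  # single-population group
  expect_equal(gs$n, c(1L, 2L))
  within <- d$per_population$He[1:2]
  expect_gte(gs$mean[2], min(within)); expect_lte(gs$mean[2], max(within))
  expect_error(group_summary(d, h, "He", group_order = "W"), "misses")
})

test_that("Kruskal-Wallis and pairwise Wilcoxon behave at the edges", {
  kw <- kruskal_wallis(rep(1, 10), rep(c("a", "b"), 5))
  expect_equal(kw$H, 0); expect_equal(kw$p, 1)
  set.seed(5)
  x <- rnorm(20)
  kw2 <- kruskal_wallis(c(x, x), rep(c("a", "b"), each = 20))
  expect_gt(kw2$p, 0.9)

  pw <- pairwise_wilcoxon(c(x, x), rep(c("a", "b"), each = 20))
  expect_equal(pw$n_pairs, 1L)  # two groups: Bonferroni factor 1
  expect_equal(pw$p_adjusted, pw$p_raw)

  v <- rnorm(30)
  g3 <- rep(c("a", "b", "c"), each = 10)
  pw3 <- pairwise_wilcoxon(v, g3)
  expect_equal(pw3$n_pairs, 3L)
  off <- !is.na(pw3$p_raw)
  expect_true(all(pw3$p_adjusted[off] >= pw3$p_raw[off]))
  expect_true(all(pw3$p_adjusted[off] <= 1))
  expect_equal(pw3$p_adjusted, t(pw3$p_adjusted))
})

test_that("HWE Monte-Carlo test matches exact enumeration for 2 alleles", {
  # exact oracle: enumerate all heterozygote counts compatible with the
  # allele counts and sum Levene probabilities <= observed
  exact_hwe_p <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    cA <- 2 * nAA + nAB
    lp <- function(h) {
      a <- (cA - h) / 2; b <- (2 * n - cA - h) / 2
      lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
        h * log(2) + lgamma(cA + 1) + lgamma(2 * n - cA + 1) -
        lgamma(2 * n + 1)
    }
    hs <- seq(cA %% 2, min(cA, 2 * n - cA), by = 2)
    probs <- vapply(hs, lp, 0)
    sum(exp(probs)[probs <= lp(nAB) + 1e-9])
  }
  g <- gt_from_copies(list(A = rep(c(8, 10), 25)))  # 25 individuals, all het
  res <- hwe_test(g, "A", "L1", n_draws = 20000, seed = 1)
  expect_equal(res$direction, "excess")
  ex <- exact_hwe_p(0, 25, 0)
  expect_lt(res$p, 0.01)
  expect_equal(res$p, ex, tolerance = 0.01)

  # a balanced case with moderate p
  g2 <- gt_from_copies(list(A = c(rep(c(8, 8), 6), rep(c(10, 10), 6),
                                  rep(c(8, 10), 13))))
  res2 <- hwe_test(g2, "A", "L1", n_draws = 20000, seed = 2)
  ex2 <- exact_hwe_p(6, 13, 6)
  expect_equal(res2$p, ex2, tolerance = 0.02)

  mono <- hwe_test(gt_from_copies(list(A = rep(9, 12))), "A", "L1")
  expect_equal(mono$p, 1)
  expect_true(is.na(mono$direction))
})

test_that("HWE scan counts rejections and is seed-stable", {
  set.seed(6)
  cp <- lapply(stats::setNames(1:3, paste0("p", 1:3)),
               function(.) sample(8:11, 20, replace = TRUE))
  g <- gt_from_copies(cp)
  s1 <- hwe_scan(g, n_draws = 500, seed = 10)
  s2 <- hwe_scan(g, n_draws = 500, seed = 10)
  expect_identical(s1$tests$p, s2$tests$p)
  expect_equal(s1$n_tests, 3L)
  expect_true(s1$reject_05_bonferroni <= s1$reject_05)
})
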