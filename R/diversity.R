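# Within-population diversity indices, group comparisons and HWE testing.

#' Unbiased expected heterozygosity
#'
#' He = n/(n-1) * (1 - sum p_i^2), with n the number of gene copies the
#' frequencies summarize (2 x individuals). This is the sample-size
#' unbiased (Nei) form standard in population-genetic software.
#'
#' @param freqs numeric vector of allele frequencies (summing to 1).
#' @param n_copies number of gene copies, >= 2.
#' @return He in \[0, 1\].
#' @export
expected_heterozygosity <- function(freqs, n_copies) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  he <- n_copies / (n_copies - 1) * (1 - sum(freqs^2))
  min(max(he, 0), 1)
}

#' Variance in repeat number (Vp)
#'
#' Sample variance (denominator n-1) of repeat values over allele copies
#' within a population. Given raw copies it is `var(copies)`; given a
#' frequency spectrum it is `n/(n-1) * (sum f_a a^2 - (sum f_a a)^2)`,
#' which equals the copy path exactly when the frequencies are integral
#' counts over `n_copies`.
#'
#' @param x either a numeric vector of repeat values (copies path;
#'   `n_copies` omitted), or a numeric vector of frequencies named by
#'   allele repeat value (frequency path; `n_copies` required).
#' @param n_copies gene-copy count for the frequency path.
#' @return Vp >= 0, in squared repeat units.
#' @export
repeat_variance <- function(x, n_copies = NULL) {
  if (is.null(n_copies)) {
    if (length(x) < 2L) stop("need >= 2 copies")
    return(stats::var(x))
  }
  if (n_copies < 2) stop("n_copies must be >= 2")
  a <- as.numeric(names(x))
  if (any(is.na(a))) stop("frequency path needs allele values as names")
  m1 <- sum(x * a)
  m2 <- sum(x * a^2)
  max(n_copies / (n_copies - 1) * (m2 - m1^2), 0)
}

#' Per-population, per-locus diversity table
#'
#' Computes He (unbiased expected heterozygosity), Vp (variance in repeat
#' number) and k (observed allele count) for every (population, locus)
#' cell, plus per-population means over loci.
#'
#' @param data a [freq_table] or [genotype_table].
#' @return list of class `diversity_table` with `per_locus` (long data
#'   frame) and `per_population` (means over loci).
#' @export
diversity_table <- function(data) {
  ft <- if (inherits(data, "genotype_table"))
    frequencies_from_genotypes(data) else data
  cell_id <- paste(ft$locus, ft$population, sep = "\r")
  cells <- split(data.frame(allele = ft$allele, frequency = ft$frequency,
                            n_copies = ft$n_copies),
                 factor(cell_id, levels = unique(cell_id)))
  key <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
  stats_mat <- t(vapply(cells, function(cell) {
    n <- cell$n_copies[1L]
    f <- cell$frequency / sum(cell$frequency)
    c(expected_heterozygosity(f, n),
      repeat_variance(stats::setNames(f, cell$allele), n),
      nrow(cell), n)
  }, numeric(4L)))
  per_locus <- data.frame(population = key[, 2L], locus = key[, 1L],
                          He = stats_mat[, 1L], Vp = stats_mat[, 2L],
                          k = stats_mat[, 3L], n_copies = stats_mat[, 4L],
                          row.names = NULL, stringsAsFactors = FALSE)
  agg <- stats::aggregate(per_locus[, c("He", "Vp", "k")],
                          by = list(population = per_locus$population),
                          FUN = mean)
  agg <- agg[match(populations(ft), agg$population), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(per_locus = per_locus, per_population = agg),
            class = "diversity_table")
}

#' @export
print.diversity_table <- function(x, ...) {
  cat(sprintf("diversity_table: %d populations x %d loci\n",
              nrow(x$per_population),
              length(unique(x$per_locus$locus))))
  print(utils::head(x$per_population), digits = 4)
  invisible(x)
}

#' Per-group summary of per-population diversity means
#'
#' Mean and standard deviation, over member populations, of the
#' per-population means of a diversity index (the quantity plotted in
#' Africa-to-America group panels).
#'
#' @param d a [diversity_table].
#' @param hierarchy a [hierarchy_config].
#' @param index `"He"`, `"Vp"` or `"k"`.
#' @param group_order optional ordering of group labels for the report
#'   (e.g. an Africa-to-America layout); defaults to first appearance.
#' @return data frame with group, n (populations), mean, sd (NA for
#'   single-population groups).
#' @export
group_summary <- function(d, hierarchy, index = c("He", "Vp", "k"),
                          group_order = NULL) {
  index <- match.arg(index)
  pp <- d$per_population
  grp <- unclass(hierarchy)[pp$population]
  if (any(is.na(grp))) stop("hierarchy does not cover all populations")
  if (is.null(group_order)) group_order <- unique(unname(grp))
  if (!all(unname(grp) %in% group_order)) stop("group_order misses groups")
  out <- do.call(rbind, lapply(group_order, function(g) {
    v <- pp[[index]][grp == g]
    if (length(v) == 0L) stop("empty group: ", g)
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based test of differences in a diversity index among all groups;
#' tie-corrected H with the chi-square approximation (the group sizes of
#' intended use are large enough for it).
#'
#' @param values numeric observations (e.g. per-population mean He).
#' @param groups group label per observation.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (stats::var(values) == 0) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Unpaired rank-sum test for every pair of groups; adjusted
#' p = min(1, raw p x number of pairs).
#'
#' @inheritParams kruskal_wallis
#' @param exact passed to [stats::wilcox.test()]; default lets R decide
#'   (normal approximation with ties).
#' @return list with symmetric matrices `p_raw` and `p_adjusted`
#'   (diagonal NA) and `n_pairs`.
#' @export
pairwise_wilcoxon <- function(values, groups, exact = NULL) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need >= 2 groups")
  npair <- choose(length(gl), 2L)
  praw <- matrix(NA_real_, length(gl), length(gl),
                 dimnames = list(gl, gl))
  for (i in seq_along(gl)[-length(gl)]) {
    for (j in (i + 1L):length(gl)) {
      a <- values[groups == gl[i]]
      b <- values[groups == gl[j]]
      if (length(a) == 0L || length(b) == 0L) stop("empty group in pair")
      p <- if (all(c(a, b) == c(a, b)[1L])) 1 else
        suppressWarnings(stats::wilcox.test(a, b, exact = exact)$p.value)
      praw[i, j] <- praw[j, i] <- p
    }
  }
  list(p_raw = praw, p_adjusted = pmin(praw * npair, 1),
       n_pairs = npair)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Tests one population x locus genotype array. The statistic is the
#' Levene conditional probability of the genotype array given the allele
#' counts; the null distribution is sampled by randomly re-pairing the
#' observed allele copies `n_draws` times, and
#' p = (# arrays with probability <= observed + 1) / (n_draws + 1).
#' Direction compares the observed heterozygote count with its
#' expectation under random pairing.
#'
#' @param g a [genotype_table].
#' @param pop,locus the cell to test.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @return list with `p`, `direction` (`"excess"`, `"deficit"` or NA for a
#'   monomorphic locus), `obs_het`, `exp_het`, `n`.
#' @export
hwe_test <- function(g, pop, locus, n_draws = 10000L, seed = NULL) {
  sub <- g[g$population == pop & g$locus == locus, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) stop("need >= 2 individuals")
  a1 <- sub$allele1; a2 <- sub$allele2
  copies <- c(a1, a2)
  alleles <- sort(unique(copies))
  if (length(alleles) == 1L) {
    return(list(p = 1, direction = NA_character_, obs_het = 0,
                exp_het = 0, n = n))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  ci <- match(copies, alleles)
  cnt <- tabulate(ci, length(alleles))
  n2 <- 2L * n
  # log conditional probability of a genotype array given allele counts:
  # log[ n! 2^h prod_a c_a! / ((2n)! prod_{a<=b} n_ab!) ]
  const <- lgamma(n + 1) + sum(lgamma(cnt + 1)) - lgamma(n2 + 1)
  A <- length(alleles)
  log_prob <- function(i1, i2) {
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    h <- sum(lo != hi)
    gt <- tabulate(lo + (hi * (hi - 1L)) %/% 2L,
                   nbins = (A * (A + 1L)) %/% 2L)
    const + h * log(2) - sum(lgamma(gt[gt > 1L] + 1))
  }
  obs_lp <- log_prob(ci[1:n], ci[(n + 1):n2])
  obs_het <- sum(a1 != a2)
  exp_het <- n * (1 - sum(cnt * (cnt - 1)) / (n2 * (n2 - 1)))
  hits <- 0L
  for (b in seq_len(n_draws)) {
    perm <- sample(ci)
    if (log_prob(perm[1:n], perm[(n + 1):n2]) <= obs_lp + 1e-9) {
      hits <- hits + 1L
    }
  }
  list(p = (hits + 1) / (n_draws + 1),
       direction = if (obs_het > exp_het) "excess" else "deficit",
       obs_het = obs_het, exp_het = exp_het, n = n)
}

#' HWE rejection summary over all populations and loci
#'
#' Runs [hwe_test()] on every (population, locus) cell and counts
#' rejections at the 5% and 1% levels, raw and Bonferroni-corrected.
#'
#' @param g a [genotype_table].
#' @param n_draws Monte-Carlo draws per cell.
#' @param seed RNG seed (split per cell deterministically).
#' @return list with the long results data frame and rejection counts.
#' @export
hwe_scan <- function(g, n_draws = 2000L, seed = NULL) {
  cells <- expand.grid(population = populations(g), locus = loci(g),
                       stringsAsFactors = FALSE)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sd_i <- if (is.null(seed)) NULL else seed + i
    h <- hwe_test(g, cells$population[i], cells$locus[i],
                  n_draws = n_draws, seed = sd_i)
    res[[i]] <- data.frame(population = cells$population[i],
                           locus = cells$locus[i], p = h$p,
                           direction = if (is.na(h$direction)) NA_character_
                                       else h$direction,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  m <- nrow(tab)
  list(tests = tab,
       n_tests = m,
       reject_05 = sum(tab$p < 0.05),
       reject_01 = sum(tab$p < 0.01),
       reject_05_bonferroni = sum(tab$p < 0.05 / m),
       reject_01_bonferroni = sum(tab$p < 0.01 / m))
}
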