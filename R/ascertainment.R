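# Marker-ascertainment experiment: forensic STR panels were chosen to be
# maximally discriminating (high heterozygosity), which compresses the
# spread of He across populations and thereby depresses fixation indices
# relative to randomly chosen genomic STRs. These tools rank loci by He,
# extract extreme panels and compare them with random panels.

#' Per-locus mean heterozygosity over population samples
#'
#' "Average He over all samples" is the unweighted mean over population
#' samples of each locus' He (not the pooled-copies He, which lives in
#' [build_ascertainment_pool()]).
#'
#' @param data a [freq_table] or [genotype_table].
#' @param pops optional population subset.
#' @return named numeric vector, one mean He per locus.
#' @export
locus_mean_he <- function(data, pops = NULL) {
  dt <- diversity_table(data)$per_locus
  if (!is.null(pops)) dt <- dt[dt$population %in% pops, , drop = FALSE]
  out <- tapply(dt$He, dt$locus, mean)
  out[loci(data)]
}

#' Select a locus panel
#'
#' @param data a [freq_table] or [genotype_table].
#' @param criterion `"highest"`/`"lowest"` mean He over population
#'   samples, `"random"` (seeded), or `"listed"` (take `loci_list`).
#' @param k panel size.
#' @param seed RNG seed for the random criterion.
#' @param loci_list loci for the listed criterion.
#' @param pops optional population subset for the He ranking.
#' @return character vector of class `locus_panel` with attributes
#'   `criterion`, `k`, `seed`. He ties are broken by locus name.
#' @export
select_panel <- function(data, criterion = c("highest", "lowest",
                                             "random", "listed"),
                         k, seed = NULL, loci_list = NULL, pops = NULL) {
  criterion <- match.arg(criterion)
  all_loci <- loci(data)
  if (criterion == "listed") {
    if (is.null(loci_list)) stop("listed criterion needs loci_list")
    if (!all(loci_list %in% all_loci)) stop("unknown locus in loci_list")
    panel <- loci_list
  } else {
    if (k > length(all_loci)) stop("k exceeds the locus count")
    if (criterion == "random") {
      if (!is.null(seed)) {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)
      }
      panel <- sample(all_loci, k)
    } else {
      he <- locus_mean_he(data, pops)
      ord <- order(if (criterion == "highest") -he else he, names(he))
      panel <- names(he)[ord][seq_len(k)]
    }
  }
  structure(panel, criterion = criterion, k = length(panel), seed = seed,
            class = "locus_panel")
}

#' Mean and across-population variance of panel heterozygosity
#'
#' Per population, He is averaged over the panel loci; the mean and the
#' (n-1 denominator) variance of these per-population means across
#' populations are returned. Low across-population variance of He is the
#' ascertainment signature of discriminability-selected panels.
#'
#' @param data a [freq_table] or [genotype_table].
#' @param panel character vector of loci.
#' @return list with `mean_he`, `var_he`, `per_population`.
#' @export
he_variance_profile <- function(data, panel) {
  dt <- diversity_table(data)$per_locus
  dt <- dt[dt$locus %in% panel, , drop = FALSE]
  per_pop <- tapply(dt$He, dt$population, mean)
  if (length(per_pop) < 2L) stop("need >= 2 populations")
  list(mean_he = mean(per_pop), var_he = stats::var(as.vector(per_pop)),
       per_population = per_pop)
}

#' Levene test for equality of variances (two samples)
#'
#' Classic Levene test: one-way F test on absolute deviations from the
#' sample centre (mean by default; median gives the Brown-Forsythe
#' variant).
#'
#' @param values_a,values_b numeric samples (each >= 2 values).
#' @param center `"mean"` or `"median"`.
#' @return list with `W`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values_a, values_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each sample needs >= 2 values")
  }
  cf <- if (center == "mean") mean else stats::median
  za <- abs(values_a - cf(values_a))
  zb <- abs(values_b - cf(values_b))
  if (stats::var(c(za, zb)) == 0) {
    stop("degenerate samples: all absolute deviations equal")
  }
  z <- c(za, zb)
  g <- factor(rep(c("a", "b"), c(length(za), length(zb))))
  n <- length(z); kg <- 2L
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  num <- sum(ng * (zg - zbar)^2) / (kg - 1)
  den <- sum((z - zg[g])^2) / (n - kg)
  W <- num / den
  list(W = W, df1 = kg - 1L, df2 = n - kg,
       p = stats::pf(W, kg - 1L, n - kg, lower.tail = FALSE))
}

#' Panel-ascertainment experiment
#'
#' Quantifies the marker-choice mechanism on a locus pool: the top-k-He
#' panel (the "forensic-style" ascertained set) is compared against the
#' bottom-k panel, the full pool, and `n_random` random k-panels, on
#' three statistics per panel: mean He, across-population variance of He,
#' and multi-locus R_ST (or F_ST). Percentiles locate the ascertained
#' panel's statistics within the random-panel distribution.
#'
#' @param pool a [freq_table] or [genotype_table] with many loci.
#' @param k panel size (13 mirrors the CODIS core).
#' @param n_random number of random panels.
#' @param seed RNG seed.
#' @param model allele-distance model for the fixation index.
#' @param pops optional population subset for the He ranking.
#' @return list of class `ascertainment_result` with `panels` (a data
#'   frame: one row per panel with mean_he, var_he, index), `percentiles`
#'   (of the top panel within the random panels), `top`, `bottom`.
#' @export
ascertainment_experiment <- function(pool, k = 13L, n_random = 50L,
                                     seed = NULL,
                                     model = c("stepwise", "identity"),
                                     pops = NULL) {
  model <- match.arg(model)
  if (length(loci(pool)) < k) stop("pool must hold >= k loci")
  top <- select_panel(pool, "highest", k, pops = pops)
  bottom <- select_panel(pool, "lowest", k, pops = pops)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  randoms <- lapply(seq_len(n_random),
                    function(i) sample(loci(pool), k))

  # cache per-locus diversity and variance components
  dt <- diversity_table(pool)$per_locus
  lc_all <- .locus_counts_all(pool)
  sig_per_locus <- vapply(lc_all, function(lc) {
    .amova2_counts(lc$counts, lc$alleles, model)$sigma2
  }, numeric(2L))

  panel_stats <- function(panel) {
    sub <- dt[dt$locus %in% panel, , drop = FALSE]
    per_pop <- tapply(sub$He, sub$population, mean)
    sig <- rowSums(sig_per_locus[, panel, drop = FALSE])
    c(mean_he = mean(per_pop), var_he = stats::var(as.vector(per_pop)),
      index = unname(sig[1L] / sum(sig)))
  }
  all_panels <- c(list(top = unclass(top), bottom = unclass(bottom),
                       pool = loci(pool)),
                  stats::setNames(randoms,
                                  sprintf("random%02d", seq_len(n_random))))
  stats_mat <- t(vapply(all_panels, panel_stats, numeric(3L)))
  panels <- data.frame(panel = rownames(stats_mat),
                       kind = c("top", "bottom", "pool",
                                rep("random", n_random)),
                       stats_mat, row.names = NULL,
                       stringsAsFactors = FALSE)
  rnd <- panels[panels$kind == "random", , drop = FALSE]
  pctl <- function(x, ref) 100 * mean(ref < x) + 50 * mean(ref == x)
  percentiles <- c(
    mean_he = pctl(panels$mean_he[1L], rnd$mean_he),
    var_he = pctl(panels$var_he[1L], rnd$var_he),
    index = pctl(panels$index[1L], rnd$index))
  structure(list(panels = panels, percentiles = percentiles,
                 top = top, bottom = bottom, model = model, k = k,
                 n_random = n_random, seed = seed),
            class = "ascertainment_result")
}

#' @export
print.ascertainment_result <- function(x, ...) {
  cat(sprintf("ascertainment experiment: k = %d, %d random panels (%s)\n",
              x$k, x$n_random, x$model))
  print(x$panels[x$panels$kind != "random", ], digits = 4)
  cat("top-panel percentiles within random panels:",
      paste(sprintf("%s = %.0f%%", names(x$percentiles), x$percentiles),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare two datasets' He distributions and variances
#'
#' The dataset-level comparison: Wilcoxon rank-sum on the per-sample He
#' distributions and a Levene test on their across-population variances,
#' with a caller-supplied Bonferroni factor for multiple dataset pairs.
#'
#' @param he_a,he_b per-population mean He vectors of the two datasets.
#' @param n_comparisons Bonferroni factor (number of dataset pairs).
#' @param center Levene centering.
#' @return data frame with both tests' raw and adjusted p-values.
#' @export
compare_datasets <- function(he_a, he_b, n_comparisons = 1L,
                             center = "mean") {
  w <- suppressWarnings(stats::wilcox.test(he_a, he_b, exact = FALSE))
  l <- levene_test(he_a, he_b, center = center)
  data.frame(
    test = c("wilcoxon_he", "levene_var_he"),
    statistic = c(unname(w$statistic), l$W),
    p_raw = c(w$p.value, l$p),
    p_adjusted = pmin(1, c(w$p.value, l$p) * n_comparisons),
    stringsAsFactors = FALSE)
}
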