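# Analysis of molecular variance for STR data.
#
# Allele copies are the analysis units. Under the stepwise model the
# distance between two copies is the squared difference of their repeat
# values, so within-set sums of squared pairwise distances reduce to sums
# of squared deviations from the set mean; under the identity model the
# distance is 0/1 and the same sums reduce to allele-count expressions.
# Fixation indices computed under the stepwise model are R statistics
# (R_ST, R_SC, R_CT), under the identity model their F analogues.
# Negative variance components are reported as computed.

# sum of pairwise distances within a copy set / (2 * set size),
# from its allele-count vector
.ssd_set <- function(counts, alleles, model) {
  n <- sum(counts)
  if (n == 0) return(0)
  if (model == "stepwise") {
    s1 <- sum(counts * alleles)
    sum(counts * alleles^2) - s1 * s1 / n
  } else {
    (n - sum(counts * counts) / n) / 2
  }
}

.check_model <- function(model) {
  match.arg(model, c("stepwise", "identity"))
}

# Two-level AMOVA on an allele-count matrix (alleles x populations).
.amova2_counts <- function(cmat, alleles, model) {
  nk <- colSums(cmat)
  if (any(nk < 2)) stop("every population needs >= 2 allele copies")
  P <- ncol(cmat)
  if (P < 2L) stop("need >= 2 populations")
  N <- sum(nk)
  ssd_wp <- sum(vapply(seq_len(P),
                       function(k) .ssd_set(cmat[, k], alleles, model), 0))
  ssd_tot <- .ssd_set(rowSums(cmat), alleles, model)
  ssd_ap <- ssd_tot - ssd_wp
  df <- c(among_pops = P - 1L, within_pops = as.integer(N - P))
  ms <- c(ssd_ap, ssd_wp) / df
  nprime <- (N - sum(nk^2) / N) / (P - 1)
  s2c <- ms[2L]
  s2b <- (ms[1L] - s2c) / nprime
  sigma2 <- c(among_pops = unname(s2b), within_pops = unname(s2c))
  tot <- sum(sigma2)
  idx_names <- if (model == "stepwise") c("RST") else c("FST")
  indices <- stats::setNames(sigma2[1L] / tot, idx_names)
  list(levels = 2L, model = model,
       strata = data.frame(stratum = names(df), df = as.numeric(df),
                           SSD = c(ssd_ap, ssd_wp), MS = as.numeric(ms),
                           row.names = NULL),
       sigma2 = sigma2, percent = 100 * sigma2 / tot,
       indices = indices, n_total = N)
}

# Three-level AMOVA; `grp` = group label per column of cmat.
.amova3_counts <- function(cmat, alleles, model, grp) {
  nk <- colSums(cmat)
  if (any(nk < 2)) stop("every population needs >= 2 allele copies")
  P <- ncol(cmat)
  grp <- as.character(grp)
  groups <- unique(grp)
  G <- length(groups)
  N <- sum(nk)
  Ng <- vapply(groups, function(g) sum(nk[grp == g]), 0)

  ssd_wp <- sum(vapply(seq_len(P),
                       function(k) .ssd_set(cmat[, k], alleles, model), 0))
  ssd_wg <- sum(vapply(groups, function(g) {
    cols <- which(grp == g)
    .ssd_set(rowSums(cmat[, cols, drop = FALSE]), alleles, model)
  }, 0))
  ssd_tot <- .ssd_set(rowSums(cmat), alleles, model)
  ssd_ag <- ssd_tot - ssd_wg
  ssd_ap_wg <- ssd_wg - ssd_wp

  df <- c(among_groups = G - 1L, among_pops_within_groups = P - G,
          within_pops = as.integer(N - P))
  degenerate <- df[2L] == 0L
  ms <- c(ssd_ag, ssd_ap_wg, ssd_wp) / ifelse(df > 0, df, NA_real_)

  sum_n2_over_Ng <- sum(vapply(groups, function(g) {
    sum(nk[grp == g]^2) / sum(nk[grp == g])
  }, 0))
  n_c <- if (P - G > 0) (N - sum_n2_over_Ng) / (P - G) else NA_real_
  n_pr <- if (G > 1L) (sum_n2_over_Ng - sum(nk^2) / N) / (G - 1) else 0
  n_dpr <- if (G > 1L) (N - sum(Ng^2) / N) / (G - 1) else NA_real_

  s2c <- ms[3L]
  s2b <- if (degenerate) 0 else (ms[2L] - s2c) / n_c
  # a single group collapses the among-groups stratum: the partition then
  # reduces exactly to the two-level AMOVA
  s2a <- if (G == 1L) 0 else (ms[1L] - s2c - n_pr * s2b) / n_dpr
  sigma2 <- c(among_groups = unname(s2a),
              among_pops_within_groups = unname(s2b),
              within_pops = unname(s2c))
  tot <- sum(sigma2)
  if (model == "stepwise") {
    indices <- c(RCT = unname(s2a / tot),
                 RSC = unname(if (degenerate) NA_real_ else
                   s2b / (s2b + s2c)),
                 RST = unname((s2a + s2b) / tot))
  } else {
    indices <- c(FCT = unname(s2a / tot),
                 FSC = unname(if (degenerate) NA_real_ else
                   s2b / (s2b + s2c)),
                 FST = unname((s2a + s2b) / tot))
  }
  list(levels = 3L, model = model,
       strata = data.frame(stratum = names(df), df = as.numeric(df),
                           SSD = c(ssd_ag, ssd_ap_wg, ssd_wp),
                           MS = as.numeric(ms), row.names = NULL),
       sigma2 = sigma2, percent = 100 * sigma2 / tot,
       indices = indices, n_total = N, degenerate = degenerate)
}

.as_amova_result <- function(res, locus = NULL) {
  res$locus <- locus
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%d-level, %s distance%s)\n", x$levels, x$model,
              if (!is.null(x$locus)) paste0(", locus ", x$locus) else ""))
  tab <- x$strata
  tab$sigma2 <- x$sigma2
  tab$percent <- x$percent
  print(tab, digits = 6)
  cat("indices:", paste(sprintf("%s = %.6f", names(x$indices), x$indices),
                        collapse = ", "), "\n")
  if (!is.null(x$p_values)) {
    cat("permutation p:",
        paste(sprintf("%s = %.4g", names(x$p_values), x$p_values),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Single-locus two-level AMOVA (among vs within populations)
#'
#' Partitions the molecular variance of one locus into among- and
#' within-population components, using allele copies as units. From a
#' [genotype_table] copies are counted directly; from a [freq_table]
#' integer copy counts are reconstructed as `frequency * n_copies`
#' reconciled by largest-remainder rounding, so the two data modes agree
#' exactly when the frequencies derive from counts.
#'
#' @param data a [freq_table] or [genotype_table].
#' @param model `"stepwise"` (squared repeat-number difference between
#'   alleles; yields R_ST) or `"identity"` (0/1 distance; yields F_ST).
#' @param locus locus name (default: first locus of `data`).
#' @param pops optional subset/order of populations.
#' @return an `amova_result`: per-stratum df/SSD/MS, variance components
#'   `sigma2`, percentages and the fixation index. Negative components are
#'   reported as computed.
#' @export
two_level_amova <- function(data, model = c("stepwise", "identity"),
                            locus = NULL, pops = NULL) {
  model <- match.arg(model)
  if (is.null(locus)) locus <- loci(data)[1L]
  lc <- .locus_counts(data, locus, pops)
  .as_amova_result(.amova2_counts(lc$counts, lc$alleles, model), locus)
}

#' Single-locus three-level (hierarchical) AMOVA
#'
#' Partitions molecular variance among geographic groups, among populations
#' within groups, and within populations, giving the fixation indices
#' R_CT (among groups), R_SC (among populations within groups) and R_ST
#' (among all populations) — F analogues under the identity model.
#'
#' @inheritParams two_level_amova
#' @param hierarchy a [hierarchy_config] mapping population -> group.
#' @return an `amova_result` with three strata; when every group holds a
#'   single population the middle stratum has zero df and is flagged
#'   `degenerate`.
#' @export
three_level_amova <- function(data, model = c("stepwise", "identity"),
                              hierarchy, locus = NULL) {
  model <- match.arg(model)
  if (is.null(locus)) locus <- loci(data)[1L]
  pops <- intersect(populations(data), names(hierarchy))
  if (!all(populations(data) %in% names(hierarchy))) {
    stop("hierarchy does not cover all populations")
  }
  lc <- .locus_counts(data, locus, pops)
  grp <- unname(unclass(hierarchy)[lc$pops])
  .as_amova_result(.amova3_counts(lc$counts, lc$alleles, model, grp), locus)
}

#' Combine per-locus AMOVA results into a multi-locus result
#'
#' Variance components are summed over loci stratum by stratum and the
#' fixation indices recomputed from the summed components (the standard
#' multi-locus combination for AMOVA).
#'
#' @param results list of `amova_result` objects with identical strata.
#' @return a combined `amova_result`; `$per_locus` keeps the inputs.
#' @export
multilocus_combine <- function(results) {
  if (length(results) == 0L) stop("no results to combine")
  lev <- unique(vapply(results, function(r) r$levels, 0L))
  mod <- unique(vapply(results, function(r) r$model, ""))
  if (length(lev) != 1L || length(mod) != 1L) {
    stop("mismatched strata or distance models across loci")
  }
  strata <- results[[1L]]$strata$stratum
  for (r in results) {
    if (!identical(r$strata$stratum, strata)) stop("mismatched strata")
  }
  sigma2 <- Reduce(`+`, lapply(results, function(r) r$sigma2))
  tot <- sum(sigma2)
  if (lev == 2L) {
    indices <- stats::setNames(sigma2[1L] / tot,
                               if (mod == "stepwise") "RST" else "FST")
  } else {
    s2a <- sigma2[1L]; s2b <- sigma2[2L]; s2c <- sigma2[3L]
    nm <- if (mod == "stepwise") c("RCT", "RSC", "RST") else
      c("FCT", "FSC", "FST")
    indices <- stats::setNames(
      c(s2a / tot, s2b / (s2b + s2c), (s2a + s2b) / tot), nm)
  }
  out <- list(levels = lev, model = mod, strata = NULL,
              sigma2 = sigma2, percent = 100 * sigma2 / tot,
              indices = indices,
              n_total = results[[1L]]$n_total,
              per_locus = results,
              loci = vapply(results, function(r)
                if (is.null(r$locus)) NA_character_ else r$locus, ""))
  ssd <- Reduce(`+`, lapply(results, function(r) r$strata$SSD))
  df <- results[[1L]]$strata$df
  out$strata <- data.frame(stratum = strata, df = df, SSD = ssd,
                           MS = ssd / ifelse(df > 0, df, NA_real_),
                           row.names = NULL)
  class(out) <- "amova_result"
  out
}

# ---- permutation machinery -------------------------------------------------

# Per-locus unit representation used by permutation schemes.
# Genotype mode: units are individuals (one shared permutation re-labels
# them for all loci jointly). Frequency mode: units are reconstructed
# allele copies, permuted per locus independently.
.perm_units <- function(data, loci_use, pops) {
  if (inherits(data, "genotype_table")) {
    ind <- attr(data, "individuals")
    pop_of <- data$population[match(ind, data$individual)]
    keep <- pop_of %in% pops
    ind <- ind[keep]; pop_of <- pop_of[keep]
    per_locus <- lapply(loci_use, function(loc) {
      sub <- data[data$locus == loc, , drop = FALSE]
      o <- match(ind, sub$individual)
      alleles <- sort(unique(c(sub$allele1, sub$allele2)))
      list(alleles = alleles,
           a_idx = cbind(match(sub$allele1[o], alleles),
                         match(sub$allele2[o], alleles)))
    })
    list(mode = "genotype", pops = pops, loci = loci_use,
         unit_pop = match(pop_of, pops), per_locus = per_locus)
  } else {
    per_locus <- lapply(loci_use, function(loc) {
      lc <- .locus_counts(data, loc, pops)
      A <- length(lc$alleles)
      idx <- rep(rep(seq_len(A), ncol(lc$counts)), as.vector(lc$counts))
      upop <- rep(rep(seq_along(lc$pops), each = A), as.vector(lc$counts))
      list(alleles = lc$alleles, a_idx = idx, unit_pop = upop)
    })
    list(mode = "frequency", pops = pops, loci = loci_use,
         per_locus = per_locus)
  }
}

# counts matrix for one locus given (possibly permuted) unit->pop labels
.units_to_counts <- function(pl, unit_pop, n_pops) {
  A <- length(pl$alleles)
  if (is.matrix(pl$a_idx)) {
    idx <- c(pl$a_idx[, 1L], pl$a_idx[, 2L]) + A * (rep(unit_pop, 2L) - 1L)
  } else {
    idx <- pl$a_idx + A * (unit_pop - 1L)
  }
  matrix(tabulate(idx, nbins = A * n_pops), nrow = A)
}

.multilocus_index <- function(units, unit_pops, grp, model, statistic) {
  n_pops <- length(units$pops)
  sig <- NULL
  for (i in seq_along(units$per_locus)) {
    pl <- units$per_locus[[i]]
    upop <- if (units$mode == "genotype") unit_pops else unit_pops[[i]]
    cmat <- .units_to_counts(pl, upop, n_pops)
    r <- if (is.null(grp)) .amova2_counts(cmat, pl$alleles, model)
         else .amova3_counts(cmat, pl$alleles, model, grp)
    sig <- if (is.null(sig)) r$sigma2 else sig + r$sigma2
  }
  tot <- sum(sig)
  switch(statistic,
         RST = , FST = if (length(sig) == 2L) sig[[1L]] / tot else
           (sig[[1L]] + sig[[2L]]) / tot,
         RSC = , FSC = sig[[2L]] / (sig[[2L]] + sig[[3L]]),
         RCT = , FCT = sig[[1L]] / tot)
}

#' Permutation test for AMOVA fixation indices
#'
#' The permutation scheme follows the index being tested: for the global
#' index (R_ST/F_ST) allele copies (frequency mode) or individuals
#' (genotype mode) are permuted among populations — across groups when a
#' hierarchy is supplied; for R_SC the units are permuted among populations
#' within their group; for R_CT whole populations are permuted among
#' groups. The p-value is `(# permuted >= observed + 1) / (n_perm + 1)`, so
#' it is floored at `1/(n_perm+1)` and safe for downstream Fisher
#' combination.
#'
#' @inheritParams two_level_amova
#' @param statistic one of `"RST"`, `"RSC"`, `"RCT"` (or the F analogues;
#'   the distance model is set by `model`).
#' @param hierarchy a [hierarchy_config]; required for `"RSC"`/`"RCT"` and
#'   for the hierarchical global index, omitted for the two-level index.
#' @param loci_use loci to combine over (default: all loci of `data`).
#' @param n_perm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return list with `observed`, `p`, `n_perm`, `perm_stats`.
#' @export
permutation_test <- function(data, model = c("stepwise", "identity"),
                             statistic = c("RST", "RSC", "RCT",
                                           "FST", "FSC", "FCT"),
                             hierarchy = NULL, loci_use = NULL,
                             n_perm = 999L, seed = NULL) {
  model <- match.arg(model)
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (statistic %in% c("RSC", "RCT", "FSC", "FCT") && is.null(hierarchy)) {
    stop("statistic ", statistic, " needs a hierarchy")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  if (is.null(loci_use)) loci_use <- loci(data)
  pops <- populations(data)
  if (!is.null(hierarchy)) pops <- intersect(pops, names(hierarchy))
  units <- .perm_units(data, loci_use, pops)
  grp <- if (is.null(hierarchy)) NULL else unname(unclass(hierarchy)[pops])

  obs_pops <- if (units$mode == "genotype") units$unit_pop else
    lapply(units$per_locus, function(pl) pl$unit_pop)
  observed <- .multilocus_index(units, obs_pops, grp, model, statistic)

  scheme <- if (statistic %in% c("RCT", "FCT")) "groups"
            else if (statistic %in% c("RSC", "FSC")) "within"
            else "units"
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (scheme == "groups") {
      pg <- sample(grp)
      perm_stats[b] <- .multilocus_index(units, obs_pops, pg, model,
                                         statistic)
    } else if (scheme == "units") {
      pp <- if (units$mode == "genotype") sample(obs_pops) else
        lapply(obs_pops, sample)
      perm_stats[b] <- .multilocus_index(units, pp, grp, model, statistic)
    } else {
      # permute units among populations within each group
      if (units$mode == "genotype") {
        pp <- obs_pops
        for (g in unique(grp)) {
          in_g <- which(grp[obs_pops] == g)
          pp[in_g] <- sample(obs_pops[in_g])
        }
      } else {
        pp <- lapply(obs_pops, function(up) {
          out <- up
          for (g in unique(grp)) {
            in_g <- which(grp[up] == g)
            out[in_g] <- sample(up[in_g])
          }
          out
        })
      }
      perm_stats[b] <- .multilocus_index(units, pp, grp, model, statistic)
    }
  }
  p <- (sum(perm_stats >= observed - 1e-12) + 1) / (n_perm + 1)
  list(observed = unname(observed), p = p, n_perm = n_perm,
       perm_stats = perm_stats, statistic = statistic)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fisher's combined probability test
#'
#' Combines independent per-locus p-values: chi2 = -2 sum(log p) on 2k df.
#' Permutation p-values must be floored above 0 upstream (the
#' `(x+1)/(B+1)` estimator guarantees this).
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `chi2`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Pairwise multi-locus fixation-index matrix
#'
#' Each entry is the multi-locus two-level index (R_ST or F_ST) for that
#' population pair, i.e. variance components summed over loci for the pair
#' and the index recomputed from the sums. Optionally a per-pair
#' permutation p-value matrix is produced.
#'
#' @inheritParams two_level_amova
#' @param loci_use loci to combine over (default all).
#' @param n_perm permutations per pair (0 = no testing).
#' @param seed RNG seed used when `n_perm > 0`.
#' @return list with `index` (symmetric matrix, zero diagonal) and, when
#'   requested, `p` (p-value matrix, diagonal NA).
#' @export
pairwise_matrix <- function(data, model = c("stepwise", "identity"),
                            loci_use = NULL, n_perm = 0L, seed = NULL) {
  model <- match.arg(model)
  if (is.null(loci_use)) loci_use <- loci(data)
  pops <- populations(data)
  P <- length(pops)
  if (P < 2L) stop("need >= 2 populations")
  # precompute per-locus counts once
  lc_all <- .locus_counts_all(data, pops)[loci_use]
  idx <- matrix(0, P, P, dimnames = list(pops, pops))
  pm <- if (n_perm > 0L) matrix(NA_real_, P, P,
                                dimnames = list(pops, pops)) else NULL
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      sig <- c(0, 0)
      per_locus_counts <- vector("list", length(loci_use))
      for (l in seq_along(lc_all)) {
        lc <- lc_all[[l]]
        cm <- lc$counts[, c(i, j), drop = FALSE]
        keep <- rowSums(cm) > 0
        cm <- cm[keep, , drop = FALSE]
        r <- .amova2_counts(cm, lc$alleles[keep], model)
        sig <- sig + r$sigma2
        per_locus_counts[[l]] <- list(cm = cm, al = lc$alleles[keep])
      }
      val <- sig[1L] / sum(sig)
      idx[i, j] <- idx[j, i] <- val
      if (n_perm > 0L) {
        perm <- numeric(n_perm)
        for (b in seq_len(n_perm)) {
          s <- c(0, 0)
          for (pl in per_locus_counts) {
            A <- nrow(pl$cm)
            copies <- rep(rep(seq_len(A), 2L), as.vector(pl$cm))
            sizes <- colSums(pl$cm)
            newpop <- sample(rep(1:2, sizes))
            cm2 <- matrix(tabulate(copies + A * (newpop - 1L), 2L * A),
                          nrow = A)
            s <- s + .amova2_counts(cm2, pl$al, model)$sigma2
          }
          perm[b] <- s[1L] / sum(s)
        }
        pv <- (sum(perm >= val - 1e-12) + 1) / (n_perm + 1)
        pm[i, j] <- pm[j, i] <- pv
      }
    }
  }
  out <- list(index = idx, model = model, loci = loci_use)
  if (!is.null(pm)) out$p <- pm
  out
}

#' Reynolds coancestry distance transform
#'
#' Maps a matrix (or vector) of pairwise fixation indices theta to the
#' drift-linearized Reynolds distance D = -ln(1 - theta). Negative indices
#' (possible for undifferentiated pairs) are clamped to 0 so D = 0;
#' indices at or above `theta_max` are capped there so D stays finite.
#'
#' @param m numeric matrix or vector of pairwise indices.
#' @param theta_max cap applied before the log transform.
#' @return object of the same shape with Reynolds distances; a matrix gets
#'   a zero diagonal.
#' @export
reynolds_transform <- function(m, theta_max = 1 - 1e-9) {
  theta <- pmin(pmax(m, 0), theta_max)
  d <- -log(1 - theta)
  if (is.matrix(m)) diag(d) <- 0
  d
}
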