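# Shared fixtures and independent oracles, all built in code.

# Brute-force AMOVA oracle: sums of squared distances computed from the
# explicit copy-by-copy distance matrix (the implementation instead uses
# allele-count identities). Returns variance components.
oracle_amova <- function(copies, pop, model, grp = NULL) {
  D <- if (model == "stepwise") outer(copies, copies, function(x, y) (x - y)^2)
       else outer(copies, copies, function(x, y) as.numeric(x != y))
  ssd <- function(sel) {
    idx <- which(sel)
    sum(D[idx, idx]) / (2 * length(idx))
  }
  pops <- unique(pop)
  P <- length(pops)
  N <- length(copies)
  nk <- as.vector(table(factor(pop, levels = pops)))
  ssd_tot <- ssd(rep(TRUE, N))
  ssd_wp <- sum(vapply(pops, function(pp) ssd(pop == pp), 0))
  if (is.null(grp)) {
    ms_a <- (ssd_tot - ssd_wp) / (P - 1)
    ms_w <- ssd_wp / (N - P)
    nprime <- (N - sum(nk^2) / N) / (P - 1)
    s2c <- ms_w
    s2b <- (ms_a - s2c) / nprime
    c(among_pops = s2b, within_pops = s2c)
  } else {
    g <- unname(grp[pop])
    groups <- unique(g)
    G <- length(groups)
    Ng <- vapply(groups, function(gg) sum(g == gg), 0)
    ssd_wg <- sum(vapply(groups, function(gg) ssd(g == gg), 0))
    ms_ag <- (ssd_tot - ssd_wg) / (G - 1)
    ms_b <- (ssd_wg - ssd_wp) / (P - G)
    ms_w <- ssd_wp / (N - P)
    npg_over_Ng <- sum(vapply(groups, function(gg) {
      sum(nk[grp[pops] == gg]^2) / sum(nk[grp[pops] == gg])
    }, 0))
    n_c <- (N - npg_over_Ng) / (P - G)
    n_pr <- (npg_over_Ng - sum(nk^2) / N) / (G - 1)
    n_dpr <- (N - sum(Ng^2) / N) / (G - 1)
    s2c <- ms_w
    s2b <- (ms_b - s2c) / n_c
    s2a <- (ms_ag - s2c - n_pr * s2b) / n_dpr
    c(among_groups = s2a, among_pops_within_groups = s2b,
      within_pops = s2c)
  }
}

# Frequency table from a named list of per-population allele-count
# vectors (names = allele repeat values) for one or more loci.
ft_from_counts <- function(counts, locus = "L1") {
  rows <- do.call(rbind, lapply(names(counts), function(pop) {
    cnt <- counts[[pop]]
    data.frame(population = pop, locus = locus,
               allele = as.numeric(names(cnt)),
               frequency = as.vector(cnt) / sum(cnt),
               n_copies = sum(cnt), stringsAsFactors = FALSE)
  }))
  freq_table(rows)
}

# Genotype table from per-population copy vectors (even lengths);
# consecutive copies are paired into individuals.
gt_from_copies <- function(copies_by_pop, locus = "L1") {
  rows <- do.call(rbind, lapply(names(copies_by_pop), function(pop) {
    cp <- copies_by_pop[[pop]]
    stopifnot(length(cp) %% 2 == 0)
    n <- length(cp) / 2
    data.frame(individual = sprintf("%s_i%02d", pop, seq_len(n)),
               population = pop, locus = locus,
               allele1 = cp[seq(1, length(cp), 2)],
               allele2 = cp[seq(2, length(cp), 2)],
               stringsAsFactors = FALSE)
  }))
  genotype_table(rows)
}

# Random small fixture: copies, population labels and a 2-3 group
# hierarchy, for oracle-equivalence sweeps.
random_fixture <- function() {
  P <- sample(2:5, 1)
  nk <- sample(seq(2, 12, 2), P, replace = TRUE)
  pops <- sprintf("p%d", seq_len(P))
  pop <- rep(pops, nk)
  alleles <- sample(c(6:14, 9.3), sum(nk), replace = TRUE)
  resample <- function(x) x[sample.int(length(x), 1)]
  G <- if (P >= 3) resample(2:min(3, P - 1)) else NA
  grp <- if (is.na(G)) NULL else {
    labels <- sprintf("g%d", seq_len(G))
    # guarantee every group label occurs at least once
    g <- stats::setNames(c(labels, sample(labels, P - G, replace = TRUE)),
                         pops)
    g
  }
  list(copies = alleles, pop = pop, pops = pops, grp = grp)
}

ft_from_fixture <- function(fx, locus = "L1") {
  counts <- lapply(split(fx$copies, fx$pop), table)
  ft_from_counts(counts[fx$pops], locus)
}
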