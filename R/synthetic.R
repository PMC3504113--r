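# Synthetic STR data generators.
#
# Two generators cover the statistical structure the pipeline assumes:
# a forward-time Wright-Fisher serial-founder expansion producing the
# out-of-Africa-style decline of diversity with distance from the origin
# (with stepwise repeat mutation, so Vp and R_ST are meaningful), and a
# Balding-Nichols compound-Dirichlet frequency model with a known
# differentiation parameter F for analytic parameter-recovery checks.

#' Parameters of the serial-founder simulator
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: a 30-deme linear expansion of demes of 200 diploids,
#' founded by 20 individuals each, 100 tetranucleotide-like loci mutating
#' at 5e-3 per copy per generation under a symmetric single-step model.
#' The expansion is rapid — 10 generations between foundings, well below
#' the mutation-drift recovery time of roughly N generations — which is
#' the regime in which serial founding imprints a persistent diversity
#' gradient along the deme chain.
#'
#' @param n_demes number of demes founded sequentially along a line.
#' @param N diploid deme size after growth.
#' @param founder_size diploid founders seeding each new deme (<= N).
#' @param generations_between_foundings generations each deme evolves
#'   before founding the next.
#' @param mu per-copy, per-generation single-step mutation rate (allele
#'   +/-1 repeat with equal probability); must lie in \[0, 0.5\].
#' @param n_loci number of independent loci.
#' @param ancestral_repeat ancestral repeat count.
#' @param sample_size diploid individuals sampled per deme.
#' @param burn_in generations of mutation-drift burn-in for the origin
#'   deme (brings He near its stepwise-model equilibrium before the
#'   expansion starts).
#' @param km_per_deme great-circle spacing between adjacent demes (km);
#'   demes are placed along the equator so straight-line and great-circle
#'   spacing agree.
#' @param n_groups contiguous blocks of demes labelled as geographic
#'   groups (the among-groups stratum of hierarchical analyses); default
#'   5 blocks, capped at the deme count.
#' @param seed RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_demes = 30L, N = 200L, founder_size = 20L,
                       generations_between_foundings = 10L, mu = 5e-3,
                       n_loci = 100L, ancestral_repeat = 10L,
                       sample_size = 50L, burn_in = 1000L,
                       km_per_deme = 500, n_groups = NULL, seed = 1L) {
  if (is.null(n_groups)) n_groups <- min(5L, n_demes)
  stopifnot(founder_size <= N, mu >= 0, mu <= 0.5, n_demes >= 1,
            N >= 1, founder_size >= 1, n_loci >= 1, sample_size >= 1,
            sample_size <= N, ancestral_repeat >= 1, n_groups >= 1,
            n_groups <= n_demes)
  structure(as.list(environment()), class = "sim_params")
}

# one Wright-Fisher generation for a copies-by-loci matrix
.wf_generation <- function(M, mu) {
  nr <- nrow(M); L <- ncol(M)
  idx <- sample.int(nr, nr * L, replace = TRUE)
  M2 <- M[cbind(idx, rep(seq_len(L), each = nr))]
  if (mu > 0) {
    u <- stats::runif(nr * L)
    M2 <- M2 - (u < mu / 2) + (u >= mu / 2 & u < mu)
    # repeat-1 floor: a downward step at the minimum repeat is suppressed
    M2[M2 < 1] <- 1
  }
  dim(M2) <- c(nr, L)
  M2
}

.wf_evolve <- function(M, generations, mu) {
  for (g in seq_len(generations)) M <- .wf_generation(M, mu)
  M
}

#' Forward-time serial-founder expansion of STR diversity
#'
#' Simulates a linear chain of demes: the origin deme is burnt in to
#' mutation-drift balance, then each new deme is founded from 2 x
#' `founder_size` gene copies of the previous deme, grown to size N in one
#' generation, and evolved `generations_between_foundings` generations
#' before founding the next. Loci are independent (no linkage); mutation
#' is strictly single-step symmetric. Each deme is sampled at the moment
#' it founds its successor, i.e. along the expansion wavefront. With
#' mu > 0 and enough loci, expected heterozygosity declines with deme
#' index — the serial-founder gradient.
#'
#' @param params a [sim_params].
#' @return list with `genotypes` (a [genotype_table]), `metadata`
#'   (a `pop_metadata` with demes spaced `km_per_deme` apart along the
#'   equator and groups as contiguous blocks) and `hierarchy`
#'   (a [hierarchy_config]).
#' @export
simulate_serial_founder <- function(params = sim_params()) {
  p <- params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  ncopy <- 2L * p$N
  M <- matrix(as.numeric(p$ancestral_repeat), ncopy, p$n_loci)
  M <- .wf_evolve(M, p$burn_in, p$mu)
  samples <- vector("list", p$n_demes)
  for (d in seq_len(p$n_demes)) {
    M <- .wf_evolve(M, p$generations_between_foundings, p$mu)
    # sample this deme: per locus, draw 2*sample_size copies without
    # replacement and pair consecutive copies into individuals
    ns <- 2L * p$sample_size
    samp <- vapply(seq_len(p$n_loci),
                   function(l) M[sample.int(ncopy, ns), l],
                   numeric(ns))
    samples[[d]] <- samp
    if (d < p$n_demes) {
      # found the next deme: a bottleneck of founder copies, then one
      # generation of growth back to 2N copies
      nf <- 2L * p$founder_size
      Mf <- vapply(seq_len(p$n_loci),
                   function(l) M[sample.int(ncopy, nf), l],
                   numeric(nf))
      grow <- vapply(seq_len(p$n_loci),
                     function(l) Mf[sample.int(nf, ncopy,
                                               replace = TRUE), l],
                     numeric(ncopy))
      M <- grow
    }
  }
  pop_ids <- sprintf("deme%02d", seq_len(p$n_demes))
  locus_ids <- sprintf("L%03d", seq_len(p$n_loci))
  rows <- vector("list", p$n_demes)
  for (d in seq_len(p$n_demes)) {
    samp <- samples[[d]]
    a1 <- samp[seq(1L, nrow(samp), by = 2L), , drop = FALSE]
    a2 <- samp[seq(2L, nrow(samp), by = 2L), , drop = FALSE]
    rows[[d]] <- data.frame(
      individual = rep(sprintf("%s_i%03d", pop_ids[d],
                               seq_len(p$sample_size)), p$n_loci),
      population = pop_ids[d],
      locus = rep(locus_ids, each = p$sample_size),
      allele1 = as.vector(a1), allele2 = as.vector(a2),
      stringsAsFactors = FALSE)
  }
  g <- genotype_table(do.call(rbind, rows))

  deg_per_km <- 360 / (2 * pi * .EARTH_RADIUS_KM)
  block <- ceiling(p$n_demes / p$n_groups)
  grp <- sprintf("G%d", ((seq_len(p$n_demes) - 1L) %/% block) + 1L)
  meta <- pop_metadata(data.frame(
    population = pop_ids, name = pop_ids, group = grp,
    lat = 0, lon = (seq_len(p$n_demes) - 1L) * p$km_per_deme * deg_per_km,
    region = grp, well_defined = TRUE, stringsAsFactors = FALSE))
  # all demes sit on one landmass: every region routes directly
  wp <- waypoint_config(paths = stats::setNames(
    rep(list(character()), length(unique(grp))), unique(grp)))
  list(genotypes = g, metadata = meta,
       hierarchy = hierarchy_config(meta), waypoints = wp)
}

#' Parameters of the Balding-Nichols frequency generator
#'
#' @param n_pops number of populations.
#' @param F differentiation parameter, strictly in (0, 1); either a
#'   scalar (same drift intensity at every locus) or a vector of length
#'   `n_loci`. Real STR panels mix loci whose mutation rates — and hence
#'   drift sensitivities — span orders of magnitude, so locus pools for
#'   ascertainment experiments are generated with per-locus F.
#' @param n_loci number of loci (used when `ancestral` is NULL).
#' @param n_copies gene copies sampled per population and locus.
#' @param ancestral optional list (one element per locus) of ancestral
#'   frequency vectors named by allele repeat value; when NULL, ancestral
#'   spectra are generated per locus: an allele count drawn uniformly from
#'   `k_range` consecutive integer repeat values around repeat 10, with
#'   Dirichlet(alpha) frequencies, alpha drawn uniformly from
#'   `alpha_range` — which makes ancestral heterozygosity vary across loci
#'   the way a random genomic STR panel's does.
#' @param k_range range of ancestral allele counts.
#' @param alpha_range range of the symmetric Dirichlet concentration.
#' @param seed RNG seed.
#' @return list of class `bn_params`.
#' @export
bn_params <- function(n_pops = 10L, F = 0.1, n_loci = 100L,
                      n_copies = 200L, ancestral = NULL,
                      k_range = c(4L, 10L), alpha_range = c(0.5, 3),
                      seed = 1L) {
  stopifnot(all(F > 0), all(F < 1), length(F) %in% c(1L, n_loci),
            n_pops >= 2, n_loci >= 1, n_copies >= 2)
  if (!is.null(ancestral)) {
    for (p0 in ancestral) {
      if (abs(sum(p0) - 1) > 1e-8) stop("ancestral frequencies must sum to 1")
    }
  }
  structure(as.list(environment()), class = "bn_params")
}

#' Balding-Nichols synthetic allele-frequency table
#'
#' For each population and locus, allele frequencies are drawn from the
#' compound-Dirichlet with mean equal to the ancestral spectrum and
#' concentration (1-F)/F, then `n_copies` gene copies are drawn
#' multinomially. The expected value of Wright's F_ST over populations is
#' the generating F, and per-locus expected heterozygosity is
#' (1-F) x ancestral He — the analytic handles the parameter-recovery
#' tests rely on.
#'
#' @param params a [bn_params].
#' @return a [freq_table] (frequencies are exact multiples of
#'   1/n_copies, so copy-count reconstruction is exact).
#' @export
simulate_balding_nichols <- function(params = bn_params()) {
  p <- params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  anc <- p$ancestral
  if (is.null(anc)) {
    anc <- lapply(seq_len(p$n_loci), function(l) {
      k <- sample(p$k_range[1L]:p$k_range[2L], 1L)
      alpha <- stats::runif(1L, p$alpha_range[1L], p$alpha_range[2L])
      f <- stats::rgamma(k, shape = alpha)
      f <- f / sum(f)
      vals <- seq(10 - floor((k - 1) / 2), length.out = k)
      stats::setNames(f, vals)
    })
  }
  n_loci <- length(anc)
  Fv <- rep_len(p$F, n_loci)
  pop_ids <- sprintf("pop%02d", seq_len(p$n_pops))
  locus_ids <- if (!is.null(names(anc))) names(anc) else
    sprintf("L%03d", seq_len(n_loci))
  acc_pop <- acc_loc <- acc_allele <- acc_freq <- vector("list",
                                                         n_loci * p$n_pops)
  r <- 0L
  for (l in seq_len(n_loci)) {
    p0 <- anc[[l]]
    vals <- as.numeric(names(p0))
    shape_scale <- (1 - Fv[l]) / Fv[l]
    for (k in seq_len(p$n_pops)) {
      gam <- stats::rgamma(length(p0), shape = p0 * shape_scale)
      if (sum(gam) == 0) gam[which.max(p0)] <- 1  # numerical underflow guard
      cnt <- as.vector(stats::rmultinom(1L, p$n_copies, gam / sum(gam)))
      keep <- cnt > 0L
      r <- r + 1L
      acc_pop[[r]] <- rep(pop_ids[k], sum(keep))
      acc_loc[[r]] <- rep(locus_ids[l], sum(keep))
      acc_allele[[r]] <- vals[keep]
      acc_freq[[r]] <- cnt[keep] / p$n_copies
    }
  }
  ft <- freq_table(data.frame(
    population = unlist(acc_pop), locus = unlist(acc_loc),
    allele = unlist(acc_allele), frequency = unlist(acc_freq),
    n_copies = p$n_copies, stringsAsFactors = FALSE))
  attr(ft, "populations") <- pop_ids
  attr(ft, "loci") <- locus_ids
  ft
}

#' Pooled-panel heterozygosity per locus
#'
#' Pools the gene copies of the panel populations and computes unbiased
#' expected heterozygosity per locus on the pooled spectrum — the
#' forensic-style ascertainment statistic (markers chosen to be most
#' discriminating in a reference panel).
#'
#' @param base a [freq_table] or [genotype_table].
#' @param panel_pops populations forming the ascertainment panel.
#' @return named numeric vector of pooled He per locus.
#' @export
build_ascertainment_pool <- function(base, panel_pops) {
  if (length(panel_pops) == 0L) stop("empty panel")
  if (!all(panel_pops %in% populations(base))) {
    stop("panel_pops must be a subset of the populations")
  }
  out <- vapply(loci(base), function(loc) {
    lc <- .locus_counts(base, loc, panel_pops)
    cnt <- rowSums(lc$counts)
    n <- sum(cnt)
    expected_heterozygosity(cnt / n, n)
  }, 0)
  stats::setNames(out, loci(base))
}
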