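# Config-driven orchestration of the full analysis workflow:
# validation -> diversity -> distance-from-origin regressions -> AMOVA ->
# pairwise matrices -> Reynolds -> MDS -> Mantel -> group tests.

#' Build a run configuration
#'
#' @param mode `"genotype"` or `"frequency"`.
#' @param genotypes,frequencies input table (object) or file path for the
#'   chosen mode.
#' @param metadata `pop_metadata` object or CSV path.
#' @param origin,origin_region origin point for distance-from-origin
#'   regressions (default Addis Ababa, SAF region).
#' @param waypoints a [waypoint_config].
#' @param drop_loci loci removed before analysis (e.g. the complex-repeat
#'   trio `FGA`, `D21S11`, `TH01` for a robustness run).
#' @param exclude_populations populations removed before analysis (e.g.
#'   MDS outliers identified by inspection).
#' @param include_not_well_defined keep populations whose metadata flags
#'   them as not well defined (excluded by default).
#' @param model allele-distance model.
#' @param n_perm_amova,n_perm_mantel permutation counts (defaults 10000
#'   and 1000, the conventional settings).
#' @param n_hwe_draws Monte-Carlo draws per HWE test (genotype mode).
#' @param mds_starts random starts for the nonmetric MDS.
#' @param group_order optional report ordering of geographic groups.
#' @param seed global seed, deterministically split across stages.
#' @param out_dir optional directory; when set, tables (TSV) and a JSON
#'   summary are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("genotype", "frequency"),
                       genotypes = NULL, frequencies = NULL,
                       metadata = NULL,
                       origin = c(9.03, 38.74), origin_region = "SAF",
                       waypoints = waypoint_config(),
                       drop_loci = character(),
                       exclude_populations = character(),
                       include_not_well_defined = FALSE,
                       model = c("stepwise", "identity"),
                       n_perm_amova = 10000L, n_perm_mantel = 1000L,
                       n_hwe_draws = 2000L, mds_starts = 16L,
                       group_order = NULL, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  stopifnot(n_perm_amova >= 1L, n_perm_mantel >= 1L)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; `genotypes`,
#' `frequencies` and `metadata` are file paths resolved relative to the
#' YAML file.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  wp <- if (is.null(y$waypoints)) waypoint_config() else
    waypoint_config(paths = lapply(y$waypoints$paths, as.character),
                    waypoints = lapply(y$waypoints$coordinates, as.numeric),
                    radius = y$waypoints$radius %||% 6371.0)
  run_config(
    mode = y$mode %||% "genotype",
    genotypes = rel(y$genotypes), frequencies = rel(y$frequencies),
    metadata = rel(y$metadata),
    origin = as.numeric(y$origin %||% c(9.03, 38.74)),
    origin_region = y$origin_region %||% "SAF",
    waypoints = wp,
    drop_loci = as.character(y$drop_loci %||% character()),
    exclude_populations = as.character(y$exclude_populations %||%
                                         character()),
    include_not_well_defined = isTRUE(y$include_not_well_defined),
    model = y$model %||% "stepwise",
    n_perm_amova = as.integer(y$n_perm_amova %||% 10000L),
    n_perm_mantel = as.integer(y$n_perm_mantel %||% 1000L),
    n_hwe_draws = as.integer(y$n_hwe_draws %||% 2000L),
    mds_starts = as.integer(y$mds_starts %||% 16L),
    group_order = y$group_order,
    seed = as.integer(y$seed %||% 1L),
    out_dir = y$out_dir)
}

.stage_seed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  offsets <- c(amova = 101L, rsc = 102L, rct = 103L, mantel = 201L,
               mds = 301L, hwe = 401L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis workflow
#'
#' Executes every stage of the analysis on one dataset and returns (and
#' optionally writes) a consolidated report: per-group diversity
#' summaries with Kruskal-Wallis and pairwise Bonferroni-Wilcoxon tests,
#' He/Vp-versus-distance-from-origin regressions, hierarchical AMOVA with
#' multi-locus fixation indices and permutation p-values, the pairwise
#' fixation-index matrix and its Reynolds transform, nonmetric MDS
#' coordinates with stress, the Mantel correlation of genetic and routed
#' geographic distances, and (genotype mode) HWE rejection counts. All
#' stages are pure functions of (inputs, config, seed).
#'
#' @param config a [run_config].
#' @return list of class `run_report` with one element per stage.
#' @export
run_all <- function(config) {
  cfg <- config
  load_tab <- function(x, reader) {
    if (is.character(x)) reader(x) else x
  }
  meta <- load_tab(cfg$metadata, read_metadata)
  if (is.null(meta)) stop("stage input: metadata is required")
  data <- if (cfg$mode == "genotype") {
    g <- load_tab(cfg$genotypes, function(p) {
      if (grepl("\\.(csv|tsv|txt)$", p)) read_genotypes_csv(p) else
        read_genotypes_genepop(p)$genotypes
    })
    if (is.null(g)) stop("stage input: genotype mode needs genotypes")
    g
  } else {
    f <- load_tab(cfg$frequencies, read_frequency_table)
    if (is.null(f)) stop("stage input: frequency mode needs frequencies")
    f
  }

  drop_pops <- cfg$exclude_populations
  if (!cfg$include_not_well_defined) {
    drop_pops <- union(drop_pops,
                       meta$population[!meta$well_defined])
  }
  keep <- !(data$population %in% drop_pops)
  df <- as.data.frame(data)[keep, , drop = FALSE]
  if (length(cfg$drop_loci) > 0L) {
    df <- df[!(df$locus %in% cfg$drop_loci), , drop = FALSE]
  }
  data <- if (cfg$mode == "genotype") genotype_table(df) else
    freq_table(df)
  meta <- meta[meta$population %in% populations(data), , drop = FALSE]
  meta <- meta[match(populations(data), meta$population), , drop = FALSE]
  if (any(is.na(meta$population))) {
    stop("stage metadata: populations missing from metadata")
  }
  hier <- hierarchy_config(meta)

  report <- list(config = cfg, populations = populations(data),
                 loci = loci(data))

  # --- diversity ---
  div <- diversity_table(data)
  grp <- unclass(hier)[div$per_population$population]
  report$diversity <- list(
    table = div,
    group_summary_he = group_summary(div, hier, "He", cfg$group_order),
    group_summary_vp = group_summary(div, hier, "Vp", cfg$group_order),
    kruskal_he = kruskal_wallis(div$per_population$He, grp),
    kruskal_vp = kruskal_wallis(div$per_population$Vp, grp),
    wilcoxon_he = pairwise_wilcoxon(div$per_population$He, grp),
    wilcoxon_vp = pairwise_wilcoxon(div$per_population$Vp, grp))

  # --- distance from origin and regressions ---
  dist0 <- distance_from_origin(meta, cfg$origin, cfg$origin_region,
                                cfg$waypoints)
  report$geodistance <- list(
    distance_km = dist0,
    regression_he = diversity_distance_regression(
      div$per_population$He, dist0[div$per_population$population]),
    regression_vp = diversity_distance_regression(
      div$per_population$Vp, dist0[div$per_population$population]))

  # --- hierarchical AMOVA, multi-locus, permutation p ---
  per_locus <- lapply(loci(data), function(loc)
    three_level_amova(data, cfg$model, hier, loc))
  combined <- multilocus_combine(per_locus)
  stat_names <- names(combined$indices)
  p_vals <- stats::setNames(numeric(3L), stat_names)
  for (s in stat_names) {
    p_vals[s] <- permutation_test(
      data, cfg$model, statistic = s, hierarchy = hier,
      n_perm = cfg$n_perm_amova,
      seed = .stage_seed(cfg$seed, switch(substr(s, 2, 3),
                                          ST = "amova", SC = "rsc",
                                          CT = "rct")))$p
  }
  per_locus_p <- vapply(loci(data), function(loc) {
    permutation_test(data, cfg$model,
                     statistic = stat_names[3L], hierarchy = hier,
                     loci_use = loc, n_perm = max(99L,
                       cfg$n_perm_amova %/% 10L),
                     seed = .stage_seed(cfg$seed, "amova") + match(loc,
                       loci(data)))$p
  }, 0)
  combined$p_values <- p_vals
  report$amova <- list(combined = combined,
                       per_locus_p = per_locus_p,
                       fisher = fisher_combine(per_locus_p))

  # --- pairwise matrices, Reynolds, MDS, Mantel ---
  pw <- pairwise_matrix(data, cfg$model)
  rey <- reynolds_transform(pw$index)
  geo <- pairwise_geo_matrix(meta, cfg$waypoints)
  report$pairwise <- list(index = pw$index, reynolds = rey, geo_km = geo)
  report$mds <- nmds(rey, n_starts = cfg$mds_starts,
                     seed = .stage_seed(cfg$seed, "mds"))
  report$mantel <- mantel(rey, geo, n_perm = cfg$n_perm_mantel,
                          seed = .stage_seed(cfg$seed, "mantel"))

  # --- HWE (genotype mode) ---
  if (cfg$mode == "genotype") {
    report$hwe <- hwe_scan(data, n_draws = cfg$n_hwe_draws,
                           seed = .stage_seed(cfg$seed, "hwe"))
  }

  class(report) <- "run_report"
  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d populations, %d loci (%s mode)\n",
              length(x$populations), length(x$loci), x$config$mode))
  idx <- x$amova$combined$indices
  cat("multi-locus indices:",
      paste(sprintf("%s = %.4f", names(idx), idx), collapse = ", "), "\n")
  cat(sprintf("Mantel r = %.3f (p = %.3g); MDS stress = %.3f\n",
              x$mantel$r, x$mantel$p, x$mds$stress))
  invisible(x)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wm <- function(m, name) {
    utils::write.table(
      data.frame(population = rownames(m), m, check.names = FALSE),
      file.path(out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  wt(report$diversity$table$per_locus, "diversity_per_locus.tsv")
  wt(report$diversity$table$per_population, "diversity_per_population.tsv")
  wt(report$diversity$group_summary_he, "group_summary_he.tsv")
  wt(report$diversity$group_summary_vp, "group_summary_vp.tsv")
  wm(report$pairwise$index, "pairwise_index.tsv")
  wm(report$pairwise$reynolds, "pairwise_reynolds.tsv")
  wm(report$pairwise$geo_km, "pairwise_geo_km.tsv")
  pts <- report$mds$points
  wt(data.frame(population = rownames(pts), dim1 = pts[, 1L],
                dim2 = pts[, 2L]), "mds_coordinates.tsv")
  amv <- report$amova$combined
  amova_tab <- data.frame(stratum = names(amv$sigma2),
                          sigma2 = amv$sigma2, percent = amv$percent)
  wt(amova_tab, "amova_components.tsv")
  summary <- list(
    seed = report$config$seed,
    mode = report$config$mode,
    model = report$config$model,
    n_populations = length(report$populations),
    n_loci = length(report$loci),
    indices = as.list(report$amova$combined$indices),
    index_p_values = as.list(report$amova$combined$p_values),
    fisher_combined_p = report$amova$fisher$p,
    regression_he = unclass(report$geodistance$regression_he),
    regression_vp = unclass(report$geodistance$regression_vp),
    kruskal_he_p = report$diversity$kruskal_he$p,
    kruskal_vp_p = report$diversity$kruskal_vp$p,
    mantel_r = report$mantel$r, mantel_p = report$mantel$p,
    mds_stress = report$mds$stress)
  if (!is.null(report$hwe)) {
    summary$hwe <- report$hwe[c("n_tests", "reject_05", "reject_01",
                                "reject_05_bonferroni",
                                "reject_01_bonferroni")]
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
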