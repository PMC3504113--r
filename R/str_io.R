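# Tabular input/output for STR allele-frequency and genotype data.
#
# Two data modes are supported, mirroring how forensic STR data are
# published: allele-frequency tables (one frequency spectrum per population
# and locus, plus the number of gene copies it summarizes) and diploid
# genotype tables (two repeat-number calls per individual and locus).
# Allele labels are repeat counts and may be non-integer for imperfect
# alleles (e.g. 9.3 = 9 full repeats plus 3 bases); they are carried as
# their literal decimal value in all repeat arithmetic.

#' Construct and validate an allele-frequency table
#'
#' A `freq_table` holds, for every (population, locus) cell, a map from
#' allele label (decimal repeat units) to relative frequency, together with
#' `n_copies`, the number of gene copies (2 x sampled individuals) the
#' frequencies summarize. It is the frequency-only data mode: analyses that
#' need allele copies (AMOVA, permutation tests) reconstruct integer copy
#' counts from `frequency * n_copies` via largest-remainder rounding.
#'
#' @param df data frame with columns `population`, `locus`, `allele`
#'   (numeric, nonnegative), `frequency` (in (0, 1]) and `n_copies`
#'   (integer gene copies, >= 2, constant within a cell).
#' @param tolerance maximum tolerated deviation of each cell's frequency sum
#'   from 1. Published forensic frequency tables are rounded, so small
#'   deviations are tolerated; the default 1e-3 is flagged in validation
#'   errors when exceeded.
#' @return the validated data frame with class `freq_table` and attributes
#'   `populations` and `loci` (orderings of first appearance).
#' @export
freq_table <- function(df, tolerance = 1e-3) {
  need <- c("population", "locus", "allele", "frequency", "n_copies")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("frequency table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(
    population = as.character(df$population),
    locus = as.character(df$locus),
    allele = as.numeric(df$allele),
    frequency = as.numeric(df$frequency),
    n_copies = as.numeric(df$n_copies),
    stringsAsFactors = FALSE
  )
  df <- df[df$frequency != 0, , drop = FALSE]
  if (nrow(df) == 0L) stop("frequency table is empty")
  if (any(!is.finite(df$allele)) || any(df$allele < 0)) {
    stop("allele labels must parse as nonnegative decimal numbers")
  }
  if (any(!is.finite(df$frequency)) || any(df$frequency <= 0) ||
      any(df$frequency > 1)) {
    stop("frequencies must lie in (0, 1]")
  }
  if (any(df$n_copies < 2) || any(df$n_copies != round(df$n_copies))) {
    stop("n_copies must be an integer >= 2")
  }
  cell <- paste(df$population, df$locus, sep = "\r")
  dup <- duplicated(cbind(cell, df$allele))
  if (any(dup)) {
    bad <- df[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicate allele %s in cell (%s, %s)",
                 format(bad$allele), bad$population, bad$locus))
  }
  sums <- tapply(df$frequency, cell, sum)
  off <- abs(sums - 1) > tolerance
  if (any(off)) {
    bad <- strsplit(names(sums)[off][1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "frequencies for (%s, %s) sum to %.6f (deviation > tolerance %g)",
      bad[1L], bad[2L], sums[off][1L], tolerance))
  }
  ncell <- tapply(df$n_copies, cell, function(x) length(unique(x)))
  if (any(ncell > 1L)) {
    bad <- strsplit(names(ncell)[ncell > 1L][1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("inconsistent n_copies within cell (%s, %s)",
                 bad[1L], bad[2L]))
  }
  df$n_copies <- as.integer(df$n_copies)
  structure(df,
            populations = unique(df$population),
            loci = unique(df$locus),
            class = c("freq_table", "data.frame"))
}

#' Construct and validate a diploid genotype table
#'
#' A `genotype_table` holds two repeat-number calls per individual and locus
#' (unordered; stored as given). The validated object is complete-case:
#' every individual carries exactly two calls at every locus.
#'
#' @param df data frame with columns `individual`, `population`, `locus`,
#'   `allele1`, `allele2` (numeric repeat units).
#' @return validated data frame of class `genotype_table` with attributes
#'   `populations`, `loci`, `individuals`.
#' @export
genotype_table <- function(df) {
  need <- c("individual", "population", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- data.frame(
    individual = as.character(df$individual),
    population = as.character(df$population),
    locus = as.character(df$locus),
    allele1 = as.numeric(df$allele1),
    allele2 = as.numeric(df$allele2),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$allele1)) || any(!is.finite(df$allele2)) ||
      any(df$allele1 <= 0) || any(df$allele2 <= 0)) {
    stop("genotype calls must be positive repeat values (no missing calls)")
  }
  if (any(duplicated(df[, c("individual", "locus")]))) {
    stop("duplicated (individual, locus) call")
  }
  loci <- unique(df$locus)
  per_ind <- table(df$individual)
  if (any(per_ind != length(loci))) {
    bad <- names(per_ind)[per_ind != length(loci)][1L]
    stop(sprintf("individual %s is not typed at all %d loci", bad,
                 length(loci)))
  }
  pop_of <- tapply(df$population, df$individual,
                   function(x) length(unique(x)))
  if (any(pop_of > 1L)) {
    stop("an individual is assigned to more than one population")
  }
  ind <- unique(df$individual)
  structure(df,
            populations = unique(df$population),
            loci = loci,
            individuals = ind,
            class = c("genotype_table", "data.frame"))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d loci (%d rows)\n",
              length(attr(x, "populations")), length(attr(x, "loci")),
              nrow(x)))
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci\n",
              length(attr(x, "individuals")),
              length(attr(x, "populations")), length(attr(x, "loci"))))
  invisible(x)
}

#' Populations / loci accessors
#'
#' @param x a `freq_table` or `genotype_table`.
#' @return character vector of population ids / locus names in table order.
#' @export
populations <- function(x) attr(x, "populations")

#' @rdname populations
#' @export
loci <- function(x) attr(x, "loci")

#' Read a long-format allele-frequency table
#'
#' Reads a tab- or comma-separated file with header columns `population`,
#' `locus`, `allele`, `frequency`, `n_copies` (the long-format dialect this
#' package defines for published frequency spectra). Rows belonging to the
#' same (population, locus) cell are merged; zero-frequency rows are
#' dropped; each cell's frequency sum is checked against 1.
#'
#' @param path file path.
#' @param tolerance allowed deviation of per-cell frequency sums from 1.
#' @return a validated [freq_table].
#' @export
read_frequency_table <- function(path, tolerance = 1e-3) {
  sep <- .sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  suppressWarnings({
    av <- as.numeric(df$allele)
    fv <- as.numeric(df$frequency)
  })
  bad <- which(is.na(av) | is.na(fv))
  if (length(bad) > 0L) {
    stop(sprintf("parse error in %s at data line %d: non-numeric allele or frequency",
                 path, bad[1L]))
  }
  freq_table(df, tolerance = tolerance)
}

#' Write a frequency table in the long-format dialect
#'
#' @param ft a [freq_table].
#' @param path output path.
#' @param sep field separator (tab by default).
#' @export
write_frequency_table <- function(ft, path, sep = "\t") {
  df <- as.data.frame(ft)
  df$frequency <- formatC(df$frequency, digits = 6, format = "f")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

# GenePop allele codes are 2 or 3 digits per allele; a 4-digit extension
# encodes decimal microvariants as repeat x 10 (0093 = 9.3, 0100 = 10).
.decode_genepop <- function(code, width) {
  v <- as.numeric(code)
  if (width == 4L) v / 10 else v
}
.encode_genepop <- function(allele, width) {
  v <- if (width == 4L) round(allele * 10) else round(allele)
  formatC(v, width = width, flag = "0")
}

#' Read genotypes from a GenePop file
#'
#' Standard GenePop dialect: a title line, one locus name per line (or one
#' comma-separated line of loci), then `POP`-separated blocks of individuals,
#' each line `id , 0809 1011 ...` with 2- or 3-digit allele codes per allele.
#' A 4-digit extension is also accepted in which codes are repeat x 10, so
#' decimal microvariants (9.3 -> 0093) survive the format. Allele codes are
#' interpreted as repeat counts. Individuals with any missing call (code 0)
#' at the analyzed loci are dropped (complete-case policy) and reported.
#'
#' Populations are named after the id of the first individual in each block
#' (with a positional fallback `pop_<k>`).
#'
#' @param path GenePop file path.
#' @return list with `genotypes` (a [genotype_table]), `populations`
#'   (population ids in file order) and `dropped` (data frame of discarded
#'   individuals with their population).
#' @export
read_genotypes_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("GenePop file too short: ", path)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP block in GenePop file: ", path)
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- unlist(strsplit(locus_lines, "\\s*,\\s*"))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names in GenePop file: ", path)

  pop_idx <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop - 1L)
  rows <- list()
  dropped <- list()
  pop_names <- character(max(pop_idx))
  for (i in body) {
    k <- pop_idx[i]
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("malformed GenePop individual line %d (no comma)", i))
    }
    id <- trimws(parts[1L])
    if (!nzchar(pop_names[k])) {
      pop_names[k] <- if (nzchar(id)) id else sprintf("pop_%d", k)
    }
    codes <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                      "\\s+")[[1L]]
    if (length(codes) != length(loci)) {
      stop(sprintf("line %d: %d allele fields for %d loci", i,
                   length(codes), length(loci)))
    }
    w <- nchar(codes)
    if (any(w %% 2L != 0L) || length(unique(w)) != 1L) {
      stop(sprintf("line %d: odd-length or mixed-width allele codes", i))
    }
    half <- w[1L] %/% 2L
    if (!half %in% c(2L, 3L, 4L)) {
      stop(sprintf("line %d: unsupported allele code width %d", i, half))
    }
    a1 <- .decode_genepop(substr(codes, 1L, half), half)
    a2 <- .decode_genepop(substr(codes, half + 1L, 2L * half), half)
    if (any(a1 == 0) || any(a2 == 0)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(individual = id, population = k,
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(individual = id, population = k, locus = loci,
                 allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("zero individuals retained from ", path)
  df <- do.call(rbind, rows)
  df$population <- pop_names[df$population]
  drop_df <- if (length(dropped) > 0L) {
    dd <- do.call(rbind, dropped)
    dd$population <- pop_names[dd$population]
    dd
  } else {
    data.frame(individual = character(), population = character(),
               stringsAsFactors = FALSE)
  }
  # disambiguate duplicate ids across populations
  df$individual <- paste(df$population, df$individual, sep = ":")
  list(genotypes = genotype_table(df),
       populations = pop_names[nzchar(pop_names)],
       dropped = drop_df)
}

#' Write genotypes to a GenePop file
#'
#' Uses the 4-digit repeat-x-10 code when any allele is non-integer (so
#' imperfect alleles such as 9.3 round-trip exactly), 3-digit codes
#' otherwise.
#'
#' @param g a [genotype_table].
#' @param path output path.
#' @param title title line content.
#' @export
write_genotypes_genepop <- function(g, path, title = "strpopgen export") {
  lc <- loci(g)
  width <- if (any(c(g$allele1, g$allele2) %% 1 != 0)) 4L else 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, lc), con)
  for (pop in populations(g)) {
    writeLines("POP", con)
    sub <- g[g$population == pop, , drop = FALSE]
    for (id in unique(sub$individual)) {
      gi <- sub[sub$individual == id, , drop = FALSE]
      gi <- gi[match(lc, gi$locus), , drop = FALSE]
      codes <- paste0(.encode_genepop(gi$allele1, width),
                      .encode_genepop(gi$allele2, width))
      writeLines(paste(id, ",", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write genotypes in the native long CSV dialect
#'
#' Columns `individual`, `population`, `locus`, `allele1`, `allele2`;
#' lossless for decimal allele labels.
#'
#' @param path file path.
#' @return a [genotype_table].
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  genotype_table(df)
}

#' @rdname read_genotypes_csv
#' @param g a [genotype_table] to write.
#' @export
write_genotypes_csv <- function(g, path) {
  utils::write.table(as.data.frame(g), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert genotypes to an allele-frequency table
#'
#' Per (population, locus), the frequency of allele `a` is its copy count
#' over 2 x individuals, and `n_copies` = 2 x individuals; this bridges the
#' genotype data mode to the frequency-only mode exactly (frequencies sum
#' to 1 by construction).
#'
#' @param g a [genotype_table].
#' @return a [freq_table].
#' @export
frequencies_from_genotypes <- function(g) {
  rows <- list()
  for (loc in loci(g)) {
    sub <- g[g$locus == loc, , drop = FALSE]
    for (pop in populations(g)) {
      a <- c(sub$allele1[sub$population == pop],
             sub$allele2[sub$population == pop])
      tab <- table(a)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pop, locus = loc,
        allele = as.numeric(names(tab)),
        frequency = as.vector(tab) / length(a),
        n_copies = length(a), stringsAsFactors = FALSE)
    }
  }
  ft <- freq_table(do.call(rbind, rows))
  attr(ft, "populations") <- populations(g)
  attr(ft, "loci") <- loci(g)
  ft
}

#' Read population metadata
#'
#' CSV/TSV with columns `population`, `name`, `group`, `lat`, `lon`,
#' `region`, `well_defined`. `group` is the geographic-group label used as
#' the among-groups stratum in hierarchical analyses; `region` keys the
#' waypoint routing table; `well_defined` flags samples of well-defined
#' geographic/ethnic origin (curation is a manual metadata decision honored
#' by filters, never inferred).
#'
#' @param path file path.
#' @return data frame of class `pop_metadata`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  pop_metadata(df)
}

#' @rdname read_metadata
#' @param df data frame with the metadata columns.
#' @export
pop_metadata <- function(df) {
  need <- c("population", "group", "lat", "lon", "region")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$name)) df$name <- df$population
  if (is.null(df$well_defined)) df$well_defined <- TRUE
  df$well_defined <- as.logical(df$well_defined)
  if (any(df$lat < -90 | df$lat > 90) ||
      any(df$lon < -180 | df$lon > 180)) {
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  }
  if (any(!nzchar(df$group)) || any(!nzchar(df$region))) {
    stop("group and region labels must be non-empty")
  }
  if (any(duplicated(df$population))) stop("duplicated population id")
  class(df) <- c("pop_metadata", "data.frame")
  df
}

#' Hierarchy configuration (population -> geographic group)
#'
#' @param pop character vector of population ids (each exactly once), or a
#'   `pop_metadata` object from which the mapping is taken.
#' @param group character vector of group labels, parallel to `pop`.
#' @return named character vector (names = populations, values = groups)
#'   of class `hierarchy_config`.
#' @export
hierarchy_config <- function(pop, group = NULL) {
  if (inherits(pop, "pop_metadata")) {
    group <- pop$group
    pop <- pop$population
  }
  if (length(pop) != length(group)) stop("pop and group lengths differ")
  if (any(duplicated(pop))) stop("every population must appear exactly once")
  if (length(unique(group)) < 2L) stop("need >= 2 groups")
  structure(stats::setNames(as.character(group), as.character(pop)),
            class = "hierarchy_config")
}

#' Drop complex loci from a dataset
#'
#' Removes the loci whose imperfect-repeat structure most strains the
#' stepwise mutation assumption. The default list (FGA, D21S11, TH01)
#' reproduces the standard 10-of-13-CODIS robustness re-run.
#'
#' @param x a [freq_table] or [genotype_table].
#' @param drop locus names to remove.
#' @return the same class of table without the dropped loci.
#' @export
drop_complex_loci <- function(x, drop = c("FGA", "D21S11", "TH01")) {
  keep <- !(x$locus %in% drop)
  if (!any(keep)) stop("dropping these loci leaves no data")
  df <- as.data.frame(x)[keep, , drop = FALSE]
  if (inherits(x, "freq_table")) freq_table(df) else genotype_table(df)
}

# ---- internal: copy-count reconstruction -----------------------------------

# Largest-remainder apportionment of n copies to allele frequencies.
.largest_remainder <- function(freq, n) {
  target <- freq * n
  base <- floor(target + 1e-9)
  extra <- as.integer(round(n) - sum(base))
  if (extra != 0L) {
    rem <- target - base
    ord <- order(if (extra > 0L) -rem else rem)
    take <- ord[seq_len(abs(extra))]
    base[take] <- base[take] + sign(extra)
  }
  as.integer(base)
}

# Per-locus allele-count matrix (alleles x populations) plus allele values.
# Frequency tables reconstruct integer counts; genotype tables count copies.
# `sub` short-circuits the per-locus subset (see .locus_counts_all).
.locus_counts <- function(x, locus, pops = NULL, sub = NULL) {
  if (inherits(x, "freq_table")) {
    if (is.null(sub)) sub <- x[x$locus == locus, , drop = FALSE]
    if (is.null(pops)) pops <- intersect(populations(x), sub$population)
    alleles <- sort(unique(sub$allele))
    cmat <- matrix(0L, length(alleles), length(pops),
                   dimnames = list(NULL, pops))
    for (j in seq_along(pops)) {
      cell <- sub[sub$population == pops[j], , drop = FALSE]
      if (nrow(cell) == 0L) stop(sprintf("no data for (%s, %s)",
                                         pops[j], locus))
      cnt <- .largest_remainder(cell$frequency, cell$n_copies[1L])
      cmat[match(cell$allele, alleles), j] <- cnt
    }
  } else if (inherits(x, "genotype_table")) {
    if (is.null(sub)) sub <- x[x$locus == locus, , drop = FALSE]
    if (is.null(pops)) pops <- intersect(populations(x), sub$population)
    a <- c(sub$allele1, sub$allele2)
    p <- c(sub$population, sub$population)
    keep <- p %in% pops
    a <- a[keep]; p <- factor(p[keep], levels = pops)
    alleles <- sort(unique(a))
    cmat <- matrix(0L, length(alleles), length(pops),
                   dimnames = list(NULL, pops))
    tb <- table(factor(a, levels = alleles), p)
    cmat[] <- as.integer(tb)
  } else {
    stop("need a freq_table or genotype_table")
  }
  list(alleles = alleles, counts = cmat, pops = pops)
}

# All loci at once (splits the table a single time).
.locus_counts_all <- function(x, pops = NULL) {
  df <- as.data.frame(x)
  cls <- class(x)[1L]
  subs <- split(df, factor(df$locus, levels = loci(x)))
  out <- lapply(loci(x), function(loc) {
    sub <- subs[[loc]]
    class(sub) <- c(cls, "data.frame")
    .locus_counts(x, loc, pops, sub = sub)
  })
  names(out) <- loci(x)
  out
}
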