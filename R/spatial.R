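# Spatial structure: nonmetric MDS of genetic distance matrices and the
# Mantel correlation between genetic and geographic distances.

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Two-dimensional nonmetric (rank-based) MDS minimizing Kruskal's
#' stress-1, best of `n_starts` initializations (the classical metric
#' solution plus seeded random configurations). Outlier populations are
#' handled by an explicit exclusion list, mirroring the practice of
#' removing a by-inspection outlier before refitting; there is no
#' automatic outlier detection.
#'
#' @param d symmetric distance matrix with population dimnames.
#' @param n_starts number of initializations.
#' @param seed RNG seed.
#' @param exclude population names removed before fitting.
#' @param k embedding dimension (2 by default).
#' @return list of class `mds_result`: `points` (centroid at the origin),
#'   `stress` (Kruskal stress-1 as a fraction), `n_starts`, `seed`,
#'   `excluded`.
#' @export
nmds <- function(d, n_starts = 16L, seed = NULL, exclude = NULL, k = 2L) {
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (!is.null(exclude)) {
    keep <- !(rownames(d) %in% exclude)
    d <- d[keep, keep, drop = FALSE]
  }
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 populations after exclusions")
  off <- d[upper.tri(d)]
  if (all(off == 0)) stop("all-zero distance matrix")
  # isoMDS needs strictly positive off-diagonal dissimilarities
  eps <- max(off) * 1e-9
  dfix <- pmax(d, eps)
  diag(dfix) <- 0
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  dd <- stats::as.dist(dfix)
  best <- NULL
  scale0 <- max(off)
  for (s in seq_len(n_starts)) {
    init <- if (s == 1L) {
      stats::cmdscale(dd, k = k)
    } else {
      matrix(stats::rnorm(n * k, sd = scale0), n, k)
    }
    if (ncol(init) < k) {  # degenerate cmdscale output
      init <- cbind(init, matrix(0, n, k - ncol(init)))
    }
    fit <- tryCatch(
      MASS::isoMDS(dd, y = init, k = k, trace = FALSE, maxit = 100),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$stress < best$stress)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all MDS starts failed")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = best$stress / 100,
                 n_starts = n_starts, seed = seed,
                 excluded = exclude %||% character()),
            class = "mds_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("nonmetric MDS: %d points, stress-1 = %.4f\n",
              nrow(x$points), x$stress))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' one-tailed permutation test for positive association (rows and columns
#' of the second matrix permuted jointly) — the standard
#' isolation-by-distance test of genetic against geographic distances.
#'
#' @param d1,d2 symmetric matrices over the same populations in the same
#'   order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 1000L, seed = NULL) {
  if (!all(dim(d1) == dim(d2))) stop("matrix dimensions differ")
  n <- nrow(d1)
  if (n < 4L) stop("need >= 4 populations")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("population order differs between matrices")
  }
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  if (stats::var(v1) == 0 || stats::var(v2) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- stats::cor(v1, v2)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    rp <- stats::cor(v1, d2[pm, pm][ut])
    if (rp >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, one-tailed p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
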