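# Ordination and distance-based group tests: principal coordinate analysis
# (Gower double-centering), PERMANOVA with label permutations, and the
# multivariate dispersion (distance-to-center) analysis, including the
# imaginary-axis correction needed for semi-metric distances such as UniFrac.

checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must carry sample names")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix diagonal must be zero")
  if (min(D) < 0) stop("distances must be non-negative")
  invisible(TRUE)
}

#' Principal coordinate analysis
#'
#' Gower-centers the squared distance matrix (`-0.5 * J D^2 J`), eigen-
#' decomposes it, and scales eigenvectors by the square roots of the positive
#' eigenvalues. Negative eigenvalues (semi-metric input) are reported but
#' receive no coordinate axes.
#'
#' @param D symmetric distance matrix with sample dimnames (n >= 3).
#' @return list of class `"PcoaOrdination"`: `points` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `proportion_explained` (over the
#'   positive eigenvalues).
#' @export
pcoa <- function(D) {
  checkDistanceMatrix(D)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  pts <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = eg$values,
                 proportion_explained = pmax(eg$values, 0) /
                   sum(pmax(eg$values, 0))),
            class = "PcoaOrdination")
}

#' @export
print.PcoaOrdination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes; first axes explain %s\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f%%",
                            100 * utils::head(x$proportion_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

# pseudo-F from a squared-distance matrix and a group assignment
permanovaF <- function(D2, labels) {
  n <- nrow(D2)
  groups <- unique(labels)
  g <- length(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (gr in groups) {
    idx <- which(labels == gr)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Distance-based sum-of-squares decomposition; the pseudo-F statistic
#' `(SS_between / (g - 1)) / (SS_within / (n - g))` is compared with its
#' distribution under random relabelings, giving
#' `p = (1 + #[F* >= F]) / (1 + n_permutations)`.
#'
#' @param D symmetric distance matrix with sample dimnames.
#' @param labels group label per sample (>= 2 groups, each with >= 2
#'   samples), in row order of `D` or named by sample.
#' @param n_permutations number of random relabelings (default 999).
#' @param seed integer seed; the same seed reproduces the same p-value.
#' @return list of class `"PermanovaResult"`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `df`.
#' @export
permanova <- function(D, labels, n_permutations = 999, seed = NULL) {
  checkDistanceMatrix(D)
  if (!is.null(names(labels))) labels <- labels[rownames(D)]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(D))
  tab <- table(labels)
  if (length(tab) < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  D2 <- D * D
  Fobs <- permanovaF(D2, labels)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(k) permanovaF(D2, sample(labels)) >= Fobs, TRUE))
  })
  structure(list(pseudo_F = Fobs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 df = c(between = length(tab) - 1L,
                        within = nrow(D) - length(tab))),
            class = "PermanovaResult")
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d/%d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$p_value, x$n_permutations))
  invisible(x)
}

# Weiszfeld iteration for the spatial median of the rows of X.
spatialMedian <- function(X, tol = 1e-8, max_iter = 1000L) {
  if (ncol(X) == 0) return(numeric(0))
  m <- colMeans(X)
  for (it in seq_len(max_iter)) {
    d <- pmax(sqrt(rowSums(sweep(X, 2, m)^2)), 1e-10)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Multivariate dispersion: per-group mean distance to center
#'
#' Embeds the distance matrix by PCoA keeping negative-eigenvalue axes as an
#' imaginary block, finds each group's spatial median (Weiszfeld iteration to
#' tolerance 1e-8) or centroid in both blocks, and measures each sample's
#' distance to its group center as `sqrt(max(d_real^2 - d_imag^2, 0))` — the
#' standard correction for semi-metric distances.
#'
#' @param D symmetric distance matrix with sample dimnames.
#' @param labels group label per sample (each group >= 2 samples).
#' @param center `"median"` (default) or `"centroid"`.
#' @return list with `group_means` (named mean distance-to-center per group)
#'   and `distances` (per-sample distances, named).
#' @export
dispersion <- function(D, labels, center = c("median", "centroid")) {
  checkDistanceMatrix(D)
  center <- match.arg(center)
  if (!is.null(names(labels))) labels <- labels[rownames(D)]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(D))
  tab <- table(labels)
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Xr <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  Xi <- eg$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eg$values[neg]), sum(neg))
  dist_to <- numeric(n)
  for (gr in names(tab)) {
    idx <- which(labels == gr)
    cr <- if (center == "median") spatialMedian(Xr[idx, , drop = FALSE])
          else colMeans(Xr[idx, , drop = FALSE])
    ci <- if (ncol(Xi) == 0) numeric(0)
          else if (center == "median") spatialMedian(Xi[idx, , drop = FALSE])
          else colMeans(Xi[idx, , drop = FALSE])
    d2r <- rowSums(sweep(Xr[idx, , drop = FALSE], 2, cr)^2)
    d2i <- if (ncol(Xi) == 0) 0
           else rowSums(sweep(Xi[idx, , drop = FALSE], 2, ci)^2)
    dist_to[idx] <- sqrt(pmax(d2r - d2i, 0))
  }
  names(dist_to) <- rownames(D)
  list(group_means = vapply(names(tab),
                            function(gr) mean(dist_to[labels == gr]), 1),
       distances = dist_to)
}
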