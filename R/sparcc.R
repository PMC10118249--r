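# Compositional correlation inference from log-ratio variances.
#
# Relative abundances live on the simplex, so naive Pearson correlations of
# proportions are spurious. Instead, for each taxon pair the variance of the
# log ratio t_ij = var(log(x_i / x_j)) is computed — a quantity invariant to
# the per-sample total — and decomposed as
#     t_ij = w_i^2 + w_j^2 - 2 rho_ij w_i w_j,
# where w_i^2 are the latent ("basis") variances and rho_ij the basis
# correlations. Under the sparsity assumption (most pairs uncorrelated), the
# row sums of T yield a linear system for the basis variances; solving it and
# inverting the decomposition gives rho. Strongly correlated pairs violate
# the assumption, so the single most correlated pair above a threshold is
# iteratively removed from the system and the system re-solved. Counts are
# converted to strictly positive fractions by Dirichlet posterior draws
# (prior = counts + 1), the whole estimate is repeated n_inner times, and the
# element-wise median is reported. Significance is assessed by permuting each
# taxon's counts across samples (destroying all associations, preserving
# marginals) and recomputing the estimate.

#' Log-ratio variance matrix
#'
#' `t_ij` = sample variance (n - 1 denominator) of `log(x_i) - log(x_j)`
#' across samples.
#'
#' @param fractions samples x taxa matrix of strictly positive fractions
#'   (n >= 3 samples).
#' @return symmetric matrix with zero diagonal and taxon dimnames.
#' @export
logratioVarianceMatrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 3) stop("need at least 3 samples")
  if (any(fractions <= 0))
    stop("fractions must be strictly positive; resample counts first")
  L <- log(fractions)
  S <- stats::cov(L)
  v <- diag(S)
  T <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * S
  T[T < 0] <- 0  # numerical noise on proportional pairs
  diag(T) <- 0
  dimnames(T) <- list(colnames(fractions), colnames(fractions))
  T
}

# One pass of the basis-variance linear system under a pair-exclusion mask.
# M omega^2 = t with M[i,i] = (D - 1) - #excluded pairs at i, M[i,j] = 1 for
# included pairs, 0 for excluded; t_i = sum over included j of t_ij.
solveBasis <- function(T, included, var_floor = 1e-10) {
  D <- ncol(T)
  M <- included * 1
  diag(M) <- rowSums(included)
  t_vec <- rowSums(T * included)
  omega2 <- tryCatch(solve(M, t_vec), error = function(e)
    stop("basis system singular after exclusions; ",
         "reduce max_exclusions or raise the exclusion threshold"))
  pmax(omega2, var_floor)
}

basisRho <- function(T, omega2) {
  w <- sqrt(omega2)
  rho <- (outer(omega2, rep(1, length(omega2))) +
          outer(rep(1, length(omega2)), omega2) - T) / (2 * outer(w, w))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- dimnames(T)
  rho
}

#' Estimate basis variances and correlations from a log-ratio variance matrix
#'
#' Solves the sparsity-approximation linear system for the basis variances,
#' forms `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)` (clipped to
#' \[-1, 1\]), then iteratively excludes the single most correlated pair with
#' `|rho| >` `exclusion_threshold` from the system and re-solves, until no
#' pair exceeds the threshold or `max_exclusions` is reached.
#'
#' @param T log-ratio variance matrix from [logratioVarianceMatrix()]
#'   (>= 4 taxa).
#' @param exclusion_threshold |rho| above which a pair violates the sparsity
#'   assumption (default 0.1).
#' @param max_exclusions cap on excluded pairs (default D - 3, keeping the
#'   system comfortably determined).
#' @return list with `omega2` (basis variances, floored at 1e-10), `rho`
#'   (correlation matrix), `n_excluded`.
#' @export
estimateBasisCorrelations <- function(T, exclusion_threshold = 0.1,
                                      max_exclusions = ncol(T) - 3L) {
  D <- ncol(T)
  if (D < 4) stop("basis estimation needs at least 4 taxa")
  included <- matrix(TRUE, D, D)
  diag(included) <- FALSE
  n_excluded <- 0L
  repeat {
    omega2 <- solveBasis(T, included)
    rho <- basisRho(T, omega2)
    if (n_excluded >= max_exclusions) break
    cand <- abs(rho)
    cand[!included] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    included[ij[1], ij[2]] <- included[ij[2], ij[1]] <- FALSE
    n_excluded <- n_excluded + 1L
  }
  list(omega2 = omega2, rho = rho, n_excluded = n_excluded)
}

dirichletFractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow = nrow(counts), dimnames = dimnames(counts))
  g / rowSums(g)
}

#' SparCC-style basis correlations for a count table
#'
#' Repeats `n_inner` times: draw per-sample fractions from the Dirichlet
#' posterior with parameters `counts + 1`, compute the log-ratio variance
#' matrix, and estimate basis correlations; the element-wise median across
#' repetitions is returned. Deterministic for a fixed seed.
#'
#' @param counts a counts-kind [OtuTable-class] (or bare counts matrix,
#'   samples x taxa); >= 4 taxa and >= 5 samples.
#' @param n_inner Dirichlet resampling repetitions (default 20).
#' @param exclusion_threshold passed to [estimateBasisCorrelations()].
#' @param seed integer seed.
#' @return a [CorrelationEstimate-class] (without p-values).
#' @seealso [sparccPvalues()]
#' @export
sparcc <- function(counts, n_inner = 20, exclusion_threshold = 0.1,
                   seed = NULL) {
  m <- if (is(counts, "OtuTable")) {
    if (tableKind(counts) != "counts") stop("sparcc expects a counts table")
    abundances(counts)
  } else as.matrix(counts)
  if (ncol(m) < 4) stop("sparcc needs at least 4 taxa")
  if (nrow(m) < 5) stop("sparcc needs at least 5 samples")
  reps <- withSeed(seed, {
    lapply(seq_len(n_inner), function(k) {
      fr <- dirichletFractions(m)
      estimateBasisCorrelations(logratioVarianceMatrix(fr),
                                exclusion_threshold = exclusion_threshold)$rho
    })
  })
  arr <- array(unlist(reps), dim = c(ncol(m), ncol(m), n_inner))
  rho <- apply(arr, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(m), colnames(m))
  new("CorrelationEstimate", rho = rho,
      pvals = matrix(numeric(0), 0, 0),
      n_inner = as.integer(n_inner), n_boot = 0L,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each replicate independently permutes every taxon's counts across samples
#' — destroying all pairwise associations while preserving each taxon's
#' marginal distribution — and recomputes the correlation estimate with the
#' same settings. Two-sided pseudo p-values are
#' `(1 + #[|rho*| >= |rho|]) / (1 + n_boot)`.
#'
#' @param counts the same counts the estimate was computed from.
#' @param est [CorrelationEstimate-class] from [sparcc()] on those counts.
#' @param n_boot permutation replicates (>= 19, so that p < 0.05 is
#'   reachable; default 100).
#' @param seed integer seed.
#' @return the estimate with its `pvals` slot filled (symmetric, entries in
#'   (0, 1], diagonal 1).
#' @export
sparccPvalues <- function(counts, est, n_boot = 100, seed = NULL) {
  stopifnot(is(est, "CorrelationEstimate"))
  if (n_boot < 19) stop("n_boot must be >= 19 to resolve p < 0.05")
  m <- if (is(counts, "OtuTable")) abundances(counts) else as.matrix(counts)
  stopifnot(identical(colnames(m), taxonNames(est)))
  obs <- abs(correlations(est))
  exceed <- matrix(0, ncol(m), ncol(m))
  withSeed(seed, {
    for (b in seq_len(n_boot)) {
      perm <- apply(m, 2, sample)
      rownames(perm) <- rownames(m)
      r_star <- sparcc(perm, n_inner = est@n_inner, seed = NULL)
      exceed <- exceed + (abs(correlations(r_star)) >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_boot)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(obs)
  new("CorrelationEstimate", rho = est@rho, pvals = p,
      n_inner = est@n_inner, n_boot = as.integer(n_boot), seed = est@seed)
}
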