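# Alpha diversity: Chao1 richness, inverse Simpson diversity, Faith's
# phylogenetic diversity, plus the richness-diversity correlation and the
# one-way ANOVA used for group comparisons.

#' Chao1 richness estimator
#'
#' With observed richness S, singleton count F1 and doubleton count F2:
#' the classic estimator S + F1^2 / (2 F2) when F2 > 0, and the
#' bias-corrected form S + F1 (F1 - 1) / (2 (F2 + 1)) when F2 = 0 (or always,
#' with `bias_corrected = TRUE`). Defined on read counts only — the estimator
#' is meaningless on proportions.
#'
#' @param counts non-negative integer vector of per-taxon read counts.
#' @param bias_corrected use the bias-corrected form for all inputs.
#' @return estimated richness (>= observed richness).
#' @examples
#' chao1(c(5, 3, 1, 1, 2))  # 5 + 2^2/(2*1) = 7
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  if (!isWholeNumber(counts))
    stop("chao1 requires counts (non-negative integers)")
  if (any(counts < 0)) stop("chao1 requires non-negative counts")
  counts <- round(counts)
  S <- sum(counts > 0)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (bias_corrected || F2 == 0) S + F1 * (F1 - 1) / (2 * (F2 + 1))
  else S + F1^2 / (2 * F2)
}

#' Inverse Simpson diversity index
#'
#' `1 / sum(p_i^2)` over the positive entries of a proportion vector; equals
#' the taxon count for a uniform community and 1 for a single-taxon one.
#'
#' @param proportions numeric vector summing to 1 (tolerance 1e-6); at least
#'   one positive entry.
#' @return the index, in \[1, S_obs\].
#' @export
inverseSimpson <- function(proportions) {
  if (!is.numeric(proportions) || !length(proportions) ||
      all(proportions == 0))
    stop("inverseSimpson needs a proportion vector with a positive entry")
  if (any(proportions < 0)) stop("negative proportions")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1")
  p <- proportions[proportions > 0]
  1 / sum(p^2)
}

#' Pearson correlation between per-sample richness and diversity
#'
#' @param richness,diversity paired numeric vectors (n >= 3), each with
#'   nonzero variance.
#' @return list with `r` (Pearson correlation) and `p_value` (two-sided, from
#'   the t transform with n - 2 df).
#' @export
richnessDiversityCorrelation <- function(richness, diversity) {
  stopifnot(length(richness) == length(diversity))
  if (length(richness) < 3) stop("need at least 3 paired samples")
  if (stats::sd(richness) == 0 || stats::sd(diversity) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(richness, diversity, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Classical one-way ANOVA across groups
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return list with `F` and `p_value` (upper tail of the F distribution).
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(y ~ f, var.equal = TRUE)
  Fv <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (is.nan(Fv)) { Fv <- 0; p <- 1 }  # zero within- and between-group SS
  list(F = Fv, p_value = p)
}

#' Per-sample diversity records
#'
#' Computes, for every sample: total reads, observed richness, singleton and
#' doubleton counts, Chao1 richness, inverse Simpson diversity, and (when a
#' tree is supplied) Faith's phylogenetic diversity over the taxa present.
#'
#' @param table a counts-kind [OtuTable-class].
#' @param tree optional rooted [ape::phylo] whose leaves cover the taxa.
#' @param bias_corrected passed to [chao1()].
#' @return data.frame with one row per sample (`sample_id`, `group`, `reads`,
#'   `s_obs`, `f1`, `f2`, `chao1`, `inv_simpson`, `faith_pd`).
#' @export
sampleDiversity <- function(table, tree = NULL, bias_corrected = FALSE) {
  stopifnot(is(table, "OtuTable"))
  if (tableKind(table) != "counts")
    stop("sampleDiversity expects a counts-kind table")
  v <- abundances(table)
  g <- sampleGroups(table)
  recs <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    p <- x / sum(x)
    pd <- if (!is.null(tree))
      faithPD(colnames(v)[x > 0], tree) else NA_real_
    data.frame(sample_id = rownames(v)[i],
               group = if (is.null(g)) NA_character_ else unname(g[i]),
               reads = sum(x), s_obs = sum(x > 0),
               f1 = sum(x == 1), f2 = sum(x == 2),
               chao1 = chao1(x, bias_corrected = bias_corrected),
               inv_simpson = inverseSimpson(p),
               faith_pd = pd, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Per-group mean +/- sd summary of diversity indices
#'
#' Rows are the indices (reads, observed taxa, Chao1, inverse Simpson, and
#' Faith's PD when available); columns are ALL plus each group; entries are
#' `mean+/-sd` strings, with the numeric means and sds returned alongside.
#'
#' @param records data.frame from [sampleDiversity()].
#' @return list with `formatted` (character data.frame shaped like a summary
#'   table) and `numeric` (long data.frame of group/index/mean/sd).
#' @export
summarizeGroups <- function(records) {
  idx_cols <- c(reads = "reads", observed_otus = "s_obs", chao1 = "chao1",
                inv_simpson = "inv_simpson", faith_pd = "faith_pd")
  if (all(is.na(records$faith_pd)))
    idx_cols <- idx_cols[names(idx_cols) != "faith_pd"]
  grps <- if (all(is.na(records$group))) character() else unique(records$group)
  cols <- c("ALL", grps)
  num <- do.call(rbind, lapply(cols, function(gr) {
    sub <- if (gr == "ALL") records else records[records$group == gr, ]
    data.frame(group = gr, index = names(idx_cols),
               mean = vapply(idx_cols, function(cn) mean(sub[[cn]]), 1),
               sd = vapply(idx_cols, function(cn) stats::sd(sub[[cn]]), 1),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  num$sd[is.na(num$sd)] <- 0  # single-sample group
  fmt <- sapply(cols, function(gr) {
    sub <- num[num$group == gr, ]
    sprintf("%.1f±%.1f", sub$mean, sub$sd)
  })
  fmt <- matrix(fmt, nrow = length(idx_cols),
                dimnames = list(names(idx_cols), cols))
  list(formatted = as.data.frame(fmt, stringsAsFactors = FALSE), numeric = num)
}
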