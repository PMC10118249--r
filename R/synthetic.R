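# Logistic-normal -> multinomial simulator with planted community structure.
#
# Latent log-abundances are multivariate normal with a block-structured
# correlation matrix: taxa inside a "club" block share a positive intra-block
# correlation, designated block pairs ("rivalries") share a negative
# cross-block correlation, and group-specific log-fold shifts move designated
# blocks up or down in particular sample groups. Exponentiated latents are
# renormalized to proportions and observed as multinomial reads at a
# uniform-random depth, which reproduces the compositional, sparse character
# of 16S OTU tables that the correlation stage assumes.

#' Specify a synthetic compositional cohort
#'
#' @param groups named integer vector: group name -> number of samples.
#' @param n_taxa total number of taxa.
#' @param blocks list of blocks, each `list(taxa = <integer indices>,
#'   cor = <intra-block correlation in (0,1)>)`. Blocks must be disjoint.
#' @param rival_pairs list of rivalries, each `list(a = <block>, b = <block>,
#'   cor = <cross-block correlation in (-1,0)>)`.
#' @param group_logfold data.frame with columns `group`, `block`, `logfold`:
#'   additive shift on the latent log scale applied to that block's taxa in
#'   that group's samples.
#' @param base_log_mean numeric vector (length `n_taxa`) of baseline latent
#'   log-abundances.
#' @param base_log_sd numeric vector (length `n_taxa` or 1) of latent log
#'   standard deviations.
#' @param depth_range integer pair: sequencing depth is drawn uniformly in
#'   `[depth_range[1], depth_range[2]]`; the minimum must be >= 100.
#' @param seed integer seed (NULL uses the ambient RNG stream).
#' @return a validated spec (class `"SyntheticSpec"`).
#' @seealso [defaultSyntheticSpec()], [generateDataset()]
#' @export
syntheticSpec <- function(groups, n_taxa, blocks = list(), rival_pairs = list(),
                          group_logfold = NULL, base_log_mean = rep(0, n_taxa),
                          base_log_sd = rep(1, n_taxa),
                          depth_range = c(2500L, 4100L), seed = NULL) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("'groups' must be a named vector (group name -> n_samples)")
  if (any(groups < 1)) stop("every group needs at least one sample")
  n_taxa <- as.integer(n_taxa)
  if (length(base_log_sd) == 1L) base_log_sd <- rep(base_log_sd, n_taxa)
  stopifnot(length(base_log_mean) == n_taxa, length(base_log_sd) == n_taxa,
            all(base_log_sd >= 0))
  if (length(depth_range) != 2L || depth_range[1] < 100 ||
      depth_range[2] < depth_range[1])
    stop("depth_range must be (min, max) with min >= 100")
  all_block_taxa <- unlist(lapply(blocks, `[[`, "taxa"))
  if (anyDuplicated(all_block_taxa)) stop("blocks must be disjoint")
  if (length(all_block_taxa) && (min(all_block_taxa) < 1 ||
                                 max(all_block_taxa) > n_taxa))
    stop("block taxon indices out of range")
  for (b in blocks)
    if (b$cor <= 0 || b$cor >= 1)
      stop("intra-block correlation must lie in (0, 1)")
  for (rp in rival_pairs) {
    if (rp$a < 1 || rp$a > length(blocks) || rp$b < 1 || rp$b > length(blocks) ||
        rp$a == rp$b)
      stop("rival pair must name two distinct existing blocks")
    if (rp$cor >= 0 || rp$cor <= -1)
      stop("cross-block correlation must lie in (-1, 0)")
  }
  if (!is.null(group_logfold)) {
    stopifnot(is.data.frame(group_logfold),
              all(c("group", "block", "logfold") %in% names(group_logfold)),
              all(group_logfold$group %in% names(groups)),
              all(group_logfold$block %in% seq_along(blocks)))
  }
  spec <- structure(
    list(groups = groups, n_taxa = n_taxa, blocks = blocks,
         rival_pairs = rival_pairs, group_logfold = group_logfold,
         base_log_mean = as.numeric(base_log_mean),
         base_log_sd = as.numeric(base_log_sd),
         depth_range = as.integer(depth_range),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "SyntheticSpec")
  # fail early if the planted correlations are jointly infeasible
  latentCorrelation(spec)
  spec
}

# Assemble the planted latent correlation matrix and check it is positive
# definite; on failure, name the blocks involved in rivalries (the usual
# offenders: |cross| too large relative to the intra-block correlations).
latentCorrelation <- function(spec) {
  D <- spec$n_taxa
  R <- diag(D)
  for (b in spec$blocks) {
    idx <- b$taxa
    R[idx, idx] <- b$cor
  }
  diag(R) <- 1
  for (rp in spec$rival_pairs) {
    ia <- spec$blocks[[rp$a]]$taxa
    ib <- spec$blocks[[rp$b]]$taxa
    R[ia, ib] <- rp$cor
    R[ib, ia] <- rp$cor
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    off <- if (length(spec$rival_pairs))
      paste(vapply(spec$rival_pairs,
                   function(rp) sprintf("(%d,%d)", rp$a, rp$b), ""),
            collapse = ", ")
    else "none"
    stop("planted correlations are not positive definite; ",
         "offending rival block pairs: ", off)
  }
  list(R = R, chol = ch)
}

#' Default synthetic cohort mirroring the study design
#'
#' Three groups of 9, 24 and 22 samples (never / former / active smokers),
#' read depths uniform in 2500-4100, three planted clubs of 6, 5 and 5 taxa
#' at intra-block correlation 0.8, one planted rivalry between blocks 1 and 2
#' at -0.5, and a smoker-enriched block 3 shifted by +2.3 (former) and +2.6
#' (active) log units — the magnitude of the dominant-genus expansion reported
#' in smokers' airways (roughly 2% to 21-28% relative abundance). Baseline
#' log-abundances place the 16 block taxa at a prevalent level and spread the
#' background taxa over a wide dynamic range so that, at these depths, only a
#' minority of taxa pass a 50% prevalence screen — as in real BAL tables.
#'
#' @param n_taxa taxon panel size (default 300; scale down for quick runs —
#'   the planted 16-taxon block structure is kept intact).
#' @param seed integer seed.
#' @return a `"SyntheticSpec"`.
#' @export
defaultSyntheticSpec <- function(n_taxa = 300, seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 32) stop("n_taxa must be at least 32 to host the planted blocks")
  blocks <- list(
    list(taxa = 1:6,   cor = 0.8),
    list(taxa = 7:11,  cor = 0.8),
    list(taxa = 12:16, cor = 0.8))
  base_mean <- c(rep(1, 16), seq(2, -14, length.out = n_taxa - 16L))
  syntheticSpec(
    groups = c(NS = 9L, FS = 24L, AS = 22L),
    n_taxa = n_taxa,
    blocks = blocks,
    rival_pairs = list(list(a = 1L, b = 2L, cor = -0.5)),
    group_logfold = data.frame(
      group = c("FS", "AS"), block = c(3L, 3L), logfold = c(2.3, 2.6)),
    base_log_mean = base_mean,
    base_log_sd = rep(1, n_taxa),
    depth_range = c(2500L, 4100L),
    seed = seed)
}

#' Generate a synthetic dataset from a spec
#'
#' Per sample: draw latent log-abundances from the block-structured
#' multivariate normal (plus the sample group's log-fold shifts),
#' exponentiate, renormalize to proportions, and draw reads multinomially at
#' a uniform-random depth. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a `"SyntheticSpec"` from [syntheticSpec()].
#' @return list of class `"SyntheticDataset"` with elements `table` (counts
#'   [OtuTable-class] with group labels), `tree` (random phylogeny over the
#'   taxa), and `truth` (latent correlation matrix, block membership, rival
#'   pairs).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  lat <- latentCorrelation(spec)
  D <- spec$n_taxa
  taxa <- sprintf("taxon_%03d", seq_len(D))
  withSeed(spec$seed, {
    rows <- list()
    groups_of <- character()
    for (g in names(spec$groups)) {
      ng <- spec$groups[[g]]
      mu <- spec$base_log_mean
      if (!is.null(spec$group_logfold)) {
        sh <- spec$group_logfold[spec$group_logfold$group == g, , drop = FALSE]
        for (k in seq_len(nrow(sh)))
          mu[spec$blocks[[sh$block[k]]]$taxa] <-
            mu[spec$blocks[[sh$block[k]]]$taxa] + sh$logfold[k]
      }
      for (i in seq_len(ng)) {
        eps <- drop(stats::rnorm(D) %*% lat$chol) * spec$base_log_sd
        p <- exp(mu + eps)
        p <- p / sum(p)
        depth <- sample(seq(spec$depth_range[1], spec$depth_range[2]), 1L)
        sid <- sprintf("%s_%02d", g, i)
        rows[[sid]] <- drop(stats::rmultinom(1L, depth, p))
        groups_of[sid] <- g
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- taxa
    tree <- generateTree(taxa, seed = deriveSeed(spec$seed, 1L))
  })
  dimnames(lat$R) <- list(taxa, taxa)
  block_of <- integer()
  for (b in seq_along(spec$blocks))
    block_of[taxa[spec$blocks[[b]]$taxa]] <- b
  structure(
    list(table = otuTable(counts, kind = "counts", groups = groups_of),
         tree = tree,
         truth = list(correlation = lat$R, blocks = block_of,
                      rival_pairs = spec$rival_pairs),
         spec = spec),
    class = "SyntheticDataset")
}

#' Generate a random rooted binary phylogeny over given taxa
#'
#' Topology is built by sequential random joins (pick two subtrees uniformly
#' at random, join them under a new internal node, repeat); every non-root
#' node receives an independent Exponential(1) branch length, so a tree on n
#' taxa has 2n - 2 edges with expected total length 2n - 2.
#'
#' @param taxon_ids character vector of leaf names (>= 2).
#' @param seed integer seed (NULL uses the ambient stream).
#' @return an [ape::phylo] rooted binary tree.
#' @export
generateTree <- function(taxon_ids, seed = NULL) {
  if (length(taxon_ids) < 2L) stop("need at least 2 taxa to build a tree")
  withSeed(seed, {
    items <- taxon_ids
    while (length(items) > 1L) {
      pick <- sample.int(length(items), 2L)
      joined <- sprintf("(%s:%.17g,%s:%.17g)",
                        items[pick[1L]], stats::rexp(1),
                        items[pick[2L]], stats::rexp(1))
      items <- c(items[-pick], joined)
    }
    ape::read.tree(text = paste0(items, ";"))
  })
}

#' Enumerate planted pair correlations of a synthetic dataset
#'
#' Lists every within-block pair (relation `"club"`) and every cross pair of
#' rival blocks (relation `"rival"`) with its planted latent correlation, for
#' parameter-recovery checks against estimates.
#'
#' @param ds a `"SyntheticDataset"`.
#' @return data.frame with columns `taxon_a`, `taxon_b`, `relation`,
#'   `block_a`, `block_b`, `correlation` (zero rows when nothing is planted).
#' @export
plantedTruthSummary <- function(ds) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  spec <- ds$spec
  taxa <- taxonNames(ds$table)
  out <- list()
  for (b in seq_along(spec$blocks)) {
    idx <- spec$blocks[[b]]$taxa
    if (length(idx) < 2L) next
    prs <- utils::combn(idx, 2L)
    out[[length(out) + 1L]] <- data.frame(
      taxon_a = taxa[prs[1L, ]], taxon_b = taxa[prs[2L, ]],
      relation = "club", block_a = b, block_b = b,
      correlation = spec$blocks[[b]]$cor, stringsAsFactors = FALSE)
  }
  for (rp in spec$rival_pairs) {
    ia <- spec$blocks[[rp$a]]$taxa
    ib <- spec$blocks[[rp$b]]$taxa
    grid <- expand.grid(i = ia, j = ib)
    out[[length(out) + 1L]] <- data.frame(
      taxon_a = taxa[grid$i], taxon_b = taxa[grid$j],
      relation = "rival", block_a = rp$a, block_b = rp$b,
      correlation = rp$cor, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      relation = character(), block_a = integer(),
                      block_b = integer(), correlation = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d samples x %d taxa, %d planted blocks, %d rivalries\n",
              nSamples(x$table), nTaxa(x$table),
              length(x$spec$blocks), length(x$spec$rival_pairs)))
  invisible(x)
}
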