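# Configuration-driven orchestration of the full downstream analysis:
# read inputs -> decontaminate -> total-sum scale -> per-group diversity and
# comparisons -> group-wise prevalence filtering -> per-group correlation
# inference, network, clustering and club reports -> cross-group UniFrac /
# PCoA / PERMANOVA / dispersion -> manifest. Every intermediate is written
# before the next stage reads it, so any stage can be rerun from disk, and
# every random stage derives its seed from the single mandatory run seed.

#' Assemble (and validate) a pipeline configuration
#'
#' Correlation networks are inferred per group on that group's own
#' prevalence-filtered taxon set, plus one pooled `ALL` analysis on the
#' uniform taxon set (taxa passing the prevalence bar in at least one group),
#' which is also the table used for the cross-group beta-diversity stage.
#'
#' @param table path to a counts TSV, or an [OtuTable-class].
#' @param metadata path to a metadata TSV, or a named sample -> group vector.
#' @param out_dir output directory (created if absent).
#' @param tree optional newick path or [ape::phylo]; enables Faith's PD and
#'   the UniFrac stage.
#' @param seed integer seed (mandatory; drives every random stage).
#' @param contaminant_patterns taxon-name substrings to drop.
#' @param min_prevalence group-wise prevalence bar (default 0.5).
#' @param n_inner,n_boot,exclusion_threshold SparCC settings.
#' @param alpha,min_abs_r network edge filters: pseudo p-value below `alpha`
#'   and |rho| at least `min_abs_r`. The default `min_abs_r = 0.4` keeps the
#'   expected number of null edges well below one per network at cohort-scale
#'   sample sizes; set it to 0 to threshold on the p-value alone.
#' @param inflation,prune,mcl_tol MCL settings.
#' @param min_club_size,rival_threshold,min_rival_edges club settings.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param orientation passed to [readCountsTable()].
#' @param verbose emit INFO messages (taxon counts surviving each filter).
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(table, metadata, out_dir, tree = NULL, seed,
                           contaminant_patterns = "Halomonas",
                           min_prevalence = 0.5,
                           n_inner = 20, n_boot = 100,
                           exclusion_threshold = 0.1,
                           alpha = 0.05, min_abs_r = 0.4,
                           inflation = 2, prune = 1e-5, mcl_tol = 1e-8,
                           min_club_size = 3, rival_threshold = -0.4,
                           min_rival_edges = 3, n_permutations = 999,
                           orientation = "samples_in_rows",
                           verbose = TRUE) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for a reproducible run")
  structure(list(
    table = table, metadata = metadata, out_dir = out_dir, tree = tree,
    seed = as.integer(seed),
    contaminant_patterns = contaminant_patterns,
    min_prevalence = min_prevalence, n_inner = n_inner, n_boot = n_boot,
    exclusion_threshold = exclusion_threshold, alpha = alpha,
    min_abs_r = min_abs_r, inflation = inflation, prune = prune,
    mcl_tol = mcl_tol, min_club_size = min_club_size,
    rival_threshold = rival_threshold, min_rival_edges = min_rival_edges,
    n_permutations = n_permutations, orientation = orientation,
    verbose = verbose), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()] arguments.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, a list with every in-memory result (diversity records
#'   and summaries, per-group correlation estimates, networks, clusterings,
#'   club reports, beta-diversity results, and the manifest). All outputs are
#'   also written under `config$out_dir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- function(...) if (isTRUE(config$verbose)) message("INFO ", sprintf(...))
  out <- function(...) file.path(config$out_dir, sprintf(...))

  ## --- input stage -------------------------------------------------------
  counts <- stageTry("read_table", {
    if (is(config$table, "OtuTable")) config$table
    else readCountsTable(config$table, orientation = config$orientation)
  })
  groups <- stageTry("read_metadata", {
    if (is.character(config$metadata) && length(config$metadata) == 1L &&
        file.exists(config$metadata)) readMetadata(config$metadata)
    else config$metadata
  })
  stageTry("join_metadata", {
    missing <- setdiff(sampleNames(counts), names(groups))
    if (length(missing))
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
    counts <- otuTable(abundances(counts), kind = "counts",
                       groups = groups[sampleNames(counts)])
  })
  tree <- stageTry("read_tree", {
    if (is.null(config$tree)) NULL
    else if (inherits(config$tree, "phylo")) config$tree
    else readTree(config$tree)
  })
  info("input: %d samples x %d taxa", nSamples(counts), nTaxa(counts))

  ## --- preprocess --------------------------------------------------------
  counts <- stageTry("decontaminate",
                     removeContaminants(counts, config$contaminant_patterns))
  info("after contaminant removal: %d taxa", nTaxa(counts))
  rel <- stageTry("normalize", totalSumScale(counts))
  writeCountsTable(rel, out("relative_abundance.tsv"))

  ## --- alpha diversity ---------------------------------------------------
  div <- stageTry("diversity", sampleDiversity(counts, tree = tree))
  utils::write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  div_summary <- summarizeGroups(div)
  utils::write.table(cbind(index = rownames(div_summary$formatted),
                           div_summary$formatted),
                     out("diversity_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rd <- stageTry("richness_diversity", {
    sets <- c(list(ALL = div), split(div, div$group))
    do.call(rbind, lapply(names(sets), function(nm) {
      s <- sets[[nm]]
      ct <- richnessDiversityCorrelation(s$s_obs, s$inv_simpson)
      data.frame(set = nm, n = nrow(s), r = ct$r, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(rd, out("richness_diversity_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  anova_res <- stageTry("anova", {
    lapply(c(chao1 = "chao1", inv_simpson = "inv_simpson",
             faith_pd = "faith_pd"), function(cn) {
      if (all(is.na(div[[cn]]))) return(NULL)
      oneWayAnova(split(div[[cn]], div$group))
    })
  })

  ## --- prevalence filtering ---------------------------------------------
  per_group <- stageTry("prevalence_filter",
                        prevalenceFilter(rel, config$min_prevalence,
                                         uniform_set = FALSE))
  uniform <- stageTry("prevalence_filter_uniform",
                      prevalenceFilter(rel, config$min_prevalence,
                                       uniform_set = TRUE))
  for (g in names(per_group)) {
    info("group %s: %d taxa pass the %.0f%% prevalence bar", g,
         nTaxa(per_group[[g]]), 100 * config$min_prevalence)
    writeCountsTable(per_group[[g]], out("%s_filtered.tsv", g))
  }
  info("uniform set: %d taxa", nTaxa(uniform))
  writeCountsTable(uniform, out("ALL_filtered.tsv"))

  ## --- per-group networks and clubs --------------------------------------
  analyses <- c(per_group, list(ALL = uniform))
  net_results <- list()
  for (k in seq_along(analyses)) {
    g <- names(analyses)[k]
    tab <- analyses[[k]]
    res <- stageTry(paste0("network_", g), {
      cts <- counts[sampleNames(tab), taxonNames(tab)]
      est <- sparcc(cts, n_inner = config$n_inner,
                    exclusion_threshold = config$exclusion_threshold,
                    seed = deriveSeed(config$seed, 100L + 2L * k))
      est <- sparccPvalues(cts, est, n_boot = config$n_boot,
                           seed = deriveSeed(config$seed, 101L + 2L * k))
      net <- buildNetwork(est, tab, alpha = config$alpha,
                          min_abs_r = config$min_abs_r)
      clustering <- mclCluster(net, inflation = config$inflation,
                               prune = config$prune, tol = config$mcl_tol)
      social <- clubStatistics(net, clustering,
                               min_club_size = config$min_club_size)
      # rivalry pools all *significant* negative edges: the effect-size
      # filter protects clustering from weak false positive edges, while
      # rival pairs are already guarded by min_rival_edges and the mean
      # correlation threshold
      net_sig <- buildNetwork(est, tab, alpha = config$alpha, min_abs_r = 0)
      rivals <- rivalClubs(net_sig, clustering,
                           rival_threshold = config$rival_threshold,
                           min_rival_edges = config$min_rival_edges,
                           min_club_size = config$min_club_size)
      ord <- heatmapOrder(est, clustering)
      writeSquareMatrix(correlations(est), out("%s_rho.tsv", g), "taxon")
      writeSquareMatrix(pValues(est), out("%s_pvalues.tsv", g), "taxon")
      writeSquareMatrix(correlations(est)[ord, ord],
                        out("%s_rho_heatmap_order.tsv", g), "taxon")
      writeNetwork(net, out("%s_network.graphml", g), "graphml", clustering)
      writeNetwork(net, out("%s_edges.tsv", g), "edgelist")
      utils::write.table(
        data.frame(taxon = names(membership(clustering)),
                   cluster = unname(membership(clustering))),
        out("%s_clusters.tsv", g), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(social, out("%s_clubs_social.tsv", g), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(rivals, out("%s_clubs_rival.tsv", g), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(estimate = est, network = net, clustering = clustering,
           social = social, rivals = rivals, heatmap_order = ord)
    })
    info("group %s: %d edges, %d social clubs, %d rival pairs", g,
         nrow(networkEdges(res$network)), nrow(res$social), nrow(res$rivals))
    net_results[[g]] <- res
  }

  ## --- cross-group beta diversity ----------------------------------------
  beta <- NULL
  if (!is.null(tree)) {
    beta <- stageTry("beta_diversity", {
      Du <- unifracMatrix(uniform, tree, method = "unweighted")
      Dw <- unifracMatrix(uniform, tree, method = "weighted",
                          normalized = TRUE, renormalize = TRUE)
      writeSquareMatrix(Du, out("unifrac_unweighted.tsv"), "sample")
      writeSquareMatrix(Dw, out("unifrac_weighted.tsv"), "sample")
      ord_u <- pcoa(Du)
      utils::write.table(
        data.frame(sample = rownames(ord_u$points), ord_u$points),
        out("pcoa_unweighted.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      labs <- sampleGroups(uniform)
      perm <- permanova(Du, labs, n_permutations = config$n_permutations,
                        seed = deriveSeed(config$seed, 900L))
      disp <- dispersion(Du, labs, center = "median")
      list(unweighted = Du, weighted = Dw, pcoa_unweighted = ord_u,
           permanova = perm, dispersion = disp)
    })
    info("PERMANOVA (unweighted UniFrac): pseudo-F %.3f, p = %.4g",
         beta$permanova$pseudo_F, beta$permanova$p_value)
  }

  ## --- manifest ----------------------------------------------------------
  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("table", "metadata", "tree", "verbose"))],
    n_samples = nSamples(counts), n_taxa = nTaxa(counts),
    groups = as.list(table(unname(sampleGroups(counts)))),
    taxa_per_analysis = lapply(analyses, nTaxa),
    anova = lapply(anova_res, function(a) if (is.null(a)) NULL else
      list(F = a$F, p_value = a$p_value)),
    permanova = if (is.null(beta)) NULL else
      list(pseudo_F = beta$permanova$pseudo_F,
           p_value = beta$permanova$p_value),
    dispersion = if (is.null(beta)) NULL else
      as.list(beta$dispersion$group_means),
    files = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(counts = counts, relative = rel, diversity = div,
                 diversity_summary = div_summary,
                 richness_diversity = rd, anova = anova_res,
                 filtered = per_group, uniform = uniform,
                 networks = net_results, beta = beta, manifest = manifest))
}
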