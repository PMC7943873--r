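#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Input paths are checked at
#' construction time. All random stages draw from explicit named seeds
#' (`gsea_seed`, `resample_seed`) recorded in the run manifest, so a config
#' reproduces every output byte.
#'
#' @param interactions Path to the interaction table (MITAB, SIF or edge
#'   list).
#' @param seeds Path to the seed gene list (one symbol per line).
#' @param gmt Path to the gene set collection (GMT).
#' @param outdir Output directory for the report bundle.
#' @param format Interaction format: `"auto"` (by extension: `.mitab`/`.tab`
#'   parse as MITAB, anything else as edge list / SIF), `"mitab"` or
#'   `"edgelist"`.
#' @param taxon Taxonomy id to filter on (`NULL` skips the filter).
#' @param keep_unknown_taxon Passed to [filter_taxon()].
#' @param order Seed expansion order: `1` or `2` expand the seed list to its
#'   first or second interactors; `0` keeps the whole interaction table as
#'   the network (the mode for analysing an existing network, e.g. a
#'   published consensus network, rather than building one around a
#'   signature).
#' @param prune Apply degree-0/1 pruning (seed-exempt)?
#' @param iterate_prune Iterate pruning to a fixpoint (sensitivity variant)?
#' @param mode Betweenness normalization (see [network_centrality()]).
#' @param h,k,k_quantile Hill parameters (see [rank_centrality()]).
#' @param n_perm,gsea_seed,weight_p,min_size,max_size GSEA parameters.
#' @param resample_seed Seed for the resampling control.
#' @param alpha Significance level for the control flags and the method
#'   grid.
#' @param thresholds Score cut-offs for the threshold-based ORA columns.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(interactions, seeds, gmt, outdir,
                            format = c("auto", "mitab", "edgelist"),
                            taxon = 9606, keep_unknown_taxon = FALSE,
                            order = 2, prune = TRUE, iterate_prune = FALSE,
                            mode = c("pairs", "standard"),
                            h = 4, k = NULL, k_quantile = 0.90,
                            n_perm = 1000, gsea_seed = 1, resample_seed = 2,
                            weight_p = 1, alpha = 0.05,
                            min_size = 10, max_size = 500,
                            thresholds = c(0.2, 0.5, 0.8)) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!order %in% c(0, 1, 2)) {
    abort("`order` must be 0 (no expansion), 1 or 2.",
          class = "netgsea_config_error")
  }
  for (p in c(interactions, seeds, gmt)) {
    if (!file.exists(p)) {
      abort(sprintf("Input path does not exist: '%s'.", p), class = "netgsea_config_error")
    }
  }
  structure(
    list(interactions = interactions, seeds = seeds, gmt = gmt,
         outdir = outdir, format = format, taxon = taxon,
         keep_unknown_taxon = keep_unknown_taxon, order = order,
         prune = prune, iterate_prune = iterate_prune, mode = mode,
         h = h, k = k, k_quantile = k_quantile, n_perm = n_perm,
         gsea_seed = gsea_seed, resample_seed = resample_seed,
         weight_p = weight_p, alpha = alpha, min_size = min_size,
         max_size = max_size, thresholds = thresholds),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring the [pipeline_config()] arguments; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key: '%s'.", unknown[[1]]),
          class = "netgsea_config_error")
  }
  do.call(pipeline_config, vals)
}

#' Run the full centrality-based enrichment pipeline
#'
#' Reads interactions, seeds and gene sets; builds, expands and prunes the
#' network; computes centralities; ranks by Hill-transformed betweenness;
#' runs GSEA, the resampling control, and the ORA threshold grid; and writes
#' the report bundle to `config$outdir`:
#' `network.graphml`, `nodes.tsv`, `centrality.tsv`, `ranked.tsv`,
#' `gsea.tsv` + `gsea_dotplot.json`, `control.tsv`, one `ora_*.tsv` per
#' threshold plus `ora_all.tsv`, `method_grid.tsv`, and `manifest.json`
#' (config echo, package version, seeds, per-stage cardinalities). A failing
#' stage aborts with the stage named and leaves a `FAILED` marker next to
#' any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `centrality`, `ranked`, `gsea`, `control`, `grid`) and the written
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "netgsea_stage_error")
    })
  }

  ingest <- stage("ingest", {
    records <- switch(
      interaction_format(config),
      mitab = read_mitab(config$interactions),
      edgelist = read_edge_list(config$interactions)
    )
    if (!is.null(config$taxon)) {
      records <- filter_taxon(records, config$taxon, config$keep_unknown_taxon)
    }
    list(records = records,
         seeds = read_seed_list(config$seeds),
         collection = read_gmt(config$gmt))
  })
  counts$records <- nrow(ingest$records)
  counts$seeds <- length(ingest$seeds)
  counts$sets <- nrow(ingest$collection)

  network <- stage("build", {
    g <- if (config$order == 0) {
      build_network(ingest$records, ingest$seeds)
    } else {
      expand_seeds(ingest$records, ingest$seeds, order = config$order)
    }
    if (config$prune) g <- prune_network(g, iterate = config$iterate_prune)
    write_graphml(g, file.path(outdir, "network.graphml"))
    write_tsv_tables(list(nodes = node_table(g)), outdir)
    g
  })
  counts$nodes <- igraph::vcount(network)
  counts$edges <- igraph::ecount(network)

  centrality <- stage("topology", {
    ct <- network_centrality(network, mode = config$mode)
    write_tsv_tables(list(centrality = ct), outdir)
    ct
  })

  ranked <- stage("rank", {
    r <- rank_centrality(centrality, h = config$h, k = config$k,
                         q = config$k_quantile)
    write_tsv_tables(list(ranked = r), outdir)
    r
  })

  gsea_res <- stage("gsea", {
    res <- gsea(ranked, ingest$collection, n_perm = config$n_perm,
                seed = config$gsea_seed, min_size = config$min_size,
                max_size = config$max_size, weight_p = config$weight_p)
    write_tsv_tables(list(gsea = tidy(res)), outdir)
    export_dotplot_json(res, file.path(outdir, "gsea_dotplot.json"))
    res
  })
  counts$sets_tested <- nrow(tidy(gsea_res))

  control <- stage("control", {
    resampled <- gsea(resample_metric(ranked, config$resample_seed),
                      ingest$collection, n_perm = config$n_perm,
                      seed = config$gsea_seed, min_size = config$min_size,
                      max_size = config$max_size, weight_p = config$weight_p)
    ctl <- control_compare(gsea_res, resampled, alpha = config$alpha)
    write_tsv_tables(list(control = ctl), outdir)
    list(flags = ctl, resampled = resampled)
  })
  counts$sets_significant <- sum(control$flags$p_adj < config$alpha)
  counts$sets_nonspecific <- sum(control$flags$nonspecific)

  grid <- stage("ora_grid", {
    scores <- setNames(ranked$score, ranked$gene)
    universe <- unique(c(ranked$gene,
                         unlist(ingest$collection$genes, use.names = FALSE)))
    tables <- list(ora_all = ora(ranked$gene, universe, ingest$collection,
                                 config$min_size, config$max_size))
    for (t in config$thresholds) {
      sel <- threshold_select(scores, t)
      if (length(sel) == 0L) {
        warn(sprintf("Threshold %.2f selects no genes; its ORA column is empty.", t))
      }
      tables[[sprintf("ora_%g", t)]] <-
        ora(sel, universe, ingest$collection, config$min_size, config$max_size)
    }
    g <- assemble_method_grid(tables, control$flags, control$resampled,
                              config$alpha)
    write_tsv_tables(c(tables, list(method_grid = g)), outdir)
    g
  })

  stage("manifest", {
    manifest <- list(
      tool = "netgsea",
      version = as.character(packageVersion("netgsea")),
      config = unclass(config),
      counts = counts
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  inform(sprintf(
    "Pipeline complete: %d records -> %d nodes / %d edges; %d sets tested, %d significant (%d nonspecific).",
    counts$records, counts$nodes, counts$edges, counts$sets_tested,
    counts$sets_significant, counts$sets_nonspecific
  ))
  invisible(list(network = network, centrality = centrality, ranked = ranked,
                 gsea = gsea_res, control = control$flags, grid = grid,
                 paths = list.files(outdir, full.names = TRUE)))
}

interaction_format <- function(config) {
  if (config$format != "auto") {
    return(config$format)
  }
  if (grepl("\\.(mitab|tab|txt25)$", config$interactions, ignore.case = TRUE)) {
    "mitab"
  } else {
    "edgelist"
  }
}

#' Pathway-by-method significance grid
#'
#' Reproduces the comparison table contrasting over-representation analysis
#' on the whole network and on score-thresholded subsets against GSEA and
#' its resampling control: one boolean column per method, one row per
#' pathway significant in at least one of them.
#'
#' @param ranked Ranked metric tibble.
#' @param collection Gene set tibble.
#' @param universe ORA universe; defaults to the union of the ranked genes
#'   and all collection members (a stand-in for a genome-wide reference set).
#' @param thresholds Score cut-offs for the subset ORA columns.
#' @param n_perm,seed,resample_seed,alpha,min_size,max_size,weight_p As in
#'   [gsea()] / [run_pipeline()].
#' @return Tibble with `set_name` and one logical column per method
#'   (`ora_all`, `ora_<threshold>`..., `gsea`, `gsea_random`).
#' @export
method_grid <- function(ranked, collection, universe = NULL,
                        thresholds = c(0.2, 0.5, 0.8),
                        n_perm = 1000, seed = 1, resample_seed = 2,
                        alpha = 0.05, min_size = 10, max_size = 500,
                        weight_p = 1) {
  if (is.null(universe)) {
    universe <- unique(c(ranked$gene, unlist(collection$genes, use.names = FALSE)))
  }
  scores <- setNames(ranked$score, ranked$gene)
  tables <- list(ora_all = ora(ranked$gene, universe, collection,
                               min_size, max_size))
  for (t in thresholds) {
    sel <- threshold_select(scores, t)
    if (length(sel) == 0L) {
      warn(sprintf("Threshold %.2f selects no genes; its ORA column is empty.", t))
    }
    tables[[sprintf("ora_%g", t)]] <- ora(sel, universe, collection,
                                          min_size, max_size)
  }
  gsea_res <- gsea(ranked, collection, n_perm = n_perm, seed = seed,
                   min_size = min_size, max_size = max_size,
                   weight_p = weight_p)
  resampled <- gsea(resample_metric(ranked, resample_seed), collection,
                    n_perm = n_perm, seed = seed, min_size = min_size,
                    max_size = max_size, weight_p = weight_p)
  flags <- control_compare(gsea_res, resampled, alpha)
  assemble_method_grid(tables, flags, resampled, alpha)
}

assemble_method_grid <- function(ora_tables, gsea_flags, resampled, alpha) {
  resa <- if (inherits(resampled, "netgsea_gsea")) resampled$result else resampled
  sig <- c(
    lapply(ora_tables, function(t) t$set_name[t$p_adj < alpha]),
    list(gsea = gsea_flags$set_name[gsea_flags$p_adj < alpha],
         gsea_random = resa$set_name[resa$p_adj < alpha])
  )
  rows <- sort(unique(unlist(sig, use.names = FALSE)))
  out <- tibble(set_name = rows)
  for (nm in names(sig)) {
    out[[nm]] <- rows %in% sig[[nm]]
  }
  out
}
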