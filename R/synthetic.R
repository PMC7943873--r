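#' Specification for a synthetic network + gene set fixture
#'
#' Describes a preferential-attachment network with designated low-degree
#' seed nodes and a gene set collection in which one set
#' (`PLANTED_CENTRAL`) is biased toward high-centrality nodes. The defaults
#' emulate the statistical shape of seed-expanded interaction networks:
#' heavy-tailed betweenness spanning orders of magnitude, a signature of
#' ~15 mostly peripheral genes, and a Reactome-sized collection of a couple
#' of dozen candidate pathways of a few dozen genes each.
#'
#' @param n_nodes Number of nodes (default 500).
#' @param attach_m Edges added per new node during preferential attachment
#'   (default 2); must be below `n_nodes`.
#' @param n_seeds Number of designated seed nodes (default 15).
#' @param n_sets Number of gene sets, one planted plus decoys (default 21).
#' @param set_size Genes per set (default 30).
#' @param hub_bias Strength of the centrality bias when sampling the planted
#'   set (default 8; 0 means uniform).
#' @param seed Integer RNG seed; the whole fixture is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 500, attach_m = 2, n_seeds = 15,
                           n_sets = 21, set_size = 30, hub_bias = 8,
                           seed = 42) {
  stopifnot(n_nodes >= 3, n_seeds >= 1, n_sets >= 1, set_size >= 1,
            hub_bias >= 0)
  if (attach_m >= n_nodes) {
    abort("`attach_m` must be smaller than `n_nodes`.")
  }
  if (n_seeds > n_nodes || set_size > n_nodes) {
    abort("`n_seeds` and `set_size` cannot exceed `n_nodes`.")
  }
  structure(list(n_nodes = n_nodes, attach_m = attach_m, n_seeds = n_seeds,
                 n_sets = n_sets, set_size = set_size, hub_bias = hub_bias,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a scale-free network with designated seeds
#'
#' Preferential attachment: the construction starts from `attach_m` isolated
#' nodes; each subsequent node attaches to `attach_m` distinct existing
#' nodes drawn with probability proportional to current degree plus one (the
#' +1 lets degree-zero nodes be chosen). The edge count is therefore exactly
#' `attach_m * (n_nodes - attach_m)`. Seed nodes are then drawn with
#' probability proportional to `1/(degree + 1)^2`, i.e. preferentially from
#' the periphery, matching the observation that signature genes are mostly
#' low-centrality while hubs are first interactors. Node labels are
#' `G0001 ...`.
#'
#' @param spec A [synthetic_spec()].
#' @return igraph network with `is_seed` vertex attribute.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  m <- spec$attach_m
  labels <- sprintf("G%04d", seq_len(n))
  withr::with_seed(spec$seed, {
    deg <- integer(n)
    from <- integer(m * (n - m))
    to <- integer(m * (n - m))
    idx <- 0L
    for (i in seq(m + 1L, n)) {
      existing <- seq_len(i - 1L)
      targets <- sample(existing, m, prob = deg[existing] + 1)
      deg[targets] <- deg[targets] + 1L
      deg[i] <- deg[i] + m
      from[idx + seq_len(m)] <- i
      to[idx + seq_len(m)] <- targets
      idx <- idx + m
    }
    g <- igraph::graph_from_data_frame(
      tibble(from = labels[from], to = labels[to]),
      directed = FALSE, vertices = tibble(name = labels)
    )
    seeds <- sample(labels, spec$n_seeds,
                    prob = 1 / (igraph::degree(g)[labels] + 1)^2)
    igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
    g
  })
}

#' Plant a centrality-biased gene set among uniform decoys
#'
#' Builds a collection of `n_sets` gene sets of equal size: one
#' (`PLANTED_CENTRAL`) sampled without replacement with probability
#' proportional to `exp(hub_bias * r)`, where `r` is the node's normalized
#' betweenness rank (1 = most central), and `n_sets - 1` decoys
#' (`DECOY_001 ...`) sampled uniformly. With `hub_bias = 0` the planted set
#' too is uniform. Sampling is driven by `spec$seed + 1` so the collection
#' is reproducible independently of the network draw.
#'
#' @param network The generated igraph network.
#' @param centrality [network_centrality()] result for it.
#' @param spec The [synthetic_spec()].
#' @return Gene set tibble in [read_gmt()] format.
#' @export
plant_sets <- function(network, centrality, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- igraph::vcount(network)
  if (spec$set_size > n) {
    abort("`set_size` exceeds the network's node count.")
  }
  cent <- setNames(centrality$betweenness, centrality$node)[igraph::V(network)$name]
  r <- (rank(cent, ties.method = "average") - 1) / max(n - 1, 1)
  nodes <- igraph::V(network)$name
  withr::with_seed(spec$seed + 1L, {
    planted <- sample(nodes, spec$set_size, prob = exp(spec$hub_bias * r))
    decoys <- purrr::map(seq_len(spec$n_sets - 1L), function(i) {
      sort(sample(nodes, spec$set_size))
    })
  })
  tibble(
    set_name = c("PLANTED_CENTRAL",
                 sprintf("DECOY_%03d", seq_len(spec$n_sets - 1L))),
    description = c("centrality-biased planted set",
                    rep("uniform decoy set", spec$n_sets - 1L)),
    genes = c(list(sort(planted)), decoys),
    size = spec$set_size
  )
}

#' Write a synthetic fixture to disk
#'
#' Emits the network as a MITAB interaction table (taxon 9606 on both
#' interactors), the collection as GMT, the seed designation as a plain
#' list, and a JSON manifest echoing the spec — files that round-trip
#' through [read_mitab()], [read_gmt()] and [read_seed_list()] to reproduce
#' the fixture exactly.
#'
#' @param network igraph network with `is_seed` attribute.
#' @param collection Gene set tibble.
#' @param directory Output directory (created if missing).
#' @param spec Optional [synthetic_spec()] echoed into the manifest.
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixtures <- function(network, collection, directory, spec = NULL) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  el <- igraph::as_edgelist(network)
  records <- tibble(
    interactor_a = el[, 1], interactor_b = el[, 2],
    taxon_a = 9606L, taxon_b = 9606L, source = "synthetic"
  )
  paths <- c(
    interactions = file.path(directory, "interactions.mitab"),
    gene_sets = file.path(directory, "sets.gmt"),
    seeds = file.path(directory, "seeds.txt"),
    manifest = file.path(directory, "manifest.json")
  )
  write_mitab(records, paths[["interactions"]])
  write_gmt(collection, paths[["gene_sets"]])
  write_seed_list(igraph::V(network)$name[igraph::V(network)$is_seed],
                  paths[["seeds"]])
  manifest <- list(
    generator = "netgsea synthetic fixture",
    spec = if (is.null(spec)) NULL else unclass(spec),
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    n_sets = nrow(collection)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
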