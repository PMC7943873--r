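#' Betweenness and closeness centrality of every node
#'
#' Betweenness of node \eqn{n_i} is \eqn{C_B(n_i) = \sum_{j<k}
#' \sigma_{jk}(n_i)/\sigma_{jk} \cdot 1/\mathrm{norm}}, where
#' \eqn{\sigma_{jk}} counts geodesics between \eqn{n_j} and \eqn{n_k} and
#' \eqn{\sigma_{jk}(n_i)} those passing through \eqn{n_i} as an interior
#' vertex (endpoints excluded). Pairs in distinct components contribute
#' nothing: their geodesic is undefined. Two normalizations are offered:
#'
#' * `"pairs"` (default): divide by \eqn{\binom{N}{2}} with \eqn{N} the total
#'   node count of the whole network, including disconnected parts.
#' * `"standard"`: divide by \eqn{(N-1)(N-2)/2}, the convention used by
#'   Cytoscape's NetworkAnalyzer. For every node the two modes differ by the
#'   exact factor \eqn{N/(N-2)}.
#'
#' Closeness of a node in a component of size \eqn{c} is
#' \eqn{(c-1)/\sum_j d(i,j)} over its reachable nodes; isolated nodes score 0.
#'
#' @param network Undirected simple igraph network.
#' @param mode Normalization, `"pairs"` or `"standard"`.
#' @param include_closeness Also compute closeness (set `FALSE` to skip on
#'   large networks).
#' @return Tibble with columns `node`, `degree`, `betweenness`, `closeness`
#'   (if requested) and `is_seed`, sorted by betweenness descending with
#'   lexicographic tie-break. Attributes `n_nodes` and `mode` record the
#'   normalization context. Networks with fewer than 3 nodes have no interior
#'   pairs, so all betweenness values are 0.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' network_centrality(g)
#' @export
network_centrality <- function(network, mode = c("pairs", "standard"),
                               include_closeness = TRUE) {
  mode <- match.arg(mode)
  n <- igraph::vcount(network)
  raw <- if (n >= 3) {
    igraph::betweenness(network, directed = FALSE, normalized = FALSE)
  } else {
    rep(0, n)
  }
  norm <- if (mode == "pairs") choose(n, 2) else (n - 1) * (n - 2) / 2
  btw <- if (n >= 3) raw / norm else rep(0, n)
  out <- tibble(
    node = igraph::V(network)$name,
    degree = as.integer(igraph::degree(network)),
    betweenness = unname(btw),
    is_seed = igraph::V(network)$is_seed %||% rep(FALSE, n)
  )
  if (include_closeness) {
    out$closeness <- unname(closeness_by_component(network))
    out <- select(out, "node", "degree", "betweenness", "closeness", "is_seed")
  }
  out <- arrange(out, desc(.data$betweenness), .data$node)
  attr(out, "n_nodes") <- n
  attr(out, "mode") <- mode
  out
}

# (c-1)/sum(d) within each connected component; isolated nodes -> 0
closeness_by_component <- function(network) {
  n <- igraph::vcount(network)
  out <- numeric(n)
  comp <- igraph::components(network)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    csize <- length(members)
    if (csize < 2) next
    d <- igraph::distances(network, v = members, to = members)
    out[members] <- (csize - 1) / rowSums(d)
  }
  names(out) <- igraph::V(network)$name
  out
}

#' Extract the subnetwork induced by the most central nodes
#'
#' Selects the `k` nodes with highest betweenness (ties broken by ascending
#' symbol), either as a count or as a fraction of the network
#' (`ceiling(fraction * N)` nodes). Optionally, seed nodes adjacent to any
#' selected node are added together with the seed-to-selected edges — the
#' "top central nodes plus interacting signature genes" view.
#'
#' @param network igraph network the centralities were computed on.
#' @param centrality Result of [network_centrality()].
#' @param k Positive count, or a fraction in (0, 1).
#' @param include_interacting_seeds Add seeds adjacent to selected nodes?
#' @return The induced igraph subnetwork.
#' @export
top_central_subnetwork <- function(network, centrality, k,
                                   include_interacting_seeds = FALSE) {
  n <- igraph::vcount(network)
  if (length(k) != 1L || !is.numeric(k) || k <= 0) {
    abort("`k` must be a positive count or a fraction in (0, 1).")
  }
  if (k < 1) k <- ceiling(k * n)
  if (k > n) {
    abort(sprintf("`k` = %d exceeds the network's %d nodes.", k, n))
  }
  ordered <- arrange(centrality, desc(.data$betweenness), .data$node)
  selected <- ordered$node[seq_len(k)]
  sub <- igraph::induced_subgraph(network, selected)
  if (include_interacting_seeds) {
    seeds <- igraph::V(network)$name[igraph::V(network)$is_seed %||% FALSE]
    extra <- setdiff(seeds, selected)
    if (length(extra) > 0L) {
      nbr <- vapply(extra, function(s) {
        any(igraph::neighbors(network, s)$name %in% selected)
      }, logical(1))
      extra <- extra[nbr]
      if (length(extra) > 0L) {
        sub <- igraph::induced_subgraph(network, c(selected, extra))
        # keep only edges with >= 1 endpoint in the central selection:
        # added seeds connect to the cluster, not to each other
        ends <- igraph::as_edgelist(sub)
        seed_only <- !(ends[, 1] %in% selected) & !(ends[, 2] %in% selected)
        sub <- igraph::delete_edges(sub, which(seed_only))
      }
    }
  }
  sub
}
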