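#' Assemble an undirected simple network from interaction records
#'
#' Collapses `(A,B)`/`(B,A)` duplicates, drops self-loops, and flags seed
#' nodes. Seeds absent from every record are added as isolated nodes so that
#' they can survive degree-based pruning: signature genes with zero
#' centrality are still part of the personalized network.
#'
#' @param records Interaction record tibble (see [read_mitab()]).
#' @param seeds Character vector of seed (signature) gene symbols.
#' @return An undirected simple igraph network with vertex attributes `name`
#'   and `is_seed`.
#' @examples
#' recs <- tibble::tibble(
#'   interactor_a = c("A", "B", "C"), interactor_b = c("B", "A", "C"),
#'   taxon_a = NA_integer_, taxon_b = NA_integer_, source = "example"
#' )
#' build_network(recs, seeds = "C")
#' @export
build_network <- function(records, seeds = character()) {
  seeds <- unique(norm_symbol(seeds))
  a <- norm_symbol(records$interactor_a)
  b <- norm_symbol(records$interactor_b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  edges <- distinct(tibble(from = lo, to = hi))
  nodes <- sort(unique(c(edges$from, edges$to, seeds)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = nodes))
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
  g
}

#' Expand a seed list to its first or second interactors
#'
#' Order 1 keeps records with at least one endpoint in the seed list (the
#' first-interactor network). Order 2 additionally keeps records touching any
#' first interactor, mimicking a second query of the interaction database
#' with the first-interactor list. Records connecting two nodes that are
#' neither seeds nor first interactors are excluded unless
#' `include_outer_edges = TRUE`.
#'
#' @param records Interaction record tibble.
#' @param seeds Seed gene symbols.
#' @param order `1` (first interactors) or `2` (second interactors).
#' @param include_outer_edges At order 2, also keep records whose two
#'   endpoints both lie in the expanded node set but touch no seed or first
#'   interactor directly.
#' @return An igraph network (via [build_network()], so seeds missing from
#'   the records appear as isolated seed nodes).
#' @export
expand_seeds <- function(records, seeds, order = 1, include_outer_edges = FALSE) {
  if (!order %in% c(1, 2)) {
    abort("`order` must be 1 (first interactors) or 2 (second interactors).")
  }
  seeds <- unique(norm_symbol(seeds))
  a <- norm_symbol(records$interactor_a)
  b <- norm_symbol(records$interactor_b)
  touch_seed <- a %in% seeds | b %in% seeds
  keep <- touch_seed
  if (order == 2) {
    first <- setdiff(unique(c(a[touch_seed], b[touch_seed])), seeds)
    touch_first <- a %in% first | b %in% first
    keep <- keep | touch_first
    if (include_outer_edges) {
      node_set <- unique(c(seeds, first, a[keep], b[keep]))
      keep <- keep | (a %in% node_set & b %in% node_set)
    }
  }
  build_network(records[keep, , drop = FALSE], seeds)
}

#' Prune isolated and terminal nodes, exempting seeds
#'
#' Removes every non-seed node whose degree on the *input* network is 0
#' (isolated) or 1 (terminal), together with its incident edge. The pass is
#' simultaneous and by default applied once, so a chain interior that becomes
#' terminal through the removal of its neighbours is kept; set
#' `iterate = TRUE` to repeat until no such node remains (a sensitivity
#' variant, not the default behaviour).
#'
#' @param network igraph network with an `is_seed` vertex attribute.
#' @param iterate Repeat pruning to a fixpoint?
#' @return The pruned igraph network.
#' @export
prune_network <- function(network, iterate = FALSE) {
  if (is.null(igraph::V(network)$is_seed)) {
    igraph::V(network)$is_seed <- FALSE
  }
  repeat {
    deg <- igraph::degree(network)
    drop <- which(deg <= 1 & !igraph::V(network)$is_seed)
    if (length(drop) == 0L) break
    network <- igraph::delete_vertices(network, drop)
    if (!iterate) break
  }
  network
}

#' Node degrees as a tibble
#'
#' Degree is the number of distinct neighbours (the network is simple, so
#' this equals the incident edge count).
#'
#' @param network igraph network.
#' @return Tibble with columns `node` and `degree`, in vertex order.
#' @export
node_degrees <- function(network) {
  tibble(node = igraph::V(network)$name,
         degree = as.integer(igraph::degree(network)))
}

#' Per-node summary table of a network
#'
#' @param network igraph network with `is_seed` attribute.
#' @return Tibble with columns `node`, `degree`, `is_seed`.
#' @export
node_table <- function(network) {
  seeds <- igraph::V(network)$is_seed %||% rep(FALSE, igraph::vcount(network))
  mutate(node_degrees(network), is_seed = seeds)
}
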