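# Independent oracles and fixture builders shared across the suite.

# Brute-force betweenness: textbook geodesic counting, no Brandes
# accumulation and no igraph shortest-path machinery. BFS from every source
# gives distances and geodesic counts sigma(s, v); for each unordered pair
# (j, k) every interior vertex i with d(j,i) + d(i,k) == d(j,k) contributes
# sigma(j,i) * sigma(i,k) / sigma(j,k).
oracle_betweenness <- function(adj, mode = c("pairs", "standard")) {
  mode <- match.arg(mode)
  n <- nrow(adj)
  stopifnot(n == ncol(adj))
  bfs_counts <- function(s) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  bfs <- lapply(seq_len(n), bfs_counts)
  cb <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in seq(j + 1, n)) {
      djk <- bfs[[j]]$dist[k]
      if (is.infinite(djk)) next  # distinct components: geodesic undefined
      for (i in seq_len(n)) {
        if (i == j || i == k) next
        if (bfs[[j]]$dist[i] + bfs[[k]]$dist[i] == djk) {
          cb[i] <- cb[i] + bfs[[j]]$sigma[i] * bfs[[k]]$sigma[i] / bfs[[j]]$sigma[k]
        }
      }
    }
  }
  norm <- if (mode == "pairs") choose(n, 2) else (n - 1) * (n - 2) / 2
  if (n < 3) rep(0, n) else cb / norm
}

# Brute-force enrichment score: materialize the whole running-sum array and
# take the maximum absolute deviation, signed.
oracle_es <- function(scores, hit_idx, weight_p = 1) {
  n <- length(scores)
  m <- length(hit_idx)
  w <- abs(scores[hit_idx])^weight_p
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / m, m)
  steps <- rep(-1 / (n - m), n)
  steps[hit_idx] <- w
  running <- cumsum(steps)
  # ties between the extrema (within float noise) resolve positive
  if (max(running) >= -min(running) - 1e-12) max(running) else min(running)
}

# Random simple undirected graph on n nodes with edge probability p,
# returned as an igraph object with single-letter-ish names.
random_graph <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.integer(runif(length(upper)) < p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  igraph::V(g)$is_seed <- FALSE
  list(graph = g, adj = adj)
}

write_lines_tmp <- function(lines, ext = "") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# two-interaction MITAB fixture rows used by several IO tests
mitab_row <- function(a, b, taxa = "taxid:9606(human)", taxb = taxa,
                      alias_a = sprintf("uniprotkb:%s(gene name)", a),
                      alias_b = sprintf("uniprotkb:%s(gene name)", b)) {
  paste(c(sprintf("uniprotkb:ID_%s", a), sprintf("uniprotkb:ID_%s", b),
          "-", "-", alias_a, alias_b, "psi-mi:\"MI:0007\"", "-", "pubmed:1",
          taxa, taxb, "psi-mi:\"MI:0915\"", "psi-mi:\"MI:0469\"", "-", "-"),
        collapse = "\t")
}

records_tbl <- function(a, b, taxon = NA_integer_) {
  tibble::tibble(interactor_a = a, interactor_b = b,
                 taxon_a = taxon, taxon_b = taxon, source = "test")
}
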