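#' Hill transformation of centrality values
#'
#' Applies the sigmoid \eqn{C' = C^h / (k + C^h)} that compresses low
#' centralities toward 0 and pushes hubs toward 1, so that only the most
#' central nodes carry weight in the enrichment score. Note that `k` sits in
#' the denominator *unraised*: it has the units of \eqn{C^h}, and the value
#' with \eqn{C^h = k} scores exactly 0.5. The conventional pharmacology form
#' \eqn{C^h/(k^h + C^h)} is available with `conventional = TRUE`.
#'
#' @param values Named numeric vector (gene -> centrality), all `>= 0`.
#' @param h Hill coefficient, `> 0`. Larger values sharpen the sigmoid.
#' @param k Half-saturation constant, `> 0`, in units of `values^h`
#'   (or of `values` when `conventional = TRUE`). See [choose_k()].
#' @param conventional Use the `k^h + C^h` denominator instead.
#' @return Named numeric vector of transformed scores in `[0, 1)`.
#' @examples
#' hill_transform(c(A = 0, B = 1e-3, C = 0.1), h = 2, k = 1e-4)
#' @export
hill_transform <- function(values, h, k, conventional = FALSE) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) {
    abort("`h` must be a single positive number.")
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    abort("`k` must be a single positive number.")
  }
  if (any(values < 0)) {
    abort("Centrality values must be non-negative.")
  }
  vh <- values^h
  denom <- if (conventional) k^h + vh else k + vh
  out <- vh / denom
  out[values == 0] <- 0
  out
}

#' Choose the Hill half-saturation constant from a target quantile
#'
#' Sets `k = Q^h`, where `Q` is the `q`-quantile of the *positive* input
#' values, so that a node sitting at quantile `q` of the positive centrality
#' distribution scores exactly 0.5 after [hill_transform()]. The default
#' `q = 0.90` aims the sigmoid's shoulder at the top decile, reproducing the
#' intended behaviour of scoring roughly the most central tenth of the
#' network highly.
#'
#' @param values Non-negative numeric vector with at least one positive
#'   entry.
#' @param h Hill coefficient the constant will be used with.
#' @param q Target quantile in (0, 1).
#' @return The constant `k` (a single positive number).
#' @export
choose_k <- function(values, h = 4, q = 0.90) {
  if (q <= 0 || q >= 1) {
    abort("`q` must lie strictly between 0 and 1.")
  }
  pos <- values[values > 0]
  if (length(pos) == 0L) {
    abort("All centrality values are zero; cannot place the half-saturation point.")
  }
  unname(quantile(pos, q, names = FALSE))^h
}

#' Assemble a ranked metric table
#'
#' Orders genes by score, descending, with ties broken by ascending symbol so
#' the ranking is fully deterministic.
#'
#' @param scores Named numeric vector (gene -> score) or a data frame with
#'   columns `gene` and `score`. Symbols must be unique.
#' @return Tibble with columns `gene` and `score`, non-increasing in `score`.
#' @export
make_ranked <- function(scores) {
  if (is.data.frame(scores)) {
    df <- tibble(gene = norm_symbol(scores$gene), score = as.numeric(scores$score))
  } else {
    if (is.null(names(scores)) && length(scores) > 0L) {
      abort("`scores` must be a named vector or a data frame with gene/score columns.")
    }
    df <- tibble(gene = norm_symbol(names(scores)), score = as.numeric(scores))
  }
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate gene symbol in ranked metric: '%s'.", dup[[1]]))
  }
  arrange(df, desc(.data$score), .data$gene)
}

#' Rank a network's nodes by Hill-transformed betweenness
#'
#' Convenience wrapper: takes a [network_centrality()] table, picks the
#' half-saturation constant with [choose_k()] unless given, applies
#' [hill_transform()] and returns the ranked metric that feeds [gsea()].
#' Zero-centrality nodes are kept with score 0: they pad the tail of the
#' list and take part in the miss penalty, just as zero-centrality signature
#' genes remain part of the network.
#'
#' @param centrality Tibble from [network_centrality()].
#' @param h Hill coefficient (default 4).
#' @param k Half-saturation constant; `NULL` to derive it from `q`.
#' @param q Target quantile for [choose_k()] when `k` is `NULL`.
#' @param conventional Passed to [hill_transform()].
#' @return Ranked tibble (`gene`, `score`) with attributes `h` and `k`.
#' @export
rank_centrality <- function(centrality, h = 4, k = NULL, q = 0.90,
                            conventional = FALSE) {
  values <- setNames(centrality$betweenness, centrality$node)
  if (is.null(k)) k <- choose_k(values, h = h, q = q)
  ranked <- make_ranked(hill_transform(values, h = h, k = k,
                                       conventional = conventional))
  attr(ranked, "h") <- h
  attr(ranked, "k") <- k
  ranked
}

#' Resample a ranked metric (specificity control)
#'
#' Randomly re-assigns the observed scores to the gene identifiers — the
#' multiset of scores is bitwise identical, only the gene-to-score map is
#' permuted — and re-ranks. Running the enrichment analysis again on this
#' control exposes pathways that come up regardless of which genes are
#' central.
#'
#' @param ranked Ranked tibble (`gene`, `score`).
#' @param seed Integer seed driving the permutation.
#' @return A ranked tibble with the same genes and the same scores under a
#'   uniformly random assignment; attribute `resample_seed` records `seed`.
#' @export
resample_metric <- function(ranked, seed) {
  n <- nrow(ranked)
  perm <- withr::with_seed(seed, sample.int(n))
  out <- make_ranked(setNames(ranked$score[perm], ranked$gene))
  attr(out, "h") <- attr(ranked, "h")
  attr(out, "k") <- attr(ranked, "k")
  attr(out, "resample_seed") <- seed
  out
}
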