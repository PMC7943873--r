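#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom. At a gene belonging to the set (a
#' hit) the running sum rises by \eqn{|s|^p / \sum_{hits} |s|^p}; at a miss
#' it falls by \eqn{1/(n - n_{hits})}. The enrichment score is the running
#' sum's maximum absolute deviation from zero, signed. The leading edge
#' contains the hit genes at or before the extremum for a positive score,
#' and the hits after it for a negative one.
#'
#' When every hit has score 0 and `weight_p > 0`, hit increments fall back
#' to equal weights `1/n_hits` (the weighted statistic is undefined there).
#'
#' @param ranked Ranked tibble (`gene`, `score`) from [make_ranked()].
#' @param members Character vector of gene symbols (the set).
#' @param weight_p Score-weighting exponent; 1 is the standard weighted
#'   statistic, 0 the classic Kolmogorov-Smirnov form.
#' @return List with elements `es` (number in `[-1, 1]`), `leading_edge`
#'   (character vector) and `profile` (tibble `position`, `gene`, `running`),
#'   the full running-sum curve.
#' @examples
#' ranked <- make_ranked(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
#' enrichment_score(ranked, c("g1", "g3"))$es  # 2/3
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  n <- nrow(ranked)
  if (n == 0L) abort("The ranked list is empty.")
  pos <- which(ranked$gene %in% norm_symbol(members))
  if (length(pos) == 0L) {
    abort("No member of the gene set occurs in the ranked universe.")
  }
  if (length(pos) == n) {
    abort("The gene set spans the entire ranked universe; the miss penalty is undefined.")
  }
  swp <- abs(ranked$score)^weight_p
  core <- es_from_positions(pos, swp, n)
  le_idx <- if (core$es >= 0) seq_len(core$idx) else seq(core$idx, length(pos))
  increments <- rep(-1 / (n - length(pos)), n)
  increments[pos] <- core$w
  list(
    es = core$es,
    leading_edge = ranked$gene[pos[le_idx]],
    profile = tibble(position = seq_len(n), gene = ranked$gene,
                     running = cumsum(increments))
  )
}

# ES from sorted hit positions only: every extremum of the running sum lies
# immediately after a hit (candidate maxima) or immediately before one
# (candidate minima), so the full n-length curve is never materialized.
es_from_positions <- function(pos, swp, n) {
  m <- length(pos)
  w_raw <- swp[pos]
  tot <- sum(w_raw)
  w <- if (tot > 0) w_raw / tot else rep(1 / m, m)
  d <- 1 / (n - m)
  cw <- cumsum(w)
  base <- d * (pos - seq_len(m))
  after <- cw - base
  before <- c(0, cw[-m]) - base
  i_max <- which.max(after)
  i_min <- which.min(before)
  # extremum magnitudes tying within float noise resolve to the positive side
  if (after[i_max] >= -before[i_min] - 1e-12) {
    list(es = after[i_max], idx = i_max, w = w)
  } else {
    list(es = before[i_min], idx = i_min, w = w)
  }
}

#' Pre-ranked GSEA with a gene-label permutation null
#'
#' Computes the enrichment score of every gene set against the ranked
#' metric, then builds a per-set null by recomputing the score for randomly
#' drawn memberships of the same size on the same ranked scores (gene-label
#' permutation — the only null available when there is a single metric
#' vector and no sample classes). The permutation p-value uses the add-one
#' correction \eqn{p = (1 + x)/(1 + n_{same sign})}, so it is never zero;
#' NES divides the observed score by the mean magnitude of same-sign null
#' scores. Benjamini-Hochberg adjustment is applied across all tested sets.
#'
#' @param ranked Ranked tibble (`gene`, `score`).
#' @param collection Gene set tibble ([read_gmt()] format).
#' @param n_perm Number of membership permutations per set.
#' @param seed Integer seed; identical inputs and seed give a bitwise
#'   identical result table.
#' @param min_size,max_size Sets are tested only if their intersection with
#'   the ranked universe has size within `[min_size, max_size]`.
#' @param weight_p Passed to the enrichment score.
#' @param exhaustive Enumerate *all* same-size memberships instead of
#'   sampling (feasible only for tiny universes; `choose(n, size)` must not
#'   exceed 100,000). The p-value then matches exact enumeration.
#' @return An object of class `netgsea_gsea`: use [tidy()] for the per-set
#'   tibble (`set_name`, `set_size`, `es`, `nes`, `p_perm`, `p_adj`,
#'   `gene_ratio`, `gene_ratio_le`, `leading_edge`), [glance()] for a
#'   one-row summary, [autoplot()] for the dot plot. `gene_ratio` is the
#'   set's gene count in the network over the network's gene total;
#'   `gene_ratio_le` is leading-edge size over set size.
#' @export
gsea <- function(ranked, collection, n_perm = 1000, seed = 1,
                 min_size = 10, max_size = 500, weight_p = 1,
                 exhaustive = FALSE) {
  n <- nrow(ranked)
  if (n == 0L) abort("The ranked list is empty.")
  swp <- abs(ranked$score)^weight_p
  universe <- ranked$gene

  prep <- purrr::map(seq_len(nrow(collection)), function(i) {
    pos <- which(universe %in% collection$genes[[i]])
    list(set_name = collection$set_name[[i]], pos = pos, m = length(pos))
  })
  skipped <- purrr::keep(prep, ~ .x$m == 0L)
  for (s in skipped) {
    inform(sprintf("Skipping set '%s': no member in the ranked universe.", s$set_name))
  }
  prep <- purrr::keep(prep, ~ .x$m >= min_size && .x$m <= max_size && .x$m < n)
  if (length(prep) == 0L) {
    return(new_gsea(empty_gsea_tbl(), n, n_perm, seed, min_size, max_size,
                    weight_p, exhaustive))
  }

  rows <- withr::with_seed(seed, purrr::map_dfr(prep, function(p) {
    obs <- es_from_positions(p$pos, swp, n)
    null_es <- null_es_values(p$m, swp, n, n_perm, exhaustive)
    same <- if (obs$es > 0) null_es > 0 else if (obs$es < 0) null_es < 0 else logical(0)
    n_same <- sum(same)
    p_perm <- (1 + sum(abs(null_es[same]) >= abs(obs$es))) / (1 + n_same)
    nes <- if (n_same > 0 && obs$es != 0) {
      obs$es / mean(abs(null_es[same]))
    } else {
      if (obs$es != 0) {
        warn(sprintf("Set '%s': no same-sign permutation scores; NES undefined.",
                     p$set_name))
      }
      NA_real_
    }
    le_idx <- if (obs$es >= 0) seq_len(obs$idx) else seq(obs$idx, p$m)
    tibble(
      set_name = p$set_name, set_size = p$m,
      es = obs$es, nes = nes, p_perm = p_perm,
      gene_ratio = p$m / n,
      gene_ratio_le = length(le_idx) / p$m,
      leading_edge = list(universe[p$pos[le_idx]])
    )
  }))

  rows$p_adj <- p.adjust(rows$p_perm, method = "BH")
  rows <- arrange(rows, .data$p_perm, desc(abs(.data$nes)))
  rows <- select(rows, "set_name", "set_size", "es", "nes", "p_perm",
                 "p_adj", "gene_ratio", "gene_ratio_le", "leading_edge")
  new_gsea(rows, n, n_perm, seed, min_size, max_size, weight_p, exhaustive)
}

null_es_values <- function(m, swp, n, n_perm, exhaustive) {
  if (exhaustive) {
    if (choose(n, m) > 1e5) {
      abort(sprintf("Exhaustive enumeration of choose(%d, %d) memberships is infeasible.",
                    n, m))
    }
    memberships <- combn(n, m, simplify = FALSE)
    vapply(memberships, function(p) es_from_positions(p, swp, n)$es, numeric(1))
  } else {
    vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample.int(n, m)), swp, n)$es
    }, numeric(1))
  }
}

new_gsea <- function(result, universe_size, n_perm, seed, min_size, max_size,
                     weight_p, exhaustive) {
  structure(
    list(result = result,
         params = list(universe_size = universe_size, n_perm = n_perm,
                       seed = seed, min_size = min_size, max_size = max_size,
                       weight_p = weight_p, exhaustive = exhaustive)),
    class = "netgsea_gsea"
  )
}

empty_gsea_tbl <- function() {
  tibble(set_name = character(), set_size = integer(), es = numeric(),
         nes = numeric(), p_perm = numeric(), p_adj = numeric(),
         gene_ratio = numeric(), gene_ratio_le = numeric(),
         leading_edge = list())
}

#' @export
print.netgsea_gsea <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Pre-ranked GSEA: %d sets tested on a universe of %d genes (%s permutations, weight %g)\n",
    nrow(x$result), p$universe_size,
    if (p$exhaustive) "exhaustive" else format(p$n_perm), p$weight_p
  ))
  print(x$result, ...)
  invisible(x)
}

#' @rdname gsea
#' @param x,object A `netgsea_gsea` object.
#' @param ... Unused.
#' @method tidy netgsea_gsea
#' @export
tidy.netgsea_gsea <- function(x, ...) x$result

#' @rdname gsea
#' @param alpha Significance level used by `glance()` to count significant
#'   sets.
#' @method glance netgsea_gsea
#' @export
glance.netgsea_gsea <- function(x, alpha = 0.05, ...) {
  tibble(
    n_sets_tested = nrow(x$result),
    n_significant = sum(x$result$p_adj < alpha),
    universe_size = x$params$universe_size,
    n_perm = x$params$n_perm,
    weight_p = x$params$weight_p,
    seed = x$params$seed
  )
}

#' Flag enrichment results that survive the resampling control
#'
#' A pathway significant on the observed (centrality-derived) metric is
#' flagged `nonspecific` when it is *also* significant on the resampled
#' metric: its enrichment does not depend on which genes are central, so it
#' carries no topological information.
#'
#' @param original GSEA result on the observed metric (`netgsea_gsea` or its
#'   tidy tibble).
#' @param resampled GSEA result on the [resample_metric()] control.
#' @param alpha Adjusted-p significance level for both runs.
#' @return The original result tibble with a logical `nonspecific` column
#'   (`FALSE` for sets not significant in the original run).
#' @export
control_compare <- function(original, resampled, alpha = 0.05) {
  orig <- if (inherits(original, "netgsea_gsea")) original$result else original
  resa <- if (inherits(resampled, "netgsea_gsea")) resampled$result else resampled
  sig_resampled <- resa$set_name[resa$p_adj < alpha]
  mutate(orig, nonspecific = .data$p_adj < alpha & .data$set_name %in% sig_resampled)
}

#' Select genes whose transformed score exceeds a threshold
#'
#' @param scores Named numeric vector or tibble (`gene`, `score`) of
#'   Hill-transformed centralities.
#' @param threshold Cut-off in `[0, 1)`; genes strictly above it are kept.
#' @return Character vector of gene symbols.
#' @export
threshold_select <- function(scores, threshold) {
  if (threshold < 0 || threshold >= 1) {
    abort("`threshold` must lie in [0, 1).")
  }
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$gene)
  }
  names(scores)[scores > threshold]
}

#' Hypergeometric over-representation analysis
#'
#' Classic Fisher-style ORA: for each gene set, the upper-tail
#' hypergeometric probability of drawing at least the observed overlap when
#' `length(selection)` genes are sampled from the universe. Selection genes
#' outside the universe are dropped with a warning. Benjamini-Hochberg
#' adjustment across the tested sets.
#'
#' @param selection Character vector of selected genes (e.g. from
#'   [threshold_select()]).
#' @param universe Character vector of all candidate genes.
#' @param collection Gene set tibble ([read_gmt()] format).
#' @param min_size,max_size Bounds on set size within the universe.
#' @return Tibble sorted by `p_hyper` with columns `set_name`, `overlap`,
#'   `set_size_in_universe`, `selection_size`, `universe_size`, `p_hyper`,
#'   `p_adj`, of class `netgsea_ora`.
#' @export
ora <- function(selection, universe, collection, min_size = 10, max_size = 500) {
  universe <- unique(norm_symbol(universe))
  selection <- unique(norm_symbol(selection))
  outside <- setdiff(selection, universe)
  if (length(outside) > 0L) {
    warn(sprintf("Dropping %d selected gene(s) outside the universe (e.g. '%s').",
                 length(outside), outside[[1]]))
    selection <- intersect(selection, universe)
  }
  n_univ <- length(universe)
  n_sel <- length(selection)
  out <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    in_univ <- intersect(collection$genes[[i]], universe)
    big_k <- length(in_univ)
    if (n_sel == 0L || big_k < min_size || big_k > max_size) {
      return(tibble())
    }
    k <- length(intersect(in_univ, selection))
    tibble(
      set_name = collection$set_name[[i]],
      overlap = k,
      set_size_in_universe = big_k,
      selection_size = n_sel,
      universe_size = n_univ,
      p_hyper = phyper(k - 1, big_k, n_univ - big_k, n_sel, lower.tail = FALSE)
    )
  })
  if (nrow(out) == 0L) {
    out <- tibble(set_name = character(), overlap = integer(),
                  set_size_in_universe = integer(), selection_size = integer(),
                  universe_size = integer(), p_hyper = numeric())
  }
  out$p_adj <- p.adjust(out$p_hyper, method = "BH")
  out <- arrange(out, .data$p_hyper, .data$set_name)
  class(out) <- c("netgsea_ora", class(out))
  out
}

#' Export dot-plot data as JSON records
#'
#' Writes the top sets of a GSEA or ORA result in the form the enrichment
#' dot plot consumes: one record per set with its gene ratio, overlap count
#' and adjusted p-value.
#'
#' @param x A `netgsea_gsea` object or `netgsea_ora` tibble.
#' @param path Output JSON path.
#' @param top_n Number of top sets (by adjusted p) to export.
#' @return `path`, invisibly.
#' @export
export_dotplot_json <- function(x, path, top_n = 20) {
  df <- dotplot_data(x)
  df <- slice_head(arrange(df, .data$p_adj), n = top_n)
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

dotplot_data <- function(x) {
  if (inherits(x, "netgsea_gsea")) {
    tibble(set_name = x$result$set_name,
           gene_ratio = x$result$gene_ratio,
           overlap_count = x$result$set_size,
           p_adj = x$result$p_adj)
  } else if (inherits(x, "netgsea_ora")) {
    tibble(set_name = x$set_name,
           gene_ratio = x$overlap / x$selection_size,
           overlap_count = x$overlap,
           p_adj = x$p_adj)
  } else {
    abort("Expected a `netgsea_gsea` or `netgsea_ora` result.")
  }
}
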