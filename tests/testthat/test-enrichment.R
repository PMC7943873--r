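ranked5 <- function() make_ranked(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))

sets_tbl <- function(...) {
  genes <- list(...)
  tibble::tibble(set_name = sprintf("S%d", seq_along(genes)),
                 description = "d", genes = genes,
                 size = lengths(genes))
}

test_that("the worked running-sum example reproduces exactly", {
  res <- enrichment_score(ranked5(), c("g1", "g3"), weight_p = 1)
  expect_equal(res$profile$running,
               c(5 / 8, 5 / 8 - 1 / 3, 5 / 8 - 1 / 3 + 3 / 8,
                 2 / 3 - 1 / 3, 0))
  expect_equal(res$es, 2 / 3)
  expect_equal(res$leading_edge, c("G1", "G3"))
})

test_that("sets at the bottom of the list score negatively", {
  ranked <- make_ranked(setNames(10:1, sprintf("g%02d", 1:10)))
  res <- enrichment_score(ranked, c("G09", "G10"), weight_p = 0)
  expect_lt(res$es, 0)
  expect_setequal(res$leading_edge, c("G09", "G10"))
})

test_that("a set covering all but one gene is degenerate but defined", {
  ranked <- ranked5()
  res <- enrichment_score(ranked, c("g1", "g2", "g4", "g5"))
  expect_true(is.finite(res$es))
  expect_lte(abs(res$es), 1)
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "entire")
  expect_error(enrichment_score(ranked, "nope"), "No member")
})

test_that("streaming ES equals the brute-force running-sum oracle", {
  withr::with_seed(17, {
    for (rep in 1:300) {
      n <- sample(3:10, 1)
      scores <- round(sort(runif(n, -1, 2), decreasing = TRUE), 3)
      genes <- sprintf("X%02d", 1:n)
      ranked <- tibble::tibble(gene = genes, score = scores)
      m <- sample.int(min(4, n - 1), 1)
      hit <- sort(sample.int(n, m))
      wp <- sample(c(0, 1, 1.5), 1)
      got <- enrichment_score(ranked, genes[hit], weight_p = wp)$es
      expect_equal(got, oracle_es(scores, hit, wp), tolerance = 1e-12)
    }
  })
})

test_that("reversing the ranked list negates ES for the unweighted statistic", {
  withr::with_seed(19, {
    for (rep in 1:50) {
      n <- sample(4:10, 1)
      genes <- sprintf("X%02d", 1:n)
      scores <- sort(runif(n), decreasing = TRUE)
      m <- sample.int(n - 1, 1)
      hit_genes <- genes[sort(sample.int(n, m))]
      fwd <- tibble::tibble(gene = genes, score = scores)
      rev <- tibble::tibble(gene = rev(genes), score = scores)
      es_f <- enrichment_score(fwd, hit_genes, weight_p = 0)$es
      es_r <- enrichment_score(rev, hit_genes, weight_p = 0)$es
      expect_equal(abs(es_f), abs(es_r), tolerance = 1e-12)
      # signs flip, except when the two extrema tie in magnitude and both
      # directions resolve to the positive side
      expect_true(abs(es_f + es_r) < 1e-12 || (es_f > 0 && es_r > 0))
    }
  })
})

test_that("zero-score hits fall back to equal increments", {
  ranked <- make_ranked(c(a = 1, b = 0, c = 0, d = 0))
  expect_silent(res <- enrichment_score(ranked, c("C", "D"), weight_p = 1))
  expect_equal(res$profile$running[1], -0.5)  # miss decrement 1/(4-2)
  expect_equal(diff(res$profile$running)[2], 0.5)  # equal hit increment 1/2
})

test_that("gsea is deterministic, ordered, and BH-monotone", {
  withr::with_seed(31, {
    genes <- sprintf("G%03d", 1:80)
    ranked <- make_ranked(setNames(sort(rexp(80), decreasing = TRUE), genes))
    coll <- sets_tbl(genes[1:12], sample(genes, 15), sample(genes, 20),
                     sample(genes, 10))
  })
  a <- gsea(ranked, coll, n_perm = 200, seed = 4)
  b <- gsea(ranked, coll, n_perm = 200, seed = 4)
  expect_identical(tidy(a), tidy(b))
  ta <- tidy(a)
  expect_true(all(abs(ta$es) <= 1))
  expect_true(all(ta$p_adj >= ta$p_perm))
  expect_equal(order(ta$p_perm), seq_len(nrow(ta)))
  # BH preserves the p-value order up to ties
  expect_true(all(diff(ta$p_adj[order(ta$p_perm)]) >= -1e-15))
  # leading edge is inside the set and the universe
  for (i in seq_len(nrow(ta))) {
    expect_true(all(ta$leading_edge[[i]] %in% coll$genes[[which(coll$set_name == ta$set_name[i])]]))
  }
})

test_that("size filters and missing sets are handled", {
  genes <- sprintf("G%03d", 1:40)
  ranked <- make_ranked(setNames(40:1, genes))
  coll <- sets_tbl(genes[1:5], genes[1:20], c("ZZZ1", "ZZZ2"))
  expect_message(res <- gsea(ranked, coll, n_perm = 50, seed = 1,
                             min_size = 10, max_size = 30),
                 "Skipping")
  expect_equal(tidy(res)$set_name, "S2")
})

test_that("exhaustive permutation p matches exact enumeration", {
  genes <- sprintf("U%d", 1:6)
  scores <- c(6, 5, 4, 3, 2, 1)
  ranked <- make_ranked(setNames(scores, genes))
  coll <- sets_tbl(c("U1", "U3"))
  res <- gsea(ranked, coll, seed = 1, min_size = 1, max_size = 5,
              exhaustive = TRUE)
  # oracle: all choose(6,2) = 15 memberships, brute-force running sums
  null_es <- apply(combn(6, 2), 2, function(h) oracle_es(ranked$score, h, 1))
  obs <- oracle_es(ranked$score, c(1, 3), 1)
  same <- null_es > 0
  p_exact <- (1 + sum(abs(null_es[same]) >= abs(obs))) / (1 + sum(same))
  expect_equal(tidy(res)$p_perm, p_exact)
  expect_equal(tidy(res)$es, obs)
})

test_that("gsea agrees with an independent GSEA implementation on ES", {
  skip_if_not_installed("fgsea")
  withr::with_seed(41, {
    genes <- sprintf("G%03d", 1:60)
    scores <- sort(rexp(60), decreasing = TRUE)
    ranked <- tibble::tibble(gene = genes, score = scores)
    members <- sample(genes, 12)
  })
  ours <- enrichment_score(ranked, members, weight_p = 1)$es
  stats_vec <- setNames(ranked$score, ranked$gene)
  theirs <- suppressWarnings(
    fgsea::fgsea(list(S = members), stats_vec, nPermSimple = 101)
  )$ES
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("the resampling control flags only doubly significant sets", {
  orig <- tibble::tibble(set_name = c("A", "B", "C"),
                         p_adj = c(0.01, 0.01, 0.5))
  resa <- tibble::tibble(set_name = c("A", "C"), p_adj = c(0.02, 0.01))
  flags <- control_compare(orig, resa, alpha = 0.05)
  expect_equal(flags$nonspecific, c(TRUE, FALSE, FALSE))
  empty <- control_compare(orig, tibble::tibble(set_name = character(),
                                                p_adj = numeric()))
  expect_false(any(empty$nonspecific))
})

test_that("threshold selection is strict and nested", {
  scores <- c(A = 0.25, B = 0.15, C = 0.85, D = 0)
  expect_setequal(threshold_select(scores, 0.2), c("A", "C"))
  expect_setequal(threshold_select(scores, 0), c("A", "B", "C"))
  n02 <- length(threshold_select(scores, 0.2))
  n05 <- length(threshold_select(scores, 0.5))
  n08 <- length(threshold_select(scores, 0.8))
  expect_true(n08 <= n05 && n05 <= n02)
  expect_error(threshold_select(scores, 1), "threshold")
})

test_that("ORA reproduces hand-computed hypergeometric tails", {
  univ <- sprintf("U%02d", 1:10)
  coll <- sets_tbl(univ[1:4])
  res <- ora(univ[1:5], univ, coll, min_size = 1, max_size = 10)
  # overlap 4 of set 4, selection 5 of 10: C(4,4) C(6,1) / C(10,5) = 6/252
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_hyper, 6 / 252)

  # single draw: enumerate all 10 possible draws by brute force
  in_set <- univ %in% univ[1:4]
  res1 <- ora(univ[1], univ, coll, min_size = 1, max_size = 10)  # overlap 1
  expect_equal(res1$p_hyper, mean(in_set))  # P(X >= 1) = K/N
  res0 <- ora(univ[10], univ, coll, min_size = 1, max_size = 10)  # overlap 0
  expect_equal(res0$p_hyper, 1)  # P(X >= 0) is certain

  # selection = universe forces every overlap to the full set size, p = 1
  resall <- ora(univ, univ, coll, min_size = 1, max_size = 10)
  expect_equal(resall$p_hyper, 1)
  expect_equal(resall$overlap, 4L)
})

test_that("ORA drops out-of-universe selections with a warning", {
  univ <- sprintf("U%02d", 1:10)
  coll <- sets_tbl(univ[1:4])
  expect_warning(res <- ora(c(univ[1:3], "ALIEN"), univ, coll,
                            min_size = 1, max_size = 10), "outside")
  expect_equal(res$selection_size, 3L)
  expect_equal(nrow(ora(character(), univ, coll, min_size = 1, max_size = 10)), 0)
})

test_that("dot-plot export writes the documented JSON records", {
  genes <- sprintf("G%03d", 1:50)
  ranked <- make_ranked(setNames(50:1, genes))
  res <- gsea(ranked, sets_tbl(genes[1:12], genes[30:45]), n_perm = 100,
              seed = 2)
  f <- tempfile(fileext = ".json")
  export_dotplot_json(res, f, top_n = 1)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_named(rec, c("set_name", "gene_ratio", "overlap_count", "p_adj"))
  expect_equal(nrow(rec), 1)
})
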