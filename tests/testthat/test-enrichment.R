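test_that("enrichment score matches hand-computed values on tiny lists", {
  # ranked list a(4), b(3), c(2), d(1); weight 1
  # set {a}: running sum jumps to +1 at position 1 -> ES = 1
  expect_equal(es_from_hits(4, 1L, 4), 1)
  # set {d}: three misses of 1/3 each, then back to 0 -> extreme is -1
  expect_equal(es_from_hits(1, 4L, 4), -1)
  # set {a, d}: after a, sum = 4/5; d contributes 1/5 after two -1/2 misses
  expect_equal(es_from_hits(c(4, 1), c(1L, 4L), 4), 4 / 5)
  # weight 0 reduces to the classic KS statistic: increments 1/k
  expect_equal(es_from_hits(c(1, 1), c(1L, 2L), 4), 1)
})

test_that("enrichment score agrees with the full-walk oracle and with fgsea", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(20:80, 1)
      scores <- sort(rnorm(n, sd = 2), decreasing = TRUE)
      k <- sample(3:10, 1)
      hit <- sort(sample.int(n, k))
      in_set <- seq_len(n) %in% hit
      for (w in c(0, 1, 1.5)) {
        got <- es_from_hits(abs(scores[hit])^w, hit, n)
        expect_equal(got, oracle_es(scores, in_set, w), tolerance = 1e-12)
        # fgsea returns 0 when the positive and negative extremes tie
        # exactly; this package documents ties as resolving positive.
        # Compare only away from that degenerate case.
        ext <- oracle_es_extremes(scores, in_set, w)
        if (abs(ext[["pos"]]) != abs(ext[["neg"]])) {
          expect_equal(got,
                       fgsea::calcGseaStat(scores, hit, gseaParam = w),
                       tolerance = 1e-12)
        } else {
          expect_equal(got, ext[["pos"]], tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("preranked GSEA detects planted sets and is seed-deterministic", {
  withr::with_seed(3, {
    score <- sort(rnorm(200, sd = 1.5), decreasing = TRUE)
  })
  ranked <- tibble::tibble(gene_symbol = sprintf("g%03d", 1:200),
                           score = score)
  sets <- list(
    top = ranked$gene_symbol[1:15],       # concentrated at the top
    bottom = ranked$gene_symbol[186:200], # concentrated at the bottom
    spread = ranked$gene_symbol[seq(5, 200, by = 13)]
  )
  res <- preranked_gsea(ranked, sets, n_perm = 500, seed = 42)
  expect_s3_class(res, "gsea_result")
  expect_setequal(res$set_name, names(sets))
  top <- res[res$set_name == "top", ]
  bottom <- res[res$set_name == "bottom", ]
  expect_gt(top$es, 0)
  expect_equal(top$direction, "enriched")
  expect_lt(top$p_value, 0.01)
  expect_lt(bottom$es, 0)
  expect_equal(bottom$direction, "depleted")
  expect_lt(bottom$p_value, 0.05)
  expect_gt(res$p_value[res$set_name == "spread"], 0.05)
  expect_true(all(res$p_value >= 1 / 501))
  expect_true(all(abs(res$es) <= 1))

  expect_identical(res, preranked_gsea(ranked, sets, n_perm = 500, seed = 42))
  other <- preranked_gsea(ranked, sets, n_perm = 500, seed = 43)
  expect_false(identical(res$p_value, other$p_value))

  # an unsorted copy of the ranking gives identical results
  shuf <- ranked[withr::with_seed(1, sample.int(200)), ]
  expect_identical(preranked_gsea(shuf, sets, n_perm = 100, seed = 1),
                   preranked_gsea(ranked, sets, n_perm = 100, seed = 1))
})

test_that("preranked GSEA enforces size bounds and input contracts", {
  ranked <- tibble::tibble(gene_symbol = letters[1:20], score = 20:1 / 4)
  sets <- list(tiny = letters[1:2], ok = letters[1:6],
               alien = c("zz", "yy", "xx", "ww", "vv"))
  expect_message(
    res <- preranked_gsea(ranked, sets, n_perm = 100, min_size = 5, seed = 1),
    "skipping"
  )
  expect_equal(res$set_name, "ok")
  expect_equal(res$size, 6L)
  expect_error(preranked_gsea(ranked[0, ], sets, seed = 1),
               class = "mircargo_invalid_input")
  expect_error(preranked_gsea(ranked, sets, n_perm = -5, seed = 1),
               class = "mircargo_invalid_parameter")
})

test_that("over-representation p-values equal the closed form and the enumeration oracle", {
  universe <- letters[1:10]
  res <- ora(c("a", "b"), list(s = c("a", "b", "c")), universe)
  expect_equal(res$overlap_size, 2L)
  expect_equal(res$p_value, 1 / 15)  # choose(3,2)/choose(10,2) by hand
  expect_equal(res$p_value, oracle_hyper_enum(10, 3, 2, 2), tolerance = 1e-12)

  # random instances against exhaustive enumeration
  withr::with_seed(5, {
    for (rep in 1:10) {
      n_u <- sample(8:16, 1)
      m <- sample(2:5, 1)
      k <- sample(2:5, 1)
      uni <- sprintf("u%02d", seq_len(n_u))
      gene_list <- sample(uni, k)
      set <- uni[seq_len(m)]
      got <- ora(gene_list, list(s = set), uni)
      expect_equal(got$p_value,
                   oracle_hyper_enum(n_u, m, k, got$overlap_size),
                   tolerance = 1e-12)
    }
  })
})

test_that("over-representation analysis is monotone and validates the universe", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(s = universe[1:10])
  p1 <- ora(universe[1:2], sets, universe)$p_value
  p2 <- ora(universe[c(1:2, 11:12)], sets, universe)$p_value  # same overlap, longer list
  expect_lt(p1, p2)
  p3 <- ora(universe[1:4], sets, universe)$p_value  # same length, larger overlap
  expect_lt(p3, p2)
  expect_error(ora(c("g01", "nope"), sets, universe),
               class = "mircargo_invalid_input")
  # genes outside the universe inside a set are ignored
  expect_equal(ora("g01", list(s = c(universe[1:10], "alien")), universe),
               ora("g01", sets, universe))
})

test_that("top-term selection and the enrichment plot behave", {
  res <- tibble::tibble(
    set_name = c("e1", "e2", "d1", "weak"),
    size = c(10L, 10L, 10L, 10L),
    es = c(0.8, 0.6, -0.7, 0.2),
    nes = c(2.5, 1.9, -2.1, 0.8),
    p_value = c(0.001, 0.01, 0.002, 0.4),
    p_adj = c(0.004, 0.02, 0.004, 0.4),
    direction = c("enriched", "enriched", "depleted", "enriched")
  )
  class(res) <- c("gsea_result", class(res))
  top <- select_top_terms(res, k = 1)
  expect_equal(top$top_enriched$set_name, "e1")
  expect_equal(top$top_depleted$set_name, "d1")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res[res$p_value > 0.3, ]), "ggplot")
})
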