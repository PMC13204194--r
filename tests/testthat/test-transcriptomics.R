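make_matrix <- function(rows, groups = NULL) {
  tpm <- tibble::tibble(transcript_id = names(rows)) |>
    dplyr::bind_cols(as.data.frame(do.call(rbind, rows)) |>
                       setNames(c("c1", "c2", "c3", "t1", "t2", "t3")))
  groups <- groups %||% tibble::tibble(
    sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
    group = rep(c("control", "treated"), each = 3))
  list(tpm = tpm, groups = groups)
}

test_that("abundance filter applies the low-TPM rule per group", {
  m <- make_matrix(list(
    keep = c(12, 15, 20, 11, 13, 14),      # no sample below 10
    drop_ctrl = c(0, 0, 0, 50, 60, 70),    # low in control only
    drop_both = c(1, 2, 3, 4, 5, 6),
    borderline = c(10, 10, 10, 10, 10, 10) # 10 is not strictly below 10
  ))
  either <- suppressMessages(filter_low_tpm(m$tpm, m$groups))
  expect_setequal(either$transcript_id, c("keep", "borderline"))
  expect_equal(attr(either, "n_removed"), 2)
  both <- suppressMessages(filter_low_tpm(m$tpm, m$groups,
                                          scope = "both_groups"))
  expect_setequal(both$transcript_id, c("keep", "drop_ctrl", "borderline"))
  expect_error(filter_low_tpm(m$tpm, m$groups, scope = "sometimes"))
})

test_that("abundance filter matches a row-by-row oracle and is idempotent", {
  sim <- sim_expression_matrix(100, 3, 0, 0, 0.5, seed = 21)
  got <- suppressMessages(filter_low_tpm(sim$tpm, sim$groups))
  grp <- split(sim$groups$sample_id, sim$groups$group)
  keep_oracle <- vapply(seq_len(nrow(sim$tpm)), function(i) {
    low <- vapply(grp, function(cols) {
      sum(unlist(sim$tpm[i, cols]) < 10) >= 2
    }, logical(1))
    !any(low)
  }, logical(1))
  expect_identical(got$transcript_id, sim$tpm$transcript_id[keep_oracle])
  twice <- suppressMessages(filter_low_tpm(got, sim$groups))
  expect_identical(twice$transcript_id, got$transcript_id)
})

test_that("differential expression is symmetric and matches stats::t.test", {
  sim <- sim_expression_matrix(60, 3, 0, 0, 0.4, seed = 31)
  deg <- differential_expression(sim$tpm, sim$groups)
  expect_equal(deg$log_fc, log2(deg$fold_change), tolerance = 1e-9)

  # cross-check p-values against the reference Welch implementation
  idx <- c(1, 7, 42)
  for (i in idx) {
    x <- log2(unlist(sim$tpm[i, c("ctrl_1", "ctrl_2", "ctrl_3")]) + 1)
    y <- log2(unlist(sim$tpm[i, c("trt_1", "trt_2", "trt_3")]) + 1)
    expect_equal(deg$p_value[i], stats::t.test(y, x)$p.value,
                 tolerance = 1e-12)
  }

  # swapping group labels negates log_fc and preserves p
  swapped <- sim$groups |>
    dplyr::mutate(group = ifelse(group == "control", "treated", "control"))
  deg_sw <- differential_expression(sim$tpm, swapped)
  expect_equal(deg_sw$log_fc, -deg$log_fc, tolerance = 1e-12)
  expect_equal(deg_sw$p_value, deg$p_value, tolerance = 1e-12)

  # permuting sample columns within groups changes nothing
  perm <- sim$tpm[, c("transcript_id", "ctrl_3", "ctrl_1", "ctrl_2",
                      "trt_2", "trt_3", "trt_1")]
  expect_equal(differential_expression(perm, sim$groups)$p_value,
               deg$p_value, tolerance = 1e-12)
})

test_that("degenerate inputs follow the documented conventions", {
  tpm <- tibble::tibble(transcript_id = c("a", "b"),
                        c1 = c(5, 1), c2 = c(5, 2), c3 = c(5, 3),
                        t1 = c(5, 1), t2 = c(5, 2), t3 = c(5, 3))
  groups <- tibble::tibble(sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                           group = rep(c("control", "treated"), each = 3))
  deg <- differential_expression(tpm, groups)
  expect_equal(deg$log_fc, c(0, 0))
  expect_equal(deg$p_value, c(1, 1))  # zero-variance row 'a' by convention
  expect_true(all(classify_drgs(deg)$call == "ns"))
})

test_that("DRG classification uses strict cutoffs on both axes", {
  rec <- tibble::tibble(
    transcript_id = c("at_lfc_boundary", "at_p_boundary", "down", "up", "ns"),
    log_fc = c(-0.5, -2, log2(1.62e-2), log2(3.16e10), 0.1),
    p_value = c(0.001, 0.01, 1.39e-3, 1.42e-12, 0.5)
  )
  called <- classify_drgs(rec)
  expect_equal(as.character(called$call),
               c("ns", "ns", "down", "up", "ns"))
  expect_equal(called$log_fc[3], -5.95, tolerance = 1e-2)

  sets <- drg_sets(rec)
  expect_equal(sets$down$transcript_id, "down")
  expect_equal(sets$up$transcript_id, "up")
  expect_error(classify_drgs(rec[0, ]), class = "mircargo_invalid_input")
})

test_that("planted effects are recovered with high sensitivity and controlled FDR", {
  sim <- sim_expression_matrix(1000, 3, 0.1, 3, 0.3, seed = 41)
  filtered <- suppressMessages(filter_low_tpm(sim$tpm, sim$groups))
  called <- classify_drgs(differential_expression(filtered, sim$groups))
  hits <- called$transcript_id[called$call != "ns"]
  truth <- sim$truth$de_transcripts
  # downregulated planted transcripts can fall below the abundance filter;
  # sensitivity is assessed among the transcripts that were actually tested
  testable <- intersect(truth, filtered$transcript_id)
  sensitivity <- mean(testable %in% hits)
  fdr <- if (length(hits) > 0) mean(!hits %in% truth) else 0
  expect_gt(sensitivity, 0.7)
  expect_lt(fdr, 0.2)
  # directions agree with the planted ones
  dir_called <- setNames(as.character(called$call), called$transcript_id)
  common <- intersect(truth, hits)
  expect_true(all(dir_called[common] == sim$truth$de_direction[common]))
})

test_that("gene collapsing averages member transcripts and sorts deterministically", {
  rec <- tibble::tibble(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                        log_fc = c(1, -1, 2, 0.5, 3))
  map <- tibble::tibble(transcript_id = c("t1", "t2", "t3", "t4"),
                        gene_symbol = c("gA", "gA", "gB", "gC"))
  ranked <- collapse_to_genes(rec, map)
  expect_equal(ranked$gene_symbol, c("gB", "gC", "gA"))  # t5 unmapped, dropped
  expect_equal(ranked$score, c(2, 0.5, 0))

  # one-to-one mapping reduces to sorting by log_fc
  map11 <- tibble::tibble(transcript_id = rec$transcript_id,
                          gene_symbol = paste0("g_", rec$transcript_id))
  r11 <- collapse_to_genes(rec, map11)
  expect_equal(r11$score, sort(rec$log_fc, decreasing = TRUE))

  # random many-to-one mapping equals a direct group-mean oracle
  sim <- sim_expression_matrix(200, 3, 0.1, 1, 0.3, seed = 51)
  deg <- differential_expression(sim$tpm, sim$groups)
  got <- collapse_to_genes(deg, sim$gene_map)
  oracle <- vapply(got$gene_symbol, function(g) {
    tx <- sim$gene_map$transcript_id[sim$gene_map$gene_symbol == g]
    mean(deg$log_fc[deg$transcript_id %in% tx])
  }, numeric(1))
  expect_equal(got$score, unname(oracle), tolerance = 1e-12)
  expect_error(collapse_to_genes(rec, map[0, ]),
               class = "mircargo_empty_result")
})
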