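test_that("generators are bit-identical under a fixed seed and diverge with it", {
  a <- sim_expression_matrix(200, 3, 0.1, 2, 0.3, seed = 5)
  b <- sim_expression_matrix(200, 3, 0.1, 2, 0.3, seed = 5)
  c <- sim_expression_matrix(200, 3, 0.1, 2, 0.3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$tpm, c$tpm))

  ids <- sprintf("m%02d", 1:12)
  expect_identical(sim_ct_card(ids, 3, 0.5, 23.8, 6, 0.3, seed = 2),
                   sim_ct_card(ids, 3, 0.5, 23.8, 6, 0.3, seed = 2))
  expect_identical(
    sim_target_dbs(ids[1:4], sprintf("G%03d", 1:100), 0.05, 0.2, 3, seed = 3),
    sim_target_dbs(ids[1:4], sprintf("G%03d", 1:100), 0.05, 0.2, 3, seed = 3))
  expect_identical(sim_genesets(letters, 5, c(3, 6), seed = 4),
                   sim_genesets(letters, 5, c(3, 6), seed = 4))
  expect_identical(sim_survival(30, 2, 0.2, seed = 5),
                   sim_survival(30, 2, 0.2, seed = 5))
})

test_that("expression generator plants the requested effects", {
  sim <- sim_expression_matrix(1000, 3, 0.1, 2, 0.3, seed = 1)
  expect_equal(dim(sim$tpm), c(1000, 7))  # id column + 6 samples
  expect_length(sim$truth$de_transcripts, 100)
  expect_true(all(sim$truth$de_transcripts %in% sim$tpm$transcript_id))
  expect_true(all(as.matrix(sim$tpm[-1]) >= 0))
  expect_setequal(sim$groups$group, c("control", "treated"))
  # planted transcripts show the shift in group means (effect 2 log2 units,
  # well above the sampling noise at dispersion 0.3)
  grp <- split(sim$groups$sample_id, sim$groups$group)
  mat <- as.matrix(sim$tpm[-1])
  rownames(mat) <- sim$tpm$transcript_id
  lfc <- log2(rowMeans(mat[, grp$treated]) + 1) -
    log2(rowMeans(mat[, grp$control]) + 1)
  planted_dir <- sim$truth$de_direction
  expect_gt(mean(sign(lfc[names(planted_dir)]) ==
                   ifelse(planted_dir == "up", 1, -1)), 0.95)
})

test_that("expression generator validates its parameters", {
  expect_error(sim_expression_matrix(100, 1, 0.1, 2, 0.3, seed = 1),
               class = "mircargo_invalid_parameter")
  expect_error(sim_expression_matrix(100, 3, 0.1, Inf, 0.3, seed = 1),
               class = "mircargo_invalid_parameter")
  expect_error(sim_expression_matrix(100, 3, 0.9, 2, 0.3, seed = 1,
                                     low_fraction = 0.3),
               class = "mircargo_invalid_parameter")
})

test_that("card generator output is recovered exactly by the calling rule in the noiseless limit", {
  ids <- sprintf("m%02d", 1:20)
  cards <- sim_ct_card(ids, 3, 0.5, 23.852, 6, 1e-9, seed = 11)
  calls <- call_expressed(cards$ev, cards$medium)
  expect_setequal(calls$target_id[calls$expressed],
                  cards$truth$true_expressed_mirnas)
  high <- call_highly_expressed(calls)
  expect_setequal(high$target_id[high$highly_expressed],
                  cards$truth$true_high_mirnas)
  # spike-in present on both cards, in every preparation
  for (card in cards[c("ev", "medium")]) {
    spike <- card[card$is_spike_in & !card$is_ntc, ]
    expect_equal(sort(unique(spike$prep_id)), sprintf("prep_%d", 1:3))
    expect_true(all(abs(spike$ct - 23.852) < 1))
  }
  expect_error(sim_ct_card(character(0), 3, 0.5, 23.8, 6, 0.3, seed = 1),
               class = "mircargo_invalid_parameter")
})

test_that("calling rule recovers planted expressed sets at realistic noise", {
  ids <- sprintf("m%02d", 1:20)
  hits <- vapply(1:20, function(s) {
    cards <- sim_ct_card(ids, 3, 0.5, 23.852, 6, 0.3, seed = 100 + s)
    calls <- call_expressed(cards$ev, cards$medium)
    setequal(calls$target_id[calls$expressed],
             cards$truth$true_expressed_mirnas)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("planted consensus pairs are exactly the consensus at zero background overlap", {
  mirnas <- sprintf("miR-%d", 1:6)
  genes <- sprintf("G%03d", 1:200)
  dbs <- sim_target_dbs(mirnas, genes, per_db_density = 0.05,
                        consensus_overlap = 0, n_dbs = 3, seed = 9,
                        planted_per_mirna = 3)
  got <- oracle_consensus(dbs$predictions, 2)
  expect_identical(got[mirnas], dbs$truth$planted_consensus_targets[mirnas])
  # zero density and zero planting: all consensus sets empty
  empty <- sim_target_dbs(mirnas, genes, 0, 0, 3, seed = 9,
                          planted_per_mirna = 0)
  expect_equal(nrow(consensus_targets(empty$predictions,
                                      db_names = empty$db_names)), 0)
  expect_error(sim_target_dbs(mirnas, genes, 0.05, 0, n_dbs = 1, seed = 1),
               class = "mircargo_invalid_parameter")
})

test_that("gene-set generator respects sizes and planting constraints", {
  sets <- sim_genesets(letters, 10, c(5, 5), seed = 3)
  expect_true(all(lengths(sets) == 5))
  expect_error(sim_genesets(letters, 5, c(3, 6), planted_list = c("zz"),
                            n_planted_sets = 1, seed = 1),
               class = "mircargo_invalid_parameter")
  expect_error(sim_genesets(letters, 5, c(3, 60), seed = 1),
               class = "mircargo_invalid_parameter")
  planted <- sim_genesets(sprintf("G%03d", 1:300), 10, c(20, 30),
                          planted_list = sprintf("G%03d", 1:50),
                          n_planted_sets = 2, seed = 4)
  for (nm in attr(planted, "planted_sets")) {
    expect_gte(mean(planted[[nm]] %in% sprintf("G%03d", 1:50)), 0.5)
  }
})

test_that("survival generator honours censoring and size constraints", {
  co <- sim_survival(40, 2, 0, seed = 2)
  expect_true(all(co$event == 1))
  expect_true(all(co$time > 0))
  expect_error(sim_survival(10, 2, 0.2, seed = 1),
               class = "mircargo_invalid_parameter")
  # hazard ratio pushes events earlier in the above-median group
  co2 <- sim_survival(400, 4, 0, seed = 3)
  high <- co2$expression > median(co2$expression)
  expect_lt(median(co2$time[high]), median(co2$time[!high]))
})

test_that("generated files round-trip losslessly through the writers and readers", {
  dir <- withr::local_tempdir()
  sim <- sim_expression_matrix(50, 3, 0.1, 2, 0.3, seed = 8)
  write_tpm_matrix(sim$tpm, file.path(dir, "tpm.tsv"))
  back <- read_tpm_matrix(file.path(dir, "tpm.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$tpm), tolerance = 1e-12)

  cards <- sim_ct_card(sprintf("m%d", 1:8), 3, 0.5, 23.8, 6, 0.3, seed = 8)
  write_ct_card(cards$ev, file.path(dir, "ev.csv"))
  ev_back <- read_ct_card(file.path(dir, "ev.csv"))
  expect_equal(ev_back$ct, cards$ev$ct, tolerance = 1e-10)
  expect_identical(ev_back$is_spike_in, cards$ev$is_spike_in)

  sets <- sim_genesets(letters, 4, c(3, 6), seed = 8)
  write_gmt(sets, file.path(dir, "sets.gmt"))
  expect_identical(read_gmt(file.path(dir, "sets.gmt")),
                   setNames(lapply(sets, identity), names(sets)))

  co <- sim_survival(20, 2, 0.3, seed = 8)
  write_survival_cohort(co, file.path(dir, "surv.tsv"))
  expect_equal(as.data.frame(read_survival_cohort(file.path(dir, "surv.tsv"))),
               as.data.frame(co), tolerance = 1e-12)
})
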