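#' Remove low-abundance transcripts from a TPM matrix
#'
#' A transcript is excluded when, within at least one experimental group
#' (`scope = "either_group"`) or within every group
#' (`scope = "both_groups"`), at least `min_low_samples` samples fall
#' strictly below `threshold` TPM.
#'
#' @param tpm Tibble with a `transcript_id` column and one numeric column
#'   per sample.
#' @param groups Tibble with `sample_id` and `group`
#'   (`"control"`/`"treated"`); every sample column of `tpm` must appear.
#' @param threshold TPM threshold (default 10); values strictly below count
#'   as low.
#' @param min_low_samples Minimum number of low samples per group to
#'   trigger removal (default 2).
#' @param scope `"either_group"` (default): the condition in one group
#'   suffices for exclusion; `"both_groups"`: it must hold in every group.
#' @return The filtered tibble, sample order preserved; the number of
#'   removed transcripts is reported and stored in the `"n_removed"`
#'   attribute. Idempotent: filtering twice equals filtering once.
#' @examples
#' sim <- sim_expression_matrix(100, 3, 0, 0, 0.3, seed = 1)
#' filtered <- filter_low_tpm(sim$tpm, sim$groups)
#' @export
filter_low_tpm <- function(tpm, groups, threshold = 10, min_low_samples = 2,
                           scope = c("either_group", "both_groups")) {
  scope <- rlang::arg_match(scope)
  assert_cols(tpm, "transcript_id", "tpm")
  assert_cols(groups, c("sample_id", "group"), "groups")
  assert_scalar_num(threshold, "threshold")
  min_low_samples <- assert_count(min_low_samples, "min_low_samples")
  sample_cols <- setdiff(names(tpm), "transcript_id")
  if (!all(sample_cols %in% groups$sample_id)) {
    rlang::abort("every sample column must be assigned to a group.",
                 class = "mircargo_invalid_input")
  }
  grp_of <- setNames(groups$group, groups$sample_id)
  if (any(table(grp_of[sample_cols]) < min_low_samples)) {
    rlang::abort("each group needs at least `min_low_samples` samples.",
                 class = "mircargo_invalid_input")
  }
  mat <- as.matrix(tpm[sample_cols])
  low_per_group <- vapply(unique(grp_of[sample_cols]), function(g) {
    cols <- sample_cols[grp_of[sample_cols] == g]
    rowSums(mat[, cols, drop = FALSE] < threshold)
  }, numeric(nrow(mat)))
  if (!is.matrix(low_per_group)) {
    low_per_group <- matrix(low_per_group, nrow = nrow(mat))
  }
  hit <- low_per_group >= min_low_samples
  remove <- if (scope == "either_group") {
    apply(hit, 1, any)
  } else {
    apply(hit, 1, all)
  }
  rlang::inform(sprintf("filter_low_tpm: removed %d of %d transcripts.",
                        sum(remove), nrow(tpm)))
  out <- tpm[!remove, , drop = FALSE]
  attr(out, "n_removed") <- sum(remove)
  out
}

# Vectorised Welch two-sample t-test on the rows of two matrices.
# Returns two-sided p-values; rows where both groups have zero variance get
# p = 1 by convention.
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  p[v1 == 0 & v2 == 0] <- 1
  list(p = p, t = t_stat)
}

#' Per-transcript differential expression between two groups
#'
#' Fold change is the ratio of pseudocounted group means of raw TPM,
#' `(mean treated + pc) / (mean control + pc)`; the p-value comes from a
#' Welch two-sample t-test on `log2(TPM + pc)`, the simplest defensible
#' location test at three-versus-three samples. Transcripts with zero
#' variance in both groups get `p_value = 1` by convention. No
#' multiple-testing correction is applied to the primary p-value (a
#' Benjamini-Hochberg column is emitted for information).
#'
#' @inheritParams filter_low_tpm
#' @param pseudocount Pseudocount added to TPM for both the fold change and
#'   the log transform (default 1).
#' @return Tibble: `transcript_id`, `fold_change`, `log_fc`
#'   (`= log2(fold_change)`), `p_value`, `p_adj`.
#' @examples
#' sim <- sim_expression_matrix(100, 3, 0.2, 2, 0.3, seed = 1)
#' deg <- differential_expression(sim$tpm, sim$groups)
#' @export
differential_expression <- function(tpm, groups, pseudocount = 1) {
  assert_cols(tpm, "transcript_id", "tpm")
  assert_cols(groups, c("sample_id", "group"), "groups")
  assert_scalar_num(pseudocount, "pseudocount")
  grp_of <- setNames(groups$group, groups$sample_id)
  sample_cols <- setdiff(names(tpm), "transcript_id")
  ctrl <- sample_cols[grp_of[sample_cols] == "control"]
  trt <- sample_cols[grp_of[sample_cols] == "treated"]
  if (length(ctrl) < 2 || length(trt) < 2) {
    rlang::abort("need >= 2 samples per group.",
                 class = "mircargo_invalid_input")
  }
  a <- as.matrix(tpm[ctrl]); b <- as.matrix(tpm[trt])
  fc <- (rowMeans(b) + pseudocount) / (rowMeans(a) + pseudocount)
  w <- welch_rows(log2(a + pseudocount), log2(b + pseudocount))
  tibble(
    transcript_id = tpm$transcript_id,
    fold_change = fc,
    log_fc = log2(fc),
    p_value = w$p,
    p_adj = p.adjust(w$p, "BH")
  )
}

#' Classify differentially regulated transcripts
#'
#' Applies strict cutoffs: `up` when `log_fc > lfc_cut` and
#' `p_value < p_cut`; `down` when `log_fc < -lfc_cut` and
#' `p_value < p_cut`; otherwise `ns`. Records sitting exactly on a cutoff
#' are `ns`.
#'
#' @param records Tibble with at least `log_fc` and `p_value` (as returned
#'   by [differential_expression()], or any table carrying those columns).
#' @param p_cut,lfc_cut Strict significance and effect-size cutoffs
#'   (defaults 0.01 and 0.5).
#' @return `classify_drgs()`: the input with a `call` factor column
#'   (`up`/`down`/`ns`); `drg_sets()`: a list with `up` and `down` tibbles,
#'   each ordered by ascending p-value.
#' @examples
#' classify_drgs(tibble::tibble(log_fc = c(-2, 0.2), p_value = c(1e-4, 0.5)))
#' @export
classify_drgs <- function(records, p_cut = 0.01, lfc_cut = 0.5) {
  if (nrow(records) == 0) {
    rlang::abort("`records` must be non-empty.",
                 class = "mircargo_invalid_input")
  }
  assert_cols(records, c("log_fc", "p_value"), "records")
  assert_scalar_num(p_cut, "p_cut")
  assert_scalar_num(lfc_cut, "lfc_cut")
  records |>
    mutate(call = factor(
      dplyr::case_when(
        .data$p_value < p_cut & .data$log_fc > lfc_cut ~ "up",
        .data$p_value < p_cut & .data$log_fc < -lfc_cut ~ "down",
        TRUE ~ "ns"
      ),
      levels = c("up", "down", "ns")
    ))
}

#' @rdname classify_drgs
#' @export
drg_sets <- function(records, p_cut = 0.01, lfc_cut = 0.5) {
  called <- classify_drgs(records, p_cut, lfc_cut)
  list(
    up = called |> filter(.data$call == "up") |> arrange(.data$p_value),
    down = called |> filter(.data$call == "down") |> arrange(.data$p_value)
  )
}

#' Collapse transcript-level results to a ranked gene list
#'
#' Transcripts without a gene mapping are dropped; each gene's score is the
#' arithmetic mean of its member transcripts' `log_fc`. The result is
#' sorted by descending score, with ties broken lexicographically by gene
#' symbol so the ranking is deterministic.
#'
#' @param records Tibble with `transcript_id` and `log_fc`.
#' @param gene_map Tibble with `transcript_id` and `gene_symbol`.
#' @return Tibble (`gene_symbol`, `score`, `n_transcripts`), sorted for
#'   use as a pre-ranked enrichment input.
#' @export
collapse_to_genes <- function(records, gene_map) {
  assert_cols(records, c("transcript_id", "log_fc"), "records")
  assert_cols(gene_map, c("transcript_id", "gene_symbol"), "gene_map")
  joined <- records |>
    inner_join(gene_map, by = "transcript_id") |>
    filter(!is.na(.data$gene_symbol))
  if (nrow(joined) == 0) {
    rlang::abort("no transcript in `records` has a gene mapping.",
                 class = "mircargo_empty_result")
  }
  joined |>
    summarise(score = mean(.data$log_fc), n_transcripts = dplyr::n(),
              .by = "gene_symbol") |>
    arrange(dplyr::desc(.data$score), .data$gene_symbol)
}

#' Volcano plot of a differential-expression table
#'
#' @param records Output of [classify_drgs()].
#' @param p_cut,lfc_cut Cutoff guides drawn on the plot.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, p_cut = 0.01, lfc_cut = 0.5) {
  assert_cols(records, c("log_fc", "p_value", "call"), "records")
  ggplot(records, aes(x = .data$log_fc, y = -log10(.data$p_value),
                      colour = .data$call)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(p_cut), linetype = "dotted") +
    geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dotted") +
    scale_colour_manual(values = c(up = "#E69F00", down = "#56B4E9",
                                   ns = "grey70")) +
    labs(x = "log2 fold change", y = "-log10 p-value", colour = NULL) +
    theme_minimal()
}
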