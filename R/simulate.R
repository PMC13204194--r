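#' Simulation ground truth
#'
#' Every generator returns, alongside its data, a `sim_truth` object
#' recording what was planted, so downstream recovery can be checked against
#' an independent oracle.
#'
#' @param ... Named truth fields.
#' @keywords internal
new_sim_truth <- function(...) {
  structure(list(...), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-group TPM expression matrix with planted effects
#'
#' Draws per-transcript baselines from a log-normal distribution
#' (`meanlog` uniform over an abundance stratum, `sdlog = dispersion`).
#' A `low_fraction` of transcripts is drawn from a low-abundance stratum so
#' that the TPM filter has something to remove. Planted differentially
#' expressed transcripts are sampled from the high-abundance stratum (so
#' their recovery measures the test, not the filter) and shifted by
#' `effect_log2fc` log2 units in the treated group, half up and half down.
#' A transcript-to-gene map is generated alongside; a small fraction of
#' transcripts is left unmapped to exercise the gene-collapsing step.
#'
#' @param n_transcripts,n_per_group Matrix dimensions; two groups of
#'   `n_per_group` samples each (`n_per_group >= 2`).
#' @param de_fraction Fraction of transcripts given a planted effect
#'   (must not exceed `1 - low_fraction`).
#' @param effect_log2fc Planted shift in log2 units (0 gives a null matrix).
#' @param dispersion Log-normal `sdlog` per transcript.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param low_fraction Fraction of transcripts drawn below the abundance
#'   filter threshold.
#' @param unmapped_fraction Fraction of transcripts with no gene symbol.
#' @return A list with `tpm` (tibble: `transcript_id` + one column per
#'   sample), `groups` (tibble: `sample_id`, `group`), `gene_map` (tibble:
#'   `transcript_id`, `gene_symbol`) and `truth` (a [new_sim_truth()] object
#'   with `de_transcripts`, `de_direction`, `seed`).
#' @examples
#' sim <- sim_expression_matrix(200, 3, 0.1, 2, 0.3, seed = 1)
#' dim(sim$tpm)
#' @export
sim_expression_matrix <- function(n_transcripts, n_per_group, de_fraction,
                                  effect_log2fc, dispersion, seed,
                                  low_fraction = 0.3,
                                  unmapped_fraction = 0.05) {
  n_transcripts <- assert_count(n_transcripts, "n_transcripts")
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  assert_fraction(de_fraction, "de_fraction")
  assert_scalar_num(effect_log2fc, "effect_log2fc")
  assert_scalar_num(dispersion, "dispersion", positive = TRUE)
  assert_fraction(low_fraction, "low_fraction")
  assert_fraction(unmapped_fraction, "unmapped_fraction")
  if (de_fraction > 1 - low_fraction + 1e-12) {
    rlang::abort("`de_fraction` must not exceed `1 - low_fraction`.",
                 class = "mircargo_invalid_parameter")
  }

  withr::with_seed(seed, {
    tid <- sprintf("TX%05d", seq_len(n_transcripts))
    n_low <- round(low_fraction * n_transcripts)
    is_low <- seq_len(n_transcripts) <= n_low   # deterministic stratum labels
    meanlog <- numeric(n_transcripts)
    meanlog[is_low] <- runif(sum(is_low), log(0.5), log(5))
    meanlog[!is_low] <- runif(sum(!is_low), log(20), log(500))

    n_de <- round(de_fraction * n_transcripts)
    de_idx <- sample(which(!is_low), n_de)
    direction <- sample(c("up", "down"), n_de, replace = TRUE)

    samples <- c(sprintf("ctrl_%d", seq_len(n_per_group)),
                 sprintf("trt_%d", seq_len(n_per_group)))
    groups <- tibble(sample_id = samples,
                     group = rep(c("control", "treated"), each = n_per_group))

    mat <- matrix(rlnorm(n_transcripts * 2 * n_per_group,
                         meanlog = meanlog, sdlog = dispersion),
                  nrow = n_transcripts)
    shift <- 2^(ifelse(direction == "up", effect_log2fc, -effect_log2fc))
    trt_cols <- n_per_group + seq_len(n_per_group)
    mat[de_idx, trt_cols] <- mat[de_idx, trt_cols] * shift
    colnames(mat) <- samples

    n_genes <- max(1L, ceiling(n_transcripts / 1.5))
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    gene_of <- sample(gene_ids, n_transcripts, replace = TRUE)
    unmapped <- sample(n_transcripts, round(unmapped_fraction * n_transcripts))
    gene_map <- tibble(transcript_id = tid, gene_symbol = gene_of) |>
      dplyr::slice(-unmapped)

    list(
      tpm = tibble(transcript_id = tid) |> dplyr::bind_cols(as_tibble(mat)),
      groups = groups,
      gene_map = gene_map,
      truth = new_sim_truth(
        de_transcripts = tid[de_idx],
        de_direction = setNames(direction, tid[de_idx]),
        seed = seed
      )
    )
  })
}

#' Simulate qPCR miRNA cards for EV preparations and medium controls
#'
#' Expressed miRNAs receive detectable EV Ct values around a per-target mean;
#' the medium control is either a non-detect or sits `medium_offset_ct`
#' cycles above the EV signal, so the expression-calling rule (clean NTC,
#' >= 4 Ct EV/medium separation in every preparation) recovers them.
#' Non-expressed miRNAs are either undetected in EVs or separated from the
#' medium by fewer than 4 cycles. A subset of the expressed miRNAs
#' (`high_fraction`) is planted in the high-abundance range (mean Ct in
#' 22-26, below the 27.5 high-expression cutoff); the rest sit at
#' 28.5-31. A spike-in row (`ath-miR159a` style) is present on every card,
#' and one clean no-template-control well per target is included.
#'
#' @param mirna_ids Character vector of target names (non-empty).
#' @param n_preps Number of EV (and medium) preparations.
#' @param expressed_fraction Fraction of targets truly present in EVs.
#' @param spike_ct Mean Ct of the spike-in row.
#' @param medium_offset_ct Ct separation between medium and EV signal for
#'   expressed targets when the medium well amplifies.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#' @param high_fraction Fraction of expressed targets planted as highly
#'   expressed.
#' @return A list with `ev` and `medium` card tibbles
#'   (`target_id`, `prep_id`, `ct`, `is_ntc`, `is_spike_in`; `NA` ct =
#'   non-detect) and `truth` holding `true_expressed_mirnas` and
#'   `true_high_mirnas`.
#' @export
sim_ct_card <- function(mirna_ids, n_preps, expressed_fraction, spike_ct,
                        medium_offset_ct, noise_sd, seed,
                        high_fraction = 0.5) {
  if (length(mirna_ids) == 0) {
    rlang::abort("`mirna_ids` must be non-empty.",
                 class = "mircargo_invalid_parameter")
  }
  n_preps <- assert_count(n_preps, "n_preps")
  assert_fraction(expressed_fraction, "expressed_fraction")
  if (expressed_fraction == 0) {
    rlang::abort("`expressed_fraction` must be > 0.",
                 class = "mircargo_invalid_parameter")
  }
  assert_scalar_num(spike_ct, "spike_ct", positive = TRUE)
  assert_scalar_num(medium_offset_ct, "medium_offset_ct", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", positive = TRUE)
  assert_fraction(high_fraction, "high_fraction")

  withr::with_seed(seed, {
    n <- length(mirna_ids)
    n_expr <- round(expressed_fraction * n)
    expressed <- sample(mirna_ids, n_expr)
    n_high <- round(high_fraction * n_expr)
    high <- sample(expressed, n_high)

    mu <- setNames(numeric(n), mirna_ids)
    mu[high] <- runif(n_high, 22, 26)
    mu[setdiff(expressed, high)] <- runif(n_expr - n_high, 28.5, 31)
    not_expr <- setdiff(mirna_ids, expressed)
    mu[not_expr] <- runif(length(not_expr), 26, 30)
    # for non-expressed targets: undetected in EVs, or separated from the
    # medium by fewer than 4 cycles
    ev_detected <- setNames(rep(TRUE, n), mirna_ids)
    ev_detected[not_expr] <- runif(length(not_expr)) < 0.5
    med_nd <- setNames(runif(n) < 0.5, mirna_ids)
    med_nd[not_expr] <- !ev_detected[not_expr]  # keep medium informative
    med_offset <- setNames(rep(medium_offset_ct, n), mirna_ids)
    med_offset[not_expr] <- runif(length(not_expr), 0.5, 3)

    preps <- sprintf("prep_%d", seq_len(n_preps))
    grid <- tidyr::expand_grid(target_id = mirna_ids, prep_id = preps)

    ev <- grid |>
      mutate(
        ct = unname(ifelse(ev_detected[.data$target_id],
                           mu[.data$target_id] + rnorm(nrow(grid), 0, noise_sd),
                           NA_real_)),
        is_ntc = FALSE, is_spike_in = FALSE
      )
    medium <- grid |>
      mutate(
        ct = unname(ifelse(med_nd[.data$target_id], NA_real_,
                           mu[.data$target_id] + med_offset[.data$target_id] +
                             rnorm(nrow(grid), 0, noise_sd))),
        is_ntc = FALSE, is_spike_in = FALSE
      )

    spike <- function() {
      dplyr::bind_rows(
        tibble(target_id = "spike-in", prep_id = preps,
               ct = spike_ct + rnorm(n_preps, 0, noise_sd / 4),
               is_ntc = FALSE, is_spike_in = TRUE),
        tibble(target_id = "spike-in", prep_id = "NTC", ct = NA_real_,
               is_ntc = TRUE, is_spike_in = TRUE)
      )
    }
    ntc <- tibble(target_id = mirna_ids, prep_id = "NTC", ct = NA_real_,
                  is_ntc = TRUE, is_spike_in = FALSE)

    list(
      ev = dplyr::bind_rows(ev, ntc, spike()),
      medium = dplyr::bind_rows(medium, ntc, spike()),
      truth = new_sim_truth(true_expressed_mirnas = sort(expressed),
                            true_high_mirnas = sort(high),
                            seed = seed)
    )
  })
}

#' Simulate per-database miRNA target prediction tables
#'
#' Background predictions for each miRNA are assigned to exactly one
#' database (sampled without replacement across databases) and duplicated
#' into a second, randomly chosen database with probability
#' `consensus_overlap`; with `consensus_overlap = 0` the only pairs found in
#' two or more databases are the planted ones. `planted_per_mirna` true
#' consensus targets per miRNA are forced into exactly two databases.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param gene_universe Non-empty character vector of gene symbols.
#' @param per_db_density Fraction of the universe predicted per database
#'   per miRNA (background predictions).
#' @param consensus_overlap Probability that a background prediction is
#'   duplicated into a second database, in `[0, 1]`.
#' @param n_dbs Number of databases (>= 2).
#' @param seed Integer seed.
#' @param planted_per_mirna True consensus targets planted per miRNA.
#' @param planted_pool Optional pool to draw planted targets from
#'   (default: the whole universe).
#' @return A list with `predictions` (long tibble: `mirna_id`, `db_name`,
#'   `gene_symbol`), `db_names`, and `truth` with
#'   `planted_consensus_targets` (named list miRNA -> gene set).
#' @export
sim_target_dbs <- function(mirna_ids, gene_universe, per_db_density,
                           consensus_overlap, n_dbs = 3, seed,
                           planted_per_mirna = 2, planted_pool = NULL) {
  if (length(gene_universe) == 0) {
    rlang::abort("`gene_universe` must be non-empty.",
                 class = "mircargo_invalid_parameter")
  }
  n_dbs <- assert_count(n_dbs, "n_dbs", min = 2L)
  assert_fraction(consensus_overlap, "consensus_overlap")
  assert_fraction(per_db_density, "per_db_density")
  planted_per_mirna <- assert_count(planted_per_mirna, "planted_per_mirna",
                                    min = 0L)
  planted_pool <- planted_pool %||% gene_universe
  if (!all(planted_pool %in% gene_universe)) {
    rlang::abort("`planted_pool` must be a subset of `gene_universe`.",
                 class = "mircargo_invalid_parameter")
  }
  k <- round(per_db_density * length(gene_universe))
  if (n_dbs * k + planted_per_mirna > length(gene_universe)) {
    rlang::abort("universe too small for the requested density and planting.",
                 class = "mircargo_invalid_parameter")
  }
  dbs <- sprintf("db%d", seq_len(n_dbs))

  withr::with_seed(seed, {
    per_mirna <- lapply(mirna_ids, function(m) {
      planted <- if (planted_per_mirna > 0) {
        sample(planted_pool, min(planted_per_mirna, length(planted_pool)))
      } else character(0)
      bg <- sample(setdiff(gene_universe, planted), n_dbs * k)
      rows <- list()
      if (k > 0) {
        for (d in seq_len(n_dbs)) {
          genes <- bg[(d - 1) * k + seq_len(k)]
          rows[[d]] <- tibble(mirna_id = m, db_name = dbs[d],
                              gene_symbol = genes)
          dup <- genes[runif(k) < consensus_overlap]
          if (length(dup) > 0) {
            other <- vapply(dup, function(g) sample(dbs[-d], 1), character(1))
            rows[[n_dbs + d]] <- tibble(mirna_id = m, db_name = other,
                                        gene_symbol = dup)
          }
        }
      }
      if (length(planted) > 0) {
        pl <- lapply(planted, function(g) {
          tibble(mirna_id = m, db_name = sample(dbs, 2), gene_symbol = g)
        })
        rows <- c(rows, pl)
      }
      list(rows = dplyr::bind_rows(rows), planted = sort(planted))
    })
    preds <- dplyr::bind_rows(lapply(per_mirna, `[[`, "rows"))
    if (nrow(preds) == 0) {
      preds <- tibble(mirna_id = character(), db_name = character(),
                      gene_symbol = character())
    }
    list(
      predictions = dplyr::distinct(preds),
      db_names = dbs,
      truth = new_sim_truth(
        planted_consensus_targets =
          setNames(lapply(per_mirna, `[[`, "planted"), mirna_ids),
        seed = seed
      )
    )
  })
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' `n_planted_sets` sets draw a fraction `planted_fraction` of their members
#' from `planted_list` (over-sampling the signal genes so that enrichment
#' tests have power); the remaining sets are uniform draws from the
#' universe.
#'
#' @param gene_universe Character vector of gene symbols.
#' @param n_sets Number of gene sets.
#' @param size_range Length-2 integer vector, inclusive set-size range; must
#'   fit within the universe.
#' @param planted_list Genes to over-sample into planted sets.
#' @param n_planted_sets Number of planted sets (first `n_planted_sets`
#'   names carry the prefix `"planted_"`).
#' @param seed Integer seed.
#' @param planted_fraction Fraction of a planted set drawn from
#'   `planted_list`.
#' @return A named list of character vectors (GMT-writable via
#'   [write_gmt()]); planted set names are recorded in the
#'   `"planted_sets"` attribute.
#' @export
sim_genesets <- function(gene_universe, n_sets, size_range,
                         planted_list = character(0), n_planted_sets = 0,
                         seed, planted_fraction = 0.8) {
  n_sets <- assert_count(n_sets, "n_sets")
  n_planted_sets <- assert_count(n_planted_sets, "n_planted_sets", min = 0L)
  if (length(size_range) != 2 || any(size_range < 1) ||
      max(size_range) > length(gene_universe)) {
    rlang::abort("`size_range` must fit within the universe size.",
                 class = "mircargo_invalid_parameter")
  }
  if (!all(planted_list %in% gene_universe)) {
    rlang::abort("`planted_list` must be a subset of `gene_universe`.",
                 class = "mircargo_invalid_parameter")
  }
  if (n_planted_sets > 0 && length(planted_list) == 0) {
    rlang::abort("planted sets requested but `planted_list` is empty.",
                 class = "mircargo_invalid_parameter")
  }
  withr::with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
    sets <- lapply(seq_len(n_sets), function(i) {
      if (i <= n_planted_sets) {
        n_pl <- min(round(planted_fraction * sizes[i]), length(planted_list))
        pl <- sample(planted_list, n_pl)
        rest <- sample(setdiff(gene_universe, pl), sizes[i] - n_pl)
        sample(c(pl, rest))
      } else {
        sample(gene_universe, sizes[i])
      }
    })
    names(sets) <- c(sprintf("planted_%02d", seq_len(n_planted_sets)),
                     sprintf("set_%03d", seq_len(n_sets - n_planted_sets)))
    attr(sets, "planted_sets") <- head(names(sets), n_planted_sets)
    sets
  })
}

#' Simulate a survival cohort with an expression-linked hazard
#'
#' Expression values are Gaussian; event times are exponential, with the
#' hazard multiplied by `hazard_ratio` for patients above the median
#' expression. Censoring is independent: with probability `censor_rate` a
#' record is censored at a uniform time before its event.
#'
#' @param n_patients Cohort size (>= 16, so two groups of >= 8 exist).
#' @param hazard_ratio Hazard multiplier for the above-median group (> 0).
#' @param censor_rate Probability a record is censored, in `[0, 1]`.
#' @param seed Integer seed.
#' @param base_hazard Baseline exponential hazard (events per time unit).
#' @return A tibble (`patient_id`, `expression`, `time`, `event`).
#' @export
sim_survival <- function(n_patients, hazard_ratio, censor_rate, seed,
                         base_hazard = 0.1) {
  n_patients <- assert_count(n_patients, "n_patients", min = 16L)
  assert_scalar_num(hazard_ratio, "hazard_ratio", positive = TRUE)
  assert_fraction(censor_rate, "censor_rate")
  assert_scalar_num(base_hazard, "base_hazard", positive = TRUE)
  withr::with_seed(seed, {
    expression <- rnorm(n_patients, 10, 2)
    high <- expression > median(expression)
    rate <- base_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(n_patients, rate)
    censored <- runif(n_patients) < censor_rate
    time <- ifelse(censored, runif(n_patients, 0, 1) * t_event, t_event)
    time <- pmax(time, .Machine$double.eps)
    tibble(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      expression = expression,
      time = time,
      event = as.integer(!censored)
    )
  })
}
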