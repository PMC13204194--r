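#' Pipeline configuration
#'
#' Collects every stage threshold with its standard default: TPM filter at
#' 10 with 2 low samples, DRG cutoffs p < 0.01 and |logFC| > 0.5, GSEA
#' permutation and size settings, the 4-cycle EV/medium separation and
#' 27.5 high-expression Ct cutoff for card calling, the 2-of-3 database
#' consensus rule, the 0.05 pathway significance level, and the minimum
#' group size of 8 for survival scan mode. One `seed` drives every
#' stochastic stage.
#'
#' @param seed Master integer seed.
#' @param ... Overrides for any default listed above, plus the synthetic
#'   scenario sizes (`sim_n_transcripts`, `sim_n_per_group`,
#'   `sim_de_fraction`, `sim_effect_log2fc`, `sim_dispersion`,
#'   `sim_n_mirnas`, `sim_n_preps`, `sim_n_sets`, `sim_n_patients`,
#'   `sim_hazard_ratio`, `sim_censor_rate`) and `out_dir` (directory for
#'   stage outputs; `NULL` keeps everything in memory).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = as.integer(seed),
    tpm_threshold = 10, min_low_samples = 2, filter_scope = "either_group",
    pseudocount = 1, p_cut = 0.01, lfc_cut = 0.5,
    gsea_n_perm = 1000, gsea_weight = 1, gsea_min_size = 5,
    gsea_max_size = 500,
    min_delta = 4, ct_cut = 27.5, ntc_ct_floor = 35,
    min_db = 2, alpha = 0.05, min_group = 8, scan_mode = "scan",
    out_dir = NULL,
    # synthetic scenario: two groups of 3, modest matrix, 24-target card,
    # 30 gene sets, mesenchymal-osteosarcoma-sized survival cohort
    sim_n_transcripts = 2000, sim_n_per_group = 3,
    sim_de_fraction = 0.05, sim_effect_log2fc = 2, sim_dispersion = 0.3,
    sim_n_mirnas = 24, sim_n_preps = 3, sim_expressed_fraction = 0.5,
    sim_spike_ct = 23.852, sim_medium_offset = 6, sim_noise_sd = 0.3,
    sim_n_sets = 30, sim_set_size = c(10, 50), sim_n_planted_sets = 3,
    sim_per_db_density = 0.02, sim_consensus_overlap = 0.1,
    sim_planted_per_mirna = 2,
    sim_n_patients = 127, sim_hazard_ratio = 3, sim_censor_rate = 0.2
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "mircargo_invalid_parameter")
  }
  structure(modifyList(defaults, overrides), class = "pipeline_config")
}

write_stage <- function(x, out_dir, file) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, file)
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    readr::write_tsv(as_tibble(x), path)
  }
  invisible(path)
}

#' Run the full integrative analysis on simulated data
#'
#' Chains every stage on inputs generated by the synthetic-data module:
#' TPM filtering, differential expression and DRG classification, gene
#' collapsing and pre-ranked GSEA, qPCR card calling (expressed and
#' highly expressed miRNAs) with delta-delta-Ct quantification, consensus
#' target integration against the downregulated genes,
#' over-representation of the targets, pathway convergence, and
#' scan-mode survival analysis. Every stochastic stage derives its seed
#' from `config$seed`, so a fixed seed yields byte-identical outputs
#' (the manifest records no clock time).
#'
#' @param config A [pipeline_config()].
#' @return A list with each stage result and a `manifest` (configuration
#'   echo, content hashes and row counts). When `config$out_dir` is set,
#'   stage tables and the manifest are also written there as TSV/JSON.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    rlang::abort("`config` must come from pipeline_config().",
                 class = "mircargo_invalid_parameter")
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seed <- config$seed

  # --- transcriptomics -------------------------------------------------
  sim <- sim_expression_matrix(
    config$sim_n_transcripts, config$sim_n_per_group,
    config$sim_de_fraction, config$sim_effect_log2fc, config$sim_dispersion,
    seed = derive_seed(seed, 1)
  )
  filtered <- filter_low_tpm(sim$tpm, sim$groups,
                             threshold = config$tpm_threshold,
                             min_low_samples = config$min_low_samples,
                             scope = config$filter_scope)
  deg <- differential_expression(filtered, sim$groups,
                                 pseudocount = config$pseudocount) |>
    classify_drgs(p_cut = config$p_cut, lfc_cut = config$lfc_cut)
  down_transcripts <- deg |> filter(.data$call == "down")
  down_genes <- sim$gene_map |>
    filter(.data$transcript_id %in% down_transcripts$transcript_id) |>
    dplyr::pull("gene_symbol") |>
    unique()
  ranked <- collapse_to_genes(deg, sim$gene_map)
  gene_universe <- sort(unique(sim$gene_map$gene_symbol))

  # --- enrichment ------------------------------------------------------
  genesets <- sim_genesets(gene_universe, config$sim_n_sets,
                           config$sim_set_size,
                           planted_list = if (length(down_genes) > 0) {
                             down_genes
                           } else {
                             gene_universe[1]
                           },
                           n_planted_sets = config$sim_n_planted_sets,
                           seed = derive_seed(seed, 2))
  gsea <- preranked_gsea(ranked, genesets, n_perm = config$gsea_n_perm,
                         weight = config$gsea_weight,
                         min_size = config$gsea_min_size,
                         max_size = config$gsea_max_size,
                         seed = derive_seed(seed, 3))

  # --- miRNA cards -----------------------------------------------------
  mirna_ids <- sprintf("miR-sim-%02d", seq_len(config$sim_n_mirnas))
  cards <- sim_ct_card(mirna_ids, config$sim_n_preps,
                       config$sim_expressed_fraction, config$sim_spike_ct,
                       config$sim_medium_offset, config$sim_noise_sd,
                       seed = derive_seed(seed, 4))
  calls <- call_expressed(cards$ev, cards$medium,
                          min_delta = config$min_delta,
                          ntc_ct_floor = config$ntc_ct_floor) |>
    call_highly_expressed(ct_cut = config$ct_cut)
  rq <- relative_quant(normalize_reference(cards$ev),
                       normalize_reference(cards$medium))
  expressed_mirnas <- calls$target_id[calls$expressed]

  # --- target integration ---------------------------------------------
  dbs <- sim_target_dbs(
    if (length(expressed_mirnas) > 0) expressed_mirnas else mirna_ids[1],
    gene_universe,
    per_db_density = config$sim_per_db_density,
    consensus_overlap = config$sim_consensus_overlap,
    n_dbs = 3, seed = derive_seed(seed, 5),
    planted_per_mirna = config$sim_planted_per_mirna,
    planted_pool = if (length(down_genes) > 0) down_genes else NULL
  )
  consensus <- consensus_targets(dbs$predictions, min_db = config$min_db,
                                 db_names = dbs$db_names)
  integration <- intersect_with_down(
    consensus,
    if (length(down_genes) > 0) down_genes else gene_universe
  )

  # --- convergence -----------------------------------------------------
  target_ora <- ora(integration$union, genesets, gene_universe)
  overlap <- overlap_pathways(
    rnaseq_results = gsea |> transmute(pathway = .data$set_name,
                                       p = .data$p_value),
    mirna_results = target_ora |> transmute(pathway = .data$set_name,
                                            p = .data$p_value),
    alpha = config$alpha
  )

  # --- survival --------------------------------------------------------
  cohort <- sim_survival(config$sim_n_patients, config$sim_hazard_ratio,
                         config$sim_censor_rate,
                         seed = derive_seed(seed, 6))
  scan <- scan_cutoff(cohort, min_group = config$min_group,
                      mode = config$scan_mode)

  results <- list(
    tpm = sim$tpm, groups = sim$groups, gene_map = sim$gene_map,
    truth = sim$truth, filtered = filtered, deg = deg, ranked = ranked,
    genesets = genesets, gsea = gsea, calls = calls, rq = rq,
    consensus = consensus, integration = integration,
    target_ora = target_ora, overlap = overlap,
    cohort = cohort, scan = scan
  )

  if (!is.null(out_dir)) {
    write_stage(sim$tpm, out_dir, "tpm.tsv")
    write_stage(sim$groups, out_dir, "groups.tsv")
    write_stage(sim$gene_map, out_dir, "gene_map.tsv")
    write_stage(deg, out_dir, "deg.tsv")
    write_stage(ranked, out_dir, "ranked_genes.tsv")
    write_stage(as_tibble(gsea), out_dir, "gsea.tsv")
    write_stage(calls, out_dir, "mirna_calls.tsv")
    write_stage(rq, out_dir, "mirna_rq.tsv")
    write_stage(consensus, out_dir, "consensus_targets.tsv")
    write_stage(tidy(overlap), out_dir, "pathway_overlap.tsv")
    write_stage(as.list(glance(overlap)), out_dir, "venn.json")
    write_stage(cohort, out_dir, "survival_cohort.tsv")
    write_stage(as.list(glance(scan)), out_dir, "survival_scan.json")
  }

  counts <- list(
    n_transcripts_input = nrow(sim$tpm),
    n_transcripts_retained = nrow(filtered),
    n_up = sum(deg$call == "up"), n_down = sum(deg$call == "down"),
    n_genes_ranked = nrow(ranked),
    n_gsea_sets = nrow(gsea),
    n_expressed_mirnas = sum(calls$expressed),
    n_highly_expressed = sum(calls$highly_expressed),
    n_consensus_pairs = nrow(consensus),
    union_size = length(integration$union),
    n_common_pathways = unname(overlap$venn["common"]),
    scan_cutoff = scan$cutoff,
    scan_p_adjusted = scan$p_adjusted
  )
  manifest <- list(
    config = unclass(config)[order(names(unclass(config)))],
    counts = counts,
    hashes = list(
      deg = rlang::hash(deg), ranked = rlang::hash(ranked),
      gsea = rlang::hash(as_tibble(gsea)), calls = rlang::hash(calls),
      consensus = rlang::hash(consensus),
      overlap = rlang::hash(tidy(overlap)),
      scan = rlang::hash(glance(scan))
    )
  )
  write_stage(manifest, out_dir, "manifest.json")
  results$manifest <- manifest
  results
}

#' Validate pipeline input files against their schemas
#'
#' Checks, without mutating anything, that each supplied file conforms to
#' its expected schema: column names and types, the `"Undetermined"`
#' non-detect token and the presence of exactly one spike-in target on Ct
#' cards, GMT structure, group labels, event coding, and (optionally)
#' that prediction tables mention only known databases.
#'
#' @param paths Named list of file paths; recognised names are `tpm`,
#'   `groups`, `gene_map`, `ct_card`, `predictions`, `gmt`, `survival`.
#' @param db_names Optional character vector of expected prediction
#'   databases.
#' @return A tibble of violations (`file`, `check`, `message`); zero rows
#'   means every file passed.
#' @export
validate_inputs <- function(paths, db_names = NULL) {
  violations <- list()
  note <- function(file, check, message) {
    violations[[length(violations) + 1]] <<-
      tibble(file = file, check = check, message = message)
  }
  try_read <- function(path, reader, file, kind) {
    if (!file.exists(path)) {
      note(file, "readable", sprintf("file not found: %s", path))
      return(NULL)
    }
    tryCatch(reader(path), error = function(e) {
      note(file, kind, conditionMessage(e))
      NULL
    })
  }
  unknown <- setdiff(names(paths),
                     c("tpm", "groups", "gene_map", "ct_card",
                       "predictions", "gmt", "survival"))
  for (u in unknown) note(u, "recognised", "unknown input kind.")

  if (!is.null(paths$tpm)) {
    x <- try_read(paths$tpm, read_tpm_matrix, "tpm", "schema")
    if (!is.null(x)) {
      numcols <- vapply(x[setdiff(names(x), "transcript_id")], is.numeric,
                        logical(1))
      if (!all(numcols)) {
        note("tpm", "numeric", "non-numeric sample column(s).")
      } else if (any(as.matrix(x[setdiff(names(x), "transcript_id")]) < 0)) {
        note("tpm", "non_negative", "negative TPM value(s).")
      }
      if (anyDuplicated(x$transcript_id)) {
        note("tpm", "unique_ids", "duplicate transcript IDs.")
      }
    }
  }
  if (!is.null(paths$groups)) {
    x <- try_read(paths$groups, read_sample_groups, "groups", "schema")
    if (!is.null(x) && !all(x$group %in% c("control", "treated"))) {
      note("groups", "labels", "group labels must be control/treated.")
    }
  }
  if (!is.null(paths$gene_map)) {
    try_read(paths$gene_map, read_gene_map, "gene_map", "schema")
  }
  if (!is.null(paths$ct_card)) {
    x <- try_read(paths$ct_card, read_ct_card, "ct_card", "schema")
    if (!is.null(x)) {
      n_spike <- length(unique(x$target_id[x$is_spike_in]))
      if (n_spike != 1) {
        note("ct_card", "spike_in",
             sprintf("expected exactly 1 spike-in target, found %d.", n_spike))
      }
      if (any(x$ct <= 0, na.rm = TRUE)) {
        note("ct_card", "ct_range", "Ct values must be positive.")
      }
    }
  }
  if (!is.null(paths$predictions)) {
    x <- try_read(paths$predictions, read_target_predictions,
                  "predictions", "schema")
    if (!is.null(x) && !is.null(db_names)) {
      bad <- setdiff(unique(x$db_name), db_names)
      if (length(bad) > 0) {
        note("predictions", "db_names",
             paste0("unknown database(s): ", paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$gmt)) {
    x <- try_read(paths$gmt, read_gmt, "gmt", "structure")
    if (!is.null(x) && any(lengths(x) == 0)) {
      note("gmt", "non_empty", "empty gene set(s).")
    }
  }
  if (!is.null(paths$survival)) {
    x <- try_read(paths$survival, read_survival_cohort, "survival", "schema")
    if (!is.null(x)) {
      if (!all(x$event %in% c(0, 1))) {
        note("survival", "event_coding", "event must be 0/1.")
      }
      if (any(x$time <= 0)) {
        note("survival", "time_positive", "times must be > 0.")
      }
    }
  }
  if (length(violations) == 0) {
    tibble(file = character(), check = character(), message = character())
  } else {
    dplyr::bind_rows(violations)
  }
}
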