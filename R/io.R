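#' Read and write pipeline file formats
#'
#' All stages exchange plain-text tabular files: a TPM matrix TSV
#' (`transcript_id` plus one numeric column per sample), a group sidecar TSV
#' (`sample_id`, `group` with values `control`/`treated`), a transcript-to-gene
#' mapping TSV (`transcript_id`, `gene_symbol`), qPCR card CSVs
#' (`target_id`, `prep_id`, `ct`, `is_ntc`, `is_spike_in`; non-detects spelled
#' `"Undetermined"`), miRNA target prediction TSVs
#' (`mirna_id`, `db_name`, `gene_symbol`), GMT gene-set files, and survival
#' cohort TSVs (`patient_id`, `expression`, `time`, `event`).
#'
#' @param path File path.
#' @param x Object to write (a tibble, or a named list of character vectors
#'   for [write_gmt()]).
#' @return Readers return a tibble ([read_gmt()] a named list of character
#'   vectors); writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_tpm_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(x, "transcript_id", "TPM matrix")
  x
}

#' @rdname pipeline_io
#' @export
write_tpm_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_sample_groups <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  assert_cols(x, c("sample_id", "group"), "sample groups")
  x
}

#' @rdname pipeline_io
#' @export
write_sample_groups <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  assert_cols(x, c("transcript_id", "gene_symbol"), "gene map")
  x
}

#' @rdname pipeline_io
#' @export
read_ct_card <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = character(),
                       col_types = readr::cols(.default = "c"))
  assert_cols(x, c("target_id", "prep_id", "ct", "is_ntc", "is_spike_in"),
              "Ct card")
  x |>
    mutate(
      ct = ifelse(.data$ct == ND_TOKEN, NA_real_, suppressWarnings(as.numeric(.data$ct))),
      is_ntc = as.logical(.data$is_ntc),
      is_spike_in = as.logical(.data$is_spike_in)
    )
}

#' @rdname pipeline_io
#' @export
write_ct_card <- function(x, path) {
  out <- x |>
    mutate(ct = ifelse(is.na(.data$ct), ND_TOKEN, format(.data$ct, digits = 15)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_target_predictions <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  assert_cols(x, c("mirna_id", "db_name", "gene_symbol"), "target predictions")
  x
}

#' @rdname pipeline_io
#' @export
write_target_predictions <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    rlang::abort(sprintf("GMT line(s) %s have fewer than 3 fields.",
                         paste(which(bad), collapse = ", ")),
                 class = "mircargo_invalid_input")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname pipeline_io
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "description") %||% rep("na", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[i], x[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_survival_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(x, c("patient_id", "expression", "time", "event"),
              "survival cohort")
  x
}

#' @rdname pipeline_io
#' @export
write_survival_cohort <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Worked-example datasets shipped with the package
#'
#' Small published summary tables from an osteoblast-EV / osteosarcoma
#' profiling study, used as worked examples and fixture inputs:
#' the top-20 down- and upregulated transcripts with fold changes and
#' p-values, the mean-Ct summary of miRNAs detected on EV qPCR cards
#' (with the ath-miR159a spike-in row), per-database miRNA target
#' predictions for three databases together with the published
#' two-of-three consensus column, and a table of Reactome pathways with
#' p-values from the miRNA-target and RNA-seq sides of the analysis.
#'
#' @param which Which dataset to load: `"deg_down"`, `"deg_up"`,
#'   `"ct_summary"`, `"target_predictions"`, `"target_consensus"`, or
#'   `"pathway_overlap"`.
#' @return A tibble.
#' @examples
#' head(worked_example("deg_down"))
#' @export
worked_example <- function(which = c("deg_down", "deg_up", "ct_summary",
                                     "target_predictions", "target_consensus",
                                     "pathway_overlap")) {
  which <- match.arg(which)
  file <- switch(which,
    deg_down = "osev_top_downregulated.tsv",
    deg_up = "osev_top_upregulated.tsv",
    ct_summary = "osev_ev_mirna_ct.csv",
    target_predictions = "osev_mirna_targets.tsv",
    target_consensus = "osev_mirna_targets_consensus.tsv",
    pathway_overlap = "osev_pathway_overlap.tsv"
  )
  path <- system.file("extdata", file, package = "mircargo", mustWork = TRUE)
  if (which == "ct_summary") {
    x <- readr::read_csv(path, show_col_types = FALSE, na = character(),
                         col_types = readr::cols(.default = "c"))
    x |>
      mutate(
        across(c("ct_mean_ev", "ct_se_ev", "ct_mean_medium", "ct_se_medium"),
               ~ ifelse(.x == ND_TOKEN, NA_real_, suppressWarnings(as.numeric(.x)))),
        is_spike_in = as.logical(.data$is_spike_in)
      )
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}
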