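#' Consensus miRNA targets across prediction databases
#'
#' A gene is a consensus target of a miRNA when it is predicted by at least
#' `min_db` of the queried databases. A database that returned no
#' prediction for a miRNA (absent rows) still counts among the queried
#' databases, so pass `db_names` explicitly when the table does not mention
#' every database for every miRNA. Gene symbols are compared
#' case-sensitively after whitespace trimming; combined identifiers such as
#' `"miR-30b-5p/miR-30c-5p"` are kept as single prediction rows.
#'
#' @param preds Long tibble (`mirna_id`, `db_name`, `gene_symbol`).
#' @param min_db Minimum number of supporting databases (default 2; must
#'   be >= 1 and at most the number of databases).
#' @param db_names Character vector of queried databases; defaults to the
#'   databases present in `preds`.
#' @return Tibble (`mirna_id`, `gene_symbol`, `n_dbs`), one row per
#'   consensus pair. Raising `min_db` never enlarges any consensus set.
#' @examples
#' consensus_targets(worked_example("target_predictions"),
#'                   db_names = c("TargetScan", "DIANA", "miRDB"))
#' @export
consensus_targets <- function(preds, min_db = 2, db_names = NULL) {
  assert_cols(preds, c("mirna_id", "db_name", "gene_symbol"), "preds")
  min_db <- assert_count(min_db, "min_db")
  db_names <- db_names %||% sort(unique(preds$db_name))
  if (min_db > length(db_names)) {
    rlang::abort("`min_db` exceeds the number of databases.",
                 class = "mircargo_invalid_parameter")
  }
  unknown <- setdiff(unique(preds$db_name), db_names)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown database(s) in predictions: ",
                        paste(unknown, collapse = ", ")),
                 class = "mircargo_invalid_input")
  }
  preds |>
    mutate(gene_symbol = trimws(.data$gene_symbol)) |>
    dplyr::distinct(.data$mirna_id, .data$db_name, .data$gene_symbol) |>
    summarise(n_dbs = dplyr::n_distinct(.data$db_name),
              .by = c("mirna_id", "gene_symbol")) |>
    filter(.data$n_dbs >= min_db) |>
    arrange(.data$mirna_id, .data$gene_symbol)
}

# Combined rows name several mature miRNAs separated by "/"; expanding them
# is what turns per-row consensus sets into per-mature counts.
expand_mature <- function(mirna_id) strsplit(mirna_id, "/", fixed = TRUE)

#' Intersect consensus targets with a downregulated gene list
#'
#' Restricts each miRNA's consensus set to the supplied downregulated
#' genes and summarises the integration: the union of targeted genes, the
#' fraction of the downregulated list it covers, and the per-gene miRNA
#' multiplicity (number of distinct mature miRNAs targeting the gene, with
#' combined prediction rows expanded into their mature members).
#'
#' @param consensus A [consensus_targets()] table.
#' @param down_genes Non-empty character vector of downregulated gene
#'   symbols.
#' @return An object of class `consensus_table` with elements `pairs`
#'   (tibble `mirna_id`, `gene_symbol`), `union` (character), `n_down`,
#'   `fraction_of_down` and `multiplicity` (tibble `gene_symbol`,
#'   `n_mirnas`). Use [tidy()] for the pairs and [glance()] for the
#'   one-row summary.
#' @export
intersect_with_down <- function(consensus, down_genes) {
  assert_cols(consensus, c("mirna_id", "gene_symbol"), "consensus")
  down_genes <- unique(trimws(down_genes))
  if (length(down_genes) == 0) {
    rlang::abort("`down_genes` must be non-empty.",
                 class = "mircargo_invalid_input")
  }
  pairs <- consensus |>
    filter(.data$gene_symbol %in% down_genes) |>
    dplyr::select("mirna_id", "gene_symbol")
  union_genes <- sort(unique(pairs$gene_symbol))
  mult <- pairs |>
    mutate(mature = expand_mature(.data$mirna_id)) |>
    tidyr::unnest("mature") |>
    summarise(n_mirnas = dplyr::n_distinct(.data$mature),
              .by = "gene_symbol") |>
    arrange(dplyr::desc(.data$n_mirnas), .data$gene_symbol)
  structure(
    list(pairs = pairs, union = union_genes, n_down = length(down_genes),
         fraction_of_down = length(union_genes) / length(down_genes),
         multiplicity = mult),
    class = "consensus_table"
  )
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf(
    "<consensus_table> %d miRNA-gene pairs; union %d genes (%.1f%% of %d downregulated)\n",
    nrow(x$pairs), length(x$union), 100 * x$fraction_of_down, x$n_down))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.consensus_table <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.consensus_table <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), union_size = length(x$union),
         n_down = x$n_down, fraction_of_down = x$fraction_of_down,
         max_multiplicity = if (nrow(x$multiplicity) > 0) {
           max(x$multiplicity$n_mirnas)
         } else {
           0L
         })
}

#' Per-gene miRNA multiplicity
#'
#' Counts, for each gene in a [intersect_with_down()] result, the distinct
#' mature miRNAs whose consensus set (restricted to the downregulated
#' list) contains it. Combined rows contribute one count per mature
#' member. Summing multiplicities over genes equals summing restricted
#' consensus-set sizes over mature miRNAs.
#'
#' @param table A `consensus_table` object.
#' @return Tibble (`gene_symbol`, `n_mirnas`), multiplicity descending.
#' @export
target_multiplicity <- function(table) {
  if (!inherits(table, "consensus_table")) {
    rlang::abort("`table` must be a consensus_table.",
                 class = "mircargo_invalid_input")
  }
  table$multiplicity
}
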