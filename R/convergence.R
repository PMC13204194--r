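# Pathway labels are matched exactly after case-folding and whitespace
# collapse; no fuzzy matching (a silent-error trap with long Reactome
# labels).
normalize_pathway <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Pathways significant on both the transcriptome and miRNA-target side
#'
#' Takes two pathway/p-value result lists — one from enrichment of the
#' observed transcriptome, one from over-representation of predicted
#' miRNA targets — and returns the pathways with `p < alpha` on both
#' sides, together with Venn counts of the two significant sets. The
#' common set is ordered by ascending transcriptome p-value.
#'
#' @param rnaseq_results,mirna_results Tibbles with `pathway` and `p`
#'   columns (any extra columns are ignored). Duplicate pathway names
#'   within one list (after normalisation) raise an error.
#' @param alpha Significance cutoff applied to both sides (default 0.05).
#'   Lowering `alpha` never enlarges the common set.
#' @return An object of class `pathway_overlap` with elements `common`
#'   (tibble `pathway`, `p_mirna`, `p_rnaseq`), `rnaseq_only`,
#'   `mirna_only` (character), `venn` (named counts) and `alpha`.
#' @examples
#' tab <- worked_example("pathway_overlap")
#' ov <- overlap_pathways(
#'   rnaseq_results = dplyr::transmute(tab, pathway, p = p_rnaseq),
#'   mirna_results = dplyr::transmute(tab, pathway, p = p_mirna)
#' )
#' glance(ov)
#' @export
overlap_pathways <- function(rnaseq_results, mirna_results, alpha = 0.05) {
  assert_cols(rnaseq_results, c("pathway", "p"), "rnaseq_results")
  assert_cols(mirna_results, c("pathway", "p"), "mirna_results")
  assert_fraction(alpha, "alpha")
  prep <- function(x, name) {
    x <- x |> mutate(key = normalize_pathway(.data$pathway))
    dup <- x$pathway[duplicated(x$key)]
    if (length(dup) > 0) {
      rlang::abort(paste0("duplicate pathway name(s) in ", name, ": ",
                          paste(unique(dup), collapse = "; ")),
                   class = "mircargo_invalid_input")
    }
    x
  }
  rna <- prep(rnaseq_results, "rnaseq_results")
  mir <- prep(mirna_results, "mirna_results")
  rna_sig <- rna |> filter(.data$p < alpha)
  mir_sig <- mir |> filter(.data$p < alpha)
  common <- inner_join(rna_sig, mir_sig, by = "key",
                       suffix = c("_rnaseq", "_mirna")) |>
    transmute(pathway = .data$pathway_rnaseq,
              p_mirna = .data$p_mirna,
              p_rnaseq = .data$p_rnaseq) |>
    arrange(.data$p_rnaseq, .data$pathway)
  unmatched <- setdiff(union(rna$key, mir$key), intersect(rna$key, mir$key))
  if (length(unmatched) > 0) {
    rlang::inform(sprintf(
      "overlap_pathways: %d pathway name(s) appear on one side only.",
      length(unmatched)))
  }
  structure(
    list(
      common = common,
      rnaseq_only = rna_sig$pathway[!rna_sig$key %in% mir_sig$key],
      mirna_only = mir_sig$pathway[!mir_sig$key %in% rna_sig$key],
      venn = c(rnaseq_only = sum(!rna_sig$key %in% mir_sig$key),
               mirna_only = sum(!mir_sig$key %in% rna_sig$key),
               common = nrow(common)),
      alpha = alpha
    ),
    class = "pathway_overlap"
  )
}

#' @export
print.pathway_overlap <- function(x, ...) {
  cat(sprintf(
    "<pathway_overlap> alpha = %g; %d transcriptome-only, %d miRNA-only, %d common\n",
    x$alpha, x$venn[["rnaseq_only"]], x$venn[["mirna_only"]],
    x$venn[["common"]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pathway_overlap <- function(x, ...) x$common

#' @exportS3Method generics::glance
glance.pathway_overlap <- function(x, ...) {
  tibble(alpha = x$alpha, n_rnaseq_only = unname(x$venn["rnaseq_only"]),
         n_mirna_only = unname(x$venn["mirna_only"]),
         n_common = unname(x$venn["common"]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pathway_overlap <- function(object, ...) {
  circles <- tibble(
    x = c(-0.6, 0.6), y = c(0, 0),
    label = c("transcriptome", "miRNA targets")
  )
  counts <- tibble(
    x = c(-1, 1, 0),
    y = c(0, 0, 0),
    n = unname(object$venn[c("rnaseq_only", "mirna_only", "common")])
  )
  angles <- seq(0, 2 * pi, length.out = 200)
  ring <- function(cx, lab) {
    tibble(x = cx + 1.1 * cos(angles), y = 1.1 * sin(angles), label = lab)
  }
  ggplot() +
    geom_path(data = dplyr::bind_rows(ring(-0.6, "a"), ring(0.6, "b")),
              aes(x = .data$x, y = .data$y, group = .data$label)) +
    geom_text(data = counts, aes(x = .data$x, y = .data$y, label = .data$n),
              size = 6) +
    geom_text(data = circles,
              aes(x = .data$x, y = c(1.3, 1.3), label = .data$label)) +
    coord_equal() +
    theme_void()
}
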