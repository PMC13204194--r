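# Weighted running-sum enrichment score evaluated only at hit positions.
# `absw` are |score|^weight values for the hits (list order), `hit_idx` the
# sorted positions of the hits in the ranked list of length n. The running
# sum increases by the normalised hit weight at a hit and decreases by
# 1/(n - k) at a miss; its extremes occur just after or just before a hit,
# so only those 2k points are evaluated. Ties in magnitude resolve to the
# positive extreme so the sign is deterministic.
es_from_hits <- function(absw, hit_idx, n) {
  k <- length(hit_idx)
  total <- sum(absw)
  inc <- if (total > 0) absw / total else rep(1 / k, k)
  miss <- 1 / (n - k)
  cum <- cumsum(inc)
  after <- cum - (hit_idx - seq_len(k)) * miss
  before <- after - inc
  es_pos <- max(after)
  es_neg <- min(before)
  if (abs(es_pos) >= abs(es_neg)) es_pos else es_neg
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Computes, for each gene set, the maximal deviation of the weighted
#' running sum over the ranked list (hit increments proportional to
#' `|score|^weight`, miss decrements uniform). The null distribution comes
#' from `n_perm` random gene-label permutations (equivalently, random hit
#' positions), the normalised enrichment score (NES) is the ES divided by
#' the mean absolute null ES of matching sign, and the p-value is the
#' add-one-smoothed fraction of matching-sign null scores at least as
#' extreme. Sets are filtered to `[min_size, max_size]` genes after
#' intersecting with the ranked list; sets with no usable overlap are
#' skipped with a message.
#'
#' @param ranked Tibble with `gene_symbol` and `score`, as produced by
#'   [collapse_to_genes()]; re-sorted by descending score (ties broken by
#'   gene symbol) if needed.
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Number of permutations (default 1000); the smallest
#'   attainable p-value is `1/(n_perm + 1)`.
#' @param weight Running-sum weight; 1 (default) weights hits by score
#'   magnitude, 0 gives the classic Kolmogorov-Smirnov statistic.
#' @param min_size,max_size Inclusive set-size bounds after intersection.
#' @param seed Integer seed for the permutation null.
#' @return A tibble of class `gsea_result`: `set_name`, `size`, `es`,
#'   `nes`, `p_value`, `p_adj` (Benjamini-Hochberg, for information),
#'   `direction` (`enriched` when `es > 0`, else `depleted`).
#' @examples
#' ranked <- tibble::tibble(gene_symbol = letters[1:10], score = 10:1 / 2)
#' sets <- list(top = letters[1:3], bottom = letters[8:10])
#' preranked_gsea(ranked, sets, n_perm = 200, min_size = 2, seed = 1)
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, weight = 1,
                           min_size = 5, max_size = 500, seed = 1) {
  assert_cols(ranked, c("gene_symbol", "score"), "ranked")
  if (nrow(ranked) == 0) {
    rlang::abort("`ranked` must be non-empty.",
                 class = "mircargo_invalid_input")
  }
  n_perm <- assert_count(n_perm, "n_perm")
  assert_scalar_num(weight, "weight")
  ranked <- ranked |>
    arrange(dplyr::desc(.data$score), .data$gene_symbol)
  genes <- ranked$gene_symbol
  absw_all <- abs(ranked$score)^weight
  n <- length(genes)

  withr::with_seed(seed, {
    rows <- lapply(names(sets), function(nm) {
      hit_idx <- sort(which(genes %in% sets[[nm]]))
      k <- length(hit_idx)
      if (k < min_size || k > max_size || k >= n) {
        rlang::inform(sprintf(
          "preranked_gsea: skipping '%s' (overlap %d outside [%d, %d]).",
          nm, k, min_size, max_size))
        return(NULL)
      }
      es <- es_from_hits(absw_all[hit_idx], hit_idx, n)
      null_es <- vapply(seq_len(n_perm), function(i) {
        idx <- sort(sample.int(n, k))
        es_from_hits(absw_all[idx], idx, n)
      }, numeric(1))
      same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
        es / mean(abs(same_sign))
      } else {
        NA_real_
      }
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      tibble(set_name = nm, size = k, es = es, nes = nes, p_value = p)
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(set_name = character(), size = integer(), es = numeric(),
                  nes = numeric(), p_value = numeric())
  }
  out <- out |>
    mutate(p_adj = p.adjust(.data$p_value, "BH"),
           direction = ifelse(.data$es > 0, "enriched", "depleted"))
  class(out) <- c("gsea_result", class(out))
  out
}

#' Select the top enriched and depleted terms
#'
#' Keeps results with `p_value < alpha`, sorts enriched terms by descending
#' NES and depleted terms by ascending NES, and truncates each list to `k`.
#'
#' @param results A [preranked_gsea()] result.
#' @param k Maximum number of terms per direction (default 10).
#' @param alpha Significance cutoff on the permutation p-value
#'   (default 0.05).
#' @return A list with `top_enriched` and `top_depleted` tibbles.
#' @export
select_top_terms <- function(results, k = 10, alpha = 0.05) {
  assert_cols(results, c("nes", "p_value", "direction"), "results")
  sig <- results |> filter(.data$p_value < alpha)
  list(
    top_enriched = sig |> filter(.data$direction == "enriched") |>
      arrange(dplyr::desc(.data$nes), .data$set_name) |> head(k),
    top_depleted = sig |> filter(.data$direction == "depleted") |>
      arrange(.data$nes, .data$set_name) |> head(k)
  )
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the p-value is the upper-tail hypergeometric probability
#' of observing at least the actual overlap when `|gene_list|` genes are
#' drawn without replacement from the universe containing
#' `|set `&#8745;` universe|` successes.
#'
#' @param gene_list Character vector of query genes; must be a subset of
#'   `universe`.
#' @param sets Named list of character vectors; each is intersected with
#'   the universe.
#' @param universe Character vector of background genes.
#' @return Tibble: `set_name`, `set_size` (within universe),
#'   `overlap_size`, `p_value`, `p_adj` (Benjamini-Hochberg).
#' @examples
#' ora(c("a", "b"), list(s = c("a", "b", "c")), letters[1:10])
#' @export
ora <- function(gene_list, sets, universe) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  bad <- setdiff(gene_list, universe)
  if (length(bad) > 0) {
    rlang::abort(paste0("gene_list not contained in universe: ",
                        paste(bad, collapse = ", ")),
                 class = "mircargo_invalid_input")
  }
  rows <- lapply(names(sets), function(nm) {
    m <- length(intersect(sets[[nm]], universe))
    q <- length(intersect(gene_list, intersect(sets[[nm]], universe)))
    p <- phyper(q - 1, m, length(universe) - m, length(gene_list),
                lower.tail = FALSE)
    tibble(set_name = nm, set_size = m, overlap_size = q, p_value = p)
  })
  dplyr::bind_rows(rows) |>
    mutate(p_adj = p.adjust(.data$p_value, "BH"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.gsea_result <- function(object, k = 10, alpha = 0.05, ...) {
  top <- select_top_terms(object, k = k, alpha = alpha)
  dat <- dplyr::bind_rows(top$top_enriched, top$top_depleted)
  if (nrow(dat) == 0) {
    return(ggplot() +
             annotate("text", x = 0, y = 0, label = "no significant terms") +
             theme_void())
  }
  ggplot(dat, aes(x = .data$nes,
                  y = stats::reorder(.data$set_name, .data$nes),
                  fill = .data$direction)) +
    geom_col() +
    scale_fill_manual(values = c(enriched = "#E69F00", depleted = "#56B4E9")) +
    labs(x = "normalised enrichment score", y = NULL, fill = NULL) +
    theme_minimal()
}
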