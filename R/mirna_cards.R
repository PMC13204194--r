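mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
se_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
}

# Non-NTC measurement wells of a card.
card_wells <- function(card) {
  assert_cols(card, c("target_id", "prep_id", "ct", "is_ntc", "is_spike_in"),
              "card")
  card |> filter(!.data$is_ntc)
}

#' Normalise a qPCR card to its reference target
#'
#' Subtracts the reference (spike-in or housekeeping) Ct from every target
#' Ct within the same preparation: `delta_ct = ct_target - ct_reference`.
#' Non-detect targets propagate as non-detect (`NA`). The reference must be
#' detected in every preparation.
#'
#' @param card Card tibble (`target_id`, `prep_id`, `ct`, `is_ntc`,
#'   `is_spike_in`); `NA` ct means non-detect.
#' @param reference Reference target id; by default the unique target
#'   flagged `is_spike_in`.
#' @return Tibble (`target_id`, `prep_id`, `delta_ct`), reference and NTC
#'   wells excluded. A common Ct shift applied to a whole preparation
#'   leaves all `delta_ct` unchanged.
#' @export
normalize_reference <- function(card, reference = NULL) {
  wells <- card_wells(card)
  if (is.null(reference)) {
    reference <- unique(wells$target_id[wells$is_spike_in])
    if (length(reference) != 1) {
      rlang::abort("card must carry exactly one spike-in/reference target.",
                   class = "mircargo_invalid_input")
    }
  }
  ref <- wells |> filter(.data$target_id == reference)
  preps <- unique(wells$prep_id)
  missing_ref <- setdiff(preps, ref$prep_id[!is.na(ref$ct)])
  if (length(missing_ref) > 0) {
    rlang::abort(paste0("reference not detected in preparation(s): ",
                        paste(missing_ref, collapse = ", ")),
                 class = "mircargo_invalid_input")
  }
  ref_ct <- setNames(ref$ct, ref$prep_id)
  wells |>
    filter(.data$target_id != reference) |>
    mutate(delta_ct = .data$ct - unname(ref_ct[.data$prep_id])) |>
    dplyr::select("target_id", "prep_id", "delta_ct")
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `delta_delta_ct` is the mean normalised Ct in the treated condition
#' minus the mean in the control condition, and the relative quantity is
#' `rq = 2^(-delta_delta_ct)` (so one cycle earlier in the treated
#' condition means a two-fold higher relative quantity).
#'
#' @param treated_dct,control_dct Outputs of [normalize_reference()] for
#'   the two conditions; targets are matched by `target_id` and non-detect
#'   preparations are dropped from the means.
#' @return Tibble (`target_id`, `delta_delta_ct`, `rq`).
#' @export
relative_quant <- function(treated_dct, control_dct) {
  assert_cols(treated_dct, c("target_id", "delta_ct"), "treated_dct")
  assert_cols(control_dct, c("target_id", "delta_ct"), "control_dct")
  mean_dct <- function(x) {
    x |> summarise(mean_dct = mean(.data$delta_ct, na.rm = TRUE),
                   .by = "target_id")
  }
  out <- inner_join(mean_dct(treated_dct), mean_dct(control_dct),
                    by = "target_id", suffix = c("_t", "_c")) |>
    mutate(delta_delta_ct = .data$mean_dct_t - .data$mean_dct_c,
           rq = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("target_id", "delta_delta_ct", "rq")
  if (nrow(out) == 0) {
    rlang::abort("no common targets between the two conditions.",
                 class = "mircargo_empty_result")
  }
  out
}

#' Call expressed miRNAs from EV and medium cards
#'
#' A target is called expressed when its no-template control is clean
#' (non-detect or Ct above `ntc_ct_floor`) and, in every EV preparation,
#' the target is detected and the medium signal is either a non-detect or
#' at least `min_delta` cycles above the EV Ct. The medium signal per
#' target is the mean Ct over its detected medium wells. Spike-in rows are
#' exempt from calling and excluded from the output.
#'
#' @param ev_card,medium_card Card tibbles with identical non-spike-in
#'   target panels.
#' @param min_delta Minimum medium-minus-EV Ct separation (default 4);
#'   a medium non-detect satisfies it by definition.
#' @param ntc_ct_floor NTC Ct above which amplification still counts as
#'   clean (default 35).
#' @return Tibble of class `mirna_calls`: `target_id`, `n_preps_ev`,
#'   `mean_ct_ev`, `se_ct_ev` (over >= 2 detected preparations, else `NA`),
#'   `max_ct_ev`, `mean_ct_medium` (`NA` when the medium never amplified),
#'   `ntc_clean`, `expressed`.
#' @export
call_expressed <- function(ev_card, medium_card, min_delta = 4,
                           ntc_ct_floor = 35) {
  assert_scalar_num(min_delta, "min_delta")
  assert_scalar_num(ntc_ct_floor, "ntc_ct_floor")
  panel <- function(card) {
    sort(unique(card$target_id[!card$is_spike_in & !card$is_ntc]))
  }
  pe <- panel(ev_card); pm <- panel(medium_card)
  if (!identical(pe, pm)) {
    rlang::abort(paste0(
      "EV and medium panels differ. Only in EV: ",
      paste(setdiff(pe, pm), collapse = ", "), "; only in medium: ",
      paste(setdiff(pm, pe), collapse = ", ")),
      class = "mircargo_invalid_input")
  }
  ev <- card_wells(ev_card) |> filter(!.data$is_spike_in)
  med <- card_wells(medium_card) |> filter(!.data$is_spike_in)
  ntc <- dplyr::bind_rows(ev_card, medium_card) |>
    filter(.data$is_ntc, !.data$is_spike_in)

  med_sum <- med |>
    summarise(mean_ct_medium = mean_or_na(.data$ct), .by = "target_id")
  ntc_sum <- ntc |>
    summarise(ntc_clean = all(is.na(.data$ct) | .data$ct > ntc_ct_floor),
              .by = "target_id")

  out <- ev |>
    summarise(
      n_preps_ev = sum(!is.na(.data$ct)),
      mean_ct_ev = mean_or_na(.data$ct),
      se_ct_ev = se_or_na(.data$ct),
      max_ct_ev = max_or_na(.data$ct),
      all_detected = !any(is.na(.data$ct)),
      .by = "target_id"
    ) |>
    left_join(med_sum, by = "target_id") |>
    left_join(ntc_sum, by = "target_id") |>
    mutate(
      ntc_clean = tidyr::replace_na(.data$ntc_clean, TRUE),
      expressed = .data$ntc_clean & .data$all_detected &
        (is.na(.data$mean_ct_medium) |
           .data$mean_ct_medium - .data$max_ct_ev >= min_delta)
    ) |>
    dplyr::select(-"all_detected") |>
    arrange(.data$target_id)
  class(out) <- c("mirna_calls", class(out))
  out
}

#' Flag highly expressed miRNAs
#'
#' A target is highly expressed when it is expressed and its EV Ct is
#' strictly below `ct_cut` in every preparation (`max_ct_ev < ct_cut`).
#' When only summary means are available (`max_ct_ev` absent or `NA`, as in
#' mean-Ct fixture tables), the rule falls back to `mean_ct_ev < ct_cut`.
#'
#' @param calls A [call_expressed()] table, or any tibble with
#'   `mean_ct_ev` and `expressed` columns (see [as_mirna_calls()]).
#' @param ct_cut Strict Ct cutoff (default 27.5); a mean of exactly 27.5
#'   is not highly expressed.
#' @return `calls` with a logical `highly_expressed` column;
#'   `highly_expressed` implies `expressed` for every input.
#' @export
call_highly_expressed <- function(calls, ct_cut = 27.5) {
  assert_cols(calls, c("mean_ct_ev", "expressed"), "calls")
  assert_scalar_num(ct_cut, "ct_cut")
  per_prep <- if ("max_ct_ev" %in% names(calls)) calls$max_ct_ev else NA_real_
  crit_ct <- ifelse(is.na(per_prep), calls$mean_ct_ev, per_prep)
  calls |>
    mutate(highly_expressed = .data$expressed & !is.na(crit_ct) &
             crit_ct < ct_cut)
}

#' Build a call table from a mean-Ct summary
#'
#' Converts a summary of already-called expressed targets (per-target mean
#' and standard-error Ct for EVs and medium, such as published card
#' summaries loaded with [worked_example()]) into the [call_expressed()]
#' table shape so that [call_highly_expressed()] can be applied in
#' mean-Ct mode. Spike-in rows are dropped; all remaining rows are marked
#' `expressed` (the summary lists detected targets by construction).
#'
#' @param summary Tibble with `target_id`, `ct_mean_ev`, `ct_se_ev`,
#'   `ct_mean_medium` and `is_spike_in`.
#' @return A `mirna_calls` tibble in mean-Ct mode (`max_ct_ev` is `NA`).
#' @export
as_mirna_calls <- function(summary) {
  assert_cols(summary, c("target_id", "ct_mean_ev", "is_spike_in"), "summary")
  out <- summary |>
    filter(!.data$is_spike_in) |>
    transmute(
      target_id = .data$target_id,
      mean_ct_ev = .data$ct_mean_ev,
      se_ct_ev = if ("ct_se_ev" %in% names(summary)) .data$ct_se_ev else NA_real_,
      max_ct_ev = NA_real_,
      mean_ct_medium = if ("ct_mean_medium" %in% names(summary)) {
        .data$ct_mean_medium
      } else {
        NA_real_
      },
      expressed = TRUE
    )
  class(out) <- c("mirna_calls", class(out))
  out
}
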