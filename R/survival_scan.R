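#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival samples, with the
#' chi-square statistic referred to one degree of freedom. Degenerate
#' inputs with no comparable event times (zero total variance) return
#' `chi_square = 0`, `p = 1` with a warning instead of failing, so that
#' cutoff scans over sparse splits stay total.
#'
#' @param group_a,group_b Tibbles with `time` (> 0) and `event`
#'   (1 = event, 0 = censored).
#' @return One-row tibble: `chi_square`, `p_value`, `n_a`, `n_b`,
#'   `n_events`. Symmetric in its two arguments.
#' @examples
#' a <- tibble::tibble(time = c(1, 2), event = c(1, 0))
#' b <- tibble::tibble(time = c(2, 2), event = c(0, 0))
#' logrank_test(a, b)
#' @export
logrank_test <- function(group_a, group_b) {
  assert_cols(group_a, c("time", "event"), "group_a")
  assert_cols(group_b, c("time", "event"), "group_b")
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    rlang::abort("both groups must be non-empty.",
                 class = "mircargo_invalid_input")
  }
  dat <- dplyr::bind_rows(
    group_a |> mutate(.grp = "a"),
    group_b |> mutate(.grp = "b")
  )
  if (sum(dat$event) == 0) {
    rlang::warn("no events in either group; returning p = 1.")
    return(tibble(chi_square = 0, p_value = 1, n_a = nrow(group_a),
                  n_b = nrow(group_b), n_events = 0L))
  }
  fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ .grp, data = dat),
    error = function(e) NULL
  )
  chi <- if (is.null(fit) || !is.finite(fit$chisq)) NA_real_ else fit$chisq
  if (is.na(chi)) {
    rlang::warn("log-rank variance is zero (no comparable event times); returning p = 1.")
    chi <- 0
  }
  tibble(chi_square = chi,
         p_value = pchisq(chi, df = 1, lower.tail = FALSE),
         n_a = nrow(group_a), n_b = nrow(group_b),
         n_events = as.integer(sum(dat$event)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for one sample.
#'
#' @param cohort Tibble with `time` and `event`.
#' @return Tibble (`time`, `n_risk`, `n_event`, `n_censor`, `survival`);
#'   survival starts at 1 and is non-increasing. Censored times shrink the
#'   risk set without dropping the curve.
#' @export
km_curve <- function(cohort) {
  assert_cols(cohort, c("time", "event"), "cohort")
  if (nrow(cohort) == 0) {
    rlang::abort("`cohort` must be non-empty.",
                 class = "mircargo_invalid_input")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = cohort)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Expression cutoff selection for Kaplan-Meier group splitting
#'
#' Splits a cohort into low/high expression groups either at the median
#' (`mode = "median"`; patients at exactly the cutoff go to the low
#' group) or by scan-mode search (`mode = "scan"`, the default): every
#' split between distinct expression values that leaves at least
#' `min_group` patients on each side is tested by log-rank, and the
#' cutoff with the minimal nominal p-value is selected. Because the
#' minimal p over many looks is anti-conservative, a Bonferroni-adjusted
#' p-value (`p_nominal` times the number of cutoffs tested, capped at 1)
#' is reported alongside. Ties in nominal p resolve to the smallest
#' cutoff.
#'
#' @param cohort Tibble with `expression`, `time`, `event`.
#' @param min_group Minimum group size for scan mode (default 8); scan
#'   mode requires `nrow(cohort) >= 2 * min_group`.
#' @param mode `"scan"` (default) or `"median"`.
#' @return An object of class `km_scan`: `mode`, `cutoff`, `n_low`,
#'   `n_high`, `chi_square`, `p_nominal`, `p_adjusted` (`NA` in median
#'   mode), `n_cutoffs_tested`, `scan_table` (per-cutoff log-rank
#'   results; one row in median mode) and `data` (the cohort with its
#'   `group` assignment). Methods: [tidy()] (per-cutoff table),
#'   [glance()] (one-row summary), [autoplot()] (KM curves at the chosen
#'   cutoff).
#' @examples
#' cohort <- sim_survival(60, hazard_ratio = 3, censor_rate = 0.2, seed = 1)
#' scan_cutoff(cohort, min_group = 8)
#' @export
scan_cutoff <- function(cohort, min_group = 8, mode = c("scan", "median")) {
  mode <- rlang::arg_match(mode)
  assert_cols(cohort, c("expression", "time", "event"), "cohort")
  min_group <- assert_count(min_group, "min_group")
  if (any(!is.finite(cohort$expression)) || any(cohort$time <= 0)) {
    rlang::abort("expression must be finite and times > 0.",
                 class = "mircargo_invalid_input")
  }
  n <- nrow(cohort)
  split_at <- function(cutoff) {
    low <- cohort |> filter(.data$expression <= cutoff)
    high <- cohort |> filter(.data$expression > cutoff)
    lr <- suppressWarnings(logrank_test(low, high))
    lr |> mutate(cutoff = cutoff, n_low = nrow(low), n_high = nrow(high))
  }

  if (mode == "median") {
    cutoff <- median(cohort$expression)
    row <- split_at(cutoff)
    scan_table <- row
    n_tested <- 1L
    p_adj <- NA_real_
  } else {
    if (n < 2 * min_group) {
      rlang::abort(sprintf(
        "scan mode needs at least 2 * min_group = %d patients (got %d).",
        2 * min_group, n), class = "mircargo_invalid_input")
    }
    values <- sort(unique(cohort$expression))
    n_low_at <- vapply(values, function(v) sum(cohort$expression <= v),
                       integer(1))
    admissible <- values[n_low_at >= min_group & (n - n_low_at) >= min_group]
    if (length(admissible) == 0) {
      rlang::abort("no admissible split satisfies the group-size constraint.",
                   class = "mircargo_invalid_input")
    }
    scan_table <- dplyr::bind_rows(lapply(admissible, split_at))
    n_tested <- length(admissible)
    best <- scan_table |>
      arrange(.data$p_value, .data$cutoff) |>
      dplyr::slice(1)
    row <- best
    cutoff <- best$cutoff
    p_adj <- min(1, best$p_value * n_tested)
  }

  structure(
    list(
      mode = mode,
      cutoff = cutoff,
      n_low = row$n_low, n_high = row$n_high,
      chi_square = row$chi_square,
      p_nominal = row$p_value,
      p_adjusted = p_adj,
      n_cutoffs_tested = n_tested,
      scan_table = scan_table |>
        dplyr::select("cutoff", "n_low", "n_high", "chi_square", "p_value"),
      data = cohort |>
        mutate(group = ifelse(.data$expression <= cutoff, "low", "high"))
    ),
    class = "km_scan"
  )
}

#' @export
print.km_scan <- function(x, ...) {
  cat(sprintf(
    "<km_scan> mode = %s; cutoff = %.4g (low %d / high %d); chi^2 = %.3f; p = %.3g%s\n",
    x$mode, x$cutoff, x$n_low, x$n_high, x$chi_square, x$p_nominal,
    if (!is.na(x$p_adjusted)) {
      sprintf(" (adjusted %.3g over %d cutoffs)", x$p_adjusted,
              x$n_cutoffs_tested)
    } else {
      ""
    }))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_scan <- function(x, ...) x$scan_table

#' @exportS3Method generics::glance
glance.km_scan <- function(x, ...) {
  tibble(mode = x$mode, cutoff = x$cutoff, n_low = x$n_low,
         n_high = x$n_high, chi_square = x$chi_square,
         p_nominal = x$p_nominal, p_adjusted = x$p_adjusted,
         n_cutoffs_tested = x$n_cutoffs_tested)
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_scan <- function(object, ...) {
  curves <- object$data |>
    tidyr::nest(.by = "group") |>
    mutate(curve = purrr::map(.data$data, km_curve)) |>
    dplyr::select("group", "curve") |>
    tidyr::unnest("curve")
  start <- curves |>
    dplyr::distinct(.data$group) |>
    mutate(time = 0, survival = 1)
  ggplot(dplyr::bind_rows(start, curves),
         aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time", y = "survival probability", colour = "expression") +
    theme_minimal()
}
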