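# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each quantity by the most direct method
# available (full loops, enumeration, closed forms) and share no code with
# the implementations they check.

# Running-sum enrichment score by direct walk over the whole ranked list.
oracle_es <- function(scores, in_set, weight) {
  n <- length(scores)
  k <- sum(in_set)
  w <- abs(scores)^weight
  total <- sum(w[in_set])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      cur <- cur + (if (total > 0) w[i] / total else 1 / k)
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  pos <- max(c(running, 0))
  neg <- min(c(running, 0))
  if (abs(pos) >= abs(neg)) pos else neg
}

# Both extremes of the same walk, to detect exact positive/negative ties
# (where tie-breaking conventions legitimately differ between tools).
oracle_es_extremes <- function(scores, in_set, weight) {
  n <- length(scores)
  k <- sum(in_set)
  w <- abs(scores)^weight
  total <- sum(w[in_set])
  cur <- 0
  running <- numeric(n)
  for (i in seq_len(n)) {
    cur <- cur + if (in_set[i]) {
      if (total > 0) w[i] / total else 1 / k
    } else {
      -1 / (n - k)
    }
    running[i] <- cur
  }
  c(pos = max(c(running, 0)), neg = min(c(running, 0)))
}

# Upper-tail hypergeometric p by exhaustive enumeration of all draws.
oracle_hyper_enum <- function(n_universe, set_size, list_size, observed) {
  draws <- utils::combn(n_universe, list_size)
  hits <- colSums(draws <= set_size)  # treat 1..set_size as the set
  mean(hits >= observed)
}

# Two-of-n-database consensus by nested loops.
oracle_consensus <- function(preds, min_db) {
  out <- list()
  for (m in unique(preds$mirna_id)) {
    sub <- preds[preds$mirna_id == m, ]
    genes <- unique(sub$gene_symbol)
    keep <- character(0)
    for (g in genes) {
      n_db <- length(unique(sub$db_name[sub$gene_symbol == g]))
      if (n_db >= min_db) keep <- c(keep, g)
    }
    out[[m]] <- sort(keep)
  }
  out
}

# Log-rank statistic from the 2x2 hypergeometric tables at each event time.
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t & event_a == 1)
    d2 <- sum(time_b == t & event_b == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# A small deterministic replicate-level card pair for delta-delta-Ct tests:
# `true_log2fc` is the planted treated/control abundance ratio in log2
# units (one cycle of Ct = one log2 unit, lower Ct = more template).
make_rq_cards <- function(targets, true_log2fc, noise_sd, seed,
                          n_preps = 3, ref_ct = 24) {
  withr::with_seed(seed, {
    base_dct <- stats::runif(length(targets), 1, 4)
    mk <- function(dct_by_target) {
      grid <- expand.grid(target_id = targets,
                          prep_id = sprintf("prep_%d", seq_len(n_preps)),
                          stringsAsFactors = FALSE)
      grid$ct <- ref_ct + dct_by_target[grid$target_id] +
        stats::rnorm(nrow(grid), 0, noise_sd)
      grid$is_ntc <- FALSE
      grid$is_spike_in <- FALSE
      spike <- data.frame(target_id = "ref", prep_id = sprintf("prep_%d", seq_len(n_preps)),
                          ct = ref_ct, is_ntc = FALSE, is_spike_in = TRUE)
      tibble::as_tibble(rbind(grid, spike))
    }
    names(base_dct) <- targets
    treated_dct <- base_dct - true_log2fc
    list(control = mk(base_dct), treated = mk(treated_dct))
  })
}
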