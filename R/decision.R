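# Sliding-window decision support. Per-epoch alerts (p_pat > t_pat) are
# aggregated over a 100-min window of 5 delivery-anchored epoch slots: a
# window with fewer than 3 scored epochs is skipped, a window recommends
# intervention iff every scored epoch in it alerts, and only windows whose
# delivery-proximal edge lies at least 40 min before delivery count --
# later decisions are too late to act on.

#' Decision-support configuration
#'
#' @param window_min Sliding window length in minutes (must be a multiple
#'   of `epoch_min`).
#' @param epoch_min Epoch length, minutes.
#' @param max_missing_epochs Windows missing more than this many epochs are
#'   skipped (default 2, i.e. at least 3 of the 5 slots must be scored).
#' @param cutoff_min_before_delivery Recommendations are only actionable at
#'   or before this many minutes before delivery.
#' @param t_pat Alert threshold on the epoch posterior; usually set by
#'   [calibrate_threshold()].
#' @return An object of class `ctg_ds_config`.
#' @export
ds_config <- function(window_min = 100, epoch_min = 20, max_missing_epochs = 2,
                      cutoff_min_before_delivery = 40, t_pat = NULL) {
  if (window_min %% epoch_min != 0) stop_config("`window_min` must be divisible by `epoch_min`")
  slots <- window_min / epoch_min
  if (max_missing_epochs < 0 || max_missing_epochs >= slots) {
    stop_config("`max_missing_epochs` must lie in [0, slots)")
  }
  if (cutoff_min_before_delivery < 0) stop_config("cutoff must be >= 0")
  structure(
    list(
      window_min = window_min,
      epoch_min = epoch_min,
      slots = as.integer(slots),
      min_valid_slots = as.integer(slots - max_missing_epochs),
      cutoff_min_before_delivery = cutoff_min_before_delivery,
      t_pat = t_pat
    ),
    class = "ctg_ds_config"
  )
}

# One row per (birth, window) for every window with enough scored epochs:
# k is the delivery-proximal epoch slot, min_p the smallest posterior in
# the window. Windows recommend iff min_p > t_pat. Vectorized: windows are
# keyed by (birth, k) and aggregated with tabulate/order, which keeps the
# calibration scan cheap.
window_table <- function(predictions, cfg, max_epoch = 35L) {
  preds <- predictions[!is.na(predictions$p_pat), , drop = FALSE]
  if (nrow(preds) == 0L) {
    return(tibble(id = character(), k = integer(), n_scored = integer(), min_p = numeric()))
  }
  slots <- cfg$slots
  k_max <- max_epoch - (slots - 1L)
  ids <- unique(preds$id)
  ii <- match(preds$id, ids)
  # epoch e belongs to windows k = e-slots+1 .. e (k >= 0, k <= k_max)
  off <- rep(0:(slots - 1L), each = nrow(preds))
  k <- rep(preds$epoch_index, slots) - off
  keep <- k >= 0L & k <= k_max
  k <- as.integer(k[keep])
  ii <- rep(ii, slots)[keep]
  p <- rep(preds$p_pat, slots)[keep]
  key <- (ii - 1L) * (k_max + 1L) + k + 1L
  n_scored <- tabulate(key, nbins = length(ids) * (k_max + 1L))
  o <- order(key, p)
  first <- !duplicated(key[o])
  key_u <- key[o][first]
  wt <- tibble(
    id = ids[(key_u - 1L) %/% (k_max + 1L) + 1L],
    k = (key_u - 1L) %% (k_max + 1L),
    n_scored = n_scored[key_u],
    min_p = p[o][first]
  )
  wt[wt$n_scored >= cfg$min_valid_slots, , drop = FALSE]
}

#' Evaluate the sliding-window recommendation rule per birth
#'
#' Applies the window rule to delivery-anchored epoch posteriors and
#' returns one row per birth. The decision time of a window is its
#' delivery-proximal edge; the reported `first_time_min` is the earliest
#' (largest) such time among recommending windows at or before the cutoff.
#' Births absent from `predictions` (e.g. every epoch excluded by the
#' validity rule) are reported as not recommended with zero windows.
#'
#' @param predictions Tibble `id`, `epoch_index`, `p_pat` (`NA` posteriors
#'   count as missing epochs).
#' @param t_pat Alert threshold; epochs alert when `p_pat > t_pat`
#'   (strict).
#' @param cfg A [ds_config()].
#' @param ids Optional character vector of births that must appear in the
#'   output even without predictions.
#' @return Tibble `id`, `recommended`, `first_time_min`,
#'   `windows_evaluated`.
#' @export
evaluate_births <- function(predictions, t_pat, cfg = ds_config(), ids = NULL) {
  ids <- ids %||% unique(predictions$id)
  cut_k <- ceiling(cfg$cutoff_min_before_delivery / cfg$epoch_min)
  wt <- window_table(predictions, cfg)
  wt <- wt[wt$k >= cut_k, , drop = FALSE]
  agg <- summarise(
    group_by(wt, .data$id),
    windows_evaluated = n(),
    rec = any(.data$min_p > t_pat),
    first_k = if (any(.data$min_p > t_pat)) max(.data$k[.data$min_p > t_pat]) else NA_integer_,
    .groups = "drop"
  )
  out <- tibble(id = ids)
  m <- match(out$id, agg$id)
  out$recommended <- !is.na(m) & !is.na(agg$rec[m]) & agg$rec[m]
  out$first_time_min <- ifelse(out$recommended, agg$first_k[m] * cfg$epoch_min, NA_real_)
  out$windows_evaluated <- ifelse(is.na(m), 0L, agg$windows_evaluated[m])
  stopifnot(all(is.na(out$first_time_min) |
    out$first_time_min >= cfg$cutoff_min_before_delivery))
  out
}

# Per-birth window score: the largest window minimum among decision-
# eligible windows. A birth is recommended at threshold t iff its score
# exceeds t, which makes threshold calibration a one-pass scan.
window_scores <- function(predictions, cfg, ids) {
  cut_k <- ceiling(cfg$cutoff_min_before_delivery / cfg$epoch_min)
  wt <- window_table(predictions, cfg)
  wt <- wt[wt$k >= cut_k, , drop = FALSE]
  s <- rep(-Inf, length(ids))
  if (nrow(wt) == 0L) {
    return(s)
  }
  ii <- match(wt$id, ids)
  o <- order(ii, -wt$min_p)
  first <- !duplicated(ii[o])
  s[ii[o][first]] <- wt$min_p[o][first]
  s
}

#' Calibrate the alert threshold to the healthy-group Caesarean rate
#'
#' Scans the distinct out-of-bag posterior values as candidate thresholds
#' and returns the smallest one whose false-positive recommendation rate
#' over the healthy training births does not exceed the target -- the
#' Caesarean delivery rate of the same training subpopulation the
#' classifier was fitted on. Exact matching is generally impossible on a
#' finite grid, so the achieved rate is the largest one not above the
#' target.
#'
#' @param oob_predictions Out-of-bag predictions ([oob_posterior()]) for
#'   the training births.
#' @param healthy_ids Ids of the healthy training births (the
#'   false-positive denominator; births without a single valid window stay
#'   unrecommended at any threshold).
#' @param target_fp_rate The Caesarean delivery rate to match (a
#'   probability).
#' @param cfg A [ds_config()].
#' @return An object of class `ctg_calibration`: `t_pat`,
#'   `achieved_fp_rate`, `target_fp_rate`, `n_healthy`, `n_candidates`.
#' @export
calibrate_threshold <- function(oob_predictions, healthy_ids, target_fp_rate,
                                cfg = ds_config()) {
  if (target_fp_rate < 0 || target_fp_rate > 1) stop_input("`target_fp_rate` must be in [0, 1]")
  healthy_ids <- unique(healthy_ids)
  hp <- oob_predictions[oob_predictions$id %in% healthy_ids, , drop = FALSE]
  s <- window_scores(hp, cfg, healthy_ids)
  if (!any(is.finite(s))) {
    stop_input("no healthy training birth has a valid decision window; cannot calibrate")
  }
  cand <- sort(unique(c(oob_predictions$p_pat[!is.na(oob_predictions$p_pat)], 1)))
  s_sorted <- sort(s[is.finite(s)])
  n <- length(s)
  # fp(t) = #(score > t) / n, non-increasing in t
  fp <- (length(s_sorted) - findInterval(cand, s_sorted)) / n
  ok <- which(fp <= target_fp_rate)
  if (length(ok) == 0L) {
    # only possible through numerical pathology; the largest candidate
    # always yields fp = 0 <= target
    ok <- length(cand)
  }
  i <- ok[1]
  structure(
    list(
      t_pat = cand[i],
      achieved_fp_rate = fp[i],
      target_fp_rate = target_fp_rate,
      n_healthy = n,
      n_candidates = length(cand)
    ),
    class = "ctg_calibration"
  )
}

#' @export
print.ctg_calibration <- function(x, ...) {
  cat(
    sprintf(
      "<ctg_calibration> t_pat = %.4f (false-positive rate %.3f vs target %.3f over %d healthy births)\n",
      x$t_pat, x$achieved_fp_rate, x$target_fp_rate, x$n_healthy
    )
  )
  invisible(x)
}

#' Recommendation rates per outcome group
#'
#' @param recommendations Output of [evaluate_births()] (a `system` column
#'   is carried through if present).
#' @param births The cohort's `births` tibble.
#' @param by_parity Also stratify by parity?
#' @return Tibble of `group` (and optionally `parity`, `system`), `n`,
#'   `n_recommended`, `rate`. Groups absent from the births are simply not
#'   listed; empty groups cannot yield a rate.
#' @export
recommendation_rates <- function(recommendations, births, by_parity = FALSE) {
  joined <- left_join(
    recommendations,
    select(births, "id", "group", "parity"),
    by = "id"
  )
  if (anyNA(joined$group)) stop_input("recommendations refer to births absent from `births`")
  keys <- c(intersect("system", names(joined)), "group", if (by_parity) "parity")
  out <- summarise(
    group_by(joined, across(all_of(keys))),
    n = n(),
    n_recommended = sum(.data$recommended),
    rate = mean(.data$recommended),
    .groups = "drop"
  )
  arrange(out, across(all_of(keys)))
}

#' Recommendation rate as a function of time before delivery
#'
#' For each time `t` on a 20-min grid, the fraction of the group whose
#' first recommendation was issued at least `t` minutes before delivery --
#' a non-increasing step function whose value at the 40-min cutoff equals
#' the overall recommendation rate.
#'
#' @inheritParams recommendation_rates
#' @param max_time_min,step_min Grid of times before delivery, minutes.
#' @return Tibble `group` (and `system` if present), `time_min`, `rate`.
#' @export
time_course <- function(recommendations, births, max_time_min = 720, step_min = 20) {
  joined <- left_join(
    recommendations,
    select(births, "id", "group"),
    by = "id"
  )
  keys <- c(intersect("system", names(joined)), "group")
  grid <- seq(0, max_time_min, by = step_min)
  out <- reframe(
    group_by(joined, across(all_of(keys))),
    time_min = grid,
    rate = vapply(
      grid,
      function(t) mean(.data$recommended & !is.na(.data$first_time_min) & .data$first_time_min >= t),
      numeric(1)
    )
  )
  class(out) <- c("ctg_timecourse", class(out))
  out
}
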