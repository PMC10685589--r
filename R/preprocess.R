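# Sampled-signal conditioning -------------------------------------------------

#' Construct a sampled signal
#'
#' A thin constructor for regularly sampled biosignal segments: a value per
#' sample, a validity flag per sample, and the sampling rate. Used by the
#' conditioning rules that operate on samples rather than labeled events.
#'
#' @param values Numeric vector of samples.
#' @param valid Logical vector, same length; `FALSE` marks lost samples.
#' @param rate_hz Sampling rate, 1 (uterine pressure) or 4 (fetal heart
#'   rate).
#' @return Tibble with columns `value`, `valid` and attribute `rate_hz`.
#' @export
sampled_signal <- function(values, valid = rep(TRUE, length(values)), rate_hz = 4) {
  if (length(values) != length(valid)) stop_input("`values` and `valid` must have equal length")
  if (!rate_hz %in% c(1, 4)) stop_input("`rate_hz` must be 1 or 4")
  out <- tibble(value = as.numeric(values), valid = as.logical(valid))
  attr(out, "rate_hz") <- rate_hz
  out
}

signal_rate <- function(signal) {
  attr(signal, "rate_hz") %||% stop_input("signal lacks a `rate_hz` attribute; build it with sampled_signal()")
}

#' Linearly interpolate short gaps in a 4 Hz signal
#'
#' Every maximal invalid run strictly shorter than `max_gap_s` that is
#' flanked by valid samples on both sides is filled by linear interpolation
#' between the flanking samples and marked valid. Runs of `max_gap_s` or
#' longer, and leading or trailing gaps (which have no flank), are left
#' untouched. The operation is idempotent.
#'
#' @param signal A [sampled_signal()] at 4 Hz.
#' @param max_gap_s Gaps shorter than this many seconds are interpolated
#'   (default 15 s).
#' @return The conditioned signal.
#' @export
interpolate_short_gaps <- function(signal, max_gap_s = 15) {
  rate <- signal_rate(signal)
  if (rate != 4) stop_input("gap interpolation is defined for the 4 Hz channel")
  v <- signal$valid
  if (!any(v)) {
    return(signal)
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max_len <- max_gap_s * rate
  value <- signal$value
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    if (r$lengths[k] >= max_len) next
    if (starts[k] == 1L || ends[k] == length(v)) next # no flank
    lo <- starts[k] - 1L
    hi <- ends[k] + 1L
    idx <- starts[k]:ends[k]
    value[idx] <- value[lo] + (value[hi] - value[lo]) * (idx - lo) / (hi - lo)
    v[idx] <- TRUE
  }
  out <- tibble(value = value, valid = v)
  attr(out, "rate_hz") <- rate
  out
}

#' Up-sample the 1 Hz uterine pressure channel to 4 Hz
#'
#' Inserts three samples between consecutive 1 Hz samples by linear
#' interpolation; original instants are reproduced exactly and the trailing
#' partial second holds the last value. A derived sample is valid only when
#' every original sample it interpolates between is valid, so an invalid
#' 1 Hz sample maps to 4 invalid samples.
#'
#' @param signal A [sampled_signal()] at 1 Hz.
#' @return A [sampled_signal()] at 4 Hz with 4x the input length.
#' @export
upsample_uterine <- function(signal) {
  rate <- signal_rate(signal)
  if (rate != 1) stop_input("`upsample_uterine()` expects the 1 Hz channel")
  n <- nrow(signal)
  if (n == 0L) {
    return(sampled_signal(numeric(), logical(), rate_hz = 4))
  }
  t_new <- (seq_len(4L * n) - 1L) / 4
  lo <- pmin(floor(t_new), n - 1L)
  hi <- pmin(ceiling(t_new), n - 1L)
  w <- t_new - lo
  value <- signal$value[lo + 1L] * (1 - w) + signal$value[hi + 1L] * w
  valid <- signal$valid[lo + 1L] & signal$valid[hi + 1L]
  sampled_signal(value, valid, rate_hz = 4)
}

# Joint interval engine -------------------------------------------------------
# Plain-vector cores; the exported surface wraps them in tibbles.

# Cut the two channels' run-length streams into the finest common partition
# of [ws, we]; fhr/up are lists with state/start/end vectors.
joint_core <- function(fhr, up, ws, we, extra_breaks = numeric()) {
  if (length(fhr$start) == 0L || length(up$start) == 0L ||
    fhr$start[1] > ws + 1e-9 || up$start[1] > ws + 1e-9 ||
    fhr$end[length(fhr$end)] < we - 1e-9 || up$end[length(up$end)] < we - 1e-9) {
    stop_input("event runs do not cover the requested window")
  }
  bp <- sort(unique(c(ws, we, extra_breaks, fhr$start, up$start)))
  bp <- bp[bp >= ws & bp <= we]
  lo <- bp[-length(bp)]
  list(
    start = lo,
    end = bp[-1],
    fhr = fhr$state[findInterval(lo, fhr$start)],
    up = up$state[findInterval(lo, up$start)]
  )
}

# Excise invalid stretches and run-length encode the joint state. Runs are
# grouped into contiguous segments: an excision (or any temporal gap, or an
# epoch boundary) starts a new segment, so no state transition is ever
# fabricated across lost signal.
encode_core <- function(iv, epoch_index = NULL) {
  ok <- iv$fhr != "invalid" & iv$up != "invalid"
  n <- sum(ok)
  if (n == 0L) {
    out <- list(
      fhr = character(), up = character(), start = numeric(),
      dwell = numeric(), segment = integer()
    )
    if (!is.null(epoch_index)) out$epoch_index <- integer()
    return(out)
  }
  start <- iv$start[ok]
  end <- iv$end[ok]
  fhr <- iv$fhr[ok]
  up <- iv$up[ok]
  if (!is.null(epoch_index)) epoch_index <- epoch_index[ok]
  gap <- c(
    TRUE,
    abs(start[-1] - end[-n]) > 1e-9 |
      (if (is.null(epoch_index)) FALSE else epoch_index[-1] != epoch_index[-n])
  )
  seg <- cumsum(gap)
  state <- paste(fhr, up, sep = "|")
  new_run <- gap | c(TRUE, state[-1] != state[-n])
  run_id <- cumsum(new_run)
  first <- which(new_run)
  out <- list(
    fhr = fhr[first],
    up = up[first],
    start = start[first],
    dwell = as.numeric(rowsum(end - start, run_id)),
    segment = seg[first]
  )
  if (!is.null(epoch_index)) out$epoch_index <- epoch_index[first]
  out
}

runs_to_core <- function(runs) {
  list(
    state = runs$state,
    start = runs$start_s,
    end = runs$start_s + runs$dwell_s
  )
}

# Epoch segmentation ----------------------------------------------------------

#' Segment a cohort's event streams into valid 20-minute epochs
#'
#' Tiles each labor backward from delivery into 20-minute epochs (epoch 0
#' ends at delivery), keeps at most 36 epochs (a 12 h horizon), and retains
#' only epochs with at least `min_valid` valid signal on *both* channels.
#' Time not covered by the labor, and time labeled invalid, both count
#' against validity. Within retained epochs the two channels are merged
#' into run-length encoded joint states; invalid stretches are excised and
#' never fabricate transitions (see [joint_runs()]).
#'
#' @param cohort A `ctg_cohort` (or any list with `births` and `events`
#'   tibbles in the cohort schema).
#' @param horizon_h Monitoring horizon before delivery, hours.
#' @param epoch_min Epoch length, minutes.
#' @param min_valid Minimum valid fraction per channel; the boundary is
#'   inclusive (an epoch with exactly 80% valid samples is kept).
#' @return An object of class `ctg_epochs`: list with
#'   * `epochs`: tibble `id`, `epoch_index` (0 = ends at delivery),
#'     `valid_fraction` (the smaller of the two channels), `n_runs`;
#'   * `runs`: tibble of joint runs for retained epochs (`id`,
#'     `epoch_index`, `segment`, `fhr_state`, `up_state`, `start_s`,
#'     `dwell_s`), chronological within epoch;
#'   * the segmentation parameters.
#' @export
segment_epochs <- function(cohort, horizon_h = 12, epoch_min = 20, min_valid = 0.8) {
  births <- cohort$births
  events <- cohort$events
  epoch_s <- epoch_min * 60
  max_epochs <- as.integer(horizon_h * 3600 / epoch_s)
  n <- nrow(births)
  ev_by_id <- split(events, factor(events$id, levels = births$id))
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    acc[[i]] <- segment_one(
      births$duration_min[i] * 60, ev_by_id[[i]],
      epoch_s, max_epochs, min_valid
    )
  }
  ep_lens <- vapply(acc, function(a) length(a$k), integer(1))
  run_lens <- vapply(acc, function(a) length(a$runs$start), integer(1))
  epochs <- tibble(
    id = rep(births$id, ep_lens),
    epoch_index = unlist(map(acc, "k"), use.names = FALSE) %||% integer(),
    valid_fraction = unlist(map(acc, "frac"), use.names = FALSE) %||% numeric()
  )
  runs <- tibble(
    id = rep(births$id, run_lens),
    epoch_index = unlist(map(acc, function(a) a$runs$epoch_index), use.names = FALSE) %||% integer(),
    segment = unlist(map(acc, function(a) a$runs$segment), use.names = FALSE) %||% integer(),
    fhr_state = unlist(map(acc, function(a) a$runs$fhr), use.names = FALSE) %||% character(),
    up_state = unlist(map(acc, function(a) a$runs$up), use.names = FALSE) %||% character(),
    start_s = unlist(map(acc, function(a) a$runs$start), use.names = FALSE) %||% numeric(),
    dwell_s = unlist(map(acc, function(a) a$runs$dwell), use.names = FALSE) %||% numeric()
  )
  nr <- count(runs, .data$id, .data$epoch_index)
  epochs <- left_join(epochs, rename(nr, n_runs = "n"), by = c("id", "epoch_index"))
  stopifnot(nrow(epochs) == 0 || max(epochs$epoch_index) <= max_epochs - 1L)
  structure(
    list(
      epochs = epochs, runs = runs,
      epoch_min = epoch_min, horizon_h = horizon_h, min_valid = min_valid
    ),
    class = "ctg_epochs"
  )
}

segment_one <- function(dur_s, ev, epoch_s, max_epochs, min_valid) {
  empty <- list(
    k = integer(), frac = numeric(),
    runs = list(
      epoch_index = integer(), segment = integer(), fhr = character(),
      up = character(), start = numeric(), dwell = numeric()
    )
  )
  if (dur_s < epoch_s || is.null(ev) || nrow(ev) == 0L) {
    return(empty)
  }
  is_fhr <- ev$channel == "fhr"
  fhr <- runs_to_core(ev[is_fhr, , drop = FALSE])
  up <- runs_to_core(ev[!is_fhr, , drop = FALSE])
  n_cand <- min(max_epochs, ceiling(dur_s / epoch_s))
  bounds <- dur_s - epoch_s * seq_len(n_cand)
  win_start <- max(0, dur_s - epoch_s * n_cand)
  iv <- joint_core(fhr, up, win_start, dur_s, extra_breaks = bounds[bounds > 0])
  k <- as.integer(floor((dur_s - (iv$start + iv$end) / 2) / epoch_s))
  len <- iv$end - iv$start

  kf <- factor(k)
  vf <- rowsum(len * (iv$fhr != "invalid"), kf)
  vu <- rowsum(len * (iv$up != "invalid"), kf)
  kk <- as.integer(levels(kf))
  frac <- pmin(vf[, 1], vu[, 1]) / epoch_s
  keep <- frac >= min_valid - 1e-12
  if (!any(keep)) {
    return(empty)
  }
  keep_k <- kk[keep]
  sel <- k %in% keep_k
  runs <- encode_core(
    list(start = iv$start[sel], end = iv$end[sel], fhr = iv$fhr[sel], up = iv$up[sel]),
    epoch_index = k[sel]
  )
  list(k = keep_k, frac = unname(frac[keep]), runs = runs)
}

#' @export
print.ctg_epochs <- function(x, ...) {
  cat(
    "<ctg_epochs> ", nrow(x$epochs), " valid ", x$epoch_min, "-min epochs from ",
    length(unique(x$epochs$id)), " births\n",
    sep = ""
  )
  invisible(x)
}
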