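# Featurization: transition counts and dwell times over the joint
# FHR x UP state set.

#' Merge two channels' runs into joint-state runs over a window
#'
#' The joint sequence changes state whenever either channel changes;
#' runs straddling the window are clipped to it. Invalid stretches (either
#' channel) are excised: the surviving runs are grouped into contiguous
#' `segment`s and transitions are only ever counted within a segment, so
#' artifact boundaries cannot fabricate transitions.
#'
#' @param fhr_runs,up_runs Tibbles with `state`, `start_s`, `dwell_s`
#'   covering the window on the FHR and UP channel respectively.
#' @param window Numeric length-2, `c(start_s, end_s)` of the window.
#' @return Tibble of joint runs: `fhr_state`, `up_state`, `start_s`,
#'   `dwell_s`, `segment`. Dwells sum to the window length minus excised
#'   time.
#' @export
joint_runs <- function(fhr_runs, up_runs, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_input("`window` must be c(start_s, end_s) with end > start")
  }
  iv <- joint_core(runs_to_core(fhr_runs), runs_to_core(up_runs), window[1], window[2])
  r <- encode_core(iv)
  tibble(
    fhr_state = r$fhr, up_state = r$up,
    start_s = r$start, dwell_s = r$dwell, segment = r$segment
  )
}

#' Count transitions between joint states
#'
#' Entry (i, j) is the number of adjacent run pairs i -> j within a
#' contiguous segment; the diagonal is structurally zero and the matrix
#' total equals the number of runs minus the number of segments.
#'
#' @param runs A joint run tibble as returned by [joint_runs()] (a
#'   `segment` column is honored; if absent all runs are one segment).
#' @return 12 x 12 integer matrix over [joint_states()], dimnames
#'   `from`/`to` in short-code order.
#' @export
transition_counts <- function(runs) {
  js <- joint_states()
  m <- matrix(0L, 12L, 12L, dimnames = list(from = js$code, to = js$code))
  n <- nrow(runs)
  if (n < 2L) {
    return(m)
  }
  seg <- runs$segment %||% rep(1L, n)
  code <- joint_index(runs$fhr_state, runs$up_state)
  same <- seg[-1] == seg[-n]
  from <- code[-n][same]
  to <- code[-1][same]
  if (length(from)) {
    flat <- (from - 1L) * 12L + to
    cnt <- tabulate(flat, nbins = 144L)
    m[] <- matrix(cnt, 12L, 12L, byrow = TRUE)
  }
  m
}

#' Dwell-time statistics per joint state
#'
#' The dwell time of an event is the time spent in one joint state before
#' transitioning into another. Each run is one visit; states never visited
#' get zeros.
#'
#' @inheritParams transition_counts
#' @return Tibble with one row per joint state: `code`, `n_visits`,
#'   `total_s`, `mean_s`.
#' @export
dwell_stats <- function(runs) {
  js <- joint_states()
  out <- tibble(
    code = js$code,
    n_visits = 0L, total_s = 0, mean_s = 0
  )
  if (nrow(runs) == 0L) {
    return(out)
  }
  code <- joint_index(runs$fhr_state, runs$up_state)
  out$n_visits <- tabulate(code, nbins = 12L)
  tot <- numeric(12)
  agg <- rowsum(runs$dwell_s, code)
  tot[as.integer(rownames(agg))] <- agg[, 1]
  out$total_s <- tot
  out$mean_s <- ifelse(out$n_visits > 0, out$total_s / out$n_visits, 0)
  out
}

feature_names <- function() {
  js <- joint_states()$code
  c(
    as.vector(t(outer(js, js, function(a, b) paste0("t_", a, "__", b)))),
    paste0("dtot_", js),
    paste0("dmean_", js),
    paste0("occ_", js)
  )
}

#' Feature vector of a single epoch
#'
#' Flattens the transition-count matrix (row-major over the fixed
#' [joint_states()] order, prefix `t_<from>__<to>`), appends per-state
#' total and mean dwell (`dtot_*`, `dmean_*`, seconds) and per-state
#' occupancy fractions (`occ_*`, total dwell over observed time), and
#' optionally the nulliparity indicator. This fixed column order is the
#' feature schema consumed by the epoch classifiers.
#'
#' @inheritParams transition_counts
#' @param include_parity Append a `nulliparity` feature?
#' @param nulliparity 0/1 value used when `include_parity = TRUE`.
#' @return A named numeric vector (length 180, plus 1 with parity).
#' @export
featurize <- function(runs, include_parity = FALSE, nulliparity = NA_real_) {
  tc <- transition_counts(runs)
  ds <- dwell_stats(runs)
  tot <- sum(ds$total_s)
  occ <- if (tot > 0) ds$total_s / tot else rep(0, 12)
  v <- c(as.vector(t(tc)), ds$total_s, ds$mean_s, occ)
  names(v) <- feature_names()
  if (include_parity) {
    v <- c(v, nulliparity = as.numeric(nulliparity))
  }
  v
}

#' Featurize every retained epoch of a cohort
#'
#' Vectorized equivalent of calling [featurize()] on each epoch of
#' [segment_epochs()] output, carrying the birth labels through. The
#' `nulliparity` column (0/1) is always present; classifiers choose whether
#' to use it.
#'
#' @param epochs A `ctg_epochs` object.
#' @param births The cohort's `births` tibble.
#' @return Tibble with one row per epoch: `id`, `epoch_index`, `group`,
#'   `parity`, `caesarean`, `nulliparity`, `valid_fraction`, then the
#'   feature columns in schema order (attribute `feature_cols`).
#' @export
extract_features <- function(epochs, births) {
  runs <- epochs$runs
  ep <- epochs$epochs
  key_levels <- paste(ep$id, ep$epoch_index)
  n_ep <- length(key_levels)
  fnames <- feature_names()
  if (n_ep == 0L) {
    out <- bind_cols(
      tibble(
        id = character(), epoch_index = integer(), group = character(),
        parity = character(), caesarean = logical(), nulliparity = numeric(),
        valid_fraction = numeric()
      ),
      as_tibble(matrix(numeric(), 0, length(fnames), dimnames = list(NULL, fnames)))
    )
    attr(out, "feature_cols") <- c(fnames, "nulliparity")
    return(out)
  }
  erow <- match(paste(runs$id, runs$epoch_index), key_levels)
  code <- joint_index(runs$fhr_state, runs$up_state)
  n <- nrow(runs)

  # transitions: adjacent runs within (epoch, segment)
  same <- erow[-1] == erow[-n] & runs$segment[-1] == runs$segment[-n]
  flat <- (erow[-n][same] - 1) * 144 + (code[-n][same] - 1) * 12 + code[-1][same]
  tmat <- matrix(tabulate(flat, nbins = n_ep * 144), n_ep, 144, byrow = TRUE)

  # dwell totals / visit counts per (epoch, state)
  flat_d <- (erow - 1) * 12 + code
  visits <- matrix(tabulate(flat_d, nbins = n_ep * 12), n_ep, 12, byrow = TRUE)
  tot <- matrix(0, n_ep, 12)
  agg <- rowsum(runs$dwell_s, flat_d)
  tot[matrix(c(
    (as.integer(rownames(agg)) - 1) %/% 12 + 1,
    (as.integer(rownames(agg)) - 1) %% 12 + 1
  ), ncol = 2)] <- agg[, 1]
  dmean <- ifelse(visits > 0, tot / visits, 0)
  occ <- tot / pmax(rowSums(tot), .Machine$double.eps)

  fm <- cbind(tmat, tot, dmean, occ)
  colnames(fm) <- fnames
  bi <- match(ep$id, births$id)
  out <- bind_cols(
    tibble(
      id = ep$id,
      epoch_index = ep$epoch_index,
      group = births$group[bi],
      parity = births$parity[bi],
      caesarean = births$caesarean[bi],
      nulliparity = as.numeric(births$parity[bi] == "nulliparous"),
      valid_fraction = ep$valid_fraction
    ),
    as_tibble(fm)
  )
  attr(out, "feature_cols") <- c(fnames, "nulliparity")
  out
}
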