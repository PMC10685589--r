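# Run-length helpers ---------------------------------------------------------
# Internal simulators work on plain (state, dwell) vectors; tibbles are
# assembled once per cohort.

# Collapse consecutive runs with the same state; drop zero-length runs.
merge_runs <- function(state, dwell) {
  keep <- dwell > 0
  state <- state[keep]
  dwell <- dwell[keep]
  if (length(state) == 0L) {
    return(list(state = character(), dwell = numeric()))
  }
  new <- c(TRUE, state[-1] != state[-length(state)])
  id <- cumsum(new)
  list(
    state = state[new],
    dwell = as.numeric(rowsum(dwell, id))
  )
}

run_starts <- function(dwell) cumsum(dwell) - dwell

runs_tibble <- function(runs) {
  tibble(
    state = runs$state,
    start_s = run_starts(runs$dwell),
    dwell_s = runs$dwell
  )
}

# Quantize dwell draws onto the channel's sampling grid, keeping them
# strictly positive.
quantize <- function(x, grid) pmax(grid, round(x / grid) * grid)

# Merge possibly overlapping [start, end] intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(list(start = numeric(), end = numeric()))
  }
  o <- order(start)
  start <- start[o]
  end <- cummax(end[o]) # within an overlapping chain the last end is the max
  new <- c(TRUE, start[-1] > end[-length(end)])
  last <- c(which(new)[-1] - 1L, length(end))
  list(start = start[new], end = end[last])
}

# Channel simulators ----------------------------------------------------------

# Uterine pressure: alternating rest / contraction renewal process on a 1 s
# grid, starting at rest. `freq_mult` raises the contraction frequency by
# shortening rest spells (part of the injected parity stress distortion).
sim_up <- function(dyn, dur_s, freq_mult = 1) {
  mu <- dyn$up_dwell_s
  mu[["rest"]] <- mu[["rest"]] / freq_mult
  states <- character()
  dwells <- numeric()
  total <- 0
  s <- "rest"
  while (total < dur_s) {
    n_blk <- max(8L, ceiling((dur_s - total) / sum(mu) * 2) * 2L)
    blk_states <- rep(
      if (s == "rest") c("rest", "contraction") else c("contraction", "rest"),
      length.out = n_blk
    )
    blk_dwells <- quantize(rexp(n_blk, 1 / mu[blk_states]), 1)
    states <- c(states, blk_states)
    dwells <- c(dwells, blk_dwells)
    total <- total + sum(blk_dwells)
    s <- if (blk_states[n_blk] == "rest") "contraction" else "rest"
  }
  cum <- cumsum(dwells)
  last <- which(cum >= dur_s)[1]
  states <- states[seq_len(last)]
  dwells <- dwells[seq_len(last)]
  dwells[last] <- dwells[last] - (cum[last] - dur_s)
  merge_runs(states, dwells)
}

# Fetal heart rate: semi-Markov chain on baseline / acceleration /
# deceleration (0.25 s grid). While a contraction is active or within 60 s
# after it ends, leaving the baseline is forced into a deceleration with
# probability `coupling` before consulting the transition matrix.
# `decel_mult` scales the deceleration-entry weight and coupling; it
# carries both the per-birth frailty and any nulliparous dynamics effect.
sim_fhr <- function(dyn, decel_mult, dur_s, up, coupling_lag_s = 60,
                    dwell_mult = 1) {
  fhr3 <- fhr_states[1:3]
  mu <- unname(dyn$fhr_dwell_s[fhr3])
  mu[3] <- mu[3] * dwell_mult
  trans <- dyn$fhr_trans
  coupling <- dyn$coupling
  if (decel_mult != 1) {
    trans["baseline", "deceleration"] <- trans["baseline", "deceleration"] * decel_mult
    trans["baseline", ] <- trans["baseline", ] / sum(trans["baseline", ])
    coupling <- min(1, coupling * decel_mult)
  }
  cum_trans <- t(apply(trans, 1, cumsum))
  c1 <- cum_trans[, 1]
  c2 <- cum_trans[, 2]
  is_con <- up$state == "contraction"
  con_start <- run_starts(up$dwell)[is_con]
  con_end <- con_start + up$dwell[is_con]
  win <- merge_intervals(con_start, con_end + coupling_lag_s)
  n_win <- length(win$start)

  # pre-drawn randomness, extended on demand; RNG use stays deterministic
  cap <- as.integer(ceiling(dur_s / min(mu))) + 16L
  ee <- rexp(cap)
  u_couple <- runif(cap)
  u_branch <- runif(cap)
  st <- integer(cap) # 1=baseline, 2=acceleration, 3=deceleration
  dw <- numeric(cap)
  s <- 1L
  total <- 0
  i <- 0L
  j <- 0L # last contraction window starting at or before `total`
  while (total < dur_s) {
    i <- i + 1L
    if (i > cap) {
      ee <- c(ee, rexp(cap))
      u_couple <- c(u_couple, runif(cap))
      u_branch <- c(u_branch, runif(cap))
      cap <- cap * 2L
      length(st) <- cap
      length(dw) <- cap
    }
    d <- ee[i] * mu[s]
    d <- max(0.25, round(d * 4) / 4)
    st[i] <- s
    dw[i] <- d
    total <- total + d
    while (j < n_win && win$start[j + 1L] <= total) j <- j + 1L
    forced <- s == 1L && u_couple[i] < coupling && j > 0L && total <= win$end[j]
    s <- if (forced) {
      3L
    } else {
      u <- u_branch[i]
      1L + (u > c1[s]) + (u > c2[s])
    }
  }
  st <- st[seq_len(i)]
  dw <- dw[seq_len(i)]
  dw[i] <- dw[i] - (sum(dw) - dur_s)
  merge_runs(fhr3[st], dw)
}

# Dropouts: a Poisson number of i.i.d. exponential-length invalid
# insertions, quantized to the channel grid.
draw_dropouts <- function(dur_s, rate, mean_len_s, grid) {
  if (rate <= 0) {
    return(list(start = numeric(), end = numeric()))
  }
  n <- rpois(1L, dur_s * rate / mean_len_s)
  if (n == 0L) {
    return(list(start = numeric(), end = numeric()))
  }
  start <- floor(runif(n, 0, dur_s) / grid) * grid
  len <- quantize(rexp(n, 1 / mean_len_s), grid)
  end <- pmin(start + len, dur_s)
  merge_intervals(start, end)
}

# Overwrite the stretches covered by `iv` with the invalid state.
overlay_invalid <- function(runs, iv) {
  if (length(iv$start) == 0L) {
    return(runs)
  }
  dur <- sum(runs$dwell)
  starts <- run_starts(runs$dwell)
  bp <- sort(unique(c(0, dur, starts, iv$start, iv$end)))
  bp <- bp[bp >= 0 & bp <= dur]
  lo <- bp[-length(bp)]
  hi <- bp[-1]
  st <- runs$state[findInterval(lo, starts)]
  hit <- findInterval(lo, iv$start)
  bad <- hit > 0L & lo < iv$end[pmax(hit, 1L)]
  st[bad] <- "invalid"
  merge_runs(st, hi - lo)
}

simulate_labor_core <- function(group, parity, dur_s, config) {
  dyn <- config$dynamics[[group]]
  eff_par <- config$effect_parity %||% "nulliparous"
  effect <- if (parity == eff_par) config$parity_dynamics_effect else 0
  sdl <- config$individual_sd %||% 0
  frailty <- if (sdl > 0) rlnorm(1L, -sdl^2 / 2, sdl) else 1
  # the injected interaction distorts the whole contraction-deceleration
  # axis: entry hazard and coupling by (1 + effect), deceleration length
  # and contraction frequency by the milder (1 + effect)^(1/4)
  soft <- (1 + effect)^0.25
  up <- sim_up(dyn, dur_s, freq_mult = soft)
  fhr <- sim_fhr(dyn, frailty * (1 + effect), dur_s, up, dwell_mult = soft)
  fhr <- overlay_invalid(fhr, draw_dropouts(dur_s, config$dropout_rate, config$dropout_mean_len_s, 0.25))
  up <- overlay_invalid(up, draw_dropouts(dur_s, config$dropout_rate, config$dropout_mean_len_s, 1))
  list(fhr = fhr, up = up)
}

# Public generator ops --------------------------------------------------------

#' Simulate one labor's CTG event streams
#'
#' Draws the fetal heart rate and uterine pressure event streams of a single
#' labor from the configured semi-Markov dynamics, inserts signal dropouts,
#' and returns both channels as run-length encoded streams covering exactly
#' the requested duration. Uses the caller's RNG stream: seed beforehand
#' for reproducibility. With `parity_dynamics_effect = 0` the conditional
#' law of the streams given duration is identical across parity, so two
#' calls from the same RNG state that differ only in parity return
#' identical streams.
#'
#' @param group One of `"healthy"`, `"acidosis"`, `"hie"`.
#' @param parity `"nulliparous"` or `"multiparous"`.
#' @param duration_min Labor duration in minutes.
#' @param config A [cohort_config()].
#' @return List with elements `fhr` and `up`, each a tibble with columns
#'   `state`, `start_s`, `dwell_s` (FHR on a 0.25 s grid at its nominal
#'   4 Hz, UP on a 1 s grid at 1 Hz).
#' @export
simulate_labor <- function(group, parity, duration_min, config) {
  group <- match.arg(group, group_levels)
  parity <- match.arg(parity, parity_levels)
  if (duration_min <= 0) stop_input("`duration_min` must be positive")
  s <- simulate_labor_core(group, parity, round(duration_min * 60), config)
  list(fhr = runs_tibble(s$fhr), up = runs_tibble(s$up))
}

#' Assign a Caesarean delivery label
#'
#' Bernoulli draw with the configured group-by-parity Caesarean delivery
#' rate. The healthy-group rate is what the decision-support threshold is
#' later calibrated against.
#'
#' @inheritParams simulate_labor
#' @return Logical scalar.
#' @export
assign_caesarean <- function(group, parity, config) {
  group <- match.arg(group, group_levels)
  parity <- match.arg(parity, parity_levels)
  rbinom(1L, 1L, config$caesarean_rate_by_group_parity[group, parity]) == 1L
}

#' Generate a synthetic delivery cohort
#'
#' Samples `n_births` deliveries: outcome group and parity from the
#' configured prevalences, log-normal labor durations (longer for
#' nulliparous mothers by the configured multiplier, truncated to
#' 30 min - 12 h of monitored signal), per-birth CTG event streams from the
#' group dynamics, and Caesarean delivery labels. The whole draw is a pure
#' function of the configuration: the same `config` (including its seed)
#' reproduces the cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @param simulate_streams If `FALSE`, skip event-stream simulation and
#'   return demographics only (fast path for prevalence studies).
#' @return An object of class `ctg_cohort`: a list with
#'   * `births`: tibble `id`, `group`, `parity`, `caesarean`,
#'     `duration_min`;
#'   * `events`: tibble `id`, `channel` (`"fhr"`/`"up"`), `state`,
#'     `start_s`, `dwell_s` (empty when `simulate_streams = FALSE`);
#'   * `config`: the configuration used.
#' @export
sample_cohort <- function(config, simulate_streams = TRUE) {
  if (!inherits(config, "ctg_cohort_config")) {
    stop_config("`config` must be built with cohort_config()")
  }
  n <- config$n_births
  with_rng_seed(config$seed, {
    group <- sample(group_levels, n, replace = TRUE, prob = config$group_probs)
    parity <- ifelse(
      runif(n) < config$nulliparity_prob_by_group[group],
      "nulliparous", "multiparous"
    )
    mean_min <- config$duration_mean_multiparous_min *
      ifelse(parity == "nulliparous", config$nulliparous_duration_multiplier, 1)
    sdlog <- config$duration_sdlog
    dur_min <- rlnorm(n, meanlog = log(mean_min) - sdlog^2 / 2, sdlog = sdlog)
    dur_min <- pmin(pmax(dur_min, 30), 720)
    dur_s <- round(dur_min * 60)

    births <- tibble(
      id = sprintf("b%05d", seq_len(n)),
      group = group,
      parity = parity,
      caesarean = rbinom(n, 1L, config$caesarean_rate_by_group_parity[cbind(group, parity)]) == 1L,
      duration_min = dur_s / 60
    )

    events <- if (simulate_streams) {
      fhr_runs <- vector("list", n)
      up_runs <- vector("list", n)
      for (i in seq_len(n)) {
        s <- simulate_labor_core(group[i], parity[i], dur_s[i], config)
        fhr_runs[[i]] <- s$fhr
        up_runs[[i]] <- s$up
      }
      stack <- function(runs_list, channel) {
        lens <- vapply(runs_list, function(r) length(r$state), integer(1))
        tibble(
          id = rep(births$id, lens),
          channel = channel,
          state = unlist(map(runs_list, "state"), use.names = FALSE),
          start_s = unlist(map(runs_list, function(r) run_starts(r$dwell)), use.names = FALSE),
          dwell_s = unlist(map(runs_list, "dwell"), use.names = FALSE)
        )
      }
      arrange(
        bind_rows(stack(fhr_runs, "fhr"), stack(up_runs, "up")),
        .data$id, .data$channel, .data$start_s
      )
    } else {
      tibble(
        id = character(), channel = character(), state = character(),
        start_s = numeric(), dwell_s = numeric()
      )
    }

    structure(
      list(births = births, events = events, config = config),
      class = "ctg_cohort"
    )
  })
}

#' @export
print.ctg_cohort <- function(x, ...) {
  n <- nrow(x$births)
  cat("<ctg_cohort> ", n, " births\n", sep = "")
  tab <- table(x$births$group, x$births$parity)
  print(tab)
  if (nrow(x$events) > 0) {
    cat("event runs:", nrow(x$events), "\n")
  } else {
    cat("(demographics only, no event streams)\n")
  }
  invisible(x)
}
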