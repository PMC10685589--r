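# Independent oracles used to check the run-length implementations.

# Sample-level 4 Hz walk: features of one window computed by labeling every
# 0.25 s sample from the raw channel runs and scanning the label sequence,
# with no use of the package's joint-run machinery.
sample_walk_features <- function(fhr_runs, up_runs, window) {
  dt <- 0.25
  t_mid <- seq(window[1] + dt / 2, window[2] - dt / 2, by = dt)
  state_at <- function(runs, t) {
    i <- findInterval(t, runs$start_s)
    end <- runs$start_s[nrow(runs)] + runs$dwell_s[nrow(runs)]
    # samples before the labor starts or after it ends are lost signal
    out <- rep("invalid", length(t))
    inside <- i > 0 & t < end
    out[inside] <- runs$state[i[inside]]
    out
  }
  f <- state_at(fhr_runs, t_mid)
  u <- state_at(up_runs, t_mid)
  valid <- f != "invalid" & u != "invalid"
  joint <- paste(f, u, sep = "|")

  js <- joint_states()
  code_of <- function(fs, us) {
    match(fs, c("baseline", "acceleration", "deceleration", "invalid")) * 3L -
      3L + match(us, c("contraction", "rest", "invalid"))
  }
  trans <- matrix(0L, 12, 12, dimnames = list(from = js$code, to = js$code))
  n_visit <- integer(12)
  total_s <- numeric(12)

  n <- length(t_mid)
  prev_ok <- FALSE
  prev_code <- NA_integer_
  run_len <- 0L
  flush <- function(code, len) {
    if (!is.na(code) && len > 0L) {
      n_visit[code] <<- n_visit[code] + 1L
      total_s[code] <<- total_s[code] + len * dt
    }
  }
  for (i in seq_len(n)) {
    if (!valid[i]) {
      flush(prev_code, run_len)
      prev_ok <- FALSE
      prev_code <- NA_integer_
      run_len <- 0L
      next
    }
    code <- code_of(f[i], u[i])
    if (prev_ok && code != prev_code) {
      trans[prev_code, code] <- trans[prev_code, code] + 1L
      flush(prev_code, run_len)
      run_len <- 0L
    }
    run_len <- run_len + 1L
    prev_code <- code
    prev_ok <- TRUE
  }
  flush(prev_code, run_len)
  list(
    trans = trans,
    dwell = tibble::tibble(
      code = js$code,
      n_visits = n_visit,
      total_s = total_s,
      mean_s = ifelse(n_visit > 0, total_s / n_visit, 0)
    )
  )
}

# Exact two-sided rank-sum p-value by full enumeration of all C(m+n, m)
# assignments of the pooled sample to the first arm.
enumerate_rank_sum_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pool), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Pearson chi-square statistic from first principles.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
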