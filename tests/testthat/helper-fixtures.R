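# Small fixtures built in code.

# A fast little cohort: enriched adverse groups so the classifier stages
# have enough individuals, short labors so generation stays cheap.
make_small_cohort <- function(n = 150, seed = 1, effect = 0,
                              duration_mean = 100, dropout = 0.05) {
  sample_cohort(cohort_config(
    n_births = n,
    group_probs = c(healthy = 0.6, acidosis = 0.2, hie = 0.2),
    duration_mean_multiparous_min = duration_mean,
    parity_dynamics_effect = effect,
    dropout_rate = dropout,
    seed = seed
  ))
}

# Hand-built single-birth cohort from explicit channel runs.
manual_cohort <- function(fhr, up, duration_min, group = "healthy",
                          parity = "nulliparous", id = "b1") {
  list(
    births = tibble::tibble(
      id = id, group = group, parity = parity,
      caesarean = FALSE, duration_min = duration_min
    ),
    events = dplyr::bind_rows(
      dplyr::mutate(fhr, channel = "fhr", id = id),
      dplyr::mutate(up, channel = "up", id = id)
    )[, c("id", "channel", "state", "start_s", "dwell_s")]
  )
}

runs_from <- function(states, dwells) {
  tibble::tibble(
    state = states,
    start_s = cumsum(c(0, dwells[-length(dwells)])),
    dwell_s = dwells
  )
}

# Synthetic epoch-feature table with a single informative feature, for
# classifier tests that need controlled separability.
make_fake_features <- function(n_healthy = 40, n_acidosis = 20, n_hie = 10,
                               epochs_per = 4, sep = 3, seed = 99,
                               flip_parity_sign = FALSE) {
  withr::with_seed(seed, {
    n_tot <- n_healthy + n_acidosis + n_hie
    ind <- tibble::tibble(
      id = sprintf("i%03d", seq_len(n_tot)),
      group = rep(c("healthy", "acidosis", "hie"), c(n_healthy, n_acidosis, n_hie)),
      # alternate parity within group so per-parity subsets keep usable pools
      parity = unlist(lapply(c(n_healthy, n_acidosis, n_hie), function(k) {
        rep(c("nulliparous", "multiparous"), length.out = k)
      }))
    )
    fe <- tidyr::crossing(ind, epoch_index = 0:(epochs_per - 1))
    sign <- if (flip_parity_sign) ifelse(fe$parity == "nulliparous", 1, -1) else 1
    fe$caesarean <- FALSE
    fe$nulliparity <- as.numeric(fe$parity == "nulliparous")
    fe$f1 <- stats::rnorm(nrow(fe)) + sep * sign * (fe$group != "healthy")
    fe$f2 <- stats::rnorm(nrow(fe))
    attr(fe, "feature_cols") <- c("f1", "f2", "nulliparity")
    fe
  })
}
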