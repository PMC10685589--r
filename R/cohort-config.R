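#' Semi-Markov event dynamics for one outcome group
#'
#' Each simulated labor is an alternating-renewal (semi-Markov) process on
#' the labeled CTG event states: the fetal heart rate channel moves between
#' baseline, acceleration and deceleration events, and the uterine pressure
#' channel alternates between contractions and rest. Dwell times are
#' exponential with state-specific means; transitions are drawn from a
#' zero-diagonal row-stochastic matrix. Contraction stress is modeled as an
#' elevated chance of entering a deceleration while a contraction is active
#' or within 60 s after it ends (`coupling`), the classic late/variable
#' deceleration physiology, without synthesizing raw waveforms.
#'
#' No quantitative per-group event dynamics are available for the clinical
#' population this generator emulates; the shipped defaults are stand-ins
#' chosen to give plausible event frequencies and a graded
#' healthy < acidosis < HIE deceleration load. See the methods vignette.
#'
#' @param fhr_dwell_s Named numeric, mean dwell (seconds) of the baseline,
#'   acceleration and deceleration states.
#' @param fhr_trans 3x3 row-stochastic transition matrix over
#'   (baseline, acceleration, deceleration) with zero diagonal.
#' @param up_dwell_s Named numeric, mean dwell (seconds) of contraction and
#'   rest.
#' @param coupling Probability that leaving the baseline state during the
#'   contraction window (contraction plus 60 s) is forced into a
#'   deceleration.
#' @return An object of class `ctg_dynamics`.
#' @export
group_dynamics <- function(fhr_dwell_s = c(baseline = 150, acceleration = 25, deceleration = 25),
                           fhr_trans = default_fhr_trans(0.30),
                           up_dwell_s = c(contraction = 60, rest = 190),
                           coupling = 0.15) {
  fhr3 <- fhr_states[1:3]
  if (!all(fhr3 %in% names(fhr_dwell_s))) {
    stop_config("`fhr_dwell_s` must name baseline, acceleration and deceleration")
  }
  if (!all(c("contraction", "rest") %in% names(up_dwell_s))) {
    stop_config("`up_dwell_s` must name contraction and rest")
  }
  if (any(fhr_dwell_s <= 0) || any(up_dwell_s <= 0)) {
    stop_config("mean dwell times must be positive")
  }
  fhr_trans <- as.matrix(fhr_trans)
  if (!identical(dim(fhr_trans), c(3L, 3L))) {
    stop_config("`fhr_trans` must be a 3x3 matrix over baseline/acceleration/deceleration")
  }
  dimnames(fhr_trans) <- list(fhr3, fhr3)
  if (any(abs(rowSums(fhr_trans) - 1) > 1e-12)) {
    stop_config("rows of `fhr_trans` must sum to 1")
  }
  if (any(diag(fhr_trans) != 0)) {
    stop_config("`fhr_trans` must have a zero diagonal (no self-transitions)")
  }
  if (any(fhr_trans < 0)) stop_config("`fhr_trans` entries must be non-negative")
  if (coupling < 0 || coupling > 1) stop_config("`coupling` must be in [0, 1]")
  structure(
    list(
      fhr_dwell_s = fhr_dwell_s[fhr3],
      fhr_trans = fhr_trans,
      up_dwell_s = up_dwell_s[c("contraction", "rest")],
      coupling = coupling
    ),
    class = "ctg_dynamics"
  )
}

# Baseline-centric transition matrix: from baseline go to a deceleration
# with probability `p_decel`, otherwise to an acceleration; accelerations
# and decelerations return to baseline (with a small direct hop).
default_fhr_trans <- function(p_decel) {
  m <- matrix(0, 3, 3, dimnames = list(fhr_states[1:3], fhr_states[1:3]))
  m["baseline", "acceleration"] <- 1 - p_decel
  m["baseline", "deceleration"] <- p_decel
  m["acceleration", "baseline"] <- 0.95
  m["acceleration", "deceleration"] <- 0.05
  m["deceleration", "baseline"] <- 0.97
  m["deceleration", "acceleration"] <- 0.03
  m
}

#' Default per-group event dynamics
#'
#' Stand-in dynamics giving a graded deceleration load across the three
#' outcome groups: infants that went on to develop acidosis or HIE show
#' more frequent and longer decelerations, shorter baseline spells, more
#' frequent contractions and a stronger contraction-deceleration coupling.
#'
#' @return Named list of [group_dynamics()] objects for `healthy`,
#'   `acidosis` and `hie`.
#' @export
default_dynamics <- function() {
  list(
    healthy = group_dynamics(
      fhr_dwell_s = c(baseline = 150, acceleration = 25, deceleration = 30),
      fhr_trans = default_fhr_trans(0.30),
      up_dwell_s = c(contraction = 60, rest = 190),
      coupling = 0.18
    ),
    acidosis = group_dynamics(
      fhr_dwell_s = c(baseline = 140, acceleration = 23, deceleration = 33),
      fhr_trans = default_fhr_trans(0.34),
      up_dwell_s = c(contraction = 63, rest = 178),
      coupling = 0.22
    ),
    hie = group_dynamics(
      fhr_dwell_s = c(baseline = 130, acceleration = 21, deceleration = 36),
      fhr_trans = default_fhr_trans(0.38),
      up_dwell_s = c(contraction = 66, rest = 166),
      coupling = 0.27
    )
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions a generated cohort emulates: the three-group
#' outcome structure (healthy / acidosis / HIE), group-specific nulliparity
#' prevalence, longer labors in nulliparous mothers, group-dependent CTG
#' event dynamics, signal dropouts, and group-by-parity Caesarean delivery
#' rates. Defaults follow the reference cohort of 40,976 births with
#' blood-gas-confirmed outcomes: group sizes 37,546 / 3,056 / 374,
#' nulliparity 57.8% / 64.5% / 66.8% and Caesarean rates near the observed
#' clinical ones.
#'
#' @param n_births Number of deliveries to simulate.
#' @param group_probs Probabilities of (healthy, acidosis, hie); must sum
#'   to 1.
#' @param nulliparity_prob_by_group Probability that a birth in each group
#'   is from a nulliparous mother.
#' @param duration_mean_multiparous_min Mean monitored labor duration for
#'   multiparous births, minutes.
#' @param nulliparous_duration_multiplier Ratio (>= 1) applied to the mean
#'   duration for nulliparous births.
#' @param duration_sdlog Log-scale standard deviation of the log-normal
#'   duration distribution.
#' @param dynamics Named list of [group_dynamics()], one per group.
#' @param parity_dynamics_effect Non-negative real. 0 is the physiological
#'   null in which parity affects only labor duration and prevalence, never
#'   the conditional law of the event streams; positive values scale the
#'   deceleration-entry hazard (and coupling) of nulliparous labors by
#'   `1 + effect`, injecting a parity-by-dynamics interaction.
#' @param effect_parity Which parity's deceleration dynamics the injected
#'   interaction scales (`"nulliparous"` by default). Direction matters for
#'   decision-support comparisons: distorting the parity that carries the
#'   minority of HIE cases is the stress test under which a pooled
#'   classifier gives up the most.
#' @param individual_sd Log-scale standard deviation of a per-birth
#'   deceleration-propensity multiplier (log-normal, mean 1) applied on
#'   top of the group dynamics. This inter-individual frailty makes the
#'   groups overlap at the birth level, as they do clinically; 0 switches
#'   it off.
#' @param caesarean_rate_by_group_parity 3x2 matrix of Caesarean delivery
#'   probabilities, rows (healthy, acidosis, hie), columns
#'   (nulliparous, multiparous).
#' @param dropout_rate Expected fraction of each channel lost to signal
#'   dropouts (inserted as `invalid` runs).
#' @param dropout_mean_len_s Mean length of a single dropout, seconds.
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts bit for bit.
#' @return An object of class `ctg_cohort_config`.
#' @export
cohort_config <- function(n_births = 1000,
                          group_probs = c(healthy = 37546, acidosis = 3056, hie = 374) / 40976,
                          nulliparity_prob_by_group = c(healthy = 0.578, acidosis = 0.645, hie = 0.668),
                          duration_mean_multiparous_min = 300,
                          nulliparous_duration_multiplier = 1.4,
                          duration_sdlog = 0.35,
                          dynamics = default_dynamics(),
                          parity_dynamics_effect = 0,
                          effect_parity = c("nulliparous", "multiparous"),
                          individual_sd = 0.7,
                          caesarean_rate_by_group_parity = default_caesarean_rates(),
                          dropout_rate = 0.05,
                          dropout_mean_len_s = 30,
                          seed = 1L) {
  if (length(n_births) != 1 || n_births < 1 || n_births != round(n_births)) {
    stop_config("`n_births` must be a positive integer")
  }
  group_probs <- as.numeric(group_probs)
  if (length(group_probs) != 3 || any(group_probs < 0) || any(group_probs > 1)) {
    stop_config("`group_probs` must be 3 probabilities in [0, 1]")
  }
  if (abs(sum(group_probs) - 1) > 1e-12) {
    stop_config("`group_probs` must sum to 1 (within 1e-12)")
  }
  np <- as.numeric(nulliparity_prob_by_group)
  if (length(np) != 3 || any(np < 0) || any(np > 1)) {
    stop_config("`nulliparity_prob_by_group` must be 3 probabilities in [0, 1]")
  }
  if (nulliparous_duration_multiplier < 1) {
    stop_config("`nulliparous_duration_multiplier` must be >= 1")
  }
  if (duration_mean_multiparous_min <= 0) stop_config("mean duration must be positive")
  if (!all(group_levels %in% names(dynamics))) {
    stop_config("`dynamics` must be a named list with healthy, acidosis and hie entries")
  }
  for (g in group_levels) {
    if (!inherits(dynamics[[g]], "ctg_dynamics")) {
      stop_config("each `dynamics` entry must be built with group_dynamics()")
    }
  }
  if (parity_dynamics_effect < 0) stop_config("`parity_dynamics_effect` must be >= 0")
  if (individual_sd < 0) stop_config("`individual_sd` must be >= 0")
  cs <- as.matrix(caesarean_rate_by_group_parity)
  if (!identical(dim(cs), c(3L, 2L)) || any(cs < 0) || any(cs > 1)) {
    stop_config("`caesarean_rate_by_group_parity` must be a 3x2 matrix of probabilities")
  }
  dimnames(cs) <- list(group_levels, parity_levels)
  if (dropout_rate < 0 || dropout_rate >= 1) stop_config("`dropout_rate` must be in [0, 1)")
  if (dropout_mean_len_s <= 0) stop_config("`dropout_mean_len_s` must be positive")
  structure(
    list(
      n_births = as.integer(n_births),
      group_probs = setNames(group_probs, group_levels),
      nulliparity_prob_by_group = setNames(np, group_levels),
      duration_mean_multiparous_min = duration_mean_multiparous_min,
      nulliparous_duration_multiplier = nulliparous_duration_multiplier,
      duration_sdlog = duration_sdlog,
      dynamics = dynamics[group_levels],
      parity_dynamics_effect = parity_dynamics_effect,
      effect_parity = match.arg(effect_parity),
      individual_sd = individual_sd,
      caesarean_rate_by_group_parity = cs,
      dropout_rate = dropout_rate,
      dropout_mean_len_s = dropout_mean_len_s,
      seed = as.integer(seed)
    ),
    class = "ctg_cohort_config"
  )
}

# Caesarean delivery rates by group and parity, matching the clinical
# rates of the reference population.
default_caesarean_rates <- function() {
  matrix(
    c(
      0.416, 0.354,
      0.345, 0.430,
      0.516, 0.636
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(group_levels, parity_levels)
  )
}
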