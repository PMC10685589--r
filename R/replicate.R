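# End-to-end fitting of the four decision systems on one train/test
# resample, and the replicated experiment that compares them.

ds_systems <- c("ds_all", "ds_all_np", "ds_np", "ds_mp", "ds_two_path")

#' Fit and evaluate the decision systems on one train/test split
#'
#' One complete protocol run: a stratified individual-level 90/10 split,
#' the requested classifiers (`c_all`, `c_all_np` and/or the
#' parity-routed pair `c_np`/`c_mp`), out-of-bag posteriors, per-system
#' threshold calibration to the Caesarean delivery rate of the healthy
#' births in the classifier's own training subpopulation, and
#' recommendation rates on the held-out test births. `"ds_two_path"` is
#' the union of `ds_np` on nulliparous and `ds_mp` on multiparous test
#' births. Train/test disjointness and per-tree class balance are asserted
#' on every run.
#'
#' @param features Cohort feature tibble from [extract_features()].
#' @param births The cohort's `births` tibble.
#' @param systems Subset of
#'   `c("ds_all", "ds_all_np", "ds_np", "ds_mp", "ds_two_path")`.
#' @param n_trees Trees per forest.
#' @param train_frac Fraction of individuals used for training.
#' @param seed Integer seed controlling split and forests.
#' @param cfg A [ds_config()].
#' @return An object of class `ctg_ds_fit`: calibrations, per-birth
#'   recommendations (with a `system` column), per-system group rates, and
#'   the split.
#' @export
fit_decision_systems <- function(features, births,
                                 systems = c("ds_all", "ds_all_np", "ds_two_path"),
                                 n_trees = 200, train_frac = 0.9, seed = 1L,
                                 cfg = ds_config()) {
  systems <- match.arg(systems, ds_systems, several.ok = TRUE)
  split <- split_train_test(births, train_frac, seed = seed)
  stopifnot(length(intersect(split$train, split$test)) == 0L) # leakage guard
  tr_feat <- features[features$id %in% split$train, , drop = FALSE]
  te_feat <- features[features$id %in% split$test, , drop = FALSE]
  tr_births <- births[births$id %in% split$train, , drop = FALSE]
  te_births <- births[births$id %in% split$test, , drop = FALSE]

  healthy_caesarean_rate <- function(b) {
    h <- b[b$group == "healthy", , drop = FALSE]
    if (nrow(h) == 0L) stop_input("no healthy births to compute the Caesarean target from")
    mean(h$caesarean)
  }

  one_path <- function(include_parity, system) {
    model <- train_forest(tr_feat,
      n_trees = n_trees, include_parity = include_parity,
      seed = seed, tag = if (include_parity) "c_all_np" else "c_all"
    )
    cal <- calibrate_threshold(
      oob_posterior(model, tr_feat),
      tr_births$id[tr_births$group == "healthy"],
      healthy_caesarean_rate(tr_births),
      cfg
    )
    rec <- evaluate_births(predict(model, te_feat), cal$t_pat, cfg, ids = te_births$id)
    rec$system <- system
    list(cal = cal, rec = rec)
  }

  parity_path <- function(par, system) {
    trf <- tr_feat[tr_feat$parity == par, , drop = FALSE]
    trb <- tr_births[tr_births$parity == par, , drop = FALSE]
    tef <- te_feat[te_feat$parity == par, , drop = FALSE]
    teb <- te_births[te_births$parity == par, , drop = FALSE]
    model <- train_forest(trf,
      n_trees = n_trees, include_parity = FALSE,
      seed = seed, tag = if (par == "nulliparous") "c_np" else "c_mp"
    )
    cal <- calibrate_threshold(
      oob_posterior(model, trf),
      trb$id[trb$group == "healthy"],
      healthy_caesarean_rate(trb),
      cfg
    )
    rec <- evaluate_births(predict(model, tef), cal$t_pat, cfg, ids = teb$id)
    rec$system <- system
    list(cal = cal, rec = rec)
  }

  fits <- list()
  if ("ds_all" %in% systems) fits$ds_all <- one_path(FALSE, "ds_all")
  if ("ds_all_np" %in% systems) fits$ds_all_np <- one_path(TRUE, "ds_all_np")
  need_np <- any(c("ds_np", "ds_two_path") %in% systems)
  need_mp <- any(c("ds_mp", "ds_two_path") %in% systems)
  if (need_np) fits$ds_np <- parity_path("nulliparous", "ds_np")
  if (need_mp) fits$ds_mp <- parity_path("multiparous", "ds_mp")

  recommendations <- list_rbind(map(fits, "rec"))
  if ("ds_two_path" %in% systems) {
    two <- bind_rows(fits$ds_np$rec, fits$ds_mp$rec)
    stopifnot(!anyDuplicated(two$id)) # the parity partition is exact
    two$system <- "ds_two_path"
    recommendations <- bind_rows(recommendations, two)
  }
  recommendations <- recommendations[recommendations$system %in% systems, , drop = FALSE]

  structure(
    list(
      calibrations = map(fits, "cal"),
      recommendations = recommendations,
      rates = recommendation_rates(recommendations, te_births),
      rates_by_parity = recommendation_rates(recommendations, te_births, by_parity = TRUE),
      split = split,
      systems = systems,
      n_trees = n_trees,
      seed = seed
    ),
    class = "ctg_ds_fit"
  )
}

#' @export
print.ctg_ds_fit <- function(x, ...) {
  cat(
    "<ctg_ds_fit> systems:", paste(x$systems, collapse = ", "),
    "| trees:", x$n_trees, "\n"
  )
  print(x$rates, n = Inf)
  invisible(x)
}

#' Replicated comparison of the decision systems
#'
#' Repeats the full protocol on `n_runs` independent train/test resamples
#' of one cohort (features are extracted once; each run redraws the split,
#' the forests and the calibrated thresholds) and aggregates per-system,
#' per-group recommendation rates: medians with notch-style confidence
#' intervals ([median_ci()]) and pairwise two-sided rank-sum tests between
#' systems within each group. Runs that fail are recorded, excluded and
#' reported rather than aborting the experiment.
#'
#' @param cohort A `ctg_cohort`.
#' @param n_runs Number of independent resamples (the full protocol uses
#'   100).
#' @param n_trees Trees per forest.
#' @param base_seed Seed fixing the entire experiment.
#' @param systems Systems to fit; see [fit_decision_systems()].
#' @param train_frac Training fraction per resample.
#' @param cfg A [ds_config()].
#' @param features Optional precomputed [extract_features()] table.
#' @return An object of class `ctg_replication` with elements `runs`
#'   (per-run rates), `summary` (medians and CIs), `tests` (pairwise
#'   rank-sum p-values per group), `example_recommendations` (per-birth
#'   recommendations of the first successful run, for audit and time
#'   courses), `failed_runs` and the experiment parameters.
#' @export
run_replicated_experiment <- function(cohort, n_runs = 100, n_trees = 200,
                                      base_seed = 1L,
                                      systems = c("ds_all", "ds_all_np", "ds_two_path"),
                                      train_frac = 0.9, cfg = ds_config(),
                                      features = NULL) {
  if (is.null(features)) {
    features <- extract_features(segment_epochs(cohort), cohort$births)
  }
  seeds <- with_rng_seed(base_seed, sample.int(.Machine$integer.max - 1L, n_runs))
  runs <- vector("list", n_runs)
  example_recommendations <- NULL
  failed <- tibble(run = integer(), message = character())
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      fit_decision_systems(
        features, cohort$births,
        systems = systems, n_trees = n_trees,
        train_frac = train_frac, seed = seeds[r], cfg = cfg
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warn(sprintf("run %d failed and was excluded: %s", r, conditionMessage(fit)))
      failed <- bind_rows(failed, tibble(run = r, message = conditionMessage(fit)))
      next
    }
    if (is.null(example_recommendations)) {
      example_recommendations <- mutate(fit$recommendations, run = r)
    }
    rates <- fit$rates
    rates$run <- r
    rates$target_fp <- NA_real_
    rates$achieved_fp <- NA_real_
    for (sys in names(fit$calibrations)) {
      sel <- rates$system == sys & rates$group == "healthy"
      rates$target_fp[sel] <- fit$calibrations[[sys]]$target_fp_rate
      rates$achieved_fp[sel] <- fit$calibrations[[sys]]$achieved_fp_rate
    }
    runs[[r]] <- rates
  }
  runs <- list_rbind(runs)
  if (nrow(runs) == 0L) stop_input("every replication run failed")

  summary <- runs |>
    group_by(.data$system, .data$group) |>
    summarise(ci = list(median_ci(.data$rate)), .groups = "drop") |>
    tidyr::unnest("ci")

  sys_done <- sort(unique(runs$system))
  tests <- if (length(sys_done) < 2) {
    tibble(group = character(), system_a = character(), system_b = character(), p_value = numeric())
  } else {
    pairs <- utils::combn(sys_done, 2, simplify = FALSE)
    list_rbind(map(sort(unique(runs$group)), function(g) {
      list_rbind(map(pairs, function(p) {
        xa <- runs$rate[runs$system == p[1] & runs$group == g]
        xb <- runs$rate[runs$system == p[2] & runs$group == g]
        t <- rank_sum_test(xa, xb)
        tibble(group = g, system_a = p[1], system_b = p[2], p_value = t$p_value)
      }))
    }))
  }

  structure(
    list(
      runs = runs, summary = summary, tests = tests,
      example_recommendations = example_recommendations,
      failed_runs = failed,
      n_runs = n_runs, n_trees = n_trees, base_seed = base_seed,
      systems = systems, train_frac = train_frac
    ),
    class = "ctg_replication"
  )
}

#' @export
print.ctg_replication <- function(x, ...) {
  ok <- length(unique(x$runs$run))
  cat(
    "<ctg_replication> ", ok, "/", x$n_runs, " runs, ",
    x$n_trees, " trees, systems: ", paste(x$systems, collapse = ", "), "\n",
    sep = ""
  )
  print(x$summary, n = Inf)
  invisible(x)
}

#' One-call pipeline: features, systems, replication and cohort statistics
#'
#' Convenience wrapper running the whole analysis on a cohort: epoch
#' segmentation, featurization, the replicated system comparison, the
#' group-by-parity table and both relative risks. Optionally writes the
#' audit files (`epochs.csv`, `features.csv`, `recommendations.csv`,
#' `timecourse.csv`, `rates_runs.csv`, `rates.json`, `report.json`) to
#' `out_dir`.
#'
#' @inheritParams run_replicated_experiment
#' @param out_dir Optional directory for the audit files.
#' @return List with `replication` (a `ctg_replication`), `table`
#'   (group-by-parity counts), `risks` (both relative risks), `epochs` and
#'   `features`.
#' @export
run_pipeline <- function(cohort, n_runs = 10, n_trees = 200, base_seed = 1L,
                         systems = c("ds_all", "ds_all_np", "ds_two_path"),
                         cfg = ds_config(), out_dir = NULL) {
  epochs <- segment_epochs(cohort)
  features <- extract_features(epochs, cohort$births)
  replication <- run_replicated_experiment(
    cohort,
    n_runs = n_runs, n_trees = n_trees, base_seed = base_seed,
    systems = systems, cfg = cfg, features = features
  )
  tab <- build_table(cohort$births)
  risks <- bind_rows(
    relative_risk(tab, "hie"),
    relative_risk(tab, "acidosis")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(epochs$epochs, file.path(out_dir, "epochs.csv"))
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    rec <- replication$example_recommendations
    readr::write_csv(rec, file.path(out_dir, "recommendations.csv"))
    readr::write_csv(
      time_course(rec, cohort$births),
      file.path(out_dir, "timecourse.csv")
    )
    readr::write_csv(replication$runs, file.path(out_dir, "rates_runs.csv"))
    jsonlite::write_json(
      replication$summary,
      file.path(out_dir, "rates.json"),
      dataframe = "rows", digits = NA
    )
    jsonlite::write_json(
      list(
        table = tab, risks = risks,
        tests = replication$tests,
        seed = base_seed, n_runs = n_runs, n_trees = n_trees
      ),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  list(
    replication = replication, table = tab, risks = risks,
    epochs = epochs, features = features
  )
}
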