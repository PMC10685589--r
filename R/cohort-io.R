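# Cohort files: births.csv (one row per delivery) and events.csv (run-
# length encoded event streams), UTF-8, header row, dot decimal.

births_cols <- c("id", "group", "parity", "caesarean", "duration_min")
events_cols <- c("id", "channel", "state", "start_s", "dwell_s")

#' Write a cohort to CSV files
#'
#' @param cohort A `ctg_cohort`.
#' @param dir Output directory (created if needed); writes `births.csv`
#'   and `events.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$births, file.path(dir, "births.csv"))
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' @param dir Directory holding `births.csv` and `events.csv`.
#' @return A `ctg_cohort` (without a generator configuration).
#' @export
read_cohort <- function(dir) {
  bf <- file.path(dir, "births.csv")
  ef <- file.path(dir, "events.csv")
  for (f in c(bf, ef)) if (!file.exists(f)) stop_input(paste("missing cohort file:", f))
  births <- readr::read_csv(bf, show_col_types = FALSE)
  events <- readr::read_csv(ef, show_col_types = FALSE)
  miss_b <- setdiff(births_cols, names(births))
  if (length(miss_b)) stop_input(paste("births.csv lacks columns:", paste(miss_b, collapse = ", ")))
  miss_e <- setdiff(events_cols, names(events))
  if (length(miss_e)) stop_input(paste("events.csv lacks columns:", paste(miss_e, collapse = ", ")))
  structure(
    list(
      births = as_tibble(births[births_cols]),
      events = as_tibble(events[events_cols]),
      config = NULL
    ),
    class = "ctg_cohort"
  )
}

#' Validate a cohort's structural invariants
#'
#' Checks label domains, duration consistency and the event-stream
#' invariants every downstream stage relies on: runs are contiguous,
#' non-overlapping, cover exactly `[0, duration]`, have positive dwells,
#' and consecutive runs carry distinct states. Issues are reported, not
#' raised.
#'
#' @param cohort A `ctg_cohort`.
#' @return Tibble `id`, `check`, `detail`; zero rows when the cohort is
#'   clean.
#' @export
validate_cohort <- function(cohort) {
  births <- cohort$births
  events <- cohort$events
  issues <- list()
  note <- function(id, check, detail) {
    issues[[length(issues) + 1L]] <<- tibble(id = id, check = check, detail = detail)
  }

  bad_group <- births$id[!births$group %in% group_levels]
  for (id in bad_group) note(id, "group_domain", "group outside healthy/acidosis/hie")
  bad_par <- births$id[!births$parity %in% parity_levels]
  for (id in bad_par) note(id, "parity_domain", "parity outside nulliparous/multiparous")
  bad_dur <- births$id[!(births$duration_min > 0)]
  for (id in bad_dur) note(id, "duration", "duration_min must be positive")

  valid_states <- list(fhr = fhr_states, up = up_states)
  for (id in intersect(unique(events$id), births$id)) {
    dur_s <- births$duration_min[births$id == id][1] * 60
    ev <- events[events$id == id, , drop = FALSE]
    for (ch in c("fhr", "up")) {
      runs <- ev[ev$channel == ch, , drop = FALSE]
      if (nrow(runs) == 0L) {
        note(id, "coverage", paste(ch, "channel has no runs"))
        next
      }
      if (any(!runs$state %in% valid_states[[ch]])) {
        note(id, "state_domain", paste(ch, "has states outside its event family"))
      }
      if (any(runs$dwell_s <= 0)) note(id, "dwell_positive", paste(ch, "has non-positive dwells"))
      o <- order(runs$start_s)
      runs <- runs[o, , drop = FALSE]
      ends <- runs$start_s + runs$dwell_s
      if (abs(runs$start_s[1]) > 1e-6 || abs(ends[nrow(runs)] - dur_s) > 1e-6) {
        note(id, "coverage", paste(ch, "runs do not span [0, duration]"))
      }
      if (nrow(runs) > 1L) {
        gaps <- runs$start_s[-1] - ends[-nrow(runs)]
        if (any(gaps > 1e-6)) note(id, "contiguity", paste(ch, "has gaps between runs"))
        if (any(gaps < -1e-6)) note(id, "overlap", paste(ch, "has overlapping runs"))
        if (any(runs$state[-1] == runs$state[-nrow(runs)])) {
          note(id, "distinct_states", paste(ch, "has consecutive runs with equal state"))
        }
      }
    }
  }
  orphans <- setdiff(unique(events$id), births$id)
  for (id in orphans) note(id, "orphan_events", "events for an id absent from births")

  if (length(issues) == 0L) {
    tibble(id = character(), check = character(), detail = character())
  } else {
    list_rbind(issues)
  }
}
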