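# Sliding-window recommendation rule and threshold calibration.

preds_of <- function(id, idx, p) tibble::tibble(id = id, epoch_index = idx, p_pat = p)

test_that("a fully alerting birth is recommended at the earliest eligible window", {
  pr <- preds_of("b1", 0:4, rep(0.9, 5))
  rec <- evaluate_births(pr, t_pat = 0.5)
  expect_true(rec$recommended)
  # earliest eligible window: slots 2..6 has 3 scored epochs, edge 40 min
  expect_equal(rec$first_time_min, 40)
  # with a longer fully-alerting record the decision comes much earlier:
  # the earliest window holding >= 3 of its 5 slots ends 15 epochs out
  pr2 <- preds_of("b1", 0:17, rep(0.9, 18))
  expect_equal(evaluate_births(pr2, 0.5)$first_time_min, 15 * 20)
})

test_that("windows missing more than two epochs are skipped even if all alert", {
  pr <- preds_of("b1", c(2L, 3L), c(0.99, 0.99))
  rec <- evaluate_births(pr, t_pat = 0.5)
  expect_false(rec$recommended)
  expect_identical(rec$windows_evaluated, 0L)

  # exactly 3 scored epochs is enough
  pr3 <- preds_of("b1", c(2L, 3L, 4L), c(0.99, 0.99, 0.99))
  expect_true(evaluate_births(pr3, 0.5)$recommended)
})

test_that("alerts confined to the final 40 minutes never recommend", {
  p <- c(0.9, 0.9, rep(0.1, 5))
  pr <- preds_of("b1", 0:6, p)
  rec <- evaluate_births(pr, t_pat = 0.5)
  expect_false(rec$recommended)
})

test_that("one non-alerting epoch inside the window vetoes it", {
  pr <- preds_of("b1", 2:6, c(0.9, 0.9, 0.2, 0.9, 0.9))
  expect_false(evaluate_births(pr, 0.5)$recommended)
  pr2 <- preds_of("b1", 2:6, rep(0.9, 5))
  expect_true(evaluate_births(pr2, 0.5)$recommended)
})

test_that("births without epochs are reported unrecommended", {
  pr <- preds_of("b1", 0:4, rep(0.9, 5))
  rec <- evaluate_births(pr, 0.5, ids = c("b1", "b2"))
  expect_identical(rec$recommended, c(TRUE, FALSE))
  expect_identical(rec$windows_evaluated[2], 0L)
})

test_that("recommendation status is monotone non-increasing in the threshold", {
  withr::with_seed(14, {
    pr <- purrr::list_rbind(purrr::map(1:30, function(i) {
      idx <- sort(sample(0:20, sample(5:15, 1)))
      preds_of(sprintf("m%02d", i), idx, runif(length(idx)))
    }))
  })
  grid <- sort(unique(pr$p_pat))
  prev <- rep(TRUE, 30)
  for (t in grid) {
    rec <- evaluate_births(pr, t, ids = sprintf("m%02d", 1:30))
    expect_true(all(prev | !rec$recommended)) # once off, stays off
    prev <- rec$recommended
  }
})

test_that("calibration picks the smallest threshold meeting the target", {
  withr::with_seed(7, {
    pr <- purrr::list_rbind(purrr::map(1:60, function(i) {
      preds_of(sprintf("h%02d", i), 2:12, runif(11, 0, 1))
    }))
  })
  ids <- sprintf("h%02d", 1:60)
  cal <- calibrate_threshold(pr, ids, target_fp_rate = 0.4)
  expect_lte(cal$achieved_fp_rate, 0.4)
  # exhaustive check against evaluate_births on the full candidate grid
  cand <- sort(unique(c(pr$p_pat, 1)))
  fp <- vapply(cand, function(t) mean(evaluate_births(pr, t, ids = ids)$recommended), numeric(1))
  expect_true(!is.unsorted(rev(fp))) # non-increasing in t
  expect_identical(cal$t_pat, cand[which(fp <= 0.4)[1]])
  expect_equal(cal$achieved_fp_rate, fp[which(fp <= 0.4)[1]])
  # one grid step below: the next lower candidate overshoots the target
  i <- match(cal$t_pat, cand)
  if (i > 1) expect_gt(fp[i - 1], 0.4)

  # boundary targets
  cal1 <- calibrate_threshold(pr, ids, 1)
  expect_identical(cal1$t_pat, cand[1])
  cal0 <- calibrate_threshold(pr, ids, 0)
  expect_identical(cal0$achieved_fp_rate, 0)
  expect_false(any(evaluate_births(pr, cal0$t_pat, ids = ids)$recommended))

  # no valid windows at all -> error
  sparse <- preds_of(ids, rep(3L, 60), runif(60))
  expect_error(calibrate_threshold(sparse, ids, 0.4), class = "ctgdss_input_error")
})

test_that("recommendation rates match hand counts and the parity partition", {
  births <- tibble::tibble(
    id = sprintf("r%02d", 1:8),
    group = rep(c("healthy", "hie"), each = 4),
    parity = rep(c("nulliparous", "multiparous"), 4),
    caesarean = FALSE, duration_min = 200
  )
  rec <- tibble::tibble(
    id = births$id,
    recommended = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    first_time_min = ifelse(c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), 60, NA),
    windows_evaluated = 5L
  )
  rr <- recommendation_rates(rec, births)
  expect_equal(rr$rate[rr$group == "healthy"], 0.25)
  expect_equal(rr$rate[rr$group == "hie"], 0.75)

  # two-path union rate = parity-weighted average of the per-parity rates
  rp <- recommendation_rates(rec, births, by_parity = TRUE)
  w <- table(births$parity[births$group == "hie"])
  joint <- sum(rp$rate[rp$group == "hie"] * w[rp$parity[rp$group == "hie"]]) / sum(w)
  expect_equal(joint, 0.75)
})

test_that("the time course is a non-increasing step function anchored at the cutoff", {
  births <- tibble::tibble(
    id = sprintf("t%02d", 1:10), group = "hie",
    parity = "nulliparous", caesarean = FALSE, duration_min = 400
  )
  rec <- tibble::tibble(
    id = births$id,
    recommended = c(rep(TRUE, 6), rep(FALSE, 4)),
    first_time_min = c(40, 60, 60, 120, 240, 400, NA, NA, NA, NA),
    windows_evaluated = 8L
  )
  tc <- time_course(rec, births)
  expect_true(all(diff(tc$rate[order(tc$time_min)]) <= 1e-12))
  expect_equal(tc$rate[tc$time_min == 40], 0.6) # overall rate at the cutoff
  expect_equal(tc$rate[tc$time_min == 100], 0.3)
  expect_equal(tc$rate[tc$time_min == 720], 0)

  none <- rec
  none$recommended <- FALSE
  none$first_time_min <- NA_real_
  expect_true(all(time_course(none, births)$rate == 0))
})
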