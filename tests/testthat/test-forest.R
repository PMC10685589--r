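# Balanced-undersampled forests: splitting, per-tree sampling, OOB
# posteriors, routing.

test_that("the stratified split is individual-level, exact and deterministic", {
  births <- tidyr::crossing(
    group = c("healthy", "acidosis", "hie"),
    parity = c("nulliparous", "multiparous"),
    i = 1:20
  )
  births$id <- sprintf("s%03d", seq_len(nrow(births)))
  sp <- split_train_test(births, 0.9, seed = 4)
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$test), births$id)
  # 18/2 in every stratum
  tr <- births[births$id %in% sp$train, ]
  expect_true(all(table(tr$group, tr$parity) == 18))
  expect_identical(sp, split_train_test(births, 0.9, seed = 4))
  too_small <- births[births$group != "hie" | births$i <= 4, ]
  expect_error(split_train_test(too_small, 0.9, seed = 1), class = "ctgdss_input_error")
})

test_that("per-tree samples honor the 2:1:1 ratio without replacement", {
  pools <- list(
    healthy = sprintf("h%03d", 1:100),
    acidosis = sprintf("a%03d", 1:50),
    hie = sprintf("e%03d", 1:10)
  )
  withr::with_seed(1, s <- draw_tree_sample(pools))
  expect_identical(length(s), 40L)
  expect_identical(sum(s %in% pools$hie), 10L)
  expect_identical(sum(s %in% pools$acidosis), 10L)
  expect_identical(sum(s %in% pools$healthy), 20L)
  expect_false(anyDuplicated(s) > 0)

  # inclusion frequency of a healthy individual ~ Binomial(n, 20/100)
  withr::with_seed(3, {
    hits <- vapply(
      1:1000, function(i) "h001" %in% draw_tree_sample(pools),
      logical(1)
    )
  })
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(mean(hits) - 0.2), 2 * se)

  expect_error(
    draw_tree_sample(list(healthy = pools$healthy[1:15], acidosis = pools$acidosis, hie = pools$hie)),
    class = "ctgdss_input_error"
  )
})

test_that("a separable fixture is learned, permuted labels are chance level", {
  fe <- make_fake_features(sep = 4)
  m <- train_forest(fe, n_trees = 120, seed = 6)
  oob <- oob_posterior(m, fe)
  ok <- !is.na(oob$p_pat)
  acc <- mean((oob$p_pat[ok] > 0.5) == (fe$group[ok] != "healthy"))
  expect_gt(acc, 0.95)

  # permute group labels at the individual level
  fe2 <- make_fake_features(sep = 4, seed = 100)
  ind <- unique(fe2$id)
  withr::with_seed(8, perm <- setNames(
    sample(fe2$group[!duplicated(fe2$id)]), ind
  ))
  fe2$group <- unname(perm[fe2$id])
  attr(fe2, "feature_cols") <- c("f1", "f2", "nulliparity")
  m2 <- train_forest(fe2, n_trees = 120, seed = 6)
  oob2 <- oob_posterior(m2, fe2)
  ok2 <- !is.na(oob2$p_pat)
  acc2 <- mean((oob2$p_pat[ok2] > 0.5) == (fe2$group[ok2] != "healthy"))
  expect_lt(abs(acc2 - 0.5), 0.15)
})

test_that("training and posteriors are reproducible given the seed", {
  fe <- make_fake_features()
  m1 <- train_forest(fe, n_trees = 50, seed = 12)
  m2 <- train_forest(fe, n_trees = 50, seed = 12)
  expect_identical(oob_posterior(m1, fe), oob_posterior(m2, fe))
  expect_identical(predict(m1, fe), predict(m2, fe))
})

test_that("OOB vote fractions equal a per-tree recount", {
  fe <- make_fake_features(n_healthy = 12, n_acidosis = 5, n_hie = 5, epochs_per = 2)
  m <- train_forest(fe, n_trees = 7, seed = 3)
  oob <- oob_posterior(m, fe)
  votes <- ctgdss:::forest_votes(m, fe) # n x trees logical, pathological votes
  inbag <- m$inbag_individuals
  for (i in seq_len(nrow(fe))) {
    oob_trees <- which(!inbag[fe$id[i], ])
    expected <- if (length(oob_trees) == 0) NA_real_ else mean(votes[i, oob_trees])
    expect_equal(oob$p_pat[i], expected)
    expect_identical(oob$n_oob_trees[i], length(oob_trees))
  }
  # full-forest posterior is the plain vote fraction
  pr <- predict(m, fe)
  expect_equal(pr$p_pat, rowMeans(votes))
})

test_that("an epoch in-bag for every tree gets a missing OOB marker", {
  fe <- make_fake_features(n_healthy = 4, n_acidosis = 2, n_hie = 2, epochs_per = 2)
  # healthy pool 4, needs 2*hie = 4 -> every healthy individual in-bag in
  # every tree; acidosis/hie pools likewise exhausted
  m <- train_forest(fe, n_trees = 3, seed = 1)
  oob <- oob_posterior(m, fe)
  expect_true(all(is.na(oob$p_pat)))
  expect_true(all(oob$n_oob_trees == 0L))
})

test_that("two-path prediction routes by parity", {
  # opposite class signatures per parity: routing is observable
  fe <- make_fake_features(sep = 4, flip_parity_sign = TRUE, seed = 55)
  np <- fe[fe$parity == "nulliparous", ]
  mp <- fe[fe$parity == "multiparous", ]
  attr(np, "feature_cols") <- attr(fe, "feature_cols")
  attr(mp, "feature_cols") <- attr(fe, "feature_cols")
  m_np <- train_forest(np, n_trees = 60, seed = 2, tag = "c_np")
  m_mp <- train_forest(mp, n_trees = 60, seed = 2, tag = "c_mp")
  routed <- predict_two_path(m_np, m_mp, fe)
  key <- function(d) paste(d$id, d$epoch_index)
  direct_np <- predict(m_np, np)
  direct_mp <- predict(m_mp, mp)
  expect_equal(
    routed$p_pat[match(key(direct_np), key(routed))],
    direct_np$p_pat
  )
  expect_equal(
    routed$p_pat[match(key(direct_mp), key(routed))],
    direct_mp$p_pat
  )
  # and the two models genuinely disagree on shared inputs
  expect_gt(mean(abs(predict(m_np, mp)$p_pat - direct_mp$p_pat)), 0.2)

  fe_na <- fe
  fe_na$parity[1] <- NA
  expect_error(predict_two_path(m_np, m_mp, fe_na), class = "ctgdss_input_error")
})

test_that("degenerate two-path with identical training data equals one-path", {
  fe <- make_fake_features(seed = 77)
  m_a <- train_forest(fe, n_trees = 40, seed = 9)
  m_b <- train_forest(fe, n_trees = 40, seed = 9)
  routed <- predict_two_path(m_a, m_b, fe)
  direct <- predict(m_a, fe)
  m <- match(
    paste(direct$id, direct$epoch_index),
    paste(routed$id, routed$epoch_index)
  )
  expect_equal(routed$p_pat[m], direct$p_pat)
})

test_that("hyperparameter tuning ranks candidates by OOB balanced accuracy", {
  fe <- make_fake_features(sep = 3, seed = 4)
  grid <- data.frame(mtry = c(1L, 2L), min_node_size = 5L, max_depth = 6L)
  res <- tune_forest(fe, grid, n_trees = 40, seed = 2)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$oob_balanced_accuracy >= 0 & res$oob_balanced_accuracy <= 1))
  expect_true(!is.unsorted(rev(res$oob_balanced_accuracy)))
})
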