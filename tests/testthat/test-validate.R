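test_that("metrics match hand-counted confusion tables", {
  # perfect prediction
  m <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(c(m$Ac, m$Se, m$Sp, m$BER), c(100, 100, 100, 0))

  # TP=9 FN=1 TN=98 FP=2
  truth <- c(rep(1, 10), rep(0, 100))
  pred <- c(rep(1, 9), 0, rep(0, 98), 1, 1)
  m <- compute_metrics(truth, pred)
  expect_identical(c(m$TP, m$FN, m$TN, m$FP), c(9L, 1L, 98L, 2L))
  expect_equal(m$Se, 90)
  expect_equal(m$Sp, 98)
  expect_equal(m$Ac, 100 * 107 / 110, tolerance = 1e-10)
  expect_equal(m$BER, 6)

  # the degenerate all-NSH predictor on mixed truth
  m <- compute_metrics(c(1, 1, 0, 0, 0), rep(0, 5))
  expect_equal(m$Se, 0)
  expect_equal(m$Sp, 100)
  expect_equal(m$BER, 50)
})

test_that("BER identity holds on random confusion tables", {
  set.seed(1)
  for (i in 1:50) {
    truth <- rbinom(200, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(200, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(truth, pred)
    expect_identical(m$BER + (m$Se + m$Sp) / 2, 100)
    expect_true(all(c(m$Ac, m$Se, m$Sp, m$BER) >= 0 &
                      c(m$Ac, m$Se, m$Sp, m$BER) <= 100))
  }
})

test_that("metrics handle empty and one-class inputs as specified", {
  expect_error(compute_metrics(integer(), integer()), "empty")
  expect_error(compute_metrics(c(0, 1), c(1, 2)), "0/1")
  expect_warning(m <- compute_metrics(c(0, 0, 0), c(0, 1, 0)), "absent")
  expect_true(is.na(m$Se))
  expect_equal(m$BER, 100 - m$Sp)
})

test_that("record folds are balanced, exhaustive and seeded", {
  plan <- make_record_folds(sprintf("r%02d", 1:17), k = 5, seed = 2)
  sizes <- as.integer(table(plan$assignment))
  expect_identical(sort(sizes, decreasing = TRUE), c(4L, 4L, 3L, 3L, 3L))
  expect_setequal(names(plan$assignment), sprintf("r%02d", 1:17))

  # leave-one-record-out when records == folds
  p5 <- make_record_folds(letters[1:5], k = 5, seed = 1)
  expect_identical(sort(as.integer(table(p5$assignment))), rep(1L, 5))

  expect_identical(make_record_folds(letters[1:9], 3, seed = 7)$assignment,
                   make_record_folds(letters[1:9], 3, seed = 7)$assignment)
  expect_error(make_record_folds(letters[1:3], 5), "fewer records")
})

test_that("no record ever sits on both sides of a split", {
  ids <- rep(sprintf("r%02d", 1:11), times = 3)
  plan <- make_record_folds(ids, k = 4, seed = 9)
  for (fold in 1:4) {
    sp <- shockadvice:::fold_split(plan, ids, fold)
    expect_length(intersect(ids[sp$train], ids[sp$test]), 0L)
    expect_identical(sort(c(sp$train, sp$test)), seq_along(ids))
  }
})

test_that("a single-config grid wins for every scorer and reruns identically", {
  stacks <- tone_stacks()
  grid <- data.frame(Ns = 1, Nd = 1, Lr = 0.005, Mo = 0.9, Re = 0.15)
  res <- grid_search_select(stacks, grid, k = 3, epochs = 2, seed = 4)
  for (w in res$winners) expect_identical(w$grid_row, 1L)
  res2 <- grid_search_select(stacks, grid, k = 3, epochs = 2, seed = 4)
  expect_identical(res$ber_table, res2$ber_table)
  expect_error(grid_search_select(stacks, grid[0, ]), "empty grid")
})

test_that("repeated CV on separable features reports perfect, stable metrics", {
  net <- tiny_trained_net()
  ev <- c(lapply(1:20, function(i)
            make_tone_stack(1L, sprintf("ev%02d", (i %% 10) + 1), 5000 + i)),
          lapply(1:20, function(i)
            make_tone_stack(0L, sprintf("ev%02d", (i %% 10) + 1), 6000 + i)))
  rep1 <- validate_cv(ev, net, classifier_spec("BS"), k = 5, reps = 1,
                      seed = 11)
  expect_identical(rep1$summary$sd, rep(0, 4))

  rep3 <- validate_cv(ev, net, classifier_spec("BS"), k = 5, reps = 3,
                      seed = 11)
  expect_equal(rep3$summary$mean[rep3$summary$metric == "Ac"], 100)
  expect_equal(rep3$summary$mean[rep3$summary$metric == "BER"], 0)
  # aggregation sanity: the mean lies inside the per-rep range
  expect_gte(mean(rep3$per_rep$Ac), min(rep3$per_rep$Ac))
  expect_lte(mean(rep3$per_rep$Ac), max(rep3$per_rep$Ac))
})

test_that("the leakage guard refuses evaluation records seen in training", {
  net <- tiny_trained_net()  # trained on records tr01..tr06
  leaky <- list(make_tone_stack(1L, "tr01", 1), make_tone_stack(0L, "x", 2))
  expect_error(validate_cv(leaky, net, classifier_spec("BS"), k = 2, reps = 1),
               "leakage")
})
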