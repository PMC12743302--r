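test_that("separable state structures are classified perfectly", {
  sm <- state_model(scales = c(WAKE = 1, NREM = 1, REM = 1),
                    dispersion = 0.05, pair_jitter = 0.05)
  tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 20,
                                                       REM = 20),
                                          units_per_area = 3, seed = 6), sm)
  sel <- select_tail(tab, "NREM", "top", 100)
  task <- classification_task(tab, sel, "REM")
  expect_equal(loo_ground_truth(task), 1)
})

test_that("label-independent features yield chance-level accuracy", {
  accs <- vapply(1:15, function(s) {
    sm <- state_model(scales = c(WAKE = 1, NREM = 1, REM = 1),
                      shared_pattern = TRUE)
    tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 14,
                                                         REM = 14),
                                            units_per_area = 3,
                                            seed = 100 + s), sm)
    task <- classification_task(tab, select_tail(tab, "NREM", "top", 100),
                                "REM")
    loo_ground_truth(task)
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("a test epoch duplicating a comparison epoch is misclassified", {
  set.seed(9)
  X <- rbind(matrix(rnorm(10 * 6, mean = 2), 10),
             matrix(rnorm(10 * 6, mean = -2), 10))
  y <- rep(c("NREM", "REM"), each = 10)
  X[1, ] <- X[15, ]  # NREM test epoch carries a REM epoch's features
  acc <- fcdrift:::.loo_accuracy(X, y, test_rows = 1:10)
  expect_equal(acc, 0.9)
})

test_that("degenerate single-class folds are refused", {
  X <- matrix(rnorm(8), 2, 4)
  # holding out the only REM epoch leaves a single-class training fold
  expect_error(fcdrift:::.loo_accuracy(X, c("REM", "NREM"), test_rows = 1),
               "single-class")
})

test_that("distinct structure at matched amplitude is detected by the null", {
  sm <- state_model(scales = c(WAKE = 1, NREM = 1, REM = 1),
                    dispersion = 0.2, pair_jitter = 0.05)
  tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 60,
                                                       REM = 120),
                                          units_per_area = 3, seed = 13), sm)
  task <- classification_task(tab, select_tail(tab, "NREM", "top", 25),
                              "REM")
  res <- stratified_shuffle_null(task, n_shuffles = 100, seed = 2)
  expect_equal(res$ground_truth, 1)
  expect_lt(res$p_value, 0.02)
  expect_false(res$indistinguishable)
  expect_true(all(res$samples >= 0 & res$samples <= 1))
})

test_that("matching failures and bin reduction behave as specified", {
  # comparison state far above the test tail: no epochs in range
  tab <- toy_fc_table(c(rep("NREM", 40), rep("REM", 40)),
                      c(1:40, 200 + 1:40), units_per_area = 3)
  task <- classification_task(tab, select_tail(tab, "NREM", "top", 25),
                              "REM")
  expect_error(stratified_shuffle_null(task, n_shuffles = 10),
               "infeasible matching")

  sm <- state_model(scales = c(WAKE = 1, NREM = 1, REM = 1),
                    shared_pattern = TRUE)
  tab2 <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 16,
                                                        REM = 60),
                                           units_per_area = 3, seed = 21),
                              sm)
  task2 <- classification_task(tab2, select_tail(tab2, "NREM", "top", 25),
                               "REM")
  expect_warning(res <- stratified_shuffle_null(task2, n_shuffles = 20,
                                                n_bins = 10, seed = 3),
                 "bins")
  expect_lte(res$n_bins, max(2, floor(length(task2$test_ids) / 2)))
})

test_that("sufficiency check separates distinct states and not exchangeable ones", {
  distinct <- vapply(1:6, function(s) {
    tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 14,
                                                         REM = 12),
                                            units_per_area = 3,
                                            seed = 300 + s), state_model())
    sufficiency_check(tab, "NREM", "REM", n_shuffles = 60,
                      seed = s)$include
  }, logical(1))
  expect_true(all(distinct))

  same <- vapply(1:10, function(s) {
    sm <- state_model(scales = c(WAKE = 1, NREM = 1, REM = 1),
                      shared_pattern = TRUE)
    tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 14,
                                                         REM = 12),
                                            units_per_area = 3,
                                            seed = 400 + s), sm)
    sufficiency_check(tab, "NREM", "REM", n_shuffles = 60,
                      seed = s)$include
  }, logical(1))
  expect_lte(mean(same), 0.3)  # nominal false-inclusion rate is 5%

  one <- toy_fc_table(c("NREM", "REM", "REM"), c(1, 2, 3))
  expect_error(sufficiency_check(one, "NREM", "REM"), "insufficient data")
})

test_that("extreme-tail control separates strongly shifted states", {
  sm <- state_model(scales = c(WAKE = 1, NREM = 0.45, REM = 1))
  tab <- generate_fc_session(session_spec(n_epochs = c(WAKE = 4, NREM = 100,
                                                       REM = 100),
                                          units_per_area = 3, seed = 17), sm)
  res <- control_extremes(tab, "NREM", "REM", n_shuffles = 60, seed = 2)
  expect_equal(res$accuracy, 1)
  expect_true(res$include)
  # with 5 epochs per class the shuffled accuracies live on a 0.1 grid
  expect_true(all(abs(res$samples * 10 - round(res$samples * 10)) < 1e-9))
})

test_that("Fisher combination reproduces the printed worked examples", {
  a <- fisher_combine(c(0.69, 0.582, 0.436, 0.742))
  expect_equal(round(a$statistic, 2), 4.08)
  expect_equal(round(a$p_combined, 2), 0.85)
  b <- fisher_combine(c(0.412, 0.003, 0.111, 0.63))
  expect_equal(round(b$statistic, 2), 18.71)
  expect_equal(round(b$p_combined, 2), 0.02)
  c2 <- fisher_combine(c(1, 1))
  expect_equal(c2$statistic, 0)
  expect_equal(c2$p_combined, 1)
  expect_warning(z <- fisher_combine(c(0, 0.5)), "clamped")
  expect_lt(z$p_combined, 1e-100)
  g <- fisher_combine(c(0.1, 0.2, 0.3, 0.4), by = c("a", "a", "b", "b"))
  expect_equal(nrow(g$per_group), 2)
  expect_equal(g$per_group$statistic[g$per_group$group == "a"],
               -2 * (log(0.1) + log(0.2)))
})

test_that("power resampling behaves at its boundary cases", {
  set.seed(8)
  nulls <- replicate(3, runif(200, 0.3, 0.6), simplify = FALSE)
  pw <- power_resample(nulls, n_reps = 300, seed = 5)
  # thresholds sit at each null's 95th percentile, so every surrogate
  # session is just significant and the combination is powered
  expect_equal(pw$thresholds,
               vapply(nulls, quantile, numeric(1), probs = 0.95,
                      names = FALSE, type = 7))
  expect_gt(pw$power, 0.9)
  expect_true(pw$proceed)
  expect_error(power_resample(list(rep(0.5, 100))), "degenerate null")
})
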