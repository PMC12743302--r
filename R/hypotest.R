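#' Feature matrix of directed inter-areal FC values
#'
#' One row per epoch, one column per directed inter-areal unit pair —
#' the feature representation used by all classifiers.
#'
#' @param table A `session_fc_table`.
#' @return Numeric matrix with epoch ids as rownames and `src->tgt` pair
#'   labels as colnames.
#' @export
fc_features <- function(table) {
  rows <- table[table$src_area != table$tgt_area, , drop = FALSE]
  stopifnot(nrow(rows) > 0)
  pair <- paste0(rows$src_unit, "->", rows$tgt_unit)
  epochs <- sort(unique(rows$epoch_id))
  pairs <- unique(pair)
  X <- matrix(NA_real_, length(epochs), length(pairs),
              dimnames = list(epochs, pairs))
  X[cbind(match(rows$epoch_id, epochs), match(pair, pairs))] <- rows$fc
  stopifnot(!anyNA(X))  # every epoch must carry the same pair set
  X
}

#' Assemble a classification task
#'
#' Bundles the test-epoch set (a tail selection of state A), the
#' comparison-epoch set (state B), their directed inter-areal FC feature
#' vectors, labels and epoch-mean aiFC values.
#'
#' @param table A `session_fc_table`.
#' @param test_sel A [select_tail()] result (state-A tail epochs).
#' @param comparison_state The state-B label.
#' @return An object of class `classification_task`: `X`, `labels`,
#'   `aifc`, `test_ids`, `comparison_ids`, `test_state`,
#'   `comparison_state`.
#' @export
classification_task <- function(table, test_sel, comparison_state) {
  stopifnot(inherits(test_sel, "tail_selection"))
  ea <- epoch_aifc(table)
  comp_ids <- ea$epoch_id[ea$state == comparison_state]
  stopifnot(length(comp_ids) > 0, length(test_sel$epoch_ids) > 0)
  ids <- c(test_sel$epoch_ids, comp_ids)
  X <- fc_features(table)
  X <- X[match(as.character(ids), rownames(X)), , drop = FALSE]
  labels <- c(rep(test_sel$state, length(test_sel$epoch_ids)),
              rep(comparison_state, length(comp_ids)))
  structure(list(X = X, labels = labels,
                 aifc = ea$aifc[match(ids, ea$epoch_id)],
                 test_ids = test_sel$epoch_ids, comparison_ids = comp_ids,
                 test_state = test_sel$state,
                 comparison_state = comparison_state),
            class = "classification_task")
}

# linear maximum-margin classifier with training-fold standardization
.fit_margin <- function(X, y) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  model <- e1071::svm(Xs, factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
  list(model = model, mu = mu, sd = sd)
}

.predict_margin <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
  as.character(stats::predict(fit$model, Xs))
}

# modified leave-one-out: only epochs at `test_rows` are individually held
# out and scored against `truth`; training uses `train_labels` for the
# remaining epochs (equal to `truth` except under label shuffling)
.loo_accuracy <- function(X, truth, test_rows, train_labels = truth) {
  correct <- vapply(test_rows, function(i) {
    y_train <- train_labels[-i]
    if (length(unique(y_train)) < 2)
      stop("degenerate fold: training labels are single-class")
    fit <- .fit_margin(X[-i, , drop = FALSE], y_train)
    .predict_margin(fit, X[i, , drop = FALSE]) == truth[i]
  }, logical(1))
  mean(correct)
}

#' Ground-truth accuracy of the modified leave-one-out classifier
#'
#' Each test epoch (state-A tail epoch) is held out in turn; a linear
#' support vector machine (cost 1, features standardized with
#' training-fold statistics) is trained on all remaining task epochs and
#' predicts the held-out epoch. Accuracy is the fraction of test epochs
#' assigned their true state; comparison epochs are never scored.
#'
#' @param task A [classification_task()].
#' @return Scalar accuracy in `[0, 1]`.
#' @export
loo_ground_truth <- function(task) {
  stopifnot(inherits(task, "classification_task"),
            length(task$test_ids) >= 2,
            length(task$comparison_ids) >= 1)
  n_test <- length(task$test_ids)
  .loo_accuracy(task$X, task$labels, seq_len(n_test))
}

#' Stratified label-shuffle null for the modified LOO classifier
#'
#' Matches the N test epochs with N comparison epochs whose aiFC lies
#' within the range of the test epochs' aiFC values, then repeatedly
#' permutes state labels within equipopulated aiFC bins of the matched
#' comparison distribution (so the null preserves magnitude matching and
#' destroys only pair-level structure), recomputing the modified LOO
#' accuracy each time. The p-value is the fraction of shuffled accuracies
#' strictly greater than the ground-truth accuracy computed on the same
#' matched task; when the ground truth does not exceed the null's 95th
#' percentile the epoch structure is declared indistinguishable between
#' the two states (the H1/H2 outcome).
#'
#' @param task A [classification_task()].
#' @param n_shuffles Number of label permutations.
#' @param n_bins Number of equipopulated aiFC bins (reduced to
#'   `max(2, floor(N/2))` with a warning when N is small).
#' @param seed Integer RNG seed.
#' @param p_correction `"none"` uses the strict fraction; `"add_one"`
#'   uses `(k+1)/(n+1)` to avoid exact zeros.
#' @return An object of class `null_result`: `ground_truth`, `samples`,
#'   `upper95`, `p_value`, `indistinguishable`, `matched_ids`, `n_bins`.
#' @export
stratified_shuffle_null <- function(task, n_shuffles = 1000, n_bins = 10,
                                    seed = 1L,
                                    p_correction = c("none", "add_one")) {
  p_correction <- match.arg(p_correction)
  stopifnot(inherits(task, "classification_task"))
  n <- length(task$test_ids)
  stopifnot(n >= 2)
  set.seed(seed)

  test_rows <- seq_len(n)
  comp_rows <- n + seq_along(task$comparison_ids)
  rng <- range(task$aifc[test_rows])
  in_range <- comp_rows[task$aifc[comp_rows] >= rng[1] &
                          task$aifc[comp_rows] <= rng[2]]
  if (length(in_range) < n)
    stop(sprintf(
      "infeasible matching: %d comparison epochs within the test aiFC range, need %d",
      length(in_range), n))
  matched <- if (length(in_range) == n) in_range else sample(in_range, n)

  rows <- c(test_rows, matched)
  X <- task$X[rows, , drop = FALSE]
  truth <- task$labels[rows]
  aifc <- task$aifc[rows]

  if (n < n_bins) {
    n_bins <- max(2L, floor(n / 2))
    warning(sprintf("fewer test epochs than bins; using %d bins", n_bins))
  }
  # equipopulated bins over the matched comparison aiFC distribution
  edges <- stats::quantile(aifc[-seq_len(n)],
                           probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7)
  bin <- findInterval(aifc, edges[-c(1, n_bins + 1)]) + 1L

  ground_truth <- .loo_accuracy(X, truth, seq_len(n))

  samples <- vapply(seq_len(n_shuffles), function(s) {
    perm <- truth
    for (b in unique(bin)) {
      members <- which(bin == b)
      if (length(members) > 1) perm[members] <- sample(perm[members])
    }
    .loo_accuracy(X, truth, seq_len(n), train_labels = perm)
  }, numeric(1))

  k <- sum(samples > ground_truth)
  p <- if (p_correction == "add_one") (k + 1) / (n_shuffles + 1)
       else k / n_shuffles
  upper95 <- stats::quantile(samples, 0.95, type = 7, names = FALSE)
  structure(list(ground_truth = ground_truth, samples = samples,
                 upper95 = upper95, p_value = p,
                 indistinguishable = ground_truth <= upper95,
                 matched_ids = task$comparison_ids[matched - n],
                 n_bins = n_bins, seed = seed),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "<null_result> ground truth %.3f vs null 95%% bound %.3f (%d shuffles)\n",
    x$ground_truth, x$upper95, length(x$samples)))
  cat(sprintf("  p = %.4g -> structure %s\n", x$p_value,
              if (x$indistinguishable) "indistinguishable (supports H1/H2)"
              else "distinguishable (H0 retained)"))
  invisible(x)
}

#' Epoch-sufficiency check for a pair of states
#'
#' Trains the classifier on all epochs of two states and scores every
#' epoch by leave-one-out; the ground-truth accuracy is compared with the
#' 95th percentile of accuracies from classifiers trained on
#' label-shuffled data. Sessions (state pairs) whose accuracy does not
#' exceed chance are flagged for exclusion: they lack the epochs needed to
#' resolve FC structure at all, so a negative H1/H2 outcome there would be
#' uninterpretable.
#'
#' @param table A `session_fc_table`.
#' @param state_a,state_b The two states.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer RNG seed.
#' @return List: `accuracy`, `upper95`, `samples`, `include`.
#' @export
sufficiency_check <- function(table, state_a, state_b, n_shuffles = 200,
                              seed = 1L) {
  ea <- epoch_aifc(table)
  ids <- ea$epoch_id[ea$state %in% c(state_a, state_b)]
  labels <- ea$state[match(ids, ea$epoch_id)]
  if (min(table(labels)) < 2)
    stop("insufficient data: need at least 2 epochs per state")
  X <- fc_features(table)
  X <- X[match(as.character(ids), rownames(X)), , drop = FALSE]
  set.seed(seed)
  all_rows <- seq_along(ids)
  accuracy <- .loo_accuracy(X, labels, all_rows)
  samples <- vapply(seq_len(n_shuffles), function(s) {
    .loo_accuracy(X, labels, all_rows, train_labels = sample(labels))
  }, numeric(1))
  upper95 <- stats::quantile(samples, 0.95, type = 7, names = FALSE)
  list(accuracy = accuracy, upper95 = upper95, samples = samples,
       include = accuracy > upper95)
}

#' Control classification of extreme tails
#'
#' Discriminates the bottom-5% aiFC epochs of state A from the top-5%
#' epochs of state B — the epochs assumed to differ most. Failure to
#' separate them (ground truth inside the two-sided 95% shuffled interval)
#' indicates insufficient sample size or estimator noise, and the session
#' is flagged for exclusion.
#'
#' @param table A `session_fc_table`.
#' @param state_a,state_b Bottom-tail and top-tail states.
#' @param pct Tail size in percent.
#' @param n_shuffles Number of label permutations.
#' @param seed Integer RNG seed.
#' @return List: `accuracy`, `lower`, `upper` (2.5th/97.5th percentiles of
#'   the shuffled accuracies), `samples`, `include` (`TRUE` when the
#'   ground truth lies outside the interval).
#' @export
control_extremes <- function(table, state_a, state_b, pct = 5,
                             n_shuffles = 200, seed = 1L) {
  bot <- select_tail(table, state_a, "bottom", pct)
  top <- select_tail(table, state_b, "top", pct)
  if (length(bot$epoch_ids) == 0 || length(top$epoch_ids) == 0)
    stop("empty tail: no epochs in the requested percentile")
  ids <- c(bot$epoch_ids, top$epoch_ids)
  labels <- rep(c(state_a, state_b),
                c(length(bot$epoch_ids), length(top$epoch_ids)))
  X <- fc_features(table)
  X <- X[match(as.character(ids), rownames(X)), , drop = FALSE]
  set.seed(seed)
  all_rows <- seq_along(ids)
  accuracy <- .loo_accuracy(X, labels, all_rows)
  samples <- vapply(seq_len(n_shuffles), function(s) {
    .loo_accuracy(X, labels, all_rows, train_labels = sample(labels))
  }, numeric(1))
  qs <- stats::quantile(samples, c(0.025, 0.975), type = 7, names = FALSE)
  list(accuracy = accuracy, lower = qs[1], upper = qs[2], samples = samples,
       include = accuracy < qs[1] || accuracy > qs[2])
}

#' Combine session p-values with Fisher's method
#'
#' `statistic = -2 * sum(log(p))` referred to a chi-square distribution
#' with `2k` degrees of freedom. Zero p-values are clamped to the smallest
#' representable double with a warning. With a `by` grouping (e.g. animal
#' ids) per-group combinations are reported alongside.
#'
#' @param p_values Numeric vector of per-session p-values in `(0, 1]`.
#' @param by Optional grouping vector (same length) for per-group
#'   combination.
#' @return An object of class `combined_result`: `p_values`, `statistic`,
#'   `df`, `p_combined`, and `per_group` (data.frame) when `by` is given.
#' @export
#' @examples
#' fisher_combine(c(0.69, 0.582, 0.436, 0.742))
fisher_combine <- function(p_values, by = NULL) {
  stopifnot(length(p_values) >= 1, all(p_values >= 0), all(p_values <= 1))
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to the smallest representable double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  statistic <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  out <- list(p_values = p_values, statistic = statistic, df = df,
              p_combined = stats::pchisq(statistic, df, lower.tail = FALSE))
  if (!is.null(by)) {
    stopifnot(length(by) == length(p_values))
    per_group <- do.call(rbind, lapply(split(p_values, by), function(pg) {
      s <- -2 * sum(log(pg))
      data.frame(statistic = s, df = 2 * length(pg),
                 p_combined = stats::pchisq(s, 2 * length(pg),
                                            lower.tail = FALSE))
    }))
    per_group$group <- rownames(per_group)
    rownames(per_group) <- NULL
    out$per_group <- per_group[c("group", "statistic", "df", "p_combined")]
  }
  structure(out, class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf("<combined_result> Fisher statistic %.2f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_combined))
  if (!is.null(x$per_group)) {
    cat("  per group:\n")
    print(x$per_group, row.names = FALSE)
  }
  invisible(x)
}

#' Resampling-based power analysis over recording sessions
#'
#' Estimates the power of the Fisher meta-analysis from pilot sessions'
#' shuffled-accuracy null distributions. For each pilot session the
#' accuracy at the null's 95th percentile (the accuracy corresponding to a
#' p-value of .05 in that session) becomes its detection threshold. Each
#' surrogate dataset samples `n_target_sessions` sessions with
#' replacement; for every sampled session its null is bootstrap-resampled
#' and the p-value of the source session's threshold accuracy under the
#' resampled null is computed; the per-session p-values are Fisher
#' combined. Power is the fraction of surrogate datasets whose combined
#' p-value is below `alpha`.
#'
#' @param nulls List of numeric vectors: the pilot sessions'
#'   shuffled-accuracy samples.
#' @param n_target_sessions Sessions per surrogate dataset.
#' @param n_reps Number of surrogate datasets.
#' @param alpha Detection level.
#' @param seed Integer RNG seed.
#' @return List: `power`, `thresholds`, `proceed` (`TRUE` when power
#'   exceeds 80%).
#' @export
power_resample <- function(nulls, n_target_sessions = 7, n_reps = 1000,
                           alpha = 0.05, seed = 1L) {
  stopifnot(is.list(nulls), length(nulls) >= 1)
  for (nu in nulls) {
    stopifnot(is.numeric(nu), length(nu) >= 2)
    if (max(nu) == min(nu))
      stop("degenerate null: all shuffled accuracies identical")
  }
  thresholds <- vapply(nulls, function(nu)
    stats::quantile(nu, 0.95, type = 7, names = FALSE), numeric(1))
  set.seed(seed)
  hits <- vapply(seq_len(n_reps), function(r) {
    sess <- sample(length(nulls), n_target_sessions, replace = TRUE)
    ps <- vapply(sess, function(k) {
      boot <- sample(nulls[[k]], length(nulls[[k]]), replace = TRUE)
      max(mean(boot > thresholds[k]), 1 / (length(boot) + 1))
    }, numeric(1))
    fisher_combine(ps)$p_combined < alpha
  }, logical(1))
  list(power = mean(hits), thresholds = thresholds,
       proceed = mean(hits) > 0.8)
}
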