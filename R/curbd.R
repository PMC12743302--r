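#' Convert a spike raster to a smoothed, normalized rate matrix
#'
#' Bins spikes of every unit in `[t0, t1)`, convolves the counts with a
#' Gaussian kernel, converts to rates and normalizes each unit to
#' `[-1, 1]` (max-abs) so that the traces live in the range of the
#' saturating odd-symmetric nonlinearity used by the rate network. Units
#' with no spikes in the window stay identically zero.
#'
#' @param raster A `spike_raster`.
#' @param t0,t1 Epoch window (s), half-open.
#' @param bin_ms Bin width (ms).
#' @param sigma_ms Gaussian smoothing width (ms); `0` disables smoothing.
#' @param unit_ids Units to include (default all units of the raster).
#' @param normalize `"global"` (default) scales all traces by the single
#'   maximum absolute rate so relative amplitudes across units are kept;
#'   `"unit"` rescales each unit to `[-1, 1]` independently; `"none"`
#'   leaves rates in Hz.
#' @return An object of class `rate_matrix`: `rates` (units x bins),
#'   `units` (data.frame subset of the raster's unit table), `bin_ms`,
#'   `sigma_ms`, `t0`, `t1`, `norm_factors`.
#' @export
spikes_to_rates <- function(raster, t0, t1, bin_ms = 10, sigma_ms = 50,
                            unit_ids = raster$units$unit_id,
                            normalize = c("global", "unit", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(t1 > t0, t0 >= 0, t1 <= raster$duration_s + 1e-9)
  n_bins <- floor((t1 - t0) * 1000 / bin_ms + 1e-9)
  stopifnot(n_bins >= 2)
  edges <- t0 + seq(0, n_bins) * bin_ms / 1000
  sp <- raster$spikes
  sp <- sp[sp$time_s >= t0 & sp$time_s < edges[n_bins + 1] &
             sp$unit_id %in% unit_ids, , drop = FALSE]
  counts <- matrix(0, nrow = length(unit_ids), ncol = n_bins)
  if (nrow(sp)) {
    ui <- match(sp$unit_id, unit_ids)
    bi <- pmin(n_bins, findInterval(sp$time_s, edges))
    for (k in seq_along(ui)) counts[ui[k], bi[k]] <- counts[ui[k], bi[k]] + 1
  }
  if (sigma_ms > 0) {
    half <- max(1L, ceiling(3 * sigma_ms / bin_ms))
    kern <- stats::dnorm(seq(-half, half) * bin_ms, sd = sigma_ms)
    kern <- kern / sum(kern)
    counts <- t(apply(counts, 1, function(row) {
      # pad by reflection so kernel mass is conserved at the edges
      padded <- c(rev(row[seq_len(half)]), row, rev(row)[seq_len(half)])
      stats::filter(padded, kern, sides = 2)[half + seq_len(n_bins)]
    }))
  }
  rates <- counts * (1000 / bin_ms)  # Hz
  norm <- rep(1, nrow(rates))
  if (normalize == "unit") {
    norm <- apply(abs(rates), 1, max)
    nz <- norm > 0
    rates[nz, ] <- rates[nz, , drop = FALSE] / norm[nz]
  } else if (normalize == "global") {
    m <- max(abs(rates))
    if (m > 0) {
      rates <- rates / m
      norm <- rep(m, nrow(rates))
    }
  }
  units <- raster$units[match(unit_ids, raster$units$unit_id), , drop = FALSE]
  structure(list(rates = rates, units = units, bin_ms = bin_ms,
                 sigma_ms = sigma_ms, t0 = t0, t1 = t1,
                 norm_factors = norm),
            class = "rate_matrix")
}

#' Hyperparameters of the data-constrained rate network
#'
#' @param tau_ms Time constant of the model units (ms).
#' @param dt_ms Integration step; defaults to the rate-matrix bin width
#'   when `NULL`.
#' @param g0 Scale of the random initial interaction matrix
#'   (`g0/sqrt(N)` entries).
#' @param ridge Regularization constant of the recursive least-squares
#'   update (initial inverse-correlation matrix is `I/ridge`).
#' @param n_passes Number of training passes through the epoch.
#' @param nonlinearity Saturating odd-symmetric unit nonlinearity
#'   (`"tanh"` is the only built-in).
#' @return An object of class `rnn_hyperparams`.
#' @export
rnn_hyperparams <- function(tau_ms = 20, dt_ms = NULL, g0 = 1.5,
                            ridge = 1, n_passes = 30,
                            nonlinearity = "tanh") {
  stopifnot(tau_ms > 0, is.null(dt_ms) || dt_ms > 0, g0 >= 0, ridge > 0,
            n_passes >= 1, nonlinearity == "tanh")
  structure(list(tau_ms = tau_ms, dt_ms = dt_ms, g0 = g0, ridge = ridge,
                 n_passes = n_passes, nonlinearity = nonlinearity),
            class = "rnn_hyperparams")
}

#' Fit a single-layer recurrent network to one epoch of population rates
#'
#' One model unit per recorded unit. The interaction matrix `J` is trained
#' by recursive least squares: at every time step the model runs forward
#' from its own state, the mismatch between model rates and the recorded
#' rates is used to update all rows of `J` with a shared inverse
#' correlation matrix, and passes through the epoch are repeated until the
#' model reproduces the data. Goodness of fit is summarized as
#' `pVar = 1 - ||data - model||_F^2 / ||data - mean(data)||_F^2`.
#'
#' @param rates A [spikes_to_rates()] result (or any `rate_matrix`).
#' @param hyper An [rnn_hyperparams()].
#' @param seed Integer RNG seed (controls the random initial `J`).
#' @return An object of class `fitted_rnn`: `J` (units x units,
#'   `J[i, j]` = interaction j -> i), `r_model` (reproduced rates),
#'   `pvar`, `pvar_per_pass`, `units`, `hyper`, `seed`.
#' @export
fit_rnn <- function(rates, hyper = rnn_hyperparams(), seed = 1L) {
  stopifnot(inherits(rates, "rate_matrix") || is.matrix(rates$rates))
  A <- rates$rates
  n <- nrow(A)
  n_t <- ncol(A)
  stopifnot(n >= 2, n_t >= 2, all(is.finite(A)))
  dt <- if (is.null(hyper$dt_ms)) rates$bin_ms else hyper$dt_ms
  alpha <- dt / hyper$tau_ms

  set.seed(seed)
  J <- matrix(stats::rnorm(n * n, sd = hyper$g0 / sqrt(n)), n, n)
  P <- diag(n) / hyper$ridge
  # targets clipped into the open range of tanh for a finite inverse
  x0 <- atanh(pmax(pmin(A[, 1], 1 - 1e-6), -1 + 1e-6))
  ss_tot <- sum((A - rowMeans(A))^2)
  if (ss_tot == 0) ss_tot <- .Machine$double.eps

  run_model <- function(J) {
    x <- x0
    R <- matrix(0, n, n_t)
    R[, 1] <- tanh(x)
    for (t in seq_len(n_t - 1)) {
      x <- x + alpha * (-x + J %*% R[, t])
      R[, t + 1] <- tanh(x)
    }
    R
  }

  pvar_per_pass <- numeric(hyper$n_passes)
  for (pass in seq_len(hyper$n_passes)) {
    x <- x0
    r <- tanh(x)
    err_fit <- 0
    for (t in seq_len(n_t - 1)) {
      x <- x + alpha * (-x + drop(J %*% r))
      r_new <- tanh(x)
      e <- r_new - A[, t + 1]
      err_fit <- err_fit + sum(e^2)
      Pr <- drop(P %*% r)
      denom <- 1 + sum(r * Pr)
      P <- P - tcrossprod(Pr) / denom
      J <- J - tcrossprod(e, Pr / denom)
      if (!all(is.finite(J)))
        stop(sprintf("non-finite interaction matrix during training (pass %d, step %d)",
                     pass, t))
      r <- r_new
    }
    # pVar of the learning-mode trajectory of this pass (first bin is the
    # initial condition and matches by construction)
    pvar_per_pass[pass] <- 1 - err_fit / ss_tot
  }

  r_model <- run_model(J)
  pvar <- 1 - sum((A - r_model)^2) / ss_tot
  structure(list(J = J, r_model = r_model, pvar = pvar,
                 pvar_per_pass = pvar_per_pass,
                 units = rates$units, bin_ms = rates$bin_ms,
                 hyper = hyper, seed = seed),
            class = "fitted_rnn")
}

#' @export
print.fitted_rnn <- function(x, ...) {
  cat(sprintf("<fitted_rnn> %d units x %d bins, pVar = %.3f (seed %d)\n",
              nrow(x$J), ncol(x$r_model), x$pvar, x$seed))
  invisible(x)
}

#' Decompose the fitted model into directed source-to-target currents
#'
#' The drive that source unit `j` delivers to target unit `i` at time `t`
#' is `J[i, j] * r_j(t)`; summing over all sources of a target recovers the
#' model's total recurrent input to that unit exactly. Self-terms are
#' excluded from the pairwise listing.
#'
#' @param model A [fit_rnn()] result.
#' @param rates Rate traces to propagate through `J` (defaults to the
#'   model's reproduced activity).
#' @return An object of class `current_series`: `pairs` (data.frame
#'   `src`, `tgt`, `src_area`, `tgt_area` if areas are known), `currents`
#'   (pairs x time matrix), `units`.
#' @export
decompose_currents <- function(model, rates = NULL) {
  stopifnot(inherits(model, "fitted_rnn"))
  R <- if (is.null(rates)) model$r_model
       else if (inherits(rates, "rate_matrix")) rates$rates
       else rates
  n <- nrow(model$J)
  stopifnot(nrow(R) == n)
  idx <- which(diag(n) == 0, arr.ind = TRUE)  # all ordered pairs i != j
  tgt <- idx[, 1]; src <- idx[, 2]
  cur <- model$J[cbind(tgt, src)] * R[src, , drop = FALSE]
  pairs <- data.frame(src = src, tgt = tgt)
  if (!is.null(model$units) && "area" %in% names(model$units)) {
    pairs$src_area <- model$units$area[src]
    pairs$tgt_area <- model$units$area[tgt]
    pairs$src_unit <- model$units$unit_id[src]
    pairs$tgt_unit <- model$units$unit_id[tgt]
  }
  structure(list(pairs = pairs, currents = cur, units = model$units),
            class = "current_series")
}

#' Epoch-level FC magnitude per directed pair
#'
#' Collapses each directed source-to-target current trace to a scalar FC
#' magnitude: the time average of the absolute current over the epoch.
#'
#' @param currents A [decompose_currents()] result.
#' @param by `"unit"` for one row per directed unit pair, `"area"` for the
#'   mean FC over unit pairs within each directed area pair.
#' @return A data.frame with the pair identifiers and an `fc` column.
#' @export
epoch_fc <- function(currents, by = c("unit", "area")) {
  by <- match.arg(by)
  stopifnot(inherits(currents, "current_series"),
            ncol(currents$currents) >= 1)
  fc <- rowMeans(abs(currents$currents))
  out <- cbind(currents$pairs, fc = fc)
  if (by == "area") {
    stopifnot(!is.null(out$src_area))
    agg <- stats::aggregate(fc ~ src_area + tgt_area, data = out, FUN = mean)
    return(agg[order(agg$src_area, agg$tgt_area), ])
  }
  out
}

#' Repeated-fit validation of the estimator against a known network
#'
#' Repeats unit subsampling, rate conversion, network fitting and current
#' decomposition on a raster produced by the spiking model, collects the
#' FC magnitude of every (undirected) region pair per run, and compares
#' the R1-R2 pair against all other pairs with a one-way ANOVA and Tukey
#' post-hoc contrasts. A run whose fit fails is logged and resampled with
#' a fresh seed.
#'
#' @param raster A `spike_raster` from [simulate_network()].
#' @param t0,t1 Analysis window (s).
#' @param n_runs Number of estimator repetitions.
#' @param units_per_area Units sampled per area (among units active in the
#'   window).
#' @param resample_units If `TRUE` (default) a fresh unit sample is drawn
#'   on every run, so the per-pair FC distributions average over unit
#'   choice as well as estimator stochasticity; `FALSE` fixes one sample
#'   and isolates the estimator's own run-to-run variability.
#' @param seed Integer RNG seed.
#' @param hyper An [rnn_hyperparams()].
#' @param bin_ms,sigma_ms Rate-conversion parameters.
#' @return An object of class `recovery_report`: `fc` (long data.frame
#'   `run`, `pair`, `fc`), `anova_p`, `tukey` (data.frame `comparison`,
#'   `diff`, `p_adj`), `max_p_r1r2` (largest Tukey p among comparisons
#'   involving R1-R2), `chosen_units`, `n_failed`.
#' @export
validate_recovery <- function(raster, t0, t1, n_runs = 200,
                              units_per_area = 1, resample_units = TRUE,
                              seed = 1L,
                              hyper = rnn_hyperparams(),
                              bin_ms = 10, sigma_ms = 50) {
  stopifnot(n_runs >= 2)
  set.seed(seed)
  areas <- sort(unique(raster$units$area))
  sp <- raster$spikes
  active <- unique(sp$unit_id[sp$time_s >= t0 & sp$time_s < t1])
  pools <- lapply(areas, function(a) {
    pool <- intersect(raster$units$unit_id[raster$units$area == a], active)
    if (length(pool) < units_per_area)
      stop(sprintf("area %d has only %d active units in the window", a,
                   length(pool)))
    pool
  })
  draw_units <- function() unlist(lapply(pools, sample, units_per_area))
  chosen <- draw_units()
  rates <- spikes_to_rates(raster, t0, t1, bin_ms = bin_ms,
                           sigma_ms = sigma_ms, unit_ids = chosen)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  n_failed <- 0L
  rows <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    if (resample_units && k > 1) {
      chosen <- draw_units()
      rates <- spikes_to_rates(raster, t0, t1, bin_ms = bin_ms,
                               sigma_ms = sigma_ms, unit_ids = chosen)
    }
    fit <- NULL
    s <- run_seeds[k]
    while (is.null(fit)) {
      fit <- tryCatch(fit_rnn(rates, hyper, seed = s), error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        s <- sample.int(.Machine$integer.max, 1)
      }
    }
    afc <- epoch_fc(decompose_currents(fit), by = "area")
    afc <- afc[afc$src_area != afc$tgt_area, ]
    pr <- paste0("R", pmin(afc$src_area, afc$tgt_area), "-R",
                 pmax(afc$src_area, afc$tgt_area))
    agg <- tapply(afc$fc, pr, mean)  # undirected region pair
    rows[[k]] <- data.frame(run = k, pair = names(agg),
                            fc = as.numeric(agg))
  }
  fc <- do.call(rbind, rows)
  fc$pair <- factor(fc$pair)
  fit_aov <- stats::aov(fc ~ pair, data = fc)
  anova_p <- summary(fit_aov)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit_aov)$pair
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  involves <- grepl("R1-R2", tukey$comparison, fixed = TRUE)
  structure(list(fc = fc, anova_p = anova_p, tukey = tukey,
                 max_p_r1r2 = max(tukey$p_adj[involves]),
                 mean_fc = sort(tapply(fc$fc, fc$pair, mean),
                                decreasing = TRUE),
                 chosen_units = chosen, n_failed = n_failed, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d runs, ANOVA p = %.3g\n",
              max(x$fc$run), x$anova_p))
  cat("  mean FC by region pair:\n")
  print(round(x$mean_fc, 4))
  cat(sprintf("  max Tukey p among R1-R2 comparisons: %.3g\n", x$max_p_r1r2))
  invisible(x)
}
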