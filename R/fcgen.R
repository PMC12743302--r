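#' State-dependent FC generating model
#'
#' Describes how directed inter-areal FC magnitudes are generated per brain
#' state: a per-pair pattern vector (the "structure"), a state-level
#' coupling scale (the "amplitude"; NREM below WAKE/REM by default,
#' matching the expected global drop of inter-areal coupling in NREM), a
#' lognormal epoch-level noise (one scalar per epoch plus independent
#' per-pair jitter, giving nonnegative magnitudes with a heavy right tail
#' and therefore overlapping cross-state distributions), a fraction of
#' state-atypical epochs whose full generating pattern is swapped with the
#' partner state's while the label is kept, and a state-invariant
#' intra-areal component.
#'
#' Pattern vectors are drawn once per state when the model is realized
#' against a session layout (see [generate_fc_session()]); `pattern_sd = 0`
#' or `shared_pattern = TRUE` makes the structure identical across states,
#' which renders equally-scaled states exchangeable.
#'
#' @param scales Named state-level coupling scales.
#' @param dispersion SD of the epoch-level lognormal noise (log scale).
#' @param pair_jitter SD of the per-pair lognormal jitter (log scale).
#' @param f_atypical Named per-state probability that an epoch is generated
#'   by the partner state (NREM swaps with REM and vice versa).
#' @param intra_scale State-invariant intra-areal coupling scale.
#' @param pattern_sd SD (log scale) of the per-pair pattern values.
#' @param shared_pattern If `TRUE` all states share one pattern vector.
#' @return An object of class `state_model`.
#' @export
state_model <- function(scales = c(WAKE = 1, NREM = 0.6, REM = 0.9),
                        dispersion = 0.3, pair_jitter = 0.25,
                        f_atypical = c(WAKE = 0, NREM = 0, REM = 0),
                        intra_scale = 1, pattern_sd = 0.4,
                        shared_pattern = FALSE) {
  stopifnot(all(scales > 0), dispersion >= 0, pair_jitter >= 0,
            all(f_atypical >= 0 & f_atypical <= 1), intra_scale > 0,
            pattern_sd >= 0,
            all(c("WAKE", "NREM", "REM") %in% names(scales)))
  structure(list(scales = scales, dispersion = dispersion,
                 pair_jitter = pair_jitter, f_atypical = f_atypical,
                 intra_scale = intra_scale, pattern_sd = pattern_sd,
                 shared_pattern = shared_pattern),
            class = "state_model")
}

#' Session layout for the synthetic generator
#'
#' @param n_epochs Named per-state epoch counts (5-s epochs).
#' @param units_per_area Units recorded per area.
#' @param n_areas Number of areas.
#' @param stim_epochs Integer ids of epochs carrying sound stimulation.
#' @param animal_id,session_id Metadata labels.
#' @param seed Integer RNG seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_epochs = c(WAKE = 60, NREM = 100, REM = 40),
                         units_per_area = 4, n_areas = 4,
                         stim_epochs = integer(0),
                         animal_id = "sim1", session_id = "s1",
                         seed = 1L) {
  stopifnot(all(n_epochs >= 0), units_per_area >= 1, n_areas >= 2,
            all(c("WAKE", "NREM", "REM") %in% names(n_epochs)))
  structure(list(n_epochs = n_epochs, units_per_area = units_per_area,
                 n_areas = n_areas, stim_epochs = as.integer(stim_epochs),
                 animal_id = animal_id, session_id = session_id,
                 seed = as.integer(seed)),
            class = "session_spec")
}

.swap_state <- c(WAKE = "WAKE", NREM = "REM", REM = "NREM")

#' Generate a labeled multi-state session of epoch-wise FC values
#'
#' Bypasses spiking simulation and draws a session FC table directly from
#' the generating model: each epoch's directed-pair FC vector is the
#' generating state's pattern times its coupling scale times lognormal
#' epoch noise. With probability `f_atypical[state]` an epoch keeps its
#' label but is generated from the partner state (REM-like epochs inside
#' NREM and vice versa). The ground-truth generating state is always
#' recorded so recovery is checkable.
#'
#' @param spec A [session_spec()].
#' @param model A [state_model()].
#' @return A `data.frame` of class `session_fc_table` with one row per
#'   (epoch, directed unit pair): `epoch_id`, `state`, `gt_state`,
#'   `stim_flag`, `n_active`, `src_unit`, `src_area`, `tgt_unit`,
#'   `tgt_area`, `fc`. Session metadata is attached as attributes
#'   (`animal_id`, `session_id`, `units_per_area`, `n_areas`, `seed`).
#' @export
#' @examples
#' tab <- generate_fc_session(session_spec(seed = 7), state_model())
#' head(tab)
generate_fc_session <- function(spec, model = state_model()) {
  stopifnot(inherits(spec, "session_spec"), inherits(model, "state_model"))
  set.seed(spec$seed)
  n_units <- spec$units_per_area * spec$n_areas
  unit_area <- rep(seq_len(spec$n_areas), each = spec$units_per_area)
  pairs <- expand.grid(src = seq_len(n_units), tgt = seq_len(n_units))
  pairs <- pairs[pairs$src != pairs$tgt, ]
  pairs$src_area <- unit_area[pairs$src]
  pairs$tgt_area <- unit_area[pairs$tgt]
  inter <- pairs$src_area != pairs$tgt_area
  n_pairs <- nrow(pairs)

  states <- c("WAKE", "NREM", "REM")
  base <- exp(stats::rnorm(n_pairs, sd = model$pattern_sd))
  patterns <- lapply(states, function(s) {
    if (model$shared_pattern) return(base)
    exp(stats::rnorm(n_pairs, sd = model$pattern_sd))
  })
  names(patterns) <- states
  intra_pattern <- exp(stats::rnorm(n_pairs, sd = model$pattern_sd))

  labels <- rep(states, spec$n_epochs[states])
  n_total <- length(labels)
  labels <- sample(labels)  # interleave states over the session timeline
  rows <- vector("list", n_total)
  for (e in seq_len(n_total)) {
    lab <- labels[e]
    gt <- lab
    if (stats::runif(1) < model$f_atypical[[lab]]) gt <- .swap_state[[lab]]
    noise <- exp(stats::rnorm(1, sd = model$dispersion) +
                   stats::rnorm(n_pairs, sd = model$pair_jitter))
    fc <- ifelse(inter,
                 patterns[[gt]] * model$scales[[gt]],
                 intra_pattern * model$intra_scale) * noise
    rows[[e]] <- data.frame(
      epoch_id = e, state = lab, gt_state = gt,
      stim_flag = e %in% spec$stim_epochs,
      n_active = n_units,
      src_unit = pairs$src, src_area = pairs$src_area,
      tgt_unit = pairs$tgt, tgt_area = pairs$tgt_area,
      fc = fc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "animal_id") <- spec$animal_id
  attr(out, "session_id") <- spec$session_id
  attr(out, "units_per_area") <- spec$units_per_area
  attr(out, "n_areas") <- spec$n_areas
  attr(out, "seed") <- spec$seed
  class(out) <- c("session_fc_table", "data.frame")
  out
}

#' Generate a spiking session with state-scaled inter-areal coupling
#'
#' Runs the four-area spiking network piecewise-stationary: the session is
#' a sequence of labeled state blocks and all inter-areal synaptic weights
#' are multiplied by the state's gain within its block. Epoch boundaries
#' fall every `epoch_s` seconds.
#'
#' @param schedule data.frame with columns `state` and `duration_s` (each
#'   duration should be a multiple of `epoch_s`).
#' @param gains Named per-state multipliers of the inter-areal weights.
#' @param connectome A [build_connectome()] result (a default-architecture
#'   realization is sampled from `seed` when `NULL`).
#' @param seed Integer RNG seed.
#' @param epoch_s Epoch length (s).
#' @param ... Passed to [simulate_network()].
#' @return List with `raster` (a `spike_raster`) and `epochs` (data.frame
#'   `epoch_id`, `t_start_s`, `state`).
#' @export
generate_spiking_session <- function(schedule,
                                     gains = c(WAKE = 1, NREM = 0.5, REM = 0.9),
                                     connectome = NULL, seed = 1L,
                                     epoch_s = 5, ...) {
  stopifnot(all(c("state", "duration_s") %in% names(schedule)),
            all(schedule$state %in% names(gains)),
            all(schedule$duration_s > 0))
  if (is.null(connectome)) connectome <- build_connectome(seed = seed)
  t_start <- cumsum(c(0, schedule$duration_s[-nrow(schedule)]))
  gain_schedule <- data.frame(t_start_s = t_start,
                              gain = unname(gains[schedule$state]))
  duration_s <- sum(schedule$duration_s)
  raster <- simulate_network(connectome, duration_s = duration_s,
                             seed = seed, gain_schedule = gain_schedule, ...)
  n_epochs <- floor(duration_s / epoch_s)
  starts <- (seq_len(n_epochs) - 1) * epoch_s
  block <- findInterval(starts, t_start)
  epochs <- data.frame(epoch_id = seq_len(n_epochs), t_start_s = starts,
                       state = schedule$state[block])
  list(raster = raster, epochs = epochs)
}
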