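#' @useDynLib fcdrift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Single-neuron parameters for one cell class
#'
#' Leaky integrate-and-fire parameters of one cell class (excitatory
#' pyramidal or inhibitory PV-like). Defaults are layer-2/3 V1 values from
#' the Allen cell-type database.
#'
#' @param C_m Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param t_ref Absolute refractory period (ms).
#' @param V_rest Resting potential (mV).
#' @param V_th Firing threshold (mV).
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' neuron_params_E()
neuron_params <- function(C_m, g_L, t_ref, V_rest, V_th) {
  stopifnot(C_m > 0, g_L > 0, t_ref >= 0, V_th > V_rest)
  structure(list(C_m = C_m, g_L = g_L, t_ref = t_ref,
                 V_rest = V_rest, V_th = V_th,
                 t_m = C_m / g_L),
            class = "neuron_params")
}

#' @rdname neuron_params
#' @export
neuron_params_E <- function() {
  neuron_params(C_m = 123.41, g_L = 2.47, t_ref = 3,
                V_rest = -80.97, V_th = -40.53)
}

#' @rdname neuron_params
#' @export
neuron_params_I <- function() {
  neuron_params(C_m = 70.95, g_L = 9.49, t_ref = 1.26,
                V_rest = -82.35, V_th = -56.32)
}

#' Synaptic kinetics and background drive
#'
#' Receptor time constants, reversal potentials, unit conductances, and the
#' rates of the background Poisson AMPA drive received by every cell
#' (roughly one thousand external afferents firing at about 1 and 1.5
#' spikes/s for E and I cells respectively).
#'
#' @param tau_AMPA,tau_GABA Gating time constants (ms).
#' @param V_E Excitatory reversal potential (mV).
#' @param g_AMPA,g_GABA Receptor conductances (nS; unity by construction).
#' @param u_bkgnd_E,u_bkgnd_I Background Poisson rates (Hz) for E and I
#'   cells.
#' @return An object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_AMPA = 2, tau_GABA = 5, V_E = 0,
                             g_AMPA = 1, g_GABA = 1,
                             u_bkgnd_E = 930, u_bkgnd_I = 1460) {
  stopifnot(tau_AMPA > 0, tau_GABA > 0, u_bkgnd_E >= 0, u_bkgnd_I >= 0)
  structure(list(tau_AMPA = tau_AMPA, tau_GABA = tau_GABA, V_E = V_E,
                 g_AMPA = g_AMPA, g_GABA = g_GABA,
                 u_bkgnd_E = u_bkgnd_E, u_bkgnd_I = u_bkgnd_I),
            class = "synapse_kinetics")
}

#' Four-area network architecture
#'
#' Wiring statistics of the four-area model: 5000 neurons split over four
#' areas, 85% excitatory per area, within-area group-to-group connection
#' probabilities and strengths (layer-2/3 V1 values), and inter-areal
#' excitatory-to-excitatory single-synapse strengths taken from
#' experimental mesoscale connectivity, with the R1-R2 pair one order of
#' magnitude stronger than every other pair.
#'
#' `P_within` and `S_within` are 2x2 matrices indexed `[source, target]`
#' over groups `c("E", "I")`. `W_between` is the 4x4 matrix of single
#' E-to-E synapse strengths `[source area, target area]` (diagonal unused),
#' multiplied by the global constant `G_between`.
#'
#' @param n_total Total neuron count across areas.
#' @param n_areas Number of areas.
#' @param frac_exc Fraction of excitatory neurons per area.
#' @param P_within Within-area connection probability matrix.
#' @param S_within Within-area group strength matrix.
#' @param G_within Within-area global coupling factor.
#' @param W_between Inter-areal E-to-E single-synapse strength matrix.
#' @param G_between Inter-areal global strength constant.
#' @param p_between Inter-areal E-to-E connection probability.
#' @return An object of class `architecture`.
#' @export
#' @examples
#' arch <- architecture()
#' arch$W_between[1, 2] / arch$W_between[3, 4]  # R1->R2 dominance
architecture <- function(n_total = 5000, n_areas = 4, frac_exc = 0.85,
                         P_within = matrix(c(0.16, 0.411, 0.395, 0.451), 2, 2,
                                           dimnames = list(c("E", "I"),
                                                           c("E", "I"))),
                         S_within = matrix(c(0.36, 0.48, 0.149, 0.68), 2, 2,
                                           dimnames = list(c("E", "I"),
                                                           c("E", "I"))),
                         G_within = 5,
                         W_between = matrix(c(NA, 1.34e-3, 6.37e-5, 1.29e-4,
                                              6.93e-4, NA, 5.61e-4, 2.67e-4,
                                              3.68e-5, 3.17e-4, NA, 1.47e-4,
                                              7.16e-5, 2.84e-4, 9.33e-5, NA),
                                            4, 4),
                         G_between = 50, p_between = 0.3) {
  stopifnot(n_total %% n_areas == 0,
            all(P_within >= 0 & P_within <= 1),
            p_between >= 0, p_between <= 1,
            frac_exc > 0, frac_exc < 1,
            nrow(W_between) == n_areas)
  n_per <- n_total / n_areas
  n_E <- floor(frac_exc * n_per)  # floor for E, remainder to I
  structure(list(n_total = n_total, n_areas = n_areas, frac_exc = frac_exc,
                 n_E_per_area = n_E, n_I_per_area = n_per - n_E,
                 P_within = P_within, S_within = S_within,
                 G_within = G_within, W_between = W_between,
                 G_between = G_between, p_between = p_between),
            class = "architecture")
}

#' Single-synapse weight from group-level statistics
#'
#' The weight of every realized synapse between two connected groups is the
#' overall group strength `s_hat`, scaled by the global coupling factor and
#' normalized by the expected number of afferents, `G * s_hat / (n_send *
#' p)`. The normalization keeps the equilibria of the network invariant to
#' its size: doubling the sending population exactly halves the weight.
#'
#' @param G Global coupling factor.
#' @param s_hat Overall strength between the two connected groups.
#' @param n_send Number of neurons in the sending population.
#' @param p Connection probability between the two groups.
#' @return Scalar synaptic weight.
#' @export
#' @examples
#' synaptic_weight(5, 0.36, 1062, 0.16)
synaptic_weight <- function(G, s_hat, n_send, p) {
  if (any(n_send < 1) || any(p <= 0))
    stop("undefined normalization: n_send must be >= 1 and p > 0")
  G * s_hat / (n_send * p)
}

#' Sample a connectome realization
#'
#' Draws the synaptic weight matrix of the four-area network: within each
#' area, Bernoulli wiring per (source group, target group) pair at the
#' probabilities of `arch$P_within` with weights from [synaptic_weight()];
#' between areas, only excitatory-to-excitatory synapses at probability
#' `arch$p_between` with weights `G_between * W_between[src, tgt]`.
#' Inhibitory neurons never project outside their own area. Self-synapses
#' are excluded.
#'
#' @param arch An [architecture()].
#' @param seed Integer RNG seed (recorded in the result).
#' @return An object of class `connectome` with elements `W` (sparse
#'   `n_total x n_total` matrix, `W[i, j]` = weight of synapse j -> i,
#'   negative for inhibitory sources), `units` (data.frame: `unit_id`,
#'   `area`, `type`), `arch`, `seed`.
#' @export
build_connectome <- function(arch = architecture(), seed = 1L) {
  stopifnot(inherits(arch, "architecture"))
  n_per <- arch$n_total / arch$n_areas
  nE <- arch$n_E_per_area
  nI <- arch$n_I_per_area
  units <- data.frame(
    unit_id = seq_len(arch$n_total),
    area = rep(seq_len(arch$n_areas), each = n_per),
    type = rep(rep(c("E", "I"), c(nE, nI)), arch$n_areas),
    stringsAsFactors = FALSE)

  set.seed(seed)
  src_list <- list()
  tgt_list <- list()
  w_list <- list()
  k <- 0L
  idx_of <- function(area, grp) {
    base <- (area - 1L) * n_per
    if (grp == "E") base + seq_len(nE) else base + nE + seq_len(nI)
  }
  # within-area wiring, one Bernoulli block per (source group, target group)
  for (a in seq_len(arch$n_areas)) {
    for (sg in c("E", "I")) {
      for (tg in c("E", "I")) {
        src <- idx_of(a, sg)
        tgt <- idx_of(a, tg)
        p <- arch$P_within[sg, tg]
        if (p <= 0) next
        w <- synaptic_weight(arch$G_within, arch$S_within[sg, tg],
                             length(src), p)
        hit <- which(stats::runif(length(src) * length(tgt)) < p)
        if (!length(hit)) next
        si <- src[(hit - 1L) %/% length(tgt) + 1L]
        ti <- tgt[(hit - 1L) %% length(tgt) + 1L]
        keep <- si != ti
        k <- k + 1L
        src_list[[k]] <- si[keep]
        tgt_list[[k]] <- ti[keep]
        w_list[[k]] <- rep(if (sg == "I") -w else w, sum(keep))
      }
    }
  }
  # inter-areal wiring: excitatory sources only
  for (a in seq_len(arch$n_areas)) {
    for (b in seq_len(arch$n_areas)) {
      if (a == b) next
      src <- idx_of(a, "E")
      tgt <- idx_of(b, "E")
      w <- arch$G_between * arch$W_between[a, b]
      hit <- which(stats::runif(length(src) * length(tgt)) < arch$p_between)
      if (!length(hit)) next
      k <- k + 1L
      src_list[[k]] <- src[(hit - 1L) %/% length(tgt) + 1L]
      tgt_list[[k]] <- tgt[(hit - 1L) %% length(tgt) + 1L]
      w_list[[k]] <- rep(w, length(hit))
    }
  }
  W <- Matrix::sparseMatrix(i = unlist(tgt_list), j = unlist(src_list),
                            x = unlist(w_list),
                            dims = c(arch$n_total, arch$n_total))
  structure(list(W = W, units = units, arch = arch, seed = seed),
            class = "connectome")
}

#' Current-injection protocol
#'
#' A constant external current applied to every neuron of one area during a
#' time window.
#'
#' @param target_area Area index receiving the current.
#' @param amplitude_pA Current amplitude (pA); 30 pA by default.
#' @param onset_s,offset_s Injection window (s).
#' @param excitatory_only If `TRUE`, only excitatory cells of the area are
#'   driven; by default all neurons of the area receive the current.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target_area, amplitude_pA = 30,
                              onset_s, offset_s, excitatory_only = FALSE) {
  stopifnot(offset_s > onset_s, amplitude_pA >= 0)
  structure(list(target_area = target_area, amplitude_pA = amplitude_pA,
                 onset_s = onset_s, offset_s = offset_s,
                 excitatory_only = excitatory_only),
            class = "stimulus_protocol")
}

#' Simulate the spiking network
#'
#' Integrates the conductance-based LIF dynamics of a sampled connectome
#' with forward Euler at `dt_ms` resolution: exponential AMPA/GABA gating,
#' per-neuron background Poisson AMPA drive at the rate of its cell class,
#' threshold-reset-refractory handling with spike detection at the end of
#' each step, and an optional constant current injection. Initial membrane
#' potentials are drawn uniformly in `[V_rest, V_th)` to avoid startup
#' synchrony.
#'
#' @param connectome A [build_connectome()] result.
#' @param duration_s Simulated time (s).
#' @param stimulus A [stimulus_protocol()] or `NULL`.
#' @param seed Integer RNG seed.
#' @param kinetics A [synapse_kinetics()].
#' @param params_E,params_I [neuron_params()] for the two cell classes.
#' @param dt_ms Integration step (ms).
#' @param gain_schedule Optional data.frame (`t_start_s`, `gain`) giving a
#'   piecewise-constant multiplier applied to all inter-areal synapses
#'   (used for state-scaled sessions); `NULL` keeps the static network.
#' @return An object of class `spike_raster`: data.frame `spikes`
#'   (`unit_id`, `time_s`), data.frame `units` (`unit_id`, `area`, `type`),
#'   plus `duration_s`, `dt_ms` and `seed` records.
#' @export
simulate_network <- function(connectome, duration_s, stimulus = NULL,
                             seed = 1L,
                             kinetics = synapse_kinetics(),
                             params_E = neuron_params_E(),
                             params_I = neuron_params_I(),
                             dt_ms = 0.1,
                             gain_schedule = NULL) {
  stopifnot(inherits(connectome, "connectome"), duration_s > 0)
  units <- connectome$units
  n <- nrow(units)
  is_E <- units$type == "E"
  pick <- function(field) {
    ifelse(is_E, params_E[[field]], params_I[[field]])
  }
  u_bk <- ifelse(is_E, kinetics$u_bkgnd_E, kinetics$u_bkgnd_I)

  stim_amp <- numeric(n)
  stim_on <- 0; stim_off <- 0
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_protocol"))
    in_area <- units$area == stimulus$target_area
    if (stimulus$excitatory_only) in_area <- in_area & is_E
    stim_amp[in_area] <- stimulus$amplitude_pA
    stim_on <- stimulus$onset_s
    stim_off <- stimulus$offset_s
  }

  W <- methods::as(connectome$W, "CsparseMatrix")
  # flag inter-areal edges for the optional state gain
  src_area <- units$area[rep(seq_len(n), diff(W@p))]
  tgt_area <- units$area[W@i + 1L]
  edge_scaled <- src_area != tgt_area

  if (is.null(gain_schedule)) {
    gain_t <- 0; gain_v <- 1
  } else {
    stopifnot(all(c("t_start_s", "gain") %in% names(gain_schedule)))
    o <- order(gain_schedule$t_start_s)
    gain_t <- gain_schedule$t_start_s[o]
    gain_v <- gain_schedule$gain[o]
  }

  set.seed(seed)
  v_rest <- pick("V_rest")
  v_th <- pick("V_th")
  v0 <- v_rest + stats::runif(n) * (v_th - v_rest)

  out <- .sim_lif_cpp(W@i, W@p, W@x, edge_scaled,
                      pick("C_m"), pick("g_L"), v_rest, v_th, pick("t_ref"),
                      u_bk,
                      kinetics$tau_AMPA, kinetics$tau_GABA,
                      kinetics$V_E, v_rest,
                      kinetics$g_AMPA, kinetics$g_GABA,
                      dt_ms, duration_s,
                      stim_amp, stim_on, stim_off,
                      gain_t, gain_v, v0)
  spikes <- data.frame(unit_id = out$unit_id, time_s = out$time_s)
  structure(list(spikes = spikes, units = units,
                 duration_s = duration_s, dt_ms = dt_ms, seed = seed),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes from %d units over %.3f s (dt %.2g ms)\n",
              nrow(x$spikes), nrow(x$units), x$duration_s, x$dt_ms))
  rate <- nrow(x$spikes) / nrow(x$units) / x$duration_s
  cat(sprintf("  mean rate %.2f Hz, seed %d\n", rate, x$seed))
  invisible(x)
}

#' Mean firing rate per area within a window
#'
#' @param raster A `spike_raster`.
#' @param t0,t1 Window bounds (s); defaults to the whole raster.
#' @return Named numeric vector of mean per-unit rates (Hz) per area.
#' @export
area_rates <- function(raster, t0 = 0, t1 = raster$duration_s) {
  sp <- raster$spikes
  sp <- sp[sp$time_s >= t0 & sp$time_s < t1, , drop = FALSE]
  area_of <- raster$units$area[match(sp$unit_id, raster$units$unit_id)]
  counts <- tabulate(area_of, nbins = max(raster$units$area))
  n_units <- tabulate(raster$units$area, nbins = max(raster$units$area))
  stats::setNames(counts / n_units / (t1 - t0),
                  paste0("R", seq_along(counts)))
}
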