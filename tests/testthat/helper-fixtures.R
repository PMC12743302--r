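# shared fixtures, memoized so expensive simulations run once per session
.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# default full-size connectome (Tables 2-5 regime)
default_connectome <- function() {
  .memo("default_connectome", function() build_connectome(architecture(),
                                                          seed = 42))
}

# full-size raster: 2 s with 30 pA into R1 from t = 1 s
demo_raster <- function() {
  .memo("demo_raster", function() {
    simulate_network(default_connectome(), duration_s = 2,
                     stimulus = stimulus_protocol(1, 30, onset_s = 1,
                                                  offset_s = 2),
                     seed = 7)
  })
}

small_arch <- function(n_total = 1000) architecture(n_total = n_total)

# minimal session FC table with one inter-areal pair per epoch and
# hand-chosen per-epoch FC values
toy_fc_table <- function(states, values, stim = rep(FALSE, length(states)),
                         n_active = 2, units_per_area = 3) {
  n <- length(states)
  df <- data.frame(epoch_id = seq_len(n), state = states,
                   gt_state = states, stim_flag = stim,
                   n_active = n_active,
                   src_unit = 1L, src_area = 1L,
                   tgt_unit = 2L, tgt_area = 2L,
                   fc = values, stringsAsFactors = FALSE)
  attr(df, "animal_id") <- "toy"
  attr(df, "session_id") <- "toy"
  attr(df, "units_per_area") <- units_per_area
  attr(df, "n_areas") <- 4L
  attr(df, "seed") <- 0L
  class(df) <- c("session_fc_table", "data.frame")
  df
}

# rate_matrix wrapper for hand-built matrices
as_rate_matrix <- function(m, bin_ms = 10) {
  structure(list(rates = m, units = NULL, bin_ms = bin_ms, sigma_ms = 0,
                 t0 = 0, t1 = ncol(m) * bin_ms / 1000,
                 norm_factors = rep(1, nrow(m))),
            class = "rate_matrix")
}

# fitted_rnn wrapper for hand-built interaction matrices
as_fitted_rnn <- function(J, r_model, units = NULL) {
  structure(list(J = J, r_model = r_model, pvar = NA_real_,
                 pvar_per_pass = numeric(0), units = units,
                 bin_ms = 10, hyper = rnn_hyperparams(), seed = 0L),
            class = "fitted_rnn")
}
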