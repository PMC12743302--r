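.format_version <- "1"

#' Read and write spike rasters as TSV
#'
#' Tab-separated serialization of a `spike_raster`: a `#`-prefixed header
#' records the format version, duration, integration step and seed,
#' followed by columns `unit_id`, `area`, `type`, `time_s` (one row per
#' spike; silent units still appear in the unit table section encoded as
#' `time_s = NA`).
#'
#' @param raster A `spike_raster`.
#' @param path Output/input file path.
#' @return `write_raster_tsv` returns `path` invisibly;
#'   `read_raster_tsv` returns a `spike_raster`.
#' @export
write_raster_tsv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  hdr <- sprintf("#fcdrift_raster\tversion=%s\tduration_s=%.10g\tdt_ms=%.10g\tseed=%d",
                 .format_version, raster$duration_s, raster$dt_ms,
                 raster$seed)
  sp <- raster$spikes
  u <- raster$units
  df <- data.frame(unit_id = c(u$unit_id, sp$unit_id),
                   area = c(u$area, u$area[match(sp$unit_id, u$unit_id)]),
                   type = c(u$type, u$type[match(sp$unit_id, u$unit_id)]),
                   time_s = c(rep(NA_real_, nrow(u)), sp$time_s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#fcdrift_raster"))
    stop("not a raster TSV (missing #fcdrift_raster header)")
  fields <- strsplit(sub("^#fcdrift_raster\t", "", hdr), "\t")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (meta[["version"]] != .format_version)
    stop(sprintf("raster format version %s not supported (expected %s)",
                 meta[["version"]], .format_version))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  need <- c("unit_id", "area", "type", "time_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("raster TSV missing column(s): %s",
                 paste(missing, collapse = ", ")))
  units <- unique(df[is.na(df$time_s), c("unit_id", "area", "type")])
  units <- units[order(units$unit_id), ]
  rownames(units) <- NULL
  spikes <- df[!is.na(df$time_s), c("unit_id", "time_s")]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, units = units,
                 duration_s = as.numeric(meta[["duration_s"]]),
                 dt_ms = as.numeric(meta[["dt_ms"]]),
                 seed = as.integer(meta[["seed"]])),
            class = "spike_raster")
}

#' Read and write session FC tables as TSV
#'
#' @param table A `session_fc_table`.
#' @param path Output/input file path.
#' @return `write_fc_table` returns `path` invisibly; `read_fc_table`
#'   returns a `session_fc_table`.
#' @export
write_fc_table <- function(table, path) {
  hdr <- sprintf(
    "#fcdrift_fc\tversion=%s\tanimal_id=%s\tsession_id=%s\tunits_per_area=%d\tn_areas=%d\tseed=%d",
    .format_version, attr(table, "animal_id"), attr(table, "session_id"),
    attr(table, "units_per_area"), attr(table, "n_areas"),
    attr(table, "seed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#fcdrift_fc"))
    stop("not an FC table TSV (missing #fcdrift_fc header)")
  fields <- strsplit(sub("^#fcdrift_fc\t", "", hdr), "\t")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (meta[["version"]] != .format_version)
    stop(sprintf("FC table format version %s not supported (expected %s)",
                 meta[["version"]], .format_version))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE)
  need <- c("epoch_id", "state", "src_unit", "src_area", "tgt_unit",
            "tgt_area", "fc")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("FC table missing column(s): %s",
                 paste(missing, collapse = ", ")))
  attr(df, "animal_id") <- meta[["animal_id"]]
  attr(df, "session_id") <- meta[["session_id"]]
  attr(df, "units_per_area") <- as.integer(meta[["units_per_area"]])
  attr(df, "n_areas") <- as.integer(meta[["n_areas"]])
  attr(df, "seed") <- as.integer(meta[["seed"]])
  class(df) <- c("session_fc_table", "data.frame")
  df
}

#' Read an epoch-label TSV
#'
#' Columns `epoch_id`, `t_start_s`, `state` with states in
#' WAKE/NREM/REM/UND; undefined (UND) epochs — transitional epochs whose
#' state markers were inconsistent — are dropped with a message.
#'
#' @param path Input file path.
#' @return data.frame of the retained epochs.
#' @export
read_epoch_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("epoch_id", "t_start_s", "state")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("epoch label TSV missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- !df$state %in% c("WAKE", "NREM", "REM", "UND")
  if (any(bad))
    stop(sprintf("unknown state label(s): %s",
                 paste(unique(df$state[bad]), collapse = ", ")))
  n_und <- sum(df$state == "UND")
  if (n_und > 0)
    message(sprintf("dropping %d UND epoch(s)", n_und))
  df[df$state != "UND", , drop = FALSE]
}

#' Append epoch FC rows from a fitted epoch to a session table
#'
#' Converts the unit-pair FC magnitudes of one fitted epoch into
#' `session_fc_table` rows.
#'
#' @param fit A [fit_rnn()] result for one epoch.
#' @param epoch_id,state,stim_flag Epoch annotation.
#' @return data.frame of rows in `session_fc_table` column layout.
#' @export
epoch_fc_rows <- function(fit, epoch_id, state, stim_flag = FALSE) {
  fc <- epoch_fc(decompose_currents(fit), by = "unit")
  data.frame(epoch_id = epoch_id, state = state, gt_state = NA_character_,
             stim_flag = stim_flag, n_active = nrow(fit$J),
             src_unit = fc$src_unit, src_area = fc$src_area,
             tgt_unit = fc$tgt_unit, tgt_area = fc$tgt_area,
             fc = fc$fc, stringsAsFactors = FALSE)
}

#' Estimate epoch-wise FC for a whole labeled session
#'
#' Runs the full estimation chain per epoch: spike binning and smoothing,
#' recurrent-network fit, current decomposition, and epoch-averaged
#' directed pair FC magnitudes, assembled into a `session_fc_table`.
#' Epochs in which fewer than two of the selected units fire are emitted
#' with `n_active` recording the deficit so the exclusion rules can drop
#' them downstream (their FC values are zero).
#'
#' @param raster A `spike_raster`.
#' @param epochs data.frame `epoch_id`, `t_start_s`, `state` (e.g. from
#'   [generate_spiking_session()] or [read_epoch_labels()]).
#' @param unit_ids Units to include.
#' @param epoch_s Epoch length (s).
#' @param hyper An [rnn_hyperparams()].
#' @param bin_ms,sigma_ms Rate-conversion parameters.
#' @param stim_epochs Epoch ids flagged as stimulation epochs.
#' @param seed Integer RNG seed.
#' @param animal_id,session_id Metadata labels.
#' @return A `session_fc_table`.
#' @export
estimate_session_fc <- function(raster, epochs, unit_ids, epoch_s = 5,
                                hyper = rnn_hyperparams(),
                                bin_ms = 10, sigma_ms = 50,
                                stim_epochs = integer(0), seed = 1L,
                                animal_id = "sim", session_id = "s1") {
  stopifnot(all(c("epoch_id", "t_start_s", "state") %in% names(epochs)))
  set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, nrow(epochs))
  sp <- raster$spikes
  rows <- vector("list", nrow(epochs))
  for (k in seq_len(nrow(epochs))) {
    t0 <- epochs$t_start_s[k]
    t1 <- t0 + epoch_s
    rates <- spikes_to_rates(raster, t0, t1, bin_ms = bin_ms,
                             sigma_ms = sigma_ms, unit_ids = unit_ids)
    n_active <- sum(rowSums(abs(rates$rates)) > 0)
    if (n_active >= 2) {
      fit <- fit_rnn(rates, hyper, seed = fit_seeds[k])
      r <- epoch_fc_rows(fit, epochs$epoch_id[k], epochs$state[k],
                         epochs$epoch_id[k] %in% stim_epochs)
    } else {
      # too few firing units to fit: zero FC placeholder rows
      fit <- NULL
      n_units <- length(unit_ids)
      grid <- expand.grid(src = seq_len(n_units), tgt = seq_len(n_units))
      grid <- grid[grid$src != grid$tgt, ]
      area <- raster$units$area[match(unit_ids, raster$units$unit_id)]
      r <- data.frame(epoch_id = epochs$epoch_id[k],
                      state = epochs$state[k], gt_state = NA_character_,
                      stim_flag = epochs$epoch_id[k] %in% stim_epochs,
                      n_active = n_active,
                      src_unit = unit_ids[grid$src], src_area = area[grid$src],
                      tgt_unit = unit_ids[grid$tgt], tgt_area = area[grid$tgt],
                      fc = 0, stringsAsFactors = FALSE)
    }
    r$n_active <- n_active
    rows[[k]] <- r
  }
  out <- do.call(rbind, rows)
  attr(out, "animal_id") <- animal_id
  attr(out, "session_id") <- session_id
  attr(out, "units_per_area") <- length(unit_ids) %/%
    length(unique(raster$units$area))
  attr(out, "n_areas") <- length(unique(raster$units$area))
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("session_fc_table", "data.frame")
  out
}

#' Run the full within-state structure test for one session
#'
#' End-to-end H1/H2 engine for one session table: exclusion rules,
#' state-magnitude gate, percentile tail selection with the cross-state
#' guard at each cutoff, modified LOO classification and the stratified
#' shuffle null. For H1 the focal state's top tails are guarded by the
#' comparison state's 5th percentile; for H2 the focal state's bottom
#' tails are guarded by the comparison state's 95th percentile.
#'
#' @param table A `session_fc_table`.
#' @param focal_state State whose tail epochs are tested (NREM for H1,
#'   REM for H2).
#' @param comparison_state State providing the comparison epochs.
#' @param side `"top"` (H1) or `"bottom"` (H2).
#' @param cutoffs Tail percentiles to test.
#' @param n_shuffles Shuffles per cutoff.
#' @param seed Integer RNG seed.
#' @return An object of class `hypothesis_result`: `magnitude` (the
#'   [state_magnitude_test()] output), `per_cutoff` (list of
#'   `null_result`s or skip reasons), `p_values` (named per cutoff),
#'   `session_id`, `animal_id`.
#' @export
run_structure_test <- function(table, focal_state, comparison_state,
                               side = c("top", "bottom"),
                               cutoffs = c(25, 15, 5), n_shuffles = 1000,
                               seed = 1L) {
  side <- match.arg(side)
  excl <- apply_exclusions(table)
  if (nrow(excl$table) == 0)
    return(structure(list(magnitude = NULL, per_cutoff = list(),
                          p_values = numeric(0), excluded = TRUE,
                          report = excl$report,
                          session_id = attr(table, "session_id"),
                          animal_id = attr(table, "animal_id")),
                     class = "hypothesis_result"))
  tab <- excl$table
  mag <- state_magnitude_test(tab)
  guard_pct <- if (side == "top") 5 else 95
  per_cutoff <- list()
  p_values <- stats::setNames(rep(NA_real_, length(cutoffs)),
                              paste0("pct", cutoffs))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(cutoffs))
  for (k in seq_along(cutoffs)) {
    sel <- select_tail(tab, focal_state, side, cutoffs[k],
                       guard_state = comparison_state,
                       guard_pct = guard_pct)
    if (length(sel$epoch_ids) < 2) {
      per_cutoff[[k]] <- list(skipped = "empty tail after guard")
      next
    }
    task <- classification_task(tab, sel, comparison_state)
    res <- tryCatch(
      stratified_shuffle_null(task, n_shuffles = n_shuffles,
                              seed = sub_seeds[k]),
      error = function(e) list(skipped = conditionMessage(e)))
    per_cutoff[[k]] <- res
    if (inherits(res, "null_result")) p_values[k] <- res$p_value
  }
  names(per_cutoff) <- paste0("pct", cutoffs)
  structure(list(magnitude = mag, per_cutoff = per_cutoff,
                 p_values = p_values, excluded = !mag$include,
                 report = excl$report,
                 session_id = attr(table, "session_id"),
                 animal_id = attr(table, "animal_id")),
            class = "hypothesis_result")
}

#' Write an analysis report as JSON
#'
#' Serializes hypothesis/combined results with a format-version field.
#'
#' @param x A result object (list-like).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  payload <- list(format_version = .format_version,
                  generated_by = "fcdrift",
                  result = unclass(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
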