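#' Apply the session and epoch exclusion rules
#'
#' Drops, in order and with disjoint attribution: (1) the whole session if
#' it holds fewer than 10 units in total; (2) epochs in which fewer than
#' two units were firing; (3) epochs with sound stimulation together with
#' both adjacent epochs; (4) the whole session if no FC value anywhere is
#' positive (no observable inter-areal communication).
#'
#' @param table A `session_fc_table` (see [generate_fc_session()]).
#' @param min_units Minimum total unit count for a session.
#' @param min_active Minimum number of firing units per epoch.
#' @return List with `table` (filtered, possibly zero rows) and `report`
#'   (data.frame `rule`, `dropped_epochs`, `dropped_session`).
#' @export
apply_exclusions <- function(table, min_units = 10, min_active = 2) {
  rules <- c("session_lt_min_units", "epoch_lt_min_active",
             "stimulation_adjacent", "session_no_fc")
  report <- data.frame(rule = rules, dropped_epochs = 0L,
                       dropped_session = FALSE)
  empty <- table[0, , drop = FALSE]

  n_units <- attr(table, "units_per_area")
  n_areas <- attr(table, "n_areas")
  total_units <- if (!is.null(n_units) && !is.null(n_areas))
    n_units * n_areas else length(unique(c(table$src_unit, table$tgt_unit)))
  if (total_units < min_units) {
    report$dropped_session[1] <- TRUE
    report$dropped_epochs[1] <- length(unique(table$epoch_id))
    return(list(table = empty, report = report))
  }

  epoch_info <- unique(table[c("epoch_id", "stim_flag", "n_active")])
  bad_active <- epoch_info$epoch_id[epoch_info$n_active < min_active]
  report$dropped_epochs[2] <- length(bad_active)
  keep <- setdiff(epoch_info$epoch_id, bad_active)

  stim <- epoch_info$epoch_id[epoch_info$stim_flag]
  stim_zone <- intersect(unique(c(stim - 1L, stim, stim + 1L)), keep)
  report$dropped_epochs[3] <- length(stim_zone)
  keep <- setdiff(keep, stim_zone)

  out <- table[table$epoch_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0 || !any(out$fc > 0)) {
    report$dropped_session[4] <- TRUE
    report$dropped_epochs[4] <- length(keep)
    out <- empty
  }
  attributes(out)[c("animal_id", "session_id", "units_per_area",
                    "n_areas", "seed")] <-
    attributes(table)[c("animal_id", "session_id", "units_per_area",
                        "n_areas", "seed")]
  class(out) <- class(table)
  list(table = out, report = report)
}

#' Epoch-mean FC over a pair scope
#'
#' Averages the directed-pair FC values of one epoch over inter-areal
#' pairs (the global aiFC value of that epoch), intra-areal pairs, or a
#' restriction to an area subset (e.g. excluding the hippocampus: pairs
#' touching an excluded area are removed from the mean).
#'
#' @param table A `session_fc_table`.
#' @param epoch_id Epoch to summarize.
#' @param scope `"inter"` or `"intra"`.
#' @param areas Areas to keep (default all).
#' @return Scalar mean FC.
#' @export
mean_aifc <- function(table, epoch_id, scope = c("inter", "intra"),
                      areas = NULL) {
  scope <- match.arg(scope)
  rows <- table[table$epoch_id == epoch_id, , drop = FALSE]
  if (nrow(rows) == 0) stop(sprintf("epoch %s not present", epoch_id))
  sel <- if (scope == "inter") rows$src_area != rows$tgt_area
         else rows$src_area == rows$tgt_area
  if (!is.null(areas))
    sel <- sel & rows$src_area %in% areas & rows$tgt_area %in% areas
  if (!any(sel)) stop("empty pair scope for this epoch")
  mean(rows$fc[sel])
}

#' Epoch-level aiFC summary of a session table
#'
#' One row per epoch with its label and epoch-mean inter-areal FC; the
#' working representation for all epoch-level statistics.
#'
#' @inheritParams mean_aifc
#' @return data.frame `epoch_id`, `state`, `gt_state` (when present),
#'   `aifc`.
#' @export
epoch_aifc <- function(table, scope = c("inter", "intra"), areas = NULL) {
  scope <- match.arg(scope)
  sel <- if (scope == "inter") table$src_area != table$tgt_area
         else table$src_area == table$tgt_area
  if (!is.null(areas))
    sel <- sel & table$src_area %in% areas & table$tgt_area %in% areas
  rows <- table[sel, , drop = FALSE]
  stopifnot(nrow(rows) > 0)
  agg <- stats::aggregate(fc ~ epoch_id + state, data = rows, FUN = mean)
  names(agg)[names(agg) == "fc"] <- "aifc"
  if ("gt_state" %in% names(table)) {
    gt <- unique(table[c("epoch_id", "gt_state")])
    agg$gt_state <- gt$gt_state[match(agg$epoch_id, gt$epoch_id)]
  }
  agg[order(agg$epoch_id), ]
}

#' Test whether FC magnitude differs across brain states
#'
#' Gate-then-test: per-state Shapiro normality on epoch-mean aiFC; if any
#' state departs from normality (or is degenerate) the across-state
#' omnibus test is the Kruskal-Wallis rank test, otherwise a one-way
#' ANOVA. A session is flagged for inclusion in the hypothesis tests when
#' the omnibus p-value is below `alpha` (states must differ in magnitude
#' for the tail-selection logic to be meaningful).
#'
#' @param table A `session_fc_table`.
#' @param alpha Inclusion threshold.
#' @return List: `normal` (named logical per state), `test` (`"anova"` or
#'   `"kruskal"`), `statistic`, `p_value`, `state_means`, `include`.
#' @export
state_magnitude_test <- function(table, alpha = 0.05) {
  ea <- epoch_aifc(table)
  states <- unique(ea$state)
  if (length(states) < 2) stop("need at least 2 states")
  counts <- table(ea$state)
  if (any(counts < 3))
    stop(sprintf("insufficient data: state %s has %d epochs (< 3)",
                 names(counts)[which.min(counts)], min(counts)))
  normal <- vapply(states, function(s) {
    x <- ea$aifc[ea$state == s]
    if (stats::sd(x) == 0) return(FALSE)  # degenerate: treat as non-normal
    if (length(x) > 5000) x <- sample(x, 5000)
    stats::shapiro.test(x)$p.value >= alpha
  }, logical(1))
  names(normal) <- states
  degenerate <- stats::sd(ea$aifc) == 0
  if (degenerate) {
    test <- "kruskal"; statistic <- 0; p <- 1
  } else if (all(normal)) {
    fit <- stats::aov(aifc ~ state, data = ea)
    s <- summary(fit)[[1]]
    test <- "anova"; statistic <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(aifc ~ factor(state), data = ea)
    test <- "kruskal"; statistic <- unname(kw$statistic); p <- kw$p.value
  }
  list(normal = normal, test = test, statistic = statistic, p_value = p,
       state_means = tapply(ea$aifc, ea$state, mean),
       include = is.finite(p) && p < alpha)
}

.pct_cut <- function(x, pct) stats::quantile(x, pct / 100, type = 7,
                                             names = FALSE)

#' Select the percentile tail of a state's aiFC distribution
#'
#' Selects the epochs of `state` whose epoch-mean aiFC lies in the top (or
#' bottom) `pct` percent of that state's distribution and, in any case,
#' beyond the guard percentile of the other state's distribution (higher
#' than the guard for top tails, lower for bottom tails). Percentiles use
#' linear interpolation between order statistics; epochs exactly at the
#' tail cutoff are excluded (strict inequality) and ties are resolved
#' deterministically by epoch id ordering of the output.
#'
#' @param table A `session_fc_table`.
#' @param state State whose tail is selected.
#' @param side `"top"` or `"bottom"`.
#' @param pct Tail size in percent (25, 15 or 5 in the standard analysis);
#'   `pct >= 100` selects all epochs of the state.
#' @param guard_state State providing the guard distribution (`NULL`
#'   disables the guard).
#' @param guard_pct Guard percentile (5 for top tails, 95 for bottom).
#' @return An object of class `tail_selection`: `epoch_ids`, `aifc`
#'   (named by epoch), `state`, `side`, `pct`, `guard_state`, `guard_pct`,
#'   `cutoff`, `guard_cutoff`, `n_candidates` (tail size before the
#'   guard).
#' @export
select_tail <- function(table, state, side = c("top", "bottom"), pct,
                        guard_state = NULL, guard_pct = NULL) {
  side <- match.arg(side)
  ea <- epoch_aifc(table)
  x <- ea$aifc[ea$state == state]
  ids <- ea$epoch_id[ea$state == state]
  stopifnot(length(x) > 0)
  if (pct >= 100) {
    in_tail <- rep(TRUE, length(x))
    cutoff <- NA_real_
  } else if (side == "top") {
    cutoff <- .pct_cut(x, 100 - pct)
    in_tail <- x > cutoff
  } else {
    cutoff <- .pct_cut(x, pct)
    in_tail <- x < cutoff
  }
  guard_cutoff <- NA_real_
  ok <- in_tail
  if (!is.null(guard_state)) {
    g <- ea$aifc[ea$state == guard_state]
    stopifnot(length(g) > 0, !is.null(guard_pct))
    guard_cutoff <- .pct_cut(g, guard_pct)
    ok <- in_tail & (if (side == "top") x > guard_cutoff else x < guard_cutoff)
  }
  o <- order(ids[ok])
  structure(list(epoch_ids = ids[ok][o],
                 aifc = stats::setNames(x[ok][o], ids[ok][o]),
                 state = state, side = side, pct = pct,
                 guard_state = guard_state, guard_pct = guard_pct,
                 cutoff = cutoff, guard_cutoff = guard_cutoff,
                 n_candidates = sum(in_tail)),
            class = "tail_selection")
}

#' @export
print.tail_selection <- function(x, ...) {
  cat(sprintf("<tail_selection> %s %d%% tail of %s: %d epochs", x$side,
              x$pct, x$state, length(x$epoch_ids)))
  if (!is.null(x$guard_state))
    cat(sprintf(" (guard: %s %gth pct = %.4g; %d before guard)",
                x$guard_state, x$guard_pct, x$guard_cutoff, x$n_candidates))
  cat("\n")
  invisible(x)
}

#' Cross-state overlap of aiFC distributions
#'
#' Summarizes how much the epoch-mean aiFC distribution of `state_a`
#' overlaps that of `state_b`: (i) the fraction of `state_a` epochs
#' falling within each quartile of `state_b`'s distribution, (ii) the
#' percentage of `state_a`'s bottom-25% epochs lying below `state_b`'s
#' 95th percentile, and (iii) the mirror statistic, the percentage of
#' `state_a`'s top-25% epochs lying above `state_b`'s 5th percentile.
#'
#' @param table A `session_fc_table`.
#' @param state_a,state_b The two states.
#' @return List: `quartile_fractions` (length 4, plus below/above mass in
#'   attributes), `pct_bottom25_below_95`, `pct_top25_above_5`.
#' @export
overlap_summary <- function(table, state_a, state_b) {
  ea <- epoch_aifc(table)
  a <- ea$aifc[ea$state == state_a]
  b <- ea$aifc[ea$state == state_b]
  stopifnot(length(a) > 0, length(b) > 0)
  qs <- stats::quantile(b, c(0, 0.25, 0.5, 0.75, 1), type = 7)
  inq <- vapply(seq_len(4), function(k)
    mean(a >= qs[k] & (if (k == 4) a <= qs[k + 1] else a < qs[k + 1])),
    numeric(1))
  names(inq) <- c("Q1", "Q2", "Q3", "Q4")
  bot <- a[a < .pct_cut(a, 25)]
  top <- a[a > .pct_cut(a, 75)]
  list(quartile_fractions = inq,
       frac_below_range = mean(a < qs[1]),
       frac_above_range = mean(a > qs[5]),
       pct_bottom25_below_95 =
         if (length(bot)) 100 * mean(bot < .pct_cut(b, 95)) else NA_real_,
       pct_top25_above_5 =
         if (length(top)) 100 * mean(top > .pct_cut(b, 5)) else NA_real_)
}
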