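#' Lysed-front depth from a fibrin field
#'
#' The front is the largest contiguous depth from the inlet face over
#' which every transverse slice's average fibrin concentration is
#' strictly below the lysis threshold.  Trapped unlysed pockets deeper
#' in the clot do not advance the front.
#'
#' @param F Fibrin concentration matrix (slices along rows, from the
#'   inlet face).
#' @param Fstar Lysis threshold (mg/ml); a slice mean exactly at `Fstar`
#'   counts as not lysed.
#' @param dx Slice thickness (m); with the default 1 the return value is
#'   a slice count.
#' @return Depth of the lysed front (m, or slices if `dx = 1`).
#' @export
front_from_field <- function(F, Fstar, dx = 1) {
  lysed <- rowMeans(F) < Fstar
  n <- match(FALSE, lysed, nomatch = nrow(F) + 1L) - 1L
  n * dx
}

#' Remaining clot mass fraction
#'
#' @param F Current fibrin field.
#' @param F0 Initial fibrin field (same shape).
#' @return `sum(F) / sum(F0)`.
#' @export
mass_fraction <- function(F, F0) {
  stopifnot(length(F) == length(F0))
  sum(F) / sum(F0)
}

#' Volume throughput across the clot
#'
#' Integrates the axial (partial-bounce-back) velocity over transverse
#' cross-sections and averages over the sections provided.  In 2D the
#' result is a volume flow per unit depth (m^2/s); in 3D, volumetric
#' (m^3/s).
#'
#' @param ux Axial velocity (m/s): matrix (2D, sections x transverse) or
#'   3D array.
#' @param dx Grid spacing (m).
#' @return Mean throughput over the sections.
#' @export
throughput <- function(ux, dx) {
  if (length(dim(ux)) == 3L)
    return(mean(apply(ux, 1L, sum)) * dx^2)
  mean(rowSums(ux)) * dx
}

# First time a non-increasing series crosses a level (linear interpolation)
.first_crossing <- function(t, y, level, decreasing = TRUE) {
  hit <- if (decreasing) y <= level else y >= level
  i <- match(TRUE, hit)
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1L])
  t[i - 1L] + (level - y[i - 1L]) * (t[i] - t[i - 1L]) / (y[i] - y[i - 1L])
}

#' Quartile lysis times
#'
#' First instants at which the remaining mass fraction reaches 0.75,
#' 0.50 and 0.25 (i.e. 25, 50 and 75% of the clot is lysed), linearly
#' interpolated between samples.  Thresholds never reached are reported
#' as `NA` (censored) rather than errors.
#'
#' @param record A `simulation_record` (or data frame with `time_s` and
#'   `mass_fraction`).
#' @return Named numeric vector `c(t25, t50, t75)` in seconds.
#' @export
lysis_quartiles <- function(record) {
  stopifnot(nrow(record) >= 2L)
  t <- record$time_s; m <- record$mass_fraction
  c(t25 = .first_crossing(t, m, 0.75),
    t50 = .first_crossing(t, m, 0.50),
    t75 = .first_crossing(t, m, 0.25))
}

#' Recanalization onset time
#'
#' First instant at which the throughput exceeds a given fraction of its
#' final value (linearly interpolated).  "Onset" is not a standard
#' quantity; the default operationalization, 50% of the final
#' throughput, is reported alongside the result.
#'
#' @param record A `simulation_record` (or data frame with `time_s` and
#'   `throughput`).
#' @param fraction_of_final Fraction of the final throughput defining
#'   the onset, in `(0, 1]`.
#' @return Onset time (s), with attribute `fraction_of_final`; `NA` for
#'   a flat zero-flow record (censored).
#' @export
recanalization_onset <- function(record, fraction_of_final = 0.5) {
  stopifnot(fraction_of_final > 0, fraction_of_final <= 1)
  t <- record$time_s; q <- record$throughput
  qf <- q[length(q)]
  if (qf <= 0) return(structure(NA_real_,
                                fraction_of_final = fraction_of_final))
  structure(.first_crossing(t, q, fraction_of_final * qf, decreasing = FALSE),
            fraction_of_final = fraction_of_final)
}

#' Seeded ensemble of clot-lysis simulations
#'
#' Runs `n_replicates` independent simulations of the given
#' configuration, with replicate seeds derived deterministically from
#' `base_seed` (base_seed + replicate index), and summarises the lysis
#' and recanalization metrics.  Replicate failures are recorded and the
#' ensemble continues.
#'
#' @param cfg A run configuration template (see [default_run_config()]);
#'   its `seed` is replaced per replicate.
#' @param n_replicates Number of replicates.
#' @param base_seed Integer base seed.
#' @param onset_fraction Fraction of final throughput defining
#'   recanalization onset.
#' @return An `ensemble_summary`: list with `replicates` (data frame:
#'   seed, t25/t50/t75, onset_s, final_throughput, stop_reason),
#'   `t50_mean`, `t50_rel_half_spread` (half the range of t50 across
#'   replicates, relative to the mean, unreached thresholds excluded),
#'   `onset_mean_s`, and `failures`.
#' @export
run_ensemble <- function(cfg, n_replicates, base_seed = 1L,
                         onset_fraction = 0.5) {
  stopifnot(n_replicates >= 1)
  rows <- vector("list", n_replicates)
  failures <- character()
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    rec <- tryCatch(run_lysis(cfg_r), error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(rec)))
      next
    }
    qt <- lysis_quartiles(rec)
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg_r$seed,
      t25_s = qt[["t25"]], t50_s = qt[["t50"]], t75_s = qt[["t75"]],
      onset_s = as.numeric(recanalization_onset(rec, onset_fraction)),
      final_throughput = rec$throughput[nrow(rec)],
      stop_reason = attr(rec, "stop_reason"))
  }
  reps <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  t50 <- reps$t50_s[!is.na(reps$t50_s)]
  structure(list(
    replicates = reps,
    t50_mean = mean(t50),
    t50_rel_half_spread = if (length(t50) >= 2)
      (max(t50) - min(t50)) / 2 / mean(t50) else 0,
    onset_mean_s = mean(reps$onset_s, na.rm = TRUE),
    onset_fraction = onset_fraction,
    failures = failures),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(paste0("lysis ensemble: %d replicates; mean t1/2 = %.0f s ",
                     "(relative half-spread %.1f%%), mean recanalization ",
                     "onset = %.0f s (%.0f%% of final throughput)\n"),
              nrow(x$replicates), x$t50_mean, 100 * x$t50_rel_half_spread,
              x$onset_mean_s, 100 * x$onset_fraction))
  if (length(x$failures)) cat("failures:\n", paste(" -", x$failures,
                                                   collapse = "\n"), "\n")
  invisible(x)
}

#' Per-column lysed-front depths
#'
#' Contiguous lysed depth from the inlet face for each transverse
#' column: the number of leading voxels with fibrin strictly below the
#' threshold.  The median across columns is the front "at the middle of
#' the interface", the reading used when a lysis interface is not flat
#' (wall-hugging films lag the bulk).
#'
#' @inheritParams front_from_field
#' @return Integer vector of lysed depths (voxels), one per column.
#' @export
front_columns <- function(F, Fstar) {
  apply(F < Fstar, 2L, function(col)
    match(FALSE, col, nomatch = length(col) + 1L) - 1L)
}
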