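#' Parameters of the one-dimensional lysis front model
#'
#' Bundles the physical parameters of the minimal front-propagation model of
#' flow-driven fibrinolysis.  The clot of length `L` and uniform fibrin
#' concentration `F0` is split into `n = round(L / Delta)` slices of thickness
#' `Delta` (then redefined as `L / n` so the slices tile the clot exactly).
#' An anti-fibrin agent enters at the inlet face at concentration `Fbar0`,
#' carried by a constant permeation velocity `u_f`, accumulates at the
#' foremost intact slice, and degrades fibrin there by a second-order
#' reaction with rate `k1` until the slice concentration drops below the
#' lysis threshold `Fstar`.
#'
#' @param F0 Initial fibrin concentration (mg/ml).  Must exceed `Fstar`.
#' @param Fstar Fibrin concentration threshold below which a slice counts as
#'   lysed (mg/ml).
#' @param Fbar0 Anti-fibrin agent concentration at the inlet (mg/ml).
#' @param k1 Second-order reaction rate ((s mg/ml)^-1).
#' @param u_f Permeation fluid speed through the clot (m/s).
#' @param Delta Slice thickness (m); internally adjusted to `L / n`.
#' @param L Clot length (m).
#'
#' @return An object of class `lysis_params`: a list with the validated
#'   fields plus the slice count `n` and the adjusted `Delta`.
#' @seealso [first_slice_time()], [lysis_schedule()], [fit_k1()]
#' @export
#' @examples
#' lysis_params(F0 = 2.4, Fstar = 0.2, Fbar0 = 1e-5, k1 = 12.5,
#'              u_f = 5e-6, Delta = 1e-4, L = 5e-3)
lysis_params <- function(F0, Fstar, Fbar0, k1, u_f, Delta, L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", nm), call. = FALSE)
    x
  }
  F0 <- num1(F0, "F0"); Fstar <- num1(Fstar, "Fstar")
  Fbar0 <- num1(Fbar0, "Fbar0"); k1 <- num1(k1, "k1")
  u_f <- num1(u_f, "u_f"); Delta <- num1(Delta, "Delta"); L <- num1(L, "L")
  if (Fstar <= 0) stop("'Fstar' must be positive", call. = FALSE)
  if (F0 <= Fstar)
    stop("'F0' must exceed 'Fstar': the model is undefined for F0 <= Fstar",
         call. = FALSE)
  if (Fbar0 <= 0) stop("'Fbar0' must be positive", call. = FALSE)
  if (k1 <= 0) stop("'k1' must be positive", call. = FALSE)
  if (u_f <= 0) stop("'u_f' must be positive", call. = FALSE)
  if (L <= 0) stop("'L' must be positive", call. = FALSE)
  if (Delta <= 0 || Delta > L)
    stop("'Delta' must satisfy 0 < Delta <= L", call. = FALSE)
  n <- max(1L, as.integer(round(L / Delta)))
  structure(
    list(F0 = F0, Fstar = Fstar, Fbar0 = Fbar0, k1 = k1, u_f = u_f,
         Delta = L / n, L = L, n = n),
    class = "lysis_params")
}

#' @export
print.lysis_params <- function(x, ...) {
  cat("1D lysis model parameters\n")
  cat(sprintf("  F0 = %g mg/ml, F* = %g mg/ml, Fbar0 = %g mg/ml\n",
              x$F0, x$Fstar, x$Fbar0))
  cat(sprintf("  k1 = %g (s mg/ml)^-1, u_f = %g m/s\n", x$k1, x$u_f))
  cat(sprintf("  L = %g m in %d slices of Delta = %g m\n", x$L, x$n, x$Delta))
  invisible(x)
}

#' Time to lyse the first clot slice
#'
#' With the anti-fibrin agent accumulating linearly at the clot face
#' (`Fbar(t) = Fbar0 * u_f * t / Delta`), integrating the second-order
#' reaction from `F0` down to the threshold `Fstar` gives
#' `t0 = sqrt(2 * Delta * log(F0 / Fstar) / (k1 * u_f * Fbar0))`.
#'
#' @param p A [lysis_params()] object.
#' @return The first-slice lysis time t0 in seconds.
#' @export
first_slice_time <- function(p) {
  stopifnot(inherits(p, "lysis_params"))
  sqrt(2 * p$Delta * log(p$F0 / p$Fstar) / (p$k1 * p$u_f * p$Fbar0))
}

#' Slice-by-slice lysis schedule
#'
#' Returns the instants `t_0 < t_1 < ... < t_{n-1}` at which successive
#' slices (0-based from the inlet face) drop below the lysis threshold.
#' The recursion is
#' `t_k = Delta / u_f + sqrt(t_{k-1}^2 + 2 * Delta * log(F0/Fstar) / (k1 * u_f * Fbar0))`:
#' the accumulated agent is advected one slice deeper (the `Delta / u_f`
#' term) and keeps growing while it lyses the next slice.  Successive
#' differences shrink, i.e. the front accelerates.
#'
#' @inheritParams first_slice_time
#' @param advection If `FALSE`, drop the `Delta / u_f` advection term
#'   (used for the closed-form continuum limit, where the telescoping sum
#'   gives `t_{n-1} = sqrt(2 * L * log(F0/Fstar) / (k1 * u_f * Fbar0))`).
#' @return Numeric vector of length `p$n`, strictly increasing.
#' @export
lysis_schedule <- function(p, advection = TRUE) {
  stopifnot(inherits(p, "lysis_params"))
  a <- 2 * p$Delta * log(p$F0 / p$Fstar) / (p$k1 * p$u_f * p$Fbar0)
  adv <- if (advection) p$Delta / p$u_f else 0
  t <- numeric(p$n)
  t[1L] <- sqrt(a)
  if (p$n > 1L)
    for (k in 2L:p$n) t[k] <- adv + sqrt(t[k - 1L]^2 + a)
  t
}

#' Front position predicted by the 1D model
#'
#' Piecewise-constant inverse of [lysis_schedule()]: the front sits at
#' `Delta` times the number of slices already lysed at time `t`; whole
#' slices lyse at the scheduled instants, nothing is interpolated.
#'
#' @inheritParams first_slice_time
#' @param t Vector of non-negative times (s).
#' @param schedule Optional precomputed [lysis_schedule()] for `p`.
#' @return Depths from the clot inlet face (m), capped at `p$L`.
#' @export
front_position <- function(p, t, schedule = NULL) {
  stopifnot(inherits(p, "lysis_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (is.null(schedule)) schedule <- lysis_schedule(p)
  pmin(p$Delta * findInterval(t, schedule), p$L)
}

#' Calibrate the reaction rate k1 against a measured front trajectory
#'
#' Finds the `k1 > 0` minimising the sum of squared differences between
#' measured front positions and the model's [front_position()] at the
#' measurement times, all other parameters held fixed.  The loss has a
#' single free parameter and is minimised by golden-section/Brent search
#' on `log(k1)` over `[1e-3, 1e5]`.  Note the schedule depends on `k1`
#' and `Fbar0` only through their product, so the fit identifies `k1`
#' only for a fixed, known `Fbar0`.
#'
#' @param traj A data frame with columns `time_s` and `position_m`
#'   (see [read_front_trajectory()]), at least 3 rows.
#' @param p A [lysis_params()] object holding the known parameters; its
#'   `k1` field is ignored and replaced by the estimate.
#' @return A list of class `k1_fit`: `k1_hat`, `rms_residual_m`,
#'   `n_points`, and `params` (the input parameters with `k1 = k1_hat`).
#' @export
fit_k1 <- function(traj, p) {
  stopifnot(inherits(p, "lysis_params"))
  traj <- as.data.frame(traj)
  if (!all(c("time_s", "position_m") %in% names(traj)))
    stop("'traj' needs columns 'time_s' and 'position_m'", call. = FALSE)
  if (nrow(traj) < 3L)
    stop("need at least 3 trajectory points to fit k1", call. = FALSE)
  if (is.unsorted(traj$time_s, strictly = TRUE))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  if (all(traj$position_m <= 0))
    stop("degenerate trajectory: all positions are zero, no information on k1",
         call. = FALSE)
  sse <- function(logk) {
    pk <- p
    pk$k1 <- exp(logk)
    sum((front_position(pk, traj$time_s) - traj$position_m)^2)
  }
  opt <- stats::optimize(sse, interval = log(c(1e-3, 1e5)), tol = 1e-10)
  k1_hat <- exp(opt$minimum)
  structure(
    list(k1_hat = k1_hat,
         rms_residual_m = sqrt(opt$objective / nrow(traj)),
         n_points = nrow(traj),
         params = { pf <- p; pf$k1 <- k1_hat; pf }),
    class = "k1_fit")
}

#' @export
print.k1_fit <- function(x, ...) {
  cat(sprintf("k1 fit: k1_hat = %.4g (s mg/ml)^-1, RMS residual = %.3g m on %d points\n",
              x$k1_hat, x$rms_residual_m, x$n_points))
  invisible(x)
}

#' Total lysis time under slice-thickness refinement
#'
#' Recomputes the total lysis time `t_{n-1}` for a series of refinements
#' of the slice thickness.  For `Delta` well below `L` the schedule is
#' insensitive to the slicing; this table quantifies that.
#'
#' @inheritParams first_slice_time
#' @param factors Refinement factors (each new `Delta` is `p$Delta / factor`).
#' @return A data frame with columns `factor`, `Delta_m`, `n_slices`,
#'   `t_total_s`; attribute `max_rel_spread` holds the maximal relative
#'   spread of `t_total_s` across rows.
#' @export
delta_convergence <- function(p, factors = c(1, 2, 4)) {
  stopifnot(inherits(p, "lysis_params"))
  if (any(factors <= 0)) stop("'factors' must be positive", call. = FALSE)
  rows <- lapply(factors, function(m) {
    pm <- lysis_params(p$F0, p$Fstar, p$Fbar0, p$k1, p$u_f,
                       Delta = p$Delta / m, L = p$L)
    sched <- lysis_schedule(pm)
    data.frame(factor = m, Delta_m = pm$Delta, n_slices = pm$n,
               t_total_s = sched[length(sched)])
  })
  out <- do.call(rbind, rows)
  tt <- out$t_total_s
  attr(out, "max_rel_spread") <- (max(tt) - min(tt)) / min(tt)
  out
}

#' Read a measured front trajectory from delimited text
#'
#' Expects two columns, time (s) and front position (m), whitespace or
#' comma separated; a header row is optional and lines starting with `#`
#' are ignored.
#'
#' @param path Path to the text file.
#' @return A data frame with columns `time_s`, `position_m`.
#' @export
read_front_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1L]])) "," else ""
  first <- strsplit(trimws(lines[[1L]]),
                    if (sep == ",") "\\s*,\\s*" else "\\s+")[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = lines, header = header, sep = sep,
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("expected two columns (time_s, position_m)",
                          call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("time_s", "position_m")
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$position_m)))
    stop("non-numeric values in trajectory file", call. = FALSE)
  if (any(df$position_m < 0))
    stop("front positions must be non-negative", call. = FALSE)
  df
}
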