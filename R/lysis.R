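#' One explicit transport step of the anti-fibrin agent
#'
#' Conservative finite-volume update on a 2D grid: first-order upwind
#' advection with the partial-bounce-back macroscopic velocity, plus
#' central-difference diffusion.  Front blocking: voxels carrying intact
#' fibrin (`blocked = TRUE`) receive every incoming flux (the agent
#' accumulates there) but emit no advective or diffusive flux, which in
#' one dimension reproduces the linear accumulation law
#' `Fbar(front, t) = Fbar0 u t / dx` of the analytical model.  Inlet
#' voxels, if given, are held at the inlet concentration (Dirichlet);
#' the far face of the last column is a free advective outflow.
#'
#' @param Fbar Matrix (nx x ny) of anti-fibrin concentration (mg/ml).
#' @param blocked Logical matrix: voxels with fibrin at or above the
#'   lysis threshold.
#' @param ux,uy Matrices of velocity components (m/s).
#' @param flags Integer matrix of node flags (walls exchange no flux).
#' @param dx Voxel size (m).
#' @param dt Time step (s).  `dt / nsub` must satisfy the advection CFL
#'   (`max|u| dt / dx <= 1`) and diffusion (`D dt / dx^2 <= 0.5`) limits.
#' @param D Diffusion coefficient (m^2/s); tPA's 3.3e-11 by default.
#' @param inlet_cells Indices of Dirichlet inlet voxels (optional).
#' @param Fbar0 Inlet concentration (mg/ml), used with `inlet_cells`.
#' @param nsub Number of equal sub-steps to take (the full update is
#'   advanced by `dt` in `nsub` explicit stages inside the kernel).
#' @param udep_x,udep_y Deposition intake velocities (m/s) used for
#'   fluxes onto blocked voxels; default to `ux`/`uy`.  The coupled
#'   simulator supplies the blocked voxel's local Darcy velocity
#'   (voxel permeability times local pressure gradient over viscosity),
#'   which is free of the sub-voxel wall-layer structure of the lattice
#'   flow field.
#' @return List: `Fbar` (updated matrix) and `mass_out` (mass advected
#'   out of the domain this step, concentration x volume units).
#' @export
transport_antifa <- function(Fbar, blocked, ux, uy, flags, dx, dt,
                             D = 3.3e-11, inlet_cells = NULL, Fbar0 = 0,
                             udep_x = ux, udep_y = uy, nsub = 1L) {
  cfl <- max(abs(ux), abs(uy)) * (dt / nsub) / dx
  if (cfl > 1)
    stop(sprintf("advection CFL %.3f > 1: reduce the transport step", cfl),
         call. = FALSE)
  if (D * (dt / nsub) / dx^2 > 0.5)
    stop(sprintf("diffusion number %.3f > 0.5: reduce the transport step",
                 D * (dt / nsub) / dx^2), call. = FALSE)
  res <- cpp_transport_step(as.numeric(Fbar), as.logical(blocked),
                            as.numeric(ux), as.numeric(uy),
                            as.numeric(udep_x), as.numeric(udep_y),
                            as.integer(flags), nrow(Fbar), ncol(Fbar),
                            dx, dt, D, as.integer(nsub),
                            if (is.null(inlet_cells)) NULL
                            else as.integer(inlet_cells) - 1L,
                            Fbar0)
  list(Fbar = matrix(res$Fbar, nrow(Fbar), ncol(Fbar)),
       mass_out = res$mass_out)
}

#' Second-order lysis reaction (explicit Euler)
#'
#' `F <- max(F - k1 F Fbar dt, 0)`.  The reaction consumes fibrin only;
#' the anti-fibrin agent acts catalytically and is left unchanged.  The
#' explicit step requires `k1 max(Fbar) dt <= 1` so that fibrin stays
#' non-negative before clamping (at exactly 1 the step removes all
#' fibrin in one go).
#'
#' @param F Fibrin concentration (any numeric shape, mg/ml).
#' @param Fbar Anti-fibrin concentration, conformable with `F` (mg/ml).
#' @param k1 Reaction rate ((s mg/ml)^-1).
#' @param dt Reaction time step (s).
#' @return Updated fibrin concentrations, same shape as `F`.
#' @export
react <- function(F, Fbar, k1, dt) {
  guard <- k1 * max(Fbar) * dt
  if (guard > 1)
    stop(sprintf(paste0("reaction positivity guard violated: k1 * max(Fbar) ",
                        "* dt = %.3f >= 1; use a smaller reaction step"), guard),
         call. = FALSE)
  pmax(F - k1 * F * Fbar * dt, 0)
}

#' Refresh the permeability state of a clot after reaction
#'
#' Recomputes fiber radius, solid fraction, permeability, bounce-back
#' fraction and the transport-blocking mask from the current fibrin
#' field.  Idempotent when the fibrin field is unchanged; any voxel
#' whose fibrin decreased gets a strictly lower `gamma`.
#'
#' @param clot A `clot_field`.
#' @param units An [lb_units()].
#' @param Fstar Lysis threshold concentration (mg/ml): voxels at or
#'   above it block anti-fibrin transport.
#' @return List: `clot` (unchanged), `chain` (see [clot_chain()]),
#'   `gamma` matrix and logical `blocked` matrix.
#' @export
update_clot_state <- function(clot, units, Fstar) {
  ch <- clot_chain(clot, units)
  list(clot = clot, chain = ch, gamma = ch$gamma,
       blocked = clot$F >= Fstar & clot$F0 > 0)
}

# Assemble the channel-with-clot simulation domain.  Layout along x:
# [inlet column | upstream lumen | clot | downstream lumen | outlet column],
# walls on both transverse boundaries.
.build_domain <- function(cfg, clot, units) {
  len <- nrow(clot$F); wid <- ncol(clot$F)
  nx <- 1L + cfg$numerics$lumen_in + len + cfg$numerics$lumen_out + 1L
  ny <- wid + 2L
  flags <- matrix(FLAG_FLUID, nx, ny)
  flags[, 1L] <- FLAG_WALL
  flags[, ny] <- FLAG_WALL
  cx <- 1L + cfg$numerics$lumen_in + seq_len(len)   # clot columns
  cy <- 1L + seq_len(wid)
  # pressure drop of grad_P over the clot length, imposed across the domain
  grad_eff <- cfg$physical$grad_P * (len * units$dx) / ((nx - 1L) * units$dx)
  st <- lb_state(lb_lattice("D2Q9"), c(nx, ny), units, flags = flags)
  st <- lb_apply_pressure_drop(st, grad_eff)
  list(state = st, nx = nx, ny = ny, cx = cx, cy = cy,
       flags = matrix(st$flags, nx, ny))
}

.embed_gamma <- function(dom, gamma_clot) {
  g <- matrix(0, dom$nx, dom$ny)
  g[dom$cx, dom$cy] <- gamma_clot
  g
}

# Deposition intake velocities: per-voxel Darcy velocity from the voxel
# permeability and the central-difference pressure gradient of the lattice
# density field.  Transversely smooth where the clot is homogeneous (the
# Brinkman boundary layer is sub-voxel), yet proportional to local
# permeability where it is not, so heterogeneity channelling is preserved.
.darcy_intake <- function(rho, kfield, dom, units) {
  nx <- dom$nx; ny <- dom$ny
  p <- matrix(rho, nx, ny) * units$cs2 * units$pressure
  p[, 1L] <- p[, 2L]           # wall rows carry no pressure information
  p[, ny] <- p[, ny - 1L]
  mu <- units$rho_phys * units$nu
  dpx <- matrix(0, nx, ny); dpy <- matrix(0, nx, ny)
  dpx[2:(nx - 1L), ] <- (p[3:nx, ] - p[1:(nx - 2L), ]) / (2 * units$dx)
  dpy[, 2:(ny - 1L)] <- (p[, 3:ny] - p[, 1:(ny - 2L)]) / (2 * units$dx)
  kd <- matrix(0, nx, ny)
  kd[dom$cx, dom$cy] <- kfield
  kd[!is.finite(kd)] <- 0
  list(x = -kd / mu * dpx, y = -kd / mu * dpy)
}

# Re-initialize populations at the series-resistance (1D resistor network)
# pressure profile implied by the current permeability field, keeping the
# current velocity field.  Pressure equilibrates diffusively through a
# low-permeability slab - O(L^2/k) lattice steps from a poor initial
# guess - so handing the solver the right axial profile up front turns
# each quasi-steady re-solve into a short polish.
.precondition_pressure <- function(st, dom, units, k_clot) {
  nx <- dom$nx; ny <- dom$ny
  k_open <- (length(dom$cy) * units$dx)^2 / 12     # open-channel equivalent
  kfield <- matrix(k_open, nx, ny)
  kfield[dom$cx, dom$cy] <- pmin(k_clot, k_open)
  R <- 1 / rowSums(kfield[, dom$cy, drop = FALSE])  # per-column resistance
  cumR <- cumsum(R)
  frac <- (cumR - R / 2) / cumR[nx]
  rho_prof <- st$rho_in + (st$rho_out - st$rho_in) * frac
  rho <- matrix(rho_prof, nx, ny)
  # keep the current bare (first-moment) velocity so momentum carries over
  rho_cur <- rowSums(st$f)
  u_bare <- (st$f %*% st$lattice$c) / rho_cur
  st$f <- lb_equilibrium(st$lattice, as.numeric(rho), u_bare)
  st
}

#' Coupled clot-flow-lysis simulation
#'
#' Runs the full mesoscopic fibrinolysis loop on a 2D channel: the clot
#' is a partial-bounce-back porous slab whose per-voxel resistance
#' follows the fibrin -> radius -> solid fraction -> Davies -> gamma
#' chain; the flow is re-solved to quasi-steady state on a configurable
#' cadence; the anti-fibrin agent is advected and diffused with front
#' blocking; and the second-order reaction dissolves fibrin, feeding
#' back into the permeability.  Fully deterministic for a given
#' configuration and seed.
#'
#' @param cfg A run configuration (see [default_run_config()]).
#' @return A `simulation_record`: data frame with columns `time_s`,
#'   `front_m` (slice-average front), `front_mid_m` (median per-column
#'   front - the front at the middle of the interface, which is how the
#'   tube experiments read it; wall-hugging remnant films do not hold it
#'   back), `mass_fraction`, `throughput` (m^2/s per unit depth) and
#'   attributes `config`, `clot0` (initial clot), `clot` (final),
#'   `u_f0` (initial mean permeation velocity, m/s), `n_resolves`,
#'   `stop_reason`, `snapshots` (if requested).
#' @export
run_lysis <- function(cfg) {
  cfg <- validate_run_config(cfg)
  ph <- cfg$physical; nm <- cfg$numerics
  units <- lb_units(nm$dx, nm$dt, ph$nu, ph$rho)
  calib <- if (is.null(ph$ns0))
    calibrate_clot(cfg$clot$F_M, ph$Rf, k0 = ph$k)
  else calibrate_clot(cfg$clot$F_M, ph$Rf, ns0 = ph$ns0)
  spec <- clot_spec(F_M = cfg$clot$F_M, kind = cfg$clot$kind,
                    length_m = ph$L, width_m = ph$width,
                    dispersion = cfg$clot$dispersion,
                    F_disk = cfg$clot$F_disk, n_disks = cfg$clot$n_disks,
                    disk_radius_m = cfg$clot$disk_radius, seed = cfg$seed)
  clot <- generate_clot(spec, calib, nm$dx)
  clot0 <- clot
  dom <- .build_domain(cfg, clot, units)
  upd <- update_clot_state(clot, units, ph$Fstar)
  st <- dom$state
  st$gamma <- as.numeric(.embed_gamma(dom, upd$gamma))
  st <- .precondition_pressure(st, dom, units, upd$chain$k)
  st <- run_to_steady(st, tol = nm$steady_tol, max_steps = nm$init_max_steps,
                      check_every = nm$check_every)
  n_resolves <- 1L

  macro <- lb_macroscopic(st, physical = TRUE)
  ux <- matrix(macro$u_phys[, 1L], dom$nx, dom$ny)
  uy <- matrix(macro$u_phys[, 2L], dom$nx, dom$ny)
  intake <- .darcy_intake(macro$rho, upd$chain$k, dom, units)
  width_m <- length(dom$cy) * units$dx
  # volume flow per unit depth: axial velocity integrated across the
  # section, averaged over every section inside the clot region
  thr <- function() mean(rowSums(ux[dom$cx, dom$cy, drop = FALSE])) * units$dx
  q0 <- thr()
  u_f0 <- q0 / width_m

  # anti-FA field: upstream lumen (and inlet column) primed at Fbar0
  Fbar <- matrix(0, dom$nx, dom$ny)
  upstream <- seq_len(1L + nm$lumen_in)
  Fbar[upstream, dom$cy] <- ph$Fbar0
  inlet_cells <- which(dom$flags == FLAG_INLET)
  blocked_dom <- matrix(FALSE, dom$nx, dom$ny)
  blocked_dom[dom$cx, dom$cy] <- upd$blocked

  dt_r <- nm$dt * nm$react_dt_factor
  L_clot <- nrow(clot$F) * units$dx
  mass0 <- sum(clot$F)
  gamma_ref <- upd$gamma

  t_now <- 0
  samples <- list()
  snaps <- list()
  stop_reason <- "t_max"
  step <- 0L
  record <- function() {
    data.frame(time_s = t_now,
               front_m = front_from_field(clot$F, ph$Fstar, dx = units$dx),
               front_mid_m = stats::median(front_columns(clot$F, ph$Fstar)) *
                 units$dx,
               mass_fraction = sum(clot$F) / mass0,
               throughput = thr())
  }
  samples[[1L]] <- record()

  repeat {
    step <- step + 1L
    # transport substeps to respect CFL/diffusion limits
    umax <- max(abs(ux), abs(uy))
    nsub <- max(1L, ceiling(umax * dt_r / (0.5 * units$dx)),
                ceiling(ph$D_antifa * dt_r / (0.25 * units$dx^2)))
    Fbar <- transport_antifa(Fbar, blocked_dom, ux, uy, dom$flags,
                             units$dx, dt_r, ph$D_antifa,
                             inlet_cells = inlet_cells, Fbar0 = ph$Fbar0,
                             udep_x = intake$x, udep_y = intake$y,
                             nsub = nsub)$Fbar
    # sub-cycle the explicit reaction so k1 * max(Fbar) * dt stays well
    # inside its positivity range even where the agent has accumulated
    Fb_clot <- Fbar[dom$cx, dom$cy]
    m <- max(1L, ceiling(ph$k1 * max(Fb_clot) * dt_r / 0.5))
    for (ss in seq_len(m))
      clot$F <- react(clot$F, Fb_clot, ph$k1, dt_r / m)
    upd <- update_clot_state(clot, units, ph$Fstar)
    blocked_dom[dom$cx, dom$cy] <- upd$blocked
    t_now <- t_now + dt_r

    resolve <- step %% nm$resolve_every == 0L ||
      max(abs(upd$gamma - gamma_ref)) > nm$resolve_dgamma
    if (resolve) {
      st_try <- st
      st_try$gamma <- as.numeric(.embed_gamma(dom, upd$gamma))
      st_try <- .precondition_pressure(st_try, dom, units, upd$chain$k)
      st_try <- tryCatch(
        lb_run(st_try, steps = nm$warm_max_steps, tol = nm$steady_tol,
               check_every = nm$check_every),
        error = function(e) e)
      if (inherits(st_try, "error")) {
        # flow has outgrown the low-Mach envelope: the vessel is
        # effectively recanalized, end the record here
        samples[[length(samples) + 1L]] <- record()
        stop_reason <- "flow_limit"
        break
      }
      st <- st_try
      n_resolves <- n_resolves + 1L
      gamma_ref <- upd$gamma
      macro <- lb_macroscopic(st, physical = TRUE)
      ux <- matrix(macro$u_phys[, 1L], dom$nx, dom$ny)
      uy <- matrix(macro$u_phys[, 2L], dom$nx, dom$ny)
      intake <- .darcy_intake(macro$rho, upd$chain$k, dom, units)
      if (isTRUE(attr(st, "max_u_lu") > cfg$stop$max_u_lu)) {
        samples[[length(samples) + 1L]] <- record()
        stop_reason <- "flow_limit"
        break
      }
    }
    if (step %% cfg$outputs$sample_every == 0L)
      samples[[length(samples) + 1L]] <- record()
    if (cfg$outputs$snapshot_every > 0L &&
        step %% cfg$outputs$snapshot_every == 0L)
      snaps[[length(snaps) + 1L]] <- list(time_s = t_now, F = clot$F,
                                          Fbar = Fbar)
    last <- samples[[length(samples)]]
    if (last$front_m >= L_clot) { stop_reason <- "front_reached_outlet"; break }
    if (last$mass_fraction < cfg$stop$mass_fraction) {
      stop_reason <- "mass_threshold"; break
    }
    if (t_now >= cfg$stop$t_max) { stop_reason <- "t_max"; break }
  }
  if (samples[[length(samples)]]$time_s < t_now)
    samples[[length(samples) + 1L]] <- record()

  rec <- do.call(rbind, samples)
  attr(rec, "config") <- cfg
  attr(rec, "clot0") <- clot0
  attr(rec, "clot") <- clot
  attr(rec, "u_f0") <- u_f0
  attr(rec, "throughput0") <- q0
  attr(rec, "n_resolves") <- n_resolves
  attr(rec, "stop_reason") <- stop_reason
  if (length(snaps)) attr(rec, "snapshots") <- snaps
  class(rec) <- c("simulation_record", "data.frame")
  rec
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf(paste0("fibrinolysis simulation: %d samples over %.0f s; ",
                     "final mass fraction %.3f, stop: %s\n"),
              nrow(x), x$time_s[nrow(x)], x$mass_fraction[nrow(x)],
              attr(x, "stop_reason")))
  invisible(x)
}
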