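#' Davies permeability of a fibrous medium
#'
#' Empirical permeability law for fibrous porous media,
#' `k = Rf^2 / (16 ns^1.5 (1 + 56 ns^3))`, which describes in vitro
#' fibrin clots well.  Strictly decreasing in the solid fraction and
#' scaling with the fiber radius squared.
#'
#' @param Rf Fiber radius (m), positive.
#' @param ns Solid fraction (volume fraction of fiber material), in
#'   `[0, 1)`.  `ns = 0` yields `Inf`, the open-voxel marker: a voxel
#'   with no remaining fiber poses no resistance and maps to a
#'   bounce-back fraction of zero.
#' @return Permeability (m^2), vectorized over the inputs.
#' @export
davies_permeability <- function(Rf, ns) {
  if (any(Rf < 0)) stop("'Rf' must be non-negative", call. = FALSE)
  if (any(ns < 0 | ns >= 1)) stop("'ns' must lie in [0, 1)", call. = FALSE)
  ifelse(ns == 0, Inf, Rf^2 / (16 * ns^1.5 * (1 + 56 * ns^3)))
}

#' Bounce-back fraction from permeability
#'
#' Maps a permeability to the partial-bounce-back fraction through
#' `gamma = 1 / (1 + 2 k / (nu dt))`.  The formula is applied in lattice
#' units (`k / dx^2` against the lattice viscosity `nu dt / dx^2`), in
#' which the grid spacing cancels, so physical `k`, `nu`, `dt` can be
#' used directly.  `k = Inf` (open voxel) maps to `gamma = 0`; `k = 0`
#' to `gamma = 1`.
#'
#' @param k Permeability (m^2), non-negative or `Inf`.
#' @param nu Kinematic viscosity (m^2/s).
#' @param dt Lattice-Boltzmann time step (s).
#' @return Bounce-back fraction in `[0, 1]`, vectorized.
#' @export
gamma_from_permeability <- function(k, nu, dt) {
  if (any(k < 0)) stop("'k' must be non-negative", call. = FALSE)
  stopifnot(nu > 0, dt > 0)
  ifelse(is.infinite(k), 0, 1 / (1 + 2 * k / (nu * dt)))
}

#' Fiber radius at a given fibrin concentration
#'
#' The lytic agent cleaves strands radially and uniformly, so fiber
#' radius shrinks with the local fibrin concentration:
#' `Rf = sqrt(Rf0^2 - (F0 - F) / (Ccal * lden))`.  Under the package's
#' calibration `Ccal * lden = F0 / Rf0^2` (fibrin mass per voxel
#' proportional to fiber cross-section) this reduces to
#' `Rf = Rf0 * sqrt(F / F0)`, with `Rf(F0) = Rf0` and `Rf(0) = 0`.
#' Round-off driving the radicand slightly negative is clamped to zero
#' (fully dissolved); the number of clamped values is attached as
#' attribute `n_clamped`.
#'
#' @param F Current fibrin concentration (mg/ml), in `[0, F0]`.
#' @param F0 Initial fibrin concentration of the voxel (mg/ml).
#' @param Rf0 Initial fiber radius (m).
#' @param lden Strand-length density of the voxel (total fiber length per
#'   volume, m^-2).
#' @param Ccal Calibration constant linking concentration loss to fiber
#'   cross-section loss.
#' @return Fiber radius (m), vectorized.
#' @export
radius_from_fibrin <- function(F, F0, Rf0, lden, Ccal) {
  if (any(F < 0) || any(F > F0 * (1 + 1e-12)))
    stop("'F' must lie in [0, F0]", call. = FALSE)
  arg <- Rf0^2 - (F0 - F) / (Ccal * lden)
  ncl <- sum(arg < 0)
  Rf <- sqrt(pmax(arg, 0))
  attr(Rf, "n_clamped") <- ncl
  Rf
}

#' Solid fraction from fiber radius and strand-length density
#'
#' `ns = pi * Rf^2 * lden`: cylinders of radius `Rf` with total length
#' `lden` per unit volume.  Values of 1 or more are non-physical packing
#' and rejected.
#'
#' @param Rf Fiber radius (m), non-negative.
#' @param lden Strand-length density (m^-2), non-negative.
#' @return Solid fraction, vectorized.
#' @export
solid_fraction <- function(Rf, lden) {
  if (any(Rf < 0) || any(lden < 0))
    stop("'Rf' and 'lden' must be non-negative", call. = FALSE)
  ns <- pi * Rf^2 * lden
  if (any(ns >= 1))
    stop("solid fraction >= 1: non-physical packing", call. = FALSE)
  ns
}

#' Calibrate the fibrin-to-permeability chain
#'
#' Anchors the mapping from fibrin concentration to permeability at a
#' reference state: fibrin concentration `F0`, fiber radius `Rf0`, and
#' either the solid fraction `ns0` or the target permeability `k0`
#' (solved from Davies' law by monotone root finding).  The
#' strand-length density and the closure constant follow as
#' `lden = ns0 / (pi Rf0^2)` and `Ccal = F0 / (Rf0^2 lden)`, so that a
#' voxel's fibrin mass is proportional to its fiber cross-section and a
#' fully lysed voxel has zero radius.
#'
#' @param F0 Reference fibrin concentration (mg/ml), positive.
#' @param Rf0 Initial fiber radius (m), positive.
#' @param ns0 Reference solid fraction (exclusive with `k0`).
#' @param k0 Reference permeability (m^2) (exclusive with `ns0`).
#' @return A `clot_calibration` object: list with `F0`, `Rf0`, `ns0`,
#'   `k0`, `lden`, `Ccal`.
#' @export
calibrate_clot <- function(F0, Rf0, ns0 = NULL, k0 = NULL) {
  stopifnot(length(F0) == 1L, length(Rf0) == 1L)
  if (F0 <= 0) stop("'F0' must be positive", call. = FALSE)
  if (Rf0 <= 0) stop("'Rf0' must be positive", call. = FALSE)
  if (is.null(ns0) == is.null(k0))
    stop("give exactly one of 'ns0' or 'k0'", call. = FALSE)
  if (is.null(ns0)) {
    stopifnot(k0 > 0)
    fn <- function(ns) davies_permeability(Rf0, ns) - k0
    lo <- 1e-8; hi <- 0.5
    if (fn(lo) < 0 || fn(hi) > 0)
      stop("no solid fraction in (0, 0.5) matches the requested permeability",
           call. = FALSE)
    ns0 <- stats::uniroot(fn, c(lo, hi), tol = 1e-14)$root
  } else {
    stopifnot(ns0 > 0, ns0 < 1)
    k0 <- davies_permeability(Rf0, ns0)
  }
  lden <- ns0 / (pi * Rf0^2)
  structure(list(F0 = F0, Rf0 = Rf0, ns0 = ns0, k0 = k0,
                 lden = lden, Ccal = F0 / (Rf0^2 * lden)),
            class = "clot_calibration")
}

#' Specification of a synthetic clot
#'
#' Describes the clot to generate: target mean fibrin concentration,
#' physical extent, and heterogeneity archetype.  `"type1"` draws each
#' voxel's concentration from a uniform law centred on the target;
#' `"type2"` scatters high-concentration disks in a lower-concentration
#' matrix whose level is solved so the whole-clot mean hits the target
#' exactly.
#'
#' @param F_M Target mean fibrin concentration (mg/ml).
#' @param kind `"homogeneous"`, `"type1"` or `"type2"`.
#' @param length_m,width_m Clot extent along and across the flow (m).
#' @param dispersion Type-1 half-range of the uniform law, as a
#'   percentage of `F_M` in `[0, 100]` (100 means concentrations span
#'   `0` to `2 F_M`).
#' @param F_disk Type-2 intra-disk concentration (mg/ml), must exceed
#'   `F_M`.
#' @param n_disks Number of disks (type 2).
#' @param disk_radius_m Disk radius (m); disks may overlap and are
#'   clipped at the clot boundary.
#' @param seed Integer seed fixing the generated field.
#' @return A `clot_spec` object.
#' @export
clot_spec <- function(F_M = 2,
                      kind = c("homogeneous", "type1", "type2"),
                      length_m = 5e-3, width_m = 3e-3,
                      dispersion = 0, F_disk = NULL, n_disks = 25L,
                      disk_radius_m = 5e-4, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(F_M > 0, length_m > 0, width_m > 0)
  if (kind == "type1" && (dispersion < 0 || dispersion > 100))
    stop("'dispersion' must lie in [0, 100]", call. = FALSE)
  if (kind == "type2") {
    if (is.null(F_disk)) stop("'F_disk' required for type-2 clots", call. = FALSE)
    if (F_disk < F_M)
      stop("'F_disk' must be at least the target mean 'F_M'", call. = FALSE)
    stopifnot(n_disks >= 1, disk_radius_m > 0)
  }
  structure(list(F_M = F_M, kind = kind, length_m = length_m,
                 width_m = width_m, dispersion = dispersion,
                 F_disk = F_disk, n_disks = as.integer(n_disks),
                 disk_radius_m = disk_radius_m, seed = as.integer(seed)),
            class = "clot_spec")
}

.clot_dims <- function(spec, dx) {
  c(max(1L, as.integer(round(spec$length_m / dx))),
    max(1L, as.integer(round(spec$width_m / dx))))
}

#' Generate a type-1 (uniformly heterogeneous) fibrin field
#'
#' Each voxel draws an independent fibrin concentration from
#' `Uniform(F_M (1 - d/100), F_M (1 + d/100))`, `d` being the dispersion
#' percentage.  Fixing the seed fixes the field bit for bit.
#'
#' @param spec A [clot_spec()] with `kind = "type1"` (or any kind;
#'   `dispersion` is what matters).
#' @param dx Voxel size (m), used to discretize the clot extent.
#' @return Matrix (length-voxels x width-voxels) of fibrin
#'   concentrations (mg/ml).
#' @export
generate_type1 <- function(spec, dx) {
  dims <- .clot_dims(spec, dx)
  set.seed(spec$seed)
  d <- spec$dispersion / 100
  matrix(stats::runif(prod(dims), spec$F_M * (1 - d), spec$F_M * (1 + d)),
         dims[1L], dims[2L])
}

#' Generate a type-2 (disk-heterogeneous) fibrin field
#'
#' Places `n_disks` disks of high concentration `F_disk` at uniformly
#' random centres over the clot rectangle (disks may overlap each other
#' and are clipped at the boundary) and fills the remaining space with
#' the outer concentration that makes the whole-clot mean equal `F_M`
#' exactly.  Configurations whose disk coverage would force a negative
#' outer concentration are rejected.
#'
#' @inheritParams generate_type1
#' @return Matrix of fibrin concentrations (mg/ml); attribute `F_outer`
#'   holds the solved matrix concentration.
#' @export
generate_type2 <- function(spec, dx) {
  if (is.null(spec$F_disk)) stop("'F_disk' missing in spec", call. = FALSE)
  dims <- .clot_dims(spec, dx)
  set.seed(spec$seed)
  cx <- stats::runif(spec$n_disks, 0.5, dims[1L] + 0.5)
  cy <- stats::runif(spec$n_disks, 0.5, dims[2L] + 0.5)
  r_vox <- spec$disk_radius_m / dx
  xs <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  ys <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  in_disk <- matrix(FALSE, dims[1L], dims[2L])
  for (j in seq_len(spec$n_disks))
    in_disk <- in_disk | ((xs - cx[j])^2 + (ys - cy[j])^2 <= r_vox^2)
  n_in <- sum(in_disk)
  n_out <- prod(dims) - n_in
  if (n_out == 0L)
    stop("disks cover the whole clot: no room for the outer matrix",
         call. = FALSE)
  F_out <- (spec$F_M * prod(dims) - spec$F_disk * n_in) / n_out
  if (F_out < 0)
    stop(sprintf(paste0("infeasible spec: disk coverage %.0f%% at F_disk = %g ",
                        "would need a negative outer concentration"),
                 100 * n_in / prod(dims), spec$F_disk), call. = FALSE)
  F <- matrix(F_out, dims[1L], dims[2L])
  F[in_disk] <- spec$F_disk
  attr(F, "F_outer") <- F_out
  F
}

#' Generate a clot field from a specification
#'
#' Dispatches to the homogeneous, type-1 or type-2 generator and wraps
#' the result with its calibration into a `clot_field`: per-voxel fibrin
#' concentration, initial concentration, and strand-length density
#' (`lden` scales with the initial concentration so that the solid
#' fraction is proportional to fibrin everywhere under a common
#' calibration).
#'
#' @param spec A [clot_spec()].
#' @param calib A [calibrate_clot()] result; its `F0` is the reference
#'   concentration at which `ns0`/`k0` hold.
#' @param dx Voxel size (m).
#' @return A `clot_field` object with matrices `F` (current fibrin),
#'   `F0` (initial fibrin), `lden`, and fields `dims`, `calib`, `spec`.
#' @export
generate_clot <- function(spec, calib, dx) {
  stopifnot(inherits(spec, "clot_spec"), inherits(calib, "clot_calibration"))
  F <- switch(spec$kind,
    homogeneous = matrix(spec$F_M, .clot_dims(spec, dx)[1L],
                         .clot_dims(spec, dx)[2L]),
    type1 = generate_type1(spec, dx),
    type2 = generate_type2(spec, dx))
  lden <- calib$lden * F / calib$F0
  structure(list(F = F, F0 = F, lden = lden, dims = dim(F), dx = dx,
                 calib = calib, spec = spec),
            class = "clot_field")
}

#' Per-voxel permeability chain of a clot field
#'
#' Applies the full mapping fibrin -> fiber radius -> solid fraction ->
#' Davies permeability -> bounce-back fraction to every voxel of the
#' clot.  Voxels whose fibrin has fully dissolved are open
#' (`k = Inf`, `gamma = 0`).
#'
#' @param clot A `clot_field`.
#' @param units An [lb_units()] (supplies `nu` and `dt` for the
#'   gamma mapping).
#' @return List of matrices: `Rf`, `ns`, `k`, `gamma`.
#' @export
clot_chain <- function(clot, units) {
  stopifnot(inherits(clot, "clot_field"))
  F <- clot$F; F0 <- clot$F0
  Rf <- matrix(0, nrow(F), ncol(F))
  live <- F0 > 0
  Rf[live] <- radius_from_fibrin(F[live], F0[live], clot$calib$Rf0,
                                 clot$lden[live], clot$calib$Ccal)
  ns <- pi * Rf^2 * clot$lden
  # solid fractions this far below any physical packing are round-off
  # residue of complete dissolution: the voxel is open
  open <- ns < 1e-12
  Rf[open] <- 0
  ns[open] <- 0
  k <- matrix(Inf, nrow(F), ncol(F))
  k[!open] <- davies_permeability(Rf[!open], ns[!open])
  g <- gamma_from_permeability(k, units$nu, units$dt)
  list(Rf = Rf, ns = ns, k = k, gamma = g)
}

#' Bounce-back fraction field of a clot
#'
#' Convenience wrapper returning only the `gamma` matrix of
#' [clot_chain()].
#'
#' @inheritParams clot_chain
#' @return Matrix of bounce-back fractions, one per clot voxel.
#' @export
clot_to_gamma <- function(clot, units) clot_chain(clot, units)$gamma
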