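#' Default run configuration
#'
#' A nested key-value configuration pre-populated with the typical
#' initial conditions of the model: solution viscosity 1e-6 m^2/s,
#' pressure gradient 7.5e3 Pa/m across the clot, tube width 5.8 mm,
#' fibrin 2 mg/ml with lysis threshold 0.2 mg/ml, anti-fibrin agent
#' 1e-5 mg/ml (10 ng/ml) at the inlet, reaction rate 12.5 (s mg/ml)^-1,
#' clot permeability 1e-13 m^2, fiber radius 140 nm, clot length 5 mm,
#' lattice steps dx = 1e-4 m and dt = 2.5e-5 s.  Blocks: `physical`,
#' `numerics`, `clot`, `outputs`, `stop`, plus the `seed`.
#'
#' @return A `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    physical = list(
      nu = 1e-6,          # kinematic viscosity [m^2/s]
      rho = 1000,         # fluid density [kg/m^3]
      grad_P = 7.5e3,     # pressure gradient across the clot [Pa/m]
      D_antifa = 3.3e-11, # anti-fibrin (tPA) diffusion coefficient [m^2/s]
      Fstar = 0.2,        # lysis threshold [mg/ml]
      Fbar0 = 1e-5,       # inlet anti-fibrin concentration [mg/ml]
      k1 = 12.5,          # reaction rate [(s mg/ml)^-1]
      Rf = 1.4e-7,        # initial fiber radius [m]
      k = 1e-13,          # reference clot permeability [m^2]
      ns0 = NULL,         # optional: solid fraction override (else from k)
      L = 5e-3,           # clot length [m]
      width = 5.8e-3),    # tube width [m]
    numerics = list(
      dx = 1e-4,          # lattice spacing [m]
      dt = 2.5e-5,        # lattice time step [s]
      lattice = "D2Q9",
      react_dt_factor = 1e3,  # reaction step = dt * factor
      resolve_every = 10L,    # flow re-solve cadence [reaction steps]
      resolve_dgamma = 0.05,  # extra re-solve trigger on max |dgamma|
      steady_tol = 1e-5,      # quasi-steady velocity tolerance
      init_max_steps = 30000L,
      warm_max_steps = 4000L,
      check_every = 100L,
      lumen_in = 3L,          # open lumen upstream of the clot [voxels]
      lumen_out = 3L),
    clot = list(
      kind = "homogeneous",   # homogeneous | type1 | type2
      F_M = 2,                # target mean fibrin [mg/ml]
      dispersion = 0,         # type-1 half-range [% of F_M]
      F_disk = NULL,          # type-2 intra-disk concentration [mg/ml]
      n_disks = 25L,
      disk_radius = 5e-4),    # type-2 disk radius [m]
    outputs = list(
      sample_every = 5L,      # sampling period [reaction steps]
      snapshot_every = 0L,    # 0 = no field snapshots
      dir = NULL),
    stop = list(
      mass_fraction = 0.005,
      t_max = 1e5,
      max_u_lu = 0.1),   # recanalization envelope: stop once the flow
                         # reaches the solver's low-Mach limit
    seed = 1L), class = "run_config")
}

.cfg_schema <- function() {
  d <- default_run_config()
  lapply(d[setdiff(names(d), "seed")], names)
}

#' Validate a run configuration
#'
#' Checks the block/key structure against the schema of
#' [default_run_config()]: unknown blocks or keys are rejected, missing
#' keys are named, and elementary type/positivity constraints enforced.
#'
#' @param cfg A `run_config`-like list.
#' @return The validated configuration (classed `run_config`).
#' @export
validate_run_config <- function(cfg) {
  schema <- .cfg_schema()
  extra <- setdiff(names(cfg), c(names(schema), "seed"))
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing_b <- setdiff(c(names(schema), "seed"), names(cfg))
  if (length(missing_b))
    stop("missing configuration block(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  for (b in names(schema)) {
    unknown <- setdiff(names(cfg[[b]]), schema[[b]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in '%s': %s", b,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    miss <- setdiff(schema[[b]], names(cfg[[b]]))
    # NULL-able keys may be absent
    nullable <- c("ns0", "F_disk", "dir")
    miss <- setdiff(miss, nullable)
    if (length(miss))
      stop(sprintf("missing key(s) in '%s': %s", b,
                   paste(miss, collapse = ", ")), call. = FALSE)
    for (k in setdiff(schema[[b]], names(cfg[[b]]))) cfg[[b]][k] <- list(NULL)
    cfg[[b]] <- cfg[[b]][schema[[b]]]   # canonical key order
  }
  ph <- cfg$physical
  for (k in c("nu", "rho", "D_antifa", "Fstar", "Fbar0", "k1", "Rf", "L",
              "width"))
    if (!is.numeric(ph[[k]]) || ph[[k]] <= 0)
      stop(sprintf("physical$%s must be a positive number", k), call. = FALSE)
  if (is.null(ph$ns0) && (!is.numeric(ph$k) || ph$k <= 0))
    stop("physical$k must be positive (or give physical$ns0)", call. = FALSE)
  if (!cfg$clot$kind %in% c("homogeneous", "type1", "type2"))
    stop("clot$kind must be homogeneous, type1 or type2", call. = FALSE)
  if (!is.numeric(cfg$seed) || is.na(cfg$seed))
    stop("seed must be an integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Reads a structured key-value configuration, overlays it on the
#' defaults (given keys override, everything else keeps its default)
#' and validates the result.  Unknown keys are fatal.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  extra <- setdiff(names(user), names(cfg))
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (b in names(user)) {
    if (b == "seed") { cfg$seed <- user$seed; next }
    for (k in names(user[[b]])) cfg[[b]][[k]] <- user[[b]][[k]]
  }
  validate_run_config(cfg)
}

#' Write a run configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a field snapshot as a legacy VTK structured-points file
#'
#' ASCII VTK legacy format, one `SCALARS` (matrices) or `VECTORS`
#' (3-column per-node) block per named field, suitable for ParaView.
#'
#' @param path Output file path.
#' @param fields Named list of matrices (all of equal dimensions).
#' @param dx Grid spacing (m).
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(path, fields, dx) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  dims <- dim(fields[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fibrolyse field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", dims[1L], dims[2L]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", dx, dx, dx),
               sprintf("POINT_DATA %d", prod(dims))), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(identical(dim(f), dims))
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest: our matrices are column-major in (x, y)
    writeLines(format(as.numeric(f), digits = 10, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(path)
}

#' Write simulation outputs with a reproducibility manifest
#'
#' Writes a `simulation_record` (or `ensemble_summary`) to a directory:
#' the time series as CSV, the resolved configuration as YAML, optional
#' VTK snapshots, an ensemble's replicate table as CSV and aggregate
#' JSON, and a `manifest.json` listing every artifact with its MD5
#' content hash.
#'
#' @param x A `simulation_record` or `ensemble_summary`.
#' @param dir Output directory (created if needed).
#' @return The manifest as a list, invisibly.
#' @export
write_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (inherits(x, "simulation_record")) {
    p <- file.path(dir, "timeseries.csv")
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    paths <- c(paths, p)
    cfg <- attr(x, "config")
    if (!is.null(cfg)) {
      p <- file.path(dir, "config.yaml")
      write_run_config(cfg, p)
      paths <- c(paths, p)
    }
    snaps <- attr(x, "snapshots")
    if (!is.null(snaps)) {
      dx <- attr(x, "config")$numerics$dx
      # fibrin lives on the clot grid, the agent on the full domain grid
      for (i in seq_along(snaps)) {
        pf <- file.path(dir, sprintf("snapshot_%04d_fibrin.vtk", i))
        write_vtk_fields(pf, list(fibrin = snaps[[i]]$F), dx)
        pa <- file.path(dir, sprintf("snapshot_%04d_antifa.vtk", i))
        write_vtk_fields(pa, list(antifa = snaps[[i]]$Fbar), dx)
        paths <- c(paths, pf, pa)
      }
    }
  } else if (inherits(x, "ensemble_summary")) {
    p <- file.path(dir, "replicates.csv")
    utils::write.csv(x$replicates, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "ensemble.json")
    jsonlite::write_json(x[c("t50_mean", "t50_rel_half_spread",
                             "onset_mean_s", "onset_fraction", "failures")],
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  } else stop("unsupported output object", call. = FALSE)
  manifest <- list(artifacts = lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
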