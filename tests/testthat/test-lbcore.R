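test_that("lattice stencils satisfy the moment and symmetry identities", {
  for (model in c("D2Q9", "D3Q19")) {
    lat <- lb_lattice(model)
    expect_equal(sum(lat$w), 1)
    expect_equal(colSums(lat$w * lat$c), rep(0, lat$dim))
    # second moment isotropy: sum w c_a c_b = cs2 delta_ab
    M2 <- t(lat$c) %*% (lat$w * lat$c)
    expect_equal(M2, diag(lat$cs2, lat$dim), tolerance = 1e-12)
    expect_equal(lat$c[1L, ], rep(0, lat$dim))   # rest velocity first
    expect_equal(lat$c[lat$opp, ], -lat$c, ignore_attr = TRUE)
  }
})

test_that("equilibrium populations reproduce density and momentum", {
  lat <- lb_lattice("D2Q9")
  # rest state: equilibrium is the weight vector
  expect_equal(as.numeric(lb_equilibrium(lat, 1, c(0, 0))), lat$w)
  # frozen hand value: rest population at rho = 1, u = (0.1, 0)
  feq <- lb_equilibrium(lat, 1, c(0.1, 0))
  expect_equal(feq[1L], 4 / 9 * (1 - 0.015), tolerance = 1e-12)
  # moments identity for random small velocities
  set.seed(1)
  rho <- stats::runif(20, 0.8, 1.2)
  u <- matrix(stats::runif(40, -0.05, 0.05), 20, 2)
  feq <- lb_equilibrium(lat, rho, u)
  expect_equal(rowSums(feq), rho, tolerance = 1e-12)
  expect_equal(feq %*% lat$c, rho * u, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("BGK collision conserves mass and momentum and has the right fixed points", {
  units <- units_tau(1)
  lat <- lb_lattice("D2Q9")
  st <- lb_state(lat, c(4L, 4L), units)
  set.seed(2)
  st$f <- matrix(stats::runif(16 * 9, 0.01, 0.2), 16, 9)
  fs <- lb_collide(st)
  expect_equal(rowSums(fs), rowSums(st$f), tolerance = 1e-12)
  expect_equal(fs %*% lat$c, st$f %*% lat$c, tolerance = 1e-12)
  # tau = 1: full relaxation to equilibrium
  rho <- rowSums(st$f)
  u <- (st$f %*% lat$c) / rho
  expect_equal(fs, lb_equilibrium(lat, rho, u), tolerance = 1e-12)
  # equilibrium is a fixed point at any tau
  st2 <- st
  st2$f <- lb_equilibrium(lat, rho, u)
  st2$units <- units_tau(0.8)
  expect_equal(lb_collide(st2), st2$f, tolerance = 1e-12)
})

test_that("streaming propagates populations and conserves mass", {
  units <- units_tau(1)
  lat <- lb_lattice("D2Q9")
  st <- lb_state(lat, c(5L, 5L), units)
  # a single marked population moves one node per step in its direction
  st$f[] <- 0
  node <- 7L   # (2, 2)
  st$f[node, 2L] <- 1   # direction (1, 0)
  fs <- st$f            # tau irrelevant for a pure streaming check
  fnew <- lb_stream_pbb(st, fs)
  expect_equal(which(fnew[, 2L] != 0), 8L)  # (3, 2)
  expect_equal(sum(fnew), sum(st$f))
  # uniform field: streaming is the identity
  stu <- lb_state(lat, c(5L, 5L), units)
  expect_equal(lb_stream_pbb(stu, stu$f), stu$f)
})

test_that("fused kernel matches the R reference step on random gray domains", {
  units <- units_tau(0.8)
  lat <- lb_lattice("D2Q9")
  set.seed(3)
  for (case in 1:3) {
    nx <- 7L; ny <- 6L
    flags <- matrix(0L, nx, ny)
    flags[, 1L] <- 1L; flags[, ny] <- 1L           # walls
    st <- lb_state(lat, c(nx, ny), units, flags = flags,
                   gamma = stats::runif(nx * ny, 0, 1))
    if (case == 2L) st <- lb_apply_pressure_drop(st, 100)
    if (case == 3L) st <- lb_set_body_force(st, 50)
    # random low-Mach states: equilibrium at random density/velocity
    # plus a small non-equilibrium perturbation
    rho <- stats::runif(nx * ny, 0.9, 1.1)
    u <- matrix(stats::runif(nx * ny * 2, -0.03, 0.03), nx * ny, 2)
    st$f <- lb_equilibrium(lat, rho, u) *
      matrix(stats::runif(nx * ny * 9, 0.98, 1.02), nx * ny, 9)
    ref <- lb_stream_pbb(st, lb_collide(st))
    got <- lb_run(st, steps = 1L)$f
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("partial bounce-back reduces to streaming and to solid bounce-back", {
  units <- units_tau(1)
  lat <- lb_lattice("D2Q9")
  set.seed(4)
  f0 <- matrix(stats::runif(25 * 9, 0.01, 0.2), 25, 9)
  # gamma = 0: identical to plain streaming (periodic box)
  st0 <- lb_state(lat, c(5L, 5L), units); st0$f <- f0
  stg <- st0; stg$gamma <- rep(0, 25)
  expect_equal(lb_stream_pbb(stg, f0), lb_stream_pbb(st0, f0))
  # gamma = 0.5 node splits a single incoming population equally:
  # transmitted part streams on, reflected part returns
  st <- lb_state(lat, c(5L, 1L), lb_units(1e-4, 2.5e-5, 1e-6))
  st$gamma <- c(0, 0, 0.5, 0, 0)
  st$f[] <- 0
  st$f[3L, 2L] <- 1          # at gray node, moving +x
  st$f[3L, 4L] <- 0.25       # at gray node, moving -x (pre-collision)
  fs <- st$f                 # inspect pure PBB streaming of fs
  fnew <- lb_stream_pbb(st, fs)
  expect_equal(fnew[4L, 2L], 0.5 * 1 + 0.5 * 0.25)  # transmitted + bounced
  expect_equal(fnew[2L, 4L], 0.5 * 0.25 + 0.5 * 1)  # transmitted + bounced
  # mass conserved
  expect_equal(sum(fnew), sum(fs))

  # gamma = 1 slab in a channel behaves as a solid wall: steady flow
  # around/none through, and total mass constant
  st1 <- lb_state(lat, c(6L, 6L), units, gamma = rep(1, 36))
  set.seed(5)
  st1$f <- matrix(stats::runif(36 * 9, 0.01, 0.2), 36, 9)
  m0 <- sum(st1$f)
  st1 <- lb_run(st1, steps = 50L)
  expect_equal(sum(st1$f), m0, tolerance = 1e-12)
  expect_equal(max(abs(lb_macroscopic(st1)$u)), 0)   # Eq-14 velocity zero
})

test_that("closed and periodic domains conserve mass over long runs", {
  units <- units_tau(1)
  lat <- lb_lattice("D2Q9")
  # periodic box with random gray field
  set.seed(6)
  st <- lb_state(lat, c(8L, 8L), units, gamma = stats::runif(64, 0, 0.9))
  st$f <- matrix(stats::runif(64 * 9, 0.01, 0.2), 64, 9)
  m0 <- sum(st$f)
  st <- lb_run(st, steps = 1000L)
  expect_equal(sum(st$f), m0, tolerance = 1e-12)
  # closed box (walls all around)
  flags <- matrix(0L, 8L, 8L)
  flags[1L, ] <- 1L; flags[8L, ] <- 1L; flags[, 1L] <- 1L; flags[, 8L] <- 1L
  st2 <- lb_state(lat, c(8L, 8L), units, flags = flags)
  set.seed(7)
  st2$f[st2$flags == 0L, ] <- matrix(stats::runif(36 * 9, 0.01, 0.2), 36, 9)
  m0 <- lb_mass(st2)
  st2 <- lb_run(st2, steps = 1000L)
  expect_equal(lb_mass(st2), m0, tolerance = 1e-12)
  # 3D periodic box, D3Q19
  lat3 <- lb_lattice("D3Q19")
  st3 <- lb_state(lat3, c(4L, 4L, 4L), units)
  set.seed(8)
  st3$f <- matrix(stats::runif(64 * 19, 0.01, 0.2), 64, 19)
  m0 <- sum(st3$f)
  st3 <- lb_run(st3, steps = 200L)
  expect_equal(sum(st3$f), m0, tolerance = 1e-12)
})

test_that("macroscopic velocity follows the partial-bounce-back convention", {
  lat <- lb_lattice("D2Q9")
  units <- units_tau(1)
  st <- lb_state(lat, c(3L, 3L), units)
  expect_equal(lb_macroscopic(st)$rho, rep(1, 9))
  expect_equal(max(abs(lb_macroscopic(st)$u)), 0)
  # gamma scales the bare momentum linearly; gamma = 1 kills it
  st$f <- lb_equilibrium(lat, rep(1, 9), matrix(rep(c(0.02, 0), each = 9), 9))
  u_bare <- lb_macroscopic(st)$u[1L, 1L]
  st$gamma <- rep(0.5, 9)
  expect_equal(lb_macroscopic(st)$u[1L, 1L], u_bare / 2, tolerance = 1e-12)
  st$gamma <- rep(1, 9)
  expect_equal(lb_macroscopic(st)$u[1L, 1L], 0)
})

test_that("shear-wave decay recovers the nominal kinematic viscosity", {
  tau <- 0.8
  units <- units_tau(tau)
  nu_lu <- (tau - 0.5) / 3
  lat <- lb_lattice("D2Q9")
  ny <- 32L
  st <- lb_state(lat, c(4L, ny), units)
  y <- rep(seq_len(ny), each = 4L)
  u0 <- 0.01 * sin(2 * pi * (y - 1) / ny)
  st$f <- lb_equilibrium(lat, rep(1, 4L * ny), cbind(u0, 0))
  a0 <- max(abs(lb_macroscopic(st)$u[, 1L]))
  steps <- 400L
  st <- lb_run(st, steps = steps)
  a1 <- max(abs(lb_macroscopic(st)$u[, 1L]))
  k2 <- (2 * pi / ny)^2
  nu_meas <- -log(a1 / a0) / (k2 * steps)
  expect_lt(abs(nu_meas - nu_lu) / nu_lu, 0.02)
})

test_that("body-force channel flow matches the plane-Poiseuille parabola", {
  res <- poiseuille_benchmark(nx = 12L, ny_fluid = 24L, max_steps = 30000L)
  expect_lt(res$max_rel_err, 0.02)
  # no-slip: extrapolated wall velocity vanishes at the half-way plane
  p <- res$profile
  expect_lt(p$simulated[1L] / max(p$simulated), 0.12)
})

test_that("pressure-driven flow is Stokes-linear and off at zero drive", {
  units <- units_tau(0.6)
  st0 <- lb_channel(20L, 12L, units, grad_P = 0, drive = "pressure")
  st0 <- run_to_steady(st0, tol = 1e-9, max_steps = 20000L)
  expect_lt(max(abs(lb_macroscopic(st0)$u)), 1e-12)

  qof <- function(gp) {
    st <- lb_channel(20L, 12L, units, grad_P = gp, drive = "pressure")
    st <- run_to_steady(st, tol = 1e-10, max_steps = 60000L)
    ux <- matrix(lb_macroscopic(st)$u[, 1L], 20L, 12L)
    mean(rowSums(ux[2:19, 2:11]))
  }
  q1 <- qof(20); q2 <- qof(40)
  expect_gt(q1, 0)
  expect_equal(q2 / q1, 2, tolerance = 0.01)
})

test_that("unstable configurations are rejected with actionable errors", {
  expect_error(lb_units(1e-4, 1e-1, 1e-6), "tau")      # tau > 2
  units <- units_tau(0.6)
  st <- lb_channel(10L, 8L, units, drive = "force")
  expect_error(lb_apply_pressure_drop(st, 1e9), "compressibility")
  # divergence reported with tau and the velocity reached
  st$force_lu <- c(0.5, 0)
  expect_error(lb_run(st, steps = 5000L), "unstable|velocity")
})
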