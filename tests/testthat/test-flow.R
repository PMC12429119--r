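test_that("quiescent state with no forcing stays exactly zero", {
  g <- straight_annulus()
  m <- csf_mesh(g, nz = 6, nr = 4, refine = 1)
  bc <- flow_bc("none", closed = TRUE)
  ops <- make_flow_ops_test(m, bc)
  state <- init_flow_state_test(m)
  props <- fluid_properties()
  for (k in 1:5) state <- flow_step(state, m, props, bc, 0.01, ops = ops)
  expect_identical(max(abs(state$w)), 0)
  expect_identical(max(abs(state$v)), 0)
  expect_lt(max(abs(state$p)), 1e-12)
})

test_that("steady annular flow matches the closed-form Poiseuille profile", {
  a <- 4e-3; b <- 7e-3
  g <- straight_annulus(a, b)
  m <- csf_mesh(g, nz = 8, nr = 16, refine = 1)
  G <- 1.0
  run <- csf_simulate(30, geometry = g, mesh = m, bc = flow_bc("none"),
                      transport = transport_params(D = 0), dt = 0.05,
                      body_force = c(G, 0), record_dt = 30,
                      probe_windows = character(0))
  wz <- cell_velocity_test(run$state, m)$wz[4, ]
  wan <- poiseuille_annulus(m$r_c[4, ], a, b, G, fluid_properties()$mu)
  expect_lt(sqrt(sum((wz - wan)^2) / sum(wan^2)), 0.01)
})

test_that("oscillatory annular flow matches the Womersley-type analytic series", {
  a <- 4e-3; b <- 7e-3
  g <- straight_annulus(a, b)
  m <- csf_mesh(g, nz = 8, nr = 24, refine = 1)
  props <- fluid_properties()
  om <- 2 * pi; G <- 50; dt <- 0.002
  bc <- flow_bc("none")
  ops <- make_flow_ops_test(m, bc)
  state <- init_flow_state_test(m)
  nsteps <- as.integer(3 / dt)
  ic <- 4L
  ts <- numeric(nsteps); wmid <- matrix(0, nsteps, m$nr)
  for (k in seq_len(nsteps)) {
    tk <- k * dt
    state <- flow_step(state, m, props, bc, dt, ops = ops,
                       body_force = c(G * cos(om * tk), 0))
    ts[k] <- tk
    wmid[k, ] <- 0.5 * (state$w[ic, ] + state$w[ic + 1L, ])
  }
  ## fit amplitude/phase over the last period, after two warm-up periods
  sel <- ts > 2
  X <- cbind(cos(om * ts[sel]), sin(om * ts[sel]))
  Wnum <- vapply(seq_len(m$nr), function(j) {
    cf <- stats::lsfit(X, wmid[sel, j], intercept = FALSE)$coefficients
    complex(real = cf[1], imaginary = -cf[2])
  }, complex(1))
  Wan <- womersley_annulus(m$r_c[ic, ], a, b, G, props$rho, props$nu, om)
  expect_lt(sqrt(sum(Mod(Wnum - Wan)^2) / sum(Mod(Wan)^2)), 0.03)
  jmid <- m$nr %/% 2
  expect_lt(Mod(Wnum[jmid] - Wan[jmid]) / Mod(Wan[jmid]), 0.03)
})

test_that("kinetic energy decays monotonically without forcing", {
  a <- 4e-3; b <- 7e-3
  g <- straight_annulus(a, b)
  m <- csf_mesh(g, nz = 8, nr = 12, refine = 1)
  bc <- flow_bc("none", closed = TRUE)
  ops <- make_flow_ops_test(m, bc)
  state <- init_flow_state_test(m)
  ## start from a nontrivial solenoidal-ish field; the first projection
  ## restores discrete incompressibility
  state$w[2:m$nz, ] <- outer(sin(pi * (2:m$nz) / m$nz), m$eta_c * (1 - m$eta_c)) * 0.05
  props <- fluid_properties()
  ke <- function(s) {
    vel <- cell_velocity_test(s, m)
    sum(0.5 * props$rho * vel$mag^2 * m$V)
  }
  state <- flow_step(state, m, props, bc, 0.01, ops = ops)  # projection
  es <- ke(state)
  for (k in 1:30) {
    state <- flow_step(state, m, props, bc, 0.01, ops = ops)
    es <- c(es, ke(state))
  }
  expect_true(all(diff(es) <= 1e-15 * es[1]))
  expect_lt(tail(es, 1), es[1])
})

test_that("every accepted step is discretely divergence-free and monitored", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 32, nr = 4)
  run <- csf_simulate(1, geometry = g, mesh = m, record_dt = 1)
  expect_lt(run$diagnostics$max_div_residual, 1e-8)
  expect_gte(run$diagnostics$max_inner_iters, 1L)
  expect_true(all(is.finite(run$state$w)), all(is.finite(run$state$p)))
})

test_that("temporal refinement of the baseline case is converged at dt = 0.01 s", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 48, nr = 6)
  tab <- timestep_study(dts = c(0.02, 0.01, 0.005), t_end = 5,
                        geometry = g, mesh = m)
  expect_identical(nrow(tab), 2L)
  expect_lt(tab$l2_change_pct[2], 1)
})

test_that("boundary resolution imposes walls, fluxes and flags over-constraint", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 32, nr = 4)
  ## Q = 0: every imposed flux is zero
  w0 <- combine_waveforms(make_cardiac(60, 1e-9), make_respiratory(12, 0), 0)
  bc0 <- flow_bc("caudal", waveform = make_respiratory(12, 0))
  b <- apply_boundary(bc0, m, 0.3)
  expect_equal(max(abs(b$w_lo)), 0)
  expect_true(b$outlet_hi)
  ## Q = 1 mL/s distributed as uniform normal velocity 1e-6 / A
  wq <- make_production(1e-6)
  bq <- apply_boundary(flow_bc("caudal", wq), m, 0)
  expect_equal(bq$w_lo, rep(1e-6 / sum(m$A_z[1, ]), m$nr), tolerance = 1e-12)
  ## radial wall faces always carry zero velocity in any simulated state
  run <- csf_simulate(0.5, geometry = g, mesh = m, record_dt = 0.5)
  expect_identical(max(abs(run$state$v[, c(1, m$nr + 1)])), 0)
  ## velocity imposed on all boundaries of a closed domain: rejected
  expect_error(flow_bc("caudal", wq, closed = TRUE), "over-constrained")
})
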