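test_that("pure diffusion reproduces the analytic variance growth 2 D t", {
  g <- straight_annulus(L = 0.2)
  m <- csf_mesh(g, nz = 200, nr = 4, refine = 1)
  state <- init_flow_state_test(m)
  D <- 1e-6
  tp <- transport_params(D = D)
  conc <- init_concentration_test(m)
  s0 <- 0.01; z0 <- 0.1
  conc$C <- matrix(exp(-(m$z_c - z0)^2 / (2 * s0^2)), m$nz, m$nr)
  variance <- function(conc) {
    mass <- sum(conc$C * m$V); zm <- sum(conc$C * m$V * m$z_c) / mass
    sum(conc$C * m$V * (m$z_c - zm)^2) / mass
  }
  v0 <- variance(conc)
  for (k in 1:100) conc <- advance_concentration(conc, state, tp, m, 0.1)
  expect_equal(variance(conc) - v0, 2 * D * 10, tolerance = 0.02)
})

test_that("uniform advection translates a blob at the flow speed", {
  g <- straight_annulus(L = 0.2)
  m <- csf_mesh(g, nz = 200, nr = 4, refine = 1)
  state <- init_flow_state_test(m)
  u0 <- 0.05
  state$w[] <- u0
  tp <- transport_params(D = 0)
  conc <- init_concentration_test(m)
  conc$C <- matrix(exp(-(m$z_c - 0.06)^2 / (2 * 0.015^2)), m$nz, m$nr)
  dt <- 0.4 * (0.2 / 200) / u0
  n <- round(1 / dt)
  for (k in seq_len(n)) conc <- advance_concentration(conc, state, tp, m, dt)
  ## centroid moved by u0 * t; peak decays mildly (scheme order), no overshoot
  mass <- sum(conc$C * m$V)
  zm <- sum(conc$C * m$V * m$z_c) / mass
  expect_equal(zm - 0.06, u0 * n * dt, tolerance = 0.01)
  expect_gt(max(conc$C), 0.9)
  expect_lte(max(conc$C), 1 + 1e-12)
  expect_gte(min(conc$C), -1e-12)
})

test_that("grid-convergence order: ~2 for the limited scheme, ~1 for first-order upwind", {
  e1 <- advection_l1_error(100, "vanleer")
  e2 <- advection_l1_error(200, "vanleer")
  expect_gte(log2(e1 / e2), 1.8)
  f1 <- advection_l1_error(200, "first-order")
  f2 <- advection_l1_error(400, "first-order")
  expect_gte(log2(f1 / f2), 0.9)
  expect_lt(log2(f1 / f2), 1.2)
})

test_that("constant concentration is preserved by divergence-free transport", {
  g <- straight_annulus()
  m <- csf_mesh(g, nz = 24, nr = 6, refine = 1)
  bc <- flow_bc("none", closed = TRUE)
  ops <- make_flow_ops_test(m, bc)
  state <- init_flow_state_test(m)
  state$w[2:m$nz, ] <- 0.01
  state <- flow_step(state, m, fluid_properties(), bc, 0.01, ops = ops)
  conc <- init_concentration_test(m)
  conc$C[] <- 1
  tp <- transport_params(D = 0)
  for (k in 1:20) conc <- advance_concentration(conc, state, tp, m, 0.01)
  expect_equal(range(conc$C), c(1, 1), tolerance = 1e-12)
})

test_that("no new extrema are created under oscillatory advection", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 48, nr = 4)
  p <- injection_protocol("25G", 0.68, 5)
  run <- csf_simulate(8, protocol = p, geometry = g, mesh = m, record_dt = 0.2)
  expect_gte(min(run$conc$C), -1e-9)
  expect_lte(max(run$conc$C), 1 + 1e-9)
})

test_that("drug mass ledger closes and matches the protocol volume", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 48, nr = 4)
  p <- injection_protocol("25G", 0.68, 30)     # run 5
  run <- csf_simulate(35, protocol = p, geometry = g, mesh = m, record_dt = 0.5)
  target <- 0.68 * 30 * needle_area("25G")
  expect_equal(run$conc$injected, target, tolerance = 1e-3)
  ## canal + stub + reservoir holds everything injected, closed to 0.1%
  total <- total_drug_mass(run$conc, m) + run$conc$out_caudal + run$conc$out_cranial
  expect_equal(total, target, tolerance = 1e-3)
  expect_lt(ledger_closure_test(run$conc, m), 1e-3)
  ## closure held at every recorded time
  closure <- abs(run$ledger$injected -
                 (run$ledger$resident + run$ledger$out_cranial + run$ledger$out_caudal))
  expect_lt(max(closure) / target, 1e-3)
})

test_that("total drug mass is the volume integral of concentration", {
  g <- straight_annulus()
  m <- csf_mesh(g, nz = 10, nr = 3, refine = 1)
  conc <- init_concentration_test(m)
  expect_identical(total_drug_mass(conc, m), 0)
  conc$C[] <- 1
  expect_equal(total_drug_mass(conc, m), m$volume, tolerance = 1e-12)
  conc$C[] <- 0.25
  expect_equal(total_drug_mass(conc$C, m), 0.25 * m$volume, tolerance = 1e-12)
})

test_that("boundedness guard rejects a CFL-violating step", {
  g <- straight_annulus(L = 0.2)
  m <- csf_mesh(g, nz = 100, nr = 3, refine = 1)
  state <- init_flow_state_test(m)
  state$w[] <- 0.05
  conc <- init_concentration_test(m)
  conc$C <- matrix(as.numeric(m$z_c > 0.05 & m$z_c < 0.1), m$nz, m$nr)
  tp <- transport_params(D = 0)
  dt_bad <- 5 * (0.2 / 100) / 0.05     # CFL = 5
  expect_error({
    for (k in 1:30) conc <- advance_concentration(conc, state, tp, m, dt_bad)
  }, "out of bounds")
})
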