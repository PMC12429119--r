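test_that("needle bore area follows pi d^2 / 4", {
  expect_equal(needle_area(needle_spec(inner_diameter = 0.413e-3)),
               1.3396e-7, tolerance = 1e-4)
  expect_equal(needle_area("25G"), pi * (0.260e-3)^2 / 4, tolerance = 1e-12)
  ## doubling the bore quadruples the area
  expect_equal(needle_area(needle_spec(inner_diameter = 0.6e-3)),
               4 * needle_area(needle_spec(inner_diameter = 0.3e-3)),
               tolerance = 1e-12)
  expect_error(needle_area(0), "positive")
  expect_error(needle_spec("19G"), "unknown gauge")
})

test_that("equal-volume speed scaling reproduces the run matrix couplings", {
  protos <- build_run_matrix()
  ## 27G reference 1.04 m/s x 10 s rescaled to 50 s: 0.208 ~ printed 0.21
  v9 <- equal_volume_speed(protos[[7]], 50)
  expect_equal(v9, 1.04 * 10 / 50, tolerance = 1e-12)
  expect_equal(round(v9, 2), 0.21)
  ## 25G reference 2.04 m/s x 10 s rescaled to 30 s gives row 5's 0.68
  expect_equal(equal_volume_speed(protos[[4]], 30), 0.68, tolerance = 1e-12)
  ## identity
  expect_equal(equal_volume_speed(protos[[4]], protos[[4]]$duration),
               protos[[4]]$speed)
  expect_error(equal_volume_speed(protos[[1]], 0), "positive")
})

test_that("run matrix carries the nine scenarios verbatim", {
  protos <- build_run_matrix()
  tab <- attr(protos, "table")
  expect_length(protos, 9L)
  expect_identical(tab$gauge, rep(c("22G", "25G", "27G"), each = 3))
  expect_identical(tab$speed, c(3.8, 1.06, 0.637, 2.04, 0.68, 0.41, 1.04, 0.35, 0.21))
  expect_identical(tab$duration, rep(c(10, 30, 50), times = 3))
  expect_identical(protos[[1]]$needle$gauge, "22G")
  expect_identical(protos[[6]]$speed, 0.41)
  expect_identical(protos[[6]]$duration, 50)
  ## derived quantities
  for (p in protos) {
    expect_equal(p$flow_rate, p$speed * needle_area(p$needle), tolerance = 1e-12)
    expect_equal(p$volume, p$flow_rate * p$duration, tolerance = 1e-12)
  }
})

test_that("within-gauge speed x duration products are near-constant", {
  tab <- attr(build_run_matrix(), "table")
  prod <- tab$speed * tab$duration
  for (rows in list(2:3, 4:6, 7:9)) {
    expect_lt(diff(range(prod[rows])) / max(prod[rows]), 0.01)
  }
  ## documented exception: run 1's product deviates from its group
  expect_gt(abs(prod[1] - prod[2]) / prod[2], 0.01)
})

test_that("injection source conserves flux and respects its time window", {
  g <- csf_geometry()
  m <- csf_mesh(g)
  p <- injection_protocol("22G", 3.8, 10, start = 2)
  s_before <- injection_source(p, m, 1)
  expect_false(s_before$active)
  expect_identical(s_before$q_vol, 0)
  s_on <- injection_source(p, m, 5)
  expect_true(s_on$active)
  expect_equal(s_on$q_vol, 3.8 * 1.3396e-7, tolerance = 1e-4)
  expect_equal(s_on$q_drug, s_on$q_vol)
  ## jet momentum rho Q v, perpendicular entry (radially inward)
  expect_equal(s_on$F_r, -998.3 * s_on$q_vol * 3.8, tolerance = 1e-12)
  expect_equal(s_on$F_z, 0)
  s_after <- injection_source(p, m, 12)
  expect_false(s_after$active)
  ## tip cell sits inside the L4-L5 window near the dural wall
  win <- locate_level(g, "L4-L5")
  zc <- m$z_c[s_on$cell[1]]
  expect_true(zc >= win[1] && zc < win[2])
  expect_identical(s_on$cell[[2]], m$nr)
})

test_that("time-integrated drug inflow equals the protocol volume", {
  ## quadrature of the (piecewise-constant) source against the closed form
  g <- csf_geometry(); m <- csf_mesh(g)
  p <- injection_protocol("25G", 2.04, 10)     # run 4
  dt <- 0.01
  ts <- seq(0, 15 - dt, by = dt)
  tot <- sum(vapply(ts, function(t) injection_source(p, m, t)$q_drug, 1)) * dt
  expect_equal(tot, 2.04 * 10 * needle_area("25G"), tolerance = 1e-3)
})

test_that("bundled run-matrix fixture matches the built protocols", {
  f <- system.file("extdata", "run_matrix.tsv", package = "csfsim")
  expect_true(nzchar(f))
  fix <- utils::read.delim(f)
  tab <- attr(build_run_matrix(), "table")
  expect_equal(fix$speed, tab$speed)
  expect_equal(fix$duration, tab$duration)
  expect_identical(fix$gauge, tab$gauge)
})
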