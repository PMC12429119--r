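## one small shared run with a snapshot for the window metrics
metrics_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- csf_geometry()
      m <- csf_mesh(g, nz = 48, nr = 4)
      p <- injection_protocol("22G", 3.8, 2)
      cache <<- csf_simulate(4, protocol = p, geometry = g, mesh = m,
                             record_dt = 0.5, snapshot_times = c(2, 4))
    }
    cache
  }
})

test_that("window means are volume-weighted percentages over the level window", {
  run <- metrics_fixture()
  m <- run$mesh
  ## uniform / zero fields through a synthetic snapshot
  run0 <- run
  run0$snapshots <- list(list(t = 4, C = matrix(0, m$nz, m$nr)))
  expect_equal(window_mean(run0, "T12-L1", 4), 0)
  run0$snapshots <- list(list(t = 4, C = matrix(0.5, m$nz, m$nr)))
  for (lab in c("C7-T1", "T12-L1", "L4-L5")) {
    expect_equal(window_mean(run0, lab, 4), 50, tolerance = 1e-12)
  }
  ## a blob entirely caudal to T12-L1 leaves the cervical window at 0
  expect_gt(window_mean(run, "L4-L5", 4), 0)
  expect_equal(window_mean(run, "C7-T1", 4), 0, tolerance = 1e-20)
  expect_error(window_mean(run, "C7-T1", 3.1), "no snapshot")
})

test_that("domain mean percentage is the conservation identity", {
  run <- metrics_fixture()
  ## after injection with everything still inside the spinal compartment:
  ## 100 * V_injected / V_compartment
  vol <- run$protocol$volume
  comp <- run$mesh$volume + run$geometry$caudal_stub_volume
  expect_equal(domain_mean_percentage(run, 4), 100 * vol / comp,
               tolerance = 1e-3)
  ## consistency with the ledger at a recorded time
  i <- which.min(abs(run$times - 4))
  expect_equal(domain_mean_percentage(run, 4) * comp / 100,
               run$ledger$resident[i] + run$ledger$out_caudal[i],
               tolerance = 1e-12)
  ## no injection: 0%
  g <- run$geometry; m <- run$mesh
  base <- csf_simulate(0.5, geometry = g, mesh = m, record_dt = 0.5)
  expect_equal(domain_mean_percentage(base, 0.5), 0)
})

test_that("heatmap table fills run x time cells with provenance", {
  run <- metrics_fixture()
  tab <- render_heatmap(list(run, run), times = c(2, 4))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("gauge", "speed", "duration", "t2", "t4") %in% names(tab)))
  expect_false(anyNA(tab[, c("t2", "t4")]))
  f <- withr::local_tempfile(fileext = ".tsv")
  render_heatmap(list(run), times = c(2, 4), file = f)
  expect_true(file.exists(f))
  expect_identical(nrow(utils::read.delim(f)), 1L)
  expect_error(render_heatmap(list()), "no runs")
  expect_error(render_heatmap(list(run), times = c(2, 999), strict = TRUE),
               "missing snapshot")
  expect_warning(render_heatmap(list(run), times = c(2, 999)), "missing")
})

test_that("cranial arrival is threshold-monotone with +Inf for non-arrival", {
  run <- metrics_fixture()
  g <- run$geometry; m <- run$mesh
  base <- csf_simulate(0.5, geometry = g, mesh = m, record_dt = 0.5)
  expect_identical(cranial_arrival(base), Inf)
  ## arrival at threshold 0 is never later than at a positive threshold
  a0 <- cranial_arrival(run, threshold = 0)
  a1 <- cranial_arrival(run, threshold = 0.01)
  expect_lte(a0, a1)
  ## adjacent to the injection site the drug registers quickly
  expect_lt(cranial_arrival(run, threshold = 0, window = "T12-L1"), Inf)
})

test_that("report tables are deterministic for a fixed configuration", {
  g <- csf_geometry()
  m <- csf_mesh(g, nz = 32, nr = 4)
  p <- injection_protocol("25G", 2.04, 1)
  r1 <- csf_simulate(2, protocol = p, geometry = g, mesh = m, record_dt = 0.5)
  r2 <- csf_simulate(2, protocol = p, geometry = g, mesh = m, record_dt = 0.5)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$window_mean_pct, r2$window_mean_pct)
  expect_identical(r1$state$p, r2$state$p)
})

test_that("window means are stable under mesh refinement", {
  g <- csf_geometry()
  f <- function(z) exp(-(z - 0.15)^2 / (2 * 0.05^2))   # smooth axial profile
  for (lv in list(c(48, 4), c(96, 8))) {
    m <- csf_mesh(g, nz = lv[1], nr = lv[2])
    C <- matrix(f(m$z_c), m$nz, m$nr)
    run <- structure(list(geometry = g, mesh = m, dt = 0.01, times = 1,
                          snapshots = list(list(t = 1, C = C))),
                     class = "csf_run")
    assign(paste0("wm", lv[1]),
           c(window_mean(run, "T12-L1", 1), window_mean(run, "L4-L5", 1)))
  }
  expect_equal(wm48, wm96, tolerance = 0.02)
})
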