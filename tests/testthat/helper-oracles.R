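## Shared fixtures and independent analytic oracles for the solver tests.

## straight annular duct posed as a csf_geometry (no reservoir, no volume
## constraint) -- the verification configuration for the flow oracles
straight_annulus <- function(a = 4e-3, b = 7e-3, L = 0.05) {
  csf_geometry(length = L,
               dura_knots = cbind(c(0, L), c(b, b)),
               cord_knots = cbind(c(0, L), c(a, a)),
               reservoir_volume = 0, caudal_stub_volume = 0,
               volume_range = NULL)
}

## closed-form steady annular Poiseuille profile for body force G (= -dp/dz)
poiseuille_annulus <- function(r, a, b, G, mu) {
  G / (4 * mu) * (b^2 - r^2 + (b^2 - a^2) * log(r / b) / log(b / a))
}

## complex velocity amplitude W(r) of oscillatory annular flow driven by
## G cos(om t):  i om W = G/rho + nu (W'' + W'/r),  W(a) = W(b) = 0.
## Independent oracle: fine-grid second-order FD + complex Thomas solve
## (entirely separate from the package's staggered time-stepping scheme).
womersley_annulus <- function(r_eval, a, b, G, rho, nu, om, n = 4000) {
  r <- seq(a, b, length.out = n + 1)
  h <- r[2] - r[1]
  ri <- r[2:n]
  lo <- 1 / h^2 - 1 / (2 * h * ri)
  di <- -2 / h^2 - 1i * om / nu
  up <- 1 / h^2 + 1 / (2 * h * ri)
  rhs <- rep(-G / (rho * nu), n - 1)
  nn <- n - 1
  cp <- complex(nn); dp <- complex(nn)
  cp[1] <- up[1] / di; dp[1] <- rhs[1] / di
  for (j in 2:nn) {
    m <- di - lo[j] * cp[j - 1]
    cp[j] <- up[j] / m
    dp[j] <- (rhs[j] - lo[j] * dp[j - 1]) / m
  }
  W <- complex(nn); W[nn] <- dp[nn]
  for (j in (nn - 1):1) W[j] <- dp[j] - cp[j] * W[j + 1]
  Wf <- c(0 + 0i, W, 0 + 0i)
  complex(real = stats::approx(r, Re(Wf), r_eval)$y,
          imaginary = stats::approx(r, Im(Wf), r_eval)$y)
}

## L1 error of advecting a Gaussian bump at uniform speed in a straight
## annulus (method-of-characteristics exact solution), for convergence-order
## checks; returns mean absolute error over the domain
advection_l1_error <- function(nz, scheme, u0 = 0.05, tend = 1.0, cfl = 0.4,
                               L = 0.2, s0 = 0.015, z0 = 0.06) {
  g <- straight_annulus(L = L)
  m <- csf_mesh(g, nz = nz, nr = 4, refine = 1)
  state <- init_flow_state_test(m)
  state$w[] <- u0
  tp <- transport_params(D = 0, scheme = scheme)
  conc <- init_concentration_test(m)
  conc$C <- matrix(exp(-(m$z_c - z0)^2 / (2 * s0^2)), m$nz, m$nr)
  dt <- cfl * (L / nz) / u0
  n <- ceiling(tend / dt); dt <- tend / n
  for (k in seq_len(n)) conc <- advance_concentration(conc, state, tp, m, dt)
  Cex <- matrix(exp(-(m$z_c - z0 - u0 * tend)^2 / (2 * s0^2)), m$nz, m$nr)
  sum(abs(conc$C - Cex) * m$V) / sum(m$V)
}

## accessors for package internals used by fixtures
init_flow_state_test <- function(mesh) csfsim:::init_flow_state(mesh)
init_concentration_test <- function(mesh) csfsim:::init_concentration(mesh)
make_flow_ops_test <- function(mesh, bc) csfsim:::make_flow_ops(mesh, bc)
cell_velocity_test <- function(state, mesh) csfsim:::cell_velocity(state, mesh)
ledger_closure_test <- function(conc, mesh) csfsim:::ledger_closure_error(conc, mesh)
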