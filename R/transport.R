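#' Drug transport parameters
#'
#' The drug is a passive miscible scalar (volume fraction C in [0, 1])
#' advected by the solved CSF velocity field and spread by molecular
#' diffusion. No diffusion coefficient is published for the modeled agent;
#' the default is the small-molecule aqueous scale 5e-10 m^2/s and is
#' config-overridable.
#'
#' @param D diffusion coefficient in m^2/s (>= 0).
#' @param scheme convection scheme for the concentration fluxes:
#'   \code{"vanleer"} (limited second-order upwind, default),
#'   \code{"minmod"}, or \code{"first-order"} upwind (the volume-fraction
#'   scheme used by the reference CFD setup).
#' @param bound_tol tolerated overshoot outside [0, 1] before a step is
#'   rejected (numerical boundedness guard).
#' @return object of class \code{transport_params}.
#' @export
transport_params <- function(D = 5e-10, scheme = "vanleer", bound_tol = 1e-6) {
  if (!is.numeric(D) || D < 0) stop("diffusion coefficient must be >= 0")
  limiter_fun(scheme)  # validates
  structure(list(D = D, scheme = scheme, bound_tol = bound_tol),
            class = "transport_params")
}

## fresh concentration field + conservation ledger (all volumes in m^3);
## out_cranial / out_caudal are the drug contents of the cranial reservoir
## and the closed sacral stub (net, so backflow returns drug to the canal)
init_concentration <- function(mesh, C0 = 0) {
  list(C = matrix(C0, mesh$nz, mesh$nr),
       injected = 0, out_cranial = 0, out_caudal = 0)
}

#' Total drug volume in the canal
#'
#' @param C concentration field: an nz x nr matrix of volume fractions, or
#'   the list holding it under \code{$C}.
#' @param mesh a \code{csf_mesh}.
#' @return sum of C x cell volume, in m^3.
#' @export
total_drug_mass <- function(C, mesh) {
  if (is.list(C)) C <- C$C
  sum(C * mesh$V)
}

#' Advance the drug concentration field by one time step
#'
#' Conservative finite-volume update of the advection-diffusion equation,
#' one-way coupled to the (divergence-free) velocity field: limited
#' second-order upwind (or first-order upwind) advective fluxes, explicit
#' central diffusion, strong-stability-preserving two-stage Runge-Kutta in
#' time. Boundary drug fluxes are accumulated into the conservation ledger
#' (cranial outflow feeds the reservoir, whose concentration is returned on
#' backflow), so injected = resident + outflowed holds to quadrature
#' precision at all times.
#'
#' @param conc concentration field list from the internal initializer
#'   (matrix \code{C} + ledger scalars).
#' @param state flow state providing face velocities \code{w}, \code{v}.
#' @param params \code{transport_params}.
#' @param mesh a \code{csf_mesh}.
#' @param dt time step in s (must respect the advective CFL limit).
#' @param src injection source terms at this time (drug inflow at volume
#'   fraction 1), see \code{\link{injection_source}}.
#' @param reservoir_volume cranial reservoir volume in m^3 (sets the
#'   backflow concentration at the cranial opening).
#' @param stub_volume closed sacral stub volume in m^3 (backflow
#'   concentration at the caudal opening).
#' @return updated concentration field list.
#' @export
advance_concentration <- function(conc, state, params, mesh, dt,
                                  src = list(active = FALSE, q_drug = 0,
                                             cell = c(NA, NA)),
                                  reservoir_volume = Inf, stub_volume = Inf) {
  psi <- limiter_fun(params$scheme)
  nz <- mesh$nz; nr <- mesh$nr
  D <- params$D
  q_drug <- if (isTRUE(src$active)) src$q_drug else 0

  res_conc <- if (is.finite(reservoir_volume) && reservoir_volume > 0)
    conc$out_cranial / reservoir_volume else 0
  stub_conc <- if (is.finite(stub_volume) && stub_volume > 0)
    conc$out_caudal / stub_volume else 0

  rhs <- function(C) {
    m <- muscl_div(C, state$w, state$v, mesh$A_z, mesh$A_r, mesh$V, psi,
                   g_lo1 = stub_conc, g_hi1 = res_conc, g_lo2 = 0, g_hi2 = 0,
                   skew = FALSE)
    ten <- -m$divF
    if (D > 0) ten <- ten + D * diffuse_scalar(C, mesh)
    if (q_drug > 0) {
      i <- src$cell[1L]; j <- src$cell[2L]
      ten[i, j] <- ten[i, j] + q_drug / mesh$V[i, j]
    }
    ## boundary drug fluxes (m^3 drug / s): lo face outward = -flux_lo1
    list(ten = ten, out_lo = -sum(m$flux_lo1), out_hi = sum(m$flux_hi1))
  }

  r1 <- rhs(conc$C)
  C1 <- conc$C + dt * r1$ten
  r2 <- rhs(C1)
  C_new <- 0.5 * (conc$C + C1 + dt * r2$ten)
  out_lo <- 0.5 * dt * (r1$out_lo + r2$out_lo)
  out_hi <- 0.5 * dt * (r1$out_hi + r2$out_hi)

  lo <- min(C_new); hi <- max(C_new)
  if (lo < -params$bound_tol || hi > 1 + params$bound_tol) {
    stop(sprintf(paste("transport step rejected: concentration out of bounds",
                       "[%.3g, %.3g] beyond tolerance %.1g (advective CFL",
                       "violation or unlimited scheme?)"), lo, hi, params$bound_tol))
  }

  conc$C <- C_new
  conc$injected <- conc$injected + q_drug * dt
  conc$out_caudal <- conc$out_caudal + out_lo
  conc$out_cranial <- conc$out_cranial + out_hi
  conc
}

## explicit axisymmetric diffusion of a cell scalar: zero-flux at walls/axis,
## zero-gradient at the axial openings (boundary exchange is advective)
diffuse_scalar <- function(C, mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  ## axial fluxes A * dC/dz at interior z-edges
  Fz <- matrix(0, nz + 1L, nr)
  dzc <- mesh$z_c[-1L] - mesh$z_c[-nz]
  Fz[2:nz, ] <- mesh$A_z[2:nz, , drop = FALSE] *
    (C[-1L, , drop = FALSE] - C[-nz, , drop = FALSE]) / dzc
  ## radial fluxes A * dC/dr at interior nodes
  Fr <- matrix(0, nz, nr + 1L)
  if (nr > 1) {
    Fr[, 2:nr] <- mesh$A_r[, 2:nr, drop = FALSE] *
      (C[, -1L, drop = FALSE] - C[, -nr, drop = FALSE]) / mesh$dr_cc
  }
  (Fz[-1L, , drop = FALSE] - Fz[-(nz + 1L), , drop = FALSE] +
   Fr[, -1L, drop = FALSE] - Fr[, -(nr + 1L), drop = FALSE]) / mesh$V
}

## ledger closure check: injected = resident + outflowed (relative to the
## injected volume, or absolute when nothing was injected yet)
ledger_closure_error <- function(conc, mesh) {
  resident <- total_drug_mass(conc$C, mesh)
  gap <- conc$injected - (resident + conc$out_cranial + conc$out_caudal)
  if (conc$injected > 0) abs(gap) / conc$injected else abs(gap)
}
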