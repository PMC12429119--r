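## Slope limiters for the upwind-biased (MUSCL) reconstruction. psi(r) = 0
## recovers first-order upwind; minmod and van Leer give limited second-order
## upwind fluxes that create no new extrema.
limiter_fun <- function(scheme) {
  switch(scheme,
         "first-order" = function(r) 0 * r,
         "minmod" = function(r) pmax(0, pmin(1, r)),
         "vanleer" = function(r) (r + abs(r)) / (1 + abs(r)),
         stop(sprintf("unknown convection scheme '%s'", scheme)))
}

## Finite-volume divergence of the advective flux of a cell field on a
## logically rectangular grid with face-normal velocities.
##   phi : n1 x n2 cell values
##   U1  : (n1+1) x n2 face velocities along dim 1 (positive = increasing index)
##   U2  : n1 x (n2+1) along dim 2
##   A1, A2 : matching face areas; V : cell volumes
##   g_* : ghost values at the four boundaries (scalar or vector), used both
##         for reconstruction and as the inflow value
## Returns flux divergence / V, velocity divergence / V (for the skew
## correction of non-conservative advected quantities), and the boundary
## fluxes along dim 1 (positive = outward at hi, inward at lo).
muscl_div <- function(phi, U1, U2, A1, A2, V, psi,
                      g_lo1 = 0, g_hi1 = 0, g_lo2 = 0, g_hi2 = 0,
                      skew = TRUE) {
  n1 <- nrow(phi); n2 <- ncol(phi)
  eps <- 1e-300

  face_vals <- function(ph, uf, glo, ghi) {
    ## ph: m x n ; returns (m+1) x n upwind-reconstructed face values
    m <- nrow(ph); n <- ncol(ph)
    ext <- rbind(matrix(glo, 1L, n), ph, matrix(ghi, 1L, n))  # rows 1..m+2
    up   <- ext[1:(m + 1L), , drop = FALSE]
    dn   <- ext[2:(m + 2L), , drop = FALSE]
    upup <- ext[c(1L, 1L, seq_len(m - 1L) + 1L), , drop = FALSE]
    dndn <- ext[c(seq_len(m - 1L) + 2L, m + 2L, m + 2L), , drop = FALSE]
    d <- dn - up
    den <- d
    z <- abs(den) < eps
    if (any(z)) den[z] <- eps
    fp <- up + (0.5 * psi((up - upup) / den)) * d   # used when uf > 0
    fm <- dn - (0.5 * psi((dn - dndn) / -den)) * d  # used when uf < 0
    pos <- uf >= 0
    val <- fp * pos + fm * (1 - pos)
    ## boundary faces: first-order outflow, ghost value on inflow
    val[1L, ] <- up[1L, ] * pos[1L, ] + ph[1L, ] * (1 - pos[1L, ])
    val[m + 1L, ] <- ph[m, ] * pos[m + 1L, ] + dn[m + 1L, ] * (1 - pos[m + 1L, ])
    val
  }

  F1 <- A1 * U1 * face_vals(phi, U1, g_lo1, g_hi1)
  F2 <- A2 * U2 * t(face_vals(t(phi), t(U2), g_lo2, g_hi2))

  divF <- (F1[-1L, , drop = FALSE] - F1[-(n1 + 1L), , drop = FALSE] +
           F2[, -1L, drop = FALSE] - F2[, -(n2 + 1L), drop = FALSE]) / V
  divU <- if (skew) {
    (A1[-1L, , drop = FALSE] * U1[-1L, , drop = FALSE] -
     A1[-(n1 + 1L), , drop = FALSE] * U1[-(n1 + 1L), , drop = FALSE] +
     A2[, -1L, drop = FALSE] * U2[, -1L, drop = FALSE] -
     A2[, -(n2 + 1L), drop = FALSE] * U2[, -(n2 + 1L), drop = FALSE]) / V
  }
  list(divF = divF, divU = divU,
       flux_lo1 = F1[1L, ], flux_hi1 = F1[n1 + 1L, ])
}

#' Iterative convergence monitor
#'
#' Tracks successive inner-iteration snapshots of a flow variable and applies
#' the normalized successive-difference criterion: converged when
#' \eqn{\max_{i,j,k} |\delta^{n+1} - \delta^n| / |\delta^{n+1}|} falls below
#' \code{tolerance}. Where \eqn{|\delta^{n+1}|} is below \code{floor} the
#' absolute difference is used instead (the zero-denominator guard).
#'
#' @param tolerance dimensionless convergence tolerance (default 1e-6).
#' @param floor denominator guard (default 1e-30).
#' @return object of class \code{convergence_monitor}.
#' @export
convergence_monitor <- function(tolerance = 1e-6, floor = 1e-30) {
  stopifnot(tolerance > 0, floor >= 0)
  structure(list(tolerance = tolerance, floor = floor,
                 snapshots = list(), metrics = numeric(0)),
            class = "convergence_monitor")
}

#' Record an iteration snapshot
#' @param mon a \code{convergence_monitor}.
#' @param x numeric array: the monitored variable at this inner iteration.
#' @return the updated monitor.
#' @export
record_iteration <- function(mon, x) {
  stopifnot(inherits(mon, "convergence_monitor"))
  n <- length(mon$snapshots)
  mon$snapshots[[n + 1L]] <- x
  if (n >= 1L) {
    mon$metrics <- c(mon$metrics, eq_metric(mon$snapshots[[n]], x, mon$floor))
  }
  mon
}

## max over grid points of |new - old| / |new|, absolute difference where
## |new| < floor
eq_metric <- function(old, new, floor = 1e-30) {
  d <- abs(new - old)
  denom <- abs(new)
  small <- denom < floor
  denom[small] <- 1
  max(d / denom)
}

#' Check the convergence criterion
#'
#' @param mon a \code{convergence_monitor} with at least two recorded
#'   snapshots.
#' @return logical: \code{TRUE} iff the latest normalized successive
#'   difference is below the tolerance.
#' @export
check_convergence <- function(mon) {
  stopifnot(inherits(mon, "convergence_monitor"))
  if (length(mon$snapshots) < 2L)
    stop("convergence check requires at least two snapshots")
  utils::tail(mon$metrics, 1L) < mon$tolerance
}
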