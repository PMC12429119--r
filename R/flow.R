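#' Fluid properties
#'
#' @param rho density in kg/m^3; default 998.3 (CSF modeled as water at room
#'   temperature).
#' @param mu dynamic viscosity in Pa s; default 0.89e-3.
#' @return object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(rho = 998.3, mu = 0.89e-3) {
  if (!is.numeric(rho) || rho <= 0) stop("density must be positive")
  if (!is.numeric(mu) || mu <= 0) stop("viscosity must be positive")
  structure(list(rho = rho, mu = mu, nu = mu / rho), class = "fluid_properties")
}

#' Flow boundary specification
#'
#' The canal has two axial openings. One may be driven by a volumetric flow
#' waveform (imposed uniform normal velocity = Q(t) / opening area); the
#' opposite end is then a pressure outlet coupled to the cranial reservoir
#' (or the caudal space). With \code{driven = "none"} both ends are pressure
#' outlets, or solid walls when \code{closed = TRUE} (used for verification
#' cases driven by a body force). All dural/pial walls are no-slip.
#'
#' @param driven \code{"caudal"} (default, the oscillating-velocity end),
#'   \code{"cranial"}, or \code{"none"}.
#' @param waveform a \code{csf_waveform} giving Q(t) at the driven opening
#'   (positive = cranially directed flow).
#' @param closed logical; with \code{driven = "none"}, make both ends
#'   no-through walls instead of outlets.
#' @return object of class \code{flow_bc}.
#' @export
flow_bc <- function(driven = c("caudal", "cranial", "none"), waveform = NULL,
                    closed = FALSE) {
  driven <- match.arg(driven)
  if (driven != "none" && is.null(waveform))
    stop("a driving waveform is required when an end is velocity-driven")
  if (driven != "none" && closed)
    stop(paste("configuration error: velocity imposed on all boundaries of a",
               "closed incompressible domain (over-constrained)"))
  if (!is.null(waveform)) stopifnot(inherits(waveform, "csf_waveform"))
  structure(list(driven = driven, waveform = waveform, closed = closed),
            class = "flow_bc")
}

#' Boundary face constraints at time t
#'
#' Resolves the boundary specification into imposed axial face velocities at
#' the two canal openings and outlet flags. Wall faces (dura, cord) always
#' carry zero velocity; the driven opening carries Q(t) distributed uniformly
#' over its face area.
#'
#' @param bc a \code{flow_bc}.
#' @param mesh a \code{csf_mesh}.
#' @param t time in s.
#' @return list with \code{w_lo}, \code{w_hi} (imposed face velocities, or
#'   NULL where the end is an outlet), \code{outlet_lo}, \code{outlet_hi}.
#' @export
apply_boundary <- function(bc, mesh, t) {
  stopifnot(inherits(bc, "flow_bc"), inherits(mesh, "csf_mesh"))
  nr <- mesh$nr; nz <- mesh$nz
  A_lo <- sum(mesh$A_z[1L, ]); A_hi <- sum(mesh$A_z[nz + 1L, ])
  out <- list(w_lo = NULL, w_hi = NULL, outlet_lo = FALSE, outlet_hi = FALSE)
  if (bc$driven == "caudal") {
    out$w_lo <- rep(waveform_eval(bc$waveform, t) / A_lo, nr)
    out$outlet_hi <- TRUE
  } else if (bc$driven == "cranial") {
    out$w_hi <- rep(-waveform_eval(bc$waveform, t) / A_hi, nr)
    out$outlet_lo <- TRUE
  } else if (bc$closed) {
    out$w_lo <- rep(0, nr); out$w_hi <- rep(0, nr)
  } else {
    out$outlet_lo <- TRUE; out$outlet_hi <- TRUE
  }
  out
}

## --- operator setup ---------------------------------------------------------

## Pressure-Poisson matrix L (rows: sum over faces of g * (phi_nb - phi_c)
## with g = A / d): symmetric negative definite once at least one outlet face
## provides a Dirichlet ghost; for fully closed domains one cell is pinned.
## Factored once per mesh + boundary-topology and reused every step.
make_flow_ops <- function(mesh, bc) {
  nz <- mesh$nz; nr <- mesh$nr
  idx <- function(i, j) (j - 1L) * nz + i
  dzc <- mesh$z_c[-1L] - mesh$z_c[-nz]            # distances between column centers

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nz * nr)
  for (j in seq_len(nr)) {
    ## interior axial faces k = 2..nz between cells (k-1, j) and (k, j)
    g <- mesh$A_z[2:nz, j] / dzc
    a <- idx(1:(nz - 1L), j); b <- idx(2:nz, j)
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, g, g)
    diag_acc[a] <- diag_acc[a] + g; diag_acc[b] <- diag_acc[b] + g
  }
  for (j in 2:nr) {
    ## interior radial faces between bands j-1 and j
    g <- mesh$A_r[, j] / mesh$dr_cc[, j - 1L]
    a <- idx(seq_len(nz), j - 1L); b <- idx(seq_len(nz), j)
    ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, g, g)
    diag_acc[a] <- diag_acc[a] + g; diag_acc[b] <- diag_acc[b] + g
  }
  bc0 <- apply_boundary(bc, mesh, 0)
  if (bc0$outlet_lo) {
    g <- mesh$A_z[1L, ] / (mesh$dz[1L] / 2)
    diag_acc[idx(1L, seq_len(nr))] <- diag_acc[idx(1L, seq_len(nr))] + g
  }
  if (bc0$outlet_hi) {
    g <- mesh$A_z[nz + 1L, ] / (mesh$dz[nz] / 2)
    diag_acc[idx(nz, seq_len(nr))] <- diag_acc[idx(nz, seq_len(nr))] + g
  }
  pinned <- !bc0$outlet_lo && !bc0$outlet_hi
  if (pinned) diag_acc[1L] <- diag_acc[1L] + max(diag_acc)  # pressure anchor

  ## assembled with flipped sign (graph Laplacian + Dirichlet outlet terms),
  ## symmetric positive definite: solve Lpos phi = -(rho/dt)(div - S)
  n <- nz * nr
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(-xx, diag_acc), dims = c(n, n))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(L), LDL = FALSE, perm = TRUE)

  ## geometry for the staggered momentum volumes (see flow_step)
  A_zc <- pi * (mesh$r_e[, -1L, drop = FALSE]^2 - mesh$r_e[, -(nr + 1L), drop = FALSE]^2)
  re_w <- mesh$re_edge[2:nz, , drop = FALSE]       # radii at interior z-edges
  rbw <- 0.5 * (re_w[, -1L, drop = FALSE] + re_w[, -(nr + 1L), drop = FALSE])
  Vw <- pi * (re_w[, -1L, drop = FALSE]^2 - re_w[, -(nr + 1L), drop = FALSE]^2) * dzc
  A2w <- 2 * pi * re_w * dzc
  A1v <- 0.5 * (mesh$A_z[, -nr, drop = FALSE] + mesh$A_z[, -1L, drop = FALSE])
  A2v <- 2 * pi * mesh$r_c * mesh$dz
  Vv <- 0.5 * (mesh$V[, -nr, drop = FALSE] + mesh$V[, -1L, drop = FALSE])

  list(chol = ch, dzc = dzc, pinned = pinned,
       outlet_lo = bc0$outlet_lo, outlet_hi = bc0$outlet_hi,
       A_zc = A_zc, re_w = re_w, rbw = rbw, Vw = Vw, A2w = A2w,
       A1v = A1v, A2v = A2v, Vv = Vv,
       Lw = radial_operator_w(mesh), Lv = radial_operator_v(mesh),
       Lw_lo = if (bc0$outlet_lo) radial_block_w(mesh, 1L),
       Lw_hi = if (bc0$outlet_hi) radial_block_w(mesh, nz + 1L),
       cache = new.env(parent = emptyenv()))
}

## radial part of the axisymmetric Laplacian acting on w (interior z-edges
## k = 2..nz, bands j = 1..nr), as a sparse matrix; walls enter as Dirichlet
## half-band fluxes, the axis as zero flux
radial_operator_w <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  nk <- nz - 1L
  idx <- function(m, j) (j - 1L) * nk + m
  ks <- 2:nz
  gap <- mesh$gap_e[ks]
  re <- mesh$re_edge[ks, , drop = FALSE]
  rb <- 0.5 * (re[, -1L, drop = FALSE] + re[, -(nr + 1L), drop = FALSE])
  drj <- outer(gap, mesh$deta)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    norm <- rb[, j] * drj[, j]
    cu <- if (j < nr) re[, j + 1L] / outer(gap, mesh$deta_cc)[, j] else
      re[, nr + 1L] / (gap * (1 - mesh$eta_c[nr]))
    cl <- if (j > 1) re[, j] / outer(gap, mesh$deta_cc)[, j - 1L] else
      ifelse(mesh$inner_wall_e[ks], re[, 1L] / (gap * mesh$eta_c[1L]), 0)
    rows <- idx(seq_len(nk), j)
    ii <- c(ii, rows); jj <- c(jj, rows); xx <- c(xx, -(cu + cl) / norm)
    if (j < nr) { ii <- c(ii, rows); jj <- c(jj, idx(seq_len(nk), j + 1L)); xx <- c(xx, cu / norm) }
    if (j > 1) { ii <- c(ii, rows); jj <- c(jj, idx(seq_len(nk), j - 1L)); xx <- c(xx, cl / norm) }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nk * nr, nk * nr))
}

## radial part of the vector Laplacian acting on v (all columns, interior
## nodes j = 2..nr): d/dr[(1/r) d(r v)/dr], walls v = 0
radial_operator_v <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  njs <- nr - 1L
  idx <- function(i, jj) (jj - 1L) * nz + i
  ii <- integer(0); jj_ <- integer(0); xx <- numeric(0)
  for (jj in seq_len(njs)) {
    j <- jj + 1L                                   # node index
    dcc <- mesh$dr_cc[, jj]                        # spacing between band centers
    cu_ <- 1 / (mesh$dr_cell[, j] * mesh$r_c[, j] * dcc)
    cl_ <- 1 / (mesh$dr_cell[, j - 1L] * mesh$r_c[, j - 1L] * dcc)
    rows <- idx(seq_len(nz), jj)
    ii <- c(ii, rows); jj_ <- c(jj_, rows)
    xx <- c(xx, -mesh$r_e[, j] * (cu_ + cl_))
    if (jj < njs) {
      ii <- c(ii, rows); jj_ <- c(jj_, idx(seq_len(nz), jj + 1L))
      xx <- c(xx, mesh$r_e[, j + 1L] * cu_)
    }
    if (jj > 1) {
      ii <- c(ii, rows); jj_ <- c(jj_, idx(seq_len(nz), jj - 1L))
      xx <- c(xx, mesh$r_e[, j - 1L] * cl_)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj_, x = xx, dims = c(nz * njs, nz * njs))
}

## radial w-operator restricted to a single z-edge k (nr x nr), used for the
## outlet-face momentum predictor
radial_block_w <- function(mesh, k) {
  nr <- mesh$nr
  gap <- mesh$gap_e[k]
  re <- mesh$re_edge[k, ]
  rb <- 0.5 * (re[-1L] + re[-(nr + 1L)])
  drj <- gap * mesh$deta
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    norm <- rb[j] * drj[j]
    cu <- if (j < nr) re[j + 1L] / (gap * mesh$deta_cc[j]) else
      re[nr + 1L] / (gap * (1 - mesh$eta_c[nr]))
    cl <- if (j > 1) re[j] / (gap * mesh$deta_cc[j - 1L]) else
      if (mesh$inner_wall_e[k]) re[1L] / (gap * mesh$eta_c[1L]) else 0
    ii <- c(ii, j); jj <- c(jj, j); xx <- c(xx, -(cu + cl) / norm)
    if (j < nr) { ii <- c(ii, j); jj <- c(jj, j + 1L); xx <- c(xx, cu / norm) }
    if (j > 1) { ii <- c(ii, j); jj <- c(jj, j - 1L); xx <- c(xx, cl / norm) }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, nr))
}

## cached LU factors of (I - nu dt L_r) for the implicit radial viscous solve
visc_factors <- function(ops, nu, dt) {
  key <- sprintf("%.17g_%.17g", nu, dt)
  f <- ops$cache[[key]]
  if (is.null(f)) {
    nw <- nrow(ops$Lw); nv <- nrow(ops$Lv)
    f <- list(
      fw = Matrix::lu(Matrix::Diagonal(nw) - nu * dt * ops$Lw),
      fv = Matrix::lu(Matrix::Diagonal(nv) - nu * dt * ops$Lv),
      fw_lo = if (!is.null(ops$Lw_lo))
        Matrix::lu(Matrix::Diagonal(nrow(ops$Lw_lo)) - nu * dt * ops$Lw_lo),
      fw_hi = if (!is.null(ops$Lw_hi))
        Matrix::lu(Matrix::Diagonal(nrow(ops$Lw_hi)) - nu * dt * ops$Lw_hi))
    ops$cache[[key]] <- f
  }
  f
}

## --- spatial operators ------------------------------------------------------

## axial viscous term for w at interior z-edges (explicit part; the radial
## part is handled implicitly through radial_operator_w)
visc_w_axial <- function(w, mesh) {
  nz <- mesh$nz
  ks <- 2:nz
  wk <- w[ks, , drop = FALSE]
  dz <- mesh$dz
  ((w[ks + 1L, , drop = FALSE] - wk) / dz[ks] -
   (wk - w[ks - 1L, , drop = FALSE]) / dz[ks - 1L]) /
    (0.5 * (dz[ks] + dz[ks - 1L]))
}

## axial viscous term for v at interior radial nodes (explicit part)
visc_v_axial <- function(v, mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  js <- 2:nr
  vi <- v[, js, drop = FALSE]
  vlo <- rbind(vi[1L, ], vi[-nz, , drop = FALSE])   # zero-gradient ends
  vhi <- rbind(vi[-1L, , drop = FALSE], vi[nz, ])
  dzm <- matrix(mesh$dz, nz, length(js))
  (vhi - 2 * vi + vlo) / dzm^2
}

## advective tendencies (skew form: flux divergence minus phi * div u) for
## both momentum components, limited second-order upwind
advect_momentum <- function(w, v, mesh, ops, psi) {
  nz <- mesh$nz; nr <- mesh$nr
  ## --- w ("cells" = interior z-edges m = 1..nz-1 <-> w[2..nz]) ---
  phi_w <- w[2:nz, , drop = FALSE]
  U1w <- 0.5 * (w[1:nz, , drop = FALSE] + w[2:(nz + 1L), , drop = FALSE])  # at column centers
  U2w <- 0.5 * (v[1:(nz - 1L), , drop = FALSE] + v[2:nz, , drop = FALSE])  # at interior z-edges
  mw <- muscl_div(phi_w, U1w, U2w, ops$A_zc, ops$A2w, ops$Vw, psi,
                  g_lo1 = w[1L, ], g_hi1 = w[nz + 1L, ],
                  g_lo2 = 0, g_hi2 = 0)
  adv_w <- mw$divF - phi_w * mw$divU

  ## --- v ("cells" = interior radial nodes j = 2..nr) ---
  phi_v <- v[, 2:nr, drop = FALSE]
  U1v <- 0.5 * (w[, 1:(nr - 1L), drop = FALSE] + w[, 2:nr, drop = FALSE])
  U2v <- 0.5 * (v[, 1:nr, drop = FALSE] + v[, 2:(nr + 1L), drop = FALSE])
  mv <- muscl_div(phi_v, U1v, U2v, ops$A1v, ops$A2v, ops$Vv, psi,
                  g_lo1 = 0, g_hi1 = 0, g_lo2 = 0, g_hi2 = 0)
  adv_v <- mv$divF - phi_v * mv$divU
  list(adv_w = adv_w, adv_v = adv_v)
}

## --- the time step ----------------------------------------------------------

#' One flow time step (incremental pressure projection)
#'
#' Advances velocity and pressure by \code{dt}: an explicit momentum
#' predictor (limited second-order upwind convection, axisymmetric viscous
#' terms, current pressure gradient, body force and injection momentum
#' source), then pressure-correction sweeps enforcing discrete
#' incompressibility (with the injection volume source on the right-hand
#' side), iterated until the normalized successive-difference criterion of
#' the inner monitor is met.
#'
#' @param state list with matrices \code{w} ((nz+1) x nr), \code{v}
#'   (nz x (nr+1)), \code{p} (nz x nr) and time \code{t}.
#' @param mesh a \code{csf_mesh}.
#' @param props \code{fluid_properties}.
#' @param bc a \code{flow_bc}.
#' @param dt time step in s.
#' @param ops precomputed operators from the internal factory (built
#'   automatically if NULL).
#' @param src injection source terms (see \code{\link{injection_source}}).
#' @param body_force c(Fz, Fr) in N/m^3 applied uniformly (default zero; the
#'   model is supine with no buoyancy term).
#' @param control solver controls: \code{scheme} (momentum convection),
#'   \code{tol} (inner tolerance, default 1e-6), \code{max_inner}.
#' @return updated state with diagnostics \code{div_residual} (max |div u -
#'   source| in 1/s), \code{inner_iters}, \code{inner_metric}.
#' @export
flow_step <- function(state, mesh, props, bc, dt, ops = NULL,
                      src = list(active = FALSE, q_vol = 0, F_z = 0, F_r = 0,
                                 cell = c(NA, NA)),
                      body_force = c(0, 0),
                      control = list()) {
  stopifnot(dt > 0)
  ctrl <- utils::modifyList(list(scheme = "minmod", tol = 1e-6, max_inner = 6L),
                            control)
  if (is.null(ops)) ops <- make_flow_ops(mesh, bc)
  nz <- mesh$nz; nr <- mesh$nr
  rho <- props$rho; nu <- props$nu
  psi <- limiter_fun(ctrl$scheme)
  w <- state$w; v <- state$v; p <- state$p
  t_new <- state$t + dt

  bcv <- apply_boundary(bc, mesh, t_new)

  ## ---- predictor ----
  ## advection: Adams-Bashforth 2 (falls back to forward Euler on the first
  ## step or after a time-step change); radial viscosity: Crank-Nicolson via
  ## a cached factor of I - nu (dt/2) L_r; axial viscosity explicit (its
  ## stability and accuracy limits are loose at canal aspect ratios)
  adv <- advect_momentum(w, v, mesh, ops, psi)
  ab2 <- !is.null(state$adv_prev) && identical(state$adv_prev$dt, dt)
  adv_w_eff <- if (ab2) 1.5 * adv$adv_w - 0.5 * state$adv_prev$adv_w else adv$adv_w
  adv_v_eff <- if (ab2) 1.5 * adv$adv_v - 0.5 * state$adv_prev$adv_v else adv$adv_v
  lw <- visc_w_axial(w, mesh)
  lv <- visc_v_axial(v, mesh)
  gpz <- (p[2:nz, , drop = FALSE] - p[1:(nz - 1L), , drop = FALSE]) / ops$dzc
  gpr <- (p[, 2:nr, drop = FALSE] - p[, 1:(nr - 1L), drop = FALSE]) / mesh$dr_cc

  lrw <- matrix(as.numeric(ops$Lw %*% as.vector(w[2:nz, , drop = FALSE])),
                nz - 1L, nr)
  lrv <- matrix(as.numeric(ops$Lv %*% as.vector(v[, 2:nr, drop = FALSE])),
                nz, nr - 1L)
  w_new <- w; v_new <- v
  w_new[2:nz, ] <- w[2:nz, , drop = FALSE] +
    dt * (-adv_w_eff + nu * (lw + 0.5 * lrw) - gpz / rho + body_force[1] / rho)
  v_new[, 2:nr] <- v[, 2:nr, drop = FALSE] +
    dt * (-adv_v_eff + nu * (lv + 0.5 * lrv) - gpr / rho + body_force[2] / rho)

  ## injection momentum source, split over the faces bounding the tip cell
  if (isTRUE(src$active) && (src$F_z != 0 || src$F_r != 0)) {
    i <- src$cell[1L]; j <- src$cell[2L]
    if (src$F_z != 0) {
      az <- src$F_z / rho
      for (k in c(i, i + 1L)) if (k >= 2L && k <= nz)
        w_new[k, j] <- w_new[k, j] + dt * 0.5 * az / ops$Vw[k - 1L, j]
    }
    if (src$F_r != 0) {
      ar <- src$F_r / rho
      faces <- intersect(c(j, j + 1L), 2:nr)
      for (jj in faces)
        v_new[i, jj] <- v_new[i, jj] + dt * (ar / length(faces)) / ops$Vv[i, jj - 1L]
    }
  }

  ## implicit half of the Crank-Nicolson radial viscous update
  vf <- visc_factors(ops, nu, 0.5 * dt)
  w_new[2:nz, ] <- matrix(as.numeric(Matrix::solve(vf$fw, as.vector(w_new[2:nz, , drop = FALSE]))),
                          nz - 1L, nr)
  v_new[, 2:nr] <- matrix(as.numeric(Matrix::solve(vf$fv, as.vector(v_new[, 2:nr, drop = FALSE]))),
                          nz, nr - 1L)

  ## boundary faces: imposed velocity, or an outlet-face momentum predictor
  ## (pressure gradient to the Dirichlet ghost p = 0 in the reservoir, body
  ## force, implicit radial viscosity) so the accumulated incremental
  ## pressure stays anchored at the outlet
  if (!is.null(bcv$w_lo)) {
    w_new[1L, ] <- bcv$w_lo
  } else {
    rhs <- w[1L, ] +
      dt * (0.5 * nu * as.numeric(ops$Lw_lo %*% w[1L, ]) -
              (p[1L, ] - 0) / (rho * mesh$dz[1L] / 2) + body_force[1] / rho)
    w_new[1L, ] <- as.numeric(Matrix::solve(vf$fw_lo, rhs))
  }
  if (!is.null(bcv$w_hi)) {
    w_new[nz + 1L, ] <- bcv$w_hi
  } else {
    rhs <- w[nz + 1L, ] +
      dt * (0.5 * nu * as.numeric(ops$Lw_hi %*% w[nz + 1L, ]) -
              (0 - p[nz, ]) / (rho * mesh$dz[nz] / 2) + body_force[1] / rho)
    w_new[nz + 1L, ] <- as.numeric(Matrix::solve(vf$fw_hi, rhs))
  }
  v_new[, 1L] <- 0; v_new[, nr + 1L] <- 0

  ## ---- pressure-correction sweeps ----
  Svol <- matrix(0, nz, nr)
  if (isTRUE(src$active) && src$q_vol != 0)
    Svol[src$cell[1L], src$cell[2L]] <- src$q_vol

  u_scale <- max(abs(w_new), abs(v_new), 1e-9)
  mon_floor <- 1e-6 * u_scale
  prev_iter <- c(w_new, v_new)
  iters <- 0L; metric <- NA_real_; history <- numeric(0)
  repeat {
    iters <- iters + 1L
    divv <- (mesh$A_z[-1L, , drop = FALSE] * w_new[-1L, , drop = FALSE] -
             mesh$A_z[-(nz + 1L), , drop = FALSE] * w_new[-(nz + 1L), , drop = FALSE] +
             mesh$A_r[, -1L, drop = FALSE] * v_new[, -1L, drop = FALSE] -
             mesh$A_r[, -(nr + 1L), drop = FALSE] * v_new[, -(nr + 1L), drop = FALSE])
    rhs <- (rho / dt) * (divv - Svol)
    phi <- matrix(as.numeric(Matrix::solve(ops$chol, as.vector(-rhs))), nz, nr)
    ## interior face corrections
    w_new[2:nz, ] <- w_new[2:nz, , drop = FALSE] -
      (dt / rho) * (phi[2:nz, , drop = FALSE] - phi[1:(nz - 1L), , drop = FALSE]) / ops$dzc
    v_new[, 2:nr] <- v_new[, 2:nr, drop = FALSE] -
      (dt / rho) * (phi[, 2:nr, drop = FALSE] - phi[, 1:(nr - 1L), drop = FALSE]) / mesh$dr_cc
    if (ops$outlet_lo)
      w_new[1L, ] <- w_new[1L, ] - (dt / rho) * phi[1L, ] / (mesh$dz[1L] / 2)
    if (ops$outlet_hi)
      w_new[nz + 1L, ] <- w_new[nz + 1L, ] + (dt / rho) * phi[nz, ] / (mesh$dz[nz] / 2)
    p <- p + phi
    cur_iter <- c(w_new, v_new)
    metric <- eq_metric(prev_iter, cur_iter, mon_floor)
    history <- c(history, metric)
    prev_iter <- cur_iter
    if (metric < ctrl$tol || iters >= ctrl$max_inner) break
  }
  if (metric >= ctrl$tol && iters >= ctrl$max_inner) {
    stop(sprintf(paste("flow solver: inner iterations did not meet the",
                       "convergence criterion (metric %.3g after %d sweeps;",
                       "history: %s)"),
                 metric, iters, paste(signif(history, 3), collapse = ", ")))
  }

  ## divergence residual (1/s), must vanish to solver tolerance
  divv <- (mesh$A_z[-1L, , drop = FALSE] * w_new[-1L, , drop = FALSE] -
           mesh$A_z[-(nz + 1L), , drop = FALSE] * w_new[-(nz + 1L), , drop = FALSE] +
           mesh$A_r[, -1L, drop = FALSE] * v_new[, -1L, drop = FALSE] -
           mesh$A_r[, -(nr + 1L), drop = FALSE] * v_new[, -(nr + 1L), drop = FALSE])
  div_res <- max(abs(divv - Svol) / mesh$V)
  if (!all(is.finite(w_new)) || !all(is.finite(v_new)))
    stop("flow solver produced non-finite velocities")

  list(w = w_new, v = v_new, p = p, t = t_new,
       adv_prev = list(adv_w = adv$adv_w, adv_v = adv$adv_v, dt = dt),
       div_residual = div_res, inner_iters = iters, inner_metric = metric)
}

## quiescent initial state
init_flow_state <- function(mesh) {
  list(w = matrix(0, mesh$nz + 1L, mesh$nr),
       v = matrix(0, mesh$nz, mesh$nr + 1L),
       p = matrix(0, mesh$nz, mesh$nr),
       t = 0)
}

## cell-centered velocity components and magnitude
cell_velocity <- function(state, mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  wc <- 0.5 * (state$w[-1L, , drop = FALSE] + state$w[-(nz + 1L), , drop = FALSE])
  vc <- 0.5 * (state$v[, -1L, drop = FALSE] + state$v[, -(nr + 1L), drop = FALSE])
  list(wz = wc, vr = vc, mag = sqrt(wc^2 + vc^2))
}

## area-weighted mean pressure over all wall faces (dura everywhere, cord
## where present, closed ends if any)
wall_pressure_mean <- function(state, mesh, ops = NULL, closed_ends = FALSE) {
  p <- state$p; nz <- mesh$nz; nr <- mesh$nr
  A <- mesh$A_r[, nr + 1L]; ps <- p[, nr]               # dura
  iw <- which(mesh$inner_wall)
  if (length(iw) > 0) { A <- c(A, mesh$A_r[iw, 1L]); ps <- c(ps, p[iw, 1L]) }
  if (closed_ends) {
    A <- c(A, mesh$A_z[1L, ], mesh$A_z[nz + 1L, ])
    ps <- c(ps, p[1L, ], p[nz, ])
  }
  sum(A * ps) / sum(A)
}
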