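#' Structured axisymmetric mesh for the CSF canal
#'
#' Builds a structured finite-volume mesh on the annular canal: \code{nz}
#' axial columns (refined within the injection window) and \code{nr} radial
#' cells spanning the local dura-cord gap. Velocity components live on faces
#' (MAC staggering): axial velocity w on the vertical faces between columns,
#' radial velocity v on the (near-)radial faces between bands; pressure and
#' concentration at cell centers. Cell volumes use exact axisymmetric
#' quadrature of the linearly interpolated wall radii, so the meshed volume
#' matches the analytic geometry volume to discretization error in the wall
#' profile only.
#'
#' @param geometry a \code{csf_geometry}.
#' @param nz axial cell count before refinement.
#' @param nr radial cells across the dura-cord gap (>= 2).
#' @param refine integer axial refinement factor (>= 1) applied inside
#'   \code{refine_window}.
#' @param refine_window vertebral window label for refinement (default the
#'   lumbar-puncture site \code{"L4-L5"}).
#' @param r_spacing radial node distribution across the gap: \code{"cosine"}
#'   (default) clusters cells at both walls to resolve the oscillatory
#'   Stokes boundary layer (~0.5 mm at cardiac frequency) without a fine
#'   uniform grid; \code{"uniform"} gives equal spacing.
#' @param cord_min cord radius (m) below which the inner boundary is treated
#'   as a free-slip axis rather than a no-slip wall. The conus tapers to a
#'   point in the profile; a no-slip filament thinner than the model's
#'   geometric fidelity would make wall drag mesh-dependent (its resistance
#'   converges only logarithmically), so sub-cutoff cord is kept in the
#'   geometry (volumes unchanged) but carries no wall stress.
#' @return object of class \code{csf_mesh}.
#' @export
csf_mesh <- function(geometry, nz = 96, nr = 6, refine = 2L,
                     refine_window = "L4-L5", cord_min = 1e-3,
                     r_spacing = c("cosine", "uniform")) {
  stopifnot(inherits(geometry, "csf_geometry"))
  if (nr < 2) stop("meshing error: need at least 2 radial cells across the gap")
  stopifnot(nz >= 4, refine >= 1)
  refine <- as.integer(refine)

  L <- geometry$length
  z_base <- seq(0, L, length.out = nz + 1L)
  if (refine > 1L) {
    win <- locate_level(geometry, refine_window)
    z_e <- numeric(0)
    for (i in seq_len(nz)) {
      a <- z_base[i]; b <- z_base[i + 1L]
      mid <- (a + b) / 2
      n_sub <- if (mid >= win[1] && mid < win[2]) refine else 1L
      z_e <- c(z_e, seq(a, b, length.out = n_sub + 1L)[-(n_sub + 1L)])
    }
    z_e <- c(z_e, L)
  } else {
    z_e <- z_base
  }
  nzt <- length(z_e) - 1L
  z_c <- 0.5 * (z_e[-1] + z_e[-length(z_e)])
  dz <- diff(z_e)

  rc_e <- geometry$cord(z_e); rd_e <- geometry$dura(z_e)
  rc_c <- geometry$cord(z_c); rd_c <- geometry$dura(z_c)
  gap_e <- rd_e - rc_e; gap_c <- rd_c - rc_c
  if (any(gap_c <= 0) || any(gap_e <= 0)) stop("meshing error: non-positive gap")

  r_spacing <- match.arg(r_spacing)
  eta_e <- switch(r_spacing,
                  uniform = (0:nr) / nr,
                  cosine = 0.5 * (1 - cos(pi * (0:nr) / nr)))
  eta_c <- 0.5 * (eta_e[-1L] + eta_e[-(nr + 1L)])
  deta <- diff(eta_e)                 # band heights (fractions of the gap)
  deta_cc <- diff(eta_c)              # center-to-center spacings

  ## radial face radii and cell-center radii per column (nzt x (nr+1) / nzt x nr)
  r_e <- outer(rc_c, rep(1, nr + 1L)) + outer(gap_c, eta_e)
  r_c <- 0.5 * (r_e[, -1L, drop = FALSE] + r_e[, -(nr + 1L), drop = FALSE])

  ## axial face areas at z-edges ((nzt+1) x nr): annular bands
  re_edge <- outer(rc_e, rep(1, nr + 1L)) + outer(gap_e, eta_e)
  A_z <- pi * (re_edge[, -1L, drop = FALSE]^2 - re_edge[, -(nr + 1L), drop = FALSE]^2)

  ## radial face areas (nzt x (nr+1)): 2 pi r dz
  A_r <- 2 * pi * r_e * dz

  ## cell volumes: axisymmetric quadrature with linear band radii in z,
  ## V = (pi dz / 3) * (ro1^2+ro1*ro2+ro2^2 - ri1^2-ri1*ri2-ri2^2),
  ## then rescaled per column to the exact profile volume so that profile
  ## knots falling inside a cell cannot break volume conservation
  q <- function(a, b) a^2 + a * b + b^2
  V <- matrix(0, nzt, nr)
  for (j in seq_len(nr)) {
    ri1 <- re_edge[-(nzt + 1L), j]; ri2 <- re_edge[-1L, j]
    ro1 <- re_edge[-(nzt + 1L), j + 1L]; ro2 <- re_edge[-1L, j + 1L]
    V[, j] <- pi * dz / 3 * (q(ro1, ro2) - q(ri1, ri2))
  }
  if (any(V <= 0)) stop("meshing error: non-positive cell volume")
  Vcol_exact <- vapply(seq_len(nzt), function(i) {
    profile_volume(geometry$dura, geometry$cord, z_e[i], z_e[i + 1L])
  }, 1)
  V <- V * (Vcol_exact / rowSums(V))

  meshed <- sum(V)
  if (abs(meshed - geometry$canal_volume) > 1e-3 * geometry$canal_volume) {
    stop(sprintf("meshed volume %.4g deviates from geometry volume %.4g by > 0.1%%",
                 meshed, geometry$canal_volume))
  }

  dr_cell <- outer(gap_c, deta)       # cell radial heights (nz x nr)
  dr_cc <- outer(gap_c, deta_cc)      # center spacings (nz x (nr-1))

  ## inner boundary type per column/edge: no-slip cord wall above the
  ## fidelity cutoff, free-slip axis below it
  inner_wall <- rc_c > cord_min
  inner_wall_e <- rc_e > cord_min

  structure(list(geometry = geometry,
                 nz = nzt, nr = nr, refine = refine,
                 z_e = z_e, z_c = z_c, dz = dz,
                 rc_e = rc_e, rd_e = rd_e, rc_c = rc_c, rd_c = rd_c,
                 gap_e = gap_e, gap_c = gap_c,
                 eta_e = eta_e, eta_c = eta_c, deta = deta, deta_cc = deta_cc,
                 r_e = r_e, r_c = r_c, re_edge = re_edge,
                 A_z = A_z, A_r = A_r, V = V,
                 dr_cell = dr_cell, dr_cc = dr_cc, cord_min = cord_min,
                 inner_wall = inner_wall, inner_wall_e = inner_wall_e,
                 volume = meshed),
            class = "csf_mesh")
}

#' @export
print.csf_mesh <- function(x, ...) {
  cat("Structured axisymmetric CSF mesh\n")
  cat(sprintf("  %d axial x %d radial cells (%d total), refine x%d\n",
              x$nz, x$nr, x$nz * x$nr, x$refine))
  cat(sprintf("  meshed volume %.2f mL (geometry %.2f mL)\n",
              x$volume * 1e6, x$geometry$canal_volume * 1e6))
  invisible(x)
}

## indices of cells whose centers lie in the half-open axial window [lo, hi)
window_columns <- function(mesh, window) {
  which(mesh$z_c >= window[1] & mesh$z_c < window[2])
}

## per-column overlap fraction of each cell's axial extent with [lo, hi):
## exact partial-cell weighting, so window averages are stable under mesh
## refinement (boundary cells enter pro rata instead of flipping in or out)
window_weights <- function(mesh, window) {
  lo <- pmax(mesh$z_e[-(mesh$nz + 1L)], window[1])
  hi <- pmin(mesh$z_e[-1L], window[2])
  pmax(0, hi - lo) / mesh$dz
}

## locate the cell containing a (z, r) point
locate_cell <- function(mesh, z, r) {
  i <- findInterval(z, mesh$z_e, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), mesh$nz)
  eta <- (r - mesh$rc_c[i]) / mesh$gap_c[i]
  j <- findInterval(eta, mesh$eta_e, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), mesh$nr)
  c(i = i, j = j)
}

#' Write a mesh (with optional cell fields) as a legacy VTK structured grid
#'
#' Plain-ASCII VTK 2.0 STRUCTURED_GRID in the (z, r) plane; cell fields are
#' written as CELL_DATA scalars. Intended for quick visualization in ParaView.
#'
#' @param mesh a \code{csf_mesh}.
#' @param file output path.
#' @param fields named list of nz x nr matrices to attach as cell data.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(mesh, file, fields = list()) {
  nz <- mesh$nz; nr <- mesh$nr
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "csfsim axisymmetric r-z grid",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz + 1L, nr + 1L),
               sprintf("POINTS %d float", (nz + 1L) * (nr + 1L))), con)
  ## grid point radii interpolated to z-edges
  for (j in seq_len(nr + 1L)) {
    r_row <- mesh$re_edge[, j]
    writeLines(sprintf("%g %g 0", mesh$z_e, r_row), con)
  }
  if (length(fields) > 0) {
    writeLines(sprintf("CELL_DATA %d", nz * nr), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", as.vector(fields[[nm]])), con)
    }
  }
  invisible(file)
}
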