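#' Mesh-independence study
#'
#' Runs the baseline (no-injection) oscillatory case at successive mesh
#' refinements and tracks the area-weighted mean pressure over all wall
#' boundaries at the final time step. Convergence is declared when the
#' relative change between the two finest levels falls below the criterion
#' (default 1 percent).
#'
#' @param geometry a \code{csf_geometry}.
#' @param levels list of c(nz, nr) mesh resolutions, coarse to fine (>= 3).
#' @param t_end simulated time per level in s (default 10).
#' @param dt time step in s.
#' @param waveform driving waveform (default \code{default_waveform()}).
#' @param criterion convergence threshold on the relative change (fraction,
#'   default 0.01).
#' @param ... further arguments to \code{\link{csf_simulate}}.
#' @return object of class \code{csf_mesh_study}: per-level element counts,
#'   mean wall pressures, successive relative changes, convergence flag.
#' @export
mesh_independence_study <- function(geometry = csf_geometry(),
                                    levels = list(c(48, 6), c(96, 12), c(192, 24)),
                                    t_end = 10, dt = 0.01, waveform = NULL,
                                    criterion = 0.01, ...) {
  if (length(levels) < 3) stop("a mesh-independence study needs >= 3 levels")
  if (is.null(waveform)) waveform <- default_waveform()
  cells <- numeric(0); pbar <- numeric(0)
  for (lv in levels) {
    mesh <- csf_mesh(geometry, nz = lv[1], nr = lv[2])
    run <- csf_simulate(t_end, protocol = NULL, geometry = geometry,
                        mesh = mesh, waveform = waveform, dt = dt,
                        record_dt = t_end, ...)
    cells <- c(cells, mesh$nz * mesh$nr)
    pbar <- c(pbar, utils::tail(run$wall_pressure, 1))
  }
  if (is.unsorted(cells, strictly = TRUE))
    stop("mesh levels must have strictly increasing element counts")
  rel <- abs(diff(pbar)) / abs(pbar[-1])
  if (length(rel) > 1 && all(diff(rel) > 0))
    stop("diagnostic failure: change grows at every refinement (no convergent trend)")
  structure(list(cells = cells, mean_wall_pressure = pbar,
                 rel_change = rel, criterion = criterion,
                 converged = utils::tail(rel, 1) < criterion),
            class = "csf_mesh_study")
}

#' @export
print.csf_mesh_study <- function(x, ...) {
  cat("Mesh-independence study (mean wall pressure at final step)\n")
  tab <- data.frame(cells = x$cells, p_wall = x$mean_wall_pressure,
                    rel_change_pct = c(NA, 100 * x$rel_change))
  print(tab, row.names = FALSE, digits = 5)
  cat(sprintf("  finest-pair change %.3g%% -> %s (criterion %g%%)\n",
              100 * utils::tail(x$rel_change, 1),
              if (x$converged) "converged" else "NOT converged",
              100 * x$criterion))
  invisible(x)
}

#' Time-step refinement study
#'
#' Runs the baseline case at a sequence of time steps on one mesh and
#' reports the relative L2 change of the cell-centered velocity field at
#' the final time between successive dt values.
#'
#' @param dts time steps in s, coarse to fine (>= 2 values).
#' @param t_end simulated time in s.
#' @param geometry,mesh,waveform as in \code{\link{csf_simulate}}.
#' @param ... further arguments to \code{\link{csf_simulate}}.
#' @return data.frame with dt pairs and percent L2 changes.
#' @export
timestep_study <- function(dts = c(0.02, 0.01, 0.005), t_end = 10,
                           geometry = csf_geometry(), mesh = NULL,
                           waveform = NULL, ...) {
  if (length(dts) < 2) stop("a time-step study needs >= 2 dt values")
  if (is.null(mesh)) mesh <- csf_mesh(geometry)
  if (is.null(waveform)) waveform <- default_waveform()
  fields <- lapply(dts, function(d) {
    run <- csf_simulate(t_end, geometry = geometry, mesh = mesh,
                        waveform = waveform, dt = d, record_dt = t_end, ...)
    vel <- cell_velocity(run$state, mesh)
    cbind(vel$wz, vel$vr)
  })
  wts <- sqrt(cbind(mesh$V, mesh$V))
  change <- vapply(seq_len(length(dts) - 1L), function(i) {
    a <- fields[[i]]; b <- fields[[i + 1L]]
    num <- sqrt(sum((wts * (a - b))^2)); den <- sqrt(sum((wts * b)^2))
    if (num == 0) 0 else 100 * num / den
  }, 1)
  data.frame(dt_coarse = dts[-length(dts)], dt_fine = dts[-1],
             l2_change_pct = change)
}
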