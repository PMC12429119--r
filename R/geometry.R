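#' Idealized spinal CSF geometry
#'
#' Constructs an axisymmetric annular model of the spinal subarachnoid space:
#' an outer dural wall and an inner spinal-cord wall, both given as piecewise
#' linear radius profiles along the canal axis, plus a lumped cranial reservoir
#' standing in for the intracranial CSF. The axial coordinate z runs from 0 at
#' the caudal (sacral) end to \code{length} at the cranial (C1) end; all units
#' are SI (m, m^3). The cord terminates at the conus medullaris near L1--L2;
#' caudal to that the cross-section is a full circle (cauda equina not
#' resolved).
#'
#' The default profiles give a canal of ~0.6 m with dura radius tapering from
#' 8 mm (lumbar) to 6.5 mm (cervical) and a cord radius up to ~4.6 mm, and a
#' reservoir sized so that total CSF volume falls in the physiological
#' 250--400 mL range.
#'
#' @param length canal length S1 -> C1 in m.
#' @param dura_knots two-column matrix or data.frame (z, radius) of dural
#'   radius knots in m; linearly interpolated, constant beyond the ends.
#' @param cord_knots as \code{dura_knots}, for the spinal cord radius. A
#'   radius of exactly 0 means no cord (full circular cross-section).
#' @param reservoir_volume lumped cranial CSF volume in m^3.
#' @param caudal_stub_volume lumped CSF volume (m^3) of the closed sacral
#'   dural sac below the caudal opening. The sac is a dead end: fluid and
#'   drug swept out of the canal during outward oscillation phases are held
#'   there and re-enter on the inflow phase, so the opening conserves drug.
#' @param volume_range length-2 numeric, admissible total CSF volume in m^3,
#'   or \code{NULL} to skip the check. Default 250--400 mL.
#' @param level_heights named numeric: relative heights of sacral, lumbar,
#'   thoracic and cervical vertebral segments (scaled to fill \code{length}).
#' @return object of class \code{csf_geometry} with the radius profile
#'   functions, the vertebral level table, and the computed volumes.
#' @export
csf_geometry <- function(length = 0.60,
                         dura_knots = NULL,
                         cord_knots = NULL,
                         reservoir_volume = 240e-6,
                         caudal_stub_volume = 5e-6,
                         volume_range = c(250e-6, 400e-6),
                         level_heights = c(sacral = 0.040, lumbar = 0.033,
                                           thoracic = 0.025, cervical = 0.0136)) {
  stopifnot(is.numeric(length), length > 0, reservoir_volume >= 0)
  levels <- vertebral_levels(length, level_heights)

  if (is.null(dura_knots)) {
    dura_knots <- cbind(z = c(0, length), r = c(8e-3, 6.5e-3))
  }
  if (is.null(cord_knots)) {
    ## conus medullaris at the L2/L1 boundary; cord thickens over ~4 cm,
    ## slight cervical enlargement
    z_conus <- levels$z_hi[levels$label == "L2"]
    cord_knots <- cbind(z = c(0, z_conus, z_conus + 0.04, 0.35 / 0.60 * length,
                              0.50 / 0.60 * length, length),
                        r = c(0, 0, 4.2e-3, 4.0e-3, 4.4e-3, 4.6e-3))
  }
  dura_knots <- as.matrix(dura_knots)
  cord_knots <- as.matrix(cord_knots)
  if (any(dura_knots[, 2] <= 0)) stop("dura radius must be positive everywhere")
  if (any(cord_knots[, 2] < 0)) stop("cord radius must be non-negative")

  dura <- stats::approxfun(dura_knots[, 1], dura_knots[, 2], rule = 2)
  cord <- stats::approxfun(cord_knots[, 1], cord_knots[, 2], rule = 2)

  ## feasibility: dura strictly above cord everywhere (checked on knot grid +
  ## fine samples, reported against the vertebral level)
  zs <- sort(unique(c(dura_knots[, 1], cord_knots[, 1],
                      seq(0, length, length.out = 257))))
  zs <- zs[zs >= 0 & zs <= length]
  bad <- which(dura(zs) <= cord(zs))
  if (base::length(bad) > 0) {
    lv <- level_at(levels, zs[bad[1]])
    stop(sprintf("infeasible radius profile: cord radius >= dura radius at z = %.4f m (level %s)",
                 zs[bad[1]], lv))
  }

  canal_volume <- profile_volume(dura, cord, 0, length)
  total_volume <- canal_volume + reservoir_volume + caudal_stub_volume
  if (!is.null(volume_range)) {
    stopifnot(base::length(volume_range) == 2L, volume_range[1] < volume_range[2])
    if (total_volume < volume_range[1] || total_volume > volume_range[2]) {
      stop(sprintf("total CSF volume %.1f mL outside configured range [%.0f, %.0f] mL",
                   total_volume * 1e6, volume_range[1] * 1e6, volume_range[2] * 1e6))
    }
  }

  structure(list(length = length,
                 dura = dura, cord = cord,
                 dura_knots = dura_knots, cord_knots = cord_knots,
                 reservoir_volume = reservoir_volume,
                 caudal_stub_volume = caudal_stub_volume,
                 canal_volume = canal_volume,
                 total_volume = total_volume,
                 levels = levels),
            class = "csf_geometry")
}

## vertebral level table: S1 (caudal, z = 0) up to C1 (cranial)
vertebral_levels <- function(length, heights) {
  labels <- c("S1", paste0("L", 5:1), paste0("T", 12:1), paste0("C", 7:1))
  h <- c(heights[["sacral"]], rep(heights[["lumbar"]], 5),
         rep(heights[["thoracic"]], 12), rep(heights[["cervical"]], 7))
  h <- h * length / sum(h)
  z_hi <- cumsum(h)
  data.frame(label = labels, z_lo = c(0, z_hi[-base::length(z_hi)]), z_hi = z_hi,
             stringsAsFactors = FALSE)
}

level_at <- function(levels, z) {
  i <- findInterval(z, c(levels$z_lo, levels$z_hi[nrow(levels)]),
                    rightmost.closed = TRUE)
  levels$label[pmin(pmax(i, 1L), nrow(levels))]
}

## exact volume of the annular region between two piecewise-linear radius
## profiles: integrand pi*(rd^2 - rc^2) is piecewise quadratic, so Simpson on
## knot-aligned panels is exact
profile_volume <- function(dura, cord, z0, z1, knots = NULL) {
  zs <- sort(unique(c(z0, z1, knots)))
  zs <- zs[zs >= z0 & zs <= z1]
  if (base::length(zs) < 2L) zs <- c(z0, z1)
  ## include environment knots if profiles are approxfuns
  kn <- c(get_knots(dura), get_knots(cord))
  zs <- sort(unique(c(zs, kn[kn > z0 & kn < z1])))
  tot <- 0
  for (i in seq_len(base::length(zs) - 1L)) {
    a <- zs[i]; b <- zs[i + 1L]; m <- (a + b) / 2
    f <- function(z) pi * (dura(z)^2 - cord(z)^2)
    tot <- tot + (b - a) / 6 * (f(a) + 4 * f(m) + f(b))
  }
  tot
}

get_knots <- function(f) {
  e <- environment(f)
  if (!is.null(e) && !is.null(e$x)) as.numeric(e$x) else numeric(0)
}

#' @export
print.csf_geometry <- function(x, ...) {
  cat("Idealized spinal CSF geometry (axisymmetric annulus + cranial reservoir)\n")
  cat(sprintf("  canal length : %.3f m (S1 caudal -> C1 cranial)\n", x$length))
  cat(sprintf("  canal volume : %.1f mL\n", x$canal_volume * 1e6))
  cat(sprintf("  reservoir    : %.1f mL\n", x$reservoir_volume * 1e6))
  cat(sprintf("  total CSF    : %.1f mL\n", x$total_volume * 1e6))
  invisible(x)
}

#' Vertebral level lookup
#'
#' Maps a vertebral level label (\code{"L4"}) or a two-level window
#' (\code{"L4-L5"}, \code{"C7-T1"}; en dash accepted) to its half-open axial
#' interval \code{[z_lo, z_hi)} in m.
#'
#' @param geometry a \code{csf_geometry} (or its \code{$levels} table).
#' @param label level or window label.
#' @return numeric length 2: \code{c(z_lo, z_hi)}.
#' @export
locate_level <- function(geometry, label) {
  levels <- if (inherits(geometry, "csf_geometry")) geometry$levels else geometry
  lab <- gsub("–", "-", toupper(trimws(label)))
  parts <- strsplit(lab, "-", fixed = TRUE)[[1]]
  idx <- match(parts, levels$label)
  if (anyNA(idx)) stop(sprintf("unknown vertebral level label: '%s'", label))
  c(z_lo = min(levels$z_lo[idx]), z_hi = max(levels$z_hi[idx]))
}
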