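#' CSF flow waveforms
#'
#' Synthesized time-periodic volumetric flow-rate signals driving the
#' oscillatory CSF motion: a cardiac component (systolic-peaked truncated
#' Fourier series, zero mean, calibrated so its positive-phase volume per
#' cycle equals the pulse volume), a respiratory component (zero-mean
#' sinusoid calibrated to a tidal CSF volume per breath), and a steady
#' production offset. The combined waveform is their pointwise sum; its mean
#' over a common period equals the production rate.
#'
#' @name waveforms
NULL

new_waveform <- function(kind, period, q, calibration) {
  structure(list(kind = kind, period = period, q = q, calibration = calibration),
            class = "csf_waveform")
}

#' Evaluate a waveform
#' @param w a \code{csf_waveform}.
#' @param t time(s) in s.
#' @return volumetric flow rate(s) in m^3/s.
#' @export
waveform_eval <- function(w, t) {
  stopifnot(inherits(w, "csf_waveform"))
  w$q(t)
}

#' @export
print.csf_waveform <- function(x, ...) {
  cat(sprintf("CSF %s waveform: period %.3g s\n", x$kind, x$period))
  for (nm in names(x$calibration)) {
    cat(sprintf("  %s = %.4g\n", nm, x$calibration[[nm]]))
  }
  invisible(x)
}

#' Cardiac CSF waveform
#'
#' Zero-mean truncated Fourier series with a sharp systolic peak,
#' \eqn{q_0(\theta) = \sum_k a_k \sin(k\theta)} with default harmonic weights
#' (1, 0.5, 0.15), scaled so the integral of the positive-flow phase over one
#' cycle equals \code{pulse_volume} (the craniocaudal stroke volume per beat).
#' A sampled waveform measured in vivo can be supplied instead via
#' \code{\link{waveform_from_table}}.
#'
#' @param heart_rate beats per minute (> 0).
#' @param pulse_volume m^3 displaced per cardiac cycle (> 0); default 1.0 mL.
#' @param harmonics numeric vector of harmonic weights for the shape.
#' @return a \code{csf_waveform}.
#' @export
make_cardiac <- function(heart_rate = 60, pulse_volume = 1.0e-6,
                         harmonics = c(1, 0.5, 0.15)) {
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop("configuration error: heart_rate must be positive")
  if (!is.numeric(pulse_volume) || pulse_volume <= 0)
    stop("configuration error: pulse_volume must be positive")
  period <- 60 / heart_rate
  om <- 2 * pi / period
  shape <- function(t) {
    th <- om * t
    s <- 0
    for (k in seq_along(harmonics)) s <- s + harmonics[k] * sin(k * th)
    s
  }
  pos <- stats::integrate(function(t) pmax(shape(t), 0), 0, period,
                          rel.tol = 1e-10, subdivisions = 1000L)$value
  amp <- pulse_volume / pos
  q <- function(t) amp * shape(t %% period)
  new_waveform("cardiac", period, q,
               list(pulse_volume = pulse_volume, heart_rate = heart_rate))
}

#' Respiratory CSF waveform
#'
#' Zero-mean sinusoid at the breathing frequency; amplitude set so the
#' positive-phase integral per breath equals \code{tidal_csf_volume}.
#'
#' @param resp_rate breaths per minute (> 0).
#' @param tidal_csf_volume m^3 displaced per respiratory cycle (>= 0).
#' @return a \code{csf_waveform}.
#' @export
make_respiratory <- function(resp_rate = 12, tidal_csf_volume = 0.5e-6) {
  if (!is.numeric(resp_rate) || resp_rate <= 0)
    stop("configuration error: resp_rate must be positive")
  if (!is.numeric(tidal_csf_volume) || tidal_csf_volume < 0)
    stop("configuration error: tidal_csf_volume must be non-negative")
  period <- 60 / resp_rate
  ## integral of max(A sin, 0) over a period = A * period / pi
  amp <- pi * tidal_csf_volume / period
  om <- 2 * pi / period
  q <- function(t) amp * sin(om * t)
  new_waveform("respiratory", period, q,
               list(tidal_csf_volume = tidal_csf_volume, resp_rate = resp_rate))
}

#' Steady CSF production component
#'
#' @param rate mean production rate in m^3/s (default 0.4 mL/min).
#' @return a \code{csf_waveform} with infinite-period constant flow.
#' @export
make_production <- function(rate = 0.4e-6 / 60) {
  if (!is.numeric(rate) || rate < 0)
    stop("configuration error: production rate must be non-negative")
  new_waveform("production", Inf, function(t) rep_len(rate, length(t)),
               list(mean_rate = rate))
}

## least common period of two finite periods (rational-multiple assumption)
common_period <- function(p1, p2) {
  if (!is.finite(p1)) return(p2)
  if (!is.finite(p2)) return(p1)
  g <- function(a, b) { while (b > 1e-9 * max(a, 1)) { t <- a %% b; a <- b; b <- t }; a }
  p1 * p2 / g(p1, p2)
}

#' Combine cardiac, respiratory and production waveforms
#'
#' Pointwise sum; the mean over the least common period equals the production
#' rate since the oscillatory components have zero mean.
#'
#' @param cardiac,respiratory \code{csf_waveform}s (periodic).
#' @param production_rate steady production in m^3/s (>= 0).
#' @return a \code{csf_waveform} of kind \code{"combined"}.
#' @export
combine_waveforms <- function(cardiac, respiratory = NULL,
                              production_rate = 0.4e-6 / 60) {
  stopifnot(inherits(cardiac, "csf_waveform"))
  if (!is.numeric(production_rate) || production_rate < 0)
    stop("configuration error: production_rate must be non-negative")
  if (is.null(respiratory)) respiratory <- make_respiratory(tidal_csf_volume = 0)
  stopifnot(inherits(respiratory, "csf_waveform"))
  period <- common_period(cardiac$period, respiratory$period)
  qc <- cardiac$q; qr <- respiratory$q
  q <- function(t) qc(t) + qr(t) + production_rate
  new_waveform("combined", period, q,
               list(mean_rate = production_rate,
                    pulse_volume = cardiac$calibration$pulse_volume,
                    tidal_csf_volume = respiratory$calibration$tidal_csf_volume))
}

#' Stroke (pulse) volume of a periodic waveform
#'
#' Integral of the positive-flow phase over one period, by adaptive
#' quadrature (relative tolerance 1e-6).
#'
#' @param w a periodic \code{csf_waveform}.
#' @return volume in m^3.
#' @export
stroke_volume <- function(w) {
  stopifnot(inherits(w, "csf_waveform"))
  if (!is.finite(w$period)) stop("stroke volume requires a finite period")
  stats::integrate(function(t) pmax(w$q(t), 0), 0, w$period,
                   rel.tol = 1e-8, subdivisions = 2000L)$value
}

#' Mean flow rate of a waveform over a time window
#'
#' @param w a \code{csf_waveform}.
#' @param over averaging window in s; defaults to one period (an integer
#'   multiple of both component periods for combined waveforms).
#' @return mean rate in m^3/s.
#' @export
waveform_mean <- function(w, over = w$period) {
  stopifnot(inherits(w, "csf_waveform"), is.finite(over), over > 0)
  stats::integrate(function(t) w$q(t), 0, over,
                   rel.tol = 1e-9, subdivisions = 5000L)$value / over
}

#' Waveform from a sampled (time, flow) table
#'
#' Builds a periodic waveform by linear interpolation of a measured sample,
#' e.g. a phase-contrast MRI flow trace. The sample must span one period;
#' the signal is wrapped periodically.
#'
#' @param t sample times in s (ascending, starting at 0).
#' @param Q sampled volumetric flow in m^3/s.
#' @param period period in s; default \code{max(t)}.
#' @param kind waveform label.
#' @return a \code{csf_waveform}.
#' @export
waveform_from_table <- function(t, Q, period = max(t), kind = "sampled") {
  stopifnot(length(t) == length(Q), length(t) >= 2, !is.unsorted(t), period > 0)
  f <- stats::approxfun(c(t[t < period], period),
                        c(Q[t < period], Q[1]), rule = 2)
  q <- function(tt) f(tt %% period)
  new_waveform(kind, period, q, list())
}

#' Read / write a sampled waveform as two-column delimited text
#'
#' Columns: t (s), Q (m^3/s); tab-separated with a header line.
#' @param file path.
#' @param w a \code{csf_waveform} (for writing).
#' @param times sample times used when writing.
#' @return for reading, a \code{csf_waveform}.
#' @export
read_waveform <- function(file) {
  d <- utils::read.delim(file)
  waveform_from_table(d[[1]], d[[2]])
}

#' @rdname read_waveform
#' @export
write_waveform <- function(w, file, times = seq(0, w$period, length.out = 201L)) {
  stopifnot(inherits(w, "csf_waveform"), is.finite(w$period))
  utils::write.table(data.frame(t = times, Q = w$q(times)), file,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
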