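#' Mean drug percentage in a vertebral window
#'
#' Volume-weighted mean drug volume fraction (x 100) over the half-open
#' axial interval of the window; cells straddling the window boundary are
#' weighted by their exact axial overlap.
#'
#' @param run a \code{csf_run}.
#' @param label vertebral window label (e.g. \code{"C7-T1"}).
#' @param t report time in s; must match a stored snapshot or (for tracked
#'   probe windows) a recorded time.
#' @return percentage in [0, 100].
#' @export
window_mean <- function(run, label, t) {
  stopifnot(inherits(run, "csf_run"))
  win <- locate_level(run$geometry, label)
  wts <- window_weights(run$mesh, win)
  if (all(wts == 0))
    stop(sprintf("empty window '%s': mesh too coarse", label))
  C <- tryCatch(snapshot_at(run, t)$C, error = function(e) NULL)
  if (!is.null(C)) {
    Vw <- run$mesh$V * wts
    return(100 * sum(C * Vw) / sum(Vw))
  }
  lab <- gsub("–", "-", toupper(label))
  if (lab %in% colnames(run$window_mean_pct)) {
    i <- which.min(abs(run$times - t))
    if (abs(run$times[i] - t) <= run$dt) return(run$window_mean_pct[i, lab])
  }
  stop(sprintf("no snapshot or tracked series available at t = %g s for '%s'",
               t, label))
}

#' Domain-mean drug percentage
#'
#' Mean drug volume fraction (x 100) over the spinal CSF compartment: the
#' meshed canal plus the closed sacral stub below the caudal opening (drug
#' shuttled into the stub by the oscillation remains spinal CSF drug).
#' Computed from the conservation ledger records, so
#' percentage x compartment volume = drug mass exactly. Set
#' \code{include_stub = FALSE} for the canal-only mean.
#'
#' @param run a \code{csf_run}.
#' @param t time in s (matched to the nearest record).
#' @param include_stub include the sacral stub compartment (default TRUE).
#' @return percentage.
#' @export
domain_mean_percentage <- function(run, t, include_stub = TRUE) {
  stopifnot(inherits(run, "csf_run"))
  i <- which.min(abs(run$times - t))
  if (abs(run$times[i] - t) > run$dt)
    stop(sprintf("no record at t = %g s", t))
  vs <- if (include_stub) run$geometry$caudal_stub_volume else 0
  mass <- run$ledger$resident[i] +
    if (include_stub) run$ledger$out_caudal[i] else 0
  100 * mass / (run$mesh$volume + vs)
}

#' Average-drug-percentage table across runs
#'
#' Builds the run x report-time table of domain-mean drug percentages (the
#' heatmap quantity), optionally writing it as tab-delimited text and
#' rendering an image.
#'
#' @param runs list of \code{csf_run} objects (e.g. from
#'   \code{\link{csf_sweep}}).
#' @param times report times in s (default 60, 200, 300).
#' @param file optional TSV output path.
#' @param image optional PNG output path for the rendered heatmap.
#' @param strict if TRUE, missing report times are an error; otherwise they
#'   yield NA cells with a warning.
#' @return data.frame with run provenance (gauge, speed, duration) and one
#'   column per report time, invisibly returned when written.
#' @export
render_heatmap <- function(runs, times = c(60, 200, 300), file = NULL,
                           image = NULL, strict = FALSE) {
  if (length(runs) == 0) stop("no runs supplied")
  rows <- lapply(runs, function(r) {
    vals <- vapply(times, function(t) {
      tryCatch(domain_mean_percentage(r, t), error = function(e) NA_real_)
    }, 1)
    p <- r$protocol
    data.frame(run = if (is.null(p)) NA_integer_ else p$run_id,
               gauge = if (is.null(p)) NA_character_ else p$needle$gauge,
               speed = if (is.null(p)) NA_real_ else p$speed,
               duration = if (is.null(p)) NA_real_ else p$duration,
               t(stats::setNames(vals, paste0("t", times))))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (anyNA(tab[, paste0("t", times)])) {
    msg <- "missing snapshot times in heatmap table"
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(image)) {
    grDevices::png(image, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    m <- as.matrix(tab[, paste0("t", times), drop = FALSE])
    graphics::image(seq_len(nrow(m)), seq_along(times), m,
                    xlab = "run", ylab = "report time [s]", axes = FALSE,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
    graphics::axis(1, at = seq_len(nrow(m)), labels = tab$run)
    graphics::axis(2, at = seq_along(times), labels = times)
    graphics::box()
  }
  invisible(tab)
}

#' Earliest cranial arrival time
#'
#' First recorded time at which the mean drug percentage in the upper
#' cervical (C7-T1) window exceeds the threshold; +Inf if never reached.
#'
#' @param run a \code{csf_run} tracking the \code{"C7-T1"} probe window.
#' @param threshold percentage threshold (default 0.01).
#' @param window window label (default \code{"C7-T1"}).
#' @return arrival time in s, or Inf.
#' @export
cranial_arrival <- function(run, threshold = 0.01, window = "C7-T1") {
  stopifnot(inherits(run, "csf_run"))
  if (!window %in% colnames(run$window_mean_pct))
    stop(sprintf("window '%s' was not tracked in this run", window))
  hit <- which(run$window_mean_pct[, window] > threshold)
  if (length(hit) == 0) Inf else run$times[hit[1]]
}

#' Rank runs by cranial transport speed
#'
#' Sorts runs by earliest C7-T1 arrival time and reports (as a logged soft
#' check) whether the high-speed large-gauge run reaches the cervical window
#' no later than the low-speed fine-gauge run.
#'
#' @param runs list of \code{csf_run}s.
#' @param threshold arrival threshold in percent.
#' @return data.frame sorted by arrival time, with attribute
#'   \code{"ordering_ok"} recording the run-1-vs-run-9 soft check (NA when
#'   either run is absent).
#' @export
cranial_transport_ordering <- function(runs, threshold = 0.01) {
  arr <- vapply(runs, cranial_arrival, 1, threshold = threshold)
  ids <- vapply(runs, function(r) {
    if (is.null(r$protocol)) NA_integer_ else r$protocol$run_id
  }, 1L)
  tab <- data.frame(run = ids, arrival = arr)
  tab <- tab[order(tab$arrival), , drop = FALSE]
  rownames(tab) <- NULL
  ok <- NA
  if (all(c(1L, 9L) %in% ids)) {
    ok <- arr[match(1L, ids)] <= arr[match(9L, ids)]
    if (!isTRUE(ok))
      message("soft check: run 1 did not reach C7-T1 before run 9")
  }
  attr(tab, "ordering_ok") <- ok
  tab
}
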