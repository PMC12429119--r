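#' Default run configuration
#'
#' All tunable parameters of the pipeline in one serializable list (SI
#' units). Every default is either a published physiological value (fluid
#' properties, pulse volume, production rate, dt) or a documented modeling
#' choice (geometry template, rates, diffusivity, resolutions).
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    geometry = list(length = 0.60, reservoir_volume = 240e-6),
    mesh = list(nz = 96, nr = 6, refine = 2),
    waveform = list(heart_rate = 60, pulse_volume = 1.0e-6,
                    resp_rate = 12, tidal_csf_volume = 0.5e-6,
                    production_rate = 0.4e-6 / 60),
    fluid = list(rho = 998.3, mu = 0.89e-3),
    transport = list(D = 5e-10, scheme = "vanleer"),
    solver = list(dt = 0.01, tol = 1e-6, max_inner = 6, cfl_max = 0.45,
                  scheme = "minmod"),
    runs = 1:9,
    t_end = 360,
    snapshot_times = c(60, 180, 360),
    record_dt = 0.1,
    seed = 1,
    strict = FALSE
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config[sort(names(config))], f)
  unname(tools::md5sum(f))
}

build_from_config <- function(cfg) {
  geometry <- do.call(csf_geometry, cfg$geometry)
  mesh <- do.call(csf_mesh, c(list(geometry = geometry), cfg$mesh))
  wf <- combine_waveforms(
    make_cardiac(cfg$waveform$heart_rate, cfg$waveform$pulse_volume),
    make_respiratory(cfg$waveform$resp_rate, cfg$waveform$tidal_csf_volume),
    cfg$waveform$production_rate)
  list(geometry = geometry, mesh = mesh, waveform = wf,
       props = do.call(fluid_properties, cfg$fluid),
       transport = do.call(transport_params, cfg$transport))
}

#' Run the configured pipeline
#'
#' config -> geometry -> waveforms -> flow + transport -> metrics, writing a
#' per-run directory with VTK snapshots, delimited-text metric tables, the
#' heatmap table and a JSON manifest (config hash, seed, package version).
#'
#' @param config a configuration list (see \code{\link{default_config}}) or
#'   the path of a YAML file holding one.
#' @param output_dir output directory (created if needed).
#' @param strict if TRUE, invariant violations and missing report times are
#'   hard failures.
#' @return list of \code{csf_run} objects, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("csfsim_"),
                         strict = NULL) {
  cfg <- read_config(if (is.list(config)) config else config)
  if (!is.null(strict)) cfg$strict <- strict
  if (cfg$solver$dt <= 0) stop("configuration error: dt must be positive")
  set.seed(cfg$seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- build_from_config(cfg)
  protos <- build_run_matrix()

  runs <- list()
  for (r in cfg$runs) {
    run <- csf_simulate(cfg$t_end, protocol = protos[[r]],
                        geometry = parts$geometry, mesh = parts$mesh,
                        waveform = parts$waveform, props = parts$props,
                        transport = parts$transport, dt = cfg$solver$dt,
                        snapshot_times = cfg$snapshot_times,
                        record_dt = cfg$record_dt,
                        control = list(tol = cfg$solver$tol,
                                       max_inner = cfg$solver$max_inner,
                                       cfl_max = cfg$solver$cfl_max,
                                       scheme = cfg$solver$scheme))
    if (cfg$strict && ledger_closure_error(run$conc, run$mesh) > 1e-3)
      stop(sprintf("strict mode: ledger closure violated in run %d", r))
    rd <- file.path(output_dir, sprintf("run%d", r))
    dir.create(rd, showWarnings = FALSE)
    for (s in run$snapshots) {
      if (is.null(s)) next
      write_vtk(run$mesh, file.path(rd, sprintf("fields_t%03.0f.vtk", s$t)),
                fields = list(concentration = s$C, pressure = s$p))
    }
    met <- data.frame(t = run$times,
                      domain_mean_pct = 100 *
                        (run$ledger$resident + run$ledger$out_caudal) /
                        (run$mesh$volume + parts$geometry$caudal_stub_volume),
                      run$window_mean_pct, check.names = FALSE)
    utils::write.table(met, file.path(rd, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(run$ledger, file.path(rd, "ledger.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(run$residual_log, file.path(rd, "residuals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    runs[[paste0("run", r)]] <- run
  }

  render_heatmap(runs, file = file.path(output_dir, "heatmap.tsv"),
                 strict = cfg$strict)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("csfsim")),
                   runs = as.integer(cfg$runs),
                   geometry_total_volume_mL = parts$geometry$total_volume * 1e6)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(runs)
}
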