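#' Default run configuration
#'
#' A nested list whose defaults reproduce the reference tortuous model: a
#' 30-degree, single-unit vessel, 1 mm mesh interval, steady inlet velocity
#' 0.156 m/s against zero outlet gauge pressure, SIMPLE solve at tolerance
#' 1e-3.
#'
#' @return a list of class `run_config` with blocks `geometry`, `fluid`,
#'   `mesh`, `solver`, `bc` and `output`.
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(L = 130, d = 3, w = 20, R = 6.318, r = 6,
                    theta_deg = 30, n = 1),
    fluid = list(mu = 0.0035, rho = 1050),
    mesh = list(interval_mm = 1),
    solver = list(mode = "steady", tolerance = 1e-3, max_iter = 4000,
                  relax_u = 0.7, relax_p = 0.3, dt = 0.01, n_cycles = 3,
                  max_inner = 60),
    bc = list(inlet_velocity = 0.156, outlet_pressure = 0,
              inlet_profile = "uniform",
              waveform = list(period = 1,
                              anchors = default_cardiac_anchors())),
    output = list(directory = ".", verbosity = 1)
  ), class = "run_config")
}

validate_config_keys <- function(cfg, template, where = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0(where, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.data.frame(template[[k]]) &&
        is.list(cfg[[k]]) && !is.data.frame(cfg[[k]])) {
      validate_config_keys(cfg[[k]], template[[k]], paste0(where, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read a run configuration from a YAML file
#'
#' Keys omitted from the file keep their defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tmpl <- default_run_config()
  if (!is.null(raw$bc$waveform$anchors)) {
    raw$bc$waveform$anchors <-
      do.call(rbind, lapply(raw$bc$waveform$anchors, as.data.frame))
  }
  validate_config_keys(raw, tmpl)
  cfg <- utils::modifyList(unclass(tmpl), raw)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$bc$waveform$anchors <-
    lapply(seq_len(nrow(cfg$bc$waveform$anchors)),
           function(i) as.list(cfg$bc$waveform$anchors[i, ]))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_geometry <- function(config) {
  g <- config$geometry
  vessel_geometry(theta_deg = g$theta_deg, n = g$n, L = g$L, d = g$d,
                  R = g$R, r = g$r, w = g$w)
}

config_solver <- function(config) {
  s <- config$solver
  solver_config(tolerance = s$tolerance, max_iter = s$max_iter,
                relax_u = s$relax_u, relax_p = s$relax_p, dt = s$dt,
                n_cycles = s$n_cycles, max_inner = s$max_inner)
}

log_msg <- function(config, ...) {
  if (isTRUE(config$output$verbosity > 0)) {
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  }
}

#' Generate geometry and mesh files for a configuration
#'
#' Writes the centerline and outline point lists, the legacy VTK mesh and a
#' plain-text mesh report into `out_dir`.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the mesh report list.
#' @export
cmd_geometry <- function(config = default_run_config(),
                         out_dir = config$output$directory) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(config)
  path <- build_centerline(geom)
  outline <- offset_lumen(path, geom$d)
  mesh <- sweep_mesh(outline, config$mesh$interval_mm)
  write_outline_csv(outline, file.path(out_dir, "centerline.csv"),
                    file.path(out_dir, "outline.csv"))
  write_vtk_mesh(mesh, file.path(out_dir, "mesh.vtk"))
  rep <- mesh_report(mesh)
  rl <- c(sprintf("cells: %d", rep$n_cells),
          sprintf("min_cell_area_m2: %.12g", rep$min_cell_area),
          sprintf("max_cell_area_m2: %.12g", rep$max_cell_area),
          sprintf("min_orthogonality_deg: %.6g", rep$min_orthogonality_deg),
          sprintf("%s_faces: %d", names(rep$patch_faces),
                  unlist(rep$patch_faces)))
  writeLines(rl, file.path(out_dir, "mesh_report.txt"))
  log_msg(config, "geometry written to %s (%d cells)", out_dir, rep$n_cells)
  invisible(rep)
}

#' Run a single simulation for a configuration
#'
#' Steady or pulsatile per `config$solver$mode`. Writes VTK field snapshots,
#' the residual history CSV and a pressure-drop CSV; outputs are a pure
#' function of the configuration (identical reruns are byte-identical).
#'
#' @inheritParams cmd_geometry
#' @return invisibly, the pressure-drop data frame.
#' @export
cmd_run <- function(config = default_run_config(),
                    out_dir = config$output$directory) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(config)
  path <- build_centerline(geom)
  mesh <- sweep_mesh(offset_lumen(path, geom$d), config$mesh$interval_mm)
  fluid <- fluid_properties(config$fluid$mu, config$fluid$rho)
  cfg <- config_solver(config)
  if (identical(config$solver$mode, "pulsatile")) {
    wf <- build_waveform(config$bc$waveform$anchors,
                         config$bc$waveform$period)
    ser <- solve_unsteady(mesh, fluid, wf, cfg)
    drops <- pulsatile_snapshot_drops(ser, mesh)
    for (i in seq_along(drops$time_s)) {
      sn <- series_snapshot(ser, drops$time_s[i], cycle = 2)
      write_vtk_fields(mesh, sn,
                       file.path(out_dir, sprintf("fields_t%g.vtk",
                                                  drops$time_s[i])))
    }
    write_residuals_csv(ser, file.path(out_dir, "residuals.csv"))
  } else {
    bc <- boundary_conditions(config$bc$inlet_velocity,
                              config$bc$outlet_pressure,
                              config$bc$inlet_profile)
    ff <- solve_steady(mesh, fluid, bc, cfg)
    drops <- pressure_drop(ff, mesh)
    write_vtk_fields(mesh, ff, file.path(out_dir, "fields.vtk"))
    write_residuals_csv(ff, file.path(out_dir, "residuals.csv"))
  }
  drops$theta_deg <- geom$theta_deg
  drops$ctn <- geom$n
  drops$centerline_length_mm <- centerline_length(path)
  write_numeric_csv(drops, file.path(out_dir, "pressure_drop.csv"))
  log_msg(config, "run complete: dp = %s Pa",
          paste(sprintf("%.2f", drops$dp_pa), collapse = "/"))
  invisible(drops)
}

#' Run the design sweep for a configuration
#'
#' @inheritParams cmd_geometry
#' @param angles,counts the design grid (defaults to the full grid).
#' @param plots also write `dp_vs_ctn.png` and `dp_vs_length.png` (steady
#'   mode; requires a functioning graphics device).
#' @return invisibly, the `sweep_result`.
#' @export
cmd_sweep <- function(config = default_run_config(),
                      out_dir = config$output$directory,
                      angles = c(30, 60, 90, 120), counts = 0:5,
                      plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fluid <- fluid_properties(config$fluid$mu, config$fluid$rho)
  cfg <- config_solver(config)
  mode <- if (identical(config$solver$mode, "pulsatile")) "pulsatile"
          else "steady"
  bc <- boundary_conditions(config$bc$inlet_velocity,
                            config$bc$outlet_pressure,
                            config$bc$inlet_profile)
  wf <- build_waveform(config$bc$waveform$anchors, config$bc$waveform$period)
  sw <- run_design_sweep(angles = angles, counts = counts, mode = mode,
                         interval_mm = config$mesh$interval_mm,
                         fluid = fluid, bc = bc, cfg = cfg, waveform = wf,
                         geometry_args = config$geometry[c("L", "d", "R",
                                                           "r", "w")],
                         verbose = config$output$verbosity > 0)
  write_sweep_csv(sw, file.path(out_dir, "sweep.csv"))
  if (plots && mode == "steady") {
    ggplot2::ggsave(file.path(out_dir, "dp_vs_ctn.png"), plot_sweep_dp(sw),
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "dp_vs_length.png"),
                    plot_sweep_length(sw), width = 6, height = 4, dpi = 150)
  }
  log_msg(config, "sweep complete: %d rows", nrow(sw$table))
  invisible(sw)
}
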