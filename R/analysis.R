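#' Inlet-to-outlet pressure drop of a solved flow field
#'
#' Length-weighted (area per unit depth) mean pressure over the cells
#' adjacent to the inlet patch minus the same mean over the outlet patch.
#' With the outlet gauge fixed at zero this is essentially the mean inlet
#' pressure.
#'
#' @param fields a `flow_fields`.
#' @param mesh the `quad_mesh` the fields were solved on.
#' @param require_converged refuse non-converged fields (default TRUE).
#' @return object of class `pressure_drop_result`: a one-row data frame with
#'   `inlet_p_pa`, `outlet_p_pa`, `dp_pa`, `mode` and (pulsatile) `time_s`.
#' @export
pressure_drop <- function(fields, mesh, require_converged = TRUE) {
  stopifnot(inherits(fields, "flow_fields"), inherits(mesh, "quad_mesh"))
  if (require_converged && !isTRUE(fields$converged)) {
    stop("fields are not converged; rerun with more iterations or pass ",
         "`require_converged = FALSE`", call. = FALSE)
  }
  f <- mesh$faces
  inl <- f$patch == "inlet"
  out <- f$patch == "outlet"
  p_in <- sum(fields$p[f$owner[inl]] * f$len[inl]) / sum(f$len[inl])
  p_out <- sum(fields$p[f$owner[out]] * f$len[out]) / sum(f$len[out])
  res <- data.frame(inlet_p_pa = p_in, outlet_p_pa = p_out,
                    dp_pa = p_in - p_out,
                    mode = if (is.null(fields$mode)) "steady" else fields$mode,
                    time_s = if (is.null(fields$time)) NA_real_
                             else fields$time)
  class(res) <- c("pressure_drop_result", "data.frame")
  res
}

#' Section-averaged pressure along the vessel
#'
#' Mean cell pressure over each sweep station ring, against the arc-length
#' position of the ring midpoint.
#'
#' @inheritParams pressure_drop
#' @return data frame with columns `s_mm` and `p_pa`.
#' @export
section_pressures <- function(fields, mesh) {
  stopifnot(inherits(fields, "flow_fields"), inherits(mesh, "quad_mesh"))
  K <- mesh$n_along
  J <- mesh$n_across
  ring <- rep(seq_len(K), each = J)
  p_ring <- as.vector(rowsum(fields$p, ring)) / J
  s_mid <- (mesh$station_s_mm[-1] + mesh$station_s_mm[-(K + 1)]) / 2
  data.frame(s_mm = s_mid, p_pa = p_ring)
}

#' Fully developed axial pressure gradient
#'
#' Least-squares slope of the section-averaged pressure over an arc-length
#' window, by default the central part of the vessel (past the entry
#' development region, short of the outlet).
#'
#' @inheritParams pressure_drop
#' @param s_range arc-length window in mm (default 25% to 85% of the length).
#' @return gradient magnitude in Pa/m (positive for pressure falling
#'   downstream).
#' @export
developed_pressure_gradient <- function(fields, mesh, s_range = NULL) {
  sp <- section_pressures(fields, mesh)
  S <- max(mesh$station_s_mm)
  if (is.null(s_range)) s_range <- c(0.25, 0.85) * S
  sel <- sp$s_mm >= s_range[1] & sp$s_mm <= s_range[2]
  fit <- stats::lm(p_pa ~ s_mm, data = sp[sel, ])
  -unname(stats::coef(fit)[2]) * 1e3   # Pa/mm -> Pa/m
}

#' Reynolds number
#'
#' `rho * U * d / mu` with the lumen diameter as the length scale.
#'
#' @param fluid a [fluid_properties()].
#' @param U characteristic (inlet) velocity in m/s.
#' @param d lumen diameter in m.
#' @export
reynolds_number <- function(fluid, U, d) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (U <= 0 || d <= 0) stop("`U` and `d` must be positive", call. = FALSE)
  fluid$rho * U * d / fluid$mu
}

# build geometry -> mesh for one design point (shared by sweep and commands)
design_mesh <- function(theta_deg, n, L = 130, d = 3, R = 6.318, r = 6,
                        w = 20, interval_mm = 1) {
  geom <- vessel_geometry(theta_deg = theta_deg, n = n, L = L, d = d,
                          R = R, r = r, w = w)
  path <- build_centerline(geom)
  outline <- offset_lumen(path, d)
  list(geom = geom, path = path, outline = outline,
       mesh = sweep_mesh(outline, interval_mm))
}

#' Run the tortuosity design sweep
#'
#' Solves every (tortuosity angle, tortuosity count) combination and collects
#' inlet-to-outlet pressure drops. The straight vessel (`n = 0`) is identical
#' for every angle, so it is solved once and its row replicated. In steady
#' mode an ordinary least-squares fit of pressure drop against centerline
#' length is attached. Non-converged points are recorded with `converged =
#' FALSE` and the sweep continues.
#'
#' @param angles tortuosity angles in degrees.
#' @param counts tortuosity counts.
#' @param mode `"steady"` or `"pulsatile"`.
#' @param interval_mm mesh interval in mm.
#' @param fluid,bc,cfg solver inputs; `bc` is ignored in pulsatile mode.
#' @param waveform pulsatile boundary waveform (pulsatile mode).
#' @param times in-cycle snapshot times for pulsatile mode.
#' @param geometry_args named list overriding `L`, `d`, `R`, `r`, `w`.
#' @param verbose print one line per design point.
#' @return object of class `sweep_result`: `$table` (one row per design point
#'   and, in pulsatile mode, per snapshot time), `$fit` and `$r_squared`
#'   (steady mode).
#' @export
run_design_sweep <- function(angles = c(30, 60, 90, 120), counts = 0:5,
                             mode = c("steady", "pulsatile"),
                             interval_mm = 1,
                             fluid = fluid_properties(),
                             bc = boundary_conditions(),
                             cfg = solver_config(),
                             waveform = build_waveform(),
                             times = c(0.26, 0.36, 0.80),
                             geometry_args = list(),
                             verbose = FALSE) {
  mode <- match.arg(mode)
  ga <- utils::modifyList(list(L = 130, d = 3, R = 6.318, r = 6, w = 20),
                          geometry_args)
  rows <- list()
  straight_rows <- NULL
  for (theta in angles) {
    for (n in counts) {
      if (n == 0 && !is.null(straight_rows)) {
        rr <- straight_rows
        rr$theta_deg <- theta
        rows[[length(rows) + 1]] <- rr
        next
      }
      dm <- design_mesh(theta, n, L = ga$L, d = ga$d, R = ga$R, r = ga$r,
                        w = ga$w, interval_mm = interval_mm)
      S <- centerline_length(dm$path)
      rr <- tryCatch({
        if (mode == "steady") {
          ff <- solve_steady(dm$mesh, fluid, bc, cfg)
          pd <- pressure_drop(ff, dm$mesh, require_converged = FALSE)
          data.frame(theta_deg = theta, ctn = n,
                     centerline_length_mm = S, dp_pa = pd$dp_pa,
                     mode = "steady", time_s = NA_real_,
                     converged = ff$converged, iterations = ff$iterations,
                     mass_imbalance = mass_balance(ff)$relative_imbalance,
                     failure = NA_character_)
        } else {
          ser <- solve_unsteady(dm$mesh, fluid, waveform, cfg,
                                snapshot_times = times)
          do.call(rbind, lapply(times, function(tt) {
            sn <- series_snapshot(ser, tt, cycle = 2)
            pd <- pressure_drop(sn, dm$mesh, require_converged = FALSE)
            data.frame(theta_deg = theta, ctn = n,
                       centerline_length_mm = S, dp_pa = pd$dp_pa,
                       mode = "pulsatile", time_s = tt,
                       converged = sn$converged, iterations = sn$iterations,
                       mass_imbalance = mass_balance(sn)$relative_imbalance,
                       failure = NA_character_)
          }))
        }
      }, error = function(e) {
        data.frame(theta_deg = theta, ctn = n, centerline_length_mm = S,
                   dp_pa = NA_real_, mode = mode, time_s = NA_real_,
                   converged = FALSE, iterations = NA_integer_,
                   mass_imbalance = NA_real_,
                   failure = conditionMessage(e))
      })
      if (verbose) {
        message(sprintf("theta=%g ctn=%d: dp = %s Pa", theta, n,
                        paste(sprintf("%.1f", rr$dp_pa), collapse = "/")))
      }
      if (n == 0) straight_rows <- rr
      rows[[length(rows) + 1]] <- rr
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  out <- list(table = table, mode = mode)
  if (mode == "steady") {
    ok <- table$converged & !is.na(table$dp_pa)
    if (sum(ok) >= 3) {
      fit <- stats::lm(dp_pa ~ centerline_length_mm, data = table[ok, ])
      out$fit <- fit
      out$r_squared <- summary(fit)$r.squared
    }
  }
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Design sweep (%s): %d rows\n", x$mode, nrow(x$table)))
  if (!is.null(x$r_squared)) {
    co <- stats::coef(x$fit)
    cat(sprintf(paste0("  dp vs centerline length: slope %.4f Pa/mm, ",
                       "intercept %.2f Pa, R^2 = %.4f\n"),
                co[2], co[1], x$r_squared))
  }
  print(utils::head(x$table, 12), row.names = FALSE)
  if (nrow(x$table) > 12) cat("  ...\n")
  invisible(x)
}

#' Pressure drops at the cardiac snapshot times of a pulsatile run
#'
#' Extracts the analysis-cycle (cycle 2) snapshots at the requested in-cycle
#' times and computes the inlet-to-outlet pressure drop of each.
#'
#' @param series a `flow_series`.
#' @param mesh the `quad_mesh` the series was solved on.
#' @param times in-cycle times in seconds (default the three cardiac
#'   anchors).
#' @param cycle cycle to analyze (default 2).
#' @return data frame with one row per time, ordered as `times`.
#' @export
pulsatile_snapshot_drops <- function(series, mesh,
                                     times = c(0.26, 0.36, 0.80),
                                     cycle = 2) {
  stopifnot(inherits(series, "flow_series"))
  do.call(rbind, lapply(times, function(tt) {
    sn <- series_snapshot(series, tt, cycle = cycle)
    pd <- pressure_drop(sn, mesh, require_converged = FALSE)
    pd$time_s <- tt
    pd
  }))
}

#' Write a sweep table to CSV
#'
#' Full-precision, locale-independent formatting so reruns of the same
#' configuration are byte-identical.
#'
#' @param sweep a `sweep_result`.
#' @param path output file.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  cols <- c("theta_deg", "ctn", "centerline_length_mm", "dp_pa", "mode",
            "time_s")
  write_numeric_csv(sweep$table[, cols], path)
}

#' Pressure drop against tortuosity count, one line per angle
#' @param sweep a steady `sweep_result`.
#' @return a ggplot object.
#' @export
plot_sweep_dp <- function(sweep) {
  tb <- sweep$table
  tb$theta <- factor(tb$theta_deg)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$ctn, y = .data$dp_pa,
                                   colour = .data$theta)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "tortuosity count", y = "pressure drop (Pa)",
                  colour = "angle (deg)")
}

#' Pressure drop against centerline length with the linear fit
#' @param sweep a steady `sweep_result`.
#' @return a ggplot object.
#' @export
plot_sweep_length <- function(sweep) {
  tb <- sweep$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$centerline_length_mm,
                                   y = .data$dp_pa)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$theta_deg))) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(x = "centerline length (mm)", y = "pressure drop (Pa)",
                  colour = "angle (deg)")
}
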