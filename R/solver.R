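#' Fluid properties
#'
#' Newtonian blood analogue: dynamic viscosity 0.0035 Pa s, density
#' 1050 kg/m^3 by default.
#'
#' @param mu dynamic viscosity in Pa s.
#' @param rho density in kg/m^3.
#' @export
fluid_properties <- function(mu = 0.0035, rho = 1050) {
  if (mu <= 0 || rho <= 0) stop("`mu` and `rho` must be positive",
                                call. = FALSE)
  structure(list(mu = mu, rho = rho), class = "fluid_properties")
}

#' Boundary condition set
#'
#' Uniform (plug) or parabolic inlet velocity, uniform outlet gauge pressure,
#' no-slip rigid walls. For pulsatile runs the inlet speed and outlet
#' pressure are taken from a waveform instead of these constants.
#'
#' @param inlet_velocity mean inlet speed in m/s (>= 0).
#' @param outlet_pressure outlet gauge pressure in Pa.
#' @param inlet_profile `"uniform"` (plug, the default) or `"parabolic"`
#'   (fully developed plane-channel profile with the same mean).
#' @export
boundary_conditions <- function(inlet_velocity = 0.156, outlet_pressure = 0,
                                inlet_profile = c("uniform", "parabolic")) {
  if (inlet_velocity < 0) stop("`inlet_velocity` must be >= 0", call. = FALSE)
  inlet_profile <- match.arg(inlet_profile)
  structure(list(inlet_velocity = inlet_velocity,
                 outlet_pressure = outlet_pressure,
                 inlet_profile = inlet_profile),
            class = "boundary_conditions")
}

#' Solver configuration
#'
#' SIMPLE pressure-velocity coupling on a collocated grid with first-order
#' upwind convection and standard (linear) pressure interpolation. Scaled
#' residuals are normalized by their first-iteration values and iteration
#' stops when all fall below `tolerance`.
#'
#' @param tolerance convergence criterion on scaled residuals (default 1e-3).
#' @param max_iter maximum outer iterations for a steady solve.
#' @param relax_u,relax_p under-relaxation factors for momentum and pressure.
#' @param dt time step in seconds for pulsatile runs (default 0.01 s, which
#'   resolves the anchor times exactly).
#' @param n_cycles number of cardiac cycles to march (default 3; the second
#'   cycle is used for analysis).
#' @param max_inner maximum SIMPLE iterations per time step.
#' @param re_limit laminar-flow guard: a warning is issued when the inlet
#'   Reynolds number reaches this value (default 2300).
#' @export
solver_config <- function(tolerance = 1e-3, max_iter = 4000,
                          relax_u = 0.7, relax_p = 0.3,
                          dt = 0.01, n_cycles = 3, max_inner = 60,
                          re_limit = 2300) {
  if (tolerance <= 0 || tolerance >= 1) stop("`tolerance` must be in (0, 1)",
                                             call. = FALSE)
  if (relax_u <= 0 || relax_u > 1 || relax_p <= 0 || relax_p > 1) {
    stop("under-relaxation factors must lie in (0, 1]", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(tolerance = tolerance, max_iter = max_iter,
                 relax_u = relax_u, relax_p = relax_p, dt = dt,
                 n_cycles = n_cycles, max_inner = max_inner,
                 re_limit = re_limit),
            class = "solver_config")
}

# --- internal: precomputed discretization context ---------------------------

# scatter-add matrix: column k adds into row idx[k]
scatter_matrix <- function(n, idx) {
  Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                       dims = c(n, length(idx)))
}

# face-mean of the parabolic plane-channel profile with mean U over [t1,t2]
parabolic_face_mean <- function(U, t1, t2, d) {
  1.5 * U * (1 - (4 / (3 * d^2)) * (t1^2 + t1 * t2 + t2^2))
}

build_solver_context <- function(mesh, fluid) {
  f <- mesh$faces
  M <- nrow(mesh$cells)
  int <- which(f$patch == "interior")
  inl <- which(f$patch == "inlet")
  out <- which(f$patch == "outlet")
  wal <- which(f$patch %in% c("wall_lower", "wall_upper"))
  ctx <- list(
    M = M, Vol = mesh$cell_area,
    mu = fluid$mu, rho = fluid$rho,
    int_o = f$owner[int], int_b = f$neigh[int],
    int_len = f$len[int], int_nx = f$nx[int], int_ny = f$ny[int],
    int_delta = f$delta[int], int_gw = f$gw[int],
    D_int = fluid$mu * f$len[int] / f$delta[int],
    inl_o = f$owner[inl], inl_len = f$len[inl],
    inl_nx = f$nx[inl], inl_ny = f$ny[inl],
    D_inl = fluid$mu * f$len[inl] / f$delta[inl],
    out_o = f$owner[out], out_len = f$len[out],
    out_nx = f$nx[out], out_ny = f$ny[out],
    out_delta = f$delta[out],
    wal_o = f$owner[wal],
    D_wal = fluid$mu * f$len[wal] / f$delta[wal],
    wal_len = f$len[wal], wal_nx = f$nx[wal], wal_ny = f$ny[wal]
  )
  # inlet face transverse extents for the parabolic profile (signed offsets
  # of the face nodes from the centerline entry point, along its normal)
  p1 <- mesh$nodes[f$n1[inl], , drop = FALSE]
  p2 <- mesh$nodes[f$n2[inl], , drop = FALSE]
  nrm <- mesh$inlet_normal
  org <- mesh$inlet_point
  ctx$inl_t1 <- (p1[, 1] - org[1]) * nrm[1] + (p1[, 2] - org[2]) * nrm[2]
  ctx$inl_t2 <- (p2[, 1] - org[1]) * nrm[1] + (p2[, 2] - org[2]) * nrm[2]

  # scatter operators (cell <- face accumulation), built once
  ctx$P_int_o <- scatter_matrix(M, ctx$int_o)
  ctx$P_int_b <- scatter_matrix(M, ctx$int_b)
  ctx$P_int_diff <- ctx$P_int_o - ctx$P_int_b
  ctx$P_int_sum <- ctx$P_int_o + ctx$P_int_b
  ctx$P_inl <- scatter_matrix(M, ctx$inl_o)
  ctx$P_out <- scatter_matrix(M, ctx$out_o)
  P_wal <- scatter_matrix(M, ctx$wal_o)
  # constant diffusive part of the momentum diagonal
  ctx$diag_D <- as.vector(ctx$P_int_sum %*% ctx$D_int +
                          ctx$P_inl %*% ctx$D_inl + P_wal %*% ctx$D_wal)

  # Green-Gauss gradient as linear operators on the cell field, with
  # zero-gradient closure at inlet/walls folded in; outlet face values enter
  # through the constant vectors gox/goy (per unit outlet value)
  gi <- ctx$int_gw
  wxi <- ctx$int_len * ctx$int_nx
  wyi <- ctx$int_len * ctx$int_ny
  tri_gi <- c(ctx$int_o, ctx$int_o, ctx$int_b, ctx$int_b,
              ctx$inl_o, ctx$wal_o)
  tri_gj <- c(ctx$int_o, ctx$int_b, ctx$int_o, ctx$int_b,
              ctx$inl_o, ctx$wal_o)
  valx <- c(gi * wxi, (1 - gi) * wxi, -gi * wxi, -(1 - gi) * wxi,
            ctx$inl_len * ctx$inl_nx, ctx$wal_len * ctx$wal_nx)
  valy <- c(gi * wyi, (1 - gi) * wyi, -gi * wyi, -(1 - gi) * wyi,
            ctx$inl_len * ctx$inl_ny, ctx$wal_len * ctx$wal_ny)
  iv <- 1 / ctx$Vol
  ctx$Gx <- Matrix::sparseMatrix(i = tri_gi, j = tri_gj, x = valx * iv[tri_gi],
                                 dims = c(M, M))
  ctx$Gy <- Matrix::sparseMatrix(i = tri_gi, j = tri_gj, x = valy * iv[tri_gi],
                                 dims = c(M, M))
  ctx$gox <- as.vector(ctx$P_out %*% (ctx$out_len * ctx$out_nx)) * iv
  ctx$goy <- as.vector(ctx$P_out %*% (ctx$out_len * ctx$out_ny)) * iv

  # shared sparsity pattern of the momentum and pressure-correction systems,
  # with the triplet -> compressed-column slot permutation cached
  tri_i <- c(seq_len(M), ctx$int_o, ctx$int_b)
  tri_j <- c(seq_len(M), ctx$int_b, ctx$int_o)
  ctx$A0 <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = 1, dims = c(M, M))
  ctx$x_ord <- order((tri_j - 1) * M + tri_i)
  ctx
}

# inlet face speeds (mean over each face) for a given mean speed U
inlet_face_speed <- function(ctx, U, profile, d) {
  if (profile == "parabolic") {
    parabolic_face_mean(U, ctx$inl_t1, ctx$inl_t2, d)
  } else {
    rep(U, length(ctx$inl_o))
  }
}

# Green-Gauss cell gradient of a cell field p with boundary face values:
# inlet/wall zero-gradient (face value = owner value), outlet fixed p_out_face
green_gauss <- function(ctx, p, p_out_face) {
  list(x = as.vector(ctx$Gx %*% p) + ctx$gox * p_out_face,
       y = as.vector(ctx$Gy %*% p) + ctx$goy * p_out_face)
}

# one SIMPLE outer iteration; returns updated state + raw residuals
simple_iteration <- function(ctx, st, relax_u, relax_p,
                             unsteady = FALSE, dt = NA, u_time = NULL) {
  M <- ctx$M
  gp <- green_gauss(ctx, st$p, st$p_out_val)

  F_int <- st$F_int
  Fp <- pmax(F_int, 0)
  Fm <- pmax(-F_int, 0)
  a_ob <- ctx$D_int + Fm       # coefficient of neighbour in owner equation
  a_bo <- ctx$D_int + Fp
  diag <- ctx$diag_D +
          as.vector(ctx$P_int_o %*% Fp + ctx$P_int_b %*% Fm +
                    ctx$P_out %*% pmax(st$F_out, 0))
  rhs_u <- -gp$x * ctx$Vol + st$rhs_in_u
  rhs_v <- -gp$y * ctx$Vol + st$rhs_in_v
  if (unsteady) {
    at <- ctx$rho * ctx$Vol / dt
    diag <- diag + at
    rhs_u <- rhs_u + at * u_time$u
    rhs_v <- rhs_v + at * u_time$v
  }
  dEff <- diag / relax_u
  rhs_u <- rhs_u + (1 - relax_u) * dEff * st$u
  rhs_v <- rhs_v + (1 - relax_u) * dEff * st$v

  A <- ctx$A0
  A@x <- c(dEff, -a_ob, -a_bo)[ctx$x_ord]
  # unrelaxed momentum residuals at the current iterate
  Au <- as.vector(A %*% st$u)
  Av <- as.vector(A %*% st$v)
  res_u <- sum(abs(rhs_u - Au))
  res_v <- sum(abs(rhs_v - Av))

  sol <- Matrix::solve(A, cbind(rhs_u, rhs_v))
  u <- as.vector(sol[, 1])
  v <- as.vector(sol[, 2])
  dP <- ctx$Vol / dEff

  # Rhie-Chow star fluxes
  gw <- ctx$int_gw
  un_f <- (gw * u[ctx$int_o] + (1 - gw) * u[ctx$int_b]) * ctx$int_nx +
          (gw * v[ctx$int_o] + (1 - gw) * v[ctx$int_b]) * ctx$int_ny
  d_f <- gw * dP[ctx$int_o] + (1 - gw) * dP[ctx$int_b]
  gpn_f <- (gw * gp$x[ctx$int_o] + (1 - gw) * gp$x[ctx$int_b]) * ctx$int_nx +
           (gw * gp$y[ctx$int_o] + (1 - gw) * gp$y[ctx$int_b]) * ctx$int_ny
  Fs_int <- ctx$rho * ctx$int_len *
    (un_f - d_f * ((st$p[ctx$int_b] - st$p[ctx$int_o]) / ctx$int_delta -
                   gpn_f))
  oo <- ctx$out_o
  Fs_out <- ctx$rho * ctx$out_len *
    (u[oo] * ctx$out_nx + v[oo] * ctx$out_ny -
     dP[oo] * ((st$p_out_val - st$p[oo]) / ctx$out_delta -
               (gp$x[oo] * ctx$out_nx + gp$y[oo] * ctx$out_ny)))

  net <- as.vector(ctx$P_int_diff %*% Fs_int + ctx$P_out %*% Fs_out) +
         st$net_in
  res_c <- sum(abs(net))

  # pressure-correction system (outlet Dirichlet p' = 0)
  c_int <- ctx$rho * ctx$int_len * d_f / ctx$int_delta
  c_out <- ctx$rho * ctx$out_len * dP[oo] / ctx$out_delta
  diag_p <- as.vector(ctx$P_int_sum %*% c_int + ctx$P_out %*% c_out)
  Ap <- ctx$A0
  Ap@x <- c(diag_p, -c_int, -c_int)[ctx$x_ord]
  pc <- as.vector(Matrix::solve(Ap, -net))

  F_int_new <- Fs_int - c_int * (pc[ctx$int_b] - pc[ctx$int_o])
  F_out_new <- Fs_out + c_out * pc[oo]
  p_new <- st$p + relax_p * pc
  gpc <- green_gauss(ctx, pc, 0)
  u <- u - dP * gpc$x
  v <- v - dP * gpc$y

  st$u <- u; st$v <- v; st$p <- p_new
  st$F_int <- F_int_new; st$F_out <- F_out_new
  list(state = st, res = c(u = res_u, v = res_v, continuity = res_c))
}

# fold the inlet boundary condition into the cached source vectors
set_inlet_bc <- function(ctx, st, ub, p_out_val) {
  # inflow direction is opposite the outward inlet normal
  ub_x <- -ub * ctx$inl_nx
  ub_y <- -ub * ctx$inl_ny
  F_inl <- -ctx$rho * ub * ctx$inl_len   # outward mass flux (< 0 for inflow)
  coef <- ctx$D_inl + pmax(-F_inl, 0)
  st$F_inl <- F_inl
  st$rhs_in_u <- as.vector(ctx$P_inl %*% (coef * ub_x))
  st$rhs_in_v <- as.vector(ctx$P_inl %*% (coef * ub_y))
  st$net_in <- as.vector(ctx$P_inl %*% F_inl)
  st$p_out_val <- p_out_val
  st
}

init_state <- function(ctx, bc_speed, bc_pout, profile, d_m,
                       u0 = NULL, v0 = NULL, p0 = NULL) {
  M <- ctx$M
  ub <- inlet_face_speed(ctx, bc_speed, profile, d_m)
  st <- list(
    u = if (is.null(u0)) numeric(M) else u0,
    v = if (is.null(v0)) numeric(M) else v0,
    p = if (is.null(p0)) rep(bc_pout, M) else p0,
    F_int = numeric(length(ctx$int_o)),
    F_out = numeric(length(ctx$out_o))
  )
  set_inlet_bc(ctx, st, ub, bc_pout)
}

run_simple <- function(ctx, st, cfg, tol, max_iter, unsteady = FALSE,
                       dt = NA, u_time = NULL, min_iter = 2) {
  ref <- NULL
  hist <- matrix(NA_real_, nrow = max_iter, ncol = 3,
                 dimnames = list(NULL, c("u", "v", "continuity")))
  for (it in seq_len(max_iter)) {
    step <- simple_iteration(ctx, st, cfg$relax_u, cfg$relax_p,
                             unsteady = unsteady, dt = dt, u_time = u_time)
    st <- step$state
    if (is.null(ref)) {
      # both momentum components share one reference so that a vanishing
      # cross-stream residual (axis-aligned channel) is not amplified
      mom <- max(step$res[c("u", "v")], 1e-30)
      ref <- c(u = mom, v = mom, continuity = max(step$res["continuity"],
                                                  1e-30))
    }
    scaled <- step$res / ref
    hist[it, ] <- scaled
    if (any(!is.finite(scaled)) || any(scaled > 1e8)) {
      stop(sprintf(paste0("solver diverged at iteration %d (scaled ",
                          "residuals %.3g %.3g %.3g)"),
                   it, scaled[1], scaled[2], scaled[3]), call. = FALSE)
    }
    # a run whose raw residuals sit at machine level (e.g. zero inflow) is
    # converged even though the relative scale is meaningless
    abs_floor <- 1e-12 * max(ref, 1)
    if (it >= min_iter && all(scaled <= tol | step$res <= abs_floor)) {
      return(list(state = st, iterations = it,
                  residuals = hist[seq_len(it), , drop = FALSE],
                  converged = TRUE))
    }
  }
  list(state = st, iterations = max_iter,
       residuals = hist, converged = FALSE)
}

as_flow_fields <- function(st, res, mesh, meta = list()) {
  structure(c(list(u = st$u, v = st$v, p = st$p,
                   F_int = st$F_int, F_out = st$F_out, F_inl = st$F_inl,
                   residuals = res$residuals,
                   iterations = res$iterations,
                   converged = res$converged),
              meta),
            class = "flow_fields")
}

#' Steady incompressible laminar Navier-Stokes solve
#'
#' Finite-volume SIMPLE iteration on the collocated quad mesh: first-order
#' upwind convection, central diffusion, standard linear pressure
#' interpolation with momentum-weighted (Rhie-Chow) face fluxes. Iteration
#' stops when all scaled residuals (momentum components and continuity,
#' each normalized by its first-iteration value) fall below the configured
#' tolerance.
#'
#' @param mesh a [sweep_mesh()] result.
#' @param fluid a [fluid_properties()].
#' @param bc a [boundary_conditions()].
#' @param cfg a [solver_config()].
#' @return object of class `flow_fields` with per-cell `u`, `v` (m/s),
#'   `p` (Pa gauge), face mass fluxes, residual history and convergence
#'   metadata.
#' @export
solve_steady <- function(mesh, fluid = fluid_properties(),
                         bc = boundary_conditions(),
                         cfg = solver_config()) {
  stopifnot(inherits(mesh, "quad_mesh"), inherits(fluid, "fluid_properties"),
            inherits(bc, "boundary_conditions"),
            inherits(cfg, "solver_config"))
  re <- fluid$rho * bc$inlet_velocity * (mesh$d_mm * 1e-3) / fluid$mu
  if (re >= cfg$re_limit) {
    warning(sprintf("inlet Reynolds number %.0f exceeds the laminar limit %g",
                    re, cfg$re_limit))
  }
  ctx <- build_solver_context(mesh, fluid)
  st <- init_state(ctx, bc$inlet_velocity, bc$outlet_pressure,
                   bc$inlet_profile, mesh$d_mm * 1e-3)
  res <- run_simple(ctx, st, cfg, cfg$tolerance, cfg$max_iter)
  if (!res$converged) {
    warning(sprintf("steady solve did not converge in %d iterations",
                    cfg$max_iter))
  }
  as_flow_fields(res$state, res, mesh,
                 meta = list(mode = "steady", reynolds = re))
}

#' @export
print.flow_fields <- function(x, ...) {
  cat(sprintf(paste0("Flow fields (%s): %d cells, %d iterations, ",
                     "converged: %s\n"),
              x$mode, length(x$u), x$iterations, x$converged))
  cat(sprintf("  peak speed %.4g m/s, pressure range [%.4g, %.4g] Pa\n",
              max(sqrt(x$u^2 + x$v^2)), min(x$p), max(x$p)))
  invisible(x)
}

#' Pulsatile (time-dependent) solve over repeated cardiac cycles
#'
#' First-order implicit time stepping with SIMPLE inner iterations per step.
#' The initial condition is the steady solution at the waveform's `t = 0`
#' boundary values. By default three cycles are marched and snapshots at the
#' requested in-cycle times are stored for every cycle; the second cycle is
#' the one intended for analysis.
#'
#' @param mesh a [sweep_mesh()] result.
#' @param fluid a [fluid_properties()].
#' @param waveform a [build_waveform()] result.
#' @param cfg a [solver_config()]; `cfg$dt` must divide the period and each
#'   snapshot time.
#' @param snapshot_times in-cycle times (seconds) at which to store fields;
#'   defaults to the three cardiac anchor times.
#' @return object of class `flow_series`: list of snapshot `flow_fields`
#'   (each with `time`, `cycle` metadata), the per-step inlet-pressure trace
#'   and run metadata.
#' @export
solve_unsteady <- function(mesh, fluid = fluid_properties(),
                           waveform = build_waveform(),
                           cfg = solver_config(),
                           snapshot_times = c(0.26, 0.36, 0.80)) {
  stopifnot(inherits(mesh, "quad_mesh"), inherits(waveform,
                                                  "pulsatile_waveform"))
  Tp <- waveform$period
  dt <- cfg$dt
  nstep_cycle <- round(Tp / dt)
  if (abs(nstep_cycle * dt - Tp) > 1e-9) {
    stop("`cfg$dt` must divide the waveform period", call. = FALSE)
  }
  snap_steps <- round(snapshot_times / dt)
  if (any(abs(snap_steps * dt - snapshot_times) > 1e-9)) {
    stop("`cfg$dt` must divide every snapshot time", call. = FALSE)
  }
  ctx <- build_solver_context(mesh, fluid)
  d_m <- mesh$d_mm * 1e-3

  w0 <- waveform_eval(waveform, 0)
  bc0 <- boundary_conditions(w0$v_in, w0$p_out)
  # the steady initial condition needs the heavier steady under-relaxation;
  # the configured factors apply to the time stepping, where the transient
  # term already stabilizes the iteration
  cfg0 <- cfg
  cfg0$relax_u <- min(cfg$relax_u, 0.7)
  cfg0$relax_p <- min(cfg$relax_p, 0.3)
  init <- solve_steady(mesh, fluid, bc0, cfg0)

  st <- init_state(ctx, w0$v_in, w0$p_out, "uniform", d_m,
                   u0 = init$u, v0 = init$v, p0 = init$p)
  st$F_int <- init$F_int
  st$F_out <- init$F_out

  snapshots <- list()
  trace_t <- trace_dpin <- numeric(0)
  total_steps <- cfg$n_cycles * nstep_cycle
  inner_iters <- integer(total_steps)
  for (m in seq_len(total_steps)) {
    t_m <- m * dt
    u_time <- list(u = st$u, v = st$v)
    wv <- waveform_eval(waveform, t_m)
    ub <- inlet_face_speed(ctx, wv$v_in, "uniform", d_m)
    st <- set_inlet_bc(ctx, st, ub, wv$p_out)
    res <- run_simple(ctx, st, cfg, cfg$tolerance, cfg$max_inner,
                      unsteady = TRUE, dt = dt, u_time = u_time)
    st <- res$state
    inner_iters[m] <- res$iterations
    cyc <- ((m - 1) %/% nstep_cycle) + 1L
    in_step <- m - (cyc - 1L) * nstep_cycle
    hit <- which(snap_steps == in_step)
    if (length(hit) > 0) {
      ff <- as_flow_fields(st, res, mesh,
                           meta = list(mode = "pulsatile",
                                       time = snapshot_times[hit[1]],
                                       cycle = cyc, global_time = t_m))
      snapshots[[length(snapshots) + 1]] <- ff
    }
    trace_t <- c(trace_t, t_m)
    inl_p <- sum(st$p[ctx$inl_o] * ctx$inl_len) / sum(ctx$inl_len)
    out_p <- sum(st$p[ctx$out_o] * ctx$out_len) / sum(ctx$out_len)
    trace_dpin <- c(trace_dpin, inl_p - out_p)
  }
  structure(list(snapshots = snapshots,
                 trace = data.frame(t = trace_t, dp = trace_dpin),
                 period = Tp, n_cycles = cfg$n_cycles, dt = dt,
                 snapshot_times = snapshot_times,
                 inner_iterations = inner_iters,
                 initial = init),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf(paste0("Pulsatile flow series: %d cycles of %g s at dt = %g s, ",
                     "%d snapshots\n"),
              x$n_cycles, x$period, x$dt, length(x$snapshots)))
  invisible(x)
}

#' Extract a stored snapshot from a pulsatile series
#'
#' @param series a `flow_series`.
#' @param time in-cycle time in seconds.
#' @param cycle cycle index (default 2, the analysis cycle).
#' @export
series_snapshot <- function(series, time, cycle = 2) {
  stopifnot(inherits(series, "flow_series"))
  for (sn in series$snapshots) {
    if (sn$cycle == cycle && abs(sn$time - time) < 1e-9) return(sn)
  }
  stored <- vapply(series$snapshots,
                   function(s) sprintf("(t=%.3g, cycle %d)", s$time, s$cycle),
                   "")
  stop("no snapshot at time ", time, " in cycle ", cycle,
       "; stored: ", paste(stored, collapse = " "), call. = FALSE)
}

#' Per-iteration scaled residual table of a run
#'
#' @param run a `flow_fields` (steady) or `flow_series` (per-snapshot final
#'   residuals).
#' @return data frame with one row per iteration and columns `iteration`,
#'   `u`, `v`, `continuity`.
#' @export
residual_history <- function(run) {
  if (inherits(run, "flow_fields")) {
    r <- run$residuals
    data.frame(iteration = seq_len(nrow(r)), u = r[, "u"], v = r[, "v"],
               continuity = r[, "continuity"])
  } else if (inherits(run, "flow_series")) {
    do.call(rbind, lapply(seq_along(run$snapshots), function(i) {
      r <- run$snapshots[[i]]$residuals
      data.frame(snapshot = i, iteration = seq_len(nrow(r)),
                 u = r[, "u"], v = r[, "v"], continuity = r[, "continuity"])
    }))
  } else stop("`run` must be flow_fields or flow_series", call. = FALSE)
}

#' Global mass balance of a converged solve
#'
#' @param fields a `flow_fields`.
#' @return list with inlet and outlet mass flow (kg/s per metre depth) and
#'   the relative imbalance.
#' @export
mass_balance <- function(fields) {
  stopifnot(inherits(fields, "flow_fields"))
  m_in <- -sum(fields$F_inl)
  m_out <- sum(fields$F_out)
  list(inlet = m_in, outlet = m_out,
       relative_imbalance = if (m_in > 0) abs(m_out - m_in) / m_in else 0)
}
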