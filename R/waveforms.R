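#' Cardiac-cycle anchor points
#'
#' The three stages of the cardiac cycle at which boundary values are known:
#' peak diastole (t1 = 0.26 s), maximum pressure (t2 = 0.36 s) and late
#' systole (t3 = 0.8 s), with inlet velocity in m/s and outlet gauge
#' pressure in Pa.
#'
#' With `shaped = TRUE` (the default) one additional shaping anchor is
#' appended at t = 0.95 s (0.28 m/s, 10200 Pa): the end-systolic minimum of
#' the cycle. Without it a periodic interpolant through only the three known
#' points is forced to accelerate from late systole straight into the next
#' diastolic peak, i.e. flow would be speeding up in late systole, which is
#' the wrong phase behaviour for a diastolic-dominant coronary waveform. The
#' shaping anchor restores the deceleration into end systole; its magnitude
#' (a modest dip below the late-systolic value) matters only through the
#' phase of the minimum.
#'
#' @param shaped append the end-systolic shaping anchor (default `TRUE`).
#' @return data frame with columns `t`, `v_in`, `p_out`.
#' @export
default_cardiac_anchors <- function(shaped = TRUE) {
  a <- data.frame(t = c(0.26, 0.36, 0.80),
                  v_in = c(0.51, 0.42, 0.318),
                  p_out = c(17850, 20206, 10869))
  if (shaped) {
    a <- rbind(a, data.frame(t = 0.95, v_in = 0.28, p_out = 10200))
  }
  a
}

#' Build a periodic pulsatile boundary waveform
#'
#' Smooth periodic interpolation (periodic cubic spline) of inlet velocity and
#' outlet pressure through a set of anchor points. The waveform passes through
#' every anchor exactly and repeats with period `period`. A single anchor
#' yields a constant waveform.
#'
#' @param anchors data frame with columns `t` (s, sorted, inside
#'   `[0, period)`), `v_in` (m/s) and `p_out` (Pa).
#' @param period cycle period in seconds (default 1 s, a resting heart beat).
#' @return object of class `pulsatile_waveform` with function components
#'   `v_in(t)` and `p_out(t)`.
#' @export
build_waveform <- function(anchors = default_cardiac_anchors(), period = 1) {
  stopifnot(is.data.frame(anchors),
            all(c("t", "v_in", "p_out") %in% names(anchors)))
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  t <- anchors$t
  if (anyDuplicated(t)) stop("duplicate anchor times", call. = FALSE)
  if (is.unsorted(t)) stop("anchor times must be sorted", call. = FALSE)
  if (any(t < 0) || any(t >= period)) {
    stop("anchor times must lie in [0, period)", call. = FALSE)
  }
  wrap <- function(x) x - period * floor(x / period)
  if (nrow(anchors) == 1) {
    v0 <- anchors$v_in[1]; p0 <- anchors$p_out[1]
    vfun <- function(tt) rep(v0, length(tt))
    pfun <- function(tt) rep(p0, length(tt))
  } else {
    # periodic spline needs matching first/last ordinates: append t[1]+period
    tk <- c(t, t[1] + period)
    vsp <- stats::splinefun(tk, c(anchors$v_in, anchors$v_in[1]),
                            method = "periodic")
    psp <- stats::splinefun(tk, c(anchors$p_out, anchors$p_out[1]),
                            method = "periodic")
    t0 <- t[1]
    vfun <- function(tt) vsp(t0 + wrap(tt - t0))
    pfun <- function(tt) psp(t0 + wrap(tt - t0))
  }
  tg <- seq(0, period, length.out = 2001)
  vmin <- min(vfun(tg))
  if (vmin < 0) {
    stop(sprintf(paste0("interpolated inlet velocity becomes negative ",
                        "(min %.4g m/s); add anchors to shape the curve"),
                 vmin), call. = FALSE)
  }
  structure(list(period = period, anchors = anchors,
                 v_in = vfun, p_out = pfun),
            class = "pulsatile_waveform")
}

#' Evaluate a waveform
#'
#' @param waveform a `pulsatile_waveform`.
#' @param t times in seconds (any real values; the waveform is periodic).
#' @return data frame with columns `t`, `v_in`, `p_out`.
#' @export
waveform_eval <- function(waveform, t) {
  stopifnot(inherits(waveform, "pulsatile_waveform"))
  data.frame(t = t, v_in = waveform$v_in(t), p_out = waveform$p_out(t))
}

#' @export
print.pulsatile_waveform <- function(x, ...) {
  cat(sprintf("Pulsatile waveform: period %g s, %d anchor(s)\n",
              x$period, nrow(x$anchors)))
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Write waveform samples to CSV
#'
#' @param waveform a `pulsatile_waveform`.
#' @param path output file.
#' @param dt sample spacing in seconds.
#' @export
write_waveform_csv <- function(waveform, path, dt = 0.01) {
  t <- seq(0, waveform$period, by = dt)
  write_numeric_csv(waveform_eval(waveform, t), path)
}

#' Plane-Poiseuille pressure drop (closed form)
#'
#' Fully developed laminar flow between parallel plates a distance `h` apart:
#' the pressure drop over a length `L` at mean velocity `U_mean` is
#' `12 * mu * U_mean * L / h^2`.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param U_mean mean velocity (m/s).
#' @param L channel length (m).
#' @param h channel height (m).
#' @return pressure drop in Pa.
#' @export
poiseuille_drop <- function(mu, U_mean, L, h) {
  if (mu <= 0 || L <= 0 || h <= 0 || U_mean < 0) {
    stop("`mu`, `L`, `h` must be positive and `U_mean` non-negative",
         call. = FALSE)
  }
  12 * mu * U_mean * L / h^2
}

#' Discrete fully developed channel pressure drop on a coarse mesh
#'
#' Independent oracle for the finite-volume solver at coarse resolution:
#' the fully developed momentum balance is discretized on `n_across` equal
#' cells across the channel with central diffusion between cell centers and a
#' half-cell diffusive flux at each wall, and solved for the axial pressure
#' gradient consistent with the prescribed mean velocity. Converges to
#' [poiseuille_drop()] as `n_across` grows, from below.
#'
#' @inheritParams poiseuille_drop
#' @param n_across number of cells across the channel (>= 2).
#' @return pressure drop in Pa over the length `L`.
#' @export
coarse_channel_drop <- function(mu, U_mean, L, h, n_across) {
  if (n_across < 2 || n_across != round(n_across)) {
    stop("`n_across` must be an integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_across)
  # T u = -beta * 1, beta = G hc^2 / mu with hc the cell height; wall rows
  # carry the half-cell flux (coefficient -3)
  Tm <- diag(-2, n)
  Tm[1, 1] <- Tm[n, n] <- -3
  for (i in seq_len(n - 1)) {
    Tm[i, i + 1] <- 1
    Tm[i + 1, i] <- 1
  }
  z <- solve(Tm, rep(-1, n))
  beta <- U_mean / mean(z)            # u = beta * z, mean(u) = U_mean
  hc <- h / n
  G <- mu * beta / hc^2               # -dp/dx
  G * L
}
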