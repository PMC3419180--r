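#' Parametric description of an idealized tortuous coronary vessel
#'
#' A planar idealized coronary artery of total axial length `L` and lumen
#' diameter `d` carrying `n` repeated tortuous units, each a tangent-continuous
#' serpentine of circular arcs with bend radii `R` (outer bends) and `r`
#' (inner bends) and interior bend angle `theta_deg` (the tortuosity angle:
#' a smaller angle means a sharper, more severe bend).
#'
#' @param theta_deg tortuosity angle in degrees, strictly between 0 and 180.
#'   Each arc of a unit subtends `180 - theta_deg` degrees so that the interior
#'   vertex angle at every bend apex equals `theta_deg`.
#' @param n tortuosity count: number of repeated tortuous units (>= 0);
#'   `n = 0` is a straight vessel.
#' @param L total axial length of the vessel in mm.
#' @param d lumen diameter (channel height) in mm.
#' @param R bend radius of the outer arcs in mm.
#' @param r bend radius of the inner arcs in mm.
#' @param w reference axial width of one tortuous unit in mm; acts as a floor
#'   on the unit's axial extent (straight spacers are inserted when the arc
#'   train alone is narrower, which keeps the offset lumen simple at sharp
#'   angles).
#' @return an object of class `vessel_geometry`.
#' @examples
#' vessel_geometry(theta_deg = 30, n = 1)
#' @export
vessel_geometry <- function(theta_deg = 30, n = 1, L = 130, d = 3,
                            R = 6.318, r = 6, w = 20) {
  if (!is.numeric(theta_deg) || length(theta_deg) != 1 ||
      theta_deg <= 0 || theta_deg >= 180) {
    stop("`theta_deg` must be a single number strictly between 0 and 180",
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  if (L <= 0 || d <= 0 || R <= 0 || r <= 0 || w <= 0) {
    stop("`L`, `d`, `R`, `r` and `w` must all be positive", call. = FALSE)
  }
  if (r - d / 2 <= 0 || R - d / 2 <= 0) {
    stop("inner wall of a bend would have non-positive radius: ",
         "need r - d/2 > 0 and R - d/2 > 0", call. = FALSE)
  }
  structure(
    list(theta_deg = theta_deg, n = as.integer(n), L = L, d = d,
         R = R, r = r, w = w),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("Idealized tortuous coronary vessel\n")
  cat(sprintf("  tortuosity angle : %g deg\n", x$theta_deg))
  cat(sprintf("  tortuosity count : %d\n", x$n))
  cat(sprintf("  axial length L   : %g mm, lumen d: %g mm\n", x$L, x$d))
  cat(sprintf("  bend radii R, r  : %g, %g mm (unit width w: %g mm)\n",
              x$R, x$r, x$w))
  invisible(x)
}

#' Build one tortuous unit as a serpentine of circular arcs
#'
#' One unit turns left by `180 - theta_deg` (outer bend, radius `R`), right by
#' the same angle twice (inner bends, radius `r`), and left again (radius `R`),
#' so the net turning is zero and the unit is antisymmetric about its midpoint.
#' When the axial extent of the four arcs alone is below `w`, straight spacers
#' are inserted at the tangent-axial junctions (half a spacer at each end, one
#' at the midpoint) so that the unit's axial extent equals `w`; this keeps
#' the offset lumen of sharp-angle units from self-intersecting.
#'
#' @param theta_deg interior bend angle in degrees, in (0, 180).
#' @param R,r bend radii in mm.
#' @param w floor on the unit axial extent in mm.
#' @return a data frame of segments with class `tortuous_unit`; columns
#'   `type` ("straight" or "arc"), `radius` (mm, `NA` for straights),
#'   `turn` (+1 left, -1 right, 0 straight), `length` (mm). Attributes
#'   `axial_extent` (mm) and `arc_subtend_rad`.
#' @export
build_tortuous_unit <- function(theta_deg, R = 6.318, r = 6, w = 20) {
  if (theta_deg <= 0 || theta_deg >= 180) {
    stop("`theta_deg` must lie strictly between 0 and 180", call. = FALSE)
  }
  if (R <= 0 || r <= 0 || w <= 0) {
    stop("`R`, `r` and `w` must be positive", call. = FALSE)
  }
  phi <- (180 - theta_deg) * pi / 180
  arc_extent <- 2 * (R + r) * sin(phi)
  g <- max(0, (w - arc_extent) / 2)   # total straight spacer per half-unit
  segs <- data.frame(
    type   = c("straight", "arc", "arc", "straight", "arc", "arc", "straight"),
    radius = c(NA, R, r, NA, r, R, NA),
    turn   = c(0, 1, -1, 0, -1, 1, 0),
    length = c(g / 2, R * phi, r * phi, g, r * phi, R * phi, g / 2),
    stringsAsFactors = FALSE
  )
  segs <- segs[segs$length > 0, , drop = FALSE]
  rownames(segs) <- NULL
  structure(segs,
            class = c("tortuous_unit", "data.frame"),
            axial_extent = arc_extent + 2 * g,
            arc_subtend_rad = phi)
}

# chain a segment table into absolute placements (start point + tangent angle
# per segment); works in mm, tangent angles in radians.
place_segments <- function(segs, x0 = 0, y0 = 0, a0 = 0) {
  m <- nrow(segs)
  out <- data.frame(type = segs$type, radius = segs$radius, turn = segs$turn,
                    length = segs$length, x0 = NA_real_, y0 = NA_real_,
                    a0 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    out$x0[i] <- x0; out$y0[i] <- y0; out$a0[i] <- a0
    if (segs$turn[i] == 0) {
      x0 <- x0 + segs$length[i] * cos(a0)
      y0 <- y0 + segs$length[i] * sin(a0)
    } else {
      rho <- segs$radius[i]; tn <- segs$turn[i]
      a1 <- a0 + tn * segs$length[i] / rho
      cx <- x0 - rho * tn * sin(a0)
      cy <- y0 + rho * tn * cos(a0)
      x0 <- cx + rho * tn * sin(a1)
      y0 <- cy - rho * tn * cos(a1)
      a0 <- a1
    }
  }
  attr(out, "end") <- c(x = x0, y = y0, angle = a0)
  out
}

#' Build the full vessel centerline
#'
#' Straight entry segment, `n` repeated tortuous units, straight exit segment.
#' The tortuous train is centered axially, so entry and exit straights have
#' equal length; the total axial extent equals `L`.
#'
#' @param geometry a [vessel_geometry()].
#' @return an object of class `centerline_path`: a segment table (placed in
#'   the plane, mm) with attributes `s_breaks` (cumulative arc length),
#'   `total_length`, `axial_length`, `s_train` (arc-length span of the
#'   tortuous train) and the generating `geometry`.
#' @export
build_centerline <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  g <- geometry
  if (g$n == 0) {
    segs <- data.frame(type = "straight", radius = NA_real_, turn = 0,
                       length = g$L, stringsAsFactors = FALSE)
    train <- c(g$L / 2, g$L / 2)
  } else {
    unit <- build_tortuous_unit(g$theta_deg, g$R, g$r, g$w)
    ux <- attr(unit, "axial_extent")
    entry <- (g$L - g$n * ux) / 2
    if (entry < 0) {
      stop(sprintf(paste0("tortuous train does not fit: %d units of axial ",
                          "extent %.3f mm exceed L = %g mm"),
                   g$n, ux, g$L), call. = FALSE)
    }
    unit_df <- as.data.frame(unit)
    segs <- rbind(
      data.frame(type = "straight", radius = NA_real_, turn = 0,
                 length = entry, stringsAsFactors = FALSE),
      do.call(rbind, replicate(g$n, unit_df, simplify = FALSE)),
      data.frame(type = "straight", radius = NA_real_, turn = 0,
                 length = entry, stringsAsFactors = FALSE)
    )
    segs <- segs[segs$length > 0, , drop = FALSE]
    rownames(segs) <- NULL
    unit_len <- sum(unit$length)
    train <- c(entry, entry + g$n * unit_len)
  }
  placed <- place_segments(segs)
  endp <- attr(placed, "end")
  if (abs(endp["x"] - g$L) > 1e-9 * max(1, g$L) || abs(endp["y"]) > 1e-9 ||
      abs(sin(endp["angle"])) > 1e-12) {
    stop("internal error: centerline does not close onto the axial direction",
         call. = FALSE)
  }
  structure(placed,
            class = c("centerline_path", "data.frame"),
            s_breaks = c(0, cumsum(placed$length)),
            total_length = sum(placed$length),
            axial_length = g$L,
            s_train = train,
            geometry = g)
}

#' Total arc length of a centerline path
#'
#' @param path a `centerline_path`.
#' @return length in mm (sum of straight lengths and arc lengths).
#' @export
centerline_length <- function(path) {
  stopifnot(inherits(path, "centerline_path"))
  attr(path, "total_length")
}

#' Evaluate a centerline path at given arc-length positions
#'
#' @param path a `centerline_path`.
#' @param s numeric vector of arc-length positions in `[0, S]` (mm).
#' @return data frame with columns `s`, `x`, `y` (mm), `angle` (tangent angle,
#'   rad), `nx`, `ny` (unit left normal).
#' @export
centerline_eval <- function(path, s) {
  stopifnot(inherits(path, "centerline_path"))
  sb <- attr(path, "s_breaks")
  S <- attr(path, "total_length")
  if (any(s < -1e-9) || any(s > S + 1e-9)) {
    stop("arc-length positions outside [0, total length]", call. = FALSE)
  }
  s <- pmin(pmax(s, 0), S)
  idx <- pmin(pmax(findInterval(s, sb, rightmost.closed = TRUE), 1L),
              nrow(path))
  sl <- s - sb[idx]
  x <- y <- ang <- numeric(length(s))
  straight <- path$turn[idx] == 0
  if (any(straight)) {
    i <- idx[straight]
    ang[straight] <- path$a0[i]
    x[straight] <- path$x0[i] + sl[straight] * cos(path$a0[i])
    y[straight] <- path$y0[i] + sl[straight] * sin(path$a0[i])
  }
  if (any(!straight)) {
    i <- idx[!straight]
    rho <- path$radius[i]; tn <- path$turn[i]; a0 <- path$a0[i]
    a <- a0 + tn * sl[!straight] / rho
    cx <- path$x0[i] - rho * tn * sin(a0)
    cy <- path$y0[i] + rho * tn * cos(a0)
    ang[!straight] <- a
    x[!straight] <- cx + rho * tn * sin(a)
    y[!straight] <- cy - rho * tn * cos(a)
  }
  data.frame(s = s, x = x, y = y, angle = ang,
             nx = -sin(ang), ny = cos(ang))
}

#' @export
print.centerline_path <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf(paste0("Centerline path: %d segments, length %.3f mm, axial ",
                     "extent %.3f mm\n"),
              nrow(x), attr(x, "total_length"), attr(x, "axial_length")))
  if (!is.null(g)) {
    cat(sprintf("  (theta = %g deg, n = %d)\n", g$theta_deg, g$n))
  }
  invisible(x)
}

#' Offset the centerline into a lumen outline
#'
#' The upper and lower walls are the normal offsets of the centerline by
#' `+d/2` and `-d/2`; the inlet and outlet sections close the outline. The
#' wall-to-wall distance along any centerline normal equals `d` exactly by
#' construction; offsetting is rejected when a bend radius would produce a
#' degenerate inner wall.
#'
#' @param path a `centerline_path`.
#' @param d lumen diameter in mm (`d = 0` collapses both walls onto the
#'   centerline).
#' @return an object of class `lumen_outline` holding the path and `d`.
#' @export
offset_lumen <- function(path, d) {
  stopifnot(inherits(path, "centerline_path"))
  if (d < 0) stop("`d` must be non-negative", call. = FALSE)
  arcs <- path$turn != 0
  if (any(arcs) && d > 0) {
    rmin <- min(path$radius[arcs])
    if (rmin - d / 2 <= 0) {
      stop(sprintf(paste0("offset self-intersects locally: min bend radius ",
                          "%.3f mm <= d/2 = %.3f mm"), rmin, d / 2),
           call. = FALSE)
    }
  }
  structure(list(path = path, d = d), class = "lumen_outline")
}

#' Sample the walls of a lumen outline
#'
#' @param outline a `lumen_outline`.
#' @param ds sampling interval along the centerline in mm.
#' @return list with data frames `upper` and `lower` (columns `s`, `x`, `y`).
#' @export
lumen_walls <- function(outline, ds = 0.5) {
  stopifnot(inherits(outline, "lumen_outline"))
  S <- centerline_length(outline$path)
  s <- unique(c(seq(0, S, by = ds), S))
  ce <- centerline_eval(outline$path, s)
  h <- outline$d / 2
  list(
    upper = data.frame(s = s, x = ce$x + h * ce$nx, y = ce$y + h * ce$ny),
    lower = data.frame(s = s, x = ce$x - h * ce$nx, y = ce$y - h * ce$ny)
  )
}

#' Closed polygon of the lumen outline
#'
#' Upper wall from inlet to outlet, outlet section, lower wall back, inlet
#' section; counter-clockwise for positive `d`.
#'
#' @inheritParams lumen_walls
#' @return two-column matrix of vertices (mm).
#' @export
lumen_polygon <- function(outline, ds = 0.5) {
  w <- lumen_walls(outline, ds)
  m <- nrow(w$upper)
  rbind(as.matrix(w$lower[, c("x", "y")]),
        as.matrix(w$upper[m:1, c("x", "y")]))
}

# shoelace area of a polygon matrix (positive for counter-clockwise)
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Test that the lumen outline is simple (non-self-intersecting)
#'
#' Brute-force segment-pair intersection test on a sampled polygon of the
#' outline; adjacent segments are excluded.
#'
#' @inheritParams lumen_walls
#' @return `TRUE` if no two non-adjacent boundary segments intersect.
#' @export
lumen_is_simple <- function(outline, ds = 0.5) {
  p <- lumen_polygon(outline, ds)
  m <- nrow(p)
  a <- p
  b <- p[c(2:m, 1), , drop = FALSE]
  # bounding-box prefilter, then orientation tests, vectorized over pairs
  idx <- utils::combn(m, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adj <- (j - i == 1) | (j - i == m - 1)
  i <- i[!adj]; j <- j[!adj]
  lo_xi <- pmin(a[i, 1], b[i, 1]); hi_xi <- pmax(a[i, 1], b[i, 1])
  lo_xj <- pmin(a[j, 1], b[j, 1]); hi_xj <- pmax(a[j, 1], b[j, 1])
  lo_yi <- pmin(a[i, 2], b[i, 2]); hi_yi <- pmax(a[i, 2], b[i, 2])
  lo_yj <- pmin(a[j, 2], b[j, 2]); hi_yj <- pmax(a[j, 2], b[j, 2])
  keep <- lo_xi <= hi_xj & lo_xj <= hi_xi & lo_yi <= hi_yj & lo_yj <= hi_yi
  if (!any(keep)) return(TRUE)
  i <- i[keep]; j <- j[keep]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' @export
print.lumen_outline <- function(x, ...) {
  cat(sprintf("Lumen outline: d = %g mm over a %.3f mm centerline\n",
              x$d, centerline_length(x$path)))
  invisible(x)
}

#' Write the lumen outline and centerline to CSV point lists
#'
#' @param outline a `lumen_outline`.
#' @param path_centerline,path_outline output file paths.
#' @param ds sampling interval in mm.
#' @return invisibly, the two file paths.
#' @export
write_outline_csv <- function(outline, path_centerline, path_outline,
                              ds = 0.5) {
  S <- centerline_length(outline$path)
  s <- unique(c(seq(0, S, by = ds), S))
  ce <- centerline_eval(outline$path, s)
  write_numeric_csv(ce[, c("s", "x", "y")], path_centerline)
  w <- lumen_walls(outline, ds)
  out <- rbind(cbind(wall = "upper", w$upper), cbind(wall = "lower", w$lower))
  write_numeric_csv(out, path_outline)
  invisible(c(path_centerline, path_outline))
}

# stable full-precision CSV writer used by all exports (byte-identical reruns)
write_numeric_csv <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
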