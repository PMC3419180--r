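#' Structured body-fitted quadrilateral mesh of the lumen
#'
#' Sweeps the cross-section along the centerline: stations are placed at
#' (near-)uniform arc-length spacing, the cross-section is divided into
#' `round(d / interval_mm)` cells, and consecutive stations are joined into
#' quadrilateral cells. Node coordinates are stored in metres; boundary faces
#' are grouped into the patches `inlet`, `outlet`, `wall_lower`, `wall_upper`.
#'
#' @param outline a [offset_lumen()] result (carries the centerline and `d`).
#' @param interval_mm nominal cell interval in mm (default 1 mm); the number
#'   of stations along the vessel is `ceil(S / interval_mm)`.
#' @return an object of class `quad_mesh`.
#' @export
sweep_mesh <- function(outline, interval_mm = 1) {
  stopifnot(inherits(outline, "lumen_outline"))
  path <- outline$path
  d <- outline$d
  if (interval_mm <= 0) stop("`interval_mm` must be positive", call. = FALSE)
  J <- round(d / interval_mm)
  if (d / interval_mm < 2) {
    stop("`interval_mm` too coarse: need at least 2 cells across the lumen",
         call. = FALSE)
  }
  S <- centerline_length(path)
  K <- ceiling(S / interval_mm - 1e-9)
  s_st <- S * (0:K) / K
  ce <- centerline_eval(path, s_st)
  tj <- -d / 2 + d * (0:J) / J
  # nodes: station-major, (K+1) x (J+1), in mm then converted to m
  nx_ <- outer(ce$x, rep(1, J + 1)) + outer(ce$nx, tj)
  ny_ <- outer(ce$y, rep(1, J + 1)) + outer(ce$ny, tj)
  nid <- function(k, j) k * (J + 1) + j + 1L        # k in 0..K, j in 0..J
  # flatten with j fastest within each station (matches nid)
  nodes <- cbind(as.vector(t(nx_)), as.vector(t(ny_))) * 1e-3

  M <- K * J
  kk <- rep(1:K, each = J)
  jj <- rep(1:J, times = K)
  cells <- cbind(nid(kk - 1L, jj - 1L), nid(kk, jj - 1L),
                 nid(kk, jj), nid(kk - 1L, jj))
  # signed area + centroid (shoelace on each quad)
  qx <- matrix(nodes[cells, 1], ncol = 4)
  qy <- matrix(nodes[cells, 2], ncol = 4)
  nxt <- c(2, 3, 4, 1)
  crossp <- qx * qy[, nxt] - qx[, nxt] * qy
  area <- 0.5 * rowSums(crossp)
  cxc <- rowSums((qx + qx[, nxt]) * crossp) / (6 * area)
  cyc <- rowSums((qy + qy[, nxt]) * crossp) / (6 * area)
  # convexity: all corner cross products share the sign of the area
  ex <- qx[, nxt] - qx; ey <- qy[, nxt] - qy
  prv <- c(4, 1, 2, 3)
  corner <- ex[, prv] * ey - ey[, prv] * ex
  bad <- which(area <= 0 | rowSums(corner <= 0) > 0)
  if (length(bad) > 0) {
    b <- bad[1]
    s_bad <- s_st[kk[b]]
    seg <- findInterval(s_bad, attr(path, "s_breaks"), rightmost.closed = TRUE)
    stop(sprintf(paste0("meshing failed: non-convex or inverted cell near ",
                        "s = %.2f mm (segment %d, %s); refine `interval_mm`"),
                 s_bad, seg, path$type[min(seg, nrow(path))]), call. = FALSE)
  }

  cell_id <- function(k, j) (k - 1L) * J + j
  face <- function(n1, n2, owner, neigh, patch) {
    data.frame(n1 = n1, n2 = n2, owner = owner, neigh = neigh,
               patch = patch, stringsAsFactors = FALSE)
  }
  # transverse faces (constant-station): inlet, interior, outlet
  fi <- face(nid(0L, 0:(J - 1)), nid(0L, 1:J), cell_id(1L, 1:J), NA, "inlet")
  fo <- face(nid(K, 0:(J - 1)), nid(K, 1:J), cell_id(K, 1:J), NA, "outlet")
  if (K > 1) {
    kk2 <- rep(1:(K - 1), each = J)
    jj2 <- rep(1:J, times = K - 1)
    ft <- face(nid(kk2, jj2 - 1L), nid(kk2, jj2),
               cell_id(kk2, jj2), cell_id(kk2 + 1L, jj2), "interior")
  } else ft <- NULL
  # longitudinal faces (constant-offset): walls, interior
  kk3 <- 1:K
  fl <- face(nid(kk3 - 1L, 0L), nid(kk3, 0L), cell_id(kk3, 1L), NA,
             "wall_lower")
  fu <- face(nid(kk3 - 1L, J), nid(kk3, J), cell_id(kk3, J), NA,
             "wall_upper")
  if (J > 1) {
    kk4 <- rep(1:K, each = J - 1)
    jj4 <- rep(1:(J - 1), times = K)
    fm <- face(nid(kk4 - 1L, jj4), nid(kk4, jj4),
               cell_id(kk4, jj4), cell_id(kk4, jj4 + 1L), "interior")
  } else fm <- NULL
  faces <- rbind(fi, fo, ft, fl, fu, fm)
  rownames(faces) <- NULL

  p1 <- nodes[faces$n1, , drop = FALSE]
  p2 <- nodes[faces$n2, , drop = FALSE]
  ev <- p2 - p1
  len <- sqrt(rowSums(ev^2))
  fnx <- ev[, 2] / len
  fny <- -ev[, 1] / len
  fcx <- (p1[, 1] + p2[, 1]) / 2
  fcy <- (p1[, 2] + p2[, 2]) / 2
  ref_x <- ifelse(is.na(faces$neigh), fcx, cxc[faces$neigh]) - cxc[faces$owner]
  ref_y <- ifelse(is.na(faces$neigh), fcy, cyc[faces$neigh]) - cyc[faces$owner]
  flip <- (fnx * ref_x + fny * ref_y) < 0
  fnx[flip] <- -fnx[flip]
  fny[flip] <- -fny[flip]
  delta <- fnx * ref_x + fny * ref_y        # owner-to-neighbour (or face) dist
  if (any(delta <= 0)) {
    stop("meshing failed: degenerate face spacing", call. = FALSE)
  }
  d_own <- sqrt((fcx - cxc[faces$owner])^2 + (fcy - cyc[faces$owner])^2)
  d_nb <- ifelse(is.na(faces$neigh), NA,
                 sqrt((fcx - cxc[faces$neigh])^2 +
                      (fcy - cyc[faces$neigh])^2))
  gw <- ifelse(is.na(faces$neigh), 1, d_nb / (d_own + d_nb))
  faces$len <- len
  faces$nx <- fnx
  faces$ny <- fny
  faces$cx <- fcx
  faces$cy <- fcy
  faces$delta <- delta
  faces$gw <- gw

  structure(
    list(nodes = nodes, cells = cells, cell_area = area,
         cell_cx = cxc, cell_cy = cyc, faces = faces,
         n_along = K, n_across = J, station_s_mm = s_st,
         interval_mm = interval_mm, d_mm = d,
         inlet_point = c(ce$x[1], ce$y[1]) * 1e-3,
         inlet_normal = c(ce$nx[1], ce$ny[1])),
    class = "quad_mesh"
  )
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf(paste0("Structured quad mesh: %d cells (%d along x %d across), ",
                     "interval %g mm\n"),
              nrow(x$cells), x$n_along, x$n_across, x$interval_mm))
  invisible(x)
}

#' Summary quality report for a quad mesh
#'
#' @param mesh a `quad_mesh`.
#' @return list with cell count, min/max cell area (m^2), minimum
#'   orthogonality angle (degrees, 90 is perfectly orthogonal) and boundary
#'   patch face counts.
#' @export
mesh_report <- function(mesh) {
  stopifnot(inherits(mesh, "quad_mesh"))
  f <- mesh$faces
  int <- f$patch == "interior"
  if (any(int)) {
    dx <- mesh$cell_cx[f$neigh[int]] - mesh$cell_cx[f$owner[int]]
    dy <- mesh$cell_cy[f$neigh[int]] - mesh$cell_cy[f$owner[int]]
    dd <- sqrt(dx^2 + dy^2)
    cosang <- (dx * f$nx[int] + dy * f$ny[int]) / dd
    min_orth <- min(90 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  } else min_orth <- 90
  patches <- table(f$patch[f$patch != "interior"])
  list(n_cells = nrow(mesh$cells),
       min_cell_area = min(mesh$cell_area),
       max_cell_area = max(mesh$cell_area),
       min_orthogonality_deg = min_orth,
       patch_faces = as.list(patches))
}

#' Total mesh area (sum of cell areas, m^2)
#' @param mesh a `quad_mesh`.
#' @export
mesh_area <- function(mesh) sum(mesh$cell_area)
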