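test_that("vessel geometry validates its invariants", {
  expect_s3_class(vessel_geometry(30, 1), "vessel_geometry")
  expect_error(vessel_geometry(theta_deg = 0), "between 0 and 180")
  expect_error(vessel_geometry(theta_deg = 200), "between 0 and 180")
  expect_error(vessel_geometry(30, -1), "non-negative")
  expect_error(vessel_geometry(30, 1.5), "non-negative integer")
  expect_error(vessel_geometry(30, 1, d = 13), "non-positive radius")
})

test_that("a tortuous unit is a zero-net-turn antisymmetric serpentine", {
  for (th in c(30, 60, 90, 120)) {
    u <- build_tortuous_unit(th)
    phi <- (180 - th) * pi / 180
    arcs <- u[u$type == "arc", ]
    # four arcs R, r, r, R each subtending (180 - theta)
    expect_equal(arcs$radius, c(6.318, 6, 6, 6.318))
    expect_equal(arcs$length / arcs$radius, rep(phi, 4), tolerance = 1e-12)
    expect_equal(sum(arcs$turn * arcs$length / arcs$radius), 0,
                 tolerance = 1e-12)
    # point symmetry about the midpoint: the segment table is a palindrome
    # (the reversed second half retraces the first with the turn sense
    # preserved under the 180-degree rotation)
    rev_u <- u[rev(seq_len(nrow(u))), ]
    expect_equal(rev_u$radius, u$radius)
    expect_equal(rev_u$turn, u$turn)
    expect_equal(rev_u$length, u$length)
  }
  # tangent-angle antisymmetry across the unit: alpha(s0 + x) = -alpha(s1 - x),
  # which maps the upper-turning half onto the lower-turning half
  p <- build_centerline(vessel_geometry(90, 1))
  tr <- attr(p, "s_train")
  x <- seq(0, diff(tr), length.out = 41)
  a_fwd <- centerline_eval(p, tr[1] + x)$angle
  a_bwd <- centerline_eval(p, tr[2] - x)$angle
  expect_equal(a_fwd, -a_bwd, tolerance = 1e-9)
})

test_that("sharper angles give longer arcs; the straight limit degenerates", {
  u30 <- build_tortuous_unit(30)
  u120 <- build_tortuous_unit(120)
  arc_len <- function(u) sum(u$length[u$type == "arc"])
  # 150-degree arcs at theta = 30 vs 60-degree arcs at theta = 120
  expect_equal(arc_len(u30), (150 * pi / 180) * 2 * (6.318 + 6),
               tolerance = 1e-12)
  expect_gt(arc_len(u30), arc_len(u120))
  # theta -> 180: arcs subtend -> 0, unit degenerates toward a straight span
  u_lim <- build_tortuous_unit(179.999)
  expect_lt(arc_len(u_lim), 1e-2)
})

test_that("centerline assembles straights + units with axial extent L", {
  p0 <- build_centerline(vessel_geometry(30, 0))
  expect_equal(centerline_length(p0), 130)
  expect_equal(nrow(p0), 1)

  p1 <- build_centerline(vessel_geometry(30, 2))
  p2 <- build_centerline(vessel_geometry(30, 1))
  expect_gt(centerline_length(p1), centerline_length(p2))

  # axial extent equals L and the path ends on the axis for every design point
  g <- design_grid()
  for (i in seq_len(nrow(g))) {
    p <- build_centerline(vessel_geometry(g$theta_deg[i], g$n[i]))
    S <- centerline_length(p)
    endp <- centerline_eval(p, S)
    expect_equal(endp$x, 130, tolerance = 1e-9)
    expect_equal(endp$y, 0, tolerance = 1e-9)
    expect_gte(S, 130 - 1e-9)
    if (g$n[i] == 0) expect_equal(S, 130)
  }
})

test_that("too many units fail with a geometry error", {
  expect_error(build_centerline(vessel_geometry(90, 6)), "does not fit")
})

test_that("centerline length is monotone in count and anti-monotone in angle", {
  S <- matrix(NA_real_, 4, 6, dimnames = list(c(30, 60, 90, 120), 0:5))
  for (th in c(30, 60, 90, 120)) for (n in 0:5) {
    S[as.character(th), as.character(n)] <-
      centerline_length(build_centerline(vessel_geometry(th, n)))
  }
  for (i in 1:4) expect_true(all(diff(S[i, ]) > 0))
  for (j in 2:6) expect_true(all(diff(S[, j]) < 0))
})

test_that("tangent direction is continuous along the path (G1)", {
  p <- build_centerline(vessel_geometry(30, 2))
  sb <- attr(p, "s_breaks")
  inner <- sb[-c(1, length(sb))]
  eps <- 1e-7
  before <- centerline_eval(p, inner - eps)$angle
  after <- centerline_eval(p, inner + eps)$angle
  expect_lt(max(abs(after - before)), 1e-6)
  # first and last segments are straight and axial
  expect_equal(p$type[c(1, nrow(p))], c("straight", "straight"))
  expect_equal(p$a0[c(1, nrow(p))], c(0, 0), tolerance = 1e-12)
})

test_that("arc length closed forms hold", {
  # single semicircle of radius 6: pi * 6
  u <- build_tortuous_unit(90, R = 6, r = 6, w = 0.001)
  semis <- u$length[u$type == "arc"][1] * 2   # two 90-degree arcs = semicircle
  expect_equal(semis, pi * 6, tolerance = 1e-12)
})

test_that("lumen offsets sit at +/- d/2 and the straight lumen is a rectangle", {
  p0 <- build_centerline(vessel_geometry(30, 0))
  o <- offset_lumen(p0, 3)
  w <- lumen_walls(o, ds = 10)
  expect_true(all(abs(w$upper$y - 1.5) < 1e-12))
  expect_true(all(abs(w$lower$y + 1.5) < 1e-12))
  expect_equal(polygon_area(lumen_polygon(o, ds = 10)), 130 * 3,
               tolerance = 1e-12)

  # wall-to-wall distance along any normal equals d everywhere on a bend
  p <- build_centerline(vessel_geometry(60, 1))
  ob <- offset_lumen(p, 3)
  wb <- lumen_walls(ob, ds = 0.37)
  gap <- sqrt((wb$upper$x - wb$lower$x)^2 + (wb$upper$y - wb$lower$y)^2)
  expect_true(all(abs(gap - 3) < 1e-9))

  # degenerate d = 0: both walls coincide with the centerline
  o0 <- offset_lumen(p, 0)
  w0 <- lumen_walls(o0, ds = 5)
  ce <- centerline_eval(p, w0$upper$s)
  expect_equal(w0$upper$x, ce$x, tolerance = 1e-12)
  expect_equal(w0$lower$y, ce$y, tolerance = 1e-12)
})

test_that("offsetting rejects lumens wider than twice the bend radius", {
  p <- build_centerline(vessel_geometry(30, 1))
  expect_error(offset_lumen(p, 12.5), "self-intersects")
})

test_that("every design-point lumen outline is simple", {
  g <- design_grid()
  for (i in seq_len(nrow(g))) {
    o <- offset_lumen(build_centerline(vessel_geometry(g$theta_deg[i],
                                                       g$n[i])), 3)
    expect_true(lumen_is_simple(o, ds = 1),
                label = sprintf("simple outline at theta=%d n=%d",
                                g$theta_deg[i], g$n[i]))
  }
})

test_that("outline export writes readable point lists", {
  o <- offset_lumen(build_centerline(vessel_geometry(60, 1)), 3)
  fc <- tempfile(fileext = ".csv")
  fo <- tempfile(fileext = ".csv")
  write_outline_csv(o, fc, fo)
  ce <- read.csv(fc)
  expect_equal(names(ce), c("s", "x", "y"))
  ou <- read.csv(fo)
  expect_setequal(unique(ou$wall), c("upper", "lower"))
})
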