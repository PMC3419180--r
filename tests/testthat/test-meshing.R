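test_that("straight channel meshes to the expected structured cell counts", {
  p0 <- build_centerline(vessel_geometry(30, 0))
  o <- offset_lumen(p0, 3)
  m1 <- sweep_mesh(o, 1)
  expect_equal(nrow(m1$cells), 390)         # 3 across x 130 along
  expect_equal(m1$n_across, 3)
  expect_equal(m1$n_along, 130)
  m05 <- sweep_mesh(o, 0.5)
  expect_equal(nrow(m05$cells), 1560)       # 6 across x 260 along
  # structured refinement: halving the interval quadruples the cell count
  expect_equal(nrow(m05$cells), 4 * nrow(m1$cells))
  # uniform straight cells are exactly 1 mm^2
  expect_equal(range(m1$cell_area), rep(1e-6, 2), tolerance = 1e-12)
})

test_that("mesh cell areas tile the lumen outline exactly", {
  for (spec in list(c(30, 1), c(90, 2))) {
    o <- offset_lumen(build_centerline(vessel_geometry(spec[1], spec[2])), 3)
    m <- sweep_mesh(o, 1)
    # polygon through the mesh's own boundary stations
    S <- centerline_length(o$path)
    poly <- lumen_polygon(o, ds = S / m$n_along) * 1e-3
    expect_equal(mesh_area(m), polygon_area(poly), tolerance = 1e-10)
    expect_true(all(m$cell_area > 0))
  }
})

test_that("boundary patches close the domain", {
  o <- offset_lumen(build_centerline(vessel_geometry(60, 1)), 3)
  m <- sweep_mesh(o, 1)
  f <- m$faces
  bnd <- f$patch != "interior"
  expect_setequal(unique(f$patch[bnd]),
                  c("inlet", "outlet", "wall_lower", "wall_upper"))
  # sum of outward boundary face normal vectors vanishes (closed boundary)
  expect_equal(sum(f$len[bnd] * f$nx[bnd]), 0, tolerance = 1e-12)
  expect_equal(sum(f$len[bnd] * f$ny[bnd]), 0, tolerance = 1e-12)
  # every interior face joins exactly two distinct cells
  int <- f$patch == "interior"
  expect_true(all(f$owner[int] != f$neigh[int]))
  expect_false(any(is.na(f$neigh[int])))
  expect_true(all(is.na(f$neigh[bnd])))
})

test_that("mesh report summarizes counts and quality", {
  o <- offset_lumen(build_centerline(vessel_geometry(30, 0)), 3)
  m <- sweep_mesh(o, 1)
  rep <- mesh_report(m)
  expect_equal(rep$n_cells, 390)
  expect_gt(rep$min_cell_area, 0)
  expect_equal(rep$min_orthogonality_deg, 90, tolerance = 1e-6)
  expect_equal(rep$patch_faces$inlet, 3)
  expect_equal(rep$patch_faces$wall_upper, 130)
  # curved mesh stays close to orthogonal
  mc <- sweep_mesh(offset_lumen(build_centerline(vessel_geometry(30, 1)),
                                3), 1)
  expect_gt(mesh_report(mc)$min_orthogonality_deg, 80)
})

test_that("meshing rejects a lumen too coarse to resolve", {
  o <- offset_lumen(build_centerline(vessel_geometry(30, 0)), 3)
  expect_error(sweep_mesh(o, 2), "at least 2 cells")
})

test_that("VTK export writes a parseable legacy file", {
  o <- offset_lumen(build_centerline(vessel_geometry(30, 0, L = 10)), 3)
  m <- sweep_mesh(o, 1)
  f <- tempfile(fileext = ".vtk")
  write_vtk_mesh(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS ", lines)))
  np <- as.integer(sub("^POINTS (\\d+) double", "\\1",
                       grep("^POINTS ", lines, value = TRUE)))
  expect_equal(np, nrow(m$nodes))
  expect_true(any(grepl("^CELLS 30 150$", lines)))
})
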