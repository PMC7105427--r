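test_that("surface mesh derives areas, centroids and unit normals", {
  # single right triangle in the xy plane, legs 3 and 4
  m <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                    rbind(c(0L, 1L, 2L)))
  expect_equal(m$element_area, 6)
  expect_equal(m$element_centroid[1, ], c(1, 4 / 3, 0))
  expect_equal(sqrt(sum(m$element_normal[1, ]^2)), 1, tolerance = 1e-12)
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(0L, 1L, 2L))), "degenerate")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(0L, 1L, 3L))), "0-based")
})

test_that("volume mesh enforces positive volumes via reorientation", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # both orientations load to the same positive volume 1/6
  m1 <- volume_mesh(pts, rbind(c(0L, 1L, 2L, 3L)))
  m2 <- volume_mesh(pts, rbind(c(0L, 2L, 1L, 3L)))
  expect_equal(m1$element_volume, 1 / 6)
  expect_equal(m2$element_volume, 1 / 6)
})

test_that("cycle window validates its sampling", {
  expect_error(cycle_window(c(0, 0.5)), "at least 3")
  expect_error(cycle_window(c(0, 0.5, 0.4)), "strictly increasing")
  expect_error(cycle_window(c(0, 0.5, 0.9), period_T = 1), "span")
  w <- uniform_window(0.8, 11, t_start = 0.8)
  expect_equal(w$period_T, 0.8)
  expect_equal(w$sample_times[1], 0.8)
  expect_equal(w$sample_times[11], 1.6)
})

test_that("node_to_element is the vertex mean, exact for constants", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(0L, 1L, 2L)))
  w <- uniform_window(1, 3)
  # nodal scalar 1,2,3 -> element value 2
  f <- field_series(array(rep(c(1, 2, 3), each = 3), dim = c(3, 3, 1)),
                    "scalar", "node", w)
  fe <- node_to_element(f, m)
  expect_equal(as.numeric(fe$values), rep(2, 3))
  # constant vector field survives exactly; components preserved
  fv <- field_series(array(rep(c(4, -1, 2), each = 9), dim = c(3, 3, 3)),
                     "vector3", "node", w)
  fve <- node_to_element(fv, m)
  expect_equal(fve$values[2, 1, ], c(4, -1, 2))
  # linear field f(x) = x equals the vertex mean = centroid x here
  fx <- field_series(array(rep(m$points[, 1], each = 3), dim = c(3, 3, 1)),
                     "scalar", "node", w)
  expect_equal(node_to_element(fx, m)$values[1, 1, 1],
               mean(m$points[, 1]))
  expect_warning(node_to_element(fe, m), "already element-attached")
})

test_that("VTP/VTU round trips preserve geometry and fields to 1e-12", {
  tube <- make_tube_surface(tube_spec(3e-3, 0.01, 1e-3, n_circ = 8L,
                                      n_axial = 2L))
  m <- tube$mesh
  vals <- matrix(rnorm(n_elements_for_test(m) * 3), ncol = 3)
  pd <- rnorm(nrow(m$points))
  path <- tempfile(fileext = ".vtp")
  write_vtp(m, path, cell_data = list(wss = vals), point_data = list(p = pd))
  back <- read_vtk_xml(path)
  expect_equal(back$mesh$points, m$points, tolerance = 1e-14)
  expect_true(all(back$mesh$triangles == m$triangles))
  expect_equal(back$cell_data$wss, vals, tolerance = 1e-14)
  expect_equal(as.numeric(back$point_data$p), pd, tolerance = 1e-14)
  # VTU with a tet mesh
  tv <- make_tube_volume(2e-3, 5e-3, n_circ = 6L, n_rad = 1L, n_axial = 2L)
  pathu <- tempfile(fileext = ".vtu")
  write_vtu(tv$mesh, pathu, point_data = list(u = rnorm(nrow(tv$mesh$points))))
  backu <- read_vtk_xml(pathu)
  expect_equal(backu$mesh$points, tv$mesh$points, tolerance = 1e-14)
  expect_true(all(backu$mesh$tets == tv$mesh$tets))
  # empty map list writes a mesh-only file
  path2 <- tempfile(fileext = ".vtp")
  expect_silent(write_metric_map(m, list(), path2))
  expect_equal(read_vtk_xml(path2)$cell_data, list())
  # NaN written verbatim with a warning
  path3 <- tempfile(fileext = ".vtp")
  nanmap <- rep(NaN, n_elements_for_test(m))
  expect_warning(write_metric_map(m, list(bad = nanmap), path3), "NaN")
  expect_true(all(is.nan(read_vtk_xml(path3)$cell_data$bad)))
  # length mismatch is an error
  expect_error(write_vtp(m, tempfile(), cell_data = list(x = 1:3)), "rows")
})

test_that("legacy VTK ASCII import reads points, cells and attributes", {
  path <- tempfile(fileext = ".vtk")
  writeLines(c(
    "# vtk DataFile Version 3.0", "fixture", "ASCII", "DATASET POLYDATA",
    "POINTS 4 float",
    "0 0 0", "1 0 0", "0 1 0", "1 1 0",
    "POLYGONS 2 8",
    "3 0 1 2", "3 1 3 2",
    "CELL_DATA 2",
    "SCALARS tawss float 1", "LOOKUP_TABLE default",
    "1.5 2.5",
    "POINT_DATA 4",
    "VECTORS vel float",
    "1 0 0", "0 1 0", "0 0 1", "1 1 1"), path)
  got <- read_vtk_legacy(path)
  expect_equal(nrow(got$mesh$points), 4L)
  expect_equal(n_elements_for_test(got$mesh), 2L)
  expect_equal(as.numeric(got$cell_data$tawss), c(1.5, 2.5))
  expect_equal(got$point_data$vel[4, ], c(1, 1, 1))
})

test_that("read_field_series assembles a series and flags mismatches", {
  tube <- make_tube_surface(tube_spec(3e-3, 0.01, 1e-3, n_circ = 8L,
                                      n_axial = 2L))
  m <- tube$mesh
  ne <- n_elements_for_test(m)
  dir <- tempfile(); dir.create(dir)
  times <- c(0, 0.5, 1)
  paths <- file.path(dir, sprintf("s%02d.vtp", 1:3))
  for (i in 1:3)
    write_vtp(m, paths[i], cell_data = list(wss = matrix(i, ne, 3)))
  got <- read_field_series(paths, times, "element", "wss", units = "Pa")
  expect_s3_class(got$field, "field_series")
  expect_equal(got$field$kind, "vector3")
  expect_equal(dim(got$field$values), c(3L, ne, 3L))
  expect_equal(got$field$values[2, 1, 1], 2)
  # differing topology -> named error
  other <- make_tube_surface(tube_spec(3e-3, 0.01, 1e-3, n_circ = 10L,
                                       n_axial = 2L))$mesh
  write_vtp(other, paths[3],
            cell_data = list(wss = matrix(3, n_elements_for_test(other), 3)))
  expect_error(read_field_series(paths, times, "element", "wss"),
               "topology mismatch at step 3")
  # missing field name lists what is available
  write_vtp(m, paths[3], cell_data = list(shear = matrix(3, ne, 3)))
  expect_error(read_field_series(paths[c(3, 3, 3)], times, "element", "wss"),
               "available")
  # node-attached input is averaged onto elements on request
  for (i in 1:3)
    write_vtp(m, paths[i], point_data = list(wss = matrix(5, nrow(m$points), 3)))
  gotn <- read_field_series(paths, times, "element", "wss")
  expect_equal(gotn$field$attachment, "element")
  expect_equal(max(abs(gotn$field$values[, , 1] - 5)), 0)
})

test_that("region masks carry consistent areas", {
  m <- strip_mesh(c(2, 4, 6))
  all_r <- whole_surface_region(m)
  expect_equal(all_r$total_area, sum(m$element_area))
  sub <- region_mask(c(0L, 2L), m, "custom")
  expect_equal(sub$total_area, m$element_area[1] + m$element_area[3])
  expect_error(region_mask(c(0L, 0L), m), "unique")
  expect_error(region_mask(5L, m), "out of range")
})

test_that("centreline arclength and interpolation behave", {
  cl <- centreline(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                   landmarks = c(transition = 1))
  expect_equal(cl$arclength, c(0, 1, 2))
  at <- centreline_at(cl, 1.5)
  expect_equal(at$point, c(1, 0.5, 0))
  expect_equal(at$tangent, c(0, 1, 0))
  p <- tempfile(fileext = ".csv")
  write_centreline_csv(cl, p)
  cl2 <- read_centreline_csv(p, landmarks = c(transition = 1))
  expect_equal(cl2$points, cl$points, ignore_attr = TRUE)
})
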