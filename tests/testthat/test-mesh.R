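# Graded cylinder tetrahedralization: tags, grading, conformity.

test_that("boundary facets carry exactly one tag and cover the surface", {
  mesh <- tube_mesh()
  sp <- mesh$spec
  a_in <- sum(riisvalve:::facet_areas(mesh$nodes, mesh$boundary$inlet))
  a_out <- sum(riisvalve:::facet_areas(mesh$nodes, mesh$boundary$outlet))
  a_wall <- sum(riisvalve:::facet_areas(mesh$nodes, mesh$boundary$wall))
  disk <- pi * sp$radius^2
  lateral <- 2 * pi * sp$radius * (sp$z_max - sp$z_min)
  expect_lt(abs(a_in - disk) / disk, 0.02)
  expect_lt(abs(a_out - disk) / disk, 0.02)
  expect_lt(abs(a_wall - lateral) / lateral, 0.02)
  # tags partition the boundary: no facet appears twice
  all_b <- rbind(mesh$boundary$inlet, mesh$boundary$outlet,
                 mesh$boundary$wall)
  keys <- apply(all_b, 1, function(r) paste(sort(r), collapse = "-"))
  expect_identical(anyDuplicated(keys), 0L)
  # inlet/outlet planarity
  expect_lt(max(abs(mesh$nodes[unique(as.vector(mesh$boundary$inlet)), 3] -
                      sp$z_min)), 1e-6)
  expect_lt(max(abs(mesh$nodes[unique(as.vector(mesh$boundary$outlet)), 3] -
                      sp$z_max)), 1e-6)
})

test_that("size grading holds inside and outside the refinement band", {
  spec <- cylinder_spec(radius = 14, z_min = -20, z_max = 60,
                        h_fine = 1.5, h_coarse = 2.25,
                        refine_zmin = -4.5, refine_zmax = 14.5)
  mesh <- generate_cylinder_mesh(spec)
  inside <- function(z) z > spec$refine_zmin & z < spec$refine_zmax
  e_in <- riisvalve:::mesh_edge_lengths(mesh, inside)
  e_out <- riisvalve:::mesh_edge_lengths(mesh, function(z) !inside(z))
  expect_lte(mean(e_in), spec$h_fine * 1.25)
  expect_lte(mean(e_out), spec$h_coarse * 1.25)
  expect_lt(mean(e_in), mean(e_out))
})

test_that("node count is near the analytic estimate for the desk mesh", {
  spec <- cylinder_spec(radius = 15, z_min = -20, z_max = 60,
                        h_fine = 1.5, h_coarse = 2.25,
                        refine_zmin = -4.5, refine_zmax = 14.5)
  mesh <- generate_cylinder_mesh(spec)
  # estimate: in-plane node density ~ 1/h^2 on the disk, layers by segment
  n2d <- pi * spec$radius^2 / spec$h_fine^2
  nlay <- (spec$refine_zmax - spec$refine_zmin) / spec$h_fine +
    (spec$z_max - spec$refine_zmax + spec$refine_zmin - spec$z_min) /
    spec$h_coarse
  est <- n2d * nlay
  expect_gt(nrow(mesh$nodes), est / 2)
  expect_lt(nrow(mesh$nodes), est * 2)
})

test_that("all cells are positively oriented and conforming", {
  mesh <- tube_mesh()
  vols <- riisvalve:::tet_volumes(mesh$nodes, mesh$cells)
  expect_true(all(vols > 0))
  expect_equal(sum(vols),
               pi * mesh$spec$radius^2 *
                 (mesh$spec$z_max - mesh$spec$z_min),
               tolerance = 0.02)
  # conformity: every interior face is shared by exactly two cells
  tt <- mesh$cells
  faces <- rbind(tt[, c(2, 3, 4)], tt[, c(1, 4, 3)],
                 tt[, c(1, 2, 4)], tt[, c(1, 3, 2)])
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- rowSums(faces) - s1 - s3
  key <- paste(s1, s2, s3)
  cnt <- table(table(key))
  expect_true(all(names(cnt) %in% c("1", "2")))
  n_boundary <- nrow(mesh$boundary$inlet) + nrow(mesh$boundary$outlet) +
    nrow(mesh$boundary$wall)
  expect_identical(unname(cnt[["1"]]), n_boundary)
})

test_that("mesh VTK round trip is exact, including nodal fields", {
  mesh <- tube_mesh()
  f <- tempfile(fileext = ".vtk")
  set.seed(5)
  g <- runif(nrow(mesh$nodes))
  vel <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  write_vtk_mesh(mesh, f, point_data = list(gamma = g, velocity = vel))
  rt <- read_vtk_mesh(f)
  expect_identical(max(abs(rt$nodes - mesh$nodes)), 0)
  expect_identical(rt$cells, matrix(as.numeric(mesh$cells),
                                    nrow = nrow(mesh$cells)))
  expect_identical(rt$point_data$gamma, g)
  expect_identical(max(abs(rt$point_data$velocity - vel)), 0)
  unlink(f)
})
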