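test_that("sphere model validates its geometry", {
  expect_error(sphere_model(radii = c(9, 8)), class = "irritmap_model_error")
  expect_error(sphere_model(conductivities = c(0, 0.3, 0.3)),
               class = "irritmap_model_error")
  mod <- sphere_model()
  mon <- cap_montage(8, radius = 9.2)
  outside <- source_space(matrix(c(0, 0, 8.5), 1))
  expect_error(sphere_leadfield(mod, mon, outside),
               class = "irritmap_geometry_error")
})

test_that("sphere potentials are linear in the dipole moment", {
  mod <- sphere_model()
  mon <- cap_montage(16, radius = 9.2)
  ss <- source_space(matrix(c(2, 1, 3), 1))
  lf <- sphere_leadfield(mod, mon, ss, reference = FALSE)
  expect_equal(as.vector(lf$gain %*% c(0, 0, 0)), rep(0, 16))
  set.seed(1)
  for (i in 1:5) {
    p1 <- rnorm(3); p2 <- rnorm(3)
    expect_equal(lf$gain %*% (p1 + p2), lf$gain %*% p1 + lf$gain %*% p2,
                 tolerance = 1e-12)
  }
})

test_that("equal-conductivity shells reproduce the homogeneous closed form", {
  mod <- sphere_model(conductivities = c(0.33, 0.33, 0.33))
  mon <- cap_montage(32, radius = 9.2)
  dips <- random_dipoles(20, 7.9, ecc_max = 0.9, seed = 3)
  for (d in dips) {
    lf <- sphere_leadfield(mod, mon, source_space(matrix(d$pos, 1)),
                           reference = FALSE)
    v <- as.vector(lf$gain %*% d$moment)
    v0 <- homogeneous_sphere_potential(d$pos, d$moment, mon$positions, 9.2,
                                       0.33)
    expect_lt(sqrt(sum((v - v0)^2)) / sqrt(sum(v0^2)), 1e-6)
  }
})

test_that("a central z-dipole produces a cos(theta) surface pattern", {
  mod <- sphere_model(conductivities = rep(0.33, 3))
  mon <- cap_montage(32, radius = 9.2)
  lf <- sphere_leadfield(mod, mon, source_space(matrix(0, 1, 3)),
                         reference = FALSE)
  v <- as.vector(lf$gain %*% c(0, 0, 1))
  ct <- mon$positions[, 3] / 9.2
  expect_equal(v, 3 / (4 * pi * 0.33 * 9.2^2) * ct, tolerance = 1e-9)
})

test_that("jointly rotating dipole and electrodes leaves potentials fixed", {
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mon <- cap_montage(24, radius = 9.2)
  mod <- sphere_model()
  pos <- c(2, -1, 3); mom <- c(1, 0.5, -2)
  v1 <- sphere_leadfield(mod, mon, source_space(matrix(pos, 1)),
                         reference = FALSE)$gain %*% mom
  mon2 <- montage(mon$names, mon$positions %*% t(rot))
  v2 <- sphere_leadfield(mod, mon2,
                         source_space(matrix(as.vector(rot %*% pos), 1)),
                         reference = FALSE)$gain %*% as.vector(rot %*% mom)
  expect_equal(as.vector(v1), as.vector(v2), tolerance = 1e-9)
})

test_that("average reference removes the common mode and is idempotent", {
  rec <- new_recording(rbind(c(3, 5), c(1, 5)), 100)
  ref <- apply_average_reference(rec)
  expect_equal(ref$data, rbind(c(1, 0), c(-1, 0)))
  expect_equal(apply_average_reference(ref)$data, ref$data)
  expect_true(ref$referenced)
  # constant potential -> all zeros
  expect_equal(apply_average_reference(new_recording(matrix(7, 4, 10),
                                                     10))$data,
               matrix(0, 4, 10))
  # two electrodes (a, b) -> ((a-b)/2, (b-a)/2)
  ab <- apply_average_reference(new_recording(matrix(c(3, 1), 2, 1), 1))
  expect_equal(as.vector(ab$data), c(1, -1))
  expect_error(apply_average_reference(new_recording(matrix(1, 1, 5), 1)),
               class = "irritmap_reference_error")
  # lead-field columns sum to zero
  lf <- fix_geom()$leadfield
  expect_lt(max(abs(colSums(lf$gain))), 1e-9 * max(abs(lf$gain)))
})

test_that("icospheres are closed, outward-oriented and spherical", {
  m <- icosphere(2, 5)
  expect_true(irritmap:::mesh_is_closed(m))
  vol <- irritmap:::mesh_volume(m)
  expect_gt(vol, 0)
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  expect_equal(unname(row_norms <- sqrt(rowSums(m$vertices^2))),
               rep(5, nrow(m$vertices)), tolerance = 1e-12)
})

test_that("OFF and PLY files round-trip a mesh", {
  m <- icosphere(1, 3, center = c(1, -2, 0.5))
  for (ext in c("off", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces)
  }
})

test_that("surface sets enforce closedness and nesting", {
  good <- fix_bem_surfaces(2)
  expect_s3_class(good, "irritmap_surface_set")
  open_mesh <- icosphere(1, 5)
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(surface_set(list(open_mesh), 0.3),
               class = "irritmap_geometry_error")
  expect_error(
    surface_set(list(icosphere(1, 5), icosphere(1, 4)), c(0.3, 0.3)),
    class = "irritmap_geometry_error")
})

test_that("BEM agrees with the analytic sphere on a coarse mesh", {
  surfs <- fix_bem_surfaces(2)
  mon <- fix_vertex_montage()
  mod <- sphere_model()
  dips <- random_dipoles(3, 7.9, ecc_max = 0.6, tangential = TRUE, seed = 5)
  pos <- do.call(rbind, lapply(dips, function(d) d$pos))
  ss <- source_space(pos)
  lfb <- bem_leadfield(surfs, mon, ss)
  lfa <- sphere_leadfield(mod, mon, ss)
  for (i in seq_along(dips)) {
    cols <- (3 * i - 2):(3 * i)
    vb <- as.vector(lfb$gain[, cols] %*% dips[[i]]$moment)
    va <- as.vector(lfa$gain[, cols] %*% dips[[i]]$moment)
    expect_lt(rdm(vb, va), 0.25)
    expect_gt(sqrt(sum(vb^2)) / sqrt(sum(va^2)), 0.75)
    expect_lt(sqrt(sum(vb^2)) / sqrt(sum(va^2)), 1.25)
  }
})

test_that("doubling all conductivities halves BEM potentials", {
  radii <- c(7.9, 8.6, 9.2)
  meshes <- lapply(radii, function(r) icosphere(1, r))
  s1 <- surface_set(meshes, c(0.33, 0.165, 0.33))
  s2 <- surface_set(meshes, 2 * c(0.33, 0.165, 0.33))
  mon <- montage(c("a", "b", "c", "d"),
                 icosphere(1, 9.2)$vertices[c(1, 10, 20, 30), ])
  ss <- source_space(matrix(c(0, 0, 3), 1))
  g1 <- bem_leadfield(s1, mon, ss, reference = FALSE)$gain
  g2 <- bem_leadfield(s2, mon, ss, reference = FALSE)$gain
  expect_equal(g2, g1 / 2, tolerance = 1e-9)
})

test_that("electrodes far from the scalp mesh are rejected", {
  surfs <- fix_bem_surfaces(2)
  mon <- montage("far", matrix(c(0, 0, 12.5), 1))
  expect_error(bem_leadfield(surfs, mon, source_space(matrix(c(0, 0, 3), 1))),
               class = "irritmap_geometry_error")
})

test_that("lead fields survive the binary cache round trip", {
  lf <- fix_geom()$leadfield
  path <- withr::local_tempfile()
  save_leadfield(lf, path)
  lf2 <- load_leadfield(path)
  expect_equal(lf2$gain, lf$gain)
  expect_equal(lf2$referenced, lf$referenced)
  expect_equal(lf2$orientation, lf$orientation)
})

test_that("montage files round-trip", {
  mon <- cap_montage(5, radius = 9.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_montage(mon, path)
  mon2 <- read_montage(path)
  expect_equal(mon2$names, mon$names)
  expect_equal(mon2$positions, mon$positions, tolerance = 1e-6,
               ignore_attr = TRUE)
})
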