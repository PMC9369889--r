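test_that("midpoints sit at voxel centroids in the world frame", {
  g <- voxel_grid(array(1500, c(1, 1, 1)), spacing = 0.3)
  p <- element_midpoints(g, bin_voxels(g))
  expect_equal(unlist(p[1, c("x", "y", "z")], use.names = FALSE),
               c(0.15, 0.15, 0.15))

  g2 <- voxel_grid(array(1500, c(2, 1, 1)), spacing = 1)
  p2 <- element_midpoints(g2, bin_voxels(g2))
  expect_equal(p2$x, c(0.5, 1.5))
  expect_equal(p2$y, c(0.5, 0.5))
  expect_equal(p2$z, c(0.5, 0.5))
})

test_that("rotated grids yield rotated centroids", {
  R <- rotation_from_angles(c(10, -20, 35))
  v <- array(runif(24, 0, 3000), c(4, 3, 2))
  g0 <- voxel_grid(v, spacing = 0.5)
  gR <- voxel_grid(v, spacing = 0.5, axes = R, origin = c(1, 2, 3))
  p0 <- as.matrix(element_midpoints(g0, bin_voxels(g0))[, c("x", "y", "z")])
  pR <- as.matrix(element_midpoints(gR, bin_voxels(gR))[, c("x", "y", "z")])
  # oracle: rotate the unrotated centroids by hand
  expect_equal(pR, sweep(p0 %*% t(R), 2, c(1, 2, 3), `+`), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("alignment of an already-aligned cloud is an axis permutation", {
  g <- voxel_grid(array(1500, c(20, 8, 5)), spacing = 1)
  pts <- element_midpoints(g, bin_voxels(g))
  tf <- estimate_alignment(pts, spacing = 1)
  # rotation must be a signed permutation matrix (here extents already sort)
  expect_equal(abs(tf$rotation), diag(3), tolerance = 1e-8)
  aligned <- apply_transform(tf, pts)
  expect_equal(apply(aligned, 2, min), rep(0.5, 3), tolerance = 1e-8)
  expect_equal(apply(aligned, 2, max), c(19.5, 7.5, 4.5), tolerance = 1e-8)
})

test_that("a known rotation is recovered up to cuboid symmetry", {
  R <- rotation_from_angles(c(0, 0, 10))
  g <- voxel_grid(array(1500, c(20, 8, 5)), spacing = 1, axes = R)
  pts <- element_midpoints(g, bin_voxels(g))
  tf <- estimate_alignment(pts, spacing = 1)
  # composed map grid->world->sample must be a signed permutation
  comp <- tf$rotation %*% R
  expect_equal(abs(comp), diag(3), tolerance = 1e-6)
  aligned <- apply_transform(tf, pts)
  expect_equal(apply(aligned, 2, max) - apply(aligned, 2, min),
               c(19, 7, 4), tolerance = 1e-6)
})

test_that("degenerate point clouds are rejected", {
  line <- tibble::tibble(x = 1:10, y = rep(0, 10), z = rep(0, 10), bin = 1L)
  expect_error(estimate_alignment(line), class = "bonecal_degenerate_input")
  expect_error(estimate_alignment(line[1:2, ]), class = "bonecal_invalid_input")
})

test_that("identity remesh at matched size and geometry is lossless", {
  set.seed(9)
  v <- array(runif(240, 0, 3000), c(10, 6, 4))
  g <- voxel_grid(v, spacing = 1.5)
  asn <- bin_voxels(g)
  pts <- element_midpoints(g, asn)
  geo <- sample_geometry(height = 6 * 1.5, thickness = 4 * 1.5,
                         length = 10 * 1.5, support_spacing = 9)
  mdl <- rebuild_mesh(pts, identity_transform(), geo, element_size = 1.5)
  expect_identical(dim(mdl$bin), dim(v))
  expect_equal(as.vector(mdl$bin), as.vector(unclass(asn)))
})

test_that("remeshing is deterministic", {
  geo <- closed_loop_geometries()[[1]]
  g <- generate_phantom(phantom_spec(geo, spacing = 1.5,
                                     fractions = closed_loop_fractions()[[1]],
                                     seed = 101))
  asn <- bin_voxels(g)
  pts <- element_midpoints(g, asn)
  tf <- estimate_alignment(pts, spacing = 1.5)
  m1 <- rebuild_mesh(pts, tf, geo, 1.5)
  m2 <- rebuild_mesh(pts, tf, geo, 1.5)
  expect_identical(m1$bin, m2$bin)
})

test_that("a rotated phantom remeshed back preserves bin fractions", {
  geo <- sample_geometry(11.58, 7.39, 68.14, 46)
  g <- generate_phantom(phantom_spec(geo, spacing = 1.0,
                                     angles_deg = c(0, 0, 10), seed = 3))
  asn <- bin_voxels(g)
  fr_src <- bin_fractions(asn)$fraction
  pts <- element_midpoints(g, asn)
  tf <- estimate_alignment(pts, spacing = 1.0)
  mdl <- rebuild_mesh(pts, tf, geo, element_size = 1.0)
  fr_out <- bin_fractions(mdl)$fraction
  expect_lt(max(abs(fr_out - fr_src)), 0.02)
  # the remeshed grid reproduces the measured box within one element
  expect_equal(dim(mdl$bin), ceiling(c(68.14, 11.58, 7.39) / 1.0))
})

test_that("empty midpoint clouds and bad element sizes are rejected", {
  geo <- sample_geometry(10, 5, 20, 12)
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          bin = integer(0))
  expect_error(rebuild_mesh(empty, identity_transform(), geo, 1),
               class = "bonecal_invalid_input")
  pts <- tibble::tibble(x = 1, y = 1, z = 1, bin = 1L)
  expect_error(rebuild_mesh(pts, identity_transform(), geo, -1),
               class = "bonecal_invalid_input")
})
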