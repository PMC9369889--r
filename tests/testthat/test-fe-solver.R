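test_that("structured meshes have the expected node and element counts", {
  m <- build_fe_mesh(uniform_beam_model(shape = c(2, 2, 2), h = 1),
                     two_bin_materials())
  expect_equal(nrow(m$nodes), 27)
  expect_equal(nrow(m$elems), 8)
  m2 <- build_fe_mesh(uniform_beam_model(shape = c(5, 3, 2), h = 1),
                      two_bin_materials())
  expect_equal(nrow(m2$nodes), 6 * 4 * 3)
  # shared nodes: every elem vertex refers to a valid node
  expect_true(all(m2$elems >= 1 & m2$elems <= nrow(m2$nodes)))
})

test_that("element moduli come from the bin table lookup", {
  mdl <- mixed_model()
  mats <- tibble::tibble(bin = 1:11, modulus = 1000 * (1:11), poisson = 0.3)
  mesh <- build_fe_mesh(mdl, mats)
  expect_equal(mesh$E, 1000 * as.vector(mdl$bin))
  # a bin present in the model but absent from the table is an error
  expect_error(build_fe_mesh(mdl, mats[mats$bin < 6, ]),
               class = "bonecal_missing_material")
})

test_that("brick element stiffness is symmetric PSD with six rigid modes", {
  K <- hex8_stiffness(E = 12000, nu = 0.3, edge = 0.3)
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_true(all(ev > -1e-8 * max(ev)))
  # rigid translation produces no force
  for (dof in 1:3) {
    u <- rep(0, 24); u[seq(dof, 24, 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  expect_error(hex8_stiffness(12000, 0.5, 0.3), class = "bonecal_invalid_input")
  expect_error(hex8_stiffness(-1, 0.3, 0.3), class = "bonecal_invalid_input")
})

test_that("single element passes the uniaxial patch test", {
  E <- 15000; nu <- 0.3; h <- 0.3; eps <- 1e-3
  K <- hex8_stiffness(E, nu, h)
  sg <- matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                 -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1), ncol = 3, byrow = TRUE)
  xyz <- (sg + 1) / 2 * h
  u <- c(t(cbind(eps * xyz[, 1], -nu * eps * xyz[, 2], -nu * eps * xyz[, 3])))
  f <- matrix(K %*% u, ncol = 3, byrow = TRUE)
  # closed form: sigma_x = E*eps spread over a face shared by 4 nodes
  expect_equal(abs(f[, 1]), rep(E * eps * h^2 / 4, 8), tolerance = 1e-10)
  expect_lt(max(abs(f[, 2:3])), 1e-10)
})

test_that("reaction force is linear in the moduli and in the deflection", {
  mdl <- mixed_model()
  mats <- two_bin_materials(E = 14000)
  setup <- bending_setup(mdl$geometry, deflection = 0.8)
  r1 <- solve_bending(mdl, setup, materials = mats)
  mats2 <- mats
  mats2$modulus <- 2 * mats$modulus
  r2 <- solve_bending(mdl, setup, materials = mats2)
  expect_equal(r2$stiffness / r1$stiffness, 2, tolerance = 1e-9)
  expect_equal(r1$curve$force_N[1], 0)
  expect_equal(r1$curve$force_N,
               r1$stiffness * r1$curve$deflection_mm, tolerance = 1e-12)
})

test_that("solution satisfies equilibrium and the residual contract", {
  mdl <- mixed_model(shape = c(20, 5, 3))
  mats <- tibble::tibble(bin = 1:11, modulus = 1500 * (1:11), poisson = 0.3)
  res <- solve_bending(mdl, bending_setup(mdl$geometry), materials = mats)
  expect_lt(res$residual, 1e-8)
  # load-line reaction balances support reactions
  expect_lt(abs(res$support_force - res$force) / res$force, 1e-6)
})

test_that("homogeneous beam stiffness approaches shear-corrected beam theory", {
  geo <- sample_geometry(height = 11.58, thickness = 7.39, length = 68.14,
                         support_spacing = 46)
  E <- 15000; nu <- 0.3
  h <- 1.5
  shape <- ceiling(c(geo$length, geo$height, geo$thickness) / h)
  mdl <- uniform_beam_model(shape = shape, h = h, geometry = geo)
  res <- solve_bending(mdl, bending_setup(geo), materials = two_bin_materials(E))
  k_beam <- beam_theory_stiffness(E, nu, shape[2] * h, shape[3] * h, res$span)
  expect_lt(abs(res$stiffness / k_beam - 1), 0.1)
})

test_that("stiffness is invariant under mirror symmetry about the load plane", {
  geo <- sample_geometry(height = 12, thickness = 6, length = 72,
                         support_spacing = 48)
  set.seed(21)
  arr <- array(sample(c(5L, 7L, 9L), 48 * 8 * 4, replace = TRUE), c(48, 8, 4))
  mdl <- binned_hex_model(arr, 1.5, geo)
  mir <- binned_hex_model(arr[48:1, , ], 1.5, geo)
  mats <- tibble::tibble(bin = 1:11, modulus = 1500 * (1:11), poisson = 0.3)
  k1 <- solve_bending(mdl, bending_setup(geo), materials = mats)$stiffness
  k2 <- solve_bending(mir, bending_setup(geo), materials = mats)$stiffness
  expect_equal(k1, k2, tolerance = 1e-4)
})

test_that("stiffness estimator uses the 0.2-0.8 mm force increment", {
  curve <- data.frame(deflection_mm = c(0, 0.2, 0.5, 0.8, 1.0),
                      force_N = c(0, 750, 1900, 3000, 3600))
  expect_equal(bending_stiffness(curve), (3000 - 750) / 0.6)
  lin <- data.frame(deflection_mm = seq(0, 1, 0.05),
                    force_N = 4321 * seq(0, 1, 0.05))
  expect_equal(bending_stiffness(lin), 4321, tolerance = 1e-12)
  # grid missing the exact endpoints: interpolation matches a hand oracle
  d <- seq(0, 1, by = 0.03)
  f <- 5000 * d + 10 * sin(20 * d)
  cr <- data.frame(deflection_mm = d, force_N = f)
  oracle <- (approx(d, f, 0.8)$y - approx(d, f, 0.2)$y) / 0.6
  expect_equal(bending_stiffness(cr), oracle, tolerance = 1e-12)
  expect_error(bending_stiffness(data.frame(deflection_mm = c(0.3, 0.4),
                                            force_N = c(1, 2))),
               class = "bonecal_invalid_input")
})

test_that("meshes too coarse to separate contact lines are rejected", {
  mdl <- uniform_beam_model(shape = c(3, 2, 2), h = 4)
  expect_error(
    solve_bending(mdl, bending_setup(mdl$geometry), materials = two_bin_materials()),
    class = "bonecal_invalid_input")
})
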