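# Small two-sample inverse problem on tiny meshes; fast enough for many
# GA runs.
tiny_problem <- function(k_exp = NULL) {
  geo <- sample_geometry(height = 6, thickness = 4.5, length = 24,
                         support_spacing = 15)
  set.seed(31)
  m1 <- binned_hex_model(array(sample(4:9, 16 * 4 * 3, TRUE), c(16, 4, 3)),
                         1.5, geo)
  m2 <- binned_hex_model(array(sample(6:11, 16 * 4 * 3, TRUE), c(16, 4, 3)),
                         1.5, geo)
  setup <- bending_setup(geo, deflection = 0.8)
  samples <- list(list(model = m1, setup = setup, k_exp = 1, label = "A"),
                  list(model = m2, setup = setup, k_exp = 1, label = "B"))
  prob <- fit_problem(samples)
  if (is.null(k_exp)) {
    truth <- evaluate_candidate(c(a = 0.388524, b = 4419.3, c = 2.20939,
                                  d = 1.17823), prob)
    prob <- with_k_exp(prob, truth$k_fea)
  } else {
    prob <- with_k_exp(prob, k_exp)
  }
  prob
}

test_that("error norm is the plain sum of squared differences", {
  expect_equal(error_norm(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(error_norm(c(1, 2), c(0, 0)), 5)
  set.seed(2)
  a <- runif(7, 1000, 6000); b <- runif(7, 1000, 6000)
  brute <- 0
  for (i in 1:7) brute <- brute + (a[i] - b[i])^2
  expect_equal(error_norm(a, b), brute)
  # quadratic scale property
  expect_equal(error_norm(3 * a, 3 * b), 9 * error_norm(a, b))
  expect_error(error_norm(1:3, 1:2), class = "bonecal_invalid_input")
})

test_that("evaluating the generating candidate returns zero error", {
  prob <- tiny_problem()
  ev <- evaluate_candidate(c(a = 0.388524, b = 4419.3, c = 2.20939,
                             d = 1.17823), prob)
  expect_true(ev$feasible)
  expect_lt(ev$err, 1e-12)
  # identical models would give identical stiffness
  s <- prob$samples[[1]]
  prob2 <- fit_problem(list(s, s))
  ev2 <- evaluate_candidate(c(0.388524, 4419.3, 2.20939, 1.17823), prob2)
  expect_equal(ev2$k_fea[1], ev2$k_fea[2])
})

test_that("the modulus cap makes extreme candidates infeasible", {
  prob <- tiny_problem()
  ev <- evaluate_candidate(c(a = 0.8, b = 5000, c = 8, d = 2), prob)
  expect_false(ev$feasible)
  expect_identical(ev$err, Inf)
  # predicate matches the law-level check
  expect_false(law_is_feasible(material_law(0.8, 5000, 8, 2, e_limit = prob$e_limit)))
})

test_that("candidate evaluations are cached on rounded coordinates", {
  prob <- tiny_problem()
  p <- c(a = 0.41, b = 4000, c = 2.5, d = 1.1)
  ev1 <- evaluate_candidate(p, prob)
  ev2 <- evaluate_candidate(p, prob)
  expect_false(isTRUE(ev1$cached))
  expect_true(ev2$cached)
  expect_identical(ev1$k_fea, ev2$k_fea)
})

test_that("identical seeds give identical search trajectories", {
  prob <- tiny_problem()
  ctrl <- ga_control(pop_size = 12, max_generations = 6,
                     stall_generations = 6)
  f1 <- fit_material_law(prob, ctrl, seed = 5)
  f2 <- fit_material_law(prob, ctrl, seed = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history$best_err, f2$history$best_err)
  f3 <- fit_material_law(prob, ctrl, seed = 6)
  expect_false(identical(f3$history$best_err, f1$history$best_err))
})

test_that("best error is monotone non-increasing across generations", {
  prob <- tiny_problem()
  fit <- fit_material_law(prob, ga_control(pop_size = 14, max_generations = 10,
                                           stall_generations = 10), seed = 3)
  expect_true(all(diff(fit$history$best_err) <= 0))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$term, c("a", "b", "c", "d"))
  expect_equal(nrow(glance(fit)), 1)
  expect_equal(nrow(sample_comparison(fit)), 2)
})

test_that("one-parameter search agrees with a grid-search oracle", {
  # freeze b, c, d near the reference values; search only the scale a
  eps <- 1e-9
  bounds <- list(a = c(0.2, 0.8), b = c(4419.3, 4419.3 + eps),
                 c = c(2.20939, 2.20939 + eps), d = c(1.17823, 1.17823 + eps))
  geo <- sample_geometry(height = 6, thickness = 4.5, length = 24,
                         support_spacing = 15)
  set.seed(31)
  m1 <- binned_hex_model(array(sample(4:9, 16 * 4 * 3, TRUE), c(16, 4, 3)),
                         1.5, geo)
  setup <- bending_setup(geo)
  prob <- fit_problem(list(list(model = m1, setup = setup, k_exp = 1)),
                      bounds = bounds)
  truth <- evaluate_candidate(c(0.3, 4419.3, 2.20939, 1.17823), prob)
  prob <- with_k_exp(prob, truth$k_fea)
  # independent oracle: dense grid over a
  grid_a <- seq(0.2, 0.8, by = 0.005)
  grid_err <- vapply(grid_a, function(a) {
    evaluate_candidate(c(a, 4419.3, 2.20939, 1.17823), prob)$err
  }, numeric(1))
  a_oracle <- grid_a[which.min(grid_err)]
  expect_equal(a_oracle, 0.3, tolerance = 0.005)
  fit <- fit_material_law(prob, ga_control(pop_size = 12, max_generations = 12,
                                           stall_generations = 12), seed = 2)
  expect_lt(abs(fit$par[["a"]] - a_oracle), 0.005)
})

test_that("an unattainable modulus cap aborts with a constraint diagnostic", {
  geo <- sample_geometry(height = 6, thickness = 4.5, length = 24,
                         support_spacing = 15)
  m <- binned_hex_model(array(6L, c(16, 4, 3)), 1.5, geo)
  prob <- fit_problem(list(list(model = m, setup = bending_setup(geo),
                                k_exp = 5000)),
                      e_limit = 1)  # nothing satisfies E <= 1 MPa
  expect_error(
    fit_material_law(prob, ga_control(pop_size = 8, max_generations = 2), seed = 1),
    class = "bonecal_no_feasible")
})

test_that("problem construction validates inputs", {
  expect_error(fit_problem(list()), class = "bonecal_invalid_input")
  geo <- sample_geometry(6, 4.5, 24, 15)
  m <- binned_hex_model(array(6L, c(16, 4, 3)), 1.5, geo)
  expect_error(
    fit_problem(list(list(model = m, setup = bending_setup(geo), k_exp = 1)),
                bounds = list(a = c(1, 0), b = c(0, 1), c = c(0, 1), d = c(0, 1))),
    class = "bonecal_invalid_input")
})
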