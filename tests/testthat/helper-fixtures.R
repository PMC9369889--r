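# Shared fixtures: all built in code, desk-scale sizes.

# The published optimal coefficient set used as reference/ground truth.
reference_law <- function() material_law(0.388524, 4419.3, 2.20939, 1.17823)

# A small homogeneous beam model: every element in the given bin.
uniform_beam_model <- function(shape = c(16, 4, 3), h = 1.5, bin = 6,
                               geometry = NULL) {
  binned_hex_model(array(as.integer(bin), shape), element_size = h,
                   geometry = geometry)
}

# Two-bin material table for homogeneous-beam tests.
two_bin_materials <- function(E = 15000, nu = 0.3) {
  tibble::tibble(bin = 1:11, modulus = E, poisson = nu)
}

# A small mixed-bin model with reproducible bin field.
mixed_model <- function(shape = c(16, 4, 3), h = 1.5, seed = 5,
                        bins = c(5L, 6L, 7L, 8L)) {
  arr <- array(0L, shape)
  set.seed(seed)
  arr[] <- sample(bins, prod(shape), replace = TRUE)
  binned_hex_model(arr, element_size = h)
}

# Desk-scale closed-loop phantom samples: three contrasting per-range
# occupancy profiles (left-side, front and back sample distributions of a
# bovine femur) on their measured geometries.
closed_loop_geometries <- function() {
  list(
    L1 = sample_geometry(height = 11.58, thickness = 7.38, length = 68.49),
    F2 = sample_geometry(height = 11.35, thickness = 6.68, length = 70.73),
    B1 = sample_geometry(height = 11.59, thickness = 7.39, length = 69.25)
  )
}

closed_loop_fractions <- function() {
  list(
    L1 = c(8.96, 3.84, 4.85, 5.39, 5.99, 7.38, 17.87, 23.55, 15.74, 5.84, 0.57) / 100,
    F2 = c(13.06, 6.17, 7.85, 12.06, 16.95, 23.93, 15.23, 2.99, 1.16, 0.52, 0.08) / 100,
    B1 = c(8.16, 1.89, 3.18, 4.35, 5.02, 7.14, 16.52, 26.79, 19.35, 5.51, 2.09) / 100
  )
}

# Generate the three desk-scale phantom samples and forward-simulate their
# pseudo-experimental curves; cached per session because the FE forward
# runs take a few seconds each.
closed_loop_samples <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_sd = 0, spacing = 1.5, element_size = 1.5) {
    key <- sprintf("%g|%g|%g", noise_sd, spacing, element_size)
    if (!is.null(cache[[key]])) return(cache[[key]])
    geos <- closed_loop_geometries()
    fracs <- closed_loop_fractions()
    truth <- ground_truth(reference_law(), noise_sd = noise_sd)
    out <- lapply(seq_along(geos), function(i) {
      g <- generate_phantom(phantom_spec(geos[[i]], spacing = spacing,
                                         fractions = fracs[[i]],
                                         seed = 100 + i))
      fw <- forward_experiment(g, truth, bending_setup(geos[[i]]),
                               seed = 200 + i, element_size = element_size)
      list(model = fw$model, setup = bending_setup(geos[[i]]),
           curve = fw$curve, k_true = fw$k_true,
           label = names(geos)[i])
    })
    cache[[key]] <- out
    out
  }
})
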