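#' Configuration for an end-to-end calibration run
#'
#' Collects everything a calibration needs: per-sample inputs (voxel grid,
#' measured force-deflection curve, measured geometry), optional hold-out
#' samples, discretisation and optimisation settings. Grids and curves may
#' be given as in-memory objects or as file paths (the grid format of
#' [write_voxel_grid()] and delimited curves for [read_curve()]).
#'
#' @param samples List of calibration samples; each a list with `grid`,
#'   `curve`, `geometry` (a [sample_geometry()]) and optionally `label`.
#' @param holdout Like `samples`, for validation only.
#' @param element_size Remeshed element edge, mm.
#' @param binning A [hu_binning()].
#' @param bounds Parameter bounds, see [default_bounds()].
#' @param e_limit Modulus bound, MPa.
#' @param nu Poisson ratio.
#' @param deflection Prescribed bending deflection, mm.
#' @param window Stiffness regression window, mm.
#' @param ga A [ga_control()].
#' @param seed RNG seed for the optimiser.
#' @param out_dir Output directory for report files, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples, holdout = list(), element_size = 0.3,
                       binning = hu_binning(), bounds = default_bounds(),
                       e_limit = 21000, nu = 0.3, deflection = 0.8,
                       window = c(0.2, 0.8), ga = ga_control(), seed = 1,
                       out_dir = NULL) {
  if (length(samples) < 1) {
    rlang::abort("Need at least one calibration sample.",
                 class = "bonecal_invalid_input")
  }
  structure(list(samples = samples, holdout = holdout,
                 element_size = element_size, binning = binning,
                 bounds = bounds, e_limit = e_limit, nu = nu,
                 deflection = deflection, window = window, ga = ga,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

# Load one configured sample and build its remeshed model + k_exp.
prepare_sample <- function(s, config, idx, require_curve = TRUE) {
  label <- if (!is.null(s$label)) s$label else paste0("S", idx)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Stage '%s' failed for sample '%s': %s",
                           name, label, conditionMessage(e)),
                   class = "bonecal_stage_error")
    })
  }
  grid <- stage("load-grid", {
    if (is.character(s$grid)) read_voxel_grid(s$grid) else s$grid
  })
  if (!inherits(grid, "voxel_grid")) {
    rlang::abort(sprintf("Sample '%s' has no voxel grid.", label),
                 class = "bonecal_stage_error")
  }
  geometry <- s$geometry
  if (!inherits(geometry, "sample_geometry")) {
    rlang::abort(sprintf("Sample '%s' has no measured geometry.", label),
                 class = "bonecal_stage_error")
  }
  k_exp <- NULL
  if (require_curve || !is.null(s$curve)) {
    curve <- stage("load-curve", {
      if (is.null(s$curve)) rlang::abort("no curve configured")
      if (is.character(s$curve)) read_curve(s$curve) else s$curve
    })
    k_exp <- stage("stiffness", {
      stiffness_from_curve(curve, config$window)$stiffness
    })
  }
  model <- stage("remesh", {
    assignment <- bin_voxels(grid, config$binning)
    pts <- element_midpoints(grid, assignment)
    tf <- estimate_alignment(pts, spacing = grid$spacing)
    rebuild_mesh(pts, tf, geometry, config$element_size, config$binning)
  })
  list(label = label, model = model, k_exp = k_exp,
       setup = bending_setup(geometry, config$deflection))
}

#' Run the full calibration workflow
#'
#' Executes the four-step loop - build per-sample models, sample candidate
#' coefficients, simulate every sample, minimise the stiffness error norm -
#' and returns the fit together with the per-sample comparison and bin
#' material table. When `config$out_dir` is set, writes `params.json`,
#' `comparison.csv`, `history.csv` and `bin_table.csv` there.
#'
#' @param config A [run_config()].
#' @return A list of class `calibration_report`: `fit` (a `bonecal_fit`),
#'   `comparison` (per-sample tibble), `bin_table`, `config`.
#' @export
run_calibration <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prepared <- lapply(seq_along(config$samples), function(i) {
    prepare_sample(config$samples[[i]], config, i)
  })
  problem <- fit_problem(
    lapply(prepared, function(p) p[c("model", "setup", "k_exp", "label")]),
    binning = config$binning, bounds = config$bounds,
    e_limit = config$e_limit, nu = config$nu)
  fit <- fit_material_law(problem, control = config$ga, seed = config$seed)
  comparison <- sample_comparison(fit)
  bin_table <- build_bin_table(config$binning, fit$law, nu = config$nu)
  report <- structure(list(fit = fit, comparison = comparison,
                           bin_table = bin_table, config = config),
                      class = "calibration_report")
  if (!is.null(config$out_dir)) write_calibration_report(report, config$out_dir)
  report
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration report\n==================\n")
  print(x$fit)
  cat("\nPer-sample stiffness comparison:\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  invisible(x)
}

write_calibration_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- report$fit
  jsonlite::write_json(
    list(a = fit$par[["a"]], b = fit$par[["b"]], c = fit$par[["c"]],
         d = fit$par[["d"]], err = fit$err,
         e_limit = fit$law$e_limit, seed = fit$seed,
         generations = fit$generations, n_evaluations = fit$n_evaluations),
    file.path(out_dir, "params.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$bin_table, file.path(out_dir, "bin_table.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Validate a fitted law on hold-out samples
#'
#' Simulates each hold-out sample with the fitted coefficients and reports
#' the signed percent difference against its measured stiffness - the
#' standard check that the law transfers to samples that took no part in
#' the calibration.
#'
#' @param config A [run_config()] with a non-empty `holdout` list.
#' @param law A fitted [material_law()] (or a `bonecal_fit`).
#' @return A tibble with `sample`, `k_exp`, `k_fea`, `pct_diff`; written to
#'   `validation.csv` under `config$out_dir` when set.
#' @export
run_validation <- function(config, law) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(law, "bonecal_fit")) law <- law$law
  stopifnot(inherits(law, "material_law"))
  if (length(config$holdout) < 1) {
    rlang::abort("No hold-out samples configured.", class = "bonecal_invalid_input")
  }
  materials <- build_bin_table(config$binning, law, nu = config$nu)
  rows <- lapply(seq_along(config$holdout), function(i) {
    p <- prepare_sample(config$holdout[[i]], config, i)
    res <- solve_bending(p$model, p$setup, materials = materials)
    tibble::tibble(sample = p$label, k_exp = p$k_exp, k_fea = res$stiffness,
                   pct_diff = percent_difference(p$k_exp, res$stiffness))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}
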