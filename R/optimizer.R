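#' Sum-of-squared-errors stiffness norm
#'
#' The objective of the inverse identification: the sum over samples of the
#' squared difference between simulated and experimental bending stiffness,
#' in N^2/mm^2.
#'
#' @param k_fea Simulated stiffness per sample, N/mm.
#' @param k_exp Experimental stiffness per sample, N/mm.
#' @return The scalar error norm.
#' @examples
#' error_norm(c(1, 2), c(0, 0))
#' @export
error_norm <- function(k_fea, k_exp) {
  if (length(k_fea) != length(k_exp) || length(k_fea) < 1) {
    rlang::abort("`k_fea` and `k_exp` must have equal positive length.",
                 class = "bonecal_invalid_input")
  }
  sum((k_fea - k_exp)^2)
}

#' Default parameter search bounds
#'
#' The coefficient domain of the inverse problem: a in \[0.2, 0.8\],
#' b in \[1200, 5000\] kg/m^3, c in \[2, 8\] kg/(m^3 HU), d in \[0.1, 2\].
#'
#' @return A named list of length-2 numeric ranges.
#' @export
default_bounds <- function() {
  list(a = c(0.2, 0.8), b = c(1200, 5000), c = c(2, 8), d = c(0.1, 2.0))
}

#' Assemble an inverse identification problem
#'
#' Bundles the calibration samples (a remeshed model, bending setup, and
#' measured stiffness each), the HU binning, the parameter bounds and the
#' modulus limit, and precomputes one reusable FE bending operator per
#' sample so that candidate evaluation amounts to a numeric refactorisation
#' rather than a cold FE build.
#'
#' @param samples A list; each element a list with `model` (a
#'   `binned_hex_model`), `setup` (a [bending_setup()]), `k_exp` (N/mm) and
#'   optionally `label`.
#' @param binning A [hu_binning()] shared by all models.
#' @param bounds Named list of parameter ranges; see [default_bounds()].
#' @param e_limit Modulus bound, MPa; candidates whose modulus at the
#'   highest bin middle exceeds it are infeasible.
#' @param nu Poisson ratio used in the FE models.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(samples, binning = hu_binning(),
                        bounds = default_bounds(), e_limit = 21000, nu = 0.3) {
  if (length(samples) < 1) {
    rlang::abort("Need at least one calibration sample.",
                 class = "bonecal_invalid_input")
  }
  for (nmb in c("a", "b", "c", "d")) {
    r <- bounds[[nmb]]
    if (is.null(r) || length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2]) {
      rlang::abort(sprintf("Bounds for `%s` must be a finite lo < hi pair.", nmb),
                   class = "bonecal_invalid_input")
    }
  }
  samples <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    stopifnot(inherits(s$model, "binned_hex_model"),
              inherits(s$setup, "bending_setup"))
    if (!is.numeric(s$k_exp) || length(s$k_exp) != 1 || !is.finite(s$k_exp)) {
      rlang::abort(sprintf("Sample %d needs a finite measured stiffness.", i),
                   class = "bonecal_invalid_input")
    }
    if (is.null(s$label)) s$label <- paste0("S", i)
    s$operator <- fe_operator(s$model, s$setup, nu = nu)
    s
  })
  structure(list(samples = samples, binning = binning, bounds = bounds,
                 e_limit = e_limit, nu = nu,
                 cache = new.env(parent = emptyenv())),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("<fit_problem> %d sample(s), %d bins, E_limit %g MPa\n",
              length(x$samples), n_bins(x$binning), x$e_limit))
  invisible(x)
}

#' Swap the experimental stiffness values of a fit problem
#'
#' Returns the same problem (models, operators and evaluation cache are
#' shared) with new per-sample measured stiffness, e.g. to refit against a
#' noisy re-measurement without rebuilding the FE structures.
#'
#' @param problem A [fit_problem()].
#' @param k_exp Numeric vector, one stiffness per sample, N/mm.
#' @return A `fit_problem`.
#' @export
with_k_exp <- function(problem, k_exp) {
  stopifnot(inherits(problem, "fit_problem"),
            length(k_exp) == length(problem$samples))
  if (!all(is.finite(k_exp))) {
    rlang::abort("All replacement stiffness values must be finite.",
                 class = "bonecal_invalid_input")
  }
  for (i in seq_along(problem$samples)) problem$samples[[i]]$k_exp <- k_exp[i]
  problem
}

candidate_key <- function(par, digits = 6) {
  paste(sprintf("%.*e", digits, par), collapse = "|")
}

#' Evaluate one candidate coefficient set
#'
#' Builds the per-bin moduli from the candidate, runs the bending
#' simulation of every sample through its precomputed operator (evaluations
#' are independent, so their order is immaterial), and returns the error
#' norm together with the feasibility flag of the modulus constraint.
#' Results are cached on the problem keyed by the candidate rounded to six
#' significant digits, so repeated solutions cost nothing.
#'
#' @param candidate Numeric vector `c(a, b, c, d)` or a named list.
#' @param problem A [fit_problem()].
#' @return A list with `err`, `feasible`, `k_fea` (per sample) and `k_exp`.
#' @export
evaluate_candidate <- function(candidate, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  par <- as.numeric(candidate[c(1, 2, 3, 4)])
  if (!is.null(names(candidate))) par <- as.numeric(unlist(candidate[c("a", "b", "c", "d")]))
  mids <- problem$binning$middles
  rho <- par[3] * mids + par[2]
  k_exp <- vapply(problem$samples, `[[`, numeric(1), "k_exp")
  if (any(rho <= 0)) {
    return(list(err = Inf, feasible = FALSE, k_fea = rep(NA_real_, length(k_exp)),
                k_exp = k_exp, reason = "non-positive apparent density"))
  }
  E_bins <- par[1] * rho^par[4]
  if (max(E_bins) > problem$e_limit) {
    return(list(err = Inf, feasible = FALSE, k_fea = rep(NA_real_, length(k_exp)),
                k_exp = k_exp, reason = "modulus limit exceeded"))
  }
  key <- candidate_key(par)
  k_fea <- problem$cache[[key]]
  cached <- !is.null(k_fea)
  if (!cached) {
    k_fea <- vapply(problem$samples, function(s) s$operator$stiffness(E_bins),
                    numeric(1))
    problem$cache[[key]] <- k_fea
  }
  list(err = error_norm(k_fea, k_exp), feasible = TRUE,
       k_fea = k_fea, k_exp = k_exp, cached = cached)
}

#' Genetic-algorithm settings
#'
#' Operator choices for the real-coded generational search: best-guided
#' difference-vector recombination (each trial individual is built from the
#' current best plus a weighted difference of two random population
#' members), per-gene binomial crossover with the parent, clipping to the
#' bounds, and greedy one-to-one replacement (a trial only displaces its
#' parent when it is at least as good), which makes the search inherently
#' elitist. Infeasible candidates receive an infinite error (death
#' penalty). The run stops early when the best error has not improved by
#' more than `stall_tol` (relative) for `stall_generations` consecutive
#' generations.
#'
#' Difference-vector recombination is used instead of blend crossover with
#' Gaussian mutation because the coefficient space of the density-
#' elasticity law contains an exact scaling degeneracy and a strongly
#' ill-conditioned curved valley; difference vectors sampled from the
#' population align with that valley automatically, where isotropic
#' mutation stalls orders of magnitude short of the attainable error.
#'
#' @param pop_size Individuals per generation.
#' @param max_generations Generation cap.
#' @param diff_weight Weight F applied to the difference vector.
#' @param crossover_prob Per-gene probability CR of taking the trial gene
#'   rather than the parent gene (one gene is always taken).
#' @param stall_generations Early-termination patience.
#' @param stall_tol Relative improvement below which a generation counts as
#'   stalled.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 200, max_generations = 30,
                       diff_weight = 0.7, crossover_prob = 0.9,
                       stall_generations = 4, stall_tol = 1e-6) {
  stopifnot(pop_size >= 4, max_generations >= 1,
            diff_weight > 0, crossover_prob > 0, crossover_prob <= 1)
  structure(list(pop_size = pop_size, max_generations = max_generations,
                 diff_weight = diff_weight, crossover_prob = crossover_prob,
                 stall_generations = stall_generations, stall_tol = stall_tol),
            class = "ga_control")
}

#' Fit the density-elasticity law by genetic-algorithm search
#'
#' Minimises the multi-sample squared stiffness error over the coefficient
#' box, subject to the modulus limit, with a real-coded generational
#' genetic algorithm. Identical seeds and settings give identical
#' trajectories. Note that the four coefficients are jointly
#' under-determined over a bounded HU range - distinct near-optimal
#' parameter sets can encode nearly the same modulus curve - so assess a
#' fit by its recovered E(HU) curve and error norm, not by raw parameter
#' values.
#'
#' @param problem A [fit_problem()].
#' @param control A [ga_control()].
#' @param seed Integer RNG seed.
#' @return An object of class `bonecal_fit`: the best feasible candidate as
#'   a [material_law()], its error norm, per-sample stiffness, the
#'   per-generation history, and evaluation counts. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_material_law <- function(problem, control = ga_control(), seed = 1) {
  stopifnot(inherits(problem, "fit_problem"), inherits(control, "ga_control"))
  bounds <- problem$bounds
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  npar <- 4L
  np <- control$pop_size

  with_seed(seed, {
    pop <- matrix(stats::runif(np * npar, rep(lo, each = np), rep(hi, each = np)),
                  nrow = np)
    colnames(pop) <- names(bounds)

    n_eval <- 0L; n_cached <- 0L
    eval_pop <- function(pop) {
      res <- apply(pop, 1, function(p) {
        ev <- evaluate_candidate(p, problem)
        n_eval <<- n_eval + 1L
        if (isTRUE(ev$cached)) n_cached <<- n_cached + 1L
        ev$err
      })
      as.numeric(res)
    }

    err <- eval_pop(pop)
    best_i <- which.min(err)
    best <- list(par = pop[best_i, ], err = err[best_i])
    history <- list()
    stall <- 0L

    for (gen in seq_len(control$max_generations)) {
      if (gen > 1) {
        bi <- which.min(err)
        for (i in seq_len(np)) {
          r <- sample.int(np - 1L, 2)
          r[r >= i] <- r[r >= i] + 1L  # two distinct members other than i
          trial <- pop[bi, ] + control$diff_weight * (pop[r[1], ] - pop[r[2], ])
          take <- stats::runif(npar) < control$crossover_prob
          take[sample.int(npar, 1)] <- TRUE
          trial <- ifelse(take, trial, pop[i, ])
          trial <- pmin(pmax(trial, lo), hi)
          ev <- evaluate_candidate(trial, problem)
          n_eval <- n_eval + 1L
          if (isTRUE(ev$cached)) n_cached <- n_cached + 1L
          if (ev$err <= err[i]) {
            pop[i, ] <- trial
            err[i] <- ev$err
            if (ev$err < err[bi]) bi <- i
          }
        }
      }
      gi <- which.min(err)
      improved <- err[gi] < best$err * (1 - control$stall_tol)
      if (err[gi] < best$err) best <- list(par = pop[gi, ], err = err[gi])
      stall <- if (improved) 0L else stall + 1L
      history[[gen]] <- tibble::tibble(
        generation = gen, best_err = best$err,
        mean_err = mean(err[is.finite(err)]),
        n_feasible = sum(is.finite(err)),
        n_evaluations = n_eval, n_cache_hits = n_cached
      )
      if (gen > 1 && stall >= control$stall_generations) break
    }

    if (!is.finite(best$err)) {
      rlang::abort(
        paste("No feasible candidate found: every sampled coefficient set",
              "violated the modulus limit or the positive-density condition."),
        class = "bonecal_no_feasible")
    }

    final <- evaluate_candidate(best$par, problem)
    law <- material_law(best$par[1], best$par[2], best$par[3], best$par[4],
                        e_limit = problem$e_limit)
    structure(list(
      law = law, par = best$par, err = best$err,
      k_fea = final$k_fea, k_exp = final$k_exp,
      labels = vapply(problem$samples, `[[`, character(1), "label"),
      history = dplyr::bind_rows(history),
      generations = length(history),
      n_evaluations = n_eval, n_cache_hits = n_cached,
      control = control, seed = seed, binning = problem$binning
    ), class = "bonecal_fit")
  })
}

#' @export
print.bonecal_fit <- function(x, ...) {
  cat(sprintf("<bonecal_fit> %d generation(s), %d evaluations (%d cache hits)\n",
              x$generations, x$n_evaluations, x$n_cache_hits))
  cat(sprintf("  err = %.4g N^2/mm^2\n", x$err))
  print(x$law)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted coefficients
#' @param x A `bonecal_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.bonecal_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = unname(x$par))
}

#' One-row fit summary
#' @param x A `bonecal_fit`.
#' @param ... Unused.
#' @return Tibble with the error norm, generation and evaluation counts and
#'   the mean absolute per-sample stiffness discrepancy in percent.
#' @export
glance.bonecal_fit <- function(x, ...) {
  tibble::tibble(
    err = x$err,
    generations = x$generations,
    n_evaluations = x$n_evaluations,
    n_samples = length(x$k_exp),
    mean_abs_pct_diff = mean(abs(percent_difference(x$k_exp, x$k_fea)))
  )
}

#' Per-sample stiffness comparison of a fit
#'
#' The calibration-report table: measured versus simulated stiffness per
#' sample with the signed percent difference.
#'
#' @param fit A `bonecal_fit`, or separate vectors via `k_exp`/`k_fea`.
#' @return Tibble with `sample`, `k_exp`, `k_fea`, `pct_diff`.
#' @export
sample_comparison <- function(fit) {
  stopifnot(inherits(fit, "bonecal_fit"))
  tibble::tibble(
    sample = fit$labels,
    k_exp = fit$k_exp,
    k_fea = fit$k_fea,
    pct_diff = percent_difference(fit$k_exp, fit$k_fea)
  )
}
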