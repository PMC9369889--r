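#' Regular 3-D grid of Hounsfield values
#'
#' A voxel grid holds one Hounsfield-unit (HU) scalar per cubic voxel of edge
#' `spacing` mm, positioned in the world (scanner) frame by `origin` (the
#' corner of voxel (1,1,1)) and a proper rotation `axes` mapping grid axes to
#' world axes. Voxels outside the sample mask may be `NA`; such voxels take
#' no part in binning, midpoint extraction or remeshing.
#'
#' @param values Numeric 3-D array of HU values (may contain `NA` for
#'   background/masked voxels).
#' @param spacing Voxel edge length, mm (isotropic). The 0.3 mm default
#'   matches the cubic elements voxel models are typically exported at.
#' @param origin Length-3 numeric, world position (mm) of the corner of the
#'   first voxel.
#' @param axes 3x3 proper rotation matrix (orthonormal, det +1); column k is
#'   the world direction of grid axis k.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(1500, c(4, 3, 2)), spacing = 0.3)
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing = 0.3, origin = c(0, 0, 0),
                       axes = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    rlang::abort("`values` must be a 3-D array.", class = "bonecal_invalid_input")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    rlang::abort("`spacing` must be a single positive number (mm).",
                 class = "bonecal_invalid_input")
  }
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 3)) ||
      max(abs(crossprod(axes) - diag(3))) > 1e-8 ||
      abs(det(axes) - 1) > 1e-8) {
    rlang::abort("`axes` must be a proper rotation (orthonormal, det +1).",
                 class = "bonecal_invalid_input")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), axes = axes),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  n_na <- sum(is.na(x$values))
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %g mm\n",
              d[1], d[2], d[3], x$spacing))
  cat(sprintf("  HU range [%g, %g], %d masked voxel(s)\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)), n_na))
  invisible(x)
}

#' Hounsfield-unit density binning
#'
#' Breakpoints partitioning the HU axis into density ranges. The default
#' edges 600, 800, ..., 2400 give 11 ranges including the two open ends,
#' with representative middles 500, 700, ..., 2300, 2500 (the open-end bins
#' use the conventional middles 500 and 2500). Intervals are half-open
#' `[lo, hi)`: the lowest bin is (-Inf, 600) and the highest [2400, Inf).
#'
#' @param edges Strictly increasing HU breakpoints.
#' @param middles Representative HU per bin, one more than `length(edges)`.
#'   By default, interval midpoints, extended by half the adjacent bin width
#'   for the open ends.
#' @return An object of class `hu_binning`.
#' @examples
#' hu_binning()$middles
#' @export
hu_binning <- function(edges = seq(600, 2400, by = 200), middles = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 1 || any(diff(edges) <= 0)) {
    rlang::abort("`edges` must be strictly increasing.", class = "bonecal_invalid_input")
  }
  if (is.null(middles)) {
    if (length(edges) == 1) {
      middles <- c(edges - 100, edges + 100)
    } else {
      inner <- (edges[-length(edges)] + edges[-1]) / 2
      middles <- c(edges[1] - diff(edges)[1] / 2, inner,
                   edges[length(edges)] + diff(edges)[length(edges) - 1] / 2)
    }
  }
  middles <- as.numeric(middles)
  if (length(middles) != length(edges) + 1) {
    rlang::abort("`middles` must have length(edges) + 1 entries.",
                 class = "bonecal_invalid_input")
  }
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  if (any(middles < lo | middles >= hi)) {
    rlang::abort("Each middle must lie inside its own bin.",
                 class = "bonecal_invalid_input")
  }
  structure(list(edges = edges, middles = middles), class = "hu_binning")
}

#' @export
print.hu_binning <- function(x, ...) {
  cat(sprintf("<hu_binning> %d bins over edges %s\n", length(x$middles),
              paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' Number of bins of an HU binning
#' @param binning A [hu_binning()].
#' @return Integer bin count.
#' @export
n_bins <- function(binning) {
  stopifnot(inherits(binning, "hu_binning"))
  length(binning$middles)
}

#' Assign voxels to density bins
#'
#' Maps every non-masked voxel of a grid to the half-open HU interval that
#' contains it. Values below the lowest edge go to bin 1, values at or above
#' the highest edge to the last bin. `NA` voxels stay `NA`.
#'
#' @param grid A [voxel_grid()].
#' @param binning A [hu_binning()].
#' @return A `bin_assignment`: an integer 3-D array of 1-based bin indices
#'   with the binning attached as attribute `binning`.
#' @examples
#' g <- voxel_grid(array(c(500, 700, 2500), c(3, 1, 1)))
#' as.vector(bin_voxels(g, hu_binning()))
#' @export
bin_voxels <- function(grid, binning = hu_binning()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(binning, "hu_binning"))
  if (length(grid$values) == 0 || all(is.na(grid$values))) {
    rlang::abort("Grid has no unmasked voxels to bin.", class = "bonecal_invalid_input")
  }
  idx <- findInterval(grid$values, binning$edges) + 1L
  a <- array(as.integer(idx), dim = dim(grid$values))
  structure(a, class = "bin_assignment", binning = binning)
}

#' Per-bin voxel counts and fractions
#'
#' Tallies a bin assignment into the per-range occupancy table: number of
#' voxels and fraction of the sample in each density range.
#'
#' @param assignment A `bin_assignment` from [bin_voxels()], or a
#'   `binned_hex_model` from [rebuild_mesh()].
#' @return A tibble with one row per bin: `bin`, `hu_middle`, `n`, `fraction`.
#'   Fractions are non-negative and sum to 1.
#' @export
bin_fractions <- function(assignment) {
  if (inherits(assignment, "binned_hex_model")) {
    binning <- assignment$binning
    idx <- assignment$bin
  } else if (inherits(assignment, "bin_assignment")) {
    binning <- attr(assignment, "binning")
    idx <- unclass(assignment)
  } else {
    rlang::abort("`assignment` must come from bin_voxels() or rebuild_mesh().",
                 class = "bonecal_invalid_input")
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    rlang::abort("Empty assignment: no voxels to tally.", class = "bonecal_invalid_input")
  }
  nb <- n_bins(binning)
  counts <- tabulate(idx, nbins = nb)
  tibble::tibble(
    bin = seq_len(nb),
    hu_middle = binning$middles,
    n = counts,
    fraction = counts / sum(counts)
  )
}

#' World-frame coordinates of voxel centroids
#'
#' Internal helper: centroid of voxel (i,j,k) in the world frame is
#' `origin + axes %*% (spacing * (ijk - 0.5))`.
#' @noRd
voxel_centroids <- function(grid, which_idx = NULL) {
  d <- dim(grid$values)
  if (is.null(which_idx)) which_idx <- seq_len(prod(d))
  ijk <- arrayInd(which_idx, d)
  local <- (ijk - 0.5) * grid$spacing
  sweep(local %*% t(grid$axes), 2, grid$origin, `+`)
}
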