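#' Measured sample geometry for three-point bending
#'
#' Physical dimensions of a cuboidal bone sample and the span between the
#' bending supports. The frame convention throughout the package is
#' x = length (L), y = height (A, the load direction), z = thickness (B).
#'
#' @param height Height A, mm (the dimension bent about).
#' @param thickness Thickness B, mm.
#' @param length Length L, mm.
#' @param support_spacing Distance between the two lower supports, mm.
#' @return An object of class `sample_geometry`.
#' @examples
#' sample_geometry(height = 11.58, thickness = 7.39, length = 68.14)
#' @export
sample_geometry <- function(height, thickness, length, support_spacing = 46) {
  vals <- c(height = height, thickness = thickness, length = length,
            support_spacing = support_spacing)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("All geometry dimensions must be positive.",
                 class = "bonecal_invalid_input")
  }
  if (support_spacing >= length) {
    rlang::abort("`support_spacing` must be smaller than the sample length.",
                 class = "bonecal_invalid_input")
  }
  structure(list(height = height, thickness = thickness, length = length,
                 support_spacing = support_spacing),
            class = "sample_geometry")
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat(sprintf("<sample_geometry> L %g x A %g x B %g mm, support span %g mm\n",
              x$length, x$height, x$thickness, x$support_spacing))
  invisible(x)
}

#' Labelled element midpoints of a voxel model
#'
#' Generates one point per unmasked voxel, at the voxel centroid in the
#' world frame, carrying the voxel's density-bin label. These temporary
#' midpoints are the carrier of the remeshing step: they survive the change
#' of coordinate frame where the element grid itself cannot.
#'
#' @param grid A [voxel_grid()].
#' @param assignment The matching `bin_assignment` from [bin_voxels()].
#' @return A tibble with columns `x`, `y`, `z` (mm, world frame) and `bin`.
#' @export
element_midpoints <- function(grid, assignment) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(assignment, "bin_assignment"))
  if (!identical(dim(grid$values), dim(unclass(assignment)))) {
    rlang::abort("Grid and assignment have different shapes.",
                 class = "bonecal_invalid_input")
  }
  keep <- which(!is.na(unclass(assignment)))
  pts <- voxel_centroids(grid, keep)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 bin = as.integer(unclass(assignment)[keep]))
}

#' Estimate the rigid transform aligning a sample with its faces
#'
#' Voxel grids inherit the scanner's coordinate frame, whose axes generally
#' do not coincide with the faces of the cuboidal sample. This estimates the
#' proper rigid transform (rotation + translation) that carries the midpoint
#' cloud into the sample frame: principal axes of the unlabelled point cloud
#' give the box orientation (for a uniformly sampled cuboid these are the
#' face normals and minimise the axis-aligned bounding box), axes are ordered
#' so the extents sort as L >= A >= B (x = length, y = height, z =
#' thickness), and the translation moves the minimum corner to the origin.
#'
#' @param points A data frame with columns `x`, `y`, `z` (and optionally
#'   `bin`), as returned by [element_midpoints()].
#' @param spacing Source voxel spacing, mm. Midpoints sit half a voxel
#'   inside the physical sample faces, so the translation places the
#'   minimum point at `spacing/2`, not at 0, making the physical box start
#'   at the origin. When `NULL` the spacing is estimated from the point
#'   density as `(bounding-box volume / n)^(1/3)`.
#' @return A `rigid_transform`: list with `rotation` (3x3, det +1) and
#'   `translation` (length 3); the aligned cloud is
#'   `rotation %*% p + translation`.
#' @export
estimate_alignment <- function(points, spacing = NULL) {
  p <- as.matrix(points[, c("x", "y", "z")])
  if (nrow(p) < 3) {
    rlang::abort("Need at least 3 points to estimate alignment.",
                 class = "bonecal_invalid_input")
  }
  ctr <- colMeans(p)
  cv <- stats::cov(p)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] <= 1e-10 * max(eg$values[1], 1e-300)) {
    rlang::abort("Degenerate (collinear or planar) point cloud.",
                 class = "bonecal_degenerate_input")
  }
  # Columns of V: box axes, eigenvalue order already gives extents L >= A >= B.
  v <- eg$vectors
  if (det(v) < 0) v[, 3] <- -v[, 3]
  rot <- t(v)
  aligned <- p %*% t(rot)
  ext <- apply(aligned, 2, max) - apply(aligned, 2, min)
  if (is.null(spacing)) spacing <- (prod(ext) / nrow(p))^(1 / 3)
  trans <- spacing / 2 - apply(aligned, 2, min)
  structure(list(rotation = rot, translation = as.numeric(trans)),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return A `rigid_transform` that leaves points unchanged.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A `rigid_transform`.
#' @param points Data frame or matrix with columns/cols `x`, `y`, `z`.
#' @return A matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")]) else as.matrix(points)
  sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation angle %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rebuild an aligned hexahedral model from labelled midpoints
#'
#' The midpoint remeshing step: a new axis-aligned grid of cubic elements is
#' generated over the measured sample box (x = length, y = height,
#' z = thickness), and each new element inherits the density bin of the
#' nearest transformed midpoint. Elements whose nearest midpoint lies
#' farther than one element diagonal fall back to the lowest density bin,
#' the conventional sink for out-of-range material.
#'
#' The grid has `ceiling(dim / element_size)` elements per axis, so the
#' meshed box reproduces each measured dimension to within one element.
#'
#' @param points Labelled midpoints (tibble with `x`, `y`, `z`, `bin`).
#' @param transform A `rigid_transform` into the sample frame, usually from
#'   [estimate_alignment()]; pass [identity_transform()] for aligned input.
#' @param geometry A [sample_geometry()] with the measured dimensions.
#' @param element_size New cubic element edge, mm.
#' @param binning The [hu_binning()] the labels refer to.
#' @return A `binned_hex_model`: list with `bin` (3-D integer array, dims
#'   nx x ny x nz), `element_size`, `geometry`, `binning`.
#' @export
rebuild_mesh <- function(points, transform, geometry, element_size = 0.3,
                         binning = hu_binning()) {
  stopifnot(inherits(geometry, "sample_geometry"), inherits(binning, "hu_binning"))
  if (nrow(points) == 0) {
    rlang::abort("Empty midpoint cloud.", class = "bonecal_invalid_input")
  }
  if (!is.numeric(element_size) || element_size <= 0) {
    rlang::abort("`element_size` must be positive.", class = "bonecal_invalid_input")
  }
  p <- apply_transform(transform, points)
  dims <- c(geometry$length, geometry$height, geometry$thickness)
  shape <- pmax(1L, as.integer(ceiling(dims / element_size - 1e-9)))

  # Element centres in the sample frame (x fastest, matching array order).
  cx <- (seq_len(shape[1]) - 0.5) * element_size
  cy <- (seq_len(shape[2]) - 0.5) * element_size
  cz <- (seq_len(shape[3]) - 0.5) * element_size
  grid_pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))

  # Nearest labelled midpoint per element, searched within one element
  # diagonal via a uniform cell list: with cell size >= the search radius,
  # every point within radius of a centre lies in its 3x3x3 neighbourhood.
  diag_len <- element_size * sqrt(3)
  cell <- diag_len * (1 + 1e-9)
  pc <- floor(p / cell)
  lo <- pmin(apply(pc, 2, min), floor(apply(grid_pts, 2, min) / cell)) - 1
  kdim <- pmax(apply(pc, 2, max), ceiling(apply(grid_pts, 2, max) / cell)) - lo + 3
  lin_key <- function(k) as.integer((k[, 1] - lo[1]) + kdim[1] *
                                      ((k[, 2] - lo[2]) + kdim[2] * (k[, 3] - lo[3])))
  pkey <- lin_key(pc)
  groups <- split(seq_len(nrow(p)), pkey)
  gkey0 <- floor(grid_pts / cell)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off_key <- as.integer(offs[, 1] + kdim[1] * (offs[, 2] + kdim[2] * offs[, 3]))
  gkey <- lin_key(gkey0)

  bin_lab <- points$bin
  nb <- n_bins(binning)
  bins <- integer(nrow(grid_pts))
  for (e in seq_len(nrow(grid_pts))) {
    cand <- unlist(groups[as.character(gkey[e] + off_key)], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) {
      bins[e] <- 1L
      next
    }
    d2 <- (p[cand, 1] - grid_pts[e, 1])^2 + (p[cand, 2] - grid_pts[e, 2])^2 +
      (p[cand, 3] - grid_pts[e, 3])^2
    m <- min(d2)
    if (m > diag_len^2) {
      bins[e] <- 1L
    } else {
      # Ties broken towards the lowest bin index.
      bins[e] <- min(bin_lab[cand[d2 <= m + 1e-12]])
    }
  }
  bins[bins > nb] <- nb

  structure(list(
    bin = array(as.integer(bins), dim = shape),
    element_size = element_size,
    geometry = geometry,
    binning = binning
  ), class = "binned_hex_model")
}

#' @export
print.binned_hex_model <- function(x, ...) {
  d <- dim(x$bin)
  cat(sprintf("<binned_hex_model> %d x %d x %d elements of %g mm (%d total)\n",
              d[1], d[2], d[3], x$element_size, prod(d)))
  print(x$geometry)
  invisible(x)
}

#' Build a hexahedral model directly from an aligned bin array
#'
#' Convenience constructor used when the bin field is already aligned with
#' the sample faces (synthetic models, identity remeshes, tests).
#'
#' @param bin 3-D integer array of bin indices (x = length, y = height,
#'   z = thickness order).
#' @param element_size Cubic element edge, mm.
#' @param geometry A [sample_geometry()]; defaults to the array's own box
#'   with a 46 mm support span (or 0.6 of the length if shorter).
#' @param binning A [hu_binning()].
#' @return A `binned_hex_model`.
#' @export
binned_hex_model <- function(bin, element_size, geometry = NULL,
                             binning = hu_binning()) {
  stopifnot(is.array(bin), length(dim(bin)) == 3)
  d <- dim(bin)
  if (is.null(geometry)) {
    L <- d[1] * element_size
    geometry <- sample_geometry(height = d[2] * element_size,
                                thickness = d[3] * element_size,
                                length = L,
                                support_spacing = min(46, 0.6 * L))
  }
  structure(list(bin = array(as.integer(bin), d), element_size = element_size,
                 geometry = geometry, binning = binning),
            class = "binned_hex_model")
}
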