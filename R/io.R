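#' Write a voxel grid to the raw-f32 + JSON sidecar format
#'
#' The grid format is a pair of files: `<name>.f32` holding the HU values
#' as little-endian IEEE float32 in column-major (x fastest) order, with
#' masked voxels stored as NaN, and `<name>.json` holding the metadata:
#' `shape`, `spacing_mm`, `origin_mm` and the row-major 3x3 `axes` matrix.
#'
#' @param grid A [voxel_grid()].
#' @param basename Output path without extension.
#' @return `basename`, invisibly.
#' @export
write_voxel_grid <- function(grid, basename) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- as.numeric(grid$values)
  v[is.na(v)] <- NaN
  con <- file(paste0(basename, ".f32"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = 4, endian = "little")
  meta <- list(
    shape = dim(grid$values),
    spacing_mm = grid$spacing,
    origin_mm = grid$origin,
    axes = as.vector(t(grid$axes))
  )
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(basename)
}

#' Read a voxel grid from the raw-f32 + JSON sidecar format
#'
#' @param basename Path without extension (or the path of either file).
#' @return A [voxel_grid()]; NaN values are restored as `NA` (masked).
#' @export
read_voxel_grid <- function(basename) {
  basename <- sub("\\.(f32|json)$", "", basename)
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(paste0(basename, ".f32"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = 4, endian = "little")
  if (length(v) != n) {
    rlang::abort("Raw f32 payload does not match the sidecar shape.",
                 class = "bonecal_invalid_input")
  }
  v[is.nan(v)] <- NA_real_
  voxel_grid(array(v, dim = shape),
             spacing = meta$spacing_mm,
             origin = meta$origin_mm,
             axes = matrix(meta$axes, 3, 3, byrow = TRUE))
}
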