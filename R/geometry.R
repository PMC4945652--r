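#' Discretize the modeled tissue volume into source cubes
#'
#' Builds a regular cuboid tiling of a rectangular tissue volume. The
#' intra-laminar footprint is square (the y-axis mirrors the x-axis), so the
#' volume spans \code{x_extent} along both x and y and \code{z_extent} across
#' depth. The coordinate convention places the electrode plane at z = 0 with
#' +z pointing toward the pial surface: the tissue occupies
#' z in [-(z_extent - grid_depth), +grid_depth].
#'
#' Cube centers are ordered x-fastest, then y, then z with the most
#' superficial plane first and the deepest plane last. Centers are not
#' materialized by the constructor (the default study volume has millions of
#' cubes); use [cube_centers()] when coordinates are needed.
#'
#' @param x_extent Intra-laminar side length of the volume (mm).
#' @param z_extent Inter-laminar (depth) extent of the volume (mm).
#' @param nx Number of cubes along x (and y).
#' @param nz Number of cubes across depth.
#' @param grid_depth Distance from the tissue top to the electrode plane (mm).
#' @return An object of class \code{"tissue_grid"}.
#' @examples
#' tg <- make_tissue_grid(11.6, 3.5, 204, 61, 1.15)
#' tg$K  # 2538576 source cubes
#' @export
make_tissue_grid <- function(x_extent = 11.6, z_extent = 3.5, nx = 204,
                             nz = 61, grid_depth = 1.15) {
  stopifnot(is.numeric(x_extent), is.numeric(z_extent),
            length(x_extent) == 1, length(z_extent) == 1)
  if (x_extent <= 0 || z_extent <= 0)
    stop("tissue extents must be positive")
  if (nx < 1 || nz < 1 || nx != round(nx) || nz != round(nz))
    stop("cube counts must be positive integers")
  if (grid_depth < 0 || grid_depth > z_extent)
    stop("grid_depth must lie within [0, z_extent]")
  dx <- x_extent / nx
  dz <- z_extent / nz
  # axis center coordinates; z descends from the pial side so the deepest
  # plane comes last
  xc <- -x_extent / 2 + dx * (seq_len(nx) - 0.5)
  zc <- grid_depth - dz * (seq_len(nz) - 0.5)
  structure(list(
    x_extent = x_extent, y_extent = x_extent, z_extent = z_extent,
    nx = as.integer(nx), ny = as.integer(nx), nz = as.integer(nz),
    grid_depth = grid_depth,
    cube_dims = c(dx, dx, dz),
    xc = xc, yc = xc, zc = zc,
    K = as.integer(nx) * as.integer(nx) * as.integer(nz)
  ), class = "tissue_grid")
}

#' Cube center coordinates of a tissue grid
#'
#' @param tissue A [make_tissue_grid()] object.
#' @param idx Optional integer vector of cube indices (x-fastest, then y,
#'   then z); defaults to all cubes.
#' @return A numeric matrix with columns x, y, z (mm), one row per cube.
#' @export
cube_centers <- function(tissue, idx = NULL) {
  stopifnot(inherits(tissue, "tissue_grid"))
  nx <- tissue$nx; ny <- tissue$ny
  if (is.null(idx)) idx <- seq_len(tissue$K)
  i0 <- idx - 1L
  ix <- i0 %% nx
  iy <- (i0 %/% nx) %% ny
  iz <- i0 %/% (nx * ny)
  cbind(x = tissue$xc[ix + 1L], y = tissue$yc[iy + 1L], z = tissue$zc[iz + 1L])
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("Tissue grid:", x$nx, "x", x$ny, "x", x$nz, "cubes (K =", x$K, ")\n")
  cat(sprintf("  extent %.3g x %.3g x %.3g mm, cube %.4g x %.4g x %.4g mm\n",
              x$x_extent, x$y_extent, x$z_extent,
              x$cube_dims[1], x$cube_dims[2], x$cube_dims[3]))
  cat(sprintf("  depth range [%.3g, %.3g] mm (electrode plane at z = 0)\n",
              -(x$z_extent - x$grid_depth), x$grid_depth))
  invisible(x)
}

#' Planar electrode grid at the electrode plane
#'
#' Positions form a regular \code{n_rows} x \code{n_cols} grid with the given
#' pitch, centered on the intra-laminar origin, all at z = 0. Electrodes are
#' ordered column-fastest (x varies fastest), matching the row-major layout
#' used by the phase-pattern matrices.
#'
#' @param n_rows,n_cols Channel counts along y and x.
#' @param pitch Inter-electrode spacing (mm).
#' @return An object of class \code{"electrode_array"} with fields
#'   \code{positions} (N x 3 matrix, mm), \code{n_rows}, \code{n_cols},
#'   \code{pitch}.
#' @examples
#' ea <- make_electrode_grid(10, 10, 0.4)  # Utah-style array, 3.6 mm on a side
#' @export
make_electrode_grid <- function(n_rows = 10, n_cols = 10, pitch = 0.4) {
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) ||
      n_cols != round(n_cols))
    stop("channel counts must be positive integers")
  if (pitch <= 0) stop("pitch must be positive")
  xs <- (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  ys <- (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  pos <- cbind(x = rep(xs, times = n_rows),
               y = rep(ys, each = n_cols),
               z = 0)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pitch = pitch, positions = pos, N = nrow(pos)
  ), class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat("Electrode array:", x$n_rows, "x", x$n_cols, "channels, pitch",
      x$pitch, "mm\n")
  cat(sprintf("  extent %.3g x %.3g mm at z = 0\n",
              (x$n_cols - 1) * x$pitch, (x$n_rows - 1) * x$pitch))
  invisible(x)
}
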