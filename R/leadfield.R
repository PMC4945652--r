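#' Potential of a constant-CSD cuboid source
#'
#' Exact potential generated at arbitrary field points by a rectangular box
#' carrying unit current source density, in an infinite homogeneous isotropic
#' medium:
#' \deqn{V(p) = \frac{1}{4\pi\sigma} \iiint_{box} \frac{dV'}{|p - r'|}.}
#' The triple integral is evaluated with the analytic corner-sum primitive of
#' \eqn{1/r} (log/arctan terms); field points inside or on the box are handled
#' by splitting the box at the field point, so the result is finite
#' everywhere.
#'
#' @param box_center Numeric length-3, box center (mm).
#' @param box_dims Numeric length-3, box edge lengths (mm), all positive.
#' @param points Field point(s): length-3 vector or n x 3 matrix (mm).
#' @param sigma Conductivity (S/m), positive.
#' @return Numeric vector of potentials per unit CSD, one per field point.
#' @examples
#' # far-field limit: cube acts as a point source of strength volume
#' box_potential_unit_csd(c(0, 0, 0), c(0.05, 0.05, 0.05), c(10, 0, 0), 1)
#' 0.05^3 / (4 * pi * 10)
#' @export
box_potential_unit_csd <- function(box_center, box_dims, points, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  if (any(box_dims <= 0)) stop("box_dims must be positive")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  .box_potential_cpp(as.numeric(box_center), as.numeric(box_dims),
                     points, sigma)
}

#' Build the LFP leadfield matrix
#'
#' Computes the N x K matrix G mapping a discretized CSD vector (one value
#' per source cube, assumed constant within each cube) to the potentials at
#' the N electrodes: V = G C. Entry (n, k) is the exact cuboid-source
#' potential of cube k at electrode n per unit CSD.
#'
#' The full matrix takes 8 N K bytes; for the default study volume prefer
#' [collapse_leadfield()], which contracts over depth against a laminar
#' profile without materializing G.
#'
#' @param tissue A [make_tissue_grid()] object.
#' @param electrodes A [make_electrode_grid()] object.
#' @param sigma Conductivity (S/m).
#' @return An object of class \code{"leadfield"} holding \code{matrix}
#'   (N x K), \code{sigma}, and the generating geometry.
#' @export
build_leadfield <- function(tissue, electrodes, sigma = 1) {
  stopifnot(inherits(tissue, "tissue_grid"),
            inherits(electrodes, "electrode_array"))
  if (sigma <= 0) stop("sigma must be positive")
  bytes <- 8 * electrodes$N * tissue$K
  if (bytes > 4e9)
    stop("full leadfield would need ", round(bytes / 1e9, 1),
         " GB; reduce the grid resolution explicitly or use ",
         "collapse_leadfield()")
  blocks <- lapply(tissue$zc, function(z)
    .leadfield_plane_cpp(tissue$xc, tissue$yc, z, tissue$cube_dims,
                         electrodes$positions, sigma))
  structure(list(
    matrix = do.call(cbind, blocks),
    sigma = sigma, tissue = tissue, electrodes = electrodes
  ), class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat("LFP leadfield:", nrow(x$matrix), "electrodes x", ncol(x$matrix),
      "source cubes, sigma =", x$sigma, "S/m\n")
  invisible(x)
}

#' Contract the leadfield over depth against a laminar CSD profile
#'
#' For separable CSDs \eqn{C(x,y,z) = C_v(z) C_h(x,y)} the forward map
#' reduces to an N x (nx ny) operator
#' \deqn{H[n, m] = \sum_z C_v(z) G[n, (m, z)],}
#' after which the LFP phasors for any intra-laminar field are
#' \code{H \%*\% ch}. This avoids materializing G (the depth planes are
#' generated and accumulated one at a time) and makes Monte-Carlo studies
#' over intra-laminar realizations cheap.
#'
#' @param tissue A [make_tissue_grid()] object.
#' @param electrodes A [make_electrode_grid()] object.
#' @param cv Complex (or numeric) laminar profile sampled at the grid's
#'   depth-plane centers \code{tissue$zc} (length nz).
#' @param sigma Conductivity (S/m).
#' @return Complex matrix N x (nx * ny), columns ordered x-fastest then y.
#' @export
collapse_leadfield <- function(tissue, electrodes, cv, sigma = 1) {
  stopifnot(inherits(tissue, "tissue_grid"),
            inherits(electrodes, "electrode_array"))
  if (length(cv) != tissue$nz)
    stop("cv must have one value per depth plane (nz = ", tissue$nz, ")")
  if (sigma <= 0) stop("sigma must be positive")
  H <- matrix(0 + 0i, electrodes$N, tissue$nx * tissue$ny)
  for (iz in seq_len(tissue$nz)) {
    if (cv[iz] == 0) next
    B <- .leadfield_plane_cpp(tissue$xc, tissue$yc, tissue$zc[iz],
                              tissue$cube_dims, electrodes$positions, sigma)
    H <- H + cv[iz] * B
  }
  H
}

#' Forward-map a CSD phasor field to LFP phasors
#'
#' Complex matrix-vector product V = G C. Volume conduction is linear, so the
#' map is exactly linear over complex CSD vectors.
#'
#' @param leadfield A [build_leadfield()] object (or a bare N x K matrix).
#' @param csd Complex vector of length K (CSD phasor per cube).
#' @return Complex vector of LFP phasors, one per electrode.
#' @export
forward_lfp <- function(leadfield, csd) {
  G <- if (inherits(leadfield, "leadfield")) leadfield$matrix else leadfield
  if (length(csd) != ncol(G))
    stop("csd length ", length(csd), " does not match the ", ncol(G),
         " source cubes of the leadfield")
  drop(G %*% csd)
}

#' Electrode-averaged leadfield sensitivity
#'
#' Averages the leadfield over electrodes (rows), giving one sensitivity
#' value per source cube. Reshape onto the tissue grid (x-fastest, then y,
#' then z) to export cross-sections.
#'
#' @param leadfield A [build_leadfield()] object.
#' @return Numeric vector of length K.
#' @export
sensitivity_map <- function(leadfield) {
  stopifnot(inherits(leadfield, "leadfield"))
  colMeans(leadfield$matrix)
}

#' Persist and reload a leadfield with its geometry metadata
#'
#' The container stores the matrix together with the full generating
#' geometry (extents, counts, pitch, depth, sigma, cube ordering convention)
#' and the package version; [read_leadfield()] validates the metadata before
#' returning the object.
#'
#' @param leadfield A [build_leadfield()] object.
#' @param path File path to write to / read from.
#' @return \code{read_leadfield} returns the validated leadfield object.
#' @export
write_leadfield <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "leadfield"))
  payload <- list(
    format = "lfpcsd-leadfield", version = 1L,
    package_version = as.character(utils::packageVersion("lfpcsd")),
    ordering = "x-fastest, then y, then z (deepest plane last)",
    tissue = unclass(leadfield$tissue),
    electrodes = unclass(leadfield$electrodes),
    sigma = leadfield$sigma,
    matrix = leadfield$matrix
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "lfpcsd-leadfield"))
    stop("not an lfpcsd leadfield container")
  tissue <- structure(payload$tissue, class = "tissue_grid")
  electrodes <- structure(payload$electrodes, class = "electrode_array")
  if (!identical(dim(payload$matrix),
                 c(electrodes$N, tissue$K)))
    stop("leadfield matrix dimensions do not match stored geometry")
  if (!is.numeric(payload$sigma) || payload$sigma <= 0)
    stop("stored sigma is invalid")
  structure(list(matrix = payload$matrix, sigma = payload$sigma,
                 tissue = tissue, electrodes = electrodes),
            class = "leadfield")
}

# per-session cache of depth-collapsed leadfields, keyed by geometry + cv hash
.lfp_cache <- new.env(parent = emptyenv())

cached_collapse <- function(tissue, electrodes, cv, sigma = 1,
                            use_cache = TRUE) {
  if (!use_cache)
    return(collapse_leadfield(tissue, electrodes, cv, sigma))
  key <- paste(
    format(c(tissue$x_extent, tissue$z_extent, tissue$grid_depth,
             electrodes$pitch, sigma), digits = 15),
    tissue$nx, tissue$nz, electrodes$n_rows, electrodes$n_cols,
    paste(format(cv, digits = 15), collapse = ","),
    collapse = "|")
  key <- paste0("k", substr(digest_key(key), 1, 48))
  if (is.null(.lfp_cache[[key]]))
    .lfp_cache[[key]] <- collapse_leadfield(tissue, electrodes, cv, sigma)
  .lfp_cache[[key]]
}

# small string hash (no external deps): sum of char codes with rolling mult
digest_key <- function(s) {
  v <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (i in seq_along(v)) {
    h1 <- (h1 * 31 + v[i]) %% 2147483647
    h2 <- (h2 * 131 + v[i]) %% 2147483629
  }
  paste0(h1, "x", h2)
}

#' Empty the in-session leadfield cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_leadfield_cache <- function() {
  n <- length(ls(.lfp_cache))
  rm(list = ls(.lfp_cache), envir = .lfp_cache)
  invisible(n)
}
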