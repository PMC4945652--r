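#' Parameters of a dipolar laminar generator
#'
#' A generator is a sink-source pair across cortical depth: two Gaussian
#' poles of opposite sign separated by the generator length L, with the
#' superficial pole (larger z, toward the pia) at \code{z0 + L/2} carrying
#' amplitude A and the deep pole at \code{z0 - L/2} carrying amplitude
#' \code{-(1 - epsilon) A}. \code{epsilon = 0} gives a balanced (current
#' conserving) dipole, \code{epsilon = 1} a monopole. Depths below the
#' electrode plane are negative z, so "a generator at depth 0.5 mm" has
#' \code{z0 = -0.5}.
#'
#' @param A Amplitude (dimensionless; phase metrics are scale invariant).
#' @param L Generator length (mm).
#' @param z0 Generator center, in electrode-plane coordinates (mm).
#' @param sigma_v Pole width (mm); defaults to L/3 so the poles partially
#'   overlap.
#' @param epsilon Imbalance in [0, 1].
#' @param phase Temporal phase offset of this generator (rad).
#' @return A list of class \code{"generator_params"}.
#' @export
generator_params <- function(A = 1, L = 1, z0 = -0.5, sigma_v = L / 3,
                             epsilon = 0, phase = 0) {
  if (L <= 0) stop("generator length L must be positive")
  if (sigma_v <= 0) stop("pole width sigma_v must be positive")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  structure(list(A = A, L = L, z0 = z0, sigma_v = sigma_v,
                 epsilon = epsilon, phase = phase),
            class = "generator_params")
}

#' Laminar profile of a single generator
#'
#' \deqn{C_v(z) = A e^{-(z - (z_0 + L/2))^2 / 2\sigma_v^2}
#'             - (1 - \epsilon) A e^{-(z - (z_0 - L/2))^2 / 2\sigma_v^2}.}
#'
#' @param z_values Depth coordinates (mm) at which to evaluate.
#' @param params A [generator_params()] object.
#' @return Real vector, one value per depth.
#' @export
generator_profile <- function(z_values, params) {
  stopifnot(inherits(params, "generator_params"))
  up <- params$z0 + params$L / 2
  lo <- params$z0 - params$L / 2
  params$A * exp(-(z_values - up)^2 / (2 * params$sigma_v^2)) -
    (1 - params$epsilon) * params$A *
      exp(-(z_values - lo)^2 / (2 * params$sigma_v^2))
}

#' Laminar profile of a superposition of generators
#'
#' Sums the profiles of several generators, each rotated by its own temporal
#' phase offset \eqn{e^{i\,\mathrm{phase}}}; the result is complex so that
#' inter-laminar phase-differences can be represented.
#'
#' @param generators A list of [generator_params()] objects (at least one).
#' @param z_values Depth coordinates (mm).
#' @return Complex vector, one value per depth.
#' @export
laminar_profile <- function(generators, z_values) {
  if (length(generators) == 0) stop("need at least one generator")
  if (inherits(generators, "generator_params")) generators <- list(generators)
  out <- complex(length(z_values))
  for (g in generators)
    out <- out + exp(1i * g$phase) * generator_profile(z_values, g)
  out
}

#' Constant laminar profile
#'
#' A depth-independent profile (all ones); used to probe the surface
#' Laplacian montage, whose derivation assumes the CSD does not vary across
#' depth.
#'
#' @param z_values Depth coordinates (mm).
#' @return Real vector of ones, one per depth.
#' @export
constant_laminar_profile <- function(z_values) {
  rep(1, length(z_values))
}

# ---- intra-laminar wave models -------------------------------------------

#' Intra-laminar wave models
#'
#' Constructors for the intra-laminar CSD component \eqn{C_h(x, y)} as
#' evaluable model objects. `ch_isotropic` is a radially propagating,
#' Gaussian-damped wave
#' \deqn{C_h = e^{i\varphi_0} e^{-i 2\pi d/\lambda} e^{-d^2 / 2\sigma_h^2}}
#' with d the distance to the wave center and wavelength
#' \eqn{\lambda = v/f} (propagation speed over temporal frequency; an
#' infinite speed gives a spatially uniform phase). `ch_plane` is a
#' unit-amplitude plane wave
#' \eqn{C_h = e^{i\varphi_0} e^{i(k_x x + k_y y)}} with
#' \eqn{|k| = 2\pi/\lambda}. `ch_superposition` sums isotropic waves.
#' `ch_uniform` is the constant field 1.
#'
#' Speeds are in m/s, frequencies in Hz, lengths in mm; the wavelength in mm
#' is \code{1000 * v / f}.
#'
#' @param phi0 Initial phase (rad).
#' @param v Propagation speed (m/s).
#' @param f Temporal frequency (Hz).
#' @param wavelength Wavelength (mm); overrides \code{v}/\code{f} if given.
#' @param sigma_h Intra-laminar width (mm); defaults to wavelength/3.
#' @param center Length-2 wave center (mm), isotropic waves only.
#' @param direction Length-2 propagation direction, plane waves only
#'   (normalized internally).
#' @param waves List of \code{ch_isotropic} models to superpose.
#' @return An object of class \code{"ch_model"}: call [eval_ch()] to obtain
#'   complex field values at points.
#' @name ch_models
NULL

wavelength_mm <- function(v, f, wavelength = NULL) {
  if (!is.null(wavelength)) return(wavelength)
  if (is.infinite(v)) return(Inf)
  if (f <= 0 || v <= 0) stop("need positive speed and frequency")
  1000 * v / f
}

#' @rdname ch_models
#' @export
ch_isotropic <- function(phi0 = 0, v = 0.1, f = 10, wavelength = NULL,
                         sigma_h = NULL, center = c(0, 0)) {
  lam <- wavelength_mm(v, f, wavelength)
  if (is.null(sigma_h)) {
    if (is.infinite(lam))
      stop("sigma_h must be given explicitly for an infinite wavelength")
    sigma_h <- lam / 3
  }
  if (sigma_h <= 0) stop("sigma_h must be positive")
  structure(list(kind = "isotropic", phi0 = phi0, wavelength = lam,
                 sigma_h = sigma_h, center = center),
            class = "ch_model")
}

#' @rdname ch_models
#' @export
ch_plane <- function(phi0 = 0, v = 0.2, f = 10, wavelength = NULL,
                     direction = c(1, 0)) {
  lam <- wavelength_mm(v, f, wavelength)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  k <- if (is.infinite(lam)) c(0, 0) else (2 * pi / lam) * direction / nrm
  structure(list(kind = "plane", phi0 = phi0, wavelength = lam, k = k),
            class = "ch_model")
}

#' @rdname ch_models
#' @export
ch_superposition <- function(waves) {
  if (length(waves) == 0) stop("need at least one wave")
  if (!all(vapply(waves, function(w)
    inherits(w, "ch_model") && w$kind == "isotropic", logical(1))))
    stop("superpositions are built from isotropic waves")
  structure(list(kind = "superposition", waves = waves), class = "ch_model")
}

#' @rdname ch_models
#' @export
ch_uniform <- function(phi0 = 0) {
  structure(list(kind = "uniform", phi0 = phi0), class = "ch_model")
}

#' Evaluate an intra-laminar model at points
#'
#' @param model A \code{ch_model} object.
#' @param points_xy Length-2 vector or n x 2 matrix of intra-laminar
#'   coordinates (mm); n x 3 matrices are accepted (z is ignored).
#' @return Complex vector of field values.
#' @export
eval_ch <- function(model, points_xy) {
  stopifnot(inherits(model, "ch_model"))
  if (is.null(dim(points_xy)))
    points_xy <- matrix(points_xy, ncol = 2, byrow = TRUE)
  x <- points_xy[, 1]; y <- points_xy[, 2]
  switch(model$kind,
    uniform = rep(exp(1i * model$phi0), length(x)),
    plane = exp(1i * (model$phi0 + model$k[1] * x + model$k[2] * y)),
    isotropic = {
      d <- sqrt((x - model$center[1])^2 + (y - model$center[2])^2)
      ph <- if (is.infinite(model$wavelength)) 0 else
        -2 * pi * d / model$wavelength
      exp(1i * (model$phi0 + ph)) * exp(-d^2 / (2 * model$sigma_h^2))
    },
    superposition = {
      out <- complex(length(x))
      for (w in model$waves) out <- out + eval_ch(w, points_xy)
      out
    },
    stop("unknown ch model kind"))
}

#' Single isotropic or plane wave evaluated at points
#'
#' Convenience wrappers around [ch_isotropic()] / [ch_plane()] plus
#' [eval_ch()].
#'
#' @param points_xy Points (mm), length-2 vector or n x 2 matrix.
#' @param params A \code{ch_model} of the matching kind.
#' @return Complex vector of field values.
#' @export
isotropic_wave <- function(points_xy, params) {
  stopifnot(inherits(params, "ch_model"), params$kind == "isotropic")
  eval_ch(params, points_xy)
}

#' @rdname isotropic_wave
#' @export
plane_wave <- function(points_xy, params) {
  stopifnot(inherits(params, "ch_model"), params$kind == "plane")
  eval_ch(params, points_xy)
}

#' Draw a random superposition of isotropic waves
#'
#' Superposes \code{n_waves} isotropic waves with centers drawn uniformly
#' over a rectangular region and initial phases uniform on [0, 2 pi). All
#' waves share speed, frequency (hence wavelength lambda = v/f) and width
#' sigma_h = lambda/3. A seed is mandatory: stochastic fields must be
#' reproducible.
#'
#' @param n_waves Number of waves.
#' @param f Temporal frequency (Hz).
#' @param v Propagation speed (m/s).
#' @param region Length-4 vector (xmin, xmax, ymin, ymax) in mm; defaults to
#'   the full default tissue footprint.
#' @param seed Integer seed (required).
#' @return A \code{ch_model} superposition.
#' @export
draw_wave_superposition <- function(n_waves = 100, f = 10, v = 0.1,
                                    region = c(-5.8, 5.8, -5.8, 5.8),
                                    seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for random wave superpositions")
  if (n_waves < 1) stop("need at least one wave")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cx <- runif(n_waves, region[1], region[2])
  cy <- runif(n_waves, region[3], region[4])
  phi0 <- runif(n_waves, 0, 2 * pi)
  ch_superposition(lapply(seq_len(n_waves), function(i)
    ch_isotropic(phi0 = phi0[i], v = v, f = f, center = c(cx[i], cy[i]))))
}

#' @rdname draw_wave_superposition
#' @param points_xy Points (mm) at which to evaluate the drawn field.
#' @export
superpose_isotropic_waves <- function(points_xy, n_waves = 100, f = 10,
                                      v = 0.1,
                                      region = c(-5.8, 5.8, -5.8, 5.8),
                                      seed) {
  eval_ch(draw_wave_superposition(n_waves, f, v, region, seed), points_xy)
}

#' Assemble a separable CSD phasor field on the tissue grid
#'
#' Outer product of a laminar profile (one value per depth plane) and an
#' intra-laminar field (one value per (x, y) node):
#' \code{C[k] = cv[z_k] * ch[xy_k]}, in the grid's cube ordering (x-fastest,
#' then y, then z).
#'
#' @param cv Complex vector of length nz.
#' @param ch Complex vector of length nx * ny (x-fastest), or a
#'   \code{ch_model} to be evaluated at the cube xy-centers.
#' @param tissue A [make_tissue_grid()] object.
#' @return Complex vector of length K.
#' @export
assemble_csd <- function(cv, ch, tissue) {
  stopifnot(inherits(tissue, "tissue_grid"))
  if (inherits(ch, "ch_model"))
    ch <- eval_ch(ch, grid_xy(tissue))
  if (length(cv) != tissue$nz)
    stop("cv length must equal nz = ", tissue$nz)
  if (length(ch) != tissue$nx * tissue$ny)
    stop("ch length must equal nx * ny = ", tissue$nx * tissue$ny)
  as.vector(outer(ch, cv))
}

#' Intra-laminar node coordinates of a tissue grid
#' @param tissue A [make_tissue_grid()] object.
#' @return (nx * ny) x 2 matrix of cube-center xy coordinates, x-fastest.
#' @export
grid_xy <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_grid"))
  cbind(x = rep(tissue$xc, times = tissue$ny),
        y = rep(tissue$yc, each = tissue$nx))
}

#' Restrict an intra-laminar CSD model to the electrode locations
#'
#' Evaluates the analytic intra-laminar model directly at the electrode
#' (x, y) positions on the electrode plane z = 0 (not a nearest-cube
#' lookup), scaled by the laminar profile's value at the plane. The result
#' is the CSD phasor the electrodes "sit in", used as the reference pattern
#' for LFP-CSD comparisons.
#'
#' @param ch A \code{ch_model}.
#' @param electrodes A [make_electrode_grid()] object (or any matrix of
#'   positions with x, y in the first two columns).
#' @param cv_at_plane Complex scalar: the laminar profile evaluated at z = 0
#'   (default 1). A negative value flips all phases by pi.
#' @return Complex vector, one value per electrode.
#' @export
restrict_to_electrodes <- function(ch, electrodes, cv_at_plane = 1) {
  pos <- if (inherits(electrodes, "electrode_array"))
    electrodes$positions else electrodes
  cv_at_plane * eval_ch(ch, pos[, 1:2, drop = FALSE])
}

#' Export a complex field as a plain table
#'
#' @param values Complex vector.
#' @param positions Matrix of coordinates (2 or 3 columns), one row per value.
#' @return data.frame with index, coordinates, re, im, amplitude, phase.
#' @export
field_to_table <- function(values, positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(values))
    stop("positions and values disagree in length")
  colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  data.frame(index = seq_along(values), positions,
             re = Re(values), im = Im(values),
             amplitude = Mod(values), phase = Arg(values))
}
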