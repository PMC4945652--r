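#' Electrode montages for complex LFP fields
#'
#' Re-referencing transforms applied to the phasor field recorded on a
#' rectangular electrode grid. All montages are linear operators; each
#' returns a \code{montage_result} holding the transformed complex values,
#' the positions of its output channels, and the output grid shape.
#'
#' \describe{
#'   \item{referential}{identity: potentials with respect to an ideal,
#'     infinitely distant reference.}
#'   \item{average-reference}{subtracts the channel-averaged potential; the
#'     output mean is exactly zero and the transform is idempotent.}
#'   \item{bipolar}{differences between neighboring electrodes along one
#'     axis; proportional to minus the electric-field component, i.e. to the
#'     extracellular current density in that direction. Output channels sit
#'     at the pair midpoints (one fewer along the chosen axis).}
#'   \item{Laplacian}{five-point discrete surface Laplacian scaled by
#'     \eqn{-\sigma'}, which by Poisson's equation estimates the
#'     intra-laminar CSD component at the plane when the laminar profile is
#'     depth-constant. Output restricted to interior electrodes (no
#'     extrapolating boundary stencils).}
#' }
#'
#' @param v Complex phasor vector, channel-ordered x-fastest (as returned by
#'   [forward_lfp()] for a [make_electrode_grid()]).
#' @param electrodes The [make_electrode_grid()] the field lives on.
#' @param axis Bipolar axis, "x" or "y".
#' @param sigma_prime Intra-laminar conductivity used by the Laplacian
#'   estimate (S/m); phases do not depend on its value.
#' @return A \code{montage_result}: list with \code{values} (complex),
#'   \code{positions} (M x 2 mm), \code{n_rows}, \code{n_cols},
#'   \code{spacing}, \code{montage}.
#' @name montages
NULL

montage_result <- function(values, positions, n_rows, n_cols, spacing,
                           montage) {
  structure(list(values = values, positions = positions,
                 n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 montage = montage),
            class = "montage_result")
}

#' @export
print.montage_result <- function(x, ...) {
  cat("Montage:", x$montage, "-", x$n_rows, "x", x$n_cols, "channels\n")
  invisible(x)
}

#' Phase pattern of a montaged field
#' @param x A \code{montage_result}.
#' @param f Frequency metadata (Hz).
#' @return A [phase_pattern()].
#' @export
montage_phase <- function(x, f = NA_real_) {
  stopifnot(inherits(x, "montage_result"))
  m <- matrix(x$values, x$n_rows, x$n_cols, byrow = TRUE)
  phase_of(m, f = f, spacing = x$spacing)
}

as_grid <- function(v, electrodes) {
  stopifnot(inherits(electrodes, "electrode_array"))
  if (length(v) != electrodes$N)
    stop("field length does not match the electrode count")
  matrix(v, electrodes$n_rows, electrodes$n_cols, byrow = TRUE)
}

#' @rdname montages
#' @export
apply_referential <- function(v, electrodes) {
  as_grid(v, electrodes)  # validates shape
  montage_result(v, electrodes$positions[, 1:2, drop = FALSE],
                 electrodes$n_rows, electrodes$n_cols, electrodes$pitch,
                 "referential")
}

#' @rdname montages
#' @export
apply_average_reference <- function(v, electrodes) {
  as_grid(v, electrodes)
  if (electrodes$N < 2) stop("average reference needs at least 2 channels")
  montage_result(v - mean(v), electrodes$positions[, 1:2, drop = FALSE],
                 electrodes$n_rows, electrodes$n_cols, electrodes$pitch,
                 "average-reference")
}

#' @rdname montages
#' @export
apply_bipolar <- function(v, electrodes, axis = c("x", "y")) {
  axis <- match.arg(axis)
  m <- as_grid(v, electrodes)
  p <- electrodes$pitch
  if (axis == "x") {
    if (ncol(m) < 2) stop("bipolar montage needs >= 2 channels along x")
    d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    xs <- (seq_len(ncol(m) - 1) - ncol(m) / 2) * p
    ys <- (seq_len(nrow(m)) - (nrow(m) + 1) / 2) * p
    nr <- nrow(m); nc <- ncol(m) - 1L
  } else {
    if (nrow(m) < 2) stop("bipolar montage needs >= 2 channels along y")
    d <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    xs <- (seq_len(ncol(m)) - (ncol(m) + 1) / 2) * p
    ys <- (seq_len(nrow(m) - 1) - nrow(m) / 2) * p
    nr <- nrow(m) - 1L; nc <- ncol(m)
  }
  pos <- cbind(x = rep(xs, times = nr), y = rep(ys, each = nc))
  montage_result(as.vector(t(d)), pos, nr, nc, p,
                 paste0("bipolar-", axis))
}

#' @rdname montages
#' @export
apply_laplacian <- function(v, electrodes, sigma_prime = 1) {
  m <- as_grid(v, electrodes)
  if (nrow(m) < 3 || ncol(m) < 3)
    stop("Laplacian montage needs at least a 3 x 3 grid")
  p <- electrodes$pitch
  ri <- 2:(nrow(m) - 1); ci <- 2:(ncol(m) - 1)
  lap <- (m[ri - 1, ci] + m[ri + 1, ci] + m[ri, ci - 1] + m[ri, ci + 1] -
            4 * m[ri, ci]) / p^2
  est <- -sigma_prime * lap
  xs <- (ci - (ncol(m) + 1) / 2) * p
  ys <- (ri - (nrow(m) + 1) / 2) * p
  pos <- cbind(x = rep(xs, times = length(ri)),
               y = rep(ys, each = length(ci)))
  montage_result(as.vector(t(est)), pos, length(ri), length(ci), p,
                 "laplacian")
}

#' Phase-coherence between a montaged LFP and the intra-laminar CSD
#'
#' Evaluates the analytic intra-laminar CSD model at the montage's own
#' output-channel positions (electrodes, pair midpoints, or interior
#' electrodes), takes phases on both sides, and returns the phase-coherence.
#'
#' @param montaged A \code{montage_result}.
#' @param ch A \code{ch_model} for the intra-laminar CSD component.
#' @param cv_at_plane Laminar profile value at the electrode plane (used to
#'   carry a possible sign flip of the CSD at z = 0).
#' @return Scalar coherence in [0, 1].
#' @export
coherence_vs_csd <- function(montaged, ch, cv_at_plane = 1) {
  stopifnot(inherits(montaged, "montage_result"))
  csd <- cv_at_plane * eval_ch(ch, montaged$positions)
  psi_m <- Arg(montaged$values)
  psi_c <- Arg(csd)
  ok <- Mod(montaged$values) > 0 & Mod(csd) > 0
  if (!any(ok)) stop("no valid channels for coherence")
  Mod(mean(exp(1i * (psi_m[ok] - psi_c[ok]))))
}
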