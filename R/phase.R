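#' Wrap angles into (-pi, pi]
#' @param theta Numeric vector of angles (rad).
#' @return Wrapped angles.
#' @export
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map the boundary -pi (from theta = odd multiples of pi) to +pi
  w[w == -pi] <- pi
  w
}

#' Phase-pattern of a phasor field on a channel grid
#'
#' Takes the argument of each complex value, wrapped to (-pi, pi], and
#' arranges it on the n_rows x n_cols channel grid. Channels with zero
#' amplitude carry no phase; they are flagged missing (NA) and excluded from
#' all metrics (their count is recorded in the \code{n_missing} attribute).
#'
#' @param phasors Complex vector, channel-ordered x-fastest (matching
#'   [make_electrode_grid()]), or an n_rows x n_cols complex matrix.
#' @param geometry An [make_electrode_grid()] object giving the grid shape
#'   and pitch; not needed if \code{phasors} is a matrix and \code{spacing}
#'   is given.
#' @param f Oscillation frequency (Hz), carried as metadata for speed
#'   conversion.
#' @param spacing Channel spacing (mm); defaults to the geometry pitch.
#' @return An object of class \code{"phase_pattern"}: a matrix of wrapped
#'   phases (rows = y, columns = x) with attributes \code{spacing} (mm) and
#'   \code{f} (Hz).
#' @export
phase_of <- function(phasors, geometry = NULL, f = NA_real_,
                     spacing = NULL) {
  if (is.matrix(phasors)) {
    m <- phasors
  } else {
    if (is.null(geometry))
      stop("geometry is required for vector input")
    stopifnot(inherits(geometry, "electrode_array"))
    if (length(phasors) != geometry$N)
      stop("phasor length does not match the electrode count")
    m <- matrix(phasors, geometry$n_rows, geometry$n_cols, byrow = TRUE)
  }
  if (is.null(spacing))
    spacing <- if (!is.null(geometry)) geometry$pitch else
      stop("spacing is required when no geometry is given")
  psi <- wrap_phase(Arg(m))
  psi[Mod(m) == 0] <- NA_real_
  phase_pattern(psi, spacing = spacing, f = f)
}

#' @rdname phase_of
#' @param psi Matrix of wrapped phases (rad).
#' @export
phase_pattern <- function(psi, spacing, f = NA_real_) {
  stopifnot(is.matrix(psi), spacing > 0)
  structure(psi, spacing = spacing, f = f,
            n_missing = sum(is.na(psi)), class = "phase_pattern")
}

#' @export
print.phase_pattern <- function(x, ...) {
  cat("Phase pattern:", nrow(x), "x", ncol(x), "channels, spacing",
      attr(x, "spacing"), "mm")
  if (is.finite(attr(x, "f"))) cat(", f =", attr(x, "f"), "Hz")
  if (attr(x, "n_missing") > 0)
    cat(" (", attr(x, "n_missing"), "missing)")
  cat("\n")
  invisible(x)
}

#' @export
plot.phase_pattern <- function(x, ...) {
  sp <- attr(x, "spacing")
  xs <- (seq_len(ncol(x)) - 1) * sp
  ys <- (seq_len(nrow(x)) - 1) * sp
  graphics::image(xs, ys, t(unclass(x)), zlim = c(-pi, pi),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", asp = 1, ...)
  invisible(x)
}

#' Kuramoto order parameter
#'
#' \eqn{r = |\langle e^{i\psi} \rangle|}, the modulus of the channel-averaged
#' unit phase vectors: 1 for perfectly aligned phases, 0 for fully dispersed
#' ones. Missing channels are excluded.
#'
#' @param psi A [phase_pattern()] (or any numeric vector/matrix of phases).
#' @return Scalar in [0, 1].
#' @export
kuramoto <- function(psi) {
  v <- as.numeric(psi)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no valid channels")
  Mod(mean(exp(1i * v)))
}

#' Spatial phase gradient by wrapped finite differences
#'
#' Approximates \eqn{\nabla\psi} on the channel grid. Every neighbor
#' difference is first wrapped into (-pi, pi] (local unwrapping, valid when
#' the spacing resolves the wavelength) and then divided by the spacing.
#' With the default central stencil, interior channels use central
#' differences and edge channels one-sided ones; \code{stencil = "forward"}
#' uses forward differences everywhere (last row/column one-sided backward).
#'
#' @param psi A [phase_pattern()].
#' @param stencil "central" (default) or "forward".
#' @return List with matrices \code{gx}, \code{gy} (rad/mm) of the same
#'   shape as the pattern.
#' @export
phase_gradient <- function(psi, stencil = c("central", "forward")) {
  stencil <- match.arg(stencil)
  stopifnot(inherits(psi, "phase_pattern"))
  if (nrow(psi) < 2 || ncol(psi) < 2)
    stop("phase gradient needs at least a 2 x 2 grid")
  h <- attr(psi, "spacing")
  m <- unclass(psi)
  diff_along <- function(m, h) {
    # m: matrix, differences along columns (x); returns same-shape matrix
    nc <- ncol(m)
    d <- wrap_phase(m[, -1, drop = FALSE] - m[, -nc, drop = FALSE]) / h
    if (stencil == "forward") {
      cbind(d, d[, nc - 1, drop = FALSE])
    } else {
      inner <- if (nc > 2)
        (d[, -1, drop = FALSE] + d[, -(nc - 1), drop = FALSE]) / 2
      else NULL
      cbind(d[, 1, drop = FALSE], inner, d[, nc - 1, drop = FALSE])
    }
  }
  gx <- diff_along(m, h)
  gy <- t(diff_along(t(m), h))
  list(gx = gx, gy = gy)
}

#' Average propagation speed from a phase-pattern
#'
#' \eqn{\bar v = 2\pi f / \langle \|\nabla\psi\| \rangle}: the
#' channel-averaged Euclidean norm of the spatial phase gradient is taken
#' first, then divided into the angular frequency (so steep-gradient
#' channels dominate the denominator). A vanishing mean gradient (a standing
#' or spatially uniform pattern) yields +Inf rather than an error. Result in
#' m/s (phases in rad, spacing in mm, f in Hz).
#'
#' @param psi A [phase_pattern()] with finite frequency metadata.
#' @param f Frequency (Hz); defaults to the pattern's metadata.
#' @param stencil Gradient stencil, see [phase_gradient()].
#' @return Scalar speed (m/s), possibly +Inf.
#' @export
average_speed <- function(psi, f = attr(psi, "f"),
                          stencil = c("central", "forward")) {
  if (!is.finite(f) || f <= 0) stop("a positive frequency is required")
  g <- phase_gradient(psi, stencil = match.arg(stencil))
  nrm <- sqrt(g$gx^2 + g$gy^2)
  mg <- mean(nrm, na.rm = TRUE)   # rad/mm
  if (mg == 0) return(Inf)
  (2 * pi * f / mg) / 1000        # mm/s -> m/s
}

#' LFP-CSD phase-coherence
#'
#' \eqn{\rho = |\langle e^{i(\psi_a - \psi_b)} \rangle|} over the channels
#' valid in both patterns: 1 when the two patterns agree up to a constant
#' offset, 0 when their difference is fully dispersed.
#'
#' @param psi_a,psi_b Phase patterns (or plain phase vectors/matrices) on
#'   the same channel set.
#' @return Scalar in [0, 1].
#' @export
phase_coherence <- function(psi_a, psi_b) {
  a <- as.numeric(psi_a); b <- as.numeric(psi_b)
  if (length(a) != length(b))
    stop("phase patterns differ in channel count")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no channels valid in both patterns")
  Mod(mean(exp(1i * (a[ok] - b[ok]))))
}

#' Two-source phase mixing and the phase-contraction check
#'
#' For two monopolar CSD phasors \eqn{C_1 = a_1 e^{i\varphi_1}},
#' \eqn{C_2 = a_2 e^{i\varphi_2}} and positive leadfield weights
#' \eqn{\beta_1, \beta_2}, the recorded LFP is
#' \eqn{V = \beta_1 C_1 + \beta_2 C_2}. Writing
#' \eqn{\psi_{CSD} = \varphi_2 - \varphi_1} (required to lie in (0, pi), the
#' regime in which the result is proven), the LFP phase always lies strictly
#' between the source phases, so phase-differences between LFPs are
#' contracted relative to those between the CSDs. The implementation uses
#' the rotated form \eqn{V = \xi \beta_1 C_1},
#' \eqn{\xi = 1 + \gamma e^{i\psi_{CSD}}},
#' \eqn{\gamma = \beta_2 a_2 / (\beta_1 a_1)}.
#'
#' @param c1,c2 Complex CSD phasors with positive amplitude.
#' @param beta1,beta2 Positive leadfield weights.
#' @return List with \code{phi_lfp} (the LFP phase, rad), \code{psi_csd}
#'   (the source phase-difference) and \code{contracted} (logical: the LFP
#'   phase lies strictly between the source phases).
#' @export
phase_between <- function(c1, c2, beta1, beta2) {
  if (beta1 <= 0 || beta2 <= 0) stop("weights must be positive")
  a1 <- Mod(c1); a2 <- Mod(c2)
  if (a1 == 0 || a2 == 0) stop("source amplitudes must be positive")
  phi1 <- Arg(c1); phi2 <- Arg(c2)
  psi_csd <- wrap_phase(phi2 - phi1)
  if (!(psi_csd > 0 && psi_csd < pi))
    stop("source phase-difference must lie in (0, pi); got ",
         format(psi_csd))
  gamma <- beta2 * a2 / (beta1 * a1)
  xi <- 1 + gamma * exp(1i * psi_csd)
  psi_xi <- Arg(xi)
  phi_lfp <- wrap_phase(phi1 + psi_xi)
  list(phi_lfp = phi_lfp, psi_csd = psi_csd,
       contracted = (psi_xi > 0 && psi_xi < psi_csd))
}
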