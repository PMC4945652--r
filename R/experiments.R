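#' Canonical frequency bands
#'
#' One representative frequency per band: theta 5 Hz, alpha 10 Hz, beta
#' 20 Hz, low gamma 40 Hz, high gamma 80 Hz.
#'
#' @return Named numeric vector of frequencies (Hz).
#' @export
band_frequencies <- function() {
  c(theta = 5, alpha = 10, beta = 20, low_gamma = 40, high_gamma = 80)
}

#' Default study geometry
#'
#' The modeled volume is 11.6 mm on each intra-laminar side (the 3.6 mm
#' electrode grid plus 4 mm margins that host off-grid sources) and 3.5 mm
#' across depth, with the 10 x 10, 0.4 mm-pitch electrode grid 1.15 mm below
#' the tissue top. \code{nx}, \code{nz} set the working resolution; the
#' default (102 x 102 x 30) halves the finest supported discretization and
#' is validated by [leadfield_convergence()].
#'
#' @param nx Cubes per intra-laminar axis.
#' @param nz Cubes across depth.
#' @return List with \code{tissue} and \code{electrodes}.
#' @export
study_geometry <- function(nx = 102, nz = 30) {
  list(tissue = make_tissue_grid(11.6, 3.5, nx, nz, 1.15),
       electrodes = make_electrode_grid(10, 10, 0.4))
}

grid_half_extent <- function(electrodes) {
  (max(electrodes$n_rows, electrodes$n_cols) - 1) * electrodes$pitch / 2
}

restore_rng <- function() {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  function() {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
}

realization_seeds <- function(seed, n) {
  reset <- restore_rng(); on.exit(reset())
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Resolution convergence check for forward-modeled phasors
#'
#' Computes the LFP phasors of a fixed smooth separable CSD (a balanced
#' 1 mm generator at 0.5 mm depth times a plane wave) at resolution
#' (nx, nz) and at (2 nx, 2 nz), and reports the largest relative amplitude
#' difference and largest absolute phase difference across electrodes.
#' A resolution is adequate for phase metrics when the amplitude change is
#' below 1\% and the phase change below 0.01 rad.
#'
#' @param nx,nz Base resolution to validate.
#' @param f Oscillation frequency of the probe CSD (Hz); the highest study
#'   band is the most demanding.
#' @param v Propagation speed of the probe plane wave (m/s).
#' @param sigma Conductivity (S/m).
#' @param use_cache Reuse depth-collapsed leadfields across calls.
#' @return List with \code{max_rel_amplitude}, \code{max_abs_phase} (rad),
#'   and \code{passed} (both below tolerance).
#' @export
leadfield_convergence <- function(nx, nz, f = 80, v = 0.2, sigma = 1,
                                  use_cache = TRUE) {
  phasors <- function(nxi, nzi) {
    geo <- study_geometry(nxi, nzi)
    cv <- laminar_profile(list(generator_params(L = 1, z0 = -0.5)),
                          geo$tissue$zc)
    H <- cached_collapse(geo$tissue, geo$electrodes, cv, sigma, use_cache)
    ch <- eval_ch(ch_plane(v = v, f = f), grid_xy(geo$tissue))
    drop(H %*% ch)
  }
  v1 <- phasors(nx, nz)
  v2 <- phasors(2L * nx, 2L * nz)
  rel_amp <- max(abs(Mod(v1) - Mod(v2)) / Mod(v2))
  dphase <- max(abs(wrap_phase(Arg(v1) - Arg(v2))))
  list(max_rel_amplitude = rel_amp, max_abs_phase = dphase,
       passed = rel_amp < 0.01 && dphase < 0.01)
}

experiment_meta <- function(...) {
  c(list(package_version = as.character(utils::packageVersion("lfpcsd"))),
    list(...))
}

#' Phase-coherence experiment: complex wave fields across bands
#'
#' For each frequency band and each imbalance value, draws seeded
#' superpositions of isotropic waves (random centers over the full tissue
#' footprint, random initial phases), forward-models the LFP through the
#' volume conductor, and records the LFP-CSD phase-coherence and the LFP
#' and CSD Kuramoto order parameters per realization. The laminar profile
#' is a single generator (default 1 mm long at 0.5 mm depth).
#'
#' @param freqs Frequencies (Hz).
#' @param eps Imbalance values.
#' @param n_realizations Realizations per band and epsilon.
#' @param seed Integer seed (mandatory).
#' @param nx,nz Working resolution.
#' @param n_waves Isotropic waves per realization.
#' @param v Wave propagation speed (m/s).
#' @param L,depth Generator length and depth below the grid (mm).
#' @param sigma Conductivity (S/m).
#' @param use_cache Reuse depth-collapsed leadfields across calls.
#' @return Long-format data.frame (band, f, epsilon, realization, metric,
#'   value) with a \code{meta} attribute recording the full configuration.
#' @export
run_phase_coherence_experiment <- function(freqs = band_frequencies(),
                                           eps = c(0, 0.5, 1),
                                           n_realizations = 500,
                                           seed,
                                           nx = 102, nz = 30,
                                           n_waves = 100, v = 0.1,
                                           L = 1, depth = 0.5,
                                           sigma = 1, use_cache = TRUE) {
  if (missing(seed)) stop("a seed is required (stochastic experiment)")
  geo <- study_geometry(nx, nz)
  xy <- grid_xy(geo$tissue)
  region <- c(-1, 1, -1, 1) * geo$tissue$x_extent / 2
  bands <- if (is.null(names(freqs))) as.character(freqs) else names(freqs)

  H <- list(); cv0 <- numeric(length(eps))
  for (j in seq_along(eps)) {
    cv <- laminar_profile(list(generator_params(L = L, z0 = -depth,
                                                epsilon = eps[j])),
                          geo$tissue$zc)
    H[[j]] <- cached_collapse(geo$tissue, geo$electrodes, cv, sigma,
                              use_cache)
    cv0[j] <- Re(laminar_profile(list(generator_params(L = L, z0 = -depth,
                                                       epsilon = eps[j])),
                                 0))
  }

  seeds <- realization_seeds(seed, length(freqs) * n_realizations)
  rows <- vector("list", length(freqs) * length(eps) * n_realizations)
  ri <- 0L
  for (b in seq_along(freqs)) {
    f <- freqs[[b]]
    for (i in seq_len(n_realizations)) {
      s <- seeds[(b - 1L) * n_realizations + i]
      model <- draw_wave_superposition(n_waves, f, v, region, seed = s)
      ch <- eval_ch(model, xy)
      for (j in seq_along(eps)) {
        V <- drop(H[[j]] %*% ch)
        psi_lfp <- phase_of(V, geo$electrodes, f = f)
        csd <- restrict_to_electrodes(model, geo$electrodes, cv0[j])
        psi_csd <- phase_of(csd, geo$electrodes, f = f)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          band = bands[b], f = f, epsilon = eps[j], realization = i,
          metric = c("rho", "r_lfp", "r_csd"),
          value = c(phase_coherence(psi_lfp, psi_csd),
                    kuramoto(psi_lfp), kuramoto(psi_csd)))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- experiment_meta(
    experiment = "phase_coherence", seed = seed, nx = nx, nz = nz,
    n_waves = n_waves, v = v, L = L, depth = depth, eps = eps,
    freqs = unname(freqs), n_realizations = n_realizations, sigma = sigma)
  out
}

#' Propagation-speed experiment: traveling plane waves
#'
#' Forward-models a plane-wave CSD (default 0.2 m/s along +x) under a
#' single-generator laminar profile for each frequency and imbalance value,
#' and estimates the spatially averaged LFP propagation speed from the
#' phase-gradient of the electrode phasors. Optionally includes the
#' "confined" case in which the balanced intra-laminar profile is windowed
#' to zero outside the electrode-grid footprint.
#'
#' @param freqs Frequencies (Hz).
#' @param eps Imbalance values.
#' @param include_confined Also run the balanced, grid-confined variant.
#' @param v CSD propagation speed (m/s).
#' @param phi0 Initial phase of the wave (rad).
#' @param direction Propagation direction (length-2).
#' @param window "hard" (indicator of the footprint) or "smooth" (raised
#'   cosine taper over one pitch) for the confined case.
#' @param L,depth Generator length and depth (mm).
#' @param nx,nz Working resolution.
#' @param sigma Conductivity (S/m).
#' @param use_cache Reuse depth-collapsed leadfields.
#' @return Long-format data.frame (case, epsilon, f, v_lfp, v_csd) with a
#'   \code{meta} attribute. The experiment is deterministic.
#' @export
run_speed_experiment <- function(freqs = band_frequencies(),
                                 eps = c(0, 0.5, 1),
                                 include_confined = TRUE,
                                 v = 0.2, phi0 = 0, direction = c(1, 0),
                                 window = c("hard", "smooth"),
                                 L = 1, depth = 0.5,
                                 nx = 102, nz = 30, sigma = 1,
                                 use_cache = TRUE) {
  window <- match.arg(window)
  geo <- study_geometry(nx, nz)
  xy <- grid_xy(geo$tissue)
  half <- grid_half_extent(geo$electrodes)
  bands <- if (is.null(names(freqs))) as.character(freqs) else names(freqs)

  Hs <- list()
  for (j in seq_along(eps)) {
    cv <- laminar_profile(list(generator_params(L = L, z0 = -depth,
                                                epsilon = eps[j])),
                          geo$tissue$zc)
    Hs[[j]] <- cached_collapse(geo$tissue, geo$electrodes, cv, sigma,
                               use_cache)
  }

  win <- if (window == "hard") {
    as.numeric(abs(xy[, 1]) <= half & abs(xy[, 2]) <= half)
  } else {
    taper <- function(u) {
      w <- rep(1, length(u))
      p <- geo$electrodes$pitch
      ramp <- (u > half - p) & (u <= half)
      w[ramp] <- 0.5 * (1 + cos(pi * (u[ramp] - (half - p)) / p))
      w[u > half] <- 0
      w
    }
    taper(abs(xy[, 1])) * taper(abs(xy[, 2]))
  }

  rows <- list()
  for (b in seq_along(freqs)) {
    f <- freqs[[b]]
    wavep <- ch_plane(phi0 = phi0, v = v, f = f, direction = direction)
    ch <- eval_ch(wavep, xy)
    csd_psi <- phase_of(restrict_to_electrodes(wavep, geo$electrodes),
                        geo$electrodes, f = f)
    v_csd <- average_speed(csd_psi)
    for (j in seq_along(eps)) {
      V <- drop(Hs[[j]] %*% ch)
      psi <- phase_of(V, geo$electrodes, f = f)
      rows[[length(rows) + 1]] <- data.frame(
        case = "full", band = bands[b], epsilon = eps[j], f = f,
        v_lfp = average_speed(psi), v_csd = v_csd)
    }
    if (include_confined) {
      V <- drop(Hs[[1]] %*% (ch * win))
      psi <- phase_of(V, geo$electrodes, f = f)
      rows[[length(rows) + 1]] <- data.frame(
        case = "confined", band = bands[b], epsilon = eps[1], f = f,
        v_lfp = average_speed(psi), v_csd = v_csd)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- experiment_meta(
    experiment = "speed", nx = nx, nz = nz, v = v, phi0 = phi0,
    direction = direction, window = window, L = L, depth = depth,
    eps = eps, freqs = unname(freqs), sigma = sigma)
  out
}

#' Laminar-phase experiment: two generators with a phase-lag
#'
#' A superficial generator (depth 0.25 mm, phase 0) and a deep generator
#' (depth 1 mm, phase swept over [0, pi]) share a common length and a
#' Gaussian intra-laminar amplitude profile with spatially uniform phase
#' (an isotropic wave at infinite speed). A single recording point at the
#' intra-laminar source center measures the LFP; the experiment maps the
#' LFP phase as a function of the deep-generator phase for several
#' deep/superficial amplitude ratios.
#'
#' @param ratios Deep-over-superficial amplitude ratios.
#' @param deep_phases Deep-generator phases (rad), default a sweep of
#'   [0, pi].
#' @param L Common generator length (mm).
#' @param depths Depths (mm, positive below the grid) of the superficial
#'   and deep generators.
#' @param sigma_h Width of the Gaussian intra-laminar profile (mm).
#' @param nx,nz Working resolution.
#' @param sigma Conductivity (S/m).
#' @return data.frame (ratio, deep_phase, phi_lfp, deep_phase_cycles,
#'   phi_lfp_cycles) with a \code{meta} attribute. Deterministic.
#' @export
run_laminar_phase_experiment <- function(ratios = c(1 / 4, 1 / 2, 1, 2),
                                         deep_phases = seq(0, pi,
                                                           length.out = 65),
                                         L = 0.5,
                                         depths = c(0.25, 1.00),
                                         sigma_h = 1,
                                         nx = 102, nz = 30, sigma = 1) {
  tissue <- make_tissue_grid(11.6, 3.5, nx, nz, 1.15)
  probe <- structure(list(n_rows = 1L, n_cols = 1L, pitch = 1,
                          positions = cbind(x = 0, y = 0, z = 0), N = 1L),
                     class = "electrode_array")
  ch <- eval_ch(ch_isotropic(v = Inf, f = 1, sigma_h = sigma_h),
                grid_xy(tissue))
  weight <- function(depth) {
    cv <- laminar_profile(list(generator_params(L = L, z0 = -depth)),
                          tissue$zc)
    Re(drop(collapse_leadfield(tissue, probe, cv, sigma) %*% ch))
  }
  beta_s <- weight(depths[1])
  beta_d <- weight(depths[2])
  rows <- list()
  for (r in ratios) {
    V <- beta_s + r * beta_d * exp(1i * deep_phases)
    phi <- wrap_phase(Arg(V))
    rows[[length(rows) + 1]] <- data.frame(
      ratio = r, deep_phase = deep_phases, phi_lfp = phi,
      deep_phase_cycles = deep_phases / (2 * pi),
      phi_lfp_cycles = phi / (2 * pi))
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- experiment_meta(
    experiment = "laminar_phase", nx = nx, nz = nz, L = L,
    depths = depths, sigma_h = sigma_h, ratios = ratios,
    beta_superficial = beta_s, beta_deep = beta_d, sigma = sigma)
  out
}

#' Montage-comparison experiment
#'
#' Repeats the phase-coherence simulation (balanced generator, seeded
#' 100-wave superpositions) and, per band and realization, applies the
#' referential, average-reference, bipolar (x), and surface-Laplacian
#' montages to the LFP phasors. Records, per montage, the phase-coherence
#' against the intra-laminar CSD evaluated at the montage's own channel
#' positions, the Kuramoto order of the montaged phases, and the CSD
#' Kuramoto order. The laminar profile is either the balanced generator or
#' a depth-constant profile.
#'
#' @param freqs Frequencies (Hz).
#' @param laminar "generator" (balanced dipole) or "constant".
#' @param montages Montage names among "referential", "average",
#'   "bipolar_x", "laplacian".
#' @param n_realizations Realizations per band.
#' @param seed Integer seed (mandatory).
#' @param nx,nz Working resolution.
#' @param n_waves,v Wave count and speed (m/s).
#' @param L,depth Generator parameters (mm), generator profile only.
#' @param sigma Conductivity (S/m); also used as the Laplacian sigma'.
#' @param use_cache Reuse depth-collapsed leadfields.
#' @return Long-format data.frame (band, f, laminar, montage, realization,
#'   metric, value) with a \code{meta} attribute.
#' @export
run_montage_experiment <- function(freqs = band_frequencies(),
                                   laminar = c("generator", "constant"),
                                   montages = c("referential", "average",
                                                "bipolar_x", "laplacian"),
                                   n_realizations = 500,
                                   seed,
                                   nx = 102, nz = 30,
                                   n_waves = 100, v = 0.1,
                                   L = 1, depth = 0.5,
                                   sigma = 1, use_cache = TRUE) {
  if (missing(seed)) stop("a seed is required (stochastic experiment)")
  laminar <- match.arg(laminar)
  geo <- study_geometry(nx, nz)
  xy <- grid_xy(geo$tissue)
  region <- c(-1, 1, -1, 1) * geo$tissue$x_extent / 2
  bands <- if (is.null(names(freqs))) as.character(freqs) else names(freqs)

  cv <- if (laminar == "generator")
    laminar_profile(list(generator_params(L = L, z0 = -depth)),
                    geo$tissue$zc)
  else constant_laminar_profile(geo$tissue$zc)
  cv0 <- if (laminar == "generator")
    Re(laminar_profile(list(generator_params(L = L, z0 = -depth)), 0))
  else 1
  H <- cached_collapse(geo$tissue, geo$electrodes, cv, sigma, use_cache)

  apply_montage <- function(name, V) {
    switch(name,
      referential = apply_referential(V, geo$electrodes),
      average = apply_average_reference(V, geo$electrodes),
      bipolar_x = apply_bipolar(V, geo$electrodes, axis = "x"),
      laplacian = apply_laplacian(V, geo$electrodes, sigma_prime = sigma),
      stop("unknown montage ", name))
  }

  seeds <- realization_seeds(seed, length(freqs) * n_realizations)
  rows <- list()
  for (b in seq_along(freqs)) {
    f <- freqs[[b]]
    for (i in seq_len(n_realizations)) {
      s <- seeds[(b - 1L) * n_realizations + i]
      model <- draw_wave_superposition(n_waves, f, v, region, seed = s)
      ch <- eval_ch(model, xy)
      V <- drop(H %*% ch)
      csd_el <- restrict_to_electrodes(model, geo$electrodes, cv0)
      r_csd <- kuramoto(phase_of(csd_el, geo$electrodes, f = f))
      for (mn in montages) {
        mres <- apply_montage(mn, V)
        rows[[length(rows) + 1]] <- data.frame(
          band = bands[b], f = f, laminar = laminar, montage = mn,
          realization = i,
          metric = c("rho", "r_montage", "r_csd"),
          value = c(coherence_vs_csd(mres, model, cv0),
                    kuramoto(montage_phase(mres, f = f)),
                    r_csd))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- experiment_meta(
    experiment = "montage", seed = seed, nx = nx, nz = nz,
    laminar = laminar, montages = montages, n_waves = n_waves, v = v,
    L = L, depth = depth, freqs = unname(freqs),
    n_realizations = n_realizations, sigma = sigma)
  out
}

#' Summarize a long-format experiment table
#'
#' Mean (or another statistic) of each metric within each combination of
#' grouping columns.
#'
#' @param tbl A result table from one of the \code{run_*} experiments.
#' @param by Grouping column names.
#' @param stat Summary function.
#' @return Aggregated data.frame.
#' @export
summarize_experiment <- function(tbl, by = c("band", "f", "metric"),
                                 stat = mean) {
  stats::aggregate(tbl["value"], by = tbl[by], FUN = stat)
}
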