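test_that("generator profile follows the two-pole Gaussian form", {
  g <- generator_params(A = 1, L = 1, z0 = -0.5, epsilon = 0)
  # balanced poles cancel at the generator center
  expect_equal(generator_profile(-0.5, g), 0, tolerance = 1e-15)
  # monopolar: value at the superficial pole is exactly A
  gm <- generator_params(A = 2, L = 1, z0 = -0.5, epsilon = 1)
  expect_equal(generator_profile(-0.5 + 0.5, gm), 2)
  # balanced, sigma_v = L/3: value at the superficial pole is A(1 - e^-4.5)
  expect_equal(generator_profile(0, g), 1 - exp(-4.5), tolerance = 1e-12)
  # superficial pole (larger z) is the positive one
  expect_gt(generator_profile(0, g), 0)
  expect_lt(generator_profile(-1, g), 0)
  expect_error(generator_params(L = -1), "positive")
  expect_error(generator_params(epsilon = 1.5), "0, 1")
})

test_that("balanced generators conserve current on a wide depth grid", {
  z <- seq(-6, 6, length.out = 2001)   # >= 4 sigma_v beyond both poles
  for (L in c(0.2, 0.5, 1)) {
    p <- generator_profile(z, generator_params(L = L, z0 = -0.3))
    expect_lt(abs(sum(p)) / sum(abs(p)), 1e-6)
  }
})

test_that("laminar superposition carries per-generator phases", {
  z <- seq(-2, 1, length.out = 50)
  g1 <- generator_params(L = 0.5, z0 = -0.5)
  expect_equal(Im(laminar_profile(list(g1), z)), rep(0, 50))
  # two equal generators in anti-phase cancel
  g2 <- generator_params(L = 0.5, z0 = -0.5, phase = pi)
  expect_equal(laminar_profile(list(g1, g2), z), complex(50),
               tolerance = 1e-12)
  # distinct anti-phase generators subtract
  g3 <- generator_params(L = 1, z0 = -1.6, phase = pi)
  expect_equal(laminar_profile(list(g1, g3), z),
               as.complex(generator_profile(z, g1) -
                            generator_profile(z, generator_params(L = 1,
                                                                  z0 = -1.6))),
               tolerance = 1e-12)
  expect_error(laminar_profile(list(), z), "at least one")

  cp <- constant_laminar_profile(z)
  expect_equal(cp, rep(1, length(z)))
  expect_equal(cp, rev(constant_laminar_profile(rev(z))))
})

test_that("isotropic wave has unit center value and 2pi/lambda phase decay", {
  w <- ch_isotropic(phi0 = 0.7, v = 0.1, f = 10)    # lambda = 10 mm
  expect_equal(isotropic_wave(c(0, 0), w), exp(0.7i))
  # at d = lambda with sigma_h = lambda/3: phase phi0 (mod 2pi), amp e^-4.5
  v <- isotropic_wave(c(10, 0), w)
  expect_equal(Mod(v), exp(-4.5), tolerance = 1e-12)
  expect_equal(wrap_phase(Arg(v) - 0.7), 0, tolerance = 1e-12)
  # phase decreases radially at 2pi/lambda rad per mm
  d <- c(0.3, 0.4)
  ph <- Arg(isotropic_wave(cbind(d, 0), w))
  expect_equal(wrap_phase(diff(ph)), -2 * pi * 0.1 / 10, tolerance = 1e-12)
})

test_that("plane wave is unit amplitude with wavelength v/f", {
  w <- ch_plane(phi0 = 0.2, v = 0.2, f = 20)        # lambda = 10 mm
  pts <- cbind(runif(20, -5, 5), runif(20, -5, 5))
  vals <- plane_wave(pts, w)
  expect_equal(Mod(vals), rep(1, 20))
  # points lambda/2 apart along propagation differ by pi
  v2 <- plane_wave(rbind(c(0, 0), c(5, 0)), w)
  expect_equal(abs(wrap_phase(diff(Arg(v2)))), pi, tolerance = 1e-12)
  expect_equal(w$wavelength, 10)
})

test_that("wave superpositions are seeded, reproducible, and reduce to one wave", {
  pts <- cbind(runif(30, -2, 2), runif(30, -2, 2))
  a <- superpose_isotropic_waves(pts, n_waves = 5, f = 10, v = 0.1, seed = 9)
  b <- superpose_isotropic_waves(pts, n_waves = 5, f = 10, v = 0.1, seed = 9)
  expect_identical(a, b)
  expect_error(superpose_isotropic_waves(pts, n_waves = 5, f = 10, v = 0.1),
               "seed")
  m1 <- draw_wave_superposition(1, f = 10, v = 0.1, seed = 4)
  expect_equal(eval_ch(m1, pts), eval_ch(m1$waves[[1]], pts))
})

test_that("spatial coherence of wave fields falls with frequency", {
  # shorter wavelengths decorrelate the phases across the electrode grid
  el <- make_electrode_grid(10, 10, 0.4)
  pts <- el$positions[, 1:2]
  freqs <- band_frequencies()
  r_mean <- sapply(freqs, function(f) {
    mean(sapply(1:100, function(s) {
      v <- superpose_isotropic_waves(pts, n_waves = 100, f = f, v = 0.1,
                                     seed = 1000 + s)
      kuramoto(Arg(v))
    }))
  })
  expect_true(all(diff(r_mean) < 0))
})

test_that("separable CSD assembly multiplies amplitudes and adds phases", {
  tg <- make_tissue_grid(2, 1, 5, 3, 0.4)
  set.seed(1)
  cv <- complex(real = rnorm(3), imaginary = rnorm(3))
  ch <- complex(real = rnorm(25), imaginary = rnorm(25))
  C <- assemble_csd(cv, ch, tg)
  expect_length(C, tg$K)
  expect_equal(assemble_csd(complex(3), ch, tg), complex(tg$K))
  a <- 2 - 1i
  expect_equal(assemble_csd(a * cv, ch, tg), a * C, tolerance = 1e-12)
  # pointwise: C[k] = cv[z_k] * ch[xy_k] in x-fastest ordering
  cc <- cube_centers(tg)
  k <- c(1, 7, 26, tg$K)
  iz <- ceiling(k / 25); ixy <- k - (iz - 1) * 25
  expect_equal(C[k], cv[iz] * ch[ixy], tolerance = 1e-15)
  expect_error(assemble_csd(cv[1:2], ch, tg), "nz")
  expect_error(assemble_csd(cv, ch[1:3], tg), "nx")
})

test_that("restriction to electrodes is analytic and sign-aware", {
  el <- make_electrode_grid(10, 10, 0.4)
  w <- ch_plane(v = 0.2, f = 20)
  r <- restrict_to_electrodes(w, el)
  # exact wavelength retained on the grid
  m <- matrix(r, 10, 10, byrow = TRUE)
  expect_equal(wrap_phase(diff(Arg(m[1, ]))),
               rep(2 * pi * 0.4 / 10, 9), tolerance = 1e-12)
  expect_equal(restrict_to_electrodes(w, el, cv_at_plane = 3 - 1i),
               (3 - 1i) * r, tolerance = 1e-12)
  # balanced 1 mm generator at 0.5 mm depth: superficial pole positive at
  # z = 0, so the restricted CSD phase equals the phase of ch
  cv0 <- Re(laminar_profile(list(generator_params(L = 1, z0 = -0.5)), 0))
  expect_gt(cv0, 0)
  expect_equal(Arg(restrict_to_electrodes(w, el, cv0)), Arg(r))
})

test_that("phasor fields depend on speed and frequency only through lambda", {
  pts <- cbind(runif(40, -5, 5), runif(40, -5, 5))
  expect_equal(eval_ch(ch_plane(v = 0.2, f = 20), pts),
               eval_ch(ch_plane(v = 0.4, f = 40), pts))
  expect_identical(
    superpose_isotropic_waves(pts, 20, f = 10, v = 0.1, seed = 3),
    superpose_isotropic_waves(pts, 20, f = 20, v = 0.2, seed = 3))
})

test_that("complex fields export as plain tables", {
  v <- c(1 + 1i, -2i)
  tb <- field_to_table(v, cbind(x = c(0, 1), y = c(2, 3)))
  expect_equal(tb$re, c(1, 0))
  expect_equal(tb$im, c(1, -2))
  expect_equal(tb$phase, Arg(v))
  expect_error(field_to_table(v, cbind(1, 2, 3)), "disagree")
})
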