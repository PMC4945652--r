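test_that("tissue grid tiles the volume with the stated cube counts", {
  tg <- make_tissue_grid(11.6, 3.5, 204, 61, 1.15)
  expect_identical(tg$K, 204L * 204L * 61L)  # 2538576 source cubes
  expect_equal(tg$cube_dims, c(11.6 / 204, 11.6 / 204, 3.5 / 61))
  # depth range: electrode plane at z = 0, pia at +grid_depth
  expect_equal(max(tg$zc) + tg$cube_dims[3] / 2, 1.15)
  expect_equal(min(tg$zc) - tg$cube_dims[3] / 2, -2.35)

  # centers reconstructible from index; tiling exact (no gaps/overlap)
  tg2 <- make_tissue_grid(2, 1, 4, 2, 0.5)
  cc <- cube_centers(tg2)
  expect_equal(nrow(cc), tg2$K)
  expect_equal(sort(unique(cc[, "x"])), -1 + 0.5 * (1:4) - 0.25)
  expect_equal(sort(unique(cc[, "z"])), c(-0.25, 0.25))
  # x varies fastest, deepest plane last
  expect_equal(cc[1:2, "x"], unname(cc[1:2, "x"]))
  expect_equal(diff(cc[1:2, "x"]), 0.5, ignore_attr = TRUE)
  expect_equal(cc[1, "z"], 0.25, ignore_attr = TRUE)
  expect_equal(cc[tg2$K, "z"], -0.25, ignore_attr = TRUE)

  # degenerate single cube centered at origin
  tg1 <- make_tissue_grid(1, 1, 1, 1, 0.5)
  expect_equal(unname(cube_centers(tg1)[1, ]), c(0, 0, 0))

  expect_error(make_tissue_grid(-1, 3.5, 10, 5, 1), "positive")
  expect_error(make_tissue_grid(1, 1, 0, 5, 0.5), "positive integers")
  expect_error(make_tissue_grid(1, 1, 4, 4, 2), "grid_depth")
})

test_that("electrode grid is centered at the plane with the stated extent", {
  ea <- make_electrode_grid(10, 10, 0.4)
  expect_identical(ea$N, 100L)
  expect_equal(max(ea$positions[, "x"]) - min(ea$positions[, "x"]), 3.6)
  expect_true(all(ea$positions[, "z"] == 0))
  expect_equal(colMeans(ea$positions), c(x = 0, y = 0, z = 0))

  e1 <- make_electrode_grid(1, 1, 0.4)
  expect_equal(unname(e1$positions[1, ]), c(0, 0, 0))

  e2 <- make_electrode_grid(2, 2, 1.0)
  expect_equal(sort(unique(e2$positions[, "x"])), c(-0.5, 0.5))
  expect_equal(sort(unique(e2$positions[, "y"])), c(-0.5, 0.5))

  expect_error(make_electrode_grid(0, 2, 0.4), "positive")
  expect_error(make_electrode_grid(2, 2, 0), "pitch")
})

test_that("box potential has the far-field, symmetry, and interior limits", {
  # cube far away acts as a point source of strength = its volume
  v <- box_potential_unit_csd(c(0, 0, 0), c(0.05, 0.05, 0.05),
                              c(10, 0, 0), sigma = 1)
  expect_equal(v, 0.05^3 / (4 * pi * 10), tolerance = 1e-4)

  # mirror-symmetric points see equal potentials
  a <- box_potential_unit_csd(c(1, 2, 3), c(0.3, 0.4, 0.5), c(1.7, 2, 3))
  b <- box_potential_unit_csd(c(1, 2, 3), c(0.3, 0.4, 0.5), c(0.3, 2, 3))
  expect_equal(a, b, tolerance = 1e-12)

  # finite (and oracle-exact) at the center of a unit cube
  skip_if_not_installed("pracma")
  v0 <- box_potential_unit_csd(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))
  expect_true(is.finite(v0) && v0 > 0)
  expect_equal(v0, box_potential_oracle(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0)),
               tolerance = 1e-6)

  expect_error(box_potential_unit_csd(c(0, 0, 0), c(1, 1, 1), c(2, 0, 0),
                                      sigma = -1), "sigma")
})

test_that("closed-form box potential matches adaptive quadrature", {
  skip_if_not_installed("pracma")
  configs <- random_box_configs(12, seed = 402)
  for (cf in configs) {
    got <- box_potential_unit_csd(cf$center, cf$dims, cf$p)
    want <- box_potential_oracle(cf$center, cf$dims, cf$p)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("leadfield entries are positive, distance-decaying, 1/sigma", {
  tissue <- make_tissue_grid(2, 1, 8, 4, 0.5)
  el <- make_electrode_grid(3, 3, 0.4)
  lf <- build_leadfield(tissue, el, sigma = 1)
  expect_true(all(is.finite(lf$matrix)) && all(lf$matrix > 0))

  lf2 <- build_leadfield(tissue, el, sigma = 2)
  expect_equal(lf2$matrix, lf$matrix / 2, tolerance = 1e-12)

  # decay with distance along a fixed ray: center electrode row, cubes of
  # the deepest plane ordered by radial distance
  cc <- cube_centers(tissue)
  n_center <- which(el$positions[, 1] == 0 & el$positions[, 2] == 0)
  deep <- which(cc[, "z"] == min(cc[, "z"]) & cc[, "y"] == cc[1, "y"])
  d <- sqrt(rowSums(sweep(cc[deep, , drop = FALSE], 2,
                          el$positions[n_center, ])^2))
  g <- lf$matrix[n_center, deep]
  expect_true(all(diff(g[order(d)]) <= 1e-12))  # ties up to roundoff

  # electrodes on cube faces stay finite (plane boundary at z = 0)
  tb <- make_tissue_grid(2, 2, 4, 2, 1)  # cube boundary exactly at z = 0
  lfb <- build_leadfield(tb, el, sigma = 1)
  expect_true(all(is.finite(lfb$matrix)) && all(lfb$matrix > 0))
})

test_that("sensitivity map is positive and peaks under the grid center", {
  geo <- tiny_geometry(16, 6)
  lf <- build_leadfield(geo$tissue, geo$electrodes)
  s <- sensitivity_map(lf)
  expect_length(s, geo$tissue$K)
  expect_true(all(s > 0))
  # electrode ordering must not matter
  perm <- sample(nrow(lf$matrix))
  lfp <- lf; lfp$matrix <- lf$matrix[perm, ]
  expect_equal(sensitivity_map(lfp), s)
  # intra-laminar cross-section at the electrode plane depth peaks centrally
  cc <- cube_centers(geo$tissue)
  plane <- which(abs(cc[, "z"] - geo$tissue$zc[which.min(abs(geo$tissue$zc))])
                 < 1e-9)
  sp <- s[plane]
  r2 <- cc[plane, "x"]^2 + cc[plane, "y"]^2
  expect_lt(max(r2[sp >= max(sp) - 1e-12]), geo$tissue$cube_dims[1]^2 * 4)
  # decays outside the grid footprint
  outside <- r2 > 3^2
  expect_lt(max(sp[outside]), max(sp))
})

test_that("forward model is exactly linear over complex CSD vectors", {
  tissue <- make_tissue_grid(2, 1, 6, 3, 0.5)
  el <- make_electrode_grid(3, 3, 0.4)
  lf <- build_leadfield(tissue, el)
  K <- tissue$K
  expect_equal(forward_lfp(lf, complex(K)), complex(el$N))

  set.seed(7)
  c1 <- complex(real = rnorm(K), imaginary = rnorm(K))
  c2 <- complex(real = rnorm(K), imaginary = rnorm(K))
  a <- 0.3 - 1.2i; b <- -2 + 0.5i
  expect_equal(forward_lfp(lf, a * c1 + b * c2),
               a * forward_lfp(lf, c1) + b * forward_lfp(lf, c2),
               tolerance = 1e-14)
  # global phase rotation rotates every LFP phasor, amplitudes unchanged
  th <- 1.1
  v1 <- forward_lfp(lf, c1); v2 <- forward_lfp(lf, exp(1i * th) * c1)
  expect_equal(Mod(v2), Mod(v1), tolerance = 1e-12)
  expect_equal(wrap_phase(Arg(v2) - Arg(v1)), rep(th, el$N),
               tolerance = 1e-12)

  expect_error(forward_lfp(lf, complex(K + 1)), "does not match")
})

test_that("collapsed leadfield equals the full forward map on separable CSDs", {
  geo <- tiny_geometry(10, 4)
  cv <- balanced_cv(geo$tissue)
  ch <- ch_plane(v = 0.2, f = 20)
  lf <- build_leadfield(geo$tissue, geo$electrodes)
  v_full <- forward_lfp(lf, assemble_csd(cv, ch, geo$tissue))
  H <- collapse_leadfield(geo$tissue, geo$electrodes, cv)
  v_coll <- drop(H %*% eval_ch(ch, grid_xy(geo$tissue)))
  expect_equal(v_coll, v_full, tolerance = 1e-12)
})

test_that("leadfield persistence round-trips and validates metadata", {
  tissue <- make_tissue_grid(1, 1, 3, 2, 0.5)
  el <- make_electrode_grid(2, 2, 0.3)
  lf <- build_leadfield(tissue, el)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  write_leadfield(lf, path)
  lf2 <- read_leadfield(path)
  expect_equal(lf2$matrix, lf$matrix)
  expect_equal(lf2$tissue$K, tissue$K)
  expect_s3_class(lf2, "leadfield")

  bad <- readRDS(path); bad$format <- "other"; saveRDS(bad, path)
  expect_error(read_leadfield(path), "not an lfpcsd leadfield")
  bad$format <- "lfpcsd-leadfield"; bad$matrix <- bad$matrix[, -1]
  saveRDS(bad, path)
  expect_error(read_leadfield(path), "dimensions")
})
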