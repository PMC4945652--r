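# Small geometries used across tests (kept coarse: phase metrics converge
# far below the full study resolution and tests exercise behavior, not
# final accuracy).

tiny_geometry <- function(nx = 24, nz = 8) study_geometry(nx, nz)

small_geometry <- function(nx = 40, nz = 14) study_geometry(nx, nz)

balanced_cv <- function(tissue, L = 1, depth = 0.5, epsilon = 0) {
  laminar_profile(list(generator_params(L = L, z0 = -depth,
                                        epsilon = epsilon)), tissue$zc)
}

# forward LFP of a separable CSD on a geometry, via the collapsed leadfield
forward_separable <- function(geo, cv, ch_model, use_cache = TRUE) {
  H <- lfpcsd:::cached_collapse(geo$tissue, geo$electrodes, cv,
                                use_cache = use_cache)
  drop(H %*% eval_ch(ch_model, grid_xy(geo$tissue)))
}
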