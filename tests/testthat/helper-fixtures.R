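# Shared miniature fixtures, built in code at test time.

# homogeneous matched-index scattering cube with its single-layer table
tiny_medium <- function(mua = 0.5, mus = 20, g = 0.8, n = 1,
                        nx = 60, nz = 60, thickness_mm = 10,
                        voxel_mm = 0.5) {
  build_slab_phantom(data.frame(thickness_mm = thickness_mm, n = n,
                                mua = mua, mus = mus, g = g),
                     nx = nx, nz = nz, voxel_mm = voxel_mm)
}

# small thoracic phantom (coarse but with every tissue class)
small_thorax <- function() {
  cfg <- phantom_config(dims = c(140L, 160L, 48L))
  list(cfg = cfg, volume = build_thoracic_phantom(cfg))
}

quick_run <- function(n_photons = 5000, n_repeats = 1, seed = 1, ...) {
  run_config(n_photons = n_photons, n_repeats = n_repeats,
             base_seed = seed, ...)
}
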