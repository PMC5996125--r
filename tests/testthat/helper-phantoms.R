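# Shared phantom fixtures, built once per test run (tracking a phantom is
# the expensive step; every consumer sees the identical object).
.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, build) {
  if (!exists(key, envir = .fx_cache)) assign(key, build(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_tube <- function() fx("tube", function() {
  generate_phantom(tube_phantom_config(seed = 1L))
})

fx_tube_bundle <- function() fx("tube_bundle", function() {
  ds <- fx_tube()
  seeds <- seeds_from_mask(ds$bundle_masks$tube, ds$field$voxel_size)
  track_bundle(ds$field, seeds)
})

fx_ilf <- function() fx("ilf", function() {
  generate_phantom(ilf_phantom_config(asymmetry = 1.17, jitter_sd = 0,
                                      seed = 1L))
})

fx_ilf_bundle_L <- function() fx("ilf_bundle_L", function() {
  ds <- fx_ilf()
  seeds <- seeds_from_mask(ds$bundle_masks$ILF_L, ds$field$voxel_size,
                           every = 2L)
  track_bundle(ds$field, seeds, hemisphere = "L", name = "ILF_L")
})

fx_crossing <- function() fx("crossing", function() {
  generate_phantom(crossing_phantom_config(jitter_sd = 5, seed = 2L))
})

# straight synthetic streamline along +y at (x, z), y in [y0, y1]
straight_streamline <- function(x, z, y0, y1, step = 0.2) {
  y <- seq(y0, y1, by = step)
  cbind(rep(x, length(y)), y, rep(z, length(y)))
}

# minimal hand-built proportion table for scale_ci (as normalize_counts
# would emit)
make_props <- function(pairs_a, pairs_b, prop, regions) {
  out <- data.frame(region_a = pairs_a, region_b = pairs_b,
                    proportion = prop)
  attr(out, "regions") <- regions
  out
}
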