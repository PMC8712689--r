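# Shared phantoms, generated once per test run. Sizes are scaled down from
# the full-size stem (1.5 cm^2) to keep the suite fast; cell diameters,
# rind thickness and distance bands keep their stated values so that the
# size-sensitive checks remain meaningful.

.phantom_cache <- new.env(parent = emptyenv())

get_phantom <- function(which = c("small", "holes", "damaged", "acceptance")) {
  which <- match.arg(which)
  if (!is.null(.phantom_cache[[which]])) return(.phantom_cache[[which]])
  pp <- switch(which,
    small = phantom_params(stem_radius_um = 1800, rind_thickness_um = 300,
                           n_bundles = 5, seed = 5),
    holes = phantom_params(stem_radius_um = 1800, rind_thickness_um = 300,
                           n_bundles = 5, hole_fraction = 0.04, seed = 6),
    damaged = phantom_params(stem_radius_um = 1800, rind_thickness_um = 300,
                             n_bundles = 5, missing_rind_arc_deg = 60,
                             seed = 8),
    acceptance = phantom_params(stem_radius_um = 2300, rind_thickness_um = 300,
                                n_bundles = 12, seed = 7)
  )
  .phantom_cache[[which]] <- generate_phantom(pp)
  .phantom_cache[[which]]
}

# constant-channel multispectral stack
const_ms <- function(value = 1, n = 8, pixel_size_um = 2.78) {
  ch <- setNames(lapply(channel_names(), function(x) matrix(value, n, n)),
                 channel_names())
  multispectral_image(ch, pixel_size_um)
}

# stack with chosen per-channel constants
ms_from <- function(values, n = 8) {
  stopifnot(length(values) == 11)
  ch <- setNames(lapply(seq_len(11), function(i) matrix(values[i], n, n)),
                 channel_names())
  multispectral_image(ch)
}
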