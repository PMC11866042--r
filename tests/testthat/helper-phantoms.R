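# Shared phantom fixtures, generated once per test run and cached.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]]))
    assign(key, generate_phantom(spec), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

# A misaligned pair with bone loss: the workhorse fixture.
small_pair <- function() {
  cached_phantom("small", phantom_spec(
    width_px = 320, height_px = 320, mpp = 1.77,
    fibrosis_field = list(type = "random", mean = 0.5, amplitude = 0.3,
                          correlation_length_px = 96),
    n_bone_blobs = 2, fat_fraction = 0.1,
    misalignment = list(rotation_deg = 3, translation_px = c(12, -7), scale = 1),
    bone_loss_fraction = 0.3, seed = 7))
}

# Constant-severity pair, aligned, no artefacts.
flat_pair <- function(value = 0.7, seed = 3) {
  cached_phantom(paste0("flat", value, "_", seed), phantom_spec(
    width_px = 256, height_px = 256, mpp = 1.77,
    fibrosis_field = list(type = "constant", value = value),
    n_bone_blobs = 1, fat_fraction = 0.08, seed = seed))
}

# A bare phantom_pair wrapper around a given field matrix, for label tests.
field_pair <- function(field) {
  structure(list(fibrosis_field = field), class = "phantom_pair")
}

# Synthetic tile table on a regular grid (0-based, half-open).
grid_tile_table <- function(nx, ny, tile_size) {
  g <- expand.grid(x0 = (seq_len(nx) - 1L) * tile_size,
                   y0 = (seq_len(ny) - 1L) * tile_size)
  tibble::tibble(index = seq_len(nrow(g)) - 1L, x0 = g$x0, y0 = g$y0,
                 tile_size = tile_size)
}
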