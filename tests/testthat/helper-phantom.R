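# Shared phantom fixtures, generated once per test run. The small grid keeps
# unit tests fast; acceptance checks use the default resolution.

small_spec <- function(...) {
  args <- list(grid_nx = 26L, grid_ny = 24L, crown_n_eta = 7L,
               crown_n_phi = 12L, surface_noise_sd = 0, stable_noise_sd = 0)
  do.call(phantom_spec, utils::modifyList(args, list(...), keep.null = TRUE))
}

null_spec <- function(...) {
  args <- list(global_transform = identity_transform(), treatment = NULL)
  do.call(small_spec, utils::modifyList(args, list(...), keep.null = TRUE))
}

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, fixture_env)) assign(name, expr, fixture_env)
  get(name, fixture_env)
}

phantom_default_small <- function() {
  fixture("default_small", generate_phantom(small_spec()))
}

phantom_null_small <- function() {
  fixture("null_small", generate_phantom(null_spec()))
}
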