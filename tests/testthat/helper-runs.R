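# Memoised end-to-end runs shared across test files (each is computed at
# most once per test_dir invocation).

.run_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

# toy-scale (N = 32) full phantom, all methods
toy_run <- function() memo("toy", {
  p <- sta_presets()$toy
  ph <- p$phantom; ph$rng_seed <- 11L
  field <- make_scatterers(ph, p$geometry, p$pulse)
  cube <- add_channel_noise(simulate_sta(field, p$geometry, p$pulse),
                            p$snr_db, 12L)
  lat <- sort(unique(c(seq(-5.7e-3, -3.3e-3, by = 0.03e-3),
                       seq(-3.2e-3, 5.2e-3, by = 0.08e-3))))
  grid <- imaging_grid(lat, seq(18e-3, 22e-3, by = 0.1e-3))
  s <- beamform_image(cube, grid, p$config)
  list(preset = p, cube = cube, grid = grid, images = s,
       metrics = image_metrics(s, p$rois))
})

# full-scale (N = 64) reference-conditions phantom, all methods, one seed
full_run <- function() memo("full", {
  p <- sta_presets()$simulation
  ph <- p$phantom; ph$rng_seed <- 21L
  field <- make_scatterers(ph, p$geometry, p$pulse)
  cube <- add_channel_noise(simulate_sta(field, p$geometry, p$pulse),
                            p$snr_db, 22L)
  lat <- sort(unique(c(seq(-8.4e-3, -5.6e-3, by = 0.02e-3),
                       seq(-2.4e-3, 2.4e-3, by = 0.08e-3),
                       seq(3.6e-3, 7.4e-3, by = 0.08e-3))))
  grid <- imaging_grid(lat, seq(21.5e-3, 26.5e-3, by = 0.1e-3))
  s <- beamform_image(cube, grid, p$config)
  list(preset = p, cube = cube, grid = grid, images = s,
       metrics = image_metrics(s, p$rois))
})

metric_of <- function(run, method, col) {
  m <- run$metrics
  m[[col]][m$method == method]
}
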