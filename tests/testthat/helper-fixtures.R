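# One shared synthetic world, built once per test run: a 50 x 50 landscape
# with 10 drifting slices, camps placed by true suitability, the presence
# raster, and a fitted presence/background model.
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101)
      truth <- gen_landscape_stack(cfg)
      camps <- gen_camps(truth, 300)
      pg <- rasterize_presences(camps, truth$grid, buffer_km = 20)
      model <- fit_enm(pg, get_slice(truth$stack, 0),
                       background_n = 1000, seed = 1)
      cache <<- list(cfg = cfg, truth = truth, camps = camps, pg = pg,
                     model = model)
    }
    cache
  }
})

# tiny all-land grid on the equator for distance/travel-time checks
equator_grid <- function(n = 50, cell = 0.1) {
  build_grid(0, n * cell, -n * cell / 2, n * cell / 2, cell_size = cell)
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(c(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}
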