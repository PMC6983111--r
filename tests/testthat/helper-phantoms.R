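# Shared, lazily-built phantom objects so expensive simulations run once
# per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# a small abnormal phantom (quarter resolution) with everything derived
small_abnormal <- function() cached("small_abnormal", function() {
  spec <- phantom_spec(spatial_shape = c(80L, 125L),
                       whitening_fraction = 0.4818, seed = 11L)
  sim <- generate_cube(spec)
  cal <- calibrate(sim$raw, sim$refs)
  mask <- segment_background(cal)
  list(spec = spec, sim = sim, cal = cal, mask = mask)
})

small_normal <- function() cached("small_normal", function() {
  spec <- phantom_spec(spatial_shape = c(80L, 125L),
                       whitening_fraction = 0, seed = 12L)
  sim <- generate_cube(spec)
  cal <- calibrate(sim$raw, sim$refs)
  mask <- segment_background(cal)
  list(spec = spec, sim = sim, cal = cal, mask = mask)
})

# calibrated + masked + range-normalized ensemble for PCA/waveband tests
pca_ensemble <- function() cached("pca_ensemble", function()
  simulate_ensemble(n_normal = 6L, n_abnormal = 6L, seed_base = 100L,
                    spatial_shape = c(80L, 125L)))

# tiny deterministic cube for I/O tests
toy_cube <- function(rows = 4L, cols = 5L, bands = 3L, seed = 42L) {
  set.seed(seed)
  hyper_cube(array(stats::runif(rows * cols * bands), c(rows, cols, bands)),
             wavelengths = seq(900, 1000, length.out = bands),
             meta = list(calibrated = FALSE))
}
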