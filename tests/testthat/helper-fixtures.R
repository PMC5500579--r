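## Shared fixtures: long simulations are cached per test file so several
## test blocks can reuse one record.
.fixture_cache <- new.env(parent = emptyenv())

cached_sim <- function(Q, D0, b, n, dt, seed, burn_in = NULL) {
  key <- paste("sim", Q, D0, b, n, dt, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_langevin(langevin_model(Q, D0, b),
                                               n = n, dt = dt, seed = seed,
                                               burn_in = burn_in)
  .fixture_cache[[key]]
}

cached_km <- function(ts, extrapolate = TRUE) {
  key <- paste("km", ts$meta$seed, ts$n, ts$meta$model$Q, extrapolate, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- km_coefficients(ts, extrapolate = extrapolate)
  .fixture_cache[[key]]
}

## OU record resampled coarsely enough that neighbouring three-point triples
## decorrelate (about two samples per relaxation time); used by the Markov
## tests. The Euler step-size warning is expected at this coarse sampling
## and irrelevant to the Markov property.
markov_ou <- function(n = 4e5, seed = 7) {
  key <- paste("mou", n, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressWarnings(
      simulate_langevin(langevin_model(500, 50), n = n, dt = 1e-3,
                        seed = seed, burn_in = 1000))
  .fixture_cache[[key]]
}

moving_average_series <- function(ts, window) {
  sm <- stats::filter(ts$values, rep(1 / window, window), sides = 1)
  time_series(as.numeric(sm[!is.na(sm)]), dt = ts$dt)
}

## hand-built KM table for exact, noiseless fit tests
km_table <- function(center, D1, D2, count = 1000, se = 1) {
  structure(data.frame(center = center, count = count,
                       D1 = D1, se_D1 = se, D2 = D2, se_D2 = se,
                       D4 = 0, se_D4 = se),
            class = c("ot_km", "data.frame"))
}
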