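# Shared fixtures: built in code, no files.

# reference second-order stretched parameter set used across tests
ref_params <- function() {
  model_params(c(4, 1), c(30, 2), beta = 0.7, offset = 5)
}

# noiseless windowed trace from a parameter set
noiseless_trace <- function(params = ref_params(), duration = 85, fs = 20) {
  sensor_trace(evaluate_response(params, (0:(duration * fs - 1)) / fs),
               sampling_rate = fs)
}

# noisy trace with known sigma; returns list(trace, sigma, clean)
noisy_trace <- function(params = ref_params(), sigma_rel = 0.01,
                        duration = 85, fs = 20, seed = 1) {
  t <- (0:(duration * fs - 1)) / fs
  clean <- evaluate_response(params, t)
  sigma <- sigma_rel * diff(range(clean))
  x <- withr::with_seed(seed, clean + rnorm(length(t), 0, sigma))
  list(trace = sensor_trace(x, sampling_rate = fs), sigma = sigma,
       clean = clean)
}

# fast fitting config for unit tests (acceptance uses the default)
quick_cfg <- function(...) {
  fit_config(n_starts = 3, ...)
}

# a small ready-made split+augmented dataset for NN tests
small_dataset <- function(n = 10, copies = 2, seed = 5,
                          archetype = archetype_mos_fast()) {
  ds <- generate_dataset(archetype, n = n, seed = seed)
  ds <- split_dataset(ds, seed = seed)
  augment_dataset(ds, copies_per_sample = copies, seed = seed)
}
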