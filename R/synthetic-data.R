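#' Sensor archetypes for synthetic exposures
#'
#' An archetype bundles the sampling intervals for the response-model
#' coefficients of a class of sensor, the measurement-noise level, and the
#' acquisition geometry (sampling rate, exposure duration, pre-onset
#' baseline). Three presets mirror a typical low-cost breath-analysis
#' array: two metal-oxide channels (decaying resistance with a slow
#' stretched term of tens of seconds plus a fast second term) and one
#' electrochemical channel (much faster settling, rising output).
#' Intervals are implementer-chosen "realistic" ranges for such hardware,
#' not measured values.
#'
#' @param name Label.
#' @param a1,tau1,beta,a2,tau2,o Length-2 `c(lo, hi)` sampling intervals
#'   for the second-order stretched response coefficients (term 1 is the
#'   slow stretched term; `tau` in seconds).
#' @param noise_sigma_rel Additive white Gaussian measurement noise sigma,
#'   as a fraction of the clean trace's range.
#' @param duration Exposure duration in seconds (default 85).
#' @param sampling_rate Hz (default 20).
#' @param pre_onset_seconds Baseline recorded before the pump switches on.
#' @param airflow_slm Pump-on airflow in standard litres per minute; must
#'   exceed the 0.2 slm onset threshold.
#' @return A `sensor_archetype` list.
#' @examples
#' archetype_mos_fast()
#' @export
sensor_archetype <- function(name, a1, tau1, beta, a2, tau2, o,
                             noise_sigma_rel = 0.01, duration = 85,
                             sampling_rate = 20, pre_onset_seconds = 5,
                             airflow_slm = 1.0) {
  ranges <- list(a1 = a1, tau1 = tau1, beta = beta, a2 = a2, tau2 = tau2,
                 o = o)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      abort(sprintf("Interval `%s` must be c(lo, hi) with lo <= hi.", nm))
    }
  }
  if (noise_sigma_rel < 0) abort("`noise_sigma_rel` must be >= 0.")
  structure(
    list(name = name, ranges = ranges, noise_sigma_rel = noise_sigma_rel,
         duration = duration, sampling_rate = sampling_rate,
         pre_onset_seconds = pre_onset_seconds, airflow_slm = airflow_slm),
    class = "sensor_archetype"
  )
}

#' @rdname sensor_archetype
#' @export
archetype_mos_fast <- function() {
  sensor_archetype(
    "mos_fast",
    a1 = c(2, 6), tau1 = c(15, 45), beta = c(0.5, 1.0),
    a2 = c(0.5, 2), tau2 = c(0.5, 5), o = c(2, 8),
    noise_sigma_rel = 0.01
  )
}

#' @rdname sensor_archetype
#' @export
archetype_mos_slow <- function() {
  sensor_archetype(
    "mos_slow",
    a1 = c(20, 60), tau1 = c(25, 60), beta = c(0.5, 0.9),
    a2 = c(5, 15), tau2 = c(1, 6), o = c(40, 110),
    noise_sigma_rel = 0.01
  )
}

#' @rdname sensor_archetype
#' @export
archetype_electrochemical <- function() {
  sensor_archetype(
    "electrochemical",
    a1 = c(-10, -4), tau1 = c(2, 8), beta = c(0.7, 1.0),
    a2 = c(-3, -1), tau2 = c(0.2, 1.5), o = c(15, 25),
    noise_sigma_rel = 0.005
  )
}

#' @export
print.sensor_archetype <- function(x, ...) {
  cat(sprintf(
    "<sensor_archetype: %s, %g s @ %g Hz, noise %g of range>\n",
    x$name, x$duration, x$sampling_rate, x$noise_sigma_rel
  ))
  invisible(x)
}

sample_parameters_impl <- function(archetype) {
  r <- archetype$ranges
  draw <- function(iv) runif(1, iv[1], iv[2])
  a1 <- draw(r$a1); tau1 <- draw(r$tau1); beta <- draw(r$beta)
  a2 <- draw(r$a2); tau2 <- draw(r$tau2); o <- draw(r$o)
  # the slow term carries the stretch: keep tau1 > tau2 by swapping
  if (tau1 < tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
  }
  model_params(c(a1, a2), c(tau1, tau2), beta = beta, offset = o)
}

#' Draw response parameters from an archetype
#'
#' Independent uniform draws within the archetype's per-coefficient
#' intervals; the two time constants are swapped if needed so the slow
#' (stretched) term always has the larger one.
#'
#' @param archetype A [sensor_archetype()].
#' @param seed Integer seed.
#' @return A [model_params()] of order 2.
#' @export
sample_parameters <- function(archetype, seed) {
  withr::with_seed(seed, sample_parameters_impl(archetype))
}

simulate_trace_impl <- function(params, archetype) {
  fs <- archetype$sampling_rate
  n_pre <- round(archetype$pre_onset_seconds * fs)
  n_post <- round(archetype$duration * fs)
  t_post <- (0:(n_post - 1)) / fs
  clean <- evaluate_response(params, t_post)
  baseline <- sum(params$amplitudes) + params$offset
  sigma <- archetype$noise_sigma_rel * diff(range(clean))
  noisy <- clean + if (sigma > 0) rnorm(n_post, 0, sigma) else 0
  values <- c(rep(baseline, n_pre), noisy)
  airflow <- c(rep(0, n_pre), rep(archetype$airflow_slm, n_post))
  t0 <- -n_pre / fs
  list(
    sensor = sensor_trace(values, sampling_rate = fs, t0_offset = t0,
                          sensor_id = archetype$name, units = "arb"),
    airflow = sensor_trace(airflow, sampling_rate = fs, t0_offset = t0,
                           sensor_id = "airflow", units = "slm"),
    onset_index = n_pre + 1L,
    clean = clean,
    sigma = sigma
  )
}

#' Simulate one sensor exposure
#'
#' Produces a raw-style recording of a single exposure: a constant
#' pre-onset baseline at the model's `t = 0` value (`a1 + a2 + o`), then
#' the model transient plus additive white Gaussian noise, together with a
#' companion airflow channel that steps from 0 to the pump flow at the
#' onset sample. Feeding the airflow channel to
#' [detect_exposure_onset()] and windowing with
#' [extract_exposure_window()] recovers the analysis window exactly.
#'
#' @param params A [model_params()] (order 2).
#' @param archetype A [sensor_archetype()] supplying geometry and noise.
#' @param seed Integer seed for the noise.
#' @return List with `sensor` and `airflow` traces, the true
#'   `onset_index`, the noise-free post-onset `clean` samples and the
#'   noise `sigma` actually used.
#' @export
simulate_trace <- function(params, archetype, seed) {
  withr::with_seed(seed, simulate_trace_impl(params, archetype))
}

new_sensor_dataset <- function(df, archetype, seed) {
  structure(
    df,
    class = c("sensor_dataset", class(tibble::tibble())),
    archetype = archetype,
    seed = seed
  )
}

#' Generate a labelled synthetic dataset
#'
#' Repeats the exposure experiment `n` times: draws response coefficients
#' from the archetype, simulates the recording, detects the onset from the
#' airflow channel and extracts the exposure window. Each row stores the
#' windowed trace, the six generating coefficients as the target vector
#' (order `a1, tau1, beta, a2, tau2, o`), and the true final value (the
#' offset `o`).
#'
#' @param archetype A [sensor_archetype()].
#' @param n Number of exposures (default 25).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A `sensor_dataset` tibble with columns `trace_id`, `trace`
#'   (list of [sensor_trace()]), the six targets, `final_value`,
#'   `provenance`, `parent_id`, `split`.
#' @examples
#' ds <- generate_dataset(archetype_mos_fast(), n = 3, seed = 42)
#' ds$final_value
#' @export
generate_dataset <- function(archetype, n = 25, seed = 1) {
  if (n < 2) abort("`n` must be at least 2.")
  rows <- withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      params <- sample_parameters_impl(archetype)
      sim <- simulate_trace_impl(params, archetype)
      onset <- detect_exposure_onset(sim$airflow)
      windowed <- extract_exposure_window(sim$sensor, onset,
                                          duration = archetype$duration)
      rec <- params_to_record(params)
      tibble::tibble(
        trace_id = sprintf("real_%03d", i),
        trace = list(windowed),
        a1 = rec$a1, tau1 = rec$tau1, beta = rec$beta,
        a2 = rec$a2, tau2 = rec$tau2, o = rec$o,
        final_value = rec$o,
        provenance = "real", parent_id = NA_character_,
        split = NA_character_
      )
    })
  })
  new_sensor_dataset(dplyr::bind_rows(rows), archetype, seed)
}

#' Split a dataset into train and test portions
#'
#' Random 80-20 split (by default) of the real samples, drawn without
#' replacement under a seed. Splitting must precede augmentation so that
#' augmented children inherit their parent's assignment — this is what
#' keeps the augmented dataset stratified (no child of a test exposure
#' ever reaches the training set).
#'
#' @param ds A `sensor_dataset` containing only real samples.
#' @param train_fraction Fraction assigned to training (default 0.8);
#'   `ceiling(train_fraction * n)` rows train, the rest test.
#' @param seed Integer seed.
#' @return The dataset with its `split` column filled in.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 1) {
  if (any(ds$provenance != "real")) {
    abort("Split must precede augmentation: augmented samples present.")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  n <- nrow(ds)
  n_train <- ceiling(train_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  ds$split <- "test"
  ds$split[idx] <- "train"
  ds
}

#' Augment a dataset by amplitude/offset scaling plus noise
#'
#' Each original exposure gains `copies_per_sample` children built by
#' decomposing the trace into its steady-state offset and the transient
#' above it, scaling the transient by `s_a` and the offset by `s_o` (each
#' drawn uniformly per copy), and adding a small amount of white Gaussian
#' noise to suppress hidden features copied from the parent:
#' `x' = s_a (x - o) + s_o o + eps`. Because the decomposition uses the
#' sample's stored offset target, the transform maps a second-order
#' stretched response to another one exactly, so the child's target vector
#' is the parent's with amplitudes scaled by `s_a` and offset by `s_o`
#' (time constants and stretching exponent unchanged). Children inherit
#' their parent's split assignment.
#'
#' @param ds A split `sensor_dataset` of real samples.
#' @param copies_per_sample Children per original (default 4, growing 25
#'   exposures to 125 rows).
#' @param amp_scale_interval Uniform interval for `s_a`, default
#'   `c(0.8, 1.2)`.
#' @param offset_scale_interval Uniform interval for `s_o`, default
#'   `c(0.9, 1.1)`.
#' @param awgn_sigma_rel Added noise sigma as a fraction of the parent
#'   trace's range, default 0.005.
#' @param seed Integer seed.
#' @return The dataset with `n * (1 + copies_per_sample)` rows.
#' @export
augment_dataset <- function(ds, copies_per_sample = 4,
                            amp_scale_interval = c(0.8, 1.2),
                            offset_scale_interval = c(0.9, 1.1),
                            awgn_sigma_rel = 0.005, seed = 1) {
  if (any(is.na(ds$split))) {
    abort("Assign the train/test split before augmenting.")
  }
  if (any(ds$provenance != "real")) {
    abort("`ds` already contains augmented samples.")
  }
  if (any(amp_scale_interval <= 0) || any(offset_scale_interval <= 0)) {
    abort("Scale intervals must be strictly positive.")
  }
  if (copies_per_sample == 0) return(ds)
  flat <- ds
  class(flat) <- c("tbl_df", "tbl", "data.frame")
  children <- withr::with_seed(seed, {
    purrr::map(seq_len(nrow(flat)), function(i) {
      parent <- flat[i, ]
      tr <- parent$trace[[1]]
      rng <- diff(range(tr$value))
      purrr::map(seq_len(copies_per_sample), function(k) {
        s_a <- runif(1, amp_scale_interval[1], amp_scale_interval[2])
        s_o <- runif(1, offset_scale_interval[1], offset_scale_interval[2])
        sigma <- awgn_sigma_rel * rng
        eps <- if (sigma > 0) rnorm(nrow(tr), 0, sigma) else 0
        o <- parent$o
        vals <- s_a * (tr$value - o) + s_o * o + eps
        child <- parent
        child$trace_id <- sprintf("aug_%s_%d", parent$trace_id, k)
        child$trace <- list(trace_with_values(tr, vals))
        child$a1 <- parent$a1 * s_a
        child$a2 <- parent$a2 * s_a
        child$o <- parent$o * s_o
        child$final_value <- parent$final_value * s_o
        child$provenance <- "augmented"
        child$parent_id <- parent$trace_id
        child
      })
    })
  })
  out <- dplyr::bind_rows(ds, dplyr::bind_rows(purrr::flatten(children)))
  new_sensor_dataset(out, attr(ds, "archetype"), attr(ds, "seed"))
}

#' Persist and reload a dataset
#'
#' Writes a dataset as a directory: `manifest.csv` (trace id, provenance,
#' parent, split, the six targets, true final value, generator seed) plus
#' one `traces/<id>.csv` recording per trace.
#'
#' @param ds A `sensor_dataset`.
#' @param dir Directory path.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the reconstructed `sensor_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- dplyr::select(tibble::as_tibble(ds), -"trace")
  manifest$sampling_rate <- purrr::map_dbl(ds$trace, trace_sampling_rate)
  manifest$seed <- attr(ds, "seed") %||% NA_integer_
  readr::write_csv(manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  purrr::walk2(ds$trace_id, ds$trace, function(id, tr) {
    rec <- tibble::tibble(time = tr$time, value = tr$value)
    write_recording(rec, file.path(dir, "traces", paste0(id, ".csv")),
                    units = c("s", trace_units(tr)))
  })
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(
    file.path(dir, "manifest.csv"),
    col_types = readr::cols(
      trace_id = readr::col_character(),
      provenance = readr::col_character(),
      parent_id = readr::col_character(),
      split = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  traces <- purrr::map2(manifest$trace_id, manifest$sampling_rate,
    function(id, fs) {
      rec <- read_recording(file.path(dir, "traces", paste0(id, ".csv")))
      sensor_trace(rec$value, sampling_rate = fs, t0_offset = rec$time[1],
                   sensor_id = id,
                   units = attr(rec, "units")[["value"]] %||% "arb")
    })
  seed <- manifest$seed[1]
  manifest$sampling_rate <- NULL
  manifest$seed <- NULL
  df <- tibble::add_column(manifest, trace = traces, .after = "trace_id")
  new_sensor_dataset(df, NULL, seed)
}

#' @export
print.sensor_dataset <- function(x, ...) {
  arch <- attr(x, "archetype")
  cat(sprintf(
    "<sensor_dataset: %d traces (%d real, %d augmented)%s, seed %s>\n",
    nrow(x), sum(x$provenance == "real"),
    sum(x$provenance == "augmented"),
    if (!is.null(arch)) paste0(", archetype ", arch$name) else "",
    format(attr(x, "seed"))
  ))
  NextMethod()
}
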