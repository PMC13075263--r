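#' Convert ADC counts to voltage
#'
#' Linear conversion for an n-bit ADC: `v = counts * v_ref / (2^bits - 1)`.
#'
#' @param counts Integer vector of raw ADC readings.
#' @param v_ref ADC reference voltage, volts.
#' @param bits ADC resolution in bits (default 12).
#' @return Voltages, same length as `counts`.
#' @examples
#' adc_to_voltage(c(0, 2048, 4095), v_ref = 3.3)
#' @export
adc_to_voltage <- function(counts, v_ref, bits = 12) {
  full_scale <- 2^bits - 1
  bad <- which(counts < 0 | counts > full_scale)
  if (length(bad) > 0) {
    abort(sprintf(
      "ADC counts out of range [0, %d] at index %d (value %g).",
      full_scale, bad[1], counts[bad[1]]
    ))
  }
  counts * v_ref / full_scale
}

#' Voltage divider to sensor resistance
#'
#' A chemiresistor is read through a voltage divider with the sensor on the
#' high side (between supply and output node) and a fixed load resistor
#' from the output node to ground, so
#' `R_s = r_load * (v_cc - v_out) / v_out`. As the sensor conducts better
#' (gas adsorbing), `v_out` rises and the inferred resistance falls.
#'
#' @param v_out Measured divider output voltage, volts; must satisfy
#'   `0 < v_out < v_cc` (equality means a short or open sensor).
#' @param v_cc Supply voltage, volts.
#' @param r_load Load resistance to ground, ohms.
#' @return Sensor resistance in ohms.
#' @export
divider_to_resistance <- function(v_out, v_cc, r_load) {
  if (any(v_out <= 0) || any(v_out >= v_cc)) {
    abort("`v_out` must satisfy 0 < v_out < v_cc (open/short condition).")
  }
  r_load * (v_cc - v_out) / v_out
}

#' Shunt-amplifier voltage to current
#'
#' An electrochemical sensor's output current (order 90 uA in ambient air)
#' is dropped across a precision shunt and amplified;
#' `I = v_amplified / (r_shunt * gain)`.
#'
#' @param v_amplified Amplified shunt voltage, volts.
#' @param r_shunt Shunt resistance, ohms (default 100).
#' @param gain Amplifier gain, dimensionless (default 225).
#' @return Current in amperes.
#' @export
shunt_amp_to_current <- function(v_amplified, r_shunt = 100, gain = 225) {
  if (r_shunt <= 0 || gain <= 0) {
    abort("`r_shunt` and `gain` must be positive.")
  }
  v_amplified / (r_shunt * gain)
}

# sliding median with replicate padding on a plain numeric vector
median_filter_vec <- function(x, window) {
  if (window %% 2 == 0 || window < 1) {
    abort("`window` must be an odd integer >= 1.")
  }
  n <- length(x)
  if (window > n) {
    abort("`window` must not exceed the signal length.")
  }
  if (window == 1) {
    return(x)
  }
  half <- (window - 1) / 2
  padded <- c(rep(x[1], half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) median(padded[i:(i + window - 1)]),
         numeric(1))
}

#' Median filter a trace
#'
#' Sliding-window median with replicate padding at the edges, preserving
#' length. With the default window of 3 samples (150 ms at 20 Hz) it
#' suppresses isolated spikes and glitch readings while leaving the much
#' slower sensor dynamics intact.
#'
#' @param trace A [sensor_trace()] or plain numeric vector.
#' @param window Odd window length in samples, default 3.
#' @return Filtered trace of the same type and length as the input.
#' @examples
#' median_filter(c(1, 1, 9, 1, 1))
#' @export
median_filter <- function(trace, window = 3) {
  if (inherits(trace, "sensor_trace")) {
    trace_with_values(trace, median_filter_vec(trace$value, window))
  } else if (is.numeric(trace)) {
    median_filter_vec(trace, window)
  } else {
    abort("`trace` must be a sensor_trace or numeric vector.")
  }
}

#' Detect the exposure onset from the airflow channel
#'
#' The exposure period starts when the pump switches on; the onset `t0` is
#' the first sample where airflow strictly exceeds the threshold
#' (default 0.2 slm, standard litres per minute).
#'
#' @param airflow A [sensor_trace()] or numeric vector of airflow in slm.
#' @param threshold Onset threshold in slm, default 0.2.
#' @return The 1-based index of the first sample above threshold.
#' @examples
#' detect_exposure_onset(sensor_trace(c(0, 0, 0.3, 1), sampling_rate = 20))
#' @export
detect_exposure_onset <- function(airflow, threshold = 0.2) {
  values <- if (inherits(airflow, "sensor_trace")) airflow$value else airflow
  idx <- which(values > threshold)
  if (length(idx) == 0) {
    abort(sprintf(
      "No exposure detected: airflow never exceeds %g slm.", threshold
    ))
  }
  idx[1]
}

#' Extract the exposure analysis window
#'
#' Returns `duration * sampling_rate` samples starting at the onset sample,
#' re-timed so the window starts at `t = 0`. The window is half-open:
#' samples `[onset, onset + duration * fs)` in 1-based indexing.
#'
#' @param trace A [sensor_trace()].
#' @param onset 1-based onset sample index, e.g. from
#'   [detect_exposure_onset()] on the companion airflow channel.
#' @param duration Window length in seconds, default 85.
#' @return A [sensor_trace()] of exactly `duration * fs` samples with
#'   `t0_offset = 0`.
#' @export
extract_exposure_window <- function(trace, onset, duration = 85) {
  assert_sensor_trace(trace)
  fs <- trace_sampling_rate(trace)
  n_out <- round(duration * fs)
  n <- nrow(trace)
  if (onset < 1 || onset > n) {
    abort("`onset` must be a valid sample index.")
  }
  avail <- (n - onset + 1) / fs
  if (onset + n_out - 1 > n) {
    abort(sprintf(
      "Insufficient samples after onset: %.2f s available, %g s requested.",
      avail, duration
    ))
  }
  trace_with_values(trace, trace$value[onset:(onset + n_out - 1)],
                    t0_offset = 0)
}

#' Read and write multi-channel recordings as CSV
#'
#' A recording is a tibble with a `time` column (seconds) and one column
#' per channel. On disk the layout is: a header row of channel names, a
#' second row of unit labels, then the samples. `read_recording()` accepts
#' a `column_map` (named list, standard name -> file column name) so files
#' with other naming conventions can be loaded without editing them.
#'
#' @param recording Tibble with a `time` column plus channel columns.
#' @param path File path.
#' @param units Character vector of unit labels, one per column (recycled
#'   from `"arb"` with `"s"` for time when omitted).
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` returns a tibble with a `units` attribute.
#' @export
write_recording <- function(recording, path, units = NULL) {
  if (!"time" %in% names(recording)) {
    abort("`recording` must contain a `time` column.")
  }
  if (is.null(units)) {
    units <- ifelse(names(recording) == "time", "s", "arb")
  }
  if (length(units) != ncol(recording)) {
    abort("`units` must have one entry per column.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(recording), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  utils::write.table(recording, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_recording
#' @param column_map Optional named list mapping standard channel names to
#'   the names used in the file, e.g. `list(airflow = "Flow_slm")`.
#' @export
read_recording <- function(path, column_map = NULL) {
  header <- readr::read_lines(path, n_max = 2)
  col_names <- strsplit(header[1], ",")[[1]]
  units <- strsplit(header[2], ",")[[1]]
  out <- readr::read_csv(
    path, skip = 2, col_names = col_names,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      file_col <- column_map[[std]]
      if (!file_col %in% names(out)) {
        abort(sprintf("Mapped column `%s` not found in %s.", file_col, path))
      }
      names(out)[names(out) == file_col] <- std
      units[col_names == file_col] <- units[col_names == file_col]
    }
  }
  attr(out, "units") <- setNames(units, names(out))
  out
}
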