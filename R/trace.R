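#' Construct a sensor trace
#'
#' A sensor trace is one uniformly sampled sensor channel in engineering
#' units, stored as a tibble with `time` (seconds) and `value` columns plus
#' acquisition metadata (sampling rate, time origin, sensor id, units).
#' Time is sample-index based: sample `k` (1-based) sits at
#' `t0_offset + (k - 1) / sampling_rate`, and `t = 0` is the exposure onset.
#'
#' @param values Numeric vector of samples in engineering units.
#' @param sampling_rate Sampling rate in Hz (default 20).
#' @param t0_offset Time of the first sample relative to exposure onset, in
#'   seconds. A windowed exposure trace has `t0_offset = 0`; a raw recording
#'   that starts before the pump switches on has a negative offset.
#' @param sensor_id Label for the sensor channel.
#' @param units Label for the engineering units (e.g. `"kOhm"`, `"uA"`).
#' @return A `sensor_trace` tibble with columns `time` and `value`.
#' @examples
#' tr <- sensor_trace(5 + exp(-(0:99) / 20), sampling_rate = 20)
#' trace_sampling_rate(tr)
#' @export
sensor_trace <- function(values, sampling_rate = 20, t0_offset = 0,
                         sensor_id = "sensor", units = "arb") {
  if (!is.numeric(values) || length(values) < 2) {
    rlang::abort("`values` must be a numeric vector of length >= 2.")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite.")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    rlang::abort("`sampling_rate` must be a single positive number.")
  }
  out <- tibble::tibble(
    time = t0_offset + (seq_along(values) - 1) / sampling_rate,
    value = as.double(values)
  )
  structure(
    out,
    class = c("sensor_trace", class(out)),
    sampling_rate = as.double(sampling_rate),
    t0_offset = as.double(t0_offset),
    sensor_id = sensor_id,
    units = units
  )
}

#' Trace metadata accessors
#'
#' @param trace A [sensor_trace()].
#' @return The sampling rate (Hz), time origin (s), sensor id or unit label.
#' @export
trace_sampling_rate <- function(trace) attr(trace, "sampling_rate")

#' @rdname trace_sampling_rate
#' @export
trace_t0_offset <- function(trace) attr(trace, "t0_offset")

#' @rdname trace_sampling_rate
#' @export
trace_sensor_id <- function(trace) attr(trace, "sensor_id")

#' @rdname trace_sampling_rate
#' @export
trace_units <- function(trace) attr(trace, "units")

#' Duration of a trace in seconds
#'
#' @param trace A [sensor_trace()].
#' @return Span covered by the samples, `length / sampling_rate`, in seconds.
#' @export
trace_duration <- function(trace) {
  nrow(trace) / trace_sampling_rate(trace)
}

# internal: rebuild a trace with new values, keeping metadata
trace_with_values <- function(trace, values, t0_offset = NULL) {
  sensor_trace(
    values,
    sampling_rate = trace_sampling_rate(trace),
    t0_offset = t0_offset %||% trace_t0_offset(trace),
    sensor_id = trace_sensor_id(trace),
    units = trace_units(trace)
  )
}

assert_sensor_trace <- function(trace, arg = "trace") {
  if (!inherits(trace, "sensor_trace")) {
    rlang::abort(sprintf("`%s` must be a sensor_trace object.", arg))
  }
  invisible(trace)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf(
    "<sensor_trace: %s, %d samples @ %g Hz, t0_offset %g s, units %s>\n",
    trace_sensor_id(x), nrow(x), trace_sampling_rate(x),
    trace_t0_offset(x), trace_units(x)
  ))
  NextMethod()
}

#' Plot a sensor trace
#'
#' @param object A [sensor_trace()].
#' @param ... Unused.
#' @return A ggplot object showing value against time, with the exposure
#'   onset (t = 0) marked when the trace starts before it.
#' @export
autoplot.sensor_trace <- function(object, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time, y = .data$value)
  ) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "time since exposure onset [s]",
      y = sprintf("%s [%s]", trace_sensor_id(object), trace_units(object))
    )
  if (trace_t0_offset(object) < 0) {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed")
  }
  p
}
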