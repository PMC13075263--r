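#' Operational ground-truth final value of a trace
#'
#' The "true" steady-state value a forecast is judged against. The default
#' is the model-free tail mean — the average of the final second of the
#' full exposure window (20 samples at 20 Hz), by which point the slow
#' term has decayed for sensors whose time constants are well inside the
#' window. The alternative reads the offset from a full-span fit of the
#' reference model.
#'
#' @param trace A full windowed [sensor_trace()].
#' @param method `"tail_mean"` (default) or `"fit_offset"`.
#' @param tail_seconds Tail-window length for `tail_mean`, default 1 s.
#' @param config [fit_config()] used by `fit_offset`.
#' @return Final value in engineering units.
#' @export
ground_truth_final_value <- function(trace,
                                     method = c("tail_mean", "fit_offset"),
                                     tail_seconds = 1,
                                     config = fit_config()) {
  assert_sensor_trace(trace)
  method <- match.arg(method)
  if (method == "tail_mean") {
    n_tail <- round(tail_seconds * trace_sampling_rate(trace))
    if (n_tail < 1 || n_tail > nrow(trace)) {
      abort(sprintf(
        "Trace too short for a %g s tail window (%d samples available).",
        tail_seconds, nrow(trace)
      ))
    }
    mean(tail(trace$value, n_tail))
  } else {
    fit <- fit_response(trace, config)
    steady_state_value(fit$params)
  }
}

#' Forecast error metrics
#'
#' Arithmetic and geometric aggregates of the absolute forecast errors:
#' MAE (mean absolute error), MAPE (mean absolute percentage error, in
#' percent of `|true|`), and their geometric counterparts GMAE and GMAPE.
#' The geometric mean down-weights extreme outliers — a single wildly
#' wrong forecast dominates the MAE but barely moves the GMAE. Exact-zero
#' errors are floored at `eps` inside the geometric means (and noted via
#' an attribute) since `log 0` is undefined; by the AM-GM inequality
#' GMAE <= MAE always.
#'
#' @param true_vals,predicted_vals Equal-length numeric vectors; true
#'   values must be nonzero for the percentage metrics.
#' @param eps Floor applied to zero errors inside geometric means.
#' @return One-row tibble: `n`, `mae`, `mape`, `gmae`, `gmape`.
#' @examples
#' error_metrics(c(10, 10), c(11, 14)) # MAE 2.5, GMAE 2
#' @export
error_metrics <- function(true_vals, predicted_vals, eps = 1e-12) {
  if (length(true_vals) != length(predicted_vals) ||
      length(true_vals) < 1) {
    abort("Inputs must be equal-length vectors of length >= 1.")
  }
  if (any(true_vals == 0)) {
    abort("Percentage errors are undefined for true values of zero.")
  }
  ae <- abs(predicted_vals - true_vals)
  ape <- ae / abs(true_vals) * 100
  floored <- any(ae < eps) || any(ape < eps)
  out <- tibble::tibble(
    n = length(ae),
    mae = mean(ae),
    mape = mean(ape),
    gmae = exp(mean(log(pmax(ae, eps)))),
    gmape = exp(mean(log(pmax(ape, eps))))
  )
  attr(out, "zero_errors_floored") <- floored
  out
}

#' Compare forecasting methods on the test split
#'
#' Evaluates up to three forecasters of the steady-state value on every
#' test-split trace, all seeing only the first `window_seconds` of the
#' exposure: truncated-fit NLLSQ extrapolation (`nllsq_tn10`), the
#' coefficient-predicting network (`dnn_param`) and the direct final-value
#' network (`dnn_final`). Per-sample errors are aggregated with
#' [error_metrics()]; samples with an absolute percentage error above 3x
#' the method's median are flagged as outliers (flagged only — no sample
#' is dropped).
#'
#' @param ds A split `sensor_dataset`.
#' @param param_model,final_model Trained [train_forecaster()] models;
#'   required when the corresponding method is requested.
#' @param methods Subset of `c("nllsq_tn10", "dnn_param", "dnn_final")`.
#' @param window_seconds Forecast window in seconds (default 10).
#' @param truth `"tail_mean"`, `"fit_offset"` or `"stored"` (the
#'   generator's true final value, synthetic data only).
#' @param fit_cfg [fit_config()] for the NLLSQ method (its `tn` is set to
#'   the window).
#' @return A `forecast_report`: list with `per_sample` and `summary`
#'   tibbles; see [tidy.forecast_report()], [autoplot.forecast_report()].
#' @export
method_comparison <- function(ds, param_model = NULL, final_model = NULL,
                              methods = c("nllsq_tn10", "dnn_param",
                                          "dnn_final"),
                              window_seconds = 10,
                              truth = c("tail_mean", "fit_offset",
                                        "stored"),
                              fit_cfg = fit_config()) {
  truth <- match.arg(truth)
  methods <- match.arg(methods, several.ok = TRUE)
  if ("dnn_param" %in% methods && is.null(param_model)) {
    abort("Method `dnn_param` requested but `param_model` is missing.")
  }
  if ("dnn_final" %in% methods && is.null(final_model)) {
    abort("Method `dnn_final` requested but `final_model` is missing.")
  }
  test <- ds[!is.na(ds$split) & ds$split == "test", ]
  if (nrow(test) == 0) abort("Test split is empty.")
  true_vals <- switch(
    truth,
    stored = test$final_value,
    tail_mean = purrr::map_dbl(test$trace, ground_truth_final_value,
                               method = "tail_mean"),
    fit_offset = purrr::map_dbl(test$trace, ground_truth_final_value,
                                method = "fit_offset", config = fit_cfg)
  )
  window_of <- function(tr, n) tr$value[1:n]
  per_method <- purrr::map(methods, function(m) {
    pred <- switch(
      m,
      nllsq_tn10 = purrr::map_dbl(test$trace, function(tr) {
        cfg <- fit_cfg
        cfg$tn <- window_seconds
        fit <- fit_response(tr, cfg)
        steady_state_value(fit$params)
      }),
      dnn_param = {
        n <- param_model$spec$input_size
        w <- t(vapply(test$trace, window_of, numeric(n), n = n))
        forecast_final_value(param_model, w)
      },
      dnn_final = {
        n <- final_model$spec$input_size
        w <- t(vapply(test$trace, window_of, numeric(n), n = n))
        forecast_final_value(final_model, w)
      }
    )
    tibble::tibble(
      method = m, trace_id = test$trace_id,
      true_value = true_vals, predicted = pred,
      abs_error = abs(pred - true_vals),
      ape = abs(pred - true_vals) / abs(true_vals) * 100
    )
  })
  per_sample <- dplyr::bind_rows(per_method)
  per_sample <- dplyr::mutate(
    dplyr::group_by(per_sample, .data$method),
    outlier = .data$ape > 3 * median(.data$ape)
  )
  per_sample <- dplyr::ungroup(per_sample)
  summary <- dplyr::group_modify(
    dplyr::group_by(per_sample, .data$method),
    ~ error_metrics(.x$true_value, .x$predicted)
  )
  summary <- dplyr::ungroup(summary)
  structure(
    list(per_sample = per_sample, summary = summary,
         window_seconds = window_seconds, truth = truth,
         n_test = nrow(test)),
    class = "forecast_report"
  )
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf(
    "<forecast_report: %d test traces, %g s window, truth = %s>\n",
    x$n_test, x$window_seconds, x$truth
  ))
  print(x$summary)
  invisible(x)
}

#' Tidy a forecast report
#'
#' @param x A `forecast_report`.
#' @param type `"summary"` (per-method aggregates) or `"samples"`
#'   (per-sample predictions with outlier flags).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.forecast_report <- function(x, type = c("summary", "samples"), ...) {
  type <- match.arg(type)
  if (type == "summary") x$summary else x$per_sample
}

#' Glance at a forecast report
#'
#' @param x A `forecast_report`.
#' @param ... Unused.
#' @return One-row tibble naming the best method by GMAPE.
#' @export
glance.forecast_report <- function(x, ...) {
  best <- x$summary$method[which.min(x$summary$gmape)]
  tibble::tibble(
    n_test = x$n_test, n_methods = nrow(x$summary),
    window_seconds = x$window_seconds, truth = x$truth,
    best_method = best, best_gmape = min(x$summary$gmape)
  )
}

#' Histogram of absolute percentage errors per method
#'
#' @param object A `forecast_report`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot faceted by method; the long right tail shows the
#'   outlier forecasts that separate the MAE from the GMAE.
#' @export
autoplot.forecast_report <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$per_sample, ggplot2::aes(x = .data$ape)) +
    ggplot2::geom_histogram(bins = bins, fill = "#7570b3",
                            colour = "white") +
    ggplot2::facet_wrap(~method, scales = "free_x") +
    ggplot2::labs(x = "absolute percentage error [%]", y = "count")
}
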