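#' Response-model forms
#'
#' The transient of an adsorptive gas sensor after a concentration step is
#' modelled by a family of decaying-exponential curves
#' \deqn{x(t) = a_1 e^{-((t+d)/\tau_1)^\beta} + \sum_{i=2}^{n} a_i e^{-t/\tau_i} + o,}
#' where the first term may carry a stretching exponent \eqn{\beta}
#' (a Kohlrausch / stretched exponential, capturing heterogeneous
#' relaxation) and an optional delay \eqn{d}. A `model_form` records which
#' features are active: the order `n` (number of exponential terms),
#' whether term 1 is stretched, and whether the delay applies.
#'
#' The four standard candidates for a single exposure are
#' first-order plain (`order 1`), first-order stretched, second-order
#' plain, and second-order stretched; [table_forms()] returns them in that
#' order. The second-order stretched form is the reference model for
#' steady-state forecasting.
#'
#' @param order Number of exponential terms, a positive integer.
#' @param stretched Logical; does term 1 carry the exponent beta?
#' @param delayed Logical; is the delay `d` applied to term 1? Delayed
#'   variants exist for model-selection experiments; they over-parameterise
#'   single-exposure fits and are not used by default.
#' @return A `model_form` list with fields `order`, `stretched`, `delayed`.
#' @examples
#' model_form(2, stretched = TRUE)
#' names(table_forms())
#' @export
model_form <- function(order = 2, stretched = TRUE, delayed = FALSE) {
  if (!is.numeric(order) || length(order) != 1 || order < 1 ||
      order != round(order)) {
    abort("`order` must be a positive integer.")
  }
  structure(
    list(order = as.integer(order), stretched = isTRUE(stretched),
         delayed = isTRUE(delayed)),
    class = "model_form"
  )
}

#' @rdname model_form
#' @export
table_forms <- function() {
  list(
    exp1           = model_form(1, stretched = FALSE),
    stretched1     = model_form(1, stretched = TRUE),
    exp2           = model_form(2, stretched = FALSE),
    stretched2     = model_form(2, stretched = TRUE)
  )
}

#' @export
print.model_form <- function(x, ...) {
  cat(sprintf(
    "<model_form: order %d%s%s>\n", x$order,
    if (x$stretched) ", stretched" else "",
    if (x$delayed) ", delayed" else ""
  ))
  invisible(x)
}

# number of free parameters when fitting this form
form_n_params <- function(form) {
  2L * form$order + 1L + as.integer(form$stretched) + as.integer(form$delayed)
}

form_label <- function(form) {
  sprintf("order%d%s%s", form$order,
          if (form$stretched) "_stretched" else "",
          if (form$delayed) "_delayed" else "")
}

#' Response-model parameters
#'
#' Coefficients of the exponential response family: per-term amplitudes
#' `a_i` (engineering units) and time constants `tau_i` (seconds), the
#' stretching exponent `beta` of term 1, an optional delay `d` (seconds),
#' and the offset `o` — the steady-state value the response settles to.
#'
#' @param amplitudes Numeric vector `a_1 ... a_n` (term 1 is the slow,
#'   possibly stretched term).
#' @param time_constants Positive numeric vector `tau_1 ... tau_n`, seconds.
#' @param beta Stretching exponent, positive; `1` gives a plain exponential.
#' @param delay Delay `d` in seconds applied to term 1; `0` when unused.
#' @param offset Steady-state offset `o` in engineering units.
#' @return A `model_params` object.
#' @examples
#' p <- model_params(c(4, 1), c(30, 2), beta = 0.7, offset = 5)
#' steady_state_value(p)
#' @export
model_params <- function(amplitudes, time_constants, beta = 1, delay = 0,
                         offset = 0) {
  if (length(amplitudes) != length(time_constants) ||
      length(amplitudes) < 1) {
    abort("`amplitudes` and `time_constants` must have equal length >= 1.")
  }
  vals <- c(amplitudes, time_constants, beta, delay, offset)
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    abort("All model parameters must be finite numbers.")
  }
  if (any(time_constants <= 0)) {
    abort("All time constants `tau_i` must be positive.")
  }
  if (beta <= 0) {
    abort("`beta` must be positive.")
  }
  structure(
    list(
      amplitudes = as.double(amplitudes),
      time_constants = as.double(time_constants),
      beta = as.double(beta),
      delay = as.double(delay),
      offset = as.double(offset)
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params: order %d, a = [%s], tau = [%s] s, beta = %g, d = %g, o = %g>\n",
    length(x$amplitudes),
    paste(signif(x$amplitudes, 4), collapse = ", "),
    paste(signif(x$time_constants, 4), collapse = ", "),
    x$beta, x$delay, x$offset
  ))
  invisible(x)
}

params_order <- function(params) length(params$amplitudes)

# implied form of a parameter set (beta == 1 collapses the stretch flag)
params_form <- function(params) {
  model_form(params_order(params),
             stretched = params$beta != 1,
             delayed = params$delay != 0)
}

#' Evaluate a response model
#'
#' Computes
#' \eqn{x(t) = a_1 e^{-((t+d)/\tau_1)^\beta} + \sum_{i \ge 2} a_i e^{-t/\tau_i} + o}
#' elementwise over a time grid. With `beta = 1` and `delay = 0` this is a
#' plain sum of exponentials. Negative times are rejected (the model
#' describes the post-onset transient); with a delay, `t + d` must be
#' non-negative, since a fractional power of a negative base is undefined.
#'
#' @param params A [model_params()] object.
#' @param times Numeric vector of times in seconds since exposure onset.
#' @param form Optional [model_form()]; when supplied, it is checked for
#'   consistency with `params` (order must match; a non-stretched form
#'   requires `beta == 1`, a non-delayed form `delay == 0`).
#' @return Numeric vector of responses in engineering units.
#' @examples
#' p <- model_params(c(1, -0.3), c(10, 1), beta = 0.7, offset = 2)
#' evaluate_response(p, c(0, 1, 10))
#' @export
evaluate_response <- function(params, times, form = NULL) {
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params object.")
  }
  if (!is.numeric(times) || !all(is.finite(times))) {
    abort("`times` must be finite numeric.")
  }
  if (!is.null(form)) {
    if (form$order != params_order(params)) {
      abort("`form$order` does not match the number of amplitude terms.")
    }
    if (!form$stretched && params$beta != 1) {
      abort("Non-stretched form requires beta == 1.")
    }
    if (!form$delayed && params$delay != 0) {
      abort("Non-delayed form requires delay == 0.")
    }
  }
  shifted <- times + params$delay
  if (any(shifted < 0)) {
    abort(paste0(
      "Negative (t + d) encountered: the response model is defined for ",
      "t + d >= 0 (stretched power of a negative base is undefined)."
    ))
  }
  x <- params$amplitudes[1] *
    exp(-(shifted / params$time_constants[1])^params$beta)
  n <- params_order(params)
  if (n >= 2) {
    for (i in 2:n) {
      x <- x + params$amplitudes[i] * exp(-times / params$time_constants[i])
    }
  }
  x + params$offset
}

#' Steady-state (final) value of a response model
#'
#' The limit of the response as `t` grows without bound: every exponential
#' term vanishes and only the offset `o` remains. This is the forecasting
#' target for breath-by-breath analysis — the value the sensor would settle
#' to if left exposed indefinitely.
#'
#' @param params A [model_params()] object.
#' @return The offset `o`, in engineering units.
#' @export
steady_state_value <- function(params) {
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params object.")
  }
  params$offset
}

#' Langmuir adsorption parameters
#'
#' Ideal monolayer adsorption: the fractional occupancy `theta` of surface
#' sites obeys \eqn{d\theta/dt = k_{ad}(1-\theta) - k_d\,\theta}, adsorption
#' proportional to free sites and desorption to occupied ones.
#'
#' @param k_ad Adsorption rate constant, 1/s, positive.
#' @param k_d Desorption rate constant, 1/s, positive.
#' @param theta0 Initial fractional occupancy in `[0, 1]`; fixes the
#'   integration constant.
#' @return A `langmuir_params` object.
#' @export
langmuir_params <- function(k_ad, k_d, theta0 = 0) {
  if (!is.numeric(k_ad) || k_ad <= 0 || !is.numeric(k_d) || k_d <= 0) {
    abort("`k_ad` and `k_d` must be positive rate constants.")
  }
  if (theta0 < 0 || theta0 > 1) {
    abort("`theta0` must lie in [0, 1].")
  }
  structure(
    list(k_ad = as.double(k_ad), k_d = as.double(k_d),
         theta0 = as.double(theta0)),
    class = "langmuir_params"
  )
}

#' Langmuir occupancy solution
#'
#' Closed-form solution of the Langmuir rate equation:
#' \deqn{\theta(t) = \frac{k_{ad} - C_1 e^{-t(k_{ad}+k_d)}}{k_{ad}+k_d},}
#' with \eqn{C_1} chosen so that \eqn{\theta(0)} equals the initial
#' occupancy. The steady state is \eqn{k_{ad}/(k_{ad}+k_d)}; the approach is
#' a single exponential with rate \eqn{k_{ad}+k_d} — the first-order
#' ancestor of the response-model family.
#'
#' @param p A [langmuir_params()] object.
#' @param times Non-negative times in seconds.
#' @return Fractional occupancy values in `[0, 1]`.
#' @examples
#' p <- langmuir_params(1, 1, theta0 = 0)
#' langmuir_occupancy(p, c(0, 1, 100))
#' @export
langmuir_occupancy <- function(p, times) {
  if (!inherits(p, "langmuir_params")) {
    abort("`p` must be a langmuir_params object.")
  }
  if (any(times < 0)) {
    abort("`times` must be non-negative.")
  }
  k <- p$k_ad + p$k_d
  c1 <- p$k_ad - p$theta0 * k
  (p$k_ad - c1 * exp(-times * k)) / k
}

#' Flatten model parameters to a one-row record
#'
#' Serialises a second-order (or first-order) parameter set to the flat
#' key layout `a1, tau1, beta, a2, tau2, o, d` used for fit persistence in
#' CSV/JSON; [record_to_params()] inverts it. A first-order set stores
#' `NA` for `a2`/`tau2`.
#'
#' @param params A [model_params()] of order 1 or 2.
#' @return A one-row tibble with columns `a1, tau1, beta, a2, tau2, o, d`.
#' @export
params_to_record <- function(params) {
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params object.")
  }
  n <- params_order(params)
  if (n > 2) {
    abort("Flat records cover orders 1 and 2 only.")
  }
  tibble::tibble(
    a1 = params$amplitudes[1],
    tau1 = params$time_constants[1],
    beta = params$beta,
    a2 = if (n >= 2) params$amplitudes[2] else NA_real_,
    tau2 = if (n >= 2) params$time_constants[2] else NA_real_,
    o = params$offset,
    d = params$delay
  )
}

#' @rdname params_to_record
#' @param record A one-row data frame (or named list) with the flat keys.
#' @export
record_to_params <- function(record) {
  record <- as.list(record)
  needed <- c("a1", "tau1", "beta", "o")
  if (!all(needed %in% names(record))) {
    abort("Record must contain at least a1, tau1, beta, o.")
  }
  second <- !is.null(record$a2) && !is.na(record$a2)
  d <- record$d
  if (is.null(d) || is.na(d)) d <- 0
  model_params(
    amplitudes = if (second) c(record$a1, record$a2) else record$a1,
    time_constants = if (second) c(record$tau1, record$tau2) else record$tau1,
    beta = record$beta,
    delay = d,
    offset = record$o
  )
}
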