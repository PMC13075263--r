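#' Fitting configuration
#'
#' Controls the multi-start nonlinear least-squares fit of a response
#' model to a trace.
#'
#' @param form The [model_form()] to fit (default: second-order stretched,
#'   the reference model).
#' @param tn Fit horizon in seconds: only samples in `[0, tn]` enter the
#'   least-squares objective. `NULL` uses the whole trace. Truncated
#'   horizons probe extrapolation: the fit is scored on the full curve.
#' @param n_starts Number of multi-start initialisations (>= 1). The first
#'   start is a data-driven heuristic; the rest jitter it by +/-50%,
#'   seeded.
#' @param max_iterations Levenberg-Marquardt iteration cap per start.
#' @param tolerance Solver tolerance (relative reduction in the sum of
#'   squares / relative parameter change) and the base of the convergence
#'   check on the projected gradient.
#' @param seed Integer seed for the start jitter; fixed seed gives a
#'   bit-identical fit.
#' @param bounds Named list of per-parameter intervals, see
#'   [default_fit_bounds()].
#' @return A `fit_config` list.
#' @export
fit_config <- function(form = model_form(2, stretched = TRUE), tn = NULL,
                       n_starts = 8, max_iterations = 200,
                       tolerance = 1e-8, seed = 1,
                       bounds = default_fit_bounds()) {
  if (!inherits(form, "model_form")) abort("`form` must be a model_form.")
  if (!is.null(tn) && tn <= 0) abort("`tn` must be positive.")
  if (n_starts < 1) abort("`n_starts` must be >= 1.")
  structure(
    list(form = form, tn = tn, n_starts = as.integer(n_starts),
         max_iterations = as.integer(max_iterations),
         tolerance = tolerance, seed = as.integer(seed), bounds = bounds),
    class = "fit_config"
  )
}

#' Default fitting bounds
#'
#' Box constraints for the Levenberg-Marquardt solver. Time constants are
#' kept in `[0.05, 500]` s (below one sample period is unresolvable at
#' 20 Hz; beyond 500 s is indistinguishable from a constant over an 85 s
#' window). The stretching exponent is kept in `[0.1, 1.5]`: fits on plain
#' exponential data sit near 1, and values far outside degenerate
#' numerically. Amplitudes and offset are unbounded in sign — an
#' electrochemical channel may rise rather than decay. The delay, used
#' only by the deliberately over-parameterised delayed variants, is kept
#' non-negative so `t + d` stays in the stretched term's domain.
#'
#' @return Named list of `c(lower, upper)` intervals.
#' @export
default_fit_bounds <- function() {
  list(
    amplitude = c(-Inf, Inf),
    tau = c(0.05, 500),
    beta = c(0.1, 1.5),
    delay = c(0, 10),
    offset = c(-Inf, Inf)
  )
}

# ---- parameter vector packing ----------------------------------------------

param_names_for <- function(form) {
  nm <- c("a1", "tau1")
  if (form$stretched) nm <- c(nm, "beta")
  if (form$order >= 2) {
    for (i in 2:form$order) nm <- c(nm, paste0("a", i), paste0("tau", i))
  }
  if (form$delayed) nm <- c(nm, "d")
  c(nm, "o")
}

pack_params <- function(params, form) {
  stopifnot(params_order(params) == form$order)
  v <- c(params$amplitudes[1], params$time_constants[1])
  if (form$stretched) v <- c(v, params$beta)
  if (form$order >= 2) {
    for (i in 2:form$order) {
      v <- c(v, params$amplitudes[i], params$time_constants[i])
    }
  }
  if (form$delayed) v <- c(v, params$delay)
  setNames(c(v, params$offset), param_names_for(form))
}

unpack_params <- function(vec, form) {
  vec <- setNames(as.double(vec), param_names_for(form))
  n <- form$order
  amps <- vec[paste0("a", seq_len(n))]
  taus <- vec[paste0("tau", seq_len(n))]
  model_params(
    amplitudes = unname(amps),
    time_constants = unname(taus),
    beta = if (form$stretched) unname(vec["beta"]) else 1,
    delay = if (form$delayed) unname(vec["d"]) else 0,
    offset = unname(vec["o"])
  )
}

bounds_for <- function(form, bounds) {
  nm <- param_names_for(form)
  lower <- upper <- setNames(numeric(length(nm)), nm)
  for (j in seq_along(nm)) {
    key <- nm[j]
    b <- if (grepl("^a", key)) bounds$amplitude
         else if (grepl("^tau", key)) bounds$tau
         else if (key == "beta") bounds$beta
         else if (key == "d") bounds$delay
         else bounds$offset
    lower[j] <- b[1]
    upper[j] <- b[2]
  }
  list(lower = lower, upper = upper)
}

# model and analytic Jacobian on a packed parameter vector
model_fun_packed <- function(vec, form, t) {
  evaluate_response(unpack_params(vec, form), t)
}

model_jac_packed <- function(vec, form, t) {
  p <- unpack_params(vec, form)
  n <- form$order
  u <- (t + p$delay) / p$time_constants[1]
  ub <- u^p$beta
  e1 <- exp(-ub)
  J <- matrix(0, nrow = length(t), ncol = length(vec),
              dimnames = list(NULL, param_names_for(form)))
  J[, "a1"] <- e1
  dtau1 <- p$amplitudes[1] * e1 * p$beta * ub / p$time_constants[1]
  dtau1[!is.finite(dtau1)] <- 0
  J[, "tau1"] <- dtau1
  if (form$stretched) {
    logu <- ifelse(u > 0, log(u), 0)
    dbeta <- -p$amplitudes[1] * e1 * ub * logu
    dbeta[!is.finite(dbeta)] <- 0
    J[, "beta"] <- dbeta
  }
  if (n >= 2) {
    for (i in 2:n) {
      ei <- exp(-t / p$time_constants[i])
      J[, paste0("a", i)] <- ei
      J[, paste0("tau", i)] <-
        p$amplitudes[i] * ei * t / p$time_constants[i]^2
    }
  }
  if (form$delayed) {
    dd <- -p$amplitudes[1] * e1 * p$beta * u^(p$beta - 1) /
      p$time_constants[1]
    dd[!is.finite(dd)] <- 0
    J[, "d"] <- dd
  }
  J[, "o"] <- 1
  J
}

# ---- initialisation ---------------------------------------------------------

# data-driven initial guess: offset from the tail of the fitted span,
# amplitude from the first sample, tau from a log-linear decay fit
initial_guess <- function(t, x, form, bounds) {
  n_tail <- max(3L, ceiling(0.05 * length(x)))
  o0 <- mean(tail(x, n_tail))
  amp_total <- x[1] - o0
  resid <- abs(x - o0)
  keep <- resid > 1e-3 * max(resid, .Machine$double.eps)
  tau_est <- if (sum(keep) >= 3) {
    sl <- stats::coef(stats::lm(log(resid[keep]) ~ t[keep]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 3
  } else {
    max(t) / 3
  }
  tau_est <- min(max(tau_est, bounds$tau[1] * 2), bounds$tau[2] / 2)
  n <- form$order
  if (n == 1) {
    amps <- amp_total
    taus <- tau_est
  } else {
    amps <- c(0.7 * amp_total, rep(0.3 * amp_total / (n - 1), n - 1))
    taus <- tau_est / 10^(seq_len(n) - 1)
    taus <- pmin(pmax(taus, bounds$tau[1] * 2), bounds$tau[2])
  }
  if (amp_total == 0) amps <- rep(1e-3 * max(abs(x), 1), n)
  v <- c(amps[1], taus[1])
  if (form$stretched) v <- c(v, 0.9)
  if (n >= 2) for (i in 2:n) v <- c(v, amps[i], taus[i])
  if (form$delayed) v <- c(v, 0.05)
  setNames(c(v, o0), param_names_for(form))
}

jitter_start <- function(start, lower, upper) {
  v <- start * runif(length(start), 0.5, 1.5)
  # jitter a near-zero offset additively so starts actually differ
  zero <- start == 0
  if (any(zero)) v[zero] <- runif(sum(zero), -0.1, 0.1)
  pmin(pmax(v, lower + 1e-9), upper - 1e-9)
}

# embed a fitted simpler model as a starting point for a richer form
embed_start <- function(params, form, bounds) {
  if (params_order(params) > form$order) return(NULL)
  if (!form$stretched && params$beta != 1) return(NULL)
  if (!form$delayed && params$delay != 0) return(NULL)
  n_extra <- form$order - params_order(params)
  amps <- c(params$amplitudes, rep(0, n_extra))
  taus <- params$time_constants
  while (length(taus) < form$order) {
    taus <- c(taus, max(tail(taus, 1) / 5, bounds$tau[1] * 2))
  }
  p <- model_params(amps, taus, beta = params$beta, delay = params$delay,
                    offset = params$offset)
  start <- pack_params(p, form)
  b <- bounds_for(form, bounds)
  pmin(pmax(start, b$lower + 1e-9), b$upper - 1e-9)
}

# ---- single and multi-start solves ------------------------------------------

run_one_start <- function(start, t_fit, x_fit, form, config, b) {
  res_fn <- function(p) x_fit - model_fun_packed(p, form, t_fit)
  jac_fn <- function(p) -model_jac_packed(p, form, t_fit)
  # nls.lm warns on hitting maxiter; convergence is judged from the info
  # code and projected gradient below, so keep the solver quiet here
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = b$lower, upper = b$upper,
      fn = res_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iterations,
        ftol = config$tolerance, ptol = config$tolerance
      )
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  par <- setNames(as.double(fit$par), names(start))
  r <- res_fn(par)
  J <- model_jac_packed(par, form, t_fit)
  g <- 2 * drop(crossprod(J, r))
  # projected gradient: at an active bound, an outward-pointing component
  # is not an optimality violation
  at_lo <- par <= b$lower + 1e-8
  at_hi <- par >= b$upper - 1e-8
  g_proj <- g
  g_proj[at_lo & g > 0] <- 0
  g_proj[at_hi & g < 0] <- 0
  deviance <- sum(r^2)
  converged <- fit$info %in% 1:4 && all(is.finite(par)) &&
    sqrt(sum(g_proj^2)) <= sqrt(config$tolerance) * (1 + deviance)
  list(par = par, deviance = deviance, converged = converged,
       info = fit$info, message = fit$message, JtJ = crossprod(J),
       niter = fit$niter)
}

#' Fit a response model to a trace
#'
#' Multi-start nonlinear least squares (Levenberg-Marquardt with box
#' bounds and analytic Jacobians). Only samples in `[0, tn]` enter the
#' objective; goodness of fit is additionally scored on the entire trace,
#' so truncated fits expose their extrapolation error. The best converged
#' start by residual sum of squares wins; if no start converges the best
#' solution is still returned, flagged `converged = FALSE`.
#'
#' @param trace A windowed [sensor_trace()] (`t0_offset = 0`).
#' @param config A [fit_config()].
#' @param extra_starts Optional list of packed start vectors or
#'   [model_params()] objects (e.g. a nested simpler fit used as a warm
#'   start); appended to the generated starts.
#' @return A `response_fit` object; see [tidy.response_fit()],
#'   [glance.response_fit()], [extrapolate_final_value()].
#' @examples
#' p <- model_params(c(4, 1), c(30, 2), beta = 0.7, offset = 5)
#' tr <- sensor_trace(evaluate_response(p, (0:1699) / 20))
#' fit <- fit_response(tr, fit_config(n_starts = 2))
#' glance(fit)
#' @export
fit_response <- function(trace, config = fit_config(), extra_starts = list()) {
  assert_sensor_trace(trace)
  form <- config$form
  t_all <- trace$time
  x_all <- trace$value
  if (any(t_all < 0)) {
    abort("`trace` must be windowed to the exposure (t0_offset = 0).")
  }
  duration <- trace_duration(trace)
  tn <- config$tn %||% duration
  if (tn > duration + 1e-9) {
    abort(sprintf(
      "Fit horizon tn = %g s exceeds the trace duration (%g s).",
      tn, duration
    ))
  }
  idx <- t_all <= tn + 1e-9
  t_fit <- t_all[idx]
  x_fit <- x_all[idx]
  n_par <- form_n_params(form)
  if (length(t_fit) < n_par) {
    abort("Fewer samples in the fit span than free parameters.")
  }
  b <- bounds_for(form, config$bounds)
  base <- initial_guess(t_fit, x_fit, form, config$bounds)
  base <- pmin(pmax(base, b$lower + 1e-9), b$upper - 1e-9)
  starts <- list(base)
  if (config$n_starts > 1) {
    withr::with_seed(config$seed, {
      for (k in seq_len(config$n_starts - 1)) {
        starts[[k + 1]] <- jitter_start(base, b$lower, b$upper)
      }
    })
  }
  for (es in extra_starts) {
    s <- if (inherits(es, "model_params")) {
      embed_start(es, form, config$bounds)
    } else {
      es
    }
    if (!is.null(s)) starts <- c(starts, list(setNames(s, names(base))))
  }
  results <- purrr::compact(
    purrr::map(starts, run_one_start, t_fit = t_fit, x_fit = x_fit,
               form = form, config = config, b = b)
  )
  if (length(results) == 0) {
    abort("All fitting starts failed outright (solver error).")
  }
  conv <- purrr::keep(results, "converged")
  pool <- if (length(conv) > 0) conv else results
  best <- pool[[which.min(purrr::map_dbl(pool, "deviance"))]]
  params <- unpack_params(best$par, form)
  pred_fit <- evaluate_response(params, t_fit)
  rmse_fit <- sqrt(mean((x_fit - pred_fit)^2))
  gof <- goodness_of_fit_impl(trace, params)
  structure(
    list(
      params = params, form = form, config = config,
      rmse_fit = rmse_fit, rmse_full = gof$rmse, nrmse_full = gof$nrmse,
      converged = best$converged, n_points_used = length(t_fit),
      deviance = best$deviance, solver_info = best$info,
      solver_message = best$message, n_starts_run = length(results),
      JtJ = best$JtJ, trace = trace, tn = tn
    ),
    class = "response_fit"
  )
}

# nrmse may be NA when the trace has zero range (handled by callers)
goodness_of_fit_impl <- function(trace, params) {
  pred <- evaluate_response(params, trace$time)
  rmse <- sqrt(mean((trace$value - pred)^2))
  rng <- diff(range(trace$value))
  list(rmse = rmse, nrmse = if (rng > 0) rmse / rng else NA_real_)
}

#' Goodness of fit of a parameter set on a trace
#'
#' Root-mean-square error between the model curve and every sample of the
#' trace, plus its normalisation by the signal range (max - min of the
#' measured trace), which makes fits comparable across sensors with very
#' different scales.
#'
#' @param trace A [sensor_trace()].
#' @param params A [model_params()].
#' @return One-row tibble with `rmse` (engineering units) and `nrmse`
#'   (dimensionless).
#' @export
goodness_of_fit <- function(trace, params) {
  assert_sensor_trace(trace)
  gof <- goodness_of_fit_impl(trace, params)
  if (is.na(gof$nrmse)) {
    abort("Signal range is zero: NRMSE is undefined for a constant trace.")
  }
  tibble::tibble(rmse = gof$rmse, nrmse = gof$nrmse)
}

#' Extrapolated final value from a fit
#'
#' The steady-state forecast implied by a fitted response model: the
#' offset `o`, i.e. the limit of the model curve at infinite time. Fitting
#' on a truncated horizon and reading this value is the naive
#' curve-extrapolation forecaster.
#'
#' @param fit A converged `response_fit`.
#' @return The forecast steady-state value, engineering units.
#' @export
extrapolate_final_value <- function(fit) {
  if (!inherits(fit, "response_fit")) {
    abort("`fit` must be a response_fit object.")
  }
  if (!fit$converged) {
    abort("Refusing to extrapolate from an unconverged fit.")
  }
  steady_state_value(fit$params)
}

#' Compare candidate model forms across traces
#'
#' Fits every form to every trace on the full span, with warm starts: each
#' richer form also starts from the embedded solution of the nested
#' simpler forms, so adding a term or freeing the stretching exponent can
#' only improve (never worsen) the achieved residual. Returns mean RMSE
#' and NRMSE per form; traces whose fit fails to converge are excluded
#' from that form's average with a warning.
#'
#' @param traces List of windowed [sensor_trace()]s.
#' @param forms Named list of [model_form()]s, default [table_forms()].
#' @param config Base [fit_config()]; its `form`/`tn` fields are ignored.
#' @return Tibble with one row per form (`form`, `order`, `stretched`,
#'   `mean_rmse`, `mean_nrmse`, `n_converged`, `n_traces`, `best`).
#' @export
compare_forms <- function(traces, forms = table_forms(),
                          config = fit_config()) {
  if (length(traces) < 1) abort("Need at least one trace.")
  if (is.null(names(forms))) names(forms) <- purrr::map_chr(forms, form_label)
  complexity <- order(purrr::map_int(forms, form_n_params))
  rows <- list()
  for (nm in names(forms)[complexity]) {
    f <- forms[[nm]]
    cfg <- fit_config(form = f, tn = NULL, n_starts = config$n_starts,
                      max_iterations = config$max_iterations,
                      tolerance = config$tolerance, seed = config$seed,
                      bounds = config$bounds)
    fits <- purrr::imap(traces, function(tr, i) {
      warm <- purrr::compact(purrr::map(rows, function(r) r$fits[[i]]$params))
      fit_response(tr, cfg, extra_starts = warm)
    })
    rows[[nm]] <- list(form = f, fits = fits)
  }
  out <- purrr::map_dfr(names(forms), function(nm) {
    f <- forms[[nm]]
    fits <- rows[[nm]]$fits
    ok <- purrr::map_lgl(fits, "converged")
    if (any(!ok)) {
      warn(sprintf(
        "compare_forms: %d/%d traces excluded for form `%s` (no convergence).",
        sum(!ok), length(fits), nm
      ))
    }
    kept <- fits[ok]
    tibble::tibble(
      form = nm, order = f$order, stretched = f$stretched,
      mean_rmse = mean(purrr::map_dbl(kept, "rmse_full")),
      mean_nrmse = mean(purrr::map_dbl(kept, "nrmse_full")),
      n_converged = sum(ok), n_traces = length(fits)
    )
  })
  out$best <- seq_len(nrow(out)) == which.min(out$mean_rmse)
  out
}

#' Truncation study: fit horizon versus full-curve error
#'
#' Fits the reference model on progressively shorter initial spans of each
#' trace and scores each fit against the entire curve, quantifying how the
#' extrapolative quality of plain curve fitting degrades as less of the
#' transient is observed.
#'
#' @param traces List of windowed [sensor_trace()]s.
#' @param horizons Fit horizons `tn` in seconds, default
#'   `c(85, 40, 20, 10)`.
#' @param config Base [fit_config()]; `tn` is overridden per horizon.
#' @return Tibble with one row per horizon (`tn_s`, `mean_rmse_full`,
#'   `mean_nrmse_full`, `n_converged`, `n_traces`).
#' @export
truncation_study <- function(traces, horizons = c(85, 40, 20, 10),
                             config = fit_config()) {
  if (length(traces) < 1) abort("Need at least one trace.")
  durations <- purrr::map_dbl(traces, trace_duration)
  if (any(horizons > min(durations) + 1e-9)) {
    abort("Every horizon must be within the trace duration.")
  }
  purrr::map_dfr(horizons, function(tn) {
    cfg <- fit_config(form = config$form, tn = tn,
                      n_starts = config$n_starts,
                      max_iterations = config$max_iterations,
                      tolerance = config$tolerance, seed = config$seed,
                      bounds = config$bounds)
    fits <- purrr::map(traces, fit_response, config = cfg)
    ok <- purrr::map_lgl(fits, "converged")
    kept <- if (any(ok)) fits[ok] else fits
    tibble::tibble(
      tn_s = tn,
      mean_rmse_full = mean(purrr::map_dbl(kept, "rmse_full")),
      mean_nrmse_full = mean(purrr::map_dbl(kept, "nrmse_full")),
      n_converged = sum(ok), n_traces = length(fits)
    )
  })
}

# ---- methods ----------------------------------------------------------------

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf(
    "<response_fit: %s, tn = %g s, rmse_fit = %.4g, rmse_full = %.4g, %s>\n",
    form_label(x$form), x$tn, x$rmse_fit, x$rmse_full,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$params)
  invisible(x)
}

#' @export
vcov.response_fit <- function(object, ...) {
  p <- length(diag(object$JtJ))
  dof <- max(object$n_points_used - p, 1)
  sigma2 <- object$deviance / dof
  V <- tryCatch(sigma2 * solve(object$JtJ),
                error = function(e) matrix(NA_real_, p, p))
  dimnames(V) <- dimnames(object$JtJ)
  V
}

#' Tidy a response fit
#'
#' @param x A `response_fit`.
#' @param conf.int Add Wald confidence intervals from the linearised
#'   covariance at the solution?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, optionally `conf.low`/`conf.high`).
#' @export
tidy.response_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  est <- pack_params(x$params, x$form)
  se <- sqrt(pmax(diag(vcov(x)), 0))
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        std.error = unname(se))
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a response fit
#'
#' @param x A `response_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit summaries.
#' @export
glance.response_fit <- function(x, ...) {
  tibble::tibble(
    form = form_label(x$form), order = x$form$order,
    stretched = x$form$stretched, tn_s = x$tn,
    rmse_fit = x$rmse_fit, rmse_full = x$rmse_full,
    nrmse_full = x$nrmse_full, deviance = x$deviance,
    converged = x$converged, n_points_used = x$n_points_used
  )
}

#' Plot a response fit over its trace
#'
#' @param object A `response_fit`.
#' @param ... Unused.
#' @return A ggplot: measured samples, fitted curve, the fit horizon `tn`
#'   (dashed) and the model's steady-state value (dotted).
#' @export
autoplot.response_fit <- function(object, ...) {
  tr <- tibble::as_tibble(object$trace)
  tr$fitted <- evaluate_response(object$params, tr$time)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = object$tn, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = steady_state_value(object$params),
                        linetype = "dotted") +
    ggplot2::labs(x = "time since exposure onset [s]",
                  y = sprintf("response [%s]", trace_units(object$trace)))
}
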