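test_that("a constant trace fits to its own level with ~zero amplitude", {
  tr <- sensor_trace(rep(7.5, 400), sampling_rate = 20)
  fit <- fit_response(tr, quick_cfg(form = model_form(1, stretched = FALSE)))
  expect_equal(fit$params$offset, 7.5, tolerance = 1e-3)
  expect_lt(abs(fit$params$amplitudes[1]), 1e-3)
  expect_lt(fit$rmse_fit, 1e-6)
})

test_that("noiseless simulate-then-fit round trip recovers all coefficients", {
  p <- ref_params()
  tr <- noiseless_trace(p)
  fit <- fit_response(tr, quick_cfg())
  expect_true(fit$converged)
  truth <- c(4, 30, 0.7, 1, 2, 5)
  est <- unlist(params_to_record(fit$params)[c("a1", "tau1", "beta",
                                               "a2", "tau2", "o")])
  expect_equal(unname(est), truth, tolerance = 0.01)
  expect_lt(fit$rmse_full, 1e-6 * diff(range(tr$value)))
})

test_that("fit residual level matches the injected noise", {
  nz <- noisy_trace(sigma_rel = 0.01, seed = 21)
  fit <- fit_response(nz$trace, quick_cfg())
  expect_gt(fit$rmse_fit, 0.8 * nz$sigma)
  expect_lt(fit$rmse_fit, 1.2 * nz$sigma)
})

test_that("goodness_of_fit matches a direct two-line oracle", {
  nz <- noisy_trace(seed = 22)
  p <- ref_params()
  gof <- goodness_of_fit(nz$trace, p)
  resid <- nz$trace$value - evaluate_response(p, nz$trace$time)
  rmse <- sqrt(mean(resid^2))
  expect_equal(gof$rmse, rmse, tolerance = 1e-12)
  expect_equal(gof$nrmse, rmse / diff(range(nz$trace$value)),
               tolerance = 1e-12)
  # exact parameters on a noiseless trace give (0, 0)
  tr0 <- noiseless_trace(p)
  gof0 <- goodness_of_fit(tr0, p)
  expect_equal(gof0$rmse, 0)
  expect_equal(gof0$nrmse, 0)
  # residuals all equal 1 give rmse 1
  tr1 <- sensor_trace(evaluate_response(p, tr0$time) + 1)
  expect_equal(goodness_of_fit(tr1, p)$rmse, 1, tolerance = 1e-12)
  expect_error(goodness_of_fit(sensor_trace(rep(2, 10)), p), "range")
})

test_that("rmse_fit on the full horizon equals rmse_full", {
  nz <- noisy_trace(seed = 23)
  fit <- fit_response(nz$trace, quick_cfg(tn = 85))
  expect_equal(fit$rmse_fit, fit$rmse_full, tolerance = 1e-12)
})

test_that("nesting: richer forms never fit worse under warm starts", {
  nz <- noisy_trace(seed = 24)
  forms <- table_forms()
  fits <- list()
  devs <- c()
  for (nm in names(forms)) {
    warm <- purrr::compact(purrr::map(fits, "params"))
    fits[[nm]] <- fit_response(nz$trace, quick_cfg(form = forms[[nm]]),
                               extra_starts = warm)
    devs[nm] <- fits[[nm]]$deviance
  }
  tol <- 1e-6 * devs[["exp1"]]
  expect_lte(devs[["stretched1"]], devs[["exp1"]] + tol)
  expect_lte(devs[["exp2"]], devs[["exp1"]] + tol)
  expect_lte(devs[["stretched2"]], devs[["exp2"]] + tol)
  expect_lte(devs[["stretched2"]], devs[["stretched1"]] + tol)
})

test_that("fits are bit-identical under a fixed seed", {
  nz <- noisy_trace(seed = 25)
  f1 <- fit_response(nz$trace, quick_cfg(seed = 42))
  f2 <- fit_response(nz$trace, quick_cfg(seed = 42))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("fit horizon beyond the trace and short traces are rejected", {
  tr <- noiseless_trace(duration = 20)
  expect_error(fit_response(tr, quick_cfg(tn = 40)), "exceeds")
  tiny <- sensor_trace(c(1, 2, 1), sampling_rate = 20)
  expect_error(fit_response(tiny, quick_cfg()), "Fewer samples")
})

test_that("extrapolation reads the fitted offset and refuses bad fits", {
  tr <- noiseless_trace()
  fit <- fit_response(tr, quick_cfg())
  expect_equal(extrapolate_final_value(fit), fit$params$offset)
  bad <- fit
  bad$converged <- FALSE
  expect_error(extrapolate_final_value(bad), "unconverged")
})

test_that("truncated noiseless fits still recover the final value", {
  tr <- noiseless_trace()
  fit40 <- fit_response(tr, quick_cfg(tn = 40))
  expect_equal(extrapolate_final_value(fit40), 5, tolerance = 0.01 * 5)
})

test_that("order-3 fits on second-order data are over-parameterised", {
  nz <- noisy_trace(seed = 26)
  fit2 <- fit_response(nz$trace, quick_cfg())
  fit3 <- fit_response(nz$trace,
                       quick_cfg(form = model_form(3, stretched = TRUE)),
                       extra_starts = list(fit2$params))
  improvement <- (fit2$rmse_fit - fit3$rmse_fit) / fit2$rmse_fit
  td <- tidy(fit3, conf.int = TRUE)
  amp_rows <- td[td$term %in% c("a1", "a2", "a3"), ]
  ci_spans_zero <- any(amp_rows$conf.low < 0 & amp_rows$conf.high > 0,
                       na.rm = TRUE)
  expect_true(improvement <= 0.01 || ci_spans_zero)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  fit <- fit_response(noiseless_trace(), quick_cfg())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("a1", "tau1", "beta", "a2", "tau2", "o"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$n_points_used, 1700L)
})
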