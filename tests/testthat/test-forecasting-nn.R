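test_that("input scaling is the max onset value, with a guarded fallback", {
  expect_equal(compute_input_scaling(c(2, 4, 3)), 4)
  expect_equal(compute_input_scaling(7), 7)
  expect_warning(f <- compute_input_scaling(c(-2, -5)), "not positive")
  expect_equal(f, 5)
})

test_that("target scaling is the per-column max over training instances", {
  expect_equal(unname(compute_target_scaling(rbind(c(1, 10), c(3, 2)))),
               c(3, 10))
  expect_equal(unname(compute_target_scaling(rbind(c(2, 2), c(2, 2)))),
               c(2, 2))
  expect_warning(f <- compute_target_scaling(cbind(c(-1, -3))),
                 "Non-positive")
  expect_equal(unname(f), 3)
})

test_that("training pairs have the documented shapes and scale to max 1", {
  ds <- small_dataset(n = 10, copies = 2, seed = 31)
  pp <- make_training_pairs(ds, "parameter")
  fp <- make_training_pairs(ds, "final_value")
  expect_equal(ncol(pp$x_train), 200)
  expect_equal(ncol(pp$y_train), 6)
  expect_equal(ncol(fp$y_train), 1)
  expect_equal(colnames(pp$y_train),
               c("a1", "tau1", "beta", "a2", "tau2", "o"))
  # after scaling, the max train first sample and each target column max is 1
  expect_equal(max(pp$x_train[, 1]), 1)
  expect_equal(unname(apply(pp$y_train, 2, max)), rep(1, 6))
  # unscaling reproduces the stored targets exactly
  back <- sweep(pp$y_train, 2, pp$f_out, "*")
  manifest <- as.matrix(tibble::as_tibble(ds)[ds$split == "train",
                                              colnames(pp$y_train)])
  expect_equal(unname(back), unname(manifest), tolerance = 1e-12)
})

test_that("scaling factors come from the training portion only", {
  ds <- small_dataset(n = 10, copies = 2, seed = 32)
  pp <- make_training_pairs(ds, "parameter")
  # perturb every test trace; factors must not move
  ds2 <- ds
  ds2$trace <- purrr::map2(ds2$trace, ds2$split, function(tr, sp) {
    if (sp == "test") sensor_trace(tr$value * 100,
                                   trace_sampling_rate(tr)) else tr
  })
  pp2 <- make_training_pairs(ds2, "parameter")
  expect_identical(pp$f_in, pp2$f_in)
  expect_identical(pp$f_out, pp2$f_out)
})

test_that("both architectures share the trunk and differ in the output layer", {
  s6 <- mlp_spec(6)
  s1 <- mlp_spec(1)
  w6 <- withr::with_seed(1, sensecast:::glorot_init(s6))
  w1 <- withr::with_seed(1, sensecast:::glorot_init(s1))
  expect_equal(dim(w6[[1]]$W), c(200, 50))
  expect_equal(dim(w6[[2]]$W), c(50, 24))
  expect_equal(dim(w6[[3]]$W), c(24, 6))
  expect_equal(dim(w1[[3]]$W), c(24, 1))
  trunk6 <- sum(lengths(purrr::map(w6[1:2], "W"))) +
    sum(lengths(purrr::map(w6[1:2], "b")))
  trunk1 <- sum(lengths(purrr::map(w1[1:2], "W"))) +
    sum(lengths(purrr::map(w1[1:2], "b")))
  expect_identical(trunk6, trunk1)
  expect_error(mlp_spec(3), "output_size")
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  ds <- small_dataset(n = 10, copies = 2, seed = 33)
  fp <- make_training_pairs(ds, "final_value")
  cfg <- training_config(epochs = 30, seed = 11)
  m1 <- train_forecaster(fp, config = cfg)
  m2 <- train_forecaster(fp, config = cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_lt(tail(m1$loss_curve, 1), m1$loss_curve[1])
})

test_that("a zeroed output layer on zero targets gives exactly zero loss", {
  ds <- small_dataset(n = 6, copies = 0, seed = 34)
  fp <- make_training_pairs(ds, "final_value")
  model <- train_forecaster(fp, config = training_config(epochs = 1))
  L <- length(model$weights)
  model$weights[[L]]$W[] <- 0
  model$weights[[L]]$b[] <- 0
  y0 <- matrix(0, nrow(fp$x_train), 1)
  expect_identical(mlp_loss(model, fp$x_train, y0), 0)
})

test_that("the network can overfit a single training sample to within 1%", {
  ds <- small_dataset(n = 6, copies = 0, seed = 35)
  fp <- make_training_pairs(ds, "final_value")
  one <- fp
  one$x_train <- fp$x_train[1, , drop = FALSE]
  one$y_train <- fp$y_train[1, , drop = FALSE]
  model <- train_forecaster(
    one, config = training_config(epochs = 400, learning_rate = 5e-3,
                                  minibatch_size = 1, seed = 2)
  )
  pred <- predict(model, one$x_train * fp$f_in)
  truth <- one$y_train[1, 1] * fp$f_out
  expect_equal(unname(pred[1, 1]), unname(truth), tolerance = 0.01)
})

test_that("parameter-mode forecasts unscale to the exact offset", {
  ds <- small_dataset(n = 6, copies = 0, seed = 36)
  pp <- make_training_pairs(ds, "parameter")
  model <- train_forecaster(pp, config = training_config(epochs = 1))
  # bypass the network: outputs equal to the true scaled coefficients
  # must map back to the true offset
  co <- sweep(pp$y_train[1, , drop = FALSE], 2, pp$f_out, "*")
  b <- default_fit_bounds()
  p <- model_params(c(co[1, "a1"], co[1, "a2"]),
                    c(co[1, "tau1"], co[1, "tau2"]),
                    beta = co[1, "beta"], offset = co[1, "o"])
  expect_equal(steady_state_value(p),
               ds[ds$split == "train", ]$o[1], tolerance = 1e-12)
  # final-value mode with unit scaling returns the raw network output
  fp <- make_training_pairs(ds, "final_value")
  fmodel <- train_forecaster(fp, config = training_config(epochs = 1))
  fmodel$f_out <- 1
  w <- fp$x_train[1, ] * fp$f_in
  raw <- sensecast:::mlp_forward(fmodel$weights,
                                 matrix(w / fmodel$f_in, 1),
                                 fmodel$spec$leaky_slope)$output
  expect_equal(forecast_final_value(fmodel, w), drop(raw))
})

test_that("cross-validation folds partition the training set", {
  ds <- small_dataset(n = 15, copies = 3, seed = 37) # 48 train rows
  fp <- make_training_pairs(ds, "final_value")
  cfg <- training_config(epochs = 5, seed = 3)
  cv <- cross_validate(fp, config = cfg, k = 4)
  expect_equal(nrow(cv), 4)
  expect_equal(sum(cv$n_val), nrow(fp$x_train))
  expect_true(all(cv$n_train + cv$n_val == nrow(fp$x_train)))
  expect_gt(stats::var(cv$train_loss), 0)
  expect_error(cross_validate(fp, config = cfg, k = 1000), "folds")
})
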