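test_that("parameter draws respect intervals, seeds and the tau ordering", {
  arch <- archetype_mos_fast()
  # degenerate intervals return the point value
  degen <- sensor_archetype("point", a1 = c(3, 3), tau1 = c(20, 20),
                            beta = c(0.8, 0.8), a2 = c(1, 1),
                            tau2 = c(2, 2), o = c(5, 5))
  p <- sample_parameters(degen, seed = 1)
  expect_equal(p$amplitudes, c(3, 1))
  expect_equal(p$time_constants, c(20, 2))
  expect_equal(p$beta, 0.8)
  expect_equal(p$offset, 5)
  # determinism
  expect_identical(sample_parameters(arch, seed = 7),
                   sample_parameters(arch, seed = 7))
  # tau1 > tau2 always
  for (s in 1:50) {
    ps <- sample_parameters(arch, seed = s)
    expect_gt(ps$time_constants[1], ps$time_constants[2])
  }
})

test_that("draws are uniform within their intervals (KS at alpha 0.01)", {
  arch <- archetype_mos_fast()
  n <- 2000
  draws <- withr::with_seed(99, purrr::map_dfr(seq_len(n), function(i) {
    params_to_record(sensecast::sample_parameters(arch, seed = i))
  }))
  r <- arch$ranges
  for (nm in names(r)) {
    col <- draws[[nm]]
    expect_true(all(col >= r[[nm]][1] & col <= r[[nm]][2]))
    # mos_fast tau intervals are disjoint, so the swap never fires and
    # every coefficient is marginally uniform
    pval <- stats::ks.test(col, "punif", r[[nm]][1], r[[nm]][2])$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("simulated traces carry the programmed structure", {
  p <- ref_params()
  arch <- archetype_mos_fast()
  # sigma = 0 reproduces the model exactly after the onset
  arch0 <- arch
  arch0$noise_sigma_rel <- 0
  sim0 <- simulate_trace(p, arch0, seed = 1)
  post <- sim0$sensor$value[sim0$onset_index:length(sim0$sensor$value)]
  expect_equal(post, sim0$clean, tolerance = 1e-12)
  # baseline holds the t = 0 model value before the onset
  pre <- sim0$sensor$value[1:(sim0$onset_index - 1)]
  expect_true(all(pre == sum(p$amplitudes) + p$offset))
  # airflow recovers the onset
  expect_equal(detect_exposure_onset(sim0$airflow), sim0$onset_index)
  # residual variance matches the requested sigma within 10%
  sim <- simulate_trace(p, arch, seed = 2)
  resid <- sim$sensor$value[sim$onset_index:length(sim$sensor$value)] -
    sim$clean
  expect_equal(stats::var(resid), sim$sigma^2, tolerance = 0.1)
})

test_that("generate_dataset yields n real, labelled, reproducible traces", {
  ds <- generate_dataset(archetype_mos_fast(), n = 25, seed = 3)
  expect_equal(nrow(ds), 25)
  expect_true(all(ds$provenance == "real"))
  expect_true(all(purrr::map_int(ds$trace, nrow) == 1700))
  expect_equal(ds$final_value, ds$o)
  ds2 <- generate_dataset(archetype_mos_fast(), n = 25, seed = 3)
  expect_identical(ds$o, ds2$o)
  expect_identical(ds$trace[[7]]$value, ds2$trace[[7]]$value)
  expect_error(generate_dataset(archetype_mos_fast(), n = 1), "at least 2")
})

test_that("stored targets round-trip through fitting on noiseless traces", {
  arch <- archetype_mos_fast()
  arch$noise_sigma_rel <- 0
  ds <- generate_dataset(arch, n = 3, seed = 4)
  for (i in seq_len(nrow(ds))) {
    fit <- fit_response(ds$trace[[i]], quick_cfg())
    est <- params_to_record(fit$params)
    truth <- ds[i, c("a1", "tau1", "beta", "a2", "tau2", "o")]
    for (nm in names(truth)) {
      expect_equal(est[[nm]], truth[[nm]], tolerance = 0.01,
                   label = sprintf("trace %d coefficient %s", i, nm))
    }
  }
})

test_that("splitting assigns sizes by ceiling and varies with the seed", {
  ds <- generate_dataset(archetype_mos_fast(), n = 25, seed = 5)
  sp <- split_dataset(ds, seed = 1)
  expect_equal(sum(sp$split == "train"), 20)
  expect_equal(sum(sp$split == "test"), 5)
  ds5 <- generate_dataset(archetype_mos_fast(), n = 5, seed = 5)
  sp5 <- split_dataset(ds5, train_fraction = 0.8, seed = 1)
  expect_equal(sum(sp5$split == "train"), 4)
  expect_equal(sum(sp5$split == "test"), 1)
  a <- split_dataset(ds, seed = 1)
  b <- split_dataset(ds, seed = 2)
  expect_equal(sum(a$split == "train"), sum(b$split == "train"))
  expect_false(identical(a$split, b$split))
  aug <- augment_dataset(a, copies_per_sample = 1, seed = 1)
  expect_error(split_dataset(aug), "augmented")
})

test_that("augmentation multiplies counts and transforms targets consistently", {
  arch <- archetype_mos_fast()
  arch$noise_sigma_rel <- 0
  ds <- split_dataset(generate_dataset(arch, n = 6, seed = 6), seed = 6)
  aug <- augment_dataset(ds, copies_per_sample = 4, seed = 6)
  expect_equal(nrow(aug), 6 * 5)
  expect_identical(augment_dataset(ds, copies_per_sample = 0, seed = 6), ds)
  # children inherit the parent split; parents exist and are real
  kids <- aug[aug$provenance == "augmented", ]
  parents <- aug[match(kids$parent_id, aug$trace_id), ]
  expect_true(all(parents$provenance == "real"))
  expect_identical(kids$split, parents$split)
  # stratification: real fraction matches in train and test
  real_frac <- tapply(aug$provenance == "real", aug$split, mean)
  expect_equal(real_frac[["train"]], real_frac[["test"]])
  # degenerate scales and zero noise give exact copies
  ident <- augment_dataset(ds, copies_per_sample = 2,
                           amp_scale_interval = c(1, 1),
                           offset_scale_interval = c(1, 1),
                           awgn_sigma_rel = 0, seed = 1)
  kid <- ident[ident$provenance == "augmented", ][1, ]
  par <- ident[ident$trace_id == kid$parent_id, ]
  expect_equal(kid$trace[[1]]$value, par$trace[[1]]$value)
  expect_equal(kid$o, par$o)
  # invalid scale intervals are rejected
  expect_error(augment_dataset(ds, amp_scale_interval = c(-1, 1)),
               "positive")
  expect_error(augment_dataset(generate_dataset(arch, n = 3, seed = 1)),
               "split")
})

test_that("noiseless augmented children still fit to their stored targets", {
  arch <- archetype_mos_fast()
  arch$noise_sigma_rel <- 0
  ds <- split_dataset(generate_dataset(arch, n = 2, seed = 8), seed = 8)
  aug <- augment_dataset(ds, copies_per_sample = 1, awgn_sigma_rel = 0,
                         seed = 8)
  kid <- aug[aug$provenance == "augmented", ][1, ]
  fit <- fit_response(kid$trace[[1]], quick_cfg())
  est <- params_to_record(fit$params)
  for (nm in c("a1", "tau1", "beta", "a2", "tau2", "o")) {
    expect_equal(est[[nm]], kid[[nm]], tolerance = 0.01, label = nm)
  }
})

test_that("datasets persist to a directory and reload intact", {
  ds <- small_dataset(n = 4, copies = 1, seed = 9)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_equal(nrow(back), nrow(ds))
  expect_equal(back$trace_id, ds$trace_id)
  expect_equal(back$o, ds$o, tolerance = 1e-12)
  expect_equal(back$split, ds$split)
  expect_equal(back$trace[[3]]$value, ds$trace[[3]]$value,
               tolerance = 1e-10)
})
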