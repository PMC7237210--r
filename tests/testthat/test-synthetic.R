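test_that("templates honor the peak normalization and spatial decay", {
  spec <- simulation_spec(num_channels = 6, num_units = 3, noise_sd = 1,
                          target_snrs = c(8, 5, 12), seed = 2)
  tm <- make_templates(spec)
  expect_identical(dim(tm$templates)[1:2], c(3L, 6L))
  for (u in 1:3) {
    expect_equal(max(abs(tm$templates[u, , ])), spec$target_snrs[u],
                 tolerance = 1e-12)
    # per-channel peak decays with distance from the source
    prof <- apply(abs(tm$templates[u, , ]), 1, max)
    d <- sqrt((tm$geometry[, 1] - tm$sources[u, 1])^2 +
                (tm$geometry[, 2] - tm$sources[u, 2])^2)
    expect_true(all(diff(prof[order(d)]) <= 1e-9))
  }
  # different seeds give different templates
  tm2 <- make_templates(simulation_spec(num_channels = 6, num_units = 3,
                                        noise_sd = 1,
                                        target_snrs = c(8, 5, 12), seed = 3))
  expect_false(identical(tm$templates, tm2$templates))
})

test_that("simulation is deterministic and leaves the caller's RNG alone", {
  spec <- simulation_spec(duration_s = 5, seed = 9)
  set.seed(1234)
  before <- rnorm(1)
  sim1 <- simulate_recording(spec)
  sim2 <- simulate_recording(spec)
  expect_identical(sim1$recording$traces, sim2$recording$traces)
  expect_identical(unclass(sim1$firings), unclass(sim2$firings))
  set.seed(1234)
  expect_identical(rnorm(1), before)
})

test_that("noiseless simulation is the exact sum of scaled templates", {
  spec <- simulation_spec(num_channels = 4, num_units = 1, duration_s = 5,
                          firing_rates = 3, noise_sd = 0,
                          amplitude_gamma_shape = 1e9, seed = 4)
  sim <- simulate_recording(spec)
  tm <- make_templates(spec)
  t1 <- unit_times(sim$firings, 1)
  expect_gt(length(t1), 0)
  # with effectively constant unit amplitude, each event is the template
  t0 <- floor(t1[1])
  clip <- sim$recording$traces[, (t0 - tm$w_pre):
                                 (t0 - tm$w_pre + dim(tm$templates)[3] - 1)]
  expect_equal(clip, tm$templates[1, , ], tolerance = 1e-3,
               ignore_attr = TRUE)
  # and comparing ground truth to itself is perfect
  cmp <- compare_sorting(sim$firings, sim$firings,
                         comparison_params(1, spec$sample_rate))
  expect_true(all(cmp$units$accuracy == 1))
})

test_that("event counts follow Poisson statistics and respect the refractory gap", {
  spec <- simulation_spec(num_units = 2, duration_s = 120,
                          firing_rates = c(5, 10), seed = 31)
  sim <- simulate_recording(spec)
  for (u in 1:2) {
    t <- unit_times(sim$firings, u)
    lam <- spec$firing_rates[u] * spec$duration_s
    expect_lt(abs(length(t) - lam), 4 * sqrt(lam))
    expect_true(all(diff(t) >= 2 * round(0.001 * spec$sample_rate)))
  }
  # an absurd rate is rejected rather than silently thinned
  # kept fraction ~ 1/(1 + rate * gap): above 500 Hz less than half survive
  expect_error(
    simulate_recording(simulation_spec(duration_s = 2, firing_rates = 900,
                                       seed = 1)),
    "refractory thinning")
})

test_that("drift displacement 0 reproduces the static simulation; drift changes amplitudes", {
  base <- simulation_spec(num_channels = 8, num_units = 1, duration_s = 10,
                          firing_rates = 8, seed = 77)
  drifting0 <- simulation_spec(num_channels = 8, num_units = 1,
                               duration_s = 10, firing_rates = 8, seed = 77,
                               drift = "linear", drift_displacement_um = 0)
  expect_identical(simulate_recording(base)$recording$traces,
                   simulate_recording(drifting0)$recording$traces)

  drifting <- simulation_spec(num_channels = 8, num_units = 1,
                              duration_s = 10, firing_rates = 8, seed = 77,
                              noise_sd = 0, drift = "linear",
                              drift_displacement_um = 15)
  static <- simulation_spec(num_channels = 8, num_units = 1,
                            duration_s = 10, firing_rates = 8, seed = 77,
                            noise_sd = 0)
  expect_false(identical(simulate_recording(drifting)$recording$traces,
                         simulate_recording(static)$recording$traces))
})

test_that("perturbations yield the analytically expected recall and precision", {
  spec <- simulation_spec(num_units = 2, duration_s = 100,
                          firing_rates = c(8, 8), seed = 51)
  sim <- simulate_recording(spec)
  params <- comparison_params(1, spec$sample_rate)
  dur <- n_samples(sim$recording)

  # identity perturbation: metrics exactly 1
  ident <- perturb_sorting(sim$firings, perturbation_spec(seed = 1), dur)
  cmp0 <- compare_sorting(sim$firings, ident$firings, params)
  expect_true(all(cmp0$units$accuracy == 1))

  # deletions only: recall ~ 0.8, precision 1
  del <- perturb_sorting(sim$firings,
                         perturbation_spec(deletion_prob = 0.2, seed = 2),
                         dur)
  cmp1 <- compare_sorting(sim$firings, del$firings, params)
  n <- min(table(sim$firings["label", ]))
  se <- 3 * sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(cmp1$units$recall - 0.8) < pmax(se, 0.03)))
  expect_true(all(cmp1$units$precision == 1))

  # insertions only: precision matches kept/(kept+inserted)
  ins <- perturb_sorting(sim$firings,
                         perturbation_spec(insertion_rate = 2, seed = 3),
                         dur, sample_rate = spec$sample_rate)
  cmp2 <- compare_sorting(sim$firings, ins$firings, params)
  expect_true(all(abs(cmp2$units$precision - ins$expected$precision) < 0.03))
  expect_true(all(cmp2$units$recall == 1))

  # jitter well under the tolerance leaves metrics at 1
  jit <- perturb_sorting(sim$firings,
                         perturbation_spec(jitter_sd = 3, seed = 4), dur)
  cmp3 <- compare_sorting(sim$firings, jit$firings, params)
  expect_true(all(cmp3$units$recall > 0.99))
})

test_that("merges and splits degrade metrics in the expected direction", {
  spec <- simulation_spec(num_units = 2, duration_s = 60,
                          firing_rates = c(6, 6), seed = 61)
  sim <- simulate_recording(spec)
  params <- comparison_params(1, spec$sample_rate)
  dur <- n_samples(sim$recording)

  # merging unit 1 into 2: the merged unit matches both, precision drops
  mrg <- perturb_sorting(sim$firings,
                         perturbation_spec(merge_pairs = list(c(1, 2)),
                                           seed = 5), dur)
  cmp <- compare_sorting(sim$firings, mrg$firings, params)
  expect_identical(cmp$shared_best, 2)
  expect_true(all(cmp$units$recall == 1))
  expect_true(all(cmp$units$precision < 0.75))

  # splitting 40% of unit 1: the best match keeps the larger fragment
  spl <- perturb_sorting(sim$firings,
                         perturbation_spec(split_fraction = c("1" = 0.4),
                                           seed = 6), dur)
  cmps <- compare_sorting(sim$firings, spl$firings, params)
  r1 <- cmps$units$recall[cmps$units$gt_label == 1]
  n1 <- sum(sim$firings["label", ] == 1)
  expect_equal(r1, 0.6, tolerance = 3 * sqrt(0.4 * 0.6 / n1) / 0.6)
  expect_equal(cmps$units$recall[cmps$units$gt_label == 2], 1)
})
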