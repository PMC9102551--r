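test_that("the translocation ratio follows its defining identities", {
  expect_equal(cytoplasmic_translocation(1, 1), 0)
  expect_equal(cytoplasmic_translocation(2, 1), 1)
  expect_error(cytoplasmic_translocation(1, 0), "> 0")
  expect_error(cytoplasmic_translocation(1, -2), "> 0")
  # scale invariance: multiplying both intensities by k leaves R unchanged
  set.seed(2)
  ics <- runif(50, 50, 200); im <- runif(50, 50, 200); k <- runif(50, 0.1, 10)
  expect_equal(cytoplasmic_translocation(k * ics, k * im),
               cytoplasmic_translocation(ics, im))
})

test_that("per-cell R series recovers a planted step and polices ROI pairing", {
  tr <- gen_roi_traces(n_cells = 6, response_amplitude = 0.8, stim_index = 10,
                       noise_sd = 0.02, seed = 14)
  s <- cell_translocation_series(tr)
  truth <- attr(tr, "truth")
  pre <- mean(s$R[s$time < truth$stim_index])
  post <- mean(s$R[s$time >= truth$stim_index])
  expect_equal(post - pre, truth$response_amplitude, tolerance = 0.05)

  # median aggregation is available
  sm <- cell_translocation_series(tr, aggregate = "median")
  expect_equal(nrow(sm), nrow(s))

  # unpaired ROI records are rejected with a message
  broken <- tr[!(tr$roi_pair_id == 1 & tr$compartment == "membrane" &
                   tr$cell_id == "cell-001"), ]
  expect_message(suppressWarnings(cell_translocation_series(broken)),
                 "unpaired")

  # a membrane-only table has no valid pairs at all
  memonly <- tr[tr$compartment == "membrane", ]
  expect_message(out <- cell_translocation_series(memonly), "no valid ROI pairs")
  expect_equal(nrow(out), 0)

  expect_warning(
    cell_translocation_series(suppressWarnings(
      gen_roi_traces(n_cells = 1, n_roi_pairs = 3, seed = 1))),
    "fewer than 4")
})

test_that("migration rate is the mean per-step speed with exclusions applied", {
  two <- data.frame(cell_id = "c1", time = c(0, 10), x = c(0, 12), y = 0)
  expect_equal(migration_rate(two)$rate, 1.2)
  still <- data.frame(cell_id = "c2", time = c(0, 10, 20), x = 1, y = 1)
  expect_equal(migration_rate(still)$rate, 0)

  tr <- gen_tracks(n_cells = 5, true_speed = 0.9, dt = 10, seed = 15)
  out <- migration_rate(tr, exclude = c("cell-002"))
  expect_equal(nrow(out), 4)
  expect_false("cell-002" %in% out$cell_id)
  expect_equal(out$rate, rep(0.9, 4), tolerance = 1e-9)

  single <- rbind(two, data.frame(cell_id = "solo", time = 0, x = 0, y = 0))
  expect_message(got <- migration_rate(single), "single-point")
  expect_equal(got$cell_id, "c1")

  # rigid translation leaves rates unchanged; scaling coordinates scales them
  shifted <- tr; shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 50
  expect_equal(migration_rate(shifted)$rate, migration_rate(tr)$rate)
  scaled <- tr; scaled$x <- 3 * scaled$x; scaled$y <- 3 * scaled$y
  expect_equal(migration_rate(scaled)$rate, 3 * migration_rate(tr)$rate)
})

test_that("peak amplitude is max minus min inside the post-stimulus window", {
  t <- seq(0, 600, by = 3)
  v <- rep(1, length(t))
  v[t == 150] <- 1.8   # window maximum
  v[t == 210] <- 0.9   # window minimum
  expect_equal(peak_amplitude(t, v, stimulus_time = 100, window = 300), 0.9)
  expect_equal(peak_amplitude(t, rep(2, length(t)), 100), 0)
  # a large pre-stimulus spike is outside the window and ignored
  v2 <- rep(1, length(t)); v2[5] <- 50
  expect_equal(peak_amplitude(t, v2, stimulus_time = 100, window = 300), 0)
  expect_error(peak_amplitude(t, v, stimulus_time = 700), "no samples")
})

test_that("dF/F0 normalises on the pre-stimulus baseline and fits the slope", {
  t <- seq(0, 400, by = 5)
  flat <- delta_f_over_f0(t, rep(3, length(t)), stimulus_time = 150)
  expect_equal(flat$trace$dff0, rep(0, length(t)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$f0, 3)

  # linear decay of known relative rate is recovered by the slope fit
  f0 <- 2
  v <- ifelse(t < 150, f0, f0 * (1 - 0.002 * (t - 150)))
  d <- delta_f_over_f0(t, v, stimulus_time = 150, slope_window = 60)
  expect_equal(d$slope, -0.002, tolerance = 1e-9)

  expect_error(delta_f_over_f0(t, v, stimulus_time = 2), "pre-stimulus")
  expect_error(delta_f_over_f0(t, v - 10, stimulus_time = 150), "F0")
})

test_that("control-normalised ratios obey the expected identities", {
  expect_equal(normalized_ratio(5, 2, 5, 2), 1)
  expect_equal(normalized_ratio(5, 2, 5, 2, log2_output = TRUE), 0)
  expect_equal(normalized_ratio(2, 1, 1, 1), 2)
  expect_equal(normalized_ratio(2, 1, 1, 1, log2_output = TRUE), 1)
  # rescaling both lanes of a sample (loading differences) cancels out
  expect_equal(normalized_ratio(7 * 2, 7 * 1, 3 * 1, 3 * 1), 2)
  expect_error(normalized_ratio(1, 0, 1, 1), "> 0")
})
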