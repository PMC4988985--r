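# F/F0 normalization, responder detection, waveform classification.

test_that("normalization gives exact closed-form ratios", {
  # constant trace -> all ratios 1
  f <- matrix(500, 2, 120)
  expect_equal(normalizeTraces(f, 50), matrix(1, 2, 120))
  # step trace: 100 for the baseline frames, 250 afterwards
  f2 <- matrix(rep(c(rep(100, 50), rep(250, 70)), each = 1), nrow = 1,
               byrow = TRUE)
  r2 <- normalizeTraces(f2, 50)
  expect_equal(unique(r2[1, 1:50]), 1)
  expect_equal(unique(r2[1, 51:120]), 2.5)
})

test_that("per-cell baseline mean of normalized traces is 1 to 1e-12", {
  nm <- normalizeTraces(simulateNetwork(smallConfig(seed = 6)))
  r <- ratioMatrix(nm)
  expect_equal(rowMeans(r[, 1:50]), rep(1, nrow(r)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("normalization is scale invariant and idempotent", {
  set.seed(42)
  f <- matrix(rlnorm(3 * 100, log(300), 0.1), 3, 100)
  r <- normalizeTraces(f, 50)
  expect_equal(normalizeTraces(f * 17.3, 50), r, tolerance = 1e-14)
  expect_equal(normalizeTraces(r, 50), r, tolerance = 1e-14)
})

test_that("normalization validates input and truncates to the first 10 min", {
  expect_error(normalizeTraces(matrix(1, 2, 30), 50), "30 frames")
  f <- matrix(100, 2, 60); f[2, 7] <- -1
  expect_error(normalizeTraces(f, 50), "frame 7")
  long <- simulateNetwork(smallConfig(seed = 7, total_duration = 900))
  nm <- normalizeTraces(long)
  expect_equal(ncol(nm), 600)
  expect_lt(max(timeStamps(nm)), 600)
})

test_that("responder calls are invariant to positive rescaling of raw input", {
  ce <- simulateNetwork(smallConfig(seed = 9))
  calls1 <- detectResponders(normalizeTraces(ce))
  f <- assay(ce, "fluorescence") * 3.7
  ce2 <- CalciumExperiment(f, timeStamps(ce), cellLayout(ce))
  calls2 <- detectResponders(normalizeTraces(ce2), stimulus_onset = 240,
                             response_horizon = 240)
  expect_identical(calls1$is_responder, calls2$is_responder)
})

test_that("a flat noiseless trace is not a responder; a sustained step is, at the right onset", {
  n_fr <- 600
  flat <- rep(100, n_fr)
  # baseline sd ~ tiny noise; step of +5 baseline SDs at t = 300
  set.seed(1)
  noisy <- 100 * (1 + rnorm(n_fr, 0, 0.01))
  step <- noisy; step[301:n_fr] <- step[301:n_fr] + 100 * 5 * 0.01 * 3
  ce <- manualExperiment(rbind(flat, noisy, step))
  calls <- detectResponders(normalizeTraces(ce), stimulus_onset = 240,
                            response_horizon = 240)
  expect_false(calls$is_responder[1])
  expect_false(calls$is_responder[2])
  expect_true(calls$is_responder[3])
  expect_equal(calls$onset_time[3], 300, tolerance = 5)
})

test_that("detection recovers simulated ground truth with high sensitivity and specificity", {
  sens <- spec <- numeric(10)
  for (s in 1:10) {
    ce <- simulateNetwork(simConfig(n_cells = 40, seed = 5000 + s))
    calls <- detectResponders(normalizeTraces(ce))
    gt <- groundTruth(ce)$truth_responder
    sens[s] <- sum(calls$is_responder & gt) / sum(gt)
    spec[s] <- sum(!calls$is_responder & !gt) / sum(!gt)
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(spec), 0.95)
})

test_that("waveform classification matches closed-form prototypes", {
  ts <- 0:599
  # single rise to a plateau
  biph <- 1 + ifelse(ts >= 250, 1.2 * (1 - exp(-(ts - 250) / 5)), 0) *
    (0.4 + 0.6 * exp(-(ts - 250) / 90))
  expect_equal(classifyResponse(biph, ts, 250, threshold = 1.1), "biphasic")
  # five full cycles above threshold
  osc <- 1 + ifelse(ts >= 250 & ts < 450, 0.8 * 0.5 *
                      (1 - cos(2 * pi * (ts - 250) / 40)), 0)
  expect_equal(classifyResponse(osc, ts, 250, threshold = 1.1), "oscillatory")
  expect_error(classifyResponse(rep(1, 600), ts, 250, threshold = 1.1),
               "no response")
})

test_that("classification agrees with simulator labels on low-noise data", {
  agree <- total <- 0
  for (s in 1:5) {
    ce <- simulateNetwork(simConfig(n_cells = 40, seed = 6000 + s,
                                    noise_sd = 0.02,
                                    response_latency_jitter_sd = 0))
    calls <- detectResponders(normalizeTraces(ce))
    gt <- groundTruth(ce)
    both <- calls$is_responder & gt$truth_responder
    agree <- agree + sum(calls$response_class[both] == gt$truth_class[both])
    total <- total + sum(both)
  }
  expect_gte(agree / total, 0.95)
})
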