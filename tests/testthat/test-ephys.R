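# Steady-state deflections and coupling-coefficient estimation.

test_that("steady-state deflection handles flat, step and settling traces", {
  t <- seq(0, 1, by = 0.001)
  expect_equal(steadyStateDeflection(rep(-60, length(t)), t,
                                     c(0, 0.1), c(0.5, 0.6)), 0)
  v <- ifelse(t >= 0.2 & t < 0.7, -70, -60)
  expect_equal(steadyStateDeflection(v, t, c(0.05, 0.2), c(0.6, 0.7)), -10)
  # exponential settling, tau = 10 ms: window >= 5 tau after onset is
  # within 1% of the asymptote
  tau <- 0.01
  vexp <- -60 - 10 * (1 - exp(-pmax(t - 0.2, 0) / tau)) *
    (t >= 0.2 & t < 0.7)
  d <- steadyStateDeflection(vexp, t, c(0.05, 0.2), c(0.2 + 5 * tau, 0.7))
  expect_lt(abs(d - (-10)) / 10, 0.01)
})

test_that("intervals straddling a step edge are rejected", {
  t <- seq(0, 1, by = 0.001)
  v <- rep(-60, length(t))
  expect_error(steadyStateDeflection(v, t, c(0.15, 0.25), c(0.5, 0.7),
                                     step_window = c(0.2, 0.7)),
               "step edge")
  expect_error(steadyStateDeflection(v, t, c(0.05, 0.2), c(0.65, 0.75),
                                     step_window = c(0.2, 0.7)),
               "within the current step")
})

test_that("coupling coefficient is exact arithmetic on clean deflections", {
  # dV1 = -10 mV, dV2 = -0.25 mV on every sweep -> cc = 0.025
  ps <- simulatePairedRecording(0.025, step_amplitude = -10, n_sweeps = 15,
                                noise_sd = 0, seed = 1)
  est <- couplingCoefficient(ps)
  expect_equal(unname(est@cc["1to2"]), 0.025, tolerance = 1e-12)
  expect_equal(unname(est@sem["1to2"]), 0, tolerance = 1e-12)
  expect_equal(unname(est@dv_injected["1to2"]), -10, tolerance = 0.01)
})

test_that("averaging order does not matter for noise-free sweeps", {
  ps <- simulatePairedRecording(0.025, n_sweeps = 10, noise_sd = 0, seed = 1)
  est <- couplingCoefficient(ps)
  avg1 <- colMeans(ps@v1); avg2 <- colMeans(ps@v2)
  on <- ps@step_onset_s; off <- ps@step_offset_s
  d1 <- steadyStateDeflection(avg1, ps@time_s, c(on - 0.1, on),
                              c(off - 0.1, off))
  d2 <- steadyStateDeflection(avg2, ps@time_s, c(on - 0.1, on),
                              c(off - 0.1, off))
  expect_equal(unname(est@cc["1to2"]), d2 / d1, tolerance = 1e-12)
})

test_that("coupling is symmetric and amplitude-invariant in the ohmic regime", {
  mk <- function(amp, seed) simulatePairedRecording(
    0.025, step_amplitude = amp, n_sweeps = 40, noise_sd = 0.02, seed = seed)
  est <- couplingCoefficient(mk(-10, 1), swapChannels(mk(-10, 2)))
  expect_lt(abs(est@cc["1to2"] - est@cc["2to1"]), 0.002)
  big <- couplingCoefficient(mk(-40, 3))
  expect_lt(abs(big@cc["1to2"] - 0.025), 0.002)
})

test_that("opposite-sign deflections yield a negative coefficient with a warning", {
  ps <- simulatePairedRecording(0, n_sweeps = 4, noise_sd = 0, seed = 1)
  # force a depolarizing follower against a hyperpolarizing injection
  ps@v2 <- ps@v2 - 0.05 * (ps@v1 - ps@holding_mv)
  expect_warning(est <- couplingCoefficient(ps), "opposite-sign")
  expect_lt(est@cc["1to2"], 0)
})

test_that("tiny injected deflections are refused", {
  ps <- simulatePairedRecording(0.025, step_amplitude = -0.5, n_sweeps = 5,
                                noise_sd = 0, seed = 1)
  expect_error(couplingCoefficient(ps), "floor")
})

test_that("classification thresholds on the z-score in both directions", {
  mkEst <- function(cc, sem) {
    dirs <- c("1to2", "2to1")
    methods::new("CouplingEstimate",
                 cc = setNames(rep(cc, 2), dirs),
                 sem = setNames(rep(sem, 2), dirs),
                 n_sweeps = setNames(c(20, 20), dirs),
                 dv_injected = setNames(c(-10, -10), dirs),
                 dv_follower = setNames(rep(cc * -10, 2), dirs),
                 coupled = NA)
  }
  expect_true(isCoupled(classifyCoupled(mkEst(0.025, 0.002))))
  expect_false(isCoupled(classifyCoupled(mkEst(0.001, 0.002))))
})

test_that("detection has high sensitivity at cc = 0.025 and a controlled false-positive rate", {
  run <- function(cc, seed) {
    # null pairs legitimately produce opposite-sign-deflection warnings
    est <- suppressWarnings(couplingCoefficient(
      simulatePairedRecording(cc, n_sweeps = 30, noise_sd = 0.1, seed = seed),
      swapChannels(simulatePairedRecording(cc, n_sweeps = 30, noise_sd = 0.1,
                                           seed = seed + 5000))))
    isCoupled(classifyCoupled(est))
  }
  hits <- vapply(1:40, function(s) run(0.025, s), logical(1))
  false_pos <- vapply(1:40, function(s) run(0, 100 + s), logical(1))
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(false_pos), 0.05)
})
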