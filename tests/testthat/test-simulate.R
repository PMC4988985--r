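# Network and paired-recording simulators: configuration checking,
# determinism, ground-truth structure.

test_that("invalid configurations fail naming the offending field", {
  expect_error(simConfig(frame_interval = 0.1), "frame_interval")
  expect_error(simConfig(responder_fraction = 1.5), "responder_fraction")
  expect_error(simConfig(coupling_strength = -1), "coupling_strength")
  expect_error(simConfig(baseline_duration = 400, stimulus_duration = 300,
                         total_duration = 600), "baseline_duration")
  expect_error(simConfig(cell_radius_range = c(5, 3)), "cell_radius_range")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- smallConfig(seed = 11, coupling_enabled = TRUE)
  a <- simulateNetwork(cfg)
  b <- simulateNetwork(cfg)
  expect_identical(assay(a, "fluorescence"), assay(b, "fluorescence"))
  expect_identical(cellLayout(a), cellLayout(b))
  expect_identical(groundTruth(a), groundTruth(b))
  d <- simulateNetwork(smallConfig(seed = 12, coupling_enabled = TRUE))
  expect_false(identical(assay(a, "fluorescence"), assay(d, "fluorescence")))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); r1 <- runif(3)
  set.seed(99); invisible(simulateNetwork(smallConfig(seed = 5)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("responder_fraction = 0 yields pure baseline traces and no calls", {
  nm <- normalizeTraces(simulateNetwork(smallConfig(seed = 2,
                                                    responder_fraction = 0)))
  resp <- detectResponders(nm)
  expect_equal(sum(resp$is_responder), 0)
  expect_true(all(groundTruth(nm)$truth_class == "none"))
})

test_that("with all heterogeneity off, responder traces are exactly identical", {
  cfg <- smallConfig(seed = 3, noise_sd = 0, additive_noise_sd = 0,
                     slow_sd = 0, coupling_strength = 0, p_biphasic = 1,
                     responder_fraction = 1, biphasic_amp_sd = 0,
                     response_latency_jitter_sd = 0, latency_wave_spread = 0,
                     f0_cv = 0)
  r <- ratioMatrix(normalizeTraces(simulateNetwork(cfg)))
  for (i in 2:nrow(r)) expect_equal(r[i, ], r[1, ], tolerance = 1e-12,
                                    ignore_attr = TRUE)
})

test_that("cell layout respects field bounds and hard-core separation", {
  lay <- cellLayout(simulateNetwork(simConfig(n_cells = 40, seed = 8)))
  expect_true(all(lay$x_um >= lay$radius_um & lay$x_um <= 150 - lay$radius_um))
  expect_true(all(lay$radius_um >= 4 & lay$radius_um <= 6))
  d <- as.matrix(dist(lay[, c("x_um", "y_um")]))
  sep <- d - outer(lay$radius_um, lay$radius_um, "+")
  diag(sep) <- Inf
  expect_true(all(sep >= 0))
})

test_that("coupling graph is symmetric, non-negative, zero-diagonal and decays with distance", {
  ce <- simulateNetwork(smallConfig(seed = 4, coupling_enabled = TRUE))
  W <- couplingGraph(ce)
  expect_identical(W, t(W))
  expect_true(all(W >= 0) && all(diag(W) == 0))
  lay <- cellLayout(ce)
  dmem <- pmax(as.matrix(dist(lay[, c("x_um", "y_um")])) -
                 outer(lay$radius_um, lay$radius_um, "+"), 0)
  ut <- upper.tri(W)
  expect_true(cor(W[ut], dmem[ut]) < -0.5)
})

test_that("coupling raises during-window synchrony in most replicate seeds", {
  wins <- vapply(1:10, function(s) {
    med <- function(coupled) {
      a <- simAnalyzed(seed = 2000 + s + coupled * 500,
                       coupled = coupled == 1, n_cells = 40)
      median(pairwiseCorrelations(a$nm, a$resp, "during")$rho, na.rm = TRUE)
    }
    med(1) > med(0)
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("median during-window synchrony is non-decreasing in coupling strength", {
  grid <- c(0, 0.5, 2)
  means <- vapply(grid, function(st) {
    mean(vapply(1:10, function(s) {
      a <- simAnalyzed(seed = 3000 + s, coupled = TRUE, n_cells = 40,
                       coupling_strength = st)
      median(pairwiseCorrelations(a$nm, a$resp, "during")$rho, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("tonic coupling makes close pairs more synchronous than distant ones", {
  margins <- vapply(1:5, function(s) {
    a <- simAnalyzed(seed = 4000 + s, coupled = TRUE, coupling_mode = "tonic")
    pw <- do.call(rbind, lapply(c("before", "during", "after"), function(w)
      pairwiseCorrelations(a$nm, a$resp, w)))
    mean(pw$rho[pw$distance_um < 5], na.rm = TRUE) -
      mean(pw$rho[pw$distance_um > 50], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(margins), 0)
})

# ---- paired recordings -------------------------------------------------

test_that("paired-recording simulator validates inputs", {
  expect_error(simulatePairedRecording(0.025, n_sweeps = 0), "n_sweeps")
  expect_error(simulatePairedRecording(-0.1), "true_cc")
})

test_that("zero coupling and zero noise give a flat follower channel", {
  ps <- simulatePairedRecording(0, n_sweeps = 5, noise_sd = 0, seed = 1)
  expect_true(all(ps@v2 == ps@holding_mv))
  expect_lt(max(ps@v1), ps@holding_mv + 1e-9)  # hyperpolarizing deflection
})

test_that("noise-free sweeps reproduce the true coupling ratio exactly", {
  ps <- simulatePairedRecording(0.025, n_sweeps = 12, noise_sd = 0, seed = 1)
  est <- couplingCoefficient(ps)
  expect_equal(unname(est@cc["1to2"]), 0.025, tolerance = 1e-12)
  # per-sweep identity, not just the average
  instep <- ps@time_s >= ps@step_offset_s - 0.05 & ps@time_s < ps@step_offset_s
  base <- ps@time_s < ps@step_onset_s
  for (s in c(1L, 7L)) {
    d1 <- mean(ps@v1[s, instep]) - mean(ps@v1[s, base])
    d2 <- mean(ps@v2[s, instep]) - mean(ps@v2[s, base])
    expect_equal(d2 / d1, 0.025, tolerance = 1e-10)
  }
})

test_that("sweep sets carry consistent geometry and swapChannels inverts roles", {
  ps <- simulatePairedRecording(0.025, n_sweeps = 10, seed = 2)
  expect_equal(nSweeps(ps), 10)
  sw <- swapChannels(ps)
  expect_identical(sw@v1, ps@v2)
  expect_identical(sw@v2, ps@v1)
  expect_equal(sw@injected_cell, 2L)
})
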