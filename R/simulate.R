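# Ground-truth simulator: coupled vs uncoupled cell networks and paired
# current-clamp recordings.

#' Simulation configuration for a gonadotrope network recording
#'
#' Returns a validated configuration describing one simulated slice
#' experiment: a field of cells imaged for `total_duration` seconds, a
#' baseline period, then a stimulus whose responders show either a biphasic
#' (fast rise, slow decay to plateau) or an oscillatory calcium waveform.
#' When coupling is enabled, pairwise gap-junction weights decay with
#' membrane distance as `coupling_strength * exp(-d / coupling_length_scale)`;
#' coupling entrains responder onset latencies toward the network mean and
#' diffusively mixes responder signals frame by frame.
#'
#' Response onset latency is `min_latency` plus a perfusion-wave term that
#' grows linearly across the field (`latency_wave_spread` seconds from one
#' edge to the other) plus Gaussian jitter, so that even without coupling
#' nearby cells respond at more similar times than distant ones.
#'
#' @param n_cells number of cells in the field.
#' @param field_size field extent in um, length-2 `c(width, height)`.
#' @param frame_interval imaging frame interval in seconds (0.5--2).
#' @param total_duration recording length in seconds.
#' @param baseline_duration pre-stimulus baseline in seconds.
#' @param stimulus_duration stimulus application in seconds.
#' @param perfusion_delay dead time of the bath-perfusion path, s: the
#'   agonist reaches the slice this long after the valve switches at the
#'   end of the baseline, so responses develop from
#'   `baseline_duration + perfusion_delay` onward (default 120 s, placing
#'   response onsets in the canonical 250--350 s analysis window).
#' @param responder_fraction probability that a cell responds to the
#'   stimulus.
#' @param p_biphasic probability that a responder is biphasic (vs
#'   oscillatory).
#' @param coupling_enabled logical; simulate gap-junction coupling?
#' @param coupling_mode `"evoked"` (coupling acts on stimulus-evoked
#'   signals and latencies only) or `"tonic"` (slow baseline fluctuations
#'   are mixed as well, so short-range pairs correlate in every window).
#' @param coupling_length_scale decay length of the coupling weights, um.
#' @param coupling_strength dimensionless weight scale (>= 0).
#' @param mixing_rounds iterations of the per-frame diffusive averaging;
#'   each round spreads a cell's signal one hop further along the coupled
#'   network, so several rounds entrain connected subnetworks to a common
#'   pattern while leaving isolated cells untouched.
#' @param response_latency_jitter_sd SD of per-cell latency jitter, s.
#' @param latency_wave_spread latency gradient across the field, s.
#' @param noise_sd multiplicative (log-normal) noise SD as a fraction of
#'   baseline fluorescence.
#' @param additive_noise_sd additive Gaussian noise SD, arbitrary units.
#' @param slow_sd stationary SD of the slow baseline calcium fluctuations
#'   (fraction of baseline fluorescence).
#' @param slow_tau correlation time of the baseline fluctuations, s
#'   (Ornstein-Uhlenbeck kinetics).
#' @param oscillation_period_mean,oscillation_period_sd oscillatory-class
#'   period distribution, s.
#' @param biphasic_amp_mean,biphasic_amp_sd biphasic peak amplitude
#'   distribution (ratio units above baseline).
#' @param osc_amp_mean,osc_amp_sd oscillation amplitude distribution.
#' @param tau_rise,tau_decay,plateau_frac biphasic waveform kinetics:
#'   rise and decay time constants (s) and the plateau fraction retained
#'   after the decay.
#' @param cell_radius_range uniform range of cell radii, um.
#' @param f0_mean,f0_cv baseline fluorescence mean (a.u.) and coefficient
#'   of variation across cells.
#' @param min_latency minimum response latency after stimulus onset, s.
#' @param seed integer seed; one global seed feeds named RNG sub-streams
#'   (layout, classes, latency, waveform, slow, baseline, noise).
#' @return a list of class `SimulationConfig`.
#' @seealso [simulateNetwork()]
#' @export
simConfig <- function(n_cells = 60,
                      field_size = c(150, 150),
                      frame_interval = 1,
                      total_duration = 600,
                      baseline_duration = 120,
                      stimulus_duration = 120,
                      perfusion_delay = 120,
                      responder_fraction = 0.4,
                      p_biphasic = 0.6,
                      coupling_enabled = FALSE,
                      coupling_mode = c("evoked", "tonic"),
                      coupling_length_scale = 15,
                      coupling_strength = 2,
                      mixing_rounds = 4,
                      response_latency_jitter_sd = 3,
                      latency_wave_spread = 40,
                      noise_sd = 0.05,
                      additive_noise_sd = 1,
                      slow_sd = 0.03,
                      slow_tau = 10,
                      oscillation_period_mean = 40,
                      oscillation_period_sd = 8,
                      biphasic_amp_mean = 1.5,
                      biphasic_amp_sd = 0.3,
                      osc_amp_mean = 0.8,
                      osc_amp_sd = 0.2,
                      tau_rise = 4,
                      tau_decay = 80,
                      plateau_frac = 0.3,
                      cell_radius_range = c(4, 6),
                      f0_mean = 500,
                      f0_cv = 0.2,
                      min_latency = 2,
                      seed = 1) {
  cfg <- list(n_cells = n_cells, field_size = field_size,
              frame_interval = frame_interval, total_duration = total_duration,
              baseline_duration = baseline_duration,
              stimulus_duration = stimulus_duration,
              perfusion_delay = perfusion_delay,
              responder_fraction = responder_fraction, p_biphasic = p_biphasic,
              coupling_enabled = coupling_enabled,
              coupling_mode = match.arg(coupling_mode),
              coupling_length_scale = coupling_length_scale,
              coupling_strength = coupling_strength,
              mixing_rounds = mixing_rounds,
              response_latency_jitter_sd = response_latency_jitter_sd,
              latency_wave_spread = latency_wave_spread,
              noise_sd = noise_sd, additive_noise_sd = additive_noise_sd,
              slow_sd = slow_sd, slow_tau = slow_tau,
              oscillation_period_mean = oscillation_period_mean,
              oscillation_period_sd = oscillation_period_sd,
              biphasic_amp_mean = biphasic_amp_mean,
              biphasic_amp_sd = biphasic_amp_sd,
              osc_amp_mean = osc_amp_mean, osc_amp_sd = osc_amp_sd,
              tau_rise = tau_rise, tau_decay = tau_decay,
              plateau_frac = plateau_frac,
              cell_radius_range = cell_radius_range,
              f0_mean = f0_mean, f0_cv = f0_cv, min_latency = min_latency,
              seed = seed)
  class(cfg) <- "SimulationConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors name the offending field.
#'
#' @param config a `SimulationConfig` (or equivalent list).
#' @return the config, invisibly, if valid.
#' @export
validateSimConfig <- function(config) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stopf("invalid configuration field '%s': %s", field, what)
  }
  chk(is.numeric(config$n_cells) && config$n_cells >= 1, "n_cells", ">= 1 required")
  chk(length(config$field_size) == 2 && all(config$field_size > 0),
      "field_size", "two positive extents required")
  chk(config$frame_interval >= 0.5 && config$frame_interval <= 2,
      "frame_interval", "must lie in [0.5, 2] s")
  chk(config$total_duration > 0, "total_duration", "must be > 0")
  chk(config$baseline_duration + config$stimulus_duration <= config$total_duration,
      "baseline_duration", "baseline + stimulus must fit in total_duration")
  chk(config$perfusion_delay >= 0, "perfusion_delay", "must be >= 0")
  for (f in c("responder_fraction", "p_biphasic"))
    chk(config[[f]] >= 0 && config[[f]] <= 1, f, "must lie in [0, 1]")
  chk(config$coupling_strength >= 0, "coupling_strength", "must be >= 0")
  chk(is.numeric(config$mixing_rounds) && config$mixing_rounds >= 1,
      "mixing_rounds", "must be >= 1")
  chk(config$coupling_length_scale > 0, "coupling_length_scale", "must be > 0")
  for (f in c("response_latency_jitter_sd", "latency_wave_spread", "noise_sd",
              "additive_noise_sd", "slow_sd", "oscillation_period_sd",
              "biphasic_amp_sd", "osc_amp_sd"))
    chk(config[[f]] >= 0, f, "must be >= 0")
  chk(config$oscillation_period_mean > 0, "oscillation_period_mean", "must be > 0")
  chk(config$slow_tau > 0, "slow_tau", "must be > 0")
  chk(length(config$cell_radius_range) == 2 && all(config$cell_radius_range > 0) &&
        diff(config$cell_radius_range) >= 0,
      "cell_radius_range", "increasing positive range required")
  chk(is.numeric(config$seed) && is.finite(config$seed), "seed", "finite number required")
  invisible(config)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$n_cells, "cells,",
      paste(x$field_size, collapse = " x "), "um field,",
      x$total_duration, "s at", x$frame_interval, "s/frame\n")
  cat(sprintf("  responders %.0f%% (biphasic %.0f%%), coupling %s (%s), seed %d\n",
              100 * x$responder_fraction, 100 * x$p_biphasic,
              if (x$coupling_enabled) "on" else "off", x$coupling_mode,
              as.integer(x$seed)))
  invisible(x)
}

# Biphasic waveform: fast sigmoidal rise, slow decay to a plateau.
biphasicWave <- function(u, amp, tau_rise, tau_decay, plateau) {
  w <- numeric(length(u))
  p <- u > 0
  w[p] <- amp * (1 - exp(-u[p] / tau_rise)) *
    (plateau + (1 - plateau) * exp(-u[p] / tau_decay))
  w
}

# Oscillatory waveform: raised-cosine cycles under a slow envelope.
oscillatoryWave <- function(u, amp, period, envelope_tau = 300) {
  w <- numeric(length(u))
  p <- u > 0
  w[p] <- amp * exp(-u[p] / envelope_tau) * 0.5 * (1 - cos(2 * pi * u[p] / period))
  w
}

#' Simulate a calcium-imaging recording of a coupled or uncoupled network
#'
#' Generates one slice experiment with known ground truth. Non-responders
#' show baseline plus noise only. Responders show, after stimulus onset plus
#' a per-cell latency, a biphasic or oscillatory calcium waveform. When
#' coupling is enabled, a pairwise weight graph
#' `w_ij = coupling_strength * exp(-d_ij / coupling_length_scale)` (membrane
#' distance `d_ij`) is built; responder latencies are entrained toward the
#' degree-weighted network mean and responder signals undergo per-frame
#' weighted diffusive averaging. In `"tonic"` mode the slow baseline
#' fluctuations are mixed as well. Identical configurations (including the
#' seed) give bit-identical output.
#'
#' Cells are placed by a hard-core process (uniform positions, rejected
#' when disks would overlap). Noise is multiplicative log-normal (unit
#' mean) plus additive Gaussian.
#'
#' @param config a [simConfig()] configuration.
#' @param label free-text group label stored with the dataset.
#' @return a [CalciumExperiment-class] with ground truth in `rowData` and
#'   the coupling graph and config in `metadata()`.
#' @examples
#' ce <- simulateNetwork(simConfig(n_cells = 12, seed = 7))
#' ce
#' @export
simulateNetwork <- function(config, label = "sim") {
  validateSimConfig(config)
  withPreservedRNG({
    n <- as.integer(config$n_cells)
    fw <- config$field_size[1]; fh <- config$field_size[2]
    nT <- as.integer(round(config$total_duration / config$frame_interval))
    times <- (seq_len(nT) - 1) * config$frame_interval

    ## layout: hard-core placement, radii first
    setStream(config$seed, "layout")
    radii <- runif(n, config$cell_radius_range[1], config$cell_radius_range[2])
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(20000L)) {
        px <- runif(1, radii[i], fw - radii[i])
        py <- runif(1, radii[i], fh - radii[i])
        if (i == 1L ||
            all((xs[seq_len(i - 1L)] - px)^2 + (ys[seq_len(i - 1L)] - py)^2 >=
                  (radii[seq_len(i - 1L)] + radii[i])^2)) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stopf("could not place %d non-overlapping cells in a %g x %g um field",
              n, fw, fh)
      xs[i] <- px; ys[i] <- py
    }
    layout <- data.frame(cell_id = sprintf("cell_%03d", seq_len(n)),
                         x_um = xs, y_um = ys, radius_um = radii,
                         stringsAsFactors = FALSE)

    ## responder flags and waveform classes
    setStream(config$seed, "classes")
    u_resp <- runif(n); u_class <- runif(n)
    responder <- u_resp < config$responder_fraction
    klass <- ifelse(responder,
                    ifelse(u_class < config$p_biphasic, "biphasic", "oscillatory"),
                    "none")

    ## onset latencies: perfusion-wave gradient + jitter
    setStream(config$seed, "latency")
    jitter <- rnorm(n, 0, config$response_latency_jitter_sd)
    latency <- pmax(0.5,
                    config$min_latency + (xs / fw) * config$latency_wave_spread +
                      jitter)

    ## waveform parameters
    setStream(config$seed, "waveform")
    amp_b <- pmax(0.2, rnorm(n, config$biphasic_amp_mean, config$biphasic_amp_sd))
    amp_o <- pmax(0.1, rnorm(n, config$osc_amp_mean, config$osc_amp_sd))
    period <- pmin(120, pmax(15, rnorm(n, config$oscillation_period_mean,
                                       config$oscillation_period_sd)))

    ## slow baseline calcium fluctuations: stationary Ornstein-Uhlenbeck
    ## (AR(1)) per cell, correlation time slow_tau
    setStream(config$seed, "slow")
    phi <- exp(-config$frame_interval / config$slow_tau)
    innov <- matrix(rnorm(n * nT), n, nT)
    slow <- matrix(0, n, nT)
    slow[, 1] <- innov[, 1]
    for (j in 2:nT)
      slow[, j] <- phi * slow[, j - 1] + sqrt(1 - phi^2) * innov[, j]
    slow <- config$slow_sd * slow

    ## coupling graph on membrane distances
    dx <- outer(xs, xs, "-"); dy <- outer(ys, ys, "-")
    dcent <- sqrt(dx^2 + dy^2)
    dmem <- pmax(dcent - outer(radii, radii, "+"), 0)
    W <- config$coupling_strength * exp(-dmem / config$coupling_length_scale)
    diag(W) <- 0

    ridx <- which(responder)
    if (config$coupling_enabled && length(ridx) > 1) {
      Wr <- W[ridx, ridx, drop = FALSE]
      deg <- rowSums(Wr)
      if (sum(deg) > 0) {
        lbar <- sum(deg * latency[ridx]) / sum(deg)
        entrain <- deg / (1 + deg)
        latency[ridx] <- (1 - entrain) * latency[ridx] + entrain * lbar
      }
    }

    ## evoked signals (stimulus reaches the slice after the perfusion delay)
    onset <- config$baseline_duration + config$perfusion_delay + latency
    evoked <- matrix(0, n, nT)
    for (i in ridx) {
      u <- times - onset[i]
      evoked[i, ] <- if (klass[i] == "biphasic")
        biphasicWave(u, amp_b[i], config$tau_rise, config$tau_decay,
                     config$plateau_frac)
      else
        oscillatoryWave(u, amp_o[i], period[i])
    }

    ## per-frame diffusive mixing among responders; iterating the local
    ## averaging operator lets influence percolate along chains of coupled
    ## neighbors, so connected subnetworks converge on a common pattern
    if (config$coupling_enabled && length(ridx) > 1) {
      Wr <- W[ridx, ridx, drop = FALSE]
      norm <- 1 + rowSums(Wr)
      mixOnce <- function(m) (m + Wr %*% m) / norm
      for (k in seq_len(config$mixing_rounds))
        evoked[ridx, ] <- mixOnce(evoked[ridx, , drop = FALSE])
      if (config$coupling_mode == "tonic") {
        ## mix the basal fluctuations, then restore each cell's stationary
        ## amplitude: coupling correlates basal activity between neighbors
        ## without damping its observed magnitude
        sl <- slow[ridx, , drop = FALSE]
        for (k in seq_len(config$mixing_rounds)) sl <- mixOnce(sl)
        sds <- apply(sl, 1, sd)
        resc <- sds > 0
        sl[resc, ] <- sl[resc, , drop = FALSE] * (config$slow_sd / sds[resc])
        slow[ridx, ] <- sl
      }
    }

    ## baseline fluorescence and noise
    setStream(config$seed, "baseline")
    sdlog <- sqrt(log(1 + config$f0_cv^2))
    f0 <- rlnorm(n, log(config$f0_mean) - sdlog^2 / 2, sdlog)

    setStream(config$seed, "noise")
    mult <- matrix(exp(rnorm(n * nT, 0, config$noise_sd) - config$noise_sd^2 / 2),
                   n, nT)
    addn <- matrix(rnorm(n * nT, 0, config$additive_noise_sd), n, nT)

    f <- f0 * (1 + evoked + slow) * mult + addn
    f <- pmax(f, 1e-3)

    truth <- data.frame(truth_responder = responder, truth_class = klass,
                        truth_onset_s = ifelse(responder, onset, NA_real_),
                        stringsAsFactors = FALSE)
    CalciumExperiment(f, times, layout, truth = truth, couplingGraph = W,
                      label = label, config = config)
  })
}

#' Simulate a paired current-clamp recording
#'
#' Simulates sweeps in which a current step injected into cell 1 produces a
#' steady-state voltage deflection set by a fixed input resistance, while
#' cell 2 shows the same deflection attenuated by the true coupling
#' coefficient. Membrane charging follows a single exponential. Independent
#' Gaussian noise is added per sample on both channels. The reverse
#' direction is available via [swapChannels()] or by simulating a second
#' set.
#'
#' @param true_cc ground-truth coupling coefficient (>= 0).
#' @param step_amplitude current step in pA (negative = hyperpolarizing).
#' @param n_sweeps number of consecutive sweeps (protocols typically use
#'   10--60).
#' @param noise_sd per-sample voltage noise SD, mV.
#' @param seed integer seed.
#' @param sample_rate samples per second.
#' @param input_resistance_gohm input resistance of the injected cell,
#'   GOhm (so pA x GOhm = mV).
#' @param tau_s membrane time constant, s.
#' @param holding_mv holding potential, mV.
#' @param baseline_s,step_s,post_s sweep segment durations, s.
#' @param injected_cell which channel receives the step (1 or 2).
#' @return a [PairedSweepSet-class].
#' @examples
#' ps <- simulatePairedRecording(true_cc = 0.025, n_sweeps = 10, seed = 1)
#' ps
#' @export
simulatePairedRecording <- function(true_cc, step_amplitude = -10,
                                    n_sweeps = 30, noise_sd = 0.1, seed = 1,
                                    sample_rate = 2000,
                                    input_resistance_gohm = 1,
                                    tau_s = 0.02, holding_mv = -60,
                                    baseline_s = 0.1, step_s = 0.5,
                                    post_s = 0.2, injected_cell = 1L) {
  if (!is.numeric(n_sweeps) || n_sweeps < 1)
    stop("n_sweeps must be a positive count")
  if (true_cc < 0) stop("true_cc must be >= 0")
  n_sweeps <- as.integer(n_sweeps)
  withPreservedRNG({
    setStream(seed, "sweeps")
    dt <- 1 / sample_rate
    total <- baseline_s + step_s + post_s
    times <- seq(0, total - dt, by = dt)
    onset <- baseline_s; offset <- baseline_s + step_s
    dv <- step_amplitude * input_resistance_gohm  # pA * GOhm = mV
    det <- numeric(length(times))
    instep <- times >= onset & times < offset
    det[instep] <- dv * (1 - exp(-(times[instep] - onset) / tau_s))
    after <- times >= offset
    det[after] <- dv * (1 - exp(-step_s / tau_s)) *
      exp(-(times[after] - offset) / tau_s)
    ns <- length(times)
    v1 <- matrix(holding_mv + rep(det, each = n_sweeps), n_sweeps, ns) +
      matrix(rnorm(n_sweeps * ns, 0, noise_sd), n_sweeps, ns)
    v2 <- matrix(holding_mv + rep(true_cc * det, each = n_sweeps), n_sweeps, ns) +
      matrix(rnorm(n_sweeps * ns, 0, noise_sd), n_sweeps, ns)
    if (injected_cell == 2L) { tmp <- v1; v1 <- v2; v2 <- tmp }
    methods::new("PairedSweepSet", time_s = times,
                 current_pa = rep(step_amplitude, n_sweeps),
                 v1 = v1, v2 = v2, holding_mv = holding_mv,
                 step_onset_s = onset, step_offset_s = offset,
                 injected_cell = as.integer(injected_cell),
                 true_cc = true_cc)
  })
}
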