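# Coupling-coefficient estimation from paired current-clamp sweeps.

#' Steady-state voltage deflection of one sweep
#'
#' Mean voltage over the steady-state interval minus the mean over the
#' baseline interval (both half-open `[start, end)`). When the current-step
#' edges are supplied, intervals straddling an edge are rejected: the
#' baseline must end at or before the step onset and the steady interval
#' must lie within the step.
#'
#' @param v voltage samples, mV.
#' @param time sample times, s.
#' @param baseline_interval,steady_interval numeric `c(start, end)` in s.
#' @param step_window optional `c(onset, offset)` of the current step used
#'   to validate the intervals.
#' @return deflection in mV.
#' @examples
#' t <- seq(0, 1, by = 0.001)
#' v <- ifelse(t >= 0.2 & t < 0.7, -70, -60)
#' steadyStateDeflection(v, t, c(0.05, 0.2), c(0.5, 0.7))  # -10
#' @export
steadyStateDeflection <- function(v, time, baseline_interval, steady_interval,
                                  step_window = NULL) {
  pick <- function(iv, what) {
    if (iv[1] >= iv[2]) stopf("%s interval must have start < end", what)
    sel <- time >= iv[1] & time < iv[2]
    if (!any(sel)) stopf("%s interval [%g, %g) contains no samples", what,
                         iv[1], iv[2])
    sel
  }
  if (!is.null(step_window)) {
    crosses <- function(iv, edge) iv[1] < edge && iv[2] > edge
    if (crosses(baseline_interval, step_window[1]) ||
        crosses(baseline_interval, step_window[2]))
      stop("baseline interval overlaps a current-step edge")
    if (steady_interval[1] < step_window[1] ||
        steady_interval[2] > step_window[2] + 1e-9)
      stop("steady-state interval must lie within the current step")
  }
  mean(v[pick(steady_interval, "steady-state")]) -
    mean(v[pick(baseline_interval, "baseline")])
}

#' Estimate the gap-junction coupling coefficient from paired sweeps
#'
#' For each sweep the steady-state deflection is measured in the injected
#' and in the follower cell; deflections are averaged across sweeps first
#' and the coupling coefficient is the ratio
#' `mean(dV_follower) / mean(dV_injected)`. The SEM comes from the spread
#' of the per-sweep ratios. A second sweep set with the injection in the
#' other cell fills the reverse direction of the estimate.
#'
#' The defaults follow the analysis convention: steady-state window = last
#' 20\% of the current step, baseline = the 100 ms preceding step onset.
#' The coefficient is positive for same-sign deflections; opposite-sign
#' deflections are reported with a negative coefficient and a warning. An
#' injected-cell deflection smaller than `min_deflection_mv` makes the
#' ratio unstable and is an error.
#'
#' @param sweeps a [PairedSweepSet-class] (its `injected_cell` slot decides
#'   which direction is measured).
#' @param sweeps_reverse optional second `PairedSweepSet` with the
#'   injection in the other cell.
#' @param baseline_interval,steady_interval override the default analysis
#'   windows, `c(start, end)` in s.
#' @param min_deflection_mv floor on `|mean(dV_injected)|` (default 1 mV).
#' @return a [CouplingEstimate-class].
#' @examples
#' ps <- simulatePairedRecording(0.025, n_sweeps = 20, noise_sd = 0, seed = 1)
#' couplingCoefficient(ps)
#' @export
couplingCoefficient <- function(sweeps, sweeps_reverse = NULL,
                                baseline_interval = NULL,
                                steady_interval = NULL,
                                min_deflection_mv = 1) {
  dirs <- c("1to2", "2to1")
  nav <- setNames(rep(NA_real_, 2), dirs)
  est <- methods::new("CouplingEstimate", cc = nav, sem = nav, n_sweeps = nav,
                      dv_injected = nav, dv_follower = nav, coupled = NA)
  est <- fillDirection(est, sweeps, baseline_interval, steady_interval,
                       min_deflection_mv)
  if (!is.null(sweeps_reverse)) {
    if (sweeps_reverse@injected_cell == sweeps@injected_cell)
      stop("sweeps_reverse must have the injection in the other cell")
    est <- fillDirection(est, sweeps_reverse, baseline_interval,
                         steady_interval, min_deflection_mv)
  }
  methods::validObject(est)
  est
}

fillDirection <- function(est, ps, baseline_interval, steady_interval,
                          min_deflection_mv) {
  onset <- ps@step_onset_s; offset <- ps@step_offset_s
  if (is.null(baseline_interval)) baseline_interval <- c(onset - 0.1, onset)
  if (is.null(steady_interval))
    steady_interval <- c(offset - 0.2 * (offset - onset), offset)
  vinj <- if (ps@injected_cell == 1L) ps@v1 else ps@v2
  vfol <- if (ps@injected_cell == 1L) ps@v2 else ps@v1
  d_inj <- apply(vinj, 1, steadyStateDeflection, time = ps@time_s,
                 baseline_interval = baseline_interval,
                 steady_interval = steady_interval,
                 step_window = c(onset, offset))
  d_fol <- apply(vfol, 1, steadyStateDeflection, time = ps@time_s,
                 baseline_interval = baseline_interval,
                 steady_interval = steady_interval,
                 step_window = c(onset, offset))
  m_inj <- mean(d_inj); m_fol <- mean(d_fol)
  if (abs(m_inj) < min_deflection_mv)
    stopf("mean injected-cell deflection %.3g mV is below the %g mV floor; ratio unstable",
          m_inj, min_deflection_mv)
  cc <- m_fol / m_inj
  if (cc < 0 && m_fol != 0)
    warning("opposite-sign deflections: coupling coefficient reported negative")
  ratios <- d_fol / d_inj
  n <- length(ratios)
  dir <- if (ps@injected_cell == 1L) "1to2" else "2to1"
  est@cc[dir] <- cc
  est@sem[dir] <- if (n > 1) sd(ratios) / sqrt(n) else 0
  est@n_sweeps[dir] <- n
  est@dv_injected[dir] <- m_inj
  est@dv_follower[dir] <- m_fol
  est
}

#' Classify a cell pair as electrically coupled
#'
#' A pair counts as coupled when the coupling coefficient exceeds
#' `z_threshold` times its SEM, positively, in every measured direction
#' (both directions when both were recorded). This operationalizes a
#' "detectable voltage deflection" as a z-score criterion; the threshold is
#' exposed.
#'
#' @param estimate a [CouplingEstimate-class].
#' @param z_threshold detection threshold in SEM units (default 3).
#' @return the estimate with its `coupled` slot set; retrieve the flag with
#'   `estimate@coupled` or [isCoupled()].
#' @export
classifyCoupled <- function(estimate, z_threshold = 3) {
  have <- !is.na(estimate@cc)
  if (!any(have)) stop("estimate has no measured direction")
  ok <- estimate@cc[have] > z_threshold * estimate@sem[have]
  estimate@coupled <- all(ok)
  estimate
}

#' @describeIn classifyCoupled the classification flag of an estimate.
#' @export
isCoupled <- function(estimate) estimate@coupled

#' Summarize coupling estimates across a cohort of pairs
#'
#' @param estimates list of classified [CouplingEstimate-class] objects.
#' @return a one-row data.frame: `n_pairs`, `n_coupled`,
#'   `fraction_coupled`, `mean_cc`, `sem_cc` (mean over measured directions
#'   of the coupled pairs).
#' @export
summarizeCoupling <- function(estimates) {
  coupled <- vapply(estimates, function(e) isTRUE(e@coupled), logical(1))
  ccs <- vapply(estimates[coupled],
                function(e) mean(e@cc, na.rm = TRUE), numeric(1))
  data.frame(n_pairs = length(estimates), n_coupled = sum(coupled),
             fraction_coupled = mean(coupled),
             mean_cc = if (length(ccs)) mean(ccs) else NA_real_,
             sem_cc = if (length(ccs) > 1) sd(ccs) / sqrt(length(ccs)) else NA_real_)
}
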