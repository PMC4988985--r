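# Trace normalization, responder detection, waveform classification.

#' Normalize fluorescence traces to relative changes (F/F0)
#'
#' Each cell's trace is divided by its baseline fluorescence F0, the mean
#' of the first `n_baseline_frames` frames, so the baseline of the
#' normalized trace averages exactly 1. Recordings longer than
#' `max_duration` (default 600 s) are truncated to their first
#' `max_duration` seconds before normalization; only that initial period is
#' used for plots and statistics.
#'
#' @param x a [CalciumExperiment-class] or a plain cells x frames matrix of
#'   strictly positive fluorescence values.
#' @param n_baseline_frames number of initial frames averaged into F0
#'   (default 50).
#' @param max_duration truncation limit in seconds (matrix input is never
#'   truncated).
#' @return for a `CalciumExperiment`, the object (possibly truncated) with
#'   an added `"ratio"` assay and `n_baseline_frames` recorded in
#'   `metadata()`; for a matrix, the ratio matrix.
#' @examples
#' m <- matrix(rep(c(100, 250), each = 5, times = 60), nrow = 1)
#' r <- normalizeTraces(m, n_baseline_frames = 10)
#' @export
normalizeTraces <- function(x, n_baseline_frames = 50, max_duration = 600) {
  if (is.matrix(x)) return(normalizeMatrix(x, n_baseline_frames))
  if (!methods::is(x, "CalciumExperiment"))
    stop("x must be a CalciumExperiment or a numeric matrix")
  ts <- timeStamps(x)
  keep <- ts - ts[1] < max_duration
  if (!all(keep)) x <- x[, keep]
  f <- assay(x, "fluorescence")
  ratio <- normalizeMatrix(f, n_baseline_frames)
  assays(x)$ratio <- ratio
  metadata(x)$n_baseline_frames <- as.integer(n_baseline_frames)
  x
}

normalizeMatrix <- function(f, n_baseline_frames) {
  if (ncol(f) < n_baseline_frames)
    stopf("recording has %d frames but %d baseline frames were requested",
          ncol(f), n_baseline_frames)
  bad <- which(f <= 0 | !is.finite(f), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-positive fluorescence at cell %s, frame %d",
          if (is.null(rownames(f))) bad[1, 1] else rownames(f)[bad[1, 1]],
          bad[1, 2])
  f0 <- rowMeans(f[, seq_len(n_baseline_frames), drop = FALSE])
  f / f0
}

#' Detect stimulus-responding cells
#'
#' A cell is called a responder when its smoothed normalized trace exceeds
#' `baseline mean + k_sd * baseline SD` for at least `min_sustained_s`
#' seconds within the response horizon `[stimulus_onset, stimulus_onset +
#' response_horizon)`. The baseline statistics are taken from the
#' pre-stimulus frames of the smoothed ratio trace. Smoothing (a short
#' boxcar) and the sustained-crossing requirement guard against single-frame
#' noise excursions over the long horizon. The onset time is the first
#' frame of the sustained crossing.
#'
#' The threshold criterion is a documented operational definition of
#' "responding"; all of its parameters are exposed.
#'
#' @param x a normalized [CalciumExperiment-class] (see
#'   [normalizeTraces()]).
#' @param stimulus_onset time at which the stimulus reaches the cells, s;
#'   defaults to the simulation config's baseline duration plus perfusion
#'   delay when present, else 240.
#' @param response_horizon seconds after onset searched for a response;
#'   defaults to stimulus duration + 120 s.
#' @param k_sd threshold in baseline SDs above the baseline mean.
#' @param smooth_frames boxcar width (frames) applied before thresholding.
#' @param min_sustained_s minimum time the trace must stay above threshold.
#' @return a data.frame with one row per cell: `cell_id`, `is_responder`,
#'   `response_class` (`"biphasic"`, `"oscillatory"` or `"none"`),
#'   `peak_ratio`, `onset_time` (NA for non-responders), `threshold`.
#' @export
detectResponders <- function(x, stimulus_onset = NULL, response_horizon = NULL,
                             k_sd = 3, smooth_frames = 5, min_sustained_s = 10) {
  ratio <- ratioMatrix(x)
  ts <- timeStamps(x)
  cfg <- metadata(x)$config
  if (is.null(stimulus_onset))
    stimulus_onset <- if (!is.null(cfg))
      cfg$baseline_duration + cfg$perfusion_delay else 240
  if (is.null(response_horizon))
    response_horizon <- if (!is.null(cfg)) cfg$stimulus_duration + 120 else 240
  horizon_end <- stimulus_onset + response_horizon
  in_horizon <- ts >= stimulus_onset & ts < horizon_end
  if (!any(in_horizon))
    stopf("response horizon [%g, %g) s contains no frames", stimulus_onset,
          horizon_end)
  pre <- ts < stimulus_onset
  if (sum(pre) < 3) stop("need at least 3 pre-stimulus frames for baseline statistics")
  dt <- frameInterval(x)
  need_run <- max(1L, as.integer(ceiling(min_sustained_s / dt)))

  ids <- cellLayout(x)$cell_id
  out <- data.frame(cell_id = ids, is_responder = FALSE,
                    response_class = "none", peak_ratio = NA_real_,
                    onset_time = NA_real_, threshold = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ratio))) {
    sm <- movingAverage(ratio[i, ], smooth_frames)
    bmean <- mean(sm[pre]); bsd <- sd(sm[pre])
    thr <- bmean + k_sd * bsd
    out$threshold[i] <- thr
    out$peak_ratio[i] <- max(ratio[i, in_horizon])
    above <- sm > thr & in_horizon
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= need_run)
    if (length(hit)) {
      out$is_responder[i] <- TRUE
      out$onset_time[i] <- ts[starts[hit[1]]]
      out$response_class[i] <- classifyResponse(
        ratio[i, ], ts, onset_time = out$onset_time[i], threshold = thr,
        smooth_frames = smooth_frames)
    }
  }
  out
}

#' Classify a responding trace as biphasic or oscillatory
#'
#' Counts local maxima of the (smoothed) normalized trace that exceed the
#' responder threshold after the onset, using a documented prominence
#' criterion (default half the peak elevation above baseline) and a minimum
#' inter-peak interval. One or two peaks followed by a plateau or decay is
#' called `"biphasic"`; three or more recurring peaks `"oscillatory"`.
#'
#' @param trace normalized ratio series of one cell.
#' @param times frame timestamps, s.
#' @param onset_time response onset, s.
#' @param threshold responder threshold on the ratio scale.
#' @param min_peak_interval_s minimum spacing between counted peaks, s.
#' @param prominence minimum peak prominence; default
#'   `0.5 * (max(trace) - 1)`.
#' @param smooth_frames boxcar width applied before peak finding.
#' @return `"biphasic"` or `"oscillatory"`.
#' @export
classifyResponse <- function(trace, times, onset_time, threshold,
                             min_peak_interval_s = 10, prominence = NULL,
                             smooth_frames = 5) {
  post <- times >= onset_time
  if (!any(post) || max(trace[post]) <= threshold)
    stop("classifyResponse() called on a trace with no response above threshold")
  sm <- movingAverage(trace, smooth_frames)[post]
  peak_ratio <- max(sm)
  if (is.null(prominence)) prominence <- 0.5 * (peak_ratio - 1)
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  min_dist <- max(1L, as.integer(round(min_peak_interval_s / dt)))
  pk <- findLocalPeaks(sm, min_height = threshold, min_distance = min_dist,
                       min_prominence = prominence)
  if (length(pk) >= 3) "oscillatory" else "biphasic"
}
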