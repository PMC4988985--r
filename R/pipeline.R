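# End-to-end orchestration: normalize -> detect responders -> window
# correlations -> group comparison -> distance regression -> short-range
# analysis, with all intermediate tables written out.

#' Pipeline configuration
#'
#' Collects every analysis parameter with the documented defaults: 50
#' baseline frames for F/F0, the before/during/after windows at
#' 100--200 / 250--350 / 500--600 s, responder threshold 3 baseline SDs,
#' membrane-distance convention with a 5 um short-range threshold,
#' per-pair significance 0.001, group-level significance 0.05 and
#' regression-comparison significance 0.001.
#'
#' @param windows named list of [timeWindow()] objects.
#' @param n_baseline_frames baseline frames for normalization.
#' @param stimulus_onset,response_horizon,k_sd responder-detection
#'   parameters (see [detectResponders()]); NULL onset/horizon defer to
#'   each dataset's stored simulation config.
#' @param distance_convention `"membrane"` or `"centroid"`.
#' @param short_range_threshold um threshold of the short-range analysis.
#' @param pair_alpha per-pair significance level (correlation maps).
#' @param group_alpha group-level significance level.
#' @param regression_alpha significance level for regression-line
#'   comparison.
#' @param positive_only restrict the distance regression to positive
#'   coefficients.
#' @param labels length-2 group labels.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(windows = defaultWindows(),
                           n_baseline_frames = 50,
                           stimulus_onset = NULL,
                           response_horizon = NULL,
                           k_sd = 3,
                           distance_convention = c("membrane", "centroid"),
                           short_range_threshold = 5,
                           pair_alpha = 0.001,
                           group_alpha = 0.05,
                           regression_alpha = 0.001,
                           positive_only = TRUE,
                           labels = c("group_a", "group_b")) {
  for (al in c(pair_alpha, group_alpha, regression_alpha))
    if (!(al > 0 && al < 1)) stop("significance levels must lie in (0, 1)")
  structure(list(windows = windows, n_baseline_frames = n_baseline_frames,
                 stimulus_onset = stimulus_onset,
                 response_horizon = response_horizon, k_sd = k_sd,
                 distance_convention = match.arg(distance_convention),
                 short_range_threshold = short_range_threshold,
                 pair_alpha = pair_alpha, group_alpha = group_alpha,
                 regression_alpha = regression_alpha,
                 positive_only = positive_only, labels = labels),
            class = "PipelineConfig")
}

stage <- function(name, label, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed for dataset '%s': %s", name, label,
          conditionMessage(e)))
}

analyzeGroup <- function(datasets, label, config) {
  pairsByWindow <- setNames(vector("list", length(config$windows)),
                            names(config$windows))
  responderCounts <- integer(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (is.character(d)) d <- stage("read", d, readRecording(d))
    dlab <- paste0(label, "_", i)
    norm <- stage("normalize", dlab,
                  normalizeTraces(d, config$n_baseline_frames))
    resp <- stage("detect_responders", dlab,
                  detectResponders(norm, stimulus_onset = config$stimulus_onset,
                                   response_horizon = config$response_horizon,
                                   k_sd = config$k_sd))
    responderCounts[dlab] <- sum(resp$is_responder)
    if (sum(resp$is_responder) < 2) next
    for (w in names(config$windows)) {
      pw <- stage("pairwise_correlations", dlab,
                  pairwiseCorrelations(norm, resp, config$windows[[w]],
                                       convention = config$distance_convention,
                                       group = label))
      pw$dataset <- dlab
      pairsByWindow[[w]] <- rbind(pairsByWindow[[w]], pw)
    }
  }
  list(pairs = pairsByWindow, responder_counts = responderCounts)
}

#' Run the full two-group synchrony pipeline
#'
#' Executes, for two groups of recordings (e.g. wild-type vs knockout
#' slices): normalization, responder detection, all-pairs window
#' correlations pooled across experiments, per-window Mann-Whitney group
#' comparison, correlation-versus-distance regression with slope/intercept
#' comparison, and the short-range (< threshold) analysis. All intermediate
#' tables are written to `out_dir` when given. The run is deterministic
#' given its inputs; the report carries no timestamps.
#'
#' @param group_a,group_b lists of [CalciumExperiment-class] objects or of
#'   directories readable by [readRecording()].
#' @param config a [pipelineConfig()].
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return a list of class `RunReport`: `responder_counts`, `pair_counts`,
#'   `group_comparisons`, `regressions`, `regression_comparisons`,
#'   `short_range`, `config`, `version`.
#' @export
runPipeline <- function(group_a, group_b, config = pipelineConfig(),
                        out_dir = NULL) {
  for (g in list(group_a, group_b))
    for (d in g) if (is.character(d) && !dir.exists(d))
      stopf("input dataset directory does not exist: %s", d)
  la <- config$labels[1]; lb <- config$labels[2]
  resA <- analyzeGroup(group_a, la, config)
  resB <- analyzeGroup(group_b, lb, config)

  wins <- names(config$windows)
  comparisons <- do.call(rbind, lapply(wins, function(w)
    stage("compare_groups", w,
          compareGroups(resA$pairs[[w]], resB$pairs[[w]], w))))

  fits <- list()
  regRows <- NULL
  regComp <- NULL
  for (w in wins) {
    fa <- stage("distance_regression", paste(la, w),
                fitDistanceRegression(resA$pairs[[w]], config$positive_only,
                                      group = la, window = w))
    fb <- stage("distance_regression", paste(lb, w),
                fitDistanceRegression(resB$pairs[[w]], config$positive_only,
                                      group = lb, window = w))
    fits[[w]] <- list(a = fa, b = fb)
    regRows <- rbind(regRows, regressionRow(fa), regressionRow(fb))
    cmp <- compareRegressions(fa, fb, alpha = config$regression_alpha)
    regComp <- rbind(regComp, data.frame(
      window = w, slope_a = fa@slope, slope_b = fb@slope,
      slope_diff = cmp@slope_diff, t_slope = cmp@t_slope,
      p_slope = cmp@p_slope, intercept_diff = cmp@intercept_diff,
      p_intercept = cmp@p_intercept, df = cmp@df,
      significant = cmp@p_slope < config$regression_alpha,
      stringsAsFactors = FALSE))
  }

  shortRange <- stage("short_range", "pooled",
                      shortRangeCompare(do.call(rbind, resA$pairs),
                                        do.call(rbind, resB$pairs),
                                        threshold = config$short_range_threshold,
                                        windows = wins))

  report <- structure(list(
    responder_counts = list(a = resA$responder_counts,
                            b = resB$responder_counts),
    pair_counts = vapply(wins, function(w) nrow(resA$pairs[[w]]) +
                           nrow(resB$pairs[[w]]), numeric(1)),
    group_comparisons = comparisons,
    regressions = regRows,
    regression_comparisons = regComp,
    short_range = shortRange,
    config = config,
    version = as.character(packageVersion("gonadosync"))
  ), class = "RunReport")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (w in wins) {
      writeTSV(resA$pairs[[w]], file.path(out_dir, sprintf("pairs_%s_%s.tsv", la, w)))
      writeTSV(resB$pairs[[w]], file.path(out_dir, sprintf("pairs_%s_%s.tsv", lb, w)))
    }
    writeTSV(comparisons, file.path(out_dir, "group_comparisons.tsv"))
    writeTSV(regRows, file.path(out_dir, "regressions.tsv"))
    writeTSV(regComp, file.path(out_dir, "regression_comparisons.tsv"))
    writeTSV(as.data.frame(shortRange), file.path(out_dir, "short_range.tsv"))
    reportForJson <- report
    reportForJson$config$windows <- lapply(config$windows, unclass)
    write_json(lapply(unclass(reportForJson), function(x)
      if (is.data.frame(x)) x else x),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, force = TRUE,
      na = "null")
  }
  report
}

regressionRow <- function(fit) {
  data.frame(group = fit@group, window = fit@window, slope = fit@slope,
             intercept = fit@intercept, se_slope = fit@se_slope,
             se_intercept = fit@se_intercept, n = fit@n,
             screen_r = fit@screen_r, screen_p = fit@screen_p,
             positive_only = fit@positive_only, stringsAsFactors = FALSE)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (gonadosync", x$version, ")\n")
  cat("  responders per dataset:\n")
  cat("    a:", paste(x$responder_counts$a, collapse = ", "), "\n")
  cat("    b:", paste(x$responder_counts$b, collapse = ", "), "\n")
  cat("  pooled pairs per window:",
      paste(sprintf("%s=%d", names(x$pair_counts), x$pair_counts),
            collapse = ", "), "\n")
  cat("  group comparisons:\n")
  print(x$group_comparisons[, c("window", "n_a", "n_b", "median_a",
                                "median_b", "p_value")], row.names = FALSE)
  cat("  regression slope comparisons:\n")
  print(x$regression_comparisons[, c("window", "slope_a", "slope_b",
                                     "p_slope", "significant")],
        row.names = FALSE)
  cat("  short-range (<", attr(x$short_range, "threshold_um"), "um):\n")
  print(as.data.frame(x$short_range)[, c("window", "n_a", "n_b", "median_a",
                                         "median_b", "p_value")],
        row.names = FALSE)
  invisible(x)
}
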