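# Pairwise Spearman synchrony within time windows, temporal heat maps,
# between-group comparison of coefficient distributions.

#' Extract a time window from normalized traces
#'
#' Frames with `start <= t < end` (half-open) are returned. At least 3
#' samples per cell are required.
#'
#' @param x a normalized [CalciumExperiment-class].
#' @param window a [timeWindow()], a window name, or numeric
#'   `c(start, end)`.
#' @return a cells x frames matrix of ratio values with the frame times in
#'   `attr(, "time_s")` and the window name in `attr(, "window")`.
#' @export
extractWindow <- function(x, window) {
  window <- asTimeWindow(window)
  ts <- timeStamps(x)
  sel <- ts >= window$start & ts < window$end
  if (sum(sel) < 3)
    stopf("window '%s' [%g, %g) contains %d frames (frame interval %g s); need >= 3",
          window$name, window$start, window$end, sum(sel),
          if (length(ts) > 1) ts[2] - ts[1] else NA_real_)
  m <- ratioMatrix(x)[, sel, drop = FALSE]
  attr(m, "time_s") <- ts[sel]
  attr(m, "window") <- window$name
  m
}

#' Spearman rank correlation with large-sample p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks
#' for ties). The p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom;
#' for `exact = TRUE` and n <= 10 with no ties, the exact permutation null
#' distribution is used instead (via [stats::cor.test()]).
#'
#' Zero-variance input makes the coefficient undefined: a degenerate
#' result (`rho = NA`, `degenerate = TRUE`) is returned and such pairs are
#' excluded downstream.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation p-value for n <= 10 (tie-free
#'   input only).
#' @return a list with `rho`, `p_value`, `n`, `degenerate`.
#' @examples
#' spearmanRho(1:4, c(10, 20, 30, 40))$rho  # 1
#' @export
spearmanRho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (exact && n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = TRUE)$p.value)
  } else {
    p <- spearmanPApprox(rho, n)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

# two-sided t approximation on n - 2 df
spearmanPApprox <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

# Full rank-correlation matrix for a cells x frames matrix. Zero-variance
# rows give NA rows/columns (flagged degenerate downstream).
rankCorMatrix <- function(m) {
  rk <- t(apply(m, 1, rank))
  sds <- apply(rk, 1, sd)
  cc <- suppressWarnings(cor(t(rk)))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- ifelse(sds == 0, NA_real_, 1)
  dimnames(cc) <- list(rownames(m), rownames(m))
  cc
}

responderIds <- function(responders) {
  if (is.data.frame(responders)) {
    if (!all(c("cell_id", "is_responder") %in% names(responders)))
      stop("responder data.frame needs 'cell_id' and 'is_responder'")
    responders$cell_id[responders$is_responder]
  } else as.character(responders)
}

#' All-pairs Spearman correlations among responding cells in a window
#'
#' Computes the Spearman coefficient between the normalized traces of every
#' unordered pair of responding cells within one time window, together with
#' the intercellular distance of each pair. Exactly `n * (n - 1) / 2` rows
#' are returned; pairs involving a zero-variance trace are kept but flagged
#' `degenerate` (rho = NA) and are excluded by downstream statistics.
#'
#' @param x a normalized [CalciumExperiment-class].
#' @param responders result of [detectResponders()] or a character vector
#'   of responder cell ids (>= 2 required).
#' @param window analysis window ([timeWindow()], name, or
#'   `c(start, end)`).
#' @param convention `"membrane"` (default) or `"centroid"` distance, see
#'   [pairDistance()].
#' @param group group label attached to every pair; defaults to the
#'   dataset label.
#' @return a data.frame of pair records: `cell_a`, `cell_b`, `window`,
#'   `rho`, `p_value`, `distance_um`, `degenerate`, `group`.
#' @export
pairwiseCorrelations <- function(x, responders, window,
                                 convention = c("membrane", "centroid"),
                                 group = NULL) {
  convention <- match.arg(convention)
  ids <- responderIds(responders)
  if (length(ids) < 2)
    stopf("need at least 2 responding cells, got %d", length(ids))
  if (is.null(group)) group <- datasetLabel(x)
  window <- asTimeWindow(window)
  m <- extractWindow(x, window)[ids, , drop = FALSE]
  nfr <- ncol(m)
  cc <- rankCorMatrix(m)
  layout <- cellLayout(x)
  dmat <- distanceMatrix(layout[match(ids, layout$cell_id), ], convention)
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  rho <- cc[ut]
  data.frame(cell_a = ids[ut[, 1]], cell_b = ids[ut[, 2]],
             window = window$name, rho = rho,
             p_value = vapply(rho, spearmanPApprox, numeric(1), n = nfr),
             distance_um = dmat[ut], degenerate = is.na(rho),
             group = group, stringsAsFactors = FALSE)
}

#' Sliding-window correlation matrices (temporal heat map)
#'
#' Computes a symmetric Spearman correlation matrix of the responding cells
#' in each position of a sliding window, the data behind temporal heat maps
#' of correlated network activity.
#'
#' @inheritParams pairwiseCorrelations
#' @param window_length sliding window length, s (>= 3 frame intervals).
#' @param step window step, s.
#' @return a list of class `CorrelationMapSeries`: `rho` (an n x n x K
#'   array), `centers` (window center times), `cell_ids`, `window_length`.
#' @export
temporalHeatmap <- function(x, responders, window_length = 50, step = 10) {
  ids <- responderIds(responders)
  if (length(ids) < 2)
    stopf("need at least 2 responding cells, got %d", length(ids))
  ts <- timeStamps(x)
  dt <- frameInterval(x)
  if (window_length < 3 * dt)
    stopf("window_length %g s is shorter than 3 frame intervals (%g s)",
          window_length, 3 * dt)
  starts <- seq(ts[1], ts[length(ts)] - window_length, by = step)
  if (!length(starts)) stop("recording shorter than one sliding window")
  arr <- array(NA_real_, dim = c(length(ids), length(ids), length(starts)),
               dimnames = list(ids, ids, NULL))
  for (k in seq_along(starts)) {
    m <- extractWindow(x, c(starts[k], starts[k] + window_length))
    arr[, , k] <- rankCorMatrix(m[ids, , drop = FALSE])
  }
  structure(list(rho = arr, centers = starts + window_length / 2,
                 cell_ids = ids, window_length = window_length),
            class = "CorrelationMapSeries")
}

#' @export
print.CorrelationMapSeries <- function(x, ...) {
  cat(sprintf("CorrelationMapSeries: %d cells, %d windows of %g s (centers %g..%g s)\n",
              length(x$cell_ids), dim(x$rho)[3], x$window_length,
              x$centers[1], x$centers[length(x$centers)]))
  invisible(x)
}

#' Average several correlation-map series element-wise
#'
#' Utility for pooling heat maps across experiments; requires matching
#' window grids and cell counts (e.g. replicate simulations of one
#' configuration).
#'
#' @param maps list of `CorrelationMapSeries` with identical dimensions.
#' @return a `CorrelationMapSeries` of element-wise means (NA-removed).
#' @export
averageHeatmaps <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  dims <- lapply(maps, function(m) dim(m$rho))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all maps must have identical dimensions to be averaged")
  arrs <- simplify2array(lapply(maps, `[[`, "rho"))
  structure(list(rho = apply(arrs, 1:3, mean, na.rm = TRUE),
                 centers = maps[[1]]$centers, cell_ids = maps[[1]]$cell_ids,
                 window_length = maps[[1]]$window_length),
            class = "CorrelationMapSeries")
}

#' Compare correlation-coefficient distributions between two groups
#'
#' Two-sided Mann-Whitney rank-sum test (normal approximation with tie
#' correction) on the Spearman coefficients of two groups of cell pairs in
#' the same window. Degenerate pairs are dropped first.
#'
#' @param pairs_a,pairs_b pair tables from [pairwiseCorrelations()]
#'   (optionally pooled over experiments).
#' @param window window name to compare; defaults to the (single) window
#'   present in `pairs_a`.
#' @return a one-row data.frame: `window`, `n_a`, `n_b`, `median_a`,
#'   `q25_a`, `q75_a`, `median_b`, `q25_b`, `q75_b`, `U`, `p_value`.
#' @export
compareGroups <- function(pairs_a, pairs_b, window = NULL) {
  if (is.null(window)) {
    w <- unique(pairs_a$window)
    if (length(w) != 1)
      stop("pairs_a contains several windows; specify 'window'")
    window <- w
  }
  a <- pairs_a$rho[pairs_a$window == window & !pairs_a$degenerate]
  b <- pairs_b$rho[pairs_b$window == window & !pairs_b$degenerate]
  if (!length(a) || !length(b))
    stopf("empty group for window '%s' (n_a = %d, n_b = %d)", window,
          length(a), length(b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  qa <- quantile(a, c(0.25, 0.75), names = FALSE)
  qb <- quantile(b, c(0.25, 0.75), names = FALSE)
  data.frame(window = window, n_a = length(a), n_b = length(b),
             median_a = median(a), q25_a = qa[1], q75_a = qa[2],
             median_b = median(b), q25_b = qb[1], q75_b = qb[2],
             U = unname(wt$statistic), p_value = wt$p.value,
             stringsAsFactors = FALSE)
}

#' Export a correlation map of significant pairs (nodes + edges)
#'
#' Builds the node/edge structure of a spatial correlation map: nodes are
#' responding cells with their coordinates; edges are pairs whose window
#' correlation is significant at `p_threshold` (default 0.001).
#'
#' @param pairs pair table from [pairwiseCorrelations()].
#' @param layout ROI layout data.frame (see [cellLayout()]).
#' @param p_threshold per-pair significance level.
#' @param file optional path; when given, the structure is written as JSON.
#' @return invisibly, a list with `nodes` and `edges` data.frames.
#' @export
exportCorrelationMap <- function(pairs, layout, p_threshold = 0.001,
                                 file = NULL) {
  ids <- unique(c(pairs$cell_a, pairs$cell_b))
  nodes <- layout[layout$cell_id %in% ids,
                  c("cell_id", "x_um", "y_um", "radius_um")]
  keep <- !pairs$degenerate & !is.na(pairs$p_value) &
    pairs$p_value < p_threshold
  edges <- pairs[keep, c("cell_a", "cell_b", "rho", "p_value", "distance_um")]
  out <- list(nodes = nodes, edges = edges, p_threshold = p_threshold)
  if (!is.null(file))
    write_json(out, file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}
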