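# Intercellular distances, correlation-vs-distance regression, slope and
# intercept comparison between groups, short-range subset analysis.

#' Distance between two cells
#'
#' `"centroid"` is the Euclidean distance between the ROI centroids;
#' `"membrane"` subtracts both radii and floors at zero, approximating the
#' gap between cell membranes.
#'
#' @param a,b one-row data.frames (or named lists) with `x_um`, `y_um`,
#'   `radius_um`.
#' @param convention `"membrane"` or `"centroid"`.
#' @return distance in um.
#' @examples
#' a <- data.frame(x_um = 0, y_um = 0, radius_um = 3)
#' b <- data.frame(x_um = 10, y_um = 0, radius_um = 2)
#' pairDistance(a, b, "membrane")  # 5
#' @export
pairDistance <- function(a, b, convention = c("membrane", "centroid")) {
  convention <- match.arg(convention)
  if (a$radius_um < 0 || b$radius_um < 0) stop("radii must be >= 0")
  d <- sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2)
  if (convention == "centroid") d else max(0, d - a$radius_um - b$radius_um)
}

# All-pairs distance matrix for an ROI layout.
distanceMatrix <- function(layout, convention = c("membrane", "centroid")) {
  convention <- match.arg(convention)
  if (any(layout$radius_um < 0)) stop("radii must be >= 0")
  d <- as.matrix(stats::dist(layout[, c("x_um", "y_um")]))
  if (convention == "membrane")
    d <- pmax(d - outer(layout$radius_um, layout$radius_um, "+"), 0)
  diag(d) <- 0
  dimnames(d) <- list(layout$cell_id, layout$cell_id)
  d
}

#' Regress pairwise correlation coefficients on intercellular distance
#'
#' Ordinary least squares of Spearman rho on pair distance, by default
#' restricted to positive coefficients (the documented filtering of the
#' distance analysis); a full-range fit is available via
#' `positive_only = FALSE` for sensitivity analysis. The prerequisite
#' Pearson correlation screen between coefficient and distance is computed
#' and reported; slope comparison is meant to follow only when this screen
#' is significant.
#'
#' @param pairs pair table from [pairwiseCorrelations()] (optionally pooled
#'   over experiments).
#' @param positive_only drop pairs with rho <= 0 before fitting.
#' @param group,window labels stored on the fit; default from the table.
#' @return a [RegressionFit-class].
#' @export
fitDistanceRegression <- function(pairs, positive_only = TRUE, group = NULL,
                                  window = NULL) {
  keep <- !pairs$degenerate & !is.na(pairs$rho)
  if (positive_only) keep <- keep & pairs$rho > 0
  d <- pairs$distance_um[keep]; r <- pairs$rho[keep]
  if (length(r) < 3)
    stopf("only %d of %d pairs remain after filtering; need >= 3",
          length(r), nrow(pairs))
  if (length(unique(d)) < 2)
    stop("all pairs lie at a single distance; slope is not identifiable")
  fit <- lm(r ~ d)
  sm <- summary(fit)
  screen <- suppressWarnings(cor.test(r, d, method = "pearson"))
  if (is.null(group)) group <- paste(unique(pairs$group), collapse = "+")
  if (is.null(window)) window <- paste(unique(pairs$window), collapse = "+")
  methods::new("RegressionFit",
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               se_slope = sm$coefficients[2, 2],
               se_intercept = sm$coefficients[1, 2],
               n = length(r),
               r = sign(unname(coef(fit)[2])) * sqrt(max(0, sm$r.squared)),
               screen_r = unname(screen$estimate), screen_p = screen$p.value,
               group = group, window = window, positive_only = positive_only)
}

#' Compare two regression lines (slopes and intercepts)
#'
#' Two-sample t-test on independent fits:
#' `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with `df = n1 + n2 - 4`, two
#' sided; intercepts analogously. A significance threshold (default 0.001,
#' the level used for regression-line comparison) is attached as metadata.
#'
#' @param fit_a,fit_b [RegressionFit-class] objects.
#' @param alpha significance threshold recorded on the result.
#' @return a [RegressionComparison-class].
#' @export
compareRegressions <- function(fit_a, fit_b, alpha = 0.001) {
  df <- fit_a@n + fit_b@n - 4
  sdiff <- fit_a@slope - fit_b@slope
  t_s <- sdiff / sqrt(fit_a@se_slope^2 + fit_b@se_slope^2)
  idiff <- fit_a@intercept - fit_b@intercept
  t_i <- idiff / sqrt(fit_a@se_intercept^2 + fit_b@se_intercept^2)
  methods::new("RegressionComparison",
               slope_diff = sdiff, t_slope = t_s,
               p_slope = 2 * pt(abs(t_s), df, lower.tail = FALSE),
               intercept_diff = idiff, t_intercept = t_i,
               p_intercept = 2 * pt(abs(t_i), df, lower.tail = FALSE),
               df = df, alpha = alpha)
}

#' Short-range (< threshold) synchrony comparison
#'
#' Restricts both groups to cell pairs closer than `threshold` um (membrane
#' distance by default, as carried in the pair tables) and runs the
#' Mann-Whitney comparison per window. This is the analysis that probes
#' coupling between immediately neighboring cells across all windows.
#'
#' @param pairs_a,pairs_b pooled pair tables (may contain several windows).
#' @param threshold distance threshold in um (default 5; must be > 0).
#' @param windows window names to analyze; defaults to all windows present
#'   in both tables.
#' @return a data.frame with one [compareGroups()] row per window plus
#'   the threshold as attribute `"threshold_um"`.
#' @export
shortRangeCompare <- function(pairs_a, pairs_b, threshold = 5,
                              windows = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0 um")
  if (is.null(windows))
    windows <- intersect(unique(pairs_a$window), unique(pairs_b$window))
  if (!length(windows)) stop("no common windows between the two groups")
  sa <- pairs_a[pairs_a$distance_um < threshold, ]
  sb <- pairs_b[pairs_b$distance_um < threshold, ]
  if (!nrow(sa) || !nrow(sb))
    stopf("no pairs under %g um in %s (observed minimum distances: %.2f / %.2f um)",
          threshold, if (!nrow(sa)) "group A" else "group B",
          min(pairs_a$distance_um), min(pairs_b$distance_um))
  res <- do.call(rbind, lapply(windows, function(w) compareGroups(sa, sb, w)))
  attr(res, "threshold_um") <- threshold
  res
}
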