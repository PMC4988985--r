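# Internal helpers: named RNG streams, smoothing, peak finding, window logic.

# Deterministic sub-seed for a named stream. Keeps layout / class / noise
# draws independent so changing one simulator setting does not scramble the
# others. Result is kept well below 2^31.
streamSeed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1e6 * 7919 + h * 104729 + 17) %% 2147483629)
}

setStream <- function(seed, stream) set.seed(streamSeed(seed, stream))

# Evaluate expr with the global RNG state protected.
withPreservedRNG <- function(expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Centered boxcar moving average with edge padding; width in frames.
movingAverage <- function(y, width) {
  width <- as.integer(width)
  if (width <= 1L) return(as.numeric(y))
  n <- length(y)
  ypad <- c(rep(y[1L], width), y, rep(y[n], width))
  sm <- stats::filter(ypad, rep(1 / width, width), sides = 2)
  as.numeric(sm[(width + 1L):(width + n)])
}

# Local maxima with minimum height, minimum peak-to-peak distance (in
# samples) and topographic prominence. Returns indices, strongest first
# retained under the distance constraint, finally sorted by position.
findLocalPeaks <- function(y, min_height = -Inf, min_distance = 1L,
                           min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(vapply(2:(n - 1L), function(i) {
    y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, logical(1))) + 1L
  cand <- cand[y[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(i) {
      left <- if (i > 1L) y[seq_len(i - 1L)] else numeric(0)
      hi_l <- which(left > y[i])
      min_l <- if (length(hi_l)) min(y[max(hi_l):i]) else min(y[1:i])
      right <- if (i < n) y[(i + 1L):n] else numeric(0)
      hi_r <- which(right > y[i])
      min_r <- if (length(hi_r)) min(y[i:(i + min(hi_r))]) else min(y[i:n])
      y[i] - max(min_l, min_r)
    }, numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (i in cand[order(y[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_distance)) keep <- c(keep, i)
  }
  sort(keep)
}

# ---- time windows ------------------------------------------------------

#' Define an analysis time window
#'
#' The three canonical windows bracket the stimulation protocol: baseline
#' activity is evaluated at 100--200 s, the stimulus response at 250--350 s
#' and the post-stimulus period at 500--600 s. Windows are half-open
#' `[start, end)` in seconds.
#'
#' @param name one of `"before"`, `"during"`, `"after"` (which carry default
#'   bounds) or `"custom"`.
#' @param start,end window bounds in seconds; required for `"custom"`,
#'   optional overrides otherwise.
#' @return an object of class `TimeWindow` (a named list with `name`,
#'   `start`, `end`).
#' @examples
#' timeWindow("during")
#' timeWindow("custom", 0, 50)
#' @export
timeWindow <- function(name = c("before", "during", "after", "custom"),
                       start = NULL, end = NULL) {
  name <- match.arg(name)
  defaults <- list(before = c(100, 200), during = c(250, 350),
                   after = c(500, 600))
  if (name == "custom") {
    if (is.null(start) || is.null(end))
      stop("custom windows need explicit 'start' and 'end'")
  } else {
    if (is.null(start)) start <- defaults[[name]][1]
    if (is.null(end)) end <- defaults[[name]][2]
  }
  if (!(is.numeric(start) && is.numeric(end) && start < end))
    stop("invalid time window: require start < end")
  structure(list(name = name, start = as.numeric(start), end = as.numeric(end)),
            class = "TimeWindow")
}

#' @export
print.TimeWindow <- function(x, ...) {
  cat(sprintf("TimeWindow '%s': [%g, %g) s\n", x$name, x$start, x$end))
  invisible(x)
}

#' The three canonical analysis windows
#'
#' @return a named list of [timeWindow()] objects (`before`, `during`,
#'   `after`).
#' @export
defaultWindows <- function() {
  list(before = timeWindow("before"), during = timeWindow("during"),
       after = timeWindow("after"))
}

asTimeWindow <- function(window) {
  if (inherits(window, "TimeWindow")) return(window)
  if (is.character(window) && length(window) == 1L) return(timeWindow(window))
  if (is.numeric(window) && length(window) == 2L)
    return(timeWindow("custom", window[1], window[2]))
  stop("'window' must be a TimeWindow, a window name, or numeric c(start, end)")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
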