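# Position-weight-matrix promoter scanning with min-max-normalized
# log-odds ("relative") scores.

# Column-wise log2 odds: frequencies regularized with a background-split
# pseudocount, works for count and frequency matrices alike.
logOddsMatrix <- function(pwm) {
  prof <- pwm@profile
  bg <- pwm@background
  pc <- pwm@pseudocount
  tot <- colSums(prof)
  p <- sweep(prof + pc * bg, 2, tot + pc, "/")
  log2(p / bg)
}

#' Relative (percent-of-maximum) PWM score of a subsequence
#'
#' The raw score is the sum over positions of
#' `log2((f + pseudocount * background) / background)` evaluated at the
#' observed base. The relative score rescales it between the per-position
#' minimum and maximum sums: `100 * (S - S_min) / (S_max - S_min)`, so the
#' consensus sequence scores 100 and the per-position-worst sequence 0. A
#' "minimal matching score" of e.g. 75 refers to this percentage.
#'
#' @param pwm a [PWMatrix-class].
#' @param subsequence DNA string of exactly the motif length; sites
#'   containing N are not scorable and return NA.
#' @return relative score in \[0, 100\].
#' @examples
#' m <- PWMatrix("toy", matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4))
#' relativeScore(m, "AC")  # 100
#' @export
relativeScore <- function(pwm, subsequence) {
  subsequence <- toupper(as.character(subsequence))
  L <- motifLength(pwm)
  if (nchar(subsequence) != L)
    stopf("subsequence length %d does not match motif length %d",
          nchar(subsequence), L)
  lo <- logOddsMatrix(pwm)
  idx <- match(strsplit(subsequence, "")[[1]], rownames(lo))
  if (anyNA(idx)) return(NA_real_)
  s <- sum(lo[cbind(idx, seq_len(L))])
  relScale(s, lo)
}

relScale <- function(s, lo) {
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  if (smax == smin) return(100)
  100 * (s - smin) / (smax - smin)
}

#' Scan a promoter window for PWM matches
#'
#' Slides the matrix over the `window_length` bp immediately upstream of
#' the transcription start site, on the plus strand and (by default) on the
#' minus strand via the reverse complement, and reports every site whose
#' relative score reaches `min_score`. Overlapping hits are all reported.
#' Sites containing N are skipped.
#'
#' Hit positions are given as `bp_upstream`: the distance from the TSS to
#' the hit edge nearest the TSS, 1-based (the base immediately upstream of
#' the TSS is position 1).
#'
#' @param pwm a [PWMatrix-class].
#' @param promoter a [PromoterSequence-class].
#' @param min_score minimal matching score, percent of maximum (default
#'   75).
#' @param both_strands scan the minus strand as well.
#' @return a data.frame sorted by `bp_upstream`: `motif`, `strand`,
#'   `bp_upstream`, `score_pct`, `match` (the motif-strand sequence of the
#'   site).
#' @export
scanPromoter <- function(pwm, promoter, min_score = 75, both_strands = TRUE) {
  W <- promoter@window_length
  L <- motifLength(pwm)
  avail <- promoter@tss_index - 1L
  if (avail < W)
    stopf("scan window of %d bp requested but only %d bp available upstream of the TSS",
          W, avail)
  if (W < L) stop("scan window is shorter than the motif")
  up <- as.character(subseq(promoter@sequence, promoter@tss_index - W,
                            promoter@tss_index - 1L))
  chars <- strsplit(up, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))  # N -> NA
  lo <- logOddsMatrix(pwm)
  np <- W - L + 1L
  scorePositions <- function(mat) {
    s <- numeric(np)
    for (k in seq_len(L)) s <- s + mat[idx[(k):(k + np - 1L)], k]
    s
  }
  hits <- list()
  plus <- scorePositions(lo)
  rel_plus <- vapply(plus, relScale, numeric(1), lo = lo)
  addHits <- function(rel, strand, mat_for_match) {
    sel <- which(!is.na(rel) & rel >= min_score)
    if (!length(sel)) return(NULL)
    site <- vapply(sel, function(p) substr(up, p, p + L - 1L), character(1))
    if (strand == "-")
      site <- vapply(site, function(s)
        as.character(reverseComplement(DNAString(s))), character(1))
    data.frame(motif = pwm@name, strand = strand,
               bp_upstream = W - (sel + L - 1L) + 1L,
               score_pct = rel[sel], match = unname(site),
               stringsAsFactors = FALSE)
  }
  hits$plus <- addHits(rel_plus, "+")
  if (both_strands) {
    lo_rc <- lo[4:1, L:1, drop = FALSE]
    rownames(lo_rc) <- c("A", "C", "G", "T")
    minus <- scorePositions(lo_rc)
    rel_minus <- vapply(minus, relScale, numeric(1), lo = lo)
    hits$minus <- addHits(rel_minus, "-")
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(motif = character(0), strand = character(0),
                      bp_upstream = integer(0), score_pct = numeric(0),
                      match = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$bp_upstream, out$strand), , drop = FALSE]
}

#' Consensus sequence of a PWM
#'
#' The base with the largest weight at each position (ties broken
#' alphabetically); by construction it attains a relative score of 100.
#'
#' @param pwm a [PWMatrix-class].
#' @return character consensus.
#' @export
consensusOf <- function(pwm) {
  lo <- logOddsMatrix(pwm)
  paste(rownames(lo)[apply(lo, 2, which.max)], collapse = "")
}
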