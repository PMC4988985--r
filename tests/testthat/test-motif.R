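# PWM scoring and promoter scanning.

test_that("consensus scores 100 and the per-position-worst sequence scores 0", {
  pwm <- toyPWM()
  expect_equal(consensusOf(pwm), "GATTACA")
  expect_equal(relativeScore(pwm, "GATTACA"), 100)
  # worst base at each position is any of the count-1 bases; e.g. all C
  # except where C is the consensus
  worst <- c("A", "C", "A", "A", "C", "A", "C")
  expect_equal(relativeScore(pwm, paste(worst, collapse = "")), 0)
  expect_true(is.na(relativeScore(pwm, "GATNACA")))
  expect_error(relativeScore(pwm, "GAT"), "length")
})

test_that("relativeScore equals brute-force per-position summation", {
  pwm <- toyPWM()
  prof <- pwm@profile
  brute <- function(s) {
    bases <- strsplit(s, "")[[1]]
    lo <- matrix(NA_real_, 4, ncol(prof), dimnames = dimnames(prof))
    for (j in seq_len(ncol(prof))) for (b in rownames(prof))
      lo[b, j] <- log2(((prof[b, j] + 0.8 * 0.25) / (sum(prof[, j]) + 0.8)) /
                         0.25)
    sc <- 0; lov <- 0; hiv <- 0
    for (j in seq_along(bases)) {
      sc <- sc + lo[bases[j], j]
      lov <- lov + min(lo[, j]); hiv <- hiv + max(lo[, j])
    }
    unname(100 * (sc - lov) / (hiv - lov))
  }
  set.seed(31)
  for (i in 1:50) {
    s <- randomDNA(7)
    expect_equal(relativeScore(pwm, s), brute(s), tolerance = 1e-12)
  }
})

test_that("minus-strand score equals plus-strand score of the reverse complement", {
  pwm <- toyPWM()
  set.seed(41)
  for (i in 1:100) {
    s <- randomDNA(7)
    prom <- promoterSequence(paste0(s, "AAAA"), tss_index = 8,
                             window_length = 7)
    hits <- scanPromoter(pwm, prom, min_score = 0)
    plus <- hits$score_pct[hits$strand == "+"]
    minus <- hits$score_pct[hits$strand == "-"]
    expect_equal(minus, relativeScore(pwm, revcomp(s)), tolerance = 1e-12)
    expect_equal(plus, relativeScore(pwm, s), tolerance = 1e-12)
  }
})

test_that("a planted consensus is recovered at its exact upstream coordinate", {
  set.seed(51)
  W <- 2000
  bg <- strsplit(randomDNA(W), "")[[1]]
  pwm <- toyPWM()
  cons <- strsplit(consensusOf(pwm), "")[[1]]
  # plant so that the TSS-proximal edge sits 725 bp upstream
  start <- W - 725 + 1 - (7 - 1)
  bg[start:(start + 6)] <- cons
  prom <- promoterSequence(paste0(paste(bg, collapse = ""), "CCCC"),
                           tss_index = W + 1, window_length = W)
  hits <- scanPromoter(pwm, prom, min_score = 90)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$bp_upstream, 725)
  expect_equal(plus$score_pct, 100)
  expect_equal(plus$match, "GATTACA")
})

test_that("scanning the reverse-complemented window mirrors hits", {
  set.seed(61)
  W <- 300
  seqs <- randomDNA(W)
  pwm <- toyPWM()
  promF <- promoterSequence(paste0(seqs, "AA"), tss_index = W + 1,
                            window_length = W)
  promR <- promoterSequence(paste0(revcomp(seqs), "AA"), tss_index = W + 1,
                            window_length = W)
  hf <- scanPromoter(pwm, promF, min_score = 60)
  hr <- scanPromoter(pwm, promR, min_score = 60)
  expect_equal(nrow(hf), nrow(hr))
  # a + hit with proximal edge at b maps to a - hit at W - b - L + 2
  L <- 7
  mapped <- sort(W - hf$bp_upstream - L + 2)
  expect_equal(sort(hr$bp_upstream), mapped)
  expect_equal(sort(hr$score_pct), sort(hf$score_pct), tolerance = 1e-12)
  flip <- c("+" = "-", "-" = "+")
  expect_equal(sort(unname(flip[hf$strand])), sort(hr$strand))
})

test_that("hit count is monotone in min_score, exhaustive at 0 and empty above 100", {
  set.seed(71)
  W <- 500
  prom <- promoterSequence(paste0(randomDNA(W), "GG"), tss_index = W + 1,
                           window_length = W)
  pwm <- toyPWM()
  counts <- vapply(c(0, 25, 50, 75, 101), function(ms)
    nrow(scanPromoter(pwm, prom, min_score = ms)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 2 * (W - 7 + 1))
  expect_equal(counts[5], 0)
})

test_that("N-containing sites are skipped and short windows are rejected", {
  pwm <- toyPWM()
  prom <- promoterSequence(paste0("GATTACA", strrep("N", 10), "GATTACA", "TT"),
                           tss_index = 25, window_length = 24)
  hits <- scanPromoter(pwm, prom, min_score = 95)
  expect_equal(nrow(hits[hits$strand == "+", ]), 2)
  expect_error(scanPromoter(pwm, promoterSequence("ACGTACGT", tss_index = 5,
                                                  window_length = 100)),
               "available")
})
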