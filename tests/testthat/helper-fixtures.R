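# Shared fixtures: small simulation configs and hand-built objects.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A small, fast field for unit tests.
smallConfig <- function(seed = 1, ...) {
  simConfig(n_cells = 20, seed = seed, ...)
}

# Simulate + normalize + detect in one go.
simAnalyzed <- function(seed = 1, coupled = FALSE, ...) {
  nm <- normalizeTraces(simulateNetwork(
    simConfig(seed = seed, coupling_enabled = coupled, ...),
    label = if (coupled) "coupled" else "uncoupled"))
  list(nm = nm, resp = detectResponders(nm))
}

poolPairs <- function(arms, window) {
  do.call(rbind, lapply(arms, function(a)
    pairwiseCorrelations(a$nm, a$resp, window)))
}

# Hand-built recording: deterministic matrix with known structure.
manualExperiment <- function(f, frame_interval = 1, radii = NULL) {
  n <- nrow(f)
  if (is.null(radii)) radii <- rep(5, n)
  layout <- data.frame(cell_id = sprintf("c%02d", seq_len(n)),
                       x_um = seq(10, by = 15, length.out = n), y_um = 20,
                       radius_um = radii)
  CalciumExperiment(f, (seq_len(ncol(f)) - 1) * frame_interval, layout)
}

# Independent brute-force Spearman oracle: mid-ranks by explicit counting,
# Pearson by the explicit sum formula (no rank()/cor()).
bruteSpearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(rx)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# A toy PWM whose consensus is GATTACA.
toyPWM <- function(name = "toy") {
  m <- matrix(1, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("G", "A", "T", "T", "A", "C", "A")
  for (j in seq_along(cons)) m[cons[j], j] <- 12
  PWMatrix(name, m)
}

randomDNA <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
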