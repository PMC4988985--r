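# Window extraction, Spearman implementation, pair tables, heat maps,
# group comparison.

test_that("window extraction is half-open and counts frames correctly", {
  nm <- normalizeTraces(simulateNetwork(smallConfig(seed = 1)))
  expect_equal(ncol(extractWindow(nm, timeWindow("before"))), 100)
  nm2 <- normalizeTraces(simulateNetwork(smallConfig(seed = 1,
                                                     frame_interval = 2)))
  expect_equal(ncol(extractWindow(nm2, timeWindow("during"))), 50)
  expect_error(extractWindow(nm, c(900, 950)), "0 frames")
})

test_that("spearmanRho matches hand-computable cases", {
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearmanRho(1:4, c(8, 6, 4, 2))$rho, -1)
  d <- spearmanRho(rep(1, 5), 1:5)
  expect_true(d$degenerate)
  expect_true(is.na(d$rho))
})

test_that("spearmanRho equals the brute-force midrank Pearson oracle", {
  set.seed(77)
  for (i in 1:200) {
    x <- sample(20, 10, replace = TRUE)  # replace=TRUE forces ties
    y <- rnorm(10)
    expect_equal(spearmanRho(x, y)$rho, bruteSpearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearmanRho p-values match the t approximation and the exact option", {
  set.seed(3)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- spearmanRho(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  x8 <- rnorm(8); y8 <- rnorm(8)
  ex <- spearmanRho(x8, y8, exact = TRUE)
  refex <- cor.test(x8, y8, method = "spearman", exact = TRUE)
  expect_equal(ex$p_value, refex$p.value, tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(50); y <- rnorm(50)
  base <- spearmanRho(x, y)$rho
  expect_equal(spearmanRho(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearmanRho(x, y^3)$rho, base, tolerance = 1e-12)
})

test_that("pair tables have exactly n(n-1)/2 unordered pairs with distances", {
  a <- simAnalyzed(seed = 21, responder_fraction = 1, n_cells = 32)
  pw <- pairwiseCorrelations(a$nm, a$resp, "during")
  n <- sum(a$resp$is_responder)
  expect_equal(nrow(pw), n * (n - 1) / 2)
  expect_false(any(duplicated(t(apply(pw[, c("cell_a", "cell_b")], 1, sort)))))
  expect_true(all(pw$distance_um >= 0))
  expect_error(pairwiseCorrelations(a$nm, a$resp$cell_id[1], "during"),
               "at least 2")
})

test_that("two identical traces give a single pair with rho 1", {
  f <- matrix(rep(100 * (1 + c(rep(0, 300), seq(0, 1, length.out = 300))),
                  2), nrow = 2, byrow = TRUE)
  ce <- manualExperiment(f)
  nm <- normalizeTraces(ce)
  pw <- pairwiseCorrelations(nm, c("c01", "c02"), "during")
  expect_equal(nrow(pw), 1)
  expect_equal(pw$rho, 1)
})

test_that("uncoupled simulations show near-zero baseline-window synchrony", {
  meds <- vapply(1:10, function(s) {
    a <- simAnalyzed(seed = 7000 + s, n_cells = 40)
    median(pairwiseCorrelations(a$nm, a$resp, "before")$rho, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(median(meds)), 0.1)
})

test_that("temporal heat maps are symmetric with unit diagonal and flag degenerates", {
  a <- simAnalyzed(seed = 22)
  ids <- a$resp$cell_id[a$resp$is_responder]
  hm <- temporalHeatmap(a$nm, a$resp)
  for (k in c(1, dim(hm$rho)[3])) {
    m <- hm$rho[, , k]
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 1, na.rm = TRUE))
  }
  # stimulus raises mean off-diagonal correlation relative to baseline
  cpl <- simAnalyzed(seed = 23, coupled = TRUE)
  hmc <- temporalHeatmap(cpl$nm, cpl$resp)
  off <- function(k) {
    m <- hmc$rho[, , k]; mean(m[upper.tri(m)], na.rm = TRUE)
  }
  pre <- which(hmc$centers < 200)
  stim <- which(hmc$centers >= 250 & hmc$centers < 400)
  expect_gt(mean(vapply(stim, off, numeric(1))),
            mean(vapply(pre, off, numeric(1))))
  # constant traces -> all degenerate
  fconst <- matrix(100, 3, 600)
  nmc <- normalizeTraces(manualExperiment(fconst))
  hm0 <- temporalHeatmap(nmc, c("c01", "c02", "c03"))
  expect_true(all(is.na(hm0$rho)))
  expect_error(temporalHeatmap(a$nm, ids[1]), "at least 2")
})

test_that("identical groups compare as indistinguishable (p near 1)", {
  a <- simAnalyzed(seed = 24)
  pw <- pairwiseCorrelations(a$nm, a$resp, "during")
  g <- compareGroups(pw, pw, "during")
  expect_gte(g$p_value, 0.99)
  expect_equal(g$median_a, g$median_b)
})

test_that("a shifted rho distribution is detected with high significance", {
  set.seed(5)
  mk <- function(shift) data.frame(
    cell_a = "a", cell_b = "b", window = "during",
    rho = pmin(0.99, pmax(-0.99, rnorm(200, 0.2 + shift, 0.2))),
    p_value = NA, distance_um = 10, degenerate = FALSE, group = "g")
  g <- compareGroups(mk(0.5), mk(0), "during")
  expect_lt(g$p_value, 0.001)
  expect_gt(g$median_a, g$median_b)
  expect_error(compareGroups(mk(0)[0, ], mk(0), "during"), "empty group")
})

test_that("correlation-map export keeps only significant edges", {
  a <- simAnalyzed(seed = 25, coupled = TRUE)
  pw <- pairwiseCorrelations(a$nm, a$resp, "during")
  path <- tempfile(fileext = ".json")
  cmap <- exportCorrelationMap(pw, cellLayout(a$nm), p_threshold = 0.001,
                               file = path)
  expect_true(file.exists(path))
  expect_true(all(cmap$edges$p_value < 0.001))
  expect_true(all(c(cmap$edges$cell_a, cmap$edges$cell_b) %in%
                    cmap$nodes$cell_id))
})
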