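# Readers and writers: trace/ROI CSVs with ground-truth JSON sidecar,
# long-format sweep CSVs, FASTA promoters, JASPAR matrices, result tables,
# optional multi-frame TIFF export/ingestion.

fmtNum <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Write a recording as traces CSV + ROI CSV + ground-truth JSON
#'
#' `traces.csv` has one row per cell (first column `cell_id`) and one
#' column per frame, the header row carrying the timestamps; `rois.csv`
#' holds `cell_id, x_um, y_um, radius_um`; `truth.json` stores the label
#' and, when present, the ground truth and coupling graph. Numeric values
#' are written at full precision so write -> read round-trips exactly.
#'
#' @param x a [CalciumExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeRecording <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- assay(x, "fluorescence")
  ts <- timeStamps(x)
  tracePath <- file.path(dir, "traces.csv")
  header <- paste(c("cell_id", fmtNum(ts)), collapse = ",")
  rows <- vapply(seq_len(nrow(f)), function(i)
    paste(c(rownames(f)[i], fmtNum(f[i, ])), collapse = ","), character(1))
  writeLines(c(header, rows), tracePath)

  roiPath <- file.path(dir, "rois.csv")
  lay <- cellLayout(x)
  roiRows <- vapply(seq_len(nrow(lay)), function(i)
    paste(c(lay$cell_id[i], fmtNum(lay$x_um[i]), fmtNum(lay$y_um[i]),
            fmtNum(lay$radius_um[i])), collapse = ","), character(1))
  writeLines(c("cell_id,x_um,y_um,radius_um", roiRows), roiPath)

  truthPath <- file.path(dir, "truth.json")
  gt <- groundTruth(x)
  sidecar <- list(label = datasetLabel(x))
  if (!is.null(gt)) sidecar$ground_truth <- gt
  W <- couplingGraph(x)
  if (!is.null(W)) sidecar$coupling_graph <- unname(W)
  write_json(sidecar, truthPath, dataframe = "columns", auto_unbox = TRUE,
             digits = NA, na = "null")
  invisible(c(traces = tracePath, rois = roiPath, truth = truthPath))
}

#' Read a recording written by [writeRecording()]
#'
#' Dimension mismatches between the trace table and the ROI table are an
#' error listing the unmatched cell ids.
#'
#' @param dir directory containing `traces.csv`, `rois.csv` and optionally
#'   `truth.json`.
#' @return a [CalciumExperiment-class].
#' @export
readRecording <- function(dir) {
  tracePath <- file.path(dir, "traces.csv")
  roiPath <- file.path(dir, "rois.csv")
  for (p in c(tracePath, roiPath))
    if (!file.exists(p)) stopf("missing input file: %s", p)
  lines <- readLines(tracePath)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ts <- as.numeric(header[-1])
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  ids <- vapply(body, `[`, character(1), 1L)
  f <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  rownames(f) <- ids
  rois <- read.csv(roiPath, stringsAsFactors = FALSE)
  missingRoi <- setdiff(ids, rois$cell_id)
  extraRoi <- setdiff(rois$cell_id, ids)
  if (length(missingRoi) || length(extraRoi))
    stopf("trace/ROI mismatch; unmatched ids: %s",
          paste(c(missingRoi, extraRoi), collapse = ", "))
  rois <- rois[match(ids, rois$cell_id), ]
  truthPath <- file.path(dir, "truth.json")
  label <- ""; truth <- NULL; W <- NULL
  if (file.exists(truthPath)) {
    sidecar <- read_json(truthPath, simplifyVector = TRUE)
    if (!is.null(sidecar$label)) label <- sidecar$label
    if (!is.null(sidecar$ground_truth))
      truth <- as.data.frame(sidecar$ground_truth)[, c("truth_responder",
                                                       "truth_class",
                                                       "truth_onset_s")]
    if (!is.null(sidecar$coupling_graph)) W <- as.matrix(sidecar$coupling_graph)
  }
  CalciumExperiment(f, ts, rois, truth = truth, couplingGraph = W,
                    label = label)
}

#' Write paired sweeps as a long-format CSV
#'
#' Columns: `sweep`, `time_s`, `i_pa` (injected current at that sample),
#' `v1_mv`, `v2_mv`. Channel 1 is the injected cell by convention of the
#' file format.
#'
#' @param x a [PairedSweepSet-class].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeSweeps <- function(x, file) {
  ps <- if (x@injected_cell == 2L) swapChannels(x) else x
  instep <- ps@time_s >= ps@step_onset_s & ps@time_s < ps@step_offset_s
  lines <- c("sweep,time_s,i_pa,v1_mv,v2_mv")
  for (s in seq_len(nSweeps(ps))) {
    i_pa <- ifelse(instep, ps@current_pa[s], 0)
    lines <- c(lines, paste(s, fmtNum(ps@time_s), fmtNum(i_pa),
                            fmtNum(ps@v1[s, ]), fmtNum(ps@v2[s, ]), sep = ","))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read paired sweeps from a long-format CSV
#'
#' The current-step window and amplitude are recovered from the `i_pa`
#' column; the holding potential is estimated from the pre-step baseline
#' of channel 1.
#'
#' @param file path to a CSV written by [writeSweeps()] (or exported in
#'   the same dialect).
#' @return a [PairedSweepSet-class] (with `true_cc = NA`).
#' @export
readSweeps <- function(file) {
  if (!file.exists(file)) stopf("missing input file: %s", file)
  d <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("sweep", "time_s", "i_pa", "v1_mv", "v2_mv")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("sweep file lacks columns: %s", paste(miss, collapse = ", "))
  sweeps <- sort(unique(d$sweep))
  d1 <- d[d$sweep == sweeps[1], ]
  times <- d1$time_s
  v1 <- t(vapply(sweeps, function(s) d$v1_mv[d$sweep == s],
                 numeric(length(times))))
  v2 <- t(vapply(sweeps, function(s) d$v2_mv[d$sweep == s],
                 numeric(length(times))))
  on <- d1$i_pa != 0
  if (!any(on)) stop("no current step found in i_pa column")
  onset <- min(times[on]); offset <- max(times[on]) + diff(times[1:2])
  amp <- vapply(sweeps, function(s) {
    ip <- d$i_pa[d$sweep == s]
    ip[ip != 0][1]
  }, numeric(1))
  holding <- mean(v1[, times < onset, drop = FALSE])
  methods::new("PairedSweepSet", time_s = times, current_pa = amp,
               v1 = v1, v2 = v2, holding_mv = holding,
               step_onset_s = onset, step_offset_s = offset,
               injected_cell = 1L, true_cc = NA_real_)
}

#' Read a promoter sequence from FASTA
#'
#' The first record is used; lowercase letters and line wrapping are
#' normalized.
#'
#' @param file FASTA path.
#' @param tss_index TSS position within the sequence; defaults to the
#'   sequence end.
#' @param window_length upstream scan window, bp.
#' @return a [PromoterSequence-class].
#' @export
readPromoterFasta <- function(file, tss_index = NULL, window_length = 5000) {
  if (!file.exists(file)) stopf("missing input file: %s", file)
  seqs <- readDNAStringSet(file)
  if (!length(seqs)) stop("FASTA file contains no sequences")
  promoterSequence(toupper(as.character(seqs[[1]])), tss_index = tss_index,
                   window_length = window_length)
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses records of the form
#' \preformatted{>MA0112.1 ESR1
#' A  [ 2  5  0 ... ]
#' C  [ 0  1 12 ... ]
#' ...}
#' Bare 4-row number blocks without base labels or brackets are accepted
#' too.
#'
#' @param file path to the matrix file.
#' @param pseudocount,background passed to [PWMatrix()].
#' @return a named list of [PWMatrix-class] objects.
#' @export
readJaspar <- function(file, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(file)) stopf("missing input file: %s", file)
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' records found; not JASPAR text format")
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stopf("record '%s' (line %d): expected 4 matrix rows, found %d",
            name, starts[i], length(block))
    rows <- lapply(seq_along(block), function(j) {
      ln <- gsub("[][]", " ", block[j])
      ln <- sub("^[ACGTacgt][:\\s]*", "", ln, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(v))
        stopf("record '%s', matrix row %d (line %d): non-numeric entries",
              name, j, starts[i] + j)
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("record '%s': ragged matrix rows", name)
    prof <- do.call(rbind, rows)
    out[[name]] <- PWMatrix(name, prof, pseudocount = pseudocount,
                            background = background)
  }
  out
}

#' Write a result table as TSV
#'
#' @param x data.frame (pair table, responder calls, comparisons, ...).
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeTSV <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export heat-map matrices as CSV files
#'
#' One CSV per sliding-window position, named by window center time.
#'
#' @param maps a `CorrelationMapSeries` from [temporalHeatmap()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeHeatmapCSV <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(maps$centers)) {
    p <- file.path(dir, sprintf("heatmap_t%06.1f.csv", maps$centers[k]))
    write.csv(maps$rho[, , k], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# ---- optional TIFF layer ----------------------------------------------

#' Render a recording as a multi-frame TIFF stack
#'
#' Rasterizes the field at 1 um/pixel, painting each cell's disk with its
#' fluorescence, frame by frame (16-bit, scaled to the stack maximum).
#' Useful for exercising image-reading code paths; requires the `tiff`
#' package.
#'
#' @param x a [CalciumExperiment-class].
#' @param file output TIFF path.
#' @param field_size raster extent `c(width, height)` in um; default covers
#'   the layout.
#' @return invisibly, the scale factor (a.u. per intensity unit) needed to
#'   recover fluorescence from pixel values.
#' @export
writeRecordingTiff <- function(x, file, field_size = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  lay <- cellLayout(x)
  if (is.null(field_size))
    field_size <- ceiling(c(max(lay$x_um + lay$radius_um),
                            max(lay$y_um + lay$radius_um)) + 1)
  f <- assay(x, "fluorescence")
  w <- as.integer(field_size[1]); h <- as.integer(field_size[2])
  px <- outer(rep(1, h), seq_len(w) - 0.5)
  py <- outer(seq_len(h) - 0.5, rep(1, w))
  masks <- lapply(seq_len(nrow(lay)), function(i)
    which((px - lay$x_um[i])^2 + (py - lay$y_um[i])^2 <= lay$radius_um[i]^2))
  scale <- max(f) * 1.05
  frames <- lapply(seq_len(ncol(f)), function(j) {
    img <- matrix(0, h, w)
    for (i in seq_len(nrow(lay))) img[masks[[i]]] <- f[i, j] / scale
    img
  })
  tiff::writeTIFF(frames, file, bits.per.sample = 16)
  invisible(scale)
}

#' Extract mean-ROI traces from a multi-frame TIFF
#'
#' Averages pixel intensities within each ROI disk per frame, the standard
#' mean-ROI extraction given a manually drawn ROI table.
#'
#' @param file TIFF path.
#' @param layout ROI table (`cell_id`, `x_um`, `y_um`, `radius_um`) at
#'   1 um/pixel.
#' @param timestamps frame times, s.
#' @param scale intensity-to-fluorescence factor (as returned by
#'   [writeRecordingTiff()]).
#' @return a [CalciumExperiment-class].
#' @export
readRecordingTiff <- function(file, layout, timestamps, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  frames <- tiff::readTIFF(file, all = TRUE)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  px <- outer(rep(1, h), seq_len(w) - 0.5)
  py <- outer(seq_len(h) - 0.5, rep(1, w))
  f <- matrix(NA_real_, nrow(layout), length(frames))
  for (i in seq_len(nrow(layout))) {
    mask <- (px - layout$x_um[i])^2 + (py - layout$y_um[i])^2 <=
      layout$radius_um[i]^2
    f[i, ] <- vapply(frames, function(fr) mean(fr[mask]) * scale, numeric(1))
  }
  rownames(f) <- layout$cell_id
  CalciumExperiment(pmax(f, 1e-6), timestamps, layout)
}
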