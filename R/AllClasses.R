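# S4 classes for recordings, paired sweeps, coupling estimates, regression
# results and position weight matrices.

#' CalciumExperiment: a calcium-imaging recording of one slice
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with cells as rows
#' and imaging frames as columns. The `"fluorescence"` assay holds raw
#' fluorescence in arbitrary units (> 0); after [normalizeTraces()] a
#' `"ratio"` assay holds the F/F0 series. `rowData` carries the ROI layout
#' (`cell_id`, `x_um`, `y_um`, `radius_um`) and, for simulated data, the
#' ground truth (`truth_responder`, `truth_class`, `truth_onset_s`).
#' `colData$time_s` holds the frame timestamps (strictly increasing,
#' constant spacing). `metadata()` may carry the simulation config, the
#' pairwise coupling graph, and a free-text group label.
#'
#' @export
setClass("CalciumExperiment", contains = "SummarizedExperiment")

setValidity("CalciumExperiment", function(object) {
  msg <- character(0)
  if (!"fluorescence" %in% assayNames(object))
    msg <- c(msg, "assay 'fluorescence' is required")
  else {
    f <- assay(object, "fluorescence")
    if (any(!is.finite(f)) || any(f <= 0))
      msg <- c(msg, "fluorescence values must be finite and strictly positive")
  }
  cd <- colData(object)
  if (!"time_s" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'time_s'")
  } else {
    ts <- cd$time_s
    if (length(ts) > 1) {
      dt <- diff(ts)
      if (any(dt <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
      else if (max(dt) - min(dt) > 1e-6 * max(dt))
        msg <- c(msg, "timestamps must have constant frame spacing")
    }
  }
  rd <- rowData(object)
  need <- c("cell_id", "x_um", "y_um", "radius_um")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData is missing: ", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(rd$cell_id)) msg <- c(msg, "cell ids must be unique")
    if (any(rd$radius_um <= 0)) msg <- c(msg, "all cell radii must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CalciumExperiment
#'
#' @param fluorescence numeric matrix, cells x frames, strictly positive.
#' @param timestamps numeric vector of frame times in seconds (constant
#'   spacing).
#' @param layout data.frame with columns `cell_id`, `x_um`, `y_um`,
#'   `radius_um`, one row per cell, in the row order of `fluorescence`.
#' @param truth optional data.frame of simulator ground truth with columns
#'   `truth_responder` (logical), `truth_class`
#'   (`"biphasic"`/`"oscillatory"`/`"none"`) and `truth_onset_s`.
#' @param couplingGraph optional symmetric non-negative weight matrix with
#'   zero diagonal describing pairwise gap-junction coupling.
#' @param label free-text group label (e.g. `"wt"`, `"ko"`).
#' @param config optional simulation configuration to store in metadata.
#' @return a [CalciumExperiment-class] object.
#' @export
CalciumExperiment <- function(fluorescence, timestamps, layout, truth = NULL,
                              couplingGraph = NULL, label = "", config = NULL) {
  fluorescence <- as.matrix(fluorescence)
  if (nrow(layout) != nrow(fluorescence))
    stopf("layout has %d rows but fluorescence has %d cells",
          nrow(layout), nrow(fluorescence))
  if (length(timestamps) != ncol(fluorescence))
    stopf("%d timestamps for %d frames", length(timestamps), ncol(fluorescence))
  rd <- DataFrame(layout)
  if (!is.null(truth)) rd <- cbind(rd, DataFrame(truth))
  rownames(fluorescence) <- layout$cell_id
  if (!is.null(couplingGraph)) {
    if (!isTRUE(all.equal(couplingGraph, t(couplingGraph))) ||
        any(diag(couplingGraph) != 0) || any(couplingGraph < 0) ||
        any(!is.finite(couplingGraph)))
      stop("couplingGraph must be symmetric, non-negative, finite, zero-diagonal")
    dimnames(couplingGraph) <- list(layout$cell_id, layout$cell_id)
  }
  se <- SummarizedExperiment(
    assays = list(fluorescence = fluorescence),
    rowData = rd,
    colData = DataFrame(time_s = as.numeric(timestamps)),
    metadata = list(label = label, config = config,
                    coupling_graph = couplingGraph)
  )
  methods::new("CalciumExperiment", se)
}

#' @describeIn CalciumExperiment frame timestamps in seconds.
#' @param x a `CalciumExperiment`.
#' @export
timeStamps <- function(x) colData(x)$time_s

#' @describeIn CalciumExperiment frame interval in seconds.
#' @export
frameInterval <- function(x) {
  ts <- timeStamps(x)
  if (length(ts) < 2) stop("recording has fewer than 2 frames")
  ts[2] - ts[1]
}

#' @describeIn CalciumExperiment ROI layout as a data.frame
#'   (`cell_id`, `x_um`, `y_um`, `radius_um`).
#' @export
cellLayout <- function(x) {
  as.data.frame(rowData(x)[, c("cell_id", "x_um", "y_um", "radius_um")])
}

#' @describeIn CalciumExperiment group label stored in metadata.
#' @export
datasetLabel <- function(x) {
  lb <- metadata(x)$label
  if (is.null(lb)) "" else lb
}

#' @describeIn CalciumExperiment simulator ground truth (or NULL).
#' @export
groundTruth <- function(x) {
  rd <- rowData(x)
  if (!"truth_responder" %in% colnames(rd)) return(NULL)
  as.data.frame(rd[, c("cell_id", "truth_responder", "truth_class",
                       "truth_onset_s")])
}

#' @describeIn CalciumExperiment pairwise coupling-weight matrix (or NULL).
#' @export
couplingGraph <- function(x) metadata(x)$coupling_graph

#' @describeIn CalciumExperiment TRUE once [normalizeTraces()] has added the
#'   `"ratio"` assay.
#' @export
isNormalized <- function(x) "ratio" %in% assayNames(x)

#' @describeIn CalciumExperiment the F/F0 ratio assay (error if the object
#'   has not been normalized).
#' @export
ratioMatrix <- function(x) {
  if (!isNormalized(x)) stop("object has no 'ratio' assay; run normalizeTraces() first")
  assay(x, "ratio")
}

setMethod("show", "CalciumExperiment", function(object) {
  cat("CalciumExperiment:", nrow(object), "cells x", ncol(object), "frames\n")
  ts <- timeStamps(object)
  cat(sprintf("  time: %g..%g s (dt = %g s)\n", ts[1], ts[length(ts)],
              if (length(ts) > 1) ts[2] - ts[1] else NA))
  cat("  label:", datasetLabel(object),
      "| normalized:", isNormalized(object), "\n")
  gt <- groundTruth(object)
  if (!is.null(gt))
    cat("  ground truth:", sum(gt$truth_responder), "responders\n")
})

# ---- paired current-clamp sweeps --------------------------------------

#' PairedSweepSet: simultaneous two-cell current-clamp sweeps
#'
#' Voltage sweeps recorded simultaneously from two cells while a current
#' step is injected into one of them. `v1`/`v2` are sweeps x samples
#' matrices in mV; `current_pa` gives the step amplitude per sweep (pA,
#' negative for hyperpolarizing steps); `injected_cell` says which channel
#' received the current. Typical protocols average 10--60 consecutive
#' sweeps.
#'
#' @slot time_s sample times in seconds.
#' @slot current_pa per-sweep injected current step amplitude (pA).
#' @slot v1,v2 voltage matrices, sweeps x samples (mV).
#' @slot holding_mv holding potential (mV).
#' @slot step_onset_s,step_offset_s current-step edges (s).
#' @slot injected_cell 1 or 2.
#' @slot true_cc simulated ground-truth coupling coefficient (NA for real
#'   data).
#' @export
setClass("PairedSweepSet",
  representation(time_s = "numeric", current_pa = "numeric",
                 v1 = "matrix", v2 = "matrix", holding_mv = "numeric",
                 step_onset_s = "numeric", step_offset_s = "numeric",
                 injected_cell = "integer", true_cc = "numeric"))

setValidity("PairedSweepSet", function(object) {
  msg <- character(0)
  if (!identical(dim(object@v1), dim(object@v2)))
    msg <- c(msg, "v1 and v2 must have the same dimensions")
  if (nrow(object@v1) < 1) msg <- c(msg, "need at least one sweep")
  if (ncol(object@v1) != length(object@time_s))
    msg <- c(msg, "sample count must match length(time_s)")
  if (length(object@current_pa) != nrow(object@v1))
    msg <- c(msg, "one current amplitude per sweep required")
  if (!object@injected_cell %in% c(1L, 2L))
    msg <- c(msg, "injected_cell must be 1 or 2")
  if (object@step_onset_s >= object@step_offset_s)
    msg <- c(msg, "step onset must precede offset")
  if (length(msg)) msg else TRUE
})

#' @describeIn PairedSweepSet number of sweeps.
#' @param x a `PairedSweepSet`.
#' @export
nSweeps <- function(x) nrow(x@v1)

#' @describeIn PairedSweepSet swap the two voltage channels (and the
#'   injected-cell annotation), giving the reverse-direction recording.
#' @export
swapChannels <- function(x) {
  methods::new("PairedSweepSet", time_s = x@time_s, current_pa = x@current_pa,
               v1 = x@v2, v2 = x@v1, holding_mv = x@holding_mv,
               step_onset_s = x@step_onset_s, step_offset_s = x@step_offset_s,
               injected_cell = if (x@injected_cell == 1L) 2L else 1L,
               true_cc = x@true_cc)
}

setMethod("show", "PairedSweepSet", function(object) {
  cat(sprintf("PairedSweepSet: %d sweeps x %d samples, step %g pA into cell %d\n",
              nSweeps(object), ncol(object@v1), object@current_pa[1],
              object@injected_cell))
  cat(sprintf("  step [%g, %g] s, holding %g mV, true cc %s\n",
              object@step_onset_s, object@step_offset_s, object@holding_mv,
              ifelse(is.na(object@true_cc), "unknown", object@true_cc)))
})

# ---- coupling estimate -------------------------------------------------

#' CouplingEstimate: bidirectional gap-junction coupling coefficient
#'
#' The coupling coefficient in each direction is the steady-state voltage
#' deflection of the follower cell divided by that of the injected cell,
#' computed on sweep-averaged deflections; the SEM comes from the spread of
#' per-sweep ratios. Slots are length-2 vectors named `"1to2"`, `"2to1"`
#' (NA where a direction was not measured).
#'
#' @slot cc,sem,n_sweeps,dv_injected,dv_follower named length-2 vectors.
#' @slot coupled logical classification flag (NA until
#'   [classifyCoupled()] is applied).
#' @export
setClass("CouplingEstimate",
  representation(cc = "numeric", sem = "numeric", n_sweeps = "numeric",
                 dv_injected = "numeric", dv_follower = "numeric",
                 coupled = "logical"))

setValidity("CouplingEstimate", function(object) {
  dirs <- c("1to2", "2to1")
  msg <- character(0)
  for (sl in c("cc", "sem", "n_sweeps", "dv_injected", "dv_follower"))
    if (!identical(names(methods::slot(object, sl)), dirs))
      msg <- c(msg, sprintf("slot '%s' must be named c('1to2','2to1')", sl))
  if (any(object@sem < 0, na.rm = TRUE)) msg <- c(msg, "SEMs must be >= 0")
  if (any(object@n_sweeps < 1, na.rm = TRUE))
    msg <- c(msg, "n_sweeps must be >= 1 where measured")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CouplingEstimate", function(object) {
  cat("CouplingEstimate\n")
  for (d in c("1to2", "2to1")) {
    if (is.na(object@cc[d])) next
    cat(sprintf("  %s: cc = %.4g +/- %.2g (SEM), dV_inj = %.3g mV, dV_fol = %.3g mV, n = %d\n",
                d, object@cc[d], object@sem[d], object@dv_injected[d],
                object@dv_follower[d], as.integer(object@n_sweeps[d])))
  }
  cat("  coupled:", object@coupled, "\n")
})

# ---- regression results ------------------------------------------------

#' RegressionFit: correlation-versus-distance regression for one group
#'
#' Ordinary least squares fit of pairwise Spearman coefficients on
#' intercellular distance, after the documented filtering (positive
#' coefficients only, by default). `screen_r`/`screen_p` report the
#' prerequisite Pearson correlation screen between coefficient and
#' distance.
#'
#' @slot slope,intercept,se_slope,se_intercept OLS estimates (slope per um).
#' @slot n number of pairs entering the fit.
#' @slot r signed correlation of the fit.
#' @slot screen_r,screen_p Pearson screen statistic and p-value.
#' @slot group,window labels.
#' @slot positive_only whether the rho > 0 filter was applied.
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric",
                 se_slope = "numeric", se_intercept = "numeric",
                 n = "integer", r = "numeric",
                 screen_r = "numeric", screen_p = "numeric",
                 group = "character", window = "character",
                 positive_only = "logical"))

setValidity("RegressionFit", function(object) {
  msg <- character(0)
  if (object@n < 3L) msg <- c(msg, "a fit needs at least 3 pairs")
  if (!is.na(object@se_slope) && object@se_slope <= 0)
    msg <- c(msg, "standard errors must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit [%s, %s window]: rho = %.4g %+.4g * d\n",
              object@group, object@window, object@intercept, object@slope))
  cat(sprintf("  SE(slope) = %.3g, SE(intercept) = %.3g, n = %d pairs\n",
              object@se_slope, object@se_intercept, object@n))
  cat(sprintf("  distance screen: r = %.3f, p = %.3g\n",
              object@screen_r, object@screen_p))
})

#' RegressionComparison: between-group slope and intercept test
#'
#' Two-sample t comparison of independent regression lines:
#' `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with `df = n1 + n2 - 4`;
#' intercepts analogously. The significance threshold used for this
#' comparison (0.001) is attached as metadata.
#'
#' @slot slope_diff,t_slope,p_slope slope contrast.
#' @slot intercept_diff,t_intercept,p_intercept intercept contrast.
#' @slot df residual degrees of freedom (n1 + n2 - 4).
#' @slot alpha significance threshold attached to the comparison.
#' @export
setClass("RegressionComparison",
  representation(slope_diff = "numeric", t_slope = "numeric",
                 p_slope = "numeric", intercept_diff = "numeric",
                 t_intercept = "numeric", p_intercept = "numeric",
                 df = "numeric", alpha = "numeric"))

setMethod("show", "RegressionComparison", function(object) {
  cat("RegressionComparison (df =", object@df, ")\n")
  cat(sprintf("  slopes:     diff = %+.4g, t = %.3f, p = %.3g\n",
              object@slope_diff, object@t_slope, object@p_slope))
  cat(sprintf("  intercepts: diff = %+.4g, t = %.3f, p = %.3g\n",
              object@intercept_diff, object@t_intercept, object@p_intercept))
  cat("  significance threshold:", object@alpha, "\n")
})

# ---- position weight matrix -------------------------------------------

#' PWMatrix: a position weight matrix over A, C, G, T
#'
#' Stores the raw per-position base counts or frequencies together with the
#' pseudocount and background model used for log-odds scoring. Columns are
#' motif positions, rows are the four bases.
#'
#' @slot name motif identifier.
#' @slot profile 4 x L non-negative matrix, rownames A, C, G, T.
#' @slot pseudocount total pseudocount distributed by background frequency.
#' @slot background named base-frequency vector (sums to 1).
#' @export
setClass("PWMatrix",
  representation(name = "character", profile = "matrix",
                 pseudocount = "numeric", background = "numeric"))

setValidity("PWMatrix", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@profile), c("A", "C", "G", "T")))
    msg <- c(msg, "profile rows must be A, C, G, T")
  if (ncol(object@profile) < 1) msg <- c(msg, "at least one position required")
  if (any(object@profile < 0)) msg <- c(msg, "profile entries must be >= 0")
  if (any(colSums(object@profile) <= 0))
    msg <- c(msg, "every position needs a positive column sum")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background frequencies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMatrix
#'
#' @param name motif identifier.
#' @param profile 4 x L matrix of counts or frequencies; rows A, C, G, T
#'   (rownames optional if already in that order).
#' @param pseudocount total pseudocount, split across bases proportional to
#'   the background (default 0.8, the convention of JASPAR-style scoring).
#' @param background base frequencies; default uniform.
#' @return a [PWMatrix-class].
#' @export
PWMatrix <- function(name, profile, pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  profile <- as.matrix(profile)
  if (nrow(profile) != 4) stop("profile must have 4 rows (A, C, G, T)")
  rownames(profile) <- c("A", "C", "G", "T")
  names(background) <- c("A", "C", "G", "T")
  methods::new("PWMatrix", name = name, profile = profile,
               pseudocount = pseudocount, background = background)
}

#' @describeIn PWMatrix motif length in bp.
#' @param x a `PWMatrix`.
#' @export
motifLength <- function(x) ncol(x@profile)

setMethod("show", "PWMatrix", function(object) {
  cat(sprintf("PWMatrix '%s': %d positions, pseudocount %g\n", object@name,
              motifLength(object), object@pseudocount))
  print(round(object@profile, 3))
})

# ---- promoter sequence -------------------------------------------------

#' PromoterSequence: a promoter with an annotated transcription start site
#'
#' Wraps a DNA sequence together with the index of the transcription start
#' site (TSS) and the length of the upstream window to scan. Hit positions
#' are reported in bp upstream of the TSS (the base immediately upstream is
#' position 1).
#'
#' @slot sequence a [Biostrings::DNAString].
#' @slot tss_index 1-based position of the TSS within `sequence`.
#' @slot window_length upstream scan window in bp (default 5000).
#' @export
setClass("PromoterSequence",
  representation(sequence = "DNAString", tss_index = "integer",
                 window_length = "integer"))

setValidity("PromoterSequence", function(object) {
  msg <- character(0)
  if (object@tss_index < 1 || object@tss_index > length(object@sequence))
    msg <- c(msg, "tss_index must lie within the sequence")
  if (object@window_length < 1) msg <- c(msg, "window_length must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterSequence
#'
#' @param sequence DNA sequence (character or `DNAString`); lowercase is
#'   normalized to uppercase, letters outside A/C/G/T/N are rejected.
#' @param tss_index 1-based TSS position within the sequence; defaults to
#'   one past the end (the whole sequence is upstream).
#' @param window_length upstream window to scan, bp.
#' @return a [PromoterSequence-class].
#' @export
promoterSequence <- function(sequence, tss_index = NULL, window_length = 5000) {
  if (is.character(sequence)) {
    sequence <- toupper(gsub("[ \t\r\n]", "", sequence))
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T", "N"))
    if (length(bad))
      stopf("sequence contains non-IUPAC-DNA letters: %s",
            paste(bad, collapse = ", "))
    sequence <- DNAString(sequence)
  }
  if (is.null(tss_index)) tss_index <- length(sequence)
  methods::new("PromoterSequence", sequence = sequence,
               tss_index = as.integer(tss_index),
               window_length = as.integer(window_length))
}

setMethod("show", "PromoterSequence", function(object) {
  cat(sprintf("PromoterSequence: %d bp, TSS at %d, scan window %d bp upstream\n",
              length(object@sequence), object@tss_index, object@window_length))
})
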