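#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib fetalT2star, .registration = TRUE
NULL

# ---------------------------------------------------------------------------
# EchoTrain
# ---------------------------------------------------------------------------

#' Echo-train metadata for a multi-echo gradient-echo acquisition
#'
#' Holds the echo times and repetition time of a multi-echo acquisition.
#' The canonical internal unit is milliseconds; BIDS sidecars (which store
#' seconds) are converted on read. At least three echoes are required for
#' mono-exponential fitting; the reference protocol uses four, spanning
#' 11.6--182 ms.
#'
#' @slot echoTimes numeric, strictly increasing echo times in milliseconds.
#' @slot repetitionTime numeric scalar, repetition time in milliseconds.
#' @export
setClass("EchoTrain",
  slots = c(echoTimes = "numeric", repetitionTime = "numeric"),
  prototype = prototype(echoTimes = c(11.6, 68.4, 125.2, 182.0),
                        repetitionTime = 2600))

setValidity("EchoTrain", function(object) {
  te <- object@echoTimes
  msgs <- character()
  if (length(te) < 1L || anyNA(te))
    msgs <- c(msgs, "echoTimes must be a non-empty numeric vector without NA")
  else {
    if (any(te <= 0)) msgs <- c(msgs, "echoTimes must all be > 0")
    if (length(te) > 1L && any(diff(te) <= 0))
      msgs <- c(msgs, "echoTimes must be strictly increasing")
  }
  if (length(object@repetitionTime) != 1L || is.na(object@repetitionTime) ||
      object@repetitionTime <= 0)
    msgs <- c(msgs, "repetitionTime must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EchoTrain
#'
#' @param echoTimes strictly increasing echo times, milliseconds.
#' @param repetitionTime repetition time, milliseconds (default 2600, i.e.
#'   the reference protocol's TR = 2.6 s).
#' @return An [EchoTrain-class] object.
#' @examples
#' echoTrain()                      # reference 4-echo protocol
#' echoTrain(c(10, 110))            # minimal train for the log-linear oracle
#' @export
echoTrain <- function(echoTimes = c(11.6, 68.4, 125.2, 182.0),
                      repetitionTime = 2600) {
  new("EchoTrain", echoTimes = as.numeric(echoTimes),
      repetitionTime = as.numeric(repetitionTime))
}

#' @describeIn echoTrain Echo times in milliseconds.
#' @param x an object with an echo train.
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @describeIn echoTrain Number of echoes.
#' @export
setGeneric("nEchoes", function(x) standardGeneric("nEchoes"))

#' @describeIn echoTrain Repetition time in milliseconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

setMethod("echoTimes", "EchoTrain", function(x) x@echoTimes)
setMethod("nEchoes", "EchoTrain", function(x) length(x@echoTimes))
setMethod("repetitionTime", "EchoTrain", function(x) x@repetitionTime)

setMethod("show", "EchoTrain", function(object) {
  cat("EchoTrain:", length(object@echoTimes), "echoes at",
      paste(format(object@echoTimes), collapse = ", "), "ms; TR",
      format(object@repetitionTime), "ms\n")
})

# ---------------------------------------------------------------------------
# MultiEchoSeries
# ---------------------------------------------------------------------------

#' Multi-echo magnitude MRI series
#'
#' A 4-D (x, y, z, echo) or 5-D (x, y, z, echo, dynamic) non-negative
#' magnitude intensity grid with its echo-train metadata, voxel size and
#' voxel-to-world affine (RAS+). The 4th dimension always indexes echoes;
#' repeated dynamics, when acquired (1--2 in the reference protocol), occupy
#' a 5th dimension so the echo axis keeps a fixed position.
#'
#' @slot data numeric array, 4-D or 5-D, all values >= 0 (magnitude data).
#' @slot echoTrain an [EchoTrain-class].
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world matrix (RAS+, 0-based voxel indices).
#' @slot nDynamics integer >= 1.
#' @export
setClass("MultiEchoSeries",
  slots = c(data = "array", echoTrain = "EchoTrain", voxelSize = "numeric",
            affine = "matrix", nDynamics = "integer"))

setValidity("MultiEchoSeries", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (!(length(d) %in% c(4L, 5L)))
    msgs <- c(msgs, "data must be a 4-D or 5-D array")
  else {
    if (d[4] != length(object@echoTrain@echoTimes))
      msgs <- c(msgs, sprintf(
        "4th dimension (%d) must equal the number of echo times (%d)",
        d[4], length(object@echoTrain@echoTimes)))
    if (length(d) == 5L && d[5] != object@nDynamics)
      msgs <- c(msgs, "5th dimension must equal nDynamics")
    if (length(d) == 4L && object@nDynamics != 1L)
      msgs <- c(msgs, "4-D data implies nDynamics == 1")
  }
  if (anyNA(object@data) || min(object@data) < 0)
    msgs <- c(msgs, "magnitude intensities must be finite and >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive numbers (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be a 4x4 matrix")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultiEchoSeries
#'
#' @param data 4-D (x,y,z,echo) or 5-D (x,y,z,echo,dynamic) non-negative
#'   array of magnitude intensities, arbitrary units.
#' @param echoTrain an [EchoTrain-class]; its length must match `dim(data)[4]`.
#' @param voxelSize voxel edge lengths in mm (default 3 mm isotropic).
#' @param affine 4x4 voxel-to-world matrix; default: diagonal scaling by
#'   `voxelSize` (RAS+).
#' @return A [MultiEchoSeries-class].
#' @export
multiEchoSeries <- function(data, echoTrain = fetalT2star::echoTrain(),
                            voxelSize = c(3, 3, 3), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  nd <- if (length(dim(data)) == 5L) dim(data)[5] else 1L
  new("MultiEchoSeries", data = data, echoTrain = echoTrain,
      voxelSize = as.numeric(voxelSize), affine = affine,
      nDynamics = as.integer(nd))
}

#' @describeIn multiEchoSeries The intensity array (4-D or 5-D).
#' @param x a `MultiEchoSeries`.
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @describeIn multiEchoSeries Voxel size in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @describeIn multiEchoSeries Number of dynamics (repeats).
#' @export
setGeneric("nDynamics", function(x) standardGeneric("nDynamics"))

setMethod("seriesData", "MultiEchoSeries", function(x) x@data)
setMethod("voxelSize", "MultiEchoSeries", function(x) x@voxelSize)
setMethod("nDynamics", "MultiEchoSeries", function(x) x@nDynamics)
setMethod("echoTimes", "MultiEchoSeries", function(x) x@echoTrain@echoTimes)
setMethod("nEchoes", "MultiEchoSeries", function(x) length(x@echoTrain@echoTimes))
setMethod("repetitionTime", "MultiEchoSeries", function(x) x@echoTrain@repetitionTime)

#' @describeIn multiEchoSeries The [EchoTrain-class] metadata.
#' @export
setGeneric("getEchoTrain", function(x) standardGeneric("getEchoTrain"))
setMethod("getEchoTrain", "MultiEchoSeries", function(x) x@echoTrain)

setMethod("show", "MultiEchoSeries", function(object) {
  d <- dim(object@data)
  cat("MultiEchoSeries: ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " echoes, ", object@nDynamics, " dynamic(s)\n", sep = "")
  cat("  voxel size:", paste(format(object@voxelSize), collapse = " x "), "mm\n")
  cat("  echo times:", paste(format(object@echoTrain@echoTimes), collapse = ", "),
      "ms\n")
})

# ---------------------------------------------------------------------------
# BrainMask
# ---------------------------------------------------------------------------

#' Binary brain region-of-interest mask
#'
#' A boolean voxel grid marking the supratentorial ROI. Supports
#' morphological erosion (conservative segmentation margin) and CSF
#' thresholding via [erodeMask()] and [applyCsfThreshold()].
#'
#' @slot grid logical 3-D array.
#' @slot voxelSize numeric(3), mm.
#' @export
setClass("BrainMask",
  slots = c(grid = "array", voxelSize = "numeric"))

setValidity("BrainMask", function(object) {
  msgs <- character()
  if (length(dim(object@grid)) != 3L || !is.logical(object@grid))
    msgs <- c(msgs, "grid must be a logical 3-D array")
  if (anyNA(object@grid))
    msgs <- c(msgs, "grid must not contain NA")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be 3 positive numbers (mm)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BrainMask
#'
#' @param grid logical (or 0/1 numeric) 3-D array.
#' @param voxelSize voxel edge lengths in mm (default 3 mm isotropic).
#' @return A [BrainMask-class].
#' @export
brainMask <- function(grid, voxelSize = c(3, 3, 3)) {
  if (!is.logical(grid)) {
    g <- array(as.logical(grid > 0.5), dim = dim(grid))
    grid <- g
  }
  new("BrainMask", grid = grid, voxelSize = as.numeric(voxelSize))
}

#' @describeIn brainMask The logical voxel grid.
#' @param x a `BrainMask`.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
setMethod("maskArray", "BrainMask", function(x) x@grid)
setMethod("voxelSize", "BrainMask", function(x) x@voxelSize)

#' @describeIn brainMask Number of voxels inside the mask.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
setMethod("nVoxels", "BrainMask", function(x) sum(x@grid))

setMethod("show", "BrainMask", function(object) {
  cat("BrainMask: ", paste(dim(object@grid), collapse = " x "), " grid, ",
      sum(object@grid), " voxels in mask (",
      format(sum(object@grid) * prod(object@voxelSize) / 1000, digits = 4),
      " mL)\n", sep = "")
})

# ---------------------------------------------------------------------------
# FitConfig
# ---------------------------------------------------------------------------

#' Configuration of the multi-start voxel-wise T2* fitter
#'
#' @slot nInit integer, number of random initialisations per voxel
#'   (default 10; the per-voxel median over converged starts is reported).
#' @slot seed integer RNG seed; per-voxel substreams are derived from
#'   (seed, voxel index) so results are independent of voxel order.
#' @slot t2starBounds numeric(2), T2* box constraints in ms (default 1--800;
#'   the upper bound sits well above tissue and CSF so it acts as a
#'   non-physical flag, not a truncation).
#' @slot s0Bounds numeric(2), S0 start/bound range as multipliers of the
#'   per-voxel maximum signal (default 0.1--2.0).
#' @slot maxIterations integer, Levenberg-Marquardt iteration cap per start.
#' @slot tolerance relative convergence tolerance on the residual sum of
#'   squares.
#' @slot minSignal voxels whose first-echo signal is below this are skipped.
#' @export
setClass("FitConfig",
  slots = c(nInit = "integer", seed = "integer", t2starBounds = "numeric",
            s0Bounds = "numeric", maxIterations = "integer",
            tolerance = "numeric", minSignal = "numeric"))

setValidity("FitConfig", function(object) {
  msgs <- character()
  if (object@nInit < 1L) msgs <- c(msgs, "nInit must be >= 1")
  if (length(object@t2starBounds) != 2L ||
      object@t2starBounds[1] <= 0 ||
      object@t2starBounds[1] >= object@t2starBounds[2])
    msgs <- c(msgs, "t2starBounds must satisfy 0 < lower < upper")
  if (length(object@s0Bounds) != 2L || object@s0Bounds[1] < 0 ||
      object@s0Bounds[1] >= object@s0Bounds[2])
    msgs <- c(msgs, "s0Bounds must satisfy 0 <= lower < upper")
  if (object@maxIterations < 1L) msgs <- c(msgs, "maxIterations must be >= 1")
  if (object@tolerance <= 0) msgs <- c(msgs, "tolerance must be > 0")
  if (object@minSignal < 0) msgs <- c(msgs, "minSignal must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FitConfig
#'
#' @param nInit number of random starts per voxel (default 10).
#' @param seed RNG seed for the start distribution (default 1).
#' @param t2starBounds T2* box bounds, ms (default `c(1, 800)`).
#' @param s0Bounds S0 bounds as multipliers of the per-voxel max signal
#'   (default `c(0.1, 2)`).
#' @param maxIterations Levenberg-Marquardt iteration cap (default 200).
#' @param tolerance relative SSE convergence tolerance (default 1e-10).
#' @param minSignal first-echo signal floor below which voxels are skipped
#'   (default 0, i.e. only exact zeros are skipped).
#' @return A [FitConfig-class].
#' @export
fitConfig <- function(nInit = 10L, seed = 1L, t2starBounds = c(1, 800),
                      s0Bounds = c(0.1, 2), maxIterations = 200L,
                      tolerance = 1e-10, minSignal = 0) {
  new("FitConfig", nInit = as.integer(nInit), seed = as.integer(seed),
      t2starBounds = as.numeric(t2starBounds), s0Bounds = as.numeric(s0Bounds),
      maxIterations = as.integer(maxIterations),
      tolerance = as.numeric(tolerance), minSignal = as.numeric(minSignal))
}

setMethod("show", "FitConfig", function(object) {
  cat("FitConfig: ", object@nInit, " starts, T2* bounds [",
      paste(format(object@t2starBounds), collapse = ", "), "] ms, seed ",
      object@seed, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# T2StarMap
# ---------------------------------------------------------------------------

#' Voxel-wise T2* and S0 maps with fit diagnostics
#'
#' The product of [fitMap()]: per-voxel T2* (ms) and S0 (proton-density
#' proxy, arbitrary units) estimates, a convergence flag, residual RMS, the
#' number of converged starts, and the provenance (fit configuration and
#' echo train) of the fit. Voxels that were outside the mask, below the
#' signal floor, or where no start converged carry `NA` estimates and
#' `fitOk = FALSE`.
#'
#' @slot t2star numeric 3-D array, ms; `NA` where not fit.
#' @slot s0 numeric 3-D array, a.u.; `NA` where not fit.
#' @slot fitOk logical 3-D array.
#' @slot residualRms numeric 3-D array, a.u.
#' @slot nConverged integer 3-D array, converged starts out of `nInit`.
#' @slot atBound logical 3-D array; TRUE where the T2* estimate is pinned at
#'   a box bound (non-physical fit, e.g. non-decaying signal).
#' @slot voxelSize numeric(3), mm.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot provenance list recording the [FitConfig-class] values and echo
#'   times actually used.
#' @export
setClass("T2StarMap",
  slots = c(t2star = "array", s0 = "array", fitOk = "array",
            residualRms = "array", nConverged = "array", atBound = "array",
            voxelSize = "numeric", affine = "matrix", provenance = "list"))

setValidity("T2StarMap", function(object) {
  msgs <- character()
  d <- dim(object@t2star)
  same <- function(a) identical(dim(a), d)
  if (length(d) != 3L) msgs <- c(msgs, "maps must be 3-D arrays")
  if (!same(object@s0) || !same(object@fitOk) || !same(object@residualRms) ||
      !same(object@nConverged) || !same(object@atBound))
    msgs <- c(msgs, "all per-voxel arrays must share the same 3-D shape")
  ok <- object@fitOk & !is.na(object@fitOk)
  if (any(is.na(object@t2star[ok])) || any(is.na(object@s0[ok])))
    msgs <- c(msgs, "fitOk voxels must carry non-missing t2star and s0")
  if (any(!is.na(object@t2star[!ok])) || any(!is.na(object@s0[!ok])))
    msgs <- c(msgs, "non-fitOk voxels must carry NA t2star and s0")
  if (any(object@s0[ok] < 0)) msgs <- c(msgs, "s0 must be >= 0 where fitOk")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn fitMap T2* array (ms) of a `T2StarMap`.
#' @param x a `T2StarMap`.
#' @export
setGeneric("t2star", function(x) standardGeneric("t2star"))
setMethod("t2star", "T2StarMap", function(x) x@t2star)

#' @describeIn fitMap S0 (proton-density proxy) array of a `T2StarMap`.
#' @export
setGeneric("s0map", function(x) standardGeneric("s0map"))
setMethod("s0map", "T2StarMap", function(x) x@s0)

#' @describeIn fitMap Logical array of per-voxel fit success.
#' @export
setGeneric("fitOk", function(x) standardGeneric("fitOk"))
setMethod("fitOk", "T2StarMap", function(x) x@fitOk)

#' @describeIn fitMap Per-voxel residual root-mean-square.
#' @export
setGeneric("residualRms", function(x) standardGeneric("residualRms"))
setMethod("residualRms", "T2StarMap", function(x) x@residualRms)

#' @describeIn fitMap Per-voxel count of converged starts.
#' @export
setGeneric("nConverged", function(x) standardGeneric("nConverged"))
setMethod("nConverged", "T2StarMap", function(x) x@nConverged)

#' @describeIn fitMap Logical array: T2* pinned at a box bound.
#' @export
setGeneric("atBound", function(x) standardGeneric("atBound"))
setMethod("atBound", "T2StarMap", function(x) x@atBound)

setMethod("voxelSize", "T2StarMap", function(x) x@voxelSize)

setMethod("show", "T2StarMap", function(object) {
  ok <- object@fitOk
  cat("T2StarMap: ", paste(dim(object@t2star), collapse = " x "), " grid, ",
      sum(ok), " fitted voxels\n", sep = "")
  if (any(ok)) {
    v <- object@t2star[ok]
    cat("  T2* range: ", format(min(v), digits = 4), " - ",
        format(max(v), digits = 4), " ms (median ",
        format(stats::median(v), digits = 4), ")\n", sep = "")
  }
})
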