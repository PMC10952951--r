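# Per-subject ROI summarisation: conservative margin (morphological
# erosion), CSF exclusion by thresholding the fitted T2* values, then mean
# T2*, histogram skewness and supratentorial volume.

# one 6-connected erosion pass via array shifts; borders erode
.erodeOnce <- function(g) {
  d <- dim(g)
  out <- g
  pad <- function(a, axis, dir) {
    idx <- lapply(d, seq_len)
    src <- idx
    if (dir > 0) { idx[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else         { idx[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    shifted <- array(FALSE, d)
    shifted[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    shifted
  }
  for (axis in 1:3) {
    out <- out & pad(g, axis, +1) & pad(g, axis, -1)
  }
  out
}

#' Erode a brain mask by a conservative margin
#'
#' Morphological erosion with a 6-connected structuring element, applied
#' `margin` times. This operationalises the conservative segmentation
#' margin used to keep non-cerebral tissue out of the ROI. Voxels on the
#' grid boundary are always eroded.
#'
#' @param mask a [BrainMask-class].
#' @param margin non-negative integer number of one-voxel erosion passes
#'   (default 1). `margin = 0` returns the mask unchanged.
#' @return An eroded [BrainMask-class], always a subset of the input.
#' @export
erodeMask <- function(mask, margin = 1L) {
  validObject(mask)
  if (margin < 0) stop("margin must be >= 0")
  g <- mask@grid
  for (k in seq_len(margin)) g <- .erodeOnce(g)
  if (!any(g))
    stop("erosion with margin ", margin, " emptied the mask")
  brainMask(g, mask@voxelSize)
}

#' Exclude CSF from an ROI by thresholding fitted T2*
#'
#' Returns the voxels of `mask` whose fitted T2* is at most `cutoff` ms and
#' whose fit succeeded. CSF has much longer T2* than brain tissue, so a
#' cutoff between the two removes all cerebrospinal fluid from the ROI;
#' failed-fit voxels are excluded along the way.
#'
#' @param map a [T2StarMap-class].
#' @param mask a [BrainMask-class] matching the map's shape.
#' @param cutoff T2* cutoff in ms (default 250, between typical tissue and
#'   CSF values).
#' @return A [BrainMask-class], a subset of `mask`.
#' @export
applyCsfThreshold <- function(map, mask, cutoff = 250) {
  validObject(map); validObject(mask)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!identical(dim(map@t2star), dim(mask@grid)))
    stop("map and mask shapes differ")
  keep <- mask@grid & map@fitOk & !is.na(map@t2star) & map@t2star <= cutoff
  if (!any(keep))
    stop("CSF threshold at ", cutoff, " ms left no voxels in the ROI")
  brainMask(keep, mask@voxelSize)
}

#' Sample skewness of a numeric vector
#'
#' Adjusted Fisher-Pearson standardised third moment
#' \eqn{G_1 = \frac{\sqrt{n(n-1)}}{n-2} \, m_3 / m_2^{3/2}} (default), or
#' the unadjusted \eqn{g_1 = m_3 / m_2^{3/2}}, where \eqn{m_k} are central
#' sample moments with denominator \eqn{n}.
#'
#' @param x numeric vector, length >= 3.
#' @param type `"G1"` (sample-size-adjusted, default) or `"g1"`.
#' @return The skewness; `NA` with a warning when the values have zero
#'   variance.
#' @examples
#' sampleSkewness(c(1, 1, 1, 5))   # exactly 2
#' @export
sampleSkewness <- function(x, type = c("G1", "g1")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero variance: skewness undefined")
    return(NA_real_)
  }
  g1 <- mean((x - m)^3) / m2^1.5
  if (type == "g1") g1 else sqrt(n * (n - 1)) / (n - 2) * g1
}

#' Summarise a T2* map over an ROI
#'
#' Computes the per-subject summary measures: arithmetic mean of the
#' in-mask fitted T2* values, histogram skewness of the same values
#' (computed on the raw voxel values, not binned counts), and ROI volume
#' (voxel count times voxel volume, in mL). Voxels whose fit failed are
#' excluded and counted in `n_excluded_fit`.
#'
#' @param map a [T2StarMap-class].
#' @param mask a [BrainMask-class]; typically the output of [erodeMask()]
#'   then [applyCsfThreshold()].
#' @param subjectId subject identifier carried into the row.
#' @param gaMri gestational age at MRI, weeks.
#' @param skewnessType `"G1"` (default) or `"g1"`, see [sampleSkewness()].
#' @param nExcludedCsf optionally, the number of voxels removed by the CSF
#'   threshold (carried through for bookkeeping).
#' @return A one-row data.frame: `subject_id`, `ga_mri`, `mean_t2star`
#'   (ms), `skewness`, `volume` (mL), `n_voxels`, `n_excluded_csf`,
#'   `n_excluded_fit`.
#' @export
summarizeROI <- function(map, mask, subjectId = NA_character_,
                         gaMri = NA_real_, skewnessType = c("G1", "g1"),
                         nExcludedCsf = NA_integer_) {
  skewnessType <- match.arg(skewnessType)
  validObject(map); validObject(mask)
  if (!identical(dim(map@t2star), dim(mask@grid)))
    stop("map and mask shapes differ")
  inMask <- mask@grid
  okVox <- inMask & map@fitOk
  nExclFit <- sum(inMask) - sum(okVox)
  vals <- map@t2star[okVox]
  n <- length(vals)
  if (n < 1L) stop("ROI is empty after exclusions")
  if (n < 3L) stop("need at least 3 voxels for summarisation")
  vol <- n * prod(mask@voxelSize) / 1000
  data.frame(subject_id = subjectId, ga_mri = gaMri,
             mean_t2star = mean(vals),
             skewness = sampleSkewness(vals, skewnessType),
             volume = vol, n_voxels = n,
             n_excluded_csf = as.integer(nExcludedCsf),
             n_excluded_fit = as.integer(nExclFit))
}
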