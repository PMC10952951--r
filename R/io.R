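# NIfTI-1 + BIDS-style JSON sidecar IO and cohort CSV IO.
# Canonical internal units: milliseconds (sidecars store seconds).

.msPerSecond <- 1000

# strip RNifti class/attributes down to a plain numeric array
.plainArray <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim = dim(a))
}

.cohortColumns <- c("subject_id", "group", "ga_mri", "ga_delivery",
                    "maternal_age", "bmi", "ethnicity", "parity", "liveborn",
                    "live_to_discharge", "rds", "ivh_grade34", "bpd", "nec",
                    "histology_available", "chorioamnionitis", "funisitis")

.ethnicityLevels <- c("White", "Mixed", "Asian", "Black", "Other")
.groupLevels <- c("preterm", "control")
.flagColumns <- c("liveborn", "live_to_discharge", "rds", "ivh_grade34",
                  "bpd", "nec", "histology_available", "chorioamnionitis",
                  "funisitis")

.asNiftiImage <- function(arr, voxelSize, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`pixdim<-`(img, c(voxelSize, rep(1, length(dim(arr)) - 3L))) -> img
  img
}

#' Read a multi-echo series from NIfTI + JSON sidecar
#'
#' Reads a 4-D (or 5-D, with dynamics) magnitude NIfTI-1 volume together
#' with a BIDS-style JSON sidecar carrying `EchoTime` (seconds, one per
#' echo) and `RepetitionTime` (seconds). Echo times are converted to
#' milliseconds, the canonical internal unit, exactly once.
#'
#' @param imagePath path to a `.nii`/`.nii.gz` file with >= 4 dimensions.
#' @param sidecarPath path to the JSON sidecar.
#' @return A validated [MultiEchoSeries-class].
#' @seealso [writeMultiEcho()]
#' @export
readMultiEcho <- function(imagePath, sidecarPath) {
  img <- RNifti::readNifti(imagePath)
  arr <- .plainArray(img)
  d <- dim(arr)
  if (length(d) < 4L)
    stop("multi-echo image must have >= 4 dimensions, got ", length(d))
  if (length(d) > 5L)
    stop("multi-echo image must have at most 5 dimensions (x,y,z,echo,dynamic)")
  if (!file.exists(sidecarPath)) stop("sidecar not found: ", sidecarPath)
  meta <- jsonlite::fromJSON(sidecarPath)
  if (is.null(meta$EchoTime))
    stop("sidecar is missing the EchoTime field (format error)")
  teMs <- as.numeric(meta$EchoTime) * .msPerSecond
  if (length(teMs) != d[4])
    stop(sprintf(paste0("metadata mismatch: sidecar lists %d echo times but ",
                        "the image has %d echo volumes"),
         length(teMs), d[4]))
  trMs <- if (!is.null(meta$RepetitionTime))
    as.numeric(meta$RepetitionTime) * .msPerSecond else 2600
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vs <- RNifti::pixdim(img)[1:3]
  multiEchoSeries(arr, echoTrain(teMs, trMs), voxelSize = vs, affine = aff)
}

#' Write a multi-echo series as NIfTI + JSON sidecar
#'
#' Intensities are stored as 32-bit float; echo times are written to the
#' sidecar in seconds per the BIDS convention. The pair is losslessly
#' re-readable by [readMultiEcho()] at stored precision.
#'
#' @param series a [MultiEchoSeries-class].
#' @param imagePath output `.nii`/`.nii.gz` path.
#' @param sidecarPath output JSON path.
#' @return Invisibly, `c(imagePath, sidecarPath)`.
#' @export
writeMultiEcho <- function(series, imagePath, sidecarPath) {
  validObject(series)
  arr <- series@data
  # stored precision is float32: round now so the written file equals the
  # object a subsequent readMultiEcho returns
  img <- .asNiftiImage(arr, series@voxelSize, series@affine)
  RNifti::writeNifti(img, imagePath, datatype = "float")
  sidecar <- list(
    EchoTime = echoTimes(series) / .msPerSecond,
    RepetitionTime = repetitionTime(series) / .msPerSecond)
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = FALSE, digits = NA)
  invisible(c(imagePath, sidecarPath))
}

#' Read / write a binary brain mask
#'
#' Masks are stored as uint8 NIfTI-1 volumes; any value > 0.5 is inside.
#'
#' @param path a `.nii`/`.nii.gz` file.
#' @return [readBrainMask()]: a [BrainMask-class].
#' @export
readBrainMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- .plainArray(img)
  if (length(dim(arr)) != 3L) stop("mask must be a 3-D volume")
  brainMask(arr > 0.5, voxelSize = RNifti::pixdim(img)[1:3])
}

#' @rdname readBrainMask
#' @param mask a [BrainMask-class].
#' @param affine optional 4x4 voxel-to-world matrix (default: diagonal).
#' @export
writeBrainMask <- function(mask, path, affine = NULL) {
  validObject(mask)
  if (is.null(affine)) affine <- diag(c(mask@voxelSize, 1))
  img <- .asNiftiImage(mask@grid + 0, mask@voxelSize, affine)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write / read a fitted T2* map set
#'
#' [writeT2StarMap()] writes `<prefix>_t2star.nii.gz`, `<prefix>_s0.nii.gz`,
#' `<prefix>_fit_ok.nii.gz` (all maps 32-bit float, T2* in ms) and a
#' `<prefix>_provenance.json` recording the fit configuration actually used.
#' `NA` estimates are stored as 0 with `fit_ok` 0.
#'
#' @param map a [T2StarMap-class].
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeT2StarMap <- function(map, prefix) {
  validObject(map)
  z <- function(a) { a[is.na(a)] <- 0; a }
  paths <- c(t2star = paste0(prefix, "_t2star.nii.gz"),
             s0 = paste0(prefix, "_s0.nii.gz"),
             fit_ok = paste0(prefix, "_fit_ok.nii.gz"),
             provenance = paste0(prefix, "_provenance.json"))
  RNifti::writeNifti(.asNiftiImage(z(map@t2star), map@voxelSize, map@affine),
                     paths["t2star"], datatype = "float")
  RNifti::writeNifti(.asNiftiImage(z(map@s0), map@voxelSize, map@affine),
                     paths["s0"], datatype = "float")
  RNifti::writeNifti(.asNiftiImage(map@fitOk + 0, map@voxelSize, map@affine),
                     paths["fit_ok"], datatype = "uint8")
  jsonlite::write_json(map@provenance, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @rdname writeT2StarMap
#' @export
readT2StarMap <- function(prefix) {
  rd <- function(sfx) RNifti::readNifti(paste0(prefix, sfx))
  t2img <- rd("_t2star.nii.gz")
  t2 <- .plainArray(t2img)
  s0 <- .plainArray(rd("_s0.nii.gz"))
  ok <- .plainArray(rd("_fit_ok.nii.gz")) > 0.5
  t2[!ok] <- NA_real_
  s0[!ok] <- NA_real_
  prov <- jsonlite::fromJSON(paste0(prefix, "_provenance.json"))
  aff <- unclass(RNifti::xform(t2img))
  attributes(aff) <- list(dim = dim(aff))
  d <- dim(t2)
  new("T2StarMap", t2star = t2, s0 = s0, fitOk = ok,
      residualRms = array(NA_real_, d),
      nConverged = array(NA_integer_, d),
      atBound = array(FALSE, d),
      voxelSize = RNifti::pixdim(t2img)[1:3], affine = aff,
      provenance = as.list(prov))
}

# ---------------------------------------------------------------------------
# Cohort tables
# ---------------------------------------------------------------------------

#' Validate a cohort table
#'
#' Checks the per-subject cohort table against its contract: known columns,
#' `group` in \{preterm, control\}, gestational age at MRI within the 18--32
#' week inclusion window, ethnicity among the declared levels, 0/1 flags,
#' and the histology implication chain
#' funisitis => chorioamnionitis => histology_available.
#'
#' @param table a data.frame with the cohort CSV columns.
#' @return The table, invisibly, with typed columns; stops with a message
#'   listing every offending row otherwise.
#' @export
validateCohortTable <- function(table) {
  missing <- setdiff(.cohortColumns, names(table))
  if (length(missing))
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  errs <- character()
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      errs <<- c(errs, sprintf("%s (rows %s)", what,
                               paste(idx, collapse = ", ")))
  }
  bad(!(table$group %in% .groupLevels),
      "group must be 'preterm' or 'control'")
  bad(!is.na(table$ga_mri) & (table$ga_mri < 18 | table$ga_mri > 32),
      "ga_mri outside the 18-32 week inclusion window")
  bad(!is.na(table$ethnicity) & !(table$ethnicity %in% .ethnicityLevels),
      paste0("unknown ethnicity level (expected ",
             paste(.ethnicityLevels, collapse = "/"), ")"))
  for (fc in .flagColumns)
    bad(!is.na(table[[fc]]) & !(table[[fc]] %in% c(0, 1)),
        sprintf("%s must be 0/1", fc))
  f1 <- function(x) !is.na(x) & x == 1
  f0 <- function(x) is.na(x) | x != 1
  bad(f1(table$funisitis) & f0(table$chorioamnionitis),
      "funisitis without chorioamnionitis")
  bad(f1(table$chorioamnionitis) & f0(table$histology_available),
      "chorioamnionitis without histology_available")
  if (length(errs))
    stop("cohort table validation failed:\n  ",
         paste(errs, collapse = "\n  "))
  table$group <- factor(table$group, levels = .groupLevels)
  table$ethnicity <- factor(table$ethnicity, levels = .ethnicityLevels)
  invisible(table)
}

#' Read a cohort CSV
#'
#' Expects the documented header
#' `subject_id,group,ga_mri,ga_delivery,maternal_age,bmi,ethnicity,parity,`
#' `liveborn,live_to_discharge,rds,ivh_grade34,bpd,nec,histology_available,`
#' `chorioamnionitis,funisitis` with missing values as empty fields and
#' flags coded 0/1. The table is validated by [validateCohortTable()].
#'
#' @param csvPath path to the CSV.
#' @return A typed, validated data.frame (`group` and `ethnicity` as
#'   factors with their declared levels).
#' @export
readCohortTable <- function(csvPath) {
  tab <- utils::read.csv(csvPath, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  tab <- validateCohortTable(tab)
  tab
}

#' @rdname readCohortTable
#' @param table a cohort data.frame.
#' @export
writeCohortTable <- function(table, csvPath) {
  validateCohortTable(table)
  out <- table
  out$group <- as.character(out$group)
  out$ethnicity <- as.character(out$ethnicity)
  utils::write.csv(out, csvPath, row.names = FALSE, na = "")
  invisible(csvPath)
}
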