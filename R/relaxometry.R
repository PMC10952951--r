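# Voxel-wise mono-exponential T2* estimation: bounded Levenberg-Marquardt
# least squares in linear signal space, repeated from random starts, with
# the per-voxel median over converged starts reported (T2* and S0
# medianed independently). Log-space fitting is avoided for estimation --
# it distorts the Rician noise weighting -- and kept only as the
# closed-form oracle loglinearFit().

#' Fit the mono-exponential decay model in a single voxel
#'
#' Runs bounded nonlinear least squares on \eqn{S(TE) = S_0 e^{-TE/T_2^*}}
#' from `nInit` random starts (T2* start uniform within `t2starBounds`, S0
#' start uniform within `s0Bounds` times the voxel's maximum signal) and
#' returns the median of the converged T2* estimates and, independently,
#' the median of the converged S0 estimates. Start positions come from a
#' per-voxel RNG substream derived from `(seed, voxelIndex)`, so results do
#' not depend on the order in which voxels are processed.
#'
#' @param signal numeric vector of per-echo magnitude intensities (>= 0),
#'   one per echo.
#' @param echoTrain an [EchoTrain-class] (or numeric echo times, ms) with at
#'   least 3 echoes.
#' @param config a [FitConfig-class].
#' @param voxelIndex 0-based linear voxel index selecting the RNG substream
#'   (default 0).
#' @return A list with `s0`, `t2star` (ms), `fitOk`, `nConverged`,
#'   `residualRms`, `atBound`.
#' @examples
#' te <- echoTrain()
#' sig <- signalModel(100, 100, echoTimes(te))
#' fitVoxel(sig, te)          # recovers S0 = 100, T2* = 100 ms
#' @export
fitVoxel <- function(signal, echoTrain, config = fitConfig(),
                     voxelIndex = 0) {
  te <- if (is(echoTrain, "EchoTrain")) echoTimes(echoTrain)
        else as.numeric(echoTrain)
  if (length(te) < 3L)
    stop("mono-exponential fitting needs at least 3 echoes (configuration error)")
  if (length(signal) != length(te))
    stop("signal length must equal the number of echoes")
  if (anyNA(signal) || any(signal < 0))
    stop("signal must be non-negative magnitude data")
  validObject(config)
  res <- .fitVoxelsCpp(matrix(signal, nrow = 1L), te,
                       as.numeric(voxelIndex), config@nInit,
                       as.numeric(config@seed),
                       config@t2starBounds[1], config@t2starBounds[2],
                       config@s0Bounds[1], config@s0Bounds[2],
                       config@maxIterations, config@tolerance)
  list(s0 = res[1, 2], t2star = res[1, 1], fitOk = res[1, 6] > 0,
       nConverged = as.integer(res[1, 3]), residualRms = res[1, 4],
       atBound = res[1, 5] > 0)
}

#' @rdname fitVoxel
#' @details `fitVoxelStarts()` exposes the individual multi-start outcomes
#'   (one row per initialisation: `s0`, `t2star`, `converged`, `sse`) that
#'   the reported voxel medians are taken over.
#' @export
fitVoxelStarts <- function(signal, echoTrain, config = fitConfig(),
                           voxelIndex = 0) {
  te <- if (is(echoTrain, "EchoTrain")) echoTimes(echoTrain)
        else as.numeric(echoTrain)
  validObject(config)
  m <- .fitVoxelStartsCpp(as.numeric(signal), te, as.numeric(voxelIndex),
                          config@nInit, as.numeric(config@seed),
                          config@t2starBounds[1], config@t2starBounds[2],
                          config@s0Bounds[1], config@s0Bounds[2],
                          config@maxIterations, config@tolerance)
  colnames(m) <- c("s0", "t2star", "converged", "sse")
  as.data.frame(m)
}

#' Fit voxel-wise T2* and S0 maps over a masked volume
#'
#' Applies [fitVoxel()] to every in-mask voxel whose first-echo signal is at
#' least `config@minSignal`. When the series carries repeated dynamics they
#' are magnitude-averaged before fitting (SNR gain; per-dynamic maps are not
#' produced). Out-of-mask and skipped voxels are `NA` with `fitOk = FALSE`.
#' For a fixed seed the result is identical on re-run and independent of
#' mask shape or voxel ordering.
#'
#' @param series a [MultiEchoSeries-class] with >= 3 echoes.
#' @param mask a [BrainMask-class] matching the series' spatial shape.
#' @param config a [FitConfig-class].
#' @return A [T2StarMap-class] with per-voxel estimates, diagnostics and
#'   provenance.
#' @export
fitMap <- function(series, mask, config = fitConfig()) {
  validObject(series); validObject(mask); validObject(config)
  d <- dim(series@data)
  if (!identical(dim(mask@grid), d[1:3]))
    stop("mask shape ", paste(dim(mask@grid), collapse = "x"),
         " does not match series spatial shape ",
         paste(d[1:3], collapse = "x"))
  if (d[4] < 3L)
    stop("mono-exponential fitting needs at least 3 echoes (configuration error)")
  arr <- series@data
  if (length(d) == 5L)                       # magnitude-average dynamics
    arr <- apply(arr, 1:4, mean)
  nspat <- prod(d[1:3])
  sigmat <- matrix(arr, nrow = nspat, ncol = d[4])
  inMask <- which(as.vector(mask@grid))
  firstEcho <- sigmat[inMask, 1L]
  fit <- inMask[firstEcho >= config@minSignal & firstEcho > 0]

  t2 <- array(NA_real_, d[1:3]); s0 <- array(NA_real_, d[1:3])
  ok <- array(FALSE, d[1:3]); rms <- array(NA_real_, d[1:3])
  ncv <- array(0L, d[1:3]); atb <- array(FALSE, d[1:3])
  if (length(fit)) {
    res <- .fitVoxelsCpp(sigmat[fit, , drop = FALSE], echoTimes(series),
                         as.numeric(fit - 1L), config@nInit,
                         as.numeric(config@seed),
                         config@t2starBounds[1], config@t2starBounds[2],
                         config@s0Bounds[1], config@s0Bounds[2],
                         config@maxIterations, config@tolerance)
    good <- res[, 6] > 0
    t2[fit] <- ifelse(good, res[, 1], NA_real_)
    s0[fit] <- ifelse(good, res[, 2], NA_real_)
    ok[fit] <- good
    rms[fit] <- res[, 4]
    ncv[fit] <- as.integer(res[, 3])
    atb[fit] <- res[, 5] > 0
  }
  prov <- list(model = "mono-exponential S(TE) = S0 * exp(-TE/T2*)",
               optimiser = "bounded Levenberg-Marquardt, linear signal space",
               n_init = config@nInit, seed = config@seed,
               t2star_bounds_ms = config@t2starBounds,
               s0_bounds_mult = config@s0Bounds,
               max_iterations = config@maxIterations,
               tolerance = config@tolerance, min_signal = config@minSignal,
               echo_times_ms = echoTimes(series),
               n_dynamics_averaged = series@nDynamics,
               median_rule = "median over converged starts, T2* and S0 independently")
  new("T2StarMap", t2star = t2, s0 = s0, fitOk = ok, residualRms = rms,
      nConverged = ncv, atBound = atb, voxelSize = series@voxelSize,
      affine = series@affine, provenance = prov)
}

#' Closed-form log-linear estimate of (S0, T2*)
#'
#' Ordinary least squares of \eqn{\ln S} on TE; the slope is \eqn{-1/T_2^*}
#' and the intercept \eqn{\ln S_0}. Exact on noiseless data, so it serves
#' as the independent oracle (and a cheap initialiser) for the nonlinear
#' fitter; it is not used for estimation on noisy data because the log
#' transform distorts the noise weighting.
#'
#' @param signal numeric vector of per-echo intensities, all > 0.
#' @param echoTrain an [EchoTrain-class] or numeric echo times (ms); >= 2
#'   echoes.
#' @return A list with `s0` and `t2star` (ms). A non-decaying (flat or
#'   rising) signal yields a non-positive slope and `t2star = Inf` or
#'   negative; callers decide how to treat it.
#' @examples
#' loglinearFit(c(90, 45), c(10, 110))   # T2* = 100/log(2) ~ 144.27 ms
#' @export
loglinearFit <- function(signal, echoTrain) {
  te <- if (is(echoTrain, "EchoTrain")) echoTimes(echoTrain)
        else as.numeric(echoTrain)
  if (length(signal) != length(te))
    stop("signal length must equal the number of echoes")
  if (length(te) < 2L) stop("need at least 2 echoes")
  if (anyNA(signal) || any(signal <= 0))
    stop("log-linear fit requires strictly positive signal")
  fit <- stats::lm.fit(cbind(1, te), log(signal))
  b <- fit$coefficients
  list(s0 = exp(b[[1]]), t2star = -1 / b[[2]])
}
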