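#' @include AllClasses.R
NULL

#' Number of frames in a trajectory
#' @param x a [Trajectory-class].
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of particles in a trajectory
#' @param x a [Trajectory-class].
#' @return integer.
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Frame times \[ps\]
#' @param x a [Trajectory-class].
#' @return numeric vector.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Position array `[nFrames, nParticles, 3]` \[nm\]
#' @param x a [Trajectory-class].
#' @return numeric array.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-frame box edge lengths \[nm\]
#' @param x a [Trajectory-class].
#' @return `[nFrames, 3]` matrix.
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Has the trajectory been laterally unwrapped?
#' @param x a [Trajectory-class].
#' @return logical.
#' @export
setGeneric("isLateralUnwrapped",
           function(x) standardGeneric("isLateralUnwrapped"))

#' Remove periodic jumps from the lateral coordinates
#'
#' @param traj a [Trajectory-class].
#' @param geom a [SlitGeometry-class]; the normal-axis coordinates are left
#'   untouched.
#' @return an unwrapped [Trajectory-class].
#' @export
setGeneric("unwrapLateral",
           function(traj, geom = slitGeometry()) {
             standardGeneric("unwrapLateral")
           })

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nParticles", "Trajectory", function(x) dim(x@coords)[2])
setMethod("frameTimes", "Trajectory", function(x) x@times)
setMethod("coords", "Trajectory", function(x) x@coords)
setMethod("boxDims", "Trajectory", function(x) x@box)
setMethod("isLateralUnwrapped", "Trajectory", function(x) x@lateralUnwrapped)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d particles\n",
              nFrames(object), nParticles(object)))
  cat(sprintf("  time: %.4g .. %.4g ps  (dt = %.4g ps)\n",
              object@times[1], object@times[length(object@times)],
              if (length(object@times) > 1) diff(object@times)[1] else NA))
  cat(sprintf("  box[1]: %.3f x %.3f x %.3f nm, lateral unwrapped: %s\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3],
              object@lateralUnwrapped))
})

setMethod("show", "SlitGeometry", function(object) {
  cat(sprintf("SlitGeometry: normal = %s, chain = %s, arrangement = %s\n",
              object@normalAxis, object@chainAxis, object@arrangement))
  cat(sprintf("  walls: [%s, %s] nm, labels: %s | %s\n",
              format(object@wallLo), format(object@wallHi),
              object@wallLabels[1], object@wallLabels[2]))
})

setMethod("show", "MSDResult", function(object) {
  cat(sprintf("MSDResult: %d lags (0 .. %.4g ps)\n",
              length(object@lags), max(object@lags)))
  cat(sprintf("  msd at max lag [nm^2]: x %.4g, y %.4g, z %.4g\n",
              object@msd[nrow(object@msd), 1],
              object@msd[nrow(object@msd), 2],
              object@msd[nrow(object@msd), 3]))
})

setMethod("show", "EinsteinFit", function(object) {
  cat("Einstein fit of parallel diffusion\n")
  cat(sprintf("  D_par,%s = %.4g nm^2/ps (%.3g m^2/s), se %.2g\n",
              names(object@dPar), object@dPar,
              object@dPar * .NM2PS_TO_M2S, object@dParSE))
  cat(sprintf("  composite D_par = %.4g nm^2/ps (%.3g m^2/s)%s\n",
              object@composite, object@composite * .NM2PS_TO_M2S,
              if (object@discrepant) "  [components discrepant]" else ""))
})

setMethod("show", "ConfinementFit", function(object) {
  cat("Restricted-diffusion fit (reflecting walls)\n")
  cat(sprintf("  L      = %.4g +/- %.2g nm\n", object@L, object@LSE))
  cat(sprintf("  D_perp = %.4g +/- %.2g nm^2/ps (%.3g m^2/s)\n",
              object@Dperp, object@DperpSE,
              object@Dperp * .NM2PS_TO_M2S))
  cat(sprintf("  corr(L, D_perp) = %.3f, converged: %s%s\n",
              object@corrLD, object@converged,
              if (object@noPlateau) "  [no plateau reached]" else ""))
})

setMethod("show", "RACFResult", function(object) {
  cat(sprintf("RACFResult: %d lags (0 .. %.4g ps), %d bonds\n",
              length(object@lags), max(object@lags), object@nBonds))
})

setMethod("show", "StretchedExpFit", function(object) {
  cat("Stretched-exponential fit: C(t) = S^2 + (1-S^2) exp(-(t/tau)^beta)\n")
  cat(sprintf("  tau = %.4g ps, beta = %.3f, S = %.3f\n",
              object@tau, object@beta, object@S))
  cat(sprintf("  plateau sampled: %s\n", object@plateauSampled))
})

setMethod("show", "AngleDistribution", function(object) {
  cat(sprintf("AngleDistribution (%s): %d bins, pooled mean = %.4g\n",
              object@angle, length(object@density), object@means[["pooled"]]))
})

setMethod("show", "DensityProfile", function(object) {
  unit <- if (object@kind == "mass") "kg/m^3" else "nm^-3"
  cat(sprintf("DensityProfile (%s): %d bins of %.3g nm, peak %.4g %s\n",
              object@kind, length(object@density), object@binWidth,
              max(object@density), unit))
})

#' @export
#' @describeIn MSDResult-class coerce to a data frame with columns
#'   `lag_ps`, `msd_x_nm2`, `msd_y_nm2`, `msd_z_nm2`, `n_origins`.
#' @param x object to coerce.
#' @param row.names,optional,... passed on (unused).
as.data.frame.MSDResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(lag_ps = x@lags, msd_x_nm2 = x@msd[, 1],
             msd_y_nm2 = x@msd[, 2], msd_z_nm2 = x@msd[, 3],
             n_origins = x@nOrigins)
}

#' @export
#' @describeIn RACFResult-class coerce to a data frame with columns
#'   `lag_ps`, `C`, `n_origins`.
#' @param x object to coerce.
#' @param row.names,optional,... passed on (unused).
as.data.frame.RACFResult <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(lag_ps = x@lags, C = x@acf, n_origins = x@nOrigins)
}
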