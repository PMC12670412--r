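#' @import methods
NULL

.AXES <- c("x", "y", "z")
.WALL_LABELS <- c("hydrophilic-110", "hydrophilic-1m10", "hydrophobic-100",
                  "synthetic")

## conversion: 1 nm^2/ps = 1e-6 m^2/s
.NM2PS_TO_M2S <- 1e-6
## 1 amu/nm^3 = 1.66053907 kg/m^3
.AMU_NM3_TO_KG_M3 <- 1.66053907
.MASS_O <- 15.9994
.MASS_H <- 1.008
.MASS_WATER <- .MASS_O + 2 * .MASS_H

#' Trajectory of particle positions in a periodic box
#'
#' Time-stamped particle positions with per-frame box dimensions. Internal
#' units are nm for lengths and ps for times throughout the package. The
#' lateral (in-plane) coordinates follow the half-open wrapping convention
#' `[0, box)` until [unwrapLateral()] has been applied, which is tracked by
#' the `lateralUnwrapped` flag.
#'
#' @slot times numeric, strictly increasing frame times \[ps\].
#' @slot coords numeric array `[nFrames, nParticles, 3]`, positions \[nm\].
#' @slot box numeric matrix `[nFrames, 3]`, box edge lengths \[nm\].
#' @slot lateralUnwrapped logical flag; `TRUE` once periodic jumps in the
#'   lateral coordinates have been removed.
#' @export
setClass("Trajectory",
  representation(times = "numeric", coords = "array", box = "matrix",
                 lateralUnwrapped = "logical"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "coords must be an [nFrames, nParticles, 3] array")
    if (length(object@times) != d[1])
      msg <- c(msg, "length(times) must equal the number of frames")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (!all(dim(object@box) == c(d[1], 3L)))
      msg <- c(msg, "box must be an [nFrames, 3] matrix")
    if (any(!is.finite(object@box)) || any(object@box <= 0))
      msg <- c(msg, "box edge lengths must be positive and finite")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
    if (length(object@lateralUnwrapped) != 1L)
      msg <- c(msg, "lateralUnwrapped must be a single logical")
    if (length(msg)) msg else TRUE
  })

#' Construct a Trajectory
#'
#' @param times frame times \[ps\], strictly increasing.
#' @param coords array `[nFrames, nParticles, 3]` of positions \[nm\].
#' @param box per-frame box edges: a length-3 vector (constant box) or an
#'   `[nFrames, 3]` matrix \[nm\].
#' @param lateralUnwrapped logical; see [Trajectory-class].
#' @return A [Trajectory-class] object.
#' @examples
#' tr <- trajectory(times = c(0, 1), coords = array(0.5, c(2, 1, 3)),
#'                  box = c(4, 4, 4))
#' nFrames(tr)
#' @export
trajectory <- function(times, coords, box, lateralUnwrapped = FALSE) {
  if (is.matrix(coords)) # single frame convenience
    coords <- array(coords, c(1L, nrow(coords), 3L))
  if (!is.matrix(box))
    box <- matrix(box, nrow = dim(coords)[1], ncol = 3L, byrow = TRUE)
  new("Trajectory", times = as.numeric(times), coords = coords, box = box,
      lateralUnwrapped = lateralUnwrapped)
}

#' Water topology: per-molecule O/H/H atom indices
#'
#' @slot oIndex,h1Index,h2Index integer vectors of atom indices (1-based),
#'   one entry per molecule; the three sets are disjoint.
#' @slot masses numeric per-atom masses \[amu\] for all particles in the
#'   associated trajectory.
#' @export
setClass("WaterTopology",
  representation(oIndex = "integer", h1Index = "integer", h2Index = "integer",
                 masses = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@oIndex)
    if (length(object@h1Index) != n || length(object@h2Index) != n)
      msg <- c(msg, "oIndex, h1Index, h2Index must have equal length")
    idx <- c(object@oIndex, object@h1Index, object@h2Index)
    if (anyDuplicated(idx))
      msg <- c(msg, "atom index triples must be disjoint")
    if (length(idx) && (min(idx) < 1L || max(idx) > length(object@masses)))
      msg <- c(msg, "atom indices out of range of masses")
    if (any(object@masses <= 0))
      msg <- c(msg, "masses must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a WaterTopology
#'
#' @param oIndex,h1Index,h2Index per-molecule atom indices (1-based).
#' @param masses per-atom masses \[amu\]; defaults to standard O/H masses
#'   placed at the given indices.
#' @return A [WaterTopology-class] object.
#' @export
waterTopology <- function(oIndex, h1Index, h2Index, masses = NULL) {
  oIndex <- as.integer(oIndex); h1Index <- as.integer(h1Index)
  h2Index <- as.integer(h2Index)
  if (is.null(masses)) {
    masses <- numeric(max(c(oIndex, h1Index, h2Index)))
    masses[oIndex] <- .MASS_O
    masses[c(h1Index, h2Index)] <- .MASS_H
    masses[masses == 0] <- .MASS_H # placeholder for non-water atoms
  }
  new("WaterTopology", oIndex = oIndex, h1Index = h1Index,
      h2Index = h2Index, masses = as.numeric(masses))
}

#' Standard water topology for n contiguous O,H,H molecules
#'
#' Convenience constructor for systems whose atoms are ordered
#' O,H,H,O,H,H,... as written by the synthetic generators.
#'
#' @param nMolecules number of water molecules.
#' @return A [WaterTopology-class].
#' @export
makeWaterTopology <- function(nMolecules) {
  base <- (seq_len(nMolecules) - 1L) * 3L
  waterTopology(base + 1L, base + 2L, base + 3L)
}

#' Slit-pore geometry
#'
#' Defines which coordinate axis is the surface normal and which in-plane
#' axis is the cellulose chain direction, plus the arrangement of the two
#' walls. The default (normal = z, chain = y) matches the usual depiction of
#' a slit pore with the surfaces perpendicular to z.
#'
#' @slot normalAxis one of `"x"`, `"y"`, `"z"`: the surface normal.
#' @slot chainAxis one of the two remaining axes: the in-plane chain
#'   direction.
#' @slot wallLo,wallHi optional nominal wall planes \[nm\] (`NA` if unknown).
#' @slot wallLabels character(2), surface tags for the lower and upper wall.
#' @slot arrangement `"parallel"` or `"antiparallel"`: whether the second
#'   wall's chain direction is parallel or reversed with respect to the
#'   first wall's.
#' @export
setClass("SlitGeometry",
  representation(normalAxis = "character", chainAxis = "character",
                 wallLo = "numeric", wallHi = "numeric",
                 wallLabels = "character", arrangement = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@normalAxis %in% .AXES)) msg <- c(msg, "invalid normalAxis")
    if (!(object@chainAxis %in% .AXES)) msg <- c(msg, "invalid chainAxis")
    if (identical(object@normalAxis, object@chainAxis))
      msg <- c(msg, "normalAxis and chainAxis must differ")
    if (!all(object@wallLabels %in% .WALL_LABELS))
      msg <- c(msg, paste("wallLabels must be among:",
                          paste(.WALL_LABELS, collapse = ", ")))
    if (!(object@arrangement %in% c("parallel", "antiparallel")))
      msg <- c(msg, "arrangement must be 'parallel' or 'antiparallel'")
    if (!is.na(object@wallLo) && !is.na(object@wallHi) &&
        object@wallLo >= object@wallHi)
      msg <- c(msg, "wallLo must be < wallHi")
    if (length(msg)) msg else TRUE
  })

#' Construct a SlitGeometry
#'
#' @param normalAxis surface-normal axis, default `"z"`.
#' @param chainAxis in-plane chain axis, default `"y"`.
#' @param wallLo,wallHi optional nominal wall positions \[nm\].
#' @param wallLabels surface tags (length 2 or recycled), from
#'   `"hydrophilic-110"`, `"hydrophilic-1m10"`, `"hydrophobic-100"`,
#'   `"synthetic"`.
#' @param arrangement `"parallel"` (default) or `"antiparallel"`.
#' @return A [SlitGeometry-class] object.
#' @examples
#' slitGeometry()
#' slitGeometry(arrangement = "antiparallel")
#' @export
slitGeometry <- function(normalAxis = "z", chainAxis = "y",
                         wallLo = NA_real_, wallHi = NA_real_,
                         wallLabels = "synthetic",
                         arrangement = "parallel") {
  new("SlitGeometry", normalAxis = normalAxis, chainAxis = chainAxis,
      wallLo = as.numeric(wallLo), wallHi = as.numeric(wallHi),
      wallLabels = rep_len(wallLabels, 2L), arrangement = arrangement)
}

#' Component-resolved mean-square displacement
#'
#' @slot lags lag times \[ps\], starting at 0.
#' @slot msd numeric matrix `[nLags, 3]` with columns `x`, `y`, `z` \[nm^2\].
#' @slot nOrigins integer count of time origins averaged at each lag.
#' @slot dt frame spacing \[ps\].
#' @slot blockMsd optional array `[nLags, 3, nBlocks]` of MSDs over
#'   disjoint particle blocks; independent particles make the block
#'   scatter an honest uncertainty for quantities fitted from the MSD
#'   (the lag-wise residuals themselves are strongly correlated).
#' @export
setClass("MSDResult",
  representation(lags = "numeric", msd = "matrix", nOrigins = "integer",
                 dt = "numeric", blockMsd = "array"),
  prototype(blockMsd = array(numeric(0), c(0L, 3L, 0L))),
  validity = function(object) {
    msg <- character()
    if (nrow(object@msd) != length(object@lags) ||
        length(object@nOrigins) != length(object@lags))
      msg <- c(msg, "lags, msd rows and nOrigins must align")
    if (!identical(colnames(object@msd), .AXES))
      msg <- c(msg, "msd columns must be x, y, z")
    if (any(object@msd < -1e-12))
      msg <- c(msg, "msd must be non-negative")
    if (length(object@lags) && object@lags[1] == 0 &&
        any(abs(object@msd[1, ]) > 1e-12))
      msg <- c(msg, "msd at lag 0 must be 0")
    if (is.unsorted(rev(object@nOrigins)))
      msg <- c(msg, "nOrigins must be non-increasing with lag")
    if (length(msg)) msg else TRUE
  })

#' Einstein-relation fit of the parallel diffusion coefficient
#'
#' @slot dPar named numeric(2): per-axis parallel diffusion coefficients
#'   \[nm^2/ps\].
#' @slot dParSE standard errors \[nm^2/ps\].
#' @slot composite unweighted mean of the two components \[nm^2/ps\].
#' @slot compositeSE combined standard error \[nm^2/ps\].
#' @slot window fitting window `c(min, max)` \[ps\].
#' @slot r2 per-axis linearity diagnostic.
#' @slot discrepant `TRUE` if the two components differ by more than 3
#'   combined standard errors.
#' @slot clipped `TRUE` if a negative fitted slope was clipped to 0.
#' @export
setClass("EinsteinFit",
  representation(dPar = "numeric", dParSE = "numeric", composite = "numeric",
                 compositeSE = "numeric", window = "numeric", r2 = "numeric",
                 discrepant = "logical", clipped = "logical"))

#' Joint (L, D_perp) restricted-diffusion fit result
#'
#' @slot L fitted confinement width \[nm\].
#' @slot Dperp fitted perpendicular diffusion coefficient \[nm^2/ps\].
#' @slot LSE,DperpSE standard errors from the Jacobian-based covariance.
#' @slot corrLD parameter correlation coefficient from the same covariance.
#' @slot residNorm residual L2 norm \[nm^2\].
#' @slot nTerms maximum number of series terms used.
#' @slot converged optimizer convergence flag.
#' @slot noPlateau `TRUE` if the perpendicular MSD was still rising at the
#'   longest lag (plateau not reached; L is then poorly defined).
#' @export
setClass("ConfinementFit",
  representation(L = "numeric", Dperp = "numeric", LSE = "numeric",
                 DperpSE = "numeric", corrLD = "numeric",
                 residNorm = "numeric", nTerms = "integer",
                 converged = "logical", noPlateau = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@L <= 0) msg <- c(msg, "L must be positive")
    if (!is.na(object@corrLD) && abs(object@corrLD) > 1 + 1e-9)
      msg <- c(msg, "|corrLD| must be <= 1")
    if (length(msg)) msg else TRUE
  })

#' P2 rotational autocorrelation function
#'
#' @slot lags lag times \[ps\].
#' @slot acf autocorrelation values, `C(0) = 1`.
#' @slot nOrigins time origins per lag.
#' @slot nBonds number of bond vectors averaged.
#' @export
setClass("RACFResult",
  representation(lags = "numeric", acf = "numeric", nOrigins = "integer",
                 nBonds = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@lags) != length(object@acf))
      msg <- c(msg, "lags and C must align")
    ## loose tolerances so that noisy synthetic curves remain representable;
    ## the estimator itself satisfies these to machine precision
    if (length(object@acf) && length(object@lags) &&
        object@lags[1] == 0 && abs(object@acf[1] - 1) > 0.1)
      msg <- c(msg, "C(0) must equal 1 (within tolerance)")
    if (any(abs(object@acf) > 1.1))
      msg <- c(msg, "|C| must be <= 1 (within tolerance)")
    if (length(msg)) msg else TRUE
  })

#' Stretched-exponential (KWW) plus order-parameter fit
#'
#' Parameters of `C(t) = S^2 + (1 - S^2) exp(-(t/tau)^beta)`.
#'
#' @slot tau correlation time \[ps\].
#' @slot beta stretch exponent in (0, 1].
#' @slot S order parameter in \[0, 1).
#' @slot tauSE,betaSE,SSE standard errors (NA when a parameter sits on a
#'   bound).
#' @slot residNorm residual L2 norm.
#' @slot plateauSampled `TRUE` if the input extended well past the decay so
#'   the plateau level was actually constrained by data.
#' @export
setClass("StretchedExpFit",
  representation(tau = "numeric", beta = "numeric", S = "numeric",
                 tauSE = "numeric", betaSE = "numeric", SSE = "numeric",
                 residNorm = "numeric", plateauSampled = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@tau <= 0) msg <- c(msg, "tau must be positive")
    if (object@beta <= 0 || object@beta > 1 + 1e-9)
      msg <- c(msg, "beta must lie in (0, 1]")
    if (object@S < 0 || object@S >= 1)
      msg <- c(msg, "S must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Normalized angular distribution (cos theta or phi)
#'
#' @slot angle `"cosTheta"` or `"phi"`.
#' @slot breaks histogram bin edges.
#' @slot density pooled probability density (unit integral).
#' @slot counts pooled raw bin counts.
#' @slot wallDensity matrix `[2, nBins]` of per-wall densities (rows
#'   `lower`, `upper`); `NA` when a wall has no samples.
#' @slot means named numeric: pooled/lower/upper means of the angle
#'   variable.
#' @slot nSkipped samples skipped (phi only: bonds parallel to the normal).
#' @export
setClass("AngleDistribution",
  representation(angle = "character", breaks = "numeric",
                 density = "numeric", counts = "integer",
                 wallDensity = "matrix", means = "numeric",
                 nSkipped = "integer"))

#' Density profile across the slit
#'
#' @slot binCenters positions along the surface normal \[nm\].
#' @slot density profile values; \[kg/m^3\] for `kind = "mass"`, molecules
#'   per nm^3 for `kind = "number"`.
#' @slot binWidth bin width \[nm\].
#' @slot kind `"mass"` or `"number"`.
#' @export
setClass("DensityProfile",
  representation(binCenters = "numeric", density = "numeric",
                 binWidth = "numeric", kind = "character"),
  validity = function(object) {
    if (any(object@density < 0)) "densities must be non-negative" else TRUE
  })

## ---- synthetic-generator parameter classes -------------------------------

#' Parameters for (slit-confined) Brownian dynamics generation
#'
#' @slot dPar lateral diffusion coefficient \[nm^2/ps\].
#' @slot dPerp perpendicular diffusion coefficient \[nm^2/ps\].
#' @slot lTrue wall separation \[nm\] (ignored by [genFreeBrownian()]).
#' @slot nParticles,nSteps,saveStride integer sizes; frames are saved every
#'   `saveStride` steps (the underlying step size stays `dt`).
#' @slot dt time step \[ps\].
#' @slot boxLateral lateral box edge \[nm\].
#' @slot seed RNG seed.
#' @export
setClass("SlitBrownianParams",
  representation(dPar = "numeric", dPerp = "numeric", lTrue = "numeric",
                 nParticles = "integer", dt = "numeric", nSteps = "integer",
                 boxLateral = "numeric", seed = "integer",
                 saveStride = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dPar < 0 || object@dPerp < 0)
      msg <- c(msg, "dPar and dPerp must be non-negative")
    if (object@lTrue <= 0 || object@dt <= 0 || object@boxLateral <= 0)
      msg <- c(msg, "lTrue, dt and boxLateral must be positive")
    if (object@nParticles < 1L || object@nSteps < 1L ||
        object@saveStride < 1L)
      msg <- c(msg, "nParticles, nSteps and saveStride must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct SlitBrownianParams
#'
#' @param dPar,dPerp diffusion coefficients \[nm^2/ps\].
#' @param lTrue wall separation \[nm\].
#' @param nParticles number of independent walkers.
#' @param dt integration time step \[ps\].
#' @param nSteps number of steps.
#' @param boxLateral lateral box edge \[nm\].
#' @param seed RNG seed (integer).
#' @param saveStride save a frame every this many steps.
#' @return A [SlitBrownianParams-class] object. A warning is emitted when
#'   the rms perpendicular step exceeds `lTrue / 4` (coarse sampling of the
#'   reflections; the saved-frame law itself remains exact).
#' @export
slitBrownianParams <- function(dPar = 1e-3, dPerp = 1e-3, lTrue = 1,
                               nParticles = 100L, dt = 0.1, nSteps = 1000L,
                               boxLateral = 4, seed = 1L, saveStride = 1L) {
  p <- new("SlitBrownianParams", dPar = dPar, dPerp = dPerp, lTrue = lTrue,
           nParticles = as.integer(nParticles), dt = dt,
           nSteps = as.integer(nSteps), boxLateral = boxLateral,
           seed = as.integer(seed), saveStride = as.integer(saveStride))
  if (sqrt(2 * dPerp * dt) >= lTrue / 4)
    warning("perpendicular rms step exceeds lTrue/4; ",
            "reflections are coarsely sampled")
  p
}

#' Parameters for rotational-diffusion (rotor) generation
#'
#' @slot model `"isotropic"` or `"cone"`.
#' @slot dR rotational diffusion coefficient \[1/ps\].
#' @slot coneHalfAngle cone half-angle \[deg\] (cone model).
#' @slot coneAxis unit 3-vector, the cone axis.
#' @slot nRotors,nSteps,saveStride integer sizes.
#' @slot dt time step \[ps\].
#' @slot seed RNG seed.
#' @export
setClass("RotorParams",
  representation(model = "character", dR = "numeric",
                 coneHalfAngle = "numeric", coneAxis = "numeric",
                 nRotors = "integer", dt = "numeric", nSteps = "integer",
                 seed = "integer", saveStride = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@model %in% c("isotropic", "cone")))
      msg <- c(msg, "model must be 'isotropic' or 'cone'")
    if (object@dR <= 0) msg <- c(msg, "dR must be positive")
    if (object@model == "cone" &&
        (object@coneHalfAngle <= 0 || object@coneHalfAngle > 180))
      msg <- c(msg, "coneHalfAngle must lie in (0, 180]")
    if (length(object@coneAxis) != 3L)
      msg <- c(msg, "coneAxis must be a 3-vector")
    if (object@nRotors < 1L || object@nSteps < 1L || object@dt <= 0)
      msg <- c(msg, "nRotors, nSteps must be >= 1 and dt > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct RotorParams
#'
#' The default time step is `0.01 / (6 dR)`, i.e. 1% of the isotropic P2
#' correlation time, keeping individual angular steps small.
#'
#' @param model `"isotropic"` or `"cone"`.
#' @param dR rotational diffusion coefficient \[1/ps\].
#' @param coneHalfAngle cone half-angle \[deg\] (cone model only).
#' @param coneAxis cone axis (normalized internally).
#' @param nRotors number of independent rotors.
#' @param dt time step \[ps\].
#' @param nSteps number of steps.
#' @param seed RNG seed.
#' @param saveStride save a frame every this many steps.
#' @return A [RotorParams-class] object.
#' @export
rotorParams <- function(model = c("isotropic", "cone"), dR = 0.01,
                        coneHalfAngle = 30, coneAxis = c(0, 0, 1),
                        nRotors = 100L, dt = 0.01 / (6 * dR),
                        nSteps = 1000L, seed = 1L, saveStride = 1L) {
  model <- match.arg(model)
  coneAxis <- coneAxis / sqrt(sum(coneAxis^2))
  new("RotorParams", model = model, dR = dR,
      coneHalfAngle = coneHalfAngle, coneAxis = coneAxis,
      nRotors = as.integer(nRotors), dt = dt, nSteps = as.integer(nSteps),
      seed = as.integer(seed), saveStride = as.integer(saveStride))
}

#' Specification for statically oriented/layered water frames
#'
#' Describes a Gaussian-mixture density along the surface normal together
#' with target angular distributions for the O-H bond vectors; used to
#' build fixtures with known structure for the orientation and density
#' analyses. Frames are drawn independently (no dynamics).
#'
#' @slot layerCenters,layerWidths,layerWeights Gaussian-mixture layers along
#'   the normal \[nm\]; weights sum to 1.
#' @slot normalExtent extent of the slab along the normal \[nm\] (samples
#'   are redrawn until inside `[0, normalExtent]`).
#' @slot boxLateral lateral box edge \[nm\].
#' @slot nMolecules,nFrames integer sizes.
#' @slot seed RNG seed.
#' @export
setClass("OrientedFrameSpec",
  representation(layerCenters = "numeric", layerWidths = "numeric",
                 layerWeights = "numeric", normalExtent = "numeric",
                 boxLateral = "numeric", nMolecules = "integer",
                 nFrames = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    k <- length(object@layerCenters)
    if (length(object@layerWidths) != k || length(object@layerWeights) != k)
      msg <- c(msg, "layer centers, widths and weights must align")
    if (abs(sum(object@layerWeights) - 1) > 1e-9)
      msg <- c(msg, "layerWeights must sum to 1")
    if (any(object@layerWidths <= 0))
      msg <- c(msg, "layerWidths must be positive")
    if (object@normalExtent <= 0 || object@boxLateral <= 0)
      msg <- c(msg, "normalExtent and boxLateral must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct an OrientedFrameSpec
#'
#' @param layerCenters,layerWidths,layerWeights Gaussian-mixture layer
#'   parameters along the normal \[nm\].
#' @param normalExtent slab extent along the normal \[nm\].
#' @param boxLateral lateral box edge \[nm\].
#' @param nMolecules,nFrames sizes.
#' @param seed RNG seed.
#' @return An [OrientedFrameSpec-class] object.
#' @export
orientedFrameSpec <- function(layerCenters = 0.5, layerWidths = 0.1,
                              layerWeights = NULL, normalExtent = 1,
                              boxLateral = 4, nMolecules = 500L,
                              nFrames = 10L, seed = 1L) {
  if (is.null(layerWeights))
    layerWeights <- rep(1 / length(layerCenters), length(layerCenters))
  new("OrientedFrameSpec", layerCenters = layerCenters,
      layerWidths = layerWidths, layerWeights = layerWeights,
      normalExtent = normalExtent, boxLateral = boxLateral,
      nMolecules = as.integer(nMolecules), nFrames = as.integer(nFrames),
      seed = as.integer(seed))
}
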