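#' @include AllClasses.R
NULL

## Draw n points uniformly on the unit sphere.
randomUnitVectors <- function(n) {
  u <- matrix(rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}

## Uniform directions within a cone of half-angle thetaC about `axis`
## (uniform in solid angle).
randomConeVectors <- function(n, thetaC, axis) {
  cosT <- runif(n, cos(thetaC), 1)
  sinT <- sqrt(pmax(0, 1 - cosT^2))
  phi <- runif(n, -pi, pi)
  ## orthonormal frame around axis
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  outer(cosT, a) + outer(sinT * cos(phi), e1) + outer(sinT * sin(phi), e2)
}

.brownianTraj <- function(params, confined) {
  p <- params
  withSeed(p@seed, {
    x0 <- cbind(runif(p@nParticles, 0, p@boxLateral),
                runif(p@nParticles, 0, p@boxLateral),
                runif(p@nParticles, 0, p@lTrue))
    raw <- .cppBrownian(x0, p@nSteps, p@saveStride,
                        sqrt(2 * p@dPar * p@dt), sqrt(2 * p@dPerp * p@dt),
                        p@lTrue, confined)
  })
  nSaved <- p@nSteps %/% p@saveStride + 1L
  co <- array(raw, c(nSaved, p@nParticles, 3L))
  ## wrap lateral coordinates into [0, box) per the storage convention
  for (ax in 1:2) co[, , ax] <- co[, , ax] %% p@boxLateral
  boxPerp <- if (confined) p@lTrue else p@boxLateral
  trajectory(times = seq(0, by = p@dt * p@saveStride, length.out = nSaved),
             coords = co,
             box = c(p@boxLateral, p@boxLateral, boxPerp),
             lateralUnwrapped = FALSE)
}

#' Generate free (unconfined) anisotropic Brownian motion
#'
#' Walkers take independent Gaussian increments of variance `2 D dt` per
#' axis (`dPar` laterally, `dPerp` along z); `lTrue` only sets the initial
#' z spread and the nominal box. Emulates a bulk reference system.
#'
#' @param params a [SlitBrownianParams-class].
#' @return a [Trajectory-class] (lateral coordinates wrapped into the box).
#' @examples
#' tr <- genFreeBrownian(slitBrownianParams(nParticles = 10, nSteps = 100))
#' tr
#' @export
genFreeBrownian <- function(params) .brownianTraj(params, confined = FALSE)

#' Generate Brownian motion confined between reflecting walls
#'
#' Lateral motion is free with coefficient `dPar`; the perpendicular
#' coordinate diffuses with `dPerp` between impenetrable reflecting walls
#' at 0 and `lTrue`, implemented by the exact folding map (overshoot is
#' reflected across the wall, repeatedly, until inside). The stationary
#' perpendicular distribution is uniform on `[0, lTrue]` and walkers start
#' from it.
#'
#' @param params a [SlitBrownianParams-class].
#' @return a [Trajectory-class].
#' @examples
#' tr <- genSlitBrownian(slitBrownianParams(lTrue = 0.5, nParticles = 10,
#'                                          nSteps = 100))
#' range(coords(tr)[, , 3]) # within [0, 0.5]
#' @export
genSlitBrownian <- function(params) {
  if (sqrt(2 * params@dPerp * params@dt) > params@lTrue)
    stop("dt too coarse: rms perpendicular step exceeds lTrue")
  .brownianTraj(params, confined = TRUE)
}

#' Generate a rotational-diffusion bond-vector time series
#'
#' Isotropic model: diffusion on the unit sphere with coefficient `dR`,
#' whose P2 autocorrelation is `exp(-6 dR t)`. Cone model: the same
#' diffusion restricted (by step rejection) to a cone of half-angle
#' `coneHalfAngle` about `coneAxis`; the P2 autocorrelation then decays to
#' the plateau `S^2` with the wobbling-in-a-cone order parameter
#' `S = cos(a) (1 + cos(a)) / 2`, where `a` is the half-angle.
#'
#' @param params a [RotorParams-class].
#' @return array `[nSavedFrames, nRotors, 3]` of unit vectors with frame
#'   times in attribute `times`.
#' @seealso [coneOrderParameter()], [coneHalfAngleFromS()]
#' @export
genRotor <- function(params) {
  p <- params
  sigma <- sqrt(2 * p@dR * p@dt)
  cone <- p@model == "cone"
  thetaC <- p@coneHalfAngle * pi / 180
  withSeed(p@seed, {
    u0 <- if (cone) randomConeVectors(p@nRotors, thetaC, p@coneAxis)
          else randomUnitVectors(p@nRotors)
    raw <- .cppRotor(u0, p@nSteps, p@saveStride, sigma, cone,
                     cos(thetaC), p@coneAxis)
  })
  nSaved <- p@nSteps %/% p@saveStride + 1L
  out <- array(raw, c(nSaved, p@nRotors, 3L))
  attr(out, "times") <- seq(0, by = p@dt * p@saveStride,
                            length.out = nSaved)
  out
}

#' Wobbling-in-a-cone order parameter
#'
#' Closed form `S = cos(a) (1 + cos(a)) / 2` for diffusion restricted to a
#' cone of half-angle `a`.
#'
#' @param halfAngleDeg cone half-angle \[deg\].
#' @return order parameter S.
#' @export
coneOrderParameter <- function(halfAngleDeg) {
  ca <- cos(halfAngleDeg * pi / 180)
  ca * (1 + ca) / 2
}

#' Invert the wobbling-in-a-cone relation
#'
#' @param S target order parameter in (0, 1).
#' @return cone half-angle \[deg\] with `coneOrderParameter()` equal to `S`.
#' @examples
#' coneHalfAngleFromS(0.8)
#' @export
coneHalfAngleFromS <- function(S) {
  ca <- (-1 + sqrt(1 + 8 * S)) / 2
  acos(ca) * 180 / pi
}

#' Generate statically layered, oriented water frames
#'
#' Molecule positions are drawn with the normal coordinate from the
#' Gaussian-mixture layer profile (truncated to `[0, normalExtent]`) and
#' uniform lateral coordinates; the two O-H bond unit vectors of each
#' molecule are drawn independently from target angular distributions
#' expressed in the global slit frame (see [phiDistribution()] for the
#' frame convention). Hydrogens are placed at the ideal O-H distance
#' (0.09572 nm) along the bonds, so the same fixture serves the density
#' operations.
#'
#' @param spec an [OrientedFrameSpec-class].
#' @param cosTheta either `"uniform"` (isotropic) or a function `n ->
#'   numeric(n)` sampling cos theta values in `[-1, 1]`.
#' @param phi either `"uniform"` or a function `n -> numeric(n)` sampling
#'   azimuths \[deg\] in `(-180, 180]`.
#' @param geom a [SlitGeometry-class] fixing the normal and chain axes.
#' @return a list with `traj` (a [Trajectory-class] of O,H,H atoms),
#'   `topology` (a [WaterTopology-class]), and `bonds` (bond-vector array
#'   as from [bondVectors()]).
#' @export
genOrientedFrames <- function(spec, cosTheta = "uniform", phi = "uniform",
                              geom = slitGeometry()) {
  s <- spec
  nTot <- s@nMolecules * s@nFrames
  sampleCos <- if (identical(cosTheta, "uniform")) {
    function(n) runif(n, -1, 1)
  } else cosTheta
  samplePhi <- if (identical(phi, "uniform")) {
    function(n) runif(n, -180, 180)
  } else phi
  iN <- axisIndex(geom@normalAxis)
  iC <- axisIndex(geom@chainAxis)
  eN <- unitAxis(geom@normalAxis)
  eC <- unitAxis(geom@chainAxis)
  eB <- c(eN[2] * eC[3] - eN[3] * eC[2],
          eN[3] * eC[1] - eN[1] * eC[3],
          eN[1] * eC[2] - eN[2] * eC[1])
  withSeed(s@seed, {
    ## mixture sampling with truncation by redraw
    zc <- numeric(0)
    while (length(zc) < nTot) {
      m <- nTot - length(zc)
      comp <- sample.int(length(s@layerWeights), m, replace = TRUE,
                         prob = s@layerWeights)
      z <- rnorm(m, s@layerCenters[comp], s@layerWidths[comp])
      zc <- c(zc, z[z >= 0 & z <= s@normalExtent])
    }
    lat1 <- runif(nTot, 0, s@boxLateral)
    lat2 <- runif(nTot, 0, s@boxLateral)
    ct <- cbind(sampleCos(nTot), sampleCos(nTot))
    ph <- cbind(samplePhi(nTot), samplePhi(nTot)) * pi / 180
  })
  st <- sqrt(pmax(1 - ct^2, 0)) # pmax(matrix, .) keeps dim
  bondOf <- function(k) {
    outer(ct[, k], eN) +
      outer(st[, k] * cos(ph[, k]), eC) +
      outer(st[, k] * sin(ph[, k]), eB)
  }
  b1 <- bondOf(1); b2 <- bondOf(2)
  latAxes <- setdiff(1:3, iN)
  opos <- matrix(0, nTot, 3)
  opos[, iN] <- zc
  opos[, latAxes[1]] <- lat1
  opos[, latAxes[2]] <- lat2
  dOH <- 0.09572
  nMol <- s@nMolecules
  co <- array(0, c(s@nFrames, 3L * nMol, 3L))
  bonds <- array(0, c(s@nFrames, 2L * nMol, 3L))
  for (f in seq_len(s@nFrames)) {
    rows <- (f - 1L) * nMol + seq_len(nMol)
    co[f, 3L * seq_len(nMol) - 2L, ] <- opos[rows, ]
    co[f, 3L * seq_len(nMol) - 1L, ] <- opos[rows, ] + dOH * b1[rows, ]
    co[f, 3L * seq_len(nMol), ] <- opos[rows, ] + dOH * b2[rows, ]
    bonds[f, 2L * seq_len(nMol) - 1L, ] <- b1[rows, ]
    bonds[f, 2L * seq_len(nMol), ] <- b2[rows, ]
  }
  box <- numeric(3)
  box[iN] <- s@normalExtent
  box[latAxes] <- s@boxLateral
  traj <- trajectory(times = seq_len(s@nFrames) - 1,
                     coords = co, box = box, lateralUnwrapped = FALSE)
  attr(bonds, "times") <- traj@times
  list(traj = traj, topology = makeWaterTopology(nMol), bonds = bonds)
}

#' Evaluate (optionally noisy) stretched-exponential RACF curves
#'
#' Direct evaluation of `C(t) = S^2 + (1 - S^2) exp(-(t/tau)^beta)`, with
#' optional additive Gaussian noise; used as ground truth for the fitting
#' routines.
#'
#' @param tau correlation time \[ps\], > 0.
#' @param beta stretch exponent in (0, 1].
#' @param S order parameter in \[0, 1).
#' @param times lag times \[ps\].
#' @param noiseSD standard deviation of additive Gaussian noise.
#' @param seed RNG seed (used when `noiseSD > 0`).
#' @return an [RACFResult-class] (validity checks relaxed for noisy
#'   curves: returned as plain values in slot `C`).
#' @examples
#' r <- synthRacf(tau = 50, beta = 1, S = 0, times = c(0, 50))
#' r@acf[2] # exp(-1)
#' @export
synthRacf <- function(tau, beta, S, times, noiseSD = 0, seed = 1L) {
  stopifnot(tau > 0, beta > 0, beta <= 1, S >= 0, S < 1)
  C <- S^2 + (1 - S^2) * exp(-(times / tau)^beta)
  if (noiseSD > 0)
    C <- C + withSeed(seed, rnorm(length(times), 0, noiseSD))
  new("RACFResult", lags = as.numeric(times), acf = C,
      nOrigins = rep(1L, length(times)), nBonds = 1L)
}

#' Write a ground-truth side-car for a generated system
#'
#' @param path output YAML path.
#' @param truth named list of true parameters (e.g. `dPar`, `dPerp`,
#'   `lTrue`, `tau`, `S`, `seed`).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(path, truth) {
  yaml::write_yaml(truth, path)
  invisible(path)
}
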