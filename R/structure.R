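#' @include AllClasses.R
NULL

#' Assign each molecule to its nearest confining surface
#'
#' Molecules below the slab midplane belong to the lower wall, molecules
#' at or above it to the upper wall. The midplane comes from the nominal
#' wall planes when the geometry carries them, otherwise from the center
#' of the occupied region (optionally shifted to `center`).
#'
#' @param normalCoords numeric vector or `[nFrames, nMolecules]` matrix of
#'   coordinates along the surface normal \[nm\].
#' @param geom a [SlitGeometry-class].
#' @param center optional midplane position \[nm\]; overrides the
#'   geometry.
#' @return character vector/matrix (same shape as input) of `"lower"` /
#'   `"upper"` labels.
#' @examples
#' g <- slitGeometry(wallLo = 0, wallHi = 1)
#' assignNearestSurface(c(0.49, 0.51), g)
#' @export
assignNearestSurface <- function(normalCoords, geom = slitGeometry(),
                                 center = NULL) {
  mid <- if (!is.null(center)) center
  else if (!is.na(geom@wallLo) && !is.na(geom@wallHi))
    (geom@wallLo + geom@wallHi) / 2
  else (min(normalCoords) + max(normalCoords)) / 2
  lab <- ifelse(normalCoords < mid, "lower", "upper")
  if (is.matrix(normalCoords))
    lab <- matrix(lab, nrow(normalCoords), ncol(normalCoords))
  lab
}

## Expand per-molecule labels to per-bond labels (2 bonds per molecule,
## interleaved as produced by bondVectors()).
.labelsForBonds <- function(labels, nBonds) {
  if (is.matrix(labels)) {
    if (ncol(labels) == nBonds) return(labels)
    if (2L * ncol(labels) == nBonds) {
      idx <- rep(seq_len(ncol(labels)), each = 2L)
      return(labels[, idx, drop = FALSE])
    }
  } else {
    if (length(labels) == nBonds) return(labels)
    if (2L * length(labels) == nBonds)
      return(labels[rep(seq_along(labels), each = 2L)])
    if (length(labels) == 1L) return(rep(labels, nBonds))
  }
  stop("labels do not match the number of bonds or molecules")
}

.angleHistogram <- function(values, labels, breaks, angle, nSkipped = 0L) {
  binW <- diff(breaks)[1]
  dens <- function(v) {
    if (!length(v)) return(rep(NA_real_, length(breaks) - 1L))
    h <- hist(v, breaks = breaks, plot = FALSE)
    h$density
  }
  pooled <- dens(values)
  counts <- hist(values, breaks = breaks, plot = FALSE)$counts
  wd <- rbind(lower = dens(values[labels == "lower"]),
              upper = dens(values[labels == "upper"]))
  means <- c(pooled = mean(values),
             lower = mean(values[labels == "lower"]),
             upper = mean(values[labels == "upper"]))
  new("AngleDistribution", angle = angle, breaks = breaks,
      density = pooled, counts = as.integer(counts), wallDensity = wd,
      means = means, nSkipped = as.integer(nSkipped))
}

#' Distribution of cos theta: bond vectors vs. the surface normal
#'
#' For each bond the cosine of the angle to the inward normal of the
#' molecule's assigned wall (+normal for the lower wall, -normal for the
#' upper wall). `cos theta` is used instead of `theta` because its
#' distribution is flat for isotropically oriented bonds, so
#' `<cos theta> = 0` signals random orientation. Densities are normalized
#' to unit integral.
#'
#' @param bonds unit-vector array `[nFrames, nBonds, 3]`.
#' @param labels wall labels per molecule or per bond (vector, or matrix
#'   `[nFrames, .]`), as from [assignNearestSurface()].
#' @param geom a [SlitGeometry-class].
#' @param nBins number of bins on `[-1, 1]`.
#' @return an [AngleDistribution-class].
#' @export
cosThetaDistribution <- function(bonds, labels, geom = slitGeometry(),
                                 nBins = 50L) {
  nB <- dim(bonds)[2]
  lab <- .labelsForBonds(labels, nB)
  if (!is.matrix(lab)) lab <- matrix(lab, dim(bonds)[1], nB, byrow = TRUE)
  iN <- axisIndex(geom@normalAxis)
  uN <- bonds[, , iN, drop = FALSE]
  dim(uN) <- dim(bonds)[1:2]
  v <- ifelse(lab == "lower", uN, -uN)
  .angleHistogram(as.vector(v), as.vector(lab),
                  seq(-1, 1, length.out = nBins + 1L), "cosTheta")
}

#' Distribution of phi: bond azimuth vs. the chain direction
#'
#' The signed azimuth of the bond's projection onto the surface plane,
#' measured from the chain axis, right-handed about the (lower-wall
#' inward) surface normal, in degrees on `(-180, 180]`. Like `cos theta`,
#' `phi` is flat for isotropic bonds. For the `antiparallel` wall
#' arrangement the second (upper) wall's surface frame is the mirror
#' image of the first's — its chain direction is reversed — so the sign
#' of `phi` is flipped for molecules assigned to the upper wall; parallel
#' walls share one frame. A fixture peaked at `+phi0` therefore registers
#' at `-phi0` when the arrangement is antiparallel and the molecules sit
#' at the second wall.
#'
#' Bonds whose in-plane projection is shorter than 1e-9 (parallel to the
#' normal) are skipped and counted in `nSkipped`.
#'
#' @inheritParams cosThetaDistribution
#' @param nBins number of bins on `(-180, 180]` (default 72, i.e. 5
#'   degree bins).
#' @return an [AngleDistribution-class]; densities are per degree.
#' @export
phiDistribution <- function(bonds, labels, geom = slitGeometry(),
                            nBins = 72L) {
  nB <- dim(bonds)[2]
  lab <- .labelsForBonds(labels, nB)
  if (!is.matrix(lab)) lab <- matrix(lab, dim(bonds)[1], nB, byrow = TRUE)
  eN <- unitAxis(geom@normalAxis)
  eC <- unitAxis(geom@chainAxis)
  eB <- c(eN[2] * eC[3] - eN[3] * eC[2],
          eN[3] * eC[1] - eN[1] * eC[3],
          eN[1] * eC[2] - eN[2] * eC[1])
  comp <- function(k) {
    m <- bonds[, , k, drop = FALSE]
    dim(m) <- dim(bonds)[1:2]
    m
  }
  uC <- comp(1) * eC[1] + comp(2) * eC[2] + comp(3) * eC[3]
  uB <- comp(1) * eB[1] + comp(2) * eB[2] + comp(3) * eB[3]
  proj <- sqrt(uC^2 + uB^2)
  keep <- proj >= 1e-9
  phi <- atan2(uB, uC) * 180 / pi
  if (geom@arrangement == "antiparallel") {
    flip <- lab == "upper"
    phi[flip] <- -phi[flip]
  }
  ## fold the closed endpoint: (-180, 180]
  phi[phi <= -180] <- phi[phi <= -180] + 360
  .angleHistogram(as.vector(phi[keep]), as.vector(lab[keep]),
                  seq(-180, 180, length.out = nBins + 1L), "phi",
                  nSkipped = sum(!keep))
}

#' Density profile across the slit
#'
#' Frame-averaged density binned along the surface normal. The mass
#' variant assigns every atom's mass to its own position, so the O-H
#' geometry sharpens the peaks; the number variant counts molecules at
#' their oxygen position.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [WaterTopology-class] selecting the water atoms.
#' @param geom a [SlitGeometry-class].
#' @param binWidth bin width \[nm\].
#' @param kind `"mass"` (kg/m^3) or `"number"` (molecules per nm^3).
#' @param range optional `c(lo, hi)` \[nm\] along the normal; defaults to
#'   the occupied range expanded to whole bins.
#' @return a [DensityProfile-class].
#' @export
densityProfile <- function(traj, topo, geom = slitGeometry(),
                           binWidth = 0.02, kind = c("mass", "number"),
                           range = NULL) {
  kind <- match.arg(kind)
  stopifnot(binWidth > 0)
  iN <- axisIndex(geom@normalAxis)
  latAx <- axisIndex(lateralAxes(geom))
  if (kind == "mass") {
    sel <- c(rbind(topo@oIndex, topo@h1Index, topo@h2Index))
    wts <- topo@masses[sel]
  } else {
    sel <- topo@oIndex
    wts <- rep(1, length(sel))
  }
  if (!length(sel)) stop("empty selection")
  z <- traj@coords[, sel, iN, drop = FALSE]
  dim(z) <- c(dim(traj@coords)[1], length(sel))
  if (is.null(range)) {
    lo <- floor(min(z) / binWidth) * binWidth
    hi <- ceiling(max(z) / binWidth + 1e-9) * binWidth
  } else {
    lo <- range[1]; hi <- range[2]
  }
  nb <- max(1L, as.integer(round((hi - lo) / binWidth)))
  hi <- lo + nb * binWidth
  area <- mean(traj@box[, latAx[1]] * traj@box[, latAx[2]])
  bin <- pmin(pmax(floor((as.vector(z) - lo) / binWidth) + 1L, 1L), nb)
  w <- rep(wts, each = nrow(z))
  counts <- vapply(seq_len(nb), function(b) sum(w[bin == b]), numeric(1))
  perFrame <- counts / nrow(z)
  dens <- perFrame / (area * binWidth)
  if (kind == "mass") dens <- dens * .AMU_NM3_TO_KG_M3
  new("DensityProfile",
      binCenters = lo + (seq_len(nb) - 0.5) * binWidth,
      density = dens, binWidth = binWidth, kind = kind)
}

#' Average water density in the slit
#'
#' Total selected water mass divided by the slit volume
#' `lateral area x L`, averaged over frames.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [WaterTopology-class].
#' @param geom a [SlitGeometry-class].
#' @param L confinement width \[nm\], typically the fitted width from
#'   [fitConfinement()].
#' @return average mass density \[kg/m^3\].
#' @export
averageSlitDensity <- function(traj, topo, geom = slitGeometry(),
                               L = NULL) {
  if (is.null(L) || !is.finite(L) || L <= 0)
    stop("L is required: fit the confinement width first ",
         "(fitConfinement) or supply a positive L")
  latAx <- axisIndex(lateralAxes(geom))
  sel <- c(topo@oIndex, topo@h1Index, topo@h2Index)
  mass <- sum(topo@masses[sel])
  area <- traj@box[, latAx[1]] * traj@box[, latAx[2]]
  mean(mass / (area * L)) * .AMU_NM3_TO_KG_M3
}

#' Orientation/density summary as JSON
#'
#' @param path output path.
#' @param summary named list (e.g. mean cos theta, mean phi, densities).
#' @return `path`, invisibly.
#' @export
writeSummaryJSON <- function(path, summary) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
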