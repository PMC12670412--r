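geomLit <- slitGeometry(wallLo = 0, wallHi = 1)

test_that("nearest-surface assignment splits at the midplane", {
  expect_equal(assignNearestSurface(c(0.5 - 1e-9, 0.5 + 1e-9), geomLit),
               c("lower", "upper"))
  ## all molecules near one wall -> single label
  expect_true(all(assignNearestSurface(rep(0.1, 5), geomLit) == "lower"))
  ## uniform slab -> balanced labels within binomial error
  set.seed(51)
  z <- runif(20000, 0, 1)
  lab <- assignNearestSurface(z, geomLit)
  expect_lt(abs(mean(lab == "lower") - 0.5), 4 * 0.5 / sqrt(20000))
})

test_that("cos theta distribution uses the assigned wall's inward normal", {
  ## all bonds along +z: lower-wall molecules see cos theta = +1,
  ## upper-wall molecules see -1
  b <- array(0, c(1, 6, 3))
  b[1, , 3] <- 1
  lab <- matrix(c(rep("lower", 3), rep("upper", 3)), 1)
  d <- cosThetaDistribution(b, lab, nBins = 10)
  expect_equal(d@means[["lower"]], 1)
  expect_equal(d@means[["upper"]], -1)
  ## density integrates to 1
  expect_equal(sum(d@density) * diff(d@breaks)[1], 1)

  ## mirror-image walls pool to a symmetric distribution
  set.seed(52)
  n <- 5000
  ct <- runif(n, 0.2, 1) # bonds tilted toward the lower inward normal
  phi <- runif(n, -pi, pi)
  st <- sqrt(1 - ct^2)
  mk <- function(sign) {
    b <- array(0, c(1, n, 3))
    b[1, , 1] <- st * cos(phi); b[1, , 2] <- st * sin(phi)
    b[1, , 3] <- sign * ct
    b
  }
  bb <- array(0, c(1, 2 * n, 3))
  bb[1, 1:n, ] <- mk(+1)[1, , ]        # at the lower wall
  bb[1, (n + 1):(2 * n), ] <- mk(-1)[1, , ] # mirrored, at the upper wall
  lab2 <- matrix(c(rep("lower", n), rep("upper", n)), 1)
  d2 <- cosThetaDistribution(bb, lab2, nBins = 20)
  expect_equal(d2@wallDensity["lower", ], d2@wallDensity["upper", ],
               tolerance = 1e-12)
})

test_that("phi distribution realizes the documented frame convention", {
  g <- slitGeometry() # normal z, chain y; b = n x c = -x
  ## in-plane bond at +45 deg from the chain axis
  u <- c(-1, 1, 0) / sqrt(2) # c-component 1/sqrt2, b-component 1/sqrt2
  b <- array(rep(u, each = 1), c(1, 1, 3))
  dLow <- phiDistribution(b, "lower", g)
  expect_equal(dLow@means[["pooled"]], 45, tolerance = 1e-9)

  ## same bond at the second wall: parallel keeps +45, antiparallel
  ## mirrors the frame and reverses the sign
  dUpPar <- phiDistribution(b, "upper", g)
  expect_equal(dUpPar@means[["pooled"]], 45, tolerance = 1e-9)
  gA <- slitGeometry(arrangement = "antiparallel")
  dUpAnti <- phiDistribution(b, "upper", gA)
  expect_equal(dUpAnti@means[["pooled"]], -45, tolerance = 1e-9)
  ## lower wall unaffected by the arrangement
  expect_equal(phiDistribution(b, "lower", gA)@means[["pooled"]], 45,
               tolerance = 1e-9)

  ## bonds parallel to the normal are skipped and counted
  bz <- array(rep(c(0, 0, 1), each = 1), c(1, 1, 3))
  dz <- phiDistribution(bz, "lower", g)
  expect_equal(dz@nSkipped, 1L)
})

test_that("phi sign reverses under the antiparallel arrangement", {
  ## a peaked fixture at +60 deg sitting at the upper wall
  set.seed(53)
  n <- 4000
  phi0 <- (60 + rnorm(n, 0, 5)) * pi / 180
  b <- array(0, c(1, n, 3))
  g <- slitGeometry()
  ## construct in the global frame: u = cos(phi) c + sin(phi) (n x c)
  b[1, , 2] <- cos(phi0)         # chain = y
  b[1, , 1] <- -sin(phi0)        # n x c = z x y = -x
  dPar <- phiDistribution(b, "upper", g)
  dAnti <- phiDistribution(b, "upper",
                           slitGeometry(arrangement = "antiparallel"))
  expect_lt(abs(dPar@means[["pooled"]] - 60), 1)
  expect_lt(abs(dAnti@means[["pooled"]] + 60), 1)
  ## the full histograms are mirror images
  expect_equal(dAnti@density, rev(dPar@density), tolerance = 1e-12)
})

test_that("density profiles recover closed-form and generated structure", {
  ## uniform slab of N molecules -> flat profile at N M_w / V
  sp <- orientedFrameSpec(layerCenters = 1.5, layerWidths = 50,
                          normalExtent = 3, boxLateral = 4,
                          nMolecules = 3000L, nFrames = 5L, seed = 54L)
  g <- genOrientedFrames(sp)
  prof <- densityProfile(g$traj, g$topology, binWidth = 0.1,
                         kind = "mass", range = c(0, 3))
  expected <- 3000 * 18.0154 / (4 * 4 * 3) * 1.66053907
  inner <- prof@binCenters > 0.2 & prof@binCenters < 2.8
  expect_lt(max(abs(prof@density[inner] - expected)) / expected, 0.1)

  ## halving the bin width conserves the profile integral
  p1 <- densityProfile(g$traj, g$topology, binWidth = 0.05, kind = "mass",
                       range = c(-0.1, 3.1))
  p2 <- densityProfile(g$traj, g$topology, binWidth = 0.025, kind = "mass",
                       range = c(-0.1, 3.1))
  expect_equal(sum(p1@density) * 0.05, sum(p2@density) * 0.025,
               tolerance = 1e-10)

  ## number density counts molecules at the oxygen position
  pn <- densityProfile(g$traj, g$topology, binWidth = 0.1, kind = "number",
                       range = c(0, 3))
  expect_equal(sum(pn@density) * 0.1 * 16, 3000, tolerance = 1e-9)
})

test_that("average slit density is exact arithmetic and scale-invariant", {
  mkSlab <- function(nMol, L, A = 16) {
    sp <- orientedFrameSpec(layerCenters = L / 2, layerWidths = 10 * L,
                            normalExtent = L, boxLateral = sqrt(A),
                            nMolecules = as.integer(nMol), nFrames = 2L,
                            seed = 55L)
    genOrientedFrames(sp)
  }
  g <- mkSlab(400, 1)
  rho <- averageSlitDensity(g$traj, g$topology, L = 1)
  expect_equal(rho, 400 * 18.0154 / 16 * 1.66053907, tolerance = 1e-6)
  ## doubling N doubles the density
  g2 <- mkSlab(800, 1)
  expect_equal(averageSlitDensity(g2$traj, g2$topology, L = 1), 2 * rho,
               tolerance = 1e-6)
  ## missing L is an instructive error
  expect_error(averageSlitDensity(g$traj, g$topology), "fitConfinement")

  ## bulk-water-like loading: N = 997 A L / (M_w amu2kg) within 1%
  L <- 3; A <- 16
  N <- round(997 * A * L / (18.0154 * 1.66053907))
  g3 <- mkSlab(N, L)
  expect_lt(abs(averageSlitDensity(g3$traj, g3$topology, L = L) - 997) /
              997, 0.01)

  ## invariant to rigid translation along the normal and to wrapping state
  tr <- g$traj
  co <- coords(tr); co[, , 3] <- co[, , 3] + 2
  bd <- boxDims(tr); bd[, 3] <- bd[, 3] + 2
  trShift <- trajectory(frameTimes(tr), co, bd)
  expect_equal(averageSlitDensity(trShift, g$topology, L = 1),
               averageSlitDensity(g$traj, g$topology, L = 1),
               tolerance = 1e-12)
})
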