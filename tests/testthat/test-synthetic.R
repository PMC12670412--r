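test_that("free Brownian generator has exact increment statistics", {
  ## D = 0 -> all particles static
  p0 <- slitBrownianParams(dPar = 0, dPerp = 0, lTrue = 1,
                           nParticles = 20L, dt = 0.1, nSteps = 50L,
                           seed = 2L)
  tr0 <- genFreeBrownian(p0)
  expect_equal(max(abs(apply(coords(tr0), 2:3, sd))), 0)

  ## single-step z-increment variance ~ 2 D dt within 3 standard errors
  n <- 1e5
  D <- 1e-3; dt <- 0.1
  p <- slitBrownianParams(dPar = D, dPerp = D, lTrue = 1,
                          nParticles = as.integer(n), dt = dt, nSteps = 1L,
                          seed = 3L)
  tr <- genFreeBrownian(p)
  dz <- coords(tr)[2, , 3] - coords(tr)[1, , 3]
  v <- var(dz)
  seV <- sqrt(2 / (n - 1)) * v
  expect_lt(abs(v - 2 * D * dt), 3 * seV)

  ## determinism: same seed -> identical trajectories
  tr2 <- genFreeBrownian(p)
  expect_identical(coords(tr), coords(tr2))
})

test_that("slit Brownian motion stays confined with uniform stationary law", {
  L <- 0.8
  p <- slitBrownianParams(dPar = 1e-3, dPerp = 1e-3, lTrue = L,
                          nParticles = 500L, dt = 0.5, nSteps = 2000L,
                          seed = 4L)
  tr <- genSlitBrownian(p)
  z <- coords(tr)[, , 3]
  expect_gte(min(z), 0)
  expect_lte(max(z), L)
  ## chi-square uniformity over 20 bins; 10^6 independent samples from a
  ## single propagation step (the folding map preserves the uniform law
  ## exactly; long-run frames are autocorrelated, so use iid samples here)
  p1 <- slitBrownianParams(dPar = 1e-3, dPerp = 1e-3, lTrue = L,
                           nParticles = 1000000L, dt = 5, nSteps = 1L,
                           seed = 14L)
  z1 <- coords(suppressWarnings(genSlitBrownian(p1)))[2, , 3]
  h <- hist(z1, breaks = seq(0, L, length.out = 21), plot = FALSE)
  expect_gt(chisq.test(h$counts)$p.value, 0.01)
  ## weakly correlated long-run frames stay uniform too
  zs <- z[seq(1, nrow(z), by = 400), ]
  h2 <- hist(zs, breaks = seq(0, L, length.out = 11), plot = FALSE)
  expect_gt(chisq.test(h2$counts)$p.value, 0.001)
  ## long-time displacement plateau ~ L^2/6 (variance of the difference
  ## of two independent uniforms)
  lagF <- 1500
  d2 <- (z[1 + lagF, ] - z[1, ])^2
  expect_lt(abs(mean(d2) - L^2 / 6),
            3 * sd(d2) / sqrt(length(d2)) + 0.01 * L^2 / 6)
  ## lateral MSD slope / 2 ~ dPar (Einstein relation)
  un <- unwrapLateral(tr)
  m <- computeMSD(un, maxLag = 400)
  f <- fitParallelD(m)
  expect_lt(abs(f@composite - 1e-3) / 1e-3, 0.1)
  ## too-coarse dt is rejected
  expect_error(
    suppressWarnings(genSlitBrownian(
      slitBrownianParams(dPerp = 10, lTrue = 0.2, dt = 1, nSteps = 10L))),
    "coarse")
})

test_that("isotropic rotor reproduces the exp(-6 D_r t) P2 decay", {
  dR <- 0.01
  p <- rotorParams("isotropic", dR = dR, nRotors = 400L, nSteps = 6000L,
                   seed = 5L, saveStride = 4L)
  b <- genRotor(p)
  nrm <- sqrt(b[, , 1]^2 + b[, , 2]^2 + b[, , 3]^2)
  expect_lt(max(abs(nrm - 1)), 1e-12)
  r <- computeRACF(b, maxLag = 200)
  sel <- r@lags <= 50
  expect_lt(max(abs(r@acf[sel] - exp(-6 * dR * r@lags[sel]))), 0.03)
  ## determinism
  b2 <- genRotor(p)
  expect_identical(b, b2)
})

test_that("cone rotor realizes the wobbling-in-a-cone order parameter", {
  ## theta_c -> 0: vectors frozen, C identically 1
  pf <- rotorParams("cone", dR = 0.05, coneHalfAngle = 1e-4,
                    nRotors = 50L, nSteps = 200L, seed = 6L)
  bf <- genRotor(pf)
  rf <- computeRACF(bf, maxLag = 50)
  expect_equal(rf@acf, rep(1, 51), tolerance = 1e-6)

  ## closed-form half-angle inversion
  expect_equal(coneOrderParameter(coneHalfAngleFromS(0.8)), 0.8,
               tolerance = 1e-12)

  ## time-averaged P2 about the axis is consistent with the S^2 plateau
  a <- coneHalfAngleFromS(0.8)
  p <- rotorParams("cone", dR = 0.05, coneHalfAngle = a, dt = 0.02,
                   nRotors = 500L, nSteps = 8000L, seed = 7L,
                   saveStride = 8L)
  b <- genRotor(p)
  r <- computeRACF(b, maxLag = 450)
  tailC <- mean(r@acf[r@lags >= 6])  # > several tau_c for this rotor
  expect_equal(sqrt(tailC), 0.8, tolerance = 0.03)
})

test_that("synthRacf evaluates the stretched-exponential model exactly", {
  r <- synthRacf(tau = 50, beta = 1, S = 0, times = c(0, 50, 1e6))
  expect_equal(r@acf, c(1, exp(-1), 0), tolerance = 1e-12)
  r2 <- synthRacf(tau = 10, beta = 0.5, S = 0.6, times = c(0, 1e8))
  expect_equal(r2@acf[2], 0.36, tolerance = 1e-9) # plateau S^2
  ## noise-free curves are monotone non-increasing
  r3 <- synthRacf(3, 0.7, 0.2, times = seq(0, 100, by = 0.5))
  expect_true(all(diff(r3@acf) <= 0))
})

test_that("oriented-frame generator reproduces its targets", {
  ## single sharp layer at the midplane -> all molecules near the center
  sp <- orientedFrameSpec(layerCenters = 0.5, layerWidths = 1e-4,
                          normalExtent = 1, nMolecules = 200L,
                          nFrames = 2L, seed = 8L)
  g <- genOrientedFrames(sp)
  zo <- coords(g$traj)[, g$topology@oIndex, 3]
  expect_lt(max(abs(zo - 0.5)), 1e-3)

  ## two-layer mixture -> density profile peaks at the specified centers
  sp2 <- orientedFrameSpec(layerCenters = c(0.3, 0.9),
                           layerWidths = c(0.04, 0.04),
                           layerWeights = c(0.5, 0.5), normalExtent = 1.2,
                           nMolecules = 4000L, nFrames = 4L, seed = 9L)
  g2 <- genOrientedFrames(sp2)
  prof <- densityProfile(g2$traj, g2$topology, binWidth = 0.02,
                         kind = "number", range = c(0, 1.2))
  pk <- prof@binCenters[order(prof@density, decreasing = TRUE)[1:8]]
  expect_lt(min(abs(pk - 0.3)), 0.021)
  expect_lt(min(abs(pk - 0.9)), 0.021)

  ## uniform angular targets -> flat recovered histograms
  sp3 <- orientedFrameSpec(layerCenters = 0.5, layerWidths = 0.2,
                           normalExtent = 1, nMolecules = 20000L,
                           nFrames = 1L, seed = 10L)
  g3 <- genOrientedFrames(sp3)
  lab <- assignNearestSurface(coords(g3$traj)[, g3$topology@oIndex, 3],
                              slitGeometry(wallLo = 0, wallHi = 1))
  ct <- cosThetaDistribution(g3$bonds, lab)
  ph <- phiDistribution(g3$bonds, lab)
  expect_gt(chisq.test(ct@counts)$p.value, 0.01)
  expect_gt(chisq.test(ph@counts)$p.value, 0.01)
  expect_lt(abs(ct@means[["pooled"]]), 4 / sqrt(3 * 40000))
  expect_lt(abs(ph@means[["pooled"]]), 4 * 180 / sqrt(3 * 40000))
})
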