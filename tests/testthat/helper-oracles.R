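# Independent reference implementations used to validate the package's
# estimators. These deliberately use the slowest, most literal formulation
# of each quantity.

# Brute-force MSD: double loop over lags and time origins.
oracleMSD <- function(X, maxLag, originStride = 1L) {
  N <- nrow(X)
  vapply(0:maxLag, function(m) {
    or <- seq(1L, N - m, by = originStride)
    mean((X[or + m, , drop = FALSE] - X[or, , drop = FALSE])^2)
  }, numeric(1))
}

# Brute-force P2 RACF: loops over lags, origins and bonds.
oracleRACF <- function(bonds, maxLag) {
  N <- dim(bonds)[1]
  B <- dim(bonds)[2]
  vapply(0:maxLag, function(m) {
    tot <- 0
    for (o in seq_len(N - m)) {
      for (b in seq_len(B)) {
        d <- sum(bonds[o, b, ] * bonds[o + m, b, ])
        tot <- tot + (3 * d^2 - 1) / 2
      }
    }
    tot / ((N - m) * B)
  }, numeric(1))
}

# Crank-Nicolson solution of the reflecting-wall diffusion problem.
# Uses the identity msd(t) = 2<z^2>_unif - 2 E[z0 h(z0,t)] where
# h solves the heat equation with h(z,0) = z and Neumann (reflecting)
# boundaries, evaluated on a cell-centered grid; Richardson extrapolation
# in (dz, dt) jointly raises the O(h^2) scheme to O(h^4).
cnReflectedMSDOnce <- function(L, D, tEnd, M, Nt) {
  dz <- L / M
  z <- (seq_len(M) - 0.5) * dz
  dt <- tEnd / Nt
  r <- D * dt / (2 * dz^2)
  main <- rep(1 + 2 * r, M); main[1] <- main[M] <- 1 + r
  off <- rep(-r, M - 1)
  Bmain <- rep(1 - 2 * r, M); Bmain[1] <- Bmain[M] <- 1 - r
  Boff <- rep(r, M - 1)
  A <- Matrix::bandSparse(M, k = c(-1, 0, 1),
                          diagonals = list(off, main, off))
  fac <- Matrix::lu(A)
  h <- z
  for (s in seq_len(Nt)) {
    rhs <- Bmain * h
    rhs[-M] <- rhs[-M] + Boff * h[-1]
    rhs[-1] <- rhs[-1] + Boff * h[-M]
    h <- as.numeric(Matrix::solve(fac, rhs))
  }
  2 * sum(z^2) * dz / L - 2 * (dz / L) * sum(z * h)
}

cnReflectedMSD <- function(L, D, tEnd, M = 1200, Nt = 1200) {
  e1 <- cnReflectedMSDOnce(L, D, tEnd, M, Nt)
  e2 <- cnReflectedMSDOnce(L, D, tEnd, 2 * M, 2 * Nt)
  (4 * e2 - e1) / 3
}

# Plain-R Monte Carlo estimate of the reflected-Brownian MSD at a single
# lag: walkers start uniform, take Gaussian steps, and are folded back
# into [0, L].
mcReflectedMSD <- function(L, D, tEnd, nWalkers, nSteps = 50L) {
  dt <- tEnd / nSteps
  z0 <- runif(nWalkers, 0, L)
  z <- z0
  fold <- function(z) {
    z <- z %% (2 * L)
    ifelse(z > L, 2 * L - z, z)
  }
  for (s in seq_len(nSteps)) z <- fold(z + rnorm(nWalkers, 0, sqrt(2 * D * dt)))
  d2 <- (z - z0)^2
  list(msd = mean(d2), se = sd(d2) / sqrt(nWalkers))
}

# Small deterministic trajectory helper for I/O and estimator tests.
randomTrajectory <- function(nFrames, nParticles, box = c(4, 4, 4),
                             seed = 1) {
  set.seed(seed)
  co <- array(runif(nFrames * nParticles * 3, 0, min(box)),
              c(nFrames, nParticles, 3))
  trajectory(times = seq_len(nFrames) - 1, coords = co, box = box,
             lateralUnwrapped = TRUE)
}
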