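#' @include AllClasses.R
NULL

## FFT-based sum of lagged products S2[m] = sum_k x_k x_{k+m} for all
## columns of X at once; returns [maxLag+1, ncol(X)].
.laggedProducts <- function(X, maxLag) {
  N <- nrow(X)
  nfft <- nextn(2L * N, c(2, 3, 5))
  Xp <- rbind(X, matrix(0, nfft - N, ncol(X)))
  F <- mvfft(Xp)
  ac <- Re(mvfft(F * Conj(F), inverse = TRUE))[seq_len(maxLag + 1L), ,
                                               drop = FALSE] / nfft
  ac
}

## MSD over all time origins for one coordinate matrix [N frames, P
## particles]; returns the particle-summed (not averaged) MSD numerators
## and the per-lag origin count, using the standard FFT decomposition
## msd(m) = S1(m) - 2 S2(m).
.msdFFTComponent <- function(X, maxLag, chunk = 256L) {
  N <- nrow(X); P <- ncol(X)
  s1 <- numeric(maxLag + 1L)
  s2 <- numeric(maxLag + 1L)
  for (start in seq(1L, P, by = chunk)) {
    cols <- start:min(P, start + chunk - 1L)
    Xi <- X[, cols, drop = FALSE]
    D <- Xi^2
    sd0 <- colSums(D)
    csFirst <- apply(D, 2, cumsum)                       # sum of first m
    csLast <- apply(D[N:1, , drop = FALSE], 2, cumsum)   # sum of last m
    m <- seq_len(maxLag)
    ## S1(m) = 2*sum(D) - (first m) - (last m), summed over particles
    s1[1] <- s1[1] + sum(sd0) * 2 - 0
    s1[m + 1L] <- s1[m + 1L] + 2 * sum(sd0) -
      rowSums(csFirst[m, , drop = FALSE]) -
      rowSums(csLast[m, , drop = FALSE])
    s2 <- s2 + rowSums(.laggedProducts(Xi, maxLag))
  }
  num <- s1 - 2 * s2
  num[1] <- 0 # lag zero, exactly
  list(num = num, nOrigins = N - 0:maxLag)
}

## Direct (strided-origin) estimator for one coordinate matrix.
.msdDirectComponent <- function(X, maxLag, originStride) {
  N <- nrow(X)
  num <- numeric(maxLag + 1L)
  nOr <- integer(maxLag + 1L)
  nOr[1] <- length(seq(1L, N, by = originStride))
  for (m in seq_len(maxLag)) {
    or <- seq(1L, N - m, by = originStride)
    d <- X[or + m, , drop = FALSE] - X[or, , drop = FALSE]
    num[m + 1L] <- sum(d * d)
    nOr[m + 1L] <- length(or)
  }
  list(num = num, nOrigins = nOr)
}

#' Component-resolved mean-square displacement
#'
#' Averages squared displacements over all particles and over time origins
#' (all origins for `originStride = 1`, a strided subset otherwise) for the
#' three coordinate axes separately. Lateral components require a
#' laterally unwrapped trajectory; the normal-axis component is computed
#' on the raw (wrapped-free, never unwrapped) coordinates, which is what
#' the reflecting-wall analysis assumes.
#'
#' @param traj a [Trajectory-class]; must be laterally unwrapped (see
#'   [unwrapLateral()]) and uniformly sampled in time.
#' @param geom a [SlitGeometry-class] identifying the normal axis.
#' @param maxLag maximum lag in frames; defaults to half the trajectory.
#' @param originStride origin subsampling stride in frames (1 = all
#'   origins).
#' @param method `"fft"` (O(N log N), all origins) or `"direct"`. The FFT
#'   path requires `originStride = 1`.
#' @param nBlocks in addition to the pooled MSD, store MSDs over this many
#'   disjoint particle blocks (for honest fit uncertainties; 0 disables,
#'   and fewer blocks are used when there are fewer particles).
#' @return an [MSDResult-class].
#' @export
computeMSD <- function(traj, geom = slitGeometry(),
                       maxLag = (nFrames(traj) - 1L) %/% 2L,
                       originStride = 1L, method = c("fft", "direct"),
                       nBlocks = 8L) {
  method <- match.arg(method)
  N <- nFrames(traj)
  if (N < 2L) stop("at least 2 frames required")
  dts <- diff(traj@times)
  if (max(abs(dts - dts[1])) > 1e-8 * dts[1])
    stop("non-uniform frame spacing")
  if (maxLag >= N) stop("maxLag must be smaller than the trajectory length")
  if (maxLag < 1L) stop("maxLag must be >= 1")
  if (!traj@lateralUnwrapped)
    stop("trajectory must be laterally unwrapped for lateral MSD ",
         "components; call unwrapLateral() first")
  if (method == "fft" && originStride != 1L)
    stop("originStride > 1 requires method = 'direct'")
  P <- nParticles(traj)
  nBlocks <- min(as.integer(nBlocks), P)
  blockOf <- if (nBlocks > 1L)
    as.integer(cut(seq_len(P), nBlocks, labels = FALSE)) else rep(1L, P)
  msd <- matrix(NA_real_, maxLag + 1L, 3L, dimnames = list(NULL, .AXES))
  blockMsd <- array(NA_real_, c(maxLag + 1L, 3L, max(nBlocks, 0L)))
  nOr <- NULL
  for (ax in 1:3) {
    X <- traj@coords[, , ax, drop = FALSE]
    dim(X) <- dim(traj@coords)[1:2]
    tot <- numeric(maxLag + 1L)
    for (b in seq_len(max(nBlocks, 1L))) {
      Xb <- X[, blockOf == b, drop = FALSE]
      comp <- if (method == "fft") .msdFFTComponent(Xb, maxLag)
              else .msdDirectComponent(Xb, maxLag, as.integer(originStride))
      tot <- tot + comp$num
      if (nBlocks > 1L)
        blockMsd[, ax, b] <- comp$num / (ncol(Xb) * comp$nOrigins)
      nOr <- comp$nOrigins
    }
    msd[, ax] <- tot / (P * nOr)
  }
  msd[msd < 0] <- 0 # guard against FFT round-off at machine precision
  if (nBlocks <= 1L) blockMsd <- array(numeric(0), c(0L, 3L, 0L))
  else blockMsd[blockMsd < 0] <- 0
  new("MSDResult", lags = 0:maxLag * dts[1], msd = msd,
      nOrigins = as.integer(nOr), dt = dts[1], blockMsd = blockMsd)
}

#' Einstein-relation fit of parallel diffusion coefficients
#'
#' Fits `msd = 2 D t (+ intercept)` by least squares over a lag window for
#' each lateral component. The default window spans 10% to 50% of the
#' maximum lag, additionally skipping lags below 2 ps (ballistic/collision
#' times in MD data); it is reported in the result and fully
#' configurable.
#'
#' @param msd an [MSDResult-class].
#' @param geom a [SlitGeometry-class]; the two non-normal axes are fitted.
#' @param window `c(min, max)` lag window \[ps\], or `NULL` for the
#'   default.
#' @param average `"fit-then-average"` (default: fit each lateral axis,
#'   then average D) or `"average-then-fit"` (average the two lateral MSDs
#'   first; both slots of the result then carry the common fit).
#' @return an [EinsteinFit-class]. Negative fitted slopes are clipped to 0
#'   with a warning and flagged in the `clipped` slot.
#' @examples
#' lag <- 0:100
#' m <- new("MSDResult", lags = as.numeric(lag),
#'          msd = cbind(x = 2 * 0.00295 * lag, y = 2 * 0.00295 * lag,
#'                      z = 0 * lag),
#'          nOrigins = rep(1000L, 101), dt = 1)
#' fitParallelD(m)
#' @export
fitParallelD <- function(msd, geom = slitGeometry(), window = NULL,
                         average = c("fit-then-average",
                                     "average-then-fit")) {
  average <- match.arg(average)
  lat <- lateralAxes(geom)
  maxLag <- max(msd@lags)
  if (is.null(window))
    window <- c(max(2, 0.1 * maxLag), 0.5 * maxLag)
  sel <- msd@lags >= window[1] & msd@lags <= window[2]
  if (sum(sel) < 5L) stop("fit window must contain at least 5 lags")
  t <- msd@lags[sel]
  nb <- if (length(msd@blockMsd)) dim(msd@blockMsd)[3] else 0L
  fitOne <- function(y) {
    fit <- lm(y ~ t)
    sm <- suppressWarnings(summary(fit)) # noise-free input is legitimate
    slope <- coef(fit)[["t"]]
    list(D = slope / 2, seOLS = sm$coefficients["t", "Std. Error"] / 2,
         r2 = sm$r.squared)
  }
  ## block-scatter standard error: MSD residuals are correlated across
  ## lags, so the OLS slope error is optimistic; disjoint particle blocks
  ## are independent and give an honest scatter of the fitted D
  blockSE <- function(ys) { # ys: [nLagSel, nBlocks]
    Ds <- apply(ys, 2, function(y) fitOne(y)$D)
    sd(Ds) / sqrt(length(Ds))
  }
  clipped <- FALSE
  if (average == "average-then-fit") {
    f <- fitOne(rowMeans(msd@msd[sel, lat, drop = FALSE]))
    se1 <- if (nb >= 2)
      blockSE((msd@blockMsd[sel, axisIndex(lat[1]), ] +
                 msd@blockMsd[sel, axisIndex(lat[2]), ]) / 2)
    else f$seOLS
    fits <- list(f, f)
    se <- c(se1, se1)
  } else {
    fits <- lapply(lat, function(ax) fitOne(msd@msd[sel, ax]))
    se <- vapply(seq_along(lat), function(k) {
      if (nb >= 2) blockSE(msd@blockMsd[sel, axisIndex(lat[k]), ])
      else fits[[k]]$seOLS
    }, numeric(1))
  }
  D <- vapply(fits, `[[`, numeric(1), "D")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  if (any(D < 0)) {
    warning("negative fitted slope clipped to 0; MSD not diffusive ",
            "over the chosen window")
    D[D < 0] <- 0
    clipped <- TRUE
  }
  names(D) <- names(se) <- names(r2) <- lat
  combSE <- sqrt(sum(se^2)) / 2
  new("EinsteinFit", dPar = D, dParSE = se, composite = mean(D),
      compositeSE = combSE, window = window, r2 = r2,
      discrepant = isTRUE(abs(diff(D)) > 3 * sqrt(sum(se^2))),
      clipped = clipped)
}

#' Composite parallel diffusion coefficient
#'
#' The unweighted mean of the two lateral components, flagging the pair as
#' discrepant when they differ by more than 3 combined standard errors.
#'
#' @param fit an [EinsteinFit-class].
#' @return named list with `D` \[nm^2/ps\], `D_m2s` \[m^2/s\], `se`, and
#'   `discrepant`.
#' @export
compositeParallelD <- function(fit) {
  list(D = fit@composite, D_m2s = nm2psToM2s(fit@composite),
       se = fit@compositeSE, discrepant = fit@discrepant)
}

#' Write an MSD table as CSV
#'
#' Columns `lag_ps,msd_x_nm2,msd_y_nm2,msd_z_nm2,n_origins`.
#'
#' @param path output path.
#' @param msd an [MSDResult-class].
#' @return `path`, invisibly.
#' @export
writeMSD <- function(path, msd) {
  write.csv(as.data.frame(msd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
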