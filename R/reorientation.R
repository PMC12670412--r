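#' @include AllClasses.R
NULL

#' Second Legendre polynomial
#'
#' `P2(x) = (3 x^2 - 1) / 2`.
#'
#' @param x numeric.
#' @return numeric.
#' @export
legendreP2 <- function(x) (3 * x^2 - 1) / 2

## <(u(t0) . u(t0+t))^2> for one bond via FFT: expand the squared dot
## product into correlations of the six quadratic components
## (xx, yy, zz with weight 1; xy, xz, yz with weight 2).
.racfFFT <- function(bonds, maxLag, chunk = 200L) {
  N <- dim(bonds)[1]; B <- dim(bonds)[2]
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  w <- c(1, 1, 1, 2, 2, 2)
  tot <- numeric(maxLag + 1L)
  for (start in seq(1L, B, by = chunk)) {
    cols <- start:min(B, start + chunk - 1L)
    for (k in seq_along(pairs)) {
      q <- bonds[, cols, pairs[[k]][1], drop = FALSE] *
        bonds[, cols, pairs[[k]][2], drop = FALSE]
      dim(q) <- c(N, length(cols))
      tot <- tot + w[k] * rowSums(.laggedProducts(q, maxLag))
    }
  }
  tot / (B * (N - 0:maxLag))
}

.racfDirect <- function(bonds, maxLag, originStride) {
  N <- dim(bonds)[1]
  C2 <- numeric(maxLag + 1L)
  nOr <- integer(maxLag + 1L)
  for (m in 0:maxLag) {
    or <- seq(1L, N - m, by = originStride)
    d <- bonds[or, , 1, drop = FALSE] * bonds[or + m, , 1, drop = FALSE] +
      bonds[or, , 2, drop = FALSE] * bonds[or + m, , 2, drop = FALSE] +
      bonds[or, , 3, drop = FALSE] * bonds[or + m, , 3, drop = FALSE]
    C2[m + 1L] <- mean(d^2)
    nOr[m + 1L] <- length(or)
  }
  list(C2 = C2, nOrigins = nOr)
}

#' P2 rotational autocorrelation function
#'
#' `C(t) = < P2( u(t0) . u(t0 + t) ) >`, averaged over all time origins
#' (or a strided subset) and over all bond vectors — both O-H bonds of
#' every molecule are pooled when the input comes from [bondVectors()].
#'
#' @param bonds unit-vector array `[nFrames, nBonds, 3]`, uniformly spaced
#'   in time, with frame times in attribute `times` (or supply `dt`).
#' @param maxLag maximum lag in frames.
#' @param originStride origin stride (1 = all origins; > 1 forces the
#'   direct estimator).
#' @param dt frame spacing \[ps\]; taken from `attr(bonds, "times")` when
#'   missing.
#' @param method `"fft"` or `"direct"`.
#' @return an [RACFResult-class].
#' @export
computeRACF <- function(bonds, maxLag = (dim(bonds)[1] - 1L) %/% 2L,
                        originStride = 1L, dt = NULL,
                        method = c("fft", "direct")) {
  method <- match.arg(method)
  N <- dim(bonds)[1]
  if (is.null(N) || length(dim(bonds)) != 3L)
    stop("bonds must be an [nFrames, nBonds, 3] array")
  if (N < 2L) stop("at least 2 frames required")
  if (is.null(dt)) {
    tm <- attr(bonds, "times")
    if (is.null(tm)) stop("supply dt or a 'times' attribute")
    d <- diff(tm)
    if (max(abs(d - d[1])) > 1e-8 * d[1])
      stop("non-uniform frame spacing")
    dt <- d[1]
  }
  if (maxLag >= N || maxLag < 1L) stop("maxLag out of range")
  nrm2 <- bonds[, , 1]^2 + bonds[, , 2]^2 + bonds[, , 3]^2
  if (max(abs(nrm2 - 1)) > 1e-6)
    stop("bond vectors must be unit length")
  if (method == "fft" && originStride == 1L) {
    C2 <- .racfFFT(bonds, maxLag)
    nOr <- as.integer(N - 0:maxLag)
  } else {
    r <- .racfDirect(bonds, maxLag, as.integer(originStride))
    C2 <- r$C2
    nOr <- r$nOrigins
  }
  C <- 1.5 * C2 - 0.5
  C[1] <- 1 # exact at lag 0 for unit vectors
  new("RACFResult", lags = 0:maxLag * dt, acf = pmin(pmax(C, -1), 1),
      nOrigins = nOr, nBonds = dim(bonds)[2])
}

#' Fit a stretched-exponential plus order-parameter model to an RACF
#'
#' Least squares of `C(t) = S^2 + (1 - S^2) exp(-(t/tau)^beta)` with
#' bounded Levenberg-Marquardt. `S` is parameterized directly (the plateau
#' is `S^2`), so the reported order parameter is the positive square root
#' of the fitted plateau.
#'
#' Initialization: `S^2` from the mean of the last 10% of lags, `tau` from
#' the lag where `C` first crosses `S^2 + (1 - S^2)/e`, `beta = 0.8`. The
#' lag grid is log-spaced subsampled before fitting so the plateau does
#' not dominate the objective; set `nFitPoints = Inf` to fit every lag.
#'
#' @param racf an [RACFResult-class].
#' @param bounds named list overriding the default box constraints
#'   `tau = c(dt, 1e3 * maxLag)`, `beta = c(0.1, 1)`, `S = c(0, 0.999)`.
#' @param init optional named vector/list with `tau`, `beta`, `S`.
#' @param nFitPoints number of log-spaced lags used in the fit.
#' @return a [StretchedExpFit-class]. An error is raised when the curve
#'   shows no decay.
#' @examples
#' r <- synthRacf(100, 0.6, 0.8, times = exp(seq(log(0.1), log(5000),
#'                                               length.out = 150)))
#' fitStretchedExp(r)
#' @export
fitStretchedExp <- function(racf, bounds = list(), init = NULL,
                            nFitPoints = 200L) {
  lags <- racf@lags
  C <- racf@acf
  if (all(C > 0.99))
    stop("degenerate fit: C(t) shows no decay")
  pos <- which(lags > 0)
  dtMin <- min(lags[pos])
  maxLag <- max(lags)
  b <- list(tau = c(dtMin, 1e3 * maxLag), beta = c(0.1, 1),
            S = c(0, 0.999))
  b[names(bounds)] <- bounds
  ## log-spaced subsample of the positive lags (+ lag 0)
  if (is.finite(nFitPoints) && length(pos) > nFitPoints) {
    li <- exp(seq(log(min(pos)), log(max(pos)), length.out = nFitPoints))
    sel <- sort(unique(c(1L, as.integer(round(li)))))
  } else sel <- seq_along(lags)
  tF <- lags[sel]; yF <- C[sel]
  if (is.null(init)) {
    nTail <- max(1L, ceiling(0.1 * length(lags)))
    S2 <- mean(tail(C, nTail))
    S0 <- sqrt(max(min(S2, 0.998^2), 0))
    thr <- S0^2 + (1 - S0^2) / exp(1)
    below <- which(C < thr)
    tau0 <- if (length(below)) max(lags[below[1]], dtMin) else maxLag / 2
    init <- c(tau = tau0, beta = 0.8, S = max(min(S0, b$S[2]), b$S[1]))
  }
  clamp <- function(v, r) max(min(v, r[2]), r[1])
  start <- list(tau = clamp(init[["tau"]], b$tau),
                beta = clamp(init[["beta"]], b$beta),
                S = clamp(init[["S"]], b$S))
  dat <- data.frame(tt = tF, yy = yF)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ S^2 + (1 - S^2) * exp(-(tt / tau)^beta), data = dat,
      start = start,
      lower = c(tau = b$tau[1], beta = b$beta[1], S = b$S[1]),
      upper = c(tau = b$tau[2], beta = b$beta[2], S = b$S[2]),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                          ptol = 1e-15)),
    error = function(e) stop("stretched-exponential fit failed: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se <- tryCatch(sqrt(pmax(diag(vcov(fit)), 0)),
                 error = function(e) rep(NA_real_, 3))
  model <- cf[["S"]]^2 + (1 - cf[["S"]]^2) *
    exp(-(tF / cf[["tau"]])^cf[["beta"]])
  new("StretchedExpFit", tau = cf[["tau"]],
      beta = min(cf[["beta"]], 1), S = cf[["S"]],
      tauSE = se[[1]], betaSE = se[[2]], SSE = se[[3]],
      residNorm = sqrt(sum((yF - model)^2)),
      plateauSampled = isTRUE(maxLag >= 5 * cf[["tau"]]))
}

#' Write an RACF as CSV (`lag_ps,C`)
#'
#' @param path output path.
#' @param racf an [RACFResult-class].
#' @return `path`, invisibly.
#' @export
writeRACF <- function(path, racf) {
  write.csv(data.frame(lag_ps = racf@lags, C = racf@acf), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write stretched-exponential fits as CSV
#'
#' Columns `system,tau_ps,beta,S,tau_se,beta_se,S_se`.
#'
#' @param path output path.
#' @param fits named list of [StretchedExpFit-class] objects.
#' @return `path`, invisibly.
#' @export
writeStretchedFits <- function(path, fits) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(system = nm, tau_ps = f@tau, beta = f@beta, S = f@S,
               tau_se = f@tauSE, beta_se = f@betaSE, S_se = f@SSE)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
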