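#' @include AllClasses.R
NULL

#' Restricted-diffusion MSD between reflecting walls
#'
#' Perpendicular mean-square displacement of a particle diffusing with
#' coefficient `Dperp` between two impenetrable reflecting walls separated
#' by `L`, starting from the uniform stationary distribution:
#'
#' \deqn{\langle z^2 \rangle(t) = \frac{L^2}{6}\left(1 -
#'   \frac{48}{\pi^4} \sum_{n\,\mathrm{odd}} \frac{2}{n^4}
#'   e^{-D_\perp n^2 \pi^2 t / L^2}\right)}
#'
#' Only odd terms contribute (the factor `1 - (-1)^n` vanishes for even
#' n). The 48/pi^4 prefactor is the unique constant for which the series
#' vanishes at t = 0, since the odd inverse fourth powers sum to pi^4/96.
#' The value grows monotonically from 0 to the plateau `L^2/6`.
#'
#' The series converges slowly as t -> 0; when more than `maxTerms` odd
#' terms would be needed for the requested tolerance, the short-time free
#' diffusion form `2 Dperp t` is used instead (the walls are not yet felt
#' at such times).
#'
#' @param t lag time(s) \[ps\], >= 0.
#' @param L wall separation \[nm\].
#' @param Dperp perpendicular diffusion coefficient \[nm^2/ps\].
#' @param tol series truncation: terms are added until the next term falls
#'   below `tol` times the plateau.
#' @param maxTerms maximum number of odd terms.
#' @return MSD value(s) \[nm^2\], with the maximum number of series terms
#'   used attached as attribute `nTerms`.
#' @examples
#' restrictedMSD(0, L = 1, Dperp = 1e-3)      # 0
#' restrictedMSD(1e6, L = 1, Dperp = 1e-3)    # ~ 1/6
#' @export
restrictedMSD <- function(t, L, Dperp, tol = 1e-12, maxTerms = 1e5) {
  stopifnot(L > 0, Dperp > 0, tol > 0, all(t >= 0))
  plateau <- L^2 / 6
  rate <- Dperp * pi^2 / L^2
  out <- numeric(length(t))
  nTermsMax <- 0L
  ## odd terms needed so that (96/pi^4) n^-4 exp(-rate n^2 t) < tol
  pref <- 96 / pi^4
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti == 0) { out[i] <- 0; next }
    ## conservative bound on the largest odd n required
    nReq <- if (rate * ti >= log(pref / tol)) 1
            else sqrt(log(pref / tol) / (rate * ti))
    if ((nReq + 1) / 2 > maxTerms) {
      ## extremely short time: series impractical, walls not yet felt
      out[i] <- 2 * Dperp * ti
      next
    }
    n <- seq(1, max(1, ceiling(nReq)) + 2, by = 2)
    terms <- exp(-rate * n^2 * ti) / n^4
    out[i] <- plateau * (1 - pref * sum(terms))
    nTermsMax <- max(nTermsMax, length(n))
  }
  out <- pmin(pmax(out, 0), plateau)
  attr(out, "nTerms") <- nTermsMax
  out
}

#' Jointly fit wall separation and perpendicular diffusion coefficient
#'
#' The central confinement estimator: nonlinear least squares of the
#' reflecting-wall restricted-diffusion model against the perpendicular
#' MSD, with `L` and `Dperp` treated as independent free parameters fitted
#' simultaneously. The long-time plateau identifies `L^2/6` regardless of
#' `Dperp`, while the initial rise constrains `Dperp`, which is why the
#' two estimates are nearly uncorrelated (see
#' [mcParameterCorrelation()]).
#'
#' Default initialization: `L0 = sqrt(6 * msd_z(maxlag))` from the plateau
#' and `D0` from the early-time slope (`msd_z ~ 2 Dperp t`). The fit uses
#' bounded Levenberg-Marquardt least squares with `L in (0, 10 L0]` and
#' `Dperp > 0`, over the full lag range by default.
#'
#' @param msdZ an [MSDResult-class] (its normal-axis component is used) or
#'   a data frame/list with elements `lags` and `msd`.
#' @param geom a [SlitGeometry-class] naming the normal axis.
#' @param init optional `c(L0, D0)` initial values.
#' @param lagRange optional `c(min, max)` lag window \[ps\] to fit over.
#' @return a [ConfinementFit-class]. If the MSD is still rising by more
#'   than 5% per decade at the longest lags, the plateau has not been
#'   sampled: a warning is emitted and the `noPlateau` flag set.
#' @export
fitConfinement <- function(msdZ, geom = slitGeometry(), init = NULL,
                           lagRange = NULL) {
  if (is(msdZ, "MSDResult")) {
    lags <- msdZ@lags
    y <- msdZ@msd[, geom@normalAxis]
  } else {
    lags <- msdZ$lags
    y <- msdZ$msd
  }
  keep <- !is.na(y)
  if (!is.null(lagRange))
    keep <- keep & lags >= lagRange[1] & lags <= lagRange[2]
  lags <- lags[keep]; y <- y[keep]
  if (length(lags) < 10L) stop("at least 10 lags required")
  tMax <- max(lags)
  hi <- y[which.min(abs(lags - tMax))]
  if (is.null(init)) {
    L0 <- sqrt(6 * hi)
    early <- which(lags > 0)[1:max(3L, min(5L, sum(lags > 0)))]
    early <- early[!is.na(early)]
    D0 <- max(mean(y[early] / (2 * lags[early])), 1e-12)
    init <- c(L0, D0)
  }
  dat <- data.frame(tt = lags, yy = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ restrictedMSD(tt, L, D), data = dat,
      start = list(L = init[1], D = init[2]),
      lower = c(L = init[1] * 1e-3, D = init[2] * 1e-6),
      upper = c(L = 10 * init[1], D = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                          ptol = 1e-15)),
    error = function(e) stop("confinement fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  corrLD <- if (all(is.finite(se)) && all(se > 0))
    vc[1, 2] / (se[1] * se[2]) else NA_real_
  model <- restrictedMSD(lags, cf[["L"]], cf[["D"]])
  ## no-plateau diagnostic: the fitted curve still rises by more than 5%
  ## per decade at the longest lag when tMax < ~5.5 relaxation times
  ## (d msd / d log10 t evaluated at tMax for the fitted model), or the
  ## optimizer ran into its upper L bound
  tauC <- cf[["L"]]^2 / (pi^2 * cf[["D"]])
  noPlateau <- isTRUE(tMax < 5.5 * tauC) ||
    cf[["L"]] >= 0.999 * 10 * init[1]
  if (noPlateau)
    warning("perpendicular MSD still rising by >5% per decade at the ",
            "longest lag; plateau not reached, L estimate unreliable")
  new("ConfinementFit", L = cf[["L"]], Dperp = cf[["D"]],
      LSE = se[1], DperpSE = se[2],
      corrLD = max(min(corrLD, 1), -1),
      residNorm = sqrt(sum((y - model)^2)),
      nTerms = attr(model, "nTerms"),
      converged = fit$convInfo$isConv %||% TRUE,
      noPlateau = noPlateau)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte Carlo correlation analysis of the (L, D_perp) fit
#'
#' Assesses the covariance of the two fitted parameters by refitting
#' resampled perpendicular-MSD curves: either residual resampling
#' (residuals of the converged fit are resampled with replacement and
#' added back to the fitted curve) or parametric noise (Gaussian noise
#' with the residual standard deviation). Returns the empirical
#' correlation of the replicate estimates with a Fisher-z confidence
#' interval.
#'
#' @param fit a converged [ConfinementFit-class].
#' @param msdZ the [MSDResult-class] (or `lags`/`msd` list) the fit was
#'   obtained from.
#' @param nRep number of replicates (>= 20).
#' @param seed RNG seed.
#' @param method `"residual"` (default) or `"parametric"`.
#' @param geom a [SlitGeometry-class].
#' @param level confidence level for the interval.
#' @return list with `correlation`, `ci` (length 2), `replicates` (data
#'   frame of L and Dperp), and `method`.
#' @export
mcParameterCorrelation <- function(fit, msdZ, nRep = 200L, seed = 1L,
                                   method = c("residual", "parametric"),
                                   geom = slitGeometry(), level = 0.95) {
  method <- match.arg(method)
  if (nRep < 20L) stop("nRep must be at least 20")
  if (!fit@converged) stop("fit must have converged")
  if (is(msdZ, "MSDResult")) {
    lags <- msdZ@lags
    y <- msdZ@msd[, geom@normalAxis]
  } else {
    lags <- msdZ$lags
    y <- msdZ$msd
  }
  mu <- restrictedMSD(lags, fit@L, fit@Dperp)
  res <- y - mu
  reps <- withSeed(seed, {
    t(vapply(seq_len(nRep), function(r) {
      yStar <- mu + if (method == "residual")
        sample(res, length(res), replace = TRUE)
      else rnorm(length(res), 0, sd(res))
      yStar <- pmax(yStar, 0)
      f <- suppressWarnings(tryCatch(
        fitConfinement(list(lags = lags, msd = yStar), geom = geom,
                       init = c(fit@L, fit@Dperp)),
        error = function(e) NULL))
      if (is.null(f)) c(NA_real_, NA_real_) else c(f@L, f@Dperp)
    }, numeric(2)))
  })
  reps <- as.data.frame(reps)
  names(reps) <- c("L", "Dperp")
  ok <- complete.cases(reps)
  r <- stats::cor(reps$L[ok], reps$Dperp[ok])
  z <- atanh(max(min(r, 1 - 1e-12), -1 + 1e-12))
  zse <- 1 / sqrt(sum(ok) - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(correlation = r, ci = tanh(c(z - q * zse, z + q * zse)),
       replicates = reps, method = method)
}

#' Write confinement fit results as CSV
#'
#' One row per system:
#' `system,L_nm,L_se,Dperp_nm2ps,Dperp_se,corr_L_D,n_terms,converged`.
#'
#' @param path output path.
#' @param fits named list of [ConfinementFit-class] objects.
#' @return `path`, invisibly.
#' @export
writeConfinementFits <- function(path, fits) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(system = nm, L_nm = f@L, L_se = f@LSE,
               Dperp_nm2ps = f@Dperp, Dperp_se = f@DperpSE,
               corr_L_D = f@corrLD, n_terms = f@nTerms,
               converged = f@converged)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
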