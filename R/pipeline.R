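#' @include AllClasses.R
NULL

## Deterministic per-system seed derived from the master seed; kept well
## below 2^31.
.systemSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) %% 1000003) * 2011 + 97 * i) %% 2000000011L
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

.analyzeSystem <- function(sys, seed, opts) {
  label <- sys$label
  geom <- do.call(slitGeometry, sys$geometry %||% list())
  if (!is.null(sys$trajectory)) {
    traj <- readTrajCSV(sys$trajectory)
    lTrueKnown <- NA_real_
  } else {
    sp <- sys$synthetic
    params <- slitBrownianParams(
      dPar = sp$dPar %||% 1e-3, dPerp = sp$dPerp %||% 1e-3,
      lTrue = sp$lTrue %||% 1,
      nParticles = sp$nParticles %||% opts$nParticles,
      dt = sp$dt %||% 0.05, nSteps = sp$nSteps %||% opts$nSteps,
      boxLateral = sp$boxLateral %||% 4, seed = seed,
      saveStride = sp$saveStride %||% opts$saveStride)
    traj <- genSlitBrownian(params)
    lTrueKnown <- params@lTrue
  }
  un <- unwrapLateral(traj, geom)
  msd <- computeMSD(un, geom, maxLag = min((nFrames(un) - 1L) %/% 2L,
                                           opts$maxLag))
  epar <- fitParallelD(msd, geom, window = opts$window)
  cfit <- fitConfinement(msd, geom)
  tau <- beta <- S <- NA_real_
  if (!is.null(sys$rotor)) {
    rp <- do.call(rotorParams, c(sys$rotor, list(seed = seed)))
    bonds <- genRotor(rp)
    racf <- computeRACF(bonds,
                        maxLag = min((dim(bonds)[1] - 1L) %/% 2L,
                                     opts$maxLag))
    sfit <- fitStretchedExp(racf)
    tau <- sfit@tau; beta <- sfit@beta; S <- sfit@S
  }
  ## synthetic point particles stand for whole water molecules
  meanDensity <- nParticles(traj) * .MASS_WATER /
    mean(traj@box[, 1] * traj@box[, 2]) / cfit@L * .AMU_NM3_TO_KG_M3
  data.frame(system = label, seed = seed,
             L_true_nm = lTrueKnown, L_nm = cfit@L, L_se = cfit@LSE,
             Dpar_nm2ps = epar@composite,
             Dperp_nm2ps = cfit@Dperp, Dperp_se = cfit@DperpSE,
             tau_ps = tau, beta = beta, S = S,
             density_kg_m3 = meanDensity,
             converged = cfit@converged, error = NA_character_)
}

.failureRow <- function(label, seed, msg) {
  data.frame(system = label, seed = seed, L_true_nm = NA_real_,
             L_nm = NA_real_, L_se = NA_real_, Dpar_nm2ps = NA_real_,
             Dperp_nm2ps = NA_real_, Dperp_se = NA_real_,
             tau_ps = NA_real_, beta = NA_real_, S = NA_real_,
             density_kg_m3 = NA_real_, converged = FALSE, error = msg)
}

#' Run the analysis pipeline over a series of systems
#'
#' Each system is either a trajectory file (columnar dialect) or a
#' synthetic slit specification; for every system the pipeline unwraps,
#' computes component MSDs, fits the parallel diffusion coefficients and
#' the joint (L, D_perp) confinement model, optionally a rotor RACF, and a
#' mean density. Failures are isolated per system and recorded in the
#' summary. Reruns with the same config and seed are byte-identical.
#'
#' @param config a named list, or path to a YAML file, with elements:
#'   `seed` (master seed), `systems` (list; each with `label` and either
#'   `trajectory` (path) or `synthetic` (parameter list), optional
#'   `geometry` and `rotor` lists), and optional `options` (`nParticles`,
#'   `nSteps`, `saveStride`, `maxLag`, `window`).
#' @param outDir optional output directory; when given, a summary CSV and
#'   a JSON manifest (config hash + seed) are written.
#' @return data frame with one row per system.
#' @export
runSeries <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  systems <- config$systems
  if (is.null(systems) || !length(systems)) stop("empty system list")
  labels <- vapply(systems, function(s) s$label %||% "", "")
  if (anyDuplicated(labels[labels != ""]) || any(labels == ""))
    stop("system labels must be present and unique")
  master <- config$seed %||% 1L
  opts <- list(nParticles = 200L, nSteps = 20000L, saveStride = 10L,
               maxLag = 1000L, window = NULL)
  opts[names(config$options %||% list())] <- config$options
  rows <- lapply(seq_along(systems), function(i) {
    seed <- .systemSeed(master, i)
    tryCatch(.analyzeSystem(systems[[i]], seed, opts),
             error = function(e) {
               .failureRow(labels[i], seed, conditionMessage(e))
             })
  })
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(outDir, "summary.csv"), row.names = FALSE,
              quote = FALSE)
    writeSummaryJSON(file.path(outDir, "manifest.json"),
                     list(seed = master, config_md5 = .configHash(config),
                          n_systems = length(systems)))
  }
  out
}

#' Generate a fixture set of synthetic slit systems
#'
#' Writes columnar trajectories plus YAML ground-truth side-cars for a
#' series of confinements; the default series covers 14 wall separations
#' over L = 0.2-3.5 nm at reduced particle counts.
#'
#' @param spec optional list (or YAML path) with `lValues`, `dPar`,
#'   `dPerp`, `nParticles`, `dt`, `nSteps`, `saveStride`, `boxLateral`,
#'   `seed`.
#' @param outDir output directory.
#' @param overwrite set `TRUE` to replace existing fixture files.
#' @return invisibly, a data frame listing the generated systems.
#' @export
makeFixtures <- function(spec = NULL, outDir, overwrite = FALSE) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  spec <- spec %||% list()
  lValues <- spec$lValues %||% seq(0.2, 3.5, length.out = 14)
  master <- spec$seed %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(lValues), function(i) {
    L <- lValues[i]
    label <- sprintf("slit_L%04.2f", L)
    trajPath <- file.path(outDir, paste0(label, ".csv"))
    truthPath <- file.path(outDir, paste0(label, ".truth.yaml"))
    if (!overwrite && (file.exists(trajPath) || file.exists(truthPath)))
      stop("fixture exists (use overwrite = TRUE): ", trajPath)
    seed <- .systemSeed(master, i)
    params <- slitBrownianParams(
      dPar = spec$dPar %||% 1e-3, dPerp = spec$dPerp %||% 1e-3,
      lTrue = L, nParticles = spec$nParticles %||% 50L,
      dt = spec$dt %||% 0.05, nSteps = spec$nSteps %||% 4000L,
      boxLateral = spec$boxLateral %||% 4, seed = seed,
      saveStride = spec$saveStride %||% 4L)
    traj <- suppressWarnings(genSlitBrownian(params))
    writeTrajCSV(trajPath, traj)
    writeGroundTruth(truthPath,
                     list(label = label, dPar = params@dPar,
                          dPerp = params@dPerp, lTrue = L,
                          seed = seed, masterSeed = master))
    data.frame(system = label, L_true_nm = L, seed = seed,
               trajectory = trajPath, truth = truthPath)
  })
  invisible(do.call(rbind, rows))
}
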