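#' @include AllClasses.R
NULL

#' Read a GROMACS GRO structure file
#'
#' Parses the fixed-column GRO text format (positions in nm). Velocity
#' columns, if present, are ignored.
#'
#' @param path path to a `.gro` file.
#' @return a list with elements `title`, `resid`, `resname`, `atomname`,
#'   `positions` (`[n, 3]` matrix, nm) and `box` (length-3, nm).
#' @examples
#' f <- tempfile(fileext = ".gro")
#' writeGro(f, structure = list(
#'   title = "one water", resid = c(1L, 1L, 1L),
#'   resname = rep("SOL", 3), atomname = c("OW", "HW1", "HW2"),
#'   positions = rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0)),
#'   box = c(4, 4, 4)))
#' str(readGro(f))
#' @export
readGro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO format error: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO format error: unparseable atom count (line 2)")
  if (length(lines) < n + 3L)
    stop("GRO format error: declared ", n, " atoms but only ",
         length(lines) - 3L, " atom lines present (count mismatch)")
  at <- lines[3:(n + 2L)]
  num <- function(s, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("GRO format error: unparseable ", what, " at line ",
           lineno[bad[1]])
    v
  }
  ln <- 3:(n + 2L)
  pos <- cbind(num(at, 21, 28, "x", ln), num(at, 29, 36, "y", ln),
               num(at, 37, 44, "z", ln))
  box <- suppressWarnings(as.numeric(
    strsplit(trimws(lines[n + 3L]), "\\s+")[[1]]))[1:3]
  if (any(is.na(box)))
    stop("GRO format error: unparseable box line (line ", n + 3L, ")")
  list(title = lines[1],
       resid = as.integer(num(at, 1, 5, "residue id", ln)),
       resname = trimws(substr(at, 6, 10)),
       atomname = trimws(substr(at, 11, 15)),
       positions = pos, box = box)
}

#' Write a GROMACS GRO structure file
#'
#' @param path output path.
#' @param structure a list as returned by [readGro()].
#' @return `path`, invisibly.
#' @export
writeGro <- function(path, structure) {
  s <- structure
  n <- nrow(s$positions)
  lines <- c(if (is.null(s$title)) "generated by slitwater" else s$title,
             sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     s$resid %% 100000L, s$resname, s$atomname,
                     seq_len(n) %% 100000L,
                     s$positions[, 1], s$positions[, 2], s$positions[, 3]),
             sprintf("%10.5f%10.5f%10.5f", s$box[1], s$box[2], s$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read the columnar trajectory dialect
#'
#' CSV with header `frame,time_ps,particle,x_nm,y_nm,z_nm`, one row per
#' particle per frame, frames contiguous and time-sorted. Per-frame box
#' edges come either from `#box <frame> <lx> <ly> <lz>` comment lines
#' embedded in the file, or from a YAML side-car (`<path>.box.yaml`)
#' holding a single `box: [lx, ly, lz]` entry or a per-frame list.
#'
#' @param path path to the CSV file.
#' @return a [Trajectory-class] with `lateralUnwrapped = FALSE`.
#' @export
readTrajCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  isBox <- startsWith(lines, "#box")
  dat <- read.csv(text = paste(lines[!isBox & !startsWith(lines, "#")],
                               collapse = "\n"))
  need <- c("frame", "time_ps", "particle", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(dat)))
    stop("trajectory format error: header must contain ",
         paste(need, collapse = ","))
  frames <- unique(dat$frame)
  nF <- length(frames)
  counts <- table(dat$frame)
  if (length(unique(as.integer(counts))) != 1L)
    stop("trajectory format error: ragged frames ",
         "(particle count differs between frames)")
  nP <- as.integer(counts[1])
  times <- dat$time_ps[match(frames, dat$frame)]
  if (any(diff(times) <= 0) || any(diff(frames) <= 0))
    stop("trajectory ordering error: frames must be time-sorted ",
         "with strictly increasing times")
  ## order within frame by particle id for a stable layout
  o <- order(dat$frame, dat$particle)
  dat <- dat[o, ]
  co <- array(0, c(nF, nP, 3L))
  co[, , 1] <- matrix(dat$x_nm, nF, nP, byrow = TRUE)
  co[, , 2] <- matrix(dat$y_nm, nF, nP, byrow = TRUE)
  co[, , 3] <- matrix(dat$z_nm, nF, nP, byrow = TRUE)
  box <- NULL
  if (any(isBox)) {
    bx <- do.call(rbind, lapply(strsplit(trimws(sub("^#box", "",
                                                    lines[isBox])), "\\s+"),
                                function(v) as.numeric(v)))
    if (ncol(bx) != 4L || any(is.na(bx)))
      stop("trajectory format error: malformed #box line")
    box <- bx[match(frames, bx[, 1]), 2:4, drop = FALSE]
    if (any(is.na(box)))
      stop("trajectory format error: missing #box entry for some frame")
  } else {
    side <- paste0(path, ".box.yaml")
    if (!file.exists(side))
      stop("trajectory format error: no #box lines and no side-car ", side)
    y <- yaml::read_yaml(side)
    box <- if (!is.null(y$box)) {
      matrix(as.numeric(y$box), nF, 3L, byrow = TRUE)
    } else {
      do.call(rbind, lapply(y$boxes, as.numeric))
    }
  }
  trajectory(times = times, coords = co, box = box,
             lateralUnwrapped = FALSE)
}

#' Write the columnar trajectory dialect
#'
#' @param path output path.
#' @param traj a [Trajectory-class].
#' @param digits positions are written with this many significant digits.
#' @return `path`, invisibly.
#' @export
writeTrajCSV <- function(path, traj, digits = 10) {
  nF <- nFrames(traj); nP <- nParticles(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("frame,time_ps,particle,x_nm,y_nm,z_nm", con)
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  for (f in seq_len(nF)) {
    writeLines(sprintf("#box %d %s %s %s", f, fmt(traj@box[f, 1]),
                       fmt(traj@box[f, 2]), fmt(traj@box[f, 3])), con)
    writeLines(paste(f, fmt(traj@times[f]), seq_len(nP),
                     fmt(traj@coords[f, , 1]), fmt(traj@coords[f, , 2]),
                     fmt(traj@coords[f, , 3]), sep = ","), con)
  }
  invisible(path)
}

#' @describeIn unwrapLateral nearest-image unwrapping of the two lateral
#'   axes; already-unwrapped trajectories are returned unchanged
#'   (idempotent). A warning is emitted when a wrapped inter-frame step
#'   reaches half a box edge, i.e. the frame spacing is too sparse for
#'   unambiguous unwrapping.
#' @export
setMethod("unwrapLateral", "Trajectory", function(traj, geom) {
  if (traj@lateralUnwrapped) return(traj)
  co <- traj@coords
  nF <- dim(co)[1]
  if (nF > 1) {
    sparse <- FALSE
    for (ax in axisIndex(lateralAxes(geom))) {
      x <- co[, , ax, drop = FALSE]
      edge <- traj@box[, ax]
      d <- x[-1, , 1, drop = FALSE] - x[-nF, , 1, drop = FALSE]
      e <- edge[-1]
      d <- d - round(d / e) * e
      if (any(abs(d) >= e / 2 * (1 - 1e-12))) sparse <- TRUE
      co[, , ax] <- apply(rbind(x[1, , 1], matrix(d, nF - 1L)), 2, cumsum)
    }
    if (sparse)
      warning("inter-frame lateral displacement reached half a box edge; ",
              "frame sampling too sparse for reliable unwrapping")
  }
  new("Trajectory", times = traj@times, coords = co, box = traj@box,
      lateralUnwrapped = TRUE)
})

#' O-H bond unit-vector time series
#'
#' Computes the two O-H bond unit vectors of every water molecule in every
#' frame, applying the minimum image convention per axis before
#' normalizing.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [WaterTopology-class].
#' @return numeric array `[nFrames, 2 * nMolecules, 3]` of unit vectors,
#'   bonds ordered (mol1 O-H1, mol1 O-H2, mol2 O-H1, ...), with the frame
#'   times attached as attribute `times`.
#' @export
bondVectors <- function(traj, topo) {
  co <- traj@coords
  nF <- dim(co)[1]
  nMol <- length(topo@oIndex)
  out <- array(NA_real_, c(nF, 2L * nMol, 3L))
  for (ax in 1:3) {
    o <- co[, topo@oIndex, ax, drop = FALSE][, , 1, drop = TRUE]
    h1 <- co[, topo@h1Index, ax, drop = FALSE][, , 1, drop = TRUE]
    h2 <- co[, topo@h2Index, ax, drop = FALSE][, , 1, drop = TRUE]
    e <- traj@box[, ax]
    d1 <- h1 - o; d2 <- h2 - o
    d1 <- d1 - round(d1 / e) * e
    d2 <- d2 - round(d2 / e) * e
    out[, 2L * seq_len(nMol) - 1L, ax] <- d1
    out[, 2L * seq_len(nMol), ax] <- d2
  }
  nrm <- sqrt(out[, , 1]^2 + out[, , 2]^2 + out[, , 3]^2)
  if (any(nrm < 1e-10))
    stop("degenerate geometry: zero-length O-H bond encountered")
  for (ax in 1:3) out[, , ax] <- out[, , ax] / nrm
  attr(out, "times") <- traj@times
  out
}
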