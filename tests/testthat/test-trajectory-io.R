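test_that("GRO reader parses a minimal one-water file", {
  f <- tempfile(fileext = ".gro")
  writeLines(c(
    "one water",
    "    3",
    "    1SOL     OW    1   0.000   0.000   0.000",
    "    1SOL    HW1    2   0.100   0.000   0.000",
    "    1SOL    HW2    3   0.000   0.100   0.000",
    "   4.00000   4.00000   4.00000"), f)
  s <- readGro(f)
  expect_equal(nrow(s$positions), 3L)
  expect_equal(s$box, c(4, 4, 4))
  expect_equal(s$positions[1, ], c(0, 0, 0))
  expect_equal(s$atomname, c("OW", "HW1", "HW2"))
})

test_that("GRO write/read roundtrips to output precision", {
  set.seed(11)
  s <- list(title = "rt", resid = rep(1:4, each = 3),
            resname = rep("SOL", 12),
            atomname = rep(c("OW", "HW1", "HW2"), 4),
            positions = matrix(runif(36, 0, 3), 12, 3), box = c(3, 3, 3))
  f <- tempfile(fileext = ".gro")
  writeGro(f, s)
  r <- readGro(f)
  expect_equal(r$positions, round(s$positions, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r$resid, s$resid)
  expect_equal(r$atomname, s$atomname)
  expect_equal(r$box, s$box)
})

test_that("malformed GRO files raise format errors", {
  f <- tempfile(fileext = ".gro")
  writeLines(c("bad count", "    6",
               "    1SOL     OW    1   0.000   0.000   0.000",
               "    1SOL    HW1    2   0.100   0.000   0.000",
               "    1SOL    HW2    3   0.000   0.100   0.000",
               "    2SOL     OW    4   1.000   1.000   1.000",
               "    2SOL    HW1    5   1.100   1.000   1.000",
               "   4.0   4.0   4.0"), f)
  expect_error(readGro(f), "count mismatch")
  f2 <- tempfile(fileext = ".gro")
  writeLines(c("bad column", "    1",
               "    1SOL     OW    1   x.000   0.000   0.000",
               "   4.0   4.0   4.0"), f2)
  expect_error(readGro(f2), "line 3")
})

test_that("columnar trajectory dialect roundtrips", {
  tr <- randomTrajectory(5, 3)
  tr@lateralUnwrapped <- FALSE
  f <- tempfile(fileext = ".csv")
  writeTrajCSV(f, tr)
  r <- readTrajCSV(f)
  expect_s4_class(r, "Trajectory")
  expect_false(isLateralUnwrapped(r))
  expect_equal(frameTimes(r), frameTimes(tr))
  expect_equal(coords(r), coords(tr), tolerance = 1e-9)
  expect_equal(boxDims(r), boxDims(tr))
})

test_that("columnar reader accepts a side-car box and rejects bad input", {
  tr <- randomTrajectory(3, 2)
  f <- tempfile(fileext = ".csv")
  ## write without #box lines, box in side-car YAML instead
  df <- data.frame(frame = rep(1:3, each = 2), time_ps = rep(0:2, each = 2),
                   particle = rep(1:2, 3),
                   x_nm = as.vector(t(coords(tr)[, , 1])),
                   y_nm = as.vector(t(coords(tr)[, , 2])),
                   z_nm = as.vector(t(coords(tr)[, , 3])))
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(box = c(4, 4, 4)), paste0(f, ".box.yaml"))
  r <- readTrajCSV(f)
  expect_equal(boxDims(r)[1, ], c(4, 4, 4))

  ## shuffled frame order -> ordering error
  f2 <- tempfile(fileext = ".csv")
  write.csv(df[c(3:6, 1:2), ], f2, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(box = c(4, 4, 4)), paste0(f2, ".box.yaml"))
  expect_error(readTrajCSV(f2), "ordering")

  ## ragged frames -> format error
  f3 <- tempfile(fileext = ".csv")
  write.csv(df[-2, ], f3, row.names = FALSE, quote = FALSE)
  expect_error(readTrajCSV(f3), "ragged")
})

test_that("unwrapLateral restores continuous paths across the boundary", {
  ## particle stepping 3.9 -> 0.1 in a 4 nm box continues to 4.1
  co <- array(0, c(2, 1, 3))
  co[1, 1, ] <- c(3.9, 1, 0.5)
  co[2, 1, ] <- c(0.1, 1, 0.5)
  tr <- trajectory(times = 0:1, coords = co, box = c(4, 4, 1))
  un <- unwrapLateral(tr)
  expect_equal(coords(un)[, 1, 1], c(3.9, 4.1))
  expect_equal(coords(un)[, 1, 3], c(0.5, 0.5)) # normal axis untouched
  expect_true(isLateralUnwrapped(un))
  ## idempotent on already-unwrapped input
  expect_identical(unwrapLateral(un), un)
})

test_that("unwrapping a drifting particle recovers total displacement", {
  ## constant drift of +0.13 nm/frame in x through many boundary crossings
  n <- 320
  x <- 0.05 + 0.13 * (0:(n - 1))
  expect_gt(max(x) / 4, 10) # at least 10 crossings
  co <- array(0.5, c(n, 1, 3))
  co[, 1, 1] <- x %% 4
  tr <- trajectory(times = 0:(n - 1), coords = co, box = c(4, 4, 1))
  un <- unwrapLateral(tr)
  expect_equal(coords(un)[n, 1, 1] - coords(un)[1, 1, 1], x[n] - x[1],
               tolerance = 1e-12)
  ## a continuous trajectory with no crossings is unchanged
  set.seed(9)
  co5 <- array(0, c(10, 4, 3))
  for (p in 1:4) for (ax in 1:3)
    co5[, p, ax] <- 2 + cumsum(runif(10, -0.05, 0.05))
  tr2 <- trajectory(times = 0:9, coords = co5, box = c(4, 4, 4))
  expect_equal(coords(unwrapLateral(tr2)), coords(tr2))
})

test_that("bond vectors are unit length and respect minimum image", {
  ## basic geometry
  co <- array(0, c(1, 3, 3))
  co[1, 2, ] <- c(0.1, 0, 0)
  co[1, 3, ] <- c(0, 0.1, 0)
  tr <- trajectory(times = 0, coords = co, box = c(4, 4, 4))
  topo <- makeWaterTopology(1)
  b <- bondVectors(tr, topo)
  expect_equal(b[1, 1, ], c(1, 0, 0))
  expect_equal(b[1, 2, ], c(0, 1, 0))

  ## PBC case: O at 3.95, H at 0.05 with box 4 -> bond along +x
  co2 <- array(0, c(1, 3, 3))
  co2[1, 1, ] <- c(3.95, 1, 1)
  co2[1, 2, ] <- c(0.05, 1, 1)
  co2[1, 3, ] <- c(3.95, 1.1, 1)
  tr2 <- trajectory(times = 0, coords = co2, box = c(4, 4, 4))
  b2 <- bondVectors(tr2, topo)
  expect_equal(b2[1, 1, ], c(1, 0, 0))

  ## property: all norms equal 1 within 1e-12 on random frames
  set.seed(5)
  nMol <- 20; nF <- 7
  co3 <- array(runif(nF * 3 * nMol * 3, 0, 4), c(nF, 3 * nMol, 3))
  tr3 <- trajectory(times = seq_len(nF) - 1, coords = co3, box = c(4, 4, 4))
  b3 <- bondVectors(tr3, makeWaterTopology(nMol))
  nrm <- sqrt(b3[, , 1]^2 + b3[, , 2]^2 + b3[, , 3]^2)
  expect_lt(max(abs(nrm - 1)), 1e-12)

  ## zero-length bond -> degenerate geometry error
  co4 <- array(0, c(1, 3, 3))
  tr4 <- trajectory(times = 0, coords = co4, box = c(4, 4, 4))
  expect_error(bondVectors(tr4, topo), "degenerate")
})

test_that("Trajectory validity enforces its invariants", {
  co <- array(0.5, c(2, 1, 3))
  expect_error(trajectory(times = c(1, 0), coords = co, box = c(4, 4, 4)),
               "increasing")
  expect_error(trajectory(times = 0:1, coords = co, box = c(4, -4, 4)),
               "positive")
  expect_error(trajectory(times = 0:2, coords = co, box = c(4, 4, 4)),
               "frames")
})
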