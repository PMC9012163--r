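test_that("counts_to_cm converts tablet counts linearly", {
  expect_equal(counts_to_cm(5080, 5080), 2.54)
  expect_equal(counts_to_cm(0, 5080), 0)
  expect_equal(counts_to_cm(2540, 5080), 1.27)
  a <- 123; b <- 4567
  expect_equal(counts_to_cm(a + b, 5080), counts_to_cm(a, 5080) + counts_to_cm(b, 5080))
  expect_error(counts_to_cm(100, 0), "positive")
  expect_error(counts_to_cm(100, -5), "positive")
})

test_that("cm-dialect traces read back with rate inference", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# dialect: cm", "t,x,y,p",
    "0.000,1.0,2.0,0.5", "0.005,1.1,2.1,0.5", "0.010,1.2,2.2,0.5"
  ), path)
  tr <- read_pen_trace(path)
  expect_s3_class(tr, "pen_trace")
  expect_equal(nrow(tr), 3)
  expect_equal(trace_meta(tr)$rate_hz, 200)
  expect_equal(tr$x, c(1.0, 1.1, 1.2))
})

test_that("raw-count dialect converts units, pressure and flips the y axis", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# dialect: raw_counts", "# lpi: 5080", "# active_height_cm: 10",
    "# pressure_max: 8191", "t,x,y,p",
    "0.00,5080,0,8191", "0.01,2540,5080,0"
  ), path)
  tr <- read_pen_trace(path)
  expect_equal(tr$x, c(2.54, 1.27))
  # raw y increases downward: count 0 is the top of the 10 cm area
  expect_equal(tr$y, c(10, 10 - 2.54))
  expect_equal(tr$p, c(1, 0))
  # flipping twice restores raw coordinates
  expect_equal(10 - tr$y, counts_to_cm(c(0, 5080), 5080))
})

test_that("malformed or inconsistent trace files are rejected with context", {
  bad_order <- withr::local_tempfile()
  writeLines(c("# dialect: cm", "t,x,y,p", "0,0,0,0.5", "0,1,1,0.5"), bad_order)
  expect_error(read_pen_trace(bad_order), "timestamps")

  bad_cell <- withr::local_tempfile()
  writeLines(c("# dialect: cm", "t,x,y,p", "0,0,0,0.5", "0.01,xx,1,0.5"), bad_cell)
  expect_error(read_pen_trace(bad_cell), "line")

  bad_press <- withr::local_tempfile()
  writeLines(c("# dialect: cm", "t,x,y,p", "0,0,0,1.5"), bad_press)
  expect_error(read_pen_trace(bad_press), "pressure")

  missing_lpi <- withr::local_tempfile()
  writeLines(c("# dialect: raw_counts", "t,x,y,p", "0,0,0,10"), missing_lpi)
  expect_error(read_pen_trace(missing_lpi), "lpi")

  expect_error(read_pen_trace(tempfile()), "no such")
})

test_that("write/read round-trips a trace to written precision", {
  set.seed(1)
  n <- 100
  tr <- make_trace(
    t = (0:(n - 1)) / 200, x = cumsum(rnorm(n, 0, 0.01)),
    y = cumsum(rnorm(n, 0, 0.01)), p = c(rep(0, 5), rep(0.7, n - 10), rep(0, 5)),
    subject_id = "S1", group = "CTRL", bigram = "ll", trial = 2L
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_pen_trace(tr, path)
  back <- read_pen_trace(path)
  expect_equal(nrow(back), n) # pen-up rows preserved
  expect_equal(back$t, tr$t, tolerance = 1e-6)
  expect_lt(max(abs(back$x - tr$x)), 1e-6)
  expect_lt(max(abs(back$y - tr$y)), 1e-6)
  expect_equal(trace_meta(back)$bigram, "ll")
  expect_equal(trace_meta(back)$trial, 2L)
})

test_that("pen_trace enforces its invariants", {
  expect_error(pen_trace(data.frame(t = numeric(0), x = numeric(0), y = numeric(0), p = numeric(0))), "no samples")
  expect_error(pen_trace(data.frame(t = c(0, 0), x = 0, y = 0, p = 0.5)), "increasing")
  expect_error(pen_trace(data.frame(t = c(0, 1), x = 0, y = 0, p = c(0.5, 2))), "pressure")
  expect_error(pen_trace(data.frame(t = c(-1, 0), x = 0, y = 0, p = 0.5)), "non-negative")
})

test_that("manifests resolve paths and reject duplicate trial keys", {
  dir <- withr::local_tempdir()
  tr <- make_trace(t = 0:9 / 200, x = 1:10 / 10, y = 1:10 / 10, p = 0.6)
  write_pen_trace(tr, file.path(dir, "a.csv"))
  write_pen_trace(tr, file.path(dir, "b.csv"))
  man <- data.frame(
    subject_id = c("S1", "S1"), group = "CTRL", bigram = c("ll", "ln"),
    trial = 1L, path = c("a.csv", "b.csv")
  )
  mpath <- file.path(dir, "manifest.csv")
  write.csv(man, mpath, row.names = FALSE)
  got <- read_manifest(mpath)
  expect_true(all(file.exists(got$path)))

  man$bigram <- "ll"
  write.csv(man, mpath, row.names = FALSE)
  expect_error(read_manifest(mpath), "unique")

  man$bigram <- c("ll", "ln")
  man$path[2] <- "missing.csv"
  write.csv(man, mpath, row.names = FALSE)
  expect_error(read_manifest(mpath), "missing")
})
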