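test_that("text rows parse into validated particle records", {
  f <- withr::local_tempfile(fileext = ".phsp")
  writeLines(c("# synthetic header", "# t e x y vx vy",
               "1 1.2 3.0 4.0 0.01 -0.02",
               "-2 0.5 -1.0 0.0 0.0 0.0",
               "3 2.5 0.0 0.0 0.1 0.1"), f)
  ps <- read_phsp(f)
  expect_s3_class(ps, "particle_set")
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$t, c(1L, 2L, 3L)) # sign dropped, positron preserved
  expect_equal(ps_r(ps)[1], 5.0)    # 3-4-5 triangle
  expect_equal(ps$vx[2], 0)
})

test_that("comma-delimited text is auto-detected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,1.2,3.0,4.0,0.01,-0.02", "2,0.5,-1.0,0.0,0.0,0.0"), f)
  ps <- read_phsp(f)
  expect_equal(ps$y, c(4, 0))
})

test_that("malformed and invalid files are rejected with informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("1 1.2 3 4 0.01 0.02", "1 1.2 3 4 oops 0.02"), f)
  expect_error(suppressWarnings(read_phsp(f)), "row 2")

  f2 <- withr::local_tempfile()
  writeLines("1 1.2 3 4 0.9 0.9", f2) # vx^2 + vy^2 = 1.62
  expect_error(read_phsp(f2), "vx\\^2 \\+ vy\\^2")

  f3 <- withr::local_tempfile()
  writeLines("7 1.2 3 4 0.0 0.0", f3)
  expect_error(read_phsp(f3), "species code")

  f4 <- withr::local_tempfile()
  writeLines("1 1.2 3 4 0.1", f4) # five columns
  expect_error(suppressWarnings(read_phsp(f4)), "6 columns|row")

  expect_error(read_phsp(file.path(tempdir(), "does-not-exist.phsp")), "not found")
})

test_that("round trips preserve all six columns in both dialects", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 1000, seed = 3))

  fb <- withr::local_tempfile(fileext = ".bin")
  write_phsp(ps, fb, format = "matrix_binary")
  back_b <- read_phsp(fb, format = "matrix_binary")
  expect_identical(unclass(back_b)[c("e", "x", "y", "vx", "vy")],
                   unclass(as.data.frame(ps))[c("e", "x", "y", "vx", "vy")])
  expect_identical(back_b$t, ps$t)

  ft <- withr::local_tempfile(fileext = ".txt")
  write_phsp(ps, ft, format = "matrix_text")
  back_t <- read_phsp(ft)
  for (col in c("e", "x", "y", "vx", "vy")) {
    expect_lt(max(abs(back_t[[col]] - ps[[col]]) / pmax(abs(ps[[col]]), 1e-30)),
              1e-9)
  }

  # binary auto-detection
  expect_equal(read_phsp(fb)$x, ps$x)
})

test_that("gzip-compressed text reads transparently", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 200, seed = 4))
  fz <- withr::local_tempfile(fileext = ".phsp.gz")
  write_phsp(ps, fz, format = "matrix_text")
  back <- read_phsp(fz)
  expect_equal(back$e, ps$e, tolerance = 1e-12)
})

test_that("writing an empty particle set errors", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 10, seed = 1))
  expect_error(write_phsp(ps[0, ], tempfile()), "empty")
})

test_that("radial distance is a true Euclidean norm", {
  expect_equal(radial_distance(3, 4), 5)
  expect_equal(radial_distance(0, 0), 0)
  expect_equal(radial_distance(-7.1, 0), 7.1)
  set.seed(1)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(radial_distance(x, y), radial_distance(-x, y))
  expect_equal(radial_distance(x, y), radial_distance(y, x))
})

test_that("vz completes the unit direction vector with the positive root", {
  ps <- particle_set(1, 1, 120, 0, 0.6, 0)
  expect_equal(ps_vz(ps), 0.8)
  ps2 <- make_synthetic_phsp(synthetic_beam_params(n = 5000, seed = 5))
  expect_true(all(ps_vz(ps2) >= 0))
  expect_equal(ps2$vx^2 + ps2$vy^2 + ps_vz(ps2)^2, rep(1, 5000), tolerance = 1e-12)
})

test_that("summary reports counts, fractions and ranges", {
  ps <- particle_set(c(1, 1, 2), c(1, 2, 3), c(0, 3, 0), c(0, 4, 1),
                     c(0, 0.1, 0), c(0, 0, 0.2))
  s <- summary(ps)
  expect_equal(s$n, 3L)
  expect_equal(unname(s$species_fractions["photon"]), 2 / 3)
  expect_equal(s$energy_range_mev, c(1, 3))
  expect_equal(s$radial_range_mm, c(0, 5))
})
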