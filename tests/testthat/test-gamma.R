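test_that("identical planes give gamma 0 and a 100% pass rate", {
  p <- test_plane()
  res <- gamma_analysis(p, p, dose_pct = 3, dist_mm = 1)
  expect_equal(res$pass_rate, 100)
  expect_lt(max(res$gamma, na.rm = TRUE), 1e-9)
  expect_true(all(is.na(res$gamma[p$values < 0.1 * max(p$values)])))
})

test_that("a half-millimetre shift passes a 1 mm DTA criterion", {
  p <- test_plane()
  shifted <- plane2d(p$values, p$spacing, origin = p$origin + c(0.5, 0))
  res <- gamma_analysis(p, shifted, dose_pct = 3, dist_mm = 1)
  expect_equal(res$pass_rate, 100)
  expect_lt(max(res$gamma, na.rm = TRUE), 1) # DTA term alone caps at 0.5
})

test_that("a 10% rescale of a flat plane fails a 3% criterion everywhere", {
  flat <- plane2d(matrix(1, 40, 40), 1)
  res <- gamma_analysis(flat, plane2d(matrix(1.10, 40, 40), 1),
                        dose_pct = 3, dist_mm = 1, threshold_pct = 10)
  expect_equal(res$pass_rate, 0)
  expect_equal(min(res$gamma, na.rm = TRUE), 10 / 3, tolerance = 1e-6)
})

test_that("interpolated search matches exhaustive brute-force gamma", {
  ref <- test_plane(n = 64, noise_sd = 0.01, seed = 71)
  ev0 <- test_plane(n = 64, noise_sd = 0.01, seed = 72)
  ev <- plane2d(1.01 * ev0$values, ev0$spacing, origin = ev0$origin + c(0.4, -0.3))
  res <- gamma_analysis(ref, ev, dose_pct = 3, dist_mm = 1)
  oracle <- brute_force_gamma(ref, ev, dose_pct = 3, dist_mm = 1)
  both <- !is.na(res$gamma) & !is.na(oracle)
  expect_gt(sum(both), 1000)
  expect_lt(max(abs(res$gamma[both] - oracle[both])), 0.01)
})

test_that("pass rate is monotone in both criteria", {
  ref <- test_plane(n = 48, noise_sd = 0.02, seed = 73)
  ev <- test_plane(n = 48, noise_sd = 0.02, seed = 74)
  ev <- plane2d(1.03 * ev$values, ev$spacing, origin = ev$origin + c(0.8, 0))
  p11 <- gamma_analysis(ref, ev, 1, 1)$pass_rate
  p31 <- gamma_analysis(ref, ev, 3, 1)$pass_rate
  p32 <- gamma_analysis(ref, ev, 3, 2)$pass_rate
  p61 <- gamma_analysis(ref, ev, 6, 1)$pass_rate
  expect_lte(p11, p31)
  expect_lte(p31, p32)
  expect_lte(p31, p61)
})

test_that("degenerate comparisons are rejected", {
  a <- test_plane(n = 16)
  b <- plane2d(a$values, a$spacing, origin = a$origin + c(500, 0))
  expect_error(gamma_analysis(a, b, 3, 1), "overlap")
  expect_error(gamma_analysis(a, a, 3, 1, threshold_pct = 200), "threshold")
})

test_that("plane text round trip preserves values and geometry", {
  p <- test_plane(n = 20, spacing = 2, noise_sd = 0.05, seed = 75)
  f <- withr::local_tempfile(fileext = ".plane")
  write_plane2d(p, f)
  q <- read_plane2d(f)
  expect_equal(q$values, p$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(q$spacing, p$spacing)
  expect_equal(q$origin, p$origin)
  # headerless matrix with CLI-supplied spacing
  f2 <- withr::local_tempfile()
  write.table(p$values, f2, row.names = FALSE, col.names = FALSE)
  q2 <- read_plane2d(f2, spacing = 2)
  expect_equal(q2$values, p$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(read_plane2d(f2), "spacing")
})

test_that("profiles extract the expected rows and columns", {
  v <- outer(seq_len(9), seq_len(11), function(i, j) i + 10 * j)
  p <- plane2d(v, 1, origin = c(-4, -5))
  prof <- extract_profile(p, "x", 0) # along x at y = 0 -> column j = 6
  expect_equal(prof$value, v[, 6])
  expect_equal(prof$pos, seq(-4, 4))
  prof_y <- extract_profile(p, "y", 2) # along y at x = 2 -> row i = 7
  expect_equal(prof_y$value, v[7, ])
  expect_error(extract_profile(p, "x", 99), "outside")
  # symmetric plane -> symmetric central profile
  s <- test_plane(n = 21)
  ps <- extract_profile(s, "x", 0)
  expect_equal(ps$value, rev(ps$value), tolerance = 1e-12)
  flatp <- plane2d(matrix(3, 5, 5), 1)
  expect_equal(extract_profile(flatp, "y", 0)$value, rep(3, 5))
})

test_that("synthetic dose-plane pairs behave like commissioning data", {
  pl <- make_synthetic_dose_planes(field_mm = 100, seed = 76)
  expect_equal(max(pl$ref$values), 1, tolerance = 0.05)
  res <- gamma_analysis(pl$ref, pl$ev, 3, 1)
  expect_gt(res$pass_rate, 95)
})
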