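test_that("grid statistics equal a brute-force recomputation", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 8e3, seed = 21))
  g <- build_direction_grid(ps, grid_n = 21, cell_mm = 7)
  oracle <- brute_force_grid_stats(ps, grid_n = 21, cell_mm = 7)
  expect_equal(nrow(g$stats), length(oracle))
  for (i in seq_len(nrow(g$stats))) {
    row <- g$stats[i, ]
    o <- oracle[[paste(row$ix, row$iy)]]
    expect_equal(row$n, o$n)
    expect_equal(row$vbar_x, o$vbar_x, tolerance = 1e-12)
    expect_equal(row$vbar_y, o$vbar_y, tolerance = 1e-12)
    if (o$n >= 2) {
      expect_equal(row$sd_x, o$sd_x, tolerance = 1e-12)
      expect_equal(row$rho_ex, o$rho_ex, tolerance = 1e-12)
      expect_equal(row$rho_v, o$rho_v, tolerance = 1e-12)
    }
  }
})

test_that("tiny hand-built bins give the expected statistics", {
  # two photons in one bin with cosines 0.1 and 0.3 -> mean 0.2; energies
  # linear in vx -> correlation exactly 1
  ps <- particle_set(c(1, 1), c(1, 3), c(0.2, 0.3), c(0.2, 0.3),
                     c(0.1, 0.3), c(0, 0))
  g <- build_direction_grid(ps)
  expect_equal(nrow(g$stats), 1L)
  expect_equal(g$stats$vbar_x, 0.2)
  expect_equal(g$stats$rho_ex, 1)
  # a single-particle bin has no spread and is flagged invalid
  ps1 <- particle_set(1, 1, 0.2, 0.2, 0.1, 0)
  g1 <- build_direction_grid(ps1)
  expect_true(is.na(g1$stats$sd_x))
  expect_false(g1$stats$cor_valid)
  # constant cosines -> correlation undefined, stored as 0 and invalid
  ps2 <- particle_set(c(1, 1, 1), c(1, 2, 3), rep(0.2, 3), rep(0.2, 3),
                      rep(0.1, 3), rep(0.05, 3))
  g2 <- build_direction_grid(ps2)
  expect_equal(g2$stats$rho_ex, 0)
  expect_false(g2$stats$cor_valid)
})

test_that("noise-free focal beam reproduces the analytic cosine field per bin", {
  p <- synthetic_beam_params(n = 2e5, seed = 22, ang_sigma = 0,
                             rho_ev_target = 0, rho_v_target = 0,
                             electron_fraction = 0)
  ps <- make_synthetic_phsp(p)
  g <- build_direction_grid(ps)
  # low-occupancy bins have mean positions off the bin centre, so the
  # analytic comparison needs enough particles per bin
  s <- g$stats[g$stats$n >= 20, ]
  L <- sqrt(s$xc^2 + s$yc^2 + 160^2)
  # residual error is the within-bin mean-position jitter (~0.3 mm / sqrt(n)
  # mapped through the ~1/160 divergence slope) maximised over ~5e3 bins
  expect_lt(max(abs(s$vbar_x - s$xc / L)), 1.5e-3)
  expect_lt(max(abs(s$vbar_y - s$yc / L)), 1.5e-3)
})

test_that("primary region follows the fractional-count rule", {
  # near-uniform occupancy: everything is primary and T reaches the corner
  set.seed(23)
  n <- 46000
  ps <- particle_set(rep(1, n), rep(1, n), runif(n, -15, 15), runif(n, -15, 15),
                     rep(0, n), rep(0, n))
  g <- build_direction_grid(ps, grid_n = 15, cell_mm = 2)
  reg <- determine_primary_region(g)
  expect_true(all(reg$mask))
  expect_equal(reg$T_mm, max(sqrt(outer(g$centers^2, g$centers^2, `+`))))
  expect_equal(reg$primary_fraction, 1)

  # a single occupied bin is its own primary region under the raw rule
  ps1 <- particle_set(rep(1, 5), rep(1, 5), rep(0.2, 5), rep(0.2, 5),
                      rep(0, 5), rep(0, 5))
  g1 <- build_direction_grid(ps1, grid_n = 15, cell_mm = 2)
  reg1 <- determine_primary_region(g1, smooth = 0)
  expect_equal(sum(reg1$mask), 1L)
})

test_that("primary photon fraction is nonincreasing in the threshold fraction", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 1e5, seed = 24))
  g <- build_direction_grid(ps)
  fr <- vapply(seq(0.05, 0.9, by = 0.05),
               function(f) determine_primary_region(g, frac = f)$primary_fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("weighted least squares recovers exact in-span coefficients", {
  # bins on a lattice with exactly linear mean cosines: the primary fit must
  # return the generating coefficients and the cubic secondary fit must
  # zero-pad them
  set.seed(25)
  centers <- seq(-14.5, 14.5, by = 1)
  gridpts <- expand.grid(xc = centers, yc = centers)
  a <- c(0.002, 0.0061, -0.0013)
  rows <- do.call(rbind, lapply(seq_len(nrow(gridpts)), function(i) {
    xc <- gridpts$xc[i]; yc <- gridpts$yc[i]
    f <- a[1] + a[2] * xc + a[3] * yc
    g <- 0.001 - 0.004 * yc + 0.002 * xc
    d <- 1e-4
    data.frame(t = 1, e = runif(4, 1, 2), x = xc, y = yc,
               vx = f + c(-d, d, -d, d), vy = g + c(d, -d, -d, d))
  }))
  ps <- particle_set(rows$t, rows$e, rows$x, rows$y, rows$vx, rows$vy)
  g <- build_direction_grid(ps, grid_n = 30, cell_mm = 1)
  reg <- determine_primary_region(g, frac = 0) # all occupied bins primary
  reg$mask <- with(g, sqrt(outer(centers^2, centers^2, `+`))) <= 8
  reg$T_mm <- 8
  ds <- fit_direction_surfaces(g, reg, min_bin_count = 2L)
  expect_equal(unname(ds$surfaces$v_x$primary), a, tolerance = 1e-9)
  expect_equal(unname(ds$surfaces$v_x$secondary), c(a, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(ds$surfaces$v_y$primary), c(0.001, -0.004, 0.002),
               tolerance = 1e-9)
})

test_that("rescaling all weights leaves WLS coefficients unchanged", {
  set.seed(26)
  X <- cbind(1, rnorm(50), rnorm(50))
  z <- drop(X %*% c(1, 2, 3)) + rnorm(50, sd = 0.1)
  w <- runif(50, 0.5, 2)
  f1 <- vsmbeam:::wls_fit(X, z, w)
  f2 <- vsmbeam:::wls_fit(X, z, 2 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("rank-deficient designs raise an error naming the surface", {
  X <- cbind(1, 1:10, 2 * (1:10)) # collinear
  expect_error(vsmbeam:::wls_fit(X, rnorm(10), rep(1, 10), label = "v^x primary"),
               "singular.*v\\^x primary")
})

test_that("fitted focal beam has the geometric divergence slope", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 3e5, seed = 27))
  g <- build_direction_grid(ps)
  reg <- determine_primary_region(g)
  ds <- fit_direction_surfaces(g, reg)
  slope <- ds$surfaces$v_x$primary[2] # d vx / d x
  expect_equal(unname(slope), 1 / 160, tolerance = 0.03)
  expect_equal(unname(ds$surfaces$v_y$primary[2]), 1 / 160, tolerance = 0.03)
})

test_that("surface evaluations are clamped to their physical ranges", {
  s <- make_const_surfaces(rho_ex = 1.5, rho_v = -2, sigma_x = -0.01)
  p <- predict_direction(s, c(0, 10), c(0, -5))
  expect_equal(p$rho_ex, c(1, 1))
  expect_equal(p$rho_v, c(-1, -1))
  expect_equal(p$sigma_x, c(0, 0))
})
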