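const_radial <- function(r0) {
  m <- list(icdf = list(u = c(0, 1), q = c(r0, r0)), bin_width = 0.1,
            segments = 30L, degree = 4L, r_max = r0, n = 1L)
  class(m) <- "radial_position_model"
  m
}

test_that("positions follow r = F^-1(U1) and theta = 360 U2", {
  m <- const_radial(5)
  p <- sample_position(m, 0.5, 0)
  expect_equal(c(p$x, p$y), c(5, 0))
  p2 <- sample_position(m, 0.2, 0.25) # quarter turn
  expect_equal(c(p2$x, p2$y), c(0, 5), tolerance = 1e-12)
  expect_equal(p2$theta_deg, 90)
  p3 <- sample_position(m, 0.2, 0.5)
  expect_equal(c(p3$x, p3$y), c(-5, 0), tolerance = 1e-12)
})

test_that("azimuths are uniform by construction", {
  set.seed(61)
  m <- const_radial(10)
  p <- sample_position(m, runif(1e5), runif(1e5))
  sector <- floor(p$theta_deg / 10) # 36 sectors
  expect_gt(chisq.test(tabulate(sector + 1, nbins = 36))$p.value, 0.001)
  expect_equal(p$x^2 + p$y^2, rep(100, 1e5), tolerance = 1e-9)
})

test_that("energy sampling hits the spectrum endpoints and the right bin", {
  set.seed(62)
  n <- 3e4
  r <- 100 * sqrt(runif(n))
  e <- ifelse(r <= 50, runif(n, 1, 2), runif(n, 4, 5)) # radially distinct spectra
  ps <- particle_set(rep(1, n), e, r, rep(0, n), rep(0, n), rep(0, n))
  em <- build_energy_model(ps, min_bin_count = 50)
  expect_true(all(sample_energy(em, rep(10, 50), runif(50)) <= 2.01))
  expect_true(all(sample_energy(em, rep(80, 50), runif(50)) >= 3.99))
  inner <- ps$e[energy_bin_index(r) == 5]
  e0 <- sample_energy(em, 9, 0)
  e1 <- sample_energy(em, 9, 1)
  expect_gte(e0, min(inner)); expect_lt(e0, quantile(inner, 0.05))
  expect_lte(e1, max(inner)); expect_gt(e1, quantile(inner, 0.95))
})

test_that("zero spread reproduces the mean-cosine surfaces exactly", {
  s <- make_const_surfaces(vbar_x = 0.6, vbar_y = 0, sigma_x = 0, sigma_y = 0)
  d <- sample_direction(s, shared_cal(), c(0, 30), c(0, 0), c(0.5, 0.9))
  expect_equal(d$vx, c(0.6, 0.6))
  expect_equal(d$vy, c(0, 0))
  expect_equal(d$vz, c(0.8, 0.8))
})

test_that("lateral-cosine correlation is recovered at a fixed position", {
  set.seed(63)
  n <- 1e5
  for (rho in c(-0.4, 0.3)) {
    s <- make_const_surfaces(sigma_x = 0.01, rho_v = rho)
    d <- sample_direction(s, shared_cal(), rep(10, n), rep(5, n), runif(n))
    expect_lt(abs(cor(d$vx, d$vy) - rho), 0.03)
    # deviations have the surface spread
    expect_equal(sd(d$vx), 0.01, tolerance = 0.02)
  }
})

test_that("energy-direction correlation is recovered through the SOU chain", {
  set.seed(64)
  n <- 1e5
  u3 <- runif(n)
  for (rho in c(0.5, -0.35)) {
    s <- make_const_surfaces(sigma_x = 0.01, rho_ex = rho)
    d <- sample_direction(s, shared_cal(), rep(10, n), rep(0, n), u3)
    # u3 is monotone in energy, so cor(u3, vx) carries the requested sign
    # and magnitude up to the mild uniform-to-normal attenuation
    expect_lt(abs(cor(u3, d$vx) - rho), 0.05)
    expect_equal(sign(cor(u3, d$vx)), sign(rho))
  }
})

test_that("the sqrt(2) erfinv scaling yields unit-variance deviates", {
  set.seed(65)
  n <- 2e5
  s <- make_const_surfaces(sigma_x = 0.02, sigma_y = 0.02)
  d <- sample_direction(s, shared_cal(), rep(0, n), rep(0, n), runif(n))
  expect_equal(sd(d$vx), 0.02, tolerance = 0.01)
  d2 <- sample_direction(s, shared_cal(), rep(0, n), rep(0, n), runif(n),
                         use_sqrt2 = FALSE)
  expect_equal(sd(d2$vx), 0.02 / sqrt(2), tolerance = 0.01)
})

test_that("directions stay on the unit sphere even with pathological spread", {
  set.seed(66)
  s <- make_const_surfaces(vbar_x = 0.9, sigma_x = 0.3, sigma_y = 0.3)
  d <- sample_direction(s, shared_cal(), rep(60, 5000), rep(0, 5000), runif(5000))
  expect_true(all(d$vx^2 + d$vy^2 <= 1))
  expect_equal(d$vx^2 + d$vy^2 + d$vz^2, rep(1, 5000), tolerance = 1e-12)
})

test_that("particle type is an independent Bernoulli draw", {
  expect_equal(sample_type(1, runif(100)), rep(1L, 100))
  expect_equal(sample_type(0.993, 0.5), 1L)
  expect_equal(sample_type(0.993, 0.9945), 2L)
  set.seed(67)
  n <- 1e5
  frac <- mean(sample_type(0.993, runif(n)) == 2L)
  expect_lt(abs(frac - 0.007), 3 * sqrt(0.007 * 0.993 / n))
})

test_that("generation is seed-deterministic and respects invariants", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 2.5e5, seed = 68))
  vsm <- build_vsm(ps, cal = shared_cal())
  a <- generate_particles(vsm, 2e4, seed = 5)
  b <- generate_particles(vsm, 2e4, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_silent(vsmbeam:::validate_particle_set(as.data.frame(a)))
  c <- generate_particles(vsm, 2e4, seed = 6)
  expect_false(identical(a$x, c$x))
  # photon fraction matches the builder's estimate
  expect_lt(abs(mean(a$t == 1L) - vsm$p_gamma), 3 * sqrt(0.007 / 2e4))
  # variable order in the record matches the phase-space layout
  expect_named(as.data.frame(a), c("t", "e", "x", "y", "vx", "vy"))
})

test_that("a reloaded model generates the identical particle stream", {
  ps <- make_synthetic_phsp(synthetic_beam_params(n = 2.5e5, seed = 69))
  vsm <- build_vsm(ps, cal = shared_cal())
  f <- withr::local_tempfile(fileext = ".vsm.json")
  write_vsm(vsm, f)
  vsm2 <- read_vsm(f)
  expect_identical(vsm2$surfaces$surfaces$v_x$primary,
                   unname(vsm$surfaces$surfaces$v_x$primary))
  expect_identical(vsm2$p_gamma, vsm$p_gamma)
  a <- generate_particles(vsm, 1e4, seed = 77)
  b <- generate_particles(vsm2, 1e4, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
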