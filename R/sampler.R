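# Particle generation from a virtual source model.
#
# Six uniform variates per particle, in a fixed sequence:
#   U1 -> radial position through the inverse-CDF spline
#   U2 -> azimuth (rotational symmetry upstream of the collimators)
#   U3 -> energy through the radial bin's inverse-CDF spline
#   U4x, U4y -> direction-cosine deviations; each is SOU-correlated to U3
#               (energy-direction correlation), turned into a standard
#               normal with the inverse error function, mixed with a
#               one-sided Cholesky step (lateral-cosine correlation) and
#               scaled by the local spread surface
#   U5 -> particle type (photon/electron), independent of the rest

#' Sample particle positions
#'
#' `r = F^-1(U1)`, `theta = 360 * U2` degrees, `(x, y) = r (cos, sin)`.
#'
#' @param m A [build_radial_model()] result.
#' @param u1,u2 Uniform variates (same length).
#' @return A list with vectors `x`, `y`, `r`, `theta_deg`.
#' @export
sample_position <- function(m, u1, u2) {
  r <- eval_icdf(m$icdf, u1)
  theta <- 2 * pi * u2
  list(x = r * cos(theta), y = r * sin(theta), r = r, theta_deg = 360 * u2)
}

#' Sample particle energies
#'
#' `e = E_h^-1(U3)` where `h` is the radial bin containing `r`.
#'
#' @param m A [build_energy_model()] result.
#' @param r Radial distances, mm.
#' @param u3 Uniform variates (retained by the caller for the
#'   energy-direction correlation).
#' @return Energies, MeV.
#' @export
sample_energy <- function(m, r, u3) {
  h <- energy_bin_index(r)
  e <- numeric(length(r))
  for (b in unique(h)) {
    sel <- h == b
    e[sel] <- eval_icdf(m$icdfs[[b]], u3[sel])
  }
  e
}

#' Sample particle directions
#'
#' Evaluates the seven direction surfaces at each position and applies the
#' correlated sampling chain: `U4x`, `U4y` are SOU-correlated to `U3` with
#' `c = g(|rho_ev|)` (reflected for negative correlations), scaled to
#' (-1, 1) and passed through the inverse error function to give standard
#' normal deviates, which are mixed as `N_x <- rho_v N_y +
#' sqrt(1 - rho_v^2) N_x` and scaled by the local spread, so
#' `v_k = vbar_k + N_k sigma_k`; finally `vz = +sqrt(1 - vx^2 - vy^2)`.
#' Draws that would leave the unit sphere are redrawn (up to `max_redraw`
#' attempts) and then clamped by renormalisation; the count is returned as
#' attribute `"n_renormalized"`.
#'
#' @param ds A [fit_direction_surfaces()] result.
#' @param cal A [sou_calibrate()] result.
#' @param x,y Positions, mm.
#' @param u3 The uniform variates that generated the energies.
#' @param lambda_e Attenuation of a normal-score correlation on the energy
#'   scale for each particle's radial bin (`cor(E^-1(U), qnorm(U))`, as
#'   stored by [build_energy_model()]).  The chain targets the surface's
#'   `corr(e, v)` on this scale; the default 1 targets the normal-score
#'   coupling directly.
#' @param use_sqrt2 Scale the inverse error function so the deviate has
#'   unit variance (default `TRUE`; `FALSE` reproduces a plain
#'   `erfinv(2 U4 - 1)` deviate with variance 1/2).
#' @param compensate_rho_v Correct the normal-mix coefficient for the
#'   coupling that `U4x` and `U4y` already share through `U3` (default
#'   `TRUE`).  Because both deviates are SOU-correlated to the same energy
#'   variate, they arrive at the mix already correlated by roughly the
#'   product of their normal-score couplings; mixing with the raw
#'   `rho_v` on top of that double-counts the correlation.  `FALSE`
#'   applies the one-sided mix literally.
#' @param max_redraw Redraw attempts before renormalising (default 100).
#' @return A list with vectors `vx`, `vy`, `vz` and attributes
#'   `"n_redrawn"`, `"n_renormalized"`.
#' @export
sample_direction <- function(ds, cal, x, y, u3, lambda_e = 1,
                             use_sqrt2 = TRUE, compensate_rho_v = TRUE,
                             max_redraw = 100L) {
  p <- predict_direction(ds, x, y)
  n <- length(x)
  lambda_e <- pmax(rep_len(lambda_e, n), 1e-6)
  rho_v <- clamp(p$rho_v, -1 + 1e-9, 1 - 1e-9)

  # the surfaces prescribe corr(e, v); the chain realizes the calibrated
  # normal-score coupling attenuated by the energy spectrum, so the SOU
  # parameter is chosen on that scale
  chain_setup <- function(rho) {
    m_req <- clamp(abs(rho) / lambda_e, 0, 1)
    cc <- sou_g_normal(cal, m_req)
    # couplings below the c = 10 floor are realized exactly by mixing the
    # weakest chain with independent draws in the right proportion
    below <- is.na(cc)
    if (any(below)) {
      m_min <- min(cummin(cal_rho_normal(cal)))
      use_chain <- stats::runif(sum(below)) < m_req[below] / m_min
      cc[below][use_chain] <- max(cal$c_grid)
    }
    list(cc = cc, rn = m_req * sign(rho), sgn = sign(rho))
  }
  chx <- chain_setup(p$rho_ex)
  chy <- chain_setup(p$rho_ey)

  if (compensate_rho_v) {
    # pre-mix coupling m of the two normal deviates via the shared U3;
    # solve a + sqrt(1 - a^2) m = rho_v for the mix coefficient a
    m <- chx$rn * chy$rn
    disc <- pmax(1 - rho_v^2 + m^2, 0)
    rho_v <- clamp((rho_v - m * sqrt(disc)) / (1 + m^2), -1 + 1e-9, 1 - 1e-9)
  }

  draw_u4 <- function(ch, idx) {
    cc <- ch$cc[idx]
    v <- stats::runif(length(idx))
    u4 <- ifelse(is.na(cc), v, sou_pair(u3[idx], ifelse(is.na(cc), 0, cc), v))
    neg <- ch$sgn[idx] < 0
    u4[neg] <- 1 - u4[neg]
    u4
  }

  draw_eps <- function(idx) {
    u4x <- draw_u4(chx, idx)
    u4y <- draw_u4(chy, idx)
    scaled_x <- clamp(2 * u4x - 1, -(1 - 1e-12), 1 - 1e-12)
    scaled_y <- clamp(2 * u4y - 1, -(1 - 1e-12), 1 - 1e-12)
    nx <- erfinv(scaled_x)
    ny <- erfinv(scaled_y)
    if (use_sqrt2) {
      nx <- sqrt(2) * nx
      ny <- sqrt(2) * ny
    }
    nx <- rho_v[idx] * ny + sqrt(1 - rho_v[idx]^2) * nx
    list(ex = nx * p$sigma_x[idx], ey = ny * p$sigma_y[idx])
  }

  eps <- draw_eps(seq_len(n))
  vx <- p$vbar_x + eps$ex
  vy <- p$vbar_y + eps$ey
  n_redrawn <- 0L
  bad <- which(vx^2 + vy^2 > 1)
  attempts <- 0L
  while (length(bad) > 0L && attempts < max_redraw) {
    n_redrawn <- max(n_redrawn, length(bad))
    eps_b <- draw_eps(bad)
    vx[bad] <- p$vbar_x[bad] + eps_b$ex
    vy[bad] <- p$vbar_y[bad] + eps_b$ey
    bad <- bad[vx[bad]^2 + vy[bad]^2 > 1]
    attempts <- attempts + 1L
  }
  n_renorm <- length(bad)
  if (n_renorm > 0L) {
    f <- sqrt((1 - 1e-12) / (vx[bad]^2 + vy[bad]^2))
    vx[bad] <- vx[bad] * f
    vy[bad] <- vy[bad] * f
  }
  out <- list(vx = vx, vy = vy, vz = sqrt(pmax(0, 1 - vx^2 - vy^2)))
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "n_renormalized") <- n_renorm
  out
}

#' Sample particle types
#'
#' Photon iff `U5 <= p_gamma`, electron otherwise, independent of all
#' other variates.
#'
#' @param p_gamma Photon fraction in `[0, 1]`.
#' @param u5 Uniform variates.
#' @return Integer species codes (1 photon, 2 electron).
#' @export
sample_type <- function(p_gamma, u5) {
  stopifnot(p_gamma >= 0, p_gamma <= 1)
  ifelse(u5 <= p_gamma, 1L, 2L)
}

#' Generate particles from a virtual source model
#'
#' Runs the full sampling sequence (position, energy, direction, type) for
#' `n` particles.  Deterministic for a fixed seed.
#'
#' @param vsm A [build_vsm()] result.
#' @param n Number of particles, `>= 1`.
#' @param seed RNG seed.
#' @param use_sqrt2 See [sample_direction()].
#' @return A [particle_set()]; the redraw/renormalisation counters of
#'   [sample_direction()] are attached as attributes.
#' @export
generate_particles <- function(vsm, n, seed = 1L, use_sqrt2 = TRUE) {
  stopifnot(inherits(vsm, "virtual_source_model"), n >= 1)
  set.seed(seed)
  n <- as.integer(n)
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  pos <- sample_position(vsm$radial, u1, u2)
  e <- sample_energy(vsm$energy, pos$r, u3)
  lam <- vsm$energy$normal_attenuation
  lambda_e <- if (is.null(lam)) 1 else lam[energy_bin_index(pos$r)]
  dir <- sample_direction(vsm$surfaces, vsm$cal, pos$x, pos$y, u3,
                          lambda_e = lambda_e, use_sqrt2 = use_sqrt2)
  u5 <- stats::runif(n)
  t <- sample_type(vsm$p_gamma, u5)
  ps <- particle_set(t, e, pos$x, pos$y, dir$vx, dir$vy, validate = FALSE)
  attr(ps, "n_redrawn") <- attr(dir, "n_redrawn")
  attr(ps, "n_renormalized") <- attr(dir, "n_renormalized")
  ps
}
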