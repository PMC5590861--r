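# Direction modelling: per-bin statistics on a regular grid over the
# scoring plane, the primary/secondary split, and the seven weighted
# polynomial surface fits that constitute the direction model.

#' Per-bin direction statistics on a regular grid
#'
#' Divides the scoring plane into `grid_n x grid_n` square cells (default
#' 141 cells of 1 x 1 mm^2, centred on the beam axis, so the extent is
#' [-70.5, +70.5) mm with cells half-open on their upper edges) and
#' computes, for the photons in each cell: the count, the mean direction
#' cosines along x and y, their sample standard deviation and standard
#' error, the Pearson correlations between energy and each lateral cosine,
#' and the correlation between the two lateral cosines.  Particles outside
#' the grid are excluded from the statistics.
#'
#' @param ps A [particle_set()].
#' @param grid_n Number of cells per axis (default 141).
#' @param cell_mm Cell size, mm (default 1).
#' @param photons_only Use photons only (default `TRUE`).
#' @return An object of class `direction_grid`: a `data.table` of per-bin
#'   statistics plus grid metadata.  Bins with fewer than 2 particles have
#'   their spread and correlation statistics flagged invalid; correlations
#'   of constant sequences are stored as 0 and flagged invalid.
#' @export
build_direction_grid <- function(ps, grid_n = 141L, cell_mm = 1, photons_only = TRUE) {
  grid_n <- as.integer(grid_n)
  half <- grid_n * cell_mm / 2
  dt <- data.table::data.table(t = ps$t, e = ps$e, x = ps$x, y = ps$y,
                               vx = ps$vx, vy = ps$vy)
  if (photons_only) dt <- dt[dt$t == 1L]
  n_species <- nrow(dt)
  ix <- as.integer(floor((dt$x + half) / cell_mm)) + 1L
  iy <- as.integer(floor((dt$y + half) / cell_mm)) + 1L
  inside <- ix >= 1L & ix <= grid_n & iy >= 1L & iy <= grid_n
  dt <- dt[inside]
  dt[, c("ix", "iy") := list(ix[inside], iy[inside])]

  safe_cor <- function(a, b) {
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  ix_ <- iy_ <- NULL # data.table NSE
  stats_dt <- dt[, {
    nn <- .N
    list(n = nn,
         vbar_x = mean(vx), vbar_y = mean(vy),
         sd_x = if (nn >= 2L) stats::sd(vx) else NA_real_,
         sd_y = if (nn >= 2L) stats::sd(vy) else NA_real_,
         rho_ex = safe_cor(e, vx), rho_ey = safe_cor(e, vy),
         rho_v = safe_cor(vx, vy),
         cor_valid = nn >= 2L && stats::sd(vx) > 0 && stats::sd(vy) > 0 && stats::sd(e) > 0)
  }, by = c("ix", "iy")]
  stats_dt[, c("se_x", "se_y") := list(stats_dt$sd_x / sqrt(stats_dt$n),
                                       stats_dt$sd_y / sqrt(stats_dt$n))]
  centers <- -half + cell_mm * (seq_len(grid_n) - 0.5)
  stats_dt[, c("xc", "yc") := list(centers[stats_dt$ix], centers[stats_dt$iy])]
  g <- list(stats = stats_dt, grid_n = grid_n, cell_mm = cell_mm, half = half,
            centers = centers, n_total = n_species, n_in_grid = nrow(dt))
  class(g) <- "direction_grid"
  g
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("<direction_grid> %d x %d cells of %.3g mm, %d of %d photons inside\n",
              x$grid_n, x$grid_n, x$cell_mm, x$n_in_grid, x$n_total))
  invisible(x)
}

# full grid_n x grid_n matrix of counts (empty bins are 0)
grid_count_matrix <- function(g) {
  m <- matrix(0L, g$grid_n, g$grid_n)
  m[cbind(g$stats$ix, g$stats$iy)] <- g$stats$n
  m
}

#' Split the grid into primary and secondary photon regions
#'
#' A bin belongs to the primary (unscattered-dominated) region when its
#' photon count is at least `frac` of the maximum bin count.  The boundary
#' radius `T` separating the regions is the radius of the largest circle
#' about the beam axis that contains only primary bins (measured at bin
#' centres); when every bin is primary, `T` is the largest bin-centre
#' radius.
#'
#' With finitely many particles per bin, Poisson speckle inflates the
#' observed maximum and lets single down-fluctuated bins puncture the
#' primary region, biasing both the threshold and `T` at moderate counts.
#' The rule is therefore applied to a box-smoothed count map (`smooth` is
#' the filter half-width; `0` applies the rule to the raw counts).  On
#' well-populated grids the two versions coincide, since the fluence
#' plateau is flat on the smoothing scale.
#'
#' @param g A [build_direction_grid()] result.
#' @param frac Count threshold as a fraction of the maximum (default 0.2).
#' @param smooth Half-width of the box mean filter applied to the count
#'   map before thresholding (default 1, i.e. 3 x 3; 0 disables).
#' @return A list with `mask` (logical `grid_n x grid_n` matrix), `T_mm`,
#'   `frac`, and `primary_fraction` (fraction of in-grid photons in primary
#'   bins).
#' @export
determine_primary_region <- function(g, frac = 0.2, smooth = 1L) {
  counts <- grid_count_matrix(g)
  if (max(counts) == 0L) stop("direction grid is empty", call. = FALSE)
  sm <- box_smooth(counts, smooth)
  mask <- sm >= frac * max(sm)
  cr <- sqrt(outer(g$centers^2, g$centers^2, `+`))
  T_mm <- if (all(mask)) max(cr) else min(cr[!mask])
  list(mask = mask, T_mm = T_mm, frac = frac, smooth = as.integer(smooth),
       primary_fraction = sum(counts[mask]) / sum(counts))
}

# box mean filter with edge renormalisation
box_smooth <- function(m, k) {
  k <- as.integer(k)
  if (k <= 0L) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  cnt <- matrix(0, n1, n2)
  for (di in -k:k) {
    for (dj in -k:k) {
      si <- max(1, 1 + di):min(n1, n1 + di); ti <- max(1, 1 - di):min(n1, n1 - di)
      sj <- max(1, 1 + dj):min(n2, n2 + dj); tj <- max(1, 1 - dj):min(n2, n2 - dj)
      out[ti, tj] <- out[ti, tj] + m[si, sj]
      cnt[ti, tj] <- cnt[ti, tj] + 1
    }
  }
  out / cnt
}

# ---- polynomial surfaces ----------------------------------------------------

# Eq-style piecewise term sets for the mean-cosine surfaces: with k the
# cosine axis and k' the other one, the primary region uses {1, k, k'} and
# the secondary region {1, k, k', k^2, k k', k^3, k^2 k'}.
vhat_design <- function(k, kp, region) {
  if (region == "primary") cbind(1, k, kp)
  else cbind(1, k, kp, k^2, k * kp, k^3, k^2 * kp)
}

surface_eval <- function(fit, x, y) {
  scale <- fit$scale %||% 1
  X <- poly2d_design(x / scale, y / scale, fit$degree)
  drop(X %*% fit$coefficients)
}

vhat_eval <- function(fit, x, y) {
  r <- radial_distance(x, y)
  k <- if (fit$axis == "x") x else y
  kp <- if (fit$axis == "x") y else x
  out <- numeric(length(x))
  prim <- r <= fit$T_mm
  if (any(prim)) {
    out[prim] <- drop(vhat_design(k[prim], kp[prim], "primary") %*% fit$primary)
  }
  if (any(!prim)) {
    out[!prim] <- drop(vhat_design(k[!prim], kp[!prim], "secondary") %*% fit$secondary)
  }
  out
}

#' Fit the seven direction surfaces
#'
#' Weighted least-squares fits to the per-bin direction statistics, with
#' inverse-variance weights `w = 1 / se^2` built from the standard error of
#' the bin's mean cosine (heteroscedasticity correction).  The mean-cosine
#' surfaces are piecewise: a linear surface `{1, k, k'}` inside the primary
#' region (`r <= T`) and a restricted cubic `{1, k, k', k^2, kk', k^3,
#' k^2k'}` outside.  The spread and correlation surfaces are single
#' full-plane polynomials of total degree 4 (`sigma^x`, `sigma^y`), 3
#' (`rho^ex`, `rho^ey`) and 5 (`rho^v`); the cross-correlation surface
#' `rho^v`, which has no variance of its own, is weighted by
#' `1 / (se_x * se_y)`.  Evaluations of the correlation surfaces are
#' clamped to [-1, 1] and the spread surfaces to `>= 0`.
#'
#' @param g A [build_direction_grid()] result.
#' @param region A [determine_primary_region()] result.
#' @param sigma_mode Which per-bin statistic the spread surfaces are fitted
#'   to: `"sd"` (sample standard deviation, the default -- this is the
#'   spread the sampler reproduces) or `"se"` (standard error of the mean,
#'   a literal reading under which the modelled spread shrinks with bin
#'   occupancy).
#' @param min_bin_count Bins with fewer photons are excluded from all fits
#'   (default 10).
#' @return An object of class `direction_surfaces` containing the seven
#'   fits, the boundary radius `T_mm`, the fit weights' provenance and
#'   per-fit adjusted r-squared values.
#' @export
fit_direction_surfaces <- function(g, region, sigma_mode = c("sd", "se"),
                                   min_bin_count = 10L) {
  sigma_mode <- match.arg(sigma_mode)
  s <- g$stats
  ok <- s$n >= min_bin_count & is.finite(s$se_x) & is.finite(s$se_y) &
    s$se_x > 0 & s$se_y > 0
  s <- s[ok]
  in_primary <- region$mask[cbind(s$ix, s$iy)]
  T_mm <- region$T_mm
  adj_r2 <- list()

  fit_vhat <- function(axis) {
    k <- if (axis == "x") s$xc else s$yc
    kp <- if (axis == "x") s$yc else s$xc
    z <- if (axis == "x") s$vbar_x else s$vbar_y
    w <- 1 / (if (axis == "x") s$se_x else s$se_y)^2
    for (reg in c("primary", "secondary")) {
      sel <- if (reg == "primary") in_primary else !in_primary
      if (sum(sel) < 10L) {
        stop("fewer than 10 valid bins for the ", reg, " mean-cosine surface (v^",
             axis, ")", call. = FALSE)
      }
    }
    fp <- wls_fit(vhat_design(k[in_primary], kp[in_primary], "primary"),
                  z[in_primary], w[in_primary],
                  label = paste0("v^", axis, " primary"))
    fs <- wls_fit(vhat_design(k[!in_primary], kp[!in_primary], "secondary"),
                  z[!in_primary], w[!in_primary],
                  label = paste0("v^", axis, " secondary"))
    adj_r2[[paste0("v_", axis)]] <<- c(primary = fp$adj_r2, secondary = fs$adj_r2)
    list(axis = axis, T_mm = T_mm, primary = fp$coefficients,
         secondary = fs$coefficients)
  }

  fit_plane <- function(z, w, degree, label) {
    if (sum(is.finite(z) & is.finite(w) & w > 0) < 10L) {
      stop("fewer than 10 valid bins for the ", label, " surface", call. = FALSE)
    }
    use <- is.finite(z) & is.finite(w) & w > 0
    X <- poly2d_design(s$xc[use] / g$half, s$yc[use] / g$half, degree)
    f <- wls_fit(X, z[use], w[use], label = label)
    adj_r2[[label]] <<- f$adj_r2
    list(degree = degree, scale = g$half, coefficients = f$coefficients)
  }

  sig_x <- if (sigma_mode == "sd") s$sd_x else s$se_x
  sig_y <- if (sigma_mode == "sd") s$sd_y else s$se_y
  cw <- ifelse(s$cor_valid, 1, 0)
  surf <- list(
    v_x = fit_vhat("x"),
    v_y = fit_vhat("y"),
    sigma_x = fit_plane(sig_x, 1 / s$se_x^2, 4L, "sigma_x"),
    sigma_y = fit_plane(sig_y, 1 / s$se_y^2, 4L, "sigma_y"),
    rho_ex = fit_plane(s$rho_ex, cw / s$se_x^2, 3L, "rho_ex"),
    rho_ey = fit_plane(s$rho_ey, cw / s$se_y^2, 3L, "rho_ey"),
    rho_v = fit_plane(s$rho_v, cw / (s$se_x * s$se_y), 5L, "rho_v")
  )
  out <- list(surfaces = surf, T_mm = T_mm, sigma_mode = sigma_mode,
              min_bin_count = as.integer(min_bin_count),
              primary_fraction = region$primary_fraction,
              frac = region$frac, half = g$half, adj_r2 = adj_r2,
              primary_mask = region$mask)
  class(out) <- "direction_surfaces"
  out
}

#' Evaluate the direction surfaces at positions
#'
#' @param ds A [fit_direction_surfaces()] result.
#' @param x,y Positions, mm.
#' @return A list of vectors `vbar_x`, `vbar_y`, `sigma_x`, `sigma_y`
#'   (clamped to `>= 0`), `rho_ex`, `rho_ey`, `rho_v` (clamped to
#'   `[-1, 1]`).
#' @export
predict_direction <- function(ds, x, y) {
  stopifnot(inherits(ds, "direction_surfaces"))
  list(
    vbar_x = vhat_eval(ds$surfaces$v_x, x, y),
    vbar_y = vhat_eval(ds$surfaces$v_y, x, y),
    sigma_x = pmax(surface_eval(ds$surfaces$sigma_x, x, y), 0),
    sigma_y = pmax(surface_eval(ds$surfaces$sigma_y, x, y), 0),
    rho_ex = clamp(surface_eval(ds$surfaces$rho_ex, x, y), -1, 1),
    rho_ey = clamp(surface_eval(ds$surfaces$rho_ey, x, y), -1, 1),
    rho_v = clamp(surface_eval(ds$surfaces$rho_v, x, y), -1, 1)
  )
}

#' Residual direction statistics on a coarse grid
#'
#' Subtracts the fitted mean-cosine surfaces from each photon's direction
#' cosines and pools the residuals on a coarse block grid.  Because the
#' mean field varies strongly across a multi-millimetre block, raw
#' block-level spreads and correlations mix the field's spatial variation
#' into the noise statistics; residual statistics isolate the stochastic
#' component that the spread and correlation surfaces model, at sample
#' sizes where correlation estimates are reliable.
#'
#' @param ps A [particle_set()].
#' @param ds A [fit_direction_surfaces()] result providing the mean field.
#' @param grid_n Blocks per axis (default 14).
#' @param cell_mm Block size, mm (default 10).
#' @param photons_only Use photons only (default `TRUE`).
#' @return A `data.table` with per-block `n`, residual spreads `sd_rx`,
#'   `sd_ry`, and residual correlations `rho_v` (x vs y) and `rho_ex`,
#'   `rho_ey` (energy vs each residual).
#' @export
direction_residual_stats <- function(ps, ds, grid_n = 14L, cell_mm = 10,
                                     photons_only = TRUE) {
  stopifnot(inherits(ds, "direction_surfaces"))
  if (photons_only) ps <- ps[ps$t == 1L, , drop = FALSE]
  pred <- predict_direction(ds, ps$x, ps$y)
  half <- grid_n * cell_mm / 2
  dt <- data.table::data.table(
    e = ps$e,
    rx = ps$vx - pred$vbar_x,
    ry = ps$vy - pred$vbar_y,
    ix = as.integer(floor((ps$x + half) / cell_mm)) + 1L,
    iy = as.integer(floor((ps$y + half) / cell_mm)) + 1L)
  dt <- dt[dt$ix >= 1L & dt$ix <= grid_n & dt$iy >= 1L & dt$iy <= grid_n]
  rx <- ry <- e <- NULL # data.table NSE
  cor_nd <- function(a, b) {
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  out <- dt[, {
    list(n = .N,
         sd_rx = stats::sd(rx), sd_ry = stats::sd(ry),
         rho_v = cor_nd(rx, ry),
         rho_ex = cor_nd(e, rx),
         rho_ey = cor_nd(e, ry))
  }, by = c("ix", "iy")]
  centers <- -half + cell_mm * (seq_len(grid_n) - 0.5)
  out[, c("xc", "yc") := list(centers[out$ix], centers[out$iy])]
  out
}

#' @export
print.direction_surfaces <- function(x, ...) {
  cat(sprintf("<direction_surfaces> T = %.2f mm, primary fraction %.4f, sigma mode '%s'\n",
              x$T_mm, x$primary_fraction, x$sigma_mode))
  invisible(x)
}
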