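# Independent oracles and small fixture builders used across the suite.

# brute-force per-bin direction statistics: plain loops over split indices,
# no shared code with build_direction_grid()
brute_force_grid_stats <- function(ps, grid_n, cell_mm) {
  half <- grid_n * cell_mm / 2
  keep <- ps$t == 1L
  df <- as.data.frame(ps)[keep, ]
  ix <- floor((df$x + half) / cell_mm) + 1
  iy <- floor((df$y + half) / cell_mm) + 1
  inside <- ix >= 1 & ix <= grid_n & iy >= 1 & iy <= grid_n
  df <- df[inside, ]
  key <- paste(ix[inside], iy[inside])
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    n <- nrow(sub)
    rec <- list(ix = as.integer(strsplit(k, " ")[[1]][1]),
                iy = as.integer(strsplit(k, " ")[[1]][2]),
                n = n,
                vbar_x = mean(sub$vx), vbar_y = mean(sub$vy),
                sd_x = if (n >= 2) sd(sub$vx) else NA_real_,
                sd_y = if (n >= 2) sd(sub$vy) else NA_real_)
    rec$rho_ex <- if (n >= 2 && sd(sub$e) > 0 && sd(sub$vx) > 0) cor(sub$e, sub$vx) else 0
    rec$rho_ey <- if (n >= 2 && sd(sub$e) > 0 && sd(sub$vy) > 0) cor(sub$e, sub$vy) else 0
    rec$rho_v <- if (n >= 2 && sd(sub$vx) > 0 && sd(sub$vy) > 0) cor(sub$vx, sub$vy) else 0
    out[[k]] <- rec
  }
  out
}

# exhaustive gamma: for each reference pixel above threshold, search every
# node of a finely interpolated evaluated plane within the given radius
brute_force_gamma <- function(ref, ev, dose_pct, dist_mm, threshold_pct = 10,
                              search_mm = 4 * dist_mm, step = dist_mm / 10) {
  rax <- list(x = ref$origin[1] + ref$spacing[1] * (seq_len(nrow(ref$values)) - 1),
              y = ref$origin[2] + ref$spacing[2] * (seq_len(ncol(ref$values)) - 1))
  eax <- list(x = ev$origin[1] + ev$spacing[1] * (seq_len(nrow(ev$values)) - 1),
              y = ev$origin[2] + ev$spacing[2] * (seq_len(ncol(ev$values)) - 1))
  d_max <- max(ref$values)
  dd_max <- dose_pct / 100 * d_max
  thresh <- threshold_pct / 100 * d_max
  offs <- expand.grid(dx = seq(-search_mm, search_mm, by = step),
                      dy = seq(-search_mm, search_mm, by = step))
  offs <- offs[offs$dx^2 + offs$dy^2 <= search_mm^2, ]
  # bilinear interpolation of the evaluated plane at arbitrary points
  interp <- function(px, py) {
    fx <- (px - eax$x[1]) / ev$spacing[1]
    fy <- (py - eax$y[1]) / ev$spacing[2]
    nx <- length(eax$x); ny <- length(eax$y)
    ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
    i0 <- pmin(pmax(floor(fx), 0), nx - 2); j0 <- pmin(pmax(floor(fy), 0), ny - 2)
    tx <- fx - i0; ty <- fy - j0
    v <- (1 - tx) * (1 - ty) * ev$values[cbind(i0 + 1, j0 + 1)] +
      tx * (1 - ty) * ev$values[cbind(i0 + 2, j0 + 1)] +
      (1 - tx) * ty * ev$values[cbind(i0 + 1, j0 + 2)] +
      tx * ty * ev$values[cbind(i0 + 2, j0 + 2)]
    v[!ok] <- NA
    v
  }
  gmap <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  for (i in seq_len(nrow(ref$values))) {
    for (j in seq_len(ncol(ref$values))) {
      rd <- ref$values[i, j]
      if (rd < thresh) next
      dv <- interp(rax$x[i] + offs$dx, rax$y[j] + offs$dy)
      g2 <- ((dv - rd) / dd_max)^2 + (offs$dx^2 + offs$dy^2) / dist_mm^2
      gmap[i, j] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  gmap
}

# constant-field direction surfaces for sampler tests
make_const_surfaces <- function(vbar_x = 0, vbar_y = 0, sigma_x = 0.01,
                                sigma_y = sigma_x, rho_ex = 0, rho_ey = 0,
                                rho_v = 0, T_mm = 50) {
  const_plane <- function(v) list(degree = 0L, scale = 1, coefficients = v)
  s <- list(surfaces = list(
    v_x = list(axis = "x", T_mm = T_mm, primary = c(vbar_x, 0, 0),
               secondary = c(vbar_x, 0, 0, 0, 0, 0, 0)),
    v_y = list(axis = "y", T_mm = T_mm, primary = c(vbar_y, 0, 0),
               secondary = c(vbar_y, 0, 0, 0, 0, 0, 0)),
    sigma_x = const_plane(sigma_x), sigma_y = const_plane(sigma_y),
    rho_ex = const_plane(rho_ex), rho_ey = const_plane(rho_ey),
    rho_v = const_plane(rho_v)),
    T_mm = T_mm, sigma_mode = "sd", min_bin_count = 10L,
    primary_fraction = 1, frac = 0.2, half = 70.5, adj_r2 = list())
  class(s) <- "direction_surfaces"
  s
}

# small calibration shared across tests (built once per test run)
shared_cal <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- sou_calibrate(seed = 42, n = 5e4)
    cal
  }
})

# smooth test plane: flattened peak with penumbra-like edges
test_plane <- function(n = 64, spacing = 1, width = 20, penumbra = 4,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  ax <- spacing * (seq_len(n) - (n + 1) / 2)
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  prof <- function(u) (erf((width - u) / penumbra) + erf((width + u) / penumbra)) / 2
  v <- outer(prof(ax), prof(ax)) + 0.02
  if (noise_sd > 0) v <- v * (1 + noise_sd * rnorm(n * n))
  plane2d(v, spacing)
}
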