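# Inverse-CDF spline models.
#
# Both the radial-position model and the per-bin energy spectra are stored
# as fitted inverse cumulative distribution functions: the empirical CDF is
# inverted onto the probability axis, least-squares fitted with a B-spline
# of the requested polynomial order and equally spaced interior knots in
# [0, 1], and finally projected onto nondecreasing values on a dense
# evaluation grid.  Sampling is then a single inverse-transform lookup.

.ICDF_EVAL_N <- 2001L

# interior knots at equal arclength along the normalised quantile curve, so
# segments concentrate where the inverse CDF bends (beam shoulder, halo
# tail) instead of being spaced uniformly in probability
arclength_knots <- function(u, q, segments) {
  if (segments <= 1L) return(NULL)
  qr <- diff(range(q))
  qn <- if (qr > 0) (q - min(q)) / qr else q * 0
  s <- c(0, cumsum(sqrt(diff(u)^2 + diff(qn)^2)))
  targets <- seq(0, max(s), length.out = segments + 1L)[-c(1, segments + 1L)]
  knots <- stats::approx(s, u, xout = targets, ties = "ordered")$y
  # keep knots strictly interior and strictly increasing
  knots <- pmin(pmax(knots, 1e-6), 1 - 1e-6)
  unique(knots)
}

# least-squares spline fit of quantile values q(u), then monotone projection.
# Returns the dense (u, q) table actually used for evaluation.
fit_icdf_spline <- function(u, q, segments, degree, eval_n = .ICDF_EVAL_N) {
  stopifnot(length(u) == length(q), segments >= 1, degree >= 1)
  u_grid <- seq(0, 1, length.out = eval_n)
  n_basis <- segments - 1L + degree + 1L
  if (length(unique(q)) > n_basis && length(u) > n_basis) {
    knots <- arclength_knots(u, q, segments)
    X <- splines::bs(u, knots = knots, degree = degree, intercept = TRUE,
                     Boundary.knots = c(0, 1))
    fit <- stats::lm.fit(X, q)
    if (anyNA(fit$coefficients)) {
      # rank-deficient basis (knots collapsed on a near-degenerate
      # quantile curve): use the raw inverted CDF instead
      q_grid <- stats::approx(u, q, xout = u_grid, rule = 2, ties = "ordered")$y
    } else {
      Xg <- splines::bs(u_grid, knots = knots, degree = degree, intercept = TRUE,
                        Boundary.knots = c(0, 1))
      q_grid <- drop(Xg %*% fit$coefficients)
    }
  } else {
    # too little structure for a spline (e.g. a degenerate spectrum):
    # fall back to the raw inverted CDF
    q_grid <- stats::approx(u, q, xout = u_grid, rule = 2, ties = "ordered")$y
  }
  # projection onto nondecreasing values at the evaluation knots
  q_grid <- cummax(q_grid)
  if (is.unsorted(q_grid)) {
    stop("inverse-CDF fit is non-monotone after constraint enforcement near u = ",
         u_grid[which(diff(q_grid) < 0)[1]], call. = FALSE)
  }
  list(u = u_grid, q = q_grid)
}

eval_icdf <- function(icdf, u) {
  stats::approx(icdf$u, icdf$q, xout = clamp(u, 0, 1), rule = 2,
                ties = "ordered")$y
}

#' Fit the radial-position model
#'
#' Histograms the radial distances with the given bin width, inverts the
#' cumulative distribution onto the probability axis and fits it with a
#' piecewise-polynomial spline (default: 30 segments of order 4), giving
#' the inverse CDF `F^-1` used for inverse-transform sampling of `r`.
#'
#' @param ps A [particle_set()] (all species).
#' @param bin_width Histogram bin width, mm (default 0.1).
#' @param segments Number of spline segments (default 30).
#' @param degree Polynomial order of each segment (default 4).
#' @return An object of class `radial_position_model` with fields `icdf`
#'   (dense monotone `(u, q)` table), `bin_width`, `segments`, `degree`
#'   and `r_max`.
#' @export
build_radial_model <- function(ps, bin_width = 0.1, segments = 30L, degree = 4L) {
  r <- ps_r(ps)
  if (length(r) < 10 * segments) {
    stop("need at least ", 10 * segments, " particles to fit the radial model",
         call. = FALSE)
  }
  r_max <- max(r)
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  counts <- tabulate(findInterval(r, breaks, left.open = TRUE) + 1L,
                     nbins = length(breaks) - 1L)
  # invert the histogram CDF: nodes at the upper edges of occupied bins
  # (plus the lower edge of the first one), which keeps the inversion well
  # posed across empty bins and for degenerate distributions
  nz <- which(counts > 0)
  cdf <- cumsum(counts) / length(r)
  xs <- c(breaks[nz[1]], breaks[nz + 1L])
  us <- c(0, cdf[nz])
  q_u <- seq(0, 1, length.out = .ICDF_EVAL_N)
  q_vals <- stats::approx(us, xs, xout = q_u, rule = 2, ties = "ordered")$y
  icdf <- fit_icdf_spline(q_u, q_vals, segments, degree)
  icdf$q <- clamp(icdf$q, 0, r_max + bin_width)
  m <- list(icdf = icdf, bin_width = bin_width, segments = as.integer(segments),
            degree = as.integer(degree), r_max = r_max, n = length(r))
  class(m) <- "radial_position_model"
  m
}

#' @export
print.radial_position_model <- function(x, ...) {
  cat(sprintf("<radial_position_model> %d segments, order %d, r_max %.2f mm (n = %d)\n",
              x$segments, x$degree, x$r_max, x$n))
  invisible(x)
}

#' Radial bin index of the energy-spectrum table
#'
#' Maps a radial distance to one of the 35 spectrum bins: 25 bins of width
#' 2 mm covering (0, 50] mm, 9 bins of width 5 mm covering (50, 95] mm and
#' a final open bin for `r > 95` mm.  The lookup is total: every `r >= 0`
#' maps to exactly one bin.
#'
#' @param r Radial distances, mm.
#' @return Integer bin indices in `1:35`.
#' @export
energy_bin_index <- function(r) {
  edges <- c(seq(2, 50, by = 2), seq(55, 95, by = 5))
  findInterval(r, edges, left.open = TRUE) + 1L
}

.N_ENERGY_BINS <- 35L

#' Fit the radially binned energy-spectrum model
#'
#' Derives one energy spectrum per radial bin (see [energy_bin_index()]),
#' inverts each empirical CDF and fits it with a piecewise-polynomial
#' spline (default: 12 segments of order 5).  Under-populated bins fall
#' back to the nearest populated bin's spectrum with a warning.
#'
#' @param ps A [particle_set()].  By default all species contribute to the
#'   spectra; set `photons_only = TRUE` to restrict to photons.
#' @param segments Number of spline segments per spectrum (default 12).
#' @param degree Polynomial order (default 5).
#' @param min_bin_count Minimum particles per bin before the fallback
#'   applies (default 100).
#' @param photons_only Restrict spectra to photons (default `FALSE`).
#' @return An object of class `energy_spectrum_model`: a list of 35 inverse
#'   CDFs plus per-bin counts, energy ranges and fallback flags.
#' @export
build_energy_model <- function(ps, segments = 12L, degree = 5L,
                               min_bin_count = 100L, photons_only = FALSE) {
  if (photons_only) ps <- ps[ps$t == 1L, , drop = FALSE]
  r <- radial_distance(ps$x, ps$y)
  h <- energy_bin_index(r)
  counts <- tabulate(h, nbins = .N_ENERGY_BINS)
  if (all(counts < min_bin_count)) {
    stop("no radial bin holds at least ", min_bin_count, " particles",
         call. = FALSE)
  }
  u_grid <- seq(0, 1, length.out = 1001L)
  icdfs <- vector("list", .N_ENERGY_BINS)
  e_range <- matrix(NA_real_, .N_ENERGY_BINS, 2L)
  fallback <- integer(.N_ENERGY_BINS)
  populated <- which(counts >= min_bin_count)
  for (b in seq_len(.N_ENERGY_BINS)) {
    src <- b
    if (counts[b] < min_bin_count) {
      src <- populated[which.min(abs(populated - b))]
      fallback[b] <- src
    }
    eb <- ps$e[h == src]
    q <- unname(stats::quantile(eb, probs = u_grid, type = 7))
    icdfs[[b]] <- fit_icdf_spline(u_grid, q, segments, degree, eval_n = 1001L)
    icdfs[[b]]$q <- clamp(icdfs[[b]]$q, min(eb), max(eb))
    e_range[b, ] <- range(eb)
  }
  # attenuation of a normal-score correlation when carried onto the energy
  # scale: cor(E^-1(U), qnorm(U)) per bin (1 for a degenerate spectrum)
  attenuation <- vapply(icdfs, function(ic) {
    m <- length(ic$u)
    inner <- 2:(m - 1L)
    if (stats::sd(ic$q[inner]) == 0) return(1)
    stats::cor(ic$q[inner], stats::qnorm(ic$u[inner]))
  }, numeric(1))
  if (any(fallback > 0)) {
    warning(sprintf("%d under-populated radial bin(s) use the nearest populated spectrum: %s",
                    sum(fallback > 0), paste(which(fallback > 0), collapse = ", ")),
            call. = FALSE)
  }
  m <- list(icdfs = icdfs, counts = counts, e_range = e_range,
            fallback = fallback, normal_attenuation = attenuation,
            segments = as.integer(segments), degree = as.integer(degree))
  class(m) <- "energy_spectrum_model"
  m
}

#' @export
print.energy_spectrum_model <- function(x, ...) {
  cat(sprintf("<energy_spectrum_model> %d radial bins (%d via fallback), %d segments, order %d\n",
              .N_ENERGY_BINS, sum(x$fallback > 0), x$segments, x$degree))
  invisible(x)
}
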