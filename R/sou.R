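# Sum-of-uniforms (SOU) correlation induction between uniform variates.
#
# Two uniforms U and V are coupled through the sum S = U + c * V; applying
# the exact CDF of S (a trapezoid: quadratic ramps on [0, min(1, c)] and
# [max(1, c), 1 + c] with a linear plateau between) maps S back to an
# exactly uniform variate U4 whose Pearson correlation with U is a
# decreasing function of c (1 at c = 0).  The map between c and the
# realised correlation has no convenient closed form and is calibrated by
# Monte Carlo once, then inverted by monotone interpolation (function g).

#' Exact CDF of the sum of uniform(0,1) and c * uniform(0,1)
#'
#' @param s Quantiles.
#' @param c SOU parameter, `>= 0`.
#' @return `P(U + c V <= s)`, the probability-integral transform used by
#'   [sou_pair()].
#' @export
sou_cdf <- function(s, c) {
  if (any(c < 0)) stop("c must be >= 0", call. = FALSE)
  nn <- max(length(s), length(c))
  s <- rep_len(s, nn)
  c <- rep_len(c, nn)
  out <- numeric(nn)
  a <- pmin(1, c); b <- pmax(1, c)
  ramp_lo <- c > 0 & s > 0 & s <= a
  plateau <- s > a & s <= b
  ramp_hi <- c > 0 & s > b & s < 1 + c
  top <- s >= 1 + c
  deg <- c == 0 # degenerate sum: CDF of uniform(0,1) itself
  out[deg] <- clamp(s[deg], 0, 1)
  out[ramp_lo] <- s[ramp_lo]^2 / (2 * c[ramp_lo])
  out[plateau] <- (2 * s[plateau] - a[plateau]) / (2 * b[plateau])
  out[ramp_hi] <- 1 - (1 + c[ramp_hi] - s[ramp_hi])^2 / (2 * c[ramp_hi])
  out[top] <- 1
  out
}

#' Correlate a uniform variate with fresh uniform noise (SOU step)
#'
#' Returns `U4 = F_s(u + c * v)` where `F_s` is [sou_cdf()].  `U4` is
#' exactly uniform on [0, 1] and positively correlated with `u`; `c = 0`
#' returns `u` unchanged (correlation 1) and larger `c` weakens the
#' coupling.
#'
#' @param u Uniform variates in `[0, 1]`.
#' @param c SOU parameter(s), `>= 0` (scalar or one per element of `u`).
#' @param v Independent uniform noise; drawn internally when omitted.
#' @return Uniform variates in `[0, 1]`, same length as `u`.
#' @export
sou_pair <- function(u, c, v = NULL) {
  if (any(c < 0)) stop("c must be >= 0", call. = FALSE)
  if (is.null(v)) v <- stats::runif(length(u))
  c <- rep_len(c, length(u))
  out <- u
  nz <- c > 0
  if (any(nz)) out[nz] <- sou_cdf(u[nz] + c[nz] * v[nz], c[nz])
  out
}

#' Calibrate the SOU correlation map
#'
#' For each `c` on the grid (default 0 to 10, step 0.2), draws `n`
#' independent uniform pairs, couples them with [sou_pair()] and records
#' the realised Pearson correlation.  The tabulated curve, made
#' nonincreasing for inversion, defines the map `g` from a requested
#' correlation magnitude to the `c` achieving it.
#'
#' @param seed RNG seed (calibration is reproducible bit for bit).
#' @param n Pairs per grid point (default 1e6, minimum 1e4).
#' @param c_grid Grid of `c` values (default `seq(0, 10, 0.2)`).
#' @return An object of class `sou_calibration` with fields `c_grid`,
#'   `rho` (realised correlations; exactly 1 at `c = 0`), `rho_mono`
#'   (nonincreasing projection used by `g`), `seed` and `n`.
#' @export
sou_calibrate <- function(seed = 1L, n = 1e6, c_grid = seq(0, 10, by = 0.2)) {
  if (n < 1e4) stop("calibration needs n >= 1e4", call. = FALSE)
  set.seed(seed)
  qn <- function(u) stats::qnorm(clamp(u, 1e-12, 1 - 1e-12))
  rho <- numeric(length(c_grid))
  rho_normal <- numeric(length(c_grid))
  for (i in seq_along(c_grid)) {
    cc <- c_grid[i]
    if (cc == 0) {
      rho[i] <- 1
      rho_normal[i] <- 1
      next
    }
    u <- stats::runif(n)
    v <- stats::runif(n)
    u4 <- sou_pair(u, cc, v)
    rho[i] <- stats::cor(u, u4)
    # correlation of the normal scores: two SOU draws sharing the same u
    # inherit this much coupling after the erfinv transform, which the
    # sampler's compensated normal mix must account for
    rho_normal[i] <- stats::cor(qn(u), qn(u4))
  }
  cal <- list(c_grid = c_grid, rho = rho, rho_mono = cummin(rho),
              rho_normal = rho_normal, seed = as.integer(seed), n = n)
  class(cal) <- "sou_calibration"
  cal
}

#' @export
print.sou_calibration <- function(x, ...) {
  cat(sprintf("<sou_calibration> %d c values in [%g, %g], n = %g, rho range [%.4f, 1]\n",
              length(x$c_grid), min(x$c_grid), max(x$c_grid), x$n, min(x$rho_mono)))
  invisible(x)
}

#' The map g from correlation magnitude to SOU parameter c
#'
#' Monotone interpolation of the calibrated curve.  `g(1) = 0`; requests
#' below the smallest calibrated correlation return `NA` (the caller draws
#' independently instead).
#'
#' @param cal A [sou_calibrate()] result.
#' @param rho Requested correlation magnitudes in `[0, 1]`.
#' @return `c` values (or `NA` where `rho` is below the calibrated range).
#' @export
sou_g <- function(cal, rho) {
  stopifnot(all(rho >= 0 & rho <= 1))
  keep <- !duplicated(cal$rho_mono)
  out <- stats::approx(rev(cal$rho_mono[keep]), rev(cal$c_grid[keep]),
                       xout = rho, rule = 2, ties = "ordered")$y
  out[rho < min(cal$rho_mono)] <- NA_real_
  out
}

cal_rho_normal <- function(cal) {
  # older archives lack the normal-score table; the uniform-scale curve is
  # a close lower bound
  cal$rho_normal %||% cal$rho
}

# inverse of the normal-score coupling curve: the c achieving a requested
# normal-score correlation magnitude (NA below the calibrated range)
sou_g_normal <- function(cal, m) {
  stopifnot(all(m >= 0 & m <= 1))
  rn_mono <- cummin(cal_rho_normal(cal))
  keep <- !duplicated(rn_mono)
  out <- stats::approx(rev(rn_mono[keep]), rev(cal$c_grid[keep]),
                       xout = m, rule = 2, ties = "ordered")$y
  out[m < min(rn_mono)] <- NA_real_
  out
}

# normal-score coupling realized at a given c
sou_rho_normal_at <- function(cal, cc) {
  out <- rep(0, length(cc))
  ok <- !is.na(cc)
  out[ok] <- stats::approx(cal$c_grid, cal_rho_normal(cal), xout = cc[ok],
                           rule = 2)$y
  out
}

#' Draw a uniform variate with a requested correlation to another
#'
#' Uses [sou_g()] to find the SOU parameter achieving `|rho|`, couples
#' `u3` with fresh noise, and reflects the result (`1 - U4`) for negative
#' `rho`.  Requests whose magnitude is below the calibrated range are
#' treated as independent draws.
#'
#' @param u3 Uniform variates in `[0, 1]`.
#' @param rho Requested Pearson correlations in `[-1, 1]` (scalar or one
#'   per element).
#' @param cal A [sou_calibrate()] result.
#' @param v Independent uniform noise; drawn internally when omitted.
#' @return Uniform variates in `[0, 1]`.
#' @export
correlated_pair_for_rho <- function(u3, rho, cal, v = NULL) {
  stopifnot(all(abs(rho) <= 1))
  n <- length(u3)
  rho <- rep_len(rho, n)
  if (is.null(v)) v <- stats::runif(n)
  cc <- sou_g(cal, abs(rho))
  indep <- is.na(cc)
  cc[indep] <- 0
  u4 <- sou_pair(u3, cc, v)
  u4[indep] <- v[indep] # below calibrated range: independent draw
  neg <- rho < 0
  u4[neg] <- 1 - u4[neg]
  u4
}
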