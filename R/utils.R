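# internal numeric helpers

.datatable.aware <- TRUE

#' Inverse error function
#'
#' Inverse of `erf`, defined on (-1, 1).  Used to turn a uniform variate
#' scaled to (-1, 1) into a normal deviate: `sqrt(2) * erfinv(2 * u - 1)`
#' is standard normal when `u` is uniform on (0, 1).
#'
#' @param x Numeric vector in (-1, 1).
#' @return Numeric vector, `erfinv(x)`.
#' @examples
#' erfinv(0)              # 0
#' sqrt(2) * erfinv(0.5)  # qnorm(0.75)
#' @export
erfinv <- function(x) {
  stopifnot(all(is.na(x) | (x > -1 & x < 1)))
  stats::qnorm((x + 1) / 2) / sqrt(2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# terms x^i * y^j with i + j <= degree, as a design matrix (intercept first)
poly2d_design <- function(x, y, degree) {
  stopifnot(degree >= 0)
  cols <- list()
  nms <- character(0)
  for (d in 0:degree) {
    for (i in d:0) {
      j <- d - i
      cols[[length(cols) + 1L]] <- x^i * y^j
      nms <- c(nms, paste0("x", i, "y", j))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

# weighted least squares with explicit design matrix; errors on rank
# deficiency so callers can report which surface failed
wls_fit <- function(X, z, w, label = "surface") {
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, z * sw)
  if (fit$rank < ncol(X)) {
    stop("singular normal equations while fitting ", label, call. = FALSE)
  }
  beta <- fit$coefficients
  # adjusted r-squared on the weighted problem
  zbar <- sum(w * z) / sum(w)
  ss_tot <- sum(w * (z - zbar)^2)
  ss_res <- sum(w * (z - drop(X %*% beta))^2)
  n <- length(z); p <- ncol(X)
  adj_r2 <- if (ss_tot > 0 && n > p) 1 - (ss_res / (n - p)) / (ss_tot / (n - 1)) else NA_real_
  list(coefficients = beta, adj_r2 = adj_r2)
}

# bilinear interpolation of a matrix given axis coordinates; points outside
# the grid return NA
bilinear_interp <- function(values, xs, ys, xout, yout) {
  nx <- length(xs); ny <- length(ys)
  stopifnot(nrow(values) == nx, ncol(values) == ny)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fx <- (xout - xs[1]) / dx
  fy <- (yout - ys[1]) / dy
  i0 <- floor(fx); j0 <- floor(fy)
  ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  # clamp upper edge into the last cell
  i0 <- clamp(i0, 0, nx - 2); j0 <- clamp(j0, 0, ny - 2)
  tx <- fx - i0; ty <- fy - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  idx <- function(i, j) i + 1L + nx * j
  v <- (1 - tx) * (1 - ty) * values[idx(i0, j0)] +
    tx * (1 - ty) * values[idx(i0 + 1L, j0)] +
    (1 - tx) * ty * values[idx(i0, j0 + 1L)] +
    tx * ty * values[idx(i0 + 1L, j0 + 1L)]
  v[!ok] <- NA_real_
  v
}
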