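# 2D dose/fluence planes and the gamma-index comparison engine.

#' Construct a 2D plane
#'
#' A dose or fluence distribution on a regular grid.  `values[i, j]` is
#' the sample at `x = origin[1] + (i - 1) * spacing[1]`,
#' `y = origin[2] + (j - 1) * spacing[2]` (mm).
#'
#' @param values Numeric matrix of finite values.
#' @param spacing Pixel spacing, mm; length 1 or 2.
#' @param origin Coordinates of `values[1, 1]`, mm (default centres the
#'   plane on the origin).
#' @return An object of class `plane2d`.
#' @export
plane2d <- function(values, spacing, origin = NULL) {
  values <- as.matrix(values)
  spacing <- rep_len(as.numeric(spacing), 2L)
  stopifnot(all(is.finite(values)), all(spacing > 0))
  if (is.null(origin)) {
    origin <- -spacing * (dim(values) - 1) / 2
  }
  p <- list(values = values, spacing = spacing, origin = as.numeric(origin))
  class(p) <- "plane2d"
  p
}

plane_axes <- function(p) {
  list(x = p$origin[1] + p$spacing[1] * (seq_len(nrow(p$values)) - 1L),
       y = p$origin[2] + p$spacing[2] * (seq_len(ncol(p$values)) - 1L))
}

#' @export
print.plane2d <- function(x, ...) {
  ax <- plane_axes(x)
  cat(sprintf("<plane2d> %d x %d pixels, spacing %.3g x %.3g mm, x [%g, %g], y [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(ax$x), max(ax$x), min(ax$y), max(ax$y)))
  invisible(x)
}

#' Read / write a 2D plane
#'
#' Text format: an optional two-line header
#' `# spacing <sx> <sy>` / `# origin <x0> <y0>` followed by the value
#' matrix (rows of the matrix = x index, whitespace-delimited).
#' Headerless matrices are accepted when `spacing` is supplied.
#'
#' @param path File path.
#' @param spacing,origin Used (and required, for `spacing`) when the file
#'   has no header.
#' @return `read_plane2d()` returns a [plane2d()]; `write_plane2d()`
#'   returns `path` invisibly.
#' @export
read_plane2d <- function(path, spacing = NULL, origin = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  sp_line <- grep("^#\\s*spacing", hdr, value = TRUE)
  or_line <- grep("^#\\s*origin", hdr, value = TRUE)
  if (length(sp_line)) spacing <- as.numeric(strsplit(trimws(sub("^#\\s*spacing", "", sp_line[1])), "\\s+")[[1]])
  if (length(or_line)) origin <- as.numeric(strsplit(trimws(sub("^#\\s*origin", "", or_line[1])), "\\s+")[[1]])
  if (is.null(spacing)) {
    stop("no spacing header in ", path, " and none supplied", call. = FALSE)
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[,[:space:]]+"), as.numeric))
  plane2d(m, spacing = spacing, origin = origin)
}

#' @rdname read_plane2d
#' @param p A [plane2d()].
#' @export
write_plane2d <- function(p, path) {
  stopifnot(inherits(p, "plane2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing %.10g %.10g", p$spacing[1], p$spacing[2]),
               sprintf("# origin %.10g %.10g", p$origin[1], p$origin[2])), con)
  utils::write.table(format(p$values, digits = 10, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a 1D profile from a plane
#'
#' Nearest-row (axis `"x"`: profile along x at fixed y) or nearest-column
#' extraction, with coordinates attached.
#'
#' @param p A [plane2d()].
#' @param axis `"x"` or `"y"`: the axis the profile runs along.
#' @param position_mm Position on the other axis; must lie inside the
#'   plane.
#' @return A data frame with columns `pos` (mm) and `value`.
#' @export
extract_profile <- function(p, axis = c("x", "y"), position_mm = 0) {
  axis <- match.arg(axis)
  ax <- plane_axes(p)
  other <- if (axis == "x") ax$y else ax$x
  if (position_mm < min(other) - 1e-9 || position_mm > max(other) + 1e-9) {
    stop("position ", position_mm, " mm lies outside the plane", call. = FALSE)
  }
  idx <- which.min(abs(other - position_mm))
  if (axis == "x") {
    data.frame(pos = ax$x, value = p$values[, idx])
  } else {
    data.frame(pos = ax$y, value = p$values[idx, ])
  }
}

#' Gamma-index comparison of two planes
#'
#' For every reference pixel with dose at or above `threshold_pct`% of the
#' reference maximum, computes
#' `gamma = min over eval positions sqrt((dd / dd_max)^2 + (dr / DTA)^2)`
#' where `dd_max` is `dose_pct`% of the global reference maximum (or of the
#' local reference dose with `global_norm = FALSE`) and DTA is `dist_mm`.
#' The evaluated plane is bilinearly upsampled to a step of at most
#' `0.1 * dist_mm` and searched within a radius of `3 * dist_mm`
#' (one-sided evaluation, reference against evaluated, as in standard
#' practice).  A pixel passes when `gamma <= 1`.
#'
#' @param ref,ev Reference and evaluated [plane2d()]s; they must overlap
#'   spatially.
#' @param dose_pct Dose-difference criterion, percent.
#' @param dist_mm Distance-to-agreement criterion, mm.
#' @param threshold_pct Low-dose threshold, percent of the reference
#'   maximum (default 10); pixels below it are excluded from the pass
#'   rate.
#' @param global_norm Normalise dose differences to the global reference
#'   maximum (default) rather than to the local reference dose.
#' @return An object of class `gamma_result`: `gamma` (matrix, `NA` below
#'   threshold), `pass_rate` (percent of evaluated pixels with
#'   `gamma <= 1`), `n_evaluated`, and the criteria.
#' @export
gamma_analysis <- function(ref, ev, dose_pct, dist_mm, threshold_pct = 10,
                           global_norm = TRUE) {
  stopifnot(inherits(ref, "plane2d"), inherits(ev, "plane2d"),
            dose_pct > 0, dist_mm > 0)
  rax <- plane_axes(ref)
  eax <- plane_axes(ev)
  if (min(rax$x) > max(eax$x) || max(rax$x) < min(eax$x) ||
      min(rax$y) > max(eax$y) || max(rax$y) < min(eax$y)) {
    stop("reference and evaluated planes do not overlap", call. = FALSE)
  }
  d_max <- max(ref$values)
  thresh <- threshold_pct / 100 * d_max
  eval_mask <- ref$values >= thresh
  if (!any(eval_mask)) stop("all reference pixels lie below the dose threshold",
                            call. = FALSE)
  search_mm <- 3 * dist_mm
  step <- dist_mm / 10

  # fine grid covering the reference extent plus the search margin,
  # clipped to the evaluated plane's extent
  fx0 <- max(min(rax$x) - search_mm, min(eax$x))
  fx1 <- min(max(rax$x) + search_mm, max(eax$x))
  fy0 <- max(min(rax$y) - search_mm, min(eax$y))
  fy1 <- min(max(rax$y) + search_mm, max(eax$y))
  fx <- seq(fx0, fx1, by = step)
  fy <- seq(fy0, fy1, by = step)
  fine <- matrix(bilinear_interp(ev$values, eax$x, eax$y,
                                 rep(fx, times = length(fy)),
                                 rep(fy, each = length(fx))),
                 nrow = length(fx))

  # reference pixel coordinates -> (fractional) fine-grid indices
  ridx <- which(eval_mask, arr.ind = TRUE)
  rx <- rax$x[ridx[, 1]]
  ry <- rax$y[ridx[, 2]]
  rd <- ref$values[eval_mask]
  gi <- round((rx - fx0) / step)
  gj <- round((ry - fy0) / step)
  dd_max <- if (global_norm) rep(dose_pct / 100 * d_max, length(rd))
            else dose_pct / 100 * rd

  # search offsets within the radius, nearest first for early exit
  kmax <- floor(search_mm / step)
  off <- expand.grid(di = -kmax:kmax, dj = -kmax:kmax)
  off_r2 <- (off$di^2 + off$dj^2) * step^2
  keep <- off_r2 <= search_mm^2
  off <- off[keep, ]
  off_r2 <- off_r2[keep]
  ord <- order(off_r2)
  off <- off[ord, ]
  off_r2 <- off_r2[ord]

  nfx <- length(fx)
  nfy <- length(fy)
  g2 <- rep(Inf, length(rd))
  act <- seq_along(rd) # pixels whose gamma could still improve
  for (kk in seq_along(off_r2)) {
    dist_term <- off_r2[kk] / dist_mm^2
    act <- act[g2[act] > dist_term]
    if (!length(act)) break
    ii <- gi[act] + off$di[kk]
    jj <- gj[act] + off$dj[kk]
    inb <- ii >= 0L & ii < nfx & jj >= 0L & jj < nfy
    if (!any(inb)) next
    sel <- act[inb]
    dv <- fine[ii[inb] + 1L + nfx * jj[inb]]
    cand <- ((dv - rd[sel]) / dd_max[sel])^2 + dist_term
    cand[is.na(cand)] <- Inf
    g2[sel] <- pmin(g2[sel], cand)
  }
  gam <- sqrt(g2)
  gmap <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  gmap[eval_mask] <- gam
  res <- list(gamma = gmap, pass_rate = 100 * mean(gam <= 1),
              n_evaluated = length(gam),
              dose_pct = dose_pct, dist_mm = dist_mm,
              threshold_pct = threshold_pct, global_norm = global_norm)
  class(res) <- "gamma_result"
  res
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%% / %g mm (threshold %g%%): pass rate %.2f%% over %d pixels\n",
              x$dose_pct, x$dist_mm, x$threshold_pct, x$pass_rate, x$n_evaluated))
  invisible(x)
}

#' Synthetic central-axis dose-plane pair
#'
#' Constructs a reference/evaluated pair of square-field dose planes for
#' exercising the gamma engine end to end: an analytic flattened profile
#' with error-function penumbrae and a Gaussian scatter envelope, plus
#' independent multiplicative noise emulating Monte Carlo statistical
#' uncertainty; the evaluated plane is additionally rescaled and shifted
#' slightly.  These planes are synthetic stand-ins -- they exercise the
#' comparison machinery, not any dose calculation.
#'
#' @param field_mm Square field size, mm.
#' @param spacing_mm Pixel spacing, mm (default 2).
#' @param margin_mm Margin beyond the field edge, mm (default 30).
#' @param penumbra_mm Penumbra width parameter, mm (default 3).
#' @param noise_sd Relative standard deviation of the per-pixel noise
#'   (default 0.004).
#' @param scale Calibration factor applied to the evaluated plane
#'   (default 1.01).
#' @param shift_mm Lateral shift of the evaluated plane, mm (default 0.3).
#' @param seed RNG seed.
#' @return A list with [plane2d()]s `ref` and `ev`.
#' @export
make_synthetic_dose_planes <- function(field_mm, spacing_mm = 2, margin_mm = 30,
                                       penumbra_mm = 3, noise_sd = 0.004,
                                       scale = 1.01, shift_mm = 0.3, seed = 1L) {
  set.seed(seed)
  half_ext <- field_mm / 2 + margin_mm
  ax <- seq(-half_ext, half_ext, by = spacing_mm)
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  prof <- function(u) {
    edge <- (erf((field_mm / 2 - u) / penumbra_mm) +
               erf((field_mm / 2 + u) / penumbra_mm)) / 2
    0.95 * edge + 0.05 * exp(-u^2 / (2 * 80^2))
  }
  dose <- function(dx) outer(prof(ax + dx), prof(ax))
  nx <- length(ax)
  ref <- dose(0) * matrix(1 + noise_sd * stats::rnorm(nx * nx), nx)
  ev <- scale * dose(shift_mm) * matrix(1 + noise_sd * stats::rnorm(nx * nx), nx)
  list(ref = plane2d(ref, spacing_mm), ev = plane2d(ev, spacing_mm))
}
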