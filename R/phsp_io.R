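# Phase-space file reading, writing and derived per-particle quantities.
#
# The on-disk format is an N x 6 matrix, one particle per row:
#   type code (|1| photon, |2| electron, |3| positron), kinetic energy (MeV),
#   x (mm), y (mm), direction cosine along x, direction cosine along y.
# The energy column is sometimes labelled "MV" in beam data; it is treated
# as MeV here, the usual phase-space convention.  Species codes may be
# stored signed in some conventions; the absolute value is taken on read.
# The direction cosine along z is never stored: all particles travel
# downstream, so vz = +sqrt(1 - vx^2 - vy^2) is recomputed on demand.

.PHSP_COLS <- c("t", "e", "x", "y", "vx", "vy")
.COSINE_TOL <- 1e-9

#' Construct a particle set
#'
#' A `particle_set` is a data frame with one row per particle and columns
#' `t` (species code: 1 photon, 2 electron, 3 positron), `e` (kinetic
#' energy, MeV), `x`, `y` (position on the scoring plane, mm) and
#' `vx`, `vy` (direction cosines along x and y).
#'
#' @param t Integer species codes; sign is ignored.
#' @param e Kinetic energies in MeV, all `> 0`.
#' @param x,y Positions on the scoring plane, mm.
#' @param vx,vy Direction cosines; must satisfy `vx^2 + vy^2 <= 1` within
#'   tolerance `1e-9`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `particle_set`.
#' @seealso [read_phsp()], [write_phsp()], [radial_distance()]
#' @export
particle_set <- function(t, e, x, y, vx, vy, validate = TRUE) {
  df <- data.frame(t = as.integer(abs(t)), e = as.numeric(e),
                   x = as.numeric(x), y = as.numeric(y),
                   vx = as.numeric(vx), vy = as.numeric(vy))
  if (validate) validate_particle_set(df)
  class(df) <- c("particle_set", "data.frame")
  df
}

validate_particle_set <- function(df, context = "particle set") {
  bad_t <- which(!df$t %in% c(1L, 2L, 3L))
  if (length(bad_t)) {
    stop(sprintf("%s: unknown species code %s at row %d",
                 context, df$t[bad_t[1]], bad_t[1]), call. = FALSE)
  }
  bad_e <- which(!is.finite(df$e) | df$e <= 0)
  if (length(bad_e)) {
    stop(sprintf("%s: non-positive or non-finite energy at row %d",
                 context, bad_e[1]), call. = FALSE)
  }
  nrm <- df$vx^2 + df$vy^2
  bad_v <- which(!is.finite(nrm) | nrm > 1 + .COSINE_TOL)
  if (length(bad_v)) {
    stop(sprintf("%s: direction cosines with vx^2 + vy^2 = %.12g > 1 at row %d",
                 context, nrm[bad_v[1]], bad_v[1]), call. = FALSE)
  }
  invisible(df)
}

#' Radial distance from the beam axis
#'
#' @param x,y Coordinates on the scoring plane, mm.
#' @return `sqrt(x^2 + y^2)`, mm.
#' @examples
#' radial_distance(3, 4) # 5
#' @export
radial_distance <- function(x, y) sqrt(x^2 + y^2)

#' Derived per-particle quantities
#'
#' `ps_r()` returns each particle's radial distance from the beam axis;
#' `ps_vz()` returns the direction cosine along z, recomputed as the
#' positive root `sqrt(1 - vx^2 - vy^2)` (all particles travel downstream).
#'
#' @param ps A [particle_set()].
#' @return Numeric vector with one element per particle.
#' @export
ps_r <- function(ps) radial_distance(ps$x, ps$y)

#' @rdname ps_r
#' @export
ps_vz <- function(ps) sqrt(pmax(0, 1 - ps$vx^2 - ps$vy^2))

#' Read a phase-space file
#'
#' Reads the N x 6 matrix format described in [particle_set()].  The text
#' dialect is whitespace- or comma-delimited, one particle per row, with an
#' optional `#`-prefixed comment header; gzip-compressed text files are read
#' transparently.  The binary dialect is row-major IEEE doubles
#' (little-endian, 6 per particle, no header).  With `format = "auto"` the
#' dialect is detected from the file content.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"matrix_text"`, `"matrix_binary"`.
#' @return A [particle_set()]; row order is preserved and species codes are
#'   stored as absolute values.
#' @export
read_phsp <- function(path, format = c("auto", "matrix_text", "matrix_binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- detect_phsp_format(path)
  m <- if (format == "matrix_text") read_phsp_text(path) else read_phsp_binary(path)
  if (ncol(m) != 6L) {
    stop(sprintf("phase-space file must have 6 columns, found %d: %s",
                 ncol(m), path), call. = FALSE)
  }
  ps <- data.frame(t = as.integer(round(abs(m[[1]]))), e = m[[2]],
                   x = m[[3]], y = m[[4]], vx = m[[5]], vy = m[[6]])
  validate_particle_set(ps, context = path)
  class(ps) <- c("particle_set", "data.frame")
  ps
}

detect_phsp_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    return("matrix_text") # gzip: only the text dialect is compressed
  }
  chunk <- c(magic, readBin(con, "raw", 510L))
  printable <- chunk %in% c(as.raw(9:13), as.raw(32:126))
  if (all(printable)) "matrix_text" else "matrix_binary"
}

is_gzipped <- function(path) {
  magic <- readBin(path, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_phsp_text <- function(path) {
  dt <- tryCatch({
    if (is_gzipped(path)) {
      lines <- readLines(gzfile(path))
      lines <- lines[!grepl("^\\s*(#|$)", lines)]
      data.table::fread(text = lines, header = FALSE, sep = "auto", fill = TRUE,
                        blank.lines.skip = TRUE, showProgress = FALSE)
    } else {
      # '#' comment lines are permitted as a header block only
      head <- readLines(path, n = 1000L)
      skip <- match(FALSE, grepl("^\\s*(#|$)", head), nomatch = 1L) - 1L
      data.table::fread(path, header = FALSE, sep = "auto", fill = TRUE,
                        skip = skip, blank.lines.skip = TRUE,
                        showProgress = FALSE)
    }
  }, error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                              call. = FALSE))
  if (ncol(dt) != 6L) {
    stop(sprintf("phase-space file must have 6 columns, found %d: %s",
                 ncol(dt), path), call. = FALSE)
  }
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      col <- suppressWarnings(as.numeric(col))
      data.table::set(dt, j = j, value = col)
    }
  }
  bad <- which(Reduce(`|`, lapply(dt, function(col) !is.finite(col))))
  if (length(bad)) {
    stop(sprintf("malformed row %d in %s", bad[1], path), call. = FALSE)
  }
  dt
}

read_phsp_binary <- function(path) {
  n_bytes <- file.size(path)
  if (n_bytes %% (6L * 8L) != 0) {
    stop("binary phase-space file size is not a multiple of 48 bytes: ",
         path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_bytes / 8, size = 8L, endian = "little")
  m <- matrix(v, ncol = 6L, byrow = TRUE)
  data.table::as.data.table(m)
}

#' Write a phase-space file
#'
#' Inverse of [read_phsp()].  Text output stores 15 significant digits so a
#' read/write round trip is lossless well beyond 6 significant digits;
#' binary output is bit-exact.
#'
#' @param ps A non-empty [particle_set()].
#' @param path Output path.  A `.gz` suffix gzip-compresses text output.
#' @param format `"matrix_text"` or `"matrix_binary"`.
#' @return `path`, invisibly.
#' @export
write_phsp <- function(ps, path, format = c("matrix_text", "matrix_binary")) {
  format <- match.arg(format)
  stopifnot(inherits(ps, "particle_set"))
  if (nrow(ps) == 0L) stop("refusing to write an empty particle set", call. = FALSE)
  if (format == "matrix_text") {
    dt <- data.table::as.data.table(unclass(ps)[.PHSP_COLS])
    data.table::fwrite(dt, path, sep = " ", col.names = FALSE,
                       compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  } else {
    m <- t(as.matrix(as.data.frame(ps)[, .PHSP_COLS]))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles\n", nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Summarise a particle set
#'
#' Species fractions, energy range and radial range — the quantities shown
#' by the `phsp info` command of the CLI.
#'
#' @param object A [particle_set()].
#' @param ... Unused.
#' @return A list with elements `n`, `species_fractions`, `energy_range_mev`
#'   and `radial_range_mm`.
#' @export
summary.particle_set <- function(object, ...) {
  frac <- c(photon = mean(object$t == 1L),
            electron = mean(object$t == 2L),
            positron = mean(object$t == 3L))
  out <- list(n = nrow(object),
              species_fractions = frac,
              energy_range_mev = range(object$e),
              radial_range_mm = range(ps_r(object)))
  class(out) <- "summary.particle_set"
  out
}

#' @export
print.summary.particle_set <- function(x, ...) {
  cat(sprintf("particles: %d\n", x$n))
  cat(sprintf("species:   photon %.4f  electron %.4f  positron %.4f\n",
              x$species_fractions[1], x$species_fractions[2], x$species_fractions[3]))
  cat(sprintf("energy:    %.4g - %.4g MeV\n", x$energy_range_mev[1], x$energy_range_mev[2]))
  cat(sprintf("radius:    %.4g - %.4g mm\n", x$radial_range_mm[1], x$radial_range_mm[2]))
  invisible(x)
}
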