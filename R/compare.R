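# Quantitative comparison of two phase spaces: distribution distances,
# fluence maps, profiles, direction statistics and species fractions.

ks_distance <- function(a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  all_v <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(all_v)
  Fb <- stats::ecdf(b)(all_v)
  max(abs(Fa - Fb))
}

# pool the 35 radial spectrum bins into contiguous groups holding at least
# min_count particles on both sides, so per-group KS distances are
# statistically meaningful at moderate sample sizes
pool_energy_bins <- function(ha, hb, min_count) {
  ca <- tabulate(ha, nbins = .N_ENERGY_BINS)
  cb <- tabulate(hb, nbins = .N_ENERGY_BINS)
  groups <- integer(.N_ENERGY_BINS)
  gid <- 1L
  acc_a <- acc_b <- 0L
  for (b in seq_len(.N_ENERGY_BINS)) {
    groups[b] <- gid
    acc_a <- acc_a + ca[b]
    acc_b <- acc_b + cb[b]
    if (acc_a >= min_count && acc_b >= min_count && b < .N_ENERGY_BINS) {
      gid <- gid + 1L
      acc_a <- acc_b <- 0L
    }
  }
  # merge a trailing underfull group into its predecessor
  last <- groups == gid
  if (gid > 1L && (sum(ca[last]) < min_count || sum(cb[last]) < min_count)) {
    groups[last] <- gid - 1L
  }
  groups
}

#' Compare two phase spaces
#'
#' Computes the radial-distribution KS distance, per-radial-group
#' energy-spectrum KS distances (the 35 spectrum bins are pooled into
#' groups with at least `min_group_count` particles per side), 2D fluence
#' maps with their central horizontal profiles, per-bin mean-cosine
#' difference maps, and the species-fraction comparison.  Optionally
#' writes a machine-readable JSON summary and diagnostic plots.
#'
#' @param a,b Non-empty [particle_set()]s (`a` is the reference).
#' @param out_dir Optional directory for `summary.json` and PNG plots.
#' @param grid_n,cell_mm Fluence/direction map geometry (defaults 141, 1).
#' @param min_group_count Minimum particles per pooled energy group
#'   (default 2e4).
#' @param make_plots Write PNG diagnostics (default: only when `out_dir`
#'   is given).
#' @return A list of class `phsp_comparison` (see Details).
#' @export
compare_phase_spaces <- function(a, b, out_dir = NULL, grid_n = 141L,
                                 cell_mm = 1, min_group_count = 2e4,
                                 make_plots = !is.null(out_dir)) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  ra <- ps_r(a); rb <- ps_r(b)
  radial_ks <- ks_distance(ra, rb)

  ha <- energy_bin_index(ra)
  hb <- energy_bin_index(rb)
  groups <- pool_energy_bins(ha, hb, min_group_count)
  energy_ks <- vapply(unique(groups), function(gid) {
    bins <- which(groups == gid)
    ks_distance(a$e[ha %in% bins], b$e[hb %in% bins])
  }, numeric(1))
  energy_table <- data.frame(group = unique(groups),
                             first_bin = vapply(unique(groups), function(g) min(which(groups == g)), 1L),
                             last_bin = vapply(unique(groups), function(g) max(which(groups == g)), 1L),
                             ks = energy_ks)

  ga <- build_direction_grid(a, grid_n = grid_n, cell_mm = cell_mm)
  gb <- build_direction_grid(b, grid_n = grid_n, cell_mm = cell_mm)
  fa <- grid_count_matrix(ga)
  fb <- grid_count_matrix(gb)
  mid <- (grid_n + 1L) %/% 2L
  profile_a <- fa[, mid]
  profile_b <- fb[, mid]

  key_cols <- c("ix", "iy")
  ma <- merge(ga$stats[, c("ix", "iy", "n", "vbar_x", "vbar_y")],
              gb$stats[, c("ix", "iy", "n", "vbar_x", "vbar_y")],
              by = key_cols, suffixes = c("_a", "_b"))
  ma$dvx <- ma$vbar_x_a - ma$vbar_x_b
  ma$dvy <- ma$vbar_y_a - ma$vbar_y_b

  species <- rbind(a = summary(a)$species_fractions,
                   b = summary(b)$species_fractions)

  out <- list(radial_ks = radial_ks,
              energy_ks = energy_table,
              fluence_a = fa, fluence_b = fb,
              profile_a = profile_a, profile_b = profile_b,
              profile_pos = ga$centers,
              cosine_diff = ma,
              species_fractions = species,
              n = c(a = nrow(a), b = nrow(b)))
  class(out) <- "phsp_comparison"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summ <- list(n = out$n, radial_ks = radial_ks,
                 energy_ks = energy_table,
                 max_abs_cosine_diff = max(abs(c(ma$dvx, ma$dvy))),
                 species_fractions = species)
    writeLines(jsonlite::toJSON(summ, digits = NA, auto_unbox = TRUE, na = "null"),
               file.path(out_dir, "summary.json"))
    if (make_plots) plot_comparison(out, out_dir)
  }
  out
}

plot_comparison <- function(cmp, out_dir) {
  if (!capabilities("png")) {
    warning("png device unavailable; skipping diagnostic plots", call. = FALSE)
    return(invisible(NULL))
  }
  png_file <- function(name) file.path(out_dir, name)
  grDevices::png(png_file("fluence_profiles.png"), width = 900, height = 600)
  graphics::plot(cmp$profile_pos, cmp$profile_a, type = "l", lwd = 2,
                 xlab = "x (mm)", ylab = "counts / bin",
                 main = "Central horizontal fluence profile")
  graphics::lines(cmp$profile_pos, cmp$profile_b, col = "red", lty = 2, lwd = 2)
  graphics::legend("topright", c("reference", "evaluated"),
                   col = c("black", "red"), lty = c(1, 2), lwd = 2)
  grDevices::dev.off()

  grDevices::png(png_file("fluence_maps.png"), width = 1200, height = 600)
  old <- graphics::par(mfrow = c(1, 2))
  graphics::image(cmp$fluence_a, main = "fluence (reference)", axes = FALSE)
  graphics::image(cmp$fluence_b, main = "fluence (evaluated)", axes = FALSE)
  graphics::par(old)
  grDevices::dev.off()

  grDevices::png(png_file("energy_ks.png"), width = 900, height = 600)
  graphics::barplot(cmp$energy_ks$ks, names.arg = cmp$energy_ks$group,
                    xlab = "radial group", ylab = "KS distance",
                    main = "Energy-spectrum KS by radial group")
  grDevices::dev.off()
  invisible(NULL)
}

#' @export
print.phsp_comparison <- function(x, ...) {
  cat("<phsp_comparison>\n")
  cat(sprintf("  n: %d vs %d\n", x$n[1], x$n[2]))
  cat(sprintf("  radial KS: %.5f\n", x$radial_ks))
  cat(sprintf("  energy KS (max over %d radial groups): %.5f\n",
              nrow(x$energy_ks), max(x$energy_ks$ks)))
  cat(sprintf("  mean-cosine |diff| (max over shared bins): %.5f\n",
              max(abs(c(x$cosine_diff$dvx, x$cosine_diff$dvy)))))
  cat("  species fractions:\n")
  print(x$species_fractions)
  invisible(x)
}
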