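# Head-group radial distribution function around the protein and the
# annular lipid shells it delimits.

#' Radial distribution of lipid head groups around the protein
#'
#' For each lipid, r is the minimum-image distance from its phosphate bead
#' to the nearest protein bead. g(r) is the phosphate count in the annulus
#' [r, r + bin_width) normalized by the mean phosphate surface density in
#' the leaflet plane, so g tends to 1 in the unperturbed bulk. Annular shell
#' boundaries are the radii of the first `n_shells` local minima of g after
#' moving-average smoothing.
#'
#' @param frame a [cg_frame()] with protein and phosphate beads.
#' @param bin_width histogram bin width, Angstrom.
#' @param r_max maximum radius, Angstrom; must not exceed half the smallest
#'   lateral box edge.
#' @param smoothing_bins moving-average window (bins) used before locating
#'   minima.
#' @param n_shells number of annular shells to delimit.
#' @return object of class `cg_rdf`: list with `bin_edges`, `r` (bin
#'   centres), `g`, `counts`, `shell_boundaries`.
#' @export
headgroup_rdf <- function(frame, bin_width = 1, r_max = 40,
                          smoothing_bins = 3, n_shells = 2) {
  if (r_max > min(frame$box[1:2]) / 2)
    stopf("r_max (%.1f A) exceeds half the smallest lateral box edge (%.1f A)",
          r_max, min(frame$box[1:2]) / 2)
  prot <- frame$coords[frame$bead_class == "PROTEIN", , drop = FALSE]
  ph <- phosphate_table(frame)
  if (!nrow(prot)) stopf("frame has no protein beads")
  if (!nrow(ph)) stopf("frame has no phosphate beads")
  r <- mi_nearest_dist(as.matrix(ph[, c("x", "y", "z")]), prot, frame$box)

  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- as.vector(table(cut(r[r < r_max], edges, right = FALSE)))
  # surface (lateral) phosphate density, both leaflets projected together
  density <- nrow(ph) / (frame$box[1] * frame$box[2])
  area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  g <- counts / (density * area)

  gs <- smooth_ma(g, smoothing_bins)
  minima <- which(diff(sign(diff(gs))) > 0) + 1L
  # only minima after the first shell peak are shell boundaries
  first_max <- which(diff(sign(diff(gs))) < 0)
  if (length(first_max)) minima <- minima[minima > first_max[1]]
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  boundaries <- centres[head(minima, n_shells)]

  structure(list(bin_edges = edges, r = centres, g = g, counts = counts,
                 shell_boundaries = boundaries,
                 n_phosphates = nrow(ph), r_values = r),
            class = "cg_rdf")
}

smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  s <- as.vector(stats::filter(x, k, sides = 2, circular = FALSE))
  s[is.na(s)] <- x[is.na(s)]
  s
}

#' @export
print.cg_rdf <- function(x, ...) {
  cat(sprintf("<cg_rdf> %d bins to %.1f A, %d phosphates\n",
              length(x$g), max(x$bin_edges), x$n_phosphates))
  if (length(x$shell_boundaries))
    cat("shell boundaries (A):",
        paste(sprintf("%.1f", x$shell_boundaries), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cg_rdf <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (A)", ylab = "g(r)", ...)
  if (length(x$shell_boundaries))
    graphics::abline(v = x$shell_boundaries, lty = 2, col = "grey40")
  invisible(x)
}
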