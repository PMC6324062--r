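# Per-leaflet surface reconstruction, thickness and deformation maps.
# Thickness is phosphate-to-phosphate: each leaflet surface is a smoothed
# field of phosphate z positions, and thickness is their difference.

#' Reconstruct per-leaflet membrane surfaces
#'
#' Each leaflet's z-surface is a Gaussian-weighted mean of its phosphate
#' z coordinates over a lateral grid (minimum-image lateral distances,
#' kernel bandwidth `bandwidth`); cells with no phosphate within
#' `3 * bandwidth` are undefined (NaN). Thickness is upper minus lower per
#' cell. Bulk thickness is the mean thickness over cells farther from any
#' protein bead than the second annular shell boundary (or
#' `r_bulk_fallback` when no boundary is supplied); the deformation map is
#' thickness minus bulk thickness.
#'
#' @param frame a [cg_frame()].
#' @param leaflets a `leaflet_assignment` from [assign_leaflets()].
#' @param grid_spacing lateral grid spacing, Angstrom.
#' @param bandwidth Gaussian kernel bandwidth, Angstrom.
#' @param shell_boundary optional second annular-shell radius (Angstrom)
#'   from [headgroup_rdf()], used as the bulk exclusion radius.
#' @param r_bulk_fallback bulk exclusion radius when `shell_boundary` is
#'   not available.
#' @return object of class `membrane_surfaces`: list with `grid_x`,
#'   `grid_y`, `grid_spacing`, matrices `upper_z`, `lower_z`, `thickness`,
#'   `deformation`, logical `bulk_mask`, scalar `bulk_thickness`, `box`.
#' @export
leaflet_surfaces <- function(frame, leaflets, grid_spacing = 2,
                             bandwidth = 5, shell_boundary = NULL,
                             r_bulk_fallback = 25) {
  ph <- phosphate_table(frame)
  ph$leaflet <- leaflets$leaflet[match(ph$lipid_id, leaflets$lipid_id)]
  if (!any(ph$leaflet == "UPPER") || !any(ph$leaflet == "LOWER"))
    stopf("empty leaflet: both UPPER and LOWER must hold lipids")

  nx <- max(1L, round(frame$box[1] / grid_spacing))
  ny <- max(1L, round(frame$box[2] / grid_spacing))
  gx <- (seq_len(nx) - 0.5) * frame$box[1] / nx
  gy <- (seq_len(ny) - 0.5) * frame$box[2] / ny
  cells <- cbind(rep(gx, times = ny), rep(gy, each = nx))

  surf_one <- function(which_leaflet) {
    p <- ph[ph$leaflet == which_leaflet, , drop = FALSE]
    d <- mi_lateral_dist_matrix(cells, as.matrix(p[, c("x", "y")]), frame$box)
    w <- exp(-d^2 / (2 * bandwidth^2))
    w[d > 3 * bandwidth] <- 0
    sw <- rowSums(w)
    z <- as.vector(w %*% p$z) / sw
    z[sw == 0] <- NaN
    matrix(z, nrow = nx, ncol = ny)
  }
  upper_z <- surf_one("UPPER")
  lower_z <- surf_one("LOWER")
  thickness <- upper_z - lower_z

  prot <- frame$coords[frame$bead_class == "PROTEIN", , drop = FALSE]
  defined <- is.finite(thickness)
  if (nrow(prot)) {
    dprot <- matrix(apply(mi_lateral_dist_matrix(cells,
                                                 prot[, 1:2, drop = FALSE],
                                                 frame$box), 1, min),
                    nrow = nx, ncol = ny)
    r_excl <- shell_boundary %||% r_bulk_fallback
    bulk <- defined & dprot > r_excl
    if (!any(bulk)) {
      warning("no bulk cells beyond the exclusion radius; ",
              "using the 25% of cells farthest from the protein")
      thr <- stats::quantile(dprot[defined], 0.75)
      bulk <- defined & dprot >= thr
    }
  } else {
    bulk <- defined
  }
  bulk_thickness <- mean(thickness[bulk])
  structure(list(grid_x = gx, grid_y = gy,
                 grid_spacing = c(frame$box[1] / nx, frame$box[2] / ny),
                 upper_z = upper_z, lower_z = lower_z,
                 thickness = thickness,
                 deformation = thickness - bulk_thickness,
                 bulk_mask = bulk, bulk_thickness = bulk_thickness,
                 box = frame$box),
            class = "membrane_surfaces")
}

#' @export
print.membrane_surfaces <- function(x, ...) {
  cat(sprintf(
    "<membrane_surfaces> %d x %d grid (%.2f A), bulk thickness %.2f A\n",
    length(x$grid_x), length(x$grid_y), mean(x$grid_spacing),
    x$bulk_thickness))
  rng <- range(x$deformation[x$bulk_mask | is.finite(x$deformation)],
               na.rm = TRUE)
  cat(sprintf("deformation range: [%.2f, %.2f] A\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.membrane_surfaces <- function(x, what = c("deformation", "thickness",
                                               "upper_z", "lower_z"), ...) {
  what <- match.arg(what)
  image(x$grid_x, x$grid_y, x[[what]], xlab = "x (A)", ylab = "y (A)",
        main = what, ...)
  invisible(x)
}

# nearest defined grid cell for lateral points; returns list(index, dist)
nearest_defined_cell <- function(surfaces, pts) {
  defined <- which(is.finite(surfaces$thickness))
  nx <- length(surfaces$grid_x)
  cx <- surfaces$grid_x[(defined - 1L) %% nx + 1L]
  cy <- surfaces$grid_y[(defined - 1L) %/% nx + 1L]
  d <- mi_lateral_dist_matrix(pts, cbind(cx, cy), surfaces$box)
  j <- apply(d, 1, which.min)
  list(index = defined[j], dist = d[cbind(seq_len(nrow(pts)), j)])
}

#' Per-residue membrane depth and local thickness
#'
#' For each protein residue (backbone-bead position), depth is the z offset
#' from the local bilayer midplane and local thickness is the thickness at
#' the nearest defined grid cell. Residues laterally far from any defined
#' cell fall back to the bulk thickness and are flagged.
#'
#' @param frame a [cg_frame()].
#' @param surfaces a `membrane_surfaces` from [leaflet_surfaces()].
#' @param flag_distance lateral distance (Angstrom) beyond which the
#'   fallback flag is raised.
#' @return data.frame: `chain_id`, `residue_index`, `residue_name`, `x`,
#'   `y`, `z`, `depth`, `local_thickness`, `flagged`.
#' @export
local_thickness_per_residue <- function(frame, surfaces,
                                        flag_distance = 2 *
                                          max(surfaces$grid_spacing)) {
  res <- residue_positions(frame)
  if (!nrow(res)) stopf("frame has no protein residues")
  nn <- nearest_defined_cell(surfaces, as.matrix(res[, c("x", "y")]))
  mid <- (surfaces$upper_z + surfaces$lower_z) / 2
  res$depth <- res$z - mid[nn$index]
  res$local_thickness <- surfaces$thickness[nn$index]
  res$flagged <- nn$dist > flag_distance
  if (any(res$flagged)) {
    res$local_thickness[res$flagged] <- surfaces$bulk_thickness
    global_mid <- mean(mid[is.finite(mid)])
    res$depth[res$flagged] <- res$z[res$flagged] - global_mid
  }
  res
}
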