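# Simplified 2D topology geometry: each helix/strand is projected into the
# plane spanned by the membrane normal and the chain's dominant lateral
# direction, then approximated by a least-squares cubic B-spline with
# adaptive knot insertion so bends and kinks survive the simplification.

# Least-squares clamped cubic B-spline with interpolated endpoints.
# With a clamped knot vector the first/last coefficients are the endpoint
# values, so the endpoint constraint fixes them and the remaining
# coefficients solve an ordinary least-squares problem.
fit_clamped_spline <- function(t, y, interior_knots = numeric(),
                               degree = 3L) {
  ord <- degree + 1L
  knots <- c(rep(t[1], ord), sort(interior_knots), rep(t[length(t)], ord))
  B <- splines::splineDesign(knots, t, ord = ord)
  K <- ncol(B)
  c1 <- y[1]; cK <- y[length(y)]
  rhs <- y - B[, 1] * c1 - B[, K] * cK
  coef <- if (K > 2) {
    mid <- lm.fit(B[, -c(1, K), drop = FALSE], rhs)$coefficients
    c(c1, mid, cK)
  } else c(c1, cK)
  coef[is.na(coef)] <- 0
  list(knots = knots, degree = degree, coef = coef,
       fitted = as.vector(B %*% coef))
}

eval_clamped_spline <- function(fit, t) {
  t <- pmin(pmax(t, fit$knots[1]), fit$knots[length(fit$knots)])
  B <- splines::splineDesign(fit$knots, t, ord = fit$degree + 1L)
  as.vector(B %*% fit$coef)
}

# centred moving average with shrinking windows at the edges
smooth_partial <- function(x, half = 3L) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

local_rmsd <- function(resid2, window = 5L) {
  half <- window %/% 2L
  n <- length(resid2)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    sqrt(mean(resid2[idx]))
  }, numeric(1))
}

fit_segment_spline <- function(t, u, v, kink_tol = 2, max_knots = 8L) {
  interior <- numeric()
  rmsd_history <- numeric()
  repeat {
    fu <- fit_clamped_spline(t, u, interior)
    fv <- fit_clamped_spline(t, v, interior)
    r2 <- (u - fu$fitted)^2 + (v - fv$fitted)^2
    rmsd_history <- c(rmsd_history, sqrt(mean(r2)))
    lr <- local_rmsd(r2)
    if (max(lr) <= kink_tol || length(interior) >= max_knots) break
    cand <- t[which.max(lr)]
    # keep knots strictly interior and distinct
    cand <- min(max(cand, t[2]), t[length(t) - 1L])
    if (any(abs(interior - cand) < 0.5)) {
      shift <- cand + 0.5
      if (any(abs(interior - shift) < 0.5)) break
      cand <- shift
    }
    interior <- sort(c(interior, cand))
  }
  list(u = fu, v = fv, interior_knots = interior,
       control_points = cbind(u = fu$coef, v = fv$coef),
       knots = fu$knots, degree = 3L,
       fitted = cbind(u = fu$fitted, v = fv$fitted),
       rmsd_history = rmsd_history)
}

# dominant lateral direction: leading eigenvector of the orientation
# tensor of the TM segments' lateral axis components
chain_projection_axis <- function(segments, res) {
  vs <- list()
  for (i in seq_len(nrow(segments))) {
    if (!isTRUE(segments$is_tm[i])) next
    sel <- res$residue_index >= segments$start_residue[i] &
      res$residue_index <= segments$end_residue[i]
    if (sum(sel) < 2) next
    ax <- prcomp(as.matrix(res[sel, c("x", "y", "z")]))$rotation[, 1]
    vs[[length(vs) + 1L]] <- ax[1:2]
  }
  if (length(vs)) {
    M <- Reduce(`+`, lapply(vs, function(v) tcrossprod(v)))
    e <- eigen(M, symmetric = TRUE)
    if (e$values[1] > 1e-8) return(e$vectors[, 1])
  }
  p <- prcomp(as.matrix(res[, c("x", "y")]))
  p$rotation[, 1]
}

#' Build 2D topology splines for one chain
#'
#' Projects each helix/strand of the chain into the plane spanned by the
#' membrane normal and the chain's dominant lateral direction (orientation
#' PCA over the TM segments), fits a cubic least-squares B-spline per
#' segment with interpolated endpoints, and inserts knots adaptively
#' wherever the local fit RMSD exceeds `kink_tol`, preserving kinks.
#' Segments shorter than 4 residues fall back to a flagged polyline.
#' Loops between consecutive segments are emitted as connections, dashed
#' when the residue numbering is discontinuous. The local membrane band
#' (upper/lower surface heights along the projection axis) is sampled
#' alongside.
#'
#' @param segments `ss_segments` with TM flags ([detect_tm_segments()]).
#' @param frame the [cg_frame()].
#' @param surfaces a `membrane_surfaces`.
#' @param chain_id chain to lay out.
#' @param kink_tol local RMSD threshold (Angstrom) triggering knot
#'   insertion.
#' @param max_knots maximum interior knots per segment.
#' @return object of class `topology_splines`: list with `chain_id`,
#'   `axis`, `center`, `splines` (per segment), `connections`, `band`.
#' @export
build_topology_splines <- function(segments, frame, surfaces,
                                   chain_id = segments$chain_id[1],
                                   kink_tol = 2, max_knots = 8L) {
  res <- residue_positions(frame)
  res <- res[res$chain_id == chain_id, , drop = FALSE]
  res <- res[order(res$residue_index), , drop = FALSE]
  seg <- segments[segments$chain_id == chain_id, , drop = FALSE]
  axis <- chain_projection_axis(seg, res)
  center <- c(mean(res$x), mean(res$y))
  proj_u <- (res$x - center[1]) * axis[1] + (res$y - center[2]) * axis[2]
  proj <- data.frame(residue_index = res$residue_index, u = proj_u,
                     v = res$z)

  elems <- which(seg$kind %in% c("HELIX", "STRAND"))
  splines_out <- list()
  for (i in elems) {
    sel <- proj$residue_index >= seg$start_residue[i] &
      proj$residue_index <= seg$end_residue[i]
    p <- proj[sel, , drop = FALSE]
    m <- nrow(p)
    info <- list(kind = seg$kind[i], start_residue = seg$start_residue[i],
                 end_residue = seg$end_residue[i],
                 is_tm = isTRUE(seg$is_tm[i]),
                 residue_index = p$residue_index, proj = cbind(p$u, p$v))
    if (m < 4) {
      splines_out[[length(splines_out) + 1L]] <-
        c(info, list(flagged = TRUE, degree = 1L,
                     control_points = cbind(u = p$u, v = p$v),
                     knots = NULL, rmsd_history = 0))
      next
    }
    uu <- p$u; vv <- p$v
    if (seg$kind[i] == "HELIX") {
      # trace the helix axis: average the backbone spiral over about two
      # helical turns, keeping the terminal projections fixed
      uu <- smooth_partial(uu, 3L); vv <- smooth_partial(vv, 3L)
      uu[c(1, m)] <- p$u[c(1, m)]; vv[c(1, m)] <- p$v[c(1, m)]
    }
    fit <- fit_segment_spline(seq_len(m), uu, vv, kink_tol = kink_tol,
                              max_knots = max_knots)
    fit$proj_smoothed <- cbind(uu, vv)
    splines_out[[length(splines_out) + 1L]] <-
      c(info, fit, list(flagged = FALSE))
  }

  conns <- NULL
  if (length(elems) > 1) {
    conns <- do.call(rbind, lapply(seq_len(length(elems) - 1L), function(k) {
      a <- elems[k]; b <- elems[k + 1L]
      gap <- seg$start_residue[b] - seg$end_residue[a]
      data.frame(from_end = seg$end_residue[a], to_start = seg$start_residue[b],
                 dashed = gap > 1 &&
                   !any(seg$kind[(a + 1L):(b - 1L)] == "LOOP" &
                          seg$start_residue[(a + 1L):(b - 1L)] ==
                            seg$end_residue[a] + 1L))
    }))
  }

  urange <- range(proj$u)
  upad <- diff(urange) * 0.2 + 5
  us <- seq(urange[1] - upad, urange[2] + upad, length.out = 60)
  pts <- cbind(center[1] + us * axis[1], center[2] + us * axis[2])
  nn <- nearest_defined_cell(surfaces, pts)
  band <- data.frame(u = us, upper = surfaces$upper_z[nn$index],
                     lower = surfaces$lower_z[nn$index])

  structure(list(chain_id = chain_id, axis = axis, center = center,
                 splines = splines_out, connections = conns, band = band),
            class = "topology_splines")
}

#' Render a topology diagram to SVG
#'
#' Draws the fitted segment splines (helices thick, strands as arrows),
#' dashed connections for discontinuous loops, and the local membrane band.
#'
#' @param topo a `topology_splines` object.
#' @param path output SVG path.
#' @param scale pixels per Angstrom.
#' @export
write_topology_svg <- function(topo, path, scale = 4) {
  all_u <- unlist(lapply(topo$splines, function(s) s$proj[, 1]))
  all_v <- unlist(lapply(topo$splines, function(s) s$proj[, 2]))
  xr <- range(c(all_u, topo$band$u)); yr <- range(c(all_v, topo$band$upper,
                                                    topo$band$lower))
  pad <- 10
  tx <- function(u) (u - xr[1] + pad) * scale
  ty <- function(v) (yr[2] - v + pad) * scale
  w <- (diff(xr) + 2 * pad) * scale
  h <- (diff(yr) + 2 * pad) * scale
  ln <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    w, h))
  pline <- function(u, v, col, width, dash = NULL) {
    sprintf('<polyline fill="none" stroke="%s" stroke-width="%.1f"%s points="%s"/>',
            col, width,
            if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash),
            paste(sprintf("%.1f,%.1f", tx(u), ty(v)), collapse = " "))
  }
  ln <- c(ln, pline(topo$band$u, topo$band$upper, "#c0c0c0", 2),
          pline(topo$band$u, topo$band$lower, "#c0c0c0", 2))
  ends <- list()
  for (s in topo$splines) {
    if (isTRUE(s$flagged) || is.null(s$knots)) {
      uu <- s$control_points[, 1]; vv <- s$control_points[, 2]
    } else {
      tt <- seq(1, length(s$residue_index), length.out = 50)
      uu <- eval_clamped_spline(s$u, tt)
      vv <- eval_clamped_spline(s$v, tt)
    }
    col <- if (s$kind == "HELIX") "#d62728" else "#1f77b4"
    ln <- c(ln, pline(uu, vv, col, if (s$is_tm) 6 else 3))
    ends[[length(ends) + 1L]] <- list(start = c(uu[1], vv[1]),
                                      end = c(uu[length(uu)], vv[length(vv)]))
  }
  if (!is.null(topo$connections)) {
    for (k in seq_len(nrow(topo$connections))) {
      a <- ends[[k]]$end; b <- ends[[k + 1L]]$start
      ln <- c(ln, pline(c(a[1], b[1]), c(a[2], b[2]), "#555555", 1.5,
                        dash = if (topo$connections$dashed[k]) "6,4" else NULL))
    }
  }
  ln <- c(ln, "</svg>")
  writeLines(ln, path)
  invisible(path)
}
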