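# Leaflet identification and lipid flip-flop detection.
#
# Leaflets are found as the two large connected components of a proximity
# graph over phosphate beads (minimum-image distances, default cutoff 15 A).
# A graph rule rather than a z-threshold keeps curved and locally deformed
# bilayers intact; the threshold would split a strongly deformed leaflet.

#' Assign lipids to bilayer leaflets
#'
#' Builds a spatial-proximity graph over phosphate beads and labels the two
#' large connected components UPPER/LOWER, UPPER being the component of
#' greater mean z once the bilayer midplane is centred at z = 0. Lipids in
#' small satellite components (e.g. a lipid caught mid-flip near the
#' midplane) are attached to the large component of their nearest phosphate
#' neighbour.
#'
#' @param frame a [cg_frame()] with at least 2 phosphate-bearing lipids.
#' @param cutoff proximity-graph edge cutoff in Angstrom.
#' @param min_component_frac components holding at least this fraction of
#'   all phosphates count as "large"; anything other than exactly two large
#'   components is a non-bilayer state and raises an error of class
#'   `cgmem_non_bilayer`.
#' @return data.frame of class `leaflet_assignment`: `lipid_id`, `leaflet`
#'   (`"UPPER"`/`"LOWER"`).
#' @export
assign_leaflets <- function(frame, cutoff = 15, min_component_frac = 0.05) {
  ph <- phosphate_table(frame)
  n <- nrow(ph)
  if (n < 2) stopf("leaflet assignment needs at least 2 lipids, got %d", n)
  xyz <- as.matrix(ph[, c("x", "y", "z")])
  d <- mi_dist_matrix(xyz, xyz, frame$box)
  adj <- d <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  big_min <- max(2L, ceiling(min_component_frac * n))
  big <- which(comp$csize >= big_min)
  if (length(big) != 2L)
    stopf(paste0("non-bilayer state: %d large phosphate component(s) ",
                 "(expected 2)"), length(big), class = "cgmem_non_bilayer")

  memb <- comp$membership
  orphan <- !(memb %in% big)
  if (any(orphan)) {
    # nearest-phosphate-neighbour vote into a large component
    for (i in which(orphan)) {
      dd <- d[i, ]
      dd[!(memb %in% big)] <- Inf
      memb[i] <- memb[which.min(dd)]
    }
  }
  mz <- tapply(ph$z, memb, mean)[as.character(big)]
  upper_comp <- big[which.max(mz)]
  out <- data.frame(lipid_id = ph$lipid_id,
                    leaflet = ifelse(memb == upper_comp, "UPPER", "LOWER"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lipid_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}

#' Track leaflet labels across a trajectory
#'
#' @param frames list of [cg_frame()] objects (same lipids throughout).
#' @inheritParams assign_leaflets
#' @return object of class `leaflet_record`: list with `lipid_id` and a
#'   lipids x frames character matrix `labels`.
#' @export
track_leaflets <- function(frames, cutoff = 15, min_component_frac = 0.05) {
  per <- lapply(frames, assign_leaflets, cutoff = cutoff,
                min_component_frac = min_component_frac)
  ids <- per[[1]]$lipid_id
  labels <- vapply(per, function(a) a$leaflet[match(ids, a$lipid_id)],
                   character(length(ids)))
  labels <- matrix(labels, nrow = length(ids),
                   dimnames = list(NULL, NULL))
  structure(list(lipid_id = ids, labels = labels, n_frames = length(frames)),
            class = "leaflet_record")
}

#' Detect lipid flip-flop events
#'
#' A flip-flop is a persistent change of leaflet label: the new label must
#' hold for at least `persistence_frames` consecutive frames. Shorter
#' excursions (flickers of an interdigitated or mid-flip lipid) emit no
#' event.
#'
#' @param records a `leaflet_record` from [track_leaflets()].
#' @param persistence_frames minimum run length, in frames, for a label to
#'   count as established.
#' @return data.frame of class `flipflop_events`: `lipid_id`,
#'   `from_leaflet`, `to_leaflet`, `start_frame`, `end_frame` (1-based frame
#'   indices; `start_frame` is the first frame showing the new label during
#'   the transition, `end_frame` the first frame of its persistent run).
#' @export
detect_flipflops <- function(records, persistence_frames = 5) {
  nf <- ncol(records$labels)
  if (nf < persistence_frames + 1)
    stopf("need at least persistence_frames + 1 = %d frames, got %d",
          persistence_frames + 1, nf)
  ev <- list()
  for (i in seq_along(records$lipid_id)) {
    lab <- records$labels[i, ]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    stable <- which(r$lengths >= persistence_frames)
    if (length(stable) < 2) next
    for (k in seq_len(length(stable) - 1L)) {
      a <- stable[k]; b <- stable[k + 1L]
      if (r$values[a] == r$values[b]) next
      # first appearance of the new label after the previous stable run
      trans <- which(r$values == r$values[b] & seq_along(r$values) > a &
                       seq_along(r$values) <= b)
      ev[[length(ev) + 1L]] <- data.frame(
        lipid_id = records$lipid_id[i],
        from_leaflet = r$values[a], to_leaflet = r$values[b],
        start_frame = starts[min(trans)], end_frame = starts[b],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(lipid_id = integer(), from_leaflet = character(),
               to_leaflet = character(), start_frame = integer(),
               end_frame = integer(), stringsAsFactors = FALSE)
  class(out) <- c("flipflop_events", "data.frame")
  out
}
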