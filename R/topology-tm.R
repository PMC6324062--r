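# Transmembrane segment detection against the explicit leaflet surfaces,
# and whole-chain topology classification. The TM test uses the local
# surface height at each residue's lateral position, not a planar average,
# so deformed membranes are treated consistently with the surface maps.

#' Detect membrane-spanning secondary-structure segments
#'
#' A helix or strand is transmembrane when its residues cross both leaflet
#' surfaces, with at least one residue beyond each surface (z above the
#' local upper surface, and z below the local lower surface). The mean tilt
#' is the angle between the segment's principal axis and the membrane
#' normal.
#'
#' @param segments an `ss_segments` data.frame ([ss_segments()]).
#' @param surfaces a `membrane_surfaces` ([leaflet_surfaces()]).
#' @param frame the [cg_frame()] the segments refer to.
#' @return the segments with `is_tm` and `mean_tilt` filled in.
#' @export
detect_tm_segments <- function(segments, surfaces, frame) {
  res <- residue_positions(frame)
  nn <- nearest_defined_cell(surfaces, as.matrix(res[, c("x", "y")]))
  res$upper <- surfaces$upper_z[nn$index]
  res$lower <- surfaces$lower_z[nn$index]
  for (i in seq_len(nrow(segments))) {
    if (!segments$kind[i] %in% c("HELIX", "STRAND")) next
    sel <- res$chain_id == segments$chain_id[i] &
      res$residue_index >= segments$start_residue[i] &
      res$residue_index <= segments$end_residue[i]
    r <- res[sel, , drop = FALSE]
    if (nrow(r) < 2) next
    segments$is_tm[i] <- any(r$z > r$upper) && any(r$z < r$lower)
    ax <- prcomp(as.matrix(r[, c("x", "y", "z")]))$rotation[, 1]
    segments$mean_tilt[i] <- acos(min(1, abs(ax[3]))) * 180 / pi
  }
  segments
}

#' Classify a chain's membrane interaction and summarize its topology
#'
#' A chain is MEMBRANE_SPANNING when it has at least one TM segment;
#' otherwise INTERFACIAL when at least `interfacial_frac` of its residues
#' sit in the interfacial band (absolute depth within 6 A of the half
#' bulk thickness); otherwise SOLUBLE.
#'
#' @param segments `ss_segments` with TM flags from [detect_tm_segments()].
#' @param depth per-residue table from [local_thickness_per_residue()].
#' @param bulk_thickness bulk bilayer thickness, Angstrom.
#' @param chain_id chain to summarize.
#' @param interfacial_frac residue fraction required for INTERFACIAL.
#' @return object of class `chain_topology`: list with `chain_id`,
#'   `interaction_class`, `tm_helix_count`, `tm_strand_count`,
#'   `summary_text`, `density_profile` (1-Angstrom histogram of residue z).
#' @export
classify_chain <- function(segments, depth, bulk_thickness,
                           chain_id = segments$chain_id[1],
                           interfacial_frac = 0.2) {
  seg <- segments[segments$chain_id == chain_id, , drop = FALSE]
  dep <- depth[depth$chain_id == chain_id, , drop = FALSE]
  nh <- sum(seg$is_tm & seg$kind == "HELIX")
  ns <- sum(seg$is_tm & seg$kind == "STRAND")
  if (nh + ns > 0) {
    cls <- "MEMBRANE_SPANNING"
  } else {
    half <- bulk_thickness / 2
    band <- abs(dep$depth) >= half - 6 & abs(dep$depth) <= half + 6
    cls <- if (mean(band) >= interfacial_frac) "INTERFACIAL" else "SOLUBLE"
  }
  parts <- character()
  if (nh > 0)
    parts <- c(parts, sprintf("%d membrane spanning %s", nh,
                              if (nh == 1) "α helix" else "α helices"))
  if (ns > 0)
    parts <- c(parts, sprintf("%d membrane spanning %s", ns,
                              if (ns == 1) "β strand" else "β strands"))
  txt <- if (length(parts)) paste(parts, collapse = " and ")
         else "No membrane spanning elements"
  brk <- seq(floor(min(dep$z)) - 1, ceiling(max(dep$z)) + 1, by = 1)
  h <- graphics::hist(dep$z, breaks = brk, plot = FALSE)
  structure(list(chain_id = chain_id, interaction_class = cls,
                 tm_helix_count = nh, tm_strand_count = ns,
                 summary_text = txt,
                 density_profile = data.frame(z = h$mids, count = h$counts)),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology> chain %s: %s (%s)\n", x$chain_id,
              x$interaction_class, x$summary_text))
  invisible(x)
}
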