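# Tabular/FASTA I/O for analysis products.

CONTACT_COUNT_COLS <- c("choline", "phosphate", "glycerol",
                        "tail_1", "tail_2", "tail_3", "tail_4",
                        "water", "ion", "flip_lipid")
CONTACT_FRACTION_COLS <- c("head_fraction", "tail_fraction", "solvent_fraction")

#' Write a residue contact profile to CSV
#'
#' One row per residue with columns `chain_id`, `residue_index`,
#' `residue_name`, the per-class contact counts (`choline`, `phosphate`,
#' `glycerol`, `tail_1`..`tail_4`, `water`, `ion`, `flip_lipid`), the
#' normalized fractions (`head_fraction`, `tail_fraction`,
#' `solvent_fraction`) and `frames_analysed`. The column set and order are
#' stable across releases.
#'
#' @param profile a `residue_contact_profile` (see [count_contacts()]).
#' @param path output CSV path.
#' @export
write_contact_table <- function(profile, path) {
  cols <- c("chain_id", "residue_index", "residue_name",
            CONTACT_COUNT_COLS, CONTACT_FRACTION_COLS)
  df <- as.data.frame(profile)[, cols, drop = FALSE]
  df$frames_analysed <- rep(attr(profile, "frames_analysed") %||% 1L,
                            nrow(df))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write contact table to '%s': %s",
                         path, conditionMessage(ok))
  invisible(path)
}

#' Read a residue contact profile written by [write_contact_table()]
#' @param path CSV path.
#' @return a `residue_contact_profile`.
#' @export
read_contact_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  frames <- if ("frames_analysed" %in% names(df)) df$frames_analysed[1] else 1L
  df$frames_analysed <- NULL
  new_contact_profile(df, frames_analysed = frames)
}

#' Read chain sequences (and optional secondary structure) from FASTA
#'
#' Record names are chain identifiers. An optional companion FASTA of equal
#' layout supplies per-residue secondary-structure strings over the alphabet
#' H (helix), E (strand), C (coil).
#'
#' @param fasta path to an amino-acid FASTA file.
#' @param ss_fasta optional path to a secondary-structure FASTA file.
#' @return data.frame with columns `chain_id`, `sequence`, `ss` (NA when
#'   not supplied).
#' @export
read_chain_sequences <- function(fasta, ss_fasta = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  out <- data.frame(chain_id = sub("\\s.*$", "", names(aa)),
                    sequence = as.character(aa), ss = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(ss_fasta)) {
    ss <- Biostrings::readBStringSet(ss_fasta)
    m <- match(out$chain_id, sub("\\s.*$", "", names(ss)))
    out$ss <- as.character(ss)[m]
    bad <- !is.na(out$ss) & nchar(out$ss) != nchar(out$sequence)
    if (any(bad))
      stopf("secondary-structure length mismatch for chain(s): %s",
            paste(out$chain_id[bad], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Export membrane surfaces
#'
#' CSV export writes one long-format row per grid cell (`x`, `y`,
#' `upper_z`, `lower_z`, `thickness`, `deformation`, `bulk`); JSON export
#' writes grid metadata plus the value matrices.
#'
#' @param surfaces a `membrane_surfaces` object ([leaflet_surfaces()]).
#' @param path output path.
#' @export
write_surfaces_csv <- function(surfaces, path) {
  g <- expand.grid(x = surfaces$grid_x, y = surfaces$grid_y)
  df <- data.frame(g,
                   upper_z = as.vector(surfaces$upper_z),
                   lower_z = as.vector(surfaces$lower_z),
                   thickness = as.vector(surfaces$thickness),
                   deformation = as.vector(surfaces$deformation),
                   bulk = as.vector(surfaces$bulk_mask))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surfaces_csv
#' @export
write_surfaces_json <- function(surfaces, path) {
  jsonlite::write_json(list(
    grid_spacing = surfaces$grid_spacing,
    grid_x = surfaces$grid_x, grid_y = surfaces$grid_y,
    box = surfaces$box,
    bulk_thickness = surfaces$bulk_thickness,
    upper_z = surfaces$upper_z, lower_z = surfaces$lower_z,
    thickness = surfaces$thickness, deformation = surfaces$deformation
  ), path, digits = NA, na = "null", auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Export a radial distribution function as two-column CSV (`r`, `g`)
#' @param rdf a `cg_rdf` object ([headgroup_rdf()]).
#' @param path output path.
#' @export
write_rdf_csv <- function(rdf, path) {
  write.csv(data.frame(r = rdf$r, g = rdf$g), path, row.names = FALSE)
  invisible(path)
}
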