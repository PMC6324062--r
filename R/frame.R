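# The frame container: one coarse-grained snapshot.

#' Construct a coarse-grained frame
#'
#' Bundles bead coordinates and identities for one snapshot. Coordinates are
#' in Angstrom throughout the package; the box is orthorhombic with periodic
#' boundaries applied laterally (x, y). Lipid molecules are grouped by
#' `(residue_name, residue_index)` since coarse-grained coordinate formats
#' carry no connectivity.
#'
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param residue_name,bead_name character vectors, length n.
#' @param residue_index integer vector (1-based), length n.
#' @param chain_id character vector, length n.
#' @param box numeric length 3, positive edge lengths in Angstrom.
#' @param frame_time time of the snapshot in ns.
#' @param class_table bead classification table
#'   (see [bead_classification_table()]).
#' @return object of class `cg_frame`: a list with elements `coords`,
#'   `bead_name`, `bead_class`, `residue_name`, `residue_index`, `chain_id`,
#'   `lipid_id` (NA for protein/solvent beads), `box`, `frame_time`.
#' @export
cg_frame <- function(coords, residue_name, residue_index, chain_id,
                     bead_name, box, frame_time = 0,
                     class_table = bead_classification_table()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (ncol(coords) != 3L) stopf("coords must be an n x 3 matrix")
  if (!all(is.finite(coords))) stopf("non-finite coordinates in frame")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stopf("box must be 3 positive edge lengths (orthorhombic)")
  stopifnot(length(residue_name) == n, length(residue_index) == n,
            length(chain_id) == n, length(bead_name) == n)

  bead_class <- classify_bead(residue_name, bead_name, class_table)
  lipid_key <- ifelse(bead_class %in% LIPID_CLASSES,
                      paste(residue_name, residue_index), NA)
  lipid_id <- match(lipid_key, unique(lipid_key[!is.na(lipid_key)]))

  fr <- structure(list(
    coords = coords,
    bead_name = as.character(bead_name),
    bead_class = bead_class,
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    chain_id = as.character(chain_id),
    lipid_id = lipid_id,
    box = box,
    frame_time = frame_time
  ), class = "cg_frame")

  # each lipid must carry exactly one phosphate bead
  ph <- which(bead_class == "PHOSPHATE")
  if (length(ph)) {
    per <- table(lipid_id[ph])
    if (any(per != 1L))
      stopf("lipid(s) with != 1 phosphate bead: %s",
            paste(names(per)[per != 1L], collapse = ", "))
  }
  fr
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame> %d beads, box %.1f x %.1f x %.1f A, t = %g ns\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3], x$frame_time))
  print(table(x$bead_class))
  invisible(x)
}

n_beads <- function(frame) nrow(frame$coords)

# phosphate bead table: one row per lipid
phosphate_table <- function(frame) {
  i <- which(frame$bead_class == "PHOSPHATE")
  data.frame(lipid_id = frame$lipid_id[i],
             x = frame$coords[i, 1], y = frame$coords[i, 2],
             z = frame$coords[i, 3])
}

#' Per-residue protein positions
#'
#' Residue position is the backbone bead ("BB") where present, otherwise the
#' centroid of the residue's beads.
#'
#' @param frame a [cg_frame()].
#' @return data.frame with `chain_id`, `residue_index`, `residue_name`,
#'   `x`, `y`, `z`; one row per protein residue, ordered by chain then index.
#' @export
residue_positions <- function(frame) {
  i <- which(frame$bead_class == "PROTEIN")
  if (!length(i)) return(data.frame(chain_id = character(),
                                    residue_index = integer(),
                                    residue_name = character(),
                                    x = numeric(), y = numeric(), z = numeric()))
  key <- paste(frame$chain_id[i], frame$residue_index[i])
  bb <- frame$bead_name[i] %in% c("BB", "CA")
  use <- rep(TRUE, length(i))
  has_bb <- key %in% key[bb]
  use[has_bb & !bb] <- FALSE
  ii <- i[use]
  kk <- key[use]
  ord <- !duplicated(kk)
  pos <- rowsum(frame$coords[ii, , drop = FALSE], kk, reorder = FALSE) /
    as.vector(table(factor(kk, levels = unique(kk))))
  out <- data.frame(chain_id = frame$chain_id[ii][ord],
                    residue_index = frame$residue_index[ii][ord],
                    residue_name = frame$residue_name[ii][ord],
                    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  out[order(out$chain_id, out$residue_index), , drop = FALSE]
}
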