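# Chemical classification of coarse-grained beads. In the MARTINI DPPC
# representation a lipid carries 12 beads: choline (NC3), phosphate (PO4),
# two glycerol beads (GL1/GL2) and two acyl chains of four beads each
# (C1A..C4A, C1B..C4B), where the tail index counts positions along the
# chain from the glycerol end.

#' @export
bead_class_levels <- c("PROTEIN", "CHOLINE", "PHOSPHATE", "GLYCEROL",
                       "TAIL_1", "TAIL_2", "TAIL_3", "TAIL_4",
                       "WATER", "ION")

HEAD_CLASSES    <- c("CHOLINE", "PHOSPHATE", "GLYCEROL")
TAIL_CLASSES    <- c("TAIL_1", "TAIL_2", "TAIL_3", "TAIL_4")
SOLVENT_CLASSES <- c("WATER", "ION")
LIPID_CLASSES   <- c(HEAD_CLASSES, TAIL_CLASSES)

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa_three_to_one <- function(res) unname(AA3[toupper(res)])
aa_one_to_three <- function(one) names(AA3)[match(toupper(one), AA3)]

#' Default bead classification table
#'
#' One row per (residue, bead) pattern mapping to a chemical bead class.
#' A bead pattern of `"*"` matches any bead name within the residue.
#' Standard amino-acid residues map to `PROTEIN` regardless of bead name.
#'
#' @param config optional path to a YAML file whose top-level `beads` key
#'   lists additional rows (`residue`, `bead`, `class`), e.g. to register
#'   other lipid species. User rows take precedence over the defaults.
#' @return data.frame with columns `residue`, `bead`, `class`.
#' @export
bead_classification_table <- function(config = NULL) {
  dppc <- data.frame(
    residue = "DPPC",
    bead = c("NC3", "PO4", "GL1", "GL2",
             "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"),
    class = c("CHOLINE", "PHOSPHATE", "GLYCEROL", "GLYCEROL",
              "TAIL_1", "TAIL_2", "TAIL_3", "TAIL_4",
              "TAIL_1", "TAIL_2", "TAIL_3", "TAIL_4"),
    stringsAsFactors = FALSE
  )
  solvent <- data.frame(
    residue = c("W", "WN", "NA+", "CL-", "ION", "ION"),
    bead    = c("*", "*", "*", "*", "NA+", "CL-"),
    class   = c("WATER", "WATER", "ION", "ION", "ION", "ION"),
    stringsAsFactors = FALSE
  )
  protein <- data.frame(residue = names(AA3), bead = "*", class = "PROTEIN",
                        stringsAsFactors = FALSE)
  tab <- rbind(dppc, solvent, protein)
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$beads)) {
      extra <- do.call(rbind, lapply(cfg$beads, function(r) {
        data.frame(residue = r$residue, bead = r$bead %||% "*",
                   class = r$class, stringsAsFactors = FALSE)
      }))
      bad <- setdiff(extra$class, bead_class_levels)
      if (length(bad))
        stopf("unknown bead class in config: %s", paste(bad, collapse = ", "))
      tab <- rbind(extra, tab)
    }
  }
  tab
}

#' Classify beads into chemical classes
#'
#' Maps `(residue_name, bead_name)` pairs to one of PROTEIN, CHOLINE,
#' PHOSPHATE, GLYCEROL, TAIL_1..TAIL_4, WATER, ION. Vectorised over inputs.
#'
#' @param residue_name,bead_name character vectors of equal length.
#' @param table classification table from [bead_classification_table()].
#' @return character vector of bead classes.
#' @examples
#' classify_bead("DPPC", "PO4")   # PHOSPHATE
#' classify_bead("LEU", "BB")     # PROTEIN
#' @export
classify_bead <- function(residue_name, bead_name,
                          table = bead_classification_table()) {
  residue_name <- toupper(trimws(residue_name))
  bead_name <- toupper(trimws(bead_name))
  key <- paste(residue_name, bead_name)
  exact <- setNames(table$class, paste(toupper(table$residue), toupper(table$bead)))
  wild_rows <- table$bead == "*"
  wild <- setNames(table$class[wild_rows], toupper(table$residue[wild_rows]))
  out <- exact[key]
  miss <- is.na(out)
  if (any(miss)) out[miss] <- wild[residue_name[miss]]
  if (anyNA(out)) {
    bad <- unique(paste0("(", residue_name[is.na(out)], ",",
                         bead_name[is.na(out)], ")"))
    stopf("unclassifiable bead(s): %s", paste(bad, collapse = ", "),
          class = "cgmem_classification_error")
  }
  unname(out)
}
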