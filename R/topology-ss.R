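# Secondary-structure segmentation from coarse-grained backbone geometry.
# A user-supplied assignment (e.g. derived from an atomistic model) always
# takes precedence: virtual-bond patterns over backbone beads are
# necessarily approximate.

#' Assign secondary structure for one chain
#'
#' If `chainseq$ss` is provided it is passed through unchanged. Otherwise
#' H/E/C states are assigned from backbone-bead geometry: a residue window
#' is helical when the i to i+3 distance falls in the helical range
#' (about 5 A for a coarse-grained alpha helix), and extended when the
#' i to i+2 spacing exceeds the extended threshold. Helices shorter than 4
#' residues and strands shorter than 3 are relabelled coil.
#'
#' @param chainseq a row of [read_chain_sequences()], or `NULL` to force
#'   geometric assignment.
#' @param frame a [cg_frame()] containing the chain.
#' @param chain_id chain to assign; defaults to `chainseq$chain_id`.
#' @param helix_range i,i+3 distance window (Angstrom) accepted as helical.
#' @param strand_min minimum i,i+2 distance (Angstrom) for extended state.
#' @return a character string over {H, E, C}, one state per residue.
#' @export
assign_secondary_structure <- function(chainseq = NULL, frame = NULL,
                                       chain_id = chainseq$chain_id[1],
                                       helix_range = c(4.2, 6.0),
                                       strand_min = 6.3) {
  if (!is.null(chainseq) && !is.na(chainseq$ss[1]) &&
      nzchar(chainseq$ss[1]))
    return(chainseq$ss[1])
  if (is.null(frame)) stopf("frame required for geometric assignment")
  res <- residue_positions(frame)
  res <- res[res$chain_id == chain_id, , drop = FALSE]
  if (!nrow(res)) stopf("chain '%s' not present in frame", chain_id)
  res <- res[order(res$residue_index), , drop = FALSE]
  xyz <- as.matrix(res[, c("x", "y", "z")])
  n <- nrow(xyz)
  state <- rep("C", n)
  seg_dist <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((xyz[i + k, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
  }
  if (n >= 4) {
    d13 <- seg_dist(3L)
    inwin <- d13 >= helix_range[1] & d13 <= helix_range[2]
    # an isolated helical i,i+3 window (e.g. across a tight turn) is not a
    # helix; require a neighbouring window to agree
    helical <- inwin & (c(inwin[-1], FALSE) | c(FALSE, inwin[-length(inwin)]))
    for (i in which(helical)) state[i:(i + 3L)] <- "H"
  }
  if (n >= 3) {
    d12 <- seg_dist(2L)
    ext <- d12 >= strand_min
    for (i in which(ext)) {
      idx <- i:(i + 2L)
      state[idx][state[idx] != "H"] <- "E"
    }
  }
  # enforce minimum segment lengths (H >= 4, E >= 3)
  r <- rle(state)
  r$values[r$values == "H" & r$lengths < 4] <- "C"
  r$values[r$values == "E" & r$lengths < 3] <- "C"
  paste(inverse.rle(r), collapse = "")
}

#' Secondary-structure segments from an H/E/C string
#'
#' @param ss secondary-structure string.
#' @param chain_id chain identifier attached to the segments.
#' @param residue_offset residue index of the first character minus one.
#' @return data.frame of class `ss_segments`: `chain_id`, `kind`
#'   (HELIX/STRAND/LOOP), `start_residue`, `end_residue`, `is_tm` (FALSE
#'   until [detect_tm_segments()]), `mean_tilt` (NA until then).
#' @export
ss_segments <- function(ss, chain_id = "A", residue_offset = 0L) {
  chars <- strsplit(ss, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kind <- c(H = "HELIX", E = "STRAND", C = "LOOP")[r$values]
  out <- data.frame(chain_id = chain_id, kind = unname(kind),
                    start_residue = starts + residue_offset,
                    end_residue = ends + residue_offset,
                    is_tm = FALSE, mean_tilt = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ss_segments", "data.frame")
  out
}
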