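# Per-residue contact profiles between the protein surface and lipid
# chemical groups, water and ions. A contact is a protein-bead/other-bead
# pair within the cutoff (minimum image); counting is per bead pair, so a
# lipid touching a residue through three beads contributes three contacts.

new_contact_profile <- function(df, frames_analysed) {
  for (cc in CONTACT_COUNT_COLS) if (!cc %in% names(df)) df[[cc]] <- 0
  head_c <- df$choline + df$phosphate + df$glycerol
  tail_c <- df$tail_1 + df$tail_2 + df$tail_3 + df$tail_4
  solv_c <- df$water + df$ion
  tot <- head_c + tail_c + solv_c
  df$head_fraction <- ifelse(tot > 0, head_c / tot, NA_real_)
  df$tail_fraction <- ifelse(tot > 0, tail_c / tot, NA_real_)
  df$solvent_fraction <- ifelse(tot > 0, solv_c / tot, NA_real_)
  structure(df, frames_analysed = as.integer(frames_analysed),
            class = c("residue_contact_profile", "data.frame"))
}

#' Count protein-residue contacts with lipid groups and solvent
#'
#' Accumulates, over all supplied frames, per-residue counts of contacts
#' with each lipid bead class (choline, phosphate, glycerol, tail 1-4),
#' water and ions. Contacts with lipids that undergo a flip-flop are
#' additionally tallied in `flip_lipid`.
#'
#' @param frames a [cg_frame()] or list of frames.
#' @param cutoff contact distance cutoff, Angstrom; must not exceed half
#'   the smallest box edge.
#' @param flip_events optional `flipflop_events` from [detect_flipflops()].
#' @return a `residue_contact_profile`: data.frame with one row per protein
#'   residue, count columns `choline`..`ion`, `flip_lipid`, the derived
#'   `head_fraction`/`tail_fraction`/`solvent_fraction` (summing to 1 for
#'   residues with at least one contact), and attribute `frames_analysed`.
#' @export
count_contacts <- function(frames, cutoff = 6, flip_events = NULL) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  if (!length(frames)) stopf("no frames supplied")
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (cutoff > min(frames[[1]]$box) / 2)
    stopf("cutoff (%.1f A) exceeds half the smallest box edge", cutoff)
  flip_lipids <- unique(flip_events$lipid_id)

  f1 <- frames[[1]]
  pi_ <- which(f1$bead_class == "PROTEIN")
  if (!length(pi_)) stopf("frame has no protein beads")
  res_key <- paste(f1$chain_id[pi_], f1$residue_index[pi_])
  res_levels <- unique(res_key)
  first <- match(res_levels, res_key)
  df <- data.frame(chain_id = f1$chain_id[pi_][first],
                   residue_index = f1$residue_index[pi_][first],
                   residue_name = f1$residue_name[pi_][first],
                   stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = length(res_levels),
                   ncol = length(CONTACT_COUNT_COLS),
                   dimnames = list(res_levels, CONTACT_COUNT_COLS))
  class_col <- c(CHOLINE = "choline", PHOSPHATE = "phosphate",
                 GLYCEROL = "glycerol", TAIL_1 = "tail_1", TAIL_2 = "tail_2",
                 TAIL_3 = "tail_3", TAIL_4 = "tail_4", WATER = "water",
                 ION = "ion")

  for (fr in frames) {
    p <- which(fr$bead_class == "PROTEIN")
    o <- which(fr$bead_class != "PROTEIN")
    if (!length(o)) next
    d <- mi_dist_matrix(fr$coords[p, , drop = FALSE],
                        fr$coords[o, , drop = FALSE], fr$box)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    rk <- paste(fr$chain_id[p], fr$residue_index[p])[hit[, 1]]
    oc <- class_col[fr$bead_class[o][hit[, 2]]]
    ri <- match(rk, res_levels)
    ci <- match(oc, CONTACT_COUNT_COLS)
    idx <- (ci - 1L) * nrow(counts) + ri
    tab <- table(idx)
    at <- as.integer(names(tab))
    counts[at] <- counts[at] + as.vector(tab)
    if (length(flip_lipids)) {
      is_flip <- fr$lipid_id[o][hit[, 2]] %in% flip_lipids
      if (any(is_flip)) {
        tf <- table(ri[is_flip])
        counts[as.integer(names(tf)), "flip_lipid"] <-
          counts[as.integer(names(tf)), "flip_lipid"] + as.vector(tf)
      }
    }
  }
  df <- cbind(df, as.data.frame(counts, row.names = NULL))
  new_contact_profile(df, frames_analysed = length(frames))
}

#' @export
print.residue_contact_profile <- function(x, ...) {
  cat(sprintf("<residue_contact_profile> %d residues, %d frame(s)\n",
              nrow(x), attr(x, "frames_analysed")))
  tot <- colSums(as.data.frame(x)[, CONTACT_COUNT_COLS, drop = FALSE])
  print(tot)
  invisible(x)
}

#' Classify the membrane environment of each residue
#'
#' The label is the argmax of the summed head-group, acyl-tail and solvent
#' contact counts; residues with no non-protein contacts are BURIED. Ties
#' resolve by the precedence HEADGROUP > ACYL_TAIL > SOLVENT.
#'
#' @param profile a `residue_contact_profile`.
#' @return data.frame: `chain_id`, `residue_index`, `residue_name`,
#'   `environment` in {HEADGROUP, ACYL_TAIL, SOLVENT, BURIED}.
#' @export
classify_environment <- function(profile) {
  df <- as.data.frame(profile)
  head_c <- df$choline + df$phosphate + df$glycerol
  tail_c <- df$tail_1 + df$tail_2 + df$tail_3 + df$tail_4
  solv_c <- df$water + df$ion
  m <- cbind(HEADGROUP = head_c, ACYL_TAIL = tail_c, SOLVENT = solv_c)
  lab <- colnames(m)[apply(m, 1, which.max)]  # which.max takes first on tie
  lab[rowSums(m) == 0] <- "BURIED"
  data.frame(df[, c("chain_id", "residue_index", "residue_name")],
             environment = lab, stringsAsFactors = FALSE)
}

#' Per-residue sequence-track table
#'
#' Assembles the per-residue tracks of the sequence view: flip-lipid
#' contacts, water+ion contacts, per-bead-class contacts (choline,
#' phosphate, glycerol, tail 1-4), stacked head/tail/solvent fractions,
#' membrane depth and local thickness, secondary structure and amino acid.
#'
#' @param profile a `residue_contact_profile` for one chain.
#' @param depth data.frame from [local_thickness_per_residue()].
#' @param chainseq one row of [read_chain_sequences()] (fields `chain_id`,
#'   `sequence`, optional `ss`).
#' @return data.frame of class `sequence_tracks`, one row per residue in
#'   sequence order.
#' @export
sequence_tracks <- function(profile, depth, chainseq) {
  cid <- chainseq$chain_id[1]
  prof <- as.data.frame(profile)
  prof <- prof[prof$chain_id == cid, , drop = FALSE]
  n <- nchar(chainseq$sequence[1])
  missing <- setdiff(seq_len(n), prof$residue_index)
  if (length(missing))
    stopf("chain %s: residues missing from contact profile: %s", cid,
          paste(head(missing, 10), collapse = ", "))
  extra <- setdiff(prof$residue_index, seq_len(n))
  if (length(extra))
    stopf("chain %s: profile residues beyond sequence length %d: %s", cid, n,
          paste(head(extra, 10), collapse = ", "))
  ord <- match(seq_len(n), prof$residue_index)
  prof <- prof[ord, , drop = FALSE]
  dep <- depth[depth$chain_id == cid, , drop = FALSE]
  dm <- match(seq_len(n), dep$residue_index)
  if (anyNA(dm))
    stopf("chain %s: residues missing from depth table: %s", cid,
          paste(head(which(is.na(dm)), 10), collapse = ", "))
  ss <- chainseq$ss[1]
  ss_chars <- if (!is.na(ss) && nzchar(ss)) strsplit(ss, "")[[1]]
              else rep(NA_character_, n)
  out <- data.frame(
    chain_id = cid,
    residue_index = seq_len(n),
    aa = strsplit(chainseq$sequence[1], "")[[1]],
    ss = ss_chars,
    flip_lipid = prof$flip_lipid,
    water_ion = prof$water + prof$ion,
    choline = prof$choline, phosphate = prof$phosphate,
    glycerol = prof$glycerol,
    tail_1 = prof$tail_1, tail_2 = prof$tail_2,
    tail_3 = prof$tail_3, tail_4 = prof$tail_4,
    head_fraction = prof$head_fraction,
    tail_fraction = prof$tail_fraction,
    solvent_fraction = prof$solvent_fraction,
    depth = dep$depth[dm],
    local_thickness = dep$local_thickness[dm],
    stringsAsFactors = FALSE)
  class(out) <- c("sequence_tracks", "data.frame")
  out
}
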