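# Ensemble aggregation across structures of one protein or family:
# alignment-indexed contact/depth/secondary-structure profiles, the
# amino-acid contact propensity scale, normalized depth distributions with
# clustering, and bulk thickness summaries.

#' Aggregate per-residue profiles across aligned members
#'
#' Carries each member's per-residue head/tail/solvent contact fractions,
#' secondary structure and membrane depth onto alignment columns, and
#' derives the per-column consensus secondary structure (modal state over
#' members with a residue there), its conservation fraction and the
#' coverage (fraction of members without a gap).
#'
#' @param alignment a `cg_alignment` ([align_members()]).
#' @param members named list (same names as the alignment) of lists with
#'   elements `profile` (a `residue_contact_profile`), `depth` (from
#'   [local_thickness_per_residue()]) and `ss` (H/E/C string). Residue `k`
#'   of a member corresponds to the k-th non-gap column of its row.
#' @return object of class `ensemble_profile`: list of member x column
#'   matrices (`head_fraction`, `tail_fraction`, `solvent_fraction`,
#'   `depth`, `ss`), plus per-column `consensus_ss`, `conservation`,
#'   `coverage`.
#' @export
aggregate_profiles <- function(alignment, members) {
  stopifnot(all(names(alignment) %in% names(members)))
  L <- nchar(alignment[1])
  nm <- names(alignment)
  mk <- function() matrix(NA_real_, nrow = length(nm), ncol = L,
                          dimnames = list(nm, NULL))
  headf <- mk(); tailf <- mk(); solvf <- mk(); depth <- mk()
  present <- matrix(FALSE, nrow = length(nm), ncol = L,
                    dimnames = list(nm, NULL))
  ssm <- matrix(NA_character_, nrow = length(nm), ncol = L,
                dimnames = list(nm, NULL))
  for (m in nm) {
    row <- strsplit(alignment[[m]], "")[[1]]
    cols <- which(row != "-")
    mem <- members[[m]]
    prof <- as.data.frame(mem$profile)
    nres <- nrow(prof)
    if (length(cols) != nres)
      stopf("member %s: %d residues in profile but %d non-gap columns",
            m, nres, length(cols))
    present[m, cols] <- TRUE
    headf[m, cols] <- prof$head_fraction
    tailf[m, cols] <- prof$tail_fraction
    solvf[m, cols] <- prof$solvent_fraction
    if (!is.null(mem$depth)) {
      dm <- match(prof$residue_index, mem$depth$residue_index)
      depth[m, cols] <- mem$depth$depth[dm]
    }
    if (!is.null(mem$ss) && !is.na(mem$ss)) {
      sschars <- strsplit(mem$ss, "")[[1]]
      if (length(sschars) != nres)
        stopf("member %s: secondary-structure length mismatch", m)
      ssm[m, cols] <- sschars
    }
  }
  consensus <- character(L); conservation <- numeric(L)
  for (j in seq_len(L)) {
    s <- ssm[, j]
    s <- s[!is.na(s)]
    if (!length(s)) { consensus[j] <- NA; conservation[j] <- NA; next }
    tb <- sort(table(s), decreasing = TRUE)
    consensus[j] <- names(tb)[1]
    conservation[j] <- tb[1] / length(s)
  }
  coverage <- colMeans(present)
  structure(list(member_ids = nm, alignment = alignment,
                 head_fraction = headf, tail_fraction = tailf,
                 solvent_fraction = solvf, depth = depth, ss = ssm,
                 present = present,
                 consensus_ss = consensus, conservation = conservation,
                 coverage = coverage),
            class = "ensemble_profile")
}

#' @export
print.ensemble_profile <- function(x, ...) {
  cat(sprintf("<ensemble_profile> %d members, %d alignment columns\n",
              length(x$member_ids), length(x$coverage)))
  cat(sprintf("mean coverage %.2f, mean SS conservation %.2f\n",
              mean(x$coverage), mean(x$conservation, na.rm = TRUE)))
  invisible(x)
}

#' Amino-acid lipid-contact propensity scale
#'
#' For each amino-acid type and each contact category (lipid head-groups,
#' lipid acyl tails, solvent) the unbiased contact probability p is the
#' fraction of residues of that type, among those with at least one
#' non-protein contact, that make at least one contact in the category.
#' Probabilities are normalized to a scale anchored at glycine = 0 with
#' the maximum at 100: s = 100 (p - p_Gly) / (max p - p_Gly). Types less
#' contact-prone than glycine take negative values.
#'
#' @param profiles a `residue_contact_profile` or list of them.
#' @param mode `"incidence"` (default; residue-level, so abundant residue
#'   types do not dominate) or `"count_share"` (per-category share of a
#'   type's total contact counts).
#' @return object of class `propensity_scale`: data.frame with one row per
#'   amino acid (`aa`), raw probabilities `p_head`, `p_tail`, `p_solvent`
#'   and normalized values `s_head`, `s_tail`, `s_solvent`.
#' @export
contact_propensity_scale <- function(profiles,
                                     mode = c("incidence", "count_share")) {
  mode <- match.arg(mode)
  if (inherits(profiles, "residue_contact_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  aa <- aa_three_to_one(df$residue_name)
  keep <- !is.na(aa)
  df <- df[keep, , drop = FALSE]; aa <- aa[keep]
  head_c <- df$choline + df$phosphate + df$glycerol
  tail_c <- df$tail_1 + df$tail_2 + df$tail_3 + df$tail_4
  solv_c <- df$water + df$ion
  surf <- head_c + tail_c + solv_c > 0
  types <- sort(unname(AA3))
  missing <- setdiff(types, unique(aa[surf]))
  if (length(missing))
    warning("no surface residues for amino-acid type(s): ",
            paste(missing, collapse = ", "))
  p_of <- function(cat_c) {
    vapply(types, function(t) {
      i <- aa == t & surf
      if (!any(i)) return(NA_real_)
      if (mode == "incidence") mean(cat_c[i] > 0)
      else sum(cat_c[i]) / sum(head_c[i] + tail_c[i] + solv_c[i])
    }, numeric(1))
  }
  p <- data.frame(aa = types, p_head = p_of(head_c), p_tail = p_of(tail_c),
                  p_solvent = p_of(solv_c), stringsAsFactors = FALSE)
  norm <- function(pv) {
    pg <- pv[p$aa == "G"]
    pmax_ <- max(pv, na.rm = TRUE)
    if (!is.finite(pg) || abs(pmax_ - pg) < 1e-12)
      stopf("degenerate propensity scale: max probability equals glycine's")
    100 * (pv - pg) / (pmax_ - pg)
  }
  p$s_head <- norm(p$p_head)
  p$s_tail <- norm(p$p_tail)
  p$s_solvent <- norm(p$p_solvent)
  class(p) <- c("propensity_scale", "data.frame")
  p
}

js_distance <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Amino-acid depth distributions along the membrane normal
#'
#' Each residue gets a normalized depth coordinate z' = 2 depth / local
#' thickness, placing the leaflet phosphate surfaces at +/-1 so bilayers of
#' different thickness are comparable. Pore-inner residues (solvent
#' contacts, |z'| < 0.8, laterally inside the convex hull of the chain's
#' TM-segment axes) are excluded. Histograms run over z' in [-2, 2] with
#' bin width 0.1; in relative mode each amino-acid histogram is normalized
#' to sum to 1. Types with similar distributions are clustered by
#' average-linkage hierarchical clustering on the Jensen-Shannon distance
#' between relative histograms (merge ties resolve by the alphabetical
#' amino-acid input order, making the dendrogram deterministic).
#'
#' @param residues data.frame with columns `aa` (one-letter), `depth`,
#'   `local_thickness`, and optionally `solvent_contacts` (count), `x`,
#'   `y`, `chain_id` for the pore-exclusion rule.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param k_clusters number of clusters to cut the tree into.
#' @param tm_hulls optional named list (by chain) of lateral polygons
#'   (n x 2 matrices) marking TM-segment axis positions; used by the
#'   pore-exclusion rule.
#' @return object of class `depth_distribution`: list with `histograms`
#'   (20 x 40 matrix), `breaks`, `mode`, `clusters` (named integer),
#'   `excluded` (number of pore residues removed), `flagged_types`.
#' @export
depth_distributions <- function(residues, mode = c("relative", "absolute"),
                                k_clusters = 4, tm_hulls = NULL) {
  mode <- match.arg(mode)
  z <- 2 * residues$depth / residues$local_thickness
  excl <- rep(FALSE, nrow(residues))
  if (!is.null(tm_hulls) && !is.null(residues$solvent_contacts) &&
      !is.null(residues$x)) {
    for (cid in names(tm_hulls)) {
      hull <- tm_hulls[[cid]]
      if (is.null(hull) || nrow(hull) < 3) next
      inchain <- residues$chain_id == cid
      inside <- mgcv::in.out(rbind(hull, hull[1, , drop = FALSE]),
                             cbind(residues$x, residues$y))
      excl <- excl | (inchain & inside & residues$solvent_contacts > 0 &
                        abs(z) < 0.8)
    }
  }
  keep <- !excl & is.finite(z)
  z <- pmin(pmax(z[keep], -2 + 1e-9), 2 - 1e-9)
  aa <- residues$aa[keep]
  breaks <- seq(-2, 2, by = 0.1)
  types <- sort(unname(AA3))
  H <- t(vapply(types, function(t) {
    zz <- z[aa == t]
    as.vector(table(cut(zz, breaks, right = FALSE)))
  }, numeric(length(breaks) - 1)))
  rownames(H) <- types
  flagged <- types[rowSums(H) == 0]
  rel <- H / pmax(rowSums(H), 1)
  out_H <- if (mode == "relative") rel else H
  clusters <- rep(NA_integer_, length(types))
  names(clusters) <- types
  ok <- rowSums(H) > 0
  if (sum(ok) >= 2) {
    n_ok <- sum(ok)
    D <- matrix(0, n_ok, n_ok, dimnames = list(types[ok], types[ok]))
    tok <- types[ok]
    for (i in seq_len(n_ok - 1)) for (j in (i + 1):n_ok)
      D[i, j] <- D[j, i] <- js_distance(rel[tok[i], ], rel[tok[j], ])
    hc <- hclust(as.dist(D), method = "average")
    clusters[tok] <- cutree(hc, k = min(k_clusters, n_ok))
  }
  structure(list(histograms = out_H, breaks = breaks, mode = mode,
                 clusters = clusters, excluded = sum(excl),
                 flagged_types = flagged),
            class = "depth_distribution")
}

#' @export
print.depth_distribution <- function(x, ...) {
  cat(sprintf("<depth_distribution> mode %s, %d pore residues excluded\n",
              x$mode, x$excluded))
  print(split(names(x$clusters), x$clusters))
  invisible(x)
}

#' Per-class bulk membrane thickness summary
#'
#' @param members list of `membrane_surfaces` objects (or numeric bulk
#'   thicknesses).
#' @param class_labels character vector, one of `"alpha_helical"` /
#'   `"beta_barrel"` per member.
#' @return data.frame: `class`, `n`, `mean_thickness`, `sd_thickness`
#'   (0 for a single member).
#' @export
thickness_summary <- function(members, class_labels) {
  known <- c("alpha_helical", "beta_barrel")
  bad <- setdiff(unique(class_labels), known)
  if (length(bad))
    stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  stopifnot(length(members) == length(class_labels))
  th <- vapply(members, function(m)
    if (is.numeric(m)) m else m$bulk_thickness, numeric(1))
  out <- do.call(rbind, lapply(intersect(known, unique(class_labels)),
    function(cl) {
      v <- th[class_labels == cl]
      data.frame(class = cl, n = length(v), mean_thickness = mean(v),
                 sd_thickness = if (length(v) > 1) sd(v) else 0)
    }))
  rownames(out) <- NULL
  out
}

#' Render the ensemble contact grid as SVG
#'
#' One row per member, one cell per alignment column, coloured by the
#' dominant contact category (head-group red, acyl tail yellow, solvent
#' blue); gaps are grey. A consensus secondary-structure strip runs along
#' the bottom, shaded darker where conservation is higher.
#'
#' @param ens an `ensemble_profile`.
#' @param path output SVG path.
#' @param cell cell size in pixels.
#' @export
write_ensemble_svg <- function(ens, path, cell = 8) {
  n <- length(ens$member_ids); L <- length(ens$coverage)
  w <- (L + 2) * cell + 80; h <- (n + 3) * cell
  ln <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h)
  for (i in seq_len(n)) for (j in seq_len(L)) {
    hf <- ens$head_fraction[i, j]
    col <- if (is.na(hf)) "#bbbbbb" else {
      tf <- ens$tail_fraction[i, j]; sf <- ens$solvent_fraction[i, j]
      c("#d62728", "#e6c229", "#1f77b4")[which.max(c(hf, tf, sf))]
    }
    ln <- c(ln, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
      80 + (j - 1) * cell, (i - 1) * cell, cell, cell, col))
  }
  for (j in seq_len(L)) {
    cons <- ens$conservation[j]
    if (is.na(cons)) next
    shade <- 230 - round(cons * 160)
    ln <- c(ln, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="rgb(%d,%d,%d)"/>',
      80 + (j - 1) * cell, (n + 1) * cell, cell, cell, shade, shade, shade))
  }
  ln <- c(ln, "</svg>")
  writeLines(ln, path)
  invisible(path)
}
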