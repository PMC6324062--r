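# Shared builders and independent brute-force oracles.

# small flat bilayer, optionally jitter-free
flat_fixture <- function(n = 64, sep = 37, jitter = 1, noise = 0.5,
                         water = FALSE, frames = 1, seed = 1, ...) {
  generate_fixture(fixture_spec(lipids_per_leaflet = n,
                                phosphate_plane_separation = sep,
                                jitter_sd = jitter, noise_sd = noise,
                                water = water, n_frames = frames,
                                seed = seed, ...))
}

# append extra beads (e.g. a synthetic protein trace) to a frame
embed_beads <- function(frame, xyz, residue_name, residue_index,
                        chain_id = "A", bead_name = "BB") {
  n <- nrow(xyz)
  cg_frame(rbind(xyz, frame$coords),
           c(rep_len(residue_name, n), frame$residue_name),
           c(residue_index, frame$residue_index),
           c(rep_len(chain_id, n), frame$chain_id),
           c(rep_len(bead_name, n), frame$bead_name),
           frame$box, frame$frame_time)
}

# straight helix-axis trace along z through the box centre
axis_trace <- function(box, z0, n, rise = 1.5, x = box[1] / 2,
                       y = box[2] / 2) {
  cbind(rep(x, n), rep(y, n), z0 + rise * (0:(n - 1)))
}

# O(N^2) minimum-image distance, one pair
mi_dist_pair <- function(a, b, box) {
  dx <- a[1] - b[1]; dx <- dx - box[1] * round(dx / box[1])
  dy <- a[2] - b[2]; dy <- dy - box[2] * round(dy / box[2])
  dz <- a[3] - b[3]
  sqrt(dx^2 + dy^2 + dz^2)
}

# brute-force per-residue, per-class contact counts
bf_contacts <- function(frame, cutoff) {
  p <- which(frame$bead_class == "PROTEIN")
  o <- which(frame$bead_class != "PROTEIN")
  out <- list()
  for (i in p) {
    key <- paste(frame$chain_id[i], frame$residue_index[i])
    if (is.null(out[[key]])) out[[key]] <- integer()
    for (j in o) {
      d <- mi_dist_pair(frame$coords[i, ], frame$coords[j, ], frame$box)
      if (d <= cutoff) {
        cl <- frame$bead_class[j]
        out[[key]][cl] <- (out[[key]][cl] %||% 0L) + 1L
      }
    }
  }
  out
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# brute-force RDF bin counts: distance of each phosphate to nearest
# protein bead, histogrammed
bf_rdf_counts <- function(frame, bin_width, r_max) {
  p <- which(frame$bead_class == "PROTEIN")
  h <- which(frame$bead_class == "PHOSPHATE")
  edges <- seq(0, r_max, by = bin_width)
  counts <- integer(length(edges) - 1)
  for (i in h) {
    d <- Inf
    for (j in p)
      d <- min(d, mi_dist_pair(frame$coords[i, ], frame$coords[j, ],
                               frame$box))
    if (d < r_max) {
      b <- findInterval(d, edges, rightmost.closed = FALSE)
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# brute-force flip-flop scan over a label matrix: a flip is a label change
# whose new label holds for >= persistence frames, relative to the last
# established label
bf_flips <- function(labels, lipid_ids, persistence) {
  ev <- list()
  for (i in seq_len(nrow(labels))) {
    lab <- labels[i, ]
    est <- NA; est_known <- FALSE
    f <- 1L
    while (f <= length(lab)) {
      run_end <- f
      while (run_end < length(lab) && lab[run_end + 1L] == lab[f])
        run_end <- run_end + 1L
      if (run_end - f + 1L >= persistence) {
        if (est_known && lab[f] != est)
          ev[[length(ev) + 1L]] <- data.frame(lipid_id = lipid_ids[i],
                                              to = lab[f])
        est <- lab[f]; est_known <- TRUE
      }
      f <- run_end + 1L
    }
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(lipid_id = integer(), to = character())
}

# exhaustive global alignment score (affine gaps, BLOSUM62), enumerating
# all alignments recursively; only usable for very short sequences
exhaustive_align_score <- function(a, b, open = -10, ext = -0.5) {
  S <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(A))
      best <- max(best, (if (prev == "X") ext else open) +
                    rec(i + 1, j, "X"))
    if (j <= length(B))
      best <- max(best, (if (prev == "Y") ext else open) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

# score a pair of gapped rows under the same affine scheme
score_gapped_pair <- function(a, b, open = -10, ext = -0.5) {
  S <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  sc <- 0; prev <- "M"
  for (k in seq_along(A)) {
    if (A[k] != "-" && B[k] != "-") { sc <- sc + S[A[k], B[k]]; prev <- "M" }
    else if (A[k] == "-") { sc <- sc + (if (prev == "Y") ext else open); prev <- "Y" }
    else { sc <- sc + (if (prev == "X") ext else open); prev <- "X" }
  }
  sc
}
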