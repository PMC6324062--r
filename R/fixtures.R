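# Synthetic coarse-grained systems with planted ground truth. The
# generator emulates a post-assembly snapshot: DPPC lipids on a jittered
# lattice in two leaflets (12 beads each in the canonical vertical
# arrangement), an optional idealised helix bundle or beta barrel spanning
# the bilayer, optional radial membrane deformation, planted flip-flops,
# and water/ion filler. Every planted quantity is recorded so analyses can
# be validated without external data.

#' Helix-bundle protein specification
#' @param n_helices number of transmembrane helices (default 7, the
#'   classic GPCR topology).
#' @param radius bundle radius, Angstrom.
#' @param kink_angle optional mid-helix kink, degrees.
#' @export
helix_bundle <- function(n_helices = 7, radius = 10, kink_angle = 0) {
  stopifnot(n_helices >= 1, radius > 0, kink_angle >= 0)
  list(type = "helix_bundle", n_helices = n_helices, radius = radius,
       kink_angle = kink_angle)
}

#' Beta-barrel protein specification
#' @param n_strands number of strands.
#' @param radius barrel radius, Angstrom.
#' @export
barrel_protein <- function(n_strands = 8, radius = 8) {
  stopifnot(n_strands >= 3, radius > 0)
  list(type = "barrel", n_strands = n_strands, radius = radius)
}

#' Radial membrane deformation specification
#'
#' Full thinning by `depth` within `range` of the protein axis, decaying
#' smoothly (Gaussian shoulder of scale `range/2`) beyond it.
#'
#' @param depth total thinning inside `range`, Angstrom (negative values
#'   thicken).
#' @param range plateau radius of the deformation, Angstrom.
#' @export
radial_deformation <- function(depth = 6, range = 10) {
  stopifnot(range > 0)
  list(type = "radial", depth = depth, range = range)
}

# per-leaflet z displacement of the planted deformation at lateral radius rho
deformation_dz <- function(def, rho) {
  (def$depth / 2) * exp(-pmax(0, rho - def$range)^2 / (2 * (def$range / 2)^2))
}

#' Synthetic-system specification
#'
#' Defaults describe a fluid-phase DPPC patch: 64 A^2 per lipid, 1 A
#' lattice jitter, phosphate planes 37 A apart (the alpha-helical
#' class-typical phosphate-to-phosphate thickness; use 33 for the
#' beta-barrel class).
#'
#' @param lipids_per_leaflet lipids per leaflet.
#' @param area_per_lipid lateral area per lipid, A^2.
#' @param phosphate_plane_separation planted phosphate-to-phosphate
#'   bilayer thickness, Angstrom.
#' @param protein `NULL`, [helix_bundle()] or [barrel_protein()].
#' @param deformation `NULL` or [radial_deformation()].
#' @param planted_flips list of `list(lipid, frame)` entries: lipid
#'   ordinal to mirror through the midplane from `frame` on.
#' @param n_frames number of frames to emit.
#' @param noise_sd per-frame rigid-lipid displacement noise, Angstrom.
#' @param jitter_sd lattice jitter, Angstrom.
#' @param water include a coarse water lattice outside the membrane slab.
#' @param n_ions number of ions of each species placed on water sites.
#' @param seed RNG seed; output is deterministic given the spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(lipids_per_leaflet = 64, area_per_lipid = 64,
                         phosphate_plane_separation = 37, protein = NULL,
                         deformation = NULL, planted_flips = list(),
                         n_frames = 1, noise_sd = 0.5, jitter_sd = 1,
                         water = TRUE, n_ions = 10, seed = 1) {
  stopifnot(lipids_per_leaflet >= 2, area_per_lipid > 0,
            phosphate_plane_separation > 0, n_frames >= 1,
            noise_sd >= 0, jitter_sd >= 0, n_ions >= 0)
  for (fl in planted_flips) {
    stopifnot(fl$lipid >= 1, fl$frame >= 1, fl$frame <= n_frames)
  }
  structure(list(lipids_per_leaflet = lipids_per_leaflet,
                 area_per_lipid = area_per_lipid,
                 phosphate_plane_separation = phosphate_plane_separation,
                 protein = protein, deformation = deformation,
                 planted_flips = planted_flips, n_frames = n_frames,
                 noise_sd = noise_sd, jitter_sd = jitter_sd, water = water,
                 n_ions = n_ions, seed = seed),
            class = "fixture_spec")
}

# 12-bead DPPC template for the upper leaflet: z offsets relative to the
# phosphate plane (negative = toward the midplane), lateral offsets split
# the two tails
dppc_template <- function() {
  data.frame(
    bead = c("NC3", "PO4", "GL1", "GL2",
             "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B"),
    dz = c(3, 0, -2.8, -3.6, -7, -10.5, -14, -17.5, -7, -10.5, -14, -17.5),
    dx = c(0, 0, -0.9, 0.9, -0.9, -0.9, -0.9, -0.9, 0.9, 0.9, 0.9, 0.9),
    stringsAsFactors = FALSE
  )
}

build_helix_bundle <- function(pr, sep, centre_xy, mid_z) {
  span <- sep + 16
  n_res <- ceiling(span / 1.5)
  rise <- 1.5; hel_r <- 2.3; twist <- 100 * pi / 180
  kink_ord <- floor(n_res / 2)
  coords <- NULL; helix_of <- integer(); seg_kind <- character()
  for (k in seq_len(pr$n_helices)) {
    th <- 2 * pi * (k - 1) / pr$n_helices
    cx <- centre_xy[1] + pr$radius * cos(th)
    cy <- centre_xy[2] + pr$radius * sin(th)
    i <- seq_len(n_res)
    z <- mid_z - span / 2 + (i - 1) * rise
    x <- cx + hel_r * cos(twist * i + th)
    y <- cy + hel_r * sin(twist * i + th)
    if (pr$kink_angle > 0) {
      top <- z > mid_z
      ang <- pr$kink_angle * pi / 180
      # tilt the top half about a lateral axis through the mid point
      zz <- z[top] - mid_z
      x[top] <- x[top] + zz * sin(ang)
      z[top] <- mid_z + zz * cos(ang)
    }
    xyz <- cbind(x, y, z)
    if (k %% 2 == 0) xyz <- xyz[rev(seq_len(n_res)), , drop = FALSE]
    coords <- rbind(coords, xyz)
    helix_of <- c(helix_of, rep(k, n_res))
    seg_kind <- c(seg_kind, rep("H", n_res))
    if (k < pr$n_helices) {
      # 3-residue loop arcing past the membrane
      nxt_th <- 2 * pi * k / pr$n_helices
      a <- coords[nrow(coords), ]
      b <- c(centre_xy[1] + pr$radius * cos(nxt_th) + hel_r,
             centre_xy[2] + pr$radius * sin(nxt_th),
             if (k %% 2 == 1) mid_z + span / 2 else mid_z - span / 2)
      s <- seq(0.25, 0.75, length.out = 3)
      loop <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
                    a[3] + sign(a[3] - mid_z) * 7)
      coords <- rbind(coords, loop)
      helix_of <- c(helix_of, rep(0L, 3))
      seg_kind <- c(seg_kind, rep("C", 3))
    }
  }
  list(coords = coords, ss = seg_kind, element_of = helix_of,
       n_elements = pr$n_helices, kink_ordinal = kink_ord,
       element_len = n_res, kind = "helix_bundle")
}

build_barrel <- function(pr, sep, centre_xy, mid_z) {
  span <- sep + 12
  spacing <- 3.5
  n_res <- ceiling(span / spacing)
  coords <- NULL; element_of <- integer(); seg_kind <- character()
  for (k in seq_len(pr$n_strands)) {
    th <- 2 * pi * (k - 1) / pr$n_strands
    cx <- centre_xy[1] + pr$radius * cos(th)
    cy <- centre_xy[2] + pr$radius * sin(th)
    i <- seq_len(n_res)
    z <- mid_z - span / 2 + (i - 1) * spacing
    xyz <- cbind(rep(cx, n_res), rep(cy, n_res), z)
    if (k %% 2 == 0) xyz <- xyz[rev(i), , drop = FALSE]
    coords <- rbind(coords, xyz)
    element_of <- c(element_of, rep(k, n_res))
    seg_kind <- c(seg_kind, rep("E", n_res))
    if (k < pr$n_strands) {
      a <- coords[nrow(coords), ]
      nxt_th <- 2 * pi * k / pr$n_strands
      b <- c(centre_xy[1] + pr$radius * cos(nxt_th),
             centre_xy[2] + pr$radius * sin(nxt_th), a[3])
      s <- seq(1 / 3, 2 / 3, length.out = 2)
      loop <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
                    a[3] + sign(a[3] - mid_z) * 2)
      coords <- rbind(coords, loop)
      element_of <- c(element_of, rep(0L, 2))
      seg_kind <- c(seg_kind, rep("C", 2))
    }
  }
  list(coords = coords, ss = seg_kind, element_of = element_of,
       n_elements = pr$n_strands, kink_ordinal = NA,
       element_len = n_res, kind = "barrel")
}

#' Generate a synthetic coarse-grained system with planted ground truth
#'
#' @param spec a [fixture_spec()].
#' @return object of class `cg_fixture`: list with `frames` (list of
#'   [cg_frame()]), `truth` (planted leaflet labels, flips, bulk
#'   thickness, deformation parameters, TM element count, per-residue
#'   environment band labels, sequence and secondary structure) and
#'   `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nlip <- spec$lipids_per_leaflet
  a <- sqrt(spec$area_per_lipid)
  n_side <- ceiling(sqrt(nlip))
  box_lat <- n_side * a
  sep <- spec$phosphate_plane_separation
  box_z <- sep + 44
  mid_z <- box_z / 2
  centre <- c(box_lat / 2, box_lat / 2)

  prot <- NULL
  if (!is.null(spec$protein)) {
    pr <- spec$protein
    if (pr$radius + 8 > box_lat / 2)
      stopf("protein radius %.1f A does not fit the %.1f A box",
            pr$radius, box_lat)
    prot <- switch(pr$type,
                   helix_bundle = build_helix_bundle(pr, sep, centre, mid_z),
                   barrel = build_barrel(pr, sep, centre, mid_z),
                   stopf("unknown protein type '%s'", pr$type))
  }

  # lattice sites, excluding the protein footprint; an annular ring of
  # lipids is packed against the protein surface so the first lipid shell
  # exists as it would after self-assembly
  sites <- expand.grid(x = (seq_len(n_side) - 0.5) * a,
                       y = (seq_len(n_side) - 0.5) * a)
  if (!is.null(prot)) {
    r_ring <- spec$protein$radius + 5.5
    n_ring <- max(6L, floor(2 * pi * r_ring / a))
    ring_th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    ring <- data.frame(x = centre[1] + r_ring * cos(ring_th),
                       y = centre[2] + r_ring * sin(ring_th))
    d <- sqrt((sites$x - centre[1])^2 + (sites$y - centre[2])^2)
    sites <- rbind(ring, sites[d > r_ring + 4, , drop = FALSE])
  }
  n_per_leaf <- min(nlip, nrow(sites))
  sites <- sites[seq_len(n_per_leaf), , drop = FALSE]

  tmpl <- dppc_template()
  def_dz <- function(x, y) {
    if (is.null(spec$deformation)) return(0)
    rho <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
    deformation_dz(spec$deformation, rho)
  }

  lip_base <- list()
  truth_leaflet <- character()
  lid <- 0L
  for (leaf in c("UPPER", "LOWER")) {
    sgn <- if (leaf == "UPPER") 1 else -1
    plane <- mid_z + sgn * sep / 2
    for (s in seq_len(n_per_leaf)) {
      lid <- lid + 1L
      jx <- sites$x[s] + rnorm(1, 0, spec$jitter_sd)
      jy <- sites$y[s] + rnorm(1, 0, spec$jitter_sd)
      jz <- rnorm(1, 0, spec$jitter_sd)
      pz <- plane + jz - sgn * def_dz(jx, jy)
      lip_base[[lid]] <- cbind(jx + tmpl$dx, rep(jy, nrow(tmpl)),
                               pz + sgn * tmpl$dz)
      truth_leaflet <- c(truth_leaflet, leaf)
    }
  }
  n_lipids <- lid

  # water lattice outside the slab, plus ions on the first sites
  wat <- NULL
  if (spec$water) {
    ws <- 5
    wx <- (seq_len(floor(box_lat / ws)) - 0.5) * ws
    wz <- (seq_len(floor(box_z / ws)) - 0.5) * ws
    wg <- expand.grid(x = wx, y = wx, z = wz)
    wg <- wg[abs(wg$z - mid_z) > sep / 2 + 4.5, , drop = FALSE]
    wat <- as.matrix(wg)
  }

  flips <- spec$planted_flips
  flip_df <- if (length(flips)) {
    data.frame(lipid_id = vapply(flips, `[[`, numeric(1), "lipid"),
               frame = vapply(flips, `[[`, numeric(1), "frame"))
  } else data.frame(lipid_id = integer(), frame = integer())
  flip_df$from_leaflet <- truth_leaflet[flip_df$lipid_id]
  flip_df$to_leaflet <- ifelse(flip_df$from_leaflet == "UPPER",
                               "LOWER", "UPPER")

  # identity tables (constant across frames)
  aa_cycle <- names(AA3)
  build_ids <- function() {
    res_name <- character(); res_idx <- integer(); bead <- character()
    chain <- character()
    if (!is.null(prot)) {
      np <- nrow(prot$coords)
      res_name <- rep(aa_cycle, length.out = np)
      res_idx <- seq_len(np)
      bead <- rep("BB", np)
      chain <- rep("A", np)
    }
    for (i in seq_len(n_lipids)) {
      res_name <- c(res_name, rep("DPPC", 12))
      res_idx <- c(res_idx, rep(i, 12))
      bead <- c(bead, tmpl$bead)
      chain <- c(chain, rep("L", 12))
    }
    if (!is.null(wat)) {
      nw <- nrow(wat)
      wres <- rep("W", nw); wbead <- rep("W", nw)
      ni <- min(spec$n_ions, nw %/% 4)
      if (ni > 0) {
        ion_idx <- seq_len(2 * ni)
        wres[ion_idx] <- rep(c("NA+", "CL-"), each = ni)
        wbead[ion_idx] <- wres[ion_idx]
      }
      res_name <- c(res_name, wres)
      res_idx <- c(res_idx, n_lipids + seq_len(nw))
      bead <- c(bead, wbead)
      chain <- c(chain, rep("S", nw))
    }
    list(res_name = res_name, res_idx = res_idx, bead = bead, chain = chain)
  }
  ids <- build_ids()

  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    lip_coords <- lip_base
    # per-frame rigid-lipid noise
    if (spec$noise_sd > 0) {
      for (i in seq_len(n_lipids)) {
        shift <- rnorm(3, 0, spec$noise_sd)
        lip_coords[[i]] <- sweep(lip_coords[[i]], 2, shift, `+`)
      }
    }
    if (nrow(flip_df)) {
      for (r in seq_len(nrow(flip_df))) {
        if (f >= flip_df$frame[r]) {
          i <- flip_df$lipid_id[r]
          lip_coords[[i]][, 3] <- 2 * mid_z - lip_coords[[i]][, 3]
        }
      }
    }
    coords <- do.call(rbind, c(if (!is.null(prot)) list(prot$coords),
                               lip_coords,
                               if (!is.null(wat)) list(wat)))
    frames[[f]] <- cg_frame(coords, residue_name = ids$res_name,
                            residue_index = ids$res_idx,
                            chain_id = ids$chain, bead_name = ids$bead,
                            box = c(box_lat, box_lat, box_z),
                            frame_time = f - 1)
  }

  truth <- list(
    leaflet = data.frame(lipid_id = seq_len(n_lipids),
                         leaflet = truth_leaflet, stringsAsFactors = FALSE),
    flips = flip_df,
    bulk_thickness = sep,
    deformation = spec$deformation,
    box = c(box_lat, box_lat, box_z),
    midplane_z = mid_z,
    n_lipids = n_lipids
  )
  if (!is.null(prot)) {
    np <- nrow(prot$coords)
    zb <- prot$coords[, 3] - mid_z
    env <- ifelse(abs(zb) < sep / 2 - 6, "ACYL_TAIL",
                  ifelse(abs(zb) <= sep / 2 + 6, "HEADGROUP", "SOLVENT"))
    # residues facing the bundle/pore interior see no lipid at all
    lat <- sqrt((prot$coords[, 1] - centre[1])^2 +
                  (prot$coords[, 2] - centre[2])^2)
    env[env != "SOLVENT" & lat < spec$protein$radius] <- "BURIED"
    truth$protein <- list(
      kind = prot$kind, tm_count = prot$n_elements,
      element_len = prot$element_len, kink_ordinal = prot$kink_ordinal,
      sequence = paste(aa_three_to_one(ids$res_name[seq_len(np)]),
                       collapse = ""),
      ss = paste(prot$ss, collapse = ""),
      environment = env)
  }
  structure(list(frames = frames, truth = truth, spec = spec),
            class = "cg_fixture")
}

#' @export
print.cg_fixture <- function(x, ...) {
  cat(sprintf("<cg_fixture> %d frame(s), %d lipids, box %.0f x %.0f x %.0f A\n",
              length(x$frames), x$truth$n_lipids, x$truth$box[1],
              x$truth$box[2], x$truth$box[3]))
  if (!is.null(x$truth$protein))
    cat(sprintf("protein: %s, %d membrane-spanning elements\n",
                x$truth$protein$kind, x$truth$protein$tm_count))
  invisible(x)
}

#' Write a fixture to disk (GRO trajectory, FASTA, ground-truth JSON)
#' @param fixture a `cg_fixture`.
#' @param dir output directory (created if missing).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gro(fixture$frames, file.path(dir, "trajectory.gro"))
  if (!is.null(fixture$truth$protein)) {
    writeLines(c(">A", fixture$truth$protein$sequence),
               file.path(dir, "sequence.fasta"))
    writeLines(c(">A", fixture$truth$protein$ss),
               file.path(dir, "secondary_structure.fasta"))
  }
  jsonlite::write_json(fixture$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' Default per-amino-acid contact probabilities for synthetic cohorts
#'
#' Twenty distinct probability triples (head, tail, solvent), assigned in
#' alphabetical one-letter order. Values are arbitrary but fixed, chosen so
#' no category is degenerate, glycine is not the maximum of any, and almost
#' every sampled residue makes at least one contact (the cohort emulates
#' surface residues, matching the conditioning of the propensity-scale
#' denominator).
#' @return data.frame: `aa`, `p_head`, `p_tail`, `p_solvent`.
#' @export
default_cohort_probabilities <- function() {
  types <- sort(unname(AA3))
  i <- seq_len(20)
  data.frame(aa = types,
             p_head = seq(0.05, 0.90, length.out = 20),
             p_tail = seq(0.92, 0.08, length.out = 20),
             p_solvent = 0.96 - 0.012 * abs(i - 10.5) + 0.002 * (i - 10) / 20,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic residue-contact cohort
#'
#' Samples residue-level contact incidences from per-amino-acid
#' probabilities (head-group, acyl-tail and solvent categories drawn
#' independently), yielding a contact profile collection for testing
#' propensity-scale recovery.
#'
#' @param probabilities data.frame as [default_cohort_probabilities()].
#' @param n_per_type residues per amino-acid type.
#' @param seed RNG seed.
#' @return a `residue_contact_profile` with `20 * n_per_type` residues.
#' @export
generate_cohort <- function(probabilities = default_cohort_probabilities(),
                            n_per_type = 500, seed = 1) {
  stopifnot(all(probabilities$p_head >= 0 & probabilities$p_head <= 1),
            all(probabilities$p_tail >= 0 & probabilities$p_tail <= 1),
            all(probabilities$p_solvent >= 0 & probabilities$p_solvent <= 1))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(probabilities)), function(i) {
    aa1 <- probabilities$aa[i]
    n <- n_per_type
    head_i <- rbinom(n, 1, probabilities$p_head[i])
    tail_i <- rbinom(n, 1, probabilities$p_tail[i])
    solv_i <- rbinom(n, 1, probabilities$p_solvent[i])
    data.frame(chain_id = "A", residue_index = 0L,
               residue_name = aa_one_to_three(aa1),
               choline = 0, phosphate = head_i * (1 + rpois(n, 2)),
               glycerol = 0,
               tail_1 = tail_i * (1 + rpois(n, 2)),
               tail_2 = 0, tail_3 = 0, tail_4 = 0,
               water = solv_i * (1 + rpois(n, 2)), ion = 0,
               flip_lipid = 0, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$residue_index <- seq_len(nrow(df))
  new_contact_profile(df, frames_analysed = 1L)
}
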