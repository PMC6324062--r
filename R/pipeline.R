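# Orchestration: the full per-structure analysis pipeline and the
# multi-structure ensemble aggregation, with on-disk bundles and run
# manifests.

#' Analysis configuration
#'
#' @param cutoff contact cutoff, Angstrom.
#' @param grid_spacing surface grid spacing, Angstrom.
#' @param bin_width RDF bin width, Angstrom.
#' @param r_max RDF maximum radius, Angstrom (clipped to the box).
#' @param persistence_frames flip-flop persistence requirement, frames.
#' @param leaflet_cutoff phosphate proximity-graph cutoff, Angstrom.
#' @param bandwidth surface kernel bandwidth, Angstrom.
#' @param kink_tol spline knot-insertion tolerance, Angstrom.
#' @param frames `"all"` or `"final10"` (analyse the final 10% of frames,
#'   approximating a post-assembly snapshot).
#' @param seed RNG seed recorded in the manifest.
#' @export
analysis_config <- function(cutoff = 6, grid_spacing = 2, bin_width = 1,
                            r_max = 40, persistence_frames = 5,
                            leaflet_cutoff = 15, bandwidth = 5,
                            kink_tol = 2, frames = "all", seed = 1) {
  num <- list(cutoff = cutoff, grid_spacing = grid_spacing,
              bin_width = bin_width, r_max = r_max,
              persistence_frames = persistence_frames,
              leaflet_cutoff = leaflet_cutoff, bandwidth = bandwidth,
              kink_tol = kink_tol)
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && v > 0,
                            logical(1))]
  if (length(bad))
    stopf("configuration parameter(s) must be positive: %s",
          paste(bad, collapse = ", "))
  structure(c(num, list(frames = frames, seed = seed)),
            class = "analysis_config")
}

select_frames <- function(frames, rule) {
  n <- length(frames)
  if (identical(rule, "final10")) {
    k <- max(1L, ceiling(0.1 * n))
    frames[(n - k + 1L):n]
  } else frames
}

#' Run the full per-structure analysis pipeline
#'
#' Executes, in order: leaflet assignment and tracking, flip-flop
#' detection, head-group RDF and annular shells, leaflet surfaces with
#' thickness/deformation maps, per-residue depth, contact profiles,
#' environment classification, secondary structure, TM detection, chain
#' classification and topology splines. All products are written to
#' `out_dir` (CSV/JSON/SVG/FASTA) together with a run manifest. A
#' non-bilayer input produces a structured failure record
#' (`failure.json`) and a result with `status = "non_bilayer"` rather
#' than an R error.
#'
#' @param input file path(s) (GRO/PDB), a list of [cg_frame()] objects, or
#'   a `cg_fixture`.
#' @param out_dir output directory (created).
#' @param config an [analysis_config()].
#' @param sequences optional FASTA path or data.frame from
#'   [read_chain_sequences()]; when absent, sequences are derived from
#'   residue names in the frame and secondary structure is assigned
#'   geometrically.
#' @return object of class `cgmem_analysis` (invisibly): all intermediate
#'   products plus `status` and `out_dir`.
#' @export
run_analyse <- function(input, out_dir, config = analysis_config(),
                        sequences = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_files <- character()
  if (inherits(input, "cg_fixture")) {
    frames <- input$frames
  } else if (inherits(input, "cg_frame")) {
    frames <- list(input)
  } else if (is.character(input)) {
    input_files <- input
    frames <- do.call(c, lapply(input, read_trajectory))
  } else frames <- input
  if (is.character(sequences)) sequences <- read_chain_sequences(sequences)

  stages <- list()
  note <- function(name, status) stages[[name]] <<- status
  fail <- function(stage, e, status) {
    rec <- list(status = status, stage = stage,
                message = conditionMessage(e), stages = stages)
    jsonlite::write_json(rec, file.path(out_dir, "failure.json"),
                         auto_unbox = TRUE)
    structure(list(status = status, stage = stage,
                   message = conditionMessage(e), out_dir = out_dir),
              class = "cgmem_analysis")
  }

  analysed <- select_frames(frames, config$frames)
  last <- analysed[[length(analysed)]]

  # --- leaflets + flips ---
  rec <- tryCatch({
    rec <- track_leaflets(analysed, cutoff = config$leaflet_cutoff)
    note("leaflets", "ok")
    rec
  }, cgmem_non_bilayer = function(e) e, error = function(e) e)
  if (inherits(rec, "condition"))
    return(fail("leaflets", rec,
                if (inherits(rec, "cgmem_non_bilayer")) "non_bilayer"
                else "stage_failure"))
  leaf_last <- data.frame(lipid_id = rec$lipid_id,
                          leaflet = rec$labels[, ncol(rec$labels)],
                          stringsAsFactors = FALSE)
  class(leaf_last) <- c("leaflet_assignment", "data.frame")
  write.csv(leaf_last, file.path(out_dir, "leaflets.csv"),
            row.names = FALSE)

  flips <- if (ncol(rec$labels) >= config$persistence_frames + 1) {
    detect_flipflops(rec, persistence_frames = config$persistence_frames)
  } else if (ncol(rec$labels) >= 2) {
    detect_flipflops(rec, persistence_frames = ncol(rec$labels) - 1L)
  } else {
    structure(data.frame(lipid_id = integer(), from_leaflet = character(),
                         to_leaflet = character(), start_frame = integer(),
                         end_frame = integer()),
              class = c("flipflop_events", "data.frame"))
  }
  note("flipflops", "ok")
  write.csv(as.data.frame(flips), file.path(out_dir, "flipflops.csv"),
            row.names = FALSE)

  has_protein <- any(last$bead_class == "PROTEIN")

  # --- RDF / shells ---
  rdf <- NULL
  if (has_protein) {
    rdf <- tryCatch(headgroup_rdf(last, bin_width = config$bin_width,
                                  r_max = min(config$r_max,
                                              min(last$box[1:2]) / 2 - 1e-6)),
                    error = function(e) e)
    if (inherits(rdf, "error")) return(fail("rdf", rdf, "stage_failure"))
    note("rdf", "ok")
    write_rdf_csv(rdf, file.path(out_dir, "rdf.csv"))
  } else note("rdf", "skipped: no protein")

  # --- surfaces ---
  shell2 <- if (!is.null(rdf) && length(rdf$shell_boundaries) >= 2)
    rdf$shell_boundaries[2] else NULL
  surf <- tryCatch(leaflet_surfaces(last, leaf_last,
                                    grid_spacing = config$grid_spacing,
                                    bandwidth = config$bandwidth,
                                    shell_boundary = shell2),
                   error = function(e) e)
  if (inherits(surf, "error")) return(fail("surfaces", surf, "stage_failure"))
  note("surfaces", "ok")
  write_surfaces_csv(surf, file.path(out_dir, "surfaces.csv"))
  write_surfaces_json(surf, file.path(out_dir, "surfaces.json"))

  depth <- NULL; profile <- NULL; env <- NULL; segments <- NULL
  chains <- list(); topo <- list()
  if (has_protein) {
    depth <- local_thickness_per_residue(last, surf)
    note("depth", "ok")
    write.csv(depth, file.path(out_dir, "residue_depth.csv"),
              row.names = FALSE)

    profile <- count_contacts(analysed, cutoff = config$cutoff,
                              flip_events = flips)
    note("contacts", "ok")
    write_contact_table(profile, file.path(out_dir, "contacts.csv"))
    env <- classify_environment(profile)
    write.csv(env, file.path(out_dir, "environment.csv"), row.names = FALSE)

    # --- topology ---
    res <- residue_positions(last)
    chain_ids <- unique(res$chain_id)
    seg_list <- list()
    ss_strings <- list()
    for (cid in chain_ids) {
      cs <- NULL
      if (!is.null(sequences) && cid %in% sequences$chain_id)
        cs <- sequences[sequences$chain_id == cid, , drop = FALSE]
      ss <- assign_secondary_structure(cs, last, chain_id = cid)
      ss_strings[[cid]] <- ss
      off <- min(res$residue_index[res$chain_id == cid]) - 1L
      seg_list[[cid]] <- ss_segments(ss, chain_id = cid,
                                     residue_offset = off)
    }
    segments <- do.call(rbind, seg_list)
    segments <- detect_tm_segments(segments, surf, last)
    note("topology", "ok")
    for (cid in chain_ids) {
      chains[[cid]] <- classify_chain(segments, depth, surf$bulk_thickness,
                                      chain_id = cid)
      topo[[cid]] <- build_topology_splines(segments, last, surf,
                                            chain_id = cid,
                                            kink_tol = config$kink_tol)
      write_topology_svg(topo[[cid]],
                         file.path(out_dir,
                                   sprintf("topology_%s.svg", cid)))
    }
    jsonlite::write_json(list(
      segments = segments,
      chains = lapply(chains, function(ch) ch[c("chain_id",
                                                "interaction_class",
                                                "tm_helix_count",
                                                "tm_strand_count",
                                                "summary_text")])),
      file.path(out_dir, "topology.json"), auto_unbox = TRUE, digits = NA,
      na = "null")

    # --- sequence + tracks ---
    fasta <- file.path(out_dir, "sequence.fasta")
    ssfa <- file.path(out_dir, "secondary_structure.fasta")
    seq_df <- derive_sequences(res, ss_strings, sequences)
    writeLines(as.vector(rbind(paste0(">", seq_df$chain_id),
                               seq_df$sequence)), fasta)
    writeLines(as.vector(rbind(paste0(">", seq_df$chain_id), seq_df$ss)),
               ssfa)
    tracks <- tryCatch({
      do.call(rbind, lapply(seq_len(nrow(seq_df)), function(i)
        sequence_tracks(profile, depth, seq_df[i, , drop = FALSE])))
    }, error = function(e) e)
    if (inherits(tracks, "error")) {
      note("tracks", paste("failed:", conditionMessage(tracks)))
      tracks <- NULL
    } else {
      note("tracks", "ok")
      write.csv(tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
    }
  }

  manifest <- list(
    package = "cgmem", version = as.character(packageVersion("cgmem")),
    parameters = unclass(config),
    n_frames_total = length(frames), n_frames_analysed = length(analysed),
    input_files = input_files,
    input_md5 = if (length(input_files))
      as.list(tools::md5sum(input_files)) else NULL,
    stages = stages, status = "ok")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")

  invisible(structure(list(
    status = "ok", out_dir = out_dir, frames = analysed,
    leaflets = rec, flips = flips, rdf = rdf, surfaces = surf,
    depth = depth, profile = profile, environment = env,
    segments = segments, chains = chains, splines = topo,
    sequences = if (has_protein) seq_df else NULL,
    tracks = if (has_protein && !is.null(tracks)) tracks else NULL,
    config = config), class = "cgmem_analysis"))
}

derive_sequences <- function(res, ss_strings, sequences) {
  out <- do.call(rbind, lapply(unique(res$chain_id), function(cid) {
    r <- res[res$chain_id == cid, , drop = FALSE]
    r <- r[order(r$residue_index), , drop = FALSE]
    sq <- paste(aa_three_to_one(r$residue_name), collapse = "")
    data.frame(chain_id = cid, sequence = sq,
               ss = ss_strings[[cid]], stringsAsFactors = FALSE)
  }))
  if (!is.null(sequences)) {
    m <- match(out$chain_id, sequences$chain_id)
    repl <- !is.na(m)
    out$sequence[repl] <- sequences$sequence[m[repl]]
  }
  out
}

#' @export
print.cgmem_analysis <- function(x, ...) {
  cat(sprintf("<cgmem_analysis> status: %s (%s)\n", x$status,
              x$out_dir %||% ""))
  if (x$status == "ok" && length(x$chains))
    for (ch in x$chains) cat(" ", ch$summary_text, "\n")
  invisible(x)
}

#' Run the ensemble aggregation over analysed structures
#'
#' Aligns the members' sequences, aggregates per-residue contact/depth/SS
#' profiles onto alignment columns, computes the contact propensity scale,
#' the amino-acid depth distributions and the per-class thickness summary,
#' and writes all products plus a manifest to `out_dir`.
#'
#' @param members named list of `cgmem_analysis` objects (from
#'   [run_analyse()]) or a named character vector of bundle directories.
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @param aligner passed to [align_members()].
#' @return object of class `cgmem_ensemble` (invisibly).
#' @export
run_ensemble <- function(members, out_dir, config = analysis_config(),
                         aligner = "builtin") {
  if (length(members) < 2) stopf("ensemble needs at least 2 members")
  if (is.character(members)) {
    missing <- members[!dir.exists(members)]
    if (length(missing))
      stopf("missing member bundle(s): %s", paste(missing, collapse = ", "))
    members <- lapply(members, read_bundle)
  }
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stopf("members must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seqs <- vapply(members, function(m) m$sequences$sequence[1], character(1))
  aln <- align_members(seqs, aligner = aligner)
  write_alignment_fasta(aln, file.path(out_dir, "alignment.fasta"))

  mem_in <- lapply(members, function(m) {
    cid <- m$sequences$chain_id[1]
    prof <- m$profile
    prof <- prof[prof$chain_id == cid, , drop = FALSE]
    list(profile = prof, depth = m$depth[m$depth$chain_id == cid, ],
         ss = m$sequences$ss[1])
  })
  ens <- aggregate_profiles(aln, mem_in)
  cols <- data.frame(column = seq_along(ens$coverage),
                     consensus_ss = ens$consensus_ss,
                     conservation = ens$conservation,
                     coverage = ens$coverage,
                     mean_head_fraction = colMeans(ens$head_fraction,
                                                   na.rm = TRUE),
                     mean_tail_fraction = colMeans(ens$tail_fraction,
                                                   na.rm = TRUE),
                     mean_depth = colMeans(ens$depth, na.rm = TRUE))
  write.csv(cols, file.path(out_dir, "ensemble_columns.csv"),
            row.names = FALSE)
  write_ensemble_svg(ens, file.path(out_dir, "ensemble.svg"))

  scale <- tryCatch(
    contact_propensity_scale(lapply(members, function(m) m$profile)),
    error = function(e) e)
  if (!inherits(scale, "error"))
    write.csv(as.data.frame(scale), file.path(out_dir, "propensity.csv"),
              row.names = FALSE)

  dd_in <- do.call(rbind, lapply(names(members), function(nm) {
    m <- members[[nm]]
    prof <- as.data.frame(m$profile)
    dm <- match(paste(prof$chain_id, prof$residue_index),
                paste(m$depth$chain_id, m$depth$residue_index))
    data.frame(aa = aa_three_to_one(prof$residue_name),
               chain_id = paste(nm, prof$chain_id),
               depth = m$depth$depth[dm],
               local_thickness = m$depth$local_thickness[dm],
               solvent_contacts = prof$water + prof$ion,
               x = m$depth$x[dm], y = m$depth$y[dm],
               stringsAsFactors = FALSE)
  }))
  dd <- depth_distributions(dd_in[!is.na(dd_in$aa), , drop = FALSE])
  hist_df <- data.frame(z_mid = (dd$breaks[-1] + dd$breaks[-length(dd$breaks)]) / 2,
                        t(dd$histograms))
  write.csv(hist_df, file.path(out_dir, "depth_histograms.csv"),
            row.names = FALSE)

  labels <- vapply(members, function(m) {
    ns <- sum(vapply(m$chains, function(ch) ch$tm_strand_count, numeric(1)))
    nh <- sum(vapply(m$chains, function(ch) ch$tm_helix_count, numeric(1)))
    if (ns > nh) "beta_barrel" else "alpha_helical"
  }, character(1))
  th <- thickness_summary(lapply(members, function(m) m$surfaces), labels)
  write.csv(th, file.path(out_dir, "thickness_summary.csv"),
            row.names = FALSE)

  jsonlite::write_json(list(
    package = "cgmem", version = as.character(packageVersion("cgmem")),
    members = names(members), parameters = unclass(config),
    status = "ok"), file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, na = "null")

  invisible(structure(list(alignment = aln, profile = ens,
                           propensity = if (inherits(scale, "error")) NULL
                                        else scale,
                           depth_distribution = dd,
                           thickness = th, out_dir = out_dir),
                      class = "cgmem_ensemble"))
}

# reconstitute the parts of an analysis bundle the ensemble stage needs
read_bundle <- function(dir) {
  profile <- read_contact_table(file.path(dir, "contacts.csv"))
  depth <- read.csv(file.path(dir, "residue_depth.csv"),
                    stringsAsFactors = FALSE)
  seqs <- read_chain_sequences(file.path(dir, "sequence.fasta"),
                               file.path(dir, "secondary_structure.fasta"))
  sj <- jsonlite::read_json(file.path(dir, "surfaces.json"),
                            simplifyVector = TRUE)
  topo <- jsonlite::read_json(file.path(dir, "topology.json"),
                              simplifyVector = TRUE)
  ch <- topo$chains
  chains <- if (is.data.frame(ch)) {
    lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ]))
  } else ch
  list(profile = profile, depth = depth, sequences = seqs,
       surfaces = list(bulk_thickness = sj$bulk_thickness),
       chains = chains)
}
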