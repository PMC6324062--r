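# shared fixture for topology tests
bundle_fx <- generate_fixture(fixture_spec(protein = helix_bundle(),
                                           seed = 1))
bundle_fr <- bundle_fx$frames[[1]]
bundle_la <- assign_leaflets(bundle_fr)
bundle_surf <- leaflet_surfaces(bundle_fr, bundle_la)

test_that("user-supplied secondary structure takes precedence", {
  cs <- data.frame(chain_id = "A", sequence = "MKT", ss = "HEC")
  expect_equal(assign_secondary_structure(cs, bundle_fr), "HEC")
})

test_that("geometric assignment labels ideal helices and extended chains", {
  # helical backbone spiral: radius 2.3 A, rise 1.5 A, 100 deg/residue
  n <- 30; th <- 100 * pi / 180; i <- 1:n
  hx <- cbind(50 + 2.3 * cos(th * i), 50 + 2.3 * sin(th * i), 20 + 1.5 * i)
  frh <- cg_frame(hx, rep("LEU", n), 1:n, rep("A", n), rep("BB", n),
                  c(100, 100, 100))
  ssh <- assign_secondary_structure(NULL, frh, chain_id = "A")
  expect_gte(mean(strsplit(ssh, "")[[1]] == "H"), 0.9)

  # fully extended: 3.5 A per residue along a line
  fre <- cg_frame(axis_trace(c(100, 100, 100), 20, n, rise = 3.5),
                  rep("LEU", n), 1:n, rep("A", n), rep("BB", n),
                  c(100, 100, 100))
  sse <- assign_secondary_structure(NULL, fre, chain_id = "A")
  expect_equal(sum(strsplit(sse, "")[[1]] == "H"), 0)
  expect_gte(mean(strsplit(sse, "")[[1]] == "E"), 0.9)

  expect_error(assign_secondary_structure(NULL, frh, chain_id = "Z"),
               "not present")
})

test_that("short helical patterns do not survive the minimum length", {
  th <- 100 * pi / 180
  spiral <- function(n) cbind(50 + 2.3 * cos(th * (1:n)),
                              50 + 2.3 * sin(th * (1:n)),
                              20 + 1.5 * (1:n))
  mk <- function(xyz) cg_frame(xyz, rep("LEU", nrow(xyz)),
                               seq_len(nrow(xyz)),
                               rep("A", nrow(xyz)),
                               rep("BB", nrow(xyz)), c(100, 100, 100))
  # a 4-residue spiral supports only one isolated helical window
  expect_false(grepl("H", assign_secondary_structure(NULL, mk(spiral(4)),
                                                     chain_id = "A")))
  # a 5-residue spiral supports two consecutive windows: a real helix
  expect_true(grepl("HHHH", assign_secondary_structure(NULL, mk(spiral(5)),
                                                       chain_id = "A")))
})

test_that("segment tables are ordered and non-overlapping", {
  seg <- ss_segments("HHHHHCCEEEECHHHH", chain_id = "Q")
  expect_equal(seg$kind, c("HELIX", "LOOP", "STRAND", "LOOP", "HELIX"))
  expect_true(all(seg$start_residue <= seg$end_residue))
  expect_true(all(diff(seg$start_residue) > 0))
  expect_equal(seg$start_residue[-1], seg$end_residue[-nrow(seg)] + 1)
})

test_that("TM detection requires crossing both local leaflet surfaces", {
  mid <- bundle_fr$box[3] / 2
  # spanning trace: z from mid-25 to mid+25 through a 37 A bilayer
  span <- embed_beads(bundle_fr,
                      axis_trace(bundle_fr$box, mid - 25, 34, x = 12,
                                 y = 12),
                      "LEU", 1000L + 1:34, chain_id = "S")
  seg <- data.frame(chain_id = "S", kind = "HELIX",
                    start_residue = 1001L, end_residue = 1034L,
                    is_tm = FALSE, mean_tilt = NA_real_)
  got <- detect_tm_segments(seg, leaflet_surfaces(span,
                                                  assign_leaflets(span)),
                            span)
  expect_true(got$is_tm)
  expect_lt(got$mean_tilt, 10)

  # surface-lying trace at z = +17: never crosses the lower surface
  flat <- embed_beads(bundle_fr,
                      cbind(12 + 1.5 * (0:19), rep(12, 20),
                            rep(mid + 17, 20)),
                      "LEU", 2000L + 1:20, chain_id = "F")
  segf <- data.frame(chain_id = "F", kind = "HELIX",
                     start_residue = 2001L, end_residue = 2020L,
                     is_tm = FALSE, mean_tilt = NA_real_)
  gotf <- detect_tm_segments(segf,
                             leaflet_surfaces(flat, assign_leaflets(flat)),
                             flat)
  expect_false(gotf$is_tm)
})

test_that("the seven-helix bundle yields seven TM helices", {
  ss <- assign_secondary_structure(NULL, bundle_fr, chain_id = "A")
  seg <- detect_tm_segments(ss_segments(ss, "A"), bundle_surf, bundle_fr)
  dep <- local_thickness_per_residue(bundle_fr, bundle_surf)
  ch <- classify_chain(seg, dep, bundle_surf$bulk_thickness)
  expect_equal(ch$tm_helix_count, 7)
  expect_equal(ch$interaction_class, "MEMBRANE_SPANNING")
  expect_equal(ch$summary_text, "7 membrane spanning α helices")
  expect_equal(sum(ch$density_profile$count), nrow(dep))
})

test_that("TM helix count is invariant under rotation about the normal", {
  ang <- 0.71
  rot <- bundle_fr
  cx <- bundle_fr$box[1] / 2; cy <- bundle_fr$box[2] / 2
  x <- bundle_fr$coords[, 1] - cx; y <- bundle_fr$coords[, 2] - cy
  rot$coords[, 1] <- cx + x * cos(ang) - y * sin(ang)
  rot$coords[, 2] <- cy + x * sin(ang) + y * cos(ang)
  la <- assign_leaflets(rot)
  surf <- leaflet_surfaces(rot, la)
  ss <- assign_secondary_structure(NULL, rot, chain_id = "A")
  seg <- detect_tm_segments(ss_segments(ss, "A"), surf, rot)
  dep <- local_thickness_per_residue(rot, surf)
  expect_equal(classify_chain(seg, dep, surf$bulk_thickness)$tm_helix_count,
               7)
})

test_that("chains far outside the membrane are soluble with no TM", {
  mid <- bundle_fr$box[3] / 2
  sol <- embed_beads(bundle_fr,
                     cbind(20 + 1.5 * (0:11), rep(20, 12),
                           rep(mid + 31, 12)),
                     "SER", 3000L + 1:12, chain_id = "X")
  surf <- leaflet_surfaces(sol, assign_leaflets(sol))
  seg <- detect_tm_segments(
    data.frame(chain_id = "X", kind = "HELIX", start_residue = 3001L,
               end_residue = 3012L, is_tm = FALSE, mean_tilt = NA_real_),
    surf, sol)
  expect_false(seg$is_tm)
  dep <- local_thickness_per_residue(sol, surf)
  ch <- classify_chain(seg, dep, surf$bulk_thickness, chain_id = "X")
  expect_equal(ch$interaction_class, "SOLUBLE")
  expect_equal(ch$tm_helix_count, 0)
})

test_that("straight axis traces are recovered as straight splines", {
  mid <- bundle_fr$box[3] / 2
  fr <- embed_beads(flat_fixture(n = 64, jitter = 0, noise = 0,
                                 seed = 2)$frames[[1]],
                    axis_trace(c(64, 64, 81), mid - 24, 33),
                    "LEU", 1:33, chain_id = "A")
  surf <- leaflet_surfaces(fr, assign_leaflets(fr))
  seg <- detect_tm_segments(
    data.frame(chain_id = "A", kind = "HELIX", start_residue = 1L,
               end_residue = 33L, is_tm = FALSE, mean_tilt = NA_real_),
    surf, fr)
  topo <- build_topology_splines(seg, fr, surf)
  sp <- topo$splines[[1]]
  expect_length(sp$interior_knots, 0)
  # the projected axis is the constant-u line
  expect_lt(max(abs(sp$fitted[, 1] - sp$proj[1, 1])), 0.5)
  expect_lt(max(abs(sp$fitted[1, ] - sp$proj[1, ])), 0.1)
  m <- nrow(sp$proj)
  expect_lt(max(abs(sp$fitted[m, ] - sp$proj[m, ])), 0.1)
})

test_that("a planted kink attracts a knot near its position", {
  mid <- bundle_fr$box[3] / 2
  n <- 34; kink_at <- 17; ang <- 30 * pi / 180
  z <- mid - 25 + 1.5 * (0:(n - 1))
  x <- rep(30, n)
  top <- seq_len(n) > kink_at
  x[top] <- 30 + (z[top] - z[kink_at]) * sin(ang)
  z[top] <- z[kink_at] + (z[top] - z[kink_at]) * cos(ang)
  fr <- embed_beads(flat_fixture(n = 64, jitter = 0, noise = 0,
                                 seed = 2)$frames[[1]],
                    cbind(x, rep(30, n), z), "LEU", 1:n, chain_id = "A")
  surf <- leaflet_surfaces(fr, assign_leaflets(fr))
  seg <- data.frame(chain_id = "A", kind = "HELIX", start_residue = 1L,
                    end_residue = n, is_tm = TRUE, mean_tilt = 15)
  topo <- build_topology_splines(seg, fr, surf, kink_tol = 0.3)
  sp <- topo$splines[[1]]
  expect_gt(length(sp$interior_knots), 0)
  expect_lte(min(abs(sp$interior_knots - kink_at)), 2)
  # fit residual is non-increasing with each knot insertion
  expect_true(all(diff(sp$rmsd_history) <= 1e-9))
})

test_that("spline endpoints interpolate terminal projections everywhere", {
  ss <- assign_secondary_structure(NULL, bundle_fr, chain_id = "A")
  seg <- detect_tm_segments(ss_segments(ss, "A"), bundle_surf, bundle_fr)
  topo <- build_topology_splines(seg, bundle_fr, bundle_surf)
  for (sp in topo$splines) {
    if (isTRUE(sp$flagged)) next
    m <- nrow(sp$proj)
    expect_lt(max(abs(sp$fitted[1, ] - sp$proj[1, ])), 0.1)
    expect_lt(max(abs(sp$fitted[m, ] - sp$proj[m, ])), 0.1)
    expect_true(all(diff(sp$rmsd_history) <= 1e-9))
  }
  expect_false(is.null(topo$band))
  expect_true(all(is.finite(topo$band$upper)))

  svg <- tempfile(fileext = ".svg")
  write_topology_svg(topo, svg)
  expect_true(any(grepl("<svg", readLines(svg))))
})

test_that("segments shorter than four residues fall back to polylines", {
  seg <- data.frame(chain_id = "A", kind = "HELIX", start_residue = 1L,
                    end_residue = 3L, is_tm = FALSE, mean_tilt = NA_real_)
  mid <- bundle_fr$box[3] / 2
  fr <- embed_beads(flat_fixture(n = 16, seed = 3)$frames[[1]],
                    axis_trace(c(32, 32, 81), mid - 2, 3), "LEU", 1:3,
                    chain_id = "A")
  surf <- leaflet_surfaces(fr, assign_leaflets(fr))
  topo <- build_topology_splines(seg, fr, surf)
  expect_true(topo$splines[[1]]$flagged)
  expect_equal(nrow(topo$splines[[1]]$control_points), 3)
})
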