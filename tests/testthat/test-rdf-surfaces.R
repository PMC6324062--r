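test_that("RDF bin counts match the brute-force pair oracle and conserve", {
  fx <- flat_fixture(n = 12, seed = 3,
                     protein = helix_bundle(n_helices = 1, radius = 1))
  fr <- fx$frames[[1]]
  expect_lte(nrow(fr$coords), 500)
  rdf <- headgroup_rdf(fr, bin_width = 1, r_max = 15)
  expect_equal(rdf$counts, bf_rdf_counts(fr, 1, 15))
  expect_equal(sum(rdf$counts), sum(rdf$r_values < 15))
  expect_true(all(is.finite(rdf$g)))
})

test_that("RDF normalization approaches 1 in the unperturbed bulk", {
  fx <- generate_fixture(fixture_spec(lipids_per_leaflet = 400,
                                      water = FALSE, jitter_sd = 0,
                                      noise_sd = 0, seed = 3))
  fr <- fx$frames[[1]]
  fr2 <- embed_beads(fr, matrix(c(fr$box[1] / 2, fr$box[2] / 2,
                                  fr$box[3] / 2), 1), "GLY", 1L)
  rdf <- headgroup_rdf(fr2, r_max = 79)
  w <- c(30, 75)
  sel <- rdf$r > w[1] & rdf$r < w[2]
  dens <- rdf$n_phosphates / (fr$box[1] * fr$box[2])
  g_int <- sum(rdf$counts[sel]) / (dens * pi * (w[2]^2 - w[1]^2))
  expect_lt(abs(g_int - 1), 0.05)
})

test_that("a planted dense shell and depletion zone set the first boundary", {
  # point protein; phosphate ring at ~7 A, nothing in 8-12, lattice beyond
  box <- c(80, 80, 60)
  ring <- 14
  th <- 2 * pi * (seq_len(ring) - 1) / ring
  shell <- cbind(40 + 7 * cos(th), 40 + 7 * sin(th), 30)
  lat <- expand.grid(x = seq(2, 78, by = 8), y = seq(2, 78, by = 8))
  far <- sqrt((lat$x - 40)^2 + (lat$y - 40)^2) > 12
  bulk <- cbind(lat$x[far], lat$y[far], 30)
  ph <- rbind(shell, bulk)
  fr <- cg_frame(rbind(c(40, 40, 30), ph),
                 c("GLY", rep("DPPC", nrow(ph))),
                 c(1L, seq_len(nrow(ph))),
                 c("A", rep("L", nrow(ph))),
                 c("BB", rep("PO4", nrow(ph))), box)
  rdf <- headgroup_rdf(fr, bin_width = 1, r_max = 30)
  expect_gte(rdf$shell_boundaries[1], 8)
  expect_lte(rdf$shell_boundaries[1], 12)
})

test_that("r_max beyond the half box is rejected", {
  fx <- flat_fixture(n = 9, seed = 1,
                     protein = helix_bundle(n_helices = 1, radius = 1))
  expect_error(headgroup_rdf(fx$frames[[1]], r_max = 1000), "half")
})

test_that("flat-bilayer surfaces recover the planted thickness", {
  fx <- flat_fixture(n = 64, sep = 37, jitter = 0, noise = 0, seed = 1)
  fr <- fx$frames[[1]]
  la <- assign_leaflets(fr)
  surf <- leaflet_surfaces(fr, la)
  expect_lt(abs(surf$bulk_thickness - 37), 0.5)
  expect_true(all(abs(surf$deformation) < 0.5, na.rm = TRUE))
  # exact identities
  expect_equal(surf$thickness, surf$upper_z - surf$lower_z)
  expect_lt(abs(mean(surf$deformation[surf$bulk_mask])), 1e-6)
})

test_that("planted radial thinning appears in the deformation map", {
  fx <- generate_fixture(fixture_spec(
    lipids_per_leaflet = 144, protein = helix_bundle(n_helices = 1,
                                                     radius = 1),
    deformation = radial_deformation(6, 10), jitter_sd = 0.3,
    noise_sd = 0, water = FALSE, seed = 4))
  fr <- fx$frames[[1]]
  surf <- leaflet_surfaces(fr, assign_leaflets(fr))
  d <- surf$deformation
  i <- which.min(d)
  cells <- expand.grid(x = surf$grid_x, y = surf$grid_y)
  rho <- sqrt((cells$x[i] - fr$box[1] / 2)^2 + (cells$y[i] - fr$box[2] / 2)^2)
  expect_gte(min(d, na.rm = TRUE), -7)
  expect_lte(min(d, na.rm = TRUE), -5)
  expect_lte(rho, 10)
})

test_that("a cell with a single supporting phosphate takes its z", {
  box <- c(40, 40, 60)
  fr <- cg_frame(rbind(c(10, 10, 48.7), c(10, 10, 11.3)),
                 c("DPPC", "DPPC"), 1:2, c("L", "L"),
                 c("PO4", "PO4"), box)
  la <- data.frame(lipid_id = 1:2, leaflet = c("UPPER", "LOWER"))
  surf <- leaflet_surfaces(fr, la, grid_spacing = 2)
  ix <- which.min(abs(surf$grid_x - 10))
  iy <- which.min(abs(surf$grid_y - 10))
  expect_equal(surf$upper_z[ix, iy], 48.7)
  expect_equal(surf$lower_z[ix, iy], 11.3)
  # far cells have no support
  fx <- which.min(abs(surf$grid_x - 30))
  expect_true(is.nan(surf$upper_z[fx, fx]))
})

test_that("empty leaflets are rejected", {
  fx <- flat_fixture(n = 9, seed = 2)
  fr <- fx$frames[[1]]
  la <- assign_leaflets(fr)
  la$leaflet[] <- "UPPER"
  expect_error(leaflet_surfaces(fr, la), "empty leaflet")
})

test_that("per-residue depth and local thickness follow the geometry", {
  fx <- flat_fixture(n = 64, sep = 37, jitter = 0, noise = 0, seed = 1)
  fr <- fx$frames[[1]]
  mid <- fr$box[3] / 2
  pts <- rbind(c(20, 20, mid),            # midplane
               c(24, 24, mid + 21))       # above the upper surface
  fr2 <- embed_beads(fr, pts, c("LEU", "SER"), 1:2)
  surf <- leaflet_surfaces(fr2, assign_leaflets(fr2))
  dep <- local_thickness_per_residue(fr2, surf)
  expect_lt(abs(dep$depth[dep$residue_index == 1]), 0.5)
  expect_gt(dep$depth[dep$residue_index == 2], 18.5)
  expect_equal(dep$local_thickness, rep(37, 2), tolerance = 0.02)
})

test_that("per-residue thickness matches the planted analytic surface", {
  fx <- generate_fixture(fixture_spec(
    lipids_per_leaflet = 144, protein = helix_bundle(n_helices = 1,
                                                     radius = 1),
    deformation = radial_deformation(6, 10), jitter_sd = 0.3,
    noise_sd = 0, water = FALSE, seed = 4))
  fr <- fx$frames[[1]]
  surf <- leaflet_surfaces(fr, assign_leaflets(fr))
  dep <- local_thickness_per_residue(fr, surf)
  rho <- sqrt((dep$x - fr$box[1] / 2)^2 + (dep$y - fr$box[2] / 2)^2)
  analytic <- 37 - 2 * cgmem:::deformation_dz(radial_deformation(6, 10), rho)
  expect_lt(max(abs(dep$local_thickness - analytic)), 0.8)
})
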