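# hand-built member: profile + depth + ss for a short chain
mk_member <- function(seq, head, tail, solv, depth = NULL, ss = NULL) {
  n <- nchar(seq)
  aa <- strsplit(seq, "")[[1]]
  df <- data.frame(chain_id = "A", residue_index = seq_len(n),
                   residue_name = vapply(aa, function(x)
                     cgmem:::aa_one_to_three(x), character(1)),
                   choline = 0, phosphate = head, glycerol = 0,
                   tail_1 = tail, tail_2 = 0, tail_3 = 0, tail_4 = 0,
                   water = solv, ion = 0, flip_lipid = 0,
                   stringsAsFactors = FALSE)
  list(profile = cgmem:::new_contact_profile(df, 1L),
       depth = data.frame(chain_id = "A", residue_index = seq_len(n),
                          depth = depth %||% rep(0, n)),
       ss = ss %||% paste(rep("H", n), collapse = ""))
}

test_that("replicated members aggregate to the single-member profile", {
  m <- mk_member("ACDEF", head = c(2, 0, 0, 1, 0), tail = c(0, 3, 0, 1, 0),
                 solv = c(0, 0, 4, 0, 0), depth = c(-5, 0, 5, 10, 15))
  aln <- align_members(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
  ens <- aggregate_profiles(aln, list(a = m, b = m, c = m))
  expect_true(all(ens$conservation == 1))
  expect_true(all(ens$coverage == 1))
  for (row in c("a", "b", "c"))
    expect_equal(unname(ens$head_fraction[row, ]),
                 m$profile$head_fraction)
  expect_equal(unname(ens$depth["b", ]), m$depth$depth)
  expect_equal(paste(ens$consensus_ss, collapse = ""), m$ss)
})

test_that("gaps lower coverage and column means match brute force", {
  m1 <- mk_member("ACDEF", head = c(1, 1, 0, 0, 1), tail = c(0, 0, 1, 1, 0),
                  solv = rep(1, 5))
  m2 <- mk_member("ACEF", head = c(1, 0, 0, 1), tail = c(0, 1, 1, 0),
                  solv = rep(1, 4))
  aln <- align_members(c(a = "ACDEF", b = "ACEF"))
  ens <- aggregate_profiles(aln, list(a = m1, b = m2))
  gap_col <- which(strsplit(aln[["b"]], "")[[1]] == "-")
  expect_length(gap_col, 1)
  expect_equal(ens$coverage[gap_col], 0.5)
  expect_equal(ens$coverage[-gap_col], rep(1, 4))
  # brute-force column means over member rows
  for (j in seq_along(ens$coverage)) {
    vals <- ens$head_fraction[, j]
    expect_equal(mean(vals, na.rm = TRUE),
                 colMeans(ens$head_fraction, na.rm = TRUE)[j])
  }
  # mismatched profile length errors
  expect_error(aggregate_profiles(aln, list(a = m2, b = m2)), "non-gap")
})

test_that("the propensity scale anchors glycine at 0 and the max at 100", {
  coh <- generate_cohort(n_per_type = 200, seed = 1)
  ps <- contact_propensity_scale(coh)
  for (col in c("s_head", "s_tail", "s_solvent")) {
    expect_equal(ps[[col]][ps$aa == "G"], 0)
    expect_equal(max(ps[[col]]), 100)
  }
})

test_that("hand-set probabilities give the expected affine values", {
  # all residues get a solvent contact; head incidence planted exactly
  # every residue gets exactly one guaranteed contact (tail or water,
  # mixed for glycine so it is never the maximum of any category)
  mk_type <- function(aa1, k, filler, n = 10) {
    three <- cgmem:::aa_one_to_three(aa1)
    data.frame(chain_id = "A", residue_index = seq_len(n),
               residue_name = three, choline = 0,
               phosphate = rep(c(1, 0), c(k, n - k)), glycerol = 0,
               tail_1 = if (filler == "tail") 1 else
                 if (filler == "mix") rep(c(1, 0), 5) else 0,
               tail_2 = 0, tail_3 = 0, tail_4 = 0,
               water = if (filler == "water") 1 else
                 if (filler == "mix") rep(c(0, 1), 5) else 0,
               ion = 0, flip_lipid = 0)
  }
  types <- sort(unname(cgmem:::AA3))
  ks <- setNames(rep(0L, 20), types)
  ks["G"] <- 2L; ks["L"] <- 8L; ks["R"] <- 5L
  fillers <- setNames(rep(c("tail", "water"), 10), types)
  fillers["G"] <- "mix"
  df <- do.call(rbind, lapply(types, function(t)
    mk_type(t, ks[t], fillers[t])))
  prof <- cgmem:::new_contact_profile(df, 1L)
  ps <- contact_propensity_scale(prof)
  expect_equal(ps$p_head[ps$aa == "G"], 0.2)
  expect_equal(ps$s_head[ps$aa == "R"], 50)
  expect_equal(ps$s_head[ps$aa == "L"], 100)
  expect_equal(ps$s_head[ps$aa == "G"], 0)
  # types below glycine go negative
  expect_lt(ps$s_head[ps$aa == "A"], 0)
})

test_that("the scale is invariant under duplicating the collection", {
  coh <- generate_cohort(n_per_type = 100, seed = 5)
  p1 <- contact_propensity_scale(coh)
  p2 <- contact_propensity_scale(list(coh, coh))
  expect_equal(p1$p_head, p2$p_head)
  expect_equal(p1$s_tail, p2$s_tail)
})

test_that("a degenerate scale (max = glycine) is an error", {
  df <- do.call(rbind, lapply(sort(unname(cgmem:::AA3)), function(t)
    data.frame(chain_id = "A", residue_index = 1:4,
               residue_name = cgmem:::aa_one_to_three(t), choline = 0,
               phosphate = 1, glycerol = 0, tail_1 = 0, tail_2 = 0,
               tail_3 = 0, tail_4 = 0, water = 0, ion = 0,
               flip_lipid = 0)))
  prof <- cgmem:::new_contact_profile(df, 1L)
  expect_error(contact_propensity_scale(prof), "degenerate")
})

test_that("planted probabilities are recovered from a large cohort", {
  probs <- default_cohort_probabilities()
  coh <- generate_cohort(probs, n_per_type = 2000, seed = 1)
  ps <- contact_propensity_scale(coh)
  expect_lt(max(abs(ps$p_head - probs$p_head)), 0.05)
  expect_lt(max(abs(ps$p_tail - probs$p_tail)), 0.05)
  expect_lt(max(abs(ps$p_solvent - probs$p_solvent)), 0.05)
})

depth_residues <- function(n = 60, seed = 2) {
  set.seed(seed)
  types <- sort(unname(cgmem:::AA3))
  do.call(rbind, lapply(types, function(t) {
    zp <- switch(t,
                 L = runif(n, -0.5, 0.5),
                 I = runif(n, -0.5, 0.5),
                 R = sample(c(-1, 1), n, TRUE) * runif(n, 0.9, 1.1),
                 runif(n, -1.5, 1.5))
    data.frame(aa = t, depth = zp * 18.5, local_thickness = 37,
               solvent_contacts = 0, x = runif(n, 0, 50),
               y = runif(n, 0, 50), chain_id = "A")
  }))
}

test_that("relative depth histograms sum to one and cluster by shape", {
  res <- depth_residues()
  dd <- depth_distributions(res, mode = "relative")
  sums <- rowSums(dd$histograms)
  expect_true(all(abs(sums - 1) < 1e-9))
  # planted separation: membrane-core Leu vs interfacial Arg
  expect_false(dd$clusters[["L"]] == dd$clusters[["R"]])
  # identical planted distributions share a cluster
  expect_equal(dd$clusters[["I"]], dd$clusters[["L"]])
  expect_true(all(!is.na(dd$clusters)))
})

test_that("absolute mode keeps raw counts", {
  res <- depth_residues(n = 40, seed = 3)
  dd <- depth_distributions(res, mode = "absolute")
  expect_equal(unname(rowSums(dd$histograms)["L"]), 40)
})

test_that("pore-inner residues are excluded by the stated rule", {
  hull <- cbind(c(10, 30, 30, 10), c(10, 10, 30, 30))
  pore <- data.frame(aa = "L", depth = 0, local_thickness = 37,
                     solvent_contacts = 3, x = 20, y = 20, chain_id = "A")
  lipid_facing <- data.frame(aa = "L", depth = 0, local_thickness = 37,
                             solvent_contacts = 0, x = 20, y = 20,
                             chain_id = "A")
  outside <- data.frame(aa = "L", depth = 0, local_thickness = 37,
                        solvent_contacts = 3, x = 45, y = 45,
                        chain_id = "A")
  res <- rbind(pore, lipid_facing, outside)
  dd <- depth_distributions(res, tm_hulls = list(A = hull))
  expect_equal(dd$excluded, 1)
  expect_equal(sum(dd$histograms["L", ] > 0) >= 1, TRUE)
})

test_that("thickness summaries recover planted class thicknesses", {
  mk_surf <- function(sep, seed) {
    fx <- flat_fixture(n = 36, sep = sep, seed = seed)
    leaflet_surfaces(fx$frames[[1]], assign_leaflets(fx$frames[[1]]))
  }
  members <- list(mk_surf(37, 1), mk_surf(37, 2), mk_surf(33, 3),
                  mk_surf(33, 4))
  labels <- c("alpha_helical", "alpha_helical", "beta_barrel",
              "beta_barrel")
  th <- thickness_summary(members, labels)
  expect_lt(abs(th$mean_thickness[th$class == "alpha_helical"] - 37), 0.5)
  expect_lt(abs(th$mean_thickness[th$class == "beta_barrel"] - 33), 0.5)

  # single member: sd 0; reordering leaves class means unchanged
  one <- thickness_summary(members[1], "alpha_helical")
  expect_equal(one$sd_thickness, 0)
  perm <- thickness_summary(members[c(3, 1, 4, 2)], labels[c(3, 1, 4, 2)])
  expect_equal(sort(perm$mean_thickness), sort(th$mean_thickness))
  expect_error(thickness_summary(members[1], "coil"), "unknown class")
})
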