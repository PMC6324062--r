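single_pair_frame <- function(d) {
  cg_frame(rbind(c(10, 10, 10), c(10, 10, 10 + d)),
           c("LEU", "DPPC"), c(1L, 1L), c("A", "L"),
           c("BB", "PO4"), c(50, 50, 50))
}

test_that("a single bead pair is counted iff within the cutoff", {
  p <- count_contacts(single_pair_frame(5), cutoff = 6)
  expect_equal(p$phosphate, 1)
  expect_equal(sum(as.data.frame(p)[, cgmem:::CONTACT_COUNT_COLS]), 1)
  expect_equal(p$head_fraction, 1)

  p0 <- count_contacts(single_pair_frame(5), cutoff = 4)
  expect_equal(sum(as.data.frame(p0)[, cgmem:::CONTACT_COUNT_COLS]), 0)
  expect_true(is.na(p0$head_fraction))

  expect_error(count_contacts(single_pair_frame(5), cutoff = 30), "half")
  expect_error(count_contacts(single_pair_frame(5), cutoff = -1),
               "positive")
})

test_that("contact counts equal the brute-force pair enumeration", {
  fx <- flat_fixture(n = 6, seed = 7, water = TRUE,
                     protein = helix_bundle(n_helices = 1, radius = 1))
  fr <- fx$frames[[1]]
  expect_lte(nrow(fr$coords), 500)
  prof <- count_contacts(fr, cutoff = 6)
  oracle <- bf_contacts(fr, 6)
  df <- as.data.frame(prof)
  col_of <- c(CHOLINE = "choline", PHOSPHATE = "phosphate",
              GLYCEROL = "glycerol", TAIL_1 = "tail_1", TAIL_2 = "tail_2",
              TAIL_3 = "tail_3", TAIL_4 = "tail_4", WATER = "water",
              ION = "ion")
  for (i in seq_len(nrow(df))) {
    key <- paste(df$chain_id[i], df$residue_index[i])
    o <- oracle[[key]]
    for (cl in names(col_of)) {
      expect_equal(df[i, col_of[cl]],
                   unname(if (is.null(o) || is.na(o[cl])) 0L else o[cl]),
                   info = paste(key, cl))
    }
  }
})

test_that("counts are additive over frames and order-invariant", {
  fx <- flat_fixture(n = 10, seed = 8, frames = 2, noise = 1,
                     protein = helix_bundle(n_helices = 1, radius = 1))
  f1 <- fx$frames[[1]]; f2 <- fx$frames[[2]]
  both <- as.data.frame(count_contacts(list(f1, f2), cutoff = 6))
  swapped <- as.data.frame(count_contacts(list(f2, f1), cutoff = 6))
  a <- as.data.frame(count_contacts(f1, cutoff = 6))
  b <- as.data.frame(count_contacts(f2, cutoff = 6))
  cols <- cgmem:::CONTACT_COUNT_COLS
  expect_equal(both[, cols], swapped[, cols])
  expect_equal(both[, cols], a[, cols] + b[, cols])
})

test_that("contacts with flipping lipids are tallied separately", {
  fr <- single_pair_frame(5)
  ev <- data.frame(lipid_id = 1L, from_leaflet = "UPPER",
                   to_leaflet = "LOWER", start_frame = 1L, end_frame = 1L)
  p <- count_contacts(fr, cutoff = 6, flip_events = ev)
  expect_equal(p$flip_lipid, 1)
  expect_equal(p$phosphate, 1)
  p0 <- count_contacts(fr, cutoff = 6)
  expect_equal(p0$flip_lipid, 0)
})

test_that("stacked fractions sum to one wherever contacts exist", {
  for (seed in c(3, 9)) {
    fx <- flat_fixture(n = 12, seed = seed, water = TRUE,
                       protein = helix_bundle(n_helices = 2, radius = 6))
    prof <- count_contacts(fx$frames[[1]], cutoff = 6)
    s <- prof$head_fraction + prof$tail_fraction + prof$solvent_fraction
    expect_true(all(abs(s[!is.na(s)] - 1) < 1e-9))
    expect_true(any(!is.na(s)))
  }
})

test_that("environment labels follow argmax with the stated tie precedence", {
  mk <- function(head, tail, solv) {
    df <- data.frame(chain_id = "A", residue_index = 1L,
                     residue_name = "LEU", choline = 0, phosphate = head,
                     glycerol = 0, tail_1 = tail, tail_2 = 0, tail_3 = 0,
                     tail_4 = 0, water = solv, ion = 0, flip_lipid = 0)
    cgmem:::new_contact_profile(df, 1L)
  }
  expect_equal(classify_environment(mk(10, 2, 1))$environment, "HEADGROUP")
  expect_equal(classify_environment(mk(0, 0, 0))$environment, "BURIED")
  expect_equal(classify_environment(mk(5, 5, 0))$environment, "HEADGROUP")
  expect_equal(classify_environment(mk(0, 4, 4))$environment, "ACYL_TAIL")
  expect_equal(classify_environment(mk(0, 1, 4))$environment, "SOLVENT")
})

test_that("environment classification matches the planted bands", {
  fx <- generate_fixture(fixture_spec(protein = helix_bundle(),
                                      n_frames = 2, seed = 5))
  prof <- count_contacts(fx$frames, cutoff = 6)
  env <- classify_environment(prof)
  truth <- fx$truth$protein$environment
  m <- match(paste("A", seq_along(truth)),
             paste(env$chain_id, env$residue_index))
  got <- env$environment[m]
  tail_band <- truth == "ACYL_TAIL"
  solv_band <- truth == "SOLVENT"
  expect_gte(mean(got[tail_band] == "ACYL_TAIL"), 0.95)
  expect_gte(mean(got[solv_band] == "SOLVENT"), 0.95)
})

test_that("sequence tracks assemble per-residue data and conserve totals", {
  fx <- generate_fixture(fixture_spec(protein = helix_bundle(), seed = 5))
  fr <- fx$frames[[1]]
  la <- assign_leaflets(fr)
  surf <- leaflet_surfaces(fr, la)
  dep <- local_thickness_per_residue(fr, surf)
  prof <- count_contacts(fr, cutoff = 6)
  cs <- data.frame(chain_id = "A", sequence = fx$truth$protein$sequence,
                   ss = fx$truth$protein$ss)
  tr <- sequence_tracks(prof, dep, cs)
  expect_equal(nrow(tr), nchar(cs$sequence))
  expect_equal(tr$aa, strsplit(cs$sequence, "")[[1]])
  expect_equal(tr$ss, strsplit(cs$ss, "")[[1]])
  # no flips planted
  expect_true(all(tr$flip_lipid == 0))
  # buried residues keep their sequence annotation
  buried <- which(tr$water_ion + tr$choline + tr$phosphate + tr$glycerol +
                    tr$tail_1 + tr$tail_2 + tr$tail_3 + tr$tail_4 == 0)
  expect_gt(length(buried), 0)
  expect_false(anyNA(tr$aa[buried]))
  # column totals equal the underlying profile totals
  pdf <- as.data.frame(prof)
  for (cc in c("choline", "phosphate", "glycerol", "tail_1"))
    expect_equal(sum(tr[[cc]]), sum(pdf[[cc]]))
  expect_equal(sum(tr$water_ion), sum(pdf$water + pdf$ion))
  expect_equal(sum(tr$tail_2 + tr$tail_3 + tr$tail_4),
               sum(pdf$tail_2 + pdf$tail_3 + pdf$tail_4))

  short <- cs; short$sequence <- substr(cs$sequence, 1, 50)
  expect_error(sequence_tracks(prof, dep, short), "beyond")
})
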