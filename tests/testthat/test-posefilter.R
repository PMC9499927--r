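map <- ramachandran_map()
fc <- filter_config()

test_that("ramachandran filter passes canonical and flags forced residues", {
  pep <- build_peptide("AAAA", helical_torsions(4))
  expect_true(filter_ramachandran(Pose(pep, -9), map)$pass)
  # one non-Gly residue forced off-map; verified by direct grid indexing
  tor <- helical_torsions(4)
  tor[2, 1:2] <- c(75, -60)
  expect_false(rama_allowed(map, 75, -60, "general"))
  v <- filter_ramachandran(Pose(build_peptide("AAAA", tor), -9), map)
  expect_false(v$pass)
  expect_equal(v$failures$resseq, 2)
  # the same region is allowed for glycine (broad mirrored regions)
  expect_true(rama_allowed(map, 75, -60, "glycine"))
  tor_g <- tor
  vg <- filter_ramachandran(Pose(build_peptide("AGAA", tor_g), -9), map)
  expect_true(vg$pass)
  # single residue: no phi/psi defined, passes vacuously
  one <- build_peptide("A", matrix(c(NA, NA, NA), 1))
  expect_true(filter_ramachandran(Pose(one, -9), map)$pass)
  # no backbone at all is an error, not a fail
  blob <- annotate(Structure(atom_row(1, "C1", "LIG", "L", 1, 0, 0, 0,
                                      element = "C")))
  expect_error(filter_ramachandran(Pose(blob, -9), map), "backbone")
})

test_that("peptide-bond filter classifies trans / cis / non-planar", {
  tor <- helical_torsions(4)
  expect_true(filter_peptide_bonds(Pose(build_peptide("AAAA", tor), -9),
                                   fc)$pass)
  tor_cis <- tor; tor_cis[2, 3] <- 0
  v <- filter_peptide_bonds(Pose(build_peptide("AAAA", tor_cis), -9), fc)
  expect_false(v$pass)
  expect_equal(v$failures$class, "cis")
  tor_np <- tor; tor_np[2, 3] <- 100
  v2 <- filter_peptide_bonds(Pose(build_peptide("AAAA", tor_np), -9), fc)
  expect_false(v2$pass)
  expect_equal(v2$failures$class, "non-planar")
  # thresholds are configurable: a 100-degree bond passes a loose window
  loose <- filter_config(omega_cis_max = 30, omega_trans_min = 95)
  expect_true(filter_peptide_bonds(Pose(build_peptide("AAAA", tor_np), -9),
                                   loose)$pass)
})

test_that("clash filter flags vdW overlap beyond the bonded neighbourhood", {
  pep <- build_peptide("AAAA", helical_torsions(4))
  expect_true(filter_clashes(Pose(pep, -9), fc)$pass)
  # move residue 1's CB to 1.0 A from the last residue's C
  at <- pep$atoms
  cb <- which(at$name == "CB" & at$resseq == 1)
  tg <- which(at$name == "C" & at$resseq == 4)
  at[cb, c("x", "y", "z")] <- at[tg, c("x", "y", "z")] + c(1, 0, 0)
  bad <- pep; bad$atoms <- at
  v <- filter_clashes(Pose(bad, -9), fc)
  expect_false(v$pass)
  expect_true(any(grepl("CB", v$failures$atom_i) |
                    grepl("CB", v$failures$atom_j)))
  # unannotated atoms are an error
  raw <- pep; raw$atoms$vdw <- NA_real_
  expect_error(filter_clashes(Pose(raw, -9), fc), "annotate")
})

test_that("energy cut keeps score <= -8.0 inclusive, preserving order", {
  pep <- build_peptide("AAA", helical_torsions(3))
  poses <- lapply(c(-10.2, -8.0, -7.9), function(s) Pose(pep, s))
  kept <- apply_energy_cut(poses, fc)
  expect_equal(vapply(kept, function(p) p$score, numeric(1)), c(-10.2, -8.0))
  expect_length(apply_energy_cut(list(), fc), 0)
  expect_length(apply_energy_cut(lapply(c(-7, -6), function(s)
    Pose(pep, s)), fc), 0)
})

test_that("cascade survivors equal the labelled oracle intersection", {
  lib <- make_pose_library(25, 8, seed = 17)
  report <- run_cascade(lib$library, map, fc)
  lab <- lib$labels
  # oracle: defect-free geometry AND score <= -8, per pose
  want <- lab[!lab$defect_rama & !lab$defect_omega & !lab$defect_clash &
                lab$score <= -8, ]
  got_keys <- vapply(report$merged, function(p)
    paste(p$compound_id, p$rank), character(1))
  expect_setequal(got_keys, paste(want$compound_id, want$rank))
  # merged list sorted ascending by score
  ms <- vapply(report$merged, function(p) p$score, numeric(1))
  expect_true(all(diff(ms) >= 0))
  # every labelled defect trips its own filter
  v <- report$verdicts
  m <- merge(v, lab, by = c("compound_id", "rank"))
  expect_true(all(!m$pass_ramachandran[m$defect_rama]))
  expect_true(all(!m$pass_peptide_bonds[m$defect_omega]))
  expect_true(all(!m$pass_clashes[m$defect_clash]))
  clean <- !m$defect_rama & !m$defect_omega & !m$defect_clash
  expect_true(all(m$pass_ramachandran[clean] & m$pass_peptide_bonds[clean] &
                    m$pass_clashes[clean]))
  # stage counts are monotone non-increasing
  expect_true(all(diff(report$counts) <= 0))
})

test_that("cascade respects top-N bookkeeping and the '(if any)' path", {
  # 1 compound, 1 perfect pose
  pep <- build_peptide("AAAA", helical_torsions(4))
  one <- list(P1 = list(Pose(pep, -9, 1, "P1")))
  rep1 <- run_cascade(one, map, fc)
  expect_length(rep1$merged, 1)
  # a compound whose examined poses all fail geometry disappears
  tor_bad <- helical_torsions(4); tor_bad[2, 3] <- 0
  badpep <- build_peptide("AAAA", tor_bad)
  two <- list(GOOD = list(Pose(pep, -9, 1, "GOOD")),
              BAD = list(Pose(badpep, -12, 1, "BAD")))
  rep2 <- run_cascade(two, map, fc)
  expect_equal(rep2$survivor_compounds, "GOOD")
  # only top_n poses are examined
  many <- list(X = lapply(1:5, function(r) Pose(pep, -9 + r * 0.1, r, "X")))
  rep3 <- run_cascade(many, map, filter_config(top_n_poses = 2))
  expect_equal(nrow(rep3$verdicts), 2)
  expect_error(run_cascade(list(), map, fc), "empty")
})

test_that("widening tolerances never shrinks the survivor set", {
  lib <- make_pose_library(10, 6, seed = 23)
  base <- run_cascade(lib$library, map, fc)
  keys <- function(r) vapply(r$merged, function(p)
    paste(p$compound_id, p$rank), character(1))
  wider <- list(
    filter_config(omega_cis_max = 10, omega_trans_min = 170),  # stricter
    filter_config(clash_overlap = 0.8),                        # looser clash
    filter_config(energy_cutoff = -7))                         # looser energy
  strict <- run_cascade(lib$library, map, wider[[1]])
  expect_true(all(keys(strict) %in% keys(base)))
  loose_clash <- run_cascade(lib$library, map, wider[[2]])
  expect_true(all(keys(base) %in% keys(loose_clash)))
  loose_energy <- run_cascade(lib$library, map, wider[[3]])
  expect_true(all(keys(base) %in% keys(loose_energy)))
})
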