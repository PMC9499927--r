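test_that("PDB round-trip preserves counts, identifiers and coordinates", {
  pep <- build_peptide("AFLK", helical_torsions(4))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep, path)
  back <- read_structure(path)[[1]]
  expect_equal(n_atoms(back), n_atoms(pep))
  expect_equal(back$atoms$name, pep$atoms$name)
  expect_equal(back$atoms$resname, pep$atoms$resname)
  expect_equal(back$atoms$chain, pep$atoms$chain)
  expect_equal(back$atoms$resseq, pep$atoms$resseq)
  expect_equal(coords(back), round(coords(pep), 3), ignore_attr = TRUE)
})

test_that("model policy and multi-model output behave", {
  pep <- build_peptide("AAA", helical_torsions(3))
  ens <- make_noisy_trajectory(pep, 0.1, n_frames = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, path)
  expect_length(read_structure(path, "all"), 3)
  expect_length(read_structure(path, "first"), 1)
  # a single-atom structure writes one ATOM record plus END
  one <- Structure(atom_row(1, "CA", "ALA", "A", 1, 1.5, 2.25, -3))
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(one, p2)
  lines <- readLines(p2)
  expect_equal(sum(startsWith(lines, "ATOM")), 1)
  expect_equal(tail(lines, 1), "END")
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  a <- atom_row(1, "CA", "ALA", "A", 1, 1, 1, 1, occupancy = 0.6,
                altloc = "A")
  b <- atom_row(2, "CA", "ALA", "A", 1, 9, 9, 9, occupancy = 0.4,
                altloc = "B")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(Structure(rbind(a, b)), path)
  st <- read_structure(path)[[1]]
  expect_equal(n_atoms(st), 1)
  expect_equal(st$atoms$x, 1)
})

test_that("read_structure errors are informative", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(read_structure(empty), "no ATOM/HETATM")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      xx.000   0.000   0.000  1.00  0.00           C"),
             bad)
  expect_error(read_structure(bad), "line 1")
})

test_that("read_pose_set orders by ascending score with stable ties", {
  pep <- build_peptide("AAA", helical_torsions(3))
  mk <- function(s) Pose(pep, s)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pose_set(list(mk(-9.1), mk(-10.2), mk(-8.4)), path)
  ps <- read_pose_set(path)
  expect_equal(vapply(ps, function(p) p$score, numeric(1)),
               c(-10.2, -9.1, -8.4))
  expect_equal(vapply(ps, function(p) p$rank, integer(1)), 1:3)
  # equal scores keep file order: mark the two copies by a coordinate
  pep2 <- set_coords(pep, coords(pep) + 5)
  write_pose_set(list(Pose(pep, -8), Pose(pep2, -8)), path)
  ps2 <- read_pose_set(path)
  expect_equal(coords(ps2[[1]]$ligand)[1, 1], round(coords(pep)[1, 1], 3))
  # a model without a score record is an error naming the model
  lines <- readLines(path)
  lines <- lines[!grepl("REMARK VINA", lines)]
  writeLines(c(lines[seq_len(which(startsWith(lines, "ENDMDL"))[1])], "END"),
             path)
  expect_error(read_pose_set(path), "model 1")
})

test_that("pose-set ordering is a permutation with non-decreasing scores", {
  lib <- make_pose_library(1, 25, defect_rates = list(rama = 0, omega = 0,
                                                      clash = 0), seed = 3)
  poses <- lib$library[[1]]
  scores <- vapply(poses, function(p) p$score, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_setequal(round(scores, 6), round(lib$labels$score, 6))
})

test_that("annotate assigns radii and polarity per the rule set", {
  pep <- build_peptide("AAS", helical_torsions(3))
  at <- pep$atoms
  expect_true(all(at$vdw > 0))
  expect_equal(unique(at$vdw[at$element == "C"]), 1.70)
  expect_true(all(at$polar[at$name == "N"]))
  expect_true(all(at$polar[at$name == "O"]))
  expect_false(any(at$polar[at$name %in% c("CA", "CB", "C")]))
  # polar count matches an independent element scan (no polar H present)
  expect_equal(sum(at$polar), sum(at$element %in% c("N", "O")))
  # idempotence
  expect_equal(annotate(pep)$atoms, at)
  # unknown element with no fallback errors, with fallback succeeds
  weird <- Structure(atom_row(1, "XX", "UNK", "A", 1, 0, 0, 0,
                              element = "XX"))
  expect_error(annotate(weird), "unknown element")
  expect_equal(annotate(weird, fallback_radius = 2.0)$atoms$vdw, 2.0)
})

test_that("polar hydrogens bonded to N/O are polar, others are not", {
  at <- rbind(atom_row(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
              atom_row(2, "H", "ALA", "A", 1, 1.0, 0, 0, element = "H"),
              atom_row(3, "CB", "ALA", "A", 1, 5, 0, 0, element = "C"),
              atom_row(4, "HB1", "ALA", "A", 1, 6.0, 0, 0, element = "H"))
  st <- annotate(Structure(at))
  expect_equal(st$atoms$polar, c(TRUE, TRUE, FALSE, FALSE))
})
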