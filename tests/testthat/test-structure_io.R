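test_that("a hand-written two-atom PDB file reads back identically", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A  10      11.104  13.207   2.100  1.00 20.00           N",
    "ATOM      2  CA  GLY A  10      12.560  13.100   2.300  1.00 20.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$atom, c("CA", "N"))  # ordered by atom name within residue
  n <- m$atoms[m$atoms$atom == "N", ]
  expect_equal(c(n$x, n$y, n$z), c(11.104, 13.207, 2.100))
  expect_equal(m$atoms$resno, c(10L, 10L))
  expect_equal(unique(m$atoms$resname), "GLY")
})

test_that("write/read round trip preserves atoms and coordinates to 3 decimals", {
  h <- make_ideal_helix(helix_spec(18, sequence = "KGIPEDKNPFKELKGGCA",
                                   resno_start = 55))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_minipdb(h, f)
  h2 <- read_structure(f)
  expect_equal(nrow(h$atoms), nrow(h2$atoms))
  expect_equal(h2$atoms$atom, h$atoms$atom)
  expect_equal(h2$atoms$resno, h$atoms$resno)
  expect_equal(h2$atoms$resname, h$atoms$resname)
  expect_lt(max(abs(as.matrix(h$atoms[, c("x", "y", "z")]) -
                      as.matrix(h2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("random 50-atom models survive the round trip", {
  set.seed(11)
  atoms <- random_cloud(50, "A", box = 50)
  m <- structure_model(atoms, "random50")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_minipdb(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), 50)
  expect_lt(max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("altloc duplicates collapse to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(f)
  m <- read_structure(f)
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)      # occupancy 0.6 conformer
  expect_equal(ca$altloc, "A")
})

test_that("altloc occupancy ties resolve towards altloc A", {
  atoms <- rbind(
    atom_row("A", 1, "ALA", "CA", 5, 0, 0, occupancy = 0.5, altloc = "B"),
    atom_row("A", 1, "ALA", "CA", 1, 0, 0, occupancy = 0.5, altloc = "A"))
  res <- npfsite:::resolve_altloc(atoms)
  expect_equal(nrow(res), 1)
  expect_equal(res$altloc, "A")
  expect_equal(res$x, 1)
})

test_that("hydrogen stripping is idempotent and leaves heavy atoms untouched", {
  m <- hydrogen_bearing_model()
  s1 <- strip_hydrogens(m)
  s2 <- strip_hydrogens(s1)
  expect_identical(s1$atoms, s2$atoms)
  heavy <- m$atoms[!m$atoms$is_hydrogen, c("x", "y", "z")]
  expect_equal(s1$atoms[, c("x", "y", "z")], heavy, ignore_attr = TRUE)
})

test_that("model_index out of range and unreadable files raise errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f, model_index = 5), "out of range")
  expect_error(read_structure(file.path(tempdir(), "no_such_file.pdb")), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", bad)
  expect_error(read_structure(bad), "parse|atoms")
})

test_that("writing an empty model is refused", {
  expect_error(structure_model(data.frame()), "lacks columns|at least one")
})

test_that("selections resolve deterministically and respect flags", {
  h <- make_ideal_helix(helix_spec(10, sequence = "AGKNPFAKLC", resno_start = 58))
  # whole chain, ordered
  all_atoms <- resolve_selection(selection(h, chain = "A"))
  expect_equal(all_atoms$resno, sort(all_atoms$resno))
  # side-chain-only on glycine is empty
  gly <- resolve_selection(selection(h, chain = "A", resno = 59,
                                     sidechain_only = TRUE))
  expect_equal(nrow(gly), 0)
  # side-chain-only keeps CB
  lys <- resolve_selection(selection(h, chain = "A", resno = 60,
                                     sidechain_only = TRUE))
  expect_equal(lys$atom, "CB")
  # residue range 60..64 exactly
  rng <- resolve_selection(selection(h, resno = 60:64))
  expect_equal(sort(unique(rng$resno)), 60:64)
  # unknown chain errors at construction
  expect_error(selection(h, chain = "Z"), "not in model")
})
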