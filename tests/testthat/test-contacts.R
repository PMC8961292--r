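test_that("a constructed pair at 3.90 A yields one record; 4.00 A yields none", {
  m39 <- two_atom_model(3.90)
  ct <- interchain_contacts(m39, selection(m39, chain = "A"),
                            selection(m39, chain = "B"))
  expect_equal(nrow(ct$records), 1)
  expect_equal(ct$records$distance, 3.90)
  m40 <- two_atom_model(4.00)
  ct0 <- interchain_contacts(m40, selection(m40, chain = "A"),
                             selection(m40, chain = "B"))
  expect_equal(nrow(ct0$records), 0)   # strict <
})

test_that("cell-list engine matches the exhaustive oracle on random fixtures", {
  for (s in c(7, 21, 99)) {
    set.seed(s)
    m <- structure_model(rbind(random_cloud(150, "A"), random_cloud(150, "B")),
                         "rand300")
    fast <- interchain_contacts(m, selection(m, chain = "A"),
                                selection(m, chain = "B"))
    slow <- npfsite:::brute_force_contacts(m, selection(m, chain = "A"),
                                           selection(m, chain = "B"))
    expect_identical(fast$records, slow$records)
  }
})

test_that("record count is non-decreasing in the cutoff", {
  set.seed(3)
  m <- structure_model(rbind(random_cloud(100, "A"), random_cloud(100, "B")))
  counts <- vapply(c(2, 3, 4, 5, 6), function(co)
    nrow(interchain_contacts(m, selection(m, chain = "A"),
                             selection(m, chain = "B"), cutoff = co)$records),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("contact tables are symmetric under swapping the selections", {
  set.seed(5)
  m <- structure_model(rbind(random_cloud(80, "A"), random_cloud(80, "B")))
  ab <- interchain_contacts(m, selection(m, chain = "A"), selection(m, chain = "B"))
  ba <- interchain_contacts(m, selection(m, chain = "B"), selection(m, chain = "A"))
  flip <- ba$pair_summary[, c("residue_b", "resname_b", "residue_a", "resname_a",
                              "min_distance", "n_contacts")]
  names(flip) <- c("residue_a", "resname_a", "residue_b", "resname_b",
                   "min_distance", "n_contacts")
  flip <- flip[order(flip$residue_a, flip$residue_b), ]
  rownames(flip) <- NULL
  expect_equal(ab$pair_summary, flip)
})

test_that("keeping hydrogens never lowers the contact count", {
  m <- hydrogen_bearing_model()
  with_h <- interchain_contacts(m, selection(m, chain = "A"),
                                selection(m, chain = "B"))
  mh <- strip_hydrogens(m)
  without_h <- interchain_contacts(mh, selection(mh, chain = "A"),
                                   selection(mh, chain = "B"))
  expect_gte(nrow(with_h$records), nrow(without_h$records))
  expect_true(any(with_h$records$involves_hydrogen))
  expect_false(any(without_h$records$involves_hydrogen))
})

test_that("overlapping selections are rejected", {
  m <- two_atom_model(3)
  expect_error(interchain_contacts(m, selection(m), selection(m, chain = "A")),
               "overlap")
})

test_that("min_distance is commutative, zero on self, exact on construction", {
  m <- two_atom_model(7.25)
  a <- selection(m, chain = "A"); b <- selection(m, chain = "B")
  expect_equal(min_distance(a, b), 7.25)
  expect_equal(min_distance(b, a), 7.25)
  expect_equal(min_distance(a, a), 0)
  empty <- selection(m, chain = "A", resno = 99)
  expect_error(min_distance(empty, b), "non-empty")
})

test_that("contact persistence flags broken pairs in a displaced conformation", {
  tc <- make_toy_pocket_complex(seed = 2)
  m <- tc$model
  ct <- interchain_contacts(m, selection(m, chain = c("A", "B")),
                            selection(m, chain = "P"))
  expect_gt(nrow(ct$records), 0)
  # identical alternative model: nothing broken
  same <- contact_persistence(ct, m)
  expect_false(any(same$broken))
  expect_equal(same$distance_in_alt, same$min_distance, tolerance = 1e-12)
  # probe chain translated +10 A: every contact broken
  moved <- m$atoms
  moved[moved$chain == "P", c("x", "y", "z")] <-
    moved[moved$chain == "P", c("x", "y", "z")] + 10
  alt <- structure_model(moved, "displaced")
  shifted <- contact_persistence(ct, alt)
  expect_true(all(shifted$broken))
  # unmapped residues are reported by name
  tiny <- structure_model(atom_row("A", 1, "ALA", "CA", 0, 0, 0))
  expect_error(contact_persistence(ct, tiny), "missing from alternative model")
})
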