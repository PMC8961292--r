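test_that("Kabsch superposition recovers applied rigid transforms", {
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  R <- npfsite:::rotation_about(c(1, 2, 3), 73)
  t_vec <- c(5, -2, 8)
  y <- sweep(x %*% R, 2, t_vec, "+")
  f <- kabsch_superpose(x, y)
  expect_lt(f$rmsd, 1e-6)
  expect_lt(max(abs(f$rotation - R)), 1e-8)
  expect_equal(det(f$rotation), 1, tolerance = 1e-10)
  expect_lt(max(abs(f$transform(x) - y)), 1e-8)
})

test_that("a 3-point toy superposition matches a rotation-grid search", {
  # brute-force oracle: planar 3-point problem, scan rotations about z
  x <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  ang <- 37
  y <- x %*% npfsite:::rotation_about(c(0, 0, 1), ang)
  grid <- seq(0, 359.99, by = 0.01)
  rms <- vapply(grid, function(a) {
    sqrt(mean(rowSums((x %*% npfsite:::rotation_about(c(0, 0, 1), a) - y)^2)))
  }, numeric(1))
  best <- grid[which.min(rms)]
  f <- kabsch_superpose(x, y)
  expect_equal(best, ang, tolerance = 0.01)
  expect_lt(abs(f$rmsd - min(rms)), 1e-3)
})

test_that("superposition agrees with an independent least-squares fit", {
  set.seed(9)
  x <- matrix(rnorm(45), 15, 3)
  y <- sweep(x %*% npfsite:::rotation_about(c(1, 0, 2), 50), 2, c(1, 2, 3), "+") +
    matrix(rnorm(45, sd = 0.3), 15, 3)
  f <- kabsch_superpose(x, y)
  # bio3d's least-squares rotation as the independent oracle
  xb <- as.numeric(t(x)); yb <- as.numeric(t(y))
  fitted <- bio3d::fit.xyz(fixed = yb, mobile = xb,
                           fixed.inds = 1:45, mobile.inds = 1:45)
  rmsd_oracle <- sqrt(mean(colSums(matrix((fitted - yb)^2, nrow = 3))))
  expect_equal(f$rmsd, rmsd_oracle, tolerance = 1e-6)
})

test_that("rmsd grows monotonically with added noise", {
  set.seed(8)
  x <- matrix(rnorm(60), 20, 3)
  rmsds <- vapply(c(0.1, 0.5, 1.0), function(sig) {
    y <- x + matrix(rnorm(60, sd = sig), 20, 3)
    kabsch_superpose(x, y)$rmsd
  }, numeric(1))
  expect_true(all(diff(rmsds) > 0))
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 paired")
})

test_that("helix axis is recovered within a degree, rotated or not", {
  h <- make_ideal_helix(helix_spec(18))
  ca <- as.matrix(h$atoms[h$atoms$atom == "CA", c("x", "y", "z")])
  expect_equal(max(ca[, 3]) - min(ca[, 3]), 25.5)   # (n-1) * rise
  ax <- fit_helix_axis(ca)
  err <- acos(min(1, abs(sum(ax$direction * c(0, 0, 1))))) * 180 / pi
  expect_lt(err, 1)
  # same helix under a known rotation
  R <- npfsite:::rotation_about(c(1, 1, 0), 40)
  target <- as.numeric(R %*% c(0, 0, 1))
  h2 <- make_ideal_helix(helix_spec(18, axis = target))
  ca2 <- as.matrix(h2$atoms[h2$atoms$atom == "CA", c("x", "y", "z")])
  ax2 <- fit_helix_axis(ca2)
  err2 <- acos(min(1, abs(sum(ax2$direction * target)))) * 180 / pi
  expect_lt(err2, 1)
  expect_error(fit_helix_axis(ca[1:4, ]), "at least 6")
})

test_that("helix phases step by the twist", {
  h <- make_ideal_helix(helix_spec(20, twist = 100))
  ca <- as.matrix(h$atoms[h$atoms$atom == "CA", c("x", "y", "z")])
  ax <- fit_helix_axis(ca)
  steps <- diff(ax$phases) %% 360
  expect_true(all(abs(steps - 100) < 1.5))
})

test_that("the H8 rotation angle recovers applied rotations within 2 degrees", {
  for (theta in c(0, 30, 115, 180, 245)) {
    fx <- build_rotation_fixture(theta)
    r <- h8_rotation_angle(fx$gpcr, fx$eh2, gpcr_chain = "R", eh2_chain = "E",
                           bw_map = fx$bw_map)
    err <- min(abs(r$angle_deg - theta), 360 - abs(r$angle_deg - theta))
    expect_lt(err, 2)
  }
})

test_that("missing correspondence residues are reported", {
  fx <- build_rotation_fixture(30)
  broken <- fx$eh2$atoms[fx$eh2$atoms$resno != 50, , drop = FALSE]
  eh2 <- structure_model(broken, "partial")
  expect_error(h8_rotation_angle(fx$gpcr, eh2, gpcr_chain = "R",
                                 eh2_chain = "E", bw_map = fx$bw_map),
               "missing correspondence")
})

test_that("the chemical classes partition the twenty amino acids", {
  cls <- chemical_classes()
  all_aas <- unlist(cls, use.names = FALSE)
  expect_equal(length(all_aas), 20)
  expect_equal(length(unique(all_aas)), 20)
  expect_setequal(all_aas, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(chemical_class_of(c("G", "Q", "K", "D", "L")),
               c("polar", "neutral", "basic", "acidic", "hydrophobic"))
})

test_that("the NPF-site score reproduces the worked rhodopsin case", {
  rho_site <- extract_site_residues(assign_bw(rhodopsin_reference()$sequence))
  sc <- npf_site_score(rho_site)
  expect_equal(sc$score, 7 / 8)   # only Thr at 8.57 misses the hydrophobic rule
  expect_false(sc$per_position$match[sc$per_position$bw == "8.57"])
  expect_true(all(sc$per_position$match[sc$per_position$bw != "8.57"]))
})

test_that("the score is bounded, permutation-invariant and handles absences", {
  perfect <- setNames(c("L", "L", "R", "L", "Q", "L", "L", "L"),
                      c("1.55", "1.56", "1.59", "12.50", "8.49", "8.50", "8.54", "8.57"))
  expect_equal(npf_site_score(perfect)$score, 1)
  all_gly <- setNames(rep("G", 8), names(perfect))
  expect_equal(npf_site_score(all_gly)$score, 0.25)
  shuffled <- perfect[c(5, 2, 8, 1, 3, 7, 4, 6)]
  expect_equal(npf_site_score(shuffled)$score, npf_site_score(perfect)$score)
  partial <- perfect[c("8.50", "8.54")]
  expect_equal(npf_site_score(partial)$score, 1)
  expect_equal(npf_site_score(partial)$n_evaluated, 2)
  expect_error(npf_site_score(setNames("L", "9.99")), "site positions")
})

test_that("conservation profiles count residues exactly", {
  rho <- rhodopsin_reference()$sequence
  msa5 <- rep(rho, 5)
  prof <- conservation_profile(msa5)
  for (p in prof$profile) {
    expect_equal(sum(p$frequencies), 1)
    expect_equal(max(p$frequencies), 1)   # identical rows: single residue
  }
  # two rows differing at one site position
  s <- strsplit(rho, "")[[1]]; s[313] <- "L"
  prof2 <- conservation_profile(c(rho, paste(s, collapse = "")))
  f850 <- prof2$profile[["8.50"]]
  expect_equal(sort(f850$frequencies[f850$frequencies > 0]), c(0.5, 0.5))
  # random MSA vs a brute-force column count
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- vapply(1:50, function(i) {
    s <- strsplit(rho, "")[[1]]
    s[313] <- sample(aas, 1)
    paste(s, collapse = "")
  }, character(1))
  msa <- c(rho, rows)
  prof3 <- conservation_profile(msa)
  counts <- table(factor(substr(msa, 313, 313), levels = sort(aas)))
  expect_equal(prof3$profile[["8.50"]]$frequencies,
               as.numeric(counts / sum(counts)))
})

test_that("frequencies sum to one at every evaluated position", {
  set.seed(4)
  rho <- rhodopsin_reference()$sequence
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  msa <- c(rho, vapply(1:10, function(i) {
    s <- strsplit(rho, "")[[1]]
    idx <- sample(seq_along(s), 30)
    s[idx] <- sample(aas, 30, replace = TRUE)
    paste(s, collapse = "")
  }, character(1)))
  prof <- conservation_profile(msa)
  for (p in prof$profile) expect_equal(sum(p$frequencies), 1)
})

test_that("the TM7-H8 lock responds to side-chain proximity", {
  mk_pair <- function(gap) {
    structure_model(rbind(
      atom_row("A", 306, "TYR", "CA", 0, 0, 0),
      atom_row("A", 306, "TYR", "OH", 1.5, 0, 0, element = "O"),
      atom_row("A", 313, "PHE", "CA", gap + 3, 0, 0),
      atom_row("A", 313, "PHE", "CZ", 1.5 + gap, 0, 0)))
  }
  locked <- tm7_h8_lock(mk_pair(3.5), resno_753 = 306, resno_850 = 313)
  expect_true(locked$locked)
  expect_equal(locked$distance, 3.5)
  open <- tm7_h8_lock(mk_pair(8), resno_753 = 306, resno_850 = 313)
  expect_false(open$locked)
  missing <- structure_model(atom_row("A", 306, "TYR", "OH", 0, 0, 0, element = "O"))
  expect_error(tm7_h8_lock(missing, resno_753 = 306, resno_850 = 313),
               "side-chain")
})

test_that("the correspondence map is one-to-one and carries the eight pairs", {
  cm <- eh2_gpcr_correspondence()
  expect_equal(nrow(cm), 8)
  expect_false(any(duplicated(cm$eh2_resno)))
  expect_false(any(duplicated(cm$bw)))
  expect_equal(cm$bw[cm$eh2_resno == 50], "8.50")   # Leu50 <-> Phe 8.50
  expect_equal(cm$bw[cm$eh2_resno == 54], "8.54")   # Trp54 <-> Met 8.54
  full <- eh2_gpcr_correspondence(include_unverified = TRUE)
  expect_true(all(full$unverified[9:nrow(full)]))
})
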