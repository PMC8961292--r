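# Fixture builders shared across the suite. Everything is generated in code;
# no binary or downloaded data.

# minimal atom-table constructor
atom_row <- function(chain, resno, resname, atom, x, y, z, element = NULL,
                     icode = "", occupancy = 1, altloc = "", het = FALSE) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", atom), 1, 1)
  data.frame(chain = chain, resno = resno, icode = icode, resname = resname,
             atom = atom, element = element, x = x, y = y, z = z,
             occupancy = occupancy, altloc = altloc, het = het,
             stringsAsFactors = FALSE)
}

# two atoms in two chains at a given separation along x
two_atom_model <- function(d, atom = "CA", resname = "ALA") {
  structure_model(rbind(
    atom_row("A", 1, resname, atom, 0, 0, 0),
    atom_row("B", 1, resname, atom, d, 0, 0)))
}

# a random multi-chain cloud of n atoms in a box, grouped 4 atoms/residue
random_cloud <- function(n, chain, box = 30) {
  k <- ceiling(n / 4)
  atoms <- data.frame(
    chain = chain, resno = rep(seq_len(k), each = 4)[seq_len(n)], icode = "",
    resname = "ALA", atom = paste0("C", sequence(rep(4, k))[seq_len(n)]),
    element = "C", x = runif(n, 0, box), y = runif(n, 0, box),
    z = runif(n, 0, box), occupancy = 1, altloc = "", het = FALSE,
    stringsAsFactors = FALSE)
  atoms
}

# hand-written PDB text with an altloc pair (A occ 0.6 at x=1, B occ 0.4 at x=9)
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# model with explicit hydrogens: two residues, heavy atoms 3.8 A apart and a
# hydrogen bridging at 2.5 A
hydrogen_bearing_model <- function() {
  structure_model(rbind(
    atom_row("A", 1, "ALA", "CA", 0, 0, 0),
    atom_row("A", 1, "ALA", "HA", 1.0, 0, 0, element = "H"),
    atom_row("B", 1, "ALA", "CA", 3.8, 0, 0),
    atom_row("B", 1, "ALA", "HA", 2.5, 0, 0, element = "H")))
}

# Synthetic receptor/EH-domain pair in which the alpha-C partners have been
# rotated about the H8 axis by a known clockwise angle (viewed from the
# distal end). Recovers the construction used in the rotation analysis.
build_rotation_fixture <- function(theta_cw) {
  tm1 <- make_ideal_helix(helix_spec(12, chain = "R", resno_start = 101,
                                     origin = c(20, 0, 0)))
  h8 <- make_ideal_helix(helix_spec(12, chain = "R", resno_start = 201,
                                    axis = c(1, 0, 0)))
  gpcr <- structure_model(rbind(tm1$atoms, h8$atoms), "syn_gpcr")
  bw_map <- c("12.50" = 101, "1.59" = 102, "1.56" = 103, "1.55" = 104,
              setNames(201:212, sprintf("8.%d", 47:58)))
  rot <- npfsite:::rotation_about(c(1, 0, 0), -theta_cw)
  grab <- function(resno, new_resno, rotate = FALSE) {
    a <- gpcr$atoms[gpcr$atoms$resno == resno, , drop = FALSE]
    if (rotate) {
      a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
    }
    a$chain <- "E"; a$resno <- new_resno
    a
  }
  cm <- eh2_gpcr_correspondence()
  ab <- cm[cm$bw %in% c("12.50", "1.59", "1.56", "1.55"), ]
  ac <- cm[!cm$bw %in% c("12.50", "1.59", "1.56", "1.55"), ]
  rows <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ab)), function(i)
      grab(bw_map[[ab$bw[i]]], ab$eh2_resno[i]))),
    do.call(rbind, lapply(seq_len(nrow(ac)), function(i)
      grab(bw_map[[ac$bw[i]]], ac$eh2_resno[i], rotate = TRUE))))
  list(gpcr = gpcr, eh2 = structure_model(rows, "syn_eh2"), bw_map = bw_map)
}

# Ggamma reference sequences (ungapped) for convenience
ref_gamma_seq <- function(isoform) {
  npfsite:::cggn_reference_sequences()[[isoform]]
}
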