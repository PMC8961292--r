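# Deterministic synthetic fixtures: ideal helices, toy pocket-peptide
# complexes with ground-truth contact lists, and Ggamma-like sequences with
# known labels. All generators are pure functions of their spec (seed
# included).

# Idealised per-atom cylindrical offsets relative to the C-alpha of the same
# residue (radius delta in A, azimuth delta in degrees, axial delta in A).
# The C-alpha trace is exact (radius, twist, rise as specified); N/C/O/CB
# placement is schematic but keeps sane bond lengths, and CB sits at the same
# azimuth as CA so that side-chain phase equals backbone phase by
# construction.
HELIX_ATOM_OFFSETS <- list(
  N = c(dr = -0.75, dphi = -26.0, dz = -0.90),
  C = c(dr = -0.64, dphi = 21.5, dz = 1.05),
  O = c(dr = -0.30, dphi = 37.0, dz = 1.95),
  CB = c(dr = 1.45, dphi = 0.0, dz = 0.50)
)

# rotation matrix carrying the z axis onto `axis` (Rodrigues)
rotation_z_to <- function(axis) {
  a <- unit(axis)
  z <- c(0, 0, 1)
  v <- cross3(z, a)
  s <- vnorm(v); cth <- sum(z * a)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Specification for an ideal alpha-helix
#'
#' Textbook alpha-helix defaults: 1.5 A rise and 100 degrees twist per
#' residue, C-alpha radius 2.3 A.
#'
#' @param n_residues number of residues (>= 1).
#' @param rise rise per residue, A.
#' @param twist twist per residue, degrees.
#' @param ca_radius C-alpha cylinder radius, A.
#' @param axis helix axis direction (unit-normalised internally).
#' @param phase0 azimuth of the first C-alpha, degrees.
#' @param sequence one-letter sequence (default poly-Ala).
#' @param origin position of the axis point at the first residue's axial level.
#' @param chain,resno_start identifiers for the emitted model.
#' @return list of class `helix_spec`.
#' @export
helix_spec <- function(n_residues, rise = 1.5, twist = 100, ca_radius = 2.3,
                       axis = c(0, 0, 1), phase0 = 0, sequence = NULL,
                       origin = c(0, 0, 0), chain = "A", resno_start = 1L) {
  stopifnot(n_residues >= 1, rise > 0, ca_radius > 0)
  if (is.null(sequence)) sequence <- paste(rep("A", n_residues), collapse = "")
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) != n_residues)
    stop("sequence length (", nchar(sequence), ") != n_residues (", n_residues, ")")
  structure(list(n_residues = as.integer(n_residues), rise = rise, twist = twist,
                 ca_radius = ca_radius, axis = unit(axis), phase0 = phase0,
                 sequence = sequence, origin = origin, chain = chain,
                 resno_start = as.integer(resno_start)),
            class = "helix_spec")
}

#' Build an ideal alpha-helix model
#'
#' C-alpha atoms lie exactly on a cylinder of `ca_radius` about the axis with
#' the specified angular and axial steps; N, C, O and (for non-glycine) CB are
#' placed by idealised internal geometry. Deterministic.
#'
#' @param spec a [helix_spec()].
#' @return A [structure_model()].
#' @export
make_ideal_helix <- function(spec) {
  stopifnot(inherits(spec, "helix_spec"))
  R <- rotation_z_to(spec$axis)
  seq1 <- strsplit(spec$sequence, "")[[1]]
  rows <- list()
  for (i in seq_len(spec$n_residues)) {
    phi_ca <- spec$phase0 + (i - 1) * spec$twist
    z_ca <- (i - 1) * spec$rise
    place <- function(dr, dphi, dz) {
      r <- spec$ca_radius + dr
      phi <- deg2rad(phi_ca + dphi)
      local <- c(r * cos(phi), r * sin(phi), z_ca + dz)
      as.numeric(R %*% local) + spec$origin
    }
    atoms <- list(N = place(HELIX_ATOM_OFFSETS$N["dr"], HELIX_ATOM_OFFSETS$N["dphi"],
                            HELIX_ATOM_OFFSETS$N["dz"]),
                  CA = place(0, 0, 0),
                  C = place(HELIX_ATOM_OFFSETS$C["dr"], HELIX_ATOM_OFFSETS$C["dphi"],
                            HELIX_ATOM_OFFSETS$C["dz"]),
                  O = place(HELIX_ATOM_OFFSETS$O["dr"], HELIX_ATOM_OFFSETS$O["dphi"],
                            HELIX_ATOM_OFFSETS$O["dz"]))
    if (seq1[i] != "G")
      atoms$CB <- place(HELIX_ATOM_OFFSETS$CB["dr"], HELIX_ATOM_OFFSETS$CB["dphi"],
                        HELIX_ATOM_OFFSETS$CB["dz"])
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = spec$chain, resno = spec$resno_start + i - 1L, icode = "",
        resname = aa1to3(seq1[i]), atom = nm,
        element = substr(nm, 1, 1),
        x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
        occupancy = 1, altloc = "", het = FALSE, stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows),
                  identifier = sprintf("ideal_helix_n%d", spec$n_residues))
}

# merge the atom tables of several models into one
combine_models <- function(models, identifier = "complex") {
  structure_model(do.call(rbind, lapply(models, function(m) m$atoms)),
                  identifier = identifier)
}

# Exhaustive O(N^2) contact enumeration; intentionally independent of the
# cell-list engine so it can serve as its oracle.
brute_force_contacts <- function(model, sel_a, sel_b, cutoff = 4.0) {
  A <- if (is.data.frame(sel_a)) sel_a else resolve_selection(sel_a)
  B <- if (is.data.frame(sel_b)) sel_b else resolve_selection(sel_b)
  recs <- empty_contact_records()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((as.numeric(A[i, c("x", "y", "z")]) -
                       as.numeric(B[j, c("x", "y", "z")]))^2))
      if (d < cutoff) {
        recs <- rbind(recs, data.frame(
          residue_a = res_key(A$chain[i], A$resno[i], A$icode[i]),
          resname_a = A$resname[i], atom_a = A$atom[i],
          residue_b = res_key(B$chain[j], B$resno[j], B$icode[j]),
          resname_b = B$resname[j], atom_b = B$atom[j],
          distance = d, involves_hydrogen = A$is_hydrogen[i] | B$is_hydrogen[j],
          stringsAsFactors = FALSE))
      }
    }
  }
  recs <- recs[order(recs$residue_a, recs$residue_b, recs$atom_a, recs$atom_b), ,
               drop = FALSE]
  rownames(recs) <- NULL
  new_contact_table(recs, cutoff)
}

#' Build a toy two-helix pocket with a placed tripeptide probe
#'
#' Two ideal helices crossing at `crossing_angle` form the pocket (chains "A"
#' and "B"); a probe peptide (chain "P", default sequence NPF) is rigidly
#' placed so that each distance target — (pocket residue, probe residue,
#' distance) triples measured as residue-residue minimum atomic distance —
#' is met within `tol`. The ground-truth contact table is enumerated by
#' exhaustive search at build time. Deterministic given the seed.
#'
#' @param seed integer seed (perturbs the probe starting pose).
#' @param probe_seq probe peptide sequence (default "NPF").
#' @param targets data.frame with columns `pocket_chain`, `pocket_resno`,
#'   `probe_resno`, `distance`. Default: one 3.9 A target from helix A
#'   residue 9 to the probe proline.
#' @param crossing_angle angle between the two pocket helices, degrees.
#' @param n_res residues per pocket helix.
#' @param cutoff contact cutoff for the truth table.
#' @param tol placement tolerance in A (default 0.05).
#' @return list: `model` (pocket + probe), `truth` (contact_table between
#'   pocket and probe), `spec` echo.
#' @export
make_toy_pocket_complex <- function(seed = 1, probe_seq = "NPF", targets = NULL,
                                    crossing_angle = 60, n_res = 18,
                                    cutoff = 4.0, tol = 0.05) {
  if (is.null(targets))
    targets <- data.frame(pocket_chain = "A", pocket_resno = 9L,
                          probe_resno = 2L, distance = 3.9,
                          stringsAsFactors = FALSE)
  hA <- make_ideal_helix(helix_spec(n_res, chain = "A"))
  axB <- c(sin(deg2rad(crossing_angle)), 0, cos(deg2rad(crossing_angle)))
  hB <- make_ideal_helix(helix_spec(n_res, chain = "B", axis = axB,
                                    origin = c(9, 0, 0), phase0 = 180))
  pocket <- combine_models(list(hA, hB), "toy_pocket")

  # extended probe: CA every 3.8 A along x, CB offset in y
  seq1 <- strsplit(toupper(probe_seq), "")[[1]]
  probe_rows <- do.call(rbind, lapply(seq_along(seq1), function(i) {
    base <- c((i - 1) * 3.8, 0, 0)
    atoms <- list(N = base + c(-1.2, 0.6, 0), CA = base, C = base + c(1.2, 0.6, 0),
                  O = base + c(1.3, 1.8, 0))
    if (seq1[i] != "G") atoms$CB <- base + c(0, -1.4, 0.6)
    do.call(rbind, lapply(names(atoms), function(nm) data.frame(
      chain = "P", resno = i, icode = "", resname = aa1to3(seq1[i]), atom = nm,
      element = substr(nm, 1, 1), x = atoms[[nm]][1], y = atoms[[nm]][2],
      z = atoms[[nm]][3], occupancy = 1, altloc = "", het = FALSE,
      stringsAsFactors = FALSE)))
  }))

  pocket_xyz <- function(chain, resno) {
    a <- pocket$atoms
    as.matrix(a[a$chain == chain & a$resno == resno, c("x", "y", "z")])
  }
  probe_xyz0 <- as.matrix(probe_rows[, c("x", "y", "z")])
  probe_center <- colMeans(probe_xyz0)

  # starting pose near the first target's pocket residue, nudged by the seed
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  jitter <- stats::runif(6, -0.5, 0.5)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  anchor <- colMeans(pocket_xyz(targets$pocket_chain[1], targets$pocket_resno[1]))
  start <- c(anchor - probe_center + c(4.5, 4.5, 0) + jitter[1:3], jitter[4:6] * 20)

  place <- function(par) {
    Rx <- rotation_about(c(1, 0, 0), par[4]); Ry <- rotation_about(c(0, 1, 0), par[5])
    Rz <- rotation_about(c(0, 0, 1), par[6])
    sweep(sweep(probe_xyz0, 2, probe_center) %*% (Rx %*% Ry %*% Rz), 2,
          probe_center + par[1:3], "+")
  }
  objective <- function(par) {
    xyz <- place(par)
    err <- vapply(seq_len(nrow(targets)), function(k) {
      pk <- pocket_xyz(targets$pocket_chain[k], targets$pocket_resno[k])
      pr <- xyz[probe_rows$resno == targets$probe_resno[k], , drop = FALSE]
      min(cross_dist(pk, pr)) - targets$distance[k]
    }, numeric(1))
    sum(err^2)
  }
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  final <- place(fit$par)
  errs <- sqrt(objective(fit$par) / nrow(targets))
  achieved <- vapply(seq_len(nrow(targets)), function(k) {
    pk <- pocket_xyz(targets$pocket_chain[k], targets$pocket_resno[k])
    pr <- final[probe_rows$resno == targets$probe_resno[k], , drop = FALSE]
    min(cross_dist(pk, pr))
  }, numeric(1))
  if (any(abs(achieved - targets$distance) > tol))
    stop("unsatisfiable distance targets: worst error ",
         sprintf("%.3f", max(abs(achieved - targets$distance))), " A")
  probe_rows[, c("x", "y", "z")] <- final
  probe <- structure_model(probe_rows, "toy_probe")
  model <- structure_model(rbind(pocket$atoms, probe$atoms), "toy_pocket_complex")
  truth <- brute_force_contacts(
    model,
    selection(model, chain = c("A", "B")),
    selection(model, chain = "P"),
    cutoff = cutoff)
  list(model = model, truth = truth,
       spec = list(seed = seed, probe_seq = probe_seq, targets = targets,
                   crossing_angle = crossing_angle, n_res = n_res,
                   cutoff = cutoff, achieved = achieved))
}

rotation_about <- function(axis, angle_deg) {
  a <- unit(axis); th <- deg2rad(angle_deg)
  vx <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * vx + (1 - cos(th)) * (vx %*% vx)
}

#' Generate a Ggamma-like sequence with ground-truth CGgammaN labels
#'
#' Segments are sampled with the reference layout (h1/H1/h1h2/H2/h2), the
#' Asn-Pro-Phe motif is forced at h2.8-h2.10, the CAAX cysteine at h2.17
#' followed by two aliphatics and one arbitrary residue, and exactly one NPF
#' trimer is guaranteed. Optional indels (insertions/deletions at positions
#' outside the NPF +/- `npf_guard` window) perturb the sequence while the
#' ground-truth labels track every surviving residue. Deterministic given the
#' seed.
#'
#' @param seed integer seed.
#' @param n_insertions,n_deletions number of indels to apply.
#' @param npf_guard half-width of the protected window around the NPF motif
#'   (default 2 residues each side).
#' @return list: `sequence`, `truth` data.frame (position, residue, segment,
#'   index; `NA` segment for inserted residues).
#' @export
make_gamma_like_sequence <- function(seed = 1, n_insertions = 0, n_deletions = 0,
                                     npf_guard = 2) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  aas <- unlist(chemical_classes(), use.names = FALSE)
  no_f <- setdiff(aas, "F")  # avoid completing accidental NPF trimers

  for (attempt in 1:50) {
    seg_chars <- list(
      h1 = c("M", sample(no_f, 6, replace = TRUE)),
      H1 = sample(no_f, 17, replace = TRUE),
      h1h2 = sample(no_f, 5, replace = TRUE),
      H2 = c(sample(no_f, 19, replace = TRUE), "P", "L", "L"),
      h2 = c(sample(no_f, 5, replace = TRUE),            # h2.1-5
             sample(c("S", "T", "E", "D"), 2, replace = TRUE),  # h2.6-7
             "N", "P", "F",                               # h2.8-10
             sample(c("K", "R"), 1), sample(c("D", "E"), 1),    # h2.11-12
             sample(no_f, 4, replace = TRUE),             # h2.13-16
             "C",                                         # h2.17
             sample(c("A", "V", "L", "I"), 2, replace = TRUE),  # h2.18-19
             sample(c("S", "L", "M", "Q"), 1))            # h2.20
    )
    chars <- unlist(seg_chars, use.names = FALSE)
    seqstr <- paste(chars, collapse = "")
    if (length(gregexpr("NPF", seqstr)[[1]]) == 1 &&
        gregexpr("NPF", seqstr)[[1]][1] > 0) break
    if (attempt == 50) stop("could not build a sequence with a unique NPF motif")
  }
  seg <- rep(names(CGGN_SEGMENTS), times = c(7, 17, 5, 22, 20))
  idx <- c(4:10, 1:17, 1:5, 1:22, 1:20)  # h1 residues occupy columns 4-10
  truth <- data.frame(residue = chars, segment = seg, index = idx,
                      stringsAsFactors = FALSE)

  npf_pos <- which(truth$segment == "h2" & truth$index %in% 8:10)
  protected <- seq(min(npf_pos) - npf_guard, max(npf_pos) + npf_guard)
  eligible <- setdiff(seq_len(nrow(truth)), protected)

  if (n_deletions > 0) {
    del <- sample(eligible, n_deletions)
    truth <- truth[-del, , drop = FALSE]
  }
  if (n_insertions > 0) {
    npf_pos <- which(truth$segment == "h2" & truth$index %in% 8:10)
    protected <- seq(min(npf_pos) - npf_guard, max(npf_pos) + npf_guard)
    slots <- setdiff(seq_len(nrow(truth)), protected)
    ins_at <- sort(sample(slots, n_insertions))
    for (k in rev(ins_at)) {
      newrow <- data.frame(residue = sample(no_f, 1), segment = NA_character_,
                           index = NA_integer_, stringsAsFactors = FALSE)
      truth <- rbind(truth[seq_len(k - 1), , drop = FALSE], newrow,
                     truth[k:nrow(truth), , drop = FALSE])
    }
  }
  truth$position <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  seqstr <- paste(truth$residue, collapse = "")
  # indels may have created or duplicated NPF trimers; regenerate if so
  if (length(gregexpr("NPF", seqstr)[[1]]) != 1 ||
      gregexpr("NPF", seqstr)[[1]][1] < 0)
    return(make_gamma_like_sequence(seed + 1000003L, n_insertions, n_deletions,
                                    npf_guard))
  list(sequence = seqstr,
       truth = truth[, c("position", "residue", "segment", "index")])
}
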