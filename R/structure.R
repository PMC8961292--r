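# Structure container and I/O.
#
# A structure_model is a light S3 wrapper around a per-atom data.frame, in the
# spirit of bio3d's pdb$atom table. Author residue numbering is the canonical
# key throughout: the literature on the Ggamma/GPCR interface refers to
# residues by author numbers (Cys316, Trp54, ...), so serial renumbering is
# never applied.

STANDARD_AA3 <- names(THREE_TO_ONE)
WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`, `het`. Missing
#'   `icode`/`altloc` default to `""`, `occupancy` to 1, `het` to `FALSE`,
#'   `element` is guessed from the atom name when absent.
#' @param identifier free-text identifier (e.g. a PDB id).
#' @param model_index which model of a multi-model file the atoms came from.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "model", model_index = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("a structure model needs at least one atom")
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  atoms$resno <- as.integer(atoms$resno)
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$is_hydrogen <- toupper(atoms$element) %in% c("H", "D")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode, atoms$atom), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(identifier = identifier,
                 model_index = as.integer(model_index),
                 atoms = atoms),
            class = "structure_model")
}

# Infer an element symbol from a PDB atom name ("CA" -> C, "1HB" -> H, ...).
guess_element <- function(atom_names) {
  vapply(atom_names, function(nm) {
    nm <- gsub("[^A-Za-z]", "", nm)
    if (nchar(nm) == 0) return("X")
    first <- toupper(substr(nm, 1, 1))
    if (first %in% c("H", "D")) return("H")
    if (toupper(substr(nm, 1, 2)) %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE"))
      return(toupper(substr(nm, 1, 2)))
    first
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s' (model %d): %d atoms, %d residues, chains: %s\n",
              x$identifier, x$model_index, nrow(a),
              length(unique(res_key(a$chain, a$resno, a$icode))),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

#' Read a macromolecular structure from a PDB or mmCIF file
#'
#' Parsing is delegated to bio3d; the result is normalised into a
#' [structure_model()]: one model of a multi-model file, one alternate-location
#' conformer per atom (highest occupancy, ties broken towards altloc "A"),
#' hydrogens and waters dropped by default.
#'
#' Hydrogen handling deserves care in this domain: some deposited NMR/cryo-EM
#' entries carry explicit hydrogens while crystal structures do not, which
#' inflates raw contact counts for the former. The consistent default is
#' heavy-atom-only, with `keep_hydrogens = TRUE` to reproduce hydrogen-bearing
#' analyses.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param model_index 1-based model to load from a multi-model file.
#' @param keep_hydrogens keep H/D atoms?
#' @param keep_het keep non-polymer heteroatoms (waters are controlled
#'   separately and always dropped unless `keep_waters`)?
#' @param keep_waters keep water molecules?
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_index = 1L, keep_hydrogens = FALSE,
                           keep_het = FALSE, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("could not parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > n_models)
    stop("model_index ", model_index, " out of range: file has ", n_models, " model(s)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  at <- pdb$atom
  n <- nrow(at)
  coords <- matrix(xyz[seq_len(3 * n)], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = as.character(at$resid),
    atom = as.character(at$elety),
    element = if (!is.null(at$elesy)) as.character(at$elesy) else NA_character_,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "
  bad <- is.na(atoms$element) | atoms$element == ""
  if (any(bad)) atoms$element[bad] <- guess_element(atoms$atom[bad])
  atoms$element <- toupper(atoms$element)

  is_water <- atoms$resname %in% WATER_RESID
  if (!keep_waters) atoms <- atoms[!is_water, , drop = FALSE]
  if (!keep_het) atoms <- atoms[!atoms$het | atoms$resname %in% STANDARD_AA3, , drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms left after filtering in '", path, "'")
  atoms <- resolve_altloc(atoms)
  structure_model(atoms,
                  identifier = sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path),
                                   ignore.case = TRUE),
                  model_index = model_index)
}

# Keep one conformer per (chain, resno, icode, atom name): highest occupancy,
# ties broken by altloc letter (so 'A' wins a 50/50 split).
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                   atoms$atom, sep = "\r")), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Drop hydrogen and deuterium atoms from a model
#' @param model a [structure_model()].
#' @return The model without H/D atoms.
#' @export
strip_hydrogens <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms[!model$atoms$is_hydrogen, , drop = FALSE]
  if (nrow(atoms) == 0) stop("model contains only hydrogens")
  structure_model(atoms, model$identifier, model$model_index)
}

#' Write a model as fixed-column PDB ATOM/HETATM records
#'
#' Coordinates are emitted at 3 decimals, so a write/read round trip preserves
#' them to +/- 0.001 Angstrom.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @export
write_minipdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0) stop("refusing to write an empty model")
  fmt_name <- function(nm, el) {
    # PDB v3.3: element right-justified in cols 13-14; 4-char names fill 13-16.
    ifelse(nchar(nm) >= 4, substr(sprintf("%-4s", nm), 1, 4),
           sprintf(" %-3s", nm))
  }
  lines <- sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$het & !(a$resname %in% STANDARD_AA3), "HETATM", "ATOM"),
                   seq_len(nrow(a)) %% 100000,
                   fmt_name(a$atom, a$element),
                   ifelse(a$altloc == "", " ", substr(a$altloc, 1, 1)),
                   substr(sprintf("%3s", a$resname), 1, 3),
                   substr(paste0(a$chain, " "), 1, 1),
                   a$resno %% 10000,
                   ifelse(a$icode == "", " ", substr(a$icode, 1, 1)),
                   a$x, a$y, a$z,
                   a$occupancy, 0,
                   sprintf("%2s", substr(a$element, 1, 2)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Locate a user-supplied deposited structure file
#'
#' Analyses of deposited entries (e.g. the EH-domain/peptide complexes or the
#' rhodopsin structures) run on user-supplied coordinate files; nothing is
#' ever downloaded. Files named `<accession>.pdb` / `<accession>.cif`
#' (optionally gzipped) are searched in `dir` (default: the
#' `npfsite.structure_dir` option) and in the package's
#' `extdata/structures` directory.
#'
#' @param accession PDB accession, e.g. `"1F8H"`.
#' @param dir optional directory to search first.
#' @return The file path, or `NA_character_` if the file is not available.
#' @export
npf_structure_path <- function(accession, dir = getOption("npfsite.structure_dir")) {
  exts <- c(".pdb", ".pdb.gz", ".ent", ".cif", ".cif.gz")
  cand <- character(0)
  for (d in c(dir, system.file("extdata", "structures", package = "npfsite"))) {
    if (is.null(d) || !nzchar(d)) next
    cand <- c(cand, file.path(d, paste0(c(accession, tolower(accession)),
                                        rep(exts, each = 2))))
  }
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Define an atom selection on a structure model
#'
#' @param model a [structure_model()].
#' @param chain chain identifier(s), or `NULL` for all chains.
#' @param resno integer vector of author residue numbers (a range like `60:64`),
#'   or `NULL` for all residues.
#' @param atoms optional character vector of atom names to keep.
#' @param sidechain_only if `TRUE`, exclude backbone atoms N, CA, C, O
#'   (CB is part of the side chain).
#' @return An object of class `selection`.
#' @export
selection <- function(model, chain = NULL, resno = NULL, atoms = NULL,
                      sidechain_only = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.null(chain)) {
    missing_chain <- setdiff(chain, unique(model$atoms$chain))
    if (length(missing_chain) > 0)
      stop("chain(s) not in model: ", paste(missing_chain, collapse = ", "))
  }
  structure(list(model = model, chain = chain, resno = resno,
                 atoms = atoms, sidechain_only = sidechain_only),
            class = "selection")
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Resolve a selection to an ordered atom table
#'
#' Order is deterministic: chain, residue number, insertion code, atom name.
#' An empty result is returned as a zero-row table, not an error.
#'
#' @param sel a [selection()].
#' @return data.frame of atoms (same columns as `model$atoms`).
#' @export
resolve_selection <- function(sel) {
  stopifnot(inherits(sel, "selection"))
  a <- sel$model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$atoms)) keep <- keep & a$atom %in% sel$atoms
  if (isTRUE(sel$sidechain_only)) keep <- keep & !(a$atom %in% BACKBONE_ATOMS)
  out <- a[keep, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$icode, out$atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}
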