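# PIC-style interaction typing within a chain.
#
# Thresholds follow the published defaults of the Protein Interactions
# Calculator: hydrophobic side-chain pairs within 5.0 A, side-chain N(K/R/H)
# to side-chain O(D/E) ion pairs within 6.0 A, donor-acceptor heavy atoms
# within 3.5 A for hydrogen bonds, aromatic ring centroids 4.5-7.0 A,
# aromatic-sulphur within 5.3 A and cation-pi within 6.0 A. All are
# overridable through the `thresholds` argument.

HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

HB_DONORS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", TRP = "NE1",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

HB_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
  TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

default_interaction_thresholds <- function() {
  list(hydrophobic = 5.0, ionic = 6.0, hydrogen_bond = 3.5,
       aromatic_min = 4.5, aromatic_max = 7.0,
       aromatic_sulphur = 5.3, cation_pi = 6.0)
}

#' Classify residue-residue interactions within a chain
#'
#' Residue pairs in the given ranges (at least `min_seq_sep` apart in
#' sequence) are typed as hydrophobic, ionic, hydrogen-bond,
#' aromatic-aromatic, aromatic-sulphur or cation-pi interactions. A pair can
#' carry several types; one row is emitted per (pair, type).
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @param ranges integer vector of author residue numbers to consider
#'   (`NULL` = whole chain).
#' @param min_seq_sep minimum |i - j| in residue numbering (default 2;
#'   adjacent residues are skipped).
#' @param thresholds named list overriding the PIC-default distances.
#' @return data.frame with residue keys/names, interaction `type` and the
#'   defining `distance`.
#' @export
intrachain_interactions <- function(model, chain, ranges = NULL, min_seq_sep = 2,
                                    thresholds = list()) {
  stopifnot(inherits(model, "structure_model"))
  th <- utils::modifyList(default_interaction_thresholds(), thresholds)
  a <- model$atoms[model$atoms$chain == chain & !model$atoms$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not found in model")
  if (!is.null(ranges)) a <- a[a$resno %in% ranges, , drop = FALSE]
  if (nrow(a) == 0) return(empty_interaction_records())

  keys <- unique(res_key(a$chain, a$resno, a$icode))
  res_list <- lapply(keys, function(k) {
    a[res_key(a$chain, a$resno, a$icode) == k, , drop = FALSE]
  })
  names(res_list) <- keys
  resnames <- vapply(res_list, function(r) r$resname[1], character(1))
  resnos <- vapply(res_list, function(r) r$resno[1], integer(1))
  unknown <- !(resnames %in% names(THREE_TO_ONE))
  if (any(unknown)) {
    warning("skipping residues of unknown type: ",
            paste(unique(resnames[unknown]), collapse = ", "))
    res_list <- res_list[!unknown]; resnames <- resnames[!unknown]
    resnos <- resnos[!unknown]; keys <- keys[!unknown]
  }
  n <- length(res_list)
  if (n < 2) return(empty_interaction_records())

  out <- list()
  add <- function(i, j, type, d) {
    out[[length(out) + 1]] <<- data.frame(
      residue_a = keys[i], resname_a = resnames[i],
      residue_b = keys[j], resname_b = resnames[j],
      type = type, distance = d, stringsAsFactors = FALSE)
  }
  sc_atoms <- function(r) r[!(r$atom %in% BACKBONE_ATOMS), , drop = FALSE]
  min_d <- function(ra, rb) {
    if (nrow(ra) == 0 || nrow(rb) == 0) return(Inf)
    min(cross_dist(ra[, c("x", "y", "z")], rb[, c("x", "y", "z")]))
  }
  centroid <- function(r, atoms) {
    ring <- r[r$atom %in% atoms, c("x", "y", "z"), drop = FALSE]
    if (nrow(ring) < 3) return(NULL)
    colMeans(ring)
  }

  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (abs(resnos[i] - resnos[j]) < min_seq_sep) next
      ri <- res_list[[i]]; rj <- res_list[[j]]
      ni <- resnames[i]; nj <- resnames[j]

      # hydrophobic: side-chain atoms of apolar residues within threshold
      if (ni %in% HYDROPHOBIC_RES && nj %in% HYDROPHOBIC_RES) {
        d <- min_d(sc_atoms(ri), sc_atoms(rj))
        if (d <= th$hydrophobic) add(i, j, "hydrophobic", d)
      }
      # ionic: side-chain N of K/R/H vs side-chain O of D/E
      basic_n <- function(r, nm) {
        if (!nm %in% c("LYS", "ARG", "HIS")) return(r[0, , drop = FALSE])
        sc <- sc_atoms(r); sc[sc$element == "N", , drop = FALSE]
      }
      acidic_o <- function(r, nm) {
        if (!nm %in% c("ASP", "GLU")) return(r[0, , drop = FALSE])
        sc <- sc_atoms(r); sc[sc$element == "O", , drop = FALSE]
      }
      d1 <- min_d(basic_n(ri, ni), acidic_o(rj, nj))
      d2 <- min_d(basic_n(rj, nj), acidic_o(ri, ni))
      d <- min(d1, d2)
      if (d <= th$ionic) add(i, j, "ionic", d)

      # hydrogen bond: donor-acceptor heavy atoms within threshold
      donors <- function(r, nm) {
        want <- c(HB_DONORS$backbone, HB_DONORS[[nm]])
        r[r$atom %in% want, , drop = FALSE]
      }
      acceptors <- function(r, nm) {
        want <- c(HB_ACCEPTORS$backbone, HB_ACCEPTORS[[nm]])
        r[r$atom %in% want, , drop = FALSE]
      }
      d <- min(min_d(donors(ri, ni), acceptors(rj, nj)),
               min_d(donors(rj, nj), acceptors(ri, ni)))
      if (d <= th$hydrogen_bond) add(i, j, "hydrogen_bond", d)

      # aromatic-aromatic: ring centroid distance within window
      ci <- if (ni %in% names(RING_ATOMS)) centroid(ri, RING_ATOMS[[ni]]) else NULL
      cj <- if (nj %in% names(RING_ATOMS)) centroid(rj, RING_ATOMS[[nj]]) else NULL
      if (!is.null(ci) && !is.null(cj)) {
        d <- vnorm(ci - cj)
        if (d >= th$aromatic_min && d <= th$aromatic_max)
          add(i, j, "aromatic_aromatic", d)
      }
      # aromatic-sulphur
      sulphur <- function(r) r[r$element == "S", , drop = FALSE]
      if (!is.null(ci) && nrow(sulphur(rj)) > 0) {
        d <- min(cross_dist(matrix(ci, 1), sulphur(rj)[, c("x", "y", "z")]))
        if (d <= th$aromatic_sulphur) add(i, j, "aromatic_sulphur", d)
      } else if (!is.null(cj) && nrow(sulphur(ri)) > 0) {
        d <- min(cross_dist(matrix(cj, 1), sulphur(ri)[, c("x", "y", "z")]))
        if (d <= th$aromatic_sulphur) add(i, j, "aromatic_sulphur", d)
      }
      # cation-pi: K/R side-chain N vs aromatic centroid
      cation_n <- function(r, nm) {
        if (!nm %in% c("LYS", "ARG")) return(r[0, , drop = FALSE])
        sc <- sc_atoms(r); sc[sc$element == "N", , drop = FALSE]
      }
      if (!is.null(cj) && nrow(cation_n(ri, ni)) > 0) {
        d <- min(cross_dist(cation_n(ri, ni)[, c("x", "y", "z")], matrix(cj, 1)))
        if (d <= th$cation_pi) add(i, j, "cation_pi", d)
      } else if (!is.null(ci) && nrow(cation_n(rj, nj)) > 0) {
        d <- min(cross_dist(cation_n(rj, nj)[, c("x", "y", "z")], matrix(ci, 1)))
        if (d <= th$cation_pi) add(i, j, "cation_pi", d)
      }
    }
  }
  if (length(out) == 0) return(empty_interaction_records())
  res <- do.call(rbind, out)
  res <- res[order(res$residue_a, res$residue_b, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_interaction_records <- function() {
  data.frame(residue_a = character(), resname_a = character(),
             residue_b = character(), resname_b = character(),
             type = character(), distance = numeric(), stringsAsFactors = FALSE)
}
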