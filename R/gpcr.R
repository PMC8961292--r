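# Ballesteros-Weinstein position transfer for class A GPCRs.
#
# Numbering is implemented by transfer from an annotated bovine rhodopsin
# reference, not by per-family motif detection: the TM1/ICL1/H8 pocket
# analysis is anchored entirely in rhodopsin-numbered positions, and
# reference transfer is deterministic and testable. Segment anchors on the
# reference (author numbering of the 348-residue bovine opsin chain, the
# 1U19 sequence): Asn55 = 1.50, Lys66/Lys67 = 12.48/12.49, Leu68 = 12.50,
# Pro303 = 7.50 (NPxxY), Phe313 = 8.50, hence Tyr306 = 7.53, Cys316 = 8.53,
# Met317 = 8.54, Thr320 = 8.57 and Asn310/Lys311/Gln312 = 8.47-8.49.

RHODOPSIN_SEQ <- paste0(
  "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLYVTVQHKKLRTPLNYILLNLAVADLFMVFGG",
  "FTTTLYTSLHGYFVFGPTGCNLEGFFATLGGEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIP",
  "EGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQESATTQKAEKEVTRMVIIMVIAFLICWLPYAG",
  "VAFYIFTHQGSDFGPIFMTIPAFFAKTSAVYNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA"
)

# segment definitions: BW minor index range and author residue range
RHODOPSIN_BW_SEGMENTS <- data.frame(
  segment = c("1", "12", "7", "8"),
  first_minor = c(30L, 48L, 33L, 47L),
  first_resno = c(35L, 66L, 286L, 310L),
  last_resno = c(64L, 69L, 309L, 321L),
  stringsAsFactors = FALSE
)

#' The annotated rhodopsin reference used for numbering transfer
#'
#' @return list: `sequence` (bovine rhodopsin, author numbering = position),
#'   `map` data.frame (resno, residue, segment, bw).
#' @export
rhodopsin_reference <- function() {
  segs <- RHODOPSIN_BW_SEGMENTS
  rows <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    resno <- segs$first_resno[i]:segs$last_resno[i]
    minor <- segs$first_minor[i] + seq_along(resno) - 1L
    data.frame(resno = resno,
               segment = segs$segment[i],
               bw = sprintf("%s.%d", segs$segment[i], minor),
               stringsAsFactors = FALSE)
  }))
  rows$residue <- strsplit(RHODOPSIN_SEQ, "")[[1]][rows$resno]
  # assert the printed anchors; a failure means the reference data is wrong
  anchors <- c("1.50" = "N", "1.55" = "Y", "1.56" = "V", "1.59" = "Q",
               "12.48" = "K", "12.49" = "K", "12.50" = "L",
               "7.50" = "P", "7.53" = "Y",
               "8.47" = "N", "8.48" = "K", "8.49" = "Q", "8.50" = "F",
               "8.53" = "C", "8.54" = "M", "8.57" = "T")
  got <- setNames(rows$residue, rows$bw)[names(anchors)]
  if (!identical(unname(got), unname(anchors)))
    stop("rhodopsin reference annotation violates its anchors")
  list(sequence = RHODOPSIN_SEQ, map = rows[, c("resno", "residue", "segment", "bw")])
}

# named map: BW label -> author resno (for geometry code)
rhodopsin_bw_resno_map <- function() {
  m <- rhodopsin_reference()$map
  setNames(m$resno, m$bw)
}

#' Assign Ballesteros-Weinstein labels to a class A GPCR sequence
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) against the annotated
#' rhodopsin reference; labels transfer across aligned columns. Insertions
#' relative to the reference stay unlabeled. Queries under the identity
#' threshold over the labeled segments are rejected as not class A-like.
#'
#' @param query amino-acid string.
#' @param min_identity minimum fractional identity over aligned TM1 + H8
#'   reference positions (default 0.25).
#' @param gap_open,gap_extend affine gap penalties.
#' @return object of class `bw_numbering`: `sequence`, `map` data.frame
#'   (position, residue, segment, bw), `identity_tm1_h8`.
#' @export
assign_bw <- function(query, min_identity = 0.25, gap_open = 10, gap_extend = 1) {
  query <- toupper(gsub("\\s", "", query))
  if (nchar(query) < 30) stop("query too short for numbering transfer")
  ref <- rhodopsin_reference()
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  blosum <- get("BLOSUM62", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(pattern = query, subject = ref$sequence,
                                       substitutionMatrix = blosum,
                                       gapOpening = gap_open, gapExtension = gap_extend,
                                       type = "global")
  pm <- alignment_position_map(aln)
  qchar <- strsplit(query, "")[[1]]
  rchar <- strsplit(ref$sequence, "")[[1]]

  seg_keep <- ref$map$segment %in% c("1", "8")
  seg_resno <- ref$map$resno[seg_keep]
  in_seg <- pm$ref %in% seg_resno
  if (sum(in_seg) == 0) stop("query does not align to TM1/H8 of the reference")
  ident <- mean(qchar[pm$query[in_seg]] == rchar[pm$ref[in_seg]])
  if (ident < min_identity)
    stop(sprintf("query is not class A-like: %.0f%% identity over TM1+H8 (need >= %.0f%%)",
                 100 * ident, 100 * min_identity))

  bw_of_resno <- setNames(ref$map$bw, ref$map$resno)
  seg_of_resno <- setNames(ref$map$segment, ref$map$resno)
  hit_bw <- bw_of_resno[as.character(pm$ref)]
  keep <- !is.na(hit_bw)
  map <- data.frame(position = pm$query[keep],
                    residue = qchar[pm$query[keep]],
                    segment = unname(seg_of_resno[as.character(pm$ref[keep])]),
                    bw = unname(hit_bw[keep]),
                    stringsAsFactors = FALSE)
  structure(list(sequence = query, map = map, identity_tm1_h8 = ident),
            class = "bw_numbering")
}

#' @export
print.bw_numbering <- function(x, ...) {
  cat(sprintf("bw_numbering: %d residues, %d labeled (TM1+H8 identity %.0f%%)\n",
              nchar(x$sequence), nrow(x$map), 100 * x$identity_tm1_h8))
  invisible(x)
}

#' The position of a Ballesteros-Weinstein label in a numbered sequence
#' @param numbered a `bw_numbering`.
#' @param bw label string, e.g. `"8.50"`.
#' @return 1-based residue position, or `NA` if absent.
#' @export
bw_position <- function(numbered, bw) {
  stopifnot(inherits(numbered, "bw_numbering"))
  hit <- numbered$map$position[numbered$map$bw == bw]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# The eight positions framing the NPF pocket.
NPF_SITE_POSITIONS <- c("1.55", "1.56", "1.59", "12.50", "8.49", "8.50", "8.54", "8.57")

#' Residue identities at the NPF-site positions
#'
#' Returns the residues occupying the eight TM1/ICL1/H8 positions that frame
#' the NPF-binding pocket (1.55, 1.56, 1.59, 12.50, 8.49, 8.50, 8.54, 8.57).
#' Positions missing from the numbering (e.g. a truncated helix 8) are
#' reported as `NA`, not as an error.
#'
#' @param numbered a `bw_numbering`.
#' @return named character vector over the eight site positions.
#' @export
extract_site_residues <- function(numbered) {
  stopifnot(inherits(numbered, "bw_numbering"))
  vapply(NPF_SITE_POSITIONS, function(bw) {
    pos <- bw_position(numbered, bw)
    if (is.na(pos)) NA_character_ else substr(numbered$sequence, pos, pos)
  }, character(1))
}
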