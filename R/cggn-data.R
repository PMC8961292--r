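# Reference data for the common Ggamma numbering (CGgammaN).
#
# Segment layout (columns of the reference alignment):
#   h1   N-terminal coil      10 columns
#   H1   first helix          17 columns
#   h1h2 hinge/loop            5 columns
#   H2   second helix         22 columns (H2.1 .. H2.22)
#   h2   C-terminal region    20 columns (h2.1 .. h2.20)
# Anchors that fix the layout: the Asn-Pro-Phe motif occupies h2.8-h2.10 in
# every isoform, the prenylated CAAX cysteine sits at h2.17 (post-NPF gaps are
# right-justified against the cysteine column), and H2 ends at H2.22
# (Ggamma2 Leu51). Boundaries of h1/H1/h1h2 are not anchored by any published
# residue label and are therefore provisional; labels in those segments are
# flagged as such in output.
#
# Provenance: Ggamma1 (GNGT1), Ggamma2 (GNG2) and Ggamma5 (GNG5) are curated
# mature human protein sequences; every residue position cited for them in the
# literature on this numbering (Ggamma1 Asn62/Pro63/Phe64 and the h2 peptide
# KGIPEDKNPFKELKGGC; Ggamma2 Pro49/Leu50/Leu51 = H2.20-22, Pro60 = h2.9,
# Ser57-Glu58 before the NPF, Cys68; Ggamma5 Thr56 = h2.7, STNPFR at
# h2.6-h2.11, Pro61 = h2.12, Cys65 = h2.17) is reproduced by these sequences.
# The other nine isoform rows are SYNTHETIC stand-ins: Ggamma-like sequences
# constructed to honour the per-isoform residue identities that are published
# (h2.11 Lys for Ggamma1/7/9/11/12, Arg for Ggamma2/3/4/5/8/10, Val for
# Ggamma13; h2.12 Asp for Ggamma7/8/12, Glu for Ggamma1/2/3/4/9/10/11/13, Pro
# for Ggamma5; Glu at h2.7 and Ser at h2.6 for Ggamma7/12), but otherwise not
# the database sequences of those isoforms. They support the alignment
# machinery and the frequency profile of anchored columns only; do not treat
# them as real Ggamma3-13 sequences.

CGGN_SEGMENTS <- c(h1 = 10L, H1 = 17L, h1h2 = 5L, H2 = 22L, h2 = 20L)

# Each row is built from per-segment strings so column arithmetic is explicit.
cggn_row <- function(h1, H1, h1h2, H2, h2) {
  segs <- c(h1, H1, h1h2, H2, h2)
  if (!all(nchar(segs) == CGGN_SEGMENTS))
    stop("bad reference row segment widths: ", paste(nchar(segs), collapse = "/"))
  paste0(h1, H1, h1h2, H2, h2)
}

CGGN_ALIGNED <- c(
  Ggamma1  = cggn_row("MPVINIEDLT", "EKDKLKMEVDQLKKEVT", "LERML",
                      "VSKCCEEVRDYVEERSGEDPLV", "KGIPEDKNPFKELKGGCVIS"),
  Ggamma2  = cggn_row("---MASNNTA", "SIAQARKLVEQLKMEAN", "IDRIK",
                      "VSKAAADLMAYCEAHAKEDPLL", "TPVPASENPFREKKFFCAIL"),
  Ggamma3  = cggn_row("---MKGETPV", "SIAQARKMVEQLKIEAS", "LCRIK",
                      "VSKAAADLMTYCDAHAKEDPLL", "TPVPTSENPFREKKFFCALL"),
  Ggamma4  = cggn_row("---MKEGMSN", "SISQARKAVEQLKMEAC", "MDRVK",
                      "VSQAAADLLAYCEAHAKEDPLL", "IPVPASENPFREKKFFCAIL"),
  Ggamma5  = cggn_row("-----MSGSS", "SVAAMKKVVQQLRLEAG", "LNRVK",
                      "VSQAAADLKQFCLQNAQHDPLL", "TGVSSSTNPFRPQKV-CSFL"),
  Ggamma7  = cggn_row("---MSATNNI", "AQARKLVEQLRIEAGIE", "RIKVS",
                      "VSKAASDLMSYCEEHARSDPLL", "LVGIPSENPFKDKKTPCIIL"),
  Ggamma8  = cggn_row("---MSSNMAK", "SIAQARKTVEQLKLEVN", "IDRMK",
                      "VSQAAAELLAFCETHAKEDPLL", "LVGVPAENPFRDKKFSCVIL"),
  Ggamma9  = cggn_row("MAQDLSEKDL", "LKMEVEQLKKEVKNTRI", "LERMP",
                      "VSKCGEEIKNYVEENSGEDPLV", "KGIPEDKNPFKEKTGGCLIS"),
  Ggamma10 = cggn_row("---MSSGASA", "SALQRLVEQLKLEAGVD", "RIKVS",
                      "VSQAAAELQQYCMQNAHKDPLL", "LVGVPAGNPFREPRSGCALL"),
  Ggamma11 = cggn_row("MPALHIEDLP", "EKEKLKMEVEQLKKQVT", "LERML",
                      "VSKCSEEFRDYVEERSGEDPLV", "KGLPEDKNPFKELRGGCVIS"),
  Ggamma12 = cggn_row("---MSSKTAS", "TNNIAQARKLVEQLKLE", "IERIK",
                      "VSQAAADLKQFCLQHAKEDPLL", "TAVPASENPFKDKKTVCIIL"),
  Ggamma13 = cggn_row("---MEEWDVP", "QMKKEVESLKYQLAFQR", "EMASK",
                      "TIPELLKWIEDNIPKDSFLNTD", "LNPDWVENPFVEKGKSCTIL")
)

# Fig-2 accessions the rows correspond to; a "synthetic" source means the row
# is a constructed stand-in for that isoform, not the accession's sequence.
CGGN_SOURCES <- data.frame(
  isoform = names(CGGN_ALIGNED),
  accession = c("NG_051196.1", "NM_053064.5", "AF493871", "AF493872.1",
                "AF493873.1", "AF493874.1", "AF493875.1", "AF493876.1",
                "AF493877.1", "AF493878.1", "AF493879.1", "AF493880.1"),
  source = c("curated", "curated", "synthetic", "synthetic", "curated",
             "synthetic", "synthetic", "synthetic", "synthetic", "synthetic",
             "synthetic", "synthetic"),
  stringsAsFactors = FALSE
)
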