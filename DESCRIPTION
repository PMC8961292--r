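Package: npfsite
Title: The GPCR TM1/ICL1/H8 NPF-Binding Site and a Common Numbering System for G Protein Gamma Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural-bioinformatics toolkit for analysing how the C-terminus
    of the heterotrimeric G protein gamma subunit engages class A GPCRs. Implements
    the CGgammaN common residue numbering for human Ggamma isoforms (segments h1,
    H1, h1h2, H2, h2 with the Asn-Pro-Phe motif fixed at h2.8-h2.10 and the CAAX
    cysteine at h2.17), Ballesteros-Weinstein position transfer for GPCR TM1, ICL1,
    TM7 and helix 8 from an annotated rhodopsin reference, an inter- and intra-chain
    atomic contact engine with a strict 4 Angstrom criterion and a PIC-style
    interaction typology, Kabsch superposition and helix-axis geometry for
    quantifying the rotation relating helix 8 to the alpha-C helix of an
    Eps15-homology (EH) domain, a conservation/plausibility score for the
    TM1/ICL1/H8 NPF-binding pocket, deterministic synthetic-fixture generators
    (ideal helices, toy pocket-peptide complexes, Ggamma-like sequences), and
    named recipes that recompute the published contact tables and distances from
    user-supplied coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
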