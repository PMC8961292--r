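# npfsite

Structural bioinformatics of the interface between G-protein-coupled
receptors (GPCRs) and the C-terminus of the G protein γ subunit.

A body of biochemistry implicates the prenylated Gγ C-terminus — and its
Asn-Pro-Phe (NPF) motif in particular — in receptor coupling, yet no solved
receptor–G protein complex shows that motif near the receptor. A structural
hypothesis places it in a pocket formed by transmembrane helix 1 (TM1),
intracellular loop 1 (ICL1) and helix 8 (H8) of class A receptors, by
analogy with the NPF-binding αB/αC cleft of Eps15-homology (EH) domains.
`npfsite` implements the analytical machinery needed to recompute and probe
that hypothesis:

* **CGγN numbering** for human Gγ isoforms — segments h1, H1, h1h2, H2, h2,
  anchored by the NPF motif at h2.8–h2.10, the CAAX cysteine at h2.17 and
  the end of helix H2 at H2.22 (labels render like `Pro63^Gγh2.9`);
* **Ballesteros–Weinstein numbering** (TM1 `1.xx`, ICL1 `12.xx`, TM7
  `7.xx`, H8 `8.xx`) by alignment transfer from an annotated bovine
  rhodopsin reference;
* an **atomic contact engine** (strict < 4 Å criterion, cell-list search
  tested against an exhaustive oracle) plus a PIC-style typology of
  hydrophobic / ionic / hydrogen-bond / aromatic / cation-π interactions;
* **geometry**: Kabsch superposition, α-helix axis fitting, and the
  rotation of H8 about its own axis that aligns its side chains with the
  EH-domain αC helix (clockwise-positive viewed from the distal end of H8);
* an **NPF-site plausibility score**: the fraction of the eight pocket
  positions (1.55, 1.56, 1.59, 12.50, 8.49, 8.50, 8.54, 8.57) carrying the
  expected residue chemistry, with per-position conservation profiles from
  any user-supplied alignment;
* **synthetic-fixture generators** (ideal helices, toy pocket–peptide
  complexes with ground-truth contact tables, Gγ-like sequences with known
  labels) so every operation is testable without downloads;
* **recipes** that replay the published contact tables and distance/angle
  measurements on locally supplied PDB/mmCIF files (`run_recipe()`, plus a
  thin CLI at `inst/scripts/npfsite`). The package never downloads data.

## Worked example

```r
library(npfsite)

# Number a Ggamma sequence and read off the NPF motif
g2 <- npfsite:::cggn_reference_sequences()[["Ggamma2"]]
n2 <- assign_cggn(g2)
label_of(n2, 60)$rendered
#> [1] "Pro60^Gγh2.9"
residue_of(n2, "h2", 17)     # the prenylated CAAX cysteine
#> [1] 68

# Number the rhodopsin sequence and score its NPF pocket
bw <- assign_bw(rhodopsin_reference()$sequence)
bw_position(bw, "8.53")      # Cys316, the prenyl-contact site on H8
#> [1] 316
site <- extract_site_residues(bw)
site
#>  1.55  1.56  1.59 12.50  8.49  8.50  8.54  8.57
#>   "Y"   "V"   "Q"   "L"   "Q"   "F"   "M"   "T"
npf_site_score(site)$score   # 7 of 8 positions match the expected chemistry
#> [1] 0.875
```

The score of 0.875 says that seven of rhodopsin's eight pocket positions
carry the chemistry the EH-domain analogy predicts (hydrophobic lining plus
charged/polar at 1.59 and 8.49); the single mismatch is Thr at 8.57.

Contacts and geometry run on any `structure_model`:

```r
tc <- make_toy_pocket_complex(seed = 1)        # two-helix pocket + NPF probe
ct <- interchain_contacts(tc$model,
                          selection(tc$model, chain = c("A", "B")),
                          selection(tc$model, chain = "P"))
ct$pair_summary                                 # residue pairs, min distances
identical(ct$records, tc$truth$records)         # matches the built-in truth
#> [1] TRUE
```

Analyses of deposited entries (the EH-domain/peptide complexes 1F8H/1FF1,
rhodopsin 1U19, the receptor–G protein complex 6QNO, ...) run on files you
supply locally — place `<accession>.pdb` where `npf_structure_path()` looks
(the `npfsite.structure_dir` option or `inst/extdata/structures`) and drive
them through `run_recipe()` with a YAML config declaring which chain plays
which role.

## Data provenance

The rhodopsin reference sequence and the Gγ1/Gγ2/Gγ5 rows of the CGγN
reference are curated sequences whose anchor residues are asserted at build
time. The remaining nine Gγ rows are clearly labelled **synthetic
stand-ins** (see `build_reference()$sources` and the vignette): they honour
the per-isoform residue identities documented for the anchored h2 columns
but are not database sequences, and exist so the alignment profile is
complete offline.

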