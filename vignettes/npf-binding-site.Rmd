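---
title: "Numbering, contacts and geometry of the GPCR TM1/ICL1/H8 NPF-binding site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numbering, contacts and geometry of the GPCR TM1/ICL1/H8 NPF-binding site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npfsite)
```

## The scientific problem

Heterotrimeric G proteins couple to G-protein-coupled receptors (GPCRs)
through contacts that the solved receptor–G protein complexes only partly
explain: the prenylated C-terminus of the Gγ subunit, and in particular its
Asn-Pro-Phe (NPF) motif, is biochemically implicated in receptor coupling,
yet no deposited structure shows it near the receptor. A structural
hypothesis places the Gγ NPF motif in a pocket formed by transmembrane
helix 1 (TM1), intracellular loop 1 (ICL1) and helix 8 (H8) of class A
GPCRs, by analogy with the NPF-binding cleft of Eps15-homology (EH)
domains, whose αB/αC helix pair crosses the same way TM1 and H8 do.

This package provides the machinery needed to state, test and recompute that
hypothesis from sequences and coordinates:

1. **CGγN**, a common residue numbering for the twelve human Gγ isoforms;
2. **Ballesteros–Weinstein (BW) transfer** for GPCR TM1/ICL1/TM7/H8 positions;
3. an **atomic contact engine** with the strict < 4 Å criterion and a
   PIC-style interaction typology;
4. **rigid-body and helix-axis geometry** (Kabsch superposition, axis
   fitting, the H8 rotation angle relating H8 to the EH-domain αC helix);
5. a **conservation/plausibility score** for the pocket;
6. deterministic **synthetic-fixture generators**; and
7. **recipes** that replay each published analysis on user-supplied files.

## The CGγN numbering

Gγ subunits share a secondary-structure architecture of two helices (H1,
H2) separated by a hinge (h1h2) and flanked by coils (h1 N-terminal, h2
C-terminal). CGγN labels a residue by segment and position within the
segment, rendered like `Gγh2.9`. Three anchors pin the scheme:

* the NPF motif occupies h2.8–h2.10 in every isoform;
* the prenylated CAAX cysteine occupies h2.17 (gaps in the short post-NPF
  region are right-justified against the cysteine column);
* helix H2 ends at H2.22.

Segment boundaries for h1/H1/h1h2 are not pinned by any published residue
label; we fix them once (h1 = 10 columns, H1 = 17, h1h2 = 5, H2 = 22,
h2 = 20) by back-calculation from the anchored labels, and mark labels in
the unanchored segments `provisional` in all output. Any layout consistent
with the anchors reproduces every label this package is asked to reproduce;
the provisional flag keeps the distinction visible.

```{r}
n2 <- assign_cggn(npfsite:::cggn_reference_sequences()[["Ggamma2"]])
label_of(n2, 60)$rendered   # the NPF proline of Ggamma2
```

**Provenance of the reference rows.** The package ships curated mature
protein sequences for Gγ1, Gγ2 and Gγ5 — every published residue/label pair
for these three isoforms is reproduced by construction and asserted at
build time. The other nine rows are *synthetic stand-ins*, clearly labelled
as such in `build_reference()$sources`: Gγ-like sequences that honour the
per-isoform identities that are published for the anchored h2 columns
(h2.7, h2.11, h2.12, the NPF and the CAAX cysteine) but are otherwise not
database sequences. They exist so the alignment machinery has a full
12-row profile to align against; analyses that depend on the actual
residue content of isoforms 3–13 outside those columns should replace the
stand-ins with real sequences (drop a FASTA next to your analysis and
align with `assign_cggn`).

Label assignment aligns the query against each reference row (BLOSUM62,
gap open 10 / extend 1) and transfers the column labels from the
highest-scoring row whose transfer places an NPF trimer on h2.8–h2.10; a
sequence no row can anchor is rejected as not numberable. Trying rows in
score order rather than only the single best makes the assignment robust
to spurious optimal alignments of remote queries, without ever moving the
NPF anchor.

## BW numbering by reference transfer

The TM1/ICL1/H8 analysis only ever uses rhodopsin-anchored positions, so
numbering is implemented as deterministic transfer from an annotated
bovine rhodopsin reference (348 residues; author numbering equals sequence
position): Asn55 = 1.50, Lys66/Lys67 = 12.48/12.49, Leu68 = 12.50,
Pro303 = 7.50, Phe313 = 8.50. The annotation is validated against sixteen
anchor identities every time it is built. Queries must reach 25 % identity
over the aligned TM1 + H8 positions; below that, position transfer from a
rhodopsin template is not meaningful and the sequence is rejected rather
than mislabeled.

```{r}
bw <- assign_bw(rhodopsin_reference()$sequence)
extract_site_residues(bw)
```

## Contacts

A contact is any atom pair at distance strictly below 4 Å (a pair at
exactly 4.00 Å is *not* a contact). The engine uses a cell-list neighbour
search and is held, by tests, to exact agreement with an exhaustive
O(N²) enumeration. Defaults worth knowing:

* backbone atoms are included (the published contact diagrams mark
  main-chain contacts); `sidechain_only` restricts to side chains;
* hydrogens are stripped on reading by default. Some depositions carry
  explicit hydrogens and some do not, which inflates raw contact counts
  for the former — the package keeps the heavy-atom default and exposes
  `keep_hydrogens = TRUE` for reproducing hydrogen-bearing analyses; the
  recipes that replay such analyses default to keeping hydrogens there;
* for multi-model (NMR) files the first model is the default and every
  recipe logs which model it used.

Within a chain, `intrachain_interactions()` types residue pairs with the
published PIC default thresholds (hydrophobic side chains ≤ 5.0 Å, K/R/H
side-chain N to D/E side-chain O ≤ 6.0 Å, donor–acceptor heavy atoms
≤ 3.5 Å, aromatic centroids 4.5–7.0 Å, aromatic–sulphur ≤ 5.3 Å,
cation–π ≤ 6.0 Å), all overridable.

## Geometry: the H8 rotation

The structural argument rests on superposing the EH-domain αB helix onto
TM1 and asking how H8 must rotate about its own axis for its side chains
to occupy the positions of the NPF-binding αC residues. The pipeline is:

1. Kabsch superposition (proper rotation, det = +1) of the αB Cα atoms
   onto their TM1/ICL1 partners from the correspondence map
   (Gly33↔12.50, Lys37↔1.59, Leu40↔1.56, Leu41↔1.55);
2. helix-axis fit for H8: centroids of a 4-residue sliding window along
   the Cα trace lie on the axis; a least-squares 3-D line through them
   gives direction (oriented N→C) and a fixed perpendicular frame;
3. azimuthal phases of the H8-side positions (8.49, 8.50, 8.54, 8.57,
   represented by Cβ — Cα for glycine — because the alignment in question
   is of side-chain positions, not backbone) and of their superposed αC
   partners, measured in the same frame;
4. the circular mean of the per-pair offsets, reported in [0°, 360°),
   positive clockwise as seen from the distal (C-terminal) end of H8 —
   the viewpoint used when describing the pocket.

On synthetic helix pairs with known applied rotations the operation
recovers the angle to better than 1°; the acceptance tolerance of 2°
absorbs axis-fit error on short helices. The αC "SLE"↔H8 "NKQ" extension
of the correspondence map is only partially pinned to author numbers in
the source material; those rows ship flagged `unverified` and are excluded
from the rotation fit by default.

## The NPF-site score

The conservation argument is qualitative: the pocket positions are
hydrophobic where the EH-domain cleft is hydrophobic, and charged/polar at
1.59 and 8.49. `npf_site_score()` operationalises this as the fraction of
present site positions whose residue falls in the expected chemical class
(partition: polar G/S/T/Y/C, neutral Q/N, basic K/R/H, acidic D/E,
hydrophobic A/V/L/I/P/W/F/M). Two deliberate choices:

* at 1.59 and 8.49 any non-hydrophobic class counts as a match, because
  the residues documented at these positions span Gln, Arg, Lys and Glu;
* tyrosine satisfies a hydrophobic expectation (its ring packs like the
  leucine it corresponds to at 1.55) even though the colour-class
  partition files Tyr under polar.

With those rules the rhodopsin site scores 7/8 = 0.875 — the single
mismatch is Thr at 8.57, a genuine chemical difference from the valine it
corresponds to in the EH domain. The equal-weight aggregate is package
plumbing, not a published statistic; weights are configurable.

## Synthetic data: what it does and does not emulate

The generators exist to close testing loops without any downloads:

* `make_ideal_helix()` builds textbook α-helices (rise 1.5 Å/residue,
  twist 100°, Cα radius 2.3 Å — configurable). The Cα trace is exact; N,
  C, O and Cβ placement is schematic with sane bond lengths, and Cβ sits
  at the Cα azimuth so side-chain phase equals backbone phase by
  construction. These helices validate the axis fitter and the rotation
  operation against ground truth.
* `make_toy_pocket_complex()` crosses two helices at ~60° (qualitatively
  like the αB/αC pair) and rigidly places a probe tripeptide to meet
  residue-distance targets within 0.05 Å, enumerating the true contact
  table exhaustively at build time.
* `make_gamma_like_sequence()` samples sequences with the reference
  segment layout, the NPF forced at h2.8–h2.10 and a CAAX tail, with
  optional indels outside a protected window around the NPF.

None of this emulates real side-chain rotamers, real sequence composition
biases, membrane context, or experimental coordinate error. Passing the
property suite therefore demonstrates the *operations* are correct
(contact enumeration exact, transforms recovered, labels anchored), not
that any biological conclusion holds; the structure-dependent measurements
(the ~40 Å NPF–Cys316 separation in the receptor–G protein complex, the
~115° H8 rotation, the contact lists of the EH-domain complexes) require
the actual deposited coordinate files, which the user supplies locally
(`?npf_structure_path`; the package never downloads).

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy conformer; exact ties go
  to altloc "A".
* Kabsch refuses fewer than 3 pairs or collinear point sets (the rotation
  is undefined); the axis fitter refuses fewer than 6 Cα positions.
* Angles are reported in [0°, 360°); circular means are used wherever
  offsets are averaged.
* The contact cutoff is strict `<`; persistence in an alternative
  conformation is `broken` at ≥ the original cutoff.
* Selections resolve in a fixed order (chain, residue number, insertion
  code, atom name), so every table the package writes is byte-stable.

## Problem sizes used by the test and acceptance runs

The shipped suites run at desk scale by choice: contact-oracle agreement
on 300–1,000-atom fixtures, three to five seeds per geometric property,
100 generated Gγ-like sequences for the numbering-recovery rate. These
sizes are far past the point where the checked properties are binary
(exact agreement, sub-degree recovery), so larger fixtures add runtime,
not information.

## Known limitations

* The CGγN reference ships only three curated isoform rows (see above);
  non-human Gγ sequences are numbered best-effort and not validated.
* BW transfer covers TM1/ICL1/TM7/H8 only, from a rhodopsin template;
  class B/C/F receptors are out of scope.
* The hydrogen-bond rule is distance-only (no angles), matching the cited
  interaction-calculator convention rather than a full geometric
  definition.
* No docking, pose generation, energetics, solvent accessibility or
  surface rendering: outputs are numeric tables.
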