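---
title: "Methods: mitochondrial variant annotation and case-control burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial variant annotation and case-control burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoburden)
```

## The analysis this package implements

mitoburden reimplements, as a tested pipeline, the analysis typical of a
small mtDNA case-control re-sequencing study: amplicon sequences (or
pre-called variant lists) are compared to the rCRS reference
(NC_012920), each variant is annotated with its gene, codon and
amino-acid effect under the vertebrate mitochondrial genetic code,
variants are classified by OXPHOS complex and novelty, and per-gene
carrier counts in cases versus controls are tested for association. The
packaged fixtures transcribe one published study of primary congenital
glaucoma (35 cases, 40 controls; 132 and 58 coding-region variants) and
serve as the acceptance surface: the package's arithmetic regenerates
the printed tallies and statistics.

## Genome model and annotation

Coordinates are 1-based inclusive throughout, matching rCRS numbering as
used in the literature (m.10398 etc.); there are no half-open intervals
anywhere user-visible. The genome is circular: position arithmetic is
modulo the genome length, and the data model supports features that wrap
the origin, although no embedded rCRS gene does (only the D-loop wraps,
and D-loop analysis is out of scope).

The embedded layout has 13 protein-coding genes, 22 tRNAs and 2 rRNAs.
Six genes (ND1, ND2, CO3, ND3, ND4, CYB) end in incomplete stop codons
completed by polyadenylation; their trailing 1–2 bases are excluded from codon
arithmetic rather than fabricating bases the genome does not contain.
Overlapping genes (ATPase8/ATPase6, ND4L/ND4, ATPase6/CO3 at a single
base) produce one annotation row per overlapping feature, because the
reading frames differ.

For an H-strand CDS starting at $s$, position $p$ lies in codon
$\lfloor (p-s)/3 \rfloor + 1$; for an L-strand CDS ending at $e$, in
codon $\lfloor (e-p)/3 \rfloor + 1$ of the reverse-complemented
sequence. Translation uses NCBI table 2 (TGA=Trp, ATA=Met, AGA/AGG=stop;
60 sense codons); the table is constructed in the package and verified
against Biostrings in the test suite. Ambiguous codons translate to an
explicit undetermined sentinel, never silently to an amino acid.

### Two classification pathways

Effects are classified two ways, never mixed silently:

* **sequence-based** — recompute the codon from a genome with sequence
  and translate both alleles (used for real or synthetic sequence
  input);
* **fixture-based** — compare the printed amino-acid pair
  (`effect_from_aa_pair()`), used to reproduce published tallies.

The separation matters because printed tables contain rows whose codon
column and amino-acid column disagree (in the packaged fixture: the rows
at positions 8843, 8875 and 14000, e.g. a printed `CCT>CCA` next to a
printed `Leu>Pro`). The published headline counts follow the amino-acid
column, so the fixture pathway does too; `reconcile()` reports every
such inconsistency without repairing it. Amino-acid spelling variants in
the fixtures ("IsoLeu", "Iso", doubled names like "SerSer", stray
punctuation) are normalized in code, and the normalization rules are
unit-tested.

Novelty has the same duality: in pipeline mode a variant is novel iff
its (position, ref, alt) triple is absent from a user-supplied
catalogue; in fixture mode novelty is the presence of a GenBank
accession in the printed row. The bundled default catalogue is exactly
the set of non-novel fixture variants — no external database ships with
the package.

## Variant calling

The external multiple-alignment step of the original Sanger workflow is
replaced by an internal global aligner (Needleman–Wunsch, linear gap
penalty) so the calling step is testable. Defaults are match +1,
mismatch −1, gap −2: amplicons are near-identical to the reference, so
any sane scheme recovers isolated variants; the parameters are exposed
for completeness. Tie-breaking is deterministic (diagonal preferred over
gaps, gap-in-sample over gap-in-reference), insertions are
left-normalized to the standard left-most placement, runs of
gap-in-sample are reported as *uncovered* rather than called as
deletions (no deletions occur in the emulated study), and columns
involving `N` never produce calls. Variants planted closer than 2 bp are
documented as unsupported for exact round-trip recovery — alignment
placement becomes ambiguous — and the synthetic generator therefore
keeps planted variants ≥2 bp apart. The aligner stores a byte traceback
matrix, so it is intended for amplicon-scale windows (a few kb), not
whole-chromosome alignment; per-window call sets merge by deduplicated
union, which equals whole-sequence calling when window overlaps exceed
twice the maximum indel length.

## Burden statistics

Carrier collapse: a subject counts once per gene if it carries at least
one qualifying (by default non-synonymous) variant, whatever the
multiplicity. The resulting 2×2 (carriers/non-carriers × cases/controls)
is tested with:

* **Exact Fisher (default).** Full hypergeometric enumeration; the
  two-sided p-value sums the probabilities of all tables whose point
  probability is ≤ that of the observed table, with a $1+10^{-7}$
  relative tolerance on the comparison to absorb floating-point ties.
  This is the convention that reproduces the printed values 0.136,
  0.495, 0.467, 0.360, 0.043 and 0.019 in the fixture's burden table.
* **Pearson χ²** without continuity correction,
  $X^2 = N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, 1 df.

The emulated study mixed tests across rows: recomputation shows its
printed ND2 (0.005) and ATPase6 (0.002) p-values match only the
uncorrected χ² (Fisher gives 0.009 and 0.003), while the other ten rows
match Fisher. mitoburden exposes an explicit per-gene policy (`fisher`,
`chi2`, or `auto` — χ² when all expected cells ≥ 5) instead of guessing.

Relative risks use the Katz log method with $z = 1.959964$ at the 95%
level, in three orientations:

* `case-cohort` (default): $RR = \frac{a/(a+b)}{c/(c+d)}$, the risk of
  being a case among carriers versus non-carriers — this reproduces 10
  of the 12 printed RRs (e.g. ND5: 3.00, CI 1.86–4.83);
* `control-cohort`: the same with the outcome swapped — the printed
  ND4L row (1.92) matches only this orientation (its case-cohort
  numerator is a zero cell);
* `exposure`: the carrier-rate ratio $\frac{a/(a+c)}{b/(b+d)}$ — the
  printed CYB row (0.57) matches only this form.

No continuity correction is applied to zero cells (the error message
says so); no multiple-testing correction is applied by default, matching
the emulated analysis.

## Risk classification

Scores are always external inputs; nothing here computes SIFT or
PolyPhen values. Thresholds: SIFT < 0.05 deleterious, ≥ 0.05 tolerated
(the boundary is tolerated); PolyPhen > 2.0 probably damaging,
[1.5, 2.0] possibly damaging (closed bracket at both ends), < 1.5
benign. The combined call is *pathogenic* iff SIFT is deleterious AND
PolyPhen is at least possibly damaging — a conjunctive policy inferred
from the emulated study treating its five pathogenic variants as
damaging under both tools; `combine = "either"` relaxes it. The
classification is monotone: lowering a SIFT score or raising a PolyPhen
score never un-calls a pathogenic variant (property-tested).

The ROS-associated set {G10398A, A12308G, G13708A} and primary LHON set
{G3460A, G11778A, T14484C} are screened purely on (position, ref, alt).

## Synthetic data: what it emulates, and what a green test establishes

The generator states the study's world: 35 cases versus 40 controls by
default, a miniature 1,650-bp circular genome echoing the real gene
organisation (H-strand tRNA/rRNA, three CDS spanning complexes I/IV/V,
one CDS on the L strand, one with an incomplete stop, intergenic
spacers), independent Bernoulli carrier draws per gene per subject, and
single-base insertions in RNA genes. Default carrier probabilities are
0.3 for a non-synonymous variant in cases versus 0.05 in controls —
roughly the contrast of the stronger fixture genes (ND5: 60% vs 10%;
ND1: 17% vs 5%) — plus 0.15 for synonymous carriers in both cohorts and
0.02 for RNA-gene insertions; all are per-gene configurable. Non-
synonymous plants are constructed by choosing a codon position where a
single-base change alters the amino acid and verifying the effect at
generation time; planted variants are kept ≥2 bp apart so round-trip
recovery is exact.

Determinism: each sample draws from a stream seeded by (master seed,
sample index), so cohorts are byte-reproducible regardless of the order
samples are generated in.

The generator does *not* emulate realistic mutational spectra,
haplogroup structure, heteroplasmy or sequencing error. A green
round-trip test therefore establishes that the alignment, calling,
annotation and carrier arithmetic are correct on clean single-base
events — not that the pipeline is robust to noisy chromatograms or
complex alleles, which are out of scope.

## Numerical choices

* Fisher tie tolerance $1+10^{-7}$ (above); the independent test oracle
  recomputes p-values from factorial ratios and agrees to $10^{-10}$
  over every admissible table with total n ≤ 30.
* Percentages are display-rounded half-up to 2 decimals (the convention
  of the emulated tables); internal math never rounds.
* The χ² statistic is computed in double precision from the closed form;
  the degenerate all-zero-margin table is an error for χ² and p = 1 for
  Fisher.
* Alignment scores are integers; scoring `N` against anything as 0 keeps
  ambiguous bases neutral.

## Design choices made where the design was open

* The published study never states which coordinate build its amino-acid
  positions derive from. The embedded standard NC_012920 layout
  reproduces every computable printed amino-acid index in the fixtures
  except one row (printed position 183 with printed notation p.T187T,
  where the notation itself agrees with our arithmetic), which settles
  the question in favour of the standard build.
* Insertions are anchored *after* the stated position (HGVS-style
  between-position insertion), consistent with the fixture's
  "2790_91" notation.
* Variant identity is the (position, ref, alt) triple; accession numbers
  are annotations (the fixture reuses one accession for two distinct
  variants).
* The "Others" burden row pools RNA-gene variants, mirroring the
  fixture's final row.
* Per-patient records keep printed clinical fields verbatim and surface
  printed variant tokens that fail to resolve against the per-variant
  table (8 such tokens in the fixture) rather than guessing.

## Known limitations

Deletions and multi-nucleotide variants are unsupported (none occur in
the emulated study). The two fixture counts the source itself cannot
support — the "eight patients (22.85%)" pathogenic-carrier figure and
the "twenty patients (57.14%)" ROS-carrier figure — are not reproduced:
the per-variant and per-patient tables they would derive from are
mutually inconsistent (the transcribed patient table yields 16 ROS-set
carriers), and the package reports what the fixtures actually contain.
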