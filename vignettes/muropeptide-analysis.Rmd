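---
title: "Identifying cross-linked muropeptides from deconvoluted LC-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cross-linked muropeptides from deconvoluted LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muroseek)
library(dplyr)
```

## The problem

Bacterial peptidoglycan is a mesh of glycan chains — alternating
N-acetylglucosamine (GlcNAc) and N-acetylmuramic acid (MurNAc) — whose short
peptide stems are cross-linked by transpeptidases. Muramidase digestion
releases soluble disaccharide-peptides (muropeptides); after borohydride
reduction these elute as single chromatographic peaks and their neutral
monoisotopic masses are read off deconvoluted high-resolution LC-MS feature
lists. Identification is then a mass-matching problem: enumerate every
plausible theoretical structure, compute its mass, and assign observed
features within a ppm tolerance.

The interesting chemistry lives in the cross-links. D,D-transpeptidases form
4-3 bonds (donor stem position 4 to the acceptor's position-3
meso-diaminopimelic acid, DAP); canonical L,D-transpeptidases form 3-3 bonds
(donor DAP to acceptor DAP). *Acetobacteraceae* such as *Gluconobacter
oxydans* additionally carry 1-3 cross-links, in which the donor stem is a
single alanine — a gm-A moiety — bonded to the acceptor's DAP. `muroseek`
generates all three dimer/trimer chemistries dynamically from a curated
monomer database, which is what makes peptidoglycans rich in 1-3 products
searchable at all.

## The mass model

Masses are neutral and monoisotopic. Each residue contributes its dehydrated
residue mass (standard amino-acid table, plus meso-DAP at 172.08479 Da and
its amidated form at −0.984016 Da relative to DAP; GlcNAc 203.07937, MurNAc
275.10049), and a molecule of $n$ subunits has

$$ M \;=\; \sum_{\text{glycans}} m_g + \sum_{\text{stems}} m_r
   \;+\; n\,(m_{\mathrm{H_2O}} + m_{\mathrm{red}})
   \;-\; (n-1)\, m_{\mathrm{H_2O}} \;+\; \Delta_{\text{mods}} , $$

one water per condensed molecule being lost per cross-link and every MurNAc
carrying the +2.015650 Da borohydride reduction. The 1,6-anhydro ring (glycan
chain cap) replaces one reduced MurNAc: net −20.026215 Da versus the reduced
form. Deacetylation is −42.010565 Da and is tracked at the molecule level:
the mass is identical whether the acetyl is lost from GlcNAc or MurNAc, and
MS1 cannot localise it. Iso-glutamate (`E`) is mass-identical to glutamate,
so no distinction is made. Charge handling belongs to the upstream
deconvolution and is out of scope; the only charged quantities produced are
the singly-protonated b/y stem-fragment masses (`stem_fragments()`) used to
sanity-check monomer identifications against MS/MS spectra.

This table of constants reproduces all 61 published *G. oxydans* theoretical
masses within ±0.0015 Da (the rounding radius of 4-decimal printing), which
is the package's calibration criterion for the whole residue table:

```{r masses}
ref <- go_reference_composition()
max(abs(muropeptide_mass(ref$structure) - ref$theoretical_mass))
```

## Database generation

`enumerate_monomer_space()` builds the candidate stems an MS/MS validation
step would screen: for *G. oxydans*-type peptidoglycan
(`go_candidate_space()`), mono- to pentapeptides with Ala at position 1,
Glu/Gln at position 2, DAP or amidated DAP at position 3, any amino acid at
position 4, and pentapeptides ending in an A–X dipeptide. The wildcard
alphabet defaults to 19 residues — the 20 standard amino acids minus
leucine, which is mass-identical to isoleucine and therefore redundant in a
mass-based search space — giving $1 + 2 + 4 + 76 + 76 = 159$ candidates.

`build_theoretical_db()` expands a curated monomer set into the search
space. A pair (acceptor, donor) is emitted iff the acceptor has DAP (plain
or amidated) at stem position 3 and the donor satisfies the enabled
chemistry: length ≥ 4 for 4-3, length ≥ 3 with position-3 DAP for 3-3,
exactly the single residue A for 1-3. Names follow the acceptor=donor
convention (the rightmost subunit donates). Trimers chain two valid bonds;
each internal subunit must be both a valid donor and a DAP acceptor, so no
branched trimers arise (one DAP accepts at most one bond). Whether an
amidated DAP can still donate a 3-3 bond (its side-chain carboxyl is
occupied by the amide) is chemically uncertain; such dimers are generated
and simply carry the `amidated` flag, keeping the search space a superset.

Design choices made here:

- **Modification variants** (one anhydro end, one deacetylation, or both)
  are generated at the multimer level from unmodified bricks; masses follow
  by additivity, which the test suite verifies against brute-force monomer
  recomputation to 1e-6 Da.
- **Isobaric merging**: entries whose masses agree within 1e-4 Da are merged
  into one entry with names joined by `|` (e.g. `gm-AEJ_NH2=gm-AEJA` and
  `gm-AEJA=gm-AEJ_NH2`, the same unordered pair bonded 4-3 versus 3-3). An
  MS1 search cannot distinguish them, so reports carry all names and an
  `ambiguous` flag rather than a false certainty.
- **`restrict_1_3_to_gmA`** narrows 1-3 generation to the canonical
  unmodified gm-A donor — useful when screening a host organism (e.g.
  *E. coli* expressing a heterologous 1-3 transpeptidase) where only
  gm-A-containing products are of interest.

## Matching, cleanup, consolidation

Matching compares every feature to every entry: a pair is a match when the
absolute signed ppm error $(m_{obs} - m_{theo})/m_{theo} \times 10^6$ is
≤ the tolerance (inclusive; default 10 ppm). A feature matching several
non-isobaric entries keeps all matches, but only the lowest-|ppm| one is
`primary` and receives the intensity, so abundance sums never double-count.
Unmatched features stay in an "unidentified" pool and total intensity is
conserved exactly — an invariant the tests assert before and after cleanup.

Deconvolution leaves satellite signals: sodium/potassium adducts
(+21.981944 / +37.955882 Da) and in-source fragments (loss of GlcNAc,
203.07937 Da, or of the whole disaccharide, 478.17986 Da). An unidentified
feature at such a delta from a directly-matched entry, within the
retention-time cleanup window (default 0.5 min) of that entry's feature, is
merged into the parent: intensity added, provenance re-flagged. Ties go to
the nearest retention time, then the lowest |ppm|. The exact satellite set
used by earlier implementations of this workflow is not documented, so both
classes are implemented and individually switchable in `search_config()`;
cleanup can never create an identification without direct evidence.

Replicates consolidate per structure to the mean assigned intensity over the
replicates where the structure was seen (absent replicates contribute
nothing), mean ± sd retention time (n−1 denominator, as appropriate for
two- or three-replicate designs), mean observed mass and mean ppm. Relative
abundances divide by the summed intensity of identified structures only —
published composition tables sum to ≈100% per sample, so the unidentified
pool is excluded from the denominator.

## Compositional metrics

The cross-linking index is `0.5 * (% dimers) + 0.33 * (% trimers)`, with
0.33 used literally as conventionally printed rather than 1/3, so recomputed
values agree digit-for-digit with published ones. The glycan chain length
inverts the level-weighted anhydro fraction. The 1-3 content counts dimers
containing a single-A donor subunit; 1-3 bonds inside trimers are not folded
into that number. The disaccharide-dipeptide class is reported twice —
stems of length ≤ 2 (which includes gm-A and reproduces published tallies)
and strictly length-2 stems — because the field's usage is ambiguous.

Recomputing from the packaged reference composition:

```{r indices}
stat <- summarize_composition(go_reference_abundances("wt_stat"))
expo <- summarize_composition(go_reference_abundances("wt_expo"))
round(c(stat$crosslink_index, expo$crosslink_index), 1)   # 19.9, 15.9
round(c(stat$pct_1_3_dimers, expo$pct_1_3_dimers), 1)     # 16.6, 5.8
```

The chain lengths recomputed this way come out near 21–22 disaccharides,
slightly below the published 24/22; the printed abundance columns are
rounded to 3 decimals and may omit trace anhydro species, and both effects
bias the reciprocal formula. The formula — not any printed value — is the
contract here, and it is verified by analytic toy cases in the tests.

## The synthetic-data generator

`simulate_features()` emits what a deconvolution step would: one feature per
structure at its theoretical mass times $(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma_{ppm}\cdot 10^{-6})$ — mass error is
multiplicative — with intensities proportional to the target composition,
plus optional adduct/in-source satellites sharing the parent retention time
and decoy features rejection-sampled to sit further than 3× the tolerance
from every theoretical mass, so they are unidentifiable by construction.
Defaults are fixed at realistic acquisition conditions: total intensity 5e9
counts (typical summed ion intensity of such runs), 3 ppm mass noise (the
upper end of observed |Δppm| values), 0.03 min retention-time jitter
(typical replicate RT sd), 10% adduct and 5% in-source satellite rates, and
20 decoys.

What passing the end-to-end test shows: with ≤3 ppm noise and a 10 ppm
tolerance, the pipeline recovers a 44-structure composition within 0.5
percentage points per structure, the generating cross-linking index within
0.3, and matches zero decoys. What it does not show: robustness to
deconvolution artefacts the generator does not model — isotope-envelope
errors, co-eluting isomers with distinct structures, chromatographic peak
splitting, charge-state misassignment — nor MS/MS-level validation of
monomers, which remains an upstream manual step.

## Numerical choices and limitations

- Tolerance comparisons are inclusive (a feature at exactly ±10 ppm
  matches); the matcher brackets candidates with a slightly widened Da
  window and then applies the exact ppm criterion, so floating-point
  rounding of the bracket can never drop a boundary case.
- Problem sizes throughout the examples and tests are desk-scale by design:
  the full *G. oxydans* database is ~1400 entries (merged) and a simulated
  run ~60 features, which a single search traverses in well under a second.
- The parser accepts at most three subunits (trimers); higher multimers are
  rare in muramidase digests and outside the generated chemistry.
- Glycosidic polymerisation beyond the disaccharide subunit, O-acetylation,
  teichoic-acid anchors, isotope-pattern simulation and FDR estimation via
  decoy databases are out of scope.
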