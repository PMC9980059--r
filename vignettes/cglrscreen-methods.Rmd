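---
title: "Methods: motif curation, product deconvolution and binding analysis for cGLR screens"
author: "cGLRscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif curation, product deconvolution and binding analysis for cGLR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cGLRscreen)
```

# Scope and model of the data

cGAS-like receptors (cGLRs) are animal innate-immune enzymes that, upon
recognizing a pathogen-associated pattern such as dsDNA or dsRNA,
synthesize a cyclic dinucleotide (CDN) second messenger that activates a
downstream STING receptor. Discovering new cGLRs and characterizing
their products involves a chain of computational steps that this package
implements as a tested library: curating candidate enzymes by a
degenerate active-site motif, predicting ligand class from protein
charge, deducing the CDN product from a biochemical assay panel,
quantifying STING binding from EMSA titrations, and summarizing the gene
family across species. Each stage has a seeded synthetic-data generator
with recorded ground truth, so the whole pipeline is testable offline.

External computations that require databases or structure tools —
homology searching, multiple alignment, tree building, structure
prediction — are out of scope; their results enter only as annotation
columns (boolean curation flags, architecture labels).

# The motif grammar and curation rule

The active-site signature of catalytically competent cGLRs is written in
a small degenerate-motif language:

```
h[QT]GS [X8-20] [DE]h [DE]h [X50-90] h[DE]h
```

where uppercase letters are fixed residues, `[...]` are residue classes,
`h` is a named hydrophobic class, and `[Xm-n]` is a spacer of `m`–`n`
arbitrary residues. Two companion motifs are used in curation: the
`G[SG]` activation loop and the `[ED]h[ED] [X50-90] [ED]` catalytic
triad of acidic residues that coordinate metal ions during nucleotide
transfer.

Design choices a user should know:

* **Hydrophobic class membership.** `h` defaults to
  {A, C, F, I, L, M, V, W, Y}, the conventional strongly hydrophobic
  set used in motif curation; it is configurable in the pattern YAML
  because the boundary residues (notably G, T) are debatable.
* **Spacer semantics.** `[X8-20]` bounds are inclusive counts of
  residues *strictly between* the flanking anchors. Adjacent spacers
  are merged by summing bounds at parse time.
* **Coordinates.** All files and reports use 0-based half-open spans.
* **Non-standard residues** (B, J, O, U, X, Z) never satisfy a fixed or
  class anchor but do count toward spacer lengths — a conservative
  choice: an ambiguous residue cannot *create* a motif but does not
  destroy the spacing of an otherwise intact one.
* **All placements are reported.** The scanner enumerates every
  distinct combination of anchor positions (equivalently, of spacer
  lengths); curation requires at least one. The scanner is validated
  against an independent oracle that exhaustively enumerates spacer
  combinations and checks residues positionally.

A candidate is *retained* by `curateRecords()` iff (1) the sequence
contains the active-site motif together with the activation-loop and
catalytic-triad motifs, (2) it shares NTase-core/helix-bundle homology,
and (3) it has predicted structural homology to known cGLRs — criteria
(2) and (3) being externally supplied booleans. Whether the loop and
triad were historically treated as part of criterion (1) or as separate
requirements is ambiguous in common practice; we require all three by
default and expose `motifCriteria = "active_site_only"` to relax,
because the triad pattern is implied by the active-site pattern for
spacer lengths up to 88 of its allowed 50–90 and the distinction rarely
changes decisions. Every exclusion lists each failed criterion; a
missing external flag is an error naming the record, never a silent
default.

**Redundancy removal.** The published workflow used an external
clustering tool at minimum identity 0.95 and coverage 1. We
re-implement this as a deterministic greedy centroid scheme:
sequences are visited longest-first (ties by id), each joining the
first representative it matches. Identity is exact matches over
alignment columns of a global alignment (unit match, zero mismatch,
affine gap open 5 / extend 1); mutual coverage of a global alignment is
min length / max length. At the default thresholds this collapses
near-identical database variants while never merging genuinely
divergent paralogs, and its determinism makes cluster membership
reproducible.

# Isoelectric point and ligand-class prediction

Charge at a given pH is the Henderson–Hasselbalch sum over ionizable
groups counted from composition (side chains of D, E, C, Y, H, K, R
plus one free N- and C-terminus): positives contribute
$1/(1+10^{pH-pK_a})$ and negatives $-1/(1+10^{pK_a-pH})$. The net
charge is strictly decreasing in pH and the termini guarantee a sign
change in [0, 14], so the isoelectric point is the unique root, found
by bisection (default tolerance $10^{-3}$ pH).

The shipped default pKa table is the EMBOSS set (N-term 8.6, C-term
3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). The pI
algorithm cited in screening work does not publish its constants;
common tables differ by up to ~0.3 pH, so reported pI values are
table-dependent. The table is named in its YAML file and swappable; a
reported pI should always be read together with the table that produced
it. Every cysteine is treated as a free thiol (no disulfides or
modifications).

Class labels follow the screening convention: pI > 8.5 is
"nucleic-acid-sensor-like" (positively charged ligand-binding surface,
as for dsDNA/dsRNA sensors), pI < 7.0 "acidic" (candidate non-nucleic-
acid ligand), otherwise "intermediate". Comparisons are strict, so a pI
exactly at a threshold is intermediate.

# Cyclic dinucleotide chemistry

A CDN is two (base, ribose-donor) units joined cyclically; unit *i*'s
donor hydroxyl (2′ or 3′) forms the phosphodiester bond to its
partner's 5′ carbon. Under cyclic symmetry each molecule has a unique
canonical form: heterodimers order bases by the community naming
convention (GMP before AMP in cGAMP, UMP before AMP in cUA — the A
unit is named last), homodimers normalize mixed donors to 2′3′. The
linkage prefix gives the first-named base's donor, then the second's,
so `2'3'-cGAMP` is c[G(2′,5′)pA(3′,5′)p]. Each heterodimer base pair
therefore has 4 linkage isomers and each homodimer 3, giving 36
candidates over {A, C, G, U} with 10 distinct molecular formulas.

Formulas are NMP + NMP − 2 H₂O over the free-acid NMP compositions and
are donor-independent (linkage isomers are constitutional isomers).
Masses use atomic constants pinned in a versioned YAML (standard atomic
weights for the average mass, principal-isotope masses for the
monoisotopic). ESI adduct arithmetic is [M−H]⁻ = M − m(H⁺),
[M−2H+Na]⁻ = M − 2m(H⁺) + m(Na⁺), [M+H]⁺ = M + m(H⁺); the nominal
value is the half-away-from-zero rounded integer, matching instrument
summary reporting — for cyclic UMP–AMP the integer m/z values 634 and
656 coincide whether read as nominal or rounded monoisotopic, so both
are reported.

# Deconvolving the product from the assay panel

The biochemical screen identifies a product through four orthogonal
readouts: which α-³²P NTPs label it, resistance to CIP (a phosphatase
that removes terminal but not internal phosphates — intact cycles
always resist), per-base label fate after nuclease P1 (which cleaves
only 3′–5′ phosphodiester bonds, exposing a 5′-phosphate that CIP then
removes), and ESI m/z.

`predictSignature()` fixes the bond bookkeeping by the chemical
nomenclature: the α-phosphate of base X sits on X's own 5′ carbon, so
the bond donated by unit *i* contains the α-phosphate of *i*'s
partner. A 2′-donor bond is P1-protected; a 3′-donor bond is cleaved
and its phosphate lost to CIP. Hence for c[U(2′,5′)pA(3′,5′)p]
(`2'3'-cUA`) the adenosine α-phosphate sits in the protected 2′–5′
bond and the A label is retained while U is lost. Informal prose
descriptions of mixed-linkage digestion sometimes attribute the
linkages to bases the other way around (naming the bond by the base
whose ribose donates rather than whose phosphate it contains); the two
conventions are not reconcilable and this package follows the chemical
name, which is unambiguous. The convention only relabels which base
survives — inference round-trips are internally consistent either way.

For a homodimer the per-base readout must still be binary, so a base is
"retained" iff *any* of its α-phosphates survives in a protected bond.
A consequence the `distinguishabilityReport()` makes explicit: 2′2′ and
2′3′ homodimers are indistinguishable by the full panel (same base set,
mass, CIP resistance, and a surviving label either way); these four
pairs are the only residual ambiguity among the 36 candidates. All
heterodimer linkage isomers are fully resolved.

`inferProduct()` treats absent observation fields as unconstrained,
never as negative evidence, and is monotone: adding a field can only
shrink the consistent set. Mass matching defaults to ±0.5 Da for
integer-valued observations and ±0.02 Da for decimal ones. An empty
consistent set is reported with a closest-candidate diagnostic rather
than silently.

# Binding isotherm fitting

EMSA titrations are fitted to the single-site isotherm
$f(c) = c/(c + K_d)$ under the trace-ligand approximation, appropriate
to the assay regime (≈20 nM probe against protein up to 50 μM). No
Hill coefficient is fitted. Because published screen affinities are
reported as preference rankings rather than numeric constants, the
package validates the estimator by recovery: least squares over
log₁₀(K_d) on a deterministic 601-point grid spanning two decades
beyond the measured concentration range, refined by golden-section
search (tolerance 10⁻¹² on the log scale). Noiseless curves recover
K_d to better than 10⁻⁶ relative error; under Gaussian noise of
sd 0.05 on an 8-point, 10 nM–100 μM titration the median relative
error across 100 seeds is below 15%. The fit is exactly
scale-equivariant in concentration units. Degenerate curves (all-zero:
"no binding detected"; all-one: saturated) return a diagnostic flag
instead of an estimate.

# Census summaries

`copyNumberTable()` counts cGLR and STING records per species over a
complete roster (zero rows included) and tabulates (n_cGLR, n_STING)
frequencies — the data behind a copy-number bubble plot. Counts come
from supplied curated annotation tables; kingdom-scale published counts
depend on database snapshots and are not recomputed at desk scale. An
`excludeMab21` flag drops records marked Mab21-like, since whether
those developmental homologs belong in an immune census is a
per-analysis decision. `architecturePrevalence()` reports exact
percentage shares per domain architecture within a family, folding
every class with share strictly below 0.5% (configurable) into
"Other". Both summaries are invariant to record order.

# What the generators emulate — and what they do not

* `genMotifProteome()` plants exactly one concrete motif instance
  (spacer lengths uniform within bounds) at a random offset in an
  i.i.d. background (uniform by default, configurable to natural
  frequencies); decoys are rejection-sampled until provably
  pattern-free. This yields exact sensitivity/specificity truth but
  does not emulate homology structure, compositional bias or domain
  order of real proteomes — passing tests certify the scanner's
  correctness, not the biological specificity of the motif.
* `genScreenObservation()` is the forward model of the assay panel
  restricted to chosen fields, with optional Gaussian m/z jitter; it
  does not model partial digestion, TLC mobility or densitometry.
* `genBindingCurve()` adds i.i.d. Gaussian noise to the isotherm and
  truncates to [0, 1] (flagged); real gel quantification noise is
  heteroscedastic and correlated across lanes.
* `genCensusTable()` draws copy numbers and architectures i.i.d. per
  species; real copy numbers are phylogenetically correlated.

Every generator seeds a private RNG stream and restores the caller's
state, so identical configurations give byte-identical output.

# Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen so
each stage completes in seconds while still exercising every code
path: 200 random scanner-oracle cases, a 50+50 planted proteome, all
36 CDN candidates with every observation-field subset, 100 seeded
binding replicates, 100 random pI sequences against a 0.01-pH grid
oracle, and 1000-record census mixtures. Bisection tolerance is 10⁻³
pH; pI is reported to 2 decimals (1 decimal where compared to reported
values); prevalence percentages are exact internally and rounded to 1
decimal for display; mass arithmetic is exact to the pinned constants
and compared at the precision the source values are printed with
(2 decimals for the average mass, integers for nominal m/z).

# Known limitations

* Criteria (2)–(3) of curation are consumed, never computed: the
  package cannot rescue a record whose external annotations are wrong.
* The greedy centroid clustering is order-deterministic but, like all
  greedy schemes, can split a cluster that a globally optimal
  partition would merge when identities sit exactly at the threshold.
* pI values are table-dependent (see above) and ignore structural
  context, disulfides and post-translational modifications.
* Only cyclic *di*nucleotides are modeled; cyclic trinucleotides and
  linear intermediates are out of scope, as is MS/MS fragmentation.
* The binding model ignores ligand depletion and cooperativity; data
  from tight binders titrated near the probe concentration will bias
  K_d upward.
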