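---
title: "Methods: ITS2 sequence-structure discrimination of Ampelomyces"
author: "its2ss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS2 sequence-structure discrimination of Ampelomyces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `its2ss`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific problem

The nuclear rDNA internal transcribed spacer region (ITS1–5.8S–ITS2) is the
standard fungal barcode, but sequence distances alone often cannot separate
*Ampelomyces* mycoparasites — which live on powdery mildew colonies — from
unrelated fungi deposited in public databases under the same genus name.
The ITS2 spacer, however, folds into a conserved four-helix ("four-fingered")
secondary structure whose details differ systematically between the true
mycoparasites and the misattributed environmental sequences. `its2ss`
operationalizes that observation: it delimits the spacer, evaluates the
5.8S/28S proximal stem thermodynamically, folds and classifies the ITS2
structure, and measures whether combining sequence with structure produces a
barcode gap that sequence alone does not.

## Delimitation

Boundaries are located with degenerate consensus anchors for the 3' end of
18S, the first and last stretches of 5.8S, and the 5' start of 28S. Each
anchor is scanned with a mismatch budget (default 4); the best hit's
significance is an analytic E-value — the expected number of equally good
hits in an iid uniform sequence of the same length, computed from the exact
Poisson-binomial distribution of per-position mismatches. Hits are accepted
below E = 0.001. This replaces profile-HMM annotation with a transparent
equivalent: the HMM parameter files behind the published annotation service
are not public, while the significance threshold and the 150-nt minimum
ITS2 length are retained as gates. Coordinates are 0-based half-open
internally and 1-based inclusive in reports; the five regions (18S flank,
ITS1, 5.8S, ITS2, 28S flank) tile the input exactly.

## Nearest-neighbor thermodynamics

Stacking free energies (37 °C) and enthalpies for the six canonical pairs
ship as a versioned table (`inst/extdata/nn_stacks_v1.tsv`, tag
`turner2004-v1`); wobble-pair terms are approximate where no exact published
value was adopted. Loop penalties are simplified length-dependent terms
(tabulated short lengths with logarithmic extrapolation), and the
multibranch term is affine (closing 3.4, per branch 0.4, unpaired free,
kcal/mol). Three deliberate simplifications relative to the full 2004
parameterization: no terminal-AU penalties, no sequence-dependent loop
bonuses, no coaxial stacking. All energies are integer tenths of kcal/mol,
so an independent loop-decomposition in R reproduces the folding engine's
MFE *exactly* (the energy audit in the test suite).

The 5.8S/28S proximal stem is scored as the optimal antiparallel duplex
between the last 25 nt of 5.8S and the first 25 nt of the 28S flank
(window configurable): intermolecular initiation (+4.1 kcal/mol) plus
stacks, with bulge/internal penalties for interruptions; ΔH accumulates
along the ΔG-optimal pairing (loops treated as purely entropic). A 28S
flank shorter than the window yields an UNMODELABLE result rather than an
error, mirroring the large unmodelable fraction in real deposits that lack
the 28S head. The free-nucleotide pattern is read at the ITS2-proximal end:
exactly one free nucleotide per strand is the TYPICAL pattern. Stability
classes use the reported thresholds — DESTABILIZED above −15 kcal/mol,
FLEXIBLE in [−19, −15] (both boundaries inside the flexible band, matching
how the source placed −19 and −15), STABLE below −19.

## Folding, decomposition and classification

`fold_mfe()` is a Zuker-style dynamic program (hairpin / stack / bulge /
internal / multibranch; interior loops capped at 30 unpaired nt) with a
deterministic traceback preferring 5'-most pairing. `decompose_helices()`
takes the stems radiating from the exterior loop — descending through a
single basal stem into the first multiloop when one exists — orders them 5'
to 3' and labels them I–IV when exactly four are present; anything else is
flagged NOT-four-fingered, never an exception. The ring between helices I
and IV is the joined exterior span (3' side of IV followed by 5' side of I),
matching the circular layout of the molecule.

Classification is a fixed rule cascade, ties broken by rule order:
(a) not four helices → UNCLASSIFIED; (b) TCCATG-like ring with only the U-U
motif → PUTATIVE; (c) GTACCC-like ring with UGG → the Model 1 family, with
the U-substituted TTACCC ring reported as Model 7; (d) GTCTCC-like ring with
UGGU+UU and the 12-nt helix II terminal loop → Model 2, or Model 3 when
helix III shows four bulges; (e) A-rich II–III spacer with UGGU and an
internal loop in helix I → Models 4–6 (Model 6 on the 3-bp helix IV stack
closing a CCC loop; otherwise split on whether bulges or internal loops
dominate helix III — the source describes the Model 4/5 difference only as
"major variations" in those elements, so the bulge-majority convention is
our concrete reading). Ring matching tolerates one mismatch; because the
source text gives the Model 2 ring as GTCTCC while its figure legend shows
GTGTCC, both are accepted and the matched variant is recorded in the
evidence list. Sub-variant labels (M1-2, M2-1, M6-2, ...) appear in the
source only as figure annotations without structural definitions; the
classifier reports family labels with free-text evidence instead.

## Sequence-structure phylogenetics

Each folded ITS2 is encoded over 12 letters (4 bases × open-paired,
close-paired, unpaired). Alignment is progressive (UPGMA guide tree on
shared k-mer distances, affine-gap Gotoh profile merging with explicit
backpointers) plus one leave-one-out refinement pass. The published
simultaneous fold-and-align approach is replaced by fold-then-encode-then-
align; the published score set is adopted directly — sequence match 50 /
mismatch 0, structure weight 200 through a RIBOSUM-style state-agreement
matrix (identical states 1, opening vs closing 0.25, paired vs unpaired 0),
indel opening 800 and extension 50. Plain-sequence alignment uses a
200 PAM/k = 2 analogue (match 1.9 / mismatch −1.1, gap opening 1.53,
extension 0.123).

Distances use pairwise deletion. K2P is the closed form with optional
discrete-gamma correction; log-det follows the determinant formula with the
marginal-frequency normalization, and the gamma correction (shape 5 for
distances, per the study convention) is applied through the standard
transform −ln x → α(x^(−1/α) − 1) — how the original software combined
log-det with a gamma shape is unspecified, so this standard reading is
recorded here. Saturated pairs (non-positive log arguments or singular
joint matrices) are flagged, reported as missing, and only capped at 1.5×
the largest finite distance when a tree must be built.

Trees are neighbor-joining (negative branches clamped at zero and counted),
scored by a discrete-gamma K2P/TN93 log-likelihood via Felsenstein pruning
with per-site rescaling; branch lengths can be re-optimized by coordinate
descent (tolerance 1e-6, two sweeps) and the gamma shape estimated on the
fixed topology. Full maximum-likelihood topology search is deliberately out
of scope: at the 20–40-taxon scale of this analysis the NJ topology plus
likelihood scoring reproduces the clade structure that matters, which is
the acceptance surface. Bootstrap supports resample alignment columns
(default 1000 replicates, seeded).

## Group statistics

Lengths are normalized to the 697-bp maximum expected from the ITS1f/ITS4
primer pair and rendered at two decimals *by truncation*, which is the
convention the source tables follow (100·157/697 = 22.5251 prints as
22.52). Kruskal–Wallis uses the tie-corrected H (delegated to
`stats::kruskal.test`); Dunn z statistics carry the tie correction and are
reported two-sided with no multiplicity adjustment, computed only after the
omnibus test on the same groups. An ITS1 indel event is a distinct gap-run
signature — an identical maximal run of gap columns, counted once however
many rows share it; the event-based convention of the original
polymorphism software is not algorithmically published, so this concrete
convention is documented and its behaviour pinned by tests (it may differ
on overlapping gaps).

## The synthetic-data generator

The generator is constructive: rather than inverse-folding, each ITS2
template is assembled from four designed stems and linkers, and the MFE
folder is required to recover the planted structure exactly. Arm blocks
were selected by a design-time randomized search with four acceptance
conditions: exact structure recovery, folding energy inside the band
reported for the group (−47.3 to −36.8 kcal/mol for *Ampelomyces* models,
−35.9 to −25.8 for the putative pattern), correct model label, and label
stability ≥ 95% under per-record mutation. Two structural conventions make
this robust: all free loops strictly alternate A and C, so no contiguous
complementary partner exists anywhere in the molecule (A pairs only U/T,
C pairs only G, and neither letter occurs in a run), and diagnostic motif
loops carry the only G/T letters. Within-group ITS2 variation is applied as
compensatory pair flips (the two partners of a planted pair exchange
letters), which preserve the planted pairing while changing the sequence;
for the *Ampelomyces* groups one flip per record (~1.3% of ITS2 sites,
matching the ~1% within-group divergence default). The putative and
outgroup templates sit in a weak-energy band with little margin, so their
records carry no ITS2 mutation — their within-group divergence is planted
in ITS1 instead, and their between-group divergence comes from
deterministic heavy flips applied outside helix III (12 flips ≈ 15%
sequence divergence, the upper end of divergence reported within the
genus). The Model 2 template carries the classifier-relevant features
(12-nt helix II terminal loop, UGGU+UU, GTCTCC ring, U-U mismatch) but not
the published bulge micro-layout: 1-nt bulges proved placement-degenerate
under MFE folding (the fold re-registers them), so 1×1 internal loops
stand in.

ITS1 sequences are group templates with exact A/T composition
(*Ampelomyces* 0.59, others 0.52 — chosen so the whole-ITS A/T content of
generated *Ampelomyces* records falls in the reported 54.05–58.92% band),
per-record deletions drawn from a small shared pool of indel events
(placed uniformly, at the head, the tail, or both ends, per group), and 1%
random substitutions. Sharing the event pool is what keeps the distinct
indel signatures per alignment near the single-digit counts seen in real
data. The putative and outgroup ITS1 templates derive from one common base
(0%, 8%, 12% divergence), since those fungi are mutually related; the
*Ampelomyces* ITS1 is an independent sequence. Region lengths follow the
reported bands: ITS1 182–192 nt (*Ampelomyces*) vs 139–143 nt (others),
5.8S constant at 157 nt, ITS2 153 nt (M1 template) vs 157 nt
(putative-pattern templates), giving whole-ITS lengths of 492–502 vs
446–457 bp.

The 5.8S and 28S anchor motifs double as the proximal-stem strands: the
duplex core was designed numerically so the nearest-neighbor model yields
ΔG = −19.0 kcal/mol exactly and ΔH = −147.8 (the reported ensemble values
are −19 and −147.1) with one free nucleotide per strand.

What the generator does *not* emulate: sequencing noise, chimeras,
intragenomic ITS heterogeneity, IUPAC ambiguity codes, partial deposits
lacking anchors, and — importantly — realistic *between-group* ITS2
homology for the *Ampelomyces*-vs-putative comparison, whose designed
divergence is larger than typically observed between congeneric fungi.
Passing tests therefore demonstrate that the pipeline recovers designed
signal exactly and is internally consistent, not that the shipped defaults
reproduce the quantitative distance values of any particular real dataset;
between-group distances reported by the acceptance script describe the
synthetic design.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 19–36 records with 15–50
bootstrap replicates; the acceptance script uses the full-scale statistics
study (376 + 15 records) for delimitation, group summaries,
Kruskal–Wallis and indel counts, and a 36-record study with 1000 bootstrap
replicates for the sequence-structure stages — the same order as the
25-sequence structure analysis it emulates. All randomness flows from one
master seed through named sub-streams, and the bundle is bit-identical
under a fixed seed (verified by checksum in the acceptance suite).
Gamma-shape estimation on the synthetic alignments tends to the upper
optimization bound because the generator plants rate-homogeneous
variation; this is expected and reported as computed. Degenerate inputs
are handled explicitly: empty FASTA, missing anchors (NO_ANCHOR
conditions), inverted anchors (INCONSISTENT_ANCHORS), all-ambiguous
content, all-gap alignment columns (stripped with a warning), saturated
distances (flagged), and stage failures in the pipeline produce a partial
bundle with a machine-readable error summary.
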