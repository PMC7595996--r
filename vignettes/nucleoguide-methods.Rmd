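---
title: "Methods: nucleosome-map-guided sgRNA positioning"
author: "nucleoguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome-map-guided sgRNA positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoguide)
```

## What the package models

dCas9 fused to a strong activation domain (VPR) acts as a programmable
transcriptional activator: an sgRNA parks it at a chosen promoter position
and, if that position is productive, the downstream gene is induced. Two
physical constraints dominate whether a position is productive. First,
dCas9 binds poorly inside positioned nucleosomes, so the protospacer should
lie in a nucleosome-free region (NFR) of the promoter. Second, the activator
must sit at a distance from the transcriptional start site (TSS) from which
it can contact the pre-initiation complex: too far and nothing happens, too
close and the bound dCas9 itself obstructs transcription (the CRISPRi
regime). `nucleoguide` operationalises both constraints from data a lab can
actually produce — an MNase-seq run and a genome annotation — and carries
the design through to orderable cloning oligos and a qPCR readout.

## Occupancy profiles

MNase digestion leaves ~147 bp of nucleosome-protected DNA, so paired-end
fragments are filtered to a mononucleosome window (default 100–200 bp; the
source data for such maps is typically PE50 sequencing) and piled into
per-base coverage, the representation used for the nucleosome occupancy
maps the design is based on. Fragment-midpoint (dyad-density) profiles are
available as an alternative estimator, but coverage is the default because
it is what the border-offset geometry below was defined against.

Peak positions on raw coverage are noisy, so the profile is convolved with a
normalised Gaussian kernel before peak calling. The default bandwidth of
σ = 20 bp was chosen once as the widest kernel that still cleanly separates
dyads of adjacent nucleosomes at the ~165 bp repeat typical of fungal
chromatin; it is a parameter, not a constant. The kernel is truncated at 4σ
and renormalised at the chromosome ends, which makes a constant profile an
exact fixed point and conserves interior signal to well within 0.1 %.

No depth normalisation is applied by default: dyad calling uses prominence
*relative to the profile maximum*, which is invariant under global scaling.
An optional mean-scaling (`meanScaleProfile()`) exists for cross-condition
display.

## Dyad calling and the 75-bp border rule

A nucleosome dyad axis is operationalised as a local maximum of the smoothed
profile. Three numerical choices make the call deterministic:

* **Plateaus.** The leftmost base of a maximal plateau is the dyad. Smoothed
  integer coverage can produce exact ties; taking the leftmost base makes
  output byte-stable.
* **Prominence filter.** A peak's topographic prominence (height minus the
  higher of the two bounding minima, scanning outward until strictly higher
  ground or a chromosome end) must reach 5 % of the profile maximum. This
  suppresses ripple maxima on nucleosome shoulders without touching real
  dyads; at a chromosome end the missing side is treated as open ground so
  that terminal nucleosomes remain callable.
* **Greedy separation.** Candidates are retained in descending height order
  subject to a minimum mutual separation of 120 bp — below the nucleosome
  repeat, comfortably above the smoothing scale, so two calls can never land
  on one nucleosome.

Between each adjacent retained dyad pair, the NFR is delimited by stepping a
fixed offset of **75 bp** inward from each dyad axis — half a nucleosome
(~73 bp of DNA on each side of the dyad) rounded to the offset used when
such maps are drawn. In the emitted BED (0-based half-open) coordinates the
region is `[d1 + 75, d2 − 75)`: both boundary coordinates are exactly 75 bp
from their dyad and the width is the dyad separation minus 150. Whether the
border *base itself* is counted inside or outside the nucleosome footprint
is not decidable from the geometry alone; this package fixes the half-open
convention above, under which no NFR base lies strictly closer than 75 bp
to a dyad axis and the arithmetic `width = separation − 2·offset` holds
exactly. Candidates narrower than 20 bp are discarded — real promoter NFRs
of interest are ~50 bp and up, and anything narrower is indistinguishable
from jitter between adjacent dyad calls — and no region is emitted outside
the outermost dyads, because the rule requires a flanking dyad on each side.

When maps from two growth conditions are available (e.g. active growth vs
stationary phase), `compareConditions()` classifies regions as shared or
condition-specific by reciprocal overlap (default 50 %, 1-to-1 pairing by
greatest overlap, leftmost partner on ties), and `combineNfrConditions()`
defaults to the **intersection** of the two NFR sets for ranking: a guide
valid under both conditions is the conservative choice when the activation
condition is not identical to the mapping condition.

## Guide enumeration and off-target vetting

`scanProtospacers()` enumerates every position, on both strands, where a
20-nt spacer is immediately followed (in sgRNA orientation) by an `NGG`
PAM. Spacers containing `N` are excluded as unsynthesizable. Off-targets are
counted by **exhaustive Hamming-distance enumeration** over every
PAM-adjacent locus in the genome, tallied by mismatch tier 0–3 with the
on-target locus excluded. A sequence-similarity search tool could stand in
here, but exact enumeration is deterministic, has explicit tier semantics,
and is strictly more stringent than a heuristic aligner; bulges (indels) are
not modelled because the vetting is defined as match/mismatch only. The
default filter keeps guides with zero exact and zero one-mismatch
off-targets; two-mismatch counts are reported but not filtered, since the
tolerance a user should apply depends on the experiment.

## Ranking

Each candidate is scored in `[0, 1]` as a weighted sum (defaults 0.4 NFR,
0.4 distance, 0.2 off-target) of:

* **NFR membership** — the fraction of spacer bases inside NFRs (1 when
  fully contained). A fractional score, rather than a binary one, lets
  guides straddling an NFR border rank between inside and outside guides.
* **Distance component** — 1 on the closed window **42–210 bp** upstream of
  the TSS, measured TSS to spacer centre, tapering linearly to zero over one
  window width on either side. The window bounds come from reported
  systematic promoter-walking experiments with dCas9 activators; they are
  `rankingConfig()` defaults, not constants, because their transferability
  across organisms is explicitly uncertain. The reported preference for
  distances below 110 bp is carried as a `preferred` annotation and does
  **not** deform the component — the score is maximal on the whole window,
  and the ranking tie-break (smaller |TSS distance| at equal totals) already
  favours closer guides.
* **Off-target component** — `1 / (1 + Σ wₖ nₖ)` with tier weights
  1, 0.5, 0.2, 0.1. Any exact off-target more than halves the component;
  distant tiers decay geometrically. Monotonicity (more off-targets never
  help) holds by construction and is property-tested.
* **CRISPRi exclusion** — the total is forced to 0 when any spacer base
  comes within 30 bp of the TSS or lies downstream of it. The blockade risk
  near the TSS is well documented but unquantified; 30 bp keeps the ~30 bp
  dCas9/sgRNA footprint clear of the TSS and is configurable.

The spacer **centre** is the distance reference because it is
strand-symmetric; PAM-proximal or PAM-distal ends would make `+` and `−`
guides at the same physical position score differently.

Ranking is a stable sort: descending total, then smaller |TSS distance|,
then `+` strand before `−`, then leftmost coordinate — identical inputs
yield byte-identical output.

**Bidirectional promoters.** Divergent gene pairs whose TSSs lie within
600 bp (twice the ~305 bp control regions that motivate the feature, to
give headroom without capturing unrelated neighbours) share one promoter
region. A guide there is scored independently against both TSSs and both
scores are always reported; the higher-scoring gene is labelled the primary
predicted target, but observed activation in such promoters does not
reliably follow guide proximity — a guide has been seen to activate the
*distal* gene of a pair orders of magnitude more strongly — so the
secondary score is explicitly not a prediction of inactivity.

**Multiplexing.** Single guides frequently fail to activate where
combinations of two or four succeed, so `selectMultiplex()` warns on
`k = 1`. Selection is greedy in rank order with a minimum pairwise
spacer-centre spacing of 30 bp (clearing the dCas9 footprint so multiplexed
guides do not compete). Greedy rather than optimal: candidate counts are
small, the greedy rule is transparent and deterministic, and an exhaustive
subset-search oracle in the test suite confirms the greedy characterisation
on randomized instances.

## Cassette output

For Pol II-expressed sgRNAs the functional guide must be released from the
transcript: the insert carries a hammerhead ribozyme whose first six bases
are the reverse complement of the spacer's first six (closing the
ribozyme's stem against the spacer), followed by a fixed catalytic core and
the spacer; the HDV ribozyme and tracrRNA scaffold reside on the
destination plasmid downstream of the cloning site, so the insert/backbone
split matches annealed-oligo insertion into a pre-cut vector. The catalytic
core and the single-stranded overhangs are configuration data, not logic:
the defaults follow the published hammerhead–sgRNA–HDV scheme, but the
exact overhangs depend on the destination backbone (for an Eco91I site,
5-nt `GTNAC`-class overhangs, which `scheme = "Eco91I"` enforces by length)
and must be confirmed by the user.

## Expression readout

`foldChange()` implements the Livak 2^-ΔΔCt method with two deliberate
choices where practice varies:

* **Technical replicates are averaged before ΔCt**, the standard Livak
  order of operations; per-fold averaging is recoverable from the
  per-sample table for sensitivity checks.
* **Dual references are combined as the arithmetic mean of the per-gene
  mean Cts** by default; `refCombine = "separate"` reports each reference
  on its own, so both views are recoverable.
* The **group fold is the mean of per-replicate folds**, with the
  exponentiated mean ΔΔCt reported alongside (`fold_from_mean_ddct`) —
  the two differ under noise and sources rarely say which was used, so both
  are printed.

Primer pairs outside 90–110 % efficiency are excluded (inclusive bounds).
Significance is a two-sided, equal-variance Student's t test on per-sample
ΔCt values, annotated `*` (p < 0.05) / `**` (p < 0.01); the degenerate
zero-variance case resolves to p = 1 at equal means by convention. Fold
changes are invariant under any global Ct shift, which the suite asserts.

## The synthetic-locus simulator

The simulator is first-class, tested code; it defines the conditions every
stochastic guarantee is stated under. `simulateGenome()` draws i.i.d. bases
at a requested GC content (default 0.5) and places gene models on a regular
layout that always includes one divergently transcribed pair, with TSS
separation fixed at 305 bp by default — the size of the compact
bidirectional control regions the ranking must handle.
`plantNucleosomes()` lays dyads on a 165-bp lattice (a typical fungal
nucleosome repeat) outside promoter NFR windows (default width 150 bp,
proximal border 30 bp upstream of the TSS), anchoring the flanking dyads
exactly 75 bp outside each window; the recorded truth NFRs are recomputed
from the *realized* dyads so the border-offset invariant holds by
construction even under jitter. `simulateFragments()` draws fragment
centres around each dyad with 10 bp Gaussian jitter (a fixture knob
emulating MNase trimming variability, not a biological claim) and lengths
from a clipped Normal(147, 15). `simulateQpcr()` plants an exact fold
change by shifting treated target Cts by −log2(fold).

What the simulator deliberately does **not** emulate: sequence-dependent
nucleosome affinity, MNase sequence bias, fuzzy or shifted nucleosomes,
copy-number or mappability artefacts, and amplification noise structure in
qPCR. Passing the recovery tests therefore demonstrates that the
algorithmic chain is correct under phased, well-sampled chromatin — it does
not certify performance on poorly phased real loci, where smoothing
bandwidth and prominence thresholds may need adjustment.

All simulators take an explicit seed, restore the caller's RNG state, and
are byte-reproducible given (parameters, seed).

## Problem sizes and verification

The test suite cross-checks every core operation against an independent
brute-force oracle on randomized instances (per-base counting for coverage
and dyad density; exhaustive local-maxima enumeration plus greedy
suppression for dyad calling; per-offset scanning for protospacer
enumeration; full Hamming enumeration for off-targets; key-sort and
exhaustive subset search for ranking and multiplex selection), 100 trials
each on 0.2–2 kb instances. The flagship stochastic property runs the full
simulate → profile → smooth → call → delineate pipeline on 40 kb worlds
with 8 genes at 30 fragments per nucleosome and requires ≥ 90 % of planted
NFRs of width ≥ 80 bp to be recovered with both borders within 20 bp —
comfortably met (border errors are typically ≤ 5 bp). These sizes were
chosen as the smallest instances that exercise every code path, including
merged divergent-promoter NFRs.

## Known limitations

* Activation *magnitude* is not predicted; the score orders positions, and
  positions 50 bp apart have produced thousand-fold different outcomes in
  bidirectional promoters for reasons the positional model cannot see.
* TSSs default to annotated gene starts; where RNA-seq-derived TSSs exist
  they should be injected via the TSS override table, and promoter regions
  overlapping a neighbouring gene's UTR can be excluded by passing a mask —
  no automatic UTR-overlap rule is imposed, since none is established.
* The off-target model is mismatch-only over a fixed PAM; Cas variants with
  other PAMs can be expressed via `pamPattern`, but bulges and non-NGG
  seed-dependent tolerance models are out of scope.
* Dyad calling reports position, height and prominence only; fuzziness and
  occupancy statistics beyond prominence are not modelled.
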