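# nucleoguide

Nucleosome-map-guided sgRNA positioning for dCas9-based transcriptional
activation (CRISPRa) in fungi and other compact genomes.

## The problem

Fusing a nuclease-dead Cas9 (dCas9) to a tripartite VP64–p65–Rta (VPR)
activation domain turns CRISPR into a programmable transcription activator:
express the right sgRNA and the activator is parked on the promoter of a
silent gene — for example a transcription factor inside a silent secondary
metabolite biosynthetic gene cluster. Whether anything happens, though,
depends almost entirely on *where* the activator lands:

* the protospacer should not be buried inside a positioned nucleosome but lie
  in a **nucleosome-free region (NFR)** of the promoter;
* the spacer centre should sit an appropriate distance upstream of the
  transcriptional start site (TSS) — systematic promoter-walking experiments
  with dCas9 activators place the productive window at roughly **42–210 bp
  upstream**, with a preference for distances below 110 bp;
* a guide binding **too close to the TSS** blocks transcription instead
  (CRISPRi) and must be excluded;
* the spacer must be **unique enough** genome-wide to avoid off-target
  activation.

`nucleoguide` implements this whole design loop as composable, tested R
functions: MNase-seq fragments → per-base occupancy profiles → dyad axes and
NFRs → PAM-anchored protospacer enumeration with exhaustive off-target
vetting → NFR/TSS-aware ranking (including divergent gene pairs sharing one
bidirectional promoter, and multiplex guide sets) → ribozyme-flanked cloning
oligos → a 2^-ΔΔCt qPCR readout of the resulting activation.

## The model in brief

**Occupancy.** MNase-protected fragments (filtered to the mononucleosome
window, default 100–200 bp around the canonical 147 bp) are piled into
per-base coverage. A Gaussian kernel (default σ = 20 bp) smooths the profile.

**Dyads and NFRs.** Nucleosome dyad axes are the peak maxima of the smoothed
profile (greedy retention by height, minimum separation 120 bp, prominence ≥
5 % of the profile maximum). Between each adjacent dyad pair `(d1, d2)` the
nucleosome-free region is the interval left after stepping a fixed
**offset of 75 bp** inward from each dyad axis: in BED (0-based half-open)
coordinates

```
NFR = [d1 + 75, d2 − 75),   width = d2 − d1 − 150,
```

so both NFR borders are exactly 75 bp from their adjacent dyad axis. Regions
narrower than 20 bp are suppressed, and nothing is called outside the
outermost dyads.

**Guide score.** Each candidate `NGG`-PAM protospacer is scored in `[0, 1]`
as a weighted sum (defaults 0.4 / 0.4 / 0.2) of

* NFR membership — fraction of spacer bases inside an NFR;
* TSS distance — 1 on the closed window `[42, 210]` bp upstream
  (spacer-centre to TSS), tapering linearly to 0 over one window width;
* off-target burden — `1 / (1 + Σ wₖ·nₖ)` over Hamming mismatch tiers
  `k = 0..3`, counted exhaustively over every PAM-adjacent locus of the
  genome;

with the total forced to 0 for any guide whose spacer comes within 30 bp of
the TSS or crosses it (CRISPRi exclusion). Multiplex sets are chosen
greedily in rank order with a minimum spacer-centre spacing of 30 bp —
single guides frequently fail where combinations of two or four activate
strongly, so `k = 1` designs trigger a warning.

**Readout.** Activation is quantified by the Livak 2^-ΔΔCt method against
dual reference genes (technical replicates averaged first, reference Cts
arithmetically averaged, primer efficiencies restricted to 90–110 %), with a
two-sided equal-variance Student's t test.

## Worked example

Everything below runs on a synthetic locus with planted ground truth — no
external data needed.

```r
library(nucleoguide)

locus   <- simulateLocus(seed = 7)                      # 20 kb, 4 genes, phased arrays
frags   <- simulateFragments(locus, fragmentsPerNucleosome = 30, seed = 7)
profile <- smoothProfile(coverageProfile(frags, "chr1", 20000), bandwidth = 20)
nfrs    <- delineateNfrs(callDyads(profile), offset = 75, condition = "15h")
nfrs[1]
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames    ranges strand | left_dyad right_dyad   condition
#>   [1]     chr1 1823-1969      * |      1748       2045         15h
```

The first called NFR spans the planted promoter gap of `gene1`; its borders
sit exactly 75 bp inside the flanking dyad axes (1748 and 2045). Designing
guides for that promoter:

```r
genome  <- locusGenome(locus); genes <- locusGenes(locus)
gene    <- genes[genes$gene_id == "gene1"]
prom    <- promoterRegion(gene, upstream = 600)
sites   <- scanProtospacers(prom, genome)                # 87 NGG-PAM sites
reports <- countOfftargetsAll(sites, genome)
kept    <- filterCandidates(sites, reports)              # 0 exact / 1-mm off-targets
scores  <- do.call(rbind, lapply(seq_along(kept), function(i)
  scoreGuide(kept[i], prom, gene, nfrs, reports[[i]])))
head(rankGuides(scores), 1)[, c("rank", "tss_distance", "nfr_component", "total")]
#>   rank tss_distance nfr_component total
#> 1    1           44             1     1
```

The top guide sits 44 bp upstream of the TSS, fully inside the NFR, and is
genome-unique. `selectMultiplex(ranked, k = 4)` picks four such guides at
least 30 bp apart, and `emitOligos()` turns each spacer into an annealed
oligo pair whose insert carries a hammerhead ribozyme whose first six bases
are the reverse complement of the spacer's first six:

```r
emitOligos("GATCGATCATTTTGGTAAGC")
#> CassetteInsert
#>  spacer:  GATCGATCATTTTGGTAAGC
#>  insert:  TCGATCCTGATGAGTCCGTGAGGACGAAACGAGTAAGCTCGTCGATCGATCATTTTGGTAAGC (63 nt)
```

Finally, the expression readout on a simulated Ct table with a planted
30-fold activation:

```r
ct <- simulateQpcr(trueFold = 30, ctNoiseSd = 0.2, nBio = 3, seed = 7)
foldChange(ct, "mdpE", c("actA", "benA"),
           treated = attr(ct, "treated"), calibrator = attr(ct, "calibrator"))
#> FoldChangeResult: mdpE vs actA+benA
#>  mean fold 30.1 (2^-mean ddCt: 29.46), t = -22.4, p = 2.33e-05 **
```

## Scope notes

The package consumes alignments (SAM/BAM) or fragment intervals (BED); read
mapping itself is out of scope. Absolute activation magnitudes are wet-lab
outcomes and are deliberately not modelled — the ranking predicts *where* to
put the activator, not *how much* transcription results. Default cassette
overhangs are placeholders: users cloning into their own backbone must
supply the overhangs matching their restriction scheme.
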