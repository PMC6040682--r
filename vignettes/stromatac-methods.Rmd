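---
title: "Methods: chromatin accessibility dynamics and Alu exaptation in stromatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility dynamics and Alu exaptation in stromatac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stromatac` analyses two-condition ATAC-seq data from decidualizing
endometrial stromal cells: which regions open or close, which transcription
factor motifs drive the change, whether those motifs are bound (footprinted),
how the composite ESR–bZIP–Pax triple motif relates to Alu elements, whether
specific Alu copies are conserved across primates, and whether chromatin
dynamics track the expression of nearby genes. This vignette documents the
models, the tunable parameters, the synthetic-data generator the tests run
against, and the design decisions taken where the underlying procedure was
open to interpretation.

## Differential accessibility

Fragments are counted into peaks with a union rule: a fragment increments
every peak it overlaps by at least one base (coordinates half-open, so an
abutting fragment does not count). The two-condition test is a deliberately
transparent negative-binomial Wald test rather than a full DESeq2-style
pipeline:

* **Normalization** — median-of-ratios size factors over peaks with
  all-positive counts.
* **Dispersion** — per-peak method-of-moments estimates
  $\hat\alpha_i = (s_i^2 - c\,\bar q_i)/\bar q_i^2$ on normalized counts
  (pooled within-condition variance, Poisson part corrected for size
  factors), then a mean–dispersion trend
  $\alpha(\mu) = a_0 + a_1/\mu$ fitted by least squares to the raw
  (unfloored) estimates. The trend value, floored at $10^{-8}$, supplies the
  dispersion in the standard error. At 3+3 replicates the raw per-peak
  estimates have ~4 degrees of freedom; using them directly inflates the
  null tail of the Wald statistic severely (a peak whose dispersion is
  underestimated can show a 2–3× inflated z), which is fatal for
  Bonferroni-scale classification. The trend removes that noise without any
  per-peak shrinkage machinery; the raw estimates remain available via
  `dispersion = "per_peak"`. Crucially the trend is fitted to the unfloored
  estimates — flooring negative moment estimates before fitting biases the
  trend and was measurably anticonservative in null calibrations.
* **Statistic** — the log2 fold change of normalized condition means with a
  0.5 pseudocount (so all-zero groups stay finite), divided by its
  delta-method standard error; two-sided normal p-values; Bonferroni
  adjustment (`min(1, p·m)`) as the classification criterion, matching the
  stringent criterion used for the published opening/closing counts.
* **Ranking** — peaks with positive fold change take ranks $1..k$ by
  ascending p; negative fold changes take the top ranks so that the most
  significant closing peak is ranked last; zero-fold-change peaks sit
  between, by descending p. Ties break by input order (stable sort), making
  the ranking a deterministic permutation of $1..m$.

Degenerate inputs: all-zero peaks are reported with `log2fc = 0`,
`p = 1` by convention; a condition with fewer than two samples is an error.

## PWM scanning and calibration

PWMs carry a pseudocount mixed with the background
($p' = (p + \epsilon b)/(1+\epsilon)$, default $\epsilon = 10^{-3}$) so
log-odds scores are finite. The hit threshold at a target p-value is
computed from the exact distribution of the score of a background-drawn
sequence, by position-wise convolution over scores discretized to a
granularity of $10^{-3}$ bits by default; the discretization error of any
score is at most $L \times$ granularity, and the scanner uses the same
integer grid as the calibration so scan and threshold can never disagree.
The threshold is the smallest *achievable* score with tail probability at
most $\alpha$; for a degenerate PWM (e.g. uniform) where no score is rare
enough, the maximum achievable score and its tail probability are reported.
Both strands are scanned; minus-strand hits are scored with the
reverse-complemented matrix at the same coordinates. The default per-motif
$\alpha$ is $10^{-4}$, the customary FIMO default.

Matched backgrounds are sampled within ±50 kb of TSSs, one candidate width
per input peak, matching the input's GC fraction to a 0.05-wide bin and its
CpG observed/expected ratio — `#CG × length / (#C × #G)`, the standard
definition — to a 0.1-wide bin, without replacement. If no candidate matches
after `max_tries` draws the nearest candidate is used and the fallback is
counted in the output (and warned about).

## The triple motif

The published composite motif gives an order (ESR, then bZIP, then Pax along
the strand) but no spacings. The scanner's defaults are: all three hits on
the same strand, in that order, each inter-hit gap between 0 and 15 bp, and
a total span of at most 50 bp (the window size used for the motif-context
search). All four choices are configurable arguments. Overlapping
arrangements are each reported, in deterministic (sequence, start, strand)
order, and the scanner is tested for exact equality against a brute-force
join over all component-hit triples. Component PWMs are inputs; the package
ships sharp synthetic stand-ins (`synthetic_pwms()`,
`inst/extdata/motifs_synthetic.meme`) — they are explicitly *not* database
PWMs for ESR1, AP-1 or Pax proteins.

Triple-motif hits are assigned to the repeat containing their midpoint; the
"3' half" of a repeat instance is determined strand-aware (for a
minus-strand element the genomic left half is its 3' half).

## Footprints

Tn5 cut sites are taken at fragment start + 4 and fragment end − 5 (0-based)
— the community-standard offsets for the transposase's 9-bp stagger;
fragments shorter than 10 bp are skipped. Profiles aggregate cuts in 200-bp
windows centered on motif midpoints, oriented by hit strand (minus-strand
windows are flipped end-for-end and the strand labels swapped), and divided
by the number of sites. The footprint statistic is a transparent pair rather
than a Wellington re-implementation:

* `depth` $= \log_2\frac{\text{mean flank cuts} + \varepsilon}
  {\text{mean core cuts} + \varepsilon}$, core = the central motif-width
  bases, flanks = 50 bp on each side, $\varepsilon = 0.5/n_{\text{sites}}$;
* `asymmetry` $= (P_{5'} - P_{3'})/(P_{5'} + P_{3'})$ over plus-strand cuts
  in the two flanks, positive when plus-strand cuts pile up 5' of the motif.

One subtlety the tests encode: flipping all hit strands negates the
asymmetry only for strand-agnostic cut patterns. The physical footprint
pattern (plus-strand excess 5', minus-strand excess 3') is itself
mirror-symmetric, so occupied sites show *positive* oriented asymmetry on
both strands — which is exactly what the aggregate plots of bound motifs
show. No Tn5 sequence-bias correction is applied, matching the published
analysis.

## Repeats in consensus coordinates

Genomic positions are mapped onto repeat consensus coordinates by
strand-aware proportional scaling
(`round(p_along / instance_length × consensus_length)`), not per-instance
alignment. For the length-filtered, near-full-length copies these analyses
use (≥ 280 bp for conservation, ≥ 300 bp for profiles, per the two published
cut-offs), the approximation is within a few bases; it is documented as an
approximation and would be inadequate for heavily rearranged copies.
Per-position conservation is reported as information content
$\ln 4 - H$ in nats (with a pseudocount of 0.25 per base and columns under
10 observations flagged); the package follows the published figure's
convention that *higher* values mean *higher* conservation, i.e. the
quantity is information content rather than raw entropy.

Family-level enrichment builds the bp-resolution 2×2 table (peak bp ×
family bp over the genome) and applies a two-sided Fisher exact test in its
hypergeometric form (usable at genome-scale counts where the network
algorithm is not). Two caveats are deliberate: the analytic expectation from
bp fractions can be cross-checked against a seeded interval shuffle
(`n_shuffle`), and the bp-level p is anticonservative under block placement
of peaks — bases within one peak are not independent — so the package's null
tests assert a calibrated odds ratio rather than a uniform p. This matches
how such tables behave in practice (published family-level tests of this
kind report p < 10⁻¹⁵ routinely).

The 5'-vs-3' end asymmetry test marks each instance's strand-aware terminal
windows (50 bp), keeps instances where exactly one end overlaps a peak, and
applies a two-sided exact binomial at p = 0.5. The exact binomial p is
discrete and stochastically dominates the uniform under the null, so
null-calibration tests check for the absence of anti-conservatism at several
levels rather than applying a Kolmogorov–Smirnov test that would reject any
discrete statistic.

## Cross-species presence/absence

For each tracked Alu copy, two 100-bp queries span the element boundaries
(50 bp outside + 50 bp inside, read 5'→3' along the element). Queries are
mapped with an internal seed-and-extend aligner — exact 13-mer seeds voting
for diagonals, ungapped +1/−2 scoring, candidates clustered within 20 bp —
so the tests need no external aligner; blast-style 12-column tabular input
is accepted as a drop-in replacement. A query is "mapped" when its best
cluster beats the runner-up by ≥ 5 score units and its best segment reaches
80% identity over ≥ 40 bp. The 40-bp floor is deliberate: an absent element
leaves only the 50-bp outer flank half alignable, so a floor above 50 bp
would make absence undetectable by construction.

The decision rule is explicit because the published text does not state
one. Both element boundaries are projected through their flank alignments;
with `D` the inferred element span (distance between projected boundaries —
for an intact locus `D ≈` element length, for a clean deletion `D ≈ 0`):

* `present` if `|D − L| ≤ 0.3 L` *and* both junction halves (the inner
  50 bp of each query) align at ≥ 60% identity (junction support is
  optional via `require_junction = FALSE`, since it is unknowable whether
  the original analysis required it);
* `absent` if `D ≤ 60` bp;
* otherwise, or when either query is unmapped / the two hits disagree in
  contig or orientation, `inconclusive`.

All tolerances are arguments. Loci excluded at query extraction (too close
to a contig edge) never appear in the matrix.

## The synthetic-data generator

The generator's defaults are the package's study conditions: 5000 peaks of
400 bp with 200 opening and 50 closing at a planted log2 effect of 2,
negative-binomial counts with dispersion 0.05 (typical for well-controlled
cell-culture ATAC replicates) at a median of 100 fragments per peak per
sample, 3+3 replicates, fragment lengths uniform on 60–120 bp (a
nucleosome-free-range simplification), 15% off-peak background fragments,
and per-sample depth factors log-normal with σ = 0.1. Motif-bearing peaks
are sampled with a 6× preference for opening peaks — motif-driven opening —
which produces the decreasing motif frequency along the accessibility
ranking seen in the real data. Occupied motif sites suppress 80% of the
Tn5 cuts falling in their core and attract motif-spanning fragments (rate
0.25 of the peak count) whose cuts land immediately 5' (plus strand) and 3'
(minus strand) of the core.

The Alu model is a fixed 300-bp synthetic consensus whose 3' half carries
the ordered ESR/bZIP/Pax sites (gaps of 5 bp, span 41 bp) and a 12-bp
poly-A tail; copies diverge by 8% per copy *outside* the protected motif
core, truncations keep the 3' end with a 170-bp floor so the planted core
always lies in the instance's 3' half. The divergence is not cosmetic: it
is what makes flank-query mapping unique, because a decoy hit of the
Alu-derived inner flank half at another copy scores well below the
orthologous locus.

Species genomes descend from a five-tip primate-like tree (chimp, human,
rhesus, two New World monkeys, and a galago outgroup). Each Alu locus
originates on an edge of the root-to-reference path (probability
proportional to branch length), is present exactly in the clade below that
edge, and is spliced out of the genomes of all other species; substitutions
accumulate at `substitution_rate × patristic distance` from the reference
(default rate 0.05 per unit branch length). This yields the expected
conservation gradient — near-complete in the chimpanzee, intermediate in
New World monkeys, zero in the strepsirrhine outgroup.

What the generator does **not** emulate: nucleosome positioning, Tn5
sequence bias, GC-dependent coverage, paralogous flank sequence, indels
other than whole-element deletions, diploidy, and graded effect sizes
(dynamic peaks all share one planted effect). Passing tests therefore show
that the implementations recover the structures they model, not that the
pipeline is robust to every artifact of real libraries.

Determinism: every stage derives an independent stream from the master seed,
and equal seeds give byte-identical outputs, including the on-disk files.

## Linkage

Peaks link to every gene whose TSS lies within 10 kb (signed strand-aware
distances, negative upstream); an optional interaction table restricts but
never extends the links. For the expression comparison, the genes linked to
the `n_top = 100` lowest-rank and `n_top` highest-rank peaks form the two
groups; a gene linked to both goes with its lowest-ranked (most opening)
peak — first-rank precedence, which in dense simulations avoids diluting
the closing group with genes that are actually driven by a top opening
peak. `n_top` counts peaks, not genes (the published "100 genes" is
ambiguous on this point). The default test is Welch's t — the groups have
no reason to share a variance — with the pooled-variance Student variant
available via `classic = TRUE` to match the published label.

## Problem sizes

The test suite and the acceptance script run the full design (5000 peaks,
20-Mb genome, ~3 million fragments) for the differential-accessibility and
linkage stages, and a 400-kb sequence-level study (200 peaks, ~70 Alu
copies, 5 species genomes) for the motif, footprint, repeat and
conservation stages; null calibrations use 250-peak simulations across 20
seeds. These sizes give every statistic enough events to be scored sharply
(e.g. ~250 dynamic peaks, ~30 informative end-asymmetry instances, ~300
presence/absence calls) while keeping a full run in minutes on one core.

## Known limitations

* The NB test is intentionally simple: no per-peak empirical-Bayes
  dispersion shrinkage, no fold-change shrinkage, no outlier refitting; on
  real data with peak-specific dispersion the trend assumption is cruder
  than DESeq2's.
* Proportional consensus mapping ignores internal indels in repeat copies.
* The internal flank mapper is ungapped; a target lineage with indels in
  the flanks would push loci to `inconclusive` rather than mis-call them.
* bp-resolution Fisher tests on interval overlap are anticonservative under
  block placement; treat their p-values as orderings, not calibrated error
  rates (the odds ratio is the interpretable quantity).
* The footprint statistic summarizes aggregate profiles; it does not call
  per-locus occupancy.
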