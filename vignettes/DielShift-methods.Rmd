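---
title: "DielShift: methods and design notes"
author: "DielShift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DielShift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DielShift)
```

# The analysis problem

Picophytoplankton such as *Micromonas* synchronize division and gene
expression to the light:dark cycle. A classic experimental design to probe
their photophysiology shifts mid-exponential, light:dark-acclimated
cultures to high light (HL), or to high light plus UV radiation (HL+UV),
a few hours into the light period, and then follows three data streams:

* **3'-biased, non-directional tag RNA-seq** of chloroplast and nuclear
  transcripts, sampled in biological triplicate at T0 and at 1 and 2.5 h
  after the shift, in both the treatment and a parallel control culture;
* **flow cytometry** of cell scatter (FALS, a size proxy) and
  chlorophyll-derived red fluorescence, normalized to spiked reference
  beads;
* **qPCR** of selected nuclear genes with an endogenous-control gene and
  a T0 calibrator.

`DielShift` implements the full analysis chain for such experiments, and a
synthetic-data generator with complete ground truth so that every stage is
testable without access to any sequencing archive.

# Quantification model

**Counting windows.** Chloroplast transcripts are recovered well along
their whole length, so chloroplast genes are counted over their full
annotated span. Nuclear libraries built from 3' tags concentrate nearly
all reads near the transcript 3' end — empirically within 8 read lengths
of the annotation end, which at 50-bp reads motivates the canonical
**403-nt window at the 3' end of the terminal exon**. On the plus strand
this is the last 403 nt of the last exon; on the minus strand, the first
403 nt (in reference coordinates) of the first exon. Terminal exons
shorter than 403 nt are used whole: the window is never extended across a
splice junction, because tag coverage beyond the terminal exon is not
interpretable under the 3'-bias model.

**Exclusions.** The libraries are non-directional, so a read cannot be
assigned by strand. Two consequences are handled explicitly:

* genes forming a *convergent overlapping pair* — opposite strands with
  overlapping 3' windows — are excluded entirely
  (`excluded_overlap`): reads in the shared region are unassignable;
* genes whose window sequences are byte-identical (recently duplicated
  paralogs) are merged into one *joint record*
  (`merged_identical`): their reads are interchangeable, so only the
  joint abundance is meaningful.

**Read assignment.** A read counts for a gene when its interval overlaps
the gene's window by at least one base, irrespective of recorded strand.
A read overlapping several windows goes to the window of greatest
overlap; exact ties are dropped. This keeps counts integral, assigns each
read at most once, and is deterministic. No minimum-overlap fraction is
imposed.

**Normalization.** Chloroplast and nuclear data live on different scales
(the chloroplast genome is present in many copies and receives roughly
half of all reads), so library-size normalization across compartments is
not meaningful. Instead each gene's count is divided by the same sample's
*housekeeping count*: the 23S rRNA gene for chloroplast genes (summing
both copies where the gene is duplicated) and *GAPDH* for nuclear genes.
Ratios are exact; a zero housekeeping count is a hard error rather than a
silent pseudocount, because every downstream number would be meaningless.

# Differential-expression framework

For each contrast the expression ratio is the **ratio of arithmetic group
means** of normalized abundances (the alternative — mean of per-replicate
ratios — is biased upward for noisy denominators; the choice is stated in
the report header). Ratios are reported as **signed folds**: +r for
r ≥ 1 and −1/r for r < 1, so a 7-fold drop prints as −7.0.

Significance comes from a one-way fixed-effects ANOVA per contrast on
log2-transformed abundances — with two groups this is the pooled-variance
F test. The log transform stabilizes the variance of ratios; a switch to
the linear scale exists. Zeros are handled by adding half the smallest
nonzero abundance of the matrix *inside the log transform only* — folds
are always computed on un-offset means.

The **contrast set** is dual-baseline: each treatment time point is
compared (i) to the experiment's T0 control and (ii) to the time-matched
control; control time points are compared to T0 and to the immediately
preceding time point; and the two experiments' T0 controls are compared
to each other as a consistency check. A gene is significant in a contrast
when it passed the inclusion filter, |signed fold| ≥ 1.5 and raw
p < 0.01. **No multiple-testing correction is applied by default** — this
is a deliberate design, mirroring the raw-p convention of the
experimental tradition this package serves; `p_adjust` switches any
`p.adjust` method on.

The **inclusion filter** requires ≥ 100 raw reads in at least one sample
(boundary inclusive), guarding against folds estimated from near-zero
counts; convergent-overlap genes are never included regardless of counts.

Folds are binned into the categories
`<1.5, 1.5–<2, 2–<4, 4–<10, 10–<30, 30–<50, ≥50` (sign preserved in the
label). Only the 10–<30 edge pair is canonical; the remaining edges
follow the fold ranges conventionally narrated for such data (2–4-fold,
4–50-fold, 30–50-fold) and are exposed as a parameter.

# Chloroplast gene-model refinement

Organelle annotations frequently truncate CDSs or miss expressed ORFs;
transcript coverage can repair both. Refinement is a **separate pass**
from quantification: extended models and novel ORF calls are reported,
never silently substituted into the counting annotation.

* `extendCDS()` extends a CDS that does not end at a stop codon,
  codon by codon, requiring mean coverage ≥ `min_depth` (default 5) over
  each successive codon, until the first in-frame stop. It never
  shortens, is idempotent, and works on both strands. Genes that reach
  the contig end without a stop, or whose downstream coverage fails the
  gate, are flagged and left unmodified.
* `detectNovelORFs()` scans maximal unannotated intervals whose mean
  depth passes `min_depth` for ORFs (ATG to in-frame stop, both strands,
  ≥ `min_codons` codons, default 100) and reports them longest-first per
  interval. Start-codon policy is ATG-only; organellar alternative starts
  are out of scope but the policy is isolated in one function.
* `improvedGeneInventory()` does the bookkeeping of a refined organelle
  annotation; with its defaults (prior 58 protein / 26 tRNA / 3 rRNA
  genes, two novel protein genes, all three rRNAs present in two copies)
  the improved inventory totals 92 genes.

There is no canonical depth threshold for this kind of refinement;
`min_depth = 5` is this package's default and both thresholds are
parameters, so sensitivity is trivial to examine.

# Cytometry and growth

Cytometry channels are reported in **bead relative units**: mean cell
signal divided by mean signal of the spiked bead population, per channel
and sample. Means are arithmetic on linear channel values. Bead relative
units are exactly invariant to instrument gain. Trajectories are
expressed as percent change from T0, `100 * (x_t - x_0) / x_0`.

Growth rates come from daily bulk fluorescence measured at a fixed clock
time in semi-continuous culture: within each transfer, μ is the
least-squares slope of ln(signal) against time (exact on noiseless
exponentials), and the series mean ± SE is taken over 3–5 consecutive
transfers. The two-point ratio alternative exists implicitly (a transfer
with two points reduces to it). Divisions per day are k = μ / ln 2, so
μ = 1.0 d⁻¹ is 1.44 divisions per day. One-way ANOVAs compare
bead-relative properties across light levels per time point; two-sample
t-tests compare growth-rate sets.

# qPCR

Relative quantification uses the 2^−ΔΔCt method: per sample,
ΔCt = Ct(target) − Ct(endogenous control); ΔΔCt subtracts the mean ΔCt of
the T0-control calibrator (replicate pooling by the mean is this
package's choice); fold = 2^−ΔΔCt. The method assumes amplification
efficiency ≈ 1, which is checked — not corrected — via the dilution
series: slope of Ct against log10 input, E = 10^(−1/slope) − 1, with the
linear dynamic range flagged at R² ≥ 0.99. A Pfaffl-corrected mode
(efficiency-adjusted ratios) is available but off by default, because the
1:1 chemistry assumption is verified separately. Condition-wise
significance is a one-way ANOVA on log2 folds at each time point.

# The synthetic-data generator

The generator produces a complete experiment with known truth. What it
emulates, and the defaults it uses:

* **Compartment structure**: a 20-kb chloroplast contig (a desk-scale
  stand-in for a ~73-kb organelle genome) receiving 50% of reads, and an
  80-kb nuclear contig; ~25 protein genes per compartment plus
  housekeeping genes.
* **3' bias**: 90% of nuclear reads start within 8 read lengths (400 bp
  at the 50-bp default) of the transcript 3' end.
* **Count noise**: per-gene per-sample totals are negative binomial
  (dispersion 0.05, a mid-range biological-replicate value; the
  literature this emulates does not state one, so it is a free
  parameter). Housekeeping genes draw with their own, much lower
  dispersion (0.005): stability across treatments is the property they
  are selected for, and the generator reproduces it.
* **Effects**: controls drift modestly over the diel course (up to
  1.5-fold across T0 to T2.5); the HL shift perturbs a minority of genes
  by 1.5–4-fold; the HL+UV shift is drastic, repressing ~30% of genes
  10–50-fold and inducing ~10% by 10–50-fold. Housekeeping genes have
  true fold 1 in every comparison.
* **Planted structures** for the refinement and exclusion logic: an
  expressed but unannotated 603-codon ORF; a gene whose annotated CDS
  stops 90 nt short of its true stop; a convergent overlapping 3' pair;
  a pair of genes with byte-identical windows; a terminal exon shorter
  than 403 nt.
* **Cytometry**: log-normal events around configured bead-relative
  trajectories — rising through the light period, dropping after the
  light-to-dark transition in controls and HL, and collapsing under
  HL+UV to −93% red fluorescence at T19.5 — with a bead population fixed
  at 4000 a.u.
* **Growth**: F(t) = F0·e^{μt}(1+ε) per transfer with 2% noise, at the
  irradiance–growth curve defaults (0.28 d⁻¹ at 6, maximum 1.78 d⁻¹ at
  240, 0.96 d⁻¹ at 750 μmol photons m⁻² s⁻¹; the intermediate levels
  150/350/470 are a smooth unimodal interpolation chosen here).
* **qPCR**: Ct = intercept − log_{1+E}(quantity) plus Gaussian noise;
  the default effect table encodes a strongly UV-induced NPQ gene
  (33-fold at T1, 42-fold at T2.5 under HL+UV), a repressed
  light-harvesting gene and a UV-induced one-helix protein gene.

What it does **not** emulate: sequencing errors and quality; reads
spanning splice junctions (each read lies within one exon);
multi-interval CDSs (each gene's CDS is a single interval); positional
coverage biases beyond the 3' tag model; instrument drift in cytometry;
inhibition or probe effects in qPCR. Passing tests therefore demonstrate
the correctness and calibration of the analysis logic under the stated
statistical structure — not robustness to artifacts absent from the
model.

All randomness derives from one global seed through named substreams
(`deriveSeed()`), so identical configurations give byte-identical output
trees, including the pipeline's run manifest (which deliberately contains
no timestamps).

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (the GFF3 and
  IRanges convention); there is no internal 0-based layer.
* Read-assignment ties are dropped, not split or randomized.
* Zero-variance comparisons: identical groups give p = 1 by convention;
  zero within-group variance with different means gives p = 0.
* A zero group-B mean makes the fold undefined; the record is flagged,
  never imputed.
* The log2 offset is half the smallest nonzero normalized abundance of
  the matrix, applied only inside the transform.
* Efficiency is undefined for a flat dilution series (error), and at
  least 3 dilution points are required.
* Empty alignment tables, zero requested events and zero depth are valid
  degenerate inputs yielding empty outputs; malformed read intervals and
  nonpositive fluorescence are hard errors naming the offender.

# Calibration and power, measured not assumed

The test suite verifies, among other properties: exact agreement of
window counting with exhaustive per-read enumeration on random fixtures;
strand-flip, rescaling, gain and antisymmetry invariances (exact); type-I
error of the two-group ANOVA within the 95% binomial band of α = 0.01
under an all-null simulation (1000 genes, n = 3, with the housekeeping
denominator held at its expected value — a *shared noisy* denominator
couples genes and widens the spread of the false-positive rate beyond
binomial, which is a real property of housekeeping normalization worth
remembering when interpreting genome-wide counts of significant genes);
and median recovery of true folds 2–32 within 10% at n = 3.

Two power limits are worth stating plainly. First, with triplicates and
raw p < 0.01, genes whose counts in the repressed condition fall to 0–2
reads (total repression of a weakly expressed gene at desk-scale depth)
cannot reach significance — the inclusion filter's rationale, visible in
the end-to-end tests, which require correct signs always but allow a
small fraction of such borderline cases to miss the significance cut.
Second, ~10-fold effects at n = 3 sit near the boundary of per-contrast
power at dispersion 0.05; at the sequencing depths of a real experiment
(millions of reads per sample) both limits recede.

Problem sizes used throughout the suite — 20-kb organelle contig, 59
genes, 30 samples, 2 × 10⁴ reads per sample (3 × 10³ for refinement
fixtures), 200 recovery simulations, 1000-gene null — are the package's
desk-scale defaults, chosen so that the full chain remains interactive.

# Known limitations

* The ANOVA is per-contrast two-group; a joint model across all
  conditions and times (e.g. limma on the full design) would share
  variance information, but is deliberately not the default because the
  framework reproduces the pairwise-comparison convention.
* Housekeeping normalization propagates denominator noise into every
  ratio of a compartment and correlates genes within a sample.
* Novel-ORF discovery reports nested ORFs sharing a stop (internal ATGs)
  individually; callers wanting one call per stop should keep the first
  (longest) record per interval.
* The CLI is a thin wrapper (`inst/scripts/dielshift.R`) over the
  exported functions; the functions themselves are the stable interface.
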