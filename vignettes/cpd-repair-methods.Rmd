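---
title: "Models and methods behind cpdrepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cpdrepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cpdrepair)
```

This vignette explains the statistical models, conventions and numerical
choices the package is built on, in the spirit of a methods supplement: what
each stage assumes, which knobs matter, and what the synthetic experiments
do and do not establish about real data.

## Lesion calling and coordinates

CPD-seq library chemistry places the 5′ end of each sequencing read
immediately 3′ of the cleaved lesion on the opposite strand. The package
therefore calls, for a plus-strand read with 1-based 5′ end $p$, a candidate
lesion on the minus strand covering plus-coordinates $(p-2,\,p-1)$, and for
a minus-strand read with 5′ end $q$, a plus-strand lesion at $(q+1,\,q+2)$.
Candidates whose dinucleotide (read 5′→3′ on the lesion strand) is not one
of TT, TC, CT, CC are discarded as background; reads whose two-base upstream
window falls off the chromosome or contains an ambiguous base are dropped
and tallied separately, since their dipyrimidine status cannot be decided.

Internally all coordinates are 1-based inclusive; BED input/output stays
0-based half-open, with the conversion confined to the I/O layer. Every
lesion — on either strand — is keyed by the **lower plus-strand coordinate**
of its 2-bp span. This single-key convention makes the track a plain tibble
with one row per genomic dipyrimidine per strand, zero-filled so that
undamaged sites are explicit: the zero-filled background is what makes
"fraction of CPDs remaining" well defined at single-nucleotide resolution.

## Gel quantification and the normalization anchor

Sequencing depth differs arbitrarily between libraries, so CPD-seq ratios
are relative. The alkaline gel supplies the absolute scale. Under random
(Poisson) cleavage, expected breaks per nucleotide equal the reciprocal of
the *number-average* fragment length, giving the lesion density

$$\varphi = 1000\left(\frac{1}{L_\mathrm{T4}} - \frac{1}{L_\mathrm{mock}}\right)
\quad \text{CPDs/kb},$$

with the mock lane removing background fragmentation. Percent repaired is
$R(t) = 100\,(1-\varphi_t/\varphi_0)$ against the 0-h-UV lane, and
$F_\mathrm{gel}(t) = 1 - R(t)/100$ (clamped to $[0,1]$) is the genome-wide
fraction remaining. Densitometry lanes are reduced to a length by taking the
migration distance at the lane's median cumulative intensity and
interpolating the ladder log-linearly; we treat this median-intensity length
as the number-average length required by the Poisson formula — the two are
not identical in general (median intensity is closer to a mass-weighted
summary), which is a known approximation of the assay itself, and the
simulation-based accuracy checks therefore run on raw fragment lengths where
the number-average is exact. No extrapolation beyond the ladder is allowed.

The per-site normalization is
$$f_i = F_\mathrm{gel}(t)\cdot
\frac{n_i(t)/N_t}{\,n_i(0)/N_0\,},$$
where $N$ is the library total over retained reads. Because the
depth-normalized genome-wide ratio is 1 by construction, the genome-wide
normalized fraction equals $F_\mathrm{gel}(t)$ *exactly*; this identity is
asserted in the tests. Regions aggregate counts before dividing (sum, then
ratio) rather than averaging per-site ratios — robust to zero-count sites
and identical to count-based metaprofile semantics. Sites with $n_i(0)=0$
are undefined and excluded from per-site output.

Replicate gel comparisons use unpaired two-sample t-tests with pooled
variance and a hand-implemented Holm–Šidák step-down adjustment
($\tilde p_i = \max_{j\le i} 1-(1-p_j)^{m-j+1}$ over ascending raw
p-values); `stats::p.adjust` offers Holm and single-step Šidák but not this
step-down variant. Gene-body strand asymmetry uses a two-sided paired t-test
over the six coding-bin (TS, NTS) pairs.

## Gene, nucleosome and TFBS profiles

**Bins.** Each coding span (TSS→TES) is divided into six equal bins oriented
with transcription; integer boundaries come from rounding cumulative edges,
with remainder bases in the last bin (deterministic and order-independent).
Three contiguous 167-bp bins flank the TSS and TES. Flank bins colliding
with a neighbouring gene are *not* masked, and a position inside two
overlapping genes is counted once per gene — metaprofile semantics are
gene-centric. The transcribed strand (TS) is the template strand, i.e. the
strand opposite the annotated mRNA sense; flanks inherit the gene's frame.
Transcription cohorts split at $>10$ (high) and $<1$ (low) mRNA/h.

**Nucleosomes.** Only strongly positioned nucleosomes (score strictly
greater than 5) enter dyad profiles. Offsets are measured on plus-strand
coordinates relative to the dyad (position 0) over ±90 bp, with the core
edges at ±73 bp; the 5′→3′ re-orientation of the minus strand
(`align_strands()`) and the unweighted strand mean (`combine_strands()`)
are explicit, separate steps, so there is a single authoritative coordinate
frame. The rotational-setting fit is a least-squares cosine
$v(o) \approx a + c_1 o + c_2 o^2 + b\cos\!\big(2\pi(o-\phi)/P\big)$ with
default period $P = 10.3$ bp over the core; the quadratic absorbs the smooth
translational bowl so the cosine captures only the helical periodicity. The
phase is always *fitted*, never hard-coded, because phase conventions differ
between nucleosome maps; reliability requires the amplitude to exceed twice
its standard error, otherwise labels are withheld. Minor-out positions are
the fitted minima of fraction remaining (fast repair where the minor groove
faces outward); for count-mode accessibility profiles (e.g. DNase cleavage)
the assignment inverts. Because a signed-offset cosine phase is destroyed by
averaging 5′→3′-aligned strands, phase fitting is done on the genomic-frame
profile — the frame in which rotational settings are drawn. The 3′-side
asymmetry index is the mean fraction over aligned offsets +10..+50 minus the
mean over −50..−10, with a standard error propagated from per-offset
binomial counting error.

**TFBS.** Core windows span ±4 bp around the motif midpoint, flanks ±100 bp
excluding the core, both strands pooled (strand-resolved output exists
behind a flag). A TF enters the scatter only with ≥100 core counts at both
timepoints; per-position profiles mask offsets with <10 counts at either
timepoint. Sites within 1 kb of a chromosome end are excluded — the boundary
case is unstated in the assay description, so the package excludes at
distance ≤1000 bp, which matches the documented keep/drop examples.
Occupancy < 10 defines low-occupancy control sites. Per-TF midpoint offsets
are user configuration (default 0) applied exactly once.

## Mutation analysis

Substitutions are folded into the pyrimidine frame exactly once
(purine-reference records are reverse-complemented), giving 6 classes × 16
trinucleotide contexts; channel totals equal the record count by
construction. "Unique mutations" removes *all* copies of any substitution
recurrent across isolates (they are most plausibly ancestral in a passaging
design); a `keep = "one"` switch retains a representative instead. A
mutation is a TS mutation when its pyrimidine-frame reference lies on the
template strand — consistent with the lesion-on-template logic of repair.
Transcriptional asymmetry normalizes strand counts by the per-strand
abundance of each context across gene bodies (TSS–TES only, matching the
asymmetry's domain):
$$A = \frac{m_\mathrm{TS}/k_\mathrm{TS}}{m_\mathrm{NTS}/k_\mathrm{NTS}},$$
with channels under 30 mutations reported but flagged, and an `Inf`
sentinel when $m_\mathrm{NTS}=0$. Indels are out of scope and skipped with a
log. CAN1 frequencies treat each `dilution` argument as the fold-dilution of
the plated aliquot, so frequency =
(CanR colonies × its dilution)/(SC colonies × its dilution).

## The synthetic-data module

The generators produce data with exactly the statistical structure the
analysis assumes, which is what makes the property tests sharp:

* **Damage** is independent Poisson per dipyrimidine with mean = dose ×
  dinucleotide propensity. Induction propensities are free parameters (the
  assay literature does not pin them); defaults order TT > TC > CT > CC.
* **Repair** is memoryless per lesion: survival to time $t$ with probability
  $e^{-k_i t}$, $k_i$ = photolyase + NER rate at the site, each modified by
  context (TS occlusion ≤ 1 on photolyase, TC-NER boost ≥ 1 on NER;
  translational, rotational-cosine and 3′-half factors inside nucleosome
  cores; occupancy-scaled attenuation `block^(occupancy/100)` within core ±
  5 bp of a TFBS). Exponential kinetics are the simplest model consistent
  with fraction-remaining curves and give closed forms for the tests.
  Chromatin factors act on the photolyase rate only: the repair-inhibition
  phenomena being modelled are photolyase phenomena, and keeping NER flat
  (apart from its TS boost) keeps the closed-form checks interpretable.
  Strain labels gate the pathways: no photoreactivation ⇒ photolyase off,
  `rad14` ⇒ NER off, `rad14phr1` ⇒ both off.
* **Calibration.** Default base rates (0.075/min photolyase, 0.0024/min NER)
  are set so that simulated *bulk* kinetics under yeast-like coverage (~70%
  genic, nucleosomes tiled at ~165 bp) reproduce the benchmark repair
  levels: ~92% of CPDs cleared in 60 min with both pathways, ~16% with NER
  alone. Naked-DNA base rates sit above the bulk-average effective rates
  because context attenuation drags the genome-wide mean down.
* **Reads** are the exact inverse of the calling convention, one read per
  lesion occurrence, so the zero-background round trip is the identity on
  tracks. Reads are clipped at chromosome ends (a fragment cannot extend
  past them); only a lesion whose read *5′ end* itself would fall off the
  chromosome is unrecoverable — the two terminal key positions per
  chromosome strand — and these are skipped with a logged count. Decoy reads
  are uniform over positions whose upstream dinucleotide is not a
  dipyrimidine: enough to exercise the filter without modelling library
  chemistry.
* **Gel lanes** are Poisson cleavage of fixed-length molecules; mock lanes
  are uncleaved. Coincident cuts (measure-zero events in the continuous
  approximation) would leave zero-length fragments and are dropped.
* **Passaging mutations** draw classes from a spectrum (specs like `"C>T"`
  or `"T>A@NTA"`), then sample matching pyrimidine-frame sites with per-site
  weight `ts_fold` on template-strand sites inside gene bodies — so the
  expected normalized asymmetry equals `ts_fold` by construction. Sites are
  sampled without replacement so the only cross-isolate duplicates are the
  injected recurrent ones: `round(f·N/(2-f))` records are copied into a
  second isolate so the unique filter removes ≈ fraction `f` of final
  records.

What the generator does **not** emulate: sequencing error, PCR duplicates,
mappability, 6-4PP-specific chemistry (a second lesion class is
representable only as a rate term), replication-associated mutation biases,
diploidy, or correlated damage. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well calibrated under the stated
statistical model — not that real libraries are free of these artifacts.

## Numerical choices and degenerate inputs

* Ties in the six-bin split go to the last bin via rounded cumulative edges.
* A gene shorter than the bin count is excluded with a message.
* `log2(TS/NTS)` is reported missing when either fraction is 0 or undefined.
* A paired test with all-zero differences returns $p=1$; a constant nonzero
  difference (zero variance) is degenerate and reported as below machine
  epsilon with a flag rather than as a spurious exact 0.
* Zero variance in both groups with equal means in the replicate test gives
  $p=1$.
* Dyads or TFBS windows running off a chromosome simply contribute nothing
  at the missing offsets; lesions at the two terminal key positions are the
  only unrecoverable ones in read simulation.
* Identical seeds and configs give byte-identical outputs everywhere; the
  pipeline stamps every output with the package version, a config hash and
  the seed.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to make their error bands
meaningful on a single CPU: 100-kb genomes (~50,000 dipyrimidine sites) for
round-trip and profile tests; 10,000 molecules per gel lane across
0.05–2 CPDs/kb; 10,000 replicates for the type-I-error calibrations; 5,500
dyads on a 1.2-Mb genome for phase recovery (±1 bp) and the 3′ asymmetry;
5 × 250 binding sites for the occupancy–occlusion rank test; and 20
isolates × ~91 mutations (three generator replicates) for the
transcribed-strand fold, on a ~70%-genic 300-kb genome. At these sizes the
Monte-Carlo error of each recovered quantity is several-fold smaller than
the band it is checked against.

## Known limitations

* The gel model equates median-intensity length with number-average length
  (see above); real densitometry calibration may differ systematically.
* Nearest-dyad assignment attributes each position to a single nucleosome;
  overlapping dyad annotations would be better served by per-dyad weights.
* The TFBS attenuation window is a square profile (core ± extension); real
  footprints taper.
* Aggregation-then-ratio weights genes by their damage counts; a
  gene-averaged profile variant would weight genes equally and is not
  currently exposed.
* `Inf` asymmetry sentinels and channels under the count floor should be
  treated qualitatively, as in any count-based spectrum analysis.
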