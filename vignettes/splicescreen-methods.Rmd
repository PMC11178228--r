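---
title: "Models and methods behind splicescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

# The scientific problem

Fission yeast splices most of its transcripts co-transcriptionally, and the
efficiency with which an intron is removed varies widely between introns
and between genetic backgrounds. Two experimental readouts dominate the
field: plate-based fluorescent splicing reporters (a YFP whose translation
requires intron removal, paired with a constitutive RFP, read by flow
cytometry as a YFP/RFP ratio) and genome-wide per-intron splicing
efficiency estimated from RNA-seq junction reads. `splicescreen`
implements both readouts and the downstream analyses used to ask *why* a
set of introns is poorly spliced in a mutant: is the defect written in the
intron sequence (splice-site motifs, length, A/T content), or is it a
property of the host gene (transcription rate, with all introns of a
pre-mRNA affected together)?

The package distinguishes these two mechanisms computationally. A
sequence-intrinsic defect shows up as a divergent splice-site composition
of the worst-spliced introns and no association with expression; a
transcription-coupled, gene-level defect shows the mirror image — normal
splice-site composition, strong association between poor splicing and high
transcription, and co-ordinated loss of splicing across all introns of the
same gene.

# The generative models

All inputs can be simulated with a ground truth, which is how the package
tests itself.

## Genome

`simulate_genome()` builds genes exon-by-exon on their transcript strand.
Defaults mirror the fission-yeast landscape: 43% of genes carry introns,
intron counts between 1 and 15 with geometrically decaying probabilities
(mean about two per intron-bearing gene), mean intron length 83 nt with a
right-skewed negative-binomial shape, and AT-rich intron bodies. Every
intron is stamped with a donor 6-mer (`GTAAGT`), a branch-point 5-mer
(`CTAAC`) whose last base sits 10 nt upstream of the 3' end, and an
acceptor `TAG`. A per-position `degeneracy` probability substitutes motif
bases to emulate the weak consensus of real fission-yeast splice sites;
the invariant `GT`/`AG` dinucleotides are protected by default so every
intron remains annotatable. The branch-point offset is a fixed default (it
is configurable) because no canonical position exists; 10 nt is within the
commonly observed 5-40 nt range. Minus-strand genes are
reverse-complemented into the chromosome, so strand handling is exercised
throughout.

## Splicing-defect models

Per-intron wild-type ("baseline") efficiency is drawn from
`Beta(30, 1.5)` — mean ~0.95 with a low-efficiency tail, which reproduces
the qualitative shape of a wild-type decile profile (most introns well
spliced, a worst decile clearly below the rest) without fitting anything.

Three genotype models transform the baseline:

* **none** — the baseline itself (the wild-type genotype).
* **transcription_coupled** — gene $g$ is affected with probability
  $\mathrm{logit}^{-1}(\alpha + \beta \log r_g)$ where $r_g$ is the gene's
  transcription rate (FPKM-like, log-normal). An affected gene multiplies
  *every* intron's baseline by one shared draw
  $\delta_g \sim Beta(1.5, 3)$. The shared multiplier is what makes
  defects travel together along a pre-mRNA.
* **motif_dependent** — intron $i$ keeps
  $\mathrm{baseline}_i (1 - \gamma m_i / 6)$, where $m_i$ counts donor-site
  mismatches to the consensus. Defects are intron-intrinsic and
  independent of the host gene.

The defaults ($\alpha=-6$, $\beta=1.5$, $\gamma=0.8$, rates
log-normal with meanlog 3 and sdlog 1.2) are scenario choices, not
estimates of any real mutant. They were picked once so that roughly the top quartile of
expressed genes has an appreciable chance of being affected and a fully
mismatched donor site loses most of its splicing, and are not tuned
afterwards.

Slowed-transcription scenarios (transcription-elongation inhibition) are
represented by a rate multiplier $\rho \in (0,1]$ applied before the
defect model; no kinetic elongation model is attempted.

## Read and event emission

Junction evidence is emitted per intron boundary: total boundary reads
$n_b \sim Poisson(\mathrm{depth} \times r_g)$ and spliced reads
$\sim Binomial(n_b, \mathrm{SE})$. Gene-level counts are negative binomial
with mean proportional to rate and fold change, `dispersion = Inf` giving
the Poisson limit. Cytometry events draw a log-normal per-cell expression
$X$; red reads $X$ through a gain, yellow reads
$\mathrm{SE} \times X$ — YFP is only made from spliced message — plus
additive Gaussian autofluorescence and multiplicative noise on both.
Scatter channels are drawn so that configurable fractions of events fail
the scatter gate (collapsed "debris" scatter) and the singlet gate
(FSC-H far off the FSC-A diagonal). Untransformed control wells have zero
coupling and report pure autofluorescence.

What the generator does *not* emulate: read-level sequences and alignment
artefacts, isoform structure, spectral overlap between channels,
instrument drift, batch effects, or biological covariation between
expression and intron content. Tests passing on these simulations
therefore demonstrate that the analysis code recovers the signals it
claims to recover under its own stated models — not that those models
exhaust real data.

## Reproducibility scheme

Every simulation unit (gene, well, replicate, stage) derives its own seed
from the master seed by the counter scheme in `subseed()`
(`(master * 69069 + index * 10007) mod 2147483629`, exact in double
precision). Growing a genome or adding wells never perturbs earlier
draws, and every `simulate_*` call is byte-reproducible for a fixed seed.

# Analysis procedures and their parameters

## Screen processing

Gating is hierarchical and fixed in order: scatter rectangle, then singlet
band, then optional fluorescence bounds. Because data-driven bounds
re-estimated on their own output would not be idempotent, estimation and
filtering are separate steps: `fit_gates()` derives concrete bounds
(central 90% scatter quantiles; singlet slope as the median FSC-H/FSC-A
ratio with a ±25% band) and `gate_events()` applies them as a pure filter.
Gating protocols of this kind fix the gate sequence but rarely any
bounds, so these defaults are the package's own and are configurable.

A well needs at least 1000 gated events to pass QC. Ratios use raw channel
medians with the untransformed control strain's PE-Texas Red median
subtracted from every well's red median before division (`red_only`, the
conventional red-channel correction); a `both` option also corrects the
FITC channel, since correcting one channel of a ratio is physically
asymmetric. Ratios are
`NA` when the corrected red is non-positive or QC failed.

Hits are called per strain by a two-sided Welch t-test of replicate ratios
against the reference strain's replicates (Welch rather than pooled
variance: a robust default at tiny replicate numbers, where equal-variance
assumptions cannot be checked), with the effect reported as
log2(mean ratio / reference mean ratio). Raw p-values are the default, with an optional Benjamini-Hochberg flag
for genome-scale screens.

## Splicing efficiency

The per-intron estimator pools both boundaries:
$$\mathrm{SE} = \frac{s_5 + s_3}{s_5 + u_5 + s_3 + u_3}$$
with coverage the denominator and a default floor of 10 boundary reads
(below it, `NA`). Pooling is chosen for symmetry between boundaries; it is
the only variant offered. When alignments rather than counts are supplied,
a read supports the spliced form only if its gap matches the annotated
intron exactly with at least 6 aligned bases on each side, and the
unspliced form only if a single aligned block spans a boundary with the
same overhang; a read counts at most once per boundary, and unannotated
junctions are logged rather than rejected.

Deciles are rank-based on wild-type SE with ties broken by intron id, so
the partition is deterministic and bin sizes differ by at most one.
"Most affected" introns rank by the wild-type-minus-mutant SE difference
by default; a mutant/wild-type ratio metric is also provided because the
phrase "most affected" is ambiguous between the two readings, and
the co-splicing filters are expressed on the ratio scale. Extreme
selection takes `floor(fraction * N)` introns (minimum one).

## Sequence features

Junction windows default to 3 exonic + 8 intronic nt (5') and 8 intronic
+ 3 exonic (3') — wide enough to cover the stamped donor/acceptor motifs
while staying inside the shortest exons; widths are configurable. Position probability matrices use the uniform-background
information content convention (0-2 bits), with an optional small-sample
correction. The per-position chi-square against background frequencies
(rare bases with expected count < 1 pooled, Benjamini-Hochberg across
positions) and the per-position KL divergence are *added* statistics
beyond the visual comparison that sequence logos support, and outputs
label them accordingly.

## Co-splicing and expression

Co-splicing profiles condition on an anchor intron of 3-intron genes
passing `se_mut/se_wt < 0.5` ("a 50% decrease", implemented as a relative
ratio, consistent with the explicitly relative `> 0.9` control filter) and
report per-position mean SE for both genotypes. The expression association
compares host-gene FPKM of the 50 worst versus 50 best spliced introns by
Welch t-test on the log scale (FPKM is log-normal-like; testing on logs
keeps the test about fold differences). The cumulative mature-mRNA
fraction multiplies per-intron efficiencies under an independence
assumption stated in the output; the worked four-intron example
(0.74, 0.71, 0.95, 0.85) gives 0.4243, and the package reports the exact
product rather than a rounded figure.

## Expression surrogate

The differential-expression module is a deliberately simplified,
fully-documented surrogate: median-of-ratios size factors (re-implemented;
the established shrinkage-based package is used only as an independent
cross-check in the test suite), log2 fold change of pseudocounted
normalised means, Welch t-test on log2(normalised + 1), and the volcano
rule `|log2fc| >= 1` (inclusive) and `p < 0.05` (exclusive). Outputs carry
`method=simplified-surrogate`; numerical agreement with shrinkage
estimators is a non-goal, and with duplicate libraries the t-test is
underpowered (the module warns).

# Numerical choices and degenerate inputs

* Zero-variance samples in any Welch comparison return p = 1 when means
  agree and p = 0 otherwise, instead of erroring on constant data.
* Ratios with non-positive corrected denominators, wells failing QC,
  introns under the coverage floor, and both-zero RT-PCR signals are `NA`,
  never silently dropped; exclusion counts are recorded.
* `0 log 0 = 0` throughout the information-content and KL computations;
  KL is infinite when the set shows a base the background lacks.
* Ties in rankings break by lower mutant SE, then lexicographic intron id;
  decile ties break by intron id.
* Empty inputs (zero genes, empty event tables, empty rankings) return
  empty but well-formed outputs; invalid parameters raise configuration
  errors before any computation.

# Problem sizes used by the tests

The test-suite scenarios use genomes of 150-500 genes, plates of up to 88
wells at 1000-2000 events per well, 20-50 seeds per property, and 300-1000
reduced null simulations. These sizes were chosen so that every property
asserted (recovery to ±0.02 SE, planted-hit ranking, nominal 5% false
positives, the two mechanism signatures) has comfortable statistical
margin under the generator's defaults, while a full run stays in the
minutes range. Monte-Carlo assertions use binomial-error allowances
(typically three standard errors) around the nominal value rather than
exact bounds, since the quantities estimated are themselves rates.

# Known limitations

* The splicing-efficiency metric is a documented stand-in for tools of
  the SPLICE-q family, not a bit-compatible clone of any of them;
  parameterisations differ across such tools.
* The DE surrogate makes no claim to reproduce counts of induced genes
  reported from real sequencing data.
* No alternative splice-site discovery, branch-point prediction from
  sequence, isoform assembly, or GO enrichment.
* The product model for mature mRNA ignores within-gene co-splicing
  correlation, which the transcription-coupled model itself generates;
  under that model the product is conservative.
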