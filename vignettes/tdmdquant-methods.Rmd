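---
title: "Quantitative models behind tdmdquant"
author: "tdmdquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative models behind tdmdquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmdquant)
```

# Scope

Target-directed microRNA degradation (TDMD) inverts the usual logic of
miRNA regulation: a "trigger" transcript that pairs to a miRNA's seed
and, across an internal loop, extensively to its 3′ region marks the
AGO–miRNA complex for ubiquitylation by the ZSWIM8–CUL3 E3 ligase and
thereby destroys the miRNA rather than the target. `tdmdquant`
implements the quantitative layer of this biology in four parts:

1. an isoform-resolved small-RNA-seq pipeline (FASTQ to counts per
   miRNA per length, 13–31 nt) with a differential-stability analysis
   of knockout-vs-control designs;
2. binding-assay models: the quadratic (ligand-depletion) titration
   isotherm with constrained fitting, co-IP gel-band quantification
   with background subtraction and T6B normalization, fold-enrichment
   with censoring, pull-down interpolation, single-site fits and
   filter-binding fractions;
3. annotation and classification of miRNA–target duplex architectures
   (seed-only, 3′-supplementary, TDMD-like, fully complementary);
4. synthetic-data generators with embedded ground truth that emulate
   each assay, so that every stage is testable end to end without
   external data.

Nothing here touches structural biology: the package quantifies reads,
bands, titrations and pairing diagrams, not cryo-EM maps.

# The small-RNA pipeline

Reads are processed in four deterministic steps. The 3′ adapter is
located at its leftmost occurrence, allowing a truncated adapter prefix
at the read end when the overlap is at least `minOverlap` (default 4 nt,
exact matching by default; a mismatch rate can be enabled). Reads
without an adapter are dropped and counted. The trimmed insert is then
mean-quality filtered: a read is kept only if its mean base quality
strictly exceeds 30, so a uniformly Q30 read is discarded. The named
upstream tools expose several per-base filtering conventions; the mean
rule was chosen because it is deterministic and single-parameter, and
the choice is isolated behind `qualityFilter()`.

Assignment is by exact string match of the first 13 nt of the insert
against a dictionary of miRNA sequences (U and T are equivalent
throughout). Species sharing a 13-nt prefix are indistinguishable by
this rule, so they are collapsed into a single entry whose name joins
the members with `/`. The recorded isoform length is the length of the
mapped read, not of the reference species; inserts shorter than 13 nt
or longer than 31 nt fall into `too_short`/`too_long` bins. Every read
ends in exactly one of six bins (assigned, unassigned, too-short,
too-long, adapter-rejected, quality-rejected), and the per-sample
counters must sum to the FASTQ read count — this conservation law is
asserted in the test suite and holds by construction.

# Differential stability

Counts are first summed over lengths per miRNA. Expression filtering
keeps a miRNA when it has strictly more than 5 reads in at least two
knockout libraries and at least 30 reads across all six libraries (the
"more than five" is strict; the total is non-strict). Size factors are
median-of-ratios: the per-sample median, over miRNAs detected in every
library, of the count divided by the miRNA's geometric mean. The
implementation is written from scratch and is checked in the tests
against an independent reference implementation.

The fold-change engine is a transparent two-group negative-binomial
estimator rather than a GLM with shrinkage (shrinkage and empirical
Bayes are out of scope by design):

* `lfc` = log2 of the ratio of pseudocounted (default 0.5) group means
  of normalized counts;
* `se` via the delta method using the NB variance model
  $\mu a + \phi\mu^2$ (with $a$ the mean reciprocal size factor),
  where $\phi$ is a per-miRNA method-of-moments dispersion pooled
  across both groups and floored at $10^{-8}$;
* `p` from the two-sided Wald statistic `lfc/se` referred to a *t*
  distribution with Welch–Satterthwaite degrees of freedom.

The *t* reference is the one deliberate refinement over a plain normal
Wald test: with three samples per group the variance estimate carries
roughly four degrees of freedom, and a normal reference is markedly
anticonservative (empirically ~12% of null miRNAs at nominal 5%). With
the Welch *t* reference the global-null type-I rate sits at 5% ± 2%,
which the acceptance suite verifies on ≥1,000 simulated miRNAs.

Potentially ZSWIM8-sensitive miRNAs are flagged three ways: (1)
BH-adjusted p < 0.05 with positive fold change; (2) the mature fold
change separated from its passenger strand's beyond their joint
standard errors — directional by default (mature above passenger),
since altered degradation moves only the mature strand, with an
absolute-separation option; passengers bypass the expression filter and
multiple passengers are summed before estimation; (3) membership in an
external annotation list. The union (plus the significant set, for
which BH on the same p-values stands in for the upstream
mixture-model adjuster behind a plug-in `padjFun` interface) is
excluded from isoform-level analysis. Exclusion operates at the summed
level only; isoform-level p-values play no role in it.

Isoform-level fold changes reuse the same estimator on individual
(miRNA, length) rows, normalized with the size factors computed on the
*summed* counts — a provenance mark on the `SizeFactors` object
enforces this contract. Centering subtracts the median fold change of
all 22-nt species, pinning the 22-nt distribution exactly at zero. The
short-isoform signal is a one-sided Wilcoxon signed-rank test of the
centered fold changes of isoforms shorter than 19 nt against zero
(alternative "greater": short isoforms accumulate upon knockout). The
underlying study reports a significant but weak signal without naming
the test; the signed-rank choice is ours — robust, exchangeable with
the centering step, and calibrated under the null — and both the 19-nt
threshold and the test live behind arguments.

# Binding models

The titration model is the quadratic (ligand-depletion) isotherm for a
RISC dilution series against total target $T$:

$$F_\mathrm{bound} \;=\; \frac{(D S + T + K_D) -
\sqrt{(D S + T + K_D)^2 - 4 D S T}}{2T}\,F_\mathrm{max}$$

with $D$ the dilution factor and $S$ the stock concentration. The
implementation evaluates the algebraically equivalent form
$2 D S F_\mathrm{max}/(b + \sqrt{b^2 - 4DST})$, which avoids
catastrophic cancellation when the discriminant approaches zero; the
tests verify agreement with a numerical mass-action equilibrium solver
to $10^{-10}$ across random parameter sweeps. Fitting uses constrained
Levenberg–Marquardt least squares over (stock, log $K_D$, $F_\max$)
from a 27-point start grid (stock at 0.1/1/10× a data-derived nominal,
$K_D$ at 0.01/1/100 nM, $F_\max$ at 0.3/0.6/0.9); $F_\max$ is bounded
in (0, 1) and $K_D$ is fit in log space. Identifiability of the stock
depends on the binding regime: the assay quantifies active complex by
titrating *limiting* amounts against a fixed target, which is
informative precisely because binding is near-stoichiometric
($K_D \ll T$). In that regime an 8-point two-fold series at 2% noise
recovers the stock with a median error of ~3%; when $K_D$ approaches
$T$ the curve turns hyperbolic, stock and $K_D$ become partially
confounded, and no fitting procedure can recover the stock tightly.
The recovery tests therefore run in the tight-binding regime, which is
the assay's working regime.

Gel quantification follows the assay's own normalization chain: blank
rectangles estimate the image background, the 0 nM (no-bait) lane the
bait-independent recovery, and the T6B lane (a TNRC6-derived peptide
that binds AGO–miRNA regardless of target) full recovery; the reported
value is the doubly background-subtracted band over the T6B reference,
invariant to any global intensity rescaling. Fold enrichment of a
trigger over a reference target censors reference values at a floor of
$10^{-3}$ (in T6B-normalized units), converting a division by a
background-level band into an explicit lower bound, so "greater than
N-fold" statements survive quantification. Concentrations required for
a given pull-down level are interpolated linearly in log concentration
between bracketing observations. Filter binding uses the two-membrane
convention (bound complex on nitrocellulose, free RNA on nylon) with
per-membrane background subtraction; lane-profile background models and
cross-gel gain normalization are out of scope.

# Duplex architecture

Coordinates are 1-based, both strands 5′→3′, and guide nucleotide 1 is
never paired (it is anchored inside AGO). A seed site is a perfect
Watson–Crick–Franklin match to guide nucleotides 2–8; G:U wobble
pairing is available behind a flag but off by default. Given a seed
site, the 3′ register search enumerates internal loops of up to 8
unpaired guide and 16 unpaired target nucleotides and keeps the
register with the most contiguous pairs involving guide nucleotides ≥9,
breaking ties toward smaller target then guide loops; the tests prove
this equal to exhaustive enumeration on inputs up to 60 nt. Flanks are
measured from the outermost paired target nucleotide to each target
end, so annotation is invariant to appended flanking sequence.

Classes are operational, not claims about biology: *full* means both
loops absent and pairing to within one nucleotide of complete (nt 1
never pairs); *TDMD-like* requires at least 8 contiguous 3′ pairs
reaching within 3 nt of the guide 3′ end across a ≥1-nt internal loop;
*seed-only* allows at most 2 incidental 3′ pairs; everything else —
including extensive pairing that stops short of the guide 3′ end — is
*supplementary*. The minimal 3′ pairing competent for TDMD is not
settled; the thresholds are configurable arguments.

# Synthetic data: what it emulates, what it does not

The generators define the study conditions under which everything is
tested. `simulateIsoformCounts()` draws negative-binomial counts with
expectation

$$\mu_{i\ell j} = sf_j \cdot base_i \cdot profile_{i\ell} \cdot
2^{\,g_j\,(lfc^{tdmd}_i + lfc^{short}_{i\ell})}$$

for species $i$, length $\ell$, sample $j$ ($g_j = 1$ for knockout).
Defaults: 3 knockout vs 3 control libraries; log-normal per-species
abundances (median 500 at the modal length); dispersion 0.05; 20%
coefficient of variation on true size factors; a unimodal length
profile peaking at 22 nt with a small 13–16-nt trimming tail; a TDMD
effect of +2 log2 units on designated sensitive species (reported
ZSWIM8-sensitive miRNAs accumulate several-fold upon knockout); and a
length-dependent effect applied below 19 nt for short-isoform studies.
Library-size and dispersion ranges of the real libraries are not
published, so these defaults are documented choices, not calibrations.
FASTQ synthesis inverts the pipeline exactly: isoform sequences are
truncated or extended with templated 3′ hairpin context (so prefix
mapping stays valid for long isoforms), adapters appended, Phred+33
qualities drawn from Q32–40 for good reads and at or below Q30 for
contaminating low-quality reads, and ground truth written to a JSON
sidecar. At zero contamination the pipeline reproduces the generating
table exactly — the round-trip law the acceptance suite asserts.

The generators deliberately omit sequencing-error models, UMIs,
ligation bias and rRNA contamination. Passing tests therefore
demonstrate the correctness of the quantification logic under the
stated model, not robustness to every artefact of real libraries.

Gel simulation uses
$intensity = background + gain \cdot fraction \cdot (1+\varepsilon)$
with mean-one log-normal noise of chosen CV on the signal term, plus
blank rectangles at the background level; titration simulation adds
truncated Gaussian noise to the exact isotherm.

# Numerical and design notes

* Problem sizes in the test and acceptance suites (≥1,000 miRNAs for
  calibration, 100 replicate gels, 50 titration seeds, ≤60-nt
  duplex-oracle inputs) were chosen so each property is measured with
  comfortable Monte-Carlo margin while the whole suite runs in a few
  minutes on one CPU.
* All generators are deterministic under a fixed seed and restore the
  caller's RNG state; distinct seeds give distinct outputs.
* Degenerate inputs fail loudly rather than silently: all-zero
  titrations and flat single-site responses are unidentifiable errors;
  centering without 22-nt entries, pull-down levels outside the
  observed range, gels missing control lanes, and size factors of the
  wrong provenance all raise informative errors.
* Negative normalized gel values (possible under noise) are clipped at
  zero with a warning; quality-free zero-length inserts bypass the
  quality filter and land in the too-short bin.
* The collapsed-name convention (`/`-joined, dictionary order) and the
  13-nt prefix length are fixed constants of the mapping contract.
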