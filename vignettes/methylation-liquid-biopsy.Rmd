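---
title: "Methods: scoring targeted bisulfite amplicon panels for liquid biopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring targeted bisulfite amplicon panels for liquid biopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

# The measurement model

Circulating tumour DNA is a small, fragmented minority of cell-free DNA.
The assay this package implements reads tumour signal out of that mixture
through three design choices:

1. **Region choice.** Panel regions are hypermethylated in tumours and
   unmethylated in normal tissues *and* blood (the dominant source of
   cfDNA), so any fully methylated molecule at a panel region is
   presumptive tumour material.
2. **Dense CpGs, short products.** Each amplicon is under 150 bp —
   matched to cfDNA fragment sizes — and contains several CpGs between
   the primers (3–21 by design). Requiring a read to be methylated at
   *every* scored CpG makes the per-read false-positive probability decay
   geometrically with CpG count: isolated methylation errors do not
   produce fully methylated reads.
3. **Methylation-biased primers.** Primers are designed on the fully
   methylated bisulfite-converted strand and typically contain 2–3 CpGs,
   so they preferentially (but not exclusively) amplify methylated
   templates. This is what lets tumour fractions below the 0.1 read
   threshold still produce detectable signal.

Per probe and sample the statistic is the fully-methylated-read fraction
$f$ over filtered reads; per sample, the Methylation Index
$\mathrm{MI} = \#\{\text{probes}: f \ge 0.1,\ \text{pass reads} \ge 100\}$
over the MI-eligible (non-BRCA1) probes, with a positive call when
$\mathrm{MI} > 2.5$. All three constants reflect the assay's validated
operating point, and all are exposed as arguments.

## Why these thresholds

* **0.1 fraction cutoff** separates the empirical bimodal distribution of
  $f$ (regions behave all-or-none within a molecule); it is applied as
  "at or above", so $f = 0.1$ exactly is positive.
* **100-read floor**: probes with very few reads can show spurious
  methylation (plausibly partially converted templates amplified in the
  absence of competition); requiring $\ge 100$ passing reads removes that
  failure mode, so low-depth probes are "not evaluable" and count as
  negative (renormalising MI by evaluable probes is deliberately *not*
  done; the validated index is a plain count).
* **MI threshold 2.5**: controls carry occasional sporadic positives
  (observed range 0–2), so the strict rule MI $\ge$ 3 keeps specificity
  at 100% while remaining sensitive; MI is integer, so 2.5 is an
  unambiguous separator.

# Discovery from beta matrices

Selection works on the centered beta scale $\beta' = \beta - 0.5$: a CpG
is a candidate when at least 50% of tumour samples have $\beta' > -0.1$
(i.e. $\beta > 0.4$) and each normal tissue's mean $\beta'$ is below
$-0.3$ (mean $\beta < 0.2$). The thresholds are quoted on the centered
scale because that is how the original criteria were stated; the
centering offset is an argument, so an M-value or raw-beta reading can be
substituted. Two further choices were genuinely open and are resolved as
follows:

* "normal tissue averages" are computed **per tissue**, not pooled — a
  pooled mean would let one unmethylated tissue mask another's signal;
* "within 300 bp" is measured **between CpG cytosine coordinates** and
  chained (single linkage), so a run of CpGs each within 300 bp of its
  neighbour forms one region; regions need at least two members.

Missing betas are excluded pairwise and never imputed. Coordinates are
0-based half-open internally and in BED output. The blood-methylation
screen is implemented as interval subtraction against a user-supplied
mask; overlap of a single base disqualifies a candidate, while abutting
intervals do not. Prognostic or clinically motivated regions can be
force-included downstream of selection — they pass primer validation like
any other region but never re-enter the selection statistics.

Primer constraints mirror the design settings (product 75–150 bp, primer
21–31 bp, Tm 64/68/72 °C with ≤ 5 °C pair difference, ≥ 2 inter-primer
CpGs). Melting temperatures use nearest-neighbour thermodynamics
(unified parameter set, 500 nM primer, 50 mM Na⁺ defaults); the original
panel was designed with commercial software whose exact Tm model is not
public, so Tm agreement is advisory — constraint checking, not primer
design, is the supported operation.

# Read processing

Reads are filtered to length **strictly greater than 100 bp** (the
sequenced products carry universal primer tails, so genuine product reads
exceed this), demultiplexed by forward-primer prefix with up to 2
mismatches (ties go to an unassigned bin; 0 mismatches reproduces exact
barcode splitting), primer-trimmed, and aligned to the probe's fully
methylated converted reference.

Alignment is global with free end gaps, match +1, mismatch −1, linear gap
−2 (all configurable), computed by `Biostrings::pairwiseAlignment` with a
substitution matrix in which a read **T opposite a reference C scores as
a match**. In a converted reference the only remaining cytosines are CpG
cytosines, so this is exactly CpG-aware C/T matching: an unmethylated
read has identity 1 against the methylated reference. Identity is
matching columns over alignment columns of the aligned region. A read
passes at identity ≥ 0.90 — the "90% homology" rule, which the original
pipeline delegated to BiQ Analyser HT without publishing a formula; this
operationalisation keeps CpG positions in the denominator. Each scored
CpG is read off the alignment: C → methylated, T → unmethylated, anything
else (gap, other base) → ambiguous, and a read with any ambiguous CpG
fails ("all CpGs identifiable"). Reads shorter than half the amplicon are
rejected as `short_alignment`. Base qualities are carried but unused, as
in the reference tooling.

One consequence of C/T-aware matching worth knowing: a deletion of a
methylated CpG cytosine can re-align its neighbouring T onto the
reference C and read as unmethylated rather than ambiguous. This mirrors
the behaviour of bisulfite aligners generally and is one reason the
identity filter and multi-CpG requirement exist.

# The simulator

The generator makes every stage testable without external data and
encodes the assay's assumptions explicitly:

* **Templates are all-or-none**: a read derives from a fully methylated
  tumour template (with probability given by the tumour fraction,
  re-weighted by amplification bias) or a fully unmethylated background
  template. Partial methylation exists in the model only as conversion
  noise.
* **Noise model**: unmethylated cytosines convert with probability 0.99
  (failures appear as spurious methylation), methylated CpGs read as
  converted with probability 0.005, substitutions occur at 0.005 per
  base. These are typical bench values for fast bisulfite kits and
  amplicon sequencing; indel noise is deliberately excluded by default so
  that exact oracle checks stay meaningful.
* **Primer footprints are primer-derived**: PCR overwrites the footprint
  with the (methylated-converted) primer sequence regardless of template,
  so footprint CpGs never inform the call — only inter-primer CpGs are
  scored, as in the assay.
* **PCR is collapsed** into a Poisson depth per probe plus an optional
  methylated-template sampling weight (`meth_bias`). The true magnitude
  of the primers' methylation bias is not quantified publicly, so the
  default is 1 (off); experiments that probe sub-threshold tumour
  fractions enable a per-probe log-uniform bias in 1–60, representing a
  primer pair with 2–3 CpGs spanning weak to strong preference.
* **Sporadic control background** is independent per probe and sample
  (rate 0.014 ≈ the observed ~0.8 positives per 54-probe control),
  reflecting that control positives show no inter-probe association.
* **Heterogeneity between tumours** is modelled by a per-probe
  methylated-compartment flag with probability 0.6 (roughly the observed
  half-of-panel positivity of typical tumours).

All randomness flows through one seed; identical configurations are
byte-identical on disk. Every emitted read is backed by a truth-table row
(template origin, planted states), which the tests reconcile exactly.

Two simulator-versus-reality caveats bound what passing tests demonstrate.
First, simulated amplicons used in end-to-end experiments are drawn at
105–150 bp so that bare amplicon reads survive the >100 bp retention
rule; real reads carry universal primer tails that provide this margin
for shorter products. Second, the simulator does not model cfDNA
fragment-length distributions, polymerase error accumulation, or
Ion-Torrent-style homopolymer indels (available behind the substitution
model only); recovery results on synthetic data therefore validate the
decision rules and their implementations, not platform-specific error
robustness.

# Numerical and testing choices

* Alignment scores are integers under the default scoring, so the
  brute-force dynamic-programming oracle in the test suite compares
  exactly, with no tolerance.
* AUC is the rank statistic (ties ½), verified against exhaustive
  case–control pair enumeration; sensitivity at 100% specificity is
  "strictly above the maximum control score".
* Discovery experiments use matrices of 300–1000 CpGs with planted
  clusters at 50 bp spacing and background CpGs 1000 bp apart, 10–20
  tumours and 4 samples per normal tissue, 50–200 noise replicates —
  sizes chosen so the whole suite exercises every stage in a few minutes
  while keeping Monte-Carlo rates stable.
* End-to-end cohorts use 10–20 probes at depth 150–1000 and 15–20
  cases/controls; at these depths the binomial error on a fraction of
  0.3 is ~±0.04 at 99% confidence, which the quantitative-recovery test
  asserts probe by probe.
* Degenerate inputs fail loudly: unsorted CpG tables are refused rather
  than re-sorted, probes with zero scored CpGs build with a warning but
  can never be "fully methylated", empty cohorts and single-class ROC
  inputs error.

# Known limitations

* Only the top converted strand is modelled; bottom-strand (G→A)
  conversion and paired-end reads are out of scope.
* Conversion efficiency is a fixed noise parameter and is not estimated
  from non-CpG cytosines, although the data would support that
  extension.
* The CHIP filter implements the published record-level rules; visual
  review is approximated by a coordinate blacklist.
* Replicate samples are reported separately; no averaging rule is
  applied.
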