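---
title: "Methods and modeling decisions in clonetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling decisions in clonetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clonetrace analyzes cellular-barcoding experiments: tumor cells are tagged
with heritable semi-random DNA barcodes from a lentiviral library (~2500
98-bp barcodes), transplanted into mice, and the clonal composition of
tumors, tumor pieces, blood and distal organs is read out by amplicon
sequencing. This vignette records the models the package implements, the
parameters that matter, and the choices made where the underlying assay
description leaves the design open.

## The measurement model

A sequencing read has the fixed structure
`[8-bp sample index][constant 5' flank][98-bp barcode][constant 3' flank]`.
Demultiplexing anchors on position: the index is matched exactly (8 bp
leaves little headroom for mismatch rescue, so rescue at Hamming distance 1
is off by default), the 5' flank must match exactly, and the barcode is
looked up in the reference library allowing up to `max_mismatch = 2`
Hamming mismatches. A read equidistant from two library barcodes is
rejected as ambiguous rather than assigned arbitrarily; every rejected read
is tallied in an unassigned count with its reason, so that assigned +
unassigned always equals the input read count. These tolerances are
package decisions: the assay description delegates read splitting to a
generic pipeline without stating its settings.

## Quality filters and normalization

Three rules are applied in a fixed order, and the order matters:

1. **Replicate depth.** Technical-replicate rows with fewer than 8000
   assigned reads are removed, and samples left with fewer than two
   replicates above that threshold are removed entirely. 8000 reads is the
   assay's stated reliability floor for a PCR replicate.
2. **Replicate support.** Within a sample, a barcode detected (count >= 1)
   in fewer than two technical replicates is zeroed. This targets
   non-reproducible PCR/index artifacts, which appear in a single
   replicate. "Detected" means at least one read: no per-replicate count
   floor beyond presence is applied, the most literal reading of the rule.
   Running this filter before the depth filter would let a shallow,
   artifact-bearing replicate lend spurious barcodes a second vote, which
   is why the order is fixed and tested.
3. **Pooling and normalization.** Same-run replicates are pooled by adding
   reads and normalizing the sum to one. Replicates that span sequencing
   runs are each normalized to one first, then summed and renormalized, so
   that a deeper run does not dominate the pooled profile.

Depth totals are computed over barcode-assigned reads only — the matrix the
filters operate on contains nothing else. No minimum-frequency threshold is
applied after normalization; the replicate-support rule is the only
barcode-level filter. Samples that end up empty are kept in QC reports but
excluded from statistics, so clone-count comparisons never silently include
zeros.

## Clonal statistics

- **Engraftment**: detected clones / injected cells (2500 by default).
- **Dispersion**: pieces in which a barcode is detected / total pieces per
  tumor, pooled over mice without per-mouse reweighting when aggregated.
- **Biomass representation**: the sum of *primary-tumor* frequencies of
  barcodes shared with a distal tissue — "how much of the tumor do the
  disseminated clones represent".
- **Fold-change classes**: distal/tumor frequency ratio over shared
  barcodes, thresholded at 10-fold by default.
- **Diversity**: Shannon \(-\sum p_i \ln p_i\) in nats and the Simpson
  index \(\sum p_i^2\), the probability two random cells share a clone.
  The classical \(\sum p_i^2\) orientation was chosen because the source
  assay never writes the formula; `complement = TRUE` switches to the
  Gini-Simpson \(1-\sum p_i^2\) if the opposite axis direction is wanted.
- **Cross-tissue regression**: OLS of log10 frequency on log10 frequency
  restricted to barcodes detected in both tissues. No pseudocounts
  anywhere: single-tissue barcodes are reported separately (the "on the
  axis" points of the scatter), never imputed into the fit. Log base 10
  matches decade-scaled axes; the Welch test on log values is base-
  invariant.

## Spatial reconstruction

Pieces of a cut tumor are compared by Hellinger distance,
\(H(p,q)=\frac{1}{\sqrt2}\lVert\sqrt p-\sqrt q\rVert_2\) over the union
barcode set — a bounded metric on frequency profiles that is insensitive to
barcode relabeling and shared zeros. The 2D reconstruction minimizes a
weighted stress between embedded and Hellinger distances by SMACOF
majorization with Kamada–Kawai weights \(w_{ij}=1/d_{ij}^2\). A
"force-directed graph" was asked of this component; stress majorization is
the deterministic, seedable member of that family, with a guaranteed
non-increasing stress sequence (which the tests assert). Initialization is
a seeded uniform configuration; the layout is reproducible given the seed
and arbitrary up to rigid motion. Hierarchical clustering uses average
linkage on the Hellinger matrix for pieces (a conventional default for
compositional distances — no linkage was specified) and Euclidean distance
on square-root frequencies for barcodes.

## The proportional-shedding null model

The null hypothesis for dissemination: every clone sheds cells into blood
or lung in proportion to its size in the primary tumor. A virtual distal
sample is then one multinomial draw of \(n\) cells over the tumor
frequencies, with \(n\) the number of cells FACS-sorted for the real
tissue. Cells, not reads, are resampled — read-depth noise belongs to the
synthetic-data generator, not to the null. For each statistic (clone
count, biomass representation, log10-frequency correlation with the
tumor), the observed value is compared to the null replicates by the
empirical two-sided p-value with the \((r+1)/(n+1)\) correction, which
cannot produce p = 0. The closed form
\(E[K]=\sum_i\bigl(1-(1-p_i)^n\bigr)\) for the expected number of detected
clones serves as the analytic oracle the Monte-Carlo path is tested
against; \(E[\text{biomass}]=\sum_i p_i\bigl(1-(1-p_i)^n\bigr)\) likewise
verifies the monotonicity of null biomass in \(n\).

The calibration test draws observed data from the null itself and checks
that p-values are approximately uniform. It uses the biomass-representation
statistic because it is continuous when tumor frequencies are continuous;
the clone count is integer-valued and its ties make a Kolmogorov–Smirnov
uniformity check inappropriate for any implementation.

## The 3D growth simulator

Cells occupy a cubic lattice, one per site. Per cell: division at rate
`b`, placing a daughter carrying the same barcode in a uniformly chosen
empty neighbor (suppressed when none — contact inhibition confines most
division to the surface); death at rate `d`; migration to an empty
neighbor at rate `M`. Growth starts from a compact cluster of 200 cells
with distinct barcodes, mirroring the experimental inoculum. Surface-
limited growth from 200 founders is what generates the broad clone-size
distributions and spatial patches the package's other modules measure.

The upstream work this emulates ran an established off-lattice C++ model
with unpublished parameters; this package's defaults are therefore its own:
`b = 1` (sets the time unit), `d = 0.1 b`, `M = 1e-3` per unit time, von
Neumann neighborhood, and a desk-scale target of 1e5 cells (real tumors are
1e7–1e8; only qualitative agreement is claimed at this scale). The core is
C++ (Rcpp) because reaching 1e5 cells takes millions of events; it consumes
R's RNG, so `set.seed` gives bit-level reproducibility end to end.
`virtual_cut` partitions cells into eight octants by recursive median
splits (balanced to within one cell), equal-count slabs, or seeded k-means
regions, and emits piece-level counts in the same schema as sequencing
data, so simulated tumors flow through the identical downstream code.

## The synthetic-data generator

`generate_ground_truth` states a world and `synthesize_counts` observes it
with the assay's noise:

- **Engraftment**: each of 2500 injected cells engrafts independently with
  probability 0.10 (the observed order of engraftment in this assay
  family).
- **Clone sizes**: log-normal with `sdlog = 2.5`, spanning ~6 orders of
  magnitude as real barcoded tumors do; a Pareto option exists. The real
  distribution was shown but never parameterized; this is the package's
  calibration choice and is not revisited.
- **Pieces**: clones occupy contiguous windows of a chain of 8 pieces,
  wider windows for larger clones, with lognormal per-piece noise — so
  adjacent pieces share clones and frequency correlates with dispersion.
- **Shedding**: blood and lung frequencies are tumor frequency times
  lognormal noise (`sigma_shed = 0.5`, calibrated only qualitatively to
  the scatter such assays show). Post-resection lung is supported only on
  a small "seeder" subset (5% of shedders) at frequencies drawn
  independently of the tumor, reproducing the observation that seeders do
  not correlate with their parental clones.
- **Noise**: replicate depths are log-normal around 1e5 reads; a
  configurable fraction is forced below the 8000-read threshold to
  exercise the depth filter; spurious barcodes are drawn from the
  *unengrafted* remainder of the library (mimicking index hopping/PCR
  chimeras) and injected into exactly one replicate each, which is
  precisely the signature the replicate-support filter removes. Sorted
  cell counts default to 1000 (blood) and 2000 (lung), consistent with
  distal compartments ~1e5-fold smaller than the tumor.
- **Treatment**: chemotherapy is modeled only as a per-clone survival
  probability (default 0.8, the observed order of clone survival), enough
  to exercise diversity comparisons; no pharmacology is modeled.

A green end-to-end test on this generator establishes that the pipeline
recovers a known truth under the stated noise model. It does not establish
performance on real data: the generator has no PCR amplification bias, no
base-level sequencing error (beyond an optional uniform substitution in
read rendering), no index cross-talk between real samples, and its
shedding noise is a single lognormal factor.

## Numerical conventions and degenerate inputs

Profiles must sum to 1 within 1e-9 (1e-6 on entry to distance
computations, where upstream rounding may have accumulated). Empty
profiles are valid objects that downstream statistics refuse with clear
errors rather than propagate as zeros. Hellinger weights in the layout are
clamped at `d >= 1e-8` to keep coincident pieces finite. The layout stops
when the relative stress change falls below 1e-10 or after 500 iterations.
Distance ties in demultiplexing reject the read; ties in median splits are
broken by cell index, keeping cuts deterministic. All stochastic entry
points take explicit seeds and restore the caller's RNG state.

## Known limitations

- The demultiplexer is exact-match on index and flank by design; it does
  not model sequencing quality scores at all.
- The lattice simulator is a minimal variant: no driver fitness classes,
  no off-lattice mechanics, no vasculature; only qualitative reproduction
  of patch structure at 1e5 cells is claimed.
- The null model tests proportional shedding only; it cannot infer
  shedding rates.
- Group-level K-S summaries average within-group pairwise p-values, a
  reproducibility heuristic of the source assay, not a calibrated test.
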