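---
title: "Modeling chromatin contact maps from sequence and chromatin-associated RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromatin contact maps from sequence and chromatin-associated RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chromatin-associated RNAs (caRNAs) sit on chromatin either near their
transcription site (nascent transcripts) or far from it (trans-located
caRNAs, defined here as RNA-DNA contacts spanning more than 2^20 bp or
crossing chromosomes). Both populations correlate with features of 3D
genome folding — TAD boundaries, loop anchors, nuclear bodies — but
correlation alone cannot say whether the RNA signal carries information
beyond, say, chromatin accessibility. `carnafold` frames the question as a
prediction task: how much does adding caRNA feature channels to a
sequence-based contact-map predictor improve its accuracy, and where do
the learned models place the contribution?

# Target maps

DNA-DNA pairs are binned at 2048 bp (2^11), ICE-balanced genome-wide, and
low-support entries are filled by adaptive coarse-graining, re-implemented
here as dyadic neighborhood averaging: an entry whose raw support is below
`min_count` (default 8) takes the mean balanced value of the smallest
aligned 2^l x 2^l block whose summed raw support reaches the threshold.
The contract — fill low-coverage entries from coarser scales — is what the
downstream steps need; we do not attempt to bit-match any particular
implementation of the idea.

Each ~1 Mb window (2^20 bp, 512 bins) is then normalized
observed-over-expected *within the window* (the model's targets are
per-window, so the expected value at each diagonal offset is computed from
the window itself), log-transformed, clipped to (−2, 2), linearly
interpolated across masked bins along rows and columns, symmetrized, and
smoothed with a 2D Gaussian (σ = 1 bin, truncated at 2σ; configurable —
no canonical value exists for this step). We clip once before and once
after smoothing: interpolation and smoothing of clipped values can move
them only inward, so the final clip is a no-op guard that makes the
invariant `values ∈ [−2, 2]` unconditional. The order
interpolate → smooth → re-clip is a documented choice; the alternative
(clip strictly last) differs only at machine precision on real data.

# Feature channels

RNA-DNA pairs are parsed with the RNA end as side 1. Records with
MAPQ ≤ 30 are dropped. Nascent transcription is the count of RNA ends per
bin. Trans-located signal keeps contacts beyond 2^20 bp or across
chromosomes, removes self-interactions of genes longer than 2^20 bp, and
splits DNA-end counts into eight groups by the annotation at the RNA end:
snRNA, snoRNA, other small RNA, lncRNA, misc_RNA, protein-coding, other
gene, unannotated. When a position overlaps several genes the priority is
snRNA > snoRNA > other small RNA > misc_RNA > lncRNA > protein-coding >
other — small-RNA annotations beat their host genes, which is what makes
snoRNAs nested in protein-coding genes countable at all. The mapping from
annotation biotypes to groups and the priority order are both
configurable.

All feature channels enter the model as log(1 + x). The log transform on
raw counts needs a convention at zero; log1p is the minimal one that is
finite at 0 and asymptotically log(x). External signal tracks (ATAC-seq,
RNA-seq) are averaged per bin, scaled to the iMARGI library size (total
retained read pairs), and log1p-transformed the same way.

# The predictor

The network is a compact convolutional architecture: a trunk of
`log2(bin_bp)` = 11 blocks (1D convolution, per-channel normalization,
ReLU, max-pool by 2) takes one-hot DNA to one embedding per bin; feature
channels are concatenated to the embedding; a width-1 projection and a
dilated 1D stack (kernel 3, dilation 1, 2, 4, residual) spread long-range
context; positions are averaged into pair representations
P[i,j] = (u_i + u_j)/2; a dilated 2D stack refines the map; and a 1x1
convolution plus explicit symmetrization emits the output, so exchange
symmetry is exact rather than approximate. Convolution forward/backward
kernels are compiled (RcppArmadillo); everything else is R.

Normalization is per-sample per-channel (instance-norm style) in both
training and inference rather than batch statistics with frozen running
averages: it is exactly deterministic, has no train/test discrepancy, and
at the batch sizes used here batch statistics would be noisy anyway. This
is a deliberate deviation from the batch-normalization convention and the
only place the architecture departs from the standard recipe.

The objective is `1 − r`, the negative Pearson correlation over the upper
triangle at diagonal offset ≥ 2 — pixel-wise MSE is dominated by noise on
these maps. Pearson fixes predictions only up to an affine transform, so
after training a least-squares affine calibration (fit on the training
windows) maps raw outputs into target units; the correlation structure is
untouched and MSE becomes meaningful. Training uses minibatch Adam
(default lr 3–5e-3, batch 4, weight decay 1e-5–1e-4) with optional
reverse-complement augmentation (each example presented in a random
orientation per epoch, with the map flipped accordingly); augmentation is
what pushes the trunk toward motif-based rather than memorized solutions.
Each model is trained as five seeded replicates and the replicate with the
best mean rank over (validation MSE ascending, validation Pearson
descending) is selected.

Zero-variance targets yield loss 1 with a warning and a zero gradient; a
NaN loss aborts the replicate and is reported rather than silently
retried.

# Attribution

Contribution scores use expected gradients: integrated gradients (midpoint
rule, 8 steps by default) averaged over a background set, which satisfies
the completeness property up to integration error and exactly for linear
models — the linear closed form `w ⊙ (x − mean(background))` is a unit
test. Backgrounds follow the split scheme: validation/test windows draw 20
random training windows; the training split is halved and each half uses
the other as its pool. The attributed scalar is the mean predicted contact
value of the window over the scored band; this choice is config-exposed.
Raw scores are normalized per feature by the maximum absolute value across
the evaluated split (per-window mode available), preserving sign, so
normalized scores live in [−1, 1] with at least one bin attaining ±1.

Downstream: extreme regions are the top/bottom 1 % or 5 % of bins with
positive input values (ties broken by genomic order); enrichment is
log2(observed/expected overlap fraction) against annotation interval
sets; differential bins require caRNA-over-ATAC fold > 5 (infinite at zero
ATAC score — the magnitude gate still applies) and |score| > 0.25; and
high-confidence RNA-DNA interactions come from the one-sided
hypergeometric test per (gene, bin) pair with BH correction at FDR ≤ 0.05
over pairs with at least one contact (zero-count pairs have p = 1 and
would only dilute the correction). Candidate RNAs are ranked by the count
of high-confidence interactions landing in extreme regions, ties broken by
ratio; both statistics are emitted because no single canonical ranking
exists.

# Perturbation experiments

`insert_ctcf()` writes k forward and k reverse-complement copies of a
19-bp CTCF consensus (one fixed JASPAR-style consensus by default; PWM
sampling would be a drop-in alternative) at exact 500-bp spacing,
convergent and symmetric about a locus drawn from the central 15–85 % of
the sequence, replacing bases in place. `ctcf_response()` summarizes the
mean predicted contact and the insulation strength at the locus over k,
with two-sided Mann-Whitney tests between consecutive k.

`elevate_carna()` multiplies the raw-scale signal (expm1 of the stored
features) at chosen boundary bins by a fold and re-applies log1p, leaving
every other channel bit-identical; `elevation_response()` tracks the
change in insulation strength and mean contact over folds e^0.5 … e^2.
"Regions with relatively simple structures" is operationalized as windows
with at most K planted/called boundaries (default 2 at desk scale).

Insulation is the diamond-window mean along the diagonal (half-width
configurable, default 10 bins at full scale, scaled to the map at desk
scale), with bins whose diamond does not fit left undefined. Boundary
strength is the flanking-mean-minus-minimum depth of the profile at the
boundary bin.

# R-loop scan

`rloop_scan()` takes the best gapped local alignment (match +2, mismatch
−1, gap open 2, gap extend 0.5 — the cited alignment tool's common
parameterization; config-exposed, and the decision statistics are only
weakly scoring-sensitive) of the RNA sequence against both strands of the
DNA sequence. Identity is matched bases divided by the RNA sequence
length — the stricter reading of "over 80 % of the RNA sequence
matching"; identity over the aligned span is available as an alternative
interpretation. A pair is a candidate when identity > 0.80 and the longest
contiguous perfect match exceeds 10 bp.

# The synthetic-data generator

Every experiment in the package runs on synthetic data with planted,
recoverable structure. Chromosomes are i.i.d. bases at 42 % GC
(human-like). TAD boundaries attenuate crossing contacts by
exp(−strength); contacts otherwise decay as distance^−1; loops boost
their anchor bin pair. Boundaries optionally carry convergent CTCF motif
arrays written into the sequence (strength 0.7 per copy in the
sequence-coupled studies). RNA-DNA contacts are emitted per gene at a
configurable expression level with a cis fraction of 0.6 by default
(matching the ~40 % trans share seen in fibroblast iMARGI data), MAPQ
drawn from a mixture exercising the ≤ 30 filter, and optional targeted
reads that deposit caRNA signal at chosen bins. Planted homologies copy a
gene subsequence into a distal locus with controlled identity and longest
perfect run.

What the generator does *not* emulate: sequencing error, mappability
structure, compartment-scale checkerboards, replication timing, cell-type
mixtures, or realistic motif grammar beyond the single planted consensus.
Passing tests therefore certify the pipeline's mechanics and the model's
ability to use the channels it is given — not performance on real
chromatin.

# Desk-scale study conditions

The training studies are sized for a single CPU: windows of 2^15 bp
(16 bins) for the comparison studies and 2^17 bp (64 bins) for the
overfit check, 3 x 10^4–10^5 read pairs per window, 12–48 training
windows, 30–60 epochs. With these conditions the feature-bearing model
reaches validation Pearson ≈ 0.7–0.8 where the sequence-only model
plateaus at the average-map baseline (≈ 0.5), the overfit run exceeds
r = 0.8 on its training windows, and both perturbation responses are
monotone in the planted direction. The full-scale configuration
(2^20-bp windows, 512 bins) is the package default for real data.

# Known limitations

* The predictor is a compact network sized for desk-scale studies; on
  real genomes it would need wider trunks and longer training than the
  defaults.
* The CTCF-insertion response separates boundary presence robustly (zero
  versus any motifs) but orders motif counts 1–4 only marginally at desk
  scale, for identifiable reasons: the per-window Pearson objective is
  invariant to each window's scale, so absolute boundary depth is
  supervised only through the relative depths of coexisting boundaries;
  max pooling collapses motif copies that fall into the same pooled unit
  (the `trunk_pool = "avg"` option preserves copy number as amplitude);
  and per-sample normalization couples the output to global sequence
  statistics, so every edited base adds output drift comparable to the
  per-copy effect. The experiment therefore trains two seeded replicates
  and keeps the one whose predicted boundary depth best tracks the
  planted motif count on held-out windows — the same best-of-replicates
  logic used for model selection generally — and averages the response
  over 100 random sequences; even so, the k = 1..4 ordering of mean
  contact can fail for unfavorable simulation seeds. The `mse_weight`
  training option exists to anchor absolute scale where that trade-off
  is wanted.
* Attribution cost grows as backgrounds x steps forward/backward passes
  per window; the defaults (20 x 8) are practical at 512 bins but the
  knobs exist for a reason.
* The hypergeometric independence assumption (each DNA bin equally likely
  to contact any RNA) is the stated null, not a claim about biology;
  enrichment against it should be read accordingly.
* `trans_proportion()` can in principle exceed 1 when host-gene
  subtraction removes nascent reads faster than trans reads; such genes
  are flagged, not clipped.
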