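---
title: "Calling deletions from long-read alignments with delnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling deletions from long-read alignments with delnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural deletions — losses of 50 bp to several kilobases — are among the
hardest germline variants to call reliably. Long reads (1–20 kb) span most
deletions outright, so the evidence for a deletion is written directly into
each read's CIGAR string as a `D` operation: a run of reference bases absent
from the read. The difficulty is separating genuine deletion signals from
the dense background of small spurious indels that long-read sequencing
chemistry and alignment produce, and doing so at positions the caller has
never seen. delnet treats this as a supervised sequence-classification
problem over genome windows, followed by a deterministic breakpoint
refinement step.

## Window feature matrices

The reference is tiled into non-overlapping windows of `m = 200` bp. For
every window, each overlapping read contributes an m-length binary bitmap:
position `j` is 1 exactly when the read's alignment places a `D` operation
over reference base `start + j`. Bitmaps are sorted by deletion count in
descending order, the first `n = 18` rows are kept (zero-padded when fewer
reads align), giving an `18 x 200` matrix per window. The row sort makes
the representation invariant to read order and concentrates the strongest
evidence in the top rows; the count of overlapping reads `p` is recorded
but not part of the matrix. Ties in the sort are broken by read name so
extraction is bit-reproducible. A window shorter than `m` at a contig tail
is zero-padded on the right; the orientation (reads on rows, window
positions on columns) is recorded in the serialized container and checked
against the model configuration at load time.

Only `D` operations count: `N` (skip) operations also consume reference
but represent spliced or skipped segments, not deletions. Unmapped,
secondary and QC-fail records are skipped; supplementary alignments are
kept because split reads carry deletion evidence. Mapping-quality
filtering is available but defaults to 0 (permissive).

## The classifier

Windows are scored in runs of `T = 100` consecutive windows, so the
recurrent core can use the fact that a multi-window deletion produces
correlated evidence in adjacent windows. The architecture:

* a fixed `1 x 2` average pool along the position axis (halves compute at
  no information cost for 1-bp-resolution binary evidence);
* six convolutional blocks, each `3 x 3` same-padding convolution → ReLU →
  squeeze-and-excitation channel re-weighting (global average pool and a
  two-layer `1 x 1` bottleneck, reduction 4) → max pool. Filter counts
  default to 4, 8, 16, 32, 64, 160; the last block's global average pool
  yields the window's `F = 160`-dimensional embedding;
* two bidirectional LSTM layers of 64 units per direction over the T
  embeddings;
* a head of two fully connected layers (64 and 32 units, dropout 0.4 after
  each) and a sigmoid output per window.

The published description of this architecture fixes `m`, `n`, `T`, `F`,
the 1x2 average pool, the number of blocks, the SE structure, the LSTM
sizes and the dropout rate, but not the per-block filter counts, kernel
sizes, SE reduction or head widths; the defaults above were chosen once so
that the encoder output is exactly 160-dimensional and the whole model
stays under one million parameters (~0.38 M), and they are all exposed in
`model_config()`.

delnet implements the network and its backpropagation itself: forward and
backward passes are expressed as dense matrix algebra, with the
allocation-heavy encoder kernels (im2col convolution, SE scaling, pooling)
in compiled code. The test suite verifies every analytic gradient against
central finite differences, and one LSTM step against the gate recursion
evaluated directly. Weight initialisation is He-uniform for ReLU layers
and Glorot-uniform elsewhere, with forget-gate biases at 1 and SE gate
biases at 2 (so channel gates start nearly open; with six multiplicative
gates in series, a neutral 0.5 starting gate attenuates activations
64-fold and slows early learning). Initialisation is seeded and recorded.

## Loss and training

Curated truth sets for structural variants are incomplete but precise:
a call absent from the truth set may simply be missing from it, while a
truth deletion missed by the model is almost certainly a real error. The
training loss therefore penalises the two mistakes asymmetrically:

    loss = ( ln(prediction - label + 1 + a) )^2,  a = 0.001

At a perfect prediction the loss is ~0; a missed true deletion costs
`(ln a)^2 ≈ 47.7` while an unconfirmed positive costs only
`(ln(2 + a))^2 ≈ 0.48`. The square applies to the logarithm, not inside
it — the other reading would make the loss negative for arguments below 1
and reward missed deletions, contradicting the loss's own design goals.
The gradient is clamped where the argument could underflow.

Training uses Adam at learning rate 0.001, epoch-wise shuffling with a
recorded seed, and a deliberately large gradient-step size (default 512
windows, i.e. about five T-window samples) so that each step sees some of
the rare positive windows — typically 97–99% of windows are negative.
Early stopping monitors window-level validation AUC with patience 10,
keeping the best-on-validation weights. Loss and calling both ignore the
zero-padded windows that complete a contig's final batch.

## From window scores to deletion calls

Windows scoring strictly above 0.5 are deletion candidates; maximal runs of
adjacent positive windows merge into candidate regions, since a deletion
longer than one window flags several in a row. Within each region, every
aligned read donates one `(location, size)` signature per CIGAR `D`
operation larger than 20 bp. Signatures are sorted by location and
clustered with single-linkage chaining at radius 40 bp: a signature joins
the current cluster when it lies within 40 bp of its predecessor. The
pairwise rule `|L_i - L_j| < 40` is ambiguous for chains (A near B, B near
C, A far from C); single linkage on sorted locations is the deterministic,
order-independent closure of that rule, and a centroid variant (join while
within 40 bp of the running cluster mean, which refuses long chains) is
available behind `linkage = "centroid"`. The largest cluster — ties going
to the smaller mean location — is averaged (half-up rounding) into the
final call's position and size, with the cluster size reported as support.
One call is emitted per region; multi-allelic regions are a documented
limitation. A region with no qualifying signatures falls back to its own
bounds, flagged IMPRECISE with support 0, rather than being silently
dropped — the classifier asserted a deletion and the disagreement is
surfaced to the user.

Signatures are restricted by default to `D` operations intersecting the
region grown by the cluster radius. With 10–20 kb reads, a read aligned in
one region often spans a *different* deletion a few kilobases away; under
the literal any-signature-of-any-aligned-read rule those distant
signatures form large competing clusters and can displace the region's own
deletion. The restriction keeps refinement local to the evidence the
region was called on (`within_region = FALSE` restores the literal rule).

Calls smaller than 50 bp are dropped — the conventional lower bound of the
structural-variant size class — and written as VCF 4.2 symbolic `<DEL>`
records with `SVTYPE`, `SVLEN`, `END`, `SUPPORT` and `IMPRECISE` INFO
fields. Internally all coordinates are 0-based half-open; `POS` in the VCF
is the 1-based first deleted base and `END = POS + size`. Genotypes are
emitted as `./.`: the method does not genotype.

## The simulator

`simulate_genome()` / `simulate_alignments()` generate the fully controlled
study condition used for training and acceptance: a uniform-random
reference; non-overlapping deletions (uniform sizes within 50 bp – 5 kb,
positions uniform subject to a spacing of two window widths so labels are
unambiguous); and long reads emitted *pre-aligned*. Read lengths are
log-uniform over 1–20 kb — mirroring the average-length spread of current
long-read datasets without claiming their exact distribution — and read
starts are uniform over the donor (deletion-applied) genome until the
target coverage is met. Because each read's CIGAR is constructed exactly
from its known donor-to-reference mapping, an implanted deletion appears as
a `D` operation of the true size at the true reference offset, making
downstream assertions exact rather than statistical. Two noise processes
are injected: spurious small deletions (default rate 5e-4 per base, sizes
1–30 bp, deliberately straddling the caller's 20 bp signature filter so the
filter and the clustering are both exercised) and base mismatches (default
1e-3, affecting sequences only, since alignments encode matches and
mismatches alike as `M`). A noise deletion drops bases *within* a matched
run, leaving the read's reference span and the implanted deletions'
coordinates in register, exactly as a correct alignment would. An optional
heterozygous mode draws half of the reads from the unmodified reference.

What the simulator does not emulate: platform-specific error profiles,
insertions and other SV classes, alignment artefacts (clipping, split
reads, mapping ambiguity in repeats), GC or coverage bias, and reference
context (the sequence is uniform-random, so there are no repeats or
low-complexity traps). Passing the synthetic acceptance bars therefore
demonstrates that the implementation is correct and that the architecture
can learn and localise deletion signatures at realistic coverage and
noise — not that these bars would be met on real genomes, where the
published full-scale benchmarks required weeks of GPU training on
multi-sample alignment data.

`make_dataset()` mirrors a chromosome-disjoint split with three
independently seeded genomes (train/validation/test), warning if seeds
coincide.

## Evaluation

`match_calls()` scores a call set against truth with a documented
simplification of the standard SV benchmarking tool: a call matches a
truth deletion when start positions differ by at most 500 bp and the size
ratio is at least 0.7 (that tool's published defaults); pairs are matched
greedily by ascending breakpoint distance, one-to-one. Precision, recall
and F1 follow. `window_auc()` is the rank-based (midrank-tie) AUC used for
early stopping and reporting. Swapping calls and truths provably swaps
precision and recall, which the tests assert, and AUC is cross-checked
against brute-force pair concordance.

## Problem sizes and numerical choices

The packaged synthetic study (`easy_fixture_config()`, used by
`scripts/acceptance.R` and the acceptance tests) uses three 1-Mb genomes
with 20 deletions of 50–2000 bp each, 30x coverage and noise rate 5e-4 —
5,000 windows per genome, about 2.7% positive. Training runs up to 20
epochs of 10 gradient steps; validation AUC exceeds 0.99 within a few
epochs, but the probabilities keep sharpening well after the ranking has
converged, and the fixed 0.5 calling threshold rewards the extra epochs
with recall. Unit tests use a reduced architecture (the `toy_model_config()`
in the test suite) where the full encoder would add nothing.

Determinism: every stochastic step (genome placement, read sampling, noise
injection, weight initialisation, shuffling, dropout) draws from an
explicitly seeded generator, and reruns are bit-identical on a single
thread. Ties are broken lexicographically (read names) or by position
(cluster means) so no output depends on input order. Degenerate inputs are
contracts, not errors: no reads in a window yields an all-zero matrix with
`p = 0`; an alignment that does not overlap a window yields a zero bitmap;
an empty candidate-region list yields a header-only VCF; a training set
with no positive window is refused with an explanatory error.

## Known limitations

* One call per candidate region: two distinct deletions merged into one
  run of positive windows yield a single refined call.
* Cross-batch context is not shared; a deletion spanning a T-window batch
  boundary is scored with truncated context on each side.
* The evaluation matcher is intentionally simpler than publication-grade
  benchmarking tools (no sequence-resolved comparison, no genotype
  concordance, no ambiguous-region handling).
* Only deletions are modelled; insertions, inversions and duplications are
  out of scope.
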