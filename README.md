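# delnet

Deletion calling from long-read alignments with a time-distributed
CNN–BLSTM window classifier and signature-cluster breakpoint refinement.

## What it does, and for whom

Long reads (1–20 kb) span most structural deletions (≥ 50 bp) outright, so
the evidence is written directly into each alignment's CIGAR string as `D`
operations. delnet is for researchers who want a self-contained,
trainable deletion caller: it converts coordinate-sorted BAM/SAM
alignments into per-window deletion feature matrices, classifies window
sequences with a deep network, and refines positive windows into
breakpoint-accurate VCF calls. A built-in simulator generates reference
sequences, truth sets and pre-aligned noisy long reads, so the entire
pipeline can be trained, tested and benchmarked on one CPU without any
external data.

## The model

The reference is tiled into windows of *m* = 200 bp. For window *w*, read
*i* contributes a bitmap (d\_{i1}, …, d\_{im}) with d\_{ij} = 1 exactly
when the alignment places a `D` operation over base *j* of the window.
Bitmaps are sorted by deletion count (descending), truncated or
zero-padded to *n* = 18 rows, giving an n × m binary matrix per window.

Runs of *T* = 100 consecutive windows are scored jointly:

* **Encoder** (applied to each window): 1 × 2 average pool, then six
  blocks of (3 × 3 conv → ReLU → squeeze-and-excitation → max pool),
  then global average pooling to an *F* = 160-dimensional embedding.
* **Recurrent core:** two bidirectional LSTM layers, 64 units per
  direction, over the T embeddings.
* **Head:** two fully connected layers (dropout 0.4) and a sigmoid; a
  window is a deletion candidate when its probability exceeds 0.5.

Training minimises the class-asymmetric loss

    L(p, y) = ( ln(p − y + 1 + a) )²,  a = 0.001,

which charges a missed true deletion (ln a)² ≈ 47.7 but an unconfirmed
positive only (ln(2+a))² ≈ 0.48 — matching the character of curated SV
truth sets, which are incomplete but rarely wrong. Optimisation is Adam
(lr 0.001) with large shuffled batches and early stopping on validation
AUC (patience 10).

Adjacent positive windows merge into candidate regions. Each region's
aligned reads donate one (location, size) signature per CIGAR `D`
operation > 20 bp; signatures are clustered by location (single linkage,
radius 40 bp), and the largest cluster's mean location and size become
the call, written as a symbolic `<DEL>` VCF record (calls < 50 bp are
dropped). Forward and backward passes of the network are implemented in
the package itself (R + compiled kernels); every analytic gradient is
verified against finite differences in the test suite.

## Worked example

Simulate a 200-kb genome with eight deletions at 30× coverage, train,
call, and evaluate:

```r
library(delnet)

cfg <- simulation_config(genome_length = 2e5, n_deletions = 8,
                         deletion_size_range = c(60, 1500),
                         coverage = 30, seed = 42)
ds <- simulate_dataset(cfg)
head(ds$genome$truth, 3)
#>   contig start size
#> 1   sim1  5802  620
#> 2   sim1 49759  380
#> 3   sim1 66309 1236

model <- train(init_model(model_config(), seed = 1),
               list(featset = ds$featset, batches = ds$batches, labels = ds$labels),
               list(featset = ds$featset, batches = ds$batches, labels = ds$labels),
               training_config(max_epochs = 12, shuffle_seed = 9))

scored <- predict_windows(model, ds$featset)
calls  <- call_deletions(scored, ds$alignments)
head(calls[, 1:5], 3)
#>   contig start size support imprecise
#> 1   sim1  5802  620      14     FALSE
#> 2   sim1 49759  380      28     FALSE
#> 3   sim1 69852 1157      33     FALSE

match_calls(calls, ds$genome$truth)
#> deletion call evaluation: TP 5  FP 0  FN 3
#> precision 1.0000  recall 0.6250  F1 0.7692
```

The first two calls hit their implanted deletions at the exact base and
size; `support` counts the clustered read signatures behind each
breakpoint. (This is a deliberately small training set — a single 200-kb
genome used for both training and validation; the full synthetic study
below trains on three disjoint 1-Mb genomes and recovers deletions with
F1 ≈ 0.97–1.0.)

A command-line wrapper with `simulate`, `extract`, `train`, `call`,
`evaluate` and `end2end` subcommands is installed at
`inst/scripts/delnet`.

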