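# Independent brute-force oracles used across the suite. These share no
# code with the package implementation: the CIGAR walker advances one
# reference base at a time, the AUC oracle counts concordant pairs, and the
# clustering oracle takes the transitive closure of the pairwise relation.

# Per-base reference-coordinate CIGAR walker: returns the window-relative
# deletion bitmap (length m) of one alignment over [win_start, win_end).
walker_bitmap <- function(cigar, pos0, win_start, win_end, m) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  bits <- integer(m)
  ref <- pos0
  for (k in seq_along(ops)) {
    if (kinds[k] %in% c("M", "=", "X", "D", "N")) {
      if (kinds[k] == "D") {
        for (r in ref:(ref + lens[k] - 1L)) {
          if (r >= win_start && r < win_end) bits[r - win_start + 1L] <- 1L
        }
      }
      ref <- ref + lens[k]
    }
    # I, S, H, P do not consume reference
  }
  bits
}

# Random CIGAR with M/D/I (and occasional S/N) runs, starting and ending
# with M so it is structurally valid.
random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  parts <- "M"
  for (i in seq_len(n_ops))
    parts <- c(parts, sample(c("D", "I", "N"), 1, prob = c(.6, .3, .1)), "M")
  lens <- vapply(parts, function(k)
    switch(k, M = sample(5:120, 1), D = sample(1:60, 1),
           I = sample(1:20, 1), N = sample(10:50, 1)), integer(1))
  if (runif(1) < 0.3) {
    parts <- c("S", parts); lens <- c(sample(5:50, 1), lens)
  }
  paste0(lens, parts, collapse = "")
}

# Rank/concordance AUC: fraction of (positive, negative) pairs with the
# positive scored higher, ties counting one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Transitive closure of |L_i - L_j| < radius. Returns cluster id per
# signature, plus whether any cluster violates the pairwise rule
# internally (an "ambiguous" chain longer than the radius end-to-end).
closure_clusters <- function(locations, radius) {
  n <- length(locations)
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(locations[i] - locations[j]) < radius && id[i] != id[j]) {
        id[id == max(id[i], id[j])] <- min(id[i], id[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ambiguous <- any(vapply(unique(id), function(k) {
    g <- locations[id == k]
    max(g) - min(g) >= radius
  }, logical(1)))
  list(id = match(id, unique(id)), ambiguous = ambiguous)
}

# Small deterministic alignment table builder for caller/feature tests.
aln_table <- function(qname, pos1, cigar, contig = "chr1", mapq = 60L,
                      flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = contig, pos = pos1,
             mapq = mapq, cigar = cigar)
}

tiny_sim_configs <- function(seed = 7L)
  list(train = simulation_config(genome_length = 1.2e5, n_deletions = 6L,
                                 deletion_size_range = c(60L, 800L),
                                 coverage = 25, seed = seed),
       val = simulation_config(genome_length = 1.2e5, n_deletions = 6L,
                               deletion_size_range = c(60L, 800L),
                               coverage = 25, seed = seed + 1L),
       test = simulation_config(genome_length = 1.2e5, n_deletions = 6L,
                                deletion_size_range = c(60L, 800L),
                                coverage = 25, seed = seed + 2L))
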