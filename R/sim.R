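#' Simulation configuration
#'
#' Describes one synthetic study condition: a random reference, implanted
#' homozygous deletions, and long reads emitted pre-aligned (their CIGARs
#' constructed exactly from the known donor-to-reference mapping) with
#' small spurious deletions and base mismatches injected at configurable
#' rates to emulate long-read sequencing noise. Defaults give the sparse
#' regime typical of real genomes: well over 95% of 200-bp windows carry no
#' deletion.
#'
#' @param genome_length Reference length in bp.
#' @param n_deletions Number of implanted deletions.
#' @param deletion_size_range `[min, max]` deletion size in bp (default
#'   50–5000, the size class the caller targets).
#' @param coverage Mean fold coverage.
#' @param read_length_range `[min, max]` read length; lengths are drawn
#'   log-uniformly (default 1–20 kb, the spread of current long-read
#'   platforms).
#' @param noise_deletion_rate Per-base probability of a spurious small D
#'   operation in a read's alignment.
#' @param noise_deletion_size_range `[min, max]` spurious deletion size
#'   (default 1–30 bp, so some noise survives the caller's 20-bp signature
#'   filter by design).
#' @param mismatch_rate Per-base substitution probability (affects read
#'   sequences only; alignments encode matches and mismatches alike as M).
#' @param heterozygous If TRUE, half of the reads are drawn from the
#'   unmodified reference.
#' @param window_size Window size used for deletion spacing (deletions are
#'   kept at least `2 * window_size` apart) and for ground-truth labels.
#' @param contig Contig name of the simulated reference.
#' @param seed Seed making the whole simulation deterministic.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(genome_length = 1e6, n_deletions = 10L,
                              deletion_size_range = c(50L, 5000L),
                              coverage = 30, read_length_range = c(1000L, 20000L),
                              noise_deletion_rate = 5e-4,
                              noise_deletion_size_range = c(1L, 30L),
                              mismatch_rate = 0.001, heterozygous = FALSE,
                              window_size = 200L, contig = "sim1", seed = 1L) {
  stopifnot(genome_length >= 1, n_deletions >= 0,
            length(deletion_size_range) == 2L,
            deletion_size_range[1] >= 1,
            diff(deletion_size_range) >= 0,
            coverage > 0, length(read_length_range) == 2L,
            read_length_range[1] >= 1, diff(read_length_range) >= 0,
            noise_deletion_rate >= 0, noise_deletion_rate <= 1,
            mismatch_rate >= 0, mismatch_rate <= 1, window_size >= 1)
  structure(list(genome_length = as.integer(genome_length),
                 n_deletions = as.integer(n_deletions),
                 deletion_size_range = as.integer(deletion_size_range),
                 coverage = coverage,
                 read_length_range = as.integer(read_length_range),
                 noise_deletion_rate = noise_deletion_rate,
                 noise_deletion_size_range = as.integer(noise_deletion_size_range),
                 mismatch_rate = mismatch_rate,
                 heterozygous = isTRUE(heterozygous),
                 window_size = as.integer(window_size),
                 contig = contig, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a reference genome with implanted deletions
#'
#' Draws a random base sequence, places `n_deletions` non-overlapping
#' deletions (uniform positions subject to a spacing of at least
#' `2 * window_size` between events and from the contig ends; sizes uniform
#' in range), and derives ground-truth window labels.
#'
#' @param cfg A [simulation_config()].
#' @return A `sim_genome`: `contig`, `length`, `sequence`, `truth`
#'   (data.frame `contig`, `start`, `size`), `windows`, `window_labels`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  gl <- cfg$genome_length
  spacing <- 2L * cfg$window_size
  sizes <- if (cfg$n_deletions > 0L)
    sample(cfg$deletion_size_range[1]:cfg$deletion_size_range[2],
           cfg$n_deletions, replace = TRUE) else integer(0)
  if (sum(sizes) + (cfg$n_deletions + 1L) * spacing >= gl)
    stop("infeasible simulation: total deletion span plus spacing (",
         sum(sizes) + (cfg$n_deletions + 1L) * spacing,
         " bp) exceeds genome length (", gl, " bp)", call. = FALSE)
  # place by distributing the free (non-deleted, non-spacing) bases
  # uniformly among the n+1 gaps
  starts <- integer(0)
  if (cfg$n_deletions > 0L) {
    free <- gl - sum(sizes) - (cfg$n_deletions + 1L) * spacing
    cuts <- sort(sample.int(free + 1L, cfg$n_deletions, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts)) + spacing
    starts <- cumsum(gaps) + c(0L, cumsum(sizes))[seq_len(cfg$n_deletions)]
  }
  truth <- data.frame(contig = rep(cfg$contig, cfg$n_deletions),
                      start = starts, size = sizes)
  sequence <- paste(sample(c("A", "C", "G", "T"), gl, replace = TRUE),
                    collapse = "")
  windows <- partition_reference(stats::setNames(gl, cfg$contig),
                                 cfg$window_size)
  structure(list(contig = cfg$contig, length = gl, sequence = sequence,
                 truth = truth, windows = windows,
                 window_labels = label_windows(windows, truth)),
            class = "sim_genome")
}

# reference coordinate of a donor (deletion-applied) coordinate
donor_to_ref <- function(d, truth) {
  if (nrow(truth) == 0L) return(d)
  br <- truth$start - c(0, cumsum(truth$size))[seq_len(nrow(truth))]
  shift <- vapply(d, function(x) sum(truth$size[br <= x]), numeric(1))
  d + shift
}

#' Simulate aligned long reads over a simulated genome
#'
#' Reads are sampled along the donor (deletion-applied) genome until the
#' target coverage is reached. Each read's CIGAR is constructed exactly
#' from its known donor-to-reference mapping: an implanted deletion inside
#' the read's span appears as a D operation of the true size at the true
#' reference offset. Spurious small deletions are then injected into match
#' runs at `noise_deletion_rate` per base, and mismatches substituted into
#' the read sequence at `mismatch_rate`.
#'
#' @param cfg A [simulation_config()].
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param with_sequence Generate read sequences (needed for SAM/FASTQ
#'   export; the feature pipeline itself only uses CIGARs).
#' @return Alignment table sorted by position (`qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, and `seq` when requested).
#' @export
simulate_alignments <- function(cfg, genome, with_sequence = FALSE) {
  set.seed(cfg$seed + 104729L)   # distinct stream from genome placement
  truth <- genome$truth
  donor_len <- genome$length - sum(truth$size)
  # deletion breakpoints in donor coordinates
  br <- if (nrow(truth)) truth$start -
    c(0, cumsum(truth$size))[seq_len(nrow(truth))] else numeric(0)
  target_bases <- cfg$coverage * donor_len
  lr <- log(as.numeric(cfg$read_length_range))
  lens <- integer(0)
  while (sum(lens) < target_bases)
    lens <- c(lens, as.integer(round(exp(stats::runif(
      max(8L, ceiling(target_bases / exp(mean(lr)) / 4)), lr[1], lr[2])))))
  lens <- lens[cumsum(as.numeric(lens)) <= target_bases + max(lens)]
  lens <- pmin(lens, donor_len)
  n_reads <- length(lens)
  starts <- vapply(lens, function(L)
    sample.int(donor_len - L + 1L, 1L) - 1L, integer(1))
  from_ref <- if (cfg$heterozygous)
    stats::runif(n_reads) < 0.5 else rep(FALSE, n_reads)

  qname <- sprintf("read%06d", seq_len(n_reads))
  pos0 <- integer(n_reads)
  cigar <- character(n_reads)
  seqs <- if (with_sequence) character(n_reads) else NULL
  donor <- if (with_sequence) apply_deletions(genome$sequence, truth) else NULL
  nd_lo <- cfg$noise_deletion_size_range[1]
  nd_hi <- cfg$noise_deletion_size_range[2]
  for (i in seq_len(n_reads)) {
    s <- starts[i]; L <- lens[i]
    if (from_ref[i]) {
      # haplotype without the deletions: donor == reference
      s <- min(s, genome$length - L)
      ref_start <- s
      segs_M <- L
      segs_D <- integer(0)
    } else {
      ref_start <- donor_to_ref(s, truth)
      inside <- which(br > s & br < s + L)
      cuts <- c(s, br[inside], s + L)
      segs_M <- as.integer(diff(cuts))
      segs_D <- truth$size[inside]
    }
    # inject noise deletions inside M runs: the read simply lacks a few
    # donor bases, so reference consumption of the run is unchanged and
    # the implanted deletions stay at their true reference coordinates.
    # op kinds: M match run, N noise deletion (consumes donor), I implanted
    # deletion (a donor junction; consumes reference only)
    kind <- character(0); lens_op <- integer(0)
    for (k in seq_along(segs_M)) {
      mlen <- segs_M[k]
      n_noise <- stats::rbinom(1L, max(mlen - 2L, 0L), cfg$noise_deletion_rate)
      if (n_noise > 0L) {
        at <- sort(sample.int(mlen - 2L, min(n_noise, mlen - 2L))) # interior
        dsz <- sample(nd_lo:nd_hi, length(at), replace = TRUE)
        cur <- 0L
        for (q in seq_along(at)) {
          if (at[q] < cur + 1L) next                # overlaps previous drop
          d <- min(dsz[q], mlen - 1L - at[q])       # keep a trailing M base
          if (d < 1L) next
          kind <- c(kind, "M", "N"); lens_op <- c(lens_op, at[q] - cur, d)
          cur <- at[q] + d
        }
        kind <- c(kind, "M"); lens_op <- c(lens_op, mlen - cur)
      } else {
        kind <- c(kind, "M"); lens_op <- c(lens_op, mlen)
      }
      if (k <= length(segs_D)) {
        kind <- c(kind, "I"); lens_op <- c(lens_op, segs_D[k])
      }
    }
    keep <- lens_op > 0L
    kind <- kind[keep]; lens_op <- lens_op[keep]
    cigar[i] <- paste0(lens_op, ifelse(kind == "M", "M", "D"), collapse = "")
    pos0[i] <- ref_start
    if (with_sequence) {
      src <- if (from_ref[i]) genome$sequence else donor
      dcur <- s
      parts <- character(0)
      for (k in seq_along(kind)) {
        if (kind[k] == "M") {
          parts <- c(parts, substr(src, dcur + 1L, dcur + lens_op[k]))
          dcur <- dcur + lens_op[k]
        } else if (kind[k] == "N") {
          dcur <- dcur + lens_op[k]   # donor bases missing from the read
        }                             # implanted D: donor junction, no move
      }
      x <- paste0(parts, collapse = "")
      if (cfg$mismatch_rate > 0) {
        nmm <- stats::rbinom(1L, nchar(x), cfg$mismatch_rate)
        if (nmm > 0L) {
          at <- sample.int(nchar(x), nmm)
          for (j in at)
            substr(x, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(x, j, j)), 1L)
        }
      }
      seqs[i] <- x
    }
  }
  aln <- data.frame(qname = qname, flag = 0L, rname = genome$contig,
                    pos = pos0 + 1L, mapq = 60L, cigar = cigar)
  if (with_sequence) aln$seq <- seqs
  aln <- aln[order(aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

apply_deletions <- function(sequence, truth) {
  if (nrow(truth) == 0L) return(sequence)
  keep_start <- c(1L, truth$start + truth$size + 1L)
  keep_end <- c(truth$start, nchar(sequence))
  paste(substring(sequence, keep_start, keep_end), collapse = "")
}

#' Write simulated alignments as SAM (optionally converting to BAM)
#'
#' @param aln Alignment table from [simulate_alignments()].
#' @param genome The `sim_genome` the reads were drawn from.
#' @param out Output SAM path.
#' @param as_bam Also produce a coordinate-sorted, indexed BAM; returns its
#'   path.
#' @return Path of the written file, invisibly.
#' @export
write_sam <- function(aln, genome, out, as_bam = FALSE) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$contig, genome$length))
  seq <- if ("seq" %in% names(aln)) aln$seq else "*"
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                 aln$cigar, seq)
  writeLines(c(hdr, rec), out)
  if (as_bam) {
    bam <- Rsamtools::asBam(out, sub("\\.sam$", "", out), overwrite = TRUE,
                            indexDestination = TRUE)
    return(invisible(bam))
  }
  invisible(out)
}

#' Write the simulated reference as FASTA
#'
#' @param genome A `sim_genome`.
#' @param out Output path.
#' @export
write_reference_fasta <- function(genome, out) {
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                genome$contig))
  Biostrings::writeXStringSet(x, out)
  invisible(out)
}

#' Simulate one complete dataset (genome, alignments, features, labels)
#'
#' @param cfg A [simulation_config()].
#' @param n Feature-matrix rows.
#' @param T_steps Windows per model sample.
#' @return A `sim_dataset`: `genome`, `alignments`, `featset`, `batches`,
#'   `labels` (per-window, aligned with `featset$windows`).
#' @export
simulate_dataset <- function(cfg, n = 18L, T_steps = 100L) {
  genome <- simulate_genome(cfg)
  aln <- simulate_alignments(cfg, genome)
  featset <- extract_region_matrices(
    aln, stats::setNames(genome$length, genome$contig),
    window_size = cfg$window_size, n = n)
  structure(list(genome = genome, alignments = aln, featset = featset,
                 batches = make_batches(featset, T_steps),
                 labels = genome$window_labels, config = cfg),
            class = "sim_dataset")
}

#' Simulate disjoint train/validation/test datasets
#'
#' Mirrors a chromosome-disjoint split: three independently seeded genomes
#' with no shared sequence, each carrying its own truth set.
#'
#' @param cfg_train,cfg_val,cfg_test [simulation_config()]s; they should
#'   use distinct seeds (a shared seed is allowed but warned about).
#' @param n,T_steps Feature/matrix dimensions passed through.
#' @return List with `train`, `val`, `test` `sim_dataset`s.
#' @export
make_dataset <- function(cfg_train, cfg_val, cfg_test, n = 18L,
                         T_steps = 100L) {
  seeds <- c(cfg_train$seed, cfg_val$seed, cfg_test$seed)
  if (anyDuplicated(seeds))
    warning("train/val/test simulation seeds overlap; ",
            "the splits will not be independent")
  list(train = simulate_dataset(cfg_train, n, T_steps),
       val = simulate_dataset(cfg_val, n, T_steps),
       test = simulate_dataset(cfg_test, n, T_steps))
}

#' The package's named easy-regime fixture
#'
#' The fixed synthetic condition used by the acceptance checks: a 1-Mb
#' genome with 20 deletions of 50–2000 bp, 30x coverage and noise-deletion
#' rate 5e-4.
#'
#' @param seed Root seed; train/val/test configs derive distinct seeds.
#' @return List of three [simulation_config()]s (`train`, `val`, `test`).
#' @export
easy_fixture_config <- function(seed = 1L) {
  mk <- function(s) simulation_config(
    genome_length = 1e6, n_deletions = 20L,
    deletion_size_range = c(50L, 2000L), coverage = 30,
    noise_deletion_rate = 5e-4, seed = s)
  list(train = mk(seed), val = mk(seed + 1000L), test = mk(seed + 2000L))
}
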