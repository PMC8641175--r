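test_that("reference partitioning tiles contigs without gaps or overlaps", {
  w <- partition_reference(c(chr1 = 1000), 200)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, seq(0, 800, 200))
  expect_equal(w$end, seq(200, 1000, 200))

  w2 <- partition_reference(c(chr1 = 1001), 200)
  expect_equal(nrow(w2), 6L)
  expect_equal(w2$start[6], 1000L)
  expect_equal(w2$end[6], 1001L)

  two <- partition_reference(c(a = 450, b = 200), 200)
  expect_equal(table(two$contig)[["a"]], 3L)
  expect_equal(two$index[two$contig == "b"], 0L)

  expect_equal(nrow(partition_reference(list(), 200)), 0L)
  expect_error(partition_reference(c(chr1 = 100), 0), "positive")
  expect_equal(formals(partition_reference)$window_size, 200L)
})

test_that("deletion bitmaps mark exactly the D-covered window positions", {
  win <- list(contig = "c", start = 0L, end = 200L, index = 0L)
  b <- extract_deletion_bitmap(list(reference_start = 0, cigar = "50M10D140M"), win)
  expect_equal(which(b$values == 1L), 51:60)
  expect_equal(b$deletion_count, 10L)

  expect_equal(
    extract_deletion_bitmap(list(reference_start = 0, cigar = "200M"),
                            win)$deletion_count, 0L)

  spill <- extract_deletion_bitmap(
    list(reference_start = 0, cigar = "10M400D10M"), win)
  expect_equal(which(spill$values == 1L), 11:200)
  expect_equal(spill$deletion_count, 190L)

  # N consumes reference but is not a deletion
  skip_op <- extract_deletion_bitmap(
    list(reference_start = 0, cigar = "50M50N100M"), win)
  expect_equal(skip_op$deletion_count, 0L)

  # alignment not overlapping the window yields an all-zero bitmap
  far <- extract_deletion_bitmap(
    list(reference_start = 5000, cigar = "10M10D10M"), win, m = 200L)
  expect_equal(far$deletion_count, 0L)

  expect_error(
    extract_deletion_bitmap(list(reference_start = 0, cigar = "50Q"), win),
    "CIGAR")
})

test_that("feature matrices sort rows by deletion count, truncate and pad", {
  win <- list(contig = "c", start = 0L, end = 200L, index = 0L)
  mk_bitmap <- function(count) {
    v <- integer(200); if (count > 0) v[seq_len(count)] <- 1L
    structure(list(values = v, deletion_count = count),
              class = "deletion_bitmap")
  }
  fm <- build_feature_matrix(
    stats::setNames(lapply(c(5, 0, 10), mk_bitmap), c("r1", "r2", "r3")),
    win, n = 18)
  expect_equal(dim(fm$mat), c(18L, 200L))
  expect_equal(rowSums(fm$mat)[1:3], c(10, 5, 0), ignore_attr = TRUE)
  expect_true(all(fm$mat[4:18, ] == 0))
  expect_equal(fm$p, 3L)

  empty <- build_feature_matrix(list(), win, n = 18)
  expect_true(all(empty$mat == 0))
  expect_equal(empty$p, 0L)

  many <- build_feature_matrix(
    stats::setNames(lapply(c(25:1), mk_bitmap), sprintf("r%02d", 25:1)),
    win, n = 18)
  expect_equal(many$p, 25L)
  expect_equal(rowSums(many$mat), as.numeric(25:8), ignore_attr = TRUE)
})

test_that("full extraction assigns reads to every overlapping window", {
  # one read spanning windows 3-5 (0-based indices 2-4) with one D op that
  # falls inside window 3
  aln <- aln_table("r1", pos1 = 401L, cigar = "250M30D200M")
  fs <- extract_region_matrices(aln, c(chr1 = 2000), window_size = 200, n = 4)
  sums <- apply(fs$array, 3, sum)
  expect_equal(which(sums > 0), 4L)            # only window [600,800)
  expect_equal(fs$p[3:5], c(1L, 1L, 1L))       # read counted in all three
  expect_equal(sum(fs$array[1, , 4]), 30)
  expect_equal(fs$p[c(1, 6)], c(0L, 0L))

  # two identical reads give two identical nonzero rows
  two <- extract_region_matrices(
    aln_table(c("a", "b"), c(1L, 1L), c("50M20D50M", "50M20D50M")),
    c(chr1 = 200), window_size = 200, n = 4)
  expect_equal(two$array[1, , 1], two$array[2, , 1])
  expect_equal(two$p[1], 2L)

  expect_error(
    extract_region_matrices(aln_table(c("a", "b"), c(500L, 10L),
                                      c("50M", "50M")),
                            c(chr1 = 1000)),
    "sort")
  expect_warning(
    extract_region_matrices(aln_table("a", 1L, "50M", contig = "chrX"),
                            c(chr1 = 400)),
    "no alignments")
})

test_that("alignment filters drop unmapped/secondary/qcfail, keep supplementary", {
  aln <- aln_table(c("u", "s", "q", "sup", "ok"), rep(1L, 5), rep("100M", 5),
                   flag = c(0x4L, 0x100L, 0x200L, 0x800L, 0x0L))
  fs <- extract_region_matrices(aln, c(chr1 = 200), window_size = 200, n = 6)
  expect_equal(fs$p[1], 2L)   # supplementary + primary survive
  fs2 <- extract_region_matrices(
    aln_table(c("lo", "hi"), c(1L, 1L), c("100M", "100M"),
              mapq = c(5L, 50L)),
    c(chr1 = 200), window_size = 200, n = 6,
    filters = alignment_filter(min_mapq = 20))
  expect_equal(fs2$p[1], 1L)
})

test_that("batches chunk windows into T with zero-padded masked tails", {
  aln <- aln_table("r", 1L, "100M")
  fs <- extract_region_matrices(aln, c(chr1 = 250 * 200), window_size = 200)
  b <- make_batches(fs, T_steps = 100)
  expect_length(b, 3L)
  expect_equal(sum(b[[3]]$mask), 50L)
  expect_true(all(is.na(b[[3]]$idx[51:100])))

  exact <- make_batches(
    extract_region_matrices(aln, c(chr1 = 100 * 200), window_size = 200),
    T_steps = 100)
  expect_length(exact, 1L)
  expect_true(all(exact[[1]]$mask))

  expect_error(make_batches(fs, 0), "positive")
})

test_that("feature sets round-trip through the tensor container", {
  cfg <- simulation_config(genome_length = 3e4, n_deletions = 2L,
                           deletion_size_range = c(60L, 300L),
                           coverage = 8, seed = 5L)
  ds <- simulate_dataset(cfg)
  stem <- file.path(tempdir(), "featset_rt")
  save_feature_set(ds$featset, stem)
  back <- load_feature_set(stem)
  expect_equal(back$array, ds$featset$array)
  expect_equal(back$windows$start, ds$featset$windows$start)
  expect_equal(back$p, ds$featset$p)
  expect_equal(back$m, ds$featset$m)
  expect_equal(back$orientation, ds$featset$orientation)
})
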