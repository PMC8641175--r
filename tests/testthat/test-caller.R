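scored_frame <- function(probs, contig = "chr1", m = 200L) {
  idx <- seq_along(probs) - 1L
  data.frame(contig = contig, start = idx * m, end = (idx + 1L) * m,
             index = idx, prob = probs)
}

test_that("thresholding keeps windows above cutoff and merges adjacent runs", {
  reg <- threshold_and_merge(scored_frame(c(.2, .9, .8, .1)))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 200L)
  expect_equal(reg$end, 600L)
  expect_equal(reg$window_count, 2L)

  expect_equal(nrow(threshold_and_merge(scored_frame(c(.1, .3)))), 0L)

  # strict inequality at the default cutoff
  expect_equal(nrow(threshold_and_merge(scored_frame(c(.5, .5)))), 0L)
  expect_equal(formals(threshold_and_merge)$cutoff, 0.5)

  # non-adjacent positives stay separate regions
  reg2 <- threshold_and_merge(scored_frame(c(.9, .1, .9)))
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$window_count, c(1L, 1L))
})

test_that("signature collection extracts qualifying D operations", {
  reg <- list(contig = "chr1", start = 1000L, end = 1400L)
  aln <- aln_table("r1", pos1 = 1001L, cigar = "100M60D100M")
  sig <- collect_signatures(reg, aln)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$location, 1100L)
  expect_equal(sig$size, 60L)

  # a 15-bp D op fails the strict >20 filter; so does exactly 20
  expect_equal(nrow(collect_signatures(
    reg, aln_table("r2", 1001L, "50M15D50M"))), 0L)
  expect_equal(nrow(collect_signatures(
    reg, aln_table("r2", 1001L, "50M20D50M"))), 0L)

  # two qualifying D ops in one read give two signatures
  two <- collect_signatures(reg, aln_table("r3", 1001L, "50M30D50M40D50M"))
  expect_equal(nrow(two), 2L)
  expect_equal(two$size, c(30L, 40L))

  expect_equal(nrow(collect_signatures(
    reg, aln_table("far", 9000L, "100M30D100M"))), 0L)

  # distant D ops of an overlapping long read are excluded by default but
  # admitted under the literal any-D-of-any-overlapping-read reading
  long_read <- aln_table("r4", 501L, "600M100D100M")  # D at 1100 w/ big span
  near <- collect_signatures(reg, long_read)
  expect_equal(near$location, 1100L)
  far_reg <- list(contig = "chr1", start = 600L, end = 800L)
  expect_equal(nrow(collect_signatures(far_reg, long_read)), 0L)
  expect_equal(nrow(collect_signatures(far_reg, long_read,
                                       within_region = FALSE)), 1L)
})

test_that("signature clustering is a deterministic partition", {
  sig <- data.frame(location = c(100, 110, 500), size = c(60, 50, 70),
                    read_id = c("a", "b", "c"))
  cl <- cluster_signatures(sig, radius = 40)
  expect_length(cl, 2L)
  expect_equal(sort(cl[[1]]$location), c(100, 110))
  expect_equal(cl[[2]]$location, 500)

  expect_length(cluster_signatures(sig[1, ], 40), 1L)
  expect_length(cluster_signatures(sig[0, ], 40), 0L)

  # chained locations: single linkage merges, centroid linkage refuses
  chain <- data.frame(location = c(100, 135, 170), size = rep(50, 3),
                      read_id = c("a", "b", "c"))
  expect_length(cluster_signatures(chain, 40, linkage = "single"), 1L)
  expect_length(cluster_signatures(chain, 40, linkage = "centroid"), 2L)
})

test_that("clustering equals transitive closure on unambiguous cases", {
  set.seed(41)
  n_checked <- 0L
  for (i in 1:200) {
    n <- sample(2:12, 1)
    loc <- sort(sample(0:600, n))
    oracle <- closure_clusters(loc, 40)
    if (oracle$ambiguous) next
    n_checked <- n_checked + 1L
    sig <- data.frame(location = loc, size = rep(50, n),
                      read_id = sprintf("r%d", seq_len(n)))
    cl <- cluster_signatures(sig, 40)
    got <- integer(n)
    for (k in seq_along(cl)) got[match(cl[[k]]$location, loc)] <- k
    expect_equal(got, oracle$id)
  }
  expect_gt(n_checked, 50L)
})

test_that("refinement averages the largest cluster, with IMPRECISE fallback", {
  reg <- list(contig = "chr1", start = 2000L, end = 2400L)
  cl <- list(data.frame(location = c(100, 110), size = c(60, 50),
                        read_id = c("a", "b")),
             data.frame(location = 500, size = 70, read_id = "c"))
  call <- refine_call(cl, reg)
  expect_equal(call$start, 105L)
  expect_equal(call$size, 55L)
  expect_equal(call$support, 2L)
  expect_false(call$imprecise)

  single <- refine_call(list(data.frame(location = 1000, size = 80,
                                        read_id = "x")), reg)
  expect_equal(c(single$start, single$size, single$support), c(1000L, 80L, 1L))

  fb <- refine_call(list(), reg)
  expect_true(fb$imprecise)
  expect_equal(c(fb$start, fb$size, fb$support), c(2000L, 400L, 0L))

  # tie on cluster size: smaller mean location wins
  tie <- refine_call(list(data.frame(location = c(900, 910), size = c(50, 50),
                                     read_id = c("a", "b")),
                          data.frame(location = c(100, 110), size = c(60, 70),
                                     read_id = c("c", "d"))), reg)
  expect_equal(tie$start, 105L)
  # averages round half-up
  half <- refine_call(list(data.frame(location = c(100, 101),
                                      size = c(50, 51),
                                      read_id = c("a", "b"))), reg)
  expect_equal(half$start, 101L)
  expect_equal(half$size, 51L)
})

test_that("VCF output converts coordinates, filters size, and round-trips", {
  calls <- data.frame(contig = "chr1", start = c(999L, 5000L, 7000L),
                      size = c(100L, 49L, 300L),
                      support = c(12L, 3L, 0L),
                      imprecise = c(FALSE, FALSE, TRUE))
  out <- file.path(tempdir(), "calls_rt.vcf")
  write_vcf(calls, c(chr1 = 100000L), out)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)          # the 49-bp call is dropped
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f1[2]), 1000L)
  expect_match(f1[8], "SVLEN=-100")
  expect_match(f1[8], "END=1100")
  expect_match(f1[8], "SUPPORT=12")
  expect_match(body[2], "IMPRECISE")

  back <- load_truth(out)
  expect_equal(back$start, c(999L, 7000L))
  expect_equal(back$size, c(100L, 300L))

  hdr_only <- file.path(tempdir(), "empty.vcf")
  write_vcf(calls[0, ], c(chr1 = 1000L), hdr_only)
  expect_true(all(startsWith(readLines(hdr_only), "#")))
  expect_equal(nrow(load_truth(hdr_only)), 0L)
})

test_that("the full calling stage recovers an implanted deletion", {
  # ten reads spanning a 120-bp deletion at 2050, with one noisy outlier
  aln <- aln_table(sprintf("r%02d", 1:11),
                   pos1 = c(rep(1801L, 10), 1701L),
                   cigar = c(rep("250M120D200M", 10), "200M25D300M"))
  probs <- rep(0.01, 20)
  probs[11] <- 0.97            # window [2000,2200) flagged by the model
  calls <- call_deletions(scored_frame(probs), aln)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 2050L)
  expect_equal(calls$size, 120L)
  expect_equal(calls$support, 10L)
})
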