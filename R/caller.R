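#' Threshold window scores and merge adjacent positive windows
#'
#' Windows scoring strictly above `cutoff` are positive; maximal runs of
#' index-consecutive positive windows on one contig merge into a single
#' candidate region (a deletion longer than one window spans several
#' adjacent windows).
#'
#' @param scored_windows data.frame from [predict_windows()] (`contig`,
#'   `start`, `end`, `index`, `prob`).
#' @param cutoff Probability threshold, strict inequality (default 0.5).
#' @return data.frame of candidate regions: `contig`, `start`, `end`,
#'   `window_count`.
#' @export
threshold_and_merge <- function(scored_windows, cutoff = 0.5) {
  pos <- scored_windows[scored_windows$prob > cutoff, , drop = FALSE]
  if (nrow(pos) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), window_count = integer()))
  pos <- pos[order(pos$contig, pos$index), , drop = FALSE]
  new_run <- c(TRUE, diff(pos$index) != 1L |
                 pos$contig[-1L] != pos$contig[-nrow(pos)])
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(pos, run), function(g)
    data.frame(contig = g$contig[1L], start = min(g$start),
               end = max(g$end), window_count = nrow(g))))
  rownames(out) <- NULL
  out
}

#' Collect per-read deletion signatures for a candidate region
#'
#' For every read aligned in the region, extracts one `(location, size)`
#' signature per CIGAR D operation of size strictly greater than `min_size`
#' (default 20 bp). Location is the reference coordinate at which the D
#' operation begins (0-based). By default only D operations that intersect
#' the region grown by `flank` bp contribute, so that distant deletions
#' spanned by the same long reads cannot hijack the region's breakpoint;
#' set `within_region = FALSE` to keep every qualifying D operation of
#' every overlapping read.
#'
#' @param region One candidate region (row of [threshold_and_merge()]'s
#'   output, or any list with `contig`, `start`, `end`).
#' @param alignments Alignment table or BAM/SAM path.
#' @param min_size Minimum D-operation size, strict (default 20).
#' @param within_region Restrict signatures to D ops intersecting the
#'   flanked region (default TRUE).
#' @param flank Expansion used by `within_region` (default 40 bp, the
#'   clustering radius).
#' @return data.frame `location`, `size`, `read_id`.
#' @export
collect_signatures <- function(region, alignments, min_size = 20L,
                               within_region = TRUE, flank = 40L) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignments(alignments, region$contig)
  a <- alignments[alignments$rname == region$contig, , drop = FALSE]
  empty <- data.frame(location = integer(), size = integer(),
                      read_id = character())
  if (nrow(a) == 0L) return(empty)
  start0 <- a$pos - 1L
  end0 <- start0 + cigar_reference_width(a$cigar)
  ov <- start0 < region$end & end0 > region$start
  a <- a[ov, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  dr <- cigar_deletion_ranges(a$cigar, a$pos - 1L)
  n_d <- vapply(dr, nrow, integer(1))
  if (sum(n_d) == 0L) return(empty)
  out <- data.frame(
    location = unlist(lapply(dr, `[[`, "start"), use.names = FALSE),
    size = unlist(lapply(dr, function(d) d$end - d$start), use.names = FALSE),
    read_id = rep(a$qname, n_d))
  out <- out[out$size > min_size, , drop = FALSE]
  if (within_region)
    out <- out[out$location < region$end + flank &
                 out$location + out$size > region$start - flank, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster deletion signatures by location
#'
#' Signatures are sorted by location and grouped deterministically. With
#' `linkage = "single"` (default) a signature joins the current cluster when
#' its location is within `radius` of the previous signature's location —
#' the transitive closure of the pairwise rule `|L_i - L_j| < radius` on
#' sorted input. With `linkage = "centroid"` it joins while within `radius`
#' of the running cluster mean location, which refuses long chains.
#'
#' @param signatures data.frame from [collect_signatures()].
#' @param radius Clustering radius in bp, strict inequality (default 40).
#' @param linkage `"single"` or `"centroid"`.
#' @return List of data.frames, one per cluster, ordered by location.
#' @export
cluster_signatures <- function(signatures, radius = 40L,
                               linkage = c("single", "centroid")) {
  linkage <- match.arg(linkage)
  stopifnot(radius > 0)
  if (is.null(signatures) || nrow(signatures) == 0L) return(list())
  s <- signatures[order(signatures$location, signatures$size), , drop = FALSE]
  n <- nrow(s)
  id <- integer(n)
  id[1L] <- 1L
  if (linkage == "single") {
    for (i in seq_len(n)[-1L])
      id[i] <- if (s$location[i] - s$location[i - 1L] < radius) id[i - 1L]
               else id[i - 1L] + 1L
  } else {
    mean_loc <- s$location[1L]
    k <- 1L
    cnt <- 1L
    for (i in seq_len(n)[-1L]) {
      if (abs(s$location[i] - mean_loc) < radius) {
        cnt <- cnt + 1L
        mean_loc <- mean_loc + (s$location[i] - mean_loc) / cnt
        id[i] <- k
      } else {
        k <- k + 1L
        cnt <- 1L
        mean_loc <- s$location[i]
        id[i] <- k
      }
    }
  }
  unname(lapply(split(s, id), function(g) { rownames(g) <- NULL; g }))
}

round_half_up <- function(x) floor(x + 0.5)

#' Refine a candidate region into a single deletion call
#'
#' Selects the cluster with the most signatures (ties broken toward the
#' smallest mean location) and averages member locations and sizes,
#' rounding half-up to whole base pairs. A region with no signatures falls
#' back to the region's own bounds with `support = 0`, flagged IMPRECISE.
#'
#' @param clusters List from [cluster_signatures()].
#' @param region The candidate region the clusters came from.
#' @return One-row data.frame: `contig`, `start`, `size`, `support`,
#'   `imprecise`, plus the region bounds `region_start`, `region_end`.
#' @export
refine_call <- function(clusters, region) {
  if (length(clusters) == 0L)
    return(data.frame(contig = region$contig, start = region$start,
                      size = region$end - region$start, support = 0L,
                      imprecise = TRUE, region_start = region$start,
                      region_end = region$end))
  sizes <- vapply(clusters, nrow, integer(1))
  means <- vapply(clusters, function(g) mean(g$location), numeric(1))
  best <- order(-sizes, means)[1L]
  g <- clusters[[best]]
  data.frame(contig = region$contig,
             start = as.integer(round_half_up(mean(g$location))),
             size = as.integer(round_half_up(mean(g$size))),
             support = nrow(g), imprecise = FALSE,
             region_start = region$start, region_end = region$end)
}

#' Call deletions from scored windows and alignments
#'
#' Full calling stage: threshold and merge windows, collect and cluster
#' CIGAR deletion signatures per candidate region, refine one call per
#' region, and drop calls smaller than `min_call_size`.
#'
#' @param scored_windows data.frame from [predict_windows()].
#' @param alignments Alignment table or BAM/SAM path.
#' @param cutoff Window probability threshold (default 0.5).
#' @param radius Signature clustering radius in bp (default 40).
#' @param min_signature_size Minimum CIGAR D size, strict (default 20).
#' @param min_call_size Minimum reported deletion size (default 50).
#' @param linkage Clustering linkage, see [cluster_signatures()].
#' @return data.frame of calls, sorted by contig and start.
#' @export
call_deletions <- function(scored_windows, alignments, cutoff = 0.5,
                           radius = 40L, min_signature_size = 20L,
                           min_call_size = 50L, linkage = "single") {
  regions <- threshold_and_merge(scored_windows, cutoff)
  if (nrow(regions) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      size = integer(), support = integer(),
                      imprecise = logical(), region_start = integer(),
                      region_end = integer()))
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  calls <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    sig <- collect_signatures(reg, alignments, min_signature_size,
                              flank = radius)
    refine_call(cluster_signatures(sig, radius, linkage), reg)
  }))
  calls <- calls[calls$size >= min_call_size, , drop = FALSE]
  calls <- calls[order(calls$contig, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
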