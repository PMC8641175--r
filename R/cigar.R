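#' @import GenomicAlignments
#' @importFrom IRanges IRanges start end width findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Reference intervals of CIGAR deletion (D) operations
#'
#' Decomposes CIGAR strings and returns, for each alignment, the 0-based
#' half-open reference intervals spanned by its D operations. N (skip)
#' operations consume reference but are not counted as deletions.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos0 Integer vector of 0-based leftmost reference positions.
#' @return A list (one element per alignment) of data.frames with columns
#'   `start`, `end` (0-based half-open reference coordinates).
#' @keywords internal
cigar_deletion_ranges <- function(cigar, pos0) {
  stopifnot(length(cigar) == length(pos0))
  if (length(cigar) == 0L) return(list())
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad))
    stop("malformed CIGAR string '", cigar[which(bad)[1L]],
         "' in alignment ", which(bad)[1L], call. = FALSE)
  rl <- tryCatch(
    GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = as.integer(pos0) + 1L, ops = "D"),
    error = function(e) stop("malformed CIGAR string: ", conditionMessage(e),
                             call. = FALSE))
  lapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    data.frame(start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
}

#' Reference span width of alignments
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference bases consumed (M/=/X/D/N).
#' @keywords internal
cigar_reference_width <- function(cigar) {
  tryCatch(
    GenomicAlignments::cigarWidthAlongReferenceSpace(cigar),
    error = function(e) stop("malformed CIGAR string: ", conditionMessage(e),
                             call. = FALSE))
}

#' Per-window deletion bitmap of one alignment
#'
#' Marks which positions of a reference window are deleted in a read's
#' alignment: position `j` (window-relative, 0-based) is 1 exactly when the
#' CIGAR places a D operation over reference coordinate `region$start + j`.
#' Positions outside the alignment's reference span, and window positions
#' beyond a short final window's end, are 0. The bitmap always has length
#' `m`, zero-padded on the right when the window is shorter than `m`.
#'
#' @param alignment List or one-row data.frame with `reference_start`
#'   (0-based) and `cigar`.
#' @param region A window as returned by [partition_reference()] (fields
#'   `start`, `end`) or a `subregion`.
#' @param m Bitmap length. Defaults to the region's own length; pass the
#'   tiling's nominal window size to obtain right-padded bitmaps for a short
#'   final window.
#' @return A `deletion_bitmap`: list with `values` (integer vector of length
#'   `m` in {0,1}) and `deletion_count`.
#' @examples
#' win <- list(contig = "c", start = 0L, end = 200L, index = 0L)
#' b <- extract_deletion_bitmap(list(reference_start = 0, cigar = "50M10D140M"), win)
#' b$deletion_count  # 10
#' @export
extract_deletion_bitmap <- function(alignment, region, m = NULL) {
  if (is.null(m)) m <- as.integer(region$end - region$start)
  m <- as.integer(m)
  values <- integer(m)
  dr <- cigar_deletion_ranges(alignment$cigar, alignment$reference_start)[[1]]
  if (nrow(dr) > 0L) {
    # clip each D interval to the window (and to the true window end for a
    # short final window)
    lo <- pmax(dr$start, region$start)
    hi <- pmin(dr$end, region$end)
    keep <- hi > lo
    if (any(keep)) {
      for (k in which(keep)) {
        j <- (lo[k]:(hi[k] - 1L)) - region$start
        values[j + 1L] <- 1L
      }
    }
  }
  structure(list(values = values, deletion_count = sum(values)),
            class = "deletion_bitmap")
}

#' Assemble a fixed-size feature matrix from per-read bitmaps
#'
#' Rows are the reads' deletion bitmaps sorted by deletion count in
#' descending order (ties broken by read name for determinism), truncated to
#' the first `n` rows when more than `n` reads align, or zero-padded to `n`
#' rows when fewer do. `p` records how many reads aligned before
#' truncation/padding.
#'
#' @param bitmaps List of `deletion_bitmap` objects (optionally named by
#'   read; names are the tie-break key).
#' @param region The window the bitmaps belong to.
#' @param n Number of matrix rows (default 18).
#' @return A `feature_matrix`: list with `region`, `mat` (n x m integer
#'   matrix), `p`.
#' @export
build_feature_matrix <- function(bitmaps, region, n = 18L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  p <- length(bitmaps)
  m <- if (p > 0L) length(bitmaps[[1L]]$values)
       else as.integer(region$end - region$start)
  mat <- matrix(0L, nrow = n, ncol = m)
  if (p > 0L) {
    lens <- vapply(bitmaps, function(b) length(b$values), integer(1))
    if (any(lens != m)) stop("all bitmaps must have equal length", call. = FALSE)
    counts <- vapply(bitmaps, function(b) b$deletion_count, numeric(1))
    nm <- names(bitmaps)
    if (is.null(nm)) nm <- sprintf("%09d", seq_len(p))
    ord <- order(-counts, nm)
    keep <- ord[seq_len(min(p, n))]
    for (i in seq_along(keep)) mat[i, ] <- bitmaps[[keep[i]]]$values
  }
  structure(list(region = region, mat = mat, p = p), class = "feature_matrix")
}
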