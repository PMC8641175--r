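#' @importFrom Rsamtools BamFile ScanBamParam scanBam scanBamFlag asBam
#'   sortBam indexBam scanBamHeader
#' @importFrom GenomicRanges GRanges
NULL

# Orientation constant shared by extraction and the network: a feature
# matrix is stored with reads on rows (n) and window positions on columns
# (m); the network convolves over the position axis.
DELNET_ORIENTATION <- "rows=reads;cols=positions"

#' Read alignments from a BAM/SAM file into the package's alignment table
#'
#' @param path BAM (indexed) or SAM file. SAM input is converted to a
#'   temporary sorted, indexed BAM first.
#' @param contig Optional contig to restrict to (requires an index).
#' @return Alignment table: data.frame with `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`.
#' @export
read_alignments <- function(path, contig = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, file.path(tempdir(), paste0(basename(path), ".tmp")),
                            overwrite = TRUE, indexDestination = TRUE)
    path <- bam
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  if (is.null(contig)) {
    param <- Rsamtools::ScanBamParam(what = what)
  } else {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (!contig %in% names(hdr)) {
      warning("contig '", contig, "' absent from alignment file")
      return(data.frame(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        mapq = integer(), cigar = character()))
    }
    param <- Rsamtools::ScanBamParam(
      what = what,
      which = GenomicRanges::GRanges(contig, IRanges::IRanges(1, hdr[[contig]])))
  }
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos,
             mapq = res$mapq, cigar = res$cigar)
}

#' Default alignment record filter
#'
#' Unmapped, secondary and QC-fail records are skipped; supplementary
#' alignments are kept because split reads carry deletion evidence.
#'
#' @param min_mapq Minimum mapping quality (default 0, permissive).
#' @return An `alignment_filter` list.
#' @export
alignment_filter <- function(min_mapq = 0L) {
  structure(list(min_mapq = as.integer(min_mapq)), class = "alignment_filter")
}

apply_alignment_filter <- function(aln, filters) {
  flag <- aln$flag
  drop <- bitwAnd(flag, 0x4L) != 0L |   # unmapped
          bitwAnd(flag, 0x100L) != 0L | # secondary
          bitwAnd(flag, 0x200L) != 0L   # QC fail
  keep <- !drop & (is.na(aln$mapq) | aln$mapq >= filters$min_mapq)
  aln[keep, , drop = FALSE]
}

#' Extract per-window feature matrices for one or all contigs
#'
#' Runs the whole window-feature pipeline in one pass: partitions each
#' contig into `window_size` windows, assigns every read to every window its
#' reference span intersects, computes each read's deletion bitmap per
#' window, and assembles fixed-size matrices (deletion-count-descending row
#' sort, truncation to `n` rows or zero-padding). Reads with no D operation
#' in a window contribute an all-zero row that counts toward `p` and may be
#' displaced by truncation.
#'
#' @param alignments Alignment table (see [read_alignments()]) or a BAM/SAM
#'   path.
#' @param contig_lengths Named vector of contig lengths. When `alignments`
#'   is a file path and this is `NULL`, lengths are taken from the header.
#' @param window_size Window length m in bp (default 200).
#' @param n Matrix rows (default 18).
#' @param filters An [alignment_filter()].
#' @return A `feature_set`: list with `windows` (data.frame), `array`
#'   (n x m x n_windows integer array), `p` (reads aligned per window),
#'   `m`, `n`, `orientation`.
#' @export
extract_region_matrices <- function(alignments, contig_lengths = NULL,
                                    window_size = 200L, n = 18L,
                                    filters = alignment_filter()) {
  if (is.character(alignments) && length(alignments) == 1L) {
    path <- alignments
    if (is.null(contig_lengths)) {
      if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        alignments <- read_alignments(path)     # converts via temp BAM
        hdr <- sam_header_targets(path)
      } else {
        hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
        alignments <- read_alignments(path)
      }
      contig_lengths <- hdr
    } else {
      alignments <- read_alignments(path)
    }
  }
  if (is.null(contig_lengths))
    stop("`contig_lengths` is required when alignments are given as a table",
         call. = FALSE)
  windows <- partition_reference(contig_lengths, window_size)
  aln <- apply_alignment_filter(alignments, filters)

  n <- as.integer(n)
  m <- as.integer(window_size)
  n_win <- nrow(windows)
  arr <- array(0L, dim = c(n, m, n_win))
  p <- integer(n_win)

  for (ctg in names(contig_lengths)) {
    widx <- which(windows$contig == ctg)
    a <- aln[aln$rname == ctg, , drop = FALSE]
    if (nrow(a) == 0L) {
      warning("no alignments on contig '", ctg, "'; matrices are all-zero")
      next
    }
    if (is.unsorted(a$pos))
      stop("alignments on contig '", ctg,
           "' are not coordinate-sorted; sort the input first", call. = FALSE)
    start0 <- a$pos - 1L
    end0 <- start0 + cigar_reference_width(a$cigar)
    win <- windows[widx, , drop = FALSE]

    # read x window assignment by reference-span intersection
    ov <- IRanges::findOverlaps(IRanges::IRanges(start0 + 1L, end0),
                                IRanges::IRanges(win$start + 1L, win$end))
    r_of <- S4Vectors::queryHits(ov)
    w_of <- S4Vectors::subjectHits(ov)

    # deleted-base intervals per read, flattened
    dr <- cigar_deletion_ranges(a$cigar, start0)
    n_d <- vapply(dr, nrow, integer(1))
    if (sum(n_d) > 0L) {
      d_read <- rep.int(seq_len(nrow(a)), n_d)
      d_start <- unlist(lapply(dr, `[[`, "start"), use.names = FALSE)
      d_end <- unlist(lapply(dr, `[[`, "end"), use.names = FALSE)
      dov <- IRanges::findOverlaps(IRanges::IRanges(d_start + 1L, d_end),
                                   IRanges::IRanges(win$start + 1L, win$end))
      di <- S4Vectors::queryHits(dov)
      dw <- S4Vectors::subjectHits(dov)
      clip_lo <- pmax(d_start[di], win$start[dw])
      clip_hi <- pmin(d_end[di], win$end[dw])
      dtab <- data.frame(read = d_read[di], win = dw,
                         lo = clip_lo, hi = clip_hi)
      key <- paste(dtab$read, dtab$win)
      cnt <- tapply(dtab$hi - dtab$lo, key, sum)
      dtab_by_win <- split(dtab, dtab$win)
    } else {
      cnt <- numeric(0)
      dtab_by_win <- list()
    }

    reads_by_win <- split(r_of, w_of)
    for (wi in names(reads_by_win)) {
      w <- as.integer(wi)
      rr <- reads_by_win[[wi]]
      counts <- unname(cnt[paste(rr, w)])
      counts[is.na(counts)] <- 0
      ord <- order(-counts, a$qname[rr])
      keep <- rr[ord][seq_len(min(length(rr), n))]
      gw <- widx[w]
      p[gw] <- length(rr)
      dt <- dtab_by_win[[wi]]
      if (!is.null(dt)) {
        row_of <- match(dt$read, keep)
        sel <- which(!is.na(row_of))
        ws <- win$start[w]
        for (k in sel) {
          cols <- (dt$lo[k]:(dt$hi[k] - 1L)) - ws + 1L
          arr[row_of[k], cols, gw] <- 1L
        }
      }
    }
  }
  structure(list(windows = windows, array = arr, p = p, m = m, n = n,
                 orientation = DELNET_ORIENTATION),
            class = "feature_set")
}

sam_header_targets <- function(sam_path) {
  lines <- readLines(sam_path, warn = FALSE)
  sq <- lines[startsWith(lines, "@SQ")]
  nm <- sub(".*\\tSN:([^\\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq))
  stats::setNames(ln, nm)
}

#' Group windows into fixed-length model input batches
#'
#' Chops each contig's ordered window sequence into non-overlapping runs of
#' `T` consecutive windows. A final short run is padded with all-zero
#' matrices; the `mask` records which positions are real. Masked positions
#' are excluded from the training loss and never reported as calls.
#'
#' @param featset A `feature_set` from [extract_region_matrices()].
#' @param T_steps Windows per batch (default 100).
#' @return List of `region_batch` objects: `contig`, `first_index`, `idx`
#'   (indices into the feature set, NA where padded), `mask`.
#' @export
make_batches <- function(featset, T_steps = 100L) {
  T_steps <- as.integer(T_steps)
  if (is.na(T_steps) || T_steps < 1L)
    stop("`T_steps` must be a positive integer", call. = FALSE)
  win <- featset$windows
  out <- list()
  for (ctg in unique(win$contig)) {
    widx <- which(win$contig == ctg)
    widx <- widx[order(win$index[widx])]
    n_w <- length(widx)
    n_b <- ceiling(n_w / T_steps)
    for (b in seq_len(n_b)) {
      lo <- (b - 1L) * T_steps + 1L
      hi <- min(b * T_steps, n_w)
      idx <- rep(NA_integer_, T_steps)
      idx[seq_len(hi - lo + 1L)] <- widx[lo:hi]
      out[[length(out) + 1L]] <- structure(
        list(contig = ctg, first_index = win$index[widx[lo]],
             idx = idx, mask = !is.na(idx)),
        class = "region_batch")
    }
  }
  out
}

#' Materialise the network input tensor for a set of windows
#'
#' @param featset A `feature_set`.
#' @param idx Window indices (NA yields an all-zero matrix).
#' @return Numeric array n x m x length(idx).
#' @keywords internal
featset_tensor <- function(featset, idx) {
  arr <- array(0, dim = c(featset$n, featset$m, length(idx)))
  real <- which(!is.na(idx))
  if (length(real)) arr[, , real] <- featset$array[, , idx[real]]
  arr
}

#' Save / load a feature set as a binary tensor container with JSON sidecar
#'
#' The container is a raw little-endian int32 dump of the n x m x W array;
#' the sidecar records `m`, `n`, `orientation`, window coordinates and `p`
#' so that training and calling can verify compatibility without re-running
#' extraction.
#'
#' @param featset A `feature_set`.
#' @param path Output stem; writes `<path>.bin` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_feature_set <- function(featset, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(featset$array), con, size = 4L, endian = "little")
  side <- list(m = featset$m, n = featset$n,
               orientation = featset$orientation,
               n_windows = nrow(featset$windows),
               windows = featset$windows, p = featset$p)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_feature_set
#' @export
load_feature_set <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_val <- side$n * side$m * side$n_windows
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_val, size = 4L, endian = "little")
  structure(list(
    windows = as.data.frame(side$windows),
    array = array(raw, dim = c(side$n, side$m, side$n_windows)),
    p = as.integer(side$p), m = as.integer(side$m), n = as.integer(side$n),
    orientation = side$orientation), class = "feature_set")
}
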