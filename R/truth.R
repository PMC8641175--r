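#' Load a truth deletion set from VCF or BED
#'
#' VCF records are kept when they describe a deletion: symbolic `<DEL>` ALT,
#' `SVTYPE=DEL`, or a REF allele longer than the ALT allele. The deletion
#' size is taken from `|SVLEN|`, then `END - POS`, then the REF/ALT length
#' difference, in that order; records where none can be parsed are skipped
#' with a warning count. BED intervals (0-based half-open) are all treated
#' as deletions. Deletions smaller than `min_size` are removed (default
#' 50 bp, the conventional SV size floor).
#'
#' @param path VCF (`.vcf`, `.vcf.gz`) or BED file.
#' @param format `"vcf"`, `"bed"`, or `"auto"` (by extension).
#' @param min_size Minimum deletion size in bp (default 50).
#' @return data.frame with `contig`, `start` (0-based first deleted base),
#'   `size`.
#' @export
load_truth <- function(path, format = c("auto", "vcf", "bed"), min_size = 50L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) "vcf"
              else stop("cannot infer format of '", path,
                        "'; pass format explicitly", call. = FALSE)
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      size = GenomicRanges::width(gr))
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    n_rec <- length(vcf)
    if (n_rec == 0L)
      return(data.frame(contig = character(), start = integer(), size = integer()))
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- vapply(VariantAnnotation::alt(vcf), function(a)
      if (length(a)) as.character(a[[1]]) else "", character(1))
    info <- VariantAnnotation::info(vcf)
    svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE)
              else rep(NA_character_, n_rec)
    svlen <- if ("SVLEN" %in% names(info))
      vapply(info$SVLEN, function(x)
        if (length(x) && !is.na(x[[1]])) as.numeric(x[[1]]) else NA_real_,
        numeric(1))
      else rep(NA_real_, n_rec)
    endf <- if ("END" %in% names(info))
      vapply(info$END, function(x)
        if (length(x) && !is.na(x[[1]])) as.numeric(x[[1]]) else NA_real_,
        numeric(1))
      else rep(NA_real_, n_rec)
    is_del <- (!is.na(svtype) & svtype == "DEL") | alt == "<DEL>" |
      (nchar(ref) > nchar(alt) & !startsWith(alt, "<") & nzchar(alt))
    pos <- GenomicRanges::start(rr)
    size <- abs(svlen)
    size[is.na(size)] <- (endf - pos)[is.na(size)]
    seqres <- is.na(size) & nchar(ref) > nchar(alt) & nzchar(alt)
    size[seqres] <- (nchar(ref) - nchar(alt))[seqres]
    bad <- is_del & (is.na(size) | size < 1)
    if (any(bad))
      warning(sum(bad), " deletion record(s) with unparseable size skipped")
    keep <- is_del & !bad
    out <- data.frame(contig = as.character(GenomicRanges::seqnames(rr))[keep],
                      start = pos[keep] - 1L,
                      size = as.integer(size[keep]))
  }
  out <- out[out$size >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label windows by overlap with truth deletions
#'
#' A window is labelled 1 exactly when its half-open interval intersects a
#' truth deletion interval `[start, start + size)` on the same contig; any
#' nonzero overlap counts, with no minimum reciprocal-overlap requirement.
#'
#' @param windows Window data.frame from [partition_reference()].
#' @param truths Truth data.frame from [load_truth()] (columns `contig`,
#'   `start`, `size`).
#' @return Integer vector of labels in {0,1}, one per window row.
#' @export
label_windows <- function(windows, truths) {
  labels <- integer(nrow(windows))
  if (is.null(truths) || nrow(truths) == 0L) return(labels)
  for (ctg in unique(windows$contig)) {
    wi <- which(windows$contig == ctg)
    tr <- truths[truths$contig == ctg, , drop = FALSE]
    if (nrow(tr) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
      IRanges::IRanges(tr$start + 1L, tr$start + tr$size))
    labels[wi[unique(S4Vectors::queryHits(ov))]] <- 1L
  }
  labels
}
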