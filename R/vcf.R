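#' Write deletion calls as a VCF 4.2 file
#'
#' Emits symbolic `<DEL>` records: `POS` is the 1-based first deleted base,
#' `INFO` carries `SVTYPE=DEL`, `SVLEN=-size`, `END=POS+size` and
#' `SUPPORT`, with `IMPRECISE` where the call fell back to region bounds.
#' Calls smaller than `min_report_size` are dropped (default 50 bp, the
#' conventional structural-variant size floor). Genotypes are emitted as
#' `./.` — the method does not genotype.
#'
#' @param calls data.frame from [call_deletions()] (or any frame with
#'   `contig`, `start` 0-based, `size`; optional `support`, `imprecise`).
#' @param contig_lengths Named vector for the `##contig` header lines.
#' @param out Output path.
#' @param min_report_size Minimum deletion size to report (default 50).
#' @param sample Sample name for the genotype column.
#' @return `out`, invisibly.
#' @export
write_vcf <- function(calls, contig_lengths, out, min_report_size = 50L,
                      sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=delnet",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(unlist(contig_lengths))),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting signature count\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Breakpoints not refined by read signatures\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  if (!is.null(calls) && nrow(calls) > 0L) {
    calls <- calls[calls$size >= min_report_size, , drop = FALSE]
    calls <- calls[order(calls$contig, calls$start), , drop = FALSE]
  }
  lines <- hdr
  if (!is.null(calls) && nrow(calls) > 0L) {
    support <- if ("support" %in% names(calls)) calls$support
               else rep(NA_integer_, nrow(calls))
    imprec <- if ("imprecise" %in% names(calls)) calls$imprecise
              else rep(FALSE, nrow(calls))
    pos <- calls$start + 1L
    info <- sprintf("SVTYPE=DEL;SVLEN=%d;END=%d", -calls$size,
                    pos + calls$size)
    info <- ifelse(is.na(support), info,
                   paste0(info, ";SUPPORT=", support))
    info <- ifelse(imprec, paste0("IMPRECISE;", info), info)
    lines <- c(lines, sprintf(
      "%s\t%d\tdel_%d\tN\t<DEL>\t.\tPASS\t%s\tGT\t./.",
      calls$contig, pos, seq_len(nrow(calls)), info))
  }
  writeLines(lines, out)
  invisible(out)
}

#' Write a truth set as BED (0-based half-open intervals)
#'
#' @param truths data.frame with `contig`, `start`, `size`.
#' @param out Output path.
#' @export
write_truth_bed <- function(truths, out) {
  utils::write.table(
    data.frame(truths$contig, truths$start, truths$start + truths$size),
    out, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(out)
}
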