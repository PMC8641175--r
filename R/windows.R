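#' Partition a reference genome into fixed-length windows
#'
#' Tiles every contig left to right with non-overlapping windows of
#' `window_size` base pairs. The final window on a contig may be shorter;
#' downstream feature extraction zero-pads its bitmaps to full length.
#' Coordinates are 0-based, half-open throughout the package.
#'
#' @param contig_lengths Named integer/numeric vector or list mapping contig
#'   name to length in bp.
#' @param window_size Window length in bp (default 200).
#' @return A data.frame with columns `contig`, `start`, `end`, `index`
#'   (0-based ordinal of the window on its contig).
#' @examples
#' partition_reference(c(chr1 = 1000), 200)
#' @export
partition_reference <- function(contig_lengths, window_size = 200L) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) || window_size < 1L)
    stop("`window_size` must be a single positive integer", call. = FALSE)
  contig_lengths <- unlist(contig_lengths)
  if (length(contig_lengths) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), index = integer()))
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("`contig_lengths` must be named by contig", call. = FALSE)
  if (any(contig_lengths < 1))
    stop("contig lengths must be >= 1", call. = FALSE)
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- as.numeric(contig_lengths[[ctg]])
    n_win <- ceiling(len / window_size)
    idx <- seq_len(n_win) - 1L
    start <- idx * window_size
    data.frame(contig = ctg, start = start,
               end = pmin(start + window_size, len), index = idx)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Construct one window descriptor
#'
#' @param contig Contig name.
#' @param start,end 0-based half-open bounds.
#' @param index Ordinal of the window on its contig (`start == index * m`
#'   for the package's regular tiling).
#' @return A `subregion` list.
#' @keywords internal
subregion <- function(contig, start, end, index) {
  stopifnot(end > start, start >= 0)
  structure(list(contig = as.character(contig), start = as.integer(start),
                 end = as.integer(end), index = as.integer(index)),
            class = "subregion")
}
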