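#' Matching criteria for call-vs-truth comparison
#'
#' A call and a truth deletion match when their starts differ by at most
#' `max_breakpoint_distance` and their size ratio `min(size) / max(size)`
#' is at least `min_size_similarity`. The defaults mirror the published
#' defaults of the standard SV benchmarking tool (500 bp, 0.7); the
#' matching here is a documented simplification (greedy nearest-first,
#' one-to-one), not a re-implementation of that tool.
#'
#' @param max_breakpoint_distance Maximum |start difference| in bp.
#' @param min_size_similarity Minimum size ratio in (0, 1].
#' @return A `match_criteria` list.
#' @export
match_criteria <- function(max_breakpoint_distance = 500L,
                           min_size_similarity = 0.7) {
  stopifnot(max_breakpoint_distance >= 0,
            min_size_similarity > 0, min_size_similarity <= 1)
  structure(list(max_breakpoint_distance = as.integer(max_breakpoint_distance),
                 min_size_similarity = min_size_similarity),
            class = "match_criteria")
}

#' Match calls against truth and report precision/recall/F1
#'
#' Candidate pairs on the same contig that satisfy the criteria are matched
#' greedily in order of ascending breakpoint distance; every call and every
#' truth record is used at most once.
#'
#' @param calls data.frame with `contig`, `start`, `size`.
#' @param truths data.frame with `contig`, `start`, `size`.
#' @param criteria A [match_criteria()].
#' @return An `eval_report` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, and `matches` (data.frame of call/truth index pairs with
#'   distances and size similarity).
#' @export
match_calls <- function(calls, truths, criteria = match_criteria()) {
  n_call <- if (is.null(calls)) 0L else nrow(calls)
  n_truth <- if (is.null(truths)) 0L else nrow(truths)
  matches <- data.frame(call = integer(), truth = integer(),
                        distance = integer(), size_similarity = numeric())
  if (n_call > 0L && n_truth > 0L) {
    cand <- do.call(rbind, lapply(seq_len(n_call), function(i) {
      same <- which(truths$contig == calls$contig[i])
      if (!length(same)) return(NULL)
      d <- abs(truths$start[same] - calls$start[i])
      sim <- pmin(truths$size[same], calls$size[i]) /
        pmax(truths$size[same], calls$size[i])
      ok <- d <= criteria$max_breakpoint_distance &
        sim >= criteria$min_size_similarity
      if (!any(ok)) return(NULL)
      data.frame(call = i, truth = same[ok], distance = d[ok],
                 size_similarity = sim[ok])
    }))
    if (!is.null(cand) && nrow(cand) > 0L) {
      cand <- cand[order(cand$distance, cand$call, cand$truth), , drop = FALSE]
      used_call <- logical(n_call)
      used_truth <- logical(n_truth)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        ci <- cand$call[k]; ti <- cand$truth[k]
        if (!used_call[ci] && !used_truth[ti]) {
          keep[k] <- TRUE
          used_call[ci] <- TRUE
          used_truth[ti] <- TRUE
        }
      }
      matches <- cand[keep, , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  tp <- nrow(matches)
  fp <- n_call - tp
  fn <- n_truth - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, matches = matches),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("deletion call evaluation: TP %d  FP %d  FN %d\n", x$tp, x$fp,
              x$fn))
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f\n", x$precision,
              x$recall, x$f1))
  invisible(x)
}

#' Window-level area under the ROC curve
#'
#' Rank-based (midrank ties) AUC of window scores against 0/1 labels.
#'
#' @param scores Numeric vector of window probabilities.
#' @param labels 0/1 vector, same length.
#' @return AUC in [0, 1].
#' @export
window_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC is undefined: labels contain a single class", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0L, 1L),
                                 direction = "<", quiet = TRUE)))
}
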