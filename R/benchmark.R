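# Benchmarking against a PCR-style truth table: sensitivity, FDR, precision,
# per-category confirmation rates, and recall against external call sets.
# All rates are computed over PCR-tested SVs only.

#' Confusion metrics over PCR-tested SVs
#'
#' `tp` = predicted and PCR-positive, `fp` = predicted and PCR-negative,
#' `fn` = PCR-positive not predicted; sensitivity = tp/(tp+fn),
#' FDR = fp/(tp+fp) (NA when nothing is predicted), precision = 1 - FDR.
#' Predictions must be restricted to tested SVs; an unknown id is an error.
#'
#' @param predicted_positive_ids character vector of predicted-positive SV
#'   ids (duplicates are ignored).
#' @param truth data.frame with `sv_id`, `pcr_result`
#'   (`POSITIVE`/`NEGATIVE`), optionally `category`.
#' @return data.frame with `tp`, `fp`, `fn`, `sensitivity`, `fdr`,
#'   `precision`.
#' @export
confusion_metrics <- function(predicted_positive_ids, truth) {
  if (nrow(truth) == 0) stop("truth table is empty")
  pred <- unique(as.character(predicted_positive_ids))
  unknown <- setdiff(pred, truth$sv_id)
  if (length(unknown)) {
    stop("prediction id(s) absent from truth: ", paste(unknown, collapse = ", "))
  }
  pos <- truth$sv_id[truth$pcr_result == "POSITIVE"]
  neg <- truth$sv_id[truth$pcr_result == "NEGATIVE"]
  tp <- length(intersect(pred, pos))
  fp <- length(intersect(pred, neg))
  fn <- length(setdiff(pos, pred))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (tp + fp) else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, sensitivity = sens, fdr = fdr,
             precision = 1 - fdr)
}

#' PCR confirmation rate per category
#'
#' @param truth data.frame with `sv_id`, `category`, `pcr_result`.
#' @return data.frame with `category`, `tested`, `confirmed`, `rate`
#'   (NA for an empty category).
#' @export
category_confirmation <- function(truth) {
  cats <- unique(truth$category)
  do.call(rbind, lapply(cats, function(cc) {
    sub <- truth[truth$category == cc, , drop = FALSE]
    data.frame(category = cc, tested = nrow(sub),
               confirmed = sum(sub$pcr_result == "POSITIVE"),
               rate = if (nrow(sub)) mean(sub$pcr_result == "POSITIVE")
                      else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Recall against an external truth call set
#'
#' Fraction of truth calls matched by at least one call under the same
#' type/orientation/window rule as [compare_technologies] (identical
#' chromosome pair, both breakpoint distances within `window`).
#'
#' @param calls merged SV table.
#' @param truth_calls SV table of truth calls (typed and oriented).
#' @param window matching window (default 500).
#' @return recall in \[0, 1\].
#' @export
external_recall <- function(calls, truth_calls, window = 500) {
  if (nrow(truth_calls) == 0) return(NA_real_)
  if (nrow(calls) == 0) return(0)
  hit <- vapply(seq_len(nrow(truth_calls)), function(i) {
    t <- truth_calls[i, ]
    any(calls$sv_type == t$sv_type &
        calls$orientation == t$orientation &
        calls$chrom1 == t$chrom1 & calls$chrom2 == t$chrom2 &
        abs(calls$pos1 - t$pos1) <= window &
        abs(calls$pos2 - t$pos2) <= window)
  }, logical(1))
  mean(hit)
}

#' Read a PCR truth table (TSV with sv_id, category, pcr_result)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
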