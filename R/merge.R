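# Within-technology merging of multi-caller SV calls and cross-technology
# comparison into common / only-SR / only-LR categories.

#' Merge multi-caller SV calls within one technology
#'
#' Calls of identical type and orientation whose two breakpoints each lie
#' within `window` bp are merged into one event.  Clustering is greedy
#' single-pass and anchored: within each (type, orientation, chromosome pair)
#' group, calls are sorted canonically, a cluster is opened at the first
#' unassigned call, and subsequent calls join it when both their breakpoints
#' are within `window` of the *anchor* (the cluster's first member).  This
#' avoids unbounded transitive chaining and is order-invariant because of the
#' canonical sort.  The representative breakpoints are taken from the first
#' PASS member if any, else from the anchor; a merged call is high-confidence
#' iff at least one member was predicted with FILTER PASS.
#'
#' @param calls an [sv_calls] data.frame, all from one technology.
#' @param window merge window in bp (default 500).
#' @return a `data.frame` with one row per merged SV: representative
#'   coordinates, `tool_count` (distinct callers), `n_members`,
#'   `high_confidence`, and a `members` list-column of member call ids.
#' @export
merge_calls <- function(calls, window = 500) {
  calls <- validate_sv_calls(as.data.frame(calls))
  if (nrow(calls) == 0) return(empty_merged())
  tech <- unique(calls$technology)
  if (length(tech) > 1) stop("merge_calls: calls from mixed technologies")
  ## canonical order makes the greedy pass permutation-invariant
  ord <- order(calls$sv_type, calls$orientation, calls$chrom1, calls$chrom2,
               calls$pos1, calls$pos2, calls$caller, calls$id,
               method = "radix")
  calls <- calls[ord, , drop = FALSE]
  okey <- ifelse(is.na(calls$orientation), "NA", calls$orientation)
  grp <- paste(calls$sv_type, okey, calls$chrom1, calls$chrom2, sep = "\r")
  res <- list()
  for (g in split(seq_len(nrow(calls)), grp)) {
    assigned <- rep(FALSE, length(g))
    for (k in seq_along(g)) {
      if (assigned[k]) next
      anchor <- calls[g[k], ]
      member_rows <- k
      assigned[k] <- TRUE
      for (j in seq_along(g)) {
        if (assigned[j]) next
        cand <- calls[g[j], ]
        if (abs(cand$pos1 - anchor$pos1) <= window &&
            abs(cand$pos2 - anchor$pos2) <= window) {
          member_rows <- c(member_rows, j)
          assigned[j] <- TRUE
        }
      }
      mem <- calls[g[member_rows], , drop = FALSE]
      rep_row <- if (any(mem$pass_filter)) mem[which(mem$pass_filter)[1], ] else mem[1, ]
      res[[length(res) + 1L]] <- data.frame(
        sv_type = anchor$sv_type, orientation = anchor$orientation,
        technology = tech,
        chrom1 = rep_row$chrom1, pos1 = rep_row$pos1,
        chrom2 = rep_row$chrom2, pos2 = rep_row$pos2,
        size = rep_row$size,
        tool_count = length(unique(mem$caller)),
        n_members = nrow(mem),
        high_confidence = any(mem$pass_filter),
        stringsAsFactors = FALSE)
      attr(res[[length(res)]], "members") <- mem$id
    }
  }
  members <- lapply(res, attr, "members")
  out <- do.call(rbind, res)
  ## deterministic ids in canonical coordinate order
  oo <- order(out$chrom1, out$pos1, out$chrom2, out$pos2, out$sv_type,
              method = "radix")
  out <- out[oo, , drop = FALSE]
  members <- members[oo]
  out$id <- sprintf("%s_m%04d", tech, seq_len(nrow(out)))
  out$members <- I(members)
  rownames(out) <- NULL
  out[, c("id", "sv_type", "orientation", "technology", "chrom1", "pos1",
          "chrom2", "pos2", "size", "tool_count", "n_members",
          "high_confidence", "members")]
}

empty_merged <- function() {
  data.frame(id = character(), sv_type = character(), orientation = character(),
             technology = character(), chrom1 = character(), pos1 = integer(),
             chrom2 = character(), pos2 = integer(), size = integer(),
             tool_count = integer(), n_members = integer(),
             high_confidence = logical(), members = I(list()),
             stringsAsFactors = FALSE)
}

#' Compare merged SV sets between technologies
#'
#' Only SVs with size > 50 bp participate (translocations, which have no
#' size, always do).  Duplications and inversions take part in cross-technology
#' *matching* only when larger than 10 kb — the linked-read pipeline reports
#' those types above 10 kb only — and below that floor they are categorized to
#' their sole technology.  A match requires identical type and orientation,
#' the same chromosome pair, and both breakpoint distances within `window`.
#' Matching is one-to-one, greedy by total breakpoint distance, which makes
#' the operation symmetric in its two inputs.
#'
#' @param sr,lr merged SV tables from [merge_calls] for the SR and LR
#'   technology.
#' @param window matching window in bp (default 500).
#' @return a `data.frame` with one row per comparison record: `category`
#'   (`COMMON`, `ONLY_SR`, `ONLY_LR`), `id`/`partner_id`, and representative
#'   fields.  A COMMON pair is emitted once, with the SR member as `id`.
#' @export
compare_technologies <- function(sr, lr, window = 500) {
  size_ok <- function(m) is.na(m$size) | m$size > 50
  sr <- sr[size_ok(sr), , drop = FALSE]
  lr <- lr[size_ok(lr), , drop = FALSE]
  matchable <- function(m) {
    !(m$sv_type %in% c("DUP", "INV")) | (!is.na(m$size) & m$size > 10000)
  }
  sm <- matchable(sr); lm <- matchable(lr)
  si <- which(sm); li <- which(lm)
  pairs <- NULL
  if (length(si) && length(li)) {
    cand <- list()
    for (a in si) {
      x <- sr[a, ]
      hit <- li[lr$sv_type[li] == x$sv_type &
                lr$orientation[li] == x$orientation &
                lr$chrom1[li] == x$chrom1 & lr$chrom2[li] == x$chrom2 &
                abs(lr$pos1[li] - x$pos1) <= window &
                abs(lr$pos2[li] - x$pos2) <= window]
      if (length(hit)) {
        cand[[length(cand) + 1L]] <- data.frame(
          a = a, b = hit,
          d = abs(lr$pos1[hit] - x$pos1) + abs(lr$pos2[hit] - x$pos2))
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$d, sr$id[cand$a], lr$id[cand$b]), , drop = FALSE]
      used_a <- logical(nrow(sr)); used_b <- logical(nrow(lr))
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        if (!used_a[cand$a[r]] && !used_b[cand$b[r]]) {
          keep[r] <- TRUE; used_a[cand$a[r]] <- TRUE; used_b[cand$b[r]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  rec <- list()
  matched_sr <- if (!is.null(pairs)) pairs$a else integer(0)
  matched_lr <- if (!is.null(pairs)) pairs$b else integer(0)
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      x <- sr[pairs$a[r], ]; y <- lr[pairs$b[r], ]
      rec[[length(rec) + 1L]] <- data.frame(
        id = x$id, partner_id = y$id, category = "COMMON",
        sv_type = x$sv_type, orientation = x$orientation,
        chrom1 = x$chrom1, pos1 = x$pos1, chrom2 = x$chrom2, pos2 = x$pos2,
        size = x$size, technology = "BOTH",
        tool_count = x$tool_count + y$tool_count,
        high_confidence = x$high_confidence || y$high_confidence,
        stringsAsFactors = FALSE)
    }
  }
  one_sided <- function(m, rows, category) {
    lapply(rows, function(a) {
      x <- m[a, ]
      data.frame(id = x$id, partner_id = NA_character_, category = category,
                 sv_type = x$sv_type, orientation = x$orientation,
                 chrom1 = x$chrom1, pos1 = x$pos1, chrom2 = x$chrom2,
                 pos2 = x$pos2, size = x$size, technology = x$technology,
                 tool_count = x$tool_count,
                 high_confidence = x$high_confidence,
                 stringsAsFactors = FALSE)
    })
  }
  rec <- c(rec,
           one_sided(sr, setdiff(seq_len(nrow(sr)), matched_sr), "ONLY_SR"),
           one_sided(lr, setdiff(seq_len(nrow(lr)), matched_lr), "ONLY_LR"))
  if (!length(rec)) {
    return(data.frame(id = character(), partner_id = character(),
                      category = character(), sv_type = character(),
                      orientation = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(), pos2 = integer(),
                      size = integer(), technology = character(),
                      tool_count = integer(), high_confidence = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rec)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2, out$id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
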