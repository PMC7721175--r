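# Breakpoint annotation: repeat class and mappability from BED tracks, and
# normalized local coverage in a 400-bp window around each breakpoint.

REPEAT_PRIORITY <- c("Satellite", "Simple_repeat", "Low_complexity", "SINE",
                     "LINE", "LTR", "DNA", "Other")

bed_to_granges <- function(bed) {
  if (is.character(bed)) {
    gr <- tryCatch(rtracklayer::import(bed, format = "bed"),
                   error = function(e) stop("malformed BED '", bed, "': ",
                                            conditionMessage(e)))
  } else gr <- bed
  gr
}

breakpoint_granges <- function(breakpoints) {
  GenomicRanges::GRanges(breakpoints$chrom,
                         IRanges::IRanges(breakpoints$pos, breakpoints$pos))
}

#' Annotate breakpoints with repeat class
#'
#' A breakpoint lies "in" a repeat interval when its single base overlaps the
#' interval (BED half-open intervals are converted by the importer).  When
#' several repeat intervals overlap one breakpoint, the class is chosen by a
#' fixed priority, most SV-artefact-prone first: Satellite > Simple_repeat >
#' Low_complexity > SINE > LINE > LTR > DNA > Other.  Unannotated classes map
#' to `Other`; no overlap gives `None`.
#'
#' @param breakpoints data.frame with `chrom`, `pos` (1-based).
#' @param repeat_bed BED path (class in column 4) or a `GRanges` with a
#'   `name` column.
#' @return character vector of repeat classes, one per breakpoint.
#' @export
annotate_repeats <- function(breakpoints, repeat_bed) {
  gr <- bed_to_granges(repeat_bed)
  cls <- as.character(gr$name)
  cls[!cls %in% REPEAT_PRIORITY] <- "Other"
  bp <- breakpoint_granges(breakpoints)
  hits <- GenomicRanges::findOverlaps(bp, gr, ignore.strand = TRUE)
  out <- rep("None", nrow(breakpoints))
  if (length(hits)) {
    rank <- match(cls[S4Vectors::subjectHits(hits)], REPEAT_PRIORITY)
    best <- tapply(rank, S4Vectors::queryHits(hits), min)
    out[as.integer(names(best))] <- REPEAT_PRIORITY[best]
  }
  out
}

#' Annotate breakpoints with mappability
#'
#' @param breakpoints data.frame with `chrom`, `pos`.
#' @param mappability_bed BED of *poor-mappability* intervals (path or
#'   `GRanges`).
#' @return logical vector: `TRUE` when the breakpoint does NOT overlap any
#'   poor-mappability interval (uniquely mappable).
#' @export
annotate_mappability <- function(breakpoints, mappability_bed) {
  gr <- bed_to_granges(mappability_bed)
  bp <- breakpoint_granges(breakpoints)
  !IRanges::overlapsAny(bp, gr, ignore.strand = TRUE)
}

#' Normalized local coverage around a breakpoint
#'
#' Mean per-base depth over the window `[pos - window/2, pos + window/2)`
#' divided by the sample mean depth.
#'
#' @param alignments coverage source: a data.frame with `chrom`, `pos`, `end`
#'   (1-based inclusive aligned spans), or a BAM path.
#' @param chrom,pos breakpoint.
#' @param window window size in bp, even (default 400).
#' @param sample_mean_depth genome-wide mean depth (> 0).
#' @param contig_lengths named lengths, used to reject off-contig breakpoints
#'   when `alignments` is a data.frame (for BAM input the header is used).
#' @return normalized local coverage (ratio >= 0).
#' @export
local_coverage <- function(alignments, chrom, pos, window = 400,
                           sample_mean_depth, contig_lengths = NULL) {
  if (window %% 2 != 0) stop("window must be even")
  if (sample_mean_depth <= 0) stop("sample_mean_depth must be positive")
  w2 <- window %/% 2
  win_start <- pos - w2; win_end <- pos + w2 - 1L   # [pos - w/2, pos + w/2)
  if (is.character(alignments)) {
    hdr <- Rsamtools::scanBamHeader(alignments)[[1]]$targets
    if (!chrom %in% names(hdr)) stop("breakpoint off-contig: ", chrom)
    p <- Rsamtools::ScanBamParam(
      what = c("pos", "qwidth"),
      which = GenomicRanges::GRanges(chrom, IRanges::IRanges(
        max(1L, win_start), win_end)),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE))
    res <- Rsamtools::scanBam(alignments, param = p)[[1]]
    aln <- data.frame(chrom = chrom, pos = res$pos,
                      end = res$pos + res$qwidth - 1L)
  } else {
    if (!is.null(contig_lengths)) {
      if (!chrom %in% names(contig_lengths) || pos < 1 ||
          pos > contig_lengths[[chrom]]) {
        stop("breakpoint off-contig: ", chrom, ":", pos)
      }
    }
    aln <- alignments[alignments$chrom == chrom, , drop = FALSE]
  }
  if (nrow(aln) == 0) return(0)
  ir <- IRanges::IRanges(aln$pos, aln$end)
  cov <- IRanges::coverage(ir)
  ## mean depth over the window; positions beyond the coverage vector are 0
  total <- 0
  sel_start <- max(1L, win_start); sel_end <- min(length(cov), win_end)
  if (sel_start <= sel_end) {
    total <- sum(IRanges::Views(cov, sel_start, sel_end))[1]
  }
  (total / window) / sample_mean_depth
}

#' Annotate a set of SVs (both breakpoints)
#'
#' Per-SV classification features use the mean of the two breakpoints'
#' normalized coverages (one symmetric feature per SV).
#'
#' @param svs SV (merged) call table.
#' @param repeat_bed,mappability_bed annotation tracks (paths or `GRanges`).
#' @param alignments coverage source (data.frame or BAM path); `NULL` skips
#'   coverage.
#' @param sample_mean_depth genome-wide mean depth.
#' @param window coverage window (default 400).
#' @return data.frame with one row per SV: per-breakpoint repeat class and
#'   mappability, and `local_coverage_norm` (mean of the two breakpoints).
#' @export
annotate_svs <- function(svs, repeat_bed = NULL, mappability_bed = NULL,
                         alignments = NULL, sample_mean_depth = NULL,
                         window = 400) {
  svs <- as.data.frame(svs)
  bps <- data.frame(chrom = c(svs$chrom1, svs$chrom2),
                    pos = c(svs$pos1, svs$pos2))
  n <- nrow(svs)
  rep_cls <- if (!is.null(repeat_bed)) annotate_repeats(bps, repeat_bed)
             else rep(NA_character_, 2 * n)
  mapp <- if (!is.null(mappability_bed)) annotate_mappability(bps, mappability_bed)
          else rep(NA, 2 * n)
  covn <- rep(NA_real_, 2 * n)
  if (!is.null(alignments)) {
    if (is.data.frame(alignments)) {
      ## precompute per-chromosome coverage once
      covs <- lapply(split(alignments, alignments$chrom), function(a)
        IRanges::coverage(IRanges::IRanges(a$pos, a$end)))
      w2 <- window %/% 2
      for (k in seq_len(2 * n)) {
        cov <- covs[[bps$chrom[k]]]
        if (is.null(cov)) { covn[k] <- 0; next }
        s <- max(1L, bps$pos[k] - w2); e <- min(length(cov), bps$pos[k] + w2 - 1L)
        tot <- if (s <= e) sum(IRanges::Views(cov, s, e))[1] else 0
        covn[k] <- (tot / window) / sample_mean_depth
      }
    } else {
      for (k in seq_len(2 * n)) {
        covn[k] <- local_coverage(alignments, bps$chrom[k], bps$pos[k],
                                  window = window,
                                  sample_mean_depth = sample_mean_depth)
      }
    }
  }
  data.frame(sv_id = svs$id,
             repeat_bp1 = rep_cls[seq_len(n)], repeat_bp2 = rep_cls[n + seq_len(n)],
             unique_mappability_bp1 = mapp[seq_len(n)],
             unique_mappability_bp2 = mapp[n + seq_len(n)],
             coverage_bp1 = covn[seq_len(n)], coverage_bp2 = covn[n + seq_len(n)],
             local_coverage_norm = (covn[seq_len(n)] + covn[n + seq_len(n)]) / 2,
             stringsAsFactors = FALSE)
}
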