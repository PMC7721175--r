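# Requantification of SV support: reads are aligned to breakpoint-fusion
# templates and junction reads (JR) and spanning pairs (SP) are counted and
# normalized per 1e8 reads / read-pairs.

#' Remove linked-read barcodes and equalize mate lengths
#'
#' Linked-read read-1 carries a 16-bp droplet barcode adjacent to its 5' end.
#' The barcode (and any following adapter bases) is removed by trimming read-1
#' to its last 125 bp equivalent: the first 16 bases are cut and the remainder
#' truncated to 125 bp.  Read-2 carries no barcode but is symmetrically
#' truncated to 125 bp so both mates have equal length.
#'
#' @param read1,read2 character vectors of mate sequences.
#' @param barcode_length barcode length in bp (default 16).
#' @param target_length output read length (default 125).
#' @return list with `read1`, `read2` (trimmed) and `barcode` (the removed
#'   16-mers).
#' @export
debarcode_linked_reads <- function(read1, read2, barcode_length = 16,
                                   target_length = 125) {
  if (any(nchar(read1) <= barcode_length)) {
    stop("read-1 shorter than or equal to the ", barcode_length, "-bp barcode")
  }
  barcode <- substr(read1, 1L, barcode_length)
  r1 <- substr(read1, barcode_length + 1L, barcode_length + target_length)
  r2 <- substr(read2, 1L, target_length)
  list(read1 = r1, read2 = r2, barcode = barcode)
}

#' Downsample read pairs
#'
#' Each pair is retained independently with probability `fraction`; mates are
#' kept or dropped together.  Deterministic for a fixed seed.
#'
#' @param pairs a data.frame of reads with columns `read_id` and `mate`
#'   (1 or 2), or any data.frame with a `read_id` column (rows sharing a
#'   `read_id` form a pair).
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return the retained subset of `pairs`.
#' @export
downsample_reads <- function(pairs, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (fraction == 1) return(pairs)
  ids <- unique(pairs$read_id)
  keep <- withr::with_seed(seed, stats::runif(length(ids)) < fraction)
  pairs[pairs$read_id %in% ids[keep], , drop = FALSE]
}

#' Align reads to a breakpoint template
#'
#' Each read is aligned, forward and reverse-complement, with a k-mer-seeded
#' banded affine-gap local aligner (match +1, mismatch -1, gap open -3, gap
#' extend -1); alignments scoring below `min_score_frac * read_length` are
#' discarded.  `aligned_bases` counts matches plus mismatches within the
#' aligned span, excluding clips.
#'
#' @param reads data.frame with columns `read_id`, `mate`, `seq`.
#' @param template a template from [build_templates], or a plain character
#'   template sequence.
#' @param min_score_frac score floor as a fraction of read length
#'   (default 0.5).
#' @return data.frame of alignments: `read_id`, `mate`, `strand`, `start`,
#'   `end` (0-based half-open on the template), `score`, `aligned_bases`,
#'   `read_length`.  Unalignable reads yield no row.
#' @export
align_to_template <- function(reads, template, min_score_frac = 0.5) {
  tseq <- if (is.list(template)) template$sequence else as.character(template)
  hits <- .align_reads_cpp(as.character(reads$seq), tseq, min_score_frac)
  if (nrow(hits) == 0) {
    return(data.frame(read_id = character(), mate = integer(),
                      strand = character(), start = integer(), end = integer(),
                      score = integer(), aligned_bases = integer(),
                      read_length = integer(), stringsAsFactors = FALSE))
  }
  ## keep the best alignment per read (+ strand ties resolved by score, start)
  df <- data.frame(read_id = reads$read_id[hits$read],
                   mate = reads$mate[hits$read], strand = hits$strand,
                   start = hits$start, end = hits$end, score = hits$score,
                   aligned_bases = hits$aligned_bases,
                   read_length = nchar(reads$seq)[hits$read],
                   stringsAsFactors = FALSE)
  df <- df[order(df$read_id, df$mate, -df$score, df$start), , drop = FALSE]
  df <- df[!duplicated(paste(df$read_id, df$mate)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Multi-template variant used by the pipeline: aligns every read against all
# templates in one pass and returns per-template alignment tables.
align_to_templates <- function(reads, templates, min_score_frac = 0.5) {
  tseqs <- vapply(templates, function(t)
    if (is.list(t)) t$sequence else as.character(t), character(1))
  hits <- .align_reads_cpp(as.character(reads$seq), tseqs, min_score_frac)
  res <- vector("list", length(templates))
  for (ti in seq_along(templates)) {
    h <- hits[hits$template == ti, , drop = FALSE]
    if (nrow(h) == 0) {
      res[[ti]] <- data.frame(read_id = character(), mate = integer(),
                              strand = character(), start = integer(),
                              end = integer(), score = integer(),
                              aligned_bases = integer(),
                              read_length = integer(), stringsAsFactors = FALSE)
      next
    }
    df <- data.frame(read_id = reads$read_id[h$read], mate = reads$mate[h$read],
                     strand = h$strand, start = h$start, end = h$end,
                     score = h$score, aligned_bases = h$aligned_bases,
                     read_length = nchar(reads$seq)[h$read],
                     stringsAsFactors = FALSE)
    df <- df[order(df$read_id, df$mate, -df$score, df$start), , drop = FALSE]
    df <- df[!duplicated(paste(df$read_id, df$mate)), , drop = FALSE]
    rownames(df) <- NULL
    res[[ti]] <- df
  }
  res
}

#' Count junction reads and spanning pairs on a template
#'
#' A junction read (JR) covers the fusion point with at least 15 aligned bases
#' on *each* side of it and has at least 70% of its bases aligned to the
#' template.  A spanning pair (SP) has one mate aligned entirely left of the
#' junction and the other entirely right, both mates passing the 70% filter,
#' facing each other (innie) with an implied insert of at most `max_insert`;
#' a pair contributes to SP only if neither mate is a junction read.  Each
#' read / pair is counted at most once.
#'
#' @param alignments alignment table from [align_to_template] for this
#'   template.
#' @param template the template the alignments refer to (for its junction).
#' @param min_junction_overlap minimal aligned bases on each side of the
#'   junction (default 15).
#' @param min_aligned_frac minimal fraction of read bases aligned
#'   (default 0.7).
#' @param max_insert maximal implied insert size for a spanning pair
#'   (default 2000).
#' @return list with integer counts `jr_raw` and `sp_raw`.
#' @export
count_support <- function(alignments, template, min_junction_overlap = 15,
                          min_aligned_frac = 0.7, max_insert = 2000) {
  J <- if (is.list(template)) template$junction else as.integer(template)
  a <- alignments
  if (nrow(a) == 0) return(list(jr_raw = 0L, sp_raw = 0L))
  frac_ok <- a$aligned_bases >= min_aligned_frac * a$read_length
  is_jr <- frac_ok & (J - a$start) >= min_junction_overlap &
    (a$end - J) >= min_junction_overlap
  jr_raw <- sum(is_jr)
  ## spanning pairs
  sp_raw <- 0L
  byread <- split(seq_len(nrow(a)), a$read_id)
  for (rows in byread) {
    if (length(rows) < 2) next
    m1 <- rows[a$mate[rows] == 1][1]; m2 <- rows[a$mate[rows] == 2][1]
    if (is.na(m1) || is.na(m2)) next
    if (!frac_ok[m1] || !frac_ok[m2]) next
    if (is_jr[m1] || is_jr[m2]) next
    left <- if (a$end[m1] <= J && a$start[m2] >= J) m1
            else if (a$end[m2] <= J && a$start[m1] >= J) m2 else NA
    if (is.na(left)) next
    right <- setdiff(c(m1, m2), left)
    ## innie: left mate on forward strand, right mate on reverse strand
    if (a$strand[left] != "+" || a$strand[right] != "-") next
    if (a$end[right] - a$start[left] > max_insert) next
    sp_raw <- sp_raw + 1L
  }
  list(jr_raw = jr_raw, sp_raw = sp_raw)
}

#' Normalize requantification support (Eqs for JR, SP, JRS)
#'
#' `jr_norm = jr_raw / total_reads * 1e8`, `sp_norm = sp_raw / total_pairs *
#' 1e8`, and the joint requantification support `jrs = jr_norm + sp_norm`.
#'
#' @param jr_raw,sp_raw raw counts.
#' @param total_reads,total_pairs totals of the prepared read set (post-trim,
#'   post-downsample); must be positive.
#' @param sv_id,source carried through to the result.
#' @return one-row data.frame: `sv_id`, `source`, `jr_raw`, `sp_raw`,
#'   `total_reads`, `total_pairs`, `jr_norm`, `sp_norm`, `jrs`.
#' @export
normalize_support <- function(jr_raw, sp_raw, total_reads, total_pairs,
                              sv_id = NA_character_, source = NA_character_) {
  if (total_reads <= 0 || total_pairs <= 0) {
    stop("total_reads and total_pairs must be positive")
  }
  jr_norm <- jr_raw / total_reads * 1e8
  sp_norm <- sp_raw / total_pairs * 1e8
  data.frame(sv_id = sv_id, source = source, jr_raw = as.integer(jr_raw),
             sp_raw = as.integer(sp_raw), total_reads = as.integer(total_reads),
             total_pairs = as.integer(total_pairs), jr_norm = jr_norm,
             sp_norm = sp_norm, jrs = jr_norm + sp_norm,
             stringsAsFactors = FALSE)
}

#' Requantify a set of SVs against a read set
#'
#' Builds (or accepts) breakpoint templates for every SV, aligns the prepared
#' reads to all templates in one pass, applies the JR/SP counting rules and
#' normalizes.  For inversions the counts of the two fusion templates are
#' summed.
#'
#' @param svs SV (merged) call table.
#' @param ref reference genome ([Biostrings::DNAStringSet] or FASTA path).
#' @param reads data.frame with `read_id`, `mate`, `seq` — already debarcoded
#'   / downsampled as appropriate.
#' @param source `"SR"` or `"LR"` label for the read set.
#' @param flank template flank (default 500).
#' @param total_reads,total_pairs denominators for normalization; default to
#'   the totals of `reads`.
#' @return data.frame with one row per SV (see [normalize_support]).
#' @export
requantify_svs <- function(svs, ref, reads, source, flank = 500,
                           total_reads = nrow(reads),
                           total_pairs = length(unique(reads$read_id))) {
  svs <- as.data.frame(svs)
  tmpl_list <- list(); owner <- integer(0)
  for (r in seq_len(nrow(svs))) {
    ts <- Filter(function(t) !isTRUE(t$skip), build_templates(svs[r, ], ref, flank))
    tmpl_list <- c(tmpl_list, ts)
    owner <- c(owner, rep(r, length(ts)))
  }
  jr <- sp <- integer(nrow(svs))
  if (length(tmpl_list)) {
    alns <- align_to_templates(reads, tmpl_list)
    for (k in seq_along(tmpl_list)) {
      cnt <- count_support(alns[[k]], tmpl_list[[k]])
      jr[owner[k]] <- jr[owner[k]] + cnt$jr_raw
      sp[owner[k]] <- sp[owner[k]] + cnt$sp_raw
    }
  }
  do.call(rbind, lapply(seq_len(nrow(svs)), function(r) {
    normalize_support(jr[r], sp[r], total_reads, total_pairs,
                      sv_id = svs$id[r], source = source)
  }))
}
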