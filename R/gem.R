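# GEM (linked-read barcode) support counting.  Anomalously aligned read pairs
# are extracted from a barcoded alignment file, and for each SV the number of
# distinct barcodes with at least one pair anchoring both breakpoints in the
# matching geometry is counted and normalized per 1e6 barcodes.

#' Extract anomalous read pairs from a barcoded BAM
#'
#' Emits read pairs "aligned without a normal alignment FLAG": not
#' proper-pair, or mates on different chromosomes, or at least one mate with
#' a supplementary/split alignment.  Pairs lacking a barcode tag are dropped
#' (their count is attached as attribute `n_no_barcode`).
#'
#' @param bam path to a coordinate-sorted, indexed BAM with per-read barcode
#'   tags.
#' @param barcode_tag tag holding the barcode (default `"BX"`).
#' @return data.frame with one row per anomalous pair: `qname`, `barcode`,
#'   and per-mate `chrom1`, `pos1`, `end1`, `strand1`, `chrom2`, `pos2`,
#'   `end2`, `strand2` (mate 1/2 ordered by coordinate), plus `interchrom`
#'   and `proper` flags.
#' @export
extract_anomalous_reads <- function(bam, barcode_tag = "BX") {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index not found for '", bam, "'")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth"),
    tag = barcode_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  supp <- bitwAnd(flag, 2048L) > 0
  df <- data.frame(qname = res$qname, chrom = as.character(res$rname),
                   pos = res$pos, end = res$pos + res$qwidth - 1L,
                   strand = as.character(res$strand),
                   first = bitwAnd(flag, 64L) > 0,
                   proper = bitwAnd(flag, 2L) > 0,
                   supp = supp,
                   barcode = res$tag[[barcode_tag]],
                   stringsAsFactors = FALSE)
  pair_anomalous_alignments(df)
}

# Shared pairing logic; also usable on simulator truth alignments (which
# carry `mate` instead of a `first` flag and may lack an `end` column).
pair_anomalous_alignments <- function(df) {
  if (is.null(df$first) && !is.null(df$mate)) df$first <- df$mate == 1
  if (is.null(df$end)) df$end <- df$pos + nchar(df$seq) - 1L
  if (is.null(df$supp)) df$supp <- FALSE
  df <- df[, intersect(c("qname", "chrom", "pos", "end", "strand", "first",
                         "proper", "supp", "barcode"), names(df))]
  has_supp <- tapply(df$supp, df$qname, any)
  prim <- df[!df$supp, , drop = FALSE]
  no_bc <- 0L
  out <- list()
  dt <- data.table::as.data.table(prim)
  grp <- dt[, .N, by = qname]
  paired <- grp$qname[grp$N == 2]
  dt <- dt[qname %in% paired]
  if (nrow(dt)) {
    d1 <- dt[first == TRUE]; d2 <- dt[first == FALSE]
    data.table::setkey(d1, qname); data.table::setkey(d2, qname)
    m <- d1[d2]
    ## i.* columns are mate 2
    interchrom <- m$chrom != m$i.chrom
    proper <- m$proper & m$i.proper
    split_pair <- as.logical(has_supp[m$qname])
    anomalous <- !proper | interchrom | split_pair
    bc <- m$barcode
    keep <- anomalous & !is.na(bc) & nzchar(bc)
    no_bc <- sum(anomalous & (is.na(bc) | !nzchar(bc)))
    m <- m[keep]
    ## order mates by coordinate (chrom, pos)
    swap <- (m$i.chrom < m$chrom) | (m$i.chrom == m$chrom & m$i.pos < m$pos)
    res <- data.frame(
      qname = m$qname, barcode = m$barcode,
      chrom1 = ifelse(swap, m$i.chrom, m$chrom),
      pos1 = ifelse(swap, m$i.pos, m$pos),
      end1 = ifelse(swap, m$i.end, m$end),
      strand1 = ifelse(swap, m$i.strand, m$strand),
      chrom2 = ifelse(swap, m$chrom, m$i.chrom),
      pos2 = ifelse(swap, m$pos, m$i.pos),
      end2 = ifelse(swap, m$end, m$i.end),
      strand2 = ifelse(swap, m$strand, m$i.strand),
      interchrom = interchrom[keep], proper = proper[keep],
      stringsAsFactors = FALSE)
  } else {
    res <- data.frame(qname = character(), barcode = character(),
                      chrom1 = character(), pos1 = integer(), end1 = integer(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = integer(), end2 = integer(), strand2 = character(),
                      interchrom = logical(), proper = logical(),
                      stringsAsFactors = FALSE)
  }
  attr(res, "n_no_barcode") <- as.integer(no_bc)
  res
}

#' GEM retrieval window from molecule statistics
#'
#' The window is the ratio of the average molecule length to the N50
#' linked-reads per molecule, rounded, floored at 200 bp (the floor prevents
#' degenerate windows on toy simulations).
#'
#' @param avg_molecule_length mean inferred molecule length in bp.
#' @param n50_reads_per_molecule N50 of reads per molecule.
#' @return window in bp.
#' @export
compute_window <- function(avg_molecule_length, n50_reads_per_molecule) {
  if (avg_molecule_length <= 0 || n50_reads_per_molecule <= 0) {
    stop("molecule statistics must be positive")
  }
  max(200L, as.integer(round(avg_molecule_length / n50_reads_per_molecule)))
}

# Junction side implied by an anchoring read: a forward-strand read lies left
# of the junction and anchors the 3' flank; a reverse-strand read the 5'.
anchor_side <- function(strand) ifelse(strand == "+", "3", "5")
anchor_pos <- function(strand, pos, end) ifelse(strand == "+", end, pos)

#' Count unique barcodes supporting one SV
#'
#' A pair supports the SV when one anchor falls within `window` of breakpoint
#' 1 and the other within `window` of breakpoint 2 (matching chromosomes),
#' and the pair geometry implies the SV's junction orientation.  The geometry
#' mapping follows standard discordant-pair conventions: a forward-strand
#' anchor contributes the 3' flank of its breakpoint, a reverse-strand anchor
#' the 5' flank (so +/- long-insert pairs support 3to5 deletions, -/+ pairs
#' 5to3 tandem duplications, +/+ pairs 3to3 and -/- pairs 5to5 inverted
#' junctions).  Barcodes are counted with set semantics: once per SV.
#'
#' @param pairs anomalous pair table from [extract_anomalous_reads].
#' @param sv single-row SV record.
#' @param window anchoring window in bp (from [compute_window]).
#' @return integer count of distinct supporting barcodes.
#' @export
count_gems <- function(pairs, sv, window) {
  sv <- as.data.frame(sv)
  if (nrow(pairs) == 0) return(0L)
  a1 <- anchor_pos(pairs$strand1, pairs$pos1, pairs$end1)
  a2 <- anchor_pos(pairs$strand2, pairs$pos2, pairs$end2)
  s1 <- anchor_side(pairs$strand1); s2 <- anchor_side(pairs$strand2)
  support <- function(pc1, pa1, ps1, pc2, pa2, ps2) {
    pc1 == sv$chrom1 & abs(pa1 - sv$pos1) <= window &
    pc2 == sv$chrom2 & abs(pa2 - sv$pos2) <= window &
    paste0(ps1, "to", ps2) == sv$orientation
  }
  ok <- support(pairs$chrom1, a1, s1, pairs$chrom2, a2, s2) |
        support(pairs$chrom2, a2, s2, pairs$chrom1, a1, s1)
  length(unique(pairs$barcode[ok]))
}

#' Normalize a GEM count (barcodes per 1e6)
#'
#' @param gem_raw supporting-barcode count.
#' @param total_gems distinct barcodes observed in the whole sample.
#' @param sv_id,window carried through.
#' @return one-row data.frame `sv_id`, `window`, `gem_raw`, `total_gems`,
#'   `gem_norm`.
#' @export
normalize_gems <- function(gem_raw, total_gems, sv_id = NA_character_,
                           window = NA_integer_) {
  if (total_gems <= 0) stop("total_gems must be positive")
  data.frame(sv_id = sv_id, window = as.integer(window),
             gem_raw = as.integer(gem_raw), total_gems = as.integer(total_gems),
             gem_norm = gem_raw / total_gems * 1e6, stringsAsFactors = FALSE)
}

#' GEM-quantify a set of SVs
#'
#' @param svs SV (merged) call table.
#' @param pairs anomalous pair table ([extract_anomalous_reads]) or a BAM
#'   path.
#' @param total_gems distinct barcodes in the whole sample.
#' @param window anchoring window (bp); compute via [compute_window].
#' @return data.frame, one row per SV.
#' @export
gem_quantify_svs <- function(svs, pairs, total_gems, window) {
  if (is.character(pairs)) pairs <- extract_anomalous_reads(pairs)
  do.call(rbind, lapply(seq_len(nrow(svs)), function(r) {
    normalize_gems(count_gems(pairs, svs[r, ], window), total_gems,
                   sv_id = svs$id[r], window = window)
  }))
}

#' Estimate molecule statistics from barcoded alignments
#'
#' Reads are grouped per barcode and chromosome; a gap larger than `max_gap`
#' between consecutive read starts splits a group into separate inferred
#' molecules.  Molecule length is the read span; reported are the average
#' molecule length and the N50 of reads per molecule (the read count c such
#' that molecules with >= c reads hold half of all reads).
#'
#' @param reads data.frame with `barcode`, `chrom`, `pos` (one row per read),
#'   or a BAM path with barcode tags.
#' @param max_gap molecule-splitting gap in bp (default 50 kb).
#' @param barcode_tag BAM barcode tag (default `"BX"`).
#' @return list with `avg_molecule_length`, `n50_reads_per_molecule`,
#'   `n_molecules`.
#' @export
estimate_molecule_stats <- function(reads, max_gap = 50000, barcode_tag = "BX") {
  if (is.character(reads)) {
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos"), tag = barcode_tag,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE))
    res <- Rsamtools::scanBam(reads, param = p)[[1]]
    reads <- data.frame(barcode = res$tag[[barcode_tag]],
                        chrom = as.character(res$rname), pos = res$pos,
                        stringsAsFactors = FALSE)
  }
  dt <- data.table::as.data.table(reads)
  dt <- dt[!is.na(barcode) & nzchar(barcode)]
  data.table::setorder(dt, barcode, chrom, pos)
  dt[, mol := cumsum(c(1L, diff(pos) > max_gap)), by = .(barcode, chrom)]
  mols <- dt[, .(len = max(pos) - min(pos) + 1L, nreads = .N),
             by = .(barcode, chrom, mol)]
  if (nrow(mols) == 0) stop("no barcoded reads found")
  counts <- sort(mols$nreads, decreasing = TRUE)
  cum <- cumsum(counts)
  n50 <- counts[which(cum >= sum(counts) / 2)[1]]
  list(avg_molecule_length = mean(mols$len),
       n50_reads_per_molecule = as.integer(n50),
       n_molecules = nrow(mols))
}

#' Count distinct barcodes in a read set or BAM
#' @param x data.frame with a `barcode` column, or BAM path.
#' @param barcode_tag BAM barcode tag.
#' @return integer count.
#' @export
total_gems_detected <- function(x, barcode_tag = "BX") {
  if (is.character(x)) {
    p <- Rsamtools::ScanBamParam(what = character(0), tag = barcode_tag)
    res <- Rsamtools::scanBam(x, param = p)[[1]]
    bc <- res$tag[[barcode_tag]]
  } else {
    bc <- x$barcode
  }
  length(unique(bc[!is.na(bc) & nzchar(bc)]))
}
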