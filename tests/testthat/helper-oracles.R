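# Independent oracles.  These re-derive expected values from first principles
# and must stay independent of the package's implementation paths.

# VCF 4.2 breakend bracket notation, hand-checked truth table.  For the
# record taken as the FIRST breakend of the pair:
#   t[p[ -> its 3' flank is fused to the mate's 5' flank   => 3to5
#   t]p] -> 3' fused to 3'                                 => 3to3
#   ]p]t -> 5' fused to 3'                                 => 5to3
#   [p[t -> 5' fused to 5'                                 => 5to5
oracle_bnd_orientation <- function(alt) {
  if (grepl("^[ACGTN]+\\[.+\\[$", alt)) "3to5"
  else if (grepl("^[ACGTN]+\\].+\\]$", alt)) "3to3"
  else if (grepl("^\\].+\\][ACGTN]+$", alt)) "5to3"
  else if (grepl("^\\[.+\\[[ACGTN]+$", alt)) "5to5"
  else NA_character_
}

# plain-character reverse complement, independent of Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# literal re-scan of alignments applying the JR/SP rules of the paper:
# >= 15 aligned bases on each side of the junction, >= 70% of read bases
# aligned; SP mates entirely on opposite sides, innie, insert <= 2 kb,
# neither mate a junction read.
oracle_count_support <- function(aln, junction, min_ovl = 15, frac = 0.7,
                                 max_insert = 2000) {
  jr <- 0L
  jr_flag <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    ok70 <- aln$aligned_bases[i] >= frac * aln$read_length[i]
    left <- junction - aln$start[i]
    right <- aln$end[i] - junction
    if (ok70 && left >= min_ovl && right >= min_ovl) {
      jr <- jr + 1L
      jr_flag[i] <- TRUE
    }
  }
  sp <- 0L
  for (q in unique(aln$read_id)) {
    rows <- which(aln$read_id == q)
    i1 <- rows[aln$mate[rows] == 1][1]
    i2 <- rows[aln$mate[rows] == 2][1]
    if (is.na(i1) || is.na(i2)) next
    ok <- aln$aligned_bases[i1] >= frac * aln$read_length[i1] &&
          aln$aligned_bases[i2] >= frac * aln$read_length[i2]
    if (!ok || jr_flag[i1] || jr_flag[i2]) next
    for (ord in list(c(i1, i2), c(i2, i1))) {
      l <- ord[1]; r <- ord[2]
      if (aln$end[l] <= junction && aln$start[r] >= junction &&
          aln$strand[l] == "+" && aln$strand[r] == "-" &&
          aln$end[r] - aln$start[l] <= max_insert) {
        sp <- sp + 1L
        break
      }
    }
  }
  list(jr_raw = jr, sp_raw = sp)
}

# nested-loop GEM oracle: for every barcode, scan all its pairs against the
# SV's two breakpoints with the +=3'/-=5' flank rule.
oracle_count_gems <- function(pairs, sv, window) {
  side <- function(strand) if (strand == "+") "3" else "5"
  apos <- function(strand, pos, end) if (strand == "+") end else pos
  hit_bc <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    a1 <- apos(p$strand1, p$pos1, p$end1)
    a2 <- apos(p$strand2, p$pos2, p$end2)
    combos <- list(
      list(c = p$chrom1, a = a1, s = side(p$strand1),
           c2 = p$chrom2, b = a2, s2 = side(p$strand2)),
      list(c = p$chrom2, a = a2, s = side(p$strand2),
           c2 = p$chrom1, b = a1, s2 = side(p$strand1)))
    for (cb in combos) {
      if (cb$c == sv$chrom1 && abs(cb$a - sv$pos1) <= window &&
          cb$c2 == sv$chrom2 && abs(cb$b - sv$pos2) <= window &&
          paste0(cb$s, "to", cb$s2) == sv$orientation) {
        hit_bc <- c(hit_bc, p$barcode)
        break
      }
    }
  }
  length(unique(hit_bc))
}

# McFadden pseudo-R2 by direct glm fit (oracle for dominance analysis)
oracle_mcfadden <- function(df, response, terms) {
  f0 <- stats::glm(stats::reformulate("1", response), data = df,
                   family = stats::binomial())
  if (length(terms) == 0) return(0)
  f1 <- stats::glm(stats::reformulate(terms, response), data = df,
                   family = stats::binomial())
  1 - as.numeric(stats::logLik(f1)) / as.numeric(stats::logLik(f0))
}

# per-base pileup oracle: depth at each position by explicit counting
oracle_pileup_depth <- function(aln, chrom, positions) {
  vapply(positions, function(p) {
    sum(aln$chrom == chrom & aln$pos <= p & aln$end >= p)
  }, numeric(1))
}
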