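# Breakpoint-fusion templates: synthetic sequences formed by fusing reference
# flanks around an SV junction according to its type/orientation.  Junction
# reads and spanning pairs are counted on these templates; larger versions
# serve as amplicon templates for PCR primer design.
#
# Coordinate conventions (1-based, A = pos1, B = pos2):
#   DEL (3to5): ref[A-f+1 .. A] + ref[B+1 .. B+f]        (A last kept, B last deleted)
#   DUP (5to3): ref[B-f+1 .. B] + ref[A .. A+f-1]        (tandem: 3' end -> own 5' start)
#   INV fusion1 (3to3): ref[A-f+1 .. A] + revcomp(ref[B-f+1 .. B])
#   INV fusion2 (5to5): revcomp(ref[A+1 .. A+f]) + ref[B+1 .. B+f]
#   TRA: the DEL/DUP/INV joins applied across chromosomes per the reported
#        orientation.
# With A = last base before / B = last base of the rearranged segment, both
# INV fusions match an in-place inversion of the genome base-exactly.

slice <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("chromosome '", chrom, "' absent from reference")
  L <- Biostrings::width(ref[chrom])
  s <- max(1L, as.integer(start)); e <- min(L, as.integer(end))
  if (s > e) stop("flank [", start, ",", end, "] fully outside chromosome ", chrom)
  as.character(Biostrings::subseq(ref[[chrom]], s, e))
}

fuse_segments <- function(ref, sv, flank, fusion) {
  A <- sv$pos1; B <- sv$pos2; c1 <- sv$chrom1; c2 <- sv$chrom2
  ty <- sv$sv_type
  f <- as.integer(flank)
  if (ty == "DEL") {
    ## A = last retained base, B = last deleted base
    left <- slice(ref, c1, A - f + 1L, A)
    right <- slice(ref, c2, B + 1L, B + f)
    orient <- "3to5"
  } else if (ty == "DUP") {
    ## tandem: 3' end of the segment (B) joined to its own 5' start (A)
    left <- slice(ref, c2, B - f + 1L, B)
    right <- slice(ref, c1, A, A + f - 1L)
    orient <- "5to3"
  } else if (ty == "INV") {
    ## A = last base before, B = last base of the inverted segment
    if (fusion == 1L) {
      left <- slice(ref, c1, A - f + 1L, A)
      right <- revcomp(slice(ref, c2, B - f + 1L, B))
      orient <- "3to3"
    } else {
      left <- revcomp(slice(ref, c1, A + 1L, A + f))
      right <- slice(ref, c2, B + 1L, B + f)
      orient <- "5to5"
    }
  } else if (ty == "TRA") {
    ## breakend coordinates are the fused bases themselves (VCF BND
    ## semantics): a 3' side contributes ref[pos-f+1 .. pos], a 5' side
    ## ref[pos .. pos+f-1] (reverse-complemented when fused head-to-head)
    orient <- sv$orientation
    left <- switch(orient,
      "3to5" = , "3to3" = slice(ref, c1, A - f + 1L, A),
      "5to3" = slice(ref, c2, B - f + 1L, B),
      "5to5" = revcomp(slice(ref, c1, A, A + f - 1L)))
    right <- switch(orient,
      "3to5" = slice(ref, c2, B, B + f - 1L),
      "5to3" = slice(ref, c1, A, A + f - 1L),
      "3to3" = revcomp(slice(ref, c2, B - f + 1L, B)),
      "5to5" = slice(ref, c2, B, B + f - 1L))
  } else {
    stop("no template defined for sv_type ", ty)
  }
  list(left = left, right = right, orientation = orient)
}

#' Build breakpoint-fusion templates for one SV
#'
#' Retrieves `flank` bp of reference sequence on either side of the two
#' breakpoints and fuses them according to the SV's type and orientation.
#' SVs of size >= 1 kb (and all translocations) get a template of length
#' `2 * flank` with the junction at `flank`; for smaller intra-chromosomal
#' SVs the flank is reduced to the SV size, so the template length is exactly
#' twice the SV size (the smallest template at least twice the SV size that
#' keeps the junction central).  Inversions produce two templates, one per
#' junction.  Flanks are clipped at chromosome ends and the junction offset
#' adjusted accordingly.
#'
#' @param sv a single-row SV record (call or merged call) with `sv_type`,
#'   `orientation`, `chrom1`, `pos1`, `chrom2`, `pos2`, `size`, `id`.
#' @param ref a [Biostrings::DNAStringSet] reference genome (named
#'   chromosomes), or a FASTA path.
#' @param flank flank length in bp (default 500, giving the 1 kb template).
#' @return a list of templates, each a list with `sv_id`, `fusion_index`,
#'   `sequence`, `junction` (0-based offset of the first base after the
#'   fusion), `left_flank`, `right_flank`.
#' @export
build_templates <- function(sv, ref, flank = 500) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  sv <- as.data.frame(sv)
  stopifnot(nrow(sv) == 1)
  if (flank < 1) stop("flank must be positive")
  if (sv$sv_type == "UNK") return(list())
  f <- flank
  if (sv$sv_type != "TRA" && !is.na(sv$size) && sv$size < 1000) {
    f <- min(as.integer(flank), as.integer(sv$size))  # template length <= 2 * size
  }
  fusions <- if (sv$sv_type == "INV") 1:2 else 1L
  out <- lapply(fusions, function(fi) {
    seg <- fuse_segments(ref, sv, f, fi)
    seq <- paste0(seg$left, seg$right)
    tmpl <- list(sv_id = sv$id, fusion_index = fi, sequence = seq,
                 junction = nchar(seg$left), left_flank = nchar(seg$left),
                 right_flank = nchar(seg$right), orientation = seg$orientation)
    nn <- sum(strsplit(seq, "")[[1]] == "N")
    tmpl$frac_n <- nn / nchar(seq)
    tmpl$skip <- tmpl$frac_n > 0.5      # ambiguous templates are flagged
    tmpl
  })
  out
}

#' Build an amplicon template for PCR primer design
#'
#' Same fusion rules as [build_templates] but with a larger flank (default
#' 300 bp, at least 100 bp up- and downstream of the breakpoints for primer
#' headroom).  Returns one FASTA-style record per fusion.
#'
#' @inheritParams build_templates
#' @param min_flank minimal flank in bp (>= 100); the default 300 leaves
#'   primer headroom.
#' @return a named character vector of sequences; names are
#'   `svid|fusionN|junction=K`.
#' @export
build_amplicon_template <- function(sv, ref, min_flank = 300) {
  if (min_flank < 100) stop("min_flank must be >= 100")
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  sv <- as.data.frame(sv)
  fusions <- if (sv$sv_type == "INV") 1:2 else 1L
  seqs <- vapply(fusions, function(fi) {
    seg <- fuse_segments(ref, sv, as.integer(min_flank), fi)
    paste0(seg$left, seg$right)
  }, character(1))
  juncs <- vapply(fusions, function(fi) {
    nchar(fuse_segments(ref, sv, as.integer(min_flank), fi)$left)
  }, integer(1))
  stats::setNames(seqs, sprintf("%s|fusion%d|junction=%d", sv$id, fusions, juncs))
}

#' Build templates for a whole call table
#'
#' @param svs an SV call or merged-call data.frame.
#' @inheritParams build_templates
#' @return flat list of templates (see [build_templates]); templates flagged
#'   `skip` (more than 50\% N) are removed.
#' @export
build_all_templates <- function(svs, ref, flank = 500) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  out <- list()
  for (r in seq_len(nrow(svs))) {
    ts <- build_templates(svs[r, ], ref, flank = flank)
    out <- c(out, Filter(function(t) !isTRUE(t$skip), ts))
  }
  out
}

#' Write templates to FASTA
#' @param templates list from [build_all_templates].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_templates_fasta <- function(templates, path) {
  seqs <- Biostrings::DNAStringSet(vapply(templates, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(templates, function(t)
    sprintf("%s|fusion%d|junction=%d", t$sv_id, t$fusion_index, t$junction),
    character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
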