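# VCF input/output for SV call sets: symbolic ALT (<DEL>/<DUP>/<INV>) with
# INFO END, and paired BND records with bracket notation.  Parsing is backed
# by VariantAnnotation::readVcf; BND mate pairing, bracket decoding and the
# read-depth-CNV drop rule are implemented here.

# Decode a single BND ALT string.  Returns list(chrom, pos, form) where form
# encodes anchor/bracket layout: "t[p[", "t]p]", "]p]t", "[p[t".
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTNacgtn.]*)(\\[|\\])([^\\[\\]:]+):([0-9]+)(\\[|\\])([ACGTNacgtn.]*)$",
    alt, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  pre <- m[2]; b1 <- m[3]; chrom <- m[4]; pos <- as.integer(m[5]); b2 <- m[6]; post <- m[7]
  if (b1 != b2) return(NULL)
  anchored_left <- nzchar(pre)          # anchor base precedes the bracket
  form <- if (anchored_left && b1 == "[") "t[p[" else
          if (anchored_left && b1 == "]") "t]p]" else
          if (!anchored_left && b1 == "]") "]p]t" else "[p[t"
  list(chrom = chrom, pos = pos, form = form)
}

# Orientation implied by a BND record taken as the *first* breakend:
#   t[p[ : 3' of this joined to 5' of mate -> 3to5
#   t]p] : 3' joined to 3'               -> 3to3
#   ]p]t : 5' joined to 3'               -> 5to3
#   [p[t : 5' joined to 5'               -> 5to5
BND_ORIENTATION <- c("t[p[" = "3to5", "t]p]" = "3to3",
                     "]p]t" = "5to3", "[p[t" = "5to5")

# The same junction read from the mate's record swaps the two sides.
flip_orientation <- function(o) {
  c("3to5" = "5to3", "5to3" = "3to5", "3to3" = "3to3", "5to5" = "5to5")[o]
}

#' Parse an SV VCF into a call table
#'
#' Reads a VCF 4.x file containing symbolic-ALT records (`<DEL>`, `<DUP>`,
#' `<INV>` with INFO `END`) and/or breakend (`BND`) records in bracket
#' notation.  A mated BND pair collapses into a single call: a translocation
#' when the breakends are on different chromosomes, otherwise a
#' DEL/DUP/INV according to the bracket orientation.  Read-depth-only CNV
#' records (`<CNV>`, `<CN*>`) carry no breakend evidence and are dropped.
#' BND records whose mate is missing are skipped with a warning.
#'
#' @param path path to a VCF file.
#' @param caller caller name recorded on every call.
#' @param technology `"SR"` or `"LR"`.
#' @return an [sv_calls] data.frame; `pass_filter` is `TRUE` iff FILTER is
#'   `PASS`.
#' @export
parse_sv_vcf <- function(path, caller, technology) {
  technology <- match.arg(technology, TECHNOLOGIES)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  n <- length(vcf)
  empty <- sv_calls()
  if (n == 0) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0(caller, "_", seq_len(n))
  alt <- vapply(seq_len(n), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    if (length(a)) as.character(a[1]) else ""
  }, character(1))
  filt <- VariantAnnotation::filt(vcf)
  pass <- !is.na(filt) & filt == "PASS"
  info <- VariantAnnotation::info(vcf)
  getinfo <- function(field) {
    if (field %in% names(info)) {
      v <- info[[field]]
      if (is(v, "List") || is.list(v)) {
        vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
               character(1))
      } else as.character(v)
    } else rep(NA_character_, n)
  }
  end_info <- suppressWarnings(as.integer(getinfo("END")))
  svtype <- getinfo("SVTYPE")
  mateid <- getinfo("MATEID")

  out <- list()
  is_bnd <- grepl("[][]", alt)
  sym <- grepl("^<.+>$", alt)
  ## symbolic records
  for (i in which(sym)) {
    tag <- toupper(gsub("[<>]", "", alt[i]))
    base <- sub(":.*$", "", tag)
    if (base %in% c("CNV") || grepl("^CN[0-9]", base)) next  # read-depth CNV
    ty <- if (base %in% c("DEL", "DUP", "INV")) base
          else if (!is.na(svtype[i]) && svtype[i] %in% c("DEL", "DUP", "INV")) svtype[i]
          else if (base == "UNK" || identical(svtype[i], "UNK")) "UNK"
          else next
    e <- end_info[i]
    if (is.na(e)) {
      warning("record ", ids[i], " lacks INFO END; skipped")
      next
    }
    bp1 <- if (ty == "DUP") pos[i] + 1L else pos[i]
    bp2 <- e
    out[[length(out) + 1L]] <- data.frame(
      id = ids[i], sv_type = ty, chrom1 = chrom[i], pos1 = bp1,
      chrom2 = chrom[i], pos2 = bp2,
      orientation = if (ty == "UNK") NA_character_ else canonical_orientation(ty),
      size = e - pos[i], caller = caller, technology = technology,
      pass_filter = pass[i], stringsAsFactors = FALSE)
  }
  ## BND records: pair mates
  bidx <- which(is_bnd)
  if (length(bidx)) {
    dec <- lapply(alt[bidx], parse_bnd_alt)
    ok <- !vapply(dec, is.null, logical(1))
    if (any(!ok)) warning(sum(!ok), " unparseable BND ALT record(s) skipped")
    bidx <- bidx[ok]; dec <- dec[ok]
    used <- rep(FALSE, length(bidx))
    key <- paste0(chrom[bidx], ":", pos[bidx])
    tgt <- vapply(dec, function(d) paste0(d$chrom, ":", d$pos), character(1))
    id_at <- stats::setNames(seq_along(bidx), ids[bidx])
    for (k in seq_along(bidx)) {
      if (used[k]) next
      i <- bidx[k]
      ## find the mate: by MATEID if present, else reciprocal coordinates
      mk <- NA_integer_
      if (!is.na(mateid[i]) && mateid[i] %in% names(id_at)) {
        cand <- id_at[[mateid[i]]]
        if (!used[cand] && cand != k) mk <- cand
      }
      if (is.na(mk)) {
        cand <- which(!used & key == tgt[k] & tgt == key[k] & seq_along(bidx) != k)
        if (length(cand)) mk <- cand[1]
      }
      if (is.na(mk)) {
        warning("BND record ", ids[i], " has no mate; skipped")
        used[k] <- TRUE
        next
      }
      used[k] <- TRUE; used[mk] <- TRUE
      j <- bidx[mk]
      ## order breakends: (chrom, pos) ascending
      first_is_k <- (chrom[i] < chrom[j]) ||
        (chrom[i] == chrom[j] && pos[i] <= pos[j])
      a <- if (first_is_k) k else mk
      b <- if (first_is_k) mk else k
      ia <- bidx[a]; ib <- bidx[b]
      orient <- unname(BND_ORIENTATION[[dec[[a]]$form]])
      c1 <- chrom[ia]; p1 <- pos[ia]; c2 <- chrom[ib]; p2 <- pos[ib]
      if (c1 != c2) {
        ty <- "TRA"; size <- NA_integer_
      } else {
        ty <- switch(orient, "3to5" = "DEL", "5to3" = "DUP", "INV")
        if (ty == "DEL") { p2 <- p2 - 1L }        # last deleted base
        if (ty == "INV" && orient == "5to5") { p1 <- p1 - 1L; p2 <- p2 - 1L }
        size <- if (ty == "DUP") p2 - p1 + 1L else p2 - p1
      }
      out[[length(out) + 1L]] <- data.frame(
        id = ids[ia], sv_type = ty, chrom1 = c1, pos1 = p1,
        chrom2 = c2, pos2 = p2, orientation = orient,
        size = size, caller = caller, technology = technology,
        pass_filter = pass[ia] || pass[ib], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  validate_sv_calls(do.call(rbind, out))
}

#' Write SV calls as VCF
#'
#' DEL/DUP/INV calls are written as symbolic-ALT records with INFO `END`;
#' translocations become two mated BND lines.  The output round-trips through
#' [parse_sv_vcf].
#'
#' @param calls an [sv_calls] data.frame (or merged calls; representative
#'   breakpoints are used).
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svintegrate",
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="ID of mate breakend">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=INV,Description="Inversion">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  for (r in seq_len(nrow(calls))) {
    x <- calls[r, ]
    filt <- if (isTRUE(x$pass_filter) || isTRUE(x$high_confidence)) "PASS" else "LowQual"
    if (x$sv_type == "TRA") {
      id1 <- paste0(x$id, "_bnd1"); id2 <- paste0(x$id, "_bnd2")
      o <- x$orientation
      ## first breakend record: form per BND_ORIENTATION inverse
      form1 <- names(BND_ORIENTATION)[match(o, BND_ORIENTATION)]
      alt1 <- bnd_alt_string(form1, x$chrom2, x$pos2)
      form2 <- names(BND_ORIENTATION)[match(flip_orientation(o), BND_ORIENTATION)]
      alt2 <- bnd_alt_string(form2, x$chrom1, x$pos1)
      lines <- c(lines,
        sprintf("%s\t%d\t%s\tN\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s",
                x$chrom1, x$pos1, id1, alt1, filt, id2),
        sprintf("%s\t%d\t%s\tN\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s",
                x$chrom2, x$pos2, id2, alt2, filt, id1))
    } else if (x$sv_type == "UNK") {
      lines <- c(lines, sprintf(
        "%s\t%d\t%s\tN\t<UNK>\t.\t%s\tSVTYPE=UNK;END=%d",
        x$chrom1, x$pos1, x$id, filt, x$pos2))
    } else {
      vpos <- if (x$sv_type == "DUP") x$pos1 - 1L else x$pos1
      lines <- c(lines, sprintf(
        "%s\t%d\t%s\tN\t<%s>\t.\t%s\tSVTYPE=%s;END=%d;SVLEN=%d",
        x$chrom1, vpos, x$id, x$sv_type, filt, x$sv_type, x$pos2,
        if (x$sv_type == "DEL") -x$size else x$size))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

bnd_alt_string <- function(form, chrom, pos) {
  p <- paste0(chrom, ":", pos)
  switch(form,
    "t[p[" = paste0("N[", p, "["),
    "t]p]" = paste0("N]", p, "]"),
    "]p]t" = paste0("]", p, "]N"),
    "[p[t" = paste0("[", p, "[N"))
}

#' Write a merged/comparison SV table as TSV
#'
#' Emits the columns id, type, orientation, chrom1, pos1, chrom2, pos2, size,
#' technology, category, tool_count, high_confidence (those present).
#'
#' @param records a merged-SV or comparison data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(records, path) {
  cols <- c("id", "sv_type", "orientation", "chrom1", "pos1", "chrom2",
            "pos2", "size", "technology", "category", "partner_id",
            "tool_count", "high_confidence")
  df <- as.data.frame(records)[, intersect(cols, names(records)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_sv_table]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
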