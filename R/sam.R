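# Plain-text SAM / FASTQ emission for simulator output.  SAM is converted to
# indexed BAM through Rsamtools when a binary alignment file is required.

#' Write paired alignments as SAM (optionally converting to BAM)
#'
#' @param aln data.frame with one row per read: `qname`, `mate` (1/2),
#'   `chrom`, `pos`, `strand`, `seq`, optional `cigar` (defaults to
#'   full-length `M`), optional `barcode` (emitted as a `BX` tag), optional
#'   logical `proper` and `supp`.  Mate fields are derived by pairing on
#'   `qname`.
#' @param contigs named integer vector of contig lengths.
#' @param path output path (`.sam`).
#' @param as_bam when `TRUE`, also produce a coordinate-sorted indexed BAM
#'   and return its path.
#' @return the SAM (or BAM) path, invisibly.
#' @export
write_sam <- function(aln, contigs, path, as_bam = FALSE) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  a <- as.data.frame(aln)
  if (is.null(a$cigar)) a$cigar <- paste0(nchar(a$seq), "M")
  if (is.null(a$proper)) a$proper <- FALSE
  if (is.null(a$supp)) a$supp <- FALSE
  ## mate lookup
  dt <- data.table::as.data.table(a)
  dt[, row := .I]
  prim <- dt[supp == FALSE]
  m1 <- prim[mate == 1]; m2 <- prim[mate == 2]
  data.table::setkey(m1, qname); data.table::setkey(m2, qname)
  mate_of <- function(d, other) {
    i <- match(d$qname, other$qname)
    list(chrom = other$chrom[i], pos = other$pos[i], strand = other$strand[i])
  }
  mt1 <- mate_of(m1, m2); mt2 <- mate_of(m2, m1)
  build <- function(d, mt) {
    flag <- 1L +
      ifelse(d$proper, 2L, 0L) +
      ifelse(d$strand == "-", 16L, 0L) +
      ifelse(!is.na(mt$strand) & mt$strand == "-", 32L, 0L) +
      ifelse(d$mate == 1, 64L, 128L) +
      ifelse(d$supp, 2048L, 0L)
    rnext <- ifelse(is.na(mt$chrom), "*",
                    ifelse(mt$chrom == d$chrom, "=", mt$chrom))
    pnext <- ifelse(is.na(mt$pos), 0L, mt$pos)
    seqs <- ifelse(d$strand == "-", revcomp(d$seq), d$seq)
    tlen <- ifelse(!is.na(mt$chrom) & mt$chrom == d$chrom,
                   ifelse(d$pos <= pnext,
                          pnext - d$pos + nchar(d$seq),
                          -(d$pos - pnext + nchar(d$seq))), 0L)
    line <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t%s",
                    d$qname, flag, d$chrom, d$pos, d$cigar, rnext, pnext,
                    as.integer(tlen), seqs, strrep("I", nchar(d$seq)))
    if (!is.null(d$barcode)) {
      has <- !is.na(d$barcode) & nzchar(d$barcode)
      line[has] <- paste0(line[has], "\tBX:Z:", d$barcode[has], "-1")
    }
    line
  }
  lines <- c(build(m1, mt1), build(m2, mt2))
  supp_rows <- dt[supp == TRUE]
  if (nrow(supp_rows)) {
    mts <- list(chrom = rep(NA_character_, nrow(supp_rows)),
                pos = rep(NA_integer_, nrow(supp_rows)),
                strand = rep(NA_character_, nrow(supp_rows)))
    lines <- c(lines, build(supp_rows, mts))
  }
  writeLines(c(hdr, lines), path)
  if (as_bam) {
    bam <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE)
    return(invisible(bam))
  }
  invisible(path)
}

#' Write reads as FASTQ (one file per mate)
#'
#' @param reads data.frame with `read_id`, `mate`, `seq`.
#' @param prefix output prefix; files `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- reads[reads$mate == m, , drop = FALSE]
    lines <- as.vector(rbind(paste0("@", r$read_id, "/", m), r$seq, "+",
                             strrep("I", nchar(r$seq))))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}
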