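#' @useDynLib svintegrate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom methods is
#' @importFrom stats glm binomial coef vcov predict logLik rbinom rnorm rpois
#'   runif setNames complete.cases plogis quantile median
#' @importFrom utils head read.delim write.table
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "TRA", "UNK")
ORIENTATIONS <- c("3to5", "5to3", "3to3", "5to5")
TECHNOLOGIES <- c("SR", "LR")

#' Construct a table of SV calls
#'
#' An SV call set is a plain `data.frame` with one row per call and a fixed
#' set of columns.  Breakend coordinates are 1-based; `bp1`/`bp2` are the
#' junction flank coordinates used directly by the template builder:
#' for a deletion `pos1` is the last retained base and `pos2` the last deleted
#' base (VCF `POS`/`END`); for a tandem duplication `pos1`/`pos2` are the first
#' and last base of the duplicated segment; for an inversion `pos1` is the
#' last base before and `pos2` the last base of the inverted segment.
#'
#' @param id character vector of call identifiers.
#' @param sv_type one of `DEL`, `DUP`, `INV`, `TRA`, `UNK`.
#' @param chrom1,pos1,chrom2,pos2 breakend coordinates (1-based).
#' @param orientation junction orientation, one of `3to5`, `5to3`, `3to3`,
#'   `5to5` (which flanks are fused).
#' @param size SV size in bp (`NA` for translocations).
#' @param caller name of the originating caller.
#' @param technology `"SR"` (conventional short-read WGS) or `"LR"`
#'   (linked-read WGS).
#' @param pass_filter logical, `TRUE` iff the caller reported FILTER `PASS`.
#' @return a `data.frame` of class `sv_calls`.
#' @export
sv_calls <- function(id = character(), sv_type = character(),
                     chrom1 = character(), pos1 = integer(),
                     chrom2 = character(), pos2 = integer(),
                     orientation = character(), size = integer(),
                     caller = character(), technology = character(),
                     pass_filter = logical()) {
  df <- data.frame(
    id = as.character(id), sv_type = as.character(sv_type),
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
    orientation = as.character(orientation), size = as.integer(size),
    caller = as.character(caller), technology = as.character(technology),
    pass_filter = as.logical(pass_filter),
    stringsAsFactors = FALSE
  )
  validate_sv_calls(df)
}

validate_sv_calls <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sv_type", "chrom1", "pos1", "chrom2", "pos2",
            "orientation", "size", "caller", "technology", "pass_filter")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sv_calls missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$sv_type %in% SV_TYPES)) stop("invalid sv_type")
    ok_or <- df$orientation %in% ORIENTATIONS | (df$sv_type == "UNK" & is.na(df$orientation))
    if (!all(ok_or)) stop("invalid orientation")
    if (!all(df$technology %in% TECHNOLOGIES)) stop("invalid technology")
    if (any(df$pos1 < 1L | df$pos2 < 1L, na.rm = TRUE)) stop("positions must be >= 1")
    intra <- df$chrom1 == df$chrom2 & df$sv_type != "TRA"
    if (any(intra & df$pos1 > df$pos2)) stop("intra-chromosomal calls need pos1 <= pos2")
    canon <- c(DEL = "3to5", DUP = "5to3")
    for (ty in names(canon)) {
      bad <- df$sv_type == ty & df$orientation != canon[[ty]]
      if (any(bad)) stop(ty, " calls must have orientation ", canon[[ty]])
    }
    bad_inv <- df$sv_type == "INV" & !df$orientation %in% c("3to3", "5to5")
    if (any(bad_inv)) stop("INV calls must have orientation 3to3 or 5to5")
  }
  class(df) <- unique(c("sv_calls", class(df)))
  df
}

canonical_orientation <- function(sv_type) {
  switch(sv_type, DEL = "3to5", DUP = "5to3", INV = "3to3", NA_character_)
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
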