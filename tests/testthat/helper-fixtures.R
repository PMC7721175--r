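# Shared fixtures: tiny call sets, toy references, small simulator configs.

make_call <- function(id = "sv1", sv_type = "DEL", chrom1 = "chr1",
                      pos1 = 1000L, chrom2 = chrom1, pos2 = 3000L,
                      orientation = NULL, size = NULL, caller = "toolA",
                      technology = "SR", pass_filter = TRUE) {
  if (is.null(orientation)) {
    orientation <- switch(sv_type, DEL = "3to5", DUP = "5to3", INV = "3to3",
                          TRA = "3to5", UNK = NA_character_)
  }
  if (is.null(size)) {
    size <- if (sv_type == "TRA") NA_integer_ else
      if (sv_type == "DUP") pos2 - pos1 + 1L else pos2 - pos1
  }
  sv_calls(id = id, sv_type = sv_type, chrom1 = chrom1, pos1 = pos1,
           chrom2 = chrom2, pos2 = pos2, orientation = orientation,
           size = size, caller = caller, technology = technology,
           pass_filter = pass_filter)
}

# random toy reference as character + DNAStringSet
toy_ref <- function(lens = c(chr1 = 5000L, chr2 = 5000L), seed = 1) {
  withr::with_seed(seed, {
    g <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  g
}

small_sim_config <- function(seed = 7, coverage_sr = 30,
                             coverage_lr_physical = 20, ...) {
  sim_config(genome_length = 2e5, n_chromosomes = 4,
             sv_counts = c(DEL = 3, DUP = 2, INV = 2, TRA = 1),
             sv_sizes = list(DEL = c(2000, 4000), DUP = c(11000, 14000),
                             INV = c(11000, 14000)),
             coverage_sr = coverage_sr,
             coverage_lr_physical = coverage_lr_physical, seed = seed, ...)
}

write_vcf_lines <- function(lines, contigs = c(chr1 = 100000, chr2 = 100000)) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate">',
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=DUP,Description="Duplication">',
           '##ALT=<ID=INV,Description="Inversion">',
           '##ALT=<ID=CNV,Description="CNV">',
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}

# labelled synthetic features from a known logistic generative model on the
# log1p scale (the classifier's own transform); used for parameter-recovery
# oracles
gen_features <- function(n, beta, seed, gem = FALSE) {
  withr::with_seed(seed, {
    ty <- sample(c("DEL", "DUP", "INV", "TRA"), n, replace = TRUE)
    z <- matrix(runif(n * 4, 0, 3), n, 4)   # log1p-scale covariates
    colnames(z) <- c("jr", "sp", "size", "cov")
    zg <- if (gem) runif(n, 0, 3) else NULL
    eta <- beta[["b0"]] + beta[["jr"]] * z[, 1] + beta[["sp"]] * z[, 2] +
      beta[["size"]] * z[, 3] + beta[["cov"]] * z[, 4] +
      (if (gem) beta[["gem"]] * zg else 0)
    y <- rbinom(n, 1, plogis(eta))
  })
  fv <- data.frame(
    sv_id = sprintf("s%05d", seq_len(n)),
    sv_type = factor(ty, levels = c("DEL", "DUP", "INV", "TRA")),
    jr_norm = expm1(z[, 1]), sp_norm = expm1(z[, 2]),
    size = expm1(z[, 3]), local_coverage_norm = expm1(z[, 4]),
    label = ifelse(y == 1, "POSITIVE", "NEGATIVE"),
    stringsAsFactors = FALSE)
  if (gem) fv$gem_norm <- expm1(zg)
  fv
}

# Debarcoded linked-read table ready for requantification.
debarcoded_reads <- function(lr_reads) {
  r1 <- lr_reads$seq[lr_reads$mate == 1]
  r2 <- lr_reads$seq[lr_reads$mate == 2]
  db <- debarcode_linked_reads(r1, r2)
  data.frame(read_id = c(lr_reads$read_id[lr_reads$mate == 1],
                         lr_reads$read_id[lr_reads$mate == 2]),
             mate = rep(1:2, c(length(db$read1), length(db$read2))),
             seq = c(db$read1, db$read2), stringsAsFactors = FALSE)
}
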