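# Synthetic data generator: a toy reference genome, implanted SVs
# (DEL/DUP/INV and reciprocal translocations), conventional paired-end reads
# (~550 bp fragments, 2x150 bp) and linked reads (50-100 kb molecules sheared
# to ~0.5 kb fragments, 16-bp droplet barcode adjacent to read-1), with
# truth-coordinate alignments so no external aligner is needed.

#' Simulator configuration
#'
#' Defaults describe the emulated libraries: 550-bp short-read fragments
#' sequenced 2x150 bp, high-molecular-weight molecules of 50-100 kb sheared
#' to ~0.5 kb fragments with a 16-bp barcode adjacent to read-1, and
#' DUP/INV sizes above the 10-kb floor below which the linked-read pipeline
#' does not report those types.
#'
#' @param genome_length total genome length (default 1 Mb).
#' @param n_chromosomes number of chromosomes (default 4).
#' @param gc GC fraction (default 0.41, human-like).
#' @param sv_counts named counts of implanted events; `TRA` counts
#'   *reciprocal* events, each contributing two junction rows to the truth
#'   set.
#' @param sv_sizes named list of size ranges (bp) per intra-chromosomal type.
#' @param coverage_sr short-read sequence coverage (fold).
#' @param coverage_lr_physical linked-read physical (molecule) coverage.
#' @param fragment_mean_sr,fragment_sd_sr short-read fragment length model.
#' @param read_length read length (bp).
#' @param molecule_length molecule length range (bp).
#' @param read_pairs_per_kb_mol sequenced fragment density per molecule
#'   (pairs per kb of molecule).
#' @param fragment_mean_lr,fragment_sd_lr linked-read fragment model (bp).
#' @param barcode_length droplet barcode length (bp).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, n_chromosomes = 4, gc = 0.41,
                       sv_counts = c(DEL = 14, DUP = 11, INV = 11, TRA = 2),
                       sv_sizes = list(DEL = c(2000, 8000),
                                       DUP = c(12000, 20000),
                                       INV = c(12000, 20000)),
                       coverage_sr = 30, coverage_lr_physical = 30,
                       fragment_mean_sr = 550, fragment_sd_sr = 60,
                       read_length = 150,
                       molecule_length = c(50000, 100000),
                       read_pairs_per_kb_mol = 1,
                       fragment_mean_lr = 500, fragment_sd_lr = 50,
                       barcode_length = 16, error_rate = 0.001, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, n_chromosomes >= 1, gc > 0, gc < 1,
            all(unlist(sv_sizes) > 50), coverage_sr > 0,
            coverage_lr_physical > 0, error_rate >= 0, error_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the configured GC content; deterministic per seed.
#'
#' @param config a [sim_config].
#' @return named character vector of chromosome sequences (`chr1`, ...).
#' @export
generate_genome <- function(config) {
  L <- round(config$genome_length / config$n_chromosomes)
  withr::with_seed(config$seed, {
    g <- vapply(seq_len(config$n_chromosomes), function(i) {
      p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  stats::setNames(g, paste0("chr", seq_len(config$n_chromosomes)))
}

rc_chr <- function(x) revcomp(x)

#' Implant SVs into a genome
#'
#' DEL removes the segment, DUP tandem-duplicates it, INV reverse-complements
#' it in place; TRA performs a reciprocal tail swap between two chromosomes
#' (each event yields two junction rows in the truth set).  Truth breakpoints
#' are on REFERENCE coordinates, using the same conventions as the template
#' builder: `pos1` = last base before / `pos2` = last base of the rearranged
#' segment (first/last base for DUP).
#'
#' @param genome named character vector from [generate_genome].
#' @param config a [sim_config].
#' @return list: `alt` (named character vector, rearranged genome), `truth`
#'   ([sv_calls]-shaped data.frame without caller columns), `blocks`
#'   (ALT-to-REF block map: `alt_chrom`, `alt_start`, `alt_end`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `strand`).
#' @export
implant_svs <- function(genome, config) {
  chroms <- names(genome)
  lens <- nchar(genome)
  n_tra <- if ("TRA" %in% names(config$sv_counts)) config$sv_counts[["TRA"]] else 0L
  if (n_tra * 2 > length(chroms)) {
    stop("each reciprocal translocation needs its own chromosome pair")
  }
  withr::with_seed(config$seed + 1L, {
    ## intra-chromosomal placements, non-overlapping with 1 kb spacing,
    ## confined to [5 kb, 0.75 L] so translocation tails stay clean
    intra_types <- rep(names(config$sv_counts), config$sv_counts)
    intra_types <- intra_types[intra_types != "TRA"]
    intra_types <- sample(intra_types)
    placements <- list()
    occupied <- stats::setNames(vector("list", length(chroms)), chroms)
    ci <- 0L
    for (ty in intra_types) {
      rng <- config$sv_sizes[[ty]]
      placed <- FALSE
      for (try in 1:500) {
        ci <- ci %% length(chroms) + 1L
        chrom <- chroms[ci]
        size <- sample(rng[1]:rng[2], 1)
        lo <- 5000L; hi <- floor(0.75 * lens[[chrom]]) - size
        if (hi <= lo) next
        s <- sample(lo:hi, 1); e <- s + size - 1L
        occ <- occupied[[chrom]]
        clash <- any(vapply(occ, function(iv) s <= iv[2] + 1000 && e >= iv[1] - 1000,
                            logical(1)))
        if (!clash) {
          occupied[[chrom]] <- c(occ, list(c(s, e)))
          placements[[length(placements) + 1L]] <-
            list(type = ty, chrom = chrom, s = s, e = e)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place ", ty, " without overlap")
    }
    ## reciprocal translocations on dedicated chromosome pairs (last pairs)
    tra <- list()
    if (n_tra > 0) {
      pool <- rev(chroms)
      for (k in seq_len(n_tra)) {
        c1 <- pool[2 * k]; c2 <- pool[2 * k - 1]
        p1 <- sample(floor(0.80 * lens[[c1]]):floor(0.92 * lens[[c1]]), 1)
        p2 <- sample(floor(0.80 * lens[[c2]]):floor(0.92 * lens[[c2]]), 1)
        tra[[k]] <- list(c1 = c1, p1 = p1, c2 = c2, p2 = p2)
      }
    }
  })
  ## build ALT chromosomes as segment lists (ref_start, ref_end, strand)
  seg_lists <- lapply(chroms, function(chrom) {
    evs <- Filter(function(p) p$chrom == chrom, placements)
    evs <- evs[order(vapply(evs, `[[`, numeric(1), "s"))]
    segs <- list(); cur <- 1L
    for (ev in evs) {
      if (ev$s > cur) segs <- c(segs, list(c(cur, ev$s - 1L, 1L)))
      if (ev$type == "DEL") {
        ## segment dropped
      } else if (ev$type == "DUP") {
        segs <- c(segs, list(c(ev$s, ev$e, 1L), c(ev$s, ev$e, 1L)))
      } else if (ev$type == "INV") {
        segs <- c(segs, list(c(ev$s, ev$e, -1L)))
      }
      cur <- ev$e + 1L
    }
    segs <- c(segs, list(c(cur, lens[[chrom]], 1L)))
    lapply(segs, function(x) list(chrom = chrom, start = x[1], end = x[2],
                                  strand = if (x[3] > 0) "+" else "-"))
  })
  names(seg_lists) <- chroms
  ## apply reciprocal tail swaps: intra events live below 0.75 L, tails are
  ## single pure segments
  split_at <- function(segs, chrom, p) {
    ## segments are ordered, the tail [p+1, L] is inside the final segment
    last <- segs[[length(segs)]]
    stopifnot(last$strand == "+", last$start <= p, p < last$end)
    head_part <- c(segs[seq_len(length(segs) - 1)],
                   list(list(chrom = chrom, start = last$start, end = p,
                             strand = "+")))
    tail_part <- list(list(chrom = chrom, start = p + 1L, end = last$end,
                           strand = "+"))
    list(head = head_part, tail = tail_part)
  }
  truth <- list()
  for (tr in tra) {
    s1 <- split_at(seg_lists[[tr$c1]], tr$c1, tr$p1)
    s2 <- split_at(seg_lists[[tr$c2]], tr$c2, tr$p2)
    seg_lists[[tr$c1]] <- c(s1$head, s2$tail)
    seg_lists[[tr$c2]] <- c(s2$head, s1$tail)
    o <- if (tr$c1 < tr$c2) list(c1 = tr$c1, p1 = tr$p1, c2 = tr$c2, p2 = tr$p2)
         else list(c1 = tr$c2, p1 = tr$p2, c2 = tr$c1, p2 = tr$p1)
    truth[[length(truth) + 1L]] <- data.frame(
      sv_type = "TRA", chrom1 = o$c1, pos1 = o$p1, chrom2 = o$c2,
      pos2 = o$p2 + 1L, orientation = "3to5", size = NA_integer_,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      sv_type = "TRA", chrom1 = o$c1, pos1 = o$p1 + 1L, chrom2 = o$c2,
      pos2 = o$p2, orientation = "5to3", size = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (ev in placements) {
    truth[[length(truth) + 1L]] <- switch(ev$type,
      DEL = data.frame(sv_type = "DEL", chrom1 = ev$chrom, pos1 = ev$s - 1L,
                       chrom2 = ev$chrom, pos2 = ev$e, orientation = "3to5",
                       size = ev$e - ev$s + 1L, stringsAsFactors = FALSE),
      DUP = data.frame(sv_type = "DUP", chrom1 = ev$chrom, pos1 = ev$s,
                       chrom2 = ev$chrom, pos2 = ev$e, orientation = "5to3",
                       size = ev$e - ev$s + 1L, stringsAsFactors = FALSE),
      INV = data.frame(sv_type = "INV", chrom1 = ev$chrom, pos1 = ev$s - 1L,
                       chrom2 = ev$chrom, pos2 = ev$e, orientation = "3to3",
                       size = ev$e - ev$s + 1L, stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$chrom1, truth$pos1, truth$chrom2, truth$pos2,
                       method = "radix"), , drop = FALSE]
  truth$id <- sprintf("truth%03d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  ## materialize ALT sequences + block map
  alt <- character(0); blocks <- list()
  for (chrom in chroms) {
    segs <- seg_lists[[chrom]]
    pieces <- vapply(segs, function(sg) {
      s <- substr(genome[[sg$chrom]], sg$start, sg$end)
      if (sg$strand == "-") rc_chr(s) else s
    }, character(1))
    alt[[chrom]] <- paste(pieces, collapse = "")
    pos <- 1L
    for (k in seq_along(segs)) {
      sg <- segs[[k]]
      w <- sg$end - sg$start + 1L
      blocks[[length(blocks) + 1L]] <- data.frame(
        alt_chrom = chrom, alt_start = pos, alt_end = pos + w - 1L,
        ref_chrom = sg$chrom, ref_start = sg$start, ref_end = sg$end,
        strand = sg$strand, stringsAsFactors = FALSE)
      pos <- pos + w
    }
  }
  list(alt = alt, truth = truth[, c("id", "sv_type", "chrom1", "pos1",
                                    "chrom2", "pos2", "orientation", "size")],
       blocks = do.call(rbind, blocks))
}

# Map ALT intervals [a1, a2] (with sequencing strand rs) to reference
# coordinates through the block map.  Reads crossing a block boundary are
# assigned to the block with the larger overlap and soft-clipped.
map_alt_to_ref <- function(blocks, alt_chrom, a1, a2, rs) {
  n <- length(a1)
  out <- data.frame(chrom = character(n), pos = integer(n), end = integer(n),
                    strand = character(n), clip_pre = integer(n),
                    clip_post = integer(n), split = logical(n),
                    stringsAsFactors = FALSE)
  for (ch in unique(alt_chrom)) {
    sel <- which(alt_chrom == ch)
    b <- blocks[blocks$alt_chrom == ch, , drop = FALSE]
    i1 <- findInterval(a1[sel], b$alt_start)
    i2 <- findInterval(a2[sel], b$alt_start)
    ## candidate block: larger overlap of the two
    ov1 <- pmin(a2[sel], b$alt_end[i1]) - pmax(a1[sel], b$alt_start[i1]) + 1L
    ov2 <- pmin(a2[sel], b$alt_end[i2]) - pmax(a1[sel], b$alt_start[i2]) + 1L
    bi <- ifelse(ov1 >= ov2, i1, i2)
    o1 <- pmax(a1[sel], b$alt_start[bi]); o2 <- pmin(a2[sel], b$alt_end[bi])
    plus <- b$strand[bi] == "+"
    r1 <- ifelse(plus, b$ref_start[bi] + (o1 - b$alt_start[bi]),
                 b$ref_end[bi] - (o2 - b$alt_start[bi]))
    r2 <- ifelse(plus, b$ref_start[bi] + (o2 - b$alt_start[bi]),
                 b$ref_end[bi] - (o1 - b$alt_start[bi]))
    st <- ifelse(plus, rs[sel], ifelse(rs[sel] == "+", "-", "+"))
    out$chrom[sel] <- b$ref_chrom[bi]
    out$pos[sel] <- as.integer(r1); out$end[sel] <- as.integer(r2)
    out$strand[sel] <- st
    out$clip_pre[sel] <- as.integer(o1 - a1[sel])
    out$clip_post[sel] <- as.integer(a2[sel] - o2)
    out$split[sel] <- (o1 > a1[sel]) | (o2 < a2[sel])
  }
  out
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

# cigar with soft clips; pre/post are in sequencing orientation after
# mapping (swap on reverse strand so the CIGAR is genome-forward).
make_cigar <- function(read_len, clip_pre, clip_post, strand) {
  pre <- ifelse(strand == "-", clip_post, clip_pre)
  post <- ifelse(strand == "-", clip_pre, clip_post)
  m <- read_len - pre - post
  paste0(ifelse(pre > 0, paste0(pre, "S"), ""), m, "M",
         ifelse(post > 0, paste0(post, "S"), ""))
}

pair_proper <- function(t1, t2, max_insert = 1200, min_insert = 100) {
  same <- t1$chrom == t2$chrom & !t1$split & !t2$split
  left_first <- t1$pos <= t2$pos
  lp <- ifelse(left_first, t1$strand, t2$strand)
  rp <- ifelse(left_first, t2$strand, t1$strand)
  ins <- pmax(t1$end, t2$end) - pmin(t1$pos, t2$pos) + 1L
  same & lp == "+" & rp == "-" & ins >= min_insert & ins <= max_insert
}

#' Simulate conventional paired-end short reads from the ALT genome
#'
#' Fragments are Normal(550, 60) truncated at 300 bp; 2x150 bp innie reads
#' with per-base substitution errors.  Read count is
#' `coverage_sr * L / (2 * read_length)`.  Truth alignments are emitted in
#' REFERENCE coordinates through the block map; reads crossing an SV junction
#' become soft-clipped/split records and SV-spanning pairs become discordant.
#'
#' @param alt_genome `alt` from [implant_svs] (named character vector).
#' @param config a [sim_config].
#' @param blocks block map from [implant_svs]; when `NULL`, the ALT genome is
#'   its own reference (identity mapping).
#' @param seed_offset offset added to `config$seed` so different read sets
#'   draw independent streams.
#' @return list: `reads` (data.frame `read_id`, `mate`, `seq`), `truth_aln`
#'   (data.frame for [write_sam] with `qname`, `mate`, `chrom`, `pos`,
#'   `strand`, `seq`, `cigar`, `proper`, `split`).
#' @export
simulate_sr_reads <- function(alt_genome, config, blocks = NULL,
                              seed_offset = 2L) {
  L <- sum(nchar(alt_genome))
  rl <- config$read_length
  n_pairs <- round(config$coverage_sr * L / (2 * rl))
  if (is.null(blocks)) {
    blocks <- do.call(rbind, lapply(names(alt_genome), function(ch) {
      data.frame(alt_chrom = ch, alt_start = 1L, alt_end = nchar(alt_genome[[ch]]),
                 ref_chrom = ch, ref_start = 1L, ref_end = nchar(alt_genome[[ch]]),
                 strand = "+", stringsAsFactors = FALSE)
    }))
  }
  withr::with_seed(config$seed + seed_offset, {
    chrom <- sample(names(alt_genome), n_pairs, replace = TRUE,
                    prob = nchar(alt_genome))
    clen <- nchar(alt_genome)[chrom]
    flen <- pmax(300L, round(stats::rnorm(n_pairs, config$fragment_mean_sr,
                                          config$fragment_sd_sr)))
    flen <- pmin(flen, clen)
    fs <- floor(stats::runif(n_pairs, 1, clen - flen + 1 + 1))
    fe <- fs + flen - 1L
    r1 <- substring(alt_genome[chrom], fs, fs + rl - 1L)
    r2 <- revcomp(substring(alt_genome[chrom], fe - rl + 1L, fe))
    r1 <- inject_errors(r1, config$error_rate)
    r2 <- inject_errors(r2, config$error_rate)
  })
  qname <- sprintf("sr%06d", seq_len(n_pairs))
  reads <- data.frame(read_id = rep(qname, 2), mate = rep(1:2, each = n_pairs),
                      seq = c(r1, r2), stringsAsFactors = FALSE)
  t1 <- map_alt_to_ref(blocks, chrom, fs, fs + rl - 1L, rep("+", n_pairs))
  t2 <- map_alt_to_ref(blocks, chrom, fe - rl + 1L, fe, rep("-", n_pairs))
  proper <- pair_proper(t1, t2)
  truth_aln <- data.frame(
    qname = rep(qname, 2), mate = rep(1:2, each = n_pairs),
    chrom = c(t1$chrom, t2$chrom), pos = c(t1$pos, t2$pos),
    strand = c(t1$strand, t2$strand), seq = c(r1, r2),
    cigar = c(make_cigar(rl, t1$clip_pre, t1$clip_post, t1$strand),
              make_cigar(rl, t2$clip_pre, t2$clip_post, t2$strand)),
    proper = rep(proper, 2), split = c(t1$split, t2$split),
    supp = FALSE, stringsAsFactors = FALSE)
  list(reads = reads, truth_aln = truth_aln)
}

int_to_barcode <- function(i, len = 16) {
  bases <- c("A", "C", "G", "T")
  vapply(i, function(x) {
    d <- integer(len)
    for (k in seq_len(len)) { d[k] <- x %% 4L; x <- x %/% 4L }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}

#' Simulate linked reads from the ALT genome
#'
#' High-molecular-weight molecules (Uniform 50-100 kb) are placed uniformly
#' until the physical coverage target is met; each receives a unique 16-bp
#' barcode.  A sparse subset of each molecule's ~0.5 kb fragments is
#' sequenced 2x150 bp with the barcode prepended to read-1.  Truth
#' alignments carry the barcode; `stats` are the realized molecule averages.
#'
#' @inheritParams simulate_sr_reads
#' @return list: `reads` (with `barcode`), `truth_aln` (with `barcode`),
#'   `molecules` (data.frame), `stats` (list `avg_molecule_length`,
#'   `n50_reads_per_molecule`), `total_gems`.
#' @export
simulate_lr_reads <- function(alt_genome, config, blocks = NULL,
                              seed_offset = 3L) {
  L <- sum(nchar(alt_genome))
  rl <- config$read_length; bl <- config$barcode_length
  if (is.null(blocks)) {
    blocks <- do.call(rbind, lapply(names(alt_genome), function(ch) {
      data.frame(alt_chrom = ch, alt_start = 1L, alt_end = nchar(alt_genome[[ch]]),
                 ref_chrom = ch, ref_start = 1L, ref_end = nchar(alt_genome[[ch]]),
                 strand = "+", stringsAsFactors = FALSE)
    }))
  }
  withr::with_seed(config$seed + seed_offset, {
    target <- config$coverage_lr_physical * L
    n_mol_guess <- ceiling(target / mean(config$molecule_length)) + 50
    mchrom <- sample(names(alt_genome), n_mol_guess, replace = TRUE,
                     prob = nchar(alt_genome))
    mlen <- round(stats::runif(n_mol_guess, config$molecule_length[1],
                               config$molecule_length[2]))
    mlen <- pmin(mlen, nchar(alt_genome)[mchrom])
    keep <- which(cumsum(as.numeric(mlen)) <= target + mean(config$molecule_length))
    n_mol <- max(keep)
    mchrom <- mchrom[seq_len(n_mol)]; mlen <- mlen[seq_len(n_mol)]
    mstart <- floor(stats::runif(n_mol, 1, nchar(alt_genome)[mchrom] - mlen + 2))
    barcode <- int_to_barcode(sample.int(4^15, n_mol), bl)
    npairs <- pmax(1L, stats::rpois(n_mol, mlen / 1000 * config$read_pairs_per_kb_mol))
    mol_id <- rep(seq_len(n_mol), npairs)
    total_pairs <- sum(npairs)
    flen <- pmax(300L, round(stats::rnorm(total_pairs, config$fragment_mean_lr,
                                          config$fragment_sd_lr)))
    flen <- pmin(flen, mlen[mol_id])
    fs <- mstart[mol_id] +
      floor(stats::runif(total_pairs, 0, mlen[mol_id] - flen + 1))
    fe <- fs + flen - 1L
    chrom <- mchrom[mol_id]
    g1 <- substring(alt_genome[chrom], fs, fs + (rl - bl) - 1L)  # 134 bp genomic
    g2 <- revcomp(substring(alt_genome[chrom], fe - rl + 1L, fe))
    g1 <- inject_errors(g1, config$error_rate)
    g2 <- inject_errors(g2, config$error_rate)
  })
  qname <- sprintf("lr%07d", seq_len(total_pairs))
  bc <- barcode[mol_id]
  reads <- data.frame(read_id = rep(qname, 2), mate = rep(1:2, each = total_pairs),
                      seq = c(paste0(bc, g1), g2),
                      barcode = rep(bc, 2), stringsAsFactors = FALSE)
  t1 <- map_alt_to_ref(blocks, chrom, fs, fs + (rl - bl) - 1L,
                       rep("+", total_pairs))
  t2 <- map_alt_to_ref(blocks, chrom, fe - rl + 1L, fe, rep("-", total_pairs))
  proper <- pair_proper(t1, t2)
  truth_aln <- data.frame(
    qname = rep(qname, 2), mate = rep(1:2, each = total_pairs),
    chrom = c(t1$chrom, t2$chrom), pos = c(t1$pos, t2$pos),
    strand = c(t1$strand, t2$strand), seq = c(g1, g2),
    cigar = c(make_cigar(rl - bl, t1$clip_pre, t1$clip_post, t1$strand),
              make_cigar(rl, t2$clip_pre, t2$clip_post, t2$strand)),
    proper = rep(proper, 2), split = c(t1$split, t2$split),
    supp = FALSE, barcode = rep(bc, 2), stringsAsFactors = FALSE)
  molecules <- data.frame(mol = seq_len(n_mol), chrom = mchrom, start = mstart,
                          end = mstart + mlen - 1L, length = mlen,
                          barcode = barcode, n_pairs = npairs,
                          stringsAsFactors = FALSE)
  counts <- sort(2L * molecules$n_pairs, decreasing = TRUE)
  n50 <- counts[which(cumsum(counts) >= sum(counts) / 2)[1]]
  list(reads = reads, truth_aln = truth_aln, molecules = molecules,
       stats = list(avg_molecule_length = mean(molecules$length),
                    n50_reads_per_molecule = as.integer(n50)),
       total_gems = n_mol)
}

#' Emit labelled per-technology call sets from the truth
#'
#' Positives are truth SVs with breakpoints jittered by at most `jitter` bp;
#' negatives are decoy SVs at random non-implanted coordinates (the
#' PCR-negative analogue: no product at the predicted junction).  Each
#' technology has independent jitter, decoys and `dropout`, so COMMON /
#' ONLY_SR / ONLY_LR categories all occur.  Two pseudo-callers per technology
#' exercise the within-technology merge.
#'
#' @param truth truth table from [implant_svs].
#' @param config a [sim_config].
#' @param ref_lengths named chromosome lengths of the reference.
#' @param jitter maximal per-breakpoint jitter in bp (default 100, so two
#'   technologies' representatives — each jittered at most twice, once per
#'   pseudo-caller — always stay within the 500-bp comparison window).
#' @param decoys number of decoy SVs per technology (default 40).
#' @param dropout named per-technology dropout probability (default 0.15
#'   each).
#' @param pass_rate probability a call carries FILTER PASS (default 0.9).
#' @param second_caller_rate probability a call is also reported by the
#'   second pseudo-caller (default 0.5).
#' @param seed_offset stream offset (default 4).
#' @return list: `sr`, `lr` ([sv_calls] data.frames), `labels` (data.frame
#'   `call_id`, `label`).
#' @export
make_labelled_callset <- function(truth, config, ref_lengths, jitter = 100,
                                  decoys = 40,
                                  dropout = c(SR = 0.15, LR = 0.15),
                                  pass_rate = 0.9, second_caller_rate = 0.5,
                                  seed_offset = 4L) {
  occupied <- lapply(stats::setNames(names(ref_lengths), names(ref_lengths)),
                     function(ch) {
    rows <- truth[truth$chrom1 == ch | truth$chrom2 == ch, , drop = FALSE]
    iv <- list()
    for (r in seq_len(nrow(rows))) {
      x <- rows[r, ]
      if (x$chrom1 == ch) iv <- c(iv, list(c(x$pos1, if (x$chrom2 == ch) x$pos2 else x$pos1)))
      if (x$chrom2 == ch && x$chrom1 != ch) iv <- c(iv, list(c(x$pos2, x$pos2)))
    }
    iv
  })
  jit <- function(p, n = length(p)) p + sample(-jitter:jitter, n, replace = TRUE)
  gen_tech <- function(tech, seed) {
    withr::with_seed(seed, {
      keep <- stats::runif(nrow(truth)) >= dropout[[tech]]
      pos_calls <- list(); labels <- list()
      for (r in which(keep)) {
        x <- truth[r, ]
        base_id <- paste0(x$id, "@", tolower(tech))
        p1 <- max(1L, jit(x$pos1, 1)); p2 <- max(1L, jit(x$pos2, 1))
        if (x$sv_type != "TRA" && p2 <= p1) { p1 <- x$pos1; p2 <- x$pos2 }
        size <- if (x$sv_type == "TRA") NA_integer_ else
          if (x$sv_type == "DUP") p2 - p1 + 1L else p2 - p1
        callers <- c("simA", if (stats::runif(1) < second_caller_rate) "simB")
        for (cl in callers) {
          q1 <- if (cl == "simA") p1 else max(1L, jit(p1, 1))
          q2 <- if (cl == "simA") p2 else max(1L, jit(p2, 1))
          if (x$sv_type != "TRA" && q2 <= q1) { q1 <- p1; q2 <- p2 }
          sz <- if (x$sv_type == "TRA") NA_integer_ else
            if (x$sv_type == "DUP") q2 - q1 + 1L else q2 - q1
          pos_calls[[length(pos_calls) + 1L]] <- data.frame(
            id = paste0(base_id, "_", cl), sv_type = x$sv_type,
            chrom1 = x$chrom1, pos1 = q1, chrom2 = x$chrom2, pos2 = q2,
            orientation = x$orientation, size = sz, caller = cl,
            technology = tech, pass_filter = stats::runif(1) < pass_rate,
            stringsAsFactors = FALSE)
          labels[[length(labels) + 1L]] <- data.frame(
            call_id = paste0(base_id, "_", cl), label = "POSITIVE",
            truth_id = x$id, stringsAsFactors = FALSE)
        }
      }
      ## decoys at non-implanted coordinates
      types <- sample(c("DEL", "DUP", "INV", "TRA"), decoys, replace = TRUE,
                      prob = c(0.4, 0.25, 0.25, 0.1))
      for (k in seq_len(decoys)) {
        ty <- types[k]
        for (try in 1:200) {
          if (ty == "TRA") {
            cc <- sample(names(ref_lengths), 2)
            p1 <- sample.int(ref_lengths[[cc[1]]] - 1000L, 1) + 500L
            p2 <- sample.int(ref_lengths[[cc[2]]] - 1000L, 1) + 500L
            c1 <- cc[1]; c2 <- cc[2]; e1 <- p1; e2 <- p2
            if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp
                           tmp <- p1; p1 <- p2; p2 <- tmp }
            sz <- NA_integer_
            iv_ok <- !any(vapply(occupied[[c1]], function(iv)
                       abs(p1 - iv[1]) < 2000 || abs(p1 - iv[2]) < 2000, logical(1))) &&
                     !any(vapply(occupied[[c2]], function(iv)
                       abs(p2 - iv[1]) < 2000 || abs(p2 - iv[2]) < 2000, logical(1)))
          } else {
            rng <- config$sv_sizes[[ty]]
            sz <- sample(rng[1]:rng[2], 1)
            c1 <- c2 <- sample(names(ref_lengths), 1)
            if (ref_lengths[[c1]] - sz - 2000 < 1000) next
            p1 <- sample(1000:(ref_lengths[[c1]] - sz - 2000), 1)
            p2 <- p1 + sz - as.integer(ty == "DUP")
            iv_ok <- !any(vapply(occupied[[c1]], function(iv)
                       p1 <= iv[2] + 2000 && p2 >= iv[1] - 2000, logical(1)))
          }
          if (iv_ok) break
        }
        did <- sprintf("decoy%s%03d@%s", tech, k, tolower(tech))
        pos_calls[[length(pos_calls) + 1L]] <- data.frame(
          id = did, sv_type = ty, chrom1 = c1, pos1 = p1, chrom2 = c2,
          pos2 = p2, orientation = canonical_orientation_or(ty),
          size = sz, caller = "simA", technology = tech,
          pass_filter = stats::runif(1) < pass_rate, stringsAsFactors = FALSE)
        labels[[length(labels) + 1L]] <- data.frame(
          call_id = did, label = "NEGATIVE", truth_id = NA_character_,
          stringsAsFactors = FALSE)
      }
      list(calls = validate_sv_calls(do.call(rbind, pos_calls)),
           labels = do.call(rbind, labels))
    })
  }
  sr <- gen_tech("SR", config$seed + seed_offset)
  lr <- gen_tech("LR", config$seed + seed_offset + 1L)
  list(sr = sr$calls, lr = lr$calls,
       labels = rbind(sr$labels, lr$labels))
}

canonical_orientation_or <- function(ty) {
  switch(ty, DEL = "3to5", DUP = "5to3", INV = "3to3", TRA = "3to5")
}

#' Label merged SVs from call-level labels
#'
#' A merged SV is POSITIVE when any member call derives from an implanted
#' truth SV, NEGATIVE when all members are decoys.
#'
#' @param merged merged table from [merge_calls].
#' @param labels label table from [make_labelled_callset].
#' @return data.frame `sv_id`, `label`, `truth_id`.
#' @export
label_merged <- function(merged, labels) {
  do.call(rbind, lapply(seq_len(nrow(merged)), function(r) {
    mem <- merged$members[[r]]
    lab <- labels[match(mem, labels$call_id), , drop = FALSE]
    pos <- any(lab$label == "POSITIVE", na.rm = TRUE)
    data.frame(sv_id = merged$id[r],
               label = if (pos) "POSITIVE" else "NEGATIVE",
               truth_id = if (pos) lab$truth_id[which(lab$label == "POSITIVE")[1]]
                          else NA_character_,
               stringsAsFactors = FALSE)
  }))
}

#' Write a genome to FASTA
#' @param genome named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
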