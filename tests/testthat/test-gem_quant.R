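# GEM (barcode) support: anomalous-pair extraction from BAM, window rule,
# orientation mapping, set semantics, normalization, molecule statistics.

mk_pair <- function(barcode, chrom1, pos1, strand1, chrom2, pos2, strand2,
                    qname = paste0("q", sample.int(1e6, 1)), rl = 150L) {
  data.frame(qname = qname, barcode = barcode,
             chrom1 = chrom1, pos1 = pos1, end1 = pos1 + rl - 1L,
             strand1 = strand1, chrom2 = chrom2, pos2 = pos2,
             end2 = pos2 + rl - 1L, strand2 = strand2,
             interchrom = chrom1 != chrom2, proper = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the GEM window is the molecule-length / N50-reads ratio", {
  expect_equal(compute_window(60000, 50), 1200L)
  expect_equal(compute_window(50000, 100), 500L)
  expect_equal(compute_window(10000, 100), 200L)   # 200-bp floor
  expect_error(compute_window(-1, 10), "positive")
  expect_error(compute_window(1000, 0), "positive")
})

test_that("count_gems counts unique barcodes matching window and geometry", {
  sv <- make_call("d", "DEL", pos1 = 10000L, pos2 = 20000L)
  ## DEL (3to5): + anchor left of bp1, - anchor right of bp2
  pairs <- rbind(
    mk_pair("B1", "chr1", 9800L, "+", "chr1", 20100L, "-", "q1"),
    mk_pair("B1", "chr1", 9700L, "+", "chr1", 20200L, "-", "q2"),
    mk_pair("B2", "chr1", 9900L, "+", "chr1", 20050L, "-", "q3"))
  expect_equal(count_gems(pairs, sv, 500L), 2L)     # B1 counted once
  ## anchor 2 windows away from bp2: not counted
  far <- mk_pair("B3", "chr1", 9900L, "+", "chr1", 21100L, "-", "q4")
  expect_equal(count_gems(far, sv, 500L), 0L)
  ## 5to5 geometry cannot support a 3to5 deletion
  wrong <- mk_pair("B4", "chr1", 10100L, "-", "chr1", 20100L, "-", "q5")
  expect_equal(count_gems(wrong, sv, 500L), 0L)
})

test_that("orientation mapping covers all four junction geometries", {
  w <- 500L
  ## duplication 5to3: - anchor at the 5' start, + anchor at the 3' end
  dup <- make_call("u", "DUP", pos1 = 10000L, pos2 = 20000L)
  expect_equal(count_gems(
    mk_pair("B1", "chr1", 10100L, "-", "chr1", 19700L, "+"), dup, w), 1L)
  ## inversion 3to3: both anchors forward
  inv <- make_call("i", "INV", pos1 = 10000L, pos2 = 20000L)
  expect_equal(count_gems(
    mk_pair("B1", "chr1", 9700L, "+", "chr1", 19700L, "+"), inv, w), 1L)
  ## inversion 5to5
  inv5 <- make_call("i5", "INV", pos1 = 10000L, pos2 = 20000L,
                    orientation = "5to5")
  expect_equal(count_gems(
    mk_pair("B1", "chr1", 10100L, "-", "chr1", 20100L, "-"), inv5, w), 1L)
  ## translocation across chromosomes
  tra <- make_call("t", "TRA", chrom1 = "chr1", pos1 = 10000L,
                   chrom2 = "chr2", pos2 = 20000L)
  expect_equal(count_gems(
    mk_pair("B1", "chr1", 9700L, "+", "chr2", 20100L, "-"), tra, w), 1L)
})

test_that("count_gems matches a nested-loop oracle and is window-monotone", {
  withr::with_seed(31, {
    n <- 1000
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_pair(sprintf("B%03d", sample.int(120, 1)),
              sample(c("chr1", "chr2"), 1), sample.int(90000L, 1),
              sample(c("+", "-"), 1), sample(c("chr1", "chr2"), 1),
              sample.int(90000L, 1), sample(c("+", "-"), 1),
              qname = paste0("q", i))
    }))
    ## duplicate some pairs within a barcode: set semantics must hold
    pairs <- rbind(pairs, pairs[sample(n, 100), ])
    svs <- rbind(
      make_call("d", "DEL", pos1 = 30000L, pos2 = 60000L),
      make_call("u", "DUP", pos1 = 20000L, pos2 = 50000L),
      make_call("i", "INV", pos1 = 10000L, pos2 = 80000L),
      make_call("t", "TRA", chrom1 = "chr1", pos1 = 40000L,
                chrom2 = "chr2", pos2 = 70000L))
    prev <- rep(-1L, nrow(svs))
    for (w in c(500L, 2000L, 8000L, 30000L)) {
      for (r in seq_len(nrow(svs))) {
        got <- count_gems(pairs, svs[r, ], w)
        expect_equal(got, oracle_count_gems(pairs, svs[r, ], w))
        expect_gte(got, prev[r])          # enlarging the window never loses GEMs
        prev[r] <- got
      }
    }
  })
})

test_that("anomalous pairs are extracted from a barcoded BAM by flags", {
  contigs <- c(chr1 = 100000L, chr2 = 100000L)
  seq150 <- strrep("A", 150)
  aln <- data.frame(
    qname = rep(c("prop", "inter", "disc"), each = 2),
    mate = rep(1:2, 3),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr1", "chr1"),
    pos = c(1000L, 1350L, 5000L, 7000L, 9000L, 15000L),
    strand = c("+", "-", "+", "-", "+", "-"),
    seq = seq150,
    proper = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    supp = FALSE,
    barcode = rep(c("AAAA", "CCCC", "GGGG"), each = 2),
    stringsAsFactors = FALSE)
  ## add a supplementary alignment for a fourth, otherwise proper pair
  aln <- rbind(aln, data.frame(
    qname = c("split", "split", "split"), mate = c(1L, 2L, 1L),
    chrom = "chr1", pos = c(20000L, 20350L, 30000L),
    strand = c("+", "-", "+"), seq = seq150,
    proper = c(TRUE, TRUE, FALSE), supp = c(FALSE, FALSE, TRUE),
    barcode = "TTTT", stringsAsFactors = FALSE))
  sam <- withr::local_tempfile(fileext = ".sam")
  bam <- write_sam(aln, contigs, sam, as_bam = TRUE)
  pairs <- extract_anomalous_reads(bam)
  ## proper innie pair excluded; inter-chromosomal, discordant and
  ## split-carrying pairs included
  expect_setequal(pairs$qname, c("inter", "disc", "split"))
  expect_true(pairs$interchrom[pairs$qname == "inter"])
  ## pairs lacking a barcode are dropped and counted
  aln2 <- aln
  aln2$barcode[aln2$qname == "disc"] <- NA
  sam2 <- withr::local_tempfile(fileext = ".sam")
  bam2 <- write_sam(aln2, contigs, sam2, as_bam = TRUE)
  pairs2 <- extract_anomalous_reads(bam2)
  expect_setequal(pairs2$qname, c("inter", "split"))
  expect_equal(attr(pairs2, "n_no_barcode"), 1L)
  expect_error(extract_anomalous_reads(withr::local_tempfile(fileext = ".bam")),
               "index")
})

test_that("GEM normalization scales per 1e6 barcodes", {
  r <- normalize_gems(2, 1e6)
  expect_equal(r$gem_norm, 2)
  expect_equal(normalize_gems(0, 100)$gem_norm, 0)
  expect_equal(normalize_gems(173, 1e8)$gem_norm, 1.73)
  expect_error(normalize_gems(1, 0), "positive")
})

test_that("molecule statistics recover known molecules from grouped reads", {
  ## two molecules on one barcode separated by > 50 kb, one on another
  reads <- data.frame(
    barcode = c(rep("B1", 6), rep("B2", 4)),
    chrom = "chr1",
    pos = c(1000L, 5000L, 9001L, 70000L, 75000L, 80001L,
            10000L, 20000L, 30000L, 40001L))
  st <- estimate_molecule_stats(reads, max_gap = 50000)
  expect_equal(st$n_molecules, 3L)
  expect_equal(st$avg_molecule_length,
               mean(c(9001 - 1000 + 1, 80001 - 70000 + 1, 40001 - 10000 + 1)))
  ## N50 reads per molecule: counts sorted desc {4, 3, 3}, cumulative
  ## {4, 7, 10}; half of the 10 reads is first reached at a 3-read molecule
  expect_equal(st$n50_reads_per_molecule, 3L)
})

test_that("implanted SVs gain GEM support; decoy coordinates do not", {
  cfg <- small_sim_config(seed = 17)
  g <- generate_genome(cfg)
  imp <- implant_svs(g, cfg)
  lr <- simulate_lr_reads(imp$alt, cfg, imp$blocks)
  pairs <- svintegrate:::pair_anomalous_alignments(lr$truth_aln)
  w <- compute_window(lr$stats$avg_molecule_length,
                      lr$stats$n50_reads_per_molecule)
  ## molecules covering each junction, counted in ALT coordinates
  to_alt <- function(chrom, pos) {
    b <- imp$blocks[imp$blocks$ref_chrom == chrom &
                      imp$blocks$ref_start <= pos &
                      imp$blocks$ref_end >= pos &
                      imp$blocks$strand == "+", , drop = FALSE][1, ]
    list(chrom = b$alt_chrom, pos = b$alt_start + (pos - b$ref_start))
  }
  for (r in seq_len(nrow(imp$truth))) {
    sv <- imp$truth[r, ]
    j <- to_alt(sv$chrom1, sv$pos1)
    covering <- sum(lr$molecules$chrom == j$chrom &
                      lr$molecules$start < j$pos - 500 &
                      lr$molecules$end > j$pos + 500)
    if (covering >= 3) {
      expect_gte(count_gems(pairs, sv, w), 1L, label = sv$id)
    }
  }
  ## a decoy far from every implanted breakpoint collects no barcodes
  bps <- c(imp$truth$pos1[imp$truth$chrom1 == "chr1"],
           imp$truth$pos2[imp$truth$chrom2 == "chr1"])
  pos <- Find(function(p) all(abs(p - bps) > w + 4000 &
                                abs(p + 4000 - bps) > w + 4000),
              seq(10000, 40000, by = 500))
  decoy <- make_call("dec", "DEL", chrom1 = "chr1", pos1 = as.integer(pos),
                     pos2 = as.integer(pos + 4000))
  expect_equal(count_gems(pairs, decoy, w), 0L)
})
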