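# core model: VCF parsing (symbolic + BND), merging, cross-technology
# comparison, table round trips.

test_that("symbolic-ALT records parse with VCF semantics", {
  path <- write_vcf_lines(c(
    "chr1\t1000\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000",
    "chr1\t20000\tdup1\tN\t<DUP>\t.\tLowQual\tSVTYPE=DUP;END=24000",
    "chr2\t500\tinv1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=2500",
    "chr2\t9000\tcnv1\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=30000"))
  out <- parse_sv_vcf(path, "delly", "SR")
  expect_equal(nrow(out), 3)            # read-depth-only CNV dropped
  del <- out[out$id == "del1", ]
  expect_equal(del$sv_type, "DEL")
  expect_equal(del$pos1, 1000L)
  expect_equal(del$pos2, 5000L)
  expect_equal(del$orientation, "3to5")
  expect_equal(del$size, 4000L)
  expect_true(del$pass_filter)
  dup <- out[out$id == "dup1", ]
  expect_false(dup$pass_filter)         # FILTER LowQual
  expect_equal(dup$orientation, "5to3")
  expect_equal(dup$pos1, 20001L)        # first duplicated base
  expect_equal(out$caller, rep("delly", 3))
  expect_equal(out$technology, rep("SR", 3))
})

test_that("BND pairs collapse per the bracket-notation truth table", {
  ## inter-chromosomal: all four forms, checked against an independent
  ## hand-built orientation oracle
  forms <- list(
    c("chr1\t500\tb1\tN\tN[chr2:900[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
      "chr2\t900\tb2\tN\t]chr1:500]N\t.\tPASS\tSVTYPE=BND;MATEID=b1"),
    c("chr1\t500\tb1\tN\tN]chr2:900]\t.\tPASS\tSVTYPE=BND;MATEID=b2",
      "chr2\t900\tb2\tN\tN]chr1:500]\t.\tPASS\tSVTYPE=BND;MATEID=b1"),
    c("chr1\t500\tb1\tN\t]chr2:900]N\t.\tPASS\tSVTYPE=BND;MATEID=b2",
      "chr2\t900\tb2\tN\tN[chr1:500[\t.\tPASS\tSVTYPE=BND;MATEID=b1"),
    c("chr1\t500\tb1\tN\t[chr2:900[N\t.\tPASS\tSVTYPE=BND;MATEID=b2",
      "chr2\t900\tb2\tN\t[chr1:500[N\t.\tPASS\tSVTYPE=BND;MATEID=b1"))
  for (lines in forms) {
    alt1 <- strsplit(lines[1], "\t")[[1]][5]
    path <- write_vcf_lines(lines)
    out <- parse_sv_vcf(path, "lumpy", "SR")
    expect_equal(nrow(out), 1)
    expect_equal(out$sv_type, "TRA")
    expect_equal(out$chrom1, "chr1")
    expect_equal(out$pos1, 500L)
    expect_equal(out$chrom2, "chr2")
    expect_equal(out$pos2, 900L)
    expect_equal(out$orientation, oracle_bnd_orientation(alt1))
  }
})

test_that("intra-chromosomal BND pairs become typed SVs", {
  path <- write_vcf_lines(c(
    "chr1\t1000\ta1\tN\tN[chr1:5001[\t.\tPASS\tSVTYPE=BND;MATEID=a2",
    "chr1\t5001\ta2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=a1",
    "chr2\t2000\tc1\tN\tN]chr2:7000]\t.\tLowQual\tSVTYPE=BND;MATEID=c2",
    "chr2\t7000\tc2\tN\tN]chr2:2000]\t.\tLowQual\tSVTYPE=BND;MATEID=c1"))
  out <- parse_sv_vcf(path, "svaba", "SR")
  del <- out[out$sv_type == "DEL", ]
  expect_equal(nrow(del), 1)
  expect_equal(c(del$pos1, del$pos2), c(1000L, 5000L))  # END-style coordinates
  expect_equal(del$size, 4000L)
  inv <- out[out$sv_type == "INV", ]
  expect_equal(inv$orientation, "3to3")
  expect_false(inv$pass_filter)
})

test_that("a BND record without its mate is skipped with a warning", {
  path <- write_vcf_lines(
    "chr1\t500\tlone\tN\tN[chr2:900[\t.\tPASS\tSVTYPE=BND;MATEID=ghost")
  expect_warning(out <- parse_sv_vcf(path, "x", "LR"), "no mate")
  expect_equal(nrow(out), 0)
})

test_that("malformed VCF raises a parse error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("this is", "not a vcf"), path)
  expect_error(parse_sv_vcf(path, "x", "SR"), "malformed VCF")
})

test_that("merge_calls honors the 500-bp window and type/orientation", {
  ## two DELs offset (300, 120) merge; tool_count counts distinct callers
  calls <- rbind(
    make_call("d1", "DEL", pos1 = 10000L, pos2 = 20000L, caller = "delly"),
    make_call("d2", "DEL", pos1 = 10300L, pos2 = 20120L, caller = "lumpy"))
  m <- merge_calls(calls)
  expect_equal(nrow(m), 1)
  expect_equal(m$tool_count, 2L)
  expect_setequal(m$members[[1]], c("d1", "d2"))
  ## 501 bp apart never merges (window is <= 500)
  far <- rbind(
    make_call("d1", "DEL", pos1 = 10000L, pos2 = 20000L),
    make_call("d2", "DEL", pos1 = 10501L, pos2 = 20000L, caller = "lumpy"))
  expect_equal(nrow(merge_calls(far)), 2)
  ## identical coordinates, different type never merge
  mixed <- rbind(
    make_call("d1", "DEL", pos1 = 10000L, pos2 = 20000L),
    make_call("u1", "DUP", pos1 = 10000L, pos2 = 20000L, caller = "lumpy"))
  expect_equal(nrow(merge_calls(mixed)), 2)
})

test_that("high_confidence reflects PASS in at least one member", {
  calls <- rbind(
    make_call("a", "DEL", pos1 = 1000L, pos2 = 2000L, pass_filter = FALSE),
    make_call("b", "DEL", pos1 = 1100L, pos2 = 2100L, caller = "lumpy",
              pass_filter = TRUE))
  m <- merge_calls(calls)
  expect_true(m$high_confidence)
  ## representative breakpoints come from the first PASS member
  expect_equal(m$pos1, 1100L)
  m2 <- merge_calls(rbind(
    make_call("a", "DEL", pos1 = 1000L, pos2 = 2000L, pass_filter = FALSE),
    make_call("b", "DEL", pos1 = 1100L, pos2 = 2100L, caller = "lumpy",
              pass_filter = FALSE)))
  expect_false(m2$high_confidence)
})

test_that("merging partitions the input and is order-invariant", {
  withr::with_seed(42, {
    n <- 40
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_call(paste0("c", i),
                sv_type = sample(c("DEL", "DUP", "INV"), 1),
                pos1 = sample(1000:30000, 1), pos2 = sample(40000:70000, 1),
                caller = sample(c("t1", "t2", "t3"), 1),
                pass_filter = runif(1) < 0.5)
    }))
    ref_part <- merge_calls(calls)
    canon <- function(m) {
      sets <- lapply(m$members, sort)
      sets[order(vapply(sets, paste, character(1), collapse = ","))]
    }
    ## each input call appears in exactly one merged SV
    all_members <- unlist(ref_part$members)
    expect_setequal(all_members, calls$id)
    expect_equal(length(all_members), nrow(calls))
    for (k in 1:5) {
      perm <- calls[sample(nrow(calls)), , drop = FALSE]
      expect_identical(canon(merge_calls(perm)), canon(ref_part))
    }
  })
})

test_that("window = 0 merges only exact duplicates", {
  calls <- rbind(
    make_call("a", "DEL", pos1 = 1000L, pos2 = 2000L),
    make_call("b", "DEL", pos1 = 1000L, pos2 = 2000L, caller = "t2"),
    make_call("c", "DEL", pos1 = 1001L, pos2 = 2000L, caller = "t3"))
  m <- merge_calls(calls, window = 0)
  expect_equal(nrow(m), 2)
})

test_that("merge_calls rejects mixed technologies", {
  calls <- rbind(make_call("a", technology = "SR"),
                 make_call("b", technology = "LR"))
  expect_error(merge_calls(calls), "mixed technologies")
})

test_that("compare_technologies applies size floors and matches by window", {
  sr <- merge_calls(rbind(
    make_call("sdel", "DEL", pos1 = 10000L, pos2 = 14000L),       # 4 kb
    make_call("sdup", "DUP", pos1 = 30000L, pos2 = 34999L),       # 5 kb
    make_call("stiny", "DEL", pos1 = 50000L, pos2 = 50040L)))     # 40 bp
  lr <- merge_calls(rbind(
    make_call("ldel", "DEL", pos1 = 10200L, pos2 = 14200L,
              technology = "LR"),
    make_call("ldup", "DUP", pos1 = 30000L, pos2 = 34999L,
              technology = "LR")))
  cmp <- compare_technologies(sr, lr)
  expect_equal(sum(cmp$category == "COMMON"), 1)            # the 4 kb DEL
  ## the 5 kb DUP is below the 10 kb DUP/INV comparison floor: one record
  ## per technology, never matched
  expect_equal(sum(cmp$category == "ONLY_SR" & cmp$sv_type == "DUP"), 1)
  expect_equal(sum(cmp$category == "ONLY_LR" & cmp$sv_type == "DUP"), 1)
  ## the 40 bp DEL is absent from the comparison entirely
  expect_false(any(cmp$pos1 == 50000))
  ## >10 kb DUPs do match
  sr2 <- merge_calls(make_call("bigdup", "DUP", pos1 = 10000L, pos2 = 25000L))
  lr2 <- merge_calls(make_call("bigdupL", "DUP", pos1 = 10100L, pos2 = 25100L,
                               technology = "LR"))
  expect_equal(compare_technologies(sr2, lr2)$category, "COMMON")
})

test_that("compare_technologies is symmetric", {
  withr::with_seed(9, {
    mk <- function(tech, n, offset = 0L) {
      merge_calls(do.call(rbind, lapply(seq_len(n), function(i)
        make_call(paste0(tech, i), "DEL", pos1 = 5000L * i + offset,
                  pos2 = 5000L * i + 2000L + offset, technology = tech))))
    }
    sr <- mk("SR", 6); lr <- mk("LR", 4, offset = 150L)
    ab <- compare_technologies(sr, lr)
    ba <- compare_technologies(lr, sr)
    expect_equal(sum(ab$category == "COMMON"), sum(ba$category == "COMMON"))
    expect_equal(sum(ab$category == "ONLY_SR"), sum(ba$category == "ONLY_LR"))
    expect_equal(sum(ab$category == "ONLY_LR"), sum(ba$category == "ONLY_SR"))
  })
})

test_that("TRA matching requires the same chromosome pair", {
  sr <- merge_calls(make_call("t1", "TRA", chrom1 = "chr1", pos1 = 1000L,
                              chrom2 = "chr2", pos2 = 5000L))
  lr <- merge_calls(make_call("t2", "TRA", chrom1 = "chr1", pos1 = 1000L,
                              chrom2 = "chr3", pos2 = 5000L,
                              technology = "LR"))
  cmp <- compare_technologies(sr, lr)
  expect_false(any(cmp$category == "COMMON"))
})

test_that("SV tables and VCFs round-trip", {
  merged <- merge_calls(rbind(
    make_call("a", "DEL", pos1 = 1000L, pos2 = 3000L),
    make_call("b", "DUP", pos1 = 20000L, pos2 = 32000L, caller = "t2"),
    make_call("c", "INV", pos1 = 5000L, pos2 = 26000L, caller = "t3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sv_table(merged, path)
  back <- read_sv_table(path)
  for (col in c("id", "sv_type", "orientation", "chrom1", "pos1", "chrom2",
                "pos2", "size", "tool_count", "high_confidence")) {
    expect_equal(back[[col]], merged[[col]], info = col)
  }
  ## empty table -> header only
  write_sv_table(empty <- merged[0, ], path)
  expect_equal(nrow(read_sv_table(path)), 0)
  ## TRA -> two mated BND lines that re-pair on parsing
  tra <- make_call("t", "TRA", chrom1 = "chr1", pos1 = 1234L,
                   chrom2 = "chr2", pos2 = 4321L)
  vpath <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(tra, vpath, contigs = c(chr1 = 100000, chr2 = 100000))
  lines <- grep("^[^#]", readLines(vpath), value = TRUE)
  expect_equal(length(lines), 2)
  back <- parse_sv_vcf(vpath, "toolA", "SR")
  expect_equal(back$sv_type, "TRA")
  expect_equal(c(back$pos1, back$pos2), c(1234L, 4321L))
  expect_equal(back$orientation, "3to5")
})
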