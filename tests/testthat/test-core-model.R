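test_that("container validators enforce the model invariants", {
  expect_error(ccr_fragments("A", "chr1", 100, 50), "start > end")
  expect_error(
    ccr_fragments(c("A", "B"), "chr1", c(100, 150), c(200, 250)),
    "overlap"
  )
  # duplication-aware mode accepts the same intervals
  expect_s3_class(
    ccr_fragments(c("A", "B"), "chr1", c(100, 150), c(200, 250),
                  allow_duplications = TRUE),
    "ccr_fragments"
  )
  expect_error(
    ccr_junctions("J1", "chr1", 100, "tail", "chr2", 50, "head",
                  inserted_seq = "ACGT", microhomology = 2L),
    "mutually exclusive"
  )
  expect_error(ccr_junctions("J1", "chr1", 100, "up", "chr2", 50, "head"),
               "head.*tail")
  expect_error(
    ccr_genome(data.frame(name = "chr1", length = 1000),
               genes = data.frame(name = "g", chrom = "chr1", start = 900, end = 1100)),
    "outside"
  )
  expect_error(
    ccr_genome(data.frame(name = c("chr1", "chr1"), length = c(10, 10))),
    "unique"
  )
})

test_that("fragment table reading handles the empty and malformed cases", {
  header <- paste(c("fragment_id", "chrom", "start", "end", "orientation",
                    "derivative", "junction_id_head", "junction_id_tail",
                    "inserted_seq", "microhomology", "deleted_nt"),
                  collapse = "\t")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(header, tf)
  out <- read_fragment_table(tf)
  expect_identical(nrow(out$fragments), 0L)
  expect_identical(nrow(out$junctions), 0L)
  expect_identical(out$derivative_names, character())

  writeLines(c(header,
               "A\tchr1\t100\t200\t.\t.\t.\t.\t.\t.\t.",
               "B\tchr1\t150\t250\t.\t.\t.\t.\t.\t.\t."), tf)
  expect_error(read_fragment_table(tf), "overlap")

  writeLines(c(header, "A\tchr1\tx\t200\t.\t.\t.\t.\t.\t.\t."), tf)
  expect_error(read_fragment_table(tf), "line 2")
})

test_that("fragment tables round-trip through write/read field-for-field", {
  s <- simulate_chromoplexy(TOY_GENOME, n_breaks = 12, seed = 21)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(s$fragments, s$junctions, tf)
  rt <- read_fragment_table(tf)

  norm <- function(df, cols) {
    df <- as.data.frame(df)[, cols]
    df <- df[order(df[[1L]]), ]
    rownames(df) <- NULL
    df
  }
  fcols <- c("fragment_id", "chrom", "start", "end", "junction_head",
             "junction_tail", "derivative", "orientation")
  expect_equal(norm(rt$fragments, fcols), norm(s$fragments, fcols))
  jcols <- c("junction_id", "chrom_a", "pos_a", "side_a", "chrom_b", "pos_b",
             "side_b", "inserted_seq", "microhomology", "deleted_nt")
  expect_equal(norm(rt$junctions, jcols), norm(s$junctions, jcols))
  expect_setequal(rt$derivative_names,
                  vapply(s$derivatives, function(d) d$name, character(1L)))

  # a second write of the re-read objects is byte-identical
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(rt$fragments, rt$junctions, tf2)
  expect_identical(readLines(tf2), readLines(tf))
})

test_that("a minimal three-fragment table round-trips", {
  fr <- ccr_fragments(c("A", "B", "C"), "chr1",
                      start = c(1, 201, 401), end = c(100, 300, 500),
                      junction_head = c(NA, "J1", "J2"),
                      junction_tail = c("J1", "J2", NA),
                      derivative = "der(chr1)", orientation = "forward")
  jx <- ccr_junctions(c("J1", "J2"),
                      chrom_a = "chr1", pos_a = c(100, 300), side_a = "tail",
                      chrom_b = "chr1", pos_b = c(201, 401), side_b = "head",
                      deleted_nt = c(100, 100))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_table(fr, jx, tf)
  rt <- read_fragment_table(tf)
  expect_identical(nrow(rt$fragments), 3L)
  expect_identical(nrow(rt$junctions), 2L)
  expect_equal(rt$junctions$deleted_nt, c(100, 100))
  expect_identical(rt$derivative_names, "der(chr1)")
})

test_that("bedpe conversion follows the 0-based and strand conventions", {
  tf <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr4\t99\t100\tchr21\t499\t500\tJ1\t.\t+\t-", tf)
  j <- read_bedpe(tf)
  # 0-based half-open end column equals the 1-based inclusive position;
  # '+' marks the tail side, '-' the head side
  expect_identical(j$pos_a, 100)
  expect_identical(j$side_a, "tail")
  expect_identical(j$pos_b, 500)
  expect_identical(j$side_b, "head")

  writeLines("chr4\t99\t100\tchr21\t499", tf)
  expect_error(read_bedpe(tf), "fewer than 6")
})

test_that("bedpe writing inverts reading for any junction list", {
  s <- simulate_chromothripsis(TOY_GENOME, n_breaks = 15, seed = 8)
  tf <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(s$junctions, tf)
  rt <- read_bedpe(tf)
  cols <- c("junction_id", "chrom_a", "pos_a", "side_a", "chrom_b", "pos_b", "side_b")
  expect_equal(as.data.frame(rt)[, cols], as.data.frame(s$junctions)[, cols])
})

test_that("VCF BND bracket notation maps to breakend sides per the spec'd semantics", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr,
    "chr4\t100\tb1\tN\tN[chr21:500[\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr21\t500\tb2\tN\t]chr4:100]N\t.\tPASS\tSVTYPE=BND;MATEID=b1"), tf)
  x <- read_vcf_bnd(tf)
  expect_identical(nrow(x), 1L)
  expect_identical(c(x$chrom_a, x$side_a), c("chr4", "tail"))
  expect_identical(c(x$chrom_b, x$side_b), c("chr21", "head"))

  writeLines(c(hdr,
    "chr4\t100\tb1\tN\t]chr21:500]N\t.\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr21\t500\tb2\tN\tN[chr4:100[\t.\tPASS\tSVTYPE=BND;MATEID=b1"), tf)
  x <- read_vcf_bnd(tf)
  expect_identical(c(x$side_a, x$side_b), c("head", "tail"))

  writeLines(hdr, tf)
  expect_identical(nrow(read_vcf_bnd(tf)), 0L)

  # unmatched mate is skipped with a warning
  writeLines(c(hdr,
    "chr4\t100\tb1\tN\tN[chr21:500[\t.\tPASS\tSVTYPE=BND;MATEID=zz"), tf)
  expect_warning(x <- read_vcf_bnd(tf), "mate")
  expect_identical(nrow(x), 0L)
})

test_that("VCF BND writing inverts reading", {
  s <- simulate_chromoplexy(TOY_GENOME, n_breaks = 12, seed = 4)
  calls <- make_noisy_callset(s$junctions, TOY_GENOME, "ill", sensitivity = 1,
                              fp_per_mbp = 0.2, position_jitter_sd = 50, seed = 6)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_bnd(calls, tf)
  rt <- read_vcf_bnd(tf, technology = "ill")
  expect_equal(as.data.frame(rt), as.data.frame(calls))
})

test_that("written BND VCFs parse with an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  s <- simulate_chromothripsis(TOY_GENOME, n_breaks = 10, seed = 13)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_bnd(s$junctions, tf)
  v <- VariantAnnotation::readVcf(tf)
  expect_identical(length(v), 2L * nrow(s$junctions))
  expect_true(all(unlist(VariantAnnotation::info(v)$SVTYPE) == "BND"))
  # positions agree record-for-record
  got <- sort(unique(paste0(
    as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(v))), ":",
    GenomicRanges::start(SummarizedExperiment::rowRanges(v)))))
  want <- sort(unique(c(paste0(s$junctions$chrom_a, ":", s$junctions$pos_a),
                        paste0(s$junctions$chrom_b, ":", s$junctions$pos_b))))
  expect_identical(got, want)
})

test_that("BED annotation readers convert to 1-based inclusive coordinates", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\ttadA", "chr1\t1000\t2500\ttadB"), tf)
  tads <- read_tads(tf)
  expect_identical(tads$start, c(1L, 1001L))
  expect_identical(tads$end, c(1000L, 2500L))
  genes <- read_genes(tf)
  expect_identical(genes$name, c("tadA", "tadB"))
})

test_that("FASTA round-trips genome sequences", {
  tf <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(SEQ_GENOME, tf)
  seqs <- read_genome_fasta(tf)
  expect_identical(seqs, SEQ_GENOME$sequences)
})
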