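test_that("microhomology length counts the ambiguous breakpoint range", {
  # upstream ...TTAC with continuation GTCG; downstream enters GTAA after
  # precedent AGGT: the break can slide 2 nt downstream, none upstream
  expect_identical(microhomology_length("TTACGTCG", "AGGTGTAA"), 2L)
  # completely dissimilar flanks
  expect_identical(microhomology_length("AAAAAAAA", "CCCCCCCC"), 0L)
  expect_error(microhomology_length("AAXA", "CCCC"), "non-ACGTN")
  expect_error(microhomology_length("AAA", "CCC"), "even")
})

test_that("microhomology matches a brute-force breakpoint-shift oracle", {
  # oracle: enumerate every breakpoint shift s and test whether the junction
  # sequence is reproduced; the ambiguous range is the maximal contiguous set
  # of valid shifts around 0
  shift_oracle <- function(left_ref, right_ref) {
    w <- nchar(left_ref) %/% 2L
    joined <- paste0(substr(left_ref, 1L, w), substr(right_ref, w + 1L, 2L * w))
    valid <- function(s) {
      alt <- paste0(substr(left_ref, 1L, w + s), substr(right_ref, w + 1L + s, 2L * w))
      identical(alt, joined)
    }
    fwd <- 0L
    for (s in seq_len(w)) { if (valid(s)) fwd <- s else break }
    back <- 0L
    for (s in seq_len(w)) { if (valid(-s)) back <- s else break }
    fwd + back
  }
  withr::with_seed(404, {
    for (rep in 1:200) {
      w <- sample(5:20, 1L)
      left <- paste(sample(c("A", "C", "G", "T"), 2L * w, TRUE), collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"), 2L * w, TRUE), collapse = "")
      # half the time, plant overlap to exercise non-zero values
      if (rep %% 2L == 0L) {
        k <- sample.int(w - 1L, 1L)
        substr(right, w + 1L, w + k) <- substr(left, w + 1L, w + k)
      }
      expect_identical(microhomology_length(left, right),
                       as.integer(shift_oracle(left, right)))
    }
  })
})

test_that("microhomology is symmetric under segment swap with reverse complement", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      w <- sample(5:15, 1L)
      left <- paste(sample(c("A", "C", "G", "T"), 2L * w, TRUE), collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"), 2L * w, TRUE), collapse = "")
      expect_identical(
        microhomology_length(left, right),
        microhomology_length(ccrsolve:::revcomp(right), ccrsolve:::revcomp(left))
      )
    }
  })
})

test_that("insertions are classified templated when copied from a flank", {
  withr::with_seed(5, {
    flanks <- replicate(4L, ccrsolve:::random_dna(600))
    ins <- substr(flanks[1L], 101L, 130L)  # 30 nt planted 100 bp into flank A
    hit <- classify_insertion(ins, flanks)
    expect_true(hit$templated)
    expect_identical(hit$flank, 1L)
    expect_identical(hit$offset, 101L)

    rc <- classify_insertion(ccrsolve:::revcomp(ins), flanks)
    expect_true(rc$templated)
    expect_true(rc$revcomp)

    random_ins <- ccrsolve:::random_dna(30L)
    expect_false(classify_insertion(random_ins, flanks)$templated)
  })
  expect_error(classify_insertion("", "ACGT"), "non-empty")
})

test_that("junction deletion measures the lost reference run beyond the breakends", {
  # balanced collinear fusion
  fr <- ccr_fragments(c("A", "B"), "chr4", start = c(1, 101), end = c(100, 200))
  j <- ccr_junctions("J1", "chr4", 100, "tail", "chr4", 101, "head")
  expect_identical(junction_deletion(j[1L, ], fr), 0)
  # 50 nt lost between the fused ends, counted once
  fr2 <- ccr_fragments(c("A", "B"), "chr4", start = c(1, 151), end = c(100, 200))
  j2 <- ccr_junctions("J1", "chr4", 100, "tail", "chr4", 151, "head")
  expect_identical(junction_deletion(j2[1L, ], fr2), 50)
})

test_that("junction deletion recovers simulated truth sizes exactly", {
  for (sd in c(2, 9)) {
    s <- simulate_chromothripsis(TOY_GENOME, n_breaks = 20, seed = sd)
    got <- vapply(seq_len(nrow(s$junctions)), function(i) {
      junction_deletion(s$junctions[i, , drop = FALSE], s$fragments)
    }, numeric(1L))
    expect_identical(got, s$junctions$deleted_nt)
  }
})

test_that("signature summary reproduces the printed small-rearrangement bins", {
  # 5 junctions: 3 balanced, deletions of 1 and 2 nt
  j <- ccr_junctions(paste0("J", 1:5), "chr7", c(100, 300, 500, 700, 900), "tail",
                     "chr11", c(100, 300, 500, 700, 900), "head",
                     deleted_nt = c(0, 0, 0, 1, 2))
  s <- summarize_signatures(j)
  get <- function(section, bin) s[s$section == section & s$bin == bin, ]
  expect_identical(get("breakpoint", "balanced")$count, 3L)
  expect_identical(get("breakpoint", "balanced")$pct, 60)
  expect_identical(get("breakpoint", "<10 nt deletion")$count, 2L)
  expect_identical(get("breakpoint", "<10 nt deletion")$pct, 40)
})

test_that("signature bins are exclusive, exhaustive and order-invariant", {
  # planted bin counts over 132 junctions
  del <- c(rep(0, 48), rep(5, 15), rep(50, 29), rep(500, 18), rep(5000, 20),
           rep(20000, 2)) # planted counts 48/15/29/18/20/2, total 132
  withr::with_seed(3, {
    del <- sample(del)
    mh <- ifelse(del > 0 & seq_along(del) %% 3L == 0L, sample(1:4, 132, TRUE), 0L)
    j <- ccr_junctions(sprintf("J%03d", 1:132), "chr4", seq(1e3, by = 1e3, length.out = 132),
                       "tail", "chrX", seq(1e3, by = 1e3, length.out = 132), "head",
                       microhomology = mh, deleted_nt = del)
  })
  s <- summarize_signatures(j)
  delbins <- s[s$section == "breakpoint" & s$bin != "total", ]
  expect_identical(sum(delbins$count), 132L)  # exhaustive partition
  expect_identical(delbins$count, c(48L, 15L, 29L, 18L, 20L, 2L))
  # reordering junctions leaves the summary unchanged
  s2 <- summarize_signatures(j[sample(nrow(j)), ])
  expect_identical(s2, s)
  # empty input gives an all-zero summary
  s0 <- summarize_signatures(ccrsolve:::empty_junctions())
  expect_true(all(s0$count[!is.na(s0$count)] == 0L))
})

test_that("sequence-level annotation recovers planted signatures", {
  s <- simulate_chromoanasynthesis(SEQ_GENOME, mh_range = 4, templated_prob = 1, seed = 31)
  ann <- annotate_junctions(s$junctions, genome = s$genome)
  planted <- !nzchar(s$junctions$inserted_seq)
  expect_true(all(ann$microhomology[planted] == 4L))
  expect_true(all(ann$templated[!planted]))

  s0 <- simulate_chromoanasynthesis(SEQ_GENOME, templated_prob = 0, seed = 32)
  ann0 <- annotate_junctions(s0$junctions, genome = s0$genome)
  expect_false(any(ann0$templated[nzchar(s0$junctions$inserted_seq)]))
})
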