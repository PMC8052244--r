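test_that("genome construction honours the requested composition", {
  g <- make_genome(n_chrom = 4, chrom_length = 1e6, genes_per_chrom = 50,
                   gene_length = 1e4, seed = 3)
  for (ch in g$chromosomes$name) {
    gg <- g$genes[g$genes$chrom == ch, ]
    expect_identical(nrow(gg), 50L)
    expect_equal(sum(gg$end - gg$start + 1) / 1e6, 0.5)  # coverage fraction
    expect_true(all(gg$start[-1L] > gg$end[-nrow(gg)]))  # non-overlapping
  }
  expect_identical(make_genome(n_chrom = 4, chrom_length = 1e6, genes_per_chrom = 50,
                               gene_length = 1e4, seed = 3), g)
  expect_error(make_genome(chrom_length = 1e5, genes_per_chrom = 10,
                           gene_length = 5e4, seed = 1),
               "infeasible")
  g0 <- make_genome(n_chrom = 1, chrom_length = 1e6, genes_per_chrom = 0, seed = 5)
  jx <- ccr_junctions("J1", "chr1", 100, "tail", "chr1", 500, "head")
  expect_identical(count_intragenic(jx, g0$genes), 0L)
})

test_that("simulators are seed-deterministic and seed-sensitive", {
  a <- simulate_chromothripsis(TOY_GENOME, seed = 6)
  b <- simulate_chromothripsis(TOY_GENOME, seed = 6)
  expect_identical(a, b)
  c_ <- simulate_chromothripsis(TOY_GENOME, seed = 7)
  expect_false(identical(a$junctions, c_$junctions))
  expect_error(simulate_chromothripsis(TOY_GENOME), "seed")
  expect_error(simulate_chromothripsis(TOY_GENOME, chroms = TOY_GENOME$chromosomes$name,
                                       seed = 1), "at most 3")
  expect_error(simulate_chromoplexy(TOY_GENOME, chroms = "chr1", seed = 1),
               "more than 2")
})

test_that("chromothripsis output keeps chain arithmetic and tiling conservation", {
  s <- simulate_chromothripsis(TOY_GENOME, chroms = "chr1", n_breaks = 20,
                               lost_frac = 0, seed = 12)
  expect_identical(nrow(s$fragments), 21L)
  expect_identical(nrow(s$junctions), 20L)
  expect_length(s$derivatives, 1L)
  # retained fragments plus deleted runs tile the chromosome exactly
  fr <- s$fragments[order(s$fragments$start), ]
  expect_equal(fr$start[1L], 1)
  expect_equal(fr$end[nrow(fr)],
               TOY_GENOME$chromosomes$length[TOY_GENOME$chromosomes$name == "chr1"])
  expect_true(all(fr$start[-1L] > fr$end[-nrow(fr)]))
  gaps <- fr$start[-1L] - fr$end[-nrow(fr)] - 1
  expect_true(all(gaps >= 0))
})

test_that("chromothripsis fusion orientations are uniform over seeds", {
  counts <- c(tail_head = 0, head_tail = 0, head_head = 0, tail_tail = 0)
  for (sd in 1:25) {
    s <- simulate_chromothripsis(TOY_GENOME, chroms = "chr1", n_breaks = 20,
                                 seed = sd)
    oc <- orientation_counts(s$derivatives)
    counts <- counts + c(oc$tail_head, oc$head_tail, oc$head_head, oc$tail_tail)
  }
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
})

test_that("chromoplexy places breakpoints intragenically at the requested bias", {
  s <- simulate_chromoplexy(TOY_GENOME, n_breaks = 50, intragenic_bias = 0.9, seed = 2)
  lut_hits <- count_intragenic(s$junctions, TOY_GENOME$genes)
  expect_gt(lut_hits / nrow(s$junctions), 0.8)
  # all deletions zero -> fully balanced signature summary
  s0 <- simulate_chromoplexy(TOY_GENOME, balanced_prob = 1, seed = 3)
  sm <- summarize_signatures(s0$junctions)
  expect_identical(sm$pct[sm$section == "breakpoint" & sm$bin == "balanced"], 100)
})

test_that("BFB cycles produce only fold-back junctions and terminal loss", {
  s1 <- simulate_bfb(TOY_GENOME, n_cycles = 1, seed = 4)
  oc1 <- orientation_counts(s1$derivatives)
  expect_identical(sum(oc1$n_junctions), 1L)
  expect_identical(sum(oc1$head_head) + sum(oc1$tail_tail), 1L)

  s10 <- simulate_bfb(TOY_GENOME, n_cycles = 10, seed = 4)
  oc10 <- orientation_counts(s10$derivatives)
  expect_identical(sum(oc10$head_head) + sum(oc10$tail_tail), sum(oc10$n_junctions))
  expect_true(s10$terminal_loss)
  expect_true(s10$has_duplications)
  # retained fragments never reach the lost chromosome end
  L <- TOY_GENOME$chromosomes$length[1L]
  expect_lt(max(s10$fragments$end), L)

  s25 <- simulate_bfb(TOY_GENOME, n_cycles = 25, seed = 4)
  expect_lt(foldback_enrichment(orientation_counts(s25$derivatives))$p_value, 1e-6)
})

test_that("chromoanasynthesis requires sequence and plants its signatures", {
  expect_error(simulate_chromoanasynthesis(TOY_GENOME, seed = 1), "sequences")
  s <- simulate_chromoanasynthesis(SEQ_GENOME, mh_range = 4, seed = 6)
  mh_junc <- s$junctions$microhomology > 0L
  expect_true(all(s$junctions$microhomology[mh_junc] == 4L))
  expect_true(any(nzchar(s$junctions$inserted_seq)))
  expect_true(s$has_duplications)
  # duplicated copies overlap their source fragment
  dups <- grepl("_dup$", s$fragments$fragment_id)
  expect_true(any(dups))
})

test_that("noisy call sets reflect sensitivity, jitter and false-positive rate", {
  s <- simulate_chromoplexy(TOY_GENOME, n_breaks = 30, seed = 10)
  none <- make_noisy_callset(s$junctions, TOY_GENOME, "null", sensitivity = 0,
                             fp_per_mbp = 0, seed = 1)
  expect_identical(nrow(none), 0L)
  exact <- make_noisy_callset(s$junctions, TOY_GENOME, "exact", sensitivity = 1,
                              fp_per_mbp = 0, position_jitter_sd = 0, seed = 1)
  expect_identical(nrow(exact), nrow(s$junctions))
  expect_equal(exact$pos_a, s$junctions$pos_a)
  jit <- make_noisy_callset(s$junctions, TOY_GENOME, "jit", sensitivity = 1,
                            fp_per_mbp = 0, position_jitter_sd = 500, seed = 1)
  expect_false(all(jit$pos_a == s$junctions$pos_a))
  expect_true(all(abs(jit$pos_a - s$junctions$pos_a) < 5000))

  mean_detected <- mean(vapply(1:40, function(sd) {
    nrow(make_noisy_callset(s$junctions, TOY_GENOME, "x", sensitivity = 0.9,
                            fp_per_mbp = 0, seed = sd))
  }, numeric(1L)))
  n <- nrow(s$junctions)
  expect_lt(abs(mean_detected - 0.9 * n), 4 * sqrt(n * 0.9 * 0.1 / 40))
})
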