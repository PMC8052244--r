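test_that("exact binomial tails agree with explicit summation and closed forms", {
  expect_error(exact_binomial_one_sided(10, 11, 0.5), "0 <= k <= n")
  expect_error(exact_binomial_one_sided(10, 5, 1), "between 0 and 1")

  t1 <- exact_binomial_one_sided(5, 0, 0.5)
  expect_identical(t1$direction, "lower")
  expect_equal(t1$p_value, 0.5^5)

  t2 <- exact_binomial_one_sided(28, 3, 0.25)
  expect_equal(t2$p_value, binom_tail_oracle(28, 3, 0.25, "lower"), tolerance = 1e-12)

  withr::with_seed(808, {
    for (rep in 1:100) {
      n <- sample(200, 1L)
      k <- sample(0:n, 1L)
      p0 <- runif(1, 0.02, 0.98)
      t <- exact_binomial_one_sided(n, k, p0)
      expect_lt(abs(t$p_value - binom_tail_oracle(n, k, p0, t$direction)), 1e-12)
      expect_true(t$p_value > 0 && t$p_value <= 1)
    }
  })
})

test_that("the upper-tail p-value is non-increasing in k", {
  p <- vapply(0:40, function(k) {
    stats::pbinom(k - 1, 40, 0.3, lower.tail = FALSE)
  }, numeric(1L))
  expect_true(all(diff(p) <= 0))
  # and the direction rule ties at k = n*p0 toward the lower tail
  t <- exact_binomial_one_sided(28, 7, 0.25)
  expect_identical(t$direction, "lower")
  expect_gte(t$p_value, 0.5)
})

test_that("fragment distribution tests use per-origin totals and uniform null", {
  # all 12 of one origin's fragments on one of four derivatives
  placed <- data.frame(
    chrom = "chr9",
    derivative = c(rep("der1", 12L)),
    stringsAsFactors = FALSE
  )
  # force four derivatives into the frame via other origins
  other <- data.frame(chrom = "chrO", derivative = paste0("der", 1:4),
                      stringsAsFactors = FALSE)
  dm <- fragment_distribution_test(rbind(placed, other))
  cell <- dm[dm$origin == "chr9" & dm$derivative == "der1", ]
  expect_equal(cell$fraction, 1)
  expect_identical(cell$direction, "upper")
  expect_equal(cell$p_value, 0.25^12)
  # zero cells are retained
  expect_identical(nrow(dm[dm$origin == "chr9", ]), 4L)
  expect_identical(sum(dm[dm$origin == "chr9", "k"]), 12L)
})

test_that("distribution-test p-values are calibrated under uniform placement", {
  withr::with_seed(99, {
    k <- stats::rbinom(2000L, 24L, 0.25)
  })
  # each fixed tail is exact, hence super-uniform under the null
  p_lower <- stats::pbinom(k, 24L, 0.25)
  p_upper <- stats::pbinom(k - 1L, 24L, 0.25, lower.tail = FALSE)
  mc_err <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(p_lower < 0.05), 0.05 + mc_err)
  expect_lte(mean(p_upper < 0.05), 0.05 + mc_err)
  # the direction-toward-deviation p is bounded by the two-tail sum
  p_dir <- ifelse(k > 6, p_upper, p_lower)
  expect_lte(mean(p_dir < 0.05), 0.10 + 2 * mc_err)
})

test_that("fusion orientation classes follow the native fused ends", {
  pl <- data.frame(derivative = "d", orientation = c("forward", "forward", "forward"),
                   stringsAsFactors = FALSE)
  oc <- orientation_counts(pl)
  expect_identical(oc$tail_head, 2L)
  expect_identical(oc$n_junctions, 2L)

  pl2 <- data.frame(derivative = "d", orientation = c("forward", "reverse"),
                    stringsAsFactors = FALSE)
  oc2 <- orientation_counts(pl2)
  expect_identical(oc2$tail_tail, 1L)

  pl3 <- data.frame(derivative = "d", orientation = c("reverse", "forward"),
                    stringsAsFactors = FALSE)
  expect_identical(orientation_counts(pl3)$head_head, 1L)
  pl4 <- data.frame(derivative = "d", orientation = c("reverse", "reverse"),
                    stringsAsFactors = FALSE)
  expect_identical(orientation_counts(pl4)$head_tail, 1L)
})

test_that("orientation tests use junction-count trials at p0 = 1/4", {
  counts <- data.frame(derivative = "der(19)", tail_head = 3L, head_tail = 9L,
                       head_head = 8L, tail_tail = 8L, n_junctions = 28L,
                       stringsAsFactors = FALSE)
  ot <- orientation_tests(counts)
  th <- ot[ot$class == "tail_head", ]
  expect_identical(th$n, 28L)
  expect_identical(th$direction, "lower")
  expect_equal(round(th$p_value, 2), 0.06)

  # symmetric counts sit at the tie rule on every class
  sym <- data.frame(derivative = "d", tail_head = 7L, head_tail = 7L,
                    head_head = 7L, tail_tail = 7L, n_junctions = 28L,
                    stringsAsFactors = FALSE)
  ots <- orientation_tests(sym)
  expect_true(all(ots$direction == "lower"))
  expect_true(all(ots$p_value >= 0.5))

  ext <- data.frame(derivative = "d", tail_head = 28L, head_tail = 0L,
                    head_head = 0L, tail_tail = 0L, n_junctions = 28L,
                    stringsAsFactors = FALSE)
  ote <- orientation_tests(ext)
  expect_equal(ote$p_value[ote$class == "tail_head"], 0.25^28)
})

test_that("fold-back enrichment pools inverted fusion classes", {
  counts <- data.frame(derivative = "d", tail_head = 0L, head_tail = 0L,
                       head_head = 10L, tail_tail = 10L, n_junctions = 20L,
                       stringsAsFactors = FALSE)
  t <- foldback_enrichment(counts)
  expect_identical(t$direction, "upper")
  expect_equal(t$p_value, 0.5^20)

  bal <- data.frame(derivative = "d", tail_head = 5L, head_tail = 5L,
                    head_head = 5L, tail_tail = 5L, n_junctions = 20L,
                    stringsAsFactors = FALSE)
  tb <- foldback_enrichment(bal)
  expect_identical(tb$direction, "lower")
  expect_gt(tb$p_value, 0.5)

  # a simulated BFB derivative is all fold-back fusions
  s <- simulate_bfb(TOY_GENOME, n_cycles = 10, seed = 5)
  oc <- orientation_counts(s$derivatives)
  expect_identical(sum(oc$head_head) + sum(oc$tail_tail), sum(oc$n_junctions))
  expect_lt(foldback_enrichment(oc)$p_value, 1e-6)
})

test_that("intragenic counting requires one breakend inside a gene", {
  genes <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  inside <- ccr_junctions("J1", "chr1", 1500, "tail", "chr2", 500, "head")
  outside <- ccr_junctions("J2", "chr1", 2500, "tail", "chr2", 500, "head")
  edge <- ccr_junctions("J3", "chr1", 2000, "tail", "chr2", 500, "head")
  expect_identical(count_intragenic(inside, genes), 1L)
  expect_identical(count_intragenic(outside, genes), 0L)
  expect_identical(count_intragenic(edge, genes), 1L)  # inclusive bounds
})

test_that("uniform junctions hit genes at the closed-form rate", {
  # genes cover fraction g; a junction is intragenic w.p. 1 - (1 - g)^2
  g <- 0.3
  L <- 1e6
  genes <- data.frame(chrom = "chr1", start = 1, end = g * L)
  withr::with_seed(21, {
    N <- 4000L
    jx <- ccr_junctions(sprintf("J%04d", 1:N),
                        "chr1", 1 + floor(runif(N) * L), "tail",
                        "chr1", 1 + floor(runif(N) * L), "head")
  })
  k <- count_intragenic(jx, genes)
  expected <- 4000 * (1 - (1 - g)^2)
  expect_lt(abs(k - expected), 4 * sqrt(4000 * 0.51 * 0.49))
})

test_that("the Monte Carlo intragenic test follows the strictly-greater rule", {
  lens <- c(chr1 = 1e5)
  genes <- data.frame(chrom = "chr1", start = 1, end = 5e4)  # 50% coverage
  withr::with_seed(9, {
    N <- 100L
    pos <- function() 1 + floor(runif(N) * 1e5)
    jx <- ccr_junctions(sprintf("J%03d", 1:N), "chr1", pos(), "tail",
                        "chr1", pos(), "head")
  })
  # nothing can exceed the maximum possible count
  all_in <- ccr_junctions(sprintf("J%03d", 1:100), "chr1", 1:100, "tail",
                          "chr1", 101:200, "head")
  mc_max <- monte_carlo_intragenic(all_in, genes, lens, iterations = 200, seed = 1)
  expect_identical(mc_max$observed, 100L)
  expect_identical(mc_max$p_value, 0)
  expect_match(mc_max$p_label, "p < 0.005")

  # an observed count of 0 is exceeded by essentially every simulation
  none_in <- ccr_junctions(sprintf("J%03d", 1:100), "chr1", 50001:50100, "tail",
                           "chr1", 60001:60100, "head")
  mc0 <- monte_carlo_intragenic(none_in, genes, lens, iterations = 200, seed = 1)
  expect_identical(mc0$observed, 0L)
  expect_gt(mc0$p_value, 0.99)
})

test_that("Monte Carlo results are reproducible and leave the RNG untouched", {
  s <- simulate_chromoplexy(TOY_GENOME, n_breaks = 20, seed = 14)
  lens <- stats::setNames(TOY_GENOME$chromosomes$length, TOY_GENOME$chromosomes$name)
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  m1 <- monte_carlo_intragenic(s$junctions, TOY_GENOME$genes, lens,
                               iterations = 300, seed = 7)
  after <- runif(3)
  expect_identical(before, after)  # the caller's RNG stream is unaffected
  m2 <- monte_carlo_intragenic(s$junctions, TOY_GENOME$genes, lens,
                               iterations = 300, seed = 7)
  expect_identical(m1, m2)
})
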