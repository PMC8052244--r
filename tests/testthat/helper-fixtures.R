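# Shared fixtures, built once per test run.

# Annotation-only genome: 4 x 10 Mbp, ~35 genes and ~9 TADs per chromosome.
TOY_GENOME <- make_genome(seed = 11)

# Small sequence-bearing genome for nucleotide-level simulations.
SEQ_GENOME <- make_genome(n_chrom = 2, chrom_length = 4e5, genes_per_chrom = 10,
                          gene_length = c(5e3, 2e4), tad_length = 1e5,
                          with_sequence = TRUE, seed = 2)

# Three collinear fragments on chr1 joined tail-to-head by two junctions,
# matched positionally (no explicit link columns).
toy_chain <- function() {
  fr <- ccr_fragments(c("A", "B", "C"), "chr1",
                      start = c(1, 201, 401), end = c(100, 300, 500))
  jx <- ccr_junctions(c("J1", "J2"),
                      chrom_a = "chr1", pos_a = c(100, 300), side_a = "tail",
                      chrom_b = "chr1", pos_b = c(201, 401), side_b = "head")
  list(fragments = fr, junctions = jx)
}

# Chain with B inverted: A(tail)-(tail)B(head)-(head)C.
toy_inverted_chain <- function() {
  fr <- ccr_fragments(c("A", "B", "C"), "chr1",
                      start = c(1, 201, 401), end = c(100, 300, 500))
  jx <- ccr_junctions(c("J1", "J2"),
                      chrom_a = "chr1", pos_a = c(100, 201), side_a = c("tail", "head"),
                      chrom_b = "chr1", pos_b = c(300, 401), side_b = c("tail", "head"))
  list(fragments = fr, junctions = jx)
}

# Fragment order + orientation of every derivative, for round-trip comparison.
chain_signature <- function(derivatives) {
  lapply(derivatives, function(d) d$chain[, c("fragment_id", "orientation")])
}

expect_same_chains <- function(reconstructed, truth) {
  expect_identical(chain_signature(reconstructed), chain_signature(truth))
}

# Independent oracle: one-sided binomial tail by explicit summation of point
# probabilities via log factorials.
binom_tail_oracle <- function(n, k, p0, direction) {
  i <- if (direction == "lower") 0:k else k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}
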