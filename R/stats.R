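#' Exact one-sided binomial test
#'
#' Computes the exact cumulative binomial tail (a sum of point probabilities,
#' never a normal approximation). The direction is chosen toward the observed
#' deviation: upper tail when `k > n * p0`, lower tail otherwise (ties at
#' `k = n * p0` use the lower tail).
#'
#' @param n Number of trials.
#' @param k Observed successes, `0 <= k <= n`.
#' @param p0 Null success probability, in (0, 1).
#' @return A list of class `ccr_binom_test`: `n`, `k`, `p0`, `direction`
#'   (`"lower"`/`"upper"`) and `p_value`.
#' @export
exact_binomial_one_sided <- function(n, k, p0) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stopf("n must be a single non-negative integer")
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n || k != round(k)) {
    stopf("k must be a single integer with 0 <= k <= n")
  }
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stopf("p0 must lie strictly between 0 and 1")
  }
  direction <- if (k > n * p0) "upper" else "lower"
  p <- if (direction == "lower") {
    stats::pbinom(k, n, p0)
  } else {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
  structure(list(n = n, k = k, p0 = p0, direction = direction, p_value = p),
            class = "ccr_binom_test")
}

#' @export
print.ccr_binom_test <- function(x, ...) {
  cat(sprintf("exact one-sided binomial test: k = %d of n = %d, p0 = %g, %s tail, p = %.4g\n",
              x$k, x$n, x$p0, x$direction, x$p_value))
  invisible(x)
}

#' Test the distribution of fragments across derivative chromosomes
#'
#' For every origin chromosome and derivative, tests whether the number of that
#' origin's fragments placed on the derivative deviates from a uniform spread:
#' trials `n` = total fragments of that origin, null probability
#' `p0 = 1 / (number of derivatives)`, one exact one-sided test per cell.
#' Derivatives carrying none of an origin's fragments are retained as `k = 0`
#' rows.
#'
#' @param placed Placed fragments, e.g. from [placed_fragments()]: a
#'   `data.frame` with at least `chrom` (origin chromosome) and `derivative`.
#' @return A `data.frame` of class `ccr_distribution_matrix` with one row per
#'   (origin, derivative): `origin`, `derivative`, `k`, `n`, `fraction`,
#'   `direction`, `p_value`.
#' @export
fragment_distribution_test <- function(placed) {
  stopifnot(all(c("chrom", "derivative") %in% names(placed)))
  if (any(is.na(placed$derivative))) stopf("every fragment needs a derivative assignment")
  derivs <- unique(placed$derivative)
  origins <- unique(placed$chrom)
  p0 <- 1 / length(derivs)
  rows <- list()
  for (o in origins) {
    n_o <- sum(placed$chrom == o)
    for (d in derivs) {
      k <- sum(placed$chrom == o & placed$derivative == d)
      t <- exact_binomial_one_sided(n_o, k, p0)
      rows[[length(rows) + 1L]] <- data.frame(
        origin = o, derivative = d, k = k, n = n_o, fraction = k / n_o,
        direction = t$direction, p_value = t$p_value, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ccr_distribution_matrix", "data.frame")
  out
}

#' Count fusion-orientation classes along derivatives
#'
#' Each adjacent fragment pair in a derivative chain is classified by the
#' native ends fused: forward-forward is tail-to-head, reverse-reverse is
#' head-to-tail, forward-reverse is tail-to-tail and reverse-forward is
#' head-to-head.
#'
#' @param derivatives A `ccr_derivative`, a list of them, or a placed-fragment
#'   `data.frame` with `derivative` and `orientation` columns in chain order.
#' @return A `data.frame` of class `ccr_orientation_counts`, one row per
#'   derivative with columns `derivative`, `tail_head`, `head_tail`,
#'   `head_head`, `tail_tail`, `n_junctions`.
#' @export
orientation_counts <- function(derivatives) {
  placed <- if (is.data.frame(derivatives)) derivatives else placed_fragments(derivatives)
  stopifnot(all(c("derivative", "orientation") %in% names(placed)))
  out <- do.call(rbind, lapply(unique(placed$derivative), function(d) {
    o <- placed$orientation[placed$derivative == d]
    cls <- fusion_class(o[-length(o)], o[-1L])
    data.frame(derivative = d,
               tail_head = sum(cls == "tail_head"),
               head_tail = sum(cls == "head_tail"),
               head_head = sum(cls == "head_head"),
               tail_tail = sum(cls == "tail_tail"),
               n_junctions = length(cls), stringsAsFactors = FALSE)
  }))
  class(out) <- c("ccr_orientation_counts", "data.frame")
  out
}

fusion_class <- function(left_orientation, right_orientation) {
  ifelse(left_orientation == "forward",
         ifelse(right_orientation == "forward", "tail_head", "tail_tail"),
         ifelse(right_orientation == "forward", "head_head", "head_tail"))
}

#' Exact binomial tests of fusion-orientation bias
#'
#' Per derivative (plus an overall row) and per fusion class, runs an exact
#' one-sided test with trials `n` = the derivative's junction count and null
#' probability `p0 = 1/4` (the number of possible fusion orientations),
#' direction toward the observed deviation.
#'
#' @param counts Output of [orientation_counts()].
#' @return `data.frame` with `derivative`, `class`, `k`, `n`, `direction`,
#'   `p_value`.
#' @export
orientation_tests <- function(counts) {
  classes <- c("tail_head", "head_tail", "head_head", "tail_tail")
  tab <- counts
  if (nrow(tab) > 1L) {
    overall <- data.frame(derivative = "overall", t(colSums(tab[classes])),
                          n_junctions = sum(tab$n_junctions), stringsAsFactors = FALSE)
    tab <- rbind(tab, overall)
  }
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    if (tab$n_junctions[i] < 1L) next
    for (cl in classes) {
      t <- exact_binomial_one_sided(tab$n_junctions[i], tab[[cl]][i], 0.25)
      rows[[length(rows) + 1L]] <- data.frame(
        derivative = tab$derivative[i], class = cl, k = t$k, n = t$n,
        direction = t$direction, p_value = t$p_value, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Fold-back (breakage-fusion-bridge) fusion enrichment
#'
#' BFB cycles produce rearrangements enriched in head-to-head and tail-to-tail
#' fusions. This tests the combined fold-back count against the null that
#' inverted and non-inverted fusions are equally likely: `k` = head-to-head +
#' tail-to-tail, `n` = total junctions, `p0 = 1/2`, exact one-sided test with
#' the usual direction rule (upper tail when `k > n/2`).
#'
#' @param counts Output of [orientation_counts()]; rows are pooled.
#' @return A `ccr_binom_test`.
#' @export
foldback_enrichment <- function(counts) {
  n <- sum(counts$n_junctions)
  if (n < 1L) stopf("no junctions to test")
  k <- sum(counts$head_head) + sum(counts$tail_tail)
  exact_binomial_one_sided(n, k, 0.5)
}

#' Count intragenic junctions
#'
#' A junction is intragenic if at least one of its two breakpoints lies within
#' a gene (inclusive interval bounds).
#'
#' @param junctions A [ccr_junctions()] table.
#' @param genes Gene intervals: `data.frame` with `chrom`, `start`, `end`.
#' @return Integer count of intragenic junctions.
#' @export
count_intragenic <- function(junctions, genes) {
  if (nrow(junctions) == 0L) return(0L)
  lut <- gene_lookup(genes)
  a <- point_in_intervals(junctions$chrom_a, junctions$pos_a, lut)
  b <- point_in_intervals(junctions$chrom_b, junctions$pos_b, lut)
  sum(a | b)
}

# Per-chromosome merged gene intervals for fast point queries.
gene_lookup <- function(genes) {
  if (is.null(genes) || nrow(genes) == 0L) return(list())
  out <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    out[[ch]] <- list(start = IRanges::start(r), end = IRanges::end(r))
  }
  out
}

point_in_intervals <- function(chrom, pos, lut) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- lut[[ch]]
    sel <- chrom == ch
    if (is.null(iv)) next
    idx <- findInterval(pos[sel], iv$start)
    out[sel] <- idx > 0L & pos[sel] <= iv$end[pmax(idx, 1L)]
  }
  out
}

#' Monte Carlo test of intragenic breakpoint enrichment
#'
#' Simulates, for each iteration, the same number of junctions as observed with
#' both breakends drawn uniformly over the concatenated lengths of the involved
#' chromosomes (every base equally likely), counts intragenic simulated
#' junctions, and reports `p` = the fraction of iterations whose simulated
#' count is strictly greater than the observed count. No pseudocount is added,
#' so the smallest reportable p-value is 0, reported as `p < 1/iterations`.
#'
#' @param junctions Observed junctions ([ccr_junctions()]).
#' @param genes Gene intervals (`chrom`, `start`, `end`).
#' @param chrom_lengths Named numeric vector of involved chromosome lengths.
#' @param iterations Number of Monte Carlo iterations (default 1000).
#' @param seed Mandatory RNG seed; results are bit-reproducible given
#'   (`seed`, `iterations`).
#' @return A list of class `ccr_mc_test`: `p_value`, `p_label`, `observed`,
#'   `iterations`, `n_junctions`, `exceed` (iterations strictly exceeding the
#'   observed count) and `ties` (iterations equalling it; useful for
#'   discreteness-aware calibration).
#' @export
monte_carlo_intragenic <- function(junctions, genes, chrom_lengths,
                                   iterations = 1000, seed) {
  if (missing(seed)) stopf("a seed is required")
  if (iterations < 1L) stopf("iterations must be >= 1")
  observed <- count_intragenic(junctions, genes)
  n_j <- nrow(junctions)
  lens <- as.numeric(chrom_lengths)
  names(lens) <- names(chrom_lengths)
  total <- sum(lens)
  offsets <- c(0, cumsum(lens))[seq_along(lens)]
  genes <- genes[genes$chrom %in% names(lens), , drop = FALSE]
  lut <- gene_lookup(genes)
  # merged gene intervals in concatenated coordinates
  gs <- numeric(0); ge <- numeric(0)
  for (ch in names(lut)) {
    off <- offsets[[match(ch, names(lens))]]
    gs <- c(gs, lut[[ch]]$start + off)
    ge <- c(ge, lut[[ch]]$end + off)
  }
  o <- order(gs); gs <- gs[o]; ge <- ge[o]
  in_gene <- function(p) {
    if (!length(gs)) return(rep(FALSE, length(p)))
    idx <- findInterval(p, gs)
    idx > 0L & p <= ge[pmax(idx, 1L)]
  }
  tallies <- with_seed(seed, {
    hits <- 0L; ties <- 0L
    for (it in seq_len(iterations)) {
      pa <- floor(stats::runif(n_j) * total) + 1
      pb <- floor(stats::runif(n_j) * total) + 1
      cnt <- sum(in_gene(pa) | in_gene(pb))
      if (cnt > observed) hits <- hits + 1L
      if (cnt == observed) ties <- ties + 1L
    }
    c(hits, ties)
  })
  exceed <- tallies[1L]
  p <- exceed / iterations
  structure(list(
    p_value = p,
    p_label = if (exceed == 0L) sprintf("p < %g", 1 / iterations) else sprintf("p = %g", p),
    observed = observed, iterations = iterations, n_junctions = n_j,
    exceed = exceed, ties = tallies[2L]
  ), class = "ccr_mc_test")
}

#' @export
print.ccr_mc_test <- function(x, ...) {
  cat(sprintf("Monte Carlo intragenic enrichment: observed %d of %d junctions intragenic; %s (%d iterations)\n",
              x$observed, x$n_junctions, x$p_label, x$iterations))
  invisible(x)
}
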