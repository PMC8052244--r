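#' Default thresholds of the mechanism decision table
#'
#' The mechanism of formation is decided from junction and fragment statistics
#' with an explicit decision table. Literature descriptions of the mechanisms
#' are qualitative; these thresholds are declared package constants that
#' formalize them, surfaced here so analyses can override any of them.
#'
#' @return Named list: `alpha` (significance level for the fold-back and
#'   intragenic tests, 0.05), `clustering_high` (breakpoint window
#'   dispersion, variance-to-mean ratio, above which breakpoints count as
#'   clustered; 5), `balanced_high` (minimum fraction of junctions with
#'   deletion < 1 kbp for a rearrangement to count as largely balanced; 0.8),
#'   `mh_elevated` (minimum fraction of junctions with 2-10 nt microhomology
#'   for a replicative signature; 0.2), `window_bp` (clustering window; 1 Mbp).
#' @export
mechanism_thresholds <- function() {
  list(alpha = 0.05, clustering_high = 5, balanced_high = 0.8,
       mh_elevated = 0.2, window_bp = 1e6)
}

#' Extract the mechanism feature vector of a rearrangement
#'
#' Computes the deterministic feature vector the decision table consumes:
#' number of chromosomes involved, presence of duplicated segments (overlapping
#' fragments of one chromosome), fraction of junctions with templated
#' insertions and with 2-10 nt microhomology, fraction of junctions that are
#' (near-)balanced (deletion < 1 kbp), the fold-back enrichment p-value (the
#' upper-tail probability of the observed head-to-head plus tail-to-tail
#' count under a 1/2 null), the Monte Carlo intragenic enrichment p-value, a
#' breakpoint clustering
#' statistic (variance-to-mean ratio of per-window breakpoint counts over the
#' involved chromosomes) and a terminal-loss flag (retained fragments of some
#' involved chromosome fail to reach a chromosome end).
#'
#' Templated-insertion fractions are computed from genome sequence via
#' [classify_insertion()] when sequences are available; otherwise a logical
#' `templated` column on the junction table is used, and absent both, the
#' fraction is 0.
#'
#' @param fragments A [ccr_fragments()] table.
#' @param junctions The matching [ccr_junctions()] table.
#' @param derivatives List of `ccr_derivative` (for orientation statistics).
#' @param genome A [ccr_genome()] (genes, chromosome lengths, optional
#'   sequences).
#' @param iterations,seed Monte Carlo settings for the intragenic test.
#' @param window_bp Clustering window width (default 1 Mbp).
#' @return A list of class `ccr_features`.
#' @export
extract_features <- function(fragments, junctions, derivatives, genome,
                             iterations = 1000, seed = 1, window_bp = 1e6) {
  n_j <- nrow(junctions)
  chroms <- unique(c(fragments$chrom, junctions$chrom_a, junctions$chrom_b))
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)

  has_dup <- FALSE
  for (ch in unique(fragments$chrom)) {
    sub <- fragments[fragments$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) has_dup <- TRUE
  }

  frac <- function(k) if (n_j == 0L) 0 else k / n_j
  templated <- if (n_j == 0L) {
    0L
  } else if (!is.null(genome$sequences)) {
    with_ins <- which(nzchar(junctions$inserted_seq))
    sum(vapply(with_ins, function(i) {
      classify_insertion(junctions$inserted_seq[i],
                         junction_flanks(junctions[i, , drop = FALSE], genome))$templated
    }, logical(1L)))
  } else if ("templated" %in% names(junctions)) {
    sum(junctions$templated %in% TRUE)
  } else 0L

  # upper-tail (enrichment) probability: a fold-back *depleted* rearrangement
  # must not look BFB-like, so the tie-rule lower tail is not used here
  if (n_j > 0L && length(derivatives)) {
    oc <- orientation_counts(derivatives)
    k_fb <- sum(oc$head_head) + sum(oc$tail_tail)
    foldback_p <- stats::pbinom(k_fb - 1, sum(oc$n_junctions), 0.5, lower.tail = FALSE)
  } else {
    foldback_p <- 1
  }
  intragenic_p <- if (n_j > 0L && !is.null(genome$genes)) {
    monte_carlo_intragenic(junctions, genome$genes, lens[chroms],
                           iterations = iterations, seed = seed)$p_value
  } else 1

  bp <- c(junctions$pos_a + cum_offset(junctions$chrom_a, lens, chroms),
          junctions$pos_b + cum_offset(junctions$chrom_b, lens, chroms))
  nbins <- max(ceiling(sum(lens[chroms]) / window_bp), 1)
  clustering <- if (length(bp) >= 2L && nbins >= 2L) {
    counts <- tabulate(pmin(floor((bp - 1) / window_bp) + 1L, nbins), nbins = nbins)
    if (mean(counts) == 0) 0 else stats::var(counts) / mean(counts)
  } else 0

  terminal_loss <- FALSE
  for (ch in intersect(chroms, unique(fragments$chrom))) {
    sub <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (min(sub$start) > 1 || max(sub$end) < lens[[ch]]) terminal_loss <- TRUE
  }

  structure(list(
    n_chromosomes_involved = length(chroms),
    has_duplications = has_dup,
    fraction_templated_insertions = frac(templated),
    fraction_microhomology_2_10 = frac(sum(junctions$microhomology >= 2L &
                                             junctions$microhomology <= 10L)),
    fraction_balanced = frac(sum(junctions$deleted_nt < 1000)),
    foldback_p = foldback_p,
    intragenic_p = intragenic_p,
    breakpoint_clustering = clustering,
    terminal_loss = terminal_loss
  ), class = "ccr_features")
}

cum_offset <- function(chrom, lens, chroms) {
  off <- c(0, cumsum(as.numeric(lens[chroms])))[seq_along(chroms)]
  names(off) <- chroms
  off[chrom]
}

#' Score candidate mechanisms of formation against a feature vector
#'
#' Evaluates each mechanism's criteria on the feature vector and scores it as
#' (number satisfied) - (number violated); the verdict is the top-scoring
#' mechanism, with ties reported as ties. Criteria:
#'
#' * **bfb** (breakage-fusion-bridge): fold-back enrichment `p < alpha`;
#'   terminal loss.
#' * **chromothripsis**: breakpoint clustering above `clustering_high`;
#'   at most 3 chromosomes involved (localized scattering of one or a few
#'   chromosomes); no duplications.
#' * **replicative** (chromoanasynthesis / FoSTeS / MMBIR, merged: the
#'   boundary between them is not operationally sharp): duplications present
#'   or templated insertions present; 2-10 nt microhomology fraction at least
#'   `mh_elevated`.
#' * **chromoplexy**: intragenic enrichment `p < alpha`; largely balanced
#'   (fraction of junctions with deletion < 1 kbp at least `balanced_high`);
#'   more than 2 chromosomes involved.
#'
#' @param features A `ccr_features` vector from [extract_features()].
#' @param alpha Significance level (default 0.05).
#' @param thresholds Threshold list, see [mechanism_thresholds()].
#' @return A list of class `ccr_mechanism_report`: `scores` (`data.frame` with
#'   `mechanism`, `n_satisfied`, `n_violated`, `score`), `criteria` (named list
#'   of logical vectors), `verdict` and `tie`.
#' @export
score_mechanisms <- function(features, alpha = 0.05,
                             thresholds = mechanism_thresholds()) {
  f <- features
  crit <- list(
    bfb = c(
      foldback_enriched = f$foldback_p < alpha,
      terminal_loss = isTRUE(f$terminal_loss)
    ),
    chromothripsis = c(
      clustered_breakpoints = f$breakpoint_clustering > thresholds$clustering_high,
      few_chromosomes = f$n_chromosomes_involved <= 3L,
      no_duplications = !isTRUE(f$has_duplications)
    ),
    replicative = c(
      duplications_or_templated = isTRUE(f$has_duplications) ||
        f$fraction_templated_insertions > 0,
      microhomology_elevated = f$fraction_microhomology_2_10 >= thresholds$mh_elevated
    ),
    chromoplexy = c(
      intragenic_enriched = f$intragenic_p < alpha,
      largely_balanced = f$fraction_balanced >= thresholds$balanced_high,
      several_chromosomes = f$n_chromosomes_involved > 2L
    )
  )
  scores <- data.frame(
    mechanism = names(crit),
    n_satisfied = vapply(crit, sum, 0L),
    n_violated = vapply(crit, function(x) sum(!x), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  scores$score <- scores$n_satisfied - scores$n_violated
  top <- scores$mechanism[scores$score == max(scores$score)]
  structure(list(
    scores = scores[order(-scores$score), , drop = FALSE],
    criteria = crit,
    verdict = if (length(top) == 1L) top else paste0("tie: ", paste(top, collapse = ", ")),
    tie = length(top) > 1L
  ), class = "ccr_mechanism_report")
}

#' @export
print.ccr_mechanism_report <- function(x, ...) {
  cat("mechanism verdict:", x$verdict, "\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}
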