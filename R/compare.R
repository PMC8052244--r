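#' Match technology SV calls against a confirmed junction truth set
#'
#' A call represents a confirmed junction when both of its breakend positions
#' lie within `max_dist` of the junction's breakends on the same chromosome
#' pair. Both breakend-to-breakend pairings are tried (corresponding-end
#' matching over the two orderings, keeping the better one). A call close to
#' several confirmed junctions represents only the closest one, closest
#' meaning minimal sum of the two end distances, ties broken by junction id
#' for determinism. Calls are not consumed: several calls may represent the
#' same junction, which counts as detected as soon as one call matches it.
#' Breakend orientation is ignored: matching is by distance only.
#'
#' @param calls A [ccr_calls()] table (one technology).
#' @param truth A [ccr_junctions()] truth set.
#' @param max_dist Maximum per-end distance in bp (default 100,000).
#' @return A list of class `ccr_match`: `technology`, `matches` (`data.frame`
#'   with `call`, `junction_id`, `distance`), `detected` (sorted junction ids
#'   with at least one matching call), `n_calls`, `truth_ids`.
#' @export
match_calls <- function(calls, truth, max_dist = 1e5) {
  n_truth <- nrow(truth)
  best_j <- rep(NA_character_, nrow(calls))
  best_d <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    da1 <- ifelse(calls$chrom_a[i] == truth$chrom_a, abs(calls$pos_a[i] - truth$pos_a), Inf)
    db1 <- ifelse(calls$chrom_b[i] == truth$chrom_b, abs(calls$pos_b[i] - truth$pos_b), Inf)
    da2 <- ifelse(calls$chrom_a[i] == truth$chrom_b, abs(calls$pos_a[i] - truth$pos_b), Inf)
    db2 <- ifelse(calls$chrom_b[i] == truth$chrom_a, abs(calls$pos_b[i] - truth$pos_a), Inf)
    ok1 <- da1 <= max_dist & db1 <= max_dist
    ok2 <- da2 <= max_dist & db2 <= max_dist
    d1 <- ifelse(ok1, da1 + db1, Inf)
    d2 <- ifelse(ok2, da2 + db2, Inf)
    d <- pmin(d1, d2)
    if (any(is.finite(d))) {
      dmin <- min(d)
      cand <- which(d == dmin)
      pick <- cand[order(truth$junction_id[cand])][1L]
      best_j[i] <- truth$junction_id[pick]
      best_d[i] <- dmin
    }
  }
  matches <- data.frame(call = seq_len(nrow(calls)), junction_id = best_j,
                        distance = best_d, stringsAsFactors = FALSE)
  structure(list(
    technology = if (nrow(calls)) calls$technology[1L] else "unknown",
    matches = matches,
    detected = sort(unique(stats::na.omit(best_j))),
    n_calls = nrow(calls),
    truth_ids = sort(truth$junction_id)
  ), class = "ccr_match")
}

#' @export
print.ccr_match <- function(x, ...) {
  cat(sprintf("%s: %d of %d truth junctions detected (%d calls)\n",
              x$technology, length(x$detected), length(x$truth_ids), x$n_calls))
  invisible(x)
}

#' Single and pairwise detection counts across technologies
#'
#' Builds the detection matrix over technologies: the diagonal holds each
#' technology's detected-junction count and cell (i, j) the size of the union
#' of technologies i and j's detected sets. All match results must have been
#' computed against the same truth set.
#'
#' @param results List of `ccr_match` results (one per technology).
#' @return Integer matrix with technology dimnames.
#' @export
pairwise_union <- function(results) {
  if (!length(results)) stopf("no match results supplied")
  ref <- results[[1L]]$truth_ids
  same <- vapply(results, function(r) identical(r$truth_ids, ref), logical(1L))
  if (!all(same)) stopf("match results were computed against different truth sets")
  techs <- vapply(results, function(r) r$technology, character(1L))
  m <- matrix(0L, length(results), length(results), dimnames = list(techs, techs))
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      m[i, j] <- length(union(results[[i]]$detected, results[[j]]$detected))
    }
  }
  m
}
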