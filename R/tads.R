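#' Assign breakpoints to TADs
#'
#' Every breakpoint is assigned to every topologically associated domain (TAD)
#' containing it (point containment, inclusive bounds); nested or overlapping
#' TADs therefore each count a shared breakpoint. Breakpoints contained in no
#' TAD are tallied as unassigned.
#'
#' @param breakpoints `data.frame` with `chrom`, `pos` (e.g. from
#'   [junction_breakpoints()]).
#' @param tads TAD intervals: `data.frame` with `tad_id`, `chrom`, `start`,
#'   `end` (1-based inclusive, see [read_tads()]).
#' @return List with `per_tad` (`data.frame`: `tad_id`, `breakpoints`) and
#'   `unassigned` (count).
#' @export
assign_breakpoints <- function(breakpoints, tads) {
  bp <- GenomicRanges::GRanges(breakpoints$chrom,
                               IRanges::IRanges(breakpoints$pos, breakpoints$pos))
  td <- GenomicRanges::GRanges(tads$chrom, IRanges::IRanges(tads$start, tads$end))
  # breakpoints on chromosomes without any TAD are legitimate (-> unassigned)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bp, td))
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(tads))
  unassigned <- sum(!seq_len(nrow(breakpoints)) %in% S4Vectors::queryHits(hits))
  list(per_tad = data.frame(tad_id = tads$tad_id, breakpoints = counts,
                            stringsAsFactors = FALSE),
       unassigned = unassigned)
}

#' All breakpoints of a junction table
#'
#' @param junctions A [ccr_junctions()] table.
#' @return `data.frame` with `junction_id`, `chrom`, `pos`, `breakend`
#'   (`"a"`/`"b"`); two rows per junction.
#' @export
junction_breakpoints <- function(junctions) {
  rbind(
    data.frame(junction_id = junctions$junction_id, chrom = junctions$chrom_a,
               pos = junctions$pos_a, breakend = "a", stringsAsFactors = FALSE),
    data.frame(junction_id = junctions$junction_id, chrom = junctions$chrom_b,
               pos = junctions$pos_b, breakend = "b", stringsAsFactors = FALSE)
  )
}

# TAD ids containing one point, as a character vector.
tads_at <- function(tads, chrom, pos) {
  tads$tad_id[tads$chrom == chrom & tads$start <= pos & tads$end >= pos]
}

#' Count junctions bridging across TADs
#'
#' A junction bridges TADs when its two breakends fall in different TADs, or
#' when exactly one breakend lies in a TAD and the other outside all TADs.
#' With nested/overlapping TADs, ends sharing at least one containing TAD do
#' not bridge. Junctions with both ends outside all TADs are not counted.
#'
#' @param junctions A [ccr_junctions()] table.
#' @param tads TAD intervals.
#' @return Integer count of bridging junctions.
#' @export
inter_tad_junctions <- function(junctions, tads) {
  sum(vapply(seq_len(nrow(junctions)), function(i) {
    a <- tads_at(tads, junctions$chrom_a[i], junctions$pos_a[i])
    b <- tads_at(tads, junctions$chrom_b[i], junctions$pos_b[i])
    if (!length(a) && !length(b)) return(FALSE)
    if (!length(a) || !length(b)) return(TRUE)
    length(intersect(a, b)) == 0L
  }, logical(1L)))
}

#' Count genes per TAD
#'
#' A gene is counted in a TAD when its interval overlaps the TAD by at least
#' one bp; a gene straddling a TAD boundary counts in both TADs.
#'
#' @param tads TAD intervals (`tad_id`, `chrom`, `start`, `end`).
#' @param genes Gene intervals (`chrom`, `start`, `end`).
#' @return `data.frame` with `tad_id`, `genes`.
#' @export
genes_in_tads <- function(tads, genes) {
  td <- GenomicRanges::GRanges(tads$chrom, IRanges::IRanges(tads$start, tads$end))
  gn <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  counts <- suppressWarnings(GenomicRanges::countOverlaps(td, gn, minoverlap = 1L))
  data.frame(tad_id = tads$tad_id, genes = as.integer(counts), stringsAsFactors = FALSE)
}

#' TAD disruption report
#'
#' Combines breakpoint assignment, junction counts, inter-TAD bridging and gene
#' content into one table over the affected TADs, with global tallies.
#'
#' @param junctions A [ccr_junctions()] table.
#' @param tads TAD intervals.
#' @param genes Optional gene intervals.
#' @return A list of class `ccr_tad_report`: `per_tad` (`data.frame` with
#'   `tad_id`, `chrom`, `start`, `end`, `breakpoints`, `junctions`,
#'   `inter_tad_junctions`, `genes`), `n_affected_tads`,
#'   `n_unassigned_breakpoints`, `n_bridging_junctions`.
#' @export
tad_report <- function(junctions, tads, genes = NULL) {
  bp <- junction_breakpoints(junctions)
  assignment <- assign_breakpoints(bp, tads)
  n <- nrow(junctions)
  tad_sets_a <- lapply(seq_len(n), function(i) tads_at(tads, junctions$chrom_a[i], junctions$pos_a[i]))
  tad_sets_b <- lapply(seq_len(n), function(i) tads_at(tads, junctions$chrom_b[i], junctions$pos_b[i]))
  junc_count <- vapply(tads$tad_id, function(t) {
    sum(vapply(seq_len(n), function(i) t %in% tad_sets_a[[i]] || t %in% tad_sets_b[[i]],
               logical(1L)))
  }, 0L)
  inter_count <- vapply(tads$tad_id, function(t) {
    sum(vapply(seq_len(n), function(i) {
      a <- tad_sets_a[[i]]; b <- tad_sets_b[[i]]
      if (!(t %in% a) && !(t %in% b)) return(FALSE)
      if (!length(a) || !length(b)) return(TRUE)
      length(intersect(a, b)) == 0L
    }, logical(1L)))
  }, 0L)
  per_tad <- data.frame(
    tad_id = tads$tad_id, chrom = tads$chrom, start = tads$start, end = tads$end,
    breakpoints = assignment$per_tad$breakpoints,
    junctions = junc_count,
    inter_tad_junctions = inter_count,
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_tad$genes <- if (is.null(genes)) NA_integer_ else genes_in_tads(tads, genes)$genes
  structure(list(
    per_tad = per_tad,
    n_affected_tads = sum(per_tad$breakpoints > 0L),
    n_unassigned_breakpoints = assignment$unassigned,
    n_bridging_junctions = inter_tad_junctions(junctions, tads)
  ), class = "ccr_tad_report")
}

#' @export
print.ccr_tad_report <- function(x, ...) {
  cat(sprintf("TAD report: %d affected TAD(s), %d bridging junction(s), %d unassigned breakpoint(s)\n",
              x$n_affected_tads, x$n_bridging_junctions, x$n_unassigned_breakpoints))
  print(utils::head(x$per_tad[x$per_tad$breakpoints > 0L, , drop = FALSE], 20L),
        row.names = FALSE)
  invisible(x)
}
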