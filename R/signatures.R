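#' Microhomology length at a breakpoint junction
#'
#' Microhomology is short identical sequence shared by both joined segments,
#' which makes the exact break position ambiguous. Both arguments are strings
#' of even length `2w` centred on the respective break: `left_ref` holds the
#' last `w` retained bases of the upstream joined segment followed by its `w`
#' reference continuation bases (the bases that would have followed had the
#' break not occurred); `right_ref` holds the `w` reference bases preceding the
#' downstream segment's start followed by its first `w` retained bases. The
#' returned value is the width of the ambiguous breakpoint range: the maximal
#' number of bases by which the break can slide downstream (entering downstream
#' bases identical to the upstream continuation) plus the symmetric upstream
#' extension. Sequences entering a junction through a reverse-oriented fragment
#' must be supplied reverse-complemented, i.e. in junction reading direction
#' (see [junction_local_sequences()]).
#'
#' @param left_ref,right_ref Junction-centred sequences as described above;
#'   equal even lengths, ACGTN alphabet (`N` never certifies a match).
#' @return Non-negative integer microhomology length.
#' @export
microhomology_length <- function(left_ref, right_ref) {
  left_ref <- check_dna(left_ref, "left_ref")
  right_ref <- check_dna(right_ref, "right_ref")
  if (nchar(left_ref) != nchar(right_ref) || nchar(left_ref) %% 2L != 0L) {
    stopf("left_ref and right_ref must have equal, even lengths")
  }
  w <- nchar(left_ref) %/% 2L
  if (w < 1L) return(0L)
  upstream_retained <- substr(left_ref, 1L, w)
  upstream_cont <- substr(left_ref, w + 1L, 2L * w)
  downstream_prec <- substr(right_ref, 1L, w)
  downstream_entering <- substr(right_ref, w + 1L, 2L * w)
  fwd <- lcp_len(downstream_entering, upstream_cont)
  back <- lcs_len(upstream_retained, downstream_prec)
  as.integer(fwd + back)
}

#' Classify a junction insertion as templated or non-templated
#'
#' An insertion is called templated when a sufficiently long stretch of it is
#' copied from reference sequence near either breakend. Insertions shorter
#' than 20 nt must match in full; for longer insertions a seed of
#' `min_match = 20` nt suffices. Both the insertion and its reverse complement
#' are searched.
#'
#' @param inserted_seq Non-empty inserted nucleotide sequence.
#' @param flank_sequences Character vector of reference sequences around the
#'   breakends (typically the windows returned by [junction_flanks()]).
#' @param min_match Minimum exact-match length; default as described above.
#' @return A list with `templated` (logical), and when templated, `flank`
#'   (index of the matching flank), `offset` (1-based match start within that
#'   flank) and `revcomp` (whether the match is on the reverse strand).
#' @export
classify_insertion <- function(inserted_seq, flank_sequences, min_match = NULL) {
  inserted_seq <- check_dna(inserted_seq, "inserted_seq")
  if (!nzchar(inserted_seq)) stopf("inserted_seq must be non-empty")
  flank_sequences <- vapply(flank_sequences, check_dna, character(1L), what = "flank")
  n <- nchar(inserted_seq)
  if (is.null(min_match)) min_match <- if (n < 20L) n else 20L
  min_match <- min(min_match, n)
  for (rc in c(FALSE, TRUE)) {
    query <- if (rc) revcomp(inserted_seq) else inserted_seq
    for (off in seq_len(n - min_match + 1L)) {
      seed <- substr(query, off, off + min_match - 1L)
      for (k in seq_along(flank_sequences)) {
        hit <- regexpr(seed, flank_sequences[k], fixed = TRUE)
        if (hit > 0L) {
          return(list(templated = TRUE, flank = k, offset = as.integer(hit), revcomp = rc))
        }
      }
    }
  }
  list(templated = FALSE, flank = NA_integer_, offset = NA_integer_, revcomp = NA)
}

#' Reference flanks around a junction's breakends
#'
#' Extracts the reference windows on both sides of both breakends, the search
#' space for templated-insertion classification.
#'
#' @param junction One-row slice of a [ccr_junctions()] table.
#' @param genome A [ccr_genome()] with sequences.
#' @param window Window width in bp on each side of each breakend (default
#'   500).
#' @return Character vector of up to four flank sequences.
#' @export
junction_flanks <- function(junction, genome, window = 500) {
  if (is.null(genome$sequences)) stopf("genome carries no sequences")
  len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  one <- function(chrom, pos) {
    s <- genome$sequences[[chrom]]
    c(substr(s, max(1, pos - window), pos),
      substr(s, pos, min(len[[chrom]], pos + window)))
  }
  c(one(junction$chrom_a, junction$pos_a), one(junction$chrom_b, junction$pos_b))
}

#' Junction-reading-direction local sequences for a breakend pair
#'
#' Builds the `left_ref`/`right_ref` inputs of [microhomology_length()] from
#' the genome: for each breakend the retained sequence and its reference
#' continuation are read in the direction the junction is traversed, reverse
#' complementing when the retained sequence extends toward higher coordinates
#' on the entering side (or when a head-side breakend is exited).
#'
#' @param junction One-row slice of a [ccr_junctions()] table; `end_a` is
#'   taken as the upstream (exited) breakend and `end_b` as the downstream
#'   (entered) breakend.
#' @param genome A [ccr_genome()] with sequences.
#' @param window Scan window `w` in nt (default 20).
#' @return List with elements `left_ref` and `right_ref`, each of length `2w`.
#' @export
junction_local_sequences <- function(junction, genome, window = 20) {
  if (is.null(genome$sequences)) stopf("genome carries no sequences")
  w <- as.integer(window)
  len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  slice <- function(chrom, from, to) {
    if (from < 1 || to > len[[chrom]]) {
      stopf("microhomology window extends beyond chromosome %s", chrom)
    }
    substr(genome$sequences[[chrom]], from, to)
  }
  # upstream breakend: retained block then continuation, junction direction
  upstream <- function(chrom, pos, side) {
    if (side == "tail") {
      paste0(slice(chrom, pos - w + 1L, pos), slice(chrom, pos + 1L, pos + w))
    } else {
      revcomp(paste0(slice(chrom, pos - w, pos - 1L), slice(chrom, pos, pos + w - 1L)))
    }
  }
  # downstream breakend: precedent then entering block, junction direction
  downstream <- function(chrom, pos, side) {
    if (side == "head") {
      paste0(slice(chrom, pos - w, pos - 1L), slice(chrom, pos, pos + w - 1L))
    } else {
      revcomp(paste0(slice(chrom, pos - w + 1L, pos), slice(chrom, pos + 1L, pos + w)))
    }
  }
  list(
    left_ref = upstream(junction$chrom_a, junction$pos_a, junction$side_a),
    right_ref = downstream(junction$chrom_b, junction$pos_b, junction$side_b)
  )
}

#' Reference nucleotides deleted at a junction
#'
#' The deletion at a junction is the reference sequence lost between each fused
#' fragment end and the nearest retained base beyond it: for every breakend the
#' uncovered reference run immediately beyond the break is located, and the
#' union of the (at most two) runs is returned, so a run flanked by both
#' breakends of a collinear fusion counts once. A breakend with no retained
#' base beyond it (terminal loss) contributes nothing. Overlapping fragments
#' are rejected: duplications must be modelled as separate fragments before
#' deletion analysis.
#'
#' @param junction One-row slice of a [ccr_junctions()] table.
#' @param fragments The full [ccr_fragments()] table of the rearrangement.
#' @return Number of deleted reference nucleotides (0 when balanced).
#' @export
junction_deletion <- function(junction, fragments) {
  validate_fragments(fragments, allow_duplications = FALSE)
  run_beyond <- function(chrom, pos, side) {
    sub <- fragments[fragments$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    inside <- sub$start <= pos & sub$end >= pos
    own <- which(inside & (sub$start == pos | sub$end == pos))
    if (any(inside & !(sub$start == pos | sub$end == pos))) {
      stopf("breakend %s:%g lies inside a fragment: overlap must be modelled as separate fragments",
            chrom, pos)
    }
    if (side == "tail") {
      nxt <- sub$start[sub$start > pos]
      if (!length(nxt)) return(NULL)
      lo <- pos + 1; hi <- min(nxt) - 1
    } else {
      prv <- sub$end[sub$end < pos]
      if (!length(prv)) return(NULL)
      lo <- max(prv) + 1; hi <- pos - 1
    }
    if (hi < lo) return(NULL)
    c(lo, hi)
  }
  runs <- list(
    a = run_beyond(junction$chrom_a, junction$pos_a, junction$side_a),
    b = run_beyond(junction$chrom_b, junction$pos_b, junction$side_b)
  )
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) return(0)
  keys <- vapply(seq_along(runs), function(i) {
    ch <- if (names(runs)[i] == "a") junction$chrom_a else junction$chrom_b
    paste(ch, runs[[i]][1L], runs[[i]][2L])
  }, character(1L))
  keep <- !duplicated(keys)
  sum(vapply(runs[keep], function(r) r[2L] - r[1L] + 1, numeric(1L)))
}

.deletion_bins <- data.frame(
  bin = c("balanced", "<10 nt deletion", "<100 nt deletion", "<1000 nt deletion",
          "<10,000 nt deletion", ">10,000 nt deletion"),
  lo = c(0, 1, 10, 100, 1000, 10000),
  hi = c(0, 9, 99, 999, 9999, Inf),
  stringsAsFactors = FALSE
)
.mh_bins <- data.frame(
  bin = c("microhomology, total", "< 2 nt", "2-10 nt"),
  lo = c(1, 1, 2), hi = c(Inf, 1, 10), stringsAsFactors = FALSE
)
.ins_bins <- data.frame(
  bin = c("insertions, total", "< 2 nt", "< 20 nt", "< 100 nt", "> 100 nt"),
  lo = c(1, 1, 2, 20, 100), hi = c(Inf, 1, 19, 99, Inf), stringsAsFactors = FALSE
)

#' Summarize junction signatures into tabulation bins
#'
#' Produces the standard junction-characteristics table: deletion size bins
#' (balanced, then half-open size classes `1-9`, `10-99`, `100-999`,
#' `1000-9999`, `>= 10000` nt), microhomology bins (`1` nt, `2-10` nt) and
#' insertion-length bins (`1`, `2-19`, `20-99`, `>= 100` nt), each with counts
#' and percentages of the total junction count (percentages rounded half-up to
#' integers, as conventionally printed). Every junction falls in exactly one
#' deletion bin; the microhomology and insertion bins partition the junctions
#' that have microhomology or an insertion, respectively.
#'
#' @param junctions A [ccr_junctions()] table with signature fields populated;
#'   an optional logical `templated` column feeds the templated-insertion
#'   count.
#' @return A `data.frame` of class `ccr_signature_summary` with columns
#'   `section`, `bin`, `count`, `pct`.
#' @export
summarize_signatures <- function(junctions) {
  validate_junctions(junctions)
  n <- nrow(junctions)
  pct <- function(k) if (n == 0L) 0 else round_half_up(100 * k / n)
  bin_counts <- function(x, bins) {
    vapply(seq_len(nrow(bins)), function(i) sum(x >= bins$lo[i] & x <= bins$hi[i]), 0L)
  }
  del <- junctions$deleted_nt
  mh <- junctions$microhomology
  ins <- nchar(junctions$inserted_seq)
  templated <- if ("templated" %in% names(junctions)) {
    sum(junctions$templated %in% TRUE)
  } else NA_integer_
  rows <- rbind(
    data.frame(section = "breakpoint", bin = "total", count = n, stringsAsFactors = FALSE),
    data.frame(section = "breakpoint", bin = .deletion_bins$bin,
               count = bin_counts(del, .deletion_bins), stringsAsFactors = FALSE),
    data.frame(section = "microhomology", bin = .mh_bins$bin,
               count = bin_counts(mh, .mh_bins), stringsAsFactors = FALSE),
    data.frame(section = "insertion", bin = .ins_bins$bin,
               count = bin_counts(ins, .ins_bins), stringsAsFactors = FALSE),
    data.frame(section = "insertion", bin = "templated",
               count = templated, stringsAsFactors = FALSE)
  )
  rows$pct <- pct(rows$count)
  class(rows) <- c("ccr_signature_summary", "data.frame")
  rows
}

#' Annotate a junction table with sequence-level signatures
#'
#' Convenience wrapper running [microhomology_length()],
#' [classify_insertion()] and [junction_deletion()] over a whole junction
#' table. Microhomology is only measured for junctions without an insertion
#' (the two are mutually exclusive); templated status only for junctions with
#' one.
#'
#' @param junctions A [ccr_junctions()] table.
#' @param fragments The matching [ccr_fragments()] table (for deletions);
#'   `NULL` keeps the stored `deleted_nt`.
#' @param genome A [ccr_genome()]; sequences are required for microhomology
#'   and templated-insertion annotation, otherwise stored values are kept.
#' @param mh_window Microhomology scan window (nt).
#' @param templated_window Templated-insertion search window (bp).
#' @return The junction table with `microhomology`, `deleted_nt` and a logical
#'   `templated` column refreshed.
#' @export
annotate_junctions <- function(junctions, fragments = NULL, genome = NULL,
                               mh_window = 20, templated_window = 500) {
  n <- nrow(junctions)
  templated <- if ("templated" %in% names(junctions)) junctions$templated else rep(NA, n)
  for (i in seq_len(n)) {
    j <- junctions[i, , drop = FALSE]
    has_ins <- nzchar(j$inserted_seq)
    if (!is.null(genome) && !is.null(genome$sequences)) {
      if (has_ins) {
        flanks <- junction_flanks(j, genome, window = templated_window)
        templated[i] <- classify_insertion(j$inserted_seq, flanks)$templated
        junctions$microhomology[i] <- 0L
      } else {
        loc <- junction_local_sequences(j, genome, window = mh_window)
        junctions$microhomology[i] <- microhomology_length(loc$left_ref, loc$right_ref)
        templated[i] <- NA
      }
    }
    if (!is.null(fragments)) {
      junctions$deleted_nt[i] <- junction_deletion(j, fragments)
    }
  }
  junctions$templated <- templated
  junctions
}
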