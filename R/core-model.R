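#' Domain containers for complex chromosomal rearrangement (CCR) analysis
#'
#' The package represents a rearrangement as three tables plus an optional
#' genome model:
#'
#' * **Fragments** (`ccr_fragments()`): oriented reference intervals, each used
#'   once in a derivative chromosome. 1-based inclusive coordinates.
#' * **Junctions** (`ccr_junctions()`): breakpoint junctions (BPJs), i.e. pairs
#'   of breakends with the junction-level signature fields (inserted sequence,
#'   microhomology, deleted nucleotides).
#' * **Calls** (`ccr_calls()`): technology-labelled SV calls in breakend form.
#' * **Genome** (`ccr_genome()`): chromosome lengths plus gene and TAD
#'   annotation intervals and optional nucleotide sequences.
#'
#' A *breakend* is a (chromosome, position, side) triple. `side = "tail"` means
#' the retained sequence extends toward lower coordinates (the break is at the
#' fragment's high-coordinate end); `side = "head"` means it extends toward
#' higher coordinates. Head is therefore the low-coordinate end of a fragment
#' in reference orientation and a reference-collinear fusion is tail-to-head.
#'
#' @name ccr-model
NULL

.sides <- c("head", "tail")

#' Construct and validate a fragment table
#'
#' @param fragment_id Unique fragment identifiers.
#' @param chrom Chromosome name of each fragment.
#' @param start,end 1-based inclusive reference interval (`start <= end`).
#' @param junction_head,junction_tail Optional ids of the junctions attached at
#'   the fragment's native head (low) and tail (high) end; `NA` for a free
#'   (telomere-bearing) end.
#' @param derivative,orientation Optional placement annotation: the derivative
#'   chromosome the fragment belongs to and its orientation
#'   (`"forward"`/`"reverse"`) within it.
#' @param allow_duplications Permit fragments of one chromosome to overlap.
#'   Only meaningful for rearrangements with duplicated segments
#'   (breakage-fusion-bridge, chromoanasynthesis); defaults to `FALSE` so that
#'   copy-neutral input is validated strictly.
#' @return A `data.frame` of class `ccr_fragments`.
#' @export
ccr_fragments <- function(fragment_id, chrom, start, end,
                          junction_head = NA_character_,
                          junction_tail = NA_character_,
                          derivative = NA_character_,
                          orientation = NA_character_,
                          allow_duplications = FALSE) {
  n <- length(fragment_id)
  df <- data.frame(
    fragment_id = as.character(fragment_id),
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    junction_head = rep_len(as.character(junction_head), n),
    junction_tail = rep_len(as.character(junction_tail), n),
    derivative = rep_len(as.character(derivative), n),
    orientation = rep_len(as.character(orientation), n),
    stringsAsFactors = FALSE
  )
  validate_fragments(df, allow_duplications = allow_duplications)
  class(df) <- c("ccr_fragments", "data.frame")
  df
}

validate_fragments <- function(df, genome = NULL, allow_duplications = FALSE) {
  if (anyDuplicated(df$fragment_id)) {
    stopf("duplicated fragment_id: %s",
          paste(unique(df$fragment_id[duplicated(df$fragment_id)]), collapse = ", "))
  }
  if (any(is.na(df$start) | is.na(df$end))) stopf("fragment start/end must not be NA")
  bad <- df$start > df$end
  if (any(bad)) stopf("fragment %s has start > end", df$fragment_id[which(bad)[1L]])
  if (any(df$start < 1)) stopf("fragment coordinates are 1-based; start < 1 found")
  ok_or <- is.na(df$orientation) | df$orientation %in% c("forward", "reverse")
  if (!all(ok_or)) stopf("orientation must be 'forward' or 'reverse'")
  if (!allow_duplications) {
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      if (nrow(sub) > 1L) {
        ov <- which(sub$start[-1L] <= sub$end[-nrow(sub)])
        if (length(ov)) {
          stopf("fragments %s and %s overlap on %s",
                sub$fragment_id[ov[1L]], sub$fragment_id[ov[1L] + 1L], ch)
        }
      }
    }
  }
  if (!is.null(genome)) {
    len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
    unk <- setdiff(df$chrom, names(len))
    if (length(unk)) stopf("fragment chromosome(s) not in genome: %s", paste(unk, collapse = ", "))
    if (any(df$end > len[df$chrom])) stopf("fragment extends beyond chromosome length")
  }
  invisible(df)
}

#' Construct and validate a junction (BPJ) table
#'
#' Microhomology and inserted sequence are mutually exclusive by construction:
#' the signature bins tabulate them as disjoint categories, so a junction with
#' both is rejected.
#'
#' @param junction_id Unique junction identifiers.
#' @param chrom_a,pos_a,side_a First breakend (chromosome, 1-based position,
#'   side in `"head"`/`"tail"`).
#' @param chrom_b,pos_b,side_b Second breakend.
#' @param inserted_seq Nucleotide sequence inserted at the junction (possibly
#'   empty).
#' @param microhomology Microhomology length in nt (non-negative).
#' @param deleted_nt Reference nucleotides lost at the junction (non-negative).
#' @param supports Comma-separated technology labels supporting the junction.
#' @return A `data.frame` of class `ccr_junctions`.
#' @export
ccr_junctions <- function(junction_id, chrom_a, pos_a, side_a,
                          chrom_b, pos_b, side_b,
                          inserted_seq = "", microhomology = 0L,
                          deleted_nt = 0L, supports = "") {
  n <- length(junction_id)
  df <- data.frame(
    junction_id = as.character(junction_id),
    chrom_a = as.character(chrom_a), pos_a = as.numeric(pos_a),
    side_a = as.character(side_a),
    chrom_b = as.character(chrom_b), pos_b = as.numeric(pos_b),
    side_b = as.character(side_b),
    inserted_seq = rep_len(as.character(inserted_seq), n),
    microhomology = rep_len(as.integer(microhomology), n),
    deleted_nt = rep_len(as.numeric(deleted_nt), n),
    supports = rep_len(as.character(supports), n),
    stringsAsFactors = FALSE
  )
  df$inserted_seq[is.na(df$inserted_seq)] <- ""
  validate_junctions(df)
  class(df) <- c("ccr_junctions", "data.frame")
  df
}

validate_junctions <- function(df) {
  if (anyDuplicated(df$junction_id)) stopf("duplicated junction_id")
  if (!all(df$side_a %in% .sides) || !all(df$side_b %in% .sides)) {
    stopf("breakend sides must be 'head' or 'tail'")
  }
  if (any(df$pos_a < 1 | df$pos_b < 1)) stopf("breakend positions are 1-based; < 1 found")
  if (any(df$microhomology < 0L)) stopf("microhomology must be non-negative")
  if (any(df$deleted_nt < 0)) stopf("deleted_nt must be non-negative")
  both <- nzchar(df$inserted_seq) & df$microhomology > 0L
  if (any(both)) {
    stopf("junction %s has both an insertion and microhomology; these are mutually exclusive",
          df$junction_id[which(both)[1L]])
  }
  invisible(df)
}

#' Construct a technology call record table
#'
#' @param technology Technology label (one per call or a single recycled value).
#' @param chrom_a,pos_a,side_a,chrom_b,pos_b,side_b Breakend pair of each call.
#' @param svtype SV type label; defaults to `"BND"`.
#' @return A `data.frame` of class `ccr_calls`.
#' @export
ccr_calls <- function(technology, chrom_a, pos_a, side_a,
                      chrom_b, pos_b, side_b, svtype = "BND") {
  n <- length(chrom_a)
  df <- data.frame(
    technology = rep_len(as.character(technology), n),
    chrom_a = as.character(chrom_a), pos_a = as.numeric(pos_a),
    side_a = as.character(side_a),
    chrom_b = as.character(chrom_b), pos_b = as.numeric(pos_b),
    side_b = as.character(side_b),
    svtype = rep_len(as.character(svtype), n),
    stringsAsFactors = FALSE
  )
  if (n && (!all(df$side_a %in% .sides) || !all(df$side_b %in% .sides))) {
    stopf("breakend sides must be 'head' or 'tail'")
  }
  class(df) <- c("ccr_calls", "data.frame")
  df
}

#' Construct and validate a genome model
#'
#' @param chromosomes `data.frame` with columns `name` and `length` (bp).
#' @param genes Optional `data.frame` with columns `name`, `chrom`, `start`,
#'   `end` and optionally `strand` (1-based inclusive intervals).
#' @param tads Optional `data.frame` with columns `tad_id`, `chrom`, `start`,
#'   `end`.
#' @param sequences Optional named character vector of per-chromosome
#'   nucleotide sequences; names must match `chromosomes$name` and lengths
#'   must equal the stated chromosome lengths.
#' @return A list of class `ccr_genome`.
#' @export
ccr_genome <- function(chromosomes, genes = NULL, tads = NULL, sequences = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name)) stopf("chromosome names must be unique")
  if (any(chromosomes$length < 1)) stopf("chromosome lengths must be positive")
  len <- stats::setNames(chromosomes$length, chromosomes$name)

  check_intervals <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    unk <- setdiff(df$chrom, names(len))
    if (length(unk)) stopf("%s on unknown chromosome(s): %s", what, paste(unk, collapse = ", "))
    if (any(df$start > df$end)) stopf("%s interval with start > end", what)
    if (any(df$start < 1) || any(df$end > len[df$chrom])) {
      stopf("%s interval outside [1, chromosome length]", what)
    }
    df
  }
  genes <- check_intervals(genes, "gene")
  tads <- check_intervals(tads, "TAD")
  if (!is.null(sequences)) {
    sequences <- vapply(sequences, check_dna, character(1L), what = "chromosome sequence")
    unk <- setdiff(names(sequences), names(len))
    if (length(unk)) stopf("sequence for unknown chromosome(s): %s", paste(unk, collapse = ", "))
    nl <- nchar(sequences)
    if (any(nl != len[names(sequences)])) stopf("sequence length disagrees with chromosome length")
  }
  structure(
    list(chromosomes = chromosomes, genes = genes, tads = tads, sequences = sequences),
    class = "ccr_genome"
  )
}

#' @export
print.ccr_genome <- function(x, ...) {
  cat("ccr_genome:", nrow(x$chromosomes), "chromosome(s),",
      sum(as.numeric(x$chromosomes$length)), "bp total\n")
  cat("  genes:", if (is.null(x$genes)) 0L else nrow(x$genes),
      " TADs:", if (is.null(x$tads)) 0L else nrow(x$tads),
      " sequences:", if (is.null(x$sequences)) "none" else "yes", "\n")
  invisible(x)
}

#' @export
print.ccr_derivative <- function(x, ...) {
  cat("derivative", x$name, "-", nrow(x$chain), "fragment(s),",
      length(x$junctions), "junction(s)\n")
  print(x$chain, ...)
  invisible(x)
}

# Referential-integrity check: every junction id referenced by fragments or
# derivatives must exist in the junction table.
check_junction_refs <- function(fragments, junctions) {
  refs <- stats::na.omit(c(fragments$junction_head, fragments$junction_tail))
  missing <- setdiff(refs, junctions$junction_id)
  if (length(missing)) {
    stopf("junction id(s) referenced but not defined: %s", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
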