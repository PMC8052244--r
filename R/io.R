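#' Read a fragment/junction table (TSV)
#'
#' The fragment table is the package's native serialization of a resolved
#' rearrangement. One row per placed fragment with columns `fragment_id`,
#' `chrom`, `start`, `end`, `orientation` (`+`/`-` or `.`), `derivative`,
#' `junction_id_head`, `junction_id_tail`, `inserted_seq`, `microhomology`,
#' `deleted_nt`. Coordinates are 1-based inclusive. `junction_id_head`/`_tail`
#' name the junction attached at the fragment's native head/tail end (`.` for a
#' free, telomere-bearing end). When `derivative` and `orientation` are given,
#' rows are grouped by derivative in chain order and the three junction
#' signature columns on row *i* describe the junction joining row *i* to row
#' *i + 1* of the same derivative (the last row of each chain leaves them
#' blank). Tables without placement annotation must leave the signature
#' columns blank; junction structure is still recovered from the link columns.
#'
#' @param path Path to a tab-separated file with the header above.
#' @param allow_duplications Accept overlapping fragments (duplicated
#'   segments); see [ccr_fragments()].
#' @return A list with elements `fragments` ([ccr_fragments()]), `junctions`
#'   ([ccr_junctions()]) and `derivative_names` (character).
#' @export
read_fragment_table <- function(path, allow_duplications = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           na.strings = character(), check.names = FALSE)
  required <- c("fragment_id", "chrom", "start", "end", "orientation",
                "derivative", "junction_id_head", "junction_id_tail",
                "inserted_seq", "microhomology", "deleted_nt")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stopf("fragment table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    return(list(fragments = ccr_fragments(character(), character(), numeric(), numeric()),
                junctions = empty_junctions(),
                derivative_names = character()))
  }
  blank <- function(x) !nzchar(x) | x == "."
  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !blank(x))
    if (length(bad)) stopf("malformed %s on line %d of %s", col, bad[1L] + 1L, path)
    out
  }
  start <- num(raw$start, "start")
  end <- num(raw$end, "end")
  if (anyNA(start) || anyNA(end)) {
    stopf("missing start/end on line %d of %s",
          which(is.na(start) | is.na(end))[1L] + 1L, path)
  }
  ori <- ifelse(blank(raw$orientation), NA_character_,
                ifelse(raw$orientation %in% c("+", "forward"), "forward",
                       ifelse(raw$orientation %in% c("-", "reverse"), "reverse", "bad")))
  if (any(ori == "bad", na.rm = TRUE)) {
    stopf("malformed orientation on line %d of %s", which(ori == "bad")[1L] + 1L, path)
  }
  fragments <- ccr_fragments(
    fragment_id = raw$fragment_id,
    chrom = raw$chrom, start = start, end = end,
    junction_head = ifelse(blank(raw$junction_id_head), NA_character_, raw$junction_id_head),
    junction_tail = ifelse(blank(raw$junction_id_tail), NA_character_, raw$junction_id_tail),
    derivative = ifelse(blank(raw$derivative), NA_character_, raw$derivative),
    orientation = ori,
    allow_duplications = allow_duplications
  )

  # Junction structure from the link columns: every junction id must occur on
  # exactly two fragment-end slots.
  occ <- rbind(
    data.frame(junction_id = fragments$junction_head, row = seq_len(nrow(fragments)),
               side = "head", stringsAsFactors = FALSE),
    data.frame(junction_id = fragments$junction_tail, row = seq_len(nrow(fragments)),
               side = "tail", stringsAsFactors = FALSE)
  )
  occ <- occ[!is.na(occ$junction_id), , drop = FALSE]
  occ <- occ[order(occ$row, occ$side == "tail"), , drop = FALSE]
  counts <- table(occ$junction_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad)) {
    stopf("junction id(s) must be referenced by exactly two fragment ends: %s",
          paste(bad, collapse = ", "))
  }
  jids <- unique(occ$junction_id)
  ends <- lapply(jids, function(j) occ[occ$junction_id == j, , drop = FALSE])
  be <- function(e, which) {
    r <- e$row[which]
    list(chrom = fragments$chrom[r],
         pos = end_coord(fragments$start[r], fragments$end[r], e$side[which]),
         side = e$side[which])
  }
  a <- lapply(ends, be, which = 1L)
  b <- lapply(ends, be, which = 2L)

  # Signature attributes via the chain-order convention.
  attrs <- data.frame(junction_id = jids,
                      inserted_seq = "", microhomology = 0L, deleted_nt = 0,
                      stringsAsFactors = FALSE)
  has_attr <- !blank(raw$inserted_seq) | !blank(raw$microhomology) | !blank(raw$deleted_nt)
  placed <- !is.na(fragments$derivative) & !is.na(fragments$orientation)
  if (any(has_attr & !placed)) {
    stopf("junction signature columns require derivative/orientation context (line %d of %s)",
          which(has_attr & !placed)[1L] + 1L, path)
  }
  if (any(placed)) {
    for (d in unique(fragments$derivative[placed])) {
      rows <- which(fragments$derivative %in% d)
      if (length(rows) < 2L) next
      for (i in seq_len(length(rows) - 1L)) {
        r1 <- rows[i]; r2 <- rows[i + 1L]
        ex <- exit_end(fragments$orientation[r1])
        en <- entry_end(fragments$orientation[r2])
        j1 <- if (ex == "head") fragments$junction_head[r1] else fragments$junction_tail[r1]
        j2 <- if (en == "head") fragments$junction_head[r2] else fragments$junction_tail[r2]
        if (is.na(j1) || is.na(j2) || j1 != j2) {
          stopf("rows %d and %d of derivative %s are not linked by a shared junction",
                r1 + 1L, r2 + 1L, d)
        }
        k <- match(j1, attrs$junction_id)
        if (!blank(raw$inserted_seq[r1])) attrs$inserted_seq[k] <- toupper(raw$inserted_seq[r1])
        if (!blank(raw$microhomology[r1])) {
          attrs$microhomology[k] <- as.integer(num(raw$microhomology[r1], "microhomology"))
        }
        if (!blank(raw$deleted_nt[r1])) attrs$deleted_nt[k] <- num(raw$deleted_nt[r1], "deleted_nt")
      }
    }
  }
  junctions <- ccr_junctions(
    junction_id = jids,
    chrom_a = vapply(a, `[[`, "", "chrom"), pos_a = vapply(a, `[[`, 0, "pos"),
    side_a = vapply(a, `[[`, "", "side"),
    chrom_b = vapply(b, `[[`, "", "chrom"), pos_b = vapply(b, `[[`, 0, "pos"),
    side_b = vapply(b, `[[`, "", "side"),
    inserted_seq = attrs$inserted_seq,
    microhomology = attrs$microhomology,
    deleted_nt = attrs$deleted_nt
  )
  check_junction_refs(fragments, junctions)
  list(fragments = fragments, junctions = junctions,
       derivative_names = unique(stats::na.omit(fragments$derivative)))
}

empty_junctions <- function() {
  ccr_junctions(character(), character(), numeric(), character(),
                character(), numeric(), character())
}

#' Write a fragment/junction table (TSV)
#'
#' Inverse of [read_fragment_table()]. When the fragments carry placement
#' annotation (`derivative` and `orientation`), rows are emitted grouped by
#' derivative in chain order and each row carries the signature fields of the
#' junction to the next row.
#'
#' @param fragments A [ccr_fragments()] table.
#' @param junctions A [ccr_junctions()] table; signature fields are written
#'   from here.
#' @param path Output file path.
#' @export
write_fragment_table <- function(fragments, junctions, path) {
  check_junction_refs(fragments, junctions)
  placed <- !is.na(fragments$derivative) & !is.na(fragments$orientation)
  # rows of each derivative go out in chain order, derived from the links
  ord <- integer(0)
  for (d in unique(fragments$derivative[placed])) {
    rows <- which(fragments$derivative %in% d)
    entry_j <- ifelse(entry_end(fragments$orientation[rows]) == "head",
                      fragments$junction_head[rows], fragments$junction_tail[rows])
    exit_j <- ifelse(exit_end(fragments$orientation[rows]) == "head",
                     fragments$junction_head[rows], fragments$junction_tail[rows])
    cur <- which(is.na(entry_j))
    if (length(cur) != 1L) {
      stopf("derivative %s does not have exactly one chain start", d)
    }
    chain <- integer(0)
    while (!is.na(cur)) {
      chain <- c(chain, rows[cur])
      if (is.na(exit_j[cur])) break
      nxt <- match(exit_j[cur], entry_j)
      if (!is.na(nxt) && rows[nxt] %in% chain) stopf("cycle in derivative %s", d)
      cur <- nxt
    }
    if (length(chain) != length(rows)) stopf("derivative %s chain is not connected", d)
    ord <- c(ord, chain)
  }
  ord <- c(ord, which(!placed))
  fr <- fragments[ord, , drop = FALSE]
  n <- nrow(fr)
  ins <- rep("", n); mh <- rep("", n); del <- rep("", n)
  if (any(placed)) {
    for (d in unique(stats::na.omit(fr$derivative))) {
      rows <- which(fr$derivative %in% d)
      if (length(rows) < 2L) next
      for (i in seq_len(length(rows) - 1L)) {
        r1 <- rows[i]
        ex <- exit_end(fr$orientation[r1])
        j <- if (ex == "head") fr$junction_head[r1] else fr$junction_tail[r1]
        k <- match(j, junctions$junction_id)
        if (is.na(k)) next
        ins[r1] <- junctions$inserted_seq[k]
        mh[r1] <- as.character(junctions$microhomology[k])
        del[r1] <- format(junctions$deleted_nt[k], scientific = FALSE)
      }
    }
  }
  dot <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
  out <- data.frame(
    fragment_id = fr$fragment_id, chrom = fr$chrom,
    start = format(fr$start, scientific = FALSE, trim = TRUE),
    end = format(fr$end, scientific = FALSE, trim = TRUE),
    orientation = dot(c("forward" = "+", "reverse" = "-")[fr$orientation]),
    derivative = dot(fr$derivative),
    junction_id_head = dot(fr$junction_head),
    junction_id_tail = dot(fr$junction_tail),
    inserted_seq = dot(ins), microhomology = dot(mh), deleted_nt = dot(del),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write junctions as bedpe
#'
#' Standard bedpe columns `chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2` with 0-based half-open intervals. The internal 1-based
#' breakend position equals the bedpe `end` column. Strand encodes the breakend
#' side: `+` means the retained segment extends toward lower coordinates
#' (tail side), `-` means head side, on both ends. Files without strand columns
#' default every side to tail.
#'
#' @param path bedpe file path.
#' @return `read_bedpe()`: a [ccr_junctions()] table.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_junctions())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L)) {
    stopf("bedpe line %d has fewer than 6 columns", which(ncol < 6L)[1L])
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1L))
  }
  side_of <- function(strand) {
    s <- ifelse(is.na(strand) | strand == ".", "+", strand)
    if (any(!s %in% c("+", "-"))) stopf("bedpe strand must be '+' or '-'")
    ifelse(s == "+", "tail", "head")
  }
  name <- get(7L)
  name <- ifelse(is.na(name) | name == ".", paste0("J", seq_along(fields)), name)
  ccr_junctions(
    junction_id = name,
    chrom_a = get(1L), pos_a = as.numeric(get(3L)), side_a = side_of(get(9L)),
    chrom_b = get(4L), pos_b = as.numeric(get(6L)), side_b = side_of(get(10L))
  )
}

#' @rdname read_bedpe
#' @param junctions A [ccr_junctions()] table to serialize.
#' @export
write_bedpe <- function(junctions, path) {
  strand <- function(side) ifelse(side == "tail", "+", "-")
  out <- data.frame(
    chrom1 = junctions$chrom_a,
    start1 = format(junctions$pos_a - 1, scientific = FALSE, trim = TRUE),
    end1 = format(junctions$pos_a, scientific = FALSE, trim = TRUE),
    chrom2 = junctions$chrom_b,
    start2 = format(junctions$pos_b - 1, scientific = FALSE, trim = TRUE),
    end2 = format(junctions$pos_b, scientific = FALSE, trim = TRUE),
    name = junctions$junction_id, score = ".",
    strand1 = strand(junctions$side_a), strand2 = strand(junctions$side_b),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Bracket notation of one breakend record. `local_side` refers to the record's
# own position, `partner_side` to the mate's.
bnd_alt <- function(partner_chrom, partner_pos, local_side, partner_side) {
  pp <- format(partner_pos, scientific = FALSE, trim = TRUE)
  bracket <- if (partner_side == "head") {
    paste0("[", partner_chrom, ":", pp, "[")
  } else {
    paste0("]", partner_chrom, ":", pp, "]")
  }
  if (local_side == "tail") paste0("N", bracket) else paste0(bracket, "N")
}

#' Read breakend (BND) records from a VCF
#'
#' Supports the BND subset of VCF 4.2: records whose ALT uses bracket
#' notation. Each mate pair is collapsed into a single call. Bracket semantics
#' follow the VCF specification: `t[p[` joins the local sequence ending at POS
#' (tail side) to the partner segment extending right of `p` (head side);
#' `]p]t` joins the partner segment extending left of `p` (tail side) to the
#' local sequence starting at POS (head side), and so on. Mates are paired via
#' the `MATEID` INFO key when present, otherwise by reciprocal coordinates;
#' records without a matching mate are skipped with a warning.
#'
#' @param path VCF file path.
#' @param technology Technology label attached to the resulting calls.
#' @return A [ccr_calls()] table, one row per mate pair.
#' @export
read_vcf_bnd <- function(path, technology = "unknown") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(ccr_calls(character(), character(), numeric(), character(),
                     character(), numeric(), character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 8L)) stopf("VCF body line with fewer than 8 columns")
  rec <- data.frame(
    chrom = vapply(f, `[`, "", 1L),
    pos = as.numeric(vapply(f, `[`, "", 2L)),
    id = vapply(f, `[`, "", 3L),
    alt = vapply(f, `[`, "", 5L),
    info = vapply(f, `[`, "", 8L),
    stringsAsFactors = FALSE
  )
  m <- regmatches(rec$alt, regexec(
    "^([ACGTNacgtn]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
    rec$alt, perl = TRUE))
  is_bnd <- lengths(m) == 7L
  rec <- rec[is_bnd, , drop = FALSE]
  m <- m[is_bnd]
  if (!nrow(rec)) {
    return(ccr_calls(character(), character(), numeric(), character(),
                     character(), numeric(), character()))
  }
  rec$local_side <- ifelse(nzchar(vapply(m, `[`, "", 2L)), "tail", "head")
  rec$p_chrom <- vapply(m, `[`, "", 4L)
  rec$p_pos <- as.numeric(vapply(m, `[`, "", 5L))
  rec$p_side <- ifelse(vapply(m, `[`, "", 3L) == "[", "head", "tail")
  rec$mateid <- sub(".*MATEID=([^;]+).*", "\\1", rec$info)
  rec$mateid[!grepl("MATEID=", rec$info)] <- NA_character_
  rec$svtype <- sub(".*SVTYPE=([^;]+).*", "\\1", rec$info)
  rec$svtype[!grepl("SVTYPE=", rec$info)] <- "BND"

  used <- rep(FALSE, nrow(rec))
  keep <- integer()
  for (i in seq_len(nrow(rec))) {
    if (used[i]) next
    j <- NA_integer_
    if (!is.na(rec$mateid[i])) {
      cand <- which(!used & rec$id == rec$mateid[i])
      if (length(cand)) j <- cand[1L]
    } else {
      cand <- which(!used & seq_len(nrow(rec)) != i &
                      rec$chrom == rec$p_chrom[i] & rec$pos == rec$p_pos[i] &
                      rec$p_chrom == rec$chrom[i] & rec$p_pos == rec$pos[i] &
                      rec$local_side == rec$p_side[i] & rec$p_side == rec$local_side[i])
      if (length(cand)) j <- cand[1L]
    }
    if (is.na(j) || j == i) {
      warning("skipping BND record without a matching mate: ", rec$id[i], call. = FALSE)
      used[i] <- TRUE
      next
    }
    used[c(i, j)] <- TRUE
    keep <- c(keep, i)
  }
  if (!length(keep)) {
    return(ccr_calls(character(), character(), numeric(), character(),
                     character(), numeric(), character()))
  }
  r <- rec[keep, , drop = FALSE]
  ccr_calls(
    technology = technology,
    chrom_a = r$chrom, pos_a = r$pos, side_a = r$local_side,
    chrom_b = r$p_chrom, pos_b = r$p_pos, side_b = r$p_side,
    svtype = r$svtype
  )
}

#' Write calls or junctions as a BND-style VCF
#'
#' Emits two mated BND records per breakend pair with `MATEID` cross
#' references; the inverse of [read_vcf_bnd()].
#'
#' @param x A [ccr_calls()] or [ccr_junctions()] table.
#' @param path Output VCF path.
#' @export
write_vcf_bnd <- function(x, path) {
  is_junc <- inherits(x, "ccr_junctions")
  ids <- if (is_junc) x$junction_id else sprintf("call%d", seq_len(nrow(x)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(0)
  for (i in seq_len(nrow(x))) {
    id1 <- paste0(ids[i], "_1"); id2 <- paste0(ids[i], "_2")
    alt1 <- bnd_alt(x$chrom_b[i], x$pos_b[i], x$side_a[i], x$side_b[i])
    alt2 <- bnd_alt(x$chrom_a[i], x$pos_a[i], x$side_b[i], x$side_a[i])
    p1 <- format(x$pos_a[i], scientific = FALSE, trim = TRUE)
    p2 <- format(x$pos_b[i], scientific = FALSE, trim = TRUE)
    rows <- c(rows,
      paste(x$chrom_a[i], p1, id1, "N", alt1, ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id2), sep = "\t"),
      paste(x$chrom_b[i], p2, id2, "N", alt2, ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", id1), sep = "\t"))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read TAD or gene annotation intervals from BED
#'
#' Thin wrappers over [rtracklayer::import()]: BED's 0-based half-open
#' intervals are converted to the package's 1-based inclusive convention.
#'
#' @param path BED file path.
#' @return `read_tads()`: `data.frame` with `tad_id`, `chrom`, `start`, `end`;
#'   `read_genes()`: `data.frame` with `name`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_tads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    tad_id = if (!is.null(gr$name)) as.character(gr$name) else paste0("tad", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_tads
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    name = if (!is.null(gr$name)) as.character(gr$name) else paste0("gene", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read or write genome sequences as FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()`: a named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @rdname read_genome_fasta
#' @param genome A [ccr_genome()] with non-`NULL` `sequences`.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequences)) stopf("genome carries no sequences")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}
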