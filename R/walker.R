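#' Build the fragment-end graph of a rearrangement
#'
#' Every DNA fragment except the terminal (telomere-bearing) ones is associated
#' with two breakpoint junctions, one at its head and one at its tail, so the
#' fragments form chains fused through the junctions. This function links
#' junction breakends to fragment ends and validates the chain structure:
#' each fragment end may carry at most one junction.
#'
#' Two linkage modes are supported. When the fragment table carries explicit
#' `junction_head`/`junction_tail` ids (the native fragment-table format) those
#' links are used and breakend positions are only validated against the linked
#' ends; this also disambiguates duplicated fragments that share coordinates.
#' Otherwise breakends are matched positionally to fragment ends of the same
#' chromosome and side, within `tolerance` bp.
#'
#' @param fragments A [ccr_fragments()] table.
#' @param junctions A [ccr_junctions()] table.
#' @param tolerance Maximum distance (bp) between a junction breakend and the
#'   fragment end it attaches to. Defaults to 0 (exact), appropriate for
#'   curated tables; raise it for noisy caller-derived input.
#' @return A list of class `ccr_graph` with the fragments and an edge table
#'   (`junction_id`, `frag_a`, `end_a`, `frag_b`, `end_b`).
#' @export
build_fragment_graph <- function(fragments, junctions, tolerance = 0) {
  explicit <- any(!is.na(fragments$junction_head)) || any(!is.na(fragments$junction_tail))
  edges <- if (explicit) {
    link_explicit(fragments, junctions, tolerance)
  } else {
    link_positional(fragments, junctions, tolerance)
  }
  slots <- c(paste(edges$frag_a, edges$end_a), paste(edges$frag_b, edges$end_b))
  dup <- slots[duplicated(slots)]
  if (length(dup)) {
    stopf("fragment end(s) matched by more than one junction: %s",
          paste(unique(dup), collapse = ", "))
  }
  structure(list(fragments = fragments, edges = edges), class = "ccr_graph")
}

link_explicit <- function(fragments, junctions, tolerance) {
  check_junction_refs(fragments, junctions)
  occ <- rbind(
    data.frame(junction_id = fragments$junction_head, frag = fragments$fragment_id,
               side = "head", stringsAsFactors = FALSE),
    data.frame(junction_id = fragments$junction_tail, frag = fragments$fragment_id,
               side = "tail", stringsAsFactors = FALSE)
  )
  occ <- occ[!is.na(occ$junction_id), , drop = FALSE]
  counts <- table(occ$junction_id)
  orphan <- setdiff(junctions$junction_id, names(counts))
  if (length(orphan)) {
    stopf("junction(s) not linked to any fragment end: %s", paste(orphan, collapse = ", "))
  }
  bad <- names(counts)[counts != 2L]
  if (length(bad)) stopf("junction(s) must link exactly two fragment ends: %s",
                         paste(bad, collapse = ", "))
  idx <- match(occ$frag, fragments$fragment_id)
  occ$coord <- end_coord(fragments$start[idx], fragments$end[idx], occ$side)
  occ$chrom <- fragments$chrom[idx]
  out <- do.call(rbind, lapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions$junction_id[i]
    e <- occ[occ$junction_id == j, , drop = FALSE]
    # pair junction breakends with the two linked ends, best assignment first
    d <- function(chrom, pos, side, k) {
      if (chrom != e$chrom[k] || side != e$side[k]) return(Inf)
      abs(pos - e$coord[k])
    }
    straight <- max(d(junctions$chrom_a[i], junctions$pos_a[i], junctions$side_a[i], 1L),
                    d(junctions$chrom_b[i], junctions$pos_b[i], junctions$side_b[i], 2L))
    crossed <- max(d(junctions$chrom_a[i], junctions$pos_a[i], junctions$side_a[i], 2L),
                   d(junctions$chrom_b[i], junctions$pos_b[i], junctions$side_b[i], 1L))
    if (min(straight, crossed) > tolerance) {
      stopf("junction %s breakends do not coincide with the linked fragment ends (tolerance %g bp)",
            j, tolerance)
    }
    o <- if (straight <= crossed) c(1L, 2L) else c(2L, 1L)
    data.frame(junction_id = j,
               frag_a = e$frag[o[1L]], end_a = e$side[o[1L]],
               frag_b = e$frag[o[2L]], end_b = e$side[o[2L]],
               stringsAsFactors = FALSE)
  }))
  out %||% data.frame(junction_id = character(), frag_a = character(), end_a = character(),
                      frag_b = character(), end_b = character(), stringsAsFactors = FALSE)
}

link_positional <- function(fragments, junctions, tolerance) {
  find_end <- function(chrom, pos, side, j) {
    coord <- end_coord(fragments$start, fragments$end, side)
    hit <- which(fragments$chrom == chrom & abs(coord - pos) <= tolerance)
    if (!length(hit)) {
      stopf("junction %s breakend %s:%g (%s) matches no fragment end (tolerance %g bp)",
            j, chrom, pos, side, tolerance)
    }
    if (length(hit) > 1L) {
      stopf("junction %s breakend %s:%g (%s) matches several fragment ends: %s",
            j, chrom, pos, side, paste(fragments$fragment_id[hit], collapse = ", "))
    }
    hit
  }
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    ia <- find_end(junctions$chrom_a[i], junctions$pos_a[i], junctions$side_a[i],
                   junctions$junction_id[i])
    ib <- find_end(junctions$chrom_b[i], junctions$pos_b[i], junctions$side_b[i],
                   junctions$junction_id[i])
    data.frame(junction_id = junctions$junction_id[i],
               frag_a = fragments$fragment_id[ia], end_a = junctions$side_a[i],
               frag_b = fragments$fragment_id[ib], end_b = junctions$side_b[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(junction_id = character(), frag_a = character(), end_a = character(),
               frag_b = character(), end_b = character(), stringsAsFactors = FALSE)
}

graph_free_ends <- function(graph) {
  fr <- graph$fragments
  all_ends <- rbind(
    data.frame(frag = fr$fragment_id, side = "head", chrom = fr$chrom,
               coord = fr$start, stringsAsFactors = FALSE),
    data.frame(frag = fr$fragment_id, side = "tail", chrom = fr$chrom,
               coord = fr$end, stringsAsFactors = FALSE)
  )
  used <- c(paste(graph$edges$frag_a, graph$edges$end_a),
            paste(graph$edges$frag_b, graph$edges$end_b))
  free <- all_ends[!(paste(all_ends$frag, all_ends$side) %in% used), , drop = FALSE]
  free[order(free$chrom, free$coord, free$frag, free$side), , drop = FALSE]
}

#' Walk one derivative chromosome from a terminal fragment
#'
#' Starting at a terminal fragment's free end, the walk crosses the fragment,
#' follows the junction attached at the opposite end to the next fragment, and
#' repeats until a fragment with a free exit end terminates the chain. A
#' fragment entered at its head is reported `forward`; entered at its tail,
#' `reverse`. Cycles are an error: germline derivative chromosomes are linear.
#'
#' @param graph A `ccr_graph` from [build_fragment_graph()].
#' @param start_fragment Fragment id at which to start.
#' @param start_end Which native end of the start fragment to begin from
#'   (`"head"` or `"tail"`); it must be free (not attached to a junction).
#' @param name Optional name for the derivative.
#' @return A list of class `ccr_derivative`: `name`, `chain` (`data.frame` with
#'   `index`, `fragment_id`, `chrom`, `start`, `end`, `orientation`) and
#'   `junctions` (ids, in chain order, length `nrow(chain) - 1`).
#' @export
walk_derivative <- function(graph, start_fragment, start_end = c("head", "tail"),
                            name = NULL) {
  start_end <- match.arg(start_end)
  fr <- graph$fragments
  if (!start_fragment %in% fr$fragment_id) stopf("unknown fragment: %s", start_fragment)
  free <- graph_free_ends(graph)
  if (!any(free$frag == start_fragment & free$side == start_end)) {
    stopf("fragment %s (%s end) is not terminal: it is attached to a junction",
          start_fragment, start_end)
  }
  edges <- graph$edges
  edge_at <- function(frag, side) {
    which((edges$frag_a == frag & edges$end_a == side) |
            (edges$frag_b == frag & edges$end_b == side))
  }
  chain_frag <- character(); chain_ori <- character(); chain_j <- character()
  cur <- start_fragment; enter <- start_end
  repeat {
    if (cur %in% chain_frag) {
      stopf("cycle detected while walking: fragment %s revisited", cur)
    }
    chain_frag <- c(chain_frag, cur)
    chain_ori <- c(chain_ori, if (enter == "head") "forward" else "reverse")
    ex <- other_side(enter)
    e <- edge_at(cur, ex)
    if (!length(e)) break
    chain_j <- c(chain_j, edges$junction_id[e])
    if (edges$frag_a[e] == cur && edges$end_a[e] == ex) {
      cur <- edges$frag_b[e]; enter <- edges$end_b[e]
    } else {
      cur <- edges$frag_a[e]; enter <- edges$end_a[e]
    }
  }
  idx <- match(chain_frag, fr$fragment_id)
  chain <- data.frame(
    index = seq_along(chain_frag),
    fragment_id = chain_frag,
    chrom = fr$chrom[idx], start = fr$start[idx], end = fr$end[idx],
    orientation = chain_ori,
    stringsAsFactors = FALSE
  )
  structure(list(name = name %||% paste0("der(", chain$chrom[1L], ")"),
                 chain = chain, junctions = chain_j),
            class = "ccr_derivative")
}

#' Reconstruct all derivative chromosomes
#'
#' Builds the fragment graph and walks every chain. Walks start
#' deterministically from the free fragment end with the lexicographically
#' smallest (chromosome, coordinate, fragment id) key, so output ordering is
#' reproducible. Every fragment must end up in exactly one derivative;
#' fragments trapped in cycles are reported as an error.
#'
#' @inheritParams build_fragment_graph
#' @return A list of `ccr_derivative` objects. Derivative names are
#'   `der(<chromosome of the starting terminal fragment>)`, suffixed when a
#'   chromosome anchors several chains.
#' @export
reconstruct_all <- function(fragments, junctions, tolerance = 0) {
  graph <- build_fragment_graph(fragments, junctions, tolerance = tolerance)
  free <- graph_free_ends(graph)
  visited <- character()
  out <- list()
  while (nrow(free)) {
    top <- free[1L, ]
    der <- walk_derivative(graph, top$frag, top$side)
    out[[length(out) + 1L]] <- der
    visited <- c(visited, der$chain$fragment_id)
    drop <- free$frag %in% der$chain$fragment_id
    free <- free[!drop, , drop = FALSE]
  }
  leftover <- setdiff(graph$fragments$fragment_id, visited)
  if (length(leftover)) {
    stopf("fragment(s) not reachable from any terminal end (cyclic structure?): %s",
          paste(leftover, collapse = ", "))
  }
  nm <- vapply(out, function(d) d$name, character(1L))
  if (anyDuplicated(nm)) {
    for (u in unique(nm[duplicated(nm)])) {
      at <- which(nm == u)
      for (k in seq_along(at)) out[[at[k]]]$name <- paste0(u, ".", k)
    }
  }
  out
}

#' Tabulate placed fragments across derivatives
#'
#' Flattens a list of derivatives into one row per placed fragment, mirroring
#' the per-derivative segment listings of a resolved rearrangement.
#'
#' @param derivatives A list of `ccr_derivative` objects (or a single one).
#' @return `data.frame` with columns `derivative`, `index`, `fragment_id`,
#'   `chrom`, `start`, `end`, `orientation`.
#' @export
placed_fragments <- function(derivatives) {
  if (inherits(derivatives, "ccr_derivative")) derivatives <- list(derivatives)
  do.call(rbind, lapply(derivatives, function(d) {
    cbind(data.frame(derivative = d$name, stringsAsFactors = FALSE), d$chain)
  }))
}
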