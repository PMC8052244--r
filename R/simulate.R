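#' Generate a synthetic genome model
#'
#' Builds a deterministic (per seed) genome for simulation: chromosomes of the
#' requested lengths, non-overlapping genes placed one per equal-width slot,
#' TADs tiling each chromosome with a small inter-TAD gap, and optional random
#' nucleotide sequence.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length (bp) per chromosome; scalar or vector.
#' @param genes_per_chrom Genes per chromosome.
#' @param gene_length Gene length range `c(min, max)` in bp (uniform); a
#'   scalar gives fixed-length genes.
#' @param tad_length TAD tile width in bp.
#' @param tad_gap Fraction of each tile left uncovered between TADs.
#' @param with_sequence Generate random ACGT sequence per chromosome.
#' @param seed Mandatory RNG seed.
#' @param chrom_names Optional chromosome names (default `chr1..chrN`).
#' @return A [ccr_genome()].
#' @export
make_genome <- function(n_chrom = 4, chrom_length = 1e7, genes_per_chrom = 35,
                        gene_length = c(2e4, 2e5), tad_length = 1e6,
                        tad_gap = 0.1, with_sequence = FALSE, seed,
                        chrom_names = NULL) {
  if (missing(seed)) stopf("a seed is required")
  lens <- rep_len(chrom_length, n_chrom)
  nms <- chrom_names %||% paste0("chr", seq_len(n_chrom))
  if (length(gene_length) == 1L) gene_length <- c(gene_length, gene_length)
  with_seed(seed, {
    genes <- list(); tads <- list(); seqs <- NULL
    for (ci in seq_len(n_chrom)) {
      L <- lens[ci]
      if (genes_per_chrom > 0L) {
        slot <- floor(L / genes_per_chrom)
        if (slot < gene_length[2L]) {
          stopf("infeasible gene density: slot width %d < max gene length %g",
                slot, gene_length[2L])
        }
        gl <- round(stats::runif(genes_per_chrom, gene_length[1L], gene_length[2L]))
        off <- floor(stats::runif(genes_per_chrom) * (slot - gl + 1))
        gstart <- (seq_len(genes_per_chrom) - 1L) * slot + off + 1
        genes[[ci]] <- data.frame(
          name = sprintf("g_%s_%03d", nms[ci], seq_len(genes_per_chrom)),
          chrom = nms[ci], start = gstart, end = gstart + gl - 1,
          strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE),
          stringsAsFactors = FALSE
        )
      }
      n_t <- floor(L / tad_length)
      if (n_t > 0L) {
        pad <- round(tad_length * tad_gap / 2)
        tads[[ci]] <- data.frame(
          tad_id = sprintf("tad_%s_%03d", nms[ci], seq_len(n_t)),
          chrom = nms[ci],
          start = (seq_len(n_t) - 1L) * tad_length + pad + 1,
          end = seq_len(n_t) * tad_length - pad,
          stringsAsFactors = FALSE
        )
      }
      if (with_sequence) {
        seqs <- c(seqs, stats::setNames(random_dna(L), nms[ci]))
      }
    }
    ccr_genome(
      chromosomes = data.frame(name = nms, length = lens, stringsAsFactors = FALSE),
      genes = if (length(genes)) do.call(rbind, genes) else NULL,
      tads = if (length(tads)) do.call(rbind, tads) else NULL,
      sequences = seqs
    )
  })
}

# --- shared simulation internals (all called inside with_seed) ---------------

split_counts <- function(n, m) {
  base <- rep(n %/% m, m)
  extra <- n %% m
  if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

draw_positions <- function(lo, hi, n, min_sep = 200) {
  if (n == 0L) return(numeric(0))
  span <- hi - lo + 1
  if (span < n * min_sep) {
    stopf("requested %d breaks exceed window capacity [%g, %g] at %g bp separation",
          n, lo, hi, min_sep)
  }
  for (attempt in seq_len(200L)) {
    p <- sort(lo - 1 + sample.int(span, n))
    if (n < 2L || all(diff(p) >= min_sep)) return(p)
  }
  stopf("could not place %d breakpoints with %g bp separation in [%g, %g]",
        n, min_sep, lo, hi)
}

# Cut one chromosome at `positions` (fragment i ends at positions[i]); the
# `deletions[i]` bases after each cut are lost. Returns n+1 fragment intervals.
shatter_chrom <- function(L, positions, deletions) {
  n <- length(positions)
  if (n == 0L) return(data.frame(start = 1, end = L))
  gap_cap <- c(diff(positions), L - positions[n]) - 1
  deletions <- pmin(deletions, pmax(gap_cap, 0))
  data.frame(start = c(1, positions + deletions + 1), end = c(positions, L))
}

# Uncovered reference runs around retained fragments of one chromosome:
# for each fragment, the run after its tail and before its head (NULL if none).
gap_runs <- function(frags) {
  frags <- frags[order(frags$start), , drop = FALSE]
  n <- nrow(frags)
  after <- vector("list", n); before <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (frags$start[i + 1L] > frags$end[i] + 1) {
        run <- c(frags$end[i] + 1, frags$start[i + 1L] - 1)
        after[[i]] <- run
        before[[i + 1L]] <- run
      }
    }
  }
  list(ids = frags$fragment_id, after = after, before = before)
}

# Assemble derivative chromosomes from per-chromosome shattered fragments.
# Each involved chromosome anchors one derivative with its two terminal
# fragments; interior fragments are pooled, optionally dropped, shuffled,
# assigned uniformly to derivatives and oriented per `orientation`.
assemble_ccr <- function(genome, chrom_frag_list, orientation = c("uniform", "forward"),
                         lost_frac = 0, dup_n = 0L) {
  orientation <- match.arg(orientation)
  chroms <- names(chrom_frag_list)
  frags <- do.call(rbind, lapply(chroms, function(ch) {
    f <- chrom_frag_list[[ch]]
    data.frame(fragment_id = sprintf("F_%s_%03d", ch, seq_len(nrow(f))),
               chrom = ch, start = f$start, end = f$end,
               interior = seq_len(nrow(f)) != 1L & seq_len(nrow(f)) != nrow(f),
               stringsAsFactors = FALSE)
  }))
  interiors <- frags$fragment_id[frags$interior]
  if (lost_frac > 0 && length(interiors)) {
    n_drop <- round(lost_frac * length(interiors))
    if (n_drop > 0L) {
      drop <- sample(interiors, n_drop)
      frags <- frags[!frags$fragment_id %in% drop, , drop = FALSE]
      interiors <- setdiff(interiors, drop)
    }
  }
  runs <- list()
  for (ch in chroms) runs[[ch]] <- gap_runs(frags[frags$chrom == ch, , drop = FALSE])
  run_beyond <- function(frag_id, chrom, side) {
    r <- runs[[chrom]]
    k <- match(frag_id, r$ids)
    if (is.na(k)) return(NULL)  # duplicated copy: same runs as its original
    if (side == "tail") r$after[[k]] else r$before[[k]]
  }

  n_der <- length(chroms)
  pool <- sample(interiors)
  der_of <- if (length(pool)) sample(n_der, length(pool), replace = TRUE) else integer(0)
  chains <- lapply(seq_len(n_der), function(d) {
    ch <- chroms[d]
    sub <- frags[frags$chrom == ch & !frags$interior, , drop = FALSE]
    left <- sub$fragment_id[which.min(sub$start)]
    right <- sub$fragment_id[which.max(sub$start)]
    mid <- pool[der_of == d]
    ids <- c(left, if (length(sub$fragment_id) > 1L) NULL, mid, right)
    if (left == right) ids <- c(left, mid)  # unshattered chromosome: one terminal
    ori <- rep("forward", length(ids))
    if (orientation == "uniform" && length(mid)) {
      ori[ids %in% mid] <- sample(c("forward", "reverse"), length(mid), replace = TRUE)
    }
    list(ids = ids, ori = ori)
  })

  # duplicated copies of interior fragments (chromoanasynthesis-style)
  dup_map <- character(0)
  if (dup_n > 0L && length(interiors)) {
    dup_src <- sample(interiors, min(dup_n, length(interiors)))
    for (s in dup_src) {
      new_id <- paste0(s, "_dup")
      dup_map <- c(dup_map, stats::setNames(s, new_id))
      d <- sample(length(chains), 1L)
      len <- length(chains[[d]]$ids)
      at <- 1L + sample.int(len - 1L, 1L)  # strictly inside the chain
      chains[[d]]$ids <- append(chains[[d]]$ids, new_id, after = at - 1L)
      chains[[d]]$ori <- append(chains[[d]]$ori, "forward", after = at - 1L)
      src <- frags[frags$fragment_id == s, , drop = FALSE]
      src$fragment_id <- new_id
      frags <- rbind(frags, src)
    }
  }

  # junctions along every chain
  jrows <- list(); jid_n <- 0L
  frags$junction_head <- NA_character_
  frags$junction_tail <- NA_character_
  frags$derivative <- NA_character_
  frags$orientation <- NA_character_
  derivatives <- list()
  for (d in seq_len(n_der)) {
    ids <- chains[[d]]$ids; ori <- chains[[d]]$ori
    dname <- paste0("der(", chroms[d], ")")
    idx <- match(ids, frags$fragment_id)
    frags$derivative[idx] <- dname
    frags$orientation[idx] <- ori
    jids <- character(0)
    if (length(ids) > 1L) {
      for (k in seq_len(length(ids) - 1L)) {
        jid_n <- jid_n + 1L
        jid <- sprintf("J%03d", jid_n)
        jids <- c(jids, jid)
        i1 <- idx[k]; i2 <- idx[k + 1L]
        ex <- exit_end(ori[k]); en <- entry_end(ori[k + 1L])
        if (ex == "head") frags$junction_head[i1] <- jid else frags$junction_tail[i1] <- jid
        if (en == "head") frags$junction_head[i2] <- jid else frags$junction_tail[i2] <- jid
        src1 <- dup_map[ids[k]]; src2 <- dup_map[ids[k + 1L]]
        r1 <- run_beyond(if (is.na(src1)) ids[k] else src1, frags$chrom[i1], ex)
        r2 <- run_beyond(if (is.na(src2)) ids[k + 1L] else src2, frags$chrom[i2], en)
        rr <- list(); if (!is.null(r1)) rr$a <- c(frags$chrom[i1], r1)
        if (!is.null(r2)) rr$b <- c(frags$chrom[i2], r2)
        keys <- vapply(rr, paste, character(1L), collapse = ":")
        rr <- rr[!duplicated(keys)]
        del <- sum(vapply(rr, function(r) as.numeric(r[3L]) - as.numeric(r[2L]) + 1,
                          numeric(1L)))
        jrows[[jid_n]] <- data.frame(
          junction_id = jid,
          chrom_a = frags$chrom[i1],
          pos_a = end_coord(frags$start[i1], frags$end[i1], ex), side_a = ex,
          chrom_b = frags$chrom[i2],
          pos_b = end_coord(frags$start[i2], frags$end[i2], en), side_b = en,
          deleted_nt = del,
          dup_adjacent = ids[k] %in% names(dup_map) || ids[k + 1L] %in% names(dup_map),
          stringsAsFactors = FALSE
        )
      }
    }
    chain <- data.frame(index = seq_along(ids), fragment_id = ids,
                        chrom = frags$chrom[idx], start = frags$start[idx],
                        end = frags$end[idx], orientation = ori,
                        stringsAsFactors = FALSE)
    derivatives[[d]] <- structure(list(name = dname, chain = chain, junctions = jids),
                                  class = "ccr_derivative")
  }
  jdf <- do.call(rbind, jrows)
  list(fragments = frags, junctions = jdf, derivatives = derivatives,
       dup_ids = names(dup_map))
}

finalize_sim <- function(genome, asm, mechanism, jextra, seed, params,
                         has_duplications = FALSE, terminal_loss = FALSE) {
  fr <- ccr_fragments(
    fragment_id = asm$fragments$fragment_id, chrom = asm$fragments$chrom,
    start = asm$fragments$start, end = asm$fragments$end,
    junction_head = asm$fragments$junction_head,
    junction_tail = asm$fragments$junction_tail,
    derivative = asm$fragments$derivative, orientation = asm$fragments$orientation,
    allow_duplications = has_duplications
  )
  j <- asm$junctions
  jc <- ccr_junctions(
    junction_id = j$junction_id,
    chrom_a = j$chrom_a, pos_a = j$pos_a, side_a = j$side_a,
    chrom_b = j$chrom_b, pos_b = j$pos_b, side_b = j$side_b,
    inserted_seq = jextra$inserted_seq, microhomology = jextra$microhomology,
    deleted_nt = j$deleted_nt
  )
  jc$templated <- jextra$templated
  structure(list(
    genome = genome, fragments = fr, junctions = jc,
    derivatives = asm$derivatives, mechanism = mechanism,
    has_duplications = has_duplications, terminal_loss = terminal_loss,
    params = params, seed = seed
  ), class = "ccr_sim")
}

#' @export
print.ccr_sim <- function(x, ...) {
  cat(sprintf("simulated %s: %d fragment(s), %d junction(s), %d derivative(s) [seed %s]\n",
              x$mechanism, nrow(x$fragments), nrow(x$junctions),
              length(x$derivatives), format(x$seed)))
  invisible(x)
}

# Annotation draws shared by the end-joining mechanisms: a fraction of
# junctions carries non-templated insertions, the rest little/no microhomology.
nhej_signatures <- function(n_junctions, insertion_prob) {
  has_ins <- stats::runif(n_junctions) < insertion_prob
  ins_len <- round(exp(stats::runif(n_junctions, log(1), log(200))))
  ins <- ifelse(has_ins,
                vapply(ins_len, random_dna, character(1L)),
                "")
  mh <- ifelse(has_ins, 0L,
               sample(0:4, n_junctions, replace = TRUE,
                      prob = c(0.55, 0.15, 0.1, 0.1, 0.1)))
  list(inserted_seq = ins, microhomology = as.integer(mh),
       templated = ifelse(has_ins, FALSE, NA))
}

#' Simulate a chromothripsis rearrangement
#'
#' One catastrophic, localized shattering of one to three chromosomes:
#' breakpoints cluster inside a random window per chromosome, a fraction of
#' interior fragments is lost, the rest are shuffled and rejoined in uniform
#' random orientation. Junction deletions additionally arise from sequence lost
#' at the cut points (log-uniform sizes over `deletion_range` for the
#' non-balanced fraction). Junctions carry NHEJ-like signatures: non-templated
#' insertions with probability `insertion_prob`, otherwise 0-4 nt of
#' microhomology.
#'
#' @param genome A [ccr_genome()].
#' @param chroms Chromosomes to shatter (at most 3).
#' @param n_breaks Total number of breakpoints, split across `chroms`.
#' @param window_frac Clustering window width as a fraction of each chromosome.
#' @param balanced_prob Probability that a cut is balanced (no deletion);
#'   default 0.36.
#' @param deletion_range Log-uniform deletion size bounds in nt; default
#'   `c(1, 26000)`, matching the observed 1 bp - 26 kbp range.
#' @param lost_frac Fraction of interior fragments lost entirely.
#' @param insertion_prob Probability a junction carries an insertion.
#' @param seed Mandatory RNG seed.
#' @return A `ccr_sim` truth object.
#' @export
simulate_chromothripsis <- function(genome, chroms = genome$chromosomes$name[1:2],
                                    n_breaks = 30, window_frac = 0.2,
                                    balanced_prob = 0.36,
                                    deletion_range = c(1, 26000),
                                    lost_frac = 0.1, insertion_prob = 0.39, seed) {
  if (missing(seed)) stopf("a seed is required")
  if (length(chroms) > 3L) stopf("chromothripsis is modelled on at most 3 chromosomes")
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  with_seed(seed, {
    per <- split_counts(n_breaks, length(chroms))
    frag_list <- list()
    for (k in seq_along(chroms)) {
      L <- lens[[chroms[k]]]
      W <- max(floor(window_frac * L), 1)
      lo <- 1 + floor(stats::runif(1) * (L - W))
      pos <- draw_positions(lo, lo + W - 1, per[k], min_sep = 200)
      del <- ifelse(stats::runif(per[k]) < balanced_prob, 0,
                    round(exp(stats::runif(per[k], log(deletion_range[1L]),
                                           log(deletion_range[2L])))))
      frag_list[[chroms[k]]] <- shatter_chrom(L, pos, del)
    }
    asm <- assemble_ccr(genome, frag_list, orientation = "uniform",
                        lost_frac = lost_frac)
    jextra <- nhej_signatures(nrow(asm$junctions), insertion_prob)
    finalize_sim(genome, asm, "chromothripsis", jextra, seed,
                 params = list(chroms = chroms, n_breaks = n_breaks,
                               window_frac = window_frac,
                               balanced_prob = balanced_prob,
                               deletion_range = deletion_range,
                               lost_frac = lost_frac))
  })
}

#' Simulate a chromoplexy rearrangement
#'
#' A chained, largely balanced rearrangement across several (> 2) chromosomes
#' with breakpoints biased into genes: with probability `intragenic_bias` a
#' breakpoint falls uniformly inside a random gene of its chromosome, otherwise
#' uniformly on the chromosome. Junction deletions are small (uniform over
#' `deletion_range` for the non-balanced fraction); fragments are exchanged
#' across chromosomes copy-neutrally with uniform orientation, and junctions
#' carry NHEJ-like signatures.
#'
#' @inheritParams simulate_chromothripsis
#' @param chroms Chromosomes involved (at least 3).
#' @param intragenic_bias Probability a breakpoint is placed inside a gene.
#' @param deletion_range Uniform deletion size bounds in nt (default
#'   `c(1, 100)`).
#' @export
simulate_chromoplexy <- function(genome, chroms = genome$chromosomes$name[1:4],
                                 n_breaks = 40, intragenic_bias = 0.85,
                                 balanced_prob = 0.5, deletion_range = c(1, 100),
                                 insertion_prob = 0.39, seed) {
  if (missing(seed)) stopf("a seed is required")
  if (length(chroms) < 3L) stopf("chromoplexy involves more than 2 chromosomes")
  if (is.null(genome$genes)) stopf("chromoplexy simulation needs gene annotation")
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  with_seed(seed, {
    per <- split_counts(n_breaks, length(chroms))
    frag_list <- list()
    for (k in seq_along(chroms)) {
      ch <- chroms[k]; L <- lens[[ch]]
      g <- genome$genes[genome$genes$chrom == ch, , drop = FALSE]
      pos <- numeric(0)
      for (attempt in seq_len(500L)) {
        need <- per[k] - length(pos)
        if (need <= 0L) break
        in_gene <- stats::runif(need) < intragenic_bias & nrow(g) > 0L
        p <- numeric(need)
        for (i in seq_len(need)) {
          if (in_gene[i]) {
            gi <- sample.int(nrow(g), 1L)
            p[i] <- g$start[gi] + floor(stats::runif(1) * (g$end[gi] - g$start[gi] + 1))
          } else {
            p[i] <- 1 + floor(stats::runif(1) * L)
          }
        }
        cand <- sort(unique(c(pos, p)))
        cand <- cand[cand > 200 & cand < L - 200]
        keep <- c(TRUE, diff(cand) >= 200)
        pos <- cand[keep]
        if (length(pos) >= per[k]) { pos <- pos[seq_len(per[k])]; break }
      }
      if (length(pos) < per[k]) stopf("could not place %d breakpoints on %s", per[k], ch)
      del <- ifelse(stats::runif(per[k]) < balanced_prob, 0,
                    round(stats::runif(per[k], deletion_range[1L], deletion_range[2L])))
      frag_list[[ch]] <- shatter_chrom(L, pos, del)
    }
    asm <- assemble_ccr(genome, frag_list, orientation = "uniform", lost_frac = 0)
    jextra <- nhej_signatures(nrow(asm$junctions), insertion_prob)
    finalize_sim(genome, asm, "chromoplexy", jextra, seed,
                 params = list(chroms = chroms, n_breaks = n_breaks,
                               intragenic_bias = intragenic_bias,
                               balanced_prob = balanced_prob,
                               deletion_range = deletion_range))
  })
}

#' Simulate breakage-fusion-bridge (BFB) cycles
#'
#' Iterative per-chromatid model: starting from a chromosome that has lost its
#' distal telomere, each cycle breaks the current chain at a random position,
#' discards the distal part and fuses the retained part to its own inverted
#' copy. Every junction is therefore a fold-back (head-to-head or tail-to-tail)
#' fusion and segments become duplicated; the terminal-loss flag is set.
#' Duplicated fragment copies receive distinct ids, so the output requires
#' duplication-aware validation.
#'
#' @param genome A [ccr_genome()].
#' @param chrom Chromosome undergoing the cycles.
#' @param n_cycles Number of breakage-fusion-bridge cycles (>= 1).
#' @param seed Mandatory RNG seed.
#' @param max_fragments Safety cap on chain growth.
#' @return A `ccr_sim` truth object.
#' @export
simulate_bfb <- function(genome, chrom = genome$chromosomes$name[1L],
                         n_cycles = 12, seed, max_fragments = 5000) {
  if (missing(seed)) stopf("a seed is required")
  if (n_cycles < 1L) stopf("n_cycles must be >= 1")
  L <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
  with_seed(seed, {
    p0 <- round(L * stats::runif(1, 0.1, 0.9))
    chain <- data.frame(start = 1, end = p0, orientation = "forward",
                        stringsAsFactors = FALSE)
    for (cy in seq_len(n_cycles)) {
      flen <- chain$end - chain$start + 1
      M <- sum(flen)
      if (M < 4) break
      cum <- cumsum(flen)
      # the break falls in the distal half of the bridge, so the retained
      # (centromere-proximal) chain keeps growing across cycles
      draw_u <- function() ceiling(M / 2) + floor(stats::runif(1) * (M - 1 - ceiling(M / 2) + 1))
      u <- draw_u()
      for (attempt in seq_len(50L)) {
        k0 <- which(cum >= u)[1L]
        if (2L * k0 <= max_fragments) break
        u <- 1 + floor(stats::runif(1) * (M - 2))
      }
      k <- which(cum >= u)[1L]
      w <- u - c(0, cum)[k]  # bases of fragment k retained
      f <- chain[k, ]
      piece <- if (f$orientation == "forward") {
        data.frame(start = f$start, end = f$start + w - 1, orientation = "forward",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(start = f$end - w + 1, end = f$end, orientation = "reverse",
                   stringsAsFactors = FALSE)
      }
      retained <- rbind(chain[seq_len(k - 1L), , drop = FALSE], piece)
      mirror <- retained[rev(seq_len(nrow(retained))), , drop = FALSE]
      mirror$orientation <- ifelse(mirror$orientation == "forward", "reverse", "forward")
      chain <- rbind(retained, mirror)
      if (nrow(chain) > max_fragments) {
        stopf("BFB chain exceeded %d fragments; reduce n_cycles", max_fragments)
      }
    }
    n <- nrow(chain)
    ids <- sprintf("F%04d", seq_len(n))
    jh <- rep(NA_character_, n); jt <- rep(NA_character_, n)
    jrows <- list()
    for (k in seq_len(n - 1L)) {
      jid <- sprintf("J%03d", k)
      ex <- exit_end(chain$orientation[k]); en <- entry_end(chain$orientation[k + 1L])
      if (ex == "head") jh[k] <- jid else jt[k] <- jid
      if (en == "head") jh[k + 1L] <- jid else jt[k + 1L] <- jid
      jrows[[k]] <- data.frame(
        junction_id = jid,
        chrom_a = chrom, pos_a = end_coord(chain$start[k], chain$end[k], ex),
        side_a = ex,
        chrom_b = chrom, pos_b = end_coord(chain$start[k + 1L], chain$end[k + 1L], en),
        side_b = en,
        deleted_nt = 0, dup_adjacent = FALSE, stringsAsFactors = FALSE
      )
    }
    dname <- paste0("der(", chrom, ")")
    asm <- list(
      fragments = data.frame(
        fragment_id = ids, chrom = chrom, start = chain$start, end = chain$end,
        interior = FALSE, junction_head = jh, junction_tail = jt,
        derivative = dname, orientation = chain$orientation,
        stringsAsFactors = FALSE
      ),
      junctions = do.call(rbind, jrows),
      derivatives = list(structure(list(
        name = dname,
        chain = data.frame(index = seq_len(n), fragment_id = ids, chrom = chrom,
                           start = chain$start, end = chain$end,
                           orientation = chain$orientation, stringsAsFactors = FALSE),
        junctions = vapply(jrows, function(r) r$junction_id, character(1L))
      ), class = "ccr_derivative"))
    )
    n_j <- if (is.null(asm$junctions)) 0L else nrow(asm$junctions)
    jextra <- list(inserted_seq = rep("", n_j), microhomology = rep(0L, n_j),
                   templated = rep(NA, n_j))
    finalize_sim(genome, asm, "bfb", jextra, seed,
                 params = list(chrom = chrom, n_cycles = n_cycles),
                 has_duplications = TRUE, terminal_loss = TRUE)
  })
}

#' Simulate a chromoanasynthesis (replicative) rearrangement
#'
#' Replication-based catastrophic rearrangement with non-clustered breakpoints:
#' fragments are rejoined collinearly with planted 2-10 nt microhomology at
#' most junctions, templated insertions copied from within 500 bp of a
#' breakend with probability `templated_prob` among insertion-bearing
#' junctions, and a fraction of interior fragments duplicated. Requires genome
#' sequence: microhomology is physically planted by editing the reference so
#' that sequence-level re-analysis recovers it.
#'
#' @inheritParams simulate_chromothripsis
#' @param chroms Chromosomes involved (default 2).
#' @param mh_range Candidate microhomology lengths (nt).
#' @param insertion_prob Probability a junction carries an insertion instead of
#'   microhomology.
#' @param templated_prob Probability an insertion is templated from nearby
#'   sequence.
#' @param dup_frac Fraction of interior fragments duplicated.
#' @return A `ccr_sim`; its `genome` element carries the edited sequences.
#' @export
simulate_chromoanasynthesis <- function(genome, chroms = genome$chromosomes$name[1:2],
                                        n_breaks = 12, mh_range = 2:10,
                                        insertion_prob = 0.5, templated_prob = 0.5,
                                        dup_frac = 0.15, seed) {
  if (missing(seed)) stopf("a seed is required")
  if (is.null(genome$sequences)) {
    stopf("chromoanasynthesis simulation needs genome sequences (make_genome(with_sequence = TRUE))")
  }
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  mh_max <- max(mh_range)
  with_seed(seed, {
    per <- split_counts(n_breaks, length(chroms))
    frag_list <- list()
    for (k in seq_along(chroms)) {
      L <- lens[[chroms[k]]]
      pos <- draw_positions(600, L - 600, per[k], min_sep = 200)
      # deletions of at least 25 nt keep each junction's microhomology scan
      # window inside lost sequence, so planted edits never interfere
      del <- sample(25:80, per[k], replace = TRUE)
      frag_list[[chroms[k]]] <- shatter_chrom(L, pos, del)
    }
    n_interior <- sum(vapply(frag_list, nrow, 0L)) - 2L * length(chroms)
    dup_n <- max(1L, round(dup_frac * n_interior))
    asm <- assemble_ccr(genome, frag_list, orientation = "forward",
                        lost_frac = 0, dup_n = dup_n)
    j <- asm$junctions
    n_j <- nrow(j)
    seqs <- genome$sequences
    base_other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    put <- function(chrom, at, value) {
      substr(seqs[[chrom]], at, at + nchar(value) - 1L) <<- value
    }
    get1 <- function(chrom, from, to) substr(seqs[[chrom]], from, to)

    has_ins <- stats::runif(n_j) < insertion_prob | j$dup_adjacent
    mh <- integer(n_j)
    for (i in which(!has_ins)) {
      k <- mh_range[sample.int(length(mh_range), 1L)]
      eA <- j$pos_a[i]; chA <- j$chrom_a[i]
      sB <- j$pos_b[i]; chB <- j$chrom_b[i]
      put(chB, sB, get1(chA, eA + 1L, eA + k))              # plant the overlap
      put(chB, sB + k, base_other(get1(chA, eA + k + 1L, eA + k + 1L)))
      put(chB, sB - 1L, base_other(get1(chA, eA, eA)))      # block extension
      mh[i] <- k
    }
    is_templated <- has_ins & stats::runif(n_j) < templated_prob
    ins <- rep("", n_j)
    for (i in which(has_ins)) {
      if (is_templated[i]) {
        len <- sample(25:60, 1L)
        off <- sample(30:400, 1L)
        src <- get1(j$chrom_a[i], j$pos_a[i] - off - len + 1L, j$pos_a[i] - off)
        ins[i] <- if (stats::runif(1) < 0.5) revcomp(src) else src
      } else {
        ins[i] <- random_dna(sample(20:80, 1L))
      }
    }
    genome2 <- ccr_genome(genome$chromosomes, genome$genes, genome$tads, seqs)
    jextra <- list(inserted_seq = ins, microhomology = mh,
                   templated = ifelse(has_ins, is_templated, NA))
    finalize_sim(genome2, asm, "chromoanasynthesis", jextra, seed,
                 params = list(chroms = chroms, n_breaks = n_breaks,
                               mh_range = mh_range, insertion_prob = insertion_prob,
                               templated_prob = templated_prob, dup_frac = dup_frac),
                 has_duplications = TRUE, terminal_loss = FALSE)
  })
}

#' Degrade a truth junction set into a technology call set
#'
#' Emulates per-technology calling behaviour: each truth junction is emitted
#' with probability `sensitivity`, both breakend positions jittered by rounded
#' zero-mean Gaussian noise of standard deviation `position_jitter_sd` (clamped
#' to the chromosome), plus uniformly placed false-positive calls at a rate of
#' `fp_per_mbp` per megabase of genome.
#'
#' @param truth A [ccr_junctions()] truth set (e.g. from a `ccr_sim`).
#' @param genome The matching [ccr_genome()].
#' @param technology Label for the call set.
#' @param sensitivity Per-junction detection probability.
#' @param fp_per_mbp Expected false positives per Mbp (Poisson).
#' @param position_jitter_sd Positional noise sd in bp.
#' @param seed Mandatory RNG seed.
#' @return A [ccr_calls()] table.
#' @export
make_noisy_callset <- function(truth, genome, technology = "tech",
                               sensitivity = 0.9, fp_per_mbp = 0.1,
                               position_jitter_sd = 0, seed) {
  if (missing(seed)) stopf("a seed is required")
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  with_seed(seed, {
    kept <- which(stats::runif(nrow(truth)) < sensitivity)
    jit <- function(pos, chrom) {
      p <- round(pos + stats::rnorm(length(pos), 0, position_jitter_sd))
      pmin(pmax(p, 1), lens[chrom])
    }
    calls <- data.frame(
      chrom_a = truth$chrom_a[kept], pos_a = jit(truth$pos_a[kept], truth$chrom_a[kept]),
      side_a = truth$side_a[kept],
      chrom_b = truth$chrom_b[kept], pos_b = jit(truth$pos_b[kept], truth$chrom_b[kept]),
      side_b = truth$side_b[kept],
      stringsAsFactors = FALSE
    )
    n_fp <- stats::rpois(1L, fp_per_mbp * sum(lens) / 1e6)
    if (n_fp > 0L) {
      rand_be <- function(n) {
        ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
        data.frame(chrom = ch, pos = 1 + floor(stats::runif(n) * lens[ch]),
                   side = sample(c("head", "tail"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
      }
      a <- rand_be(n_fp); b <- rand_be(n_fp)
      calls <- rbind(calls, data.frame(
        chrom_a = a$chrom, pos_a = a$pos, side_a = a$side,
        chrom_b = b$chrom, pos_b = b$pos, side_b = b$side,
        stringsAsFactors = FALSE
      ))
    }
    ccr_calls(technology, calls$chrom_a, calls$pos_a, calls$side_a,
              calls$chrom_b, calls$pos_b, calls$side_b)
  })
}
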