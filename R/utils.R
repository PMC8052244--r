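# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Rounds .5 away from zero, matching how the tabulated percentages are printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(abs(x) * p + 0.5) / p * sign(x)
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) {
    stop(what, " contains non-ACGTN characters", call. = FALSE)
  }
  toupper(x)
}

# Longest common prefix / suffix length of two equal-purpose strings.
# "N" is treated as never matching (an unknown base cannot certify ambiguity).
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1L]]
  bv <- strsplit(substr(b, 1L, n), "")[[1L]]
  ok <- av == bv & av != "N"
  if (all(ok)) n else which(!ok)[1L] - 1L
}

lcs_len <- function(a, b) {
  ra <- paste(rev(strsplit(a, "")[[1L]]), collapse = "")
  rb <- paste(rev(strsplit(b, "")[[1L]]), collapse = "")
  lcp_len(ra, rb)
}

# Coordinate of a fragment's native end; broadcasts a scalar side over vectors.
end_coord <- function(start, end, side) {
  n <- max(length(start), length(end), length(side))
  ifelse(rep_len(side, n) == "head", rep_len(start, n), rep_len(end, n))
}

other_side <- function(side) ifelse(side == "head", "tail", "head")

# Exit/entry ends of a placed fragment given its orientation.
exit_end <- function(orientation) ifelse(orientation == "forward", "tail", "head")
entry_end <- function(orientation) ifelse(orientation == "forward", "head", "tail")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
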