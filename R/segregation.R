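#' Enumerate gametes of a carrier of balanced rearrangements
#'
#' Models alternate / adjacent-I style meiotic segregation for a carrier of one
#' or more independent balanced rearrangements: every involved homolog pair
#' contributes exactly one chromosome to the gamete, either the normal or the
#' derivative homolog (3:1 segregation and recombination within the
#' multivalent are outside this model). A gamete is chromosomally balanced iff,
#' within every rearrangement group, the choices are homogeneous: all normal or
#' all derivative (any mixture leaves that rearrangement's reciprocal exchanges
#' unbalanced).
#'
#' @param groups List of character vectors; each vector names the chromosomes
#'   participating in one rearrangement (size >= 2). Groups must be disjoint.
#' @return A `data.frame` of class `ccr_gametes` with one column per involved
#'   chromosome (values `"normal"`/`"derivative"`) and a logical `balanced`
#'   column; `2^(total chromosomes)` rows.
#' @export
enumerate_gametes <- function(groups) {
  if (is.character(groups)) groups <- list(groups)
  chroms <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(chroms)) {
    stopf("rearrangement groups must be disjoint; repeated: %s",
          paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  if (any(lengths(groups) < 2L)) stopf("every rearrangement group needs >= 2 chromosomes")
  if (!length(chroms)) {
    out <- data.frame(balanced = TRUE)
    class(out) <- c("ccr_gametes", "data.frame")
    return(out)
  }
  choices <- rep(list(c("normal", "derivative")), length(chroms))
  names(choices) <- chroms
  out <- expand.grid(choices, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$balanced <- Reduce(`&`, lapply(groups, function(g) {
    sub <- out[, g, drop = FALSE]
    apply(sub == "normal", 1L, all) | apply(sub == "derivative", 1L, all)
  }))
  class(out) <- c("ccr_gametes", "data.frame")
  attr(out, "groups") <- groups
  out
}

#' Balanced fraction of an enumerated gamete set
#'
#' For `g` independent rearrangement groups over `c` chromosomes the closed
#' form is `2^g / 2^c`; this computes the fraction from the enumeration.
#'
#' @param gametes Output of [enumerate_gametes()].
#' @return List with `n_total`, `n_balanced`, `fraction` and `percent`.
#' @export
balanced_fraction <- function(gametes) {
  if (!nrow(gametes)) stopf("gamete table is empty")
  n <- nrow(gametes)
  k <- sum(gametes$balanced)
  list(n_total = n, n_balanced = k, fraction = k / n, percent = 100 * k / n)
}
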