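---
title: "Resolving and interpreting complex chromosomal rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving and interpreting complex chromosomal rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrsolve)
```

## The analysis model

A complex chromosomal rearrangement (CCR) is described here by two tables. A
*fragment* is a 1-based inclusive reference interval used once in a derivative
chromosome; a *breakpoint junction* (BPJ) is a pair of *breakends*, each a
(chromosome, position, side) triple. `side = "head"` means the retained
sequence extends toward higher coordinates (the low-coordinate end of a
fragment in reference orientation), `side = "tail"` the opposite. A
reference-collinear fusion is therefore tail-to-head. These conventions fix
the four fusion-orientation classes (tail-to-head, head-to-tail, head-to-head,
tail-to-tail) used throughout.

Except for the two telomere-bearing terminal fragments of each derivative,
every fragment carries one junction at its head and one at its tail, so the
junction set induces chains of fragments. `reconstruct_all()` walks these
chains: starting from a terminal (free) fragment end, it crosses the fragment,
follows the junction at the opposite end, and repeats; a fragment entered at
its head is reported `forward`, at its tail `reverse`. The walk is a faithful
formalization of the "walking" procedure used to assemble derivative
chromosomes from curated junction tables.

Numerical choices in the walker:

* **Breakend-to-fragment-end matching tolerance** defaults to 0 bp: curated
  tables are exact. A `tolerance` argument admits sloppier, caller-derived
  input. When the fragment table carries explicit junction link columns those
  are used instead of positional matching, which also disambiguates duplicated
  fragment copies that share coordinates (breakage-fusion-bridge output).
* **Cycles are an error**, never silently broken: germline derivative
  chromosomes are linear, so a cycle indicates an inconsistent junction set.
* **Deterministic start order**: chains are walked from the free end with the
  lexicographically smallest (chromosome, coordinate, fragment id) key, making
  output ordering reproducible.

## Junction signatures

The nucleotide-level signature of a junction carries the imprint of the repair
mechanism. Three quantities are computed:

* `microhomology_length()` measures the width of the ambiguous breakpoint
  range: the number of positions the break can slide while reproducing the
  observed junction sequence, summed over the downstream and upstream
  directions (a symmetric definition; one-sided conventions exist, so the
  choice is declared rather than inferred). The scan window defaults to 20 nt,
  comfortably above the few-nucleotide microhomology that end-joining repair
  leaves while keeping windows local. `N` bases never certify a match.
* `classify_insertion()` calls an insertion *templated* when a seed of at
  least `min_match` nucleotides occurs exactly (or reverse-complemented) in
  the reference within 500 bp of either breakend. Insertions shorter than
  20 nt must match in full; longer ones need a 20-nt seed, making a chance hit
  (probability about $4^{-20}$ per position) negligible. The 500-bp window
  formalizes "templated from nearby sequence" and is configurable.
* `junction_deletion()` reports the reference sequence lost at a junction: the
  uncovered run immediately beyond each breakend, with the union taken so a
  run flanked by both breakends of a collinear fusion counts once. A breakend
  with no retained sequence beyond it (terminal loss) contributes nothing.
  Overlapping fragments are rejected here; duplications must be modelled as
  separate fragments.

`summarize_signatures()` bins these into the conventional table: deletion size
classes (balanced, 1–9, 10–99, 100–999, 1000–9999, ≥ 10000 nt), microhomology
classes (1 nt, 2–10 nt) and insertion-length classes (1, 2–19, 20–99,
≥ 100 nt). The bin edges are half-open and mutually exclusive, so each
junction lands in exactly one deletion class; percentages use the total
junction count as denominator and are rounded half-up to integers, matching
how such tables are conventionally printed. Microhomology and insertions are
stored as mutually exclusive fields, since signature tables tabulate them as
disjoint categories.

## Statistical assessment

All binomial tests are **exact one-sided tails** — sums of point
probabilities, never a normal approximation. The direction is chosen toward
the observed deviation, with a declared tie rule: at $k = np_0$ exactly, the
lower tail is used. The exact tail is what reproduces published per-cell
p-values in this kind of analysis; online calculators based on normal
approximations do not reproduce all of them, which is why the package computes
its own.

* `fragment_distribution_test()` asks whether fragments of each origin
  chromosome spread uniformly over the derivatives: for origin $o$ and
  derivative $d$, $k$ = fragments of $o$ on $d$, $n$ = all fragments of $o$,
  $p_0 = 1/(\#\text{derivatives})$.
* `orientation_tests()` tests each fusion class per derivative with $n$ = the
  derivative's junction count and $p_0 = 1/4$. The trial count is the number
  of junctions (adjacent fragment pairs), the quantity whose four classes sum
  to $n$; using fragment counts would make the class counts and trials
  inconsistent.
* `foldback_enrichment()` pools head-to-head and tail-to-tail fusions
  ($p_0 = 1/2$), the orientation signature of breakage-fusion-bridge cycles.
* `monte_carlo_intragenic()` draws, per iteration, the observed number of
  junctions with both breakends uniform over the concatenated involved
  chromosomes and reports $p$ = fraction of iterations with *strictly more*
  intragenic junctions than observed (a junction is intragenic when either
  breakend lies in a gene, inclusive bounds). No pseudocount is added, exactly
  as the procedure is usually worded; a zero estimate is reported as
  $p < 1/\text{iterations}$. The generator is seeded once per call and leaves
  the caller's RNG stream untouched, so results are bit-reproducible.

One calibration subtlety: the intragenic count is discrete, so under the null
the strictly-greater p-value is sub-uniform by the tie mass. The test suite
therefore calibrates the *randomized* p-value
$(\#\{>\} + U\,\#\{=\})/\text{iterations}$, the standard discreteness-aware
construction; the reported p-value keeps the plain strictly-greater rule.

## Mechanism classification

Literature descriptions of CCR-forming mechanisms are narrative. The package
formalizes them as an explicit decision table over a deterministic feature
vector (`extract_features()`): chromosomes involved, duplications present
(overlapping fragments), fraction of junctions with templated insertions and
with 2–10 nt microhomology, fraction near-balanced (deletion < 1 kbp), the
fold-back *enrichment* (upper-tail) probability, the Monte Carlo intragenic
p-value, a breakpoint clustering statistic (variance-to-mean ratio of 1-Mbp
window counts — about 1 for Poisson scatter, large for localized shattering)
and a terminal-loss flag. Criteria per mechanism (`score_mechanisms()`):

| mechanism | criteria |
|---|---|
| BFB | fold-back enrichment $p < \alpha$; terminal loss |
| chromothripsis | clustering > 5; ≤ 3 chromosomes; no duplications |
| replicative (chromoanasynthesis / FoSTeS / MMBIR) | duplications or templated insertions; 2–10 nt microhomology fraction ≥ 0.2 |
| chromoplexy | intragenic enrichment $p < \alpha$; near-balanced fraction ≥ 0.8; > 2 chromosomes |

Each mechanism scores (#satisfied − #violated); the verdict is the argmax,
ties reported as ties. The thresholds ($\alpha = 0.05$, clustering 5,
balanced 0.8, microhomology 0.2) are declared package constants
(`mechanism_thresholds()`), a formalization rather than a published
prescription; the microhomology threshold is set at 0.2 so that a small
replicative rearrangement with one 2–10 nt microhomology junction among five
qualifies. Chromoanasynthesis and generic replicative error are merged into
one category because their operational boundary — both show templated
insertions and microhomology, duplications are frequent but not obligate in
small events — is not sharp enough for a count-based table to separate.

The fold-back feature deliberately uses the upper-tail probability rather
than the direction-toward-deviation p-value: a rearrangement *depleted* of
fold-back fusions would otherwise produce a small p and look BFB-like.

## Meiotic segregation

`enumerate_gametes()` models alternate/adjacent-I-style segregation: every
involved homolog pair contributes exactly one chromosome, normal or
derivative, giving $2^c$ gametes for $c$ involved chromosomes. A gamete is
balanced iff each rearrangement group is homogeneous (all normal or all
derivative), so $2^g$ of them are balanced for $g$ independent rearrangements.
A carrier of a 4-chromosome plus a 2-chromosome rearrangement thus has
$4/64 = 6.25\%$ balanced gametes versus $2/4 = 50\%$ for a simple reciprocal
translocation — the arithmetic behind fertility problems in such carriers.
3:1 segregation and recombination within the multivalent are deliberately out
of scope of this model.

## TAD disruption and call-set benchmarking

TAD intersection uses point containment for breakpoints (the tabix-style
query) and ≥ 1 bp overlap for genes; a breakpoint in nested/overlapping TADs
increments each, and a junction *bridges* TADs when its ends share no
containing TAD, including the one-end-outside case (how junctions with one
unassignable breakend are counted is a declared choice — they are counted).

`match_calls()` implements the standard truth-set comparison: a call
represents a junction when both breakend distances (same chromosome,
corresponding ends, better of the two orderings) are within 100 kbp; a call
near several junctions counts only toward the closest, *closest* meaning the
minimal sum of the two end distances with ties broken by junction id.
Orientation is ignored — matching is purely positional, as distance-based SV
merging tools behave. Calls are not consumed: detection asks whether a truth
junction has at least one representing call, not for a one-to-one pairing.

## What the simulator emulates — and what it does not

The simulators generate fully annotated truth (fragments with links,
junctions with signatures, derivative chains) so that every pipeline stage
can be exercised and checked for *exact* recovery:

* `simulate_chromothripsis()`: breakpoints clustered in a random window per
  chromosome (default window 20% of the chromosome, ≤ 3 chromosomes), uniform
  re-orientation and shuffling, 36% balanced cuts and log-uniform deletion
  sizes on [1, 26000] nt otherwise — the observed 1 bp–26 kbp deletion range
  of a large germline CCR — plus 10% of interior fragments lost outright.
* `simulate_chromoplexy()`: ≥ 3 chromosomes, breakpoints placed inside genes
  with probability 0.85 (a strong transcription-coupled bias) and uniformly
  otherwise, small deletions (≤ 100 nt, half balanced), copy-neutral
  cross-chromosome chaining, uniform orientation.
* `simulate_bfb()`: per-chromatid breakage-fusion-bridge cycles; each cycle
  breaks the bridge in its distal half, discards the acentric part and folds
  the retained chain back on itself. Every junction is a fold-back fusion,
  segments are duplicated (distinct ids per copy) and the terminal loss flag
  is set. Sister-chromatid dynamics are not modelled; the orientation
  signature is what the classifier needs.
* `simulate_chromoanasynthesis()`: non-clustered breaks, collinear rejoining,
  planted 2–10 nt microhomology (physically edited into the genome sequence so
  sequence re-analysis recovers the planted length exactly — junction
  deletions of ≥ 25 nt keep each 20-nt microhomology scan window inside lost
  sequence so plants never interfere), templated insertions copied from
  within 500 bp of a breakend, and duplicated interior fragments.
* `make_noisy_callset()`: per-technology degradation — Bernoulli sensitivity,
  Gaussian positional jitter, uniform Poisson false positives — emulating the
  qualitative behaviour of short-read, long-read, linked-read and optical-map
  pipelines (resolution and sensitivity differences), not any specific caller.

Junction signature fields in the annotation-only simulators (chromothripsis,
chromoplexy) are simulated labels, not sequence-derived; only the
chromoanasynthesis simulator plants signatures into actual sequence. Passing
tests on simulated data therefore demonstrate the pipeline's internal
consistency and statistical behaviour under the stated generative models —
not performance on real genomes, where repeat structure, reference errors and
caller-specific artifacts dominate. Breakpoint placement is also independent
of replication timing and 3D contact structure, both of which shape real CCR
breakpoints.

Default problem sizes were chosen to be statistically informative at desk
scale: 4 × 10 Mbp annotation genomes (gene coverage ≈ 35%, 1-Mbp TADs at 90%
coverage), 30–40 breakpoints per simulated CCR, 2 × 400 kbp sequence genomes
for nucleotide-level simulation, 250–1000 Monte Carlo iterations, and 50
seeds per mechanism for the recovery properties.

## Known limitations

* The fragment-table TSV stores junction signature fields on the row of the
  upstream fragment in chain order, so signature columns require placement
  (derivative/orientation) context; unplaced tables carry structure only.
* Only the BND subset of VCF is read or written; symbolic `<DEL>`-style
  records, CRAM/BAM evidence and liftover are out of scope.
* The classifier is a transparent decision table, not a probabilistic mixture
  model: it reports criteria satisfaction, not posterior probabilities, and
  inherits the declared thresholds.
* `balanced_fraction()`'s closed form ($2^g/2^c$) assumes independent
  rearrangement groups and two-choice segregation; aneuploid (3:1) modes would
  need a different model.
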