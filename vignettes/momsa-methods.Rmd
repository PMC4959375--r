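---
title: "Multiobjective multiple sequence alignment with momsa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective multiple sequence alignment with momsa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momsa)
```

## The problem

A multiple sequence alignment (MSA) of $m$ sequences $A_1, \dots, A_m$ over a
residue alphabet $\Sigma$ is an $m$-tuple of equal-length rows
$B_1, \dots, B_m$ over $\Sigma \cup \{\text{-}\}$ such that (i) all rows have
the same length, (ii) deleting the indel characters from row $i$ recovers
$A_i$ exactly, and (iii) no column consists only of indels.  Classical
aligners collapse alignment quality into one weighted score, typically a
substitution score minus a gap penalty; the weighting is arbitrary, and a
single "best" alignment hides how the trade-off between similarity and gap
count shapes the result.

`momsa` instead treats the two ingredients as separate objectives.  For a
column $j$ let

$$S_s(j) = \sum_{1 \le i < k \le m} s(b_{i,j}, b_{k,j}), \qquad
  S_d(j) = \sum_{1 \le i < k \le m} d(b_{i,j}, b_{k,j}),$$

where $s(\cdot,\cdot)$ is a substitution-matrix score over residue pairs and
$d(\cdot,\cdot)$ is 1 for a residue/indel pair and 0 otherwise.  The
biobjective sum-of-pairs score of an alignment $\phi$ is

$$BSP(\phi) = \Bigl(\; \textstyle\sum_j S_s(j) \;\uparrow,\;
                 \sum_j S_d(j) \;\downarrow \Bigr),$$

with the substitution component maximized and the indel-pair count
minimized.  An alignment dominates another when it is at least as good in
both components and strictly better in one.  The deliverable is not a
single alignment but an approximation of the *non-dominated score set*: one
representative alignment per non-dominated $(BSP_s, BSP_d)$ vector,
returned as a Pareto archive.

### Gap-pair conventions

Read literally, $d$ could also count indel/indel pairs.  The default here
is $d(\text{-},\text{-}) = 0$, which makes all-gap columns score-neutral
(consistent with deleting them) and preserves the exact identity
$SP = BSP_s + W_d \cdot BSP_d$ linking the classical weighted sum-of-pairs
score $SP$ (gap weight $W_d$) to the score vector.  The literal reading is
available via `count_double_gaps = TRUE`; the identity then no longer
holds, which is why it is not the default.  Scores are exact integers
throughout — matrices are integral and both objectives are sums of integer
cells — so there is no floating-point drift anywhere in the scoring or in
the hypervolume computations.

## The k-block neighborhood

Local search needs a move that rearranges gaps without destroying
feasibility.  Two alignments are *k-block neighbors* when they have the
same size, differ in exactly one row, and the residues whose positions
differ number at most $k$ and sit at contiguous positions in both
alignments.  Operationally (`block_moves()`, `apply_move()`): a contiguous
block of at most $k$ residues in one row slides across the indel run
immediately adjacent to it, by 1 up to the full run length, to the right or
to the left.  Because residue order is preserved and other rows are fixed,
a block can never travel past another residue, so the slide realization and
the positional definition coincide; the test suite verifies this
equivalence against a brute-force enumerator (`brute_force_neighbors()`)
that rewrites rows wholesale and checks the conditions directly.

Moves can create all-gap columns (for instance when the only residue of a
column slides away); these are deleted immediately, which can make two
distinct moves collapse onto the same neighbor.  `neighbors()` therefore
returns the stripped, deduplicated set.  Enumeration order is a fixed
sweep — rows top to bottom, block start left to right, block size
ascending, right shifts before left shifts, increasing distance — so the
search is reproducible under a seed.  The sweep is applied to every row:
the neighbor conditions allow any single row to differ, and restricting
moves to the first row would make the neighborhood depend on input order.

Within a search step the move list is generated per expanded alignment and
consumed one move at a time, interleaved with archive insertion, so the
archive update happens as the stream is produced.

## Pareto local search

`pls()` keeps an archive of mutually non-dominated score vectors, one
representative alignment each, with an explored flag.  One iteration picks
an unexplored entry uniformly at random, enumerates its full k-block
neighborhood, and offers every neighbor to the archive: a neighbor is
accepted iff its score vector is neither dominated by nor equal to an
archived vector, and acceptance evicts the entries it dominates.  The
search terminates naturally when every entry is explored — the archive is
then a *Pareto local optimal set*: re-sweeping every archived alignment's
neighborhood accepts nothing (`verify_local_optimum()` checks exactly
this).  A random draw among unexplored entries is equivalent to the
"fewest prior expansions" rule, because an entry is expanded at most once
and evicted entries never return (equal score vectors are rejected).

Keeping one representative per score vector bounds memory and matches the
non-dominated-score-set semantics, at a price: the search cannot drift
along equal-score plateaus.  This is a deliberate trade-off, and the
perturbation layer below is what compensates for it.

Starting alignments matter.  `random_start()` pads every sequence to the
length of the longest one with uniformly placed indels (the longest
sequence receives none), producing feasible alignments of the minimum
possible length — and hence the minimum possible indel count for that
length family.  Higher-quality starts from external aligners (Clustal
Omega, T-Coffee) can be supplied as aligned FASTA or Clustal files via
`read_alignment()`; running those programs is outside this package's
scope.  Starting alignments always seed the search: a start whose score is
dominated is still expanded, it just does not enter the archive.

## Pareto iterated local search

k-block moves conserve the total gap count (stripping can only lower it),
so plain PLS can never reach score vectors that need *more* gaps than its
starts carry, and it gets trapped in Pareto local optimal sets.  `pils()`
escapes both ways: it repeatedly (1) selects up to `perturb_select = 5`
archived alignments whose score vectors are spread across the front —
sorting by indel count and taking the entries at the 0, ¼, ½, ¾ and 1
quantile positions (deduplicated, topped up at random), so both extremes
are always included — (2) inserts one indel run of length `gap_size` at a
uniformly random position into every row of each selected alignment,
(3) restarts PLS from the perturbed set alone, and (4) accepts by merging
the new archive into the old one and filtering dominated scores.  The
merge-and-filter acceptance makes the archive's hypervolume non-decreasing
across rounds, an invariant the tests audit on every run.

The budget is split equally: each inner PLS run is capped at
$\text{budget}/(P+1)$, in evaluations or wall-clock seconds.  With a
finite budget the perturbation loop runs until the budget is exhausted, so
$P$ governs the granularity — small $P$ gives few deep PLS runs, large $P$
many shallow ones.  With an unbounded budget exactly $P$ rounds run, each
inner PLS to natural termination; `P = 0` is plain PLS either way.  The
budget-driven loop is the behavior of iterated local search under a global
time limit; the fixed-round variant is its deterministic degenerate case,
convenient for small reproducible examples.

Evaluation-count budgets make runs exactly reproducible: identical inputs,
configuration and seed give byte-identical archives.  Wall-clock budgets
mirror CPU-time-limited experiments but are inherently machine-dependent.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | `"Min"` | block-size bound; fractional specifiers `Min`, `Min/2`, …, `Min/16` resolve as $\lceil \mathrm{Min}/c \rceil$ (floor 1) against the shortest sequence length |
| `P` | 4 | budget-slice divisor / round count (see above) |
| `perturb_select` | 5 | alignments perturbed per round |
| `gap_size` | $\max(1, \lceil \mathrm{Min}/16 \rceil)$ | inserted indel-run length, tied to the smallest-sequence scale like the `k` grid |
| `n_starts` | 5 | random starting alignments when none are supplied |
| `max_evals` / `max_seconds` | unbounded | evaluation / wall-clock budget |

Large `k` explores aggressively and suits instances with few sequences;
small `k` keeps neighborhoods tractable when $m$ is large.  The default
substitution matrix is the $\pm 1$ identity matrix over the input alphabet;
any NCBI-format PAM/BLOSUM file can be supplied instead.

## Evaluating fronts

Approximation quality is measured by the *hypervolume indicator*: the area
dominated by a score front, bounded by a reference point that every front
point strictly dominates.  `reference_point()` uses (minimum substitution
score − 1, maximum indel count + 1); `hypervolume()` sorts the front on
the substitution score and sums disjoint slabs, working directly on the
maximize/minimize orientation, and is exact for integer scores — the tests
check it cell-for-cell against an independent grid-counting oracle
(`grid_hypervolume()`).  To compare runs, `reference_front()` merges all
run fronts, extracts the non-dominated scores, and computes the reference
hypervolume; each run is then reported as a percentage of that value
(`hv_percentage()`), 100% meaning the run matches the merged front.

Against a trusted reference alignment, `sp_tc_ratios()` reports the
fraction of reference-aligned residue pairs reproduced by the test
alignment (SP) and the fraction of reference columns whose full residue
tuple appears as a test column (TC), the classic benchmark-database
measures.  Identical alignments give 1/1, and TC = 1 forces SP = 1; the
converse fails in general, so no ordering between the two is assumed.  A
column mask restricts scoring to annotated core blocks when the reference
provides them; an optional matrix-weighted SP variant (pairs weighted by
their substitution score, shifted to positive weights) accommodates
protocols that couple the SP ratio to a scoring matrix — the unweighted
ratio is the standard and the default.

## Synthetic families and oracles

`generate_family()` evolves one random ancestor into $m$ descendants
independently: per-site substitutions at `substitution_rate`, and
insertion/deletion events at `indel_rate` (split evenly) with
truncated-geometric lengths.  The generator emulates small equidistant
protein families at a controlled divergence.  It deliberately omits much
of real protein evolution — no rate heterogeneity across sites, no
conserved domains or motif structure, no codon constraints, no
insertion-rate asymmetry — so passing tests demonstrate the *search and
scoring machinery* on realistically shaped inputs, not biological accuracy
of alignments on real families.

Three independent oracles anchor the tests without external data:

* `exact_pairwise_front()` — dynamic programming over the pairwise lattice
  propagating a per-cell Pareto set of (substitution score, indel count)
  vectors with one witness alignment per vector; dominated vectors are
  pruned per cell, ties keep the first witness.  It shares the scoring
  convention (each residue/indel position counts 1) so heuristic and
  oracle optimize the identical objective.
* `enumerate_pairwise_front()` — full recursive enumeration of every
  feasible pairwise alignment (total length at most $|a|+|b|$ since no
  column may be all-gap), used to certify the DP on short sequences.
* `brute_force_neighbors()` and `grid_hypervolume()` — the
  condition-checking and cell-counting counterparts described above.

Exact multiobjective dynamic programming for $m \ge 3$ is exponential and
out of scope; the pairwise oracle is the ground truth the heuristic is
measured against.

## The recovery experiment

The headline validation asks whether budget-driven PILS recovers what the
exact oracle proves attainable.  Twenty two-sequence families are drawn
from the generator at its defaults (ancestor length 10, substitution rate
0.15, indel rate 0.05, maximum indel length 2, protein alphabet), keeping
families whose sequence lengths fall in 8–12 so the exhaustive machinery
stays comfortable; each is searched 10 times (`P = 4`, `k = "Min"` — the
large-`k` end, which is the right regime for very few sequences — 5 random
starts, `gap_size` at its default of 1, 20000 evaluations per run, a
budget three orders of magnitude beyond what a single natural PLS
termination consumes).  Each run's archive hypervolume is expressed as a
percentage of the exact front's, with one shared reference point built
from the union of both fronts so the comparison is well defined.  The
same runs are instrumented to audit the three structural invariants:
round-wise hypervolume monotonicity, archive non-domination after every
insertion, and the Pareto-local-optimality of naturally terminated PLS
archives.

Two properties of the outcome deserve honesty.  First, no run can exceed
100% — the exact front dominates everything — and the tests assert this.
Second, recovery is excellent on average but not uniform: on a minority of
families some seeds lock onto a wrong "gap skeleton" whose every
single-move repair is dominated, and no amount of budget frees them — a
deceptive Pareto local optimum, which is precisely the failure mode
iterated perturbation mitigates but cannot abolish.  The suite therefore
asserts the experiment-level mean recovery (≥ 95%) rather than a uniform
per-family bound, and the acceptance script reports the per-family minimum
alongside the mean so the non-uniformity stays visible.

## Numerical and degenerate-input choices

* All scores, score vectors and hypervolumes are integer-exact; dominance
  ties are resolved by the archive's first-representative rule.
* `strip_all_gap_columns()` refuses an alignment that would become empty;
  `validate_alignment()` never throws, it reports violations with 1-based
  coordinates (matching the $b_{i,j}$ indexing convention).
* Fractional `k` and `gap_size` specifiers floor at 1 so very short
  instances remain searchable.
* Perturbation of an archive smaller than `perturb_select` takes the whole
  archive; a selection that collides on quantile positions is topped up at
  random.
* Sequence sets reject the indel character outright; alignments are only
  validated against a sequence set on request, so files can be inspected
  before being bound to inputs.

## Known limitations

* The exact oracle is pairwise only; for $m \ge 3$ quality is assessed via
  invariants and relative hypervolume, not against ground truth.
* Affine or position-specific gap costs, sequence weighting, and archive
  size capping are not implemented; objectives are the two described.
* Wall-clock budgets trade reproducibility for realism; use evaluation
  budgets when determinism matters.
* `read_alignment()` accepts aligned FASTA and Clustal `.aln`; other
  alignment interchange formats must be converted externally.
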