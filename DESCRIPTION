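Package: momsa
Title: Multiobjective Multiple Sequence Alignment by Pareto Local Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heuristic multiobjective multiple sequence alignment. Alignments are
    scored by the biobjective sum-of-pairs vector (substitution score to maximize,
    indel pair count to minimize) and searched with Pareto local search over a
    k-block gap-shift neighborhood, optionally embedded in Pareto iterated local
    search with gap-insertion perturbation.  Includes hypervolume-based evaluation
    of score fronts, SP/TC quality ratios against reference alignments, a synthetic
    sequence-family generator, and independent oracles (exact biobjective pairwise
    dynamic programming, brute-force neighborhood enumeration, grid hypervolume
    counting) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
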