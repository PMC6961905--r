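---
title: "Measuring the treeness of a corpus of ideas: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the treeness of a corpus of ideas: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ideotree treats a corpus of cultural objects — historical tree-of-life
diagrams in the motivating application — as taxa in a cladistic analysis.
This vignette is the package's own account of the methods: the model behind
each statistic, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
decisions a reader would otherwise have to reverse-engineer from the code.

## The parsimony model

Characters are unordered, unweighted multistate codes. The score of a tree
is its Fitch length: the minimum number of state changes needed to explain
all leaf states. Missing (`?`) and inapplicable (`-`) cells are both scored
as fully ambiguous — the cell may take any state observed in that character
— which is the convention of mainstream parsimony software; the package
keeps the two symbols apart only for file round-tripping. A character with
data on at most one leaf can never force a change.

Searches are heuristic: `n_replicates` random-addition sequences (each
taxon inserted on the length-minimising edge, ties broken by a seeded
shuffle of candidate edges) followed by branch swapping. The three
neighbourhoods are nested — NNI ⊂ SPR ⊂ TBR — with TBR implemented as SPR
plus re-rooting of the pruned subtree at any of its edges. Swapping is
first-improvement by default (`steepest = FALSE`); all distinct equally
shortest trees encountered are kept up to `max_trees` (default 5000, with a
saturation flag — the count of co-optimal trees is implementation-sensitive
and is not a promised quantity). Every stochastic choice derives from the
`seed` in the `search_config`, so runs are exactly reproducible. The search
is validated against exhaustive enumeration (all `(2n−5)!!` topologies, up
to 8 leaves) in the test suite, where it attains the global optimum in well
over 95% of random instances at 2 replicates.

Rooting uses an all-zero hypothetical ancestor added as an ordinary
terminal: since state 0 codes the absence of a trait, this encodes the
assumption that idea evolution is gain-biased and the emptiest diagram is
basal. Reported lengths include the ancestor's subtending changes.

## Ancestral states and events

ACCTRAN/DELTRAN optimization is implemented as a 0/1-cost dynamic
programme (Sankoff recursion) with a traceback that starts at the ancestor
leaf. Whenever several states tie for the minimum on an edge, ACCTRAN
prefers changing state on the current (rootward) edge and DELTRAN prefers
keeping the parent state; both realize the same minimal change count. The
canonical three-taxon chain with states 1,0,1 resolves under ACCTRAN to a
basal gain plus a reversion rather than two convergent gains, which is what
"favouring reversions over convergences" demands. Each change is classified
by rule: a *reversion* if the target state already occurred on the path
above the edge, otherwise a *gain*, downgraded to *convergence* when the
same (character, state) is gained on more than one edge.

Strict consensus trees contain polytomies; these are scored as *hard*
polytomies (the DP on the multifurcating tree as given). A hard polytomy
can never need fewer steps than any binary resolution, and the test suite
asserts this monotonicity. How PAUP*-style ACCTRAN handles polytomies
exactly is not documented in the sources this design follows; the
hard-polytomy rule is our stated choice, not an inference.

## Treeness statistics

With `S` the best search length, `M` the sum of character amplitudes and
`G` the star-tree length: `CI = M/S`, `RI = (G−S)/(G−M)`. Degenerate cases
(`S = 0`, `G = M`) are reported as `NA` with a warning, never as silent
zeros. HER replaces `G` with `A`, the mean best length over matrices whose
columns were independently permuted across taxa — preserving each
character's exact state multiset, with missing cells shuffled along. The
per-replicate search is deliberately light (default 2 additions + SPR) and
both the replicate count and effort are recorded in the report, because `A`
is itself a heuristic estimate.

The delta-score is computed on mismatch distances (proportion different
among pairwise-complete characters) over the one-hot recoded matrix — the
convention split-network software applies to multistate data. Each quartet
contributes `(s₃−s₂)/(s₃−s₁)` from its sorted pairwise-sum triple, 0 for
the degenerate `s₃ = s₁` case. Exact mode enumerates all `C(n,4)` quartets
in vectorized chunks; sampled mode draws quartets under a seed and, by the
test suite's check, tracks the exact value closely at modest sample sizes.
The distance convention is a knob (`recode_binary` first or not) because it
shifts δ; the packaged default is the recoded matrix.

## Bremer support

The decay index of a clade is estimated by a reverse-constraint search:
hill-climbing that rejects any tree displaying the clade's bipartition,
started from the best trees with the clade's stem edge broken by an NNI
(plus fresh constrained random additions). Heuristic decay values are upper
bounds; the search effort is stored in each record so values are compared
at like effort. At ≤7 taxa with TBR the estimates equal the exhaustive
decay index in the test suite.

## The generator: what it emulates, what it does not

`simulate_tree` draws a random rooted binary topology with continuous node
dates spanning the configured year range (default 1555–2012; dates strictly
increase rootwards-to-tipwards). `simulate_matrix` evolves each character
from state 0 with per-edge gain probability `gain_rate` (successive states
for multistate characters) and loss probability `loss_rate`; horizontal
borrowing then overwrites each cell with probability `h` by the value of a
donor published no later than the recipient, recipients processed in date
order so borrowed states propagate forward in time only; finally cells are
masked missing/inapplicable. The full event log is returned, so tests can
demand exact recovery of planted changes.

Defaults mirror the motivating corpus's shape (235 × 141, 19/141
multistate, years 1555–2012). The rates are a design choice: per-edge
`gain_rate = 0.02` and `loss_rate = 0.005` make a character change roughly
once on a tree of a few dozen diagrams — matrices where most characters are
clean markers and a minority are homoplastic, which is the regime the
treeness statistics are meant to discriminate. Analyses and tests run far
smaller than the default shape (12–20 taxa, 30–60 characters; the
per-script sizes are stated in `analysis/`), chosen so the whole workflow
re-runs in minutes on one core.

What the generator does *not* emulate: correlated characters (real coded
features overlap conceptually), clade-restricted borrowing (donors are
uniform among date-eligible taxa), heterogeneous rates across lineages, and
non-random missingness. Passing tests therefore show the pipeline is
correct and well-calibrated under independent characters and uniform
borrowing — not that real corpora satisfy those assumptions.

## Calibration of RI and δ against borrowing

`ri_vs_borrowing` runs the full simulate–search–score loop over a grid of
borrowing rates. Under the packaged regime (16 taxa × 40 characters,
`gain_rate = 0.05`, 20 seeds per rate) RI falls and δ rises monotonically
in `h`, with one-sided Kendall trend tests far below 0.05; pure-vertical
corpora at default rates sit comfortably above the RI ≈ 0.60 line that the
cultural-phylogenetics literature reads as predominantly vertical
transmission. Because replicate-level RI at these sizes is heavy-tailed (a
single extra convergent gain moves a small denominator), the test suite
asserts the 20-seed mean for the high-treeness claims and a per-replicate
floor of 0.6.

## Circulation hypotheses

For a chosen character state, each ACCTRAN gain edge is an occurrence,
dated by the earliest publication year in the clade it subtends (the clade
"contains" its oldest diagram). Dated occurrences are ordered and connected
by arrows — a chain oldest→next→… by default, or a star from the oldest
(`mode = "star"`), since the source figures admit both readings. Ties in
years yield arrows in both directions flagged as unresolved; reversions are
listed but excluded from arrows unless requested; undated occurrences are
excluded with a warning. No arrow ever points from a younger to a strictly
older occurrence — authors cannot read ideas not yet published — and the
output is labelled what it is: hypotheses for historical analysis, not
inferred borrowings.

## Numerical and I/O decisions

- State codes are positions in the shared symbol alphabet (`FORMAT
  SYMBOLS`), so symbol "0" is code 0 in every character and the all-zero
  ancestor is well defined.
- NEXUS input accepts `DATA` and `CHARACTERS` blocks, interleaved or not,
  with `SYMBOLS`/`MISSING`/`GAP` honoured; parse errors name the offending
  taxon or line.
- Topology identity during search uses exact split fingerprints (sums of
  powers of two in doubles) up to 52 tips, with a string fallback above.
- Tie-breaking everywhere — insertion edges, neighbour order — is a seeded
  permutation of a deterministic candidate order; equal-length neighbour
  collection is capped by `max_trees` with the cap flagged.
- Decimal commas in source-era reports ("0,4") are read as decimal points.
- Character indices in all reports are 1-based, matching the "Character #k"
  convention of the motivating corpus.

## Known limitations

Search cost grows quickly with taxon count in pure R; the packaged
workflows stay at a few dozen taxa, and a corpus at the motivating scale
(a few hundred taxa) needs patience or reduced effort settings. Bremer
values are upper bounds under heuristic effort. The delta-score depends on
the distance convention, recorded in the report. The generator's borrowing
model is memoryless and uniform; inference of *who* borrowed from whom is
outside what any of these statistics can establish.
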