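# ideotree

Cladistic analysis of cultural corpora coded as character matrices — built
for the question "how tree-like is the history of an idea?". The motivating
case is a corpus of historical tree-of-life diagrams: each published diagram
is an operational taxonomic unit (OTU), each conceptual or graphical feature
an unordered multistate character, and the degree to which shared features
fit a single rooted hierarchy ("treeness") measures how much of the history
is vertical inheritance of ideas versus horizontal borrowing between
contemporaries.

## What it computes

Given a taxa × characters matrix `X` (missing `?`, inapplicable `-`):

- **Maximum parsimony.** Fitch scoring of unordered characters; heuristic
  search by seeded random-addition sequences plus NNI/SPR/TBR branch
  swapping, rooted on an all-zero hypothetical ancestor (ideas are gained,
  so the diagram with no coded ideas is basal). The result is the set of
  equally shortest trees of length `S` and their strict consensus.
- **Treeness.** With `M = Σ_c (states_c − 1)` (minimum conceivable steps)
  and `G` the star-tree length, the consistency index `CI = M/S`, retention
  index `RI = (G−S)/(G−M)`, and the homoplasy excess ratio
  `HER = (A−S)/(A−M)` where `A` is the mean search length over
  column-permuted copies of the matrix. On the one-hot recoded matrix, the
  quartet delta-score `δ = mean_q (s₃−s₂)/(s₃−s₁)` over the three sorted
  pairwise-distance sums of every quartet (0 = perfectly tree-like).
- **Character optimization.** ACCTRAN/DELTRAN ancestral states with every
  change classified as gain, reversion, or convergence, and per-clade
  synapomorphy listings.
- **Support.** Bremer decay indices from reverse-constraint searches (the
  extra steps needed before clade-free trees become optimal).
- **Circulation of ideas.** For a homoplastic character state, its origin
  clades are dated by their oldest member and chained into directed
  transfer hypotheses — arrows never point from a younger to an older
  occurrence.
- **Simulation.** A generator of dated trees and matrices with controlled
  vertical change, horizontal borrowing rate `h`, and masking, used to
  validate the whole pipeline and calibrate RI/δ against `h`.

## Worked example

```r
library(ideotree)

cfg <- simulation_config(n_taxa = 14, n_chars = 35, missing_fraction = 0.03,
                         seed = 5)
dat <- simulate_matrix(simulate_tree(cfg))
write_nexus(dat$matrix, "matrix.nex")
write.csv(dat$years, "years.csv", row.names = FALSE)

report <- run_all("matrix.nex", "years.csv", outdir = "out",
                  search = search_config(3, "SPR", 30, seed = 2),
                  her_reps = 6, seed = 3)
print(report)
```

```
run report
  matrix: 14 taxa x 35 characters (0 multistate, 7 informative)
  search: 30 tree(s) of length 12 (cap hit)
  CI = 0.917  RI = 0.947  HER = 0.838  delta = 0.221
  top clades by Bremer support:
                                clade size bremer n_supporting_chars
3             t11;t12;t13;t2;t3;t5;t6    7      2                  2
1 t1;t11;t12;t13;t2;t3;t4;t5;t6;t8;t9   11      1                  1
2                               t1;t8    2      1                  1
```

Read: the 30 equally shortest trees need 12 steps; CI/RI near 1 and a low
δ say the matrix is strongly hierarchical — as it should be, since this
corpus was simulated without borrowing (`h = 0`). The best-supported clade
survives until trees two steps longer are accepted and is justified by two
stem synapomorphies.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `06_calibration.R`), each writing its tables under
`results/`.

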