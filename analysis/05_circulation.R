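#!/usr/bin/env Rscript
## Circulation of ideas: for the most homoplastic character of the corpus,
## locate its convergent origins on the consensus, date each origin clade by
## its oldest diagram, and emit date-directed transfer hypotheses.

library(ideotree)

cm0 <- read_nexus("results/sim/matrix.nex")
cm <- add_hypothetical_ancestor(cm0)
years <- read_year_table("results/sim/years.csv", cm0)
best <- heuristic_search(cm, search_config(5, "SPR", 50, seed = 7))
recon <- acctran_optimize(strict_consensus(best), cm, root = "ANC")

pci <- per_character_ci(recon)
j <- which.max(pci$s - pci$m)
ev <- recon$events
cand <- ev[ev$character == j & ev$to > 0L, ]
state <- as.integer(names(sort(table(cand$to), decreasing = TRUE))[1])
occ <- homoplastic_occurrences(recon, j, state, years)
hyp <- infer_transfers(occ, mode = "chain")
print(hyp)

jsonlite::write_json(list(character = j, state = state,
                          occurrences = occ, arrows = hyp$arrows,
                          note = hyp$note),
                     "results/circulation.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("character #%d (state %d): %d occurrence(s), %d arrow(s); results/circulation.json\n",
            j, state, nrow(occ), nrow(hyp$arrows)))
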