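#' Run the full analysis pipeline
#'
#' One call reproducing the whole protocol on a matrix: read (or take) the
#' character matrix, audit informative characters, attach the all-zero
#' hypothetical ancestor, heuristic parsimony search, strict consensus,
#' ACCTRAN optimization, CI/RI, permutation HER, one-hot recoding, mismatch
#' distances and quartet delta-score, Bremer support table, and (when a year
#' table is supplied) circulation hypotheses for the requested characters.
#' Any stage failure aborts with the stage name; outputs written so far are
#' preserved.
#'
#' @param matrix_path path to a NEXUS matrix, or a [character_matrix()].
#' @param years_path optional path to a taxon,year CSV (or a data frame);
#'   when absent the circulation stage is marked skipped.
#' @param outdir optional output directory; when given, writes
#'   `report.json`, `trees.nwk`, `consensus.nwk`, `support.tsv`.
#' @param root_label label for the hypothetical ancestor.
#' @param search a [search_config()].
#' @param her_reps HER permutation replicates (0 skips HER).
#' @param delta_mode `"exact"` or `"sampled"` (see [delta_score()]).
#' @param delta_samples quartet sample size for sampled mode.
#' @param circulate_characters character indices for circulation analysis;
#'   `NULL` picks the most homoplastic character.
#' @param support whether to compute the Bremer support table.
#' @param seed master seed for HER and sampled delta.
#' @return a `run_report` list; see fields in the example below.
#' @export
run_all <- function(matrix_path, years_path = NULL, outdir = NULL,
                    root_label = "ANC",
                    search = search_config(n_replicates = 5, swap = "SPR",
                                           max_trees = 100),
                    her_reps = 20, delta_mode = "exact",
                    delta_samples = 1e5,
                    circulate_characters = NULL, support = TRUE,
                    seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cm0 <- stage("read", {
    if (inherits(matrix_path, "character_matrix")) matrix_path
    else read_nexus(matrix_path)
  })
  years <- stage("years", {
    if (is.null(years_path)) NULL
    else if (is.data.frame(years_path)) years_path
    else read_year_table(years_path, cm0)
  })
  info <- stage("audit", informative_characters(cm0))
  nst <- vapply(seq_len(cm0$n_chars), function(j) n_observed_states(cm0, j), 0L)
  cm <- stage("root", add_hypothetical_ancestor(cm0, root_label))
  best <- stage("search", heuristic_search(cm, search))
  cons <- stage("consensus", strict_consensus(best))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(vapply(best$trees, write_newick, ""),
               file.path(outdir, "trees.nwk"))
    writeLines(write_newick(cons), file.path(outdir, "consensus.nwk"))
  }
  recon <- stage("acctran", acctran_optimize(cons, cm, root = root_label))
  M <- min_steps(cm); G <- max_steps_star(cm)
  her <- if (her_reps >= 2) {
    stage("her", homoplasy_excess_ratio(cm, best$length, n_reps = her_reps,
                                        seed = seed))
  } else NULL
  bin <- stage("recode", recode_binary(cm0))
  dmat <- stage("distances", hamming_distance_matrix(bin))
  delta <- stage("delta", delta_score(dmat, mode = delta_mode,
                                      sample_size = delta_samples,
                                      seed = seed))
  report_treeness <- treeness_report(cm, best$length, her = her,
                                     delta = delta)
  supp <- if (support) {
    stage("support", support_table(cm, best, root = root_label,
                                   config = search_config(
                                     n_replicates = 2, swap = "SPR",
                                     max_trees = 1, seed = seed)))
  } else NULL
  if (!is.null(outdir) && !is.null(supp)) {
    utils::write.table(supp, file.path(outdir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  circulation <- stage("circulation", {
    if (is.null(years)) {
      list(skipped = TRUE, reason = "no year table supplied")
    } else {
      pci <- per_character_ci(recon)
      chars <- circulate_characters
      if (is.null(chars)) {
        excess <- pci$s - pci$m
        chars <- if (max(excess) > 0) which.max(excess) else integer(0)
      }
      hyps <- lapply(chars, function(j) {
        ev <- recon$events
        cand <- ev[ev$character == j & ev$to > 0L, , drop = FALSE]
        if (!nrow(cand)) return(NULL)
        st <- as.integer(names(sort(table(cand$to), decreasing = TRUE))[1])
        occ <- homoplastic_occurrences(recon, j, st, years)
        infer_transfers(occ)
      })
      list(skipped = FALSE, characters = chars,
           hypotheses = Filter(Negate(is.null), hyps))
    }
  })
  report <- list(
    config = list(search = unclass(search), her_reps = her_reps,
                  delta_mode = delta_mode, seed = seed,
                  root_label = root_label),
    matrix = list(n_taxa = cm0$n_taxa, n_chars = cm0$n_chars,
                  n_multistate = sum(nst > 2L),
                  n_informative = info$n_informative),
    search = list(length = best$length, n_trees = length(best$trees),
                  cap_hit = best$cap_hit),
    treeness = unclass(report_treeness),
    consensus_newick = write_newick(cons),
    support = supp,
    circulation = circulation
  )
  class(report) <- "run_report"
  if (!is.null(outdir)) {
    json <- report
    json$support <- if (!is.null(supp)) supp else NULL
    json$circulation <- if (isTRUE(circulation$skipped)) circulation else
      list(skipped = FALSE, characters = circulation$characters)
    jsonlite::write_json(lapply(unclass(json), unclass_deep),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("run report\n")
  cat(sprintf("  matrix: %d taxa x %d characters (%d multistate, %d informative)\n",
              x$matrix$n_taxa, x$matrix$n_chars, x$matrix$n_multistate,
              x$matrix$n_informative))
  cat(sprintf("  search: %d tree(s) of length %d%s\n", x$search$n_trees,
              x$search$length, if (x$search$cap_hit) " (cap hit)" else ""))
  cat(sprintf("  CI = %.3f  RI = %.3f  HER = %s  delta = %s\n",
              x$treeness$CI, x$treeness$RI,
              ifelse(is.na(x$treeness$HER), "-", sprintf("%.3f", x$treeness$HER)),
              ifelse(is.na(x$treeness$delta), "-", sprintf("%.3f", x$treeness$delta))))
  if (!is.null(x$support) && nrow(x$support)) {
    cat("  top clades by Bremer support:\n")
    print(utils::head(x$support, 3))
  }
  invisible(x)
}
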