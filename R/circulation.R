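#' Occurrences of a homoplastic character state
#'
#' For one character and state, lists each edge of the reconstruction where
#' that state arises (the ACCTRAN change events with that target state), the
#' clade each edge subtends, and the earliest publication year within the
#' clade — the clade "contains" its oldest diagram, which anchors the
#' direction of any transfer. Occurrences whose clade has no dated taxon are
#' kept but flagged undated (they cannot take part in arrows).
#'
#' @param recon a [acctran_optimize()] reconstruction.
#' @param character 1-based character index.
#' @param state target state code.
#' @param years data frame from [read_year_table()] (`taxon`, `year`).
#' @return data frame with one row per occurrence: `edge_child` (node id),
#'   `clade` (labels collapsed by `;`), `year` (earliest in clade, `NA` if
#'   undated), `kind` (event kind of the underlying change).
#' @export
homoplastic_occurrences <- function(recon, character, state, years) {
  ev <- recon$events
  sel <- ev[ev$character == character & ev$to == state, , drop = FALSE]
  if (!nrow(sel)) {
    stop("character ", character, " never reaches state ", state,
         " on this reconstruction")
  }
  tree <- recon$tree
  n <- length(tree$tip.label)
  below <- tips_below_all(tree)
  ymap <- stats::setNames(years$year, years$taxon)
  rows <- lapply(seq_len(nrow(sel)), function(r) {
    v <- sel$child[r]
    tips <- tree$tip.label[below[[v]]]
    ys <- ymap[tips]
    data.frame(edge_child = v,
               clade = paste(sort(tips), collapse = ";"),
               year = if (all(is.na(ys))) NA_integer_ else
                 as.integer(min(ys, na.rm = TRUE)),
               kind = sel$kind[r])
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$year))) {
    warning(sum(is.na(out$year)), " occurrence(s) without dated taxa ",
            "excluded from transfer arrows")
  }
  out
}

tips_below_all <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below
}

#' Date-directed transfer hypotheses
#'
#' Orders the dated occurrences of a homoplastic state by their earliest
#' publication year and emits directed arrows describing how the idea may
#' have circulated: either a chain from the oldest occurrence to the next
#' and so on (`mode = "chain"`), or a star from the oldest occurrence to
#' every later one (`mode = "star"`) — the figures the procedure mimics are
#' described, not formalized, so both readings are available. Authors cannot
#' read ideas not yet published, so no arrow ever points from a younger to a
#' strictly older occurrence; occurrences with tied years get arrows in both
#' directions, flagged as unresolved ties. Reversions (losses) are listed
#' among occurrences but excluded from arrows by default. The output is a
#' hypothesis to be tested by historical analysis, not an inference of
#' actual borrowing.
#'
#' @param occurrences data frame from [homoplastic_occurrences()].
#' @param mode `"chain"` (default) or `"star"`.
#' @param include_reversions also let reversion events carry arrows.
#' @return object of class `transfer_hypothesis` with fields `occurrences`,
#'   `arrows` (data frame `from`, `to`, `from_year`, `to_year`, `tie`),
#'   `mode`, `note`, and `reason` when no arrows could be drawn.
#' @export
infer_transfers <- function(occurrences, mode = c("chain", "star"),
                            include_reversions = FALSE) {
  mode <- match.arg(mode)
  occ <- occurrences
  use <- !is.na(occ$year)
  if (!include_reversions) use <- use & occ$kind != "reversion"
  idx <- which(use)
  note <- "hypotheses of transfers to be tested by further historical analyses"
  if (length(idx) < 2L) {
    return(structure(list(
      occurrences = occ,
      arrows = data.frame(from = integer(0), to = integer(0),
                          from_year = integer(0), to_year = integer(0),
                          tie = logical(0)),
      mode = mode, note = note,
      reason = "fewer than 2 dated occurrences"), class = "transfer_hypothesis"))
  }
  idx <- idx[order(occ$year[idx])]
  arrows <- list()
  add <- function(a, b) {
    tie <- occ$year[a] == occ$year[b]
    arrows[[length(arrows) + 1L]] <<- data.frame(
      from = a, to = b, from_year = occ$year[a], to_year = occ$year[b],
      tie = tie)
    if (tie) {
      arrows[[length(arrows) + 1L]] <<- data.frame(
        from = b, to = a, from_year = occ$year[b], to_year = occ$year[a],
        tie = TRUE)
    }
  }
  if (mode == "chain") {
    for (i in seq_len(length(idx) - 1L)) add(idx[i], idx[i + 1L])
  } else {
    for (i in seq(2L, length(idx))) add(idx[1L], idx[i])
  }
  arr <- unique(do.call(rbind, arrows))
  structure(list(occurrences = occ, arrows = arr, mode = mode, note = note,
                 reason = NULL),
            class = "transfer_hypothesis")
}

#' @export
print.transfer_hypothesis <- function(x, ...) {
  cat("transfer hypothesis (", x$mode, " reading): ",
      nrow(x$occurrences), " occurrence(s), ", nrow(x$arrows),
      " arrow(s)\n", sep = "")
  if (!is.null(x$reason)) cat("  no arrows:", x$reason, "\n")
  cat(" ", x$note, "\n")
  invisible(x)
}
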