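#' Character matrix for parsimony analysis
#'
#' A `character_matrix` holds a taxa-by-characters table of unordered
#' multistate codes, the container behind every downstream computation
#' (parsimony length `S`, minimum steps `M`, star-tree steps `G`). Cells are
#' integer state codes (position of the symbol in the shared symbol alphabet,
#' 0-based, so symbol `"0"` is code `0L`), `NA` for missing data, and `NA`
#' flagged in the `inapplicable` mask for inapplicable cells. Missing and
#' inapplicable cells are treated identically by all scoring functions; the
#' distinction is preserved only for round-tripping files.
#'
#' @param states integer matrix (taxa in rows, characters in columns); `NA`
#'   marks cells without data.
#' @param taxa character vector of unique, non-empty taxon labels; defaults to
#'   `rownames(states)`.
#' @param char_labels optional character vector of character names.
#' @param inapplicable logical matrix of the same dimension marking which `NA`
#'   cells were coded inapplicable (`"-"`) rather than missing (`"?"`).
#' @param symbols shared state alphabet in code order; code `k` is written as
#'   `symbols[k + 1]`.
#'
#' @return an object of class `character_matrix` with fields `states`,
#'   `taxa`, `char_labels`, `inapplicable`, `symbols`, `n_taxa`, `n_chars`.
#' @export
character_matrix <- function(states, taxa = rownames(states),
                             char_labels = colnames(states),
                             inapplicable = NULL,
                             symbols = as.character(0:9)) {
  if (!is.matrix(states)) states <- as.matrix(states)
  storage.mode(states) <- "integer"
  n <- nrow(states)
  k <- ncol(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  taxa <- as.character(taxa)
  if (length(taxa) != n) stop("length(taxa) must equal nrow(states)")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (any(!nzchar(taxa))) stop("taxon labels must be non-empty")
  if (is.null(inapplicable)) {
    inapplicable <- matrix(FALSE, n, k)
  }
  if (!all(dim(inapplicable) == c(n, k))) {
    stop("inapplicable mask dimension mismatch")
  }
  inapplicable[!is.na(states)] <- FALSE
  obs <- states[!is.na(states)]
  if (length(obs) && (min(obs) < 0L || max(obs) >= length(symbols))) {
    stop("state codes must lie in [0, length(symbols) - 1]")
  }
  dimnames(states) <- list(taxa, char_labels)
  structure(
    list(states = states, taxa = taxa,
         char_labels = if (is.null(char_labels)) NULL else as.character(char_labels),
         inapplicable = inapplicable, symbols = as.character(symbols),
         n_taxa = n, n_chars = k),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", x$n_taxa, "taxa x", x$n_chars, "characters\n")
  nmiss <- sum(is.na(x$states) & !x$inapplicable)
  ninap <- sum(x$inapplicable)
  cat("  missing cells:", nmiss, " inapplicable cells:", ninap, "\n")
  nst <- vapply(seq_len(x$n_chars), function(j) n_observed_states(x, j), 0L)
  cat("  multistate (>2 observed states):", sum(nst > 2L), "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) c(x$n_taxa, x$n_chars)

## Observed (non-missing) state codes of character j, sorted.
observed_states <- function(cm, j) {
  sort(unique(cm$states[, j][!is.na(cm$states[, j])]))
}

n_observed_states <- function(cm, j) length(observed_states(cm, j))

#' Parsimony-informative characters
#'
#' A character is parsimony-informative iff at least two of its states each
#' occur in at least two taxa (missing/inapplicable cells excluded): only such
#' characters can favour one topology over another. Constant characters and
#' autapomorphies are uninformative.
#'
#' @param cm a [character_matrix()].
#' @return list with `informative` (logical per character), `n_informative`,
#'   `n_uninformative`, and a per-character data frame `table`
#'   (`character`, `n_states`, `informative`).
#' @export
informative_characters <- function(cm) {
  flags <- vapply(seq_len(cm$n_chars), function(j) {
    tab <- table(cm$states[, j])
    sum(tab >= 2L) >= 2L
  }, logical(1))
  list(
    informative = flags,
    n_informative = sum(flags),
    n_uninformative = sum(!flags),
    table = data.frame(
      character = seq_len(cm$n_chars),
      n_states = vapply(seq_len(cm$n_chars), function(j) n_observed_states(cm, j), 0L),
      informative = flags
    )
  )
}

#' One-hot recoding of multistate characters
#'
#' Characters with more than two observed states are decomposed into one
#' binary indicator per observed state (1 = the taxon shows that state, 0 =
#' it shows another one); binary and constant characters pass through
#' unchanged. Missing/inapplicable cells propagate to every indicator. This
#' is the standard expansion used to feed multistate matrices to split-network
#' software, and it preserves every state distinction: two taxa agree on the
#' original character iff they agree on all its indicators.
#'
#' @param cm a [character_matrix()].
#' @return a `character_matrix` of binary characters with attribute
#'   `recode_map`, a data frame mapping each output column to its source
#'   (`orig_char`, `new_char`, `state` code or `NA` for pass-through).
#' @export
recode_binary <- function(cm) {
  cols <- list()
  inap <- list()
  map <- list()
  labs <- list()
  for (j in seq_len(cm$n_chars)) {
    sj <- cm$states[, j]
    obs <- observed_states(cm, j)
    lab <- if (is.null(cm$char_labels)) paste0("c", j) else cm$char_labels[j]
    if (length(obs) <= 2L) {
      cols[[length(cols) + 1L]] <- sj
      inap[[length(inap) + 1L]] <- cm$inapplicable[, j]
      map[[length(map) + 1L]] <- data.frame(orig_char = j, state = NA_integer_)
      labs[[length(labs) + 1L]] <- lab
    } else {
      for (s in obs) {
        ind <- ifelse(is.na(sj), NA_integer_, ifelse(sj == s, 1L, 0L))
        cols[[length(cols) + 1L]] <- ind
        inap[[length(inap) + 1L]] <- cm$inapplicable[, j]
        map[[length(map) + 1L]] <- data.frame(orig_char = j, state = s)
        labs[[length(labs) + 1L]] <- paste0(lab, ":", cm$symbols[s + 1L])
      }
    }
  }
  out <- character_matrix(
    do.call(cbind, cols), taxa = cm$taxa,
    char_labels = unlist(labs),
    inapplicable = do.call(cbind, inap),
    symbols = cm$symbols
  )
  m <- do.call(rbind, map)
  m$new_char <- seq_len(nrow(m))
  attr(out, "recode_map") <- m[, c("orig_char", "new_char", "state")]
  out
}

#' Attach the all-zero hypothetical ancestor
#'
#' Adds one taxon whose every cell is state 0 (the symbol coding absence of a
#' trait). Rooting searches on this terminal encodes the assumption that the
#' ancestral diagram carries none of the coded ideas, i.e. that idea evolution
#' proceeds by gains.
#'
#' @param cm a [character_matrix()].
#' @param label label for the new taxon (must not already be present).
#' @return a `character_matrix` with one extra all-zero row; existing cells
#'   untouched.
#' @export
add_hypothetical_ancestor <- function(cm, label = "ANC") {
  if (label %in% cm$taxa) stop("taxon label already present: ", label)
  if (cm$n_chars < 1L) stop("matrix has no characters")
  states <- rbind(cm$states, rep(0L, cm$n_chars))
  inap <- rbind(cm$inapplicable, rep(FALSE, cm$n_chars))
  character_matrix(states, taxa = c(cm$taxa, label),
                   char_labels = cm$char_labels,
                   inapplicable = inap, symbols = cm$symbols)
}

## Subset/reorder taxa (internal).
subset_taxa <- function(cm, taxa) {
  idx <- match(taxa, cm$taxa)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  character_matrix(cm$states[idx, , drop = FALSE], taxa = taxa,
                   char_labels = cm$char_labels,
                   inapplicable = cm$inapplicable[idx, , drop = FALSE],
                   symbols = cm$symbols)
}
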