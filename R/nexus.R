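#' Read a NEXUS character matrix
#'
#' Parses a NEXUS `DATA` or `CHARACTERS` block (PAUP*-style, interleaved or
#' not) into a [character_matrix()]. The `FORMAT` line's `SYMBOLS`, `MISSING`
#' and `GAP` settings are honoured; defaults are symbols `0123456789`,
#' missing `?`, gap `-`. State symbols map to consecutive integer codes in
#' symbol order; the gap symbol maps to an inapplicable cell and the missing
#' symbol to a missing cell (both scored as fully ambiguous downstream).
#'
#' @param path path to a NEXUS file.
#' @return a [character_matrix()].
#' @export
read_nexus <- function(path) {
  raw <- readLines(path, warn = FALSE)
  txt <- strip_nexus_comments(raw)
  joined <- paste(txt, collapse = "\n")
  if (!grepl("#NEXUS", joined, ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  }
  block <- extract_matrix_block(txt)
  fmt <- block$format
  ntax <- block$ntax
  nchar_ <- block$nchar
  rows <- parse_matrix_rows(block$matrix_lines, fmt, nchar_, block$matrix_line0)
  if (!is.null(ntax) && length(rows) != ntax) {
    stop("matrix has ", length(rows), " taxa but DIMENSIONS declares NTAX=", ntax)
  }
  taxa <- names(rows)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon in MATRIX: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  syms <- strsplit(fmt$symbols, "")[[1]]
  n <- length(rows)
  states <- matrix(NA_integer_, n, nchar_)
  inap <- matrix(FALSE, n, nchar_)
  for (i in seq_len(n)) {
    cells <- rows[[i]]
    if (length(cells) != nchar_) {
      stop("taxon '", taxa[i], "': row has ", length(cells),
           " characters, expected NCHAR=", nchar_)
    }
    code <- match(cells, syms) - 1L
    bad <- is.na(code) & cells != fmt$missing & cells != fmt$gap
    if (any(bad)) {
      stop("taxon '", taxa[i], "': unknown state symbol(s) ",
           paste(unique(cells[bad]), collapse = " "),
           " (symbols are \"", fmt$symbols, "\")")
    }
    states[i, ] <- code
    inap[i, cells == fmt$gap] <- TRUE
  }
  character_matrix(states, taxa = taxa, inapplicable = inap, symbols = syms)
}

## Remove [...] comments (possibly spanning lines) from NEXUS text.
strip_nexus_comments <- function(lines) {
  depth <- 0L
  out <- character(length(lines))
  for (i in seq_along(lines)) {
    chars <- strsplit(lines[i], "")[[1]]
    keep <- character(0)
    for (ch in chars) {
      if (ch == "[") depth <- depth + 1L
      else if (ch == "]") { if (depth > 0L) depth <- depth - 1L }
      else if (depth == 0L) keep <- c(keep, ch)
    }
    out[i] <- paste(keep, collapse = "")
  }
  out
}

extract_matrix_block <- function(txt) {
  up <- toupper(txt)
  beg <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(beg)) stop("no DATA or CHARACTERS block found")
  b <- beg[1]
  ends <- grep("^\\s*END\\s*;", up)
  e <- ends[ends > b][1]
  if (is.na(e)) stop("DATA/CHARACTERS block not terminated by END;")
  body <- txt[(b + 1):(e - 1)]
  bup <- toupper(body)
  ntax <- nchar_ <- NULL
  dim_i <- grep("DIMENSIONS", bup)
  if (!length(dim_i)) stop("DIMENSIONS line missing in DATA/CHARACTERS block")
  dl <- body[dim_i[1]]
  m <- regmatches(dl, regexpr("NTAX\\s*=\\s*[0-9]+", toupper(dl)))
  if (length(m)) ntax <- as.integer(sub(".*=\\s*", "", m))
  m <- regmatches(dl, regexpr("NCHAR\\s*=\\s*[0-9]+", toupper(dl)))
  if (!length(m)) stop("NCHAR missing on DIMENSIONS line")
  nchar_ <- as.integer(sub(".*=\\s*", "", m))
  fmt <- list(symbols = "0123456789", missing = "?", gap = "-",
              interleave = FALSE)
  fmt_i <- grep("^\\s*FORMAT", bup)
  if (length(fmt_i)) {
    fl <- body[fmt_i[1]]
    m <- regmatches(fl, regexpr("SYMBOLS\\s*=\\s*\"[^\"]*\"", fl, ignore.case = TRUE))
    if (length(m)) fmt$symbols <- gsub("\\s", "", sub(".*\"([^\"]*)\".*", "\\1", m))
    m <- regmatches(fl, regexpr("MISSING\\s*=\\s*\\S", fl, ignore.case = TRUE))
    if (length(m)) fmt$missing <- substr(m, nchar(m), nchar(m))
    m <- regmatches(fl, regexpr("GAP\\s*=\\s*\\S", fl, ignore.case = TRUE))
    if (length(m)) fmt$gap <- substr(m, nchar(m), nchar(m))
    fmt$interleave <- grepl("INTERLEAVE", fl, ignore.case = TRUE)
  }
  mat_i <- grep("^\\s*MATRIX\\s*$|^\\s*MATRIX\\b", bup)
  if (!length(mat_i)) stop("MATRIX keyword missing in DATA/CHARACTERS block")
  mtx <- body[(mat_i[1] + 1):length(body)]
  semi <- grep(";", mtx)
  if (!length(semi)) stop("MATRIX not terminated by ';'")
  last <- semi[1]
  mtx[last] <- sub(";.*$", "", mtx[last])
  mtx <- mtx[seq_len(last)]
  list(format = fmt, ntax = ntax, nchar = nchar_,
       matrix_lines = mtx, matrix_line0 = mat_i[1])
}

## Parse matrix rows; supports quoted labels and interleaving. Returns a named
## list of per-taxon character vectors of single-character cells.
parse_matrix_rows <- function(lines, fmt, nchar_, line0) {
  rows <- list()
  order <- character(0)
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (startsWith(ln, "'") || startsWith(ln, "\"")) {
      q <- substr(ln, 1, 1)
      rest <- substring(ln, 2)
      pos <- regexpr(q, rest, fixed = TRUE)
      if (pos < 0) stop("line ", line0 + k, ": unterminated quoted taxon label")
      label <- substr(rest, 1, pos - 1)
      data <- substring(rest, pos + 1)
    } else {
      sp <- regexpr("\\s", ln)
      if (sp < 0) stop("line ", line0 + k, ": no states after taxon label")
      label <- substr(ln, 1, sp - 1)
      data <- substring(ln, sp + 1)
    }
    cells <- strsplit(gsub("\\s", "", data), "")[[1]]
    if (!length(cells)) stop("line ", line0 + k, ": taxon '", label, "' has no states")
    if (is.null(rows[[label]])) {
      rows[[label]] <- cells
      order <- c(order, label)
    } else if (fmt$interleave) {
      rows[[label]] <- c(rows[[label]], cells)
    } else {
      stop("line ", line0 + k, ": duplicate taxon in MATRIX: ", label)
    }
  }
  rows[order]
}

#' Write a character matrix as a NEXUS DATA block
#'
#' @param cm a [character_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(cm, path) {
  used <- observed_codes_max(cm)
  syms <- paste(cm$symbols[seq_len(max(used + 1L, 2L))], collapse = "")
  pad <- max(nchar(cm$taxa)) + 2L
  rows <- vapply(seq_len(cm$n_taxa), function(i) {
    cells <- cm$symbols[cm$states[i, ] + 1L]
    cells[is.na(cm$states[i, ])] <- "?"
    cells[cm$inapplicable[i, ]] <- "-"
    paste0(formatC(safe_label(cm$taxa[i]), width = -pad), paste(cells, collapse = ""))
  }, character(1))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", cm$n_taxa, cm$n_chars),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;", syms),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  ), path)
  invisible(path)
}

observed_codes_max <- function(cm) {
  obs <- cm$states[!is.na(cm$states)]
  if (!length(obs)) 0L else max(obs)
}

safe_label <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.]", x)
  x[needs] <- paste0("'", x[needs], "'")
  x
}

#' Export a character matrix as tab-delimited text
#'
#' One row per taxon: the label, a tab, and the state string with `?` for
#' missing and `-` for inapplicable cells.
#'
#' @param cm a [character_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(cm, path) {
  rows <- vapply(seq_len(cm$n_taxa), function(i) {
    cells <- cm$symbols[cm$states[i, ] + 1L]
    cells[is.na(cm$states[i, ])] <- "?"
    cells[cm$inapplicable[i, ]] <- "-"
    paste0(cm$taxa[i], "\t", paste(cells, collapse = ""))
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a taxon-to-publication-year table
#'
#' Reads a CSV with header columns `taxon` and `year` (calendar years). Every
#' taxon in the file must be a row of `cm`; taxa of `cm` without a year are
#' reported in the `missing_taxa` attribute so that undated diagrams can be
#' flagged in circulation analyses.
#'
#' @param path path to a CSV file with columns `taxon`, `year`.
#' @param cm the [character_matrix()] the labels must resolve against.
#' @return data frame with columns `taxon`, `year` and attribute
#'   `missing_taxa` (matrix taxa absent from the file).
#' @export
read_year_table <- function(path, cm) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L && ncol(df) < 2L) {
    df <- data.frame(taxon = character(0), year = integer(0))
  }
  if (!all(c("taxon", "year") %in% names(df))) {
    stop("year table must have header columns 'taxon' and 'year'")
  }
  df <- df[, c("taxon", "year")]
  if (nrow(df)) {
    yr <- suppressWarnings(as.numeric(df$year))
    if (anyNA(yr) || any(yr != as.integer(yr))) {
      stop("non-integer year(s) for: ",
           paste(df$taxon[is.na(yr) | yr != as.integer(yr)], collapse = ", "))
    }
    df$year <- as.integer(yr)
    if (any(df$year < 1400L | df$year > 2100L)) {
      stop("year(s) outside [1400, 2100] for: ",
           paste(df$taxon[df$year < 1400L | df$year > 2100L], collapse = ", "))
    }
    if (anyDuplicated(df$taxon)) {
      stop("duplicate taxon row(s): ",
           paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
    }
    unknown <- setdiff(df$taxon, cm$taxa)
    if (length(unknown)) {
      stop("taxa not in matrix: ", paste(unknown, collapse = ", "))
    }
  }
  attr(df, "missing_taxa") <- setdiff(cm$taxa, df$taxon)
  df
}
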