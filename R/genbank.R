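## Minimal GenBank flat-file feature-table layer.
##
## Only the subset of the format that antiSMASH 5.x region files use is
## handled: LOCUS line, FEATURES table with `key  location` lines and
## /qualifier="value" continuation lines, ORIGIN/`//` terminator.  No R
## package in this stack parses GenBank *feature tables* (as opposed to
## sequences), so this is written by hand against that dialect.
##
## GenBank locations are 1-based inclusive on disk; everything downstream of
## this file is 0-based half-open.

# Parse a `start..end` / `complement(start..end)` location.  join(...) spans
# degrade to their outer envelope with a note (the assembly-line features we
# consume are never compound in antiSMASH region files).
.gb_parse_location <- function(loc, lineno) {
  strand <- "+"
  note <- character(0)
  raw <- loc
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    note <- sprintf("compound location collapsed to outer span: %s", raw)
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  nums <- as.numeric(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2 || anyNA(nums)) {
    stop(sprintf("malformed GenBank location '%s' at line %d", raw, lineno),
         call. = FALSE)
  }
  list(start = min(nums) - 1, end = max(nums), strand = strand, note = note)
}

# Read the FEATURES table of one GenBank record into a tibble with one row
# per feature: key, start, end (0-based half-open), strand, qualifiers
# (named list of character vectors; repeated qualifiers accumulate).
gb_read_features <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0) {
    stop("malformed GenBank document: no FEATURES table", call. = FALSE)
  }
  i <- feat_start[1] + 1
  end_idx <- grep("^(ORIGIN|CONTIG|//)", lines)
  end_idx <- c(end_idx[end_idx > i], length(lines) + 1)[1]

  feats <- list()
  cur <- NULL
  cur_qual <- NULL     # name of qualifier being continued
  notes <- character(0)

  flush <- function() {
    if (!is.null(cur)) feats[[length(feats) + 1]] <<- cur
    cur <<- NULL
  }

  while (i < end_idx) {
    line <- lines[i]
    if (grepl("^ {5}\\S", line)) {                       # new feature
      flush()
      key <- trimws(substr(line, 1, 20))
      loc <- trimws(substr(line, 21, nchar(line)))
      j <- i + 1                                          # wrapped locations
      while (j < end_idx && grepl("^ {21}[^/]", lines[j]) &&
             grepl("[0-9.,)(]$", loc)) {
        loc <- paste0(loc, trimws(lines[j]))
        j <- j + 1
        break                                             # one continuation is enough here
      }
      parsed <- .gb_parse_location(loc, i)
      notes <- c(notes, parsed$note)
      cur <- list(key = key, start = parsed$start, end = parsed$end,
                  strand = parsed$strand, qualifiers = list())
      cur_qual <- NULL
    } else if (grepl("^ {21}/", line)) {                  # qualifier
      q <- sub("^ {21}/", "", line)
      if (grepl("=", q)) {
        name <- sub("=.*$", "", q)
        val <- sub("^[^=]*=", "", q)
        val <- gsub("^\"|\"$", "", val)
        cur_qual <- name
      } else {                                            # flag qualifier
        name <- q
        val <- "true"
        cur_qual <- NULL
      }
      if (!is.null(cur)) {
        cur$qualifiers[[name]] <- c(cur$qualifiers[[name]], val)
      }
    } else if (grepl("^ {21}\\S", line) && !is.null(cur) && !is.null(cur_qual)) {
      # continuation of a quoted qualifier value
      n <- length(cur$qualifiers[[cur_qual]])
      cur$qualifiers[[cur_qual]][n] <-
        paste(cur$qualifiers[[cur_qual]][n], gsub("^\"|\"$", "", trimws(line)))
    }
    i <- i + 1
  }
  flush()

  if (length(feats) == 0) {
    return(list(features = tibble::tibble(
      key = character(0), start = numeric(0), end = numeric(0),
      strand = character(0), qualifiers = list()), notes = notes))
  }
  tab <- tibble::tibble(
    key = purrr::map_chr(feats, "key"),
    start = purrr::map_dbl(feats, "start"),
    end = purrr::map_dbl(feats, "end"),
    strand = purrr::map_chr(feats, "strand"),
    qualifiers = purrr::map(feats, "qualifiers")
  )
  list(features = tab, notes = notes)
}

# ---- writing ---------------------------------------------------------------

.gb_wrap_qualifier <- function(name, value, width = 79) {
  # wrap at spaces only; an unbreakable token longer than the line width is
  # emitted overlong rather than cut mid-token (continuation lines are
  # rejoined with a space on parsing)
  text <- sprintf("/%s=\"%s\"", name, value)
  out <- character(0)
  prefix <- strrep(" ", 21)
  avail <- width - 21
  while (nchar(text) > avail) {
    spaces <- gregexpr(" ", text, fixed = TRUE)[[1]]
    spaces <- spaces[spaces > 1]
    if (length(spaces) == 0 || spaces[1] == -1) break
    fit <- spaces[spaces <= avail + 1]
    brk <- if (length(fit) > 0) max(fit) else min(spaces)
    out <- c(out, paste0(prefix, substr(text, 1, brk - 1)))
    text <- substr(text, brk + 1, nchar(text))
  }
  c(out, paste0(prefix, text))
}

# One feature block. start/end come in 0-based half-open and are written
# 1-based inclusive; qualifiers is a named list of character vectors.
gb_format_feature <- function(key, start, end, strand, qualifiers) {
  loc <- sprintf("%d..%d", start + 1, end)
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  head <- sprintf("     %-16s%s", key, loc)
  quals <- unlist(purrr::imap(qualifiers, function(vals, name) {
    unlist(lapply(vals, function(v) .gb_wrap_qualifier(name, v)))
  }), use.names = FALSE)
  c(head, quals)
}

gb_format_record <- function(locus, length_bp, feature_lines) {
  c(
    sprintf("LOCUS       %-23s %d bp    DNA     linear   BCT 01-JAN-1980", locus, length_bp),
    sprintf("DEFINITION  %s synthetic antiSMASH-dialect region.", locus),
    sprintf("ACCESSION   %s", locus),
    "FEATURES             Location/Qualifiers",
    feature_lines,
    "ORIGIN",
    "//"
  )
}
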