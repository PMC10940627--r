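# NEXUS input/output for morphology matrices ---------------------------------
#
# The dialect handled here is the one morphology matrices are normally
# deposited in: digit state symbols, '?' missing, '-' inapplicable (gap),
# parenthesised or braced polymorphism, and per-character ordering flags in
# an ASSUMPTIONS block TYPESET command (ord/unord). ape's NEXUS data reader
# drops polymorphism and ordering metadata, hence the dedicated parser.

strip_nexus_comments <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # bracketed comments may span lines; non-greedy removal
  txt <- gsub("\\[[^]]*\\]", "", txt)
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

nexus_error <- function(line_no, msg) {
  stop(sprintf("NEXUS parse error at line %d: %s", line_no, msg), call. = FALSE)
}

# Expand a TYPESET spec like "1-3 5 7-9" into integer indices.
expand_char_list <- function(spec, nchar_total, line_no) {
  out <- integer(0)
  for (tok in strsplit(trimws(spec), "[[:space:]]+")[[1]]) {
    if (tok == "") next
    if (grepl("^[0-9]+-[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (tok == ".") {
      out <- c(out, nchar_total)
    } else if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else {
      nexus_error(line_no, paste0("cannot parse character list token '", tok, "'"))
    }
  }
  if (any(out < 1L | out > nchar_total))
    nexus_error(line_no, "character index outside 1..NCHAR in TYPESET")
  out
}

#' Read a NEXUS morphological character matrix
#'
#' Parses a NEXUS file with a `CHARACTERS` or `DATA` block holding digit
#' state symbols, `?` for missing, `-` for inapplicable, and parenthesised or
#' braced polymorphic cells. Per-character ordered/unordered flags are read
#' from an `ASSUMPTIONS` block `TYPESET` command (`ord:`/`unord:` groups)
#' when present; otherwise every character is unordered.
#'
#' @param path Path to the NEXUS file.
#' @return A [character_matrix()].
#' @seealso [write_nexus_matrix()]
#' @export
read_nexus_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- strip_nexus_comments(readLines(path, warn = FALSE))
  up <- toupper(lines)
  if (!any(grepl("#NEXUS", up))) nexus_error(1L, "missing #NEXUS header")

  blk_start <- grep("^\\s*BEGIN\\s+(CHARACTERS|DATA)\\s*;", up)
  if (length(blk_start) == 0L)
    nexus_error(1L, "no CHARACTERS/DATA block found")
  blk_start <- blk_start[1]

  ntax <- nchar_total <- NA_integer_
  symbols <- as.character(0:9)
  missing_sym <- "?"; gap_sym <- "-"

  i <- blk_start
  repeat {
    i <- i + 1L
    if (i > length(lines)) nexus_error(blk_start, "unterminated CHARACTERS block")
    ln <- up[i]
    if (grepl("^\\s*DIMENSIONS", ln)) {
      mt <- regmatches(ln, regexec("NTAX\\s*=\\s*([0-9]+)", ln))[[1]]
      if (length(mt) == 2L) ntax <- as.integer(mt[2])
      mc <- regmatches(ln, regexec("NCHAR\\s*=\\s*([0-9]+)", ln))[[1]]
      if (length(mc) == 2L) nchar_total <- as.integer(mc[2])
    } else if (grepl("^\\s*FORMAT", ln)) {
      ms <- regmatches(lines[i], regexec("SYMBOLS\\s*=\\s*\"([^\"]*)\"", lines[i], ignore.case = TRUE))[[1]]
      if (length(ms) == 2L) symbols <- strsplit(gsub("\\s", "", ms[2]), "")[[1]]
      mm <- regmatches(ln, regexec("MISSING\\s*=\\s*(\\S)", ln))[[1]]
      if (length(mm) == 2L) missing_sym <- mm[2]
      mg <- regmatches(ln, regexec("GAP\\s*=\\s*(\\S)", ln))[[1]]
      if (length(mg) == 2L) gap_sym <- mg[2]
    } else if (grepl("^\\s*MATRIX\\s*$", ln)) {
      break
    }
  }
  if (is.na(nchar_total)) nexus_error(blk_start, "DIMENSIONS NCHAR missing")
  if (!all(symbols %in% as.character(0:9)))
    nexus_error(blk_start, "only digit state symbols are supported")

  taxa <- character(0)
  rows <- list()
  matrix_start <- i
  repeat {
    i <- i + 1L
    if (i > length(lines)) nexus_error(matrix_start, "MATRIX not terminated by ';'")
    raw <- trimws(lines[i])
    if (raw == "") next
    if (grepl("^;", raw)) break
    terminated <- grepl(";\\s*$", raw)
    raw <- sub(";\\s*$", "", raw)
    m <- regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", raw)
    parts <- regmatches(raw, m)[[1]]
    if (length(parts) != 3L)
      nexus_error(i, "expected '<taxon> <states>'")
    label <- gsub("^['\"]|['\"]$", "", parts[2])
    seqtxt <- gsub("\\s", "", parts[3])
    toks <- tokenize_states(seqtxt, i)
    if (label %in% taxa) nexus_error(i, paste0("duplicate taxon '", label, "'"))
    taxa <- c(taxa, label)
    rows[[label]] <- toks
    bad <- setdiff(unlist(strsplit(unlist(toks), "")),
                   c(symbols, missing_sym, gap_sym, "(", ")", "{", "}"))
    if (length(bad))
      nexus_error(i, paste0("state symbol(s) outside declared SYMBOLS: ",
                            paste(unique(bad), collapse = " ")))
    if (length(toks) != nchar_total)
      nexus_error(i, sprintf("taxon '%s' has %d characters, expected %d",
                             label, length(toks), nchar_total))
    if (terminated) break
  }
  if (!is.na(ntax) && length(taxa) != ntax)
    nexus_error(matrix_start, sprintf("found %d taxa, DIMENSIONS declared %d",
                                      length(taxa), ntax))

  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa
  cells[cells == missing_sym] <- "?"
  cells[cells == gap_sym] <- "-"

  ordering <- rep("unordered", nchar_total)
  assum <- grep("^\\s*BEGIN\\s+ASSUMPTIONS\\s*;", up)
  if (length(assum)) {
    j <- assum[1]
    repeat {
      j <- j + 1L
      if (j > length(lines) || grepl("^\\s*END\\s*;", up[j])) break
      if (grepl("^\\s*TYPESET", up[j])) {
        spec <- sub("^[^=]*=", "", lines[j])
        spec <- sub(";\\s*$", "", spec)
        for (grp in strsplit(spec, ",", fixed = TRUE)[[1]]) {
          kv <- strsplit(grp, ":", fixed = TRUE)[[1]]
          if (length(kv) != 2L) nexus_error(j, "malformed TYPESET group")
          kind <- tolower(trimws(kv[1]))
          idx <- expand_char_list(kv[2], nchar_total, j)
          if (kind %in% c("ord", "ordered")) ordering[idx] <- "ordered"
          else if (kind %in% c("unord", "unordered")) ordering[idx] <- "unordered"
        }
      }
    }
  }

  character_matrix(cells, ordering = ordering)
}

# Split a whitespace-free state string into per-character tokens, keeping
# parenthesised/braced polymorphism groups intact.
tokenize_states <- function(txt, line_no) {
  chars <- strsplit(txt, "")[[1]]
  toks <- character(0)
  k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      end <- k
      while (end <= length(chars) && chars[end] != close) end <- end + 1L
      if (end > length(chars)) nexus_error(line_no, "unclosed polymorphism group")
      toks <- c(toks, paste(chars[k:end], collapse = ""))
      k <- end + 1L
    } else {
      toks <- c(toks, ch)
      k <- k + 1L
    }
  }
  toks
}

#' Write a character matrix to NEXUS
#'
#' Writes a `DATA` block (digit symbols, `?` missing, `-` gap, parenthesised
#' polymorphism) plus an `ASSUMPTIONS` block recording ordered characters, in
#' a form [read_nexus_matrix()] reads back losslessly.
#'
#' @param m A [character_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(m, path) {
  toks <- cm_tokens(m)
  used <- sort(unique(unlist(lapply(as.vector(m$states[!is.na(m$states)]), decode_states))))
  if (length(used) == 0L) used <- 0L
  lab <- taxon_labels(m)
  quoted <- ifelse(grepl("[^A-Za-z0-9_.]", lab), paste0("'", lab, "'"), lab)
  pad <- formatC(quoted, width = max(nchar(quoted)) + 2L, flag = "-")
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_char(m)),
    sprintf("\tFORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;", paste(used, collapse = "")),
    "\tMATRIX",
    paste0("\t", pad, apply(toks, 1, paste, collapse = "")),
    "\t;",
    "END;"
  )
  ord <- which(m$ordering == "ordered")
  unord <- which(m$ordering == "unordered")
  groups <- c(
    if (length(ord)) paste0("ord: ", paste(ord, collapse = " ")),
    if (length(unord)) paste0("unord: ", paste(unord, collapse = " "))
  )
  out <- c(out,
           "BEGIN ASSUMPTIONS;",
           paste0("\tTYPESET * default = ", paste(groups, collapse = ", "), ";"),
           "END;")
  writeLines(out, path)
  invisible(path)
}
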