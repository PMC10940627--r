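# Discrete character matrices ------------------------------------------------
#
# Cells are stored as integer bitmasks: bit i set <=> state i is present in
# the cell, so "0" -> 1L, "1" -> 2L, "(01)" -> 3L. Missing ('?') and
# inapplicable ('-') cells are NA in the state matrix; inapplicable cells are
# additionally flagged so the distinction survives a round-trip even though
# both are treated as unscored downstream.

MAX_STATE <- 30L

encode_states <- function(states) {
  states <- as.integer(states)
  if (length(states) == 0L) stop("state set must be non-empty")
  if (any(is.na(states)) || any(states < 0L) || any(states > MAX_STATE))
    stop("states must be integers in 0..", MAX_STATE)
  mask <- 0L
  for (s in unique(states)) mask <- bitwOr(mask, bitwShiftL(1L, s))
  mask
}

decode_states <- function(mask) {
  if (is.na(mask)) return(integer(0))
  which(bitwAnd(mask, bitwShiftL(1L, 0:MAX_STATE)) != 0L) - 1L
}

# Parse one cell token ("0", "?", "-", "(01)", "{01}") into list(mask, gap).
parse_cell <- function(txt) {
  txt <- trimws(txt)
  if (txt == "?") return(list(mask = NA_integer_, gap = FALSE))
  if (txt == "-") return(list(mask = NA_integer_, gap = TRUE))
  body <- sub("^[({]", "", sub("[)}]$", "", txt))
  chars <- strsplit(body, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% as.character(0:9)))
    stop("cannot parse cell '", txt, "'")
  list(mask = encode_states(as.integer(chars)), gap = FALSE)
}

format_cell <- function(mask, gap = FALSE) {
  if (is.na(mask)) return(if (gap) "-" else "?")
  st <- decode_states(mask)
  if (length(st) == 1L) as.character(st) else paste0("(", paste(st, collapse = ""), ")")
}

#' Construct a discrete character matrix
#'
#' Builds the taxa-by-characters object consumed by the distance, ancestral
#' state reconstruction and rate functions. Cells are given as strings in the
#' usual morphology-matrix notation: a digit for a single state, `"(01)"` (or
#' `"{01}"`) for a polymorphic cell, `"?"` for missing and `"-"` for
#' inapplicable. Inapplicable cells are recorded as such but treated as
#' missing by every downstream computation.
#'
#' @param cells Character matrix with unique rownames (taxon labels); each
#'   entry a cell token as above. Alternatively an integer matrix of single
#'   states (NA = missing).
#' @param ordering Character vector, one of `"ordered"`/`"unordered"` per
#'   character. Default: all unordered.
#' @return An object of class `character_matrix` with components `states`
#'   (integer bitmask matrix, NA = unscored), `gap` (logical matrix flagging
#'   inapplicable cells) and `ordering`.
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1", "?"), B = c("0", "(01)", "2")))
#' cell_states(m, "B", 2)
#' @export
character_matrix <- function(cells, ordering = NULL) {
  if (is.numeric(cells)) {
    num <- cells
    cells <- matrix(NA_character_, nrow(num), ncol(num), dimnames = dimnames(num))
    cells[!is.na(num)] <- as.character(as.integer(num[!is.na(num)]))
    cells[is.na(num)] <- "?"
  }
  if (!is.matrix(cells) || !is.character(cells))
    stop("'cells' must be a character matrix")
  if (is.null(rownames(cells))) stop("'cells' must have taxon rownames")
  states <- matrix(NA_integer_, nrow(cells), ncol(cells))
  gap <- matrix(FALSE, nrow(cells), ncol(cells))
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(ncol(cells))) {
      p <- parse_cell(cells[i, j])
      states[i, j] <- p$mask
      gap[i, j] <- p$gap
    }
  }
  dimnames(states) <- dimnames(gap) <- list(rownames(cells), colnames(cells))
  new_character_matrix(states, gap, ordering)
}

new_character_matrix <- function(states, gap = NULL, ordering = NULL) {
  if (is.null(gap)) gap <- matrix(FALSE, nrow(states), ncol(states), dimnames = dimnames(states))
  if (is.null(ordering)) ordering <- rep("unordered", ncol(states))
  ordering <- match.arg(ordering, c("unordered", "ordered"), several.ok = TRUE)
  if (length(ordering) == 1L) ordering <- rep(ordering, ncol(states))
  if (length(ordering) != ncol(states))
    stop("'ordering' must have one flag per character")
  labels <- rownames(states)
  if (is.null(labels) || anyDuplicated(labels))
    stop("taxon labels must be present and unique")
  obj <- structure(
    list(states = states, gap = gap, ordering = ordering),
    class = "character_matrix"
  )
  obj
}

#' @export
dim.character_matrix <- function(x) dim(x$states)

n_taxa <- function(m) nrow(m$states)
n_char <- function(m) ncol(m$states)

#' Taxon labels of a character matrix
#' @param m A `character_matrix`.
#' @return Character vector of row labels.
#' @export
taxon_labels <- function(m) rownames(m$states)

#' States present in one cell
#' @param m A `character_matrix`.
#' @param taxon Row label or index.
#' @param char Character (column) index.
#' @return Integer vector of states; empty when the cell is unscored.
#' @export
cell_states <- function(m, taxon, char) decode_states(m$states[taxon, char])

#' Observed state range per character
#'
#' The minimum and maximum state observed for each character across the whole
#' matrix (polymorphic cells contribute every state in their set). The range
#' defines the maximum possible distance of an ordered character.
#'
#' @param m A `character_matrix`.
#' @return A 2-row matrix (`min`, `max`) with one column per character; NA
#'   for characters with no scored cell.
#' @export
state_ranges <- function(m) {
  out <- sapply(seq_len(n_char(m)), function(j) {
    masks <- m$states[, j]
    masks <- masks[!is.na(masks)]
    if (length(masks) == 0L) return(c(NA_integer_, NA_integer_))
    all_states <- unique(unlist(lapply(masks, decode_states)))
    c(min(all_states), max(all_states))
  })
  rownames(out) <- c("min", "max")
  colnames(out) <- colnames(m$states)
  out
}

# Row subset, keeping all characters.
#' @export
`[.character_matrix` <- function(x, i, ...) {
  new_character_matrix(x$states[i, , drop = FALSE], x$gap[i, , drop = FALSE], x$ordering)
}

# Stack two matrices with identical characters (used to append node rows).
cm_bind_rows <- function(a, b) {
  stopifnot(n_char(a) == n_char(b), identical(a$ordering, b$ordering))
  new_character_matrix(rbind(a$states, b$states), rbind(a$gap, b$gap), a$ordering)
}

# Cell tokens, for display and NEXUS writing.
cm_tokens <- function(m) {
  out <- matrix("", n_taxa(m), n_char(m), dimnames = dimnames(m$states))
  for (i in seq_len(n_taxa(m)))
    for (j in seq_len(n_char(m)))
      out[i, j] <- format_cell(m$states[i, j], m$gap[i, j])
  out
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", n_taxa(x), "taxa x", n_char(x), "characters\n")
  cat("  ordered characters:", sum(x$ordering == "ordered"), "\n")
  cat(sprintf("  unscored cells: %.1f%%\n", 100 * mean(is.na(x$states))))
  invisible(x)
}
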