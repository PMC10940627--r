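# Gower and maximum observable rescaled distances ----------------------------
#
# Per comparable character (both cells scored):
#   d_i   = |x - y| for ordered characters, 0/1 (shared state or not) for
#           unordered; polymorphic cells take the minimum over the two state
#           sets, so overlapping sets give d_i = 0.
#   max_i = the character's observed state range if ordered, 1 if unordered.
# GC   = sum(d_i) / n_comparable      (mean per-character distance)
# MORD = sum(d_i) / sum(max_i)        (rescaled to the maximum possible
#                                      distance, hence bounded in [0, 1])

# Minimum |x - y| over two state sets; 0 whenever the sets overlap.
set_min_dist <- function(mask_a, mask_b, ordered) {
  if (bitwAnd(mask_a, mask_b) != 0L) return(0)
  if (!ordered) return(1)
  sa <- decode_states(mask_a); sb <- decode_states(mask_b)
  min(abs(outer(sa, sb, "-")))
}

#' Distance between two rows of a character matrix
#'
#' Computes the Gower coefficient (GC) or maximum observable rescaled
#' distance (MORD) between two taxa, together with the number of characters
#' scorable in both.
#'
#' @param m A [character_matrix()].
#' @param a,b Row labels or indices.
#' @param metric `"MORD"` (default) or `"GC"`.
#' @return List with `distance` (NA when no character is comparable) and
#'   `comparable` (count of characters scored in both rows).
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1", "?", "2"),
#'                             B = c("0", "0", "1", "0")),
#'                       ordering = c("unordered", "unordered", "unordered", "ordered"))
#' pair_distance(m, "A", "B", metric = "GC")$distance    # 1
#' pair_distance(m, "A", "B", metric = "MORD")$distance  # 0.75
#' @export
pair_distance <- function(m, a, b, metric = c("MORD", "GC")) {
  metric <- match.arg(metric)
  ranges <- state_ranges(m)
  xa <- m$states[a, ]; xb <- m$states[b, ]
  sumd <- summax <- 0
  ncomp <- 0L
  for (j in seq_len(n_char(m))) {
    if (is.na(xa[j]) || is.na(xb[j])) next
    ordered <- m$ordering[j] == "ordered"
    sumd <- sumd + set_min_dist(xa[j], xb[j], ordered)
    summax <- summax + if (ordered) ranges["max", j] - ranges["min", j] else 1
    ncomp <- ncomp + 1L
  }
  if (ncomp == 0L) return(list(distance = NA_real_, comparable = 0L))
  value <- if (metric == "GC") sumd / ncomp
           else if (summax == 0) 0 else sumd / summax
  list(distance = unname(value), comparable = ncomp)
}

#' Pairwise distance matrix of a character matrix
#'
#' All pairwise GC or MORD distances. Any pair with no character scorable in
#' both taxa has no defined distance and raises an error naming the pair
#' (drop such taxa before ordination).
#'
#' The per-character work is vectorised over taxa via lookup tables between
#' the distinct cell values of each character, so the cost is roughly
#' characters x taxa^2 rather than per-pair loops.
#'
#' @param m A [character_matrix()] with at least 2 taxa.
#' @param metric `"MORD"` (default) or `"GC"`.
#' @return An object of class `morph_dist`: list with `labels`, `d`
#'   (symmetric distance matrix, zero diagonal), `comparable` (matrix of
#'   comparable-character counts) and `metric`.
#' @export
distance_matrix <- function(m, metric = c("MORD", "GC")) {
  metric <- match.arg(metric)
  n <- n_taxa(m)
  if (n < 2L) stop("need at least 2 taxa")
  ranges <- state_ranges(m)
  sumd <- summax <- matrix(0, n, n)
  ncomp <- matrix(0L, n, n)
  for (j in seq_len(n_char(m))) {
    col <- m$states[, j]
    scored <- !is.na(col)
    if (!any(scored)) next
    um <- unique(col[scored])
    u <- length(um)
    ordered <- m$ordering[j] == "ordered"
    dd <- matrix(0, u, u)
    if (u > 1L) {
      for (p in seq_len(u - 1L)) for (q in (p + 1L):u)
        dd[p, q] <- dd[q, p] <- set_min_dist(um[p], um[q], ordered)
    }
    maxj <- if (ordered) ranges["max", j] - ranges["min", j] else 1
    code <- match(col, um)
    code[is.na(code)] <- u + 1L
    ddx <- rbind(cbind(dd, NA_real_), NA_real_)
    contrib <- ddx[code, code, drop = FALSE]
    ok <- !is.na(contrib)
    sumd[ok] <- sumd[ok] + contrib[ok]
    summax[ok] <- summax[ok] + maxj
    ncomp[ok] <- ncomp[ok] + 1L
  }
  d <- if (metric == "GC") sumd / ncomp else sumd / summax
  d[ncomp > 0 & summax == 0 & metric == "MORD"] <- 0
  d[ncomp == 0L] <- NA_real_
  diag(d) <- 0
  labels <- taxon_labels(m)
  dimnames(d) <- dimnames(ncomp) <- list(labels, labels)
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(und)) {
    pairs <- apply(und, 1, function(ij) paste(labels[ij[1]], labels[ij[2]], sep = " / "))
    stop("no comparable characters for pair(s): ",
         paste(utils::head(pairs, 5), collapse = "; "),
         if (nrow(und) > 5) sprintf(" (and %d more)", nrow(und) - 5) else "")
  }
  structure(list(labels = labels, d = d, comparable = ncomp, metric = metric),
            class = "morph_dist")
}

#' @export
print.morph_dist <- function(x, ...) {
  cat("morph_dist:", x$metric, "distances among", length(x$labels), "points\n")
  invisible(x)
}

#' Export a distance matrix as square CSV
#' @param dm A `morph_dist`.
#' @param path Output path.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(dm$d, path, row.names = TRUE)
  invisible(path)
}
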