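# Time-calibrated trees ------------------------------------------------------
#
# A `time_tree` wraps an ape "phylo" object with an explicit root age so that
# every node carries an age in Ma before present (larger = older). Ages are
# what the slicing, ancestral-state and rate machinery consume; branch
# lengths are durations in Ma. Trees must be rooted and fully bifurcating:
# node counts and change tables assume one internal node per speciation.

#' Create a time tree from an ape phylogeny
#'
#' @param phy An `ape::phylo` object, rooted, bifurcating, with branch
#'   lengths in Ma.
#' @param root_age Age of the root in Ma before present. Default: the
#'   maximum root-to-tip path length, which places the farthest tip at age 0
#'   (the present).
#' @return An object of class `time_tree`: a list with `phy`, `root_age` and
#'   `ages` (numeric, indexed by ape node number, tips first).
#' @export
time_tree <- function(phy, root_age = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo object")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy))
    stop("tree contains polytomies; resolve them (e.g. ape::multi2di) before use")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  phy <- ensure_node_labels(phy)
  depths <- ape::node.depth.edgelength(phy)
  if (is.null(root_age)) root_age <- max(depths)
  ages <- root_age - depths
  if (min(ages) < -1e-6)
    stop("negative node age: root_age smaller than the deepest root-to-tip path")
  ages[ages < 0] <- 0
  structure(list(phy = phy, root_age = root_age, ages = ages), class = "time_tree")
}

ensure_node_labels <- function(phy) {
  n <- ape::Ntip(phy)
  need <- is.null(phy$node.label) || any(is.na(phy$node.label)) || any(phy$node.label == "")
  if (need) phy$node.label <- paste0("node", seq_len(phy$Nnode) + n)
  if (anyDuplicated(c(phy$tip.label, phy$node.label)))
    phy$node.label <- paste0("node", seq_len(phy$Nnode) + n)
  phy
}

#' Read a Newick tree as a time tree
#'
#' @param text A Newick string, or the path of a file containing one.
#' @param root_age Optional root age in Ma; defaults to the maximum
#'   root-to-tip path length so the farthest tip sits at the present.
#' @return A [time_tree()].
#' @examples
#' tt <- read_newick_tree("((A:1,B:1):1,C:2);")
#' tt$root_age  # 2
#' @export
read_newick_tree <- function(text, root_age = NULL) {
  phy <- if (grepl("\\(", text)) ape::read.tree(text = text) else ape::read.tree(file = text)
  if (is.null(phy)) stop("could not parse Newick input")
  time_tree(phy, root_age = root_age)
}

#' Write a time tree to Newick
#' @param tt A [time_tree()].
#' @param path Output path; when `NULL` the Newick string is returned.
#' @export
write_newick_tree <- function(tt, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tt$phy))
  ape::write.tree(tt$phy, file = path)
  invisible(path)
}

#' Node ages of a time tree
#' @param tt A [time_tree()].
#' @return Named numeric vector of ages (Ma), one per tip and internal node,
#'   in ape node order.
#' @export
node_ages <- function(tt) {
  stats::setNames(tt$ages, tree_labels(tt))
}

#' Tip and node labels in ape node order
#' @param tt A [time_tree()].
#' @export
tree_labels <- function(tt) c(tt$phy$tip.label, tt$phy$node.label)

# Per-branch bookkeeping used by slicing and rate counting.
branch_table <- function(tt) {
  e <- tt$phy$edge
  lab <- tree_labels(tt)
  data.frame(
    parent = e[, 1], child = e[, 2],
    parent_label = lab[e[, 1]], child_label = lab[e[, 2]],
    parent_age = tt$ages[e[, 1]], child_age = tt$ages[e[, 2]],
    duration = tt$phy$edge.length,
    stringsAsFactors = FALSE
  )
}

#' Trim a time tree to a set of tips
#'
#' Drops all tips not in `keep`, suppressing the resulting unary nodes (their
#' branch durations are summed) while preserving the ages of every retained
#' node — including across a change of root when the old root becomes unary.
#'
#' @param tt A [time_tree()].
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A [time_tree()] on the retained tips.
#' @export
trim_tree <- function(tt, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tt$phy$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("'keep' must contain at least 2 tips")
  old_ages <- stats::setNames(tt$ages[seq_along(tt$phy$tip.label)], tt$phy$tip.label)
  phy <- ape::drop.tip(tt$phy, setdiff(tt$phy$tip.label, keep))
  # root-to-tip depths are preserved by drop.tip, so any retained tip anchors
  # the new root's age
  depths <- ape::node.depth.edgelength(phy)
  tip_idx <- seq_len(ape::Ntip(phy))
  root_age <- max(old_ages[phy$tip.label] + depths[tip_idx])
  time_tree(phy, root_age = root_age)
}

#' Floor zero-length branches
#'
#' Replaces every branch shorter than `floor` with a branch of duration
#' `floor`, then recomputes node ages tip-upward (a parent's age becomes the
#' maximum over its children of child age + branch duration) so that every
#' parent is strictly older than its children. Tip ages are left unchanged.
#'
#' @param tt A [time_tree()].
#' @param floor Minimum branch duration in Ma (default 0.001).
#' @return A [time_tree()] with all branch durations >= `floor`.
#' @export
adjust_zero_branches <- function(tt, floor = 0.001) {
  if (floor <= 0) stop("'floor' must be positive")
  phy <- tt$phy
  n <- ape::Ntip(phy)
  ages <- tt$ages
  # postorder over edges: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")
  eo <- ord$edge
  do <- pmax(ord$edge.length, floor)
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    ages[p] <- max(ages[p], ages[ch] + do[k])
  }
  # rebuild durations from the adjusted ages
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  out <- tt
  out$phy <- phy
  out$ages <- ages
  out$root_age <- ages[n + 1L]
  out
}

#' @export
print.time_tree <- function(x, ...) {
  cat("time_tree:", ape::Ntip(x$phy), "tips,", x$phy$Nnode,
      "internal nodes, root age", format(x$root_age, digits = 6), "Ma\n")
  invisible(x)
}

# Stratigraphic ranges --------------------------------------------------------

#' Read first/last appearance ranges
#'
#' Reads a CSV with columns `taxon`, `fad`, `lad` (first and last appearance
#' data in Ma; extant taxa have `fad = lad = 0`).
#'
#' @param path CSV path.
#' @return A validated data frame of ranges.
#' @export
read_strat_ranges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_strat_ranges(df)
}

validate_strat_ranges <- function(df) {
  need <- c("taxon", "fad", "lad")
  if (!all(need %in% names(df)))
    stop("ranges need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in ranges")
  bad <- df$fad < df$lad | df$lad < 0
  if (any(bad))
    stop("invalid range (need fad >= lad >= 0) for: ",
         paste(df$taxon[bad], collapse = ", "))
  df
}

#' Write stratigraphic ranges to CSV
#' @param ranges Data frame with `taxon`, `fad`, `lad`.
#' @param path Output path.
#' @export
write_strat_ranges <- function(ranges, path) {
  utils::write.csv(validate_strat_ranges(ranges), path, row.names = FALSE)
  invisible(path)
}
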