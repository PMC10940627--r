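# Time bins and tree slicing -------------------------------------------------
#
# Bins are given as a strictly decreasing vector of edges in Ma, oldest
# first. Bin i covers ages [young_i, old_i) — closed at its young edge,
# open at its old edge — except the oldest bin, which is closed at both
# ends. An age exactly on a shared edge therefore belongs to the older bin,
# and age-0 points fall in the youngest bin.

#' Period-level bins used for tip-only disparity
#'
#' Triassic through a combined Neogene-Quaternary bin:
#' 252, 201.4, 145, 66, 23, 0 Ma.
#' @return Numeric vector of bin edges, oldest first.
#' @export
bins_periods <- function() c(252, 201.4, 145, 66, 23, 0)

#' Uniform 10-Ma bins
#' @param oldest,youngest Edges in Ma (defaults 300 and 0).
#' @param width Bin width in Ma (default 10).
#' @return Numeric vector of bin edges, oldest first.
#' @export
bins_10ma <- function(oldest = 300, youngest = 0, width = 10) {
  seq(oldest, youngest, by = -width)
}

#' Time bins for the rate analysis
#'
#' Period-level bins with the Cretaceous split into Early/Late and a
#' combined Neogene-Present bin:
#' 330.36, 299, 252, 201, 145, 100, 66, 23, 0 Ma (8 bins).
#' @return Numeric vector of bin edges, oldest first.
#' @export
bins_rates <- function() c(330.36, 299, 252, 201, 145, 100, 66, 23, 0)

check_bins <- function(bins) {
  if (length(bins) < 2L || any(diff(bins) >= 0))
    stop("'bins' must be a strictly decreasing vector of >= 2 edges (Ma, oldest first)")
  bins
}

#' Bin midpoints
#' @param bins Edge vector, oldest first.
#' @return Midpoint ages, one per bin, oldest first.
#' @export
bin_midpoints <- function(bins) {
  check_bins(bins)
  (bins[-length(bins)] + bins[-1]) / 2
}

bin_labels <- function(bins) {
  paste0(bins[-length(bins)], "-", bins[-1])
}

#' Assign taxa to time bins from stratigraphic ranges
#'
#' A taxon is a member of every bin its `[lad, fad]` range overlaps, under
#' the half-open convention described above: a range touching a shared edge
#' only joins the older bin, and extant taxa (`fad = lad = 0`) join only the
#' youngest bin. Taxa whose range lies entirely outside the bins are dropped
#' with a warning.
#'
#' @param ranges Data frame with `taxon`, `fad`, `lad` (Ma).
#' @param bins Bin edge vector, oldest first.
#' @return Object of class `subset_series`: list of member vectors, one per
#'   bin, with bin metadata attached.
#' @export
bin_membership_discrete <- function(ranges, bins) {
  ranges <- validate_strat_ranges(ranges)
  check_bins(bins)
  nb <- length(bins) - 1L
  members <- vector("list", nb)
  hit <- rep(FALSE, nrow(ranges))
  for (b in seq_len(nb)) {
    old <- bins[b]; young <- bins[b + 1L]
    inb <- ranges$fad >= young & ranges$lad < old
    if (b == 1L) inb <- ranges$fad >= young & ranges$lad <= old
    members[[b]] <- ranges$taxon[inb]
    hit <- hit | inb
  }
  if (any(!hit))
    warning("range(s) outside all bins, excluded: ",
            paste(ranges$taxon[!hit], collapse = ", "))
  structure(list(members = members, bins = bins, times = bin_midpoints(bins),
                 type = "discrete", model = NA_character_, seed = NA_integer_),
            class = "subset_series")
}

#' Sample morphospace occupants at time slices through the tree
#'
#' At slice age `t` every branch spanning `t` (parent older than `t`, child
#' at or younger than `t`) contributes exactly one morphospace row: with
#' `f = (parent_age - t) / (parent_age - child_age)` the child's row is
#' chosen with probability `f` under the gradual-split model (selection
#' probability linear in time along the branch), or with probability 1/2
#' under the punctuated model. A tip or node lying exactly at `t`
#' contributes itself deterministically. The number of points per slice thus
#' equals the number of lineages crossing it, whatever the model or seed.
#'
#' @param tt A [time_tree()].
#' @param times Slice ages in Ma, each within `[0, root age]`; slices older
#'   than the root yield empty sets with a warning.
#' @param model `"gradual_split"` or `"punctuated"`.
#' @param seed Integer seed making the sampling reproducible.
#' @param ord Optional [pcoa()] ordination; when supplied, its rows must
#'   cover all tips and nodes of the tree.
#' @return A `subset_series` whose members are tip/node labels.
#' @export
slice_continuous <- function(tt, times, model = c("gradual_split", "punctuated"),
                             seed = 1L, ord = NULL) {
  model <- match.arg(model)
  if (!is.null(ord)) {
    missing_rows <- setdiff(tree_labels(tt), ord$labels)
    if (length(missing_rows))
      stop("ordination lacks rows for: ", paste(utils::head(missing_rows, 5), collapse = ", "))
  }
  bt <- branch_table(tt)
  root_label <- tt$phy$node.label[1]
  if (any(times > tt$root_age + 1e-9))
    warning("slice(s) older than the root yield empty sets")
  set.seed(seed)
  members <- lapply(times, function(t) {
    if (t > tt$root_age + 1e-9) return(character(0))
    if (abs(t - tt$root_age) <= 1e-9) return(root_label)
    cross <- bt$parent_age > t + 1e-12 & bt$child_age <= t + 1e-12
    seg <- bt[cross, , drop = FALSE]
    if (nrow(seg) == 0L) return(character(0))
    f <- (seg$parent_age - t) / (seg$parent_age - seg$child_age)
    p_child <- switch(model,
                      gradual_split = f,
                      punctuated = ifelse(abs(seg$child_age - t) <= 1e-12, 1, 0.5))
    take_child <- stats::runif(nrow(seg)) < p_child
    # a child exactly at the slice contributes itself deterministically
    take_child[abs(seg$child_age - t) <= 1e-12] <- TRUE
    ifelse(take_child, seg$child_label, seg$parent_label)
  })
  structure(list(members = members, bins = NULL, times = times,
                 type = "continuous", model = model, seed = seed),
            class = "subset_series")
}

#' @export
print.subset_series <- function(x, ...) {
  cat("subset_series (", x$type, "): ", length(x$members), " subsets, n = ",
      paste(vapply(x$members, length, integer(1)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export a subset series as TSV
#' @param ss A `subset_series`.
#' @param path Output path.
#' @param tt Optional [time_tree()] used to label members as tip or node.
#' @export
write_subsets_tsv <- function(ss, path, tt = NULL) {
  rows <- do.call(rbind, lapply(seq_along(ss$members), function(i) {
    mem <- ss$members[[i]]
    if (length(mem) == 0L) return(NULL)
    data.frame(time = ss$times[i], member = mem)
  }))
  if (is.null(rows))
    rows <- data.frame(time = numeric(0), member = character(0))
  if (!is.null(tt))
    rows$source <- ifelse(rows$member %in% tt$phy$tip.label, "tip", "node")
  rows$model <- ss$model
  rows$seed <- ss$seed
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
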