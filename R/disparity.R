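# Disparity metrics, bootstrap and rarefaction -------------------------------
#
# Two metrics summarise a set of morphospace points across ALL retained
# ordination axes (a leading-axes subset would make the value depend on an
# arbitrary cut-off): the sum of per-axis sample variances measures the size
# of the occupied space, and the mean Euclidean distance from the origin its
# position (the origin, not the subset centroid — positional shifts are the
# point of the metric).

#' Sum of variances of a point set
#'
#' Sum over axes of the sample variance (denominator n-1) of the
#' coordinates; 0 for a single point.
#'
#' @param points Numeric matrix, points x axes.
#' @return Non-negative scalar.
#' @export
sum_of_variances <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (nrow(points) == 1L) return(0)
  sum(apply(points, 2, stats::var))
}

#' Mean distance from the morphospace origin
#'
#' Mean Euclidean norm of the points over all axes.
#'
#' @param points Numeric matrix, points x axes.
#' @return Non-negative scalar.
#' @export
mean_dist_from_origin <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  mean(sqrt(rowSums(points^2)))
}

disparity_metric <- function(name) {
  switch(name,
         sum_of_variances = sum_of_variances,
         mean_dist_from_origin = mean_dist_from_origin,
         stop("unknown metric '", name, "'"))
}

#' Bootstrapped disparity through time
#'
#' For each subset (time bin or slice) the observed metric plus `n_boot`
#' bootstrap replicates: resamples with replacement of size n — or of size
#' `rarefy_to` when given and smaller than n, which holds sampling constant
#' across bins — summarised by the 2.5/25/50/75/97.5 percentiles. Empty bins
#' produce a gap (NA row), not a zero: absence of data is not absence of
#' disparity. Single-point bins are flagged degenerate.
#'
#' @param subsets A `subset_series` from [bin_membership_discrete()] or
#'   [slice_continuous()].
#' @param ord A [pcoa()] ordination containing every subset member.
#' @param metric `"sum_of_variances"` or `"mean_dist_from_origin"`.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param rarefy_to Optional fixed resample size.
#' @param seed Integer seed.
#' @return Object of class `disparity_curve`: a data frame with one row per
#'   subset (`time`, `n`, `observed`, `p2.5` ... `p97.5`, `degenerate`);
#'   the replicate matrix and settings are attached as attributes.
#' @export
bootstrap_disparity <- function(subsets, ord,
                                metric = c("sum_of_variances", "mean_dist_from_origin"),
                                n_boot = 500L, rarefy_to = NULL, seed = 1L) {
  metric <- match.arg(metric)
  if (n_boot < 1L) stop("'n_boot' must be >= 1")
  fn <- disparity_metric(metric)
  unknown <- setdiff(unique(unlist(subsets$members)), ord$labels)
  if (length(unknown))
    stop("subset member(s) not in ordination: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  set.seed(seed)
  nb <- length(subsets$members)
  reps <- matrix(NA_real_, n_boot, nb)
  rows <- vector("list", nb)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  for (b in seq_len(nb)) {
    mem <- subsets$members[[b]]
    n <- length(mem)
    if (n == 0L) {
      rows[[b]] <- data.frame(time = subsets$times[b], n = 0L, observed = NA_real_,
                              p2.5 = NA_real_, p25 = NA_real_, p50 = NA_real_,
                              p75 = NA_real_, p97.5 = NA_real_, degenerate = NA)
      next
    }
    pts <- ord$coords[mem, , drop = FALSE]
    size <- if (!is.null(rarefy_to) && rarefy_to < n) rarefy_to else n
    reps[, b] <- vapply(seq_len(n_boot), function(r) {
      fn(pts[sample.int(n, size, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    qv <- stats::quantile(reps[, b], qs, names = FALSE)
    rows[[b]] <- data.frame(time = subsets$times[b], n = n, observed = fn(pts),
                            p2.5 = qv[1], p25 = qv[2], p50 = qv[3],
                            p75 = qv[4], p97.5 = qv[5], degenerate = n < 2L)
  }
  out <- do.call(rbind, rows)
  if (!is.null(subsets$bins)) out$bin <- bin_labels(subsets$bins)
  attr(out, "replicates") <- reps
  attr(out, "metric") <- metric
  attr(out, "n_boot") <- n_boot
  attr(out, "rarefaction") <- if (is.null(rarefy_to)) NA_integer_ else rarefy_to
  attr(out, "model") <- subsets$model
  attr(out, "seed") <- seed
  class(out) <- c("disparity_curve", "data.frame")
  out
}

#' Restrict an ordination to a clade
#'
#' Keeps the rows of an existing morphospace that belong to a clade —
#' coordinates are NOT re-ordinated, so clade curves stay commensurable with
#' the full-space ones. The clade is either the most recent common ancestor
#' of `tips` (all its descendant tips and nodes, the MRCA included) or an
#' explicit `labels` vector.
#'
#' @param ord A [pcoa()] ordination.
#' @param tt A [time_tree()] (needed when `tips` is used).
#' @param tips Tip labels whose MRCA defines the clade.
#' @param labels Explicit row labels (alternative to `tips`).
#' @return An `ordination` restricted to the clade's rows.
#' @export
subset_by_clade <- function(ord, tt = NULL, tips = NULL, labels = NULL) {
  if (is.null(labels)) {
    if (is.null(tt) || is.null(tips)) stop("supply 'labels', or 'tt' plus 'tips'")
    labels <- clade_members(tt, tips)
  }
  labels <- unique(labels)
  if (length(labels) == 0L) stop("empty clade")
  missing_rows <- setdiff(labels, ord$labels)
  if (length(missing_rows))
    stop("labels not in ordination: ", paste(utils::head(missing_rows, 5), collapse = ", "))
  keep <- ord$labels[ord$labels %in% labels]
  out <- ord
  out$labels <- keep
  out$coords <- ord$coords[keep, , drop = FALSE]
  out
}

# All tip and node labels of the clade spanned by `tips` (MRCA included).
clade_members <- function(tt, tips) {
  phy <- tt$phy
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1L) return(tips)
  mrca <- ape::getMRCA(phy, tips)
  desc <- descendant_nodes(phy, mrca)
  lab <- tree_labels(tt)
  lab[c(mrca, desc)]
}

# All descendants (tips and internal nodes) of `node`, by edge traversal.
descendant_nodes <- function(phy, node) {
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  out <- kids
  while (length(kids)) {
    kids <- phy$edge[phy$edge[, 1] %in% kids, 2]
    out <- c(out, kids)
  }
  out
}

#' Export a disparity curve as tidy CSV
#' @param curve A `disparity_curve`.
#' @param path Output path.
#' @export
write_disparity_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$metric <- attr(curve, "metric")
  df$rarefaction <- attr(curve, "rarefaction")
  df$model <- attr(curve, "model")
  df$seed <- attr(curve, "seed")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
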