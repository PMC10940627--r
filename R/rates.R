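# Poisson models of character-change rates -----------------------------------
#
# Changes are counted between the assigned states at the two ends of every
# branch (|x - y| for ordered characters, 0/1 for unordered; characters
# missing at either end contribute neither changes nor exposure). Exposure
# is branch duration x number of scorable characters, so a rate is in
# character changes per Ma per character-lineage and stays comparable across
# bins with uneven missing data. A branch crossing several bins has its
# changes and exposure apportioned proportionally to the duration spent in
# each bin.

#' Count inferred character changes per branch and time bin
#'
#' @param tt A [time_tree()].
#' @param augmented Node-augmented matrix from [reconstruct_all()] on the
#'   same tree (tip rows may be polymorphic; the minimum-distance rule is
#'   used, as for distances).
#' @param bins Bin edge vector, oldest first, covering the whole tree span.
#' @return Object of class `change_table`: data frame with one row per
#'   (branch, bin) with positive overlap — `branch` (child node/tip label),
#'   `bin`, `bin_old`, `bin_young`, `changes`, `exposure` — plus per-branch
#'   totals in attributes.
#' @export
count_changes <- function(tt, augmented, bins) {
  check_bins(bins)
  if (bins[1] < tt$root_age - 1e-9)
    stop("bins do not cover the tree: oldest edge ", bins[1],
         " < root age ", format(tt$root_age))
  lab <- tree_labels(tt)
  if (!all(lab %in% taxon_labels(augmented)))
    stop("augmented matrix lacks rows for some tips/nodes")
  st <- augmented$states[lab, , drop = FALSE]
  ord_flags <- augmented$ordering == "ordered"
  bt <- branch_table(tt)
  nb <- length(bins) - 1L
  rows <- vector("list", nrow(bt))
  for (e in seq_len(nrow(bt))) {
    xa <- st[bt$parent_label[e], ]
    xb <- st[bt$child_label[e], ]
    comp <- which(!is.na(xa) & !is.na(xb))
    n_scor <- length(comp)
    ch <- 0
    for (j in comp) ch <- ch + set_min_dist(xa[j], xb[j], ord_flags[j])
    dur <- bt$duration[e]
    expo <- dur * n_scor
    # apportion to bins by overlap of [child_age, parent_age] with each bin
    old_a <- bt$parent_age[e]; young_a <- bt$child_age[e]
    ov <- pmax(0, pmin(old_a, bins[-length(bins)]) - pmax(young_a, bins[-1]))
    if (dur > 0) frac <- ov / dur
    else { # zero-duration branch: assign to the bin holding its age
      frac <- rep(0, nb)
      b <- which(young_a >= bins[-1] & young_a < bins[-length(bins)])
      if (length(b) == 0L) b <- 1L
      frac[b[1]] <- 1
    }
    keep <- which(frac > 0)
    if (length(keep) == 0L) next
    rows[[e]] <- data.frame(
      branch = bt$child_label[e], bin = keep,
      bin_old = bins[keep], bin_young = bins[keep + 1L],
      changes = ch * frac[keep], exposure = expo * frac[keep]
    )
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("change_table", "data.frame"),
            bins = bins, n_bins = nb)
}

#' Enumerate contiguous partitions of ordered time bins
#'
#' All ways of cutting `B` ordered bins into contiguous blocks that share a
#' rate: one partition per subset of the `B - 1` internal boundaries, hence
#' `2^(B-1)` partitions.
#'
#' @param B Number of bins (>= 1).
#' @return List of integer vectors; element `i` of a vector is the block
#'   (rate class) of bin `i`.
#' @examples
#' length(enumerate_contiguous_partitions(8)) # 128
#' @export
enumerate_contiguous_partitions <- function(B) {
  if (B < 1L) stop("'B' must be >= 1")
  if (B == 1L) return(list(1L))
  lapply(0:(2^(B - 1L) - 1L), function(mask) {
    cuts <- bitwAnd(bitwShiftR(mask, 0:(B - 2L)), 1L)
    cumsum(c(1L, cuts))
  })
}

# Shared Poisson fit over arbitrary rate classes. `cls` assigns each row of
# the change table to a class.
fit_poisson_classes <- function(ct, cls, partition = NULL) {
  ok <- ct$exposure > 0
  cells <- ct[ok, , drop = FALSE]
  cls <- cls[ok]
  if (any(table(factor(cls, levels = unique(cls))) == 0))
    stop("empty rate class")
  tot_c <- tapply(cells$changes, cls, sum)
  tot_t <- tapply(cells$exposure, cls, sum)
  if (any(tot_t <= 0)) stop("rate class with zero exposure")
  lambda <- tot_c / tot_t
  lam_cell <- lambda[as.character(cls)]
  mu <- lam_cell * cells$exposure
  term <- ifelse(cells$changes == 0 & mu == 0, 0,
                 cells$changes * log(mu) - mu - lgamma(cells$changes + 1))
  lnL <- sum(term)
  k <- length(lambda)
  n <- nrow(cells)
  aicc <- -2 * lnL + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(partition = partition, classes = sort(unique(cls)),
                 lambda = as.numeric(lambda), class_labels = names(lambda),
                 lnL = lnL, k = k, n = n, AICc = aicc),
            class = "rate_model")
}

#' Fit a Poisson rate model for a bin partition
#'
#' Each block of contiguous bins shares one rate; the maximum-likelihood
#' rate of a block is total changes / total exposure over its cells. The
#' log-likelihood treats each (branch, bin) cell with positive exposure as
#' an independent Poisson observation, and AICc uses that cell count as the
#' sample size: `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param ct A [count_changes()] table.
#' @param partition Integer vector assigning each bin to a block, e.g.
#'   `c(1, 1, 2)`, as produced by [enumerate_contiguous_partitions()].
#' @return A `rate_model`: `lambda` per block (changes per Ma per
#'   character-lineage), `lnL`, `k`, `n`, `AICc`.
#' @export
fit_rate_model <- function(ct, partition) {
  nb <- attr(ct, "n_bins")
  if (length(partition) != nb)
    stop("partition length ", length(partition), " != number of bins ", nb)
  fit_poisson_classes(ct, partition[ct$bin], partition = partition)
}

#' Select the best rate model by AICc
#'
#' @param models List of `rate_model` objects.
#' @return List with `best` (minimal AICc; ties broken by smaller `k`, then
#'   list order), `table` (one row per model with `delta_AICc`) and `models`.
#' @export
select_best <- function(models) {
  if (length(models) == 0L) stop("no models")
  tab <- data.frame(
    model = seq_along(models),
    partition = vapply(models, function(m)
      if (is.null(m$partition)) NA_character_ else paste(m$partition, collapse = ""),
      character(1)),
    k = vapply(models, function(m) m$k, numeric(1)),
    lnL = vapply(models, function(m) m$lnL, numeric(1)),
    AICc = vapply(models, function(m) m$AICc, numeric(1))
  )
  ord <- order(tab$AICc, tab$k, tab$model)
  best_i <- ord[1]
  tab$delta_AICc <- tab$AICc - tab$AICc[best_i]
  list(best = models[[best_i]], best_index = best_i, table = tab, models = models)
}

#' Fit all contiguous time-bin rate models and select by AICc
#'
#' Convenience wrapper: enumerates every contiguous partition of the table's
#' bins (128 models for the default 8 bins), fits each and selects the best.
#'
#' @param ct A [count_changes()] table.
#' @return As [select_best()].
#' @export
fit_time_models <- function(ct) {
  parts <- enumerate_contiguous_partitions(attr(ct, "n_bins"))
  select_best(lapply(parts, function(p) fit_rate_model(ct, p)))
}

#' Compare clade rates against the background
#'
#' Fits (a) a single-rate model over all branches and (b), for each named
#' clade, a two-rate model separating the clade's branches from the
#' background, with exposures summed over all time. AICc decides whether a
#' separate clade rate is warranted.
#'
#' @param ct A [count_changes()] table.
#' @param clades Named list of branch-label vectors (branches are identified
#'   by their child tip/node label, see [clade_branches()]). No clade may
#'   cover every branch.
#' @return As [select_best()]; the model table rows are named
#'   `single` and one per clade.
#' @export
fit_clade_models <- function(ct, clades) {
  if (length(clades) == 0L || is.null(names(clades)))
    stop("'clades' must be a named list of branch-label vectors")
  models <- list(fit_poisson_classes(ct, rep(1L, nrow(ct)), partition = NULL))
  for (nm in names(clades)) {
    br <- clades[[nm]]
    if (length(br) == 0L) stop("empty clade branch set: ", nm)
    inside <- ct$branch %in% br
    if (all(inside)) stop("clade '", nm, "' covers every branch; no background left")
    if (!any(inside)) stop("clade '", nm, "' matches no branch in the change table")
    models <- c(models, list(fit_poisson_classes(ct, ifelse(inside, 2L, 1L))))
  }
  out <- select_best(models)
  out$table$model <- c("single", names(clades))
  out
}

#' Branch set of a clade
#'
#' The branches (identified by child label) inside the clade spanned by the
#' MRCA of `tips` — i.e. every edge whose child is the MRCA's descendant.
#' The stem branch leading to the MRCA is excluded (crown-group reading);
#' set `include_stem = TRUE` to add it.
#'
#' @param tt A [time_tree()].
#' @param tips Tip labels defining the clade.
#' @param include_stem Include the branch subtending the MRCA?
#' @return Character vector of child labels.
#' @export
clade_branches <- function(tt, tips, include_stem = FALSE) {
  phy <- tt$phy
  if (length(tips) < 2L) stop("need >= 2 tips to define a clade")
  mrca <- ape::getMRCA(phy, tips)
  desc <- descendant_nodes(phy, mrca)
  lab <- tree_labels(tt)
  out <- lab[desc]
  if (include_stem) out <- c(lab[mrca], out)
  out
}

#' Per-bin point rate estimates
#'
#' The saturated estimate (one rate per bin): total changes over total
#' exposure within each bin.
#'
#' @param ct A [count_changes()] table.
#' @return Data frame with `bin`, `bin_old`, `bin_young`, `changes`,
#'   `exposure`, `rate`.
#' @export
rate_points <- function(ct) {
  bins <- attr(ct, "bins")
  agg_c <- tapply(ct$changes, ct$bin, sum)
  agg_t <- tapply(ct$exposure, ct$bin, sum)
  b <- as.integer(names(agg_c))
  data.frame(bin = b, bin_old = bins[b], bin_young = bins[b + 1L],
             changes = as.numeric(agg_c), exposure = as.numeric(agg_t),
             rate = as.numeric(agg_c) / as.numeric(agg_t))
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model: k =", x$k, " lnL =", format(x$lnL, digits = 6),
      " AICc =", format(x$AICc, digits = 6), "\n")
  cat("  lambda:", paste(format(x$lambda, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Export a model-selection table as CSV
#' @param sel Result of [select_best()] / [fit_time_models()].
#' @param path Output path.
#' @export
write_rate_models_csv <- function(sel, path) {
  tab <- sel$table
  tab$lambda <- vapply(sel$models, function(m)
    paste(format(m$lambda, digits = 6), collapse = ";"), character(1))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
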