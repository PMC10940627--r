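# End-to-end analyses --------------------------------------------------------
#
# Two published-style analyses from one configuration:
#   OT    — "only taxa": distances + PCoA on the tips, discrete bin
#           membership from stratigraphic ranges, bootstrapped disparity.
#   POASR — ancestral states are reconstructed first, tips and nodes are
#           ordinated together, the tree is sliced continuously through
#           time, and rate / environmental analyses follow.
# One seed in the config is split deterministically per stage, so whole runs
# are reproducible while stages stay independent.

#' Build an analysis configuration
#'
#' Inputs may be in-memory objects ([character_matrix()], [time_tree()],
#' range data frames) or file paths (NEXUS, Newick, CSV), which are loaded
#' on construction.
#'
#' @param matrix Character matrix or NEXUS path.
#' @param tree Time tree or Newick path (required for POASR).
#' @param ranges Ranges data frame or CSV path (required for OT).
#' @param clades Optional named list of tip-label vectors.
#' @param env Optional named list of environmental series (numeric vectors
#'   on the slice grid, oldest first) or CSV paths.
#' @param bins `"periods"`, `"10ma"`, or a custom decreasing edge vector.
#' @param rate_bins Edge vector for the rate analysis (default
#'   [bins_rates()]).
#' @param slice_models Subset of `c("gradual_split", "punctuated")`.
#' @param metrics Subset of the disparity metric names.
#' @param n_boot Bootstrap replicates (default 500).
#' @param rarefy Rarefaction levels, e.g. `c(6, 3)`; `NA` entries mean
#'   unrarefied and one unrarefied curve is always produced.
#' @param seed Master seed.
#' @param outdir Optional directory for CSV exports.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(matrix, tree = NULL, ranges = NULL, clades = NULL,
                            env = NULL, bins = "periods",
                            rate_bins = bins_rates(),
                            slice_models = c("gradual_split", "punctuated"),
                            metrics = c("sum_of_variances", "mean_dist_from_origin"),
                            n_boot = 500L, rarefy = c(6L, 3L), seed = 1L,
                            outdir = NULL) {
  if (is.character(matrix)) matrix <- read_nexus_matrix(matrix)
  if (is.character(tree)) tree <- read_newick_tree(tree)
  if (is.character(ranges)) ranges <- read_strat_ranges(ranges)
  if (!is.null(env))
    env <- lapply(env, function(e) if (is.character(e)) read_series_csv(e)$value else e)
  if (is.character(bins) && length(bins) == 1L)
    bins <- switch(bins, periods = bins_periods(), "10ma" = bins_10ma(),
                   stop("unknown bin preset '", bins, "'"))
  check_bins(bins)
  slice_models <- match.arg(slice_models, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  structure(list(matrix = matrix, tree = tree, ranges = ranges, clades = clades,
                 env = env, bins = bins, rate_bins = rate_bins,
                 slice_models = slice_models, metrics = metrics,
                 n_boot = as.integer(n_boot), rarefy = rarefy,
                 seed = as.integer(seed), outdir = outdir),
            class = "analysis_config")
}

# Deterministic per-stage seeds below 2^31.
stage_seed <- function(seed, stage) {
  (seed * 7919L + stage * 104729L) %% 2147483629L
}

curve_set <- function(subsets, ord, config, model_tag) {
  levels <- unique(c(NA_integer_, config$rarefy))
  out <- list()
  i <- 0L
  for (metric in config$metrics) {
    for (lv in levels) {
      i <- i + 1L
      cv <- bootstrap_disparity(
        subsets, ord, metric = metric, n_boot = config$n_boot,
        rarefy_to = if (is.na(lv)) NULL else lv,
        seed = stage_seed(config$seed, 100L + i)
      )
      nm <- paste0(metric, if (is.na(lv)) "" else paste0("_rarefy", lv),
                   if (!is.na(model_tag)) paste0("_", model_tag) else "")
      out[[nm]] <- cv
    }
  }
  out
}

#' Run the tips-only (OT) disparity analysis
#'
#' MORD distances among the scored taxa, PCoA (Cailliez), discrete time-bin
#' membership from the stratigraphic ranges, and bootstrapped disparity
#' curves for each configured metric and rarefaction level.
#'
#' @param config An [analysis_config()] with `matrix` and `ranges`.
#' @return List with `ordination`, `subsets` and `curves` (one
#'   `disparity_curve` per metric x rarefaction level).
#' @export
run_ot <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$ranges)) stop("OT analysis needs stratigraphic ranges")
  dm <- distance_matrix(config$matrix, metric = "MORD")
  ord <- pcoa(dm, correction = "cailliez")
  subsets <- bin_membership_discrete(config$ranges, config$bins)
  curves <- curve_set(subsets, ord, config, NA_character_)
  res <- list(ordination = ord, subsets = subsets, curves = curves)
  export_results(res, config, prefix = "ot")
  res
}

#' Run the node-augmented (POASR) analysis
#'
#' Ancestral states are reconstructed for every character, tips and nodes
#' are ordinated together, and the tree is sliced at the midpoints of the
#' configured bins under each slicing model. Change counting, exhaustive
#' time-bin rate models with AICc selection, optional clade rate models and
#' optional environmental correlations follow.
#'
#' @param config An [analysis_config()] with `matrix` and `tree`.
#' @return List with `augmented`, `ordination`, `curves`, `clade_curves`,
#'   `rates` (point estimates, full AICc table and best model),
#'   `clade_rates`, `env_correlations`.
#' @export
run_poasr <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$tree)) stop("POASR analysis needs a time tree")
  tt <- config$tree
  aug <- reconstruct_all(tt, config$matrix)
  dm <- distance_matrix(aug, metric = "MORD")
  ord <- pcoa(dm, correction = "cailliez")
  times <- bin_midpoints(config$bins)
  times <- times[times <= tt$root_age]

  curves <- list()
  for (model in config$slice_models) {
    ss <- slice_continuous(tt, times, model = model,
                           seed = stage_seed(config$seed, match(model, config$slice_models)))
    curves <- c(curves, curve_set(ss, ord, config,
                                  model_tag = sub("_split", "", model)))
  }

  clade_curves <- list()
  if (!is.null(config$clades)) {
    for (nm in names(config$clades)) {
      sub_ord <- subset_by_clade(ord, tt, tips = config$clades[[nm]])
      ss <- slice_continuous(tt, times, model = config$slice_models[1],
                             seed = stage_seed(config$seed, 50L))
      ss$members <- lapply(ss$members, intersect, sub_ord$labels)
      clade_curves[[nm]] <- bootstrap_disparity(
        ss, sub_ord, metric = config$metrics[1], n_boot = config$n_boot,
        seed = stage_seed(config$seed, 60L + match(nm, names(config$clades))))
    }
  }

  ct <- count_changes(tt, aug, config$rate_bins)
  rates <- fit_time_models(ct)
  rates$points <- rate_points(ct)

  clade_rates <- NULL
  if (!is.null(config$clades)) {
    branch_sets <- lapply(config$clades, function(tp) clade_branches(tt, tp))
    clade_rates <- fit_clade_models(ct, branch_sets)
  }

  env_cor <- NULL
  if (!is.null(config$env)) {
    env_cor <- list()
    for (dnm in names(config$env)) {
      for (cnm in names(curves)) {
        med <- curves[[cnm]]$p50
        if (anyNA(med) || length(med) != length(config$env[[dnm]])) next
        env_cor[[paste(dnm, cnm, sep = ".")]] <-
          correlate_disparity_series(config$env[[dnm]], med)
      }
    }
  }

  res <- list(augmented = aug, ordination = ord, curves = curves,
              clade_curves = clade_curves, change_table = ct, rates = rates,
              clade_rates = clade_rates, env_correlations = env_cor)
  export_results(res, config, prefix = "poasr")
  res
}

#' POASR disparity across several trees
#'
#' Re-runs the ordination + disparity stages of [run_poasr()] on each tree
#' (e.g. a posterior sample) and summarises the per-bin medians across
#' trees. Trees whose tips do not match the matrix are skipped with a
#' warning.
#'
#' @param config An [analysis_config()].
#' @param trees List of [time_tree()] objects sharing the matrix's tips.
#' @return List with `per_tree` (matrix of per-bin medians, trees x bins)
#'   and `envelope` (per-bin min/median/max across trees).
#' @export
run_multitree <- function(config, trees) {
  if (length(trees) == 0L) stop("no trees supplied")
  metric <- config$metrics[1]
  model <- config$slice_models[1]
  meds <- list()
  for (i in seq_along(trees)) {
    tt <- trees[[i]]
    if (!setequal(tt$phy$tip.label, taxon_labels(config$matrix))) {
      warning("tree ", i, " skipped: tip labels do not match the matrix")
      next
    }
    aug <- reconstruct_all(tt, config$matrix)
    ord <- pcoa(distance_matrix(aug, metric = "MORD"), correction = "cailliez")
    times <- bin_midpoints(config$bins)
    times <- times[times <= tt$root_age]
    # same per-stage seeds as run_poasr's first curve, so a single-tree run
    # reproduces its medians exactly
    ss <- slice_continuous(tt, times, model = model,
                           seed = stage_seed(config$seed, 1L))
    cv <- bootstrap_disparity(ss, ord, metric = metric, n_boot = config$n_boot,
                              seed = stage_seed(config$seed, 101L))
    meds[[length(meds) + 1L]] <- stats::setNames(cv$p50, signif(cv$time, 10))
  }
  if (length(meds) == 0L) stop("no usable tree")
  all_times <- names(meds[[1]])
  per_tree <- do.call(rbind, lapply(meds, function(x) x[all_times]))
  na_safe <- function(x, f) if (all(is.na(x))) NA_real_ else f(x[!is.na(x)])
  envelope <- data.frame(
    time = as.numeric(all_times),
    min = apply(per_tree, 2, na_safe, min),
    median = apply(per_tree, 2, na_safe, stats::median),
    max = apply(per_tree, 2, na_safe, max)
  )
  list(per_tree = per_tree, envelope = envelope)
}

export_results <- function(res, config, prefix) {
  if (is.null(config$outdir)) return(invisible(NULL))
  od <- config$outdir
  if (!is.null(res$ordination))
    write_ordination_csv(res$ordination,
                         file.path(od, paste0(prefix, "_coords.csv")),
                         file.path(od, paste0(prefix, "_eigenvalues.csv")))
  for (nm in names(res$curves))
    write_disparity_csv(res$curves[[nm]],
                        file.path(od, paste0(prefix, "_curve_", nm, ".csv")))
  if (!is.null(res$rates)) {
    write_rate_models_csv(res$rates, file.path(od, paste0(prefix, "_rate_models.csv")))
    utils::write.csv(res$rates$points,
                     file.path(od, paste0(prefix, "_rate_points.csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$clade_rates))
    write_rate_models_csv(res$clade_rates,
                          file.path(od, paste0(prefix, "_clade_rate_models.csv")))
  invisible(NULL)
}
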