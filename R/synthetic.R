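# Synthetic data with known truth --------------------------------------------
#
# Generators for dated trees with fossil and extant tips, Mk-evolved
# multistate characters with time-varying rates, masked missing data and
# ARIMA-like environmental series. Every generated quantity the estimators
# target (true per-bin change counts, true node states) is recorded, so the
# whole pipeline can be validated end to end without external data.

#' Simulate a dated tree with extinct and extant tips
#'
#' A birth-death tree is grown over `root_age` Ma (via `ape::rlineage`);
#' lineages that die before the present become fossil tips at their
#' extinction age. The simulation is retried until at least `n_extant`
#' survivors and `n_fossil` extinct tips exist, then exactly that many of
#' each are kept (uniformly sampled) and the tree is trimmed with ages
#' preserved. Fossil tips receive a stratigraphic range bracketing their
#' age (`fad = age + U(0, range_window)`, `lad = max(0, age - U(0,
#' range_window))`); extant tips get `fad = lad = 0`.
#'
#' @param n_extant,n_fossil Numbers of surviving and fossil tips
#'   (`n_extant + n_fossil >= 2`).
#' @param root_age Age of the simulation origin in Ma (default 300).
#' @param birth,death Per-lineage rates per Ma. By default `death = 0.02`
#'   and `birth = death + log(max(n_extant, 2)) / root_age`, which targets
#'   roughly `n_extant` survivors in expectation.
#' @param range_window Half-width bound of the FAD/LAD bracket (Ma).
#' @param fossil_sampling `"stratified_age"` (default) spreads the sampled
#'   fossils across the time span by picking one extinct tip per age
#'   quantile, mirroring a fossil record with occurrences throughout the
#'   clade's history; `"uniform"` samples extinct tips uniformly, which
#'   under birth-death concentrates fossils near the present.
#' @param seed Integer seed.
#' @param max_tries Retries before giving up.
#' @return List with `tree` (a [time_tree()]) and `ranges` (taxon/fad/lad
#'   data frame).
#' @export
simulate_tree <- function(n_extant, n_fossil, root_age = 300, birth = NULL,
                          death = 0.02, range_window = 5,
                          fossil_sampling = c("stratified_age", "uniform"),
                          seed = 1L, max_tries = 200L) {
  fossil_sampling <- match.arg(fossil_sampling)
  if (n_extant + n_fossil < 2L) stop("need at least 2 tips in total")
  if (is.null(birth)) birth <- death + log(max(n_extant, 2)) / root_age
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    phy <- tryCatch(ape::rlineage(birth, death, Tmax = root_age),
                    error = function(e) NULL)
    if (is.null(phy) || ape::Ntip(phy) < 2L || ape::Ntip(phy) > 10000L) next
    tt <- tryCatch(time_tree(phy, root_age = root_age), error = function(e) NULL)
    if (is.null(tt)) next
    tip_ages <- tt$ages[seq_len(ape::Ntip(phy))]
    extant <- phy$tip.label[tip_ages <= 1e-8]
    fossil <- phy$tip.label[tip_ages > 1e-8]
    if (length(extant) < n_extant || length(fossil) < n_fossil) next
    picked_fossil <- if (n_fossil == 0L) character(0)
    else if (fossil_sampling == "uniform" || n_fossil == length(fossil)) {
      sample(fossil, n_fossil)
    } else {
      # one fossil per age quantile, so the sample spans the record
      ord_f <- fossil[order(tip_ages[match(fossil, phy$tip.label)])]
      grp <- cut(seq_along(ord_f), breaks = n_fossil, labels = FALSE)
      vapply(split(ord_f, grp), function(g) g[sample.int(length(g), 1L)], character(1))
    }
    keep <- c(sample(extant, n_extant), picked_fossil)
    out <- tryCatch(trim_tree(tt, keep), error = function(e) NULL)
    if (is.null(out)) next
    ages <- node_ages(out)[out$phy$tip.label]
    is_ext <- ages <= 1e-8
    fad <- ifelse(is_ext, 0, ages + stats::runif(length(ages), 0, range_window))
    lad <- ifelse(is_ext, 0, pmax(0, ages - stats::runif(length(ages), 0, range_window)))
    ranges <- data.frame(taxon = out$phy$tip.label, fad = fad, lad = lad,
                         row.names = NULL)
    return(list(tree = out, ranges = validate_strat_ranges(ranges)))
  }
  stop("could not simulate a tree with ", n_extant, " extant and ",
       n_fossil, " fossil tips in ", max_tries, " tries; adjust birth/death")
}

#' Pick a clade of intermediate size from a tree
#'
#' Utility for clade-level tests: samples an internal (non-root) node whose
#' descendant tip count lies in `[min_tips, max_frac * n_tips]` and returns
#' its tip labels.
#'
#' @param tt A [time_tree()].
#' @param min_tips Minimum clade tip count (default 3).
#' @param max_frac Maximum fraction of all tips (default 0.5).
#' @param seed Integer seed.
#' @return Character vector of tip labels.
#' @export
sample_clade <- function(tt, min_tips = 3L, max_frac = 0.5, seed = 1L) {
  phy <- tt$phy
  n <- ape::Ntip(phy)
  set.seed(seed)
  nodes <- setdiff(n + seq_len(phy$Nnode), n + 1L)
  sizes <- vapply(nodes, function(v) {
    d <- descendant_nodes(phy, v)
    sum(d <= n)
  }, numeric(1))
  ok <- nodes[sizes >= min_tips & sizes <= max_frac * n]
  if (length(ok) == 0L) stop("no clade of the requested size exists")
  v <- if (length(ok) == 1L) ok else sample(ok, 1)
  d <- descendant_nodes(phy, v)
  phy$tip.label[d[d <= n]]
}

check_rate_blocks <- function(blocks, root_age) {
  need <- c("old", "young", "rate")
  if (!all(need %in% names(blocks))) stop("rate blocks need columns old, young, rate")
  if (any(blocks$rate < 0)) stop("rates must be >= 0")
  if (blocks$old[1] < root_age - 1e-9) stop("first block must cover the root age")
  if (utils::tail(blocks$young, 1) != 0) stop("last block must end at 0 Ma")
  if (nrow(blocks) > 1 && any(abs(blocks$young[-nrow(blocks)] - blocks$old[-1]) > 1e-9))
    stop("rate blocks must tile the time span contiguously")
  blocks
}

#' Simulate discrete characters down a dated tree
#'
#' Each character starts from a uniformly drawn root state and evolves along
#' every branch as a jump process: within a rate block the number of changes
#' on a branch segment is Poisson with mean `rate x duration` (rate in
#' changes per Ma), and each change moves to a uniformly chosen different
#' state. Exact change counts and times are recorded, so the generating
#' per-bin change totals — the quantity the rate estimators target — are
#' known exactly.
#'
#' @param tt A [time_tree()].
#' @param n_char Number of characters.
#' @param n_states States per character (states are `0..n_states-1`).
#' @param rate_blocks Data frame `old`, `young`, `rate` tiling
#'   `[root age, 0]`, oldest block first.
#' @param branch_rate_multiplier Optional named numeric vector (by branch
#'   child label) scaling the local rate on those branches — e.g. a clade
#'   evolving at 3x the background.
#' @param seed Integer seed.
#' @return List with `matrix` (tip-level [character_matrix()]) and `truth`:
#'   `states` (all tips+nodes x characters), `changes` (one row per realised
#'   change: character, branch child label, age), `rate_blocks`, `n_states`,
#'   `branch_rate_multiplier`.
#' @export
simulate_characters <- function(tt, n_char, n_states = 4L, rate_blocks,
                                branch_rate_multiplier = NULL, seed = 1L) {
  if (n_states < 2L) stop("'n_states' must be >= 2")
  rate_blocks <- check_rate_blocks(rate_blocks, tt$root_age)
  set.seed(seed)
  phy <- tt$phy
  n_tip <- ape::Ntip(phy)
  lab <- tree_labels(tt)
  bt <- branch_table(tt)
  # parents before children
  pre <- rev(ape::reorder.phylo(phy, "postorder")$edge[, 2])
  edge_of_child <- match(seq_along(lab), phy$edge[, 2])
  states <- matrix(NA_integer_, length(lab), n_char, dimnames = list(lab, NULL))
  chg <- list()
  for (j in seq_len(n_char)) {
    s <- integer(length(lab))
    s[n_tip + 1L] <- sample.int(n_states, 1L) - 1L
    for (ch in pre) {
      e <- edge_of_child[ch]
      p_age <- bt$parent_age[e]; c_age <- bt$child_age[e]
      cur <- s[bt$parent[e]]
      mult <- 1
      if (!is.null(branch_rate_multiplier)) {
        mm <- branch_rate_multiplier[bt$child_label[e]]
        if (!is.na(mm)) mult <- mm
      }
      ages <- numeric(0)
      for (b in seq_len(nrow(rate_blocks))) {
        hi <- min(p_age, rate_blocks$old[b])
        lo <- max(c_age, rate_blocks$young[b])
        if (hi <= lo) next
        n_ev <- stats::rpois(1, mult * rate_blocks$rate[b] * (hi - lo))
        if (n_ev > 0) ages <- c(ages, stats::runif(n_ev, lo, hi))
      }
      if (length(ages)) {
        ages <- sort(ages, decreasing = TRUE)
        for (a in ages) {
          others <- setdiff(0:(n_states - 1L), cur)
          cur <- others[sample.int(length(others), 1L)]
        }
        chg[[length(chg) + 1L]] <- data.frame(character = j,
                                              branch = bt$child_label[e],
                                              age = ages)
      }
      s[ch] <- cur
    }
    states[, j] <- s
  }
  tip_states <- states[seq_len(n_tip), , drop = FALSE]
  m <- new_character_matrix(
    matrix(vapply(tip_states, encode_states, integer(1)),
           n_tip, n_char, dimnames = list(lab[seq_len(n_tip)], NULL))
  )
  changes <- if (length(chg)) do.call(rbind, chg)
             else data.frame(character = integer(0), branch = character(0), age = numeric(0))
  list(matrix = m,
       truth = list(states = states, changes = changes,
                    rate_blocks = rate_blocks, n_states = n_states,
                    branch_rate_multiplier = branch_rate_multiplier))
}

#' True change counts per time bin
#'
#' Bins the realised change times of a [simulate_characters()] truth record.
#'
#' @param truth The `truth` component.
#' @param bins Bin edge vector, oldest first.
#' @return Integer vector of change counts, one per bin.
#' @export
true_changes_per_bin <- function(truth, bins) {
  check_bins(bins)
  nb <- length(bins) - 1L
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    old <- bins[b]; young <- bins[b + 1L]
    inb <- truth$changes$age >= young & truth$changes$age < old
    if (b == 1L) inb <- truth$changes$age >= young & truth$changes$age <= old
    counts[b] <- sum(inb)
  }
  counts
}

#' Mask cells as missing
#'
#' Sets each targeted cell to MISSING independently with probability
#' `fraction`, emulating the incomplete scoring of fossil material. Node
#' rows (or any rows not listed in `rows`) are untouched.
#'
#' @param m A [character_matrix()].
#' @param fraction Probability in `[0, 1]` that a cell is masked.
#' @param seed Integer seed.
#' @param rows Row labels to mask (default: all rows).
#' @return The masked [character_matrix()].
#' @export
mask_missing <- function(m, fraction, seed = 1L, rows = taxon_labels(m)) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  set.seed(seed)
  states <- m$states
  idx <- which(rownames(states) %in% rows)
  mask <- matrix(stats::runif(length(idx) * ncol(states)) < fraction,
                 length(idx), ncol(states))
  sub <- states[idx, , drop = FALSE]
  sub[mask] <- NA_integer_
  states[idx, ] <- sub
  new_character_matrix(states, m$gap, m$ordering)
}

#' Random character matrix (no tree)
#'
#' Uniform random states with optional missing cells — the quickest way to
#' exercise distance and ordination code on arbitrary inputs.
#'
#' @param n_taxa,n_char Dimensions.
#' @param n_states States per character: a scalar, or a length-2 range from
#'   which each character's state count is drawn.
#' @param missing Missing-cell probability.
#' @param seed Integer seed.
#' @return A [character_matrix()] with taxa `t1..tn`.
#' @export
random_character_matrix <- function(n_taxa, n_char, n_states = 3L,
                                    missing = 0, seed = 1L) {
  set.seed(seed)
  ks <- if (length(n_states) == 2L)
    sample(n_states[1]:n_states[2], n_char, replace = TRUE)
  else rep(n_states, n_char)
  states <- matrix(NA_integer_, n_taxa, n_char,
                   dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  for (j in seq_len(n_char)) {
    vals <- sample.int(ks[j], n_taxa, replace = TRUE) - 1L
    col <- vapply(vals, encode_states, integer(1))
    col[stats::runif(n_taxa) < missing] <- NA_integer_
    states[, j] <- col
  }
  new_character_matrix(states)
}

#' Simulate an environmental-style time series
#'
#' ARIMA process on a uniform grid (via `stats::arima.sim`), standing in
#' for temperature- or CO2-like drivers.
#'
#' @param n Series length.
#' @param order `c(p, d, q)`.
#' @param ar,ma Coefficient vectors matching `order`.
#' @param mean Added constant.
#' @param sd Innovation standard deviation.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_series <- function(n, order = c(1, 0, 0), ar = 0.5, ma = numeric(0),
                            mean = 0, sd = 1, seed = 1L) {
  set.seed(seed)
  model <- list(order = order)
  if (order[1] > 0) model$ar <- ar
  if (order[3] > 0) model$ma <- ma
  as.numeric(stats::arima.sim(model, n = n, sd = sd)) + mean
}
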