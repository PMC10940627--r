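# change table from known endpoint states, no ASR involved
aug_from_states <- function(tt, states) {
  morphodtt:::new_character_matrix(
    apply(states, c(1, 2), function(s)
      if (is.na(s)) NA_integer_ else morphodtt:::encode_states(as.integer(s)))
  )
}

test_that("changes are counted per the ordered/unordered rules", {
  tt <- read_newick_tree("(A:10,B:10);")
  nodes <- tt$phy$node.label
  states <- matrix(c(2L, 0L, 0L), 3, 1, dimnames = list(c("A", "B", nodes), NULL))
  # ancestor 0 -> descendant 2
  aug_u <- aug_from_states(tt, states)
  ct_u <- count_changes(tt, aug_u, bins = c(10, 0))
  expect_equal(sum(ct_u$changes[ct_u$branch == "A"]), 1) # unordered: 1
  aug_o <- morphodtt:::new_character_matrix(aug_u$states, ordering = "ordered")
  ct_o <- count_changes(tt, aug_o, bins = c(10, 0))
  expect_equal(sum(ct_o$changes[ct_o$branch == "A"]), 2) # ordered: |2-0|
  # identical endpoints: zero changes, full exposure
  expect_equal(sum(ct_u$changes[ct_u$branch == "B"]), 0)
  expect_equal(sum(ct_u$exposure[ct_u$branch == "B"]), 10)
})

test_that("a branch spanning two bins is apportioned proportionally", {
  # branch from age 10 (parent) to 0; bins split at 4 -> 60:40
  tt <- read_newick_tree("(A:10,B:10);")
  nodes <- tt$phy$node.label
  states <- matrix(c(1L, 0L, 0L), 3, 1, dimnames = list(c("A", "B", nodes), NULL))
  ct <- count_changes(tt, aug_from_states(tt, states), bins = c(10, 4, 0))
  a <- ct[ct$branch == "A", ]
  expect_equal(a$changes[a$bin == 1], 0.6)
  expect_equal(a$changes[a$bin == 2], 0.4)
  expect_equal(a$exposure[a$bin == 1], 6)
  expect_equal(a$exposure[a$bin == 2], 4)
})

test_that("missing endpoints contribute neither changes nor exposure", {
  tt <- read_newick_tree("(A:10,B:10);")
  nodes <- tt$phy$node.label
  states <- matrix(c(NA, 0L, 0L, 1L, 1L, 0L), 3, 2,
                   dimnames = list(c("A", "B", nodes), NULL))
  ct <- count_changes(tt, aug_from_states(tt, states), bins = c(10, 0))
  expect_equal(sum(ct$exposure[ct$branch == "A"]), 10)  # 1 scorable char only
  expect_equal(sum(ct$exposure[ct$branch == "B"]), 20)
})

test_that("per-branch exposure sums to duration times scorable characters", {
  sim <- simulate_tree(8, 4, root_age = 180, seed = 10)
  blocks <- data.frame(old = 180, young = 0, rate = 0.01)
  sc <- simulate_characters(sim$tree, 10, 3, blocks, seed = 2)
  aug <- aug_from_states(sim$tree, sc$truth$states)
  aug <- morphodtt:::new_character_matrix(
    mask_missing(aug, 0.2, seed = 3, rows = sim$tree$phy$tip.label)$states)
  ct <- count_changes(sim$tree, aug, bins = bins_10ma(180, 0))
  bt <- morphodtt:::branch_table(sim$tree)
  for (e in seq_len(nrow(bt))) {
    lab <- bt$child_label[e]
    xa <- aug$states[bt$parent_label[e], ]; xb <- aug$states[lab, ]
    n_scor <- sum(!is.na(xa) & !is.na(xb))
    expect_equal(sum(ct$exposure[ct$branch == lab]), bt$duration[e] * n_scor,
                 tolerance = 1e-9)
  }
  expect_error(count_changes(sim$tree, aug, bins = c(100, 0)), "do not cover")
})

test_that("contiguous partitions enumerate the compositions", {
  expect_equal(enumerate_contiguous_partitions(1), list(1L))
  p3 <- enumerate_contiguous_partitions(3)
  expect_length(p3, 4L)
  canon <- lapply(p3, paste, collapse = "")
  expect_setequal(unlist(canon), c("111", "112", "122", "123"))
  expect_length(enumerate_contiguous_partitions(8), 128L)
  # brute-force count for B <= 10: one partition per boundary subset
  for (B in 1:10)
    expect_length(enumerate_contiguous_partitions(B), 2^(B - 1))
  expect_error(enumerate_contiguous_partitions(0), ">= 1")
})

test_that("Poisson fits recover the closed-form MLE and AICc", {
  ct <- structure(
    data.frame(branch = paste0("b", 1:10), bin = rep(1:2, each = 5),
               bin_old = rep(c(100, 50), each = 5), bin_young = rep(c(50, 0), each = 5),
               changes = c(rep(0.7, 5), rep(2, 5)), exposure = rep(10, 10)),
    class = c("change_table", "data.frame"), bins = c(100, 50, 0), n_bins = 2L)
  one <- fit_rate_model(ct, c(1L, 1L))
  expect_equal(one$lambda, sum(ct$changes) / sum(ct$exposure)) # 13.5/100
  # lnL equals the direct per-cell sum
  lam <- one$lambda
  direct <- sum(ct$changes * log(lam * ct$exposure) - lam * ct$exposure -
                lgamma(ct$changes + 1))
  expect_equal(one$lnL, direct, tolerance = 1e-12)
  expect_equal(one$AICc, -2 * one$lnL + 2 * 1 + 2 * 1 * 2 / (10 - 1 - 1))
  two <- fit_rate_model(ct, c(1L, 2L))
  expect_equal(two$lambda, c(0.07, 0.2))
  expect_equal(two$AICc, -2 * two$lnL + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1))
  # zero changes: rate 0 and log-likelihood 0
  ct0 <- ct; ct0$changes <- 0
  z <- fit_rate_model(ct0, c(1L, 1L))
  expect_equal(z$lambda, 0)
  expect_equal(z$lnL, 0)
})

test_that("merged-block rates are bracketed by their parts and lnL is monotone", {
  set.seed(12)
  ct <- structure(
    data.frame(branch = paste0("b", 1:30), bin = rep(1:3, each = 10),
               bin_old = 0, bin_young = 0,
               changes = rpois(30, 3), exposure = runif(30, 5, 20)),
    class = c("change_table", "data.frame"), bins = c(3, 2, 1, 0), n_bins = 3L)
  full <- fit_rate_model(ct, c(1L, 2L, 3L))
  merged <- fit_rate_model(ct, c(1L, 1L, 2L))
  expect_gte(merged$lambda[1], min(full$lambda[1:2]) - 1e-12)
  expect_lte(merged$lambda[1], max(full$lambda[1:2]) + 1e-12)
  for (p in enumerate_contiguous_partitions(3))
    expect_gte(full$lnL, fit_rate_model(ct, p)$lnL - 1e-9)
})

test_that("AICc selection prefers parsimony and reports deltas", {
  mk <- function(aicc, k) structure(list(AICc = aicc, k = k, lnL = 0, partition = k),
                                    class = "rate_model")
  sel <- select_best(list(mk(10, 1), mk(12, 2)))
  expect_equal(sel$best_index, 1L)
  expect_equal(sel$table$delta_AICc, c(0, 2))
  tie <- select_best(list(mk(10, 3), mk(10, 1)))
  expect_equal(tie$best$k, 1)
  single <- select_best(list(mk(5, 1)))
  expect_equal(single$table$delta_AICc, 0)
})

test_that("clade models penalise a redundant second rate and detect a real one", {
  # redundant: identical change density inside and outside the clade
  ct <- structure(
    data.frame(branch = paste0("b", 1:20), bin = 1L, bin_old = 10, bin_young = 0,
               changes = rep(1, 20), exposure = rep(10, 20)),
    class = c("change_table", "data.frame"), bins = c(10, 0), n_bins = 1L)
  sel <- fit_clade_models(ct, list(cl = paste0("b", 1:10)))
  expect_equal(sel$table$model[sel$best_index], "single")
  expect_gt(sel$table$delta_AICc[sel$table$model == "cl"], 0)
  expect_error(fit_clade_models(ct, list(cl = paste0("b", 1:20))), "every branch")
  expect_error(fit_clade_models(ct, list(cl = character(0))), "empty clade")

  # real: clade rate 3x background, counted from the true simulated states
  wins <- 0
  for (seed in 1:20) {
    sim <- simulate_tree(24, 8, root_age = 150, seed = 300 + seed)
    clade_tips <- sample_clade(sim$tree, min_tips = 6, max_frac = 0.5,
                               seed = seed)
    cl_branches <- clade_branches(sim$tree, clade_tips)
    base <- data.frame(old = 150, young = 0, rate = 0.01)
    mult <- stats::setNames(rep(3, length(cl_branches)), cl_branches)
    sc <- simulate_characters(sim$tree, 20, 4, base,
                              branch_rate_multiplier = mult, seed = 400 + seed)
    ct2 <- count_changes(sim$tree, aug_from_states(sim$tree, sc$truth$states),
                         bins = c(150, 0))
    sel2 <- fit_clade_models(ct2, list(fast = cl_branches))
    if (sel2$table$model[sel2$best_index] == "fast") wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("per-bin point estimates aggregate changes over exposure", {
  ct <- structure(
    data.frame(branch = c("a", "b", "a"), bin = c(1L, 1L, 2L),
               bin_old = c(20, 20, 10), bin_young = c(10, 10, 0),
               changes = c(2, 4, 1), exposure = c(10, 20, 10)),
    class = c("change_table", "data.frame"), bins = c(20, 10, 0), n_bins = 2L)
  rp <- rate_points(ct)
  expect_equal(rp$rate, c(6 / 30, 1 / 10))
})
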