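test_that("degenerate reconstructions behave as specified", {
  tt <- read_newick_tree("(A:1,B:1);")
  # invariant character: the shared state with probability 1
  inv <- mk_marginal_asr(tt, c(A = "0", B = "0"))
  expect_equal(unname(inv$probabilities[1, "0"]), 1, tolerance = 1e-6)
  expect_equal(unname(inv$states), 0L)
  # symmetric cherry: (0.5, 0.5), tie broken to the lower state
  tie <- mk_marginal_asr(tt, c(A = "0", B = "1"))
  expect_equal(unname(tie$probabilities[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(tie$states), 0L)
  # fewer than 2 scored tips: no reconstruction
  expect_null(mk_marginal_asr(tt, c(A = "0", B = "?")))
})

test_that("pruning likelihood equals explicit summation on a 3-tip tree", {
  tt <- read_newick_tree("((A:0.7,B:1.3):0.9,C:2.1);")
  masks <- c(morphodtt:::encode_states(0L), morphodtt:::encode_states(1L),
             morphodtt:::encode_states(2L))
  names(masks) <- c("A", "B", "C")
  for (q in c(0.05, 0.3, 1.2)) {
    po <- ape::reorder.phylo(tt$phy, "postorder")
    tiplik <- diag(3)[match(c(0, 1, 2), 0:2), ]
    dp <- morphodtt:::mk_down_pass(po$edge, po$edge.length, 3L, 2L, tiplik, q)
    oracle <- oracle_mk_enumeration(tt$phy, q,
                                    list(1L, 2L, 3L), k = 3)
    expect_equal(dp$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("marginal argmax matches full enumeration on an 8-tip tree", {
  tt <- balanced_tree8()
  n_match <- n_nodes <- 0
  for (seed in 1:20) {
    blocks <- data.frame(old = tt$root_age, young = 0, rate = 0.4)
    sim <- simulate_characters(tt, n_char = 1, n_states = 3,
                               rate_blocks = blocks, seed = seed)
    x <- sim$truth$states[tt$phy$tip.label, 1]
    if (length(unique(x)) < 2) next
    fit <- mk_marginal_asr(tt, stats::setNames(as.character(x), names(x)))
    obs <- sort(unique(x))
    oracle <- oracle_mk_enumeration(tt$phy, fit$q,
                                    lapply(x, function(s) match(s, obs)),
                                    k = length(obs))
    # a node matches when the fitted argmax attains the oracle's maximum
    # (exact posterior ties are genuinely ambiguous either way)
    fit_idx <- match(unname(fit$states), obs)
    n_nodes <- n_nodes + length(fit_idx)
    pmax_oracle <- apply(oracle$marginals, 1, max)
    p_of_fit <- oracle$marginals[cbind(seq_along(fit_idx), fit_idx)]
    n_match <- n_match + sum(p_of_fit >= pmax_oracle - 1e-9)
    # probabilities themselves agree, not just the argmax
    expect_equal(unname(fit$probabilities), oracle$marginals, tolerance = 1e-6)
  }
  expect_gte(n_match / n_nodes, 0.95)
})

test_that("marginal probabilities do not depend on tip label order", {
  tt <- balanced_tree8()
  x <- c(A = "0", B = "1", C = "0", D = "?", E = "2", F = "1", G = "0", H = "2")
  f1 <- mk_marginal_asr(tt, x)
  f2 <- mk_marginal_asr(tt, rev(x))
  expect_equal(f1$probabilities, f2$probabilities, tolerance = 1e-12)
})

test_that("reconstruct_all returns the node-augmented matrix", {
  sim <- simulate_tree(6, 3, root_age = 150, seed = 3)
  blocks <- data.frame(old = 150, young = 0, rate = 0.03)
  sc <- simulate_characters(sim$tree, n_char = 6, n_states = 3,
                            rate_blocks = blocks, seed = 4)
  m <- mask_missing(sc$matrix, 0.2, seed = 5)
  aug <- reconstruct_all(sim$tree, m)
  n <- ape::Ntip(sim$tree$phy)
  expect_equal(n_taxa(aug), 2L * n - 1L)
  node_rows <- setdiff(taxon_labels(aug), sim$tree$phy$tip.label)
  for (lab in node_rows) {
    for (j in seq_len(morphodtt:::n_char(aug))) {
      st <- cell_states(aug, lab, j)
      expect_lte(length(st), 1L) # assigned states are single, never polymorphic
    }
  }
  # a 2-tip tree gives 3 rows
  tt2 <- read_newick_tree("(A:1,B:1);")
  m2 <- character_matrix(rbind(A = c("0", "0"), B = c("1", "0")))
  expect_equal(n_taxa(reconstruct_all(tt2, m2)), 3L)
})

test_that("characters scored for fewer than 2 tips give MISSING node cells", {
  tt <- read_newick_tree("((A:1,B:1):1,C:2);")
  m <- character_matrix(rbind(A = c("0", "1"), B = c("?", "0"), C = c("?", "1")))
  aug <- reconstruct_all(tt, m)
  nodes <- setdiff(taxon_labels(aug), c("A", "B", "C"))
  expect_true(all(is.na(aug$states[nodes, 1])))
  expect_true(all(!is.na(aug$states[nodes, 2])))
})

test_that("root state accuracy improves with tip count", {
  set.seed(77)
  acc_for <- function(n_tip, seeds) {
    hits <- 0; tot <- 0
    for (s in seeds) {
      sim <- simulate_tree(n_tip, 0, root_age = 60, seed = s + n_tip * 1000)
      blocks <- data.frame(old = 60, young = 0, rate = 0.008)
      sc <- simulate_characters(sim$tree, n_char = 1, n_states = 3,
                                rate_blocks = blocks, seed = s)
      x <- sc$truth$states[sim$tree$phy$tip.label, 1]
      if (length(unique(x)) < 2) next
      fit <- mk_marginal_asr(sim$tree, stats::setNames(as.character(x), names(x)))
      root_lab <- sim$tree$phy$node.label[1]
      truth_root <- sc$truth$states[root_lab, 1]
      hits <- hits + (unname(fit$states[root_lab]) == truth_root)
      tot <- tot + 1
    }
    hits / tot
  }
  seeds <- 1:50
  a_small <- acc_for(4, seeds)
  a_large <- acc_for(24, seeds)
  expect_gte(a_large, a_small)
})
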