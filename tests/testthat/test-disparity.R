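test_that("sum of variances and origin distance follow their definitions", {
  expect_equal(sum_of_variances(rbind(c(0, 0), c(2, 0))), 2.0)
  expect_equal(sum_of_variances(rbind(c(1, 5))), 0)
  expect_equal(mean_dist_from_origin(rbind(c(3, 4), c(0, 0))), 2.5)
  expect_equal(mean_dist_from_origin(rbind(c(0, 0), c(0, 0))), 0)
  # origin-anchored, not centroid-anchored: translation changes the value
  pts <- rbind(c(1, 0), c(-1, 0))
  expect_false(isTRUE(all.equal(mean_dist_from_origin(pts),
                                mean_dist_from_origin(pts + 10))))
  # ...but sum of variances is translation invariant
  expect_equal(sum_of_variances(pts), sum_of_variances(pts + 10))
  expect_error(sum_of_variances(matrix(0, 0, 2)), "empty")
})

test_that("sum of variances equals a per-axis brute-force loop", {
  set.seed(31)
  pts <- matrix(rnorm(40), 8, 5)
  brute <- 0
  for (ax in 1:5) {
    mu <- mean(pts[, ax])
    brute <- brute + sum((pts[, ax] - mu)^2) / (nrow(pts) - 1)
  }
  expect_equal(sum_of_variances(pts), brute, tolerance = 1e-12)
})

make_ord <- function(coords) {
  structure(list(labels = rownames(coords), coords = coords,
                 eigenvalues = rep(1, ncol(coords)), correction = "none"),
            class = "ordination")
}

test_that("bootstrap curves have the declared shape and reproducibility", {
  set.seed(4)
  coords <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("p", 1:15), NULL))
  ord <- make_ord(coords)
  ss <- structure(list(members = list(paste0("p", 1:6), paste0("p", 7:15), character(0)),
                       times = c(30, 20, 10), bins = NULL,
                       type = "discrete", model = NA, seed = NA),
                  class = "subset_series")
  cv <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 500, seed = 2)
  reps <- attr(cv, "replicates")
  expect_equal(nrow(reps), 500L)
  expect_equal(sum(!is.na(reps[, 1])), 500L)
  expect_true(all(is.na(reps[, 3])))            # empty bin -> gap, not zero
  expect_true(is.na(cv$observed[3]))
  expect_true(all(diff(as.numeric(cv[1, c("p2.5", "p25", "p50", "p75", "p97.5")])) >= 0))
  cv2 <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 500, seed = 2)
  expect_identical(as.data.frame(cv), as.data.frame(cv2))
  expect_error(bootstrap_disparity(ss, ord, "not_a_metric"), "arg")
})

test_that("a bin of identical points collapses the envelope", {
  coords <- matrix(rep(c(1, 2), each = 4), 4, 2, dimnames = list(paste0("p", 1:4), NULL))
  ord <- make_ord(coords)
  ss <- structure(list(members = list(paste0("p", 1:4)), times = 1, bins = NULL,
                       type = "discrete", model = NA, seed = NA),
                  class = "subset_series")
  cv <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 100, seed = 1)
  expect_equal(cv$p2.5, cv$p97.5)
  expect_equal(cv$p50, cv$observed)
})

test_that("rarefaction resamples at the requested size", {
  coords <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("p", 1:20), NULL))
  ord <- make_ord(coords)
  ss <- structure(list(members = list(paste0("p", 1:10)), times = 1, bins = NULL,
                       type = "discrete", model = NA, seed = NA),
                  class = "subset_series")
  cv <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 50,
                            rarefy_to = 3, seed = 9)
  # replicate the contract manually: same seed, resamples of size 3
  set.seed(9)
  pts <- ord$coords[paste0("p", 1:10), ]
  manual <- vapply(1:50, function(r)
    sum_of_variances(pts[sample.int(10, 3, replace = TRUE), , drop = FALSE]),
    numeric(1))
  expect_equal(as.numeric(attr(cv, "replicates")), manual)
})

test_that("bootstrap median converges to the observed value", {
  # the bin must be large enough that the (n-1)/n resampling bias of the
  # variance sits below the tolerance
  set.seed(5)
  coords <- matrix(rnorm(400), 200, 2, dimnames = list(paste0("p", 1:200), NULL))
  ord <- make_ord(coords)
  ss <- structure(list(members = list(paste0("p", 1:200)), times = 1, bins = NULL,
                       type = "discrete", model = NA, seed = NA),
                  class = "subset_series")
  cv <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 10000, seed = 3)
  expect_equal(cv$p50, cv$observed, tolerance = 0.02)
})

test_that("rarefying to 3 widens the bootstrap envelope on average", {
  widths <- function(cv) cv$p97.5 - cv$p2.5
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    coords <- matrix(rnorm(48), 24, 2, dimnames = list(paste0("p", 1:24), NULL))
    ord <- make_ord(coords)
    ss <- structure(list(members = list(paste0("p", 1:12), paste0("p", 13:24)),
                         times = c(2, 1), bins = NULL,
                         type = "discrete", model = NA, seed = NA),
                    class = "subset_series")
    full <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 200, seed = seed)
    rare <- bootstrap_disparity(ss, ord, "sum_of_variances", n_boot = 200,
                                rarefy_to = 3, seed = seed)
    if (mean(widths(rare)) >= mean(widths(full))) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("clade subsets keep coordinates and pick the right rows", {
  tt <- read_newick_tree("((A:1,B:1):1,(C:1,D:1):1);")
  coords <- matrix(seq_len(14), 7, 2,
                   dimnames = list(tree_labels(tt), NULL))
  ord <- make_ord(coords)
  all_rows <- subset_by_clade(ord, tt, tips = c("A", "B", "C", "D"))
  expect_equal(nrow(all_rows$coords), 7L)
  cherry <- subset_by_clade(ord, tt, tips = c("A", "B"))
  expect_equal(sort(cherry$labels), sort(c("A", "B", tt$phy$node.label[2])))
  expect_equal(cherry$coords, coords[cherry$labels, ])
  # explicit label list: input order of the ordination, no duplicates
  lst <- subset_by_clade(ord, labels = c("D", "A", "D"))
  expect_equal(lst$labels, c("A", "D"))
  expect_error(subset_by_clade(ord, labels = character(0)), "empty clade")
})
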