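test_that("2x2 chi-square matches the closed form and the stats oracle", {
  even <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  # hand oracle: n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 80*(900-100)^2/40^4
  strong <- chi_square_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(strong$statistic, 20.0)

  degen <- chi_square_2x2(matrix(c(5, 0, 0, 0), 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  withr::with_seed(11, {
    for (i in 1:25) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      got <- chi_square_2x2(tab)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, unname(ref$p.value))
    }
  })
})

test_that("candidate enumeration builds midpoints and contiguous category cuts", {
  p <- induction_params(min_node = 1)
  d <- tibble::tibble(x = c(1, 2, 3, 1, 2, 3),
                      intent_flag = c("C", "C", "P", "C", "P", "P"))
  cand <- enumerate_candidate_splits(d, "x", p)
  expect_equal(cand$threshold, c(1.5, 2.5))
  expect_equal(unique(cand$multiplier), 2L)

  withr::with_seed(5, {
    d4 <- tibble::tibble(g = sample(c("a", "b", "c", "d"), 120, replace = TRUE),
                         intent_flag = sample(c("C", "P"), 120, replace = TRUE))
  })
  cand4 <- enumerate_candidate_splits(d4, "g", p)
  expect_equal(nrow(cand4), 3)
  expect_equal(unique(cand4$multiplier), 3L)
  # contiguous in palliative-rate order: left sets are nested
  for (j in 2:3) {
    expect_true(all(cand4$left_set[[j - 1]] %in% cand4$left_set[[j]]))
  }

  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 10),
                       intent_flag = rep(c("C", "P"), 10))
  cand2 <- enumerate_candidate_splits(d2, "g", p)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$multiplier, 1L)

  const <- tibble::tibble(x = rep(7, 10),
                          intent_flag = rep(c("C", "P"), 5))
  expect_equal(nrow(enumerate_candidate_splits(const, "x", p)), 0)
})

test_that("the threshold cap subsamples candidates evenly", {
  withr::with_seed(6, {
    d <- tibble::tibble(x = runif(500), intent_flag = sample(c("C", "P"), 500,
                                                             replace = TRUE))
  })
  p <- induction_params(min_node = 1, continuous_threshold_cap = 16)
  cand <- enumerate_candidate_splits(d, "x", p)
  expect_equal(nrow(cand), 16)
  expect_equal(unique(cand$multiplier), 16L)
  # evenly spaced in rank: child sizes grow by roughly n/cap per step
  steps <- diff(cand$n_left)
  expect_true(max(steps) - min(steps) <= 2)
})

test_that("best_split prefers a perfectly separating variable and honours min_node", {
  withr::with_seed(7, {
    d <- tibble::tibble(
      sep = rep(c(100, 900), each = 50),
      noise = runif(100),
      intent_flag = rep(c("C", "P"), each = 50))
  })
  s <- best_split(d, c("noise", "sep"), induction_params(min_node = 10))
  expect_equal(s$variable, "sep")
  expect_equal(s$threshold, 500)

  # no split can leave both children >= 400 in a node of 500
  withr::with_seed(8, {
    d2 <- tibble::tibble(x = runif(500),
                         intent_flag = sample(c("C", "P"), 500, replace = TRUE))
  })
  expect_null(best_split(d2, "x", induction_params(min_node = 400)))
})

test_that("best_split equals the exhaustive brute-force oracle on random data", {
  checked <- 0
  for (seed in 1:60) {
    d <- random_split_dataset(seed)
    vars <- setdiff(names(d), "intent_flag")
    params <- induction_params(alpha = 0.5, min_node = 5,
                               continuous_threshold_cap = nrow(d) + 1)
    impl <- best_split(d, vars, params)
    orac <- oracle_best_split(d, vars, params)
    if (is.null(orac)) {
      expect_null(impl)
    } else {
      expect_false(is.null(impl))
      expect_equal(impl$p_adj, orac$best_p_adj, tolerance = 1e-9)
      expect_true(split_matches_oracle(impl, d, orac))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 20)
})

test_that("grow_tree stops on purity and recovers exact separations", {
  pure <- tibble::tibble(fraction_size = runif(50, 100, 300),
                         intent_flag = "C")
  t1 <- grow_tree(pure, "fraction_size", induction_params(min_node = 5))
  expect_equal(t1$n_leaves, 1)
  expect_equal(t1$root$label, "C")

  sep <- tibble::tibble(fraction_size = rep(c(200, 300), each = 40),
                        intent_flag = rep(c("C", "P"), each = 40))
  t2 <- grow_tree(sep, "fraction_size", induction_params(min_node = 10))
  expect_equal(t2$n_leaves, 2)
  expect_equal(t2$root$split$threshold, 250)
  expect_equal(predict(t2, sep)$label, sep$intent_flag)

  expect_error(grow_tree(sep[0, ], "fraction_size"), "empty")
})

test_that("node supports are conserved down the tree", {
  recs <- draw_from_generative_tree(4000, purity = 0.9, seed = 21)
  tree <- grow_tree(recs, generative_tree()$variables,
                    induction_params(min_node = 100))
  check <- function(node) {
    expect_equal(node$n_C + node$n_P, node$n)
    if (!node$is_leaf) {
      expect_equal(node$left$n + node$right$n, node$n)
      expect_equal(node$label, NULL)
      check(node$left)
      check(node$right)
    } else {
      expect_equal(node$label, if (node$n_C >= node$n_P) "C" else "P")
    }
  }
  check(tree$root)
  leaf_n <- tidy(tree)
  expect_equal(sum(leaf_n$n[leaf_n$type == "leaf"]), nrow(recs))
})

test_that("grow_tree is invariant to row order", {
  recs <- draw_from_generative_tree(3000, purity = 0.85, seed = 31)
  params <- induction_params(min_node = 150)
  t1 <- grow_tree(recs, generative_tree()$variables, params)
  withr::with_seed(32, perm <- sample(nrow(recs)))
  t2 <- grow_tree(recs[perm, ], generative_tree()$variables, params)
  expect_equal(tidy(t1), tidy(t2))
})

test_that("stricter stopping parameters never deepen the tree", {
  recs <- draw_from_generative_tree(3000, purity = 0.85, seed = 41)
  vars <- generative_tree()$variables
  base <- grow_tree(recs, vars, induction_params(alpha = 0.2, min_node = 100))
  depth <- function(tr) glance(tr)$depth
  expect_lte(depth(grow_tree(recs, vars,
                             induction_params(alpha = 0.2, min_node = 400))),
             depth(base))
  expect_lte(depth(grow_tree(recs, vars,
                             induction_params(alpha = 0.001, min_node = 100))),
             depth(base))
})

test_that("the published-tree fixture reproduces the stated paths", {
  pt <- published_tree()
  # high-dose bone treatment: palliative
  bone <- classify(pt, tibble::tibble(
    fraction_size = 400, body_region_group = "Bone - spine/limb/chest/head",
    site_group = "Lung", days_from_first = 0))
  expect_equal(bone$label, "P")
  # high-dose skin-to-skin: curative
  skin <- classify(pt, tibble::tibble(
    fraction_size = 350, body_region_group = "Skin",
    site_group = "Skin", days_from_first = 0))
  expect_equal(skin$label, "C")
  # 277 itself goes to the high-dose side ("greater or equal to")
  edge <- classify(pt, tibble::tibble(
    fraction_size = 277, body_region_group = "Chest",
    site_group = "Lung", days_from_first = 10))
  expect_equal(edge$label, "P")
  # low-dose endpoints are not stated in text
  low <- classify(pt, tibble::tibble(
    fraction_size = 200, body_region_group = "Chest",
    site_group = "Breast", days_from_first = 10))
  expect_equal(low$label, "unspecified")
})

test_that("classification signals the blocking variable on missing values", {
  pt <- published_tree()
  blocked <- classify(pt, tibble::tibble(
    fraction_size = NA_real_, body_region_group = "Chest",
    site_group = "Lung", days_from_first = 5))
  expect_true(is.na(blocked$label))
  expect_equal(blocked$missing_variable, "fraction_size")

  # a single-leaf tree classifies everything
  leafy <- grow_tree(tibble::tibble(fraction_size = runif(30, 150, 250),
                                    intent_flag = "C"),
                     "fraction_size", induction_params(min_node = 5))
  expect_equal(predict(leafy, random_complete_records(50, 2))$label,
               rep("C", 50))
})
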