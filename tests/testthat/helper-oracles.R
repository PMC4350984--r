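# Independent oracles and fixture builders used across the suite.

# --- exhaustive best-split oracle -------------------------------------------
# Enumerates every threshold (midpoints between consecutive distinct values)
# for continuous variables and every binary partition of observed levels for
# categorical variables, scoring each with stats::chisq.test (Pearson, no
# continuity correction).  Bonferroni multipliers follow the same convention
# as the implementation: number of midpoints for continuous, k-1 contiguous
# cuts for a k-level categorical (the chi-square-optimal binary partition of
# a two-class outcome is always contiguous in the class-rate ordering, so
# the exhaustive argmax is comparable).
oracle_chi2 <- function(left, y) {
  tab <- table(factor(left, levels = c(TRUE, FALSE)),
               factor(y, levels = c("C", "P")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(stat = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value))
}

oracle_candidates <- function(data, variable) {
  x <- data[[variable]]
  y <- data$intent_flag
  out <- list()
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) < 2) return(out)
    mids <- (ux[-1] + ux[-length(ux)]) / 2
    mult <- length(mids)
    for (t in mids) {
      cs <- oracle_chi2(x < t, y)
      out[[length(out) + 1]] <- list(
        variable = variable, left = list(threshold = t),
        left_mask = x < t, chi2 = cs$stat, p_raw = cs$p,
        multiplier = mult)
    }
  } else {
    levs <- sort(unique(as.character(x)))
    k <- length(levs)
    if (k < 2) return(out)
    mult <- k - 1
    # all partitions, anchored on the first level to skip complements
    for (code in 0:(2^(k - 1) - 1)) {
      inset <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(k - 2))) > 0))
      left <- levs[inset]
      if (length(left) == k) next
      cs <- oracle_chi2(as.character(x) %in% left, y)
      out[[length(out) + 1]] <- list(
        variable = variable, left = list(set = left),
        left_mask = as.character(x) %in% left, chi2 = cs$stat,
        p_raw = cs$p, multiplier = mult)
    }
  }
  out
}

oracle_best_split <- function(data, variables, params) {
  cands <- unlist(lapply(variables, function(v)
    oracle_candidates(data, v)), recursive = FALSE)
  if (length(cands) == 0) return(NULL)
  keep <- Filter(function(cd) {
    nl <- sum(cd$left_mask)
    nl >= params$min_node && (nrow(data) - nl) >= params$min_node &&
      min(1, cd$p_raw * cd$multiplier) < params$alpha
  }, cands)
  if (length(keep) == 0) return(NULL)
  p_adj <- vapply(keep, function(cd) min(1, cd$p_raw * cd$multiplier),
                  numeric(1))
  best_p <- min(p_adj)
  list(best_p_adj = best_p,
       argmin = keep[p_adj <= best_p + 1e-9])
}

# set-equality of an implementation split with any oracle argmin candidate
# (categorical partitions compare up to complement)
split_matches_oracle <- function(impl, data, oracle_set) {
  for (cd in oracle_set$argmin) {
    if (cd$variable != impl$variable) next
    if (!is.null(cd$left$threshold) && impl$kind == "threshold") {
      if (isTRUE(all.equal(cd$left$threshold, impl$threshold))) return(TRUE)
    }
    if (!is.null(cd$left$set) && impl$kind == "category") {
      levs <- sort(unique(as.character(data[[impl$variable]])))
      a <- sort(cd$left$set)
      b <- sort(impl$left_set[[1]])
      if (identical(a, b) || identical(a, sort(setdiff(levs, b)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# --- random small datasets for the oracle property --------------------------
random_split_dataset <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(30:200, 1)
    n_vars <- sample(1:3, 1)
    cols <- list()
    for (i in seq_len(n_vars)) {
      if (runif(1) < 0.5) {
        # continuous, sometimes with heavy ties
        pool <- if (runif(1) < 0.5) sample(50:900, 8) else round(runif(40, 0, 500), 1)
        cols[[paste0("x", i)]] <- sample(pool, n, replace = TRUE)
      } else {
        k <- sample(2:5, 1)
        cols[[paste0("x", i)]] <- sample(letters[1:k], n, replace = TRUE)
      }
    }
    d <- tibble::as_tibble(cols)
    # class depends weakly on the first variable so splits exist sometimes
    x1 <- d[[1]]
    score <- if (is.numeric(x1)) scale(x1)[, 1] else
      as.integer(factor(x1)) - mean(as.integer(factor(x1)))
    p <- 1 / (1 + exp(-(runif(1, -0.5, 0.5) + runif(1, -1.5, 1.5) * score)))
    d$intent_flag <- ifelse(runif(n) < p, "P", "C")
    d
  })
}

# --- known generative tree for recovery experiments --------------------------
# Root: fraction_size >= 277 cGy.  Low-dose branch: days_from_first >= 290
# (mostly curative below, palliative re-treatments above).  High-dose branch:
# body-region partition (bone/brain/chest/abdomen/neck/pelvis palliative).
# Leaf weights make the days margin exactly uniform and keep fraction size
# the strongest marginal predictor.
generative_tree <- function() {
  pal_regions <- c("Bone - spine/limb/chest/head", "Brain", "Chest",
                   "Abdomen", "Neck", "Pelvis - single side",
                   "Pelvis - both sides")
  all_regions <- grouping_maps()$body_region_groups
  leaf <- function(label) rtrole:::new_leaf(NA_integer_, NA_integer_,
                                            NA_integer_, label = label)
  sp <- function(variable, kind, threshold = NA_real_, left_set = NULL,
                 right_set = NULL) {
    list(variable = variable, kind = kind, threshold = threshold,
         left_set = left_set, right_set = right_set, chi2 = NA_real_,
         p_raw = NA_real_, multiplier = NA_integer_, p_adj = NA_real_,
         n_left = NA_integer_, n_right = NA_integer_)
  }
  internal <- function(split, left, right) {
    list(is_leaf = FALSE, n = NA_integer_, n_C = NA_integer_,
         n_P = NA_integer_, split = split, left = left, right = right)
  }
  root <- internal(
    sp("fraction_size", "threshold", threshold = 277),
    internal(sp("days_from_first", "threshold", threshold = 290),
             leaf("C"), leaf("P")),
    internal(sp("body_region_group", "category", left_set = pal_regions,
                right_set = setdiff(all_regions, pal_regions)),
             leaf("P"), leaf("C")))
  rtrole:::new_trr_tree(
    root,
    variables = c("fraction_size", "body_region_group", "days_from_first"),
    params = induction_params(), n = NA_integer_,
    provenance = "generative-fixture")
}

generative_leaf_weights <- function() {
  # leaves in left-to-right order: low-dose early C, low-dose late P,
  # high-dose palliative-region P, high-dose other-region C
  c(0.5 * 290 / 365, 0.5 * 75 / 365, 0.40, 0.10)
}

draw_from_generative_tree <- function(n, purity, seed) {
  generate_from_tree(generative_tree(), purity = purity, n = n, seed = seed,
                     leaf_weights = generative_leaf_weights())
}

# records drawn uniformly over the full feature space (complete rows)
random_complete_records <- function(n, seed) {
  maps <- grouping_maps()
  withr::with_seed(seed, tibble::tibble(
    fraction_size = runif(n, 100, 1000),
    days_from_first = floor(runif(n, 0, 365)),
    body_region_group = sample(maps$body_region_groups, n, replace = TRUE),
    site_group = sample(maps$site_groups, n, replace = TRUE)))
}
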