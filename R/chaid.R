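#' Induction parameters for the chi-square partitioning tree
#'
#' @param alpha Retention threshold on the Bonferroni-adjusted p-value: a
#'   split is kept only if `p_adj < alpha`.  Default 0.2.
#' @param min_node Minimum number of records in each child of a split.
#'   Default 400.
#' @param max_depth Optional cap on tree depth (root = depth 0); `Inf`
#'   for none.
#' @param continuous_threshold_cap Maximum number of candidate thresholds
#'   evaluated per continuous variable at a node; when the number of
#'   midpoints between consecutive distinct values exceeds the cap, an
#'   evenly spaced (by rank) subset is used.  Default 64.
#' @return A list of class `trr_params`.
#' @examples
#' induction_params(alpha = 0.05, min_node = 50)
#' @export
induction_params <- function(alpha = 0.2, min_node = 400, max_depth = Inf,
                             continuous_threshold_cap = 64) {
  stopifnot(alpha > 0, alpha <= 1, min_node >= 1, max_depth >= 0,
            continuous_threshold_cap >= 1)
  structure(list(alpha = alpha, min_node = min_node, max_depth = max_depth,
                 continuous_threshold_cap = continuous_threshold_cap),
            class = "trr_params")
}

#' Pearson chi-square test for a 2x2 table
#'
#' The statistic is `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree
#' of freedom, with no continuity correction (splitting operates at large
#' n).  A table with any zero marginal is degenerate: statistic 0, p 1.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of
#'   non-negative counts.
#' @return List with `statistic`, `p_value`, `degenerate`.
#' @examples
#' chi_square_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(is.na(x)) || any(x < 0)) {
    abort("chi_square_2x2() needs four non-negative counts")
  }
  if (is.matrix(table)) {
    a <- as.numeric(table[1, 1]); b <- as.numeric(table[1, 2])
    cc <- as.numeric(table[2, 1]); d <- as.numeric(table[2, 2])
  } else {
    a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  }
  n <- a + b + cc + d
  m <- c(a + b, cc + d, a + cc, b + d)
  if (any(m == 0)) {
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  }
  stat <- n * (a * d - b * cc)^2 / prod(m)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# Vectorised chi-square for many 2x2 tables given left-child counts.
# nl/pl: size and palliative count of the left child; n/p totals fixed.
chi2_from_left <- function(nl, pl, n, p) {
  nl <- as.numeric(nl); pl <- as.numeric(pl)
  n <- as.numeric(n); p <- as.numeric(p)
  a <- nl - pl            # left C
  b <- pl                 # left P
  cc <- (n - nl) - (p - pl)
  d <- p - pl
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  stat <- ifelse(denom == 0, 0, n * (a * d - b * cc)^2 / denom)
  pval <- ifelse(denom == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  list(stat = stat, p = pval)
}

#' Enumerate candidate binary splits of one variable at a node
#'
#' For a continuous variable, candidate thresholds are the midpoints
#' between consecutive distinct observed values (an evenly spaced subset
#' when there are more than `continuous_threshold_cap`); records with
#' value `>= threshold` go right.  For a categorical variable, the levels
#' observed at the node are sorted by their palliative proportion and the
#' k-1 contiguous cuts of that ordering form the candidates (exact for a
#' binary outcome).  The Bonferroni multiplier of every candidate is the
#' number of candidates evaluated for that variable; candidates whose
#' children would fall below `min_node` are marked ineligible but still
#' counted in the multiplier.
#'
#' @param node_data Tibble with the variable column and `intent_flag`
#'   (values `"C"`/`"P"`, no missing values).
#' @param variable Column name to split on.
#' @param params [induction_params()].
#' @return Tibble of candidates: `variable`, `kind`, `threshold`,
#'   `left_set` (list column), `cut_index`, `chi2`, `p_raw`, `multiplier`,
#'   `p_adj`, `n_left`, `n_right`, `eligible`.  Zero rows for a constant
#'   variable.
#' @export
enumerate_candidate_splits <- function(node_data, variable,
                                       params = induction_params()) {
  x <- node_data[[variable]]
  if (anyNA(x)) abort(paste0("missing values in '", variable,
                             "' at a split node (induction uses complete rows)"))
  y <- node_data$intent_flag == "P"
  n <- length(x)
  p <- sum(y)
  empty <- tibble::tibble(variable = character(), kind = character(),
                          threshold = double(), left_set = list(),
                          cut_index = integer(), chi2 = double(),
                          p_raw = double(), multiplier = integer(),
                          p_adj = double(), n_left = integer(),
                          n_right = integer(), eligible = logical())
  if (n == 0) return(empty)

  if (is.numeric(x)) {
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    change <- which(diff(xs) > 0)
    if (length(change) == 0) return(empty)
    cum_p <- cumsum(ys)
    mids <- (xs[change] + xs[change + 1]) / 2
    nl <- change
    pl <- cum_p[change]
    cap <- params$continuous_threshold_cap
    if (length(mids) > cap) {
      keep <- unique(round(seq(1, length(mids), length.out = cap)))
      mids <- mids[keep]; nl <- nl[keep]; pl <- pl[keep]
    }
    cs <- chi2_from_left(nl, pl, n, p)
    k <- length(mids)
    tibble::tibble(variable = variable, kind = "threshold", threshold = mids,
                   left_set = vector("list", k), cut_index = seq_len(k),
                   chi2 = cs$stat, p_raw = cs$p, multiplier = k,
                   p_adj = pmin(1, cs$p * k),
                   n_left = as.integer(nl), n_right = as.integer(n - nl),
                   eligible = nl >= params$min_node &
                     (n - nl) >= params$min_node)
  } else {
    x <- as.character(x)
    lev_n <- tapply(rep(1L, n), x, sum)
    lev_p <- tapply(y, x, sum)
    levs <- names(lev_n)
    if (length(levs) < 2) return(empty)
    prop <- lev_p[levs] / lev_n[levs]
    # deterministic ordering: palliative proportion, then label
    o <- order(prop, levs)
    levs <- levs[o]
    cn <- cumsum(as.numeric(lev_n[levs]))
    cp <- cumsum(as.numeric(lev_p[levs]))
    k <- length(levs) - 1L
    nl <- cn[seq_len(k)]
    pl <- cp[seq_len(k)]
    cs <- chi2_from_left(nl, pl, n, p)
    tibble::tibble(variable = variable, kind = "category",
                   threshold = NA_real_,
                   left_set = lapply(seq_len(k), function(j) levs[seq_len(j)]),
                   cut_index = seq_len(k),
                   chi2 = cs$stat, p_raw = cs$p, multiplier = k,
                   p_adj = pmin(1, cs$p * k),
                   n_left = as.integer(nl), n_right = as.integer(n - nl),
                   eligible = nl >= params$min_node &
                     (n - nl) >= params$min_node)
  }
}

#' Select the best split at a node
#'
#' Evaluates every candidate split of every variable and returns the
#' eligible candidate (both children at least `min_node` records) with the
#' smallest Bonferroni-adjusted p-value, provided it is below `alpha`.
#' Ties are broken by larger chi-square statistic, then by the position of
#' the variable in `variables`, then by smaller threshold / earlier
#' category cut.
#'
#' @inheritParams enumerate_candidate_splits
#' @param variables Character vector of candidate split variables.
#' @return A one-row candidate tibble (with a `right_set` list column
#'   added for categorical splits), or `NULL` when no split qualifies.
#' @export
best_split <- function(node_data, variables, params = induction_params()) {
  cands <- purrr::map(variables, function(v)
    enumerate_candidate_splits(node_data, v, params))
  cands <- dplyr::bind_rows(cands)
  ok <- cands$eligible & cands$p_adj < params$alpha
  if (!any(ok)) return(NULL)
  cands <- cands[ok, , drop = FALSE]
  key <- order(cands$p_adj, -cands$chi2,
               match(cands$variable, variables),
               ifelse(cands$kind == "threshold", cands$threshold,
                      cands$cut_index))
  best <- cands[key[1], , drop = FALSE]
  if (best$kind == "category") {
    x <- as.character(node_data[[best$variable]])
    best$right_set <- list(setdiff(sort(unique(x)), best$left_set[[1]]))
  } else {
    best$right_set <- list(NULL)
  }
  best
}

new_leaf <- function(n, n_C, n_P, label = NULL) {
  if (is.null(label)) label <- if (n_C >= n_P) "C" else "P"  # tie -> C
  list(is_leaf = TRUE, label = label, n = n, n_C = n_C, n_P = n_P)
}

#' Grow a binary chi-square partitioning tree
#'
#' Recursive application of [best_split()] starting from all training
#' records: the most significant Bonferroni-adjusted chi-square split forms
#' each branching, and branching stops when no candidate split reaches
#' `alpha` with both children holding at least `min_node` records.  Leaves
#' are labelled by the majority `intent_flag` of their records (exact ties
#' go to `"C"`, the overall majority class).  The result is deterministic
#' given the data and parameters, and invariant to row order.
#'
#' @param training_data Tibble with `intent_flag` in `{"C","P"}` and
#'   complete values on every variable in `variables`.
#' @param variables Character vector of predictor columns (continuous or
#'   categorical).
#' @param params [induction_params()].
#' @return An object of class `trr_tree`.
#' @examples
#' d <- tibble::tibble(fraction_size = rep(c(200, 800), each = 50),
#'                     intent_flag = rep(c("C", "P"), each = 50))
#' grow_tree(d, "fraction_size", induction_params(min_node = 10))
#' @export
grow_tree <- function(training_data, variables, params = induction_params()) {
  if (nrow(training_data) == 0) abort("grow_tree(): empty training data")
  if (!all(training_data$intent_flag %in% c("C", "P"))) {
    abort("grow_tree(): intent_flag must be 'C' or 'P' on every training row")
  }
  miss <- variables[vapply(variables, function(v)
    anyNA(training_data[[v]]), logical(1))]
  if (length(miss) > 0) {
    abort(paste0("grow_tree(): missing values in predictor(s): ",
                 paste(miss, collapse = ", ")))
  }

  build <- function(df, depth) {
    n <- nrow(df)
    n_P <- sum(df$intent_flag == "P")
    n_C <- n - n_P
    if (n_C == 0 || n_P == 0 || depth >= params$max_depth ||
        n < 2 * params$min_node) {
      return(new_leaf(n, n_C, n_P))
    }
    s <- best_split(df, variables, params)
    if (is.null(s)) return(new_leaf(n, n_C, n_P))
    x <- df[[s$variable]]
    go_left <- if (s$kind == "threshold") x < s$threshold else
      as.character(x) %in% s$left_set[[1]]
    list(is_leaf = FALSE, n = n, n_C = n_C, n_P = n_P,
         split = list(variable = s$variable, kind = s$kind,
                      threshold = s$threshold,
                      left_set = s$left_set[[1]], right_set = s$right_set[[1]],
                      chi2 = s$chi2, p_raw = s$p_raw,
                      multiplier = s$multiplier, p_adj = s$p_adj,
                      n_left = s$n_left, n_right = s$n_right),
         left = build(df[go_left, , drop = FALSE], depth + 1),
         right = build(df[!go_left, , drop = FALSE], depth + 1))
  }

  root <- build(training_data, 0)
  new_trr_tree(root, variables, params,
               n = nrow(training_data), provenance = "fitted")
}

# assign preorder node ids and left-to-right leaf ids
number_nodes <- function(root) {
  node_id <- 0L
  leaf_id <- 0L
  walk <- function(node, depth) {
    node_id <<- node_id + 1L
    node$node_id <- node_id
    node$depth <- depth
    if (node$is_leaf) {
      leaf_id <<- leaf_id + 1L
      node$leaf_id <- leaf_id
    } else {
      node$left <- walk(node$left, depth + 1)
      node$right <- walk(node$right, depth + 1)
    }
    node
  }
  walk(root, 0L)
}

new_trr_tree <- function(root, variables, params, n, provenance) {
  root <- number_nodes(root)
  count <- function(node) if (node$is_leaf) c(1L, 1L) else
    c(1L, 0L) + count(node$left) + count(node$right)
  cnt <- count(root)
  structure(list(root = root, variables = variables, params = params,
                 n = n, n_nodes = cnt[1], n_leaves = cnt[2],
                 provenance = provenance),
            class = "trr_tree")
}

tree_depth <- function(tree) {
  d <- function(node) if (node$is_leaf) node$depth else
    max(d(node$left), d(node$right))
  d(tree$root)
}

#' @export
print.trr_tree <- function(x, ...) {
  cat(sprintf("<trr_tree> %s | %d nodes, %d leaves, depth %d, n = %s\n",
              x$provenance, x$n_nodes, x$n_leaves, tree_depth(x),
              if (is.na(x$n)) "?" else format(x$n)))
  fmt_set <- function(s) paste0("{", paste(s, collapse = ", "), "}")
  show <- function(node, prefix, tag) {
    if (node$is_leaf) {
      cat(sprintf("%s%s leaf #%d -> %s (n=%s, C=%s, P=%s)\n", prefix, tag,
                  node$leaf_id, node$label,
                  format(node$n), format(node$n_C), format(node$n_P)))
    } else {
      s <- node$split
      desc <- if (s$kind == "threshold") {
        sprintf("%s >= %s ?", s$variable, format(s$threshold))
      } else {
        sprintf("%s in %s ?", s$variable, fmt_set(s$left_set))
      }
      cat(sprintf("%s%s %s  (p_adj=%.3g)\n", prefix, tag, desc,
                  if (is.null(s$p_adj) || is.na(s$p_adj)) NA else s$p_adj))
      lab <- if (s$kind == "threshold") c("[<] ", "[>=] ") else
        c("[in] ", "[out] ")
      show(node$left, paste0(prefix, "  "), lab[1])
      show(node$right, paste0(prefix, "  "), lab[2])
    }
  }
  show(x$root, "", "")
  invisible(x)
}
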