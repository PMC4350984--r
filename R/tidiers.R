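#' Tidy a classification tree into a per-node tibble
#'
#' @param x A `trr_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node: `node_id`, `depth`, `type`,
#'   `leaf_id`, `label`, `variable`, `kind`, `threshold`, `left_set`
#'   (list column), `n`, `n_C`, `n_P`, `chi2`, `p_adj`.
#' @exportS3Method generics::tidy
tidy.trr_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node) {
    if (node$is_leaf) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        node_id = node$node_id, depth = node$depth, type = "leaf",
        leaf_id = node$leaf_id, label = node$label,
        variable = NA_character_, kind = NA_character_,
        threshold = NA_real_, left_set = list(NULL),
        n = node$n, n_C = node$n_C, n_P = node$n_P,
        chi2 = NA_real_, p_adj = NA_real_)
    } else {
      s <- node$split
      rows[[length(rows) + 1]] <<- tibble::tibble(
        node_id = node$node_id, depth = node$depth, type = "internal",
        leaf_id = NA_integer_, label = NA_character_,
        variable = s$variable, kind = s$kind,
        threshold = s$threshold, left_set = list(s$left_set),
        n = node$n, n_C = node$n_C, n_P = node$n_P,
        chi2 = s$chi2, p_adj = s$p_adj)
      walk(node$left)
      walk(node$right)
    }
  }
  walk(x$root)
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$node_id)
}

#' One-row summary of a classification tree
#'
#' @param x A `trr_tree`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_nodes`, `n_leaves`, `depth`,
#'   `training_accuracy` (majority-label resubstitution accuracy, `NA`
#'   for fixture trees without supports), `provenance`.
#' @exportS3Method generics::glance
glance.trr_tree <- function(x, ...) {
  acc <- NA_real_
  if (!is.na(x$n)) {
    correct <- 0
    walk <- function(node) {
      if (node$is_leaf) {
        correct <<- correct + max(node$n_C, node$n_P)
      } else {
        walk(node$left); walk(node$right)
      }
    }
    walk(x$root)
    acc <- correct / x$n
  }
  tibble::tibble(n = x$n, n_nodes = x$n_nodes, n_leaves = x$n_leaves,
                 depth = tree_depth(x), training_accuracy = acc,
                 provenance = x$provenance)
}

#' Tidy a model cascade into its ranking table
#'
#' One row per model, in model-id order: the internal-validation summary
#' (variables, number of rules, accuracy, misclassification, rank).
#'
#' @param x A `trr_cascade`.
#' @param ... Unused.
#' @return Tibble: `model_id`, `variables` (collapsed string), `n_rules`,
#'   `valid_misclassification`, `accuracy`, `rank`.
#' @exportS3Method generics::tidy
tidy.trr_cascade <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) tibble::tibble(
    model_id = m$model_id,
    variables = paste(m$variables, collapse = "+"),
    n_rules = m$tree$n_leaves,
    valid_misclassification = m$valid_misclassification,
    accuracy = 1 - m$valid_misclassification,
    rank = m$rank))
}

#' @exportS3Method generics::glance
glance.trr_cascade <- function(x, ...) {
  tb <- tidy(x)
  best <- tb[tb$rank == 1, ]
  tibble::tibble(n_models = nrow(tb), n_train = x$n_train,
                 n_valid = x$n_valid, best_model_id = best$model_id,
                 best_accuracy = best$accuracy)
}

#' Tidy a rule set (conditions rendered as text)
#'
#' @param x A `trr_ruleset`.
#' @param ... Unused.
#' @return Tibble: `rule_id`, `conditions` (text), `label`, `support`,
#'   `purity`.
#' @exportS3Method generics::tidy
tidy.trr_ruleset <- function(x, ...) {
  rs <- tibble::as_tibble(x)
  txt <- vapply(rs$conditions, function(cond) {
    if (nrow(cond) == 0) return("TRUE")
    paste(vapply(seq_len(nrow(cond)),
                 function(i) render_condition(cond[i, ]), character(1)),
          collapse = " AND ")
  }, character(1))
  tibble::tibble(rule_id = rs$rule_id, conditions = txt, label = rs$label,
                 support = rs$support, purity = rs$purity)
}

#' @exportS3Method generics::tidy
tidy.trr_confusion <- function(x, ...) {
  tibble::tibble(
    true = c("C", "C", "P", "P"), predicted = c("C", "P", "C", "P"),
    n = c(x$n_CC, x$n_CP, x$n_PC, x$n_PP))
}

#' @exportS3Method generics::glance
glance.trr_confusion <- function(x, ...) {
  tibble::tibble(n = x$total, accuracy = x$accuracy,
                 accuracy_lo = x$accuracy_lo, accuracy_hi = x$accuracy_hi,
                 rate_CP = x$rate_CP, rate_PC = x$rate_PC)
}

#' Plot a classification tree as a node-link diagram
#'
#' @param object A `trr_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trr_tree <- function(object, ...) {
  nodes <- tidy(object)
  # horizontal position: order of first leaf under each node
  pos <- numeric(max(nodes$node_id))
  edges <- list()
  layout <- function(node) {
    if (node$is_leaf) {
      pos[node$node_id] <<- node$leaf_id
    } else {
      layout(node$left); layout(node$right)
      pos[node$node_id] <<- (pos[node$left$node_id] +
                               pos[node$right$node_id]) / 2
      edges[[length(edges) + 1]] <<- tibble::tibble(
        x = pos[node$node_id], y = -node$depth,
        xend = pos[c(node$left$node_id, node$right$node_id)],
        yend = -(node$depth + 1))
    }
  }
  layout(object$root)
  nodes$x <- pos[nodes$node_id]
  nodes$y <- -nodes$depth
  nodes$text <- ifelse(
    nodes$type == "leaf", paste0(nodes$label, "\n", ifelse(
      is.na(nodes$n), "", paste0("n=", nodes$n))),
    ifelse(nodes$kind == "threshold",
           paste0(nodes$variable, "\n>= ", signif(nodes$threshold, 4)),
           nodes$variable))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (length(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = dplyr::bind_rows(edges),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend), colour = "grey60")
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$text,
                                       fill = .data$type),
                          size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(leaf = "#cfe8cf",
                                          internal = "#dde3ee")) +
    ggplot2::theme_void()
}

#' Plot the cascade's internal-validation accuracy by model
#'
#' @param object A `trr_cascade`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trr_cascade <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$model_id),
                                   y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#5b8bb2") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("rank ", .data$rank)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "model", y = "validation accuracy",
                  title = "Reduced-variable model cascade") +
    ggplot2::theme_minimal()
}

#' Plot a population quality report
#'
#' @param object A `trr_quality_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trr_quality_report <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$measure, y = .data$estimate,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "% of treatment records") +
    ggplot2::theme_minimal()
}
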