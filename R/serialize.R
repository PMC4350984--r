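params_to_list <- function(params) {
  p <- unclass(params)
  if (is.infinite(p$max_depth)) p$max_depth <- NULL  # null = uncapped
  p
}

node_to_list <- function(node) {
  if (node$is_leaf) {
    list(type = "leaf", node_id = node$node_id, leaf_id = node$leaf_id,
         label = node$label, n = node$n, n_C = node$n_C, n_P = node$n_P)
  } else {
    s <- node$split
    list(type = "internal", node_id = node$node_id,
         n = node$n, n_C = node$n_C, n_P = node$n_P,
         split = list(variable = s$variable, kind = s$kind,
                      threshold = s$threshold,
                      left_set = as.list(s$left_set),
                      right_set = as.list(s$right_set),
                      chi2 = s$chi2, p_raw = s$p_raw,
                      multiplier = s$multiplier, p_adj = s$p_adj,
                      n_left = s$n_left, n_right = s$n_right),
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(x) {
  na_int <- function(v) if (is.null(v) || length(v) == 0) NA_integer_ else
    as.integer(v)
  na_dbl <- function(v) if (is.null(v) || length(v) == 0) NA_real_ else
    as.numeric(v)
  if (x$type == "leaf") {
    list(is_leaf = TRUE, label = x$label, n = na_int(x$n),
         n_C = na_int(x$n_C), n_P = na_int(x$n_P))
  } else {
    s <- x$split
    list(is_leaf = FALSE, n = na_int(x$n), n_C = na_int(x$n_C),
         n_P = na_int(x$n_P),
         split = list(variable = s$variable, kind = s$kind,
                      threshold = na_dbl(s$threshold),
                      left_set = unlist(s$left_set),
                      right_set = unlist(s$right_set),
                      chi2 = na_dbl(s$chi2), p_raw = na_dbl(s$p_raw),
                      multiplier = na_int(s$multiplier),
                      p_adj = na_dbl(s$p_adj),
                      n_left = na_int(s$n_left), n_right = na_int(s$n_right)),
         left = node_from_list(x$left), right = node_from_list(x$right))
  }
}

#' Serialize a tree to JSON
#'
#' Stable format (`format: trr_tree v1`): nodes with split definitions
#' and supports, induction parameters, variable list and provenance.
#'
#' @param tree A `trr_tree`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(format = "trr_tree v1",
              provenance = tree$provenance,
              n = tree$n,
              variables = as.list(tree$variables),
              params = params_to_list(tree$params),
              root = node_to_list(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname tree_to_json
#' @param json JSON string or path to a JSON file.
#' @export
tree_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                          simplifyVector = FALSE)
  if (!identical(x$format, "trr_tree v1")) {
    abort("tree_from_json(): unrecognised format")
  }
  p <- x$params
  params <- induction_params(
    alpha = p$alpha, min_node = p$min_node,
    max_depth = if (is.null(p$max_depth)) Inf else as.numeric(p$max_depth),
    continuous_threshold_cap = p$continuous_threshold_cap)
  n <- if (is.null(x$n)) NA_integer_ else as.integer(x$n)
  new_trr_tree(node_from_list(x$root), unlist(x$variables), params,
               n = n, provenance = x$provenance)
}

#' Serialize a model cascade to JSON
#'
#' Bundle of member trees plus the ranking table.
#' @param cascade A `trr_cascade`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
cascade_to_json <- function(cascade, path = NULL) {
  obj <- list(
    format = "trr_cascade v1",
    n_train = cascade$n_train, n_valid = cascade$n_valid,
    params = params_to_list(cascade$params),
    models = lapply(cascade$models, function(m) {
      list(model_id = m$model_id, variables = as.list(m$variables),
           valid_misclassification = m$valid_misclassification,
           rank = m$rank,
           tree = jsonlite::fromJSON(tree_to_json(m$tree),
                                     simplifyVector = FALSE))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname cascade_to_json
#' @param json JSON string or path.
#' @export
cascade_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                          simplifyVector = FALSE)
  if (!identical(x$format, "trr_cascade v1")) {
    abort("cascade_from_json(): unrecognised format")
  }
  p <- x$params
  params <- induction_params(
    alpha = p$alpha, min_node = p$min_node,
    max_depth = if (is.null(p$max_depth)) Inf else as.numeric(p$max_depth),
    continuous_threshold_cap = p$continuous_threshold_cap)
  models <- lapply(x$models, function(m) {
    list(model_id = as.integer(m$model_id),
         variables = unlist(m$variables),
         tree = tree_from_json(jsonlite::toJSON(m$tree, auto_unbox = TRUE, na = "null",
                                                null = "null", digits = NA)),
         valid_misclassification = m$valid_misclassification,
         rank = as.integer(m$rank))
  })
  structure(list(models = models, params = params,
                 n_train = as.integer(x$n_train),
                 n_valid = as.integer(x$n_valid)),
            class = "trr_cascade")
}
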