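#' Default classification-variable subsets for the model cascade
#'
#' Seven nested subsets of the four classification variables, every one
#' containing time from first treatment: the full model; the three models
#' dropping disease site, body region, or both; and the three models
#' without fraction size.  One tree is grown per subset and the family is
#' ranked by validation misclassification to classify records with
#' missing predictors.
#'
#' @return Named list of character vectors (names `"1"` .. `"7"`).
#' @export
default_model_subsets <- function() {
  list(
    `1` = c("fraction_size", "site_group", "body_region_group", "days_from_first"),
    `2` = c("fraction_size", "body_region_group", "days_from_first"),
    `3` = c("fraction_size", "site_group", "days_from_first"),
    `4` = c("fraction_size", "days_from_first"),
    `5` = c("site_group", "body_region_group", "days_from_first"),
    `6` = c("body_region_group", "days_from_first"),
    `7` = c("site_group", "days_from_first")
  )
}

#' Build a ranked cascade of trees over variable subsets
#'
#' Grows one tree per variable subset on the training partition
#' (restricted to rows complete on the union of the subsets, as tree
#' induction requires complete predictors) and computes each tree's
#' misclassification rate on the validation partition.  Models are ranked
#' ascending by validation misclassification; ties prefer the larger
#' variable subset (more information), then the smaller model id.
#'
#' @param train_set,valid_set Tibbles of treatment records with
#'   `intent_flag` in `{"C","P"}`.
#' @param subsets Named list of variable subsets; default
#'   [default_model_subsets()].
#' @param params [induction_params()].
#' @return An object of class `trr_cascade`: list of models, each with
#'   `model_id`, `variables`, `tree`, `valid_misclassification`, `rank`.
#' @export
build_cascade <- function(train_set, valid_set,
                          subsets = default_model_subsets(),
                          params = induction_params()) {
  if (length(subsets) == 0) abort("build_cascade(): empty subset list")
  if (is.null(names(subsets))) names(subsets) <- as.character(seq_along(subsets))
  all_vars <- unique(unlist(subsets))

  complete_on <- function(df, vars) {
    keep <- !Reduce(`|`, lapply(vars, function(v) is.na(df[[v]])))
    keep & df$intent_flag %in% c("C", "P")
  }
  train <- train_set[complete_on(train_set, all_vars), , drop = FALSE]
  valid <- valid_set[complete_on(valid_set, all_vars), , drop = FALSE]
  if (nrow(train) == 0) abort("build_cascade(): no complete training rows")
  if (nrow(valid) == 0) abort("build_cascade(): no complete validation rows")

  models <- purrr::imap(subsets, function(vars, id) {
    tree <- grow_tree(train, vars, params)
    pred <- predict(tree, valid)$label
    # a validation record the tree cannot route (category unseen in
    # training) counts as misclassified
    list(model_id = as.integer(id), variables = vars, tree = tree,
         valid_misclassification = mean(is.na(pred) |
                                          pred != valid$intent_flag))
  })
  mis <- vapply(models, `[[`, numeric(1), "valid_misclassification")
  sizes <- lengths(subsets)
  ids <- vapply(models, `[[`, integer(1), "model_id")
  o <- order(mis, -sizes, ids)
  rank <- integer(length(models))
  rank[o] <- seq_along(models)
  for (i in seq_along(models)) models[[i]]$rank <- rank[i]

  structure(list(models = models, params = params,
                 n_train = nrow(train), n_valid = nrow(valid)),
            class = "trr_cascade")
}

#' Classify records through the model cascade
#'
#' Each record is classified by the highest-ranked model (rank 1 = lowest
#' validation misclassification) whose classification variables are all
#' non-missing on that record.  Records to which no model applies are
#' reported as unclassifiable (`NA` label), never defaulted to a class.
#' For complete records the result equals the rank-1 model's prediction.
#'
#' @param cascade A `trr_cascade`.
#' @param records Tibble of treatment records.
#' @return Tibble with one row per record: `label`, `model_id` (model
#'   used, `NA` if unclassifiable), `leaf_id`.
#' @export
classify_with_cascade <- function(cascade, records) {
  n <- nrow(records)
  label <- rep(NA_character_, n)
  model_id <- rep(NA_integer_, n)
  leaf_id <- rep(NA_integer_, n)
  assigned <- rep(FALSE, n)

  by_rank <- cascade$models[order(vapply(cascade$models, `[[`,
                                         integer(1), "rank"))]
  for (m in by_rank) {
    applicable <- !Reduce(`|`, lapply(m$variables,
                                      function(v) is.na(records[[v]])))
    idx <- which(!assigned & applicable)
    if (length(idx) == 0) next
    pred <- predict(m$tree, records[idx, , drop = FALSE])
    label[idx] <- pred$label
    leaf_id[idx] <- pred$leaf_id
    model_id[idx] <- m$model_id
    assigned[idx] <- TRUE
  }
  tibble::tibble(label = label, model_id = model_id, leaf_id = leaf_id)
}

#' @export
print.trr_cascade <- function(x, ...) {
  cat(sprintf("<trr_cascade> %d models (train n = %d, valid n = %d)\n",
              length(x$models), x$n_train, x$n_valid))
  print(tidy(x))
  invisible(x)
}
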