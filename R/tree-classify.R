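#' Classify treatment records with a fitted or fixture tree
#'
#' Descends the tree for every row of `newdata`.  A threshold test sends
#' values `>= threshold` to the right child.  A record whose value is
#' missing (or, for a categorical split, outside both category sets) at
#' some split cannot be routed: its label is `NA` and the blocking
#' variable is reported, so callers can fall back to the missing-data
#' cascade ([classify_with_cascade()]).
#'
#' @param object A `trr_tree`.
#' @param newdata Tibble of treatment records.
#' @param ... Unused.
#' @return Tibble with one row per record: `label` (`"C"`, `"P"`,
#'   `"unspecified"` for fixture leaves whose published label is unstated,
#'   or `NA` when routing failed), `leaf_id`, `prop_C`, `prop_P` (leaf
#'   class proportions, `NA` for fixture leaves without supports) and
#'   `missing_variable`.
#' @examples
#' predict(published_tree(),
#'         tibble::tibble(fraction_size = 400,
#'                        body_region_group = "Bone - spine/limb/chest/head"))
#' @export
predict.trr_tree <- function(object, newdata, ...) {
  n <- nrow(newdata)
  label <- rep(NA_character_, n)
  leaf_id <- rep(NA_integer_, n)
  prop_C <- rep(NA_real_, n)
  prop_P <- rep(NA_real_, n)
  missing_variable <- rep(NA_character_, n)

  route <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (node$is_leaf) {
      label[idx] <<- node$label
      leaf_id[idx] <<- node$leaf_id
      if (!is.na(node$n) && node$n > 0) {
        prop_C[idx] <<- node$n_C / node$n
        prop_P[idx] <<- node$n_P / node$n
      }
      return(invisible(NULL))
    }
    s <- node$split
    v <- newdata[[s$variable]]
    if (is.null(v)) {
      missing_variable[idx] <<- s$variable
      return(invisible(NULL))
    }
    v <- v[idx]
    if (s$kind == "threshold") {
      go_right <- v >= s$threshold
      blocked <- is.na(go_right)
      go_right[blocked] <- FALSE
      go_left <- !go_right & !blocked
    } else {
      vc <- as.character(v)
      go_left <- vc %in% s$left_set
      go_right <- vc %in% s$right_set
      blocked <- !(go_left | go_right)   # missing or unseen category
    }
    missing_variable[idx[blocked]] <<- s$variable
    route(node$left, idx[go_left])
    route(node$right, idx[go_right])
  }
  route(object$root, seq_len(n))
  tibble::tibble(label = label, leaf_id = leaf_id,
                 prop_C = prop_C, prop_P = prop_P,
                 missing_variable = missing_variable)
}

#' Classify a single treatment record
#'
#' Thin single-record wrapper around [predict.trr_tree()].
#'
#' @param tree A `trr_tree`.
#' @param record One-row tibble (or list coercible to one).
#' @return List with `label`, `leaf_id`, `prop_C`, `prop_P`,
#'   `missing_variable` (non-`NA` when descent was blocked by a missing
#'   value, in which case `label` is `NA`).
#' @export
classify <- function(tree, record) {
  record <- tibble::as_tibble(record)
  if (nrow(record) != 1) abort("classify() takes exactly one record")
  as.list(predict(tree, record))
}

#' The published reference classification tree (partial fixture)
#'
#' Encodes the structure of the reference tree derived from the Ontario
#' administrative data, to the extent its paths are stated in text: the
#' root fraction-size split at 277 cGy; on the high-dose side a
#' body-region split whose bone/brain/chest/abdomen/neck/pelvis branch is
#' palliative, followed by a disease-site split whose
#' prostate/head-neck/skin branch is curative; and on the low-dose side a
#' time-from-first-treatment split at 75 days (about two and a half
#' months).  End points whose labels are not stated carry the label
#' `"unspecified"`, and supports are unknown (`NA`): the fixture is
#' intentionally partial and meant for worked examples and tests, not as a
#' substitute for fitting.
#'
#' @return A `trr_tree` with provenance `"published-fixture"`.
#' @examples
#' published_tree()
#' @export
published_tree <- function() {
  palliative_regions <- c(
    "Abdomen", "Chest", "Brain", "Bone - spine/limb/chest/head", "Neck",
    "Pelvis - single side", "Pelvis - both sides")
  other_regions <- setdiff(grouping_maps()$body_region_groups,
                           palliative_regions)
  curative_sites <- c("Prostate/Testis/Penis", "Head/neck", "Skin")
  other_sites <- setdiff(c(grouping_maps()$site_groups, "ungrouped"),
                         curative_sites)
  na_leaf <- function(label) new_leaf(NA_integer_, NA_integer_, NA_integer_,
                                      label = label)
  sp <- function(variable, kind, threshold = NA_real_, left_set = NULL,
                 right_set = NULL) {
    list(variable = variable, kind = kind, threshold = threshold,
         left_set = left_set, right_set = right_set,
         chi2 = NA_real_, p_raw = NA_real_, multiplier = NA_integer_,
         p_adj = NA_real_, n_left = NA_integer_, n_right = NA_integer_)
  }
  internal <- function(split, left, right) {
    list(is_leaf = FALSE, n = NA_integer_, n_C = NA_integer_,
         n_P = NA_integer_, split = split, left = left, right = right)
  }

  root <- internal(
    sp("fraction_size", "threshold", threshold = 277),
    # fraction_size < 277 cGy: time from first treatment, labels unstated
    internal(sp("days_from_first", "threshold", threshold = 75),
             na_leaf("unspecified"), na_leaf("unspecified")),
    # fraction_size >= 277 cGy
    internal(sp("body_region_group", "category",
                left_set = palliative_regions, right_set = other_regions),
             na_leaf("P"),
             internal(sp("site_group", "category",
                         left_set = curative_sites, right_set = other_sites),
                      na_leaf("C"), na_leaf("unspecified"))))
  new_trr_tree(root,
               variables = c("fraction_size", "body_region_group",
                             "site_group", "days_from_first"),
               params = induction_params(),
               n = NA_integer_, provenance = "published-fixture")
}
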