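#' Extract classification rules from a tree
#'
#' Follows the path from the root to every leaf and records the
#' conjunction of split conditions along it, yielding exactly one rule per
#' leaf.  Rules are mutually exclusive and (over records complete on the
#' variables used) exhaustive by construction, so applying the rule set
#' reproduces tree descent exactly.  Conditions are kept in root-to-leaf
#' order; relations are `<` / `>=` for threshold splits and `in` for both
#' sides of a category split (each side carrying its explicit category
#' set).
#'
#' @param tree A `trr_tree`.
#' @return An object of class `trr_ruleset`: tibble with `rule_id`
#'   (leaf order), `label`, `support` (leaf record count, `NA` for the
#'   published fixture), `n_C`, `n_P`, `purity` (majority-class fraction)
#'   and a `conditions` list column of tibbles
#'   (`variable`, `relation`, `value`).
#' @examples
#' extract_rules(published_tree())
#' @export
extract_rules <- function(tree) {
  rules <- list()
  walk <- function(node, conds) {
    if (node$is_leaf) {
      purity <- if (!is.na(node$n) && node$n > 0)
        max(node$n_C, node$n_P) / node$n else NA_real_
      rules[[length(rules) + 1]] <<- tibble::tibble(
        rule_id = node$leaf_id, label = node$label,
        support = as.integer(node$n), n_C = as.integer(node$n_C),
        n_P = as.integer(node$n_P), purity = purity,
        conditions = list(conds))
      return(invisible(NULL))
    }
    s <- node$split
    if (s$kind == "threshold") {
      lc <- tibble::tibble(variable = s$variable, relation = "<",
                           value = list(s$threshold))
      rc <- tibble::tibble(variable = s$variable, relation = ">=",
                           value = list(s$threshold))
    } else {
      lc <- tibble::tibble(variable = s$variable, relation = "in",
                           value = list(s$left_set))
      rc <- tibble::tibble(variable = s$variable, relation = "in",
                           value = list(s$right_set))
    }
    walk(node$left, dplyr::bind_rows(conds, lc))
    walk(node$right, dplyr::bind_rows(conds, rc))
  }
  empty <- tibble::tibble(variable = character(), relation = character(),
                          value = list())
  walk(tree$root, empty)
  out <- dplyr::bind_rows(rules) |> dplyr::arrange(.data$rule_id)
  structure(out, class = c("trr_ruleset", class(out)),
            variables = tree$variables, provenance = tree$provenance)
}

condition_mask <- function(cond, records) {
  n <- nrow(records)
  m <- rep(TRUE, n)
  for (i in seq_len(nrow(cond))) {
    v <- records[[cond$variable[i]]]
    if (is.null(v)) return(rep(FALSE, n))
    val <- cond$value[[i]]
    mi <- switch(cond$relation[i],
                 "<" = v < val[[1]],
                 ">=" = v >= val[[1]],
                 "in" = as.character(v) %in% val,
                 "not_in" = !(as.character(v) %in% val) & !is.na(v),
                 abort(paste0("unknown relation: ", cond$relation[i])))
    mi[is.na(mi)] <- FALSE
    m <- m & mi
  }
  m
}

#' Apply a rule set to treatment records
#'
#' Evaluates each rule's conjunctive conditions over the records.  For a
#' record complete on the variables the rules use, exactly one rule
#' matches and the label equals tree descent on the source tree.  A record
#' with a missing (or unseen categorical) value on its path matches no
#' rule and is reported with an `NA` label.
#'
#' @param ruleset A `trr_ruleset` from [extract_rules()].
#' @param records Tibble of treatment records.
#' @return Tibble with `label`, `rule_id` (`NA` when no rule matched) and
#'   `n_matched` (number of matching rules; 0 signals a blocked record,
#'   values above 1 would indicate a malformed rule set).
#' @export
apply_rules <- function(ruleset, records) {
  n <- nrow(records)
  rs <- tibble::as_tibble(ruleset)
  masks <- lapply(rs$conditions, condition_mask, records = records)
  n_matched <- Reduce(`+`, lapply(masks, as.integer))
  label <- rep(NA_character_, n)
  rule_id <- rep(NA_integer_, n)
  # later rules never overwrite: rules are mutually exclusive by construction
  for (j in rev(seq_len(nrow(rs)))) {
    hit <- masks[[j]]
    label[hit] <- rs$label[j]
    rule_id[hit] <- rs$rule_id[j]
  }
  tibble::tibble(label = label, rule_id = rule_id, n_matched = n_matched)
}

rule_units <- c(fraction_size = "cGy", days_from_first = "days")

format_value <- function(x) {
  if (is.na(x)) return("NA")
  # shortest plain-decimal representation that round-trips exactly
  for (d in 1:17) {
    cand <- format(x, digits = d, scientific = FALSE, trim = TRUE)
    if (as.numeric(cand) == x) return(cand)
  }
  sprintf("%.17g", x)
}

render_condition <- function(cond_row) {
  v <- cond_row$variable
  rel <- cond_row$relation
  if (rel %in% c("<", ">=")) {
    unit <- rule_units[v]
    paste0(v, " ", rel, " ", format_value(cond_row$value[[1]]),
           if (!is.na(unit)) paste0(" ", unit) else "")
  } else {
    op <- if (rel == "in") "IN" else "NOT IN"
    paste0(v, " ", op, " {", paste(cond_row$value[[1]], collapse = ", "), "}")
  }
}

#' Render a rule set as numbered plain-text IF/THEN rules
#'
#' One line per rule in rule-id order, in a small versioned grammar that
#' [parse_rules()] reads back:
#' `"<id>: IF <cond> AND <cond> THEN <label> [support=.., purity=..]"`.
#' Threshold conditions carry their units (cGy, days); an empty condition
#' list renders as `IF TRUE`.
#'
#' @param ruleset A `trr_ruleset`.
#' @return Character scalar (lines joined by newlines).
#' @examples
#' cat(render_rules(extract_rules(published_tree())))
#' @export
render_rules <- function(ruleset) {
  rs <- tibble::as_tibble(ruleset)
  lines <- c("RULESET v1",
             paste0("# variables: ",
                    paste(attr(ruleset, "variables"), collapse = ", ")),
             paste0("# provenance: ", attr(ruleset, "provenance") %||% "unknown"))
  for (j in seq_len(nrow(rs))) {
    cond <- rs$conditions[[j]]
    cond_txt <- if (nrow(cond) == 0) "TRUE" else
      paste(vapply(seq_len(nrow(cond)),
                   function(i) render_condition(cond[i, ]), character(1)),
            collapse = " AND ")
    lines <- c(lines, sprintf(
      "%d: IF %s THEN %s [support=%s, purity=%s]",
      rs$rule_id[j], cond_txt, rs$label[j],
      if (is.na(rs$support[j])) "NA" else as.character(rs$support[j]),
      if (is.na(rs$purity[j])) "NA" else format_value(rs$purity[j])))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

parse_condition <- function(txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec(
    "^([A-Za-z0-9_.]+) (NOT IN|IN) \\{(.*)\\}$", txt))[[1]]
  if (length(m) == 4) {
    vals <- trimws(strsplit(m[4], ",", fixed = TRUE)[[1]])
    return(tibble::tibble(variable = m[2],
                          relation = if (m[3] == "IN") "in" else "not_in",
                          value = list(vals)))
  }
  m <- regmatches(txt, regexec(
    "^([A-Za-z0-9_.]+) (>=|<) ([-0-9.eE+]+)( [A-Za-z]+)?$", txt))[[1]]
  if (length(m) >= 4) {
    return(tibble::tibble(variable = m[2], relation = m[3],
                          value = list(as.numeric(m[4]))))
  }
  abort(paste0("cannot parse rule condition: '", txt, "'"))
}

#' Parse rules rendered by [render_rules()]
#'
#' @param text Character scalar or vector of lines in the `RULESET v1`
#'   grammar.
#' @return A `trr_ruleset` (class counts `n_C`/`n_P` are not part of the
#'   text grammar and come back as `NA`; support and purity round-trip).
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  if (length(lines) == 0 || lines[1] != "RULESET v1") {
    abort("parse_rules(): missing 'RULESET v1' header")
  }
  vars <- character()
  prov <- "parsed"
  rows <- list()
  for (ln in lines[-1]) {
    if (ln == "") next
    if (startsWith(ln, "# variables:")) {
      vars <- trimws(strsplit(sub("^# variables:", "", ln), ",")[[1]])
      next
    }
    if (startsWith(ln, "# provenance:")) {
      prov <- trimws(sub("^# provenance:", "", ln))
      next
    }
    if (startsWith(ln, "#")) next
    m <- regmatches(ln, regexec(
      "^([0-9]+): IF (.*) THEN ([A-Za-z]+) \\[support=([^,]+), purity=([^]]+)\\]$",
      ln))[[1]]
    if (length(m) != 6) abort(paste0("cannot parse rule line: '", ln, "'"))
    cond_txt <- m[3]
    conds <- if (cond_txt == "TRUE") {
      tibble::tibble(variable = character(), relation = character(),
                     value = list())
    } else {
      dplyr::bind_rows(lapply(strsplit(cond_txt, " AND ", fixed = TRUE)[[1]],
                              parse_condition))
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      rule_id = as.integer(m[2]), label = m[4],
      support = if (m[5] == "NA") NA_integer_ else as.integer(m[5]),
      n_C = NA_integer_, n_P = NA_integer_,
      purity = if (m[6] == "NA") NA_real_ else as.numeric(m[6]),
      conditions = list(conds))
  }
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$rule_id)
  structure(out, class = c("trr_ruleset", class(out)),
            variables = vars, provenance = prov)
}

#' @export
print.trr_ruleset <- function(x, ...) {
  cat(render_rules(x))
  invisible(x)
}
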