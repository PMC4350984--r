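#' Grouping maps for disease sites and irradiated body regions
#'
#' Administrative radiotherapy records carry a 3-digit ICD-9 primary-site
#' code and a verbatim description of the irradiated body region.  Both are
#' collapsed into coarser groups before tree induction: disease sites by
#' anatomic region and likelihood of radiotherapy use, body regions by
#' proximity and by whether the region is typically treated with curative
#' or palliative aim.  The default maps are shipped as editable CSV files
#' under `inst/extdata/` (`site_groups.csv`, `body_region_map.csv`).
#'
#' @return A list with elements `site_map` (tibble: `icd9`, `site_group`),
#'   `body_region_map` (tibble: `verbatim`, `body_region_group`),
#'   `site_groups` (character vector of all site-group labels) and
#'   `body_region_groups` (character vector of all region-group labels).
#' @examples
#' maps <- grouping_maps()
#' head(maps$site_map)
#' @export
grouping_maps <- function() {
  site_map <- read_extdata_csv("site_groups.csv")
  region_map <- read_extdata_csv("body_region_map.csv")
  list(
    site_map = site_map,
    body_region_map = region_map,
    site_groups = read_extdata_csv("site_profile.csv")$site_group,
    body_region_groups = read_extdata_csv("region_profile.csv")$body_region_group
  )
}

#' Reference profile of classification variables
#'
#' Published marginal counts of curative and palliative treatment records
#' by body-region group and by disease-site group in the Ontario
#' administrative data used to derive the reference classifier, together
#' with the printed integer percentages.  Shipped as editable CSV data;
#' used as the default frequency profile of the synthetic generator and as
#' a worked-example input.
#'
#' @param which `"site"` or `"body_region"`.
#' @return A tibble with columns `n_curative`, `pct_curative`,
#'   `n_palliative`, `pct_palliative` and the group label.
#' @examples
#' variable_profile("body_region")
#' @export
variable_profile <- function(which = c("site", "body_region")) {
  which <- match.arg(which)
  read_extdata_csv(if (which == "site") "site_profile.csv" else "region_profile.csv")
}

#' Map ICD-9 primary-site codes to disease-site groups
#'
#' Codes are treated as integer 3-digit ICD-9 codes (malignant neoplasms,
#' 140--208).  Longer codes (sub-site digits, e.g. 1629 for 162.9) are
#' truncated to their leading three digits.  Codes not covered by the map
#' return the `"ungrouped"` sentinel rather than erroring, so the function
#' is total on any integer input.
#'
#' @param icd9 Integer vector of ICD-9 codes (NA allowed).
#' @param maps Grouping maps as returned by [grouping_maps()].
#' @return Character vector of site-group labels (`NA` for `NA` input,
#'   `"ungrouped"` for unmapped codes).
#' @examples
#' group_disease_site(c(162, 203, 139, 1749))
#' @export
group_disease_site <- function(icd9, maps = grouping_maps()) {
  code <- suppressWarnings(as.numeric(icd9))
  code <- floor(code)
  # truncate sub-codes (e.g. 1629 -> 162) to the leading 3 digits
  repeat {
    over <- !is.na(code) & code > 999
    if (!any(over)) break
    code[over] <- code[over] %/% 10
  }
  out <- maps$site_map$site_group[match(code, maps$site_map$icd9)]
  out[is.na(out) & !is.na(code)] <- "ungrouped"
  out
}

#' Map verbatim body-region descriptions to body-region groups
#'
#' Matching is case-insensitive on the trimmed verbatim label.  Labels that
#' already equal a group name pass through unchanged; unmapped labels
#' return `"ungrouped"`.
#'
#' @inheritParams group_disease_site
#' @param verbatim Character vector of verbatim region descriptions.
#' @return Character vector of body-region-group labels.
#' @export
group_body_region <- function(verbatim, maps = grouping_maps()) {
  x <- tolower(trimws(as.character(verbatim)))
  out <- maps$body_region_map$body_region_group[
    match(x, tolower(maps$body_region_map$verbatim))]
  already <- is.na(out) & x %in% tolower(maps$body_region_groups)
  out[already] <- maps$body_region_groups[
    match(x[already], tolower(maps$body_region_groups))]
  out[is.na(out) & !is.na(x) & x != ""] <- "ungrouped"
  out
}

#' Default vocabulary mapping recorded intent strings to C/P
#'
#' Curative-family terms (curative, radical, adjuvant) map to `"C"`,
#' palliative terms to `"P"`.  Fully overridable.
#' @return Named character vector (names = lower-case intent strings).
#' @export
default_intent_vocabulary <- function() {
  c(curative = "C", radical = "C", adjuvant = "C",
    c = "C", cur = "C",
    palliative = "P", palliation = "P", p = "P", pall = "P")
}

#' Collapse recorded treatment intent to a binary flag
#'
#' @param intent_raw Character vector of recorded intent strings (NA for
#'   missing).
#' @param vocabulary Named character vector mapping lower-case intent
#'   strings to `"C"` or `"P"`; see [default_intent_vocabulary()].
#' @return Character vector with values `"C"`, `"P"` or `NA`.  Non-missing
#'   strings absent from the vocabulary become `NA` with a warning naming
#'   the unmapped values.
#' @examples
#' binarize_intent(c("palliative", "Radical", NA, "unknown"))
#' @export
binarize_intent <- function(intent_raw, vocabulary = default_intent_vocabulary()) {
  x <- tolower(trimws(as.character(intent_raw)))
  x[x == ""] <- NA_character_
  out <- unname(vocabulary[x])
  unmapped <- !is.na(x) & is.na(out)
  if (any(unmapped)) {
    warn(paste0("unmapped intent value(s) set to missing: ",
                paste(unique(x[unmapped]), collapse = ", ")))
  }
  out
}

#' Days elapsed since the first treatment for the same cancer
#'
#' For every record, computes the number of whole days between its
#' treatment date and the earliest treatment date observed for the same
#' `cancer_id`.  The result is independent of row order and of shifting
#' all dates by a constant.
#'
#' @param records Tibble with at least `cancer_id` and `treat_date`
#'   (a `Date`).
#' @return The input tibble with an integer `days_from_first` column
#'   (added or overwritten).  Zero rows in, zero rows out.
#' @examples
#' recs <- tibble::tibble(cancer_id = c("a", "a"),
#'                        treat_date = as.Date("2006-01-02") + c(7, 0))
#' compute_days_from_first(recs)$days_from_first
#' @export
compute_days_from_first <- function(records) {
  if (nrow(records) == 0) {
    records$days_from_first <- integer(0)
    return(records)
  }
  if (anyNA(records$treat_date)) {
    abort("compute_days_from_first() requires a valid treat_date on every record")
  }
  records |>
    dplyr::group_by(.data$cancer_id) |>
    dplyr::mutate(days_from_first =
                    as.integer(.data$treat_date - min(.data$treat_date))) |>
    dplyr::ungroup()
}

trr_record_columns <- function() {
  c("patient_id", "cancer_id", "treat_date", "fraction_size",
    "body_region_group", "site_group", "days_from_first", "technique",
    "intent_raw", "intent_flag")
}

#' Read administrative radiotherapy treatment records from CSV
#'
#' One row per daily treatment fraction.  Column names in the file are
#' resolved through `schema`, a named list/vector mapping canonical field
#' names to file column names; canonical names present in the file need no
#' entry.  Required fields: `patient_id`, `treat_date`.  All other fields
#' are optional; unparseable optional values become missing.  `cancer_id`
#' defaults to `patient_id` when absent, and `intent_flag` is derived from
#' `intent_raw` via [binarize_intent()] when not supplied directly.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector, e.g.
#'   `c(patient_id = "mrn", treat_date = "date_of_treatment")`.
#' @param intent_vocabulary Passed to [binarize_intent()].
#' @param compute_days If `TRUE` (default) and `days_from_first` is not a
#'   file column, derive it with [compute_days_from_first()].
#' @return A tibble of treatment records in file row order with the
#'   canonical columns (see [compute_days_from_first()] and the package
#'   vignette); extra file columns are preserved.
#' @export
read_records <- function(path, schema = character(),
                         intent_vocabulary = default_intent_vocabulary(),
                         compute_days = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  raw <- tibble::as_tibble(raw)
  schema <- unlist(schema)

  col_for <- function(canonical) {
    file_col <- if (canonical %in% names(schema)) schema[[canonical]] else canonical
    if (file_col %in% names(raw)) raw[[file_col]] else NULL
  }
  required <- c("patient_id", "treat_date")
  for (cn in required) {
    if (is.null(col_for(cn))) {
      abort(paste0("required column not found in ", path, ": '", cn,
                   "' (add a schema entry mapping it to a file column)"))
    }
  }

  n <- nrow(raw)
  blank_to_na <- function(x) {
    x <- trimws(x)
    x[x == "" | toupper(x) == "NA"] <- NA_character_
    x
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(blank_to_na(x)))

  treat_date_chr <- blank_to_na(col_for("treat_date"))
  treat_date <- as.Date(treat_date_chr, format = "%Y-%m-%d")
  bad <- which(!is.na(treat_date_chr) & is.na(treat_date))
  bad <- c(bad, which(is.na(treat_date_chr)))
  if (length(bad) > 0) {
    abort(paste0("unparseable or missing treat_date (expected ISO-8601) at row(s): ",
                 paste(sort(head(bad, 10)), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""))
  }

  out <- tibble::tibble(
    patient_id = blank_to_na(col_for("patient_id")),
    cancer_id = {
      ci <- col_for("cancer_id")
      if (is.null(ci)) blank_to_na(col_for("patient_id")) else blank_to_na(ci)
    },
    treat_date = treat_date,
    fraction_size = if (is.null(col_for("fraction_size"))) NA_real_ else
      num_or_na(col_for("fraction_size")),
    body_region_group = if (is.null(col_for("body_region_group"))) NA_character_ else
      blank_to_na(col_for("body_region_group")),
    site_group = if (is.null(col_for("site_group"))) NA_character_ else
      blank_to_na(col_for("site_group")),
    technique = if (is.null(col_for("technique"))) NA_character_ else
      blank_to_na(col_for("technique")),
    intent_raw = if (is.null(col_for("intent_raw"))) NA_character_ else
      blank_to_na(col_for("intent_raw"))
  )
  # fraction sizes must be positive doses; anything else is unusable
  out$fraction_size[!is.na(out$fraction_size) & out$fraction_size <= 0] <- NA_real_

  if (!is.null(col_for("intent_flag"))) {
    fl <- toupper(blank_to_na(col_for("intent_flag")))
    fl[!fl %in% c("C", "P")] <- NA_character_
    out$intent_flag <- fl
  } else {
    out$intent_flag <- suppressWarnings(binarize_intent(out$intent_raw, intent_vocabulary))
  }

  if (!is.null(col_for("days_from_first"))) {
    d <- num_or_na(col_for("days_from_first"))
    d[!is.na(d) & d < 0] <- NA_real_
    out$days_from_first <- as.integer(d)
  } else if (compute_days) {
    out <- compute_days_from_first(out)
  } else {
    out$days_from_first <- NA_integer_
  }
  out[, trr_record_columns()]
}

#' Write treatment records to CSV
#'
#' Inverse of [read_records()]: a file written here and read back
#' reproduces all canonical field values.  The hidden `true_role` column
#' produced by the synthetic generator is dropped unless `sidecar` is
#' given, in which case `record_id`/`true_role` pairs are written there.
#'
#' @param records Tibble of treatment records.
#' @param path Output CSV path.
#' @param sidecar Optional path for a hidden-truth CSV (`true_role`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, sidecar = NULL) {
  keep <- intersect(trr_record_columns(), names(records))
  out <- records[, keep]
  out$treat_date <- format(out$treat_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(sidecar) && "true_role" %in% names(records)) {
    write.csv(data.frame(row = seq_len(nrow(records)),
                         true_role = records$true_role),
              sidecar, row.names = FALSE, na = "")
  }
  invisible(path)
}
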