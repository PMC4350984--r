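#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `estimate`, `lo`, `hi`.  The interval always
#'   contains the point estimate and is well behaved near 0 and 1.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) return(tibble::tibble(estimate = NA_real_, lo = NA_real_,
                                    hi = NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(estimate = p, lo = max(0, centre - half),
                 hi = min(1, centre + half))
}

#' Randomly partition records into training, validation and test sets
#'
#' Seeded multinomial assignment of each record to one of the three
#' partitions; disjoint and exhaustive, reproducible per seed.
#'
#' @param records Tibble of treatment records.
#' @param fractions Length-3 numeric (train, valid, test) summing to 1;
#'   default `c(0.40, 0.30, 0.30)`.
#' @param seed Integer seed.
#' @return Named list of tibbles: `train`, `valid`, `test`.
#' @export
split_dataset <- function(records, fractions = c(train = 0.40, valid = 0.30,
                                                 test = 0.30), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("split_dataset(): fractions must be three positives summing to 1")
  }
  assign <- with_seed(seed, sample(c("train", "valid", "test"),
                                   nrow(records), replace = TRUE,
                                   prob = fractions))
  list(train = records[assign == "train", , drop = FALSE],
       valid = records[assign == "valid", , drop = FALSE],
       test = records[assign == "test", , drop = FALSE])
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Confusion matrix of predicted vs reference C/P labels
#'
#' Counts are indexed true class then predicted class: `n_CP` is the
#' number of truly (or reference-) curative records predicted palliative.
#' `accuracy + rate_CP + rate_PC = 1` exactly; the accuracy interval is a
#' 95% Wilson score interval.
#'
#' @param predicted,reference Equal-length character vectors with values
#'   in `{"C","P"}`.
#' @return Object of class `trr_confusion`.
#' @examples
#' confusion_matrix(c("C", "P", "C"), c("C", "P", "P"))
#' @export
confusion_matrix <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    abort("confusion_matrix(): length mismatch")
  }
  ok <- c("C", "P")
  if (!all(predicted %in% ok) || !all(reference %in% ok)) {
    abort("confusion_matrix(): labels must be 'C' or 'P' (no missing)")
  }
  n_CC <- sum(reference == "C" & predicted == "C")
  n_CP <- sum(reference == "C" & predicted == "P")
  n_PC <- sum(reference == "P" & predicted == "C")
  n_PP <- sum(reference == "P" & predicted == "P")
  total <- n_CC + n_CP + n_PC + n_PP
  ci <- wilson_ci(n_CC + n_PP, total)
  structure(list(n_CC = n_CC, n_CP = n_CP, n_PC = n_PC, n_PP = n_PP,
                 total = total,
                 accuracy = (n_CC + n_PP) / total,
                 accuracy_lo = ci$lo, accuracy_hi = ci$hi,
                 rate_CP = n_CP / total, rate_PC = n_PC / total),
            class = "trr_confusion")
}

#' @export
print.trr_confusion <- function(x, ...) {
  cat(sprintf(paste0("<trr_confusion> n = %d\n",
                     "  accuracy %.1f%% (%.1f%%, %.1f%%)\n",
                     "  C to P: %.1f%%   P to C: %.1f%%\n"),
              x$total, 100 * x$accuracy, 100 * x$accuracy_lo,
              100 * x$accuracy_hi, 100 * x$rate_CP, 100 * x$rate_PC))
  invisible(x)
}

#' Diagnostic accuracy metrics with palliation as the target outcome
#'
#' Sensitivity `n_PP / (n_PP + n_PC)`, specificity `n_CC / (n_CC + n_CP)`,
#' positive predictive value `n_PP / (n_PP + n_CP)` and negative
#' predictive value `n_CC / (n_CC + n_PC)`, each with a 95% Wilson score
#' interval.  A metric with a zero denominator is reported as `NA`.
#'
#' @param cm A `trr_confusion`.
#' @return Tibble with `metric`, `estimate`, `lo`, `hi`, `num`, `den`.
#' @export
diagnostic_metrics <- function(cm) {
  rows <- list(
    sensitivity = c(cm$n_PP, cm$n_PP + cm$n_PC),
    specificity = c(cm$n_CC, cm$n_CC + cm$n_CP),
    ppv = c(cm$n_PP, cm$n_PP + cm$n_CP),
    npv = c(cm$n_CC, cm$n_CC + cm$n_PC))
  purrr::imap_dfr(rows, function(xd, nm) {
    ci <- wilson_ci(xd[1], xd[2])
    tibble::tibble(metric = nm, estimate = ci$estimate, lo = ci$lo,
                   hi = ci$hi, num = xd[1], den = xd[2])
  })
}

#' Draw a stratified random sample of patients for a manual audit
#'
#' Within each stratum (typically centre x period x agreement between the
#' tree classification and the recorded intent flag), draws a seeded
#' simple random sample of patients and returns all treatment records of
#' the sampled patients, with the stratum expansion weight `N_h / n_h`
#' attached to every sampled record.
#'
#' @param records Tibble with a patient identifier column and a stratum
#'   column; the stratum must be constant within patient.
#' @param n_h Named integer vector: patients to sample per stratum (names
#'   = stratum values).  Must not exceed the stratum's patient count.
#' @param seed Integer seed.
#' @param id_var,stratum_var Column names (defaults `"patient_id"`,
#'   `"stratum"`).
#' @return Tibble of the sampled patients' records with columns `.weight`
#'   (expansion weight) and the originals.
#' @export
stratified_audit_sample <- function(records, n_h, seed = 1L,
                                    id_var = "patient_id",
                                    stratum_var = "stratum") {
  pts <- dplyr::distinct(records[, c(id_var, stratum_var)])
  if (anyDuplicated(pts[[id_var]]) > 0) {
    abort("stratified_audit_sample(): stratum must be constant within patient")
  }
  out <- list()
  for (h in names(n_h)) {
    ids <- pts[[id_var]][pts[[stratum_var]] == h]
    N_hh <- length(ids)
    if (n_h[[h]] == 0) next
    if (N_hh == 0) abort(paste0("empty stratum with requested sample: ", h))
    if (n_h[[h]] > N_hh) {
      abort(sprintf("stratum '%s': requested %d patients but only %d exist",
                    h, n_h[[h]], N_hh))
    }
    take <- with_seed(seed + match(h, names(n_h)),
                      sample(ids, n_h[[h]], replace = FALSE))
    sub <- records[records[[id_var]] %in% take, , drop = FALSE]
    sub$.weight <- N_hh / n_h[[h]]
    out[[h]] <- sub
  }
  dplyr::bind_rows(out)
}

ratio_ci <- function(num_h, den_h, n_h, w_h, conf = 0.95) {
  X <- sum(w_h * num_h)
  Y <- sum(w_h * den_h)
  if (Y <= 0) return(c(NA_real_, NA_real_, NA_real_))
  R <- X / Y
  # linearised variance of the expansion-weighted ratio: per audited unit
  # z = num_i - R * den_i, Var = sum_h w_h^2 n_h s2_h(z) / Y^2
  var_sum <- 0
  for (h in seq_along(n_h)) {
    nh <- n_h[h]
    if (nh <= 1) next
    # z takes value (1 - R) on num units, -R on den-only units, 0 otherwise
    n1 <- num_h[h]; n0 <- den_h[h] - num_h[h]
    zbar <- (n1 * (1 - R) - n0 * R) / nh
    ssq <- n1 * (1 - R - zbar)^2 + n0 * (-R - zbar)^2 + (nh - n1 - n0) * zbar^2
    var_sum <- var_sum + w_h[h]^2 * nh * (ssq / (nh - 1))
  }
  se <- sqrt(var_sum) / Y
  z <- qnorm(1 - (1 - conf) / 2)
  c(R, max(0, R - z * se), min(1, R + z * se))
}

#' Expansion-weighted diagnostic metrics from a stratified audit
#'
#' Projects per-stratum audited confusion counts to the population with
#' expansion weights `w_h = N_h / n_h`: every metric is a ratio of
#' weighted counts (e.g. sensitivity
#' `sum_h w_h TP_h / sum_h w_h (TP_h + FN_h)`).  With a single stratum of
#' weight 1 this reduces exactly to [diagnostic_metrics()] point
#' estimates, and scaling all `N_h` by a constant leaves every metric
#' unchanged.  Confidence intervals use a normal approximation with a
#' linearised variance for the weighted ratio.
#'
#' @param counts Tibble with one row per stratum and columns `TP`, `FP`,
#'   `TN`, `FN` (palliative = positive) and either `w` (expansion weight)
#'   or `N_h`/`n_audit` from which `w = N_h / n_audit` is derived.
#' @return Object of class `trr_audit_estimate`: tibble `metric`,
#'   `estimate`, `lo`, `hi`.  Metrics: sensitivity, specificity, ppv,
#'   npv, pct_correct, pct_incorrect.
#' @examples
#' stratified_estimates(tibble::tibble(
#'   N_h = c(900, 100), n_audit = c(90, 50),
#'   TP = c(30, 20), FN = c(10, 20), FP = c(5, 5), TN = c(45, 5)))
#' @export
stratified_estimates <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"w" %in% names(counts)) {
    counts$w <- counts$N_h / counts$n_audit
  }
  if (any(counts$w < 1 - 1e-9)) abort("expansion weights must be >= 1")
  n_h <- counts$TP + counts$FP + counts$TN + counts$FN
  w <- counts$w
  metric <- function(nm, num, den) {
    ci <- ratio_ci(num, den, n_h, w)
    tibble::tibble(metric = nm, estimate = ci[1], lo = ci[2], hi = ci[3])
  }
  out <- dplyr::bind_rows(
    metric("sensitivity", counts$TP, counts$TP + counts$FN),
    metric("specificity", counts$TN, counts$TN + counts$FP),
    metric("ppv", counts$TP, counts$TP + counts$FP),
    metric("npv", counts$TN, counts$TN + counts$FN),
    metric("pct_correct", counts$TP + counts$TN, n_h),
    metric("pct_incorrect", counts$FP + counts$FN, n_h))
  structure(out, class = c("trr_audit_estimate", class(out)))
}

#' Population data-quality report for the classifier and the intent flag
#'
#' Projects stratum-specific audited correctness rates to the whole
#' record population with expansion weights, producing the familiar
#' three-row quality table (% correct, % incorrect, % missing) for both
#' the tree/cascade classification and the recorded intent flag.  The
#' intent flag's % missing is observed directly from the full data set
#' (not estimated through the audit), and the classifier's % missing is
#' the observed share of records the cascade could not classify.  Records
#' whose intent flag is missing form their own stratum in which the
#' intent flag is never correct.
#'
#' @param records Full record set (tibble) with `intent_flag`.
#' @param predicted Character vector of classifier labels for `records`
#'   (`NA` = unclassifiable).
#' @param audit Tibble with one row per audited stratum: `stratum`,
#'   `n_audited`, `pred_correct`, `intent_correct` (counts among audited
#'   records).  Strata are the agreement classes `"agree"`, `"disagree"`,
#'   `"intent_missing"` as produced by [agreement_stratum()].
#' @param unaudited How to treat population strata absent from `audit`:
#'   `"unavailable"` (default) marks the report cells `NA`;
#'   `"assume_correct"` treats both classifications as correct there (the
#'   assumption implicit in auditing only disagreement records, which
#'   over-states success rates).
#' @return Object of class `trr_quality_report`: tibble `measure`
#'   (`pct_correct`, `pct_incorrect`, `pct_missing`), `method`
#'   (`classification_rules`, `intent_flag`), `estimate`, `lo`, `hi`
#'   (percentages, 95% normal-approximation CIs; `NA` CI for the observed
#'   missing shares).
#' @export
population_quality_report <- function(records, predicted, audit,
                                      unaudited = c("unavailable",
                                                    "assume_correct")) {
  unaudited <- match.arg(unaudited)
  stratum <- agreement_stratum(predicted, records$intent_flag)
  N <- length(stratum)
  strata <- sort(unique(stratum))
  N_h <- vapply(strata, function(h) sum(stratum == h), numeric(1))

  audit <- tibble::as_tibble(audit)
  get_rate <- function(h, what) {
    row <- audit[audit$stratum == h, , drop = FALSE]
    if (nrow(row) == 1) {
      c(p = row[[what]] / row$n_audited,
        v = row[[what]] / row$n_audited * (1 - row[[what]] / row$n_audited) /
          row$n_audited)
    } else if (unaudited == "assume_correct") {
      # disagree stratum: at most one of the two methods can be right,
      # but the optimistic reading treats each as correct when unaudited
      c(p = if (what == "intent_correct" && h == "intent_missing") 0 else 1,
        v = 0)
    } else {
      c(p = NA_real_, v = NA_real_)
    }
  }

  project <- function(what) {
    p <- 0; v <- 0
    for (h in strata) {
      r <- get_rate(h, what)
      pr <- if (what == "intent_correct" && h == "intent_missing") 0 else r["p"]
      vr <- if (what == "intent_correct" && h == "intent_missing") 0 else r["v"]
      if (is.na(pr)) return(c(NA_real_, NA_real_))
      p <- p + (N_h[[h]] / N) * unname(pr)
      v <- v + (N_h[[h]] / N)^2 * unname(vr)
    }
    c(p, sqrt(v))
  }

  z <- qnorm(0.975)
  pred_missing <- mean(is.na(predicted))
  intent_missing <- mean(is.na(records$intent_flag))

  pc <- project("pred_correct")
  # classifier correctness measured over classified records; NA predictions
  # occupy the % missing row
  ic <- project("intent_correct")

  row <- function(measure, method, est, se) {
    tibble::tibble(measure = measure, method = method,
                   estimate = 100 * est,
                   lo = if (is.na(se)) NA_real_ else
                     100 * max(0, est - z * se),
                   hi = if (is.na(se)) NA_real_ else
                     100 * min(1, est + z * se))
  }
  out <- dplyr::bind_rows(
    row("pct_correct", "classification_rules", pc[1], pc[2]),
    row("pct_incorrect", "classification_rules",
        if (is.na(pc[1])) NA_real_ else 1 - pc[1] - pred_missing, pc[2]),
    row("pct_missing", "classification_rules", pred_missing, NA),
    row("pct_correct", "intent_flag", ic[1], ic[2]),
    row("pct_incorrect", "intent_flag",
        if (is.na(ic[1])) NA_real_ else 1 - ic[1] - intent_missing, ic[2]),
    row("pct_missing", "intent_flag", intent_missing, NA))
  structure(out, class = c("trr_quality_report", class(out)))
}

#' Agreement stratum of each record
#'
#' `"agree"` / `"disagree"` between the classifier label and the intent
#' flag; `"intent_missing"` when the intent flag is absent (agreement is
#' undefined there).
#'
#' @param predicted,intent_flag Character vectors (`NA` allowed).
#' @return Character vector of stratum labels.
#' @export
agreement_stratum <- function(predicted, intent_flag) {
  out <- ifelse(is.na(intent_flag), "intent_missing",
                ifelse(!is.na(predicted) & predicted == intent_flag,
                       "agree", "disagree"))
  out
}

#' Summarise an audited sample into per-stratum report counts
#'
#' Convenience reduction from audited records (with known `true_role`)
#' to the `audit` table consumed by [population_quality_report()].
#'
#' @param audited Tibble of audited records with columns `stratum`,
#'   `true_role`, `predicted`, `intent_flag`.
#' @return Tibble `stratum`, `n_audited`, `pred_correct`,
#'   `intent_correct`.
#' @export
summarise_audit <- function(audited) {
  audited |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_audited = dplyr::n(),
      pred_correct = sum(!is.na(.data$predicted) &
                           .data$predicted == .data$true_role),
      intent_correct = sum(!is.na(.data$intent_flag) &
                             .data$intent_flag == .data$true_role),
      .groups = "drop")
}
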