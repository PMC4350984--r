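#' Configuration of the synthetic record generator
#'
#' Defaults emulate the marginal structure of the Ontario administrative
#' radiotherapy data the reference classifier was derived from: about 14%
#' of treatment records palliative; curative courses of 15--35 daily
#' fractions with dose per fraction centred at 200 cGy; palliative courses
#' of 1--10 fractions at 250--800 cGy centred at 300 cGy; per-variable
#' missingness 1% (fraction size), 9% (body region), 3% (disease site),
#' 0% (treatment date); recorded intent wrong on 4% of records and absent
#' on 18.8% (3.4% is the corresponding modern-period figure).  The joint
#' site x region frequency table is a coarse editable approximation
#' shipped as CSV data ([trr_extdata] `site_region_weights.csv`).
#'
#' Intent-label noise is a per-record three-way draw (missing with
#' `intent_missing_rate`, flipped with `intent_flip_rate`, otherwise
#' faithful), so the configured rates are directly the population shares
#' of missing and incorrect intent.
#'
#' @param n_patients Number of patients to simulate.
#' @param palliative_record_fraction Target share of treatment records
#'   (daily fractions) that are palliative; the first-course palliative
#'   probability is solved from the regimen means and the retreatment
#'   rate to hit this share in expectation.
#' @param curative_fractions,palliative_fractions Integer vectors of
#'   course lengths sampled uniformly.
#' @param curative_dose_levels,curative_dose_probs Dose-per-fraction
#'   levels (cGy) and probabilities for curative courses (median 200 at
#'   defaults).
#' @param palliative_dose_levels,palliative_dose_probs Same for
#'   palliative courses (median 300 at defaults).
#' @param retreat_prob Probability that a patient receives a second,
#'   later course; retreatments are palliative with probability
#'   `retreat_palliative_prob` (re-treatments are mostly palliative).
#' @param retreat_palliative_prob See above.
#' @param missing_rates Named numeric: masking probability per variable
#'   (`fraction_size`, `body_region_group`, `site_group`,
#'   `days_from_first`).
#' @param intent_flip_rate,intent_missing_rate Intent-label noise rates.
#' @param start_window Date range for first-course start dates.
#' @return List of class `trr_synth_config`.
#' @export
synth_config <- function(n_patients = 2000,
                         palliative_record_fraction = 0.14,
                         curative_fractions = 15:35,
                         palliative_fractions = 1:10,
                         curative_dose_levels = c(180, 200, 225, 250),
                         curative_dose_probs = c(0.20, 0.55, 0.10, 0.15),
                         palliative_dose_levels = c(250, 300, 400, 500, 800),
                         palliative_dose_probs = c(0.15, 0.45, 0.20, 0.08, 0.12),
                         retreat_prob = 0.15,
                         retreat_palliative_prob = 0.9,
                         missing_rates = c(fraction_size = 0.01,
                                           body_region_group = 0.09,
                                           site_group = 0.03,
                                           days_from_first = 0),
                         intent_flip_rate = 0.04,
                         intent_missing_rate = 0.188,
                         start_window = as.Date(c("2005-04-01", "2008-06-30"))) {
  stopifnot(n_patients >= 1,
            palliative_record_fraction > 0, palliative_record_fraction < 1,
            all(missing_rates >= 0 & missing_rates <= 1),
            intent_flip_rate >= 0, intent_missing_rate >= 0,
            intent_flip_rate + intent_missing_rate <= 1,
            all(curative_dose_levels > 0), all(palliative_dose_levels > 0))
  # expected course lengths
  L_c <- mean(curative_fractions)
  L_p <- mean(palliative_fractions)
  t <- palliative_record_fraction
  r <- retreat_prob
  q <- retreat_palliative_prob
  # solve E[palliative records] = t * E[records] for the first-course
  # palliative probability s:
  #   L_p s + r q L_p = t (L_c (1-s) + L_p s + r (q L_p + (1-q) L_c))
  s <- (t * (L_c + r * q * L_p + r * (1 - q) * L_c) - r * q * L_p) /
    (L_p + t * (L_c - L_p))
  if (s <= 0 || s >= 1) {
    abort("synth_config(): palliative_record_fraction unreachable under the configured regimens")
  }
  structure(list(
    n_patients = n_patients,
    palliative_record_fraction = palliative_record_fraction,
    first_course_palliative_prob = s,
    curative_fractions = curative_fractions,
    palliative_fractions = palliative_fractions,
    curative_dose_levels = curative_dose_levels,
    curative_dose_probs = curative_dose_probs / sum(curative_dose_probs),
    palliative_dose_levels = palliative_dose_levels,
    palliative_dose_probs = palliative_dose_probs / sum(palliative_dose_probs),
    retreat_prob = retreat_prob,
    retreat_palliative_prob = retreat_palliative_prob,
    missing_rates = missing_rates,
    intent_flip_rate = intent_flip_rate,
    intent_missing_rate = intent_missing_rate,
    start_window = start_window
  ), class = "trr_synth_config")
}

# n consecutive weekdays starting at `start`
weekday_run <- function(start, n) {
  days <- start + seq(0, by = 1, length.out = ceiling(n * 7 / 5) + 4)
  days <- days[!format(days, "%u") %in% c("6", "7")]
  days[seq_len(n)]
}

sample_site_region <- function(n, role) {
  w <- read_extdata_csv("site_region_weights.csv")
  probs <- if (role == "P") w$w_palliative else w$w_curative
  idx <- sample.int(nrow(w), n, replace = TRUE, prob = probs)
  list(site = w$site_group[idx], region = w$body_region_group[idx])
}

#' Generate synthetic administrative radiotherapy records
#'
#' Simulates patients, courses (consecutive weekday fractions) and daily
#' treatment records according to a [synth_config()]: each course has a
#' latent therapeutic role driving its regimen (length, dose per
#' fraction) and its site/region draw; recorded intent is the true role
#' corrupted by the configured flip/missing noise; classification
#' variables are masked independently at the configured rates.  Fully
#' reproducible per seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return Tibble of treatment records (one per daily fraction) with the
#'   canonical record columns plus the hidden ground truth `true_role`
#'   (and `course_id`).  `true_role` is for evaluation only and is
#'   dropped by [write_records()] unless a sidecar is requested.
#' @examples
#' recs <- generate_records(synth_config(n_patients = 50), seed = 1)
#' table(recs$true_role)
#' @export
generate_records <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "trr_synth_config"))
  with_seed(seed, {
    np <- config$n_patients
    first_role <- ifelse(runif(np) < config$first_course_palliative_prob,
                         "P", "C")
    retreat <- runif(np) < config$retreat_prob
    retreat_role <- ifelse(runif(np) < config$retreat_palliative_prob,
                           "P", "C")
    start0 <- config$start_window[1] +
      floor(runif(np) * as.integer(diff(config$start_window)))

    courses <- tibble::tibble(
      patient = rep(seq_len(np), times = 1 + retreat),
      course = unlist(lapply(retreat, function(r) seq_len(1 + r))),
      role = unlist(purrr::map2(first_role,
                                ifelse(retreat, retreat_role, NA),
                                function(a, b) c(a, b[!is.na(b)])))
    )
    nc <- nrow(courses)
    is_pal <- courses$role == "P"
    len <- integer(nc)
    len[is_pal] <- sample(config$palliative_fractions, sum(is_pal),
                          replace = TRUE)
    len[!is_pal] <- sample(config$curative_fractions, sum(!is_pal),
                           replace = TRUE)
    dose <- numeric(nc)
    dose[is_pal] <- sample(config$palliative_dose_levels, sum(is_pal),
                           replace = TRUE, prob = config$palliative_dose_probs)
    dose[!is_pal] <- sample(config$curative_dose_levels, sum(!is_pal),
                            replace = TRUE, prob = config$curative_dose_probs)
    sr <- list(site = character(nc), region = character(nc))
    pal_sr <- sample_site_region(sum(is_pal), "P")
    cur_sr <- sample_site_region(sum(!is_pal), "C")
    sr$site[is_pal] <- pal_sr$site; sr$region[is_pal] <- pal_sr$region
    sr$site[!is_pal] <- cur_sr$site; sr$region[!is_pal] <- cur_sr$region
    # one primary per patient: retreat keeps the first course's disease site
    first_site <- sr$site[courses$course == 1][courses$patient]
    sr$site <- first_site
    # retreat starts 30-300 days after the first course start
    gap <- 30 + floor(runif(nc) * 271)
    start <- start0[courses$patient] + ifelse(courses$course == 1, 0, gap)

    recs <- tibble::tibble(
      patient_id = sprintf("pt%05d", rep(courses$patient, len)),
      course_id = rep(sprintf("pt%05d-c%d", courses$patient, courses$course),
                      len),
      fraction_size = rep(dose, len),
      body_region_group = rep(sr$region, len),
      site_group = rep(sr$site, len),
      true_role = rep(courses$role, len),
      technique = NA_character_
    )
    recs$treat_date <- as.Date(unlist(purrr::map2(
      start, len, function(s, l) weekday_run(s, l))), origin = "1970-01-01")
    recs$cancer_id <- recs$patient_id
    recs <- compute_days_from_first(recs)

    n <- nrow(recs)
    # intent noise: three-way draw so the configured rates are directly
    # the population shares of missing and incorrect intent
    u <- runif(n)
    intent <- recs$true_role
    intent[u < config$intent_missing_rate] <- NA_character_
    flip <- u >= config$intent_missing_rate &
      u < config$intent_missing_rate + config$intent_flip_rate
    intent[flip] <- ifelse(recs$true_role[flip] == "C", "P", "C")
    recs$intent_raw <- ifelse(is.na(intent), NA_character_,
                              ifelse(intent == "C", "curative", "palliative"))
    recs$intent_flag <- intent

    mr <- config$missing_rates
    mask <- function(x, rate) {
      if (rate > 0) x[runif(length(x)) < rate] <- NA
      x
    }
    recs$fraction_size <- mask(recs$fraction_size, mr[["fraction_size"]])
    recs$body_region_group <- mask(recs$body_region_group,
                                   mr[["body_region_group"]])
    recs$site_group <- mask(recs$site_group, mr[["site_group"]])
    recs$days_from_first <- mask(recs$days_from_first,
                                 mr[["days_from_first"]])
    recs[, c(trr_record_columns(), "course_id", "true_role")]
  })
}

# walk a tree collecting per-leaf feature regions
leaf_regions <- function(tree, numeric_ranges, category_domains) {
  out <- list()
  walk <- function(node, num, cat) {
    if (node$is_leaf) {
      out[[length(out) + 1]] <<- list(leaf_id = node$leaf_id,
                                      label = node$label,
                                      num = num, cat = cat)
      return(invisible(NULL))
    }
    s <- node$split
    if (s$kind == "threshold") {
      lo <- num[[s$variable]][1]; hi <- num[[s$variable]][2]
      nl <- num; nl[[s$variable]] <- c(lo, min(hi, s$threshold))
      nr <- num; nr[[s$variable]] <- c(max(lo, s$threshold), hi)
      walk(node$left, nl, cat)
      walk(node$right, nr, cat)
    } else {
      cl <- cat; cl[[s$variable]] <- intersect(cat[[s$variable]], s$left_set)
      cr <- cat; cr[[s$variable]] <- intersect(cat[[s$variable]], s$right_set)
      walk(node$left, num, cl)
      walk(node$right, num, cr)
    }
  }
  walk(tree$root, numeric_ranges, category_domains)
  out
}

#' Generate records from a known tree (recovery-test harness)
#'
#' Draws records uniformly within each leaf's feature region of a fully
#' labelled tree, assigning the leaf's label as the true role with
#' probability `purity` (the Bayes-optimal classifier of the generated
#' population is then the tree itself).  The recorded intent equals the
#' true role, so a tree grown on this data can be compared against the
#' generative truth.
#'
#' @param tree A `trr_tree` whose leaves are all labelled `"C"` or `"P"`.
#' @param purity Probability in (0.5, 1] that a record's true role equals
#'   its leaf label.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param numeric_ranges Named list of `c(lo, hi)` feature ranges
#'   (defaults: fraction_size 100--1000 cGy, days_from_first 0--365).
#' @param category_domains Named list of category vectors (defaults: the
#'   shipped body-region and site vocabularies).
#' @param leaf_weights Leaf selection probabilities (default uniform over
#'   leaves).
#' @return Tibble with the tree's variables, `true_role`, `intent_flag`
#'   and `leaf_id` (generating leaf).
#' @export
generate_from_tree <- function(tree, purity, n, seed = 1L,
                               numeric_ranges = list(
                                 fraction_size = c(100, 1000),
                                 days_from_first = c(0, 365)),
                               category_domains = list(
                                 body_region_group = grouping_maps()$body_region_groups,
                                 site_group = grouping_maps()$site_groups),
                               leaf_weights = NULL) {
  stopifnot(purity > 0.5, purity <= 1)
  regions <- leaf_regions(tree, numeric_ranges, category_domains)
  labels <- vapply(regions, `[[`, character(1), "label")
  if (any(!labels %in% c("C", "P"))) {
    abort("generate_from_tree(): every leaf must be labelled 'C' or 'P'")
  }
  if (is.null(leaf_weights)) leaf_weights <- rep(1, length(regions))
  with_seed(seed, {
    pick <- sample.int(length(regions), n, replace = TRUE,
                       prob = leaf_weights)
    cols <- list()
    for (v in tree$variables) {
      if (v %in% names(numeric_ranges)) {
        lo <- vapply(regions, function(r) r$num[[v]][1], numeric(1))[pick]
        hi <- vapply(regions, function(r) r$num[[v]][2], numeric(1))[pick]
        x <- lo + runif(n) * (hi - lo)
        if (v == "days_from_first") x <- floor(x)
        cols[[v]] <- x
      } else {
        cols[[v]] <- vapply(seq_len(n), function(i) {
          dom <- regions[[pick[i]]]$cat[[v]]
          dom[sample.int(length(dom), 1)]
        }, character(1))
      }
    }
    out <- tibble::as_tibble(cols)
    keep <- runif(n) < purity
    lab <- labels[pick]
    out$true_role <- ifelse(keep, lab, ifelse(lab == "C", "P", "C"))
    out$intent_flag <- out$true_role
    out$leaf_id <- vapply(regions, `[[`, integer(1), "leaf_id")[pick]
    out
  })
}
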