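#' Default abnormality cutoffs for the visual rating scales
#'
#' Returns the age-adjusted cutoff table used to decide whether a rating on
#' each of the three scales counts as abnormal. Medial temporal atrophy (MTA,
#' 0-4 per hemisphere, averaged bilaterally) uses age-band-specific cutoffs:
#' a composite score >= 1.5, 1.5, 2 and 2.5 is abnormal at ages 45-64, 65-74,
#' 75-84 and 85-94 years respectively. Posterior atrophy (PA, 0-3) and the
#' frontal subscale of global cortical atrophy (GCA-F, 0-3) use a single
#' age-independent cutoff: a score >= 1 is abnormal.
#'
#' @return A list with components `mta_bands` (data.frame with columns
#'   `age_low`, `age_high`, `threshold`), `pa_threshold` and `gca_f_threshold`.
#' @examples
#' default_cutoffs()
#' @export
default_cutoffs <- function() {
  list(
    mta_bands = data.frame(
      age_low   = c(45, 65, 75, 85),
      age_high  = c(64, 74, 84, 94),
      threshold = c(1.5, 1.5, 2, 2.5)
    ),
    pa_threshold    = 1,
    gca_f_threshold = 1
  )
}

validate_cutoffs <- function(cutoffs) {
  b <- cutoffs$mta_bands
  stopifnot(
    is.data.frame(b),
    all(c("age_low", "age_high", "threshold") %in% names(b)),
    nrow(b) >= 1,
    all(b$age_low <= b$age_high)
  )
  if (nrow(b) > 1) {
    ord <- order(b$age_low)
    b <- b[ord, ]
    if (any(b$age_low[-1] != b$age_high[-nrow(b)] + 1))
      stop("MTA age bands must be contiguous and non-overlapping")
    if (is.unsorted(b$threshold))
      stop("MTA thresholds must be non-decreasing with age")
  }
  invisible(cutoffs)
}

#' Age-specific MTA abnormality cutoff
#'
#' Looks up the abnormality threshold for the (bilaterally averaged) MTA score
#' at a given age.
#'
#' @param age Numeric vector of ages in years.
#' @param cutoffs Cutoff table, see [default_cutoffs()].
#' @param clamp If `TRUE`, ages outside the configured bands are clamped to the
#'   nearest band instead of raising an error.
#' @return Numeric vector of thresholds in rating units.
#' @examples
#' mta_cutoff(c(50, 80, 90)) # 1.5, 2, 2.5
#' @export
mta_cutoff <- function(age, cutoffs = default_cutoffs(), clamp = FALSE) {
  validate_cutoffs(cutoffs)
  b <- cutoffs$mta_bands[order(cutoffs$mta_bands$age_low), ]
  stopifnot(is.numeric(age))
  if (clamp) {
    age <- pmin(pmax(age, min(b$age_low)), max(b$age_high))
  }
  idx <- findInterval(age, c(b$age_low, max(b$age_high) + 1))
  out_of_band <- is.na(age) | idx < 1 | idx > nrow(b) | age > max(b$age_high)
  if (any(out_of_band, na.rm = TRUE)) {
    stop(sprintf(
      "age outside configured bands (%d-%d years): %s; set clamp = TRUE to clamp",
      min(b$age_low), max(b$age_high),
      paste(age[out_of_band], collapse = ", ")
    ))
  }
  b$threshold[idx]
}

check_rating <- function(x, max, name) {
  bad <- !is.na(x) & (x < 0 | x > max | x != round(x))
  if (any(bad))
    stop(sprintf("%s must be an integer in 0-%d; offending values: %s",
                 name, max, paste(unique(x[bad]), collapse = ", ")))
  invisible(x)
}

#' Composite bilateral MTA score
#'
#' Combines left and right MTA ratings into one composite score. The default
#' (and the only rule compatible with the half-point cutoffs) is the
#' arithmetic mean of the two sides, yielding values on a 0-4 grid in steps of
#' 0.5. A `max` rule (worst side) is available as an alternative.
#'
#' @param mta_left,mta_right Integer ratings 0-4.
#' @param rule `"mean"` (default) or `"max"`.
#' @return Numeric vector of composite scores.
#' @examples
#' composite_mta(1, 2) # 1.5
#' @export
composite_mta <- function(mta_left, mta_right, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  check_rating(mta_left, 4, "mta_left")
  check_rating(mta_right, 4, "mta_right")
  if (rule == "mean") (mta_left + mta_right) / 2 else pmax(mta_left, mta_right)
}

#' Abnormality flag for a rating score
#'
#' A score is abnormal when it reaches or exceeds its threshold (inclusive,
#' matching the ">=" convention of the published cutoffs).
#'
#' @param score Numeric rating score(s).
#' @param threshold Numeric threshold(s) in the same units.
#' @return Logical vector.
#' @export
is_abnormal <- function(score, threshold) {
  score >= threshold
}

#' Subtype labels
#'
#' The four mutually exclusive atrophy-pattern classes, in the conventional
#' reporting order.
#' @return Character vector of the four labels.
#' @export
subtype_levels <- function() {
  c("typical", "limbic_predominant", "hippocampal_sparing", "no_atrophy")
}

#' Classify atrophy-pattern subtype from visual ratings
#'
#' Applies the four-way decision rule: abnormal MTA together with abnormal PA
#' and/or GCA-F is `typical`; abnormal MTA with normal PA and GCA-F is
#' `limbic_predominant`; normal MTA with abnormal PA and/or GCA-F is
#' `hippocampal_sparing`; all scales normal is `no_atrophy`. MTA abnormality
#' uses the age-specific cutoff on the bilateral composite; PA and GCA-F use
#' their fixed cutoff.
#'
#' All arguments are vectorized over subjects.
#'
#' @param mta_left,mta_right Integer MTA ratings 0-4 per hemisphere.
#' @param pa Integer posterior atrophy rating 0-3.
#' @param gca_f Integer frontal atrophy rating 0-3.
#' @param age Age in years (must fall in a configured band unless `clamp`).
#' @param cutoffs Cutoff table, see [default_cutoffs()].
#' @param clamp Clamp out-of-band ages to the nearest band.
#' @param mta_rule Bilateral combination rule, see [composite_mta()].
#' @return Factor with levels [subtype_levels()].
#' @examples
#' classify_subtype(2, 2, 1, 0, age = 70)  # typical
#' classify_subtype(1, 1, 0, 0, age = 80)  # no_atrophy
#' @export
classify_subtype <- function(mta_left, mta_right, pa, gca_f, age,
                             cutoffs = default_cutoffs(), clamp = FALSE,
                             mta_rule = c("mean", "max")) {
  check_rating(pa, 3, "pa")
  check_rating(gca_f, 3, "gca_f")
  comp <- composite_mta(mta_left, mta_right, rule = mta_rule)
  thr <- mta_cutoff(age, cutoffs = cutoffs, clamp = clamp)
  mta_abn <- is_abnormal(comp, thr)
  ctx_abn <- is_abnormal(pa, cutoffs$pa_threshold) |
    is_abnormal(gca_f, cutoffs$gca_f_threshold)
  lab <- ifelse(mta_abn & ctx_abn, "typical",
         ifelse(mta_abn & !ctx_abn, "limbic_predominant",
         ifelse(!mta_abn & ctx_abn, "hippocampal_sparing", "no_atrophy")))
  factor(lab, levels = subtype_levels())
}

#' Classify a cohort and tabulate subtype prevalence
#'
#' Applies [classify_subtype()] to every patient row of a cohort table and
#' returns per-subject labels plus a prevalence table. Only rows whose `dx`
#' column equals `ad_value` are labelled; other rows (controls) pass through
#' with an `NA` label. Rows with missing rating fields are skipped with a
#' warning listing the affected ids.
#'
#' @param data Data frame with columns `id`, `age`, `dx`, `mta_l`, `mta_r`,
#'   `pa`, `gca_f`.
#' @param ad_value Value of `dx` marking patients to classify (default "AD").
#' @param ... Passed on to [classify_subtype()].
#' @return List with `labels` (data.frame `id`, `subtype`) and `prevalence`
#'   (data.frame `subtype`, `n`, `pct`).
#' @export
classify_cohort <- function(data, ad_value = "AD", ...) {
  req <- c("id", "age", "dx", "mta_l", "mta_r", "pa", "gca_f")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))

  labels <- data.frame(id = data$id,
                       subtype = factor(rep(NA_character_, nrow(data)),
                                        levels = subtype_levels()))
  is_ad <- !is.na(data$dx) & data$dx == ad_value
  rating_cols <- c("age", "mta_l", "mta_r", "pa", "gca_f")
  incomplete <- is_ad & !stats::complete.cases(data[rating_cols])
  if (any(incomplete)) {
    warning("skipping subjects with missing rating fields: ",
            paste(data$id[incomplete], collapse = ", "))
  }
  use <- is_ad & !incomplete
  if (any(use)) {
    labels$subtype[use] <- classify_subtype(
      data$mta_l[use], data$mta_r[use], data$pa[use], data$gca_f[use],
      age = data$age[use], ...
    )
  }
  counts <- table(labels$subtype)
  n_tot <- sum(counts)
  prevalence <- data.frame(
    subtype = names(counts),
    n = as.integer(counts),
    pct = if (n_tot > 0) 100 * as.integer(counts) / n_tot else rep(NA_real_, length(counts)),
    row.names = NULL
  )
  list(labels = labels, prevalence = prevalence)
}
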