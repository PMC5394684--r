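avlt_item_cols <- function() {
  c("avlt_t1", "avlt_t2", "avlt_t3", "avlt_t4", "avlt_t5",
    "avlt_b", "avlt_imm", "avlt_del", "avlt_rec")
}

#' Memory component names
#'
#' The five performance components plus the derived percentage scores and
#' gain.
#' @return Character vector.
#' @export
memory_components <- function() {
  c("learning", "interference", "immediate", "delayed", "recognition",
    "delayed_pct", "recognition_pct", "gain")
}

#' Derive AVLT memory components from raw item scores
#'
#' Computes, per subject: `learning` (sum of the five list-A learning trials,
#' 0-75, indexing learning capacity), `interference` (list-B recall),
#' `immediate` (list-A free recall right after list B), `delayed` (list-A
#' free recall after 30 minutes), `recognition` (hits out of 15),
#' `delayed_pct` and `recognition_pct` (percent of the 15-word maximum), and
#' `gain = recognition_pct - delayed_pct`. Gain quantifies the benefit from
#' retrieval cues: a high gain means recognition is preserved relative to
#' free recall, i.e. the subject stores information but has trouble
#' retrieving it without help.
#'
#' Items outside 0-15 raise an error. A missing item makes only the
#' components that depend on it missing.
#'
#' @param data Data frame with columns `avlt_t1`..`avlt_t5`, `avlt_b`,
#'   `avlt_imm`, `avlt_del`, `avlt_rec` (and optionally `id`).
#' @return Data frame of components, one row per subject, `id` preserved.
#' @examples
#' derive_components(data.frame(avlt_t1 = 10, avlt_t2 = 10, avlt_t3 = 10,
#'   avlt_t4 = 10, avlt_t5 = 10, avlt_b = 5, avlt_imm = 9, avlt_del = 6,
#'   avlt_rec = 12))
#' @export
derive_components <- function(data) {
  cols <- avlt_item_cols()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing AVLT columns: ", paste(missing_cols, collapse = ", "))
  for (cl in cols) {
    x <- data[[cl]]
    if (any(!is.na(x) & (x < 0 | x > 15)))
      stop(cl, " outside the 0-15 item range")
  }
  trials <- as.matrix(data[paste0("avlt_t", 1:5)])
  out <- data.frame(
    learning = rowSums(trials),      # NA if any trial missing
    interference = data$avlt_b,
    immediate = data$avlt_imm,
    delayed = data$avlt_del,
    recognition = data$avlt_rec
  )
  out$delayed_pct <- 100 * out$delayed / 15
  out$recognition_pct <- 100 * out$recognition / 15
  out$gain <- out$recognition_pct - out$delayed_pct
  if ("id" %in% names(data)) out <- cbind(id = data$id, out)
  out
}

#' Reference norms for memory components
#'
#' Component-wise mean and SD (denominator n-1) in a designated reference
#' group, used to convert raw component scores to z units and to flag
#' clinical impairment.
#'
#' @param reference Data frame of components for the reference subjects
#'   (output of [derive_components()]).
#' @param components Which components to norm (default all present).
#' @return Object of class `memory_norms`: data.frame `component`, `mean`,
#'   `sd`, `n`.
#' @export
fit_norms <- function(reference, components = intersect(memory_components(),
                                                        names(reference))) {
  stopifnot(length(components) >= 1)
  rows <- lapply(components, function(cp) {
    x <- reference[[cp]]
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("need >= 2 reference values for ", cp)
    s <- stats::sd(x)
    if (s == 0) stop("zero variance in reference component ", cp)
    data.frame(component = cp, mean = mean(x), sd = s, n = length(x))
  })
  structure(do.call(rbind, rows), class = c("memory_norms", "data.frame"))
}

norm_z <- function(components, norms) {
  z <- components
  for (i in seq_len(nrow(norms))) {
    cp <- norms$component[i]
    if (cp %in% names(z))
      z[[cp]] <- (components[[cp]] - norms$mean[i]) / norms$sd[i]
  }
  z[intersect(c("id", norms$component), names(z))]
}

#' Flag clinical impairment against reference norms
#'
#' A performance component (learning, interference, immediate, delayed,
#' recognition) is impaired when its z score against the reference group is
#' at or below `-threshold` SD (boundary inclusive). Gain is reversed: a
#' *high* gain indicates retrieval problems, so it is flagged when its
#' z score is at or above `+threshold`.
#'
#' @param components Data frame of component scores.
#' @param norms A `memory_norms` object from [fit_norms()].
#' @param threshold Impairment cutoff in SD units (default 1.5).
#' @return Data frame of logical flags (plus `id` if present).
#' @export
classify_impairment <- function(components, norms, threshold = 1.5) {
  stopifnot(inherits(norms, "memory_norms"), threshold > 0)
  z <- norm_z(components, norms)
  flags <- z
  for (cp in setdiff(names(z), "id")) {
    flags[[cp]] <- if (cp == "gain") z[[cp]] >= threshold else z[[cp]] <= -threshold
  }
  flags
}

#' Impairment frequency table by subtype
#'
#' Percentage of labelled patients flagged as clinically impaired per memory
#' component and subtype, with the per-cell denominator (non-missing count).
#'
#' @param components Component scores for the patients, including `id`.
#' @param labels Data frame `id`, `subtype` (from [classify_cohort()]).
#' @param norms Reference norms from [fit_norms()].
#' @param threshold SD cutoff, see [classify_impairment()].
#' @param components_use Components to tabulate (default: the five
#'   performance components plus gain).
#' @return Data frame `component`, one `pct_<subtype>` and `n_<subtype>`
#'   column pair per subtype; empty cells are `NA`.
#' @export
impairment_table <- function(components, labels, norms, threshold = 1.5,
                             components_use = c("learning", "interference",
                                                "immediate", "delayed",
                                                "recognition", "gain")) {
  merged <- merge(components, labels, by = "id")
  merged <- merged[!is.na(merged$subtype), ]
  flags <- classify_impairment(merged, norms, threshold)
  flags$subtype <- merged$subtype
  out <- data.frame(component = components_use)
  for (st in subtype_levels()) {
    sub <- flags[flags$subtype == st, components_use, drop = FALSE]
    n <- vapply(sub, function(x) sum(!is.na(x)), integer(1))
    pct <- vapply(sub, function(x) {
      k <- sum(!is.na(x))
      if (k == 0) NA_real_ else 100 * mean(x, na.rm = TRUE)
    }, numeric(1))
    out[[paste0("pct_", st)]] <- pct
    out[[paste0("n_", st)]] <- n
  }
  out
}

#' Split-plot ANOVA: memory component by subtype interaction
#'
#' Tests whether the profile across memory components differs between
#' subtypes. Component scores are first standardized against the reference
#' norms so the within-subject factor levels share a scale, then analysed as
#' a split-plot design (between factor: group; within factor: component;
#' subject as the error stratum). Optional covariates are residualized out of
#' the z scores (per component, centered) before the ANOVA. Post-hoc
#' pairwise group contrasts per component are Welch t tests with
#' Benjamini-Hochberg adjustment across the whole contrast family.
#'
#' @param components Component scores including `id`.
#' @param groups Data frame `id`, `group` (2+ groups after merging).
#' @param norms Reference norms from [fit_norms()].
#' @param components_use Within-factor levels (default the five performance
#'   components).
#' @param covariates Optional data frame `id` plus covariate columns.
#' @return List with `anova` (the full split-plot table), `interaction`
#'   (`F`, `df1`, `df2`, `p`), and `posthoc` (component, pair, t, raw and
#'   BH-adjusted p).
#' @export
component_by_group_anova <- function(components, groups, norms,
                                     components_use = c("learning",
                                                        "interference",
                                                        "immediate",
                                                        "delayed",
                                                        "recognition"),
                                     covariates = NULL) {
  z <- norm_z(components, norms)
  stopifnot("id" %in% names(z))
  merged <- merge(z, groups, by = "id")
  merged <- merged[!is.na(merged$group), ]
  if (length(unique(merged$group)) < 2)
    stop("need >= 2 groups for the component-by-group interaction")
  long <- stats::reshape(
    merged[c("id", "group", components_use)],
    direction = "long", varying = components_use, v.names = "z",
    timevar = "component", times = components_use, idvar = "id"
  )
  long <- long[!is.na(long$z), ]
  n_comp <- tapply(long$component, long$id, function(x) length(unique(x)))
  keep <- names(n_comp)[n_comp >= 2]
  long <- long[long$id %in% keep, ]
  long$id <- factor(long$id)
  long$group <- factor(long$group)
  long$component <- factor(long$component, levels = components_use)

  if (!is.null(covariates)) {
    long <- merge(long, covariates, by = "id")
    cv <- setdiff(names(covariates), "id")
    for (v in cv) long[[v]] <- long[[v]] - mean(long[[v]], na.rm = TRUE)
    resid_form <- stats::as.formula(paste("z ~", paste(cv, collapse = " + ")))
    long$z <- stats::resid(stats::lm(resid_form, data = long)) +
      mean(long$z, na.rm = TRUE)
  }

  fit <- stats::aov(z ~ group * component + Error(id), data = long)
  sm <- summary(fit)
  within <- sm[["Error: Within"]][[1]]
  ix <- grep("^group:component", rownames(within))
  res <- grep("Residuals", rownames(within))
  interaction <- list(
    F = within[ix, "F value"],
    df1 = within[ix, "Df"],
    df2 = within[res, "Df"],
    p = within[ix, "Pr(>F)"]
  )

  gl <- levels(long$group)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  ph <- do.call(rbind, lapply(components_use, function(cp) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- long$z[long$component == cp & long$group == pr[1]]
      b <- long$z[long$component == cp & long$group == pr[2]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      tt <- stats::t.test(a, b)
      data.frame(component = cp, group1 = pr[1], group2 = pr[2],
                 diff = unname(tt$estimate[1] - tt$estimate[2]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }))
  ph$p_adj <- bh_adjust(ph$p)
  list(anova = sm, interaction = interaction, posthoc = ph)
}
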