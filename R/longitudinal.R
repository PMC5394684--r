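lmm_formula <- function(outcome, quadratic = FALSE, covariates = NULL,
                        random_slope = FALSE) {
  fixed <- "group * time"
  if (quadratic) fixed <- paste(fixed, "+ group * I(time^2)")
  if (length(covariates)) fixed <- paste(fixed, "+",
                                         paste(covariates, collapse = " + "))
  ran <- if (random_slope) "(1 + time | id)" else "(1 | id)"
  stats::as.formula(paste(outcome, "~", fixed, "+", ran))
}

#' Fit the longitudinal random-intercept mixed model
#'
#' Fits `outcome ~ group * time + (1 | id)` by REML (lmerTest), the model
#' used to estimate per-group linear progression slopes: fixed effects are
#' group, time and their interaction; the random effect is a per-subject
#' intercept. All rows with an observed outcome contribute, so subjects with
#' missing visits are retained with their available time points. Optional
#' centered covariates and a quadratic time term can be added, and a random
#' slope variant is available behind a flag.
#'
#' @param data Long-format data frame with columns `id`, `group`, `time` and
#'   the outcome.
#' @param outcome Outcome column name (e.g. `"cdr"` or `"mmse"`).
#' @param ref_group Reference level for the group factor (default `"hc"` if
#'   present, else first level).
#' @param quadratic Add `time^2` and its group interaction.
#' @param covariates Optional covariate column names; centered before entry.
#' @param random_slope Add a per-subject random slope on time.
#' @return Object of class `subtype_lmm`: list with the `lmerTest` fit
#'   (`model`), `outcome`, `groups`, `ref_group`, `converged`, `quadratic`.
#' @export
fit_lmm <- function(data, outcome, ref_group = NULL, quadratic = FALSE,
                    covariates = NULL, random_slope = FALSE) {
  stopifnot(all(c("id", "group", "time", outcome) %in% names(data)))
  d <- data[!is.na(data[[outcome]]), ]
  d$id <- factor(d$id)
  groups <- unique(as.character(d$group))
  if (is.null(ref_group)) ref_group <- if ("hc" %in% groups) "hc" else groups[1]
  stopifnot(ref_group %in% groups)
  d$group <- stats::relevel(factor(d$group), ref = ref_group)
  for (v in covariates) d[[v]] <- d[[v]] - mean(d[[v]], na.rm = TRUE)

  form <- lmm_formula(outcome, quadratic, covariates, random_slope)
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = TRUE)),
    warning = function(w) {
      if (grepl("singular|boundary", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  # converged = optimizer reported success; lme4's post-hoc gradient checks
  # fire spuriously on boundary fits (e.g. zero variance components)
  conv <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  structure(list(model = fit, outcome = outcome,
                 groups = levels(d$group), ref_group = ref_group,
                 converged = conv, quadratic = quadratic,
                 covariates = covariates, data = d),
            class = "subtype_lmm")
}

#' @export
print.subtype_lmm <- function(x, ...) {
  cat("Longitudinal mixed model for", x$outcome,
      if (x$quadratic) "(with quadratic time)" else "", "\n")
  print(group_slopes(x))
  invisible(x)
}

check_converged <- function(fit) {
  if (!fit$converged) stop("mixed model did not converge; refusing to report")
  invisible(fit)
}

# indices of the fixed-effect terms making up group g's slope
slope_contrast_vector <- function(fit, g) {
  fe <- names(lme4::fixef(fit$model))
  L <- stats::setNames(numeric(length(fe)), fe)
  L["time"] <- 1
  inter <- paste0("group", g, ":time")
  if (inter %in% fe) L[inter] <- 1
  L
}

#' Per-group progression slopes from a fitted mixed model
#'
#' Resolves the reference slope plus interaction offsets into absolute
#' per-group linear slopes with standard errors (from the fixed-effect
#' covariance of the corresponding contrast).
#'
#' @param fit A `subtype_lmm` from [fit_lmm()].
#' @return Data frame `group`, `slope`, `se`.
#' @export
group_slopes <- function(fit) {
  check_converged(fit)
  V <- as.matrix(stats::vcov(fit$model))
  fe <- lme4::fixef(fit$model)
  rows <- lapply(fit$groups, function(g) {
    L <- slope_contrast_vector(fit, g)
    data.frame(group = g,
               slope = drop(L %*% fe),
               se = sqrt(drop(t(L) %*% V %*% L)))
  })
  do.call(rbind, rows)
}

#' Pairwise slope contrasts with BH adjustment
#'
#' Wald t tests of slope differences between groups, with Satterthwaite
#' degrees of freedom, Benjamini-Hochberg adjusted across the requested pair
#' family.
#'
#' @param fit A `subtype_lmm` from [fit_lmm()].
#' @param pairs List of length-2 character vectors of group names; default
#'   all unordered pairs.
#' @return Data frame `group1`, `group2`, `diff`, `se`, `df`, `t`, `p`,
#'   `p_adj`.
#' @export
slope_contrasts <- function(fit, pairs = NULL) {
  check_converged(fit)
  if (is.null(pairs)) pairs <- utils::combn(fit$groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    if (!all(pr %in% fit$groups))
      stop("unknown group(s): ", paste(setdiff(pr, fit$groups), collapse = ", "))
    if (pr[1] == pr[2])
      return(data.frame(group1 = pr[1], group2 = pr[2], diff = 0,
                        se = NA_real_, df = NA_real_, t = NA_real_, p = 1))
    L <- slope_contrast_vector(fit, pr[1]) - slope_contrast_vector(fit, pr[2])
    ct <- lmerTest::contest(fit$model, L, joint = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               diff = ct[["Estimate"]], se = ct[["Std. Error"]],
               df = ct[["df"]], t = ct[["t value"]], p = ct[["Pr(>|t|)"]])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Test linear versus quadratic progression
#'
#' Adds `time^2` and `group:time^2` fixed effects and compares the two
#' models by a likelihood-ratio test on ML refits (fixed-effect structures
#' differ, so REML likelihoods are not comparable).
#'
#' @param data Long-format visit table, see [fit_lmm()].
#' @param outcome Outcome column name.
#' @param ... Passed to [fit_lmm()] (e.g. `ref_group`, `covariates`).
#' @return List with `chisq`, `df`, `p`, and the two `subtype_lmm` fits.
#' @export
test_quadratic <- function(data, outcome, ...) {
  if (length(unique(data$time[!is.na(data[[outcome]])])) < 3)
    stop("quadratic time requires >= 3 distinct time points")
  lin <- fit_lmm(data, outcome, quadratic = FALSE, ...)
  quad <- fit_lmm(data, outcome, quadratic = TRUE, ...)
  cmp <- suppressMessages(anova(quad$model, lin$model))  # refits with ML
  list(chisq = cmp[["Chisq"]][2], df = cmp[["Df"]][2],
       p = cmp[["Pr(>Chisq)"]][2], linear = lin, quadratic = quad)
}

#' Mean rating trajectories by group and visit
#'
#' Group-by-time mean scores for each visual rating scale with per-cell n;
#' the MTA sides are averaged into the bilateral composite first.
#'
#' @param longitudinal Long-format data frame with `group`, `time` and any of
#'   `mta_l`/`mta_r`, `pa`, `gca_f`.
#' @return Data frame `group`, `time`, `n`, and mean columns for the scales
#'   present (`mta` composite, `pa`, `gca_f`).
#' @export
rating_trajectories <- function(longitudinal) {
  d <- longitudinal
  scales <- character(0)
  if (all(c("mta_l", "mta_r") %in% names(d))) {
    d$mta <- composite_mta(d$mta_l, d$mta_r)
    scales <- c(scales, "mta")
  }
  scales <- c(scales, intersect(c("pa", "gca_f"), names(d)))
  if (!length(scales)) stop("no rating columns found")
  agg <- stats::aggregate(d[scales], by = d[c("group", "time")],
                          FUN = mean, na.rm = TRUE)
  n <- stats::aggregate(list(n = d[[scales[1]]]), by = d[c("group", "time")],
                        FUN = function(x) sum(!is.na(x)))
  out <- merge(n, agg, by = c("group", "time"))
  out[order(out$group, out$time), ]
}
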