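#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-stream seeds per generator stage, kept below 2^31
sub_seed <- function(seed, stage) {
  offset <- c(cross_section = 11L, memory = 23L, longitudinal = 37L,
              ratings = 53L)[[stage]]
  (as.integer(seed) %% 2000000000L) + offset
}

#' Group-level demographic and clinical defaults
#'
#' Per-group means and dispersions for the synthetic cohort: age, education,
#' percent female, baseline MMSE and CDR, and the binary biomarker
#' prevalences (APOE e4 carriage, abnormal CSF amyloid-beta and total tau).
#' Values follow the baseline characteristics of the ADNI-1-like sample the
#' generator emulates.
#'
#' @return Data frame with one row per group.
#' @export
default_demographics <- function() {
  data.frame(
    group      = c("hc", subtype_levels()),
    age_mean   = c(75.9, 77.7, 72.3, 78.2, 69.2),
    age_sd     = c(5.0, 6.4, 7.1, 8.2, 6.9),
    edu_mean   = c(16.0, 15.0, 14.6, 14.9, 13.6),
    edu_sd     = c(2.9, 3.4, 2.2, 3.1, 3.7),
    pct_female = c(48.7, 37.0, 57.6, 48.6, 73.3),
    mmse_mean  = c(29.1, 22.9, 23.2, 23.7, 24.2),
    mmse_sd    = c(1.0, 2.1, 1.9, 2.2, 1.5),
    cdr_mean   = c(0, 0.8, 0.7, 0.7, 0.7),
    cdr_sd     = c(0, 0.2, 0.2, 0.3, 0.2),
    apoe4_pct  = c(26.5, 69.0, 69.7, 51.4, 73.3),
    csf_ab_pct = c(40.0, 96.0, 90.0, 85.0, 91.7),
    csf_tau_pct = c(21.2, 56.0, 75.0, 75.0, 66.7)
  )
}

#' AVLT raw-score generation constants
#'
#' Healthy-control means/SDs for the raw AVLT items (words out of 15), and
#' per-group downward shifts in control-SD units per memory component. The
#' shifts are free calibration constants chosen so that the expected
#' impairment frequencies qualitatively reproduce the published ordering
#' (typical worst at learning; hippocampal-sparing most interference-prone;
#' the no-atrophy group retaining the best recognition).
#'
#' @return List with `hc_means`, `hc_sds` (named per item) and `shifts`
#'   (matrix group x component, SD units; positive = worse).
#' @export
default_avlt_structure <- function() {
  items <- c("t1", "t2", "t3", "t4", "t5", "b", "imm", "del", "rec")
  hc_means <- c(t1 = 5.5, t2 = 8, t3 = 9.5, t4 = 10.5, t5 = 11,
                b = 5, imm = 9.5, del = 9, rec = 13)
  hc_sds <- c(t1 = 2, t2 = 2, t3 = 2, t4 = 2, t5 = 2,
              b = 2, imm = 2.5, del = 3, rec = 2)
  shifts <- rbind(
    hc                  = c(learning = 0,    interference = 0,    immediate = 0,
                            delayed = 0,     recognition = 0),
    typical             = c(2.7, 1.2, 2.3, 2.6, 2.2),
    limbic_predominant  = c(2.2, 1.1, 1.9, 2.7, 2.3),
    hippocampal_sparing = c(2.4, 1.3, 1.9, 2.4, 1.9),
    no_atrophy          = c(2.1, 1.0, 1.9, 2.2, 1.6)
  )
  colnames(shifts) <- c("learning", "interference", "immediate",
                        "delayed", "recognition")
  list(items = items, hc_means = hc_means, hc_sds = hc_sds, shifts = shifts)
}

#' Non-memory cognitive battery generation constants
#'
#' The battery is generated on a standardized (z) scale, oriented so that
#' higher is always better, with an exchangeable correlation of 0.3 among
#' tests and per-group mean shifts (free calibration constants). Controls and
#' typical AD separate clearly; the atypical subtypes overlap heavily,
#' mirroring the discriminability structure the random-forest screening is
#' meant to expose.
#'
#' @return List with `tests`, `rho` and `shifts` (group x test, z units,
#'   negative = worse).
#' @export
default_battery_structure <- function() {
  tests <- c("tmtb", "ds", "bnt", "vegetables", "digit_span", "clock")
  shifts <- rbind(
    hc                  = rep(0, 6),
    typical             = c(-1.6, -1.5, -1.3, -1.6, -1.2, -1.4),
    limbic_predominant  = c(-1.1, -1.0, -0.9, -1.1, -0.8, -0.9),
    hippocampal_sparing = c(-1.3, -1.2, -1.0, -1.2, -0.9, -1.1),
    no_atrophy          = c(-1.0, -1.0, -0.8, -1.0, -0.8, -0.9)
  )
  colnames(shifts) <- tests
  list(tests = tests, rho = 0.3, shifts = shifts)
}

#' Within-group memory-outcome structure
#'
#' Standardized coefficients linking delayed free recall to the non-memory
#' battery and learning inside each group, used to couple the generated
#' delayed-recall score to its predictors on the latent (z) scale. Defaults
#' are the published group-specific standardized betas that survived the
#' stability screening: controls and the limbic-predominant/typical subtypes
#' depend on learning alone; hippocampal-sparing on executive function and
#' semantic fluency; the no-atrophy group on learning plus a negative
#' attention/processing-speed term.
#'
#' @return Matrix group x predictor of standardized coefficients.
#' @export
default_memory_structure <- function() {
  preds <- c("tmtb", "ds", "bnt", "vegetables", "learning")
  m <- rbind(
    hc                  = c(0, 0, 0, 0, 0.744),
    typical             = c(0, 0, 0, 0, 0.560),
    limbic_predominant  = c(0, 0, 0, 0, 0.483),
    hippocampal_sparing = c(0.548, 0, 0, 0.455, 0),
    no_atrophy          = c(0, -0.336, 0, 0, 0.725)
  )
  colnames(m) <- preds
  m
}

#' Longitudinal trajectory defaults
#'
#' Per-group fixed-effect intercepts and linear slopes for CDR and MMSE over
#' the 0/1/2-year visit schedule, plus variance components. Slopes are the
#' published per-year fixed-effect estimates: CDR 0.03 (controls), 0.29
#' (typical), 0.28 (limbic-predominant), 0.16 (hippocampal-sparing), 0.14
#' (no atrophy); MMSE -0.01, -2.69, -3.08, -1.48 and -1.60 (the no-atrophy
#' MMSE slope is a calibration constant inside the published AD range, as no
#' estimate is printed for that group). Intercepts equal the baseline group
#' means. Random-intercept and residual SDs (CDR 0.2/0.15; MMSE 1.5/1.0) are
#' free calibration constants: the source analysis reports fixed effects only.
#'
#' @return Nested list with elements `cdr` and `mmse`, each containing
#'   `intercept`, `slope`, `quad` (named per group), `sigma_b`, `sigma`.
#' @export
default_trajectory <- function() {
  groups <- c("hc", subtype_levels())
  nm <- function(x) stats::setNames(x, groups)
  list(
    cdr = list(
      intercept = nm(c(0, 0.8, 0.7, 0.7, 0.7)),
      slope     = nm(c(0.03, 0.29, 0.28, 0.16, 0.14)),
      quad      = nm(rep(0, 5)),
      sigma_b   = 0.2,
      sigma     = 0.15
    ),
    mmse = list(
      intercept = nm(c(29.1, 22.9, 23.2, 23.7, 24.2)),
      slope     = nm(c(-0.01, -2.69, -3.08, -1.48, -1.60)),
      quad      = nm(rep(0, 5)),
      sigma_b   = 1.5,
      sigma     = 1.0
    )
  )
}

#' Specification for a synthetic cohort
#'
#' Bundles every generator parameter with its seed. Defaults reproduce the
#' structure of the emulated study sample: 230 controls and 198 AD patients
#' split 100/33/35/30 across the four atrophy subtypes, three annual visits,
#' demographic and trajectory parameters as in [default_demographics()] and
#' [default_trajectory()].
#'
#' @param group_sizes Named integer vector over groups `hc` plus
#'   [subtype_levels()].
#' @param demographics See [default_demographics()].
#' @param avlt See [default_avlt_structure()].
#' @param battery See [default_battery_structure()].
#' @param memory_structure See [default_memory_structure()]; set `NULL` to
#'   generate delayed recall independently of the battery.
#' @param trajectory See [default_trajectory()].
#' @param visit_times Strictly increasing visit times in years.
#' @param retention Probability that each follow-up visit is observed
#'   (baseline is always observed); 1 keeps every visit.
#' @param rating_step_prob Named per-scale probabilities that an ordinal
#'   rating increases by one step at each follow-up visit.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(hc = 230, typical = 100,
                                        limbic_predominant = 33,
                                        hippocampal_sparing = 35,
                                        no_atrophy = 30),
                        demographics = default_demographics(),
                        avlt = default_avlt_structure(),
                        battery = default_battery_structure(),
                        memory_structure = default_memory_structure(),
                        trajectory = default_trajectory(),
                        visit_times = c(0, 1, 2),
                        retention = 1,
                        rating_step_prob = c(mta = 0.15, pa = 0.08, gca_f = 0.08),
                        seed = 1L) {
  stopifnot(
    all(group_sizes > 0),
    all(names(group_sizes) %in% c("hc", subtype_levels())),
    !is.unsorted(visit_times, strictly = TRUE),
    retention >= 0, retention <= 1,
    all(rating_step_prob >= 0), all(rating_step_prob <= 1),
    all(demographics$age_sd >= 0), all(demographics$mmse_sd >= 0)
  )
  structure(
    list(group_sizes = group_sizes, demographics = demographics,
         avlt = avlt, battery = battery,
         memory_structure = memory_structure, trajectory = trajectory,
         visit_times = visit_times, retention = retention,
         rating_step_prob = rating_step_prob, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Admissible composite-MTA grid (0, 0.5, ..., 4) for a label's MTA predicate
# given the subject's age-band threshold.
mta_grid_for <- function(abnormal, threshold) {
  grid <- seq(0, 4, by = 0.5)
  g <- if (abnormal) grid[grid >= threshold] else grid[grid < threshold]
  if (!length(g))
    stop("no admissible composite MTA value for threshold ", threshold)
  g
}

# Split a composite (mean) MTA score into integer left/right ratings.
split_composite <- function(comp) {
  l <- floor(comp)
  r <- ceiling(comp)
  swap <- stats::runif(length(comp)) < 0.5
  data.frame(mta_l = ifelse(swap, r, l), mta_r = ifelse(swap, l, r))
}

# Sample PA and GCA-F jointly given whether the label requires cortical
# abnormality (>=1 on at least one scale) or normality (both 0).
sample_cortex <- function(n, abnormal) {
  if (!abnormal) return(data.frame(pa = rep(0L, n), gca_f = rep(0L, n)))
  # uniform over the 15 (pa, gca_f) pairs in {0..3}^2 with max >= 1
  pairs <- expand.grid(pa = 0:3, gca_f = 0:3)
  pairs <- pairs[pairs$pa >= 1 | pairs$gca_f >= 1, ]
  pick <- pairs[sample.int(nrow(pairs), n, replace = TRUE), ]
  data.frame(pa = pick$pa, gca_f = pick$gca_f)
}

sample_ratings_for_label <- function(label, age, cutoffs = default_cutoffs()) {
  n <- length(age)
  thr <- mta_cutoff(age, cutoffs)
  mta_abn <- label %in% c("typical", "limbic_predominant")
  ctx_abn <- label %in% c("typical", "hippocampal_sparing")
  comp <- vapply(thr, function(t) {
    g <- mta_grid_for(mta_abn, t)
    g[sample.int(length(g), 1L)]
  }, numeric(1))
  cbind(split_composite(comp), sample_cortex(n, ctx_abn))
}

round_clamp <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# Draw n x p standardized predictors with correlation sigma
rmvn_std <- function(n, sigma) {
  p <- nrow(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% chol(sigma)
}

#' Generate the cross-sectional table of a synthetic cohort
#'
#' Draws one record per subject: demographics, baseline MMSE/CDR, binary
#' biomarker flags, visual ratings, raw AVLT items and the standardized
#' non-memory battery. For AD subjects the ratings are sampled uniformly from
#' the admissible region of the assigned subtype's predicate given the
#' subject's age band, so [classify_subtype()] recovers the generating label
#' by construction. Controls receive normal-range ratings and no label.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame, one row per subject, with a `group` column holding the
#'   generating label (`hc` for controls).
#' @export
generate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(sub_seed(spec$seed, "cross_section"), {
    demo <- spec$demographics
    rows <- lapply(names(spec$group_sizes), function(g) {
      n <- spec$group_sizes[[g]]
      d <- demo[demo$group == g, ]
      if (nrow(d) != 1) stop("no demographic row for group ", g)
      age <- round_clamp(stats::rnorm(n, d$age_mean, d$age_sd), 46, 93)
      out <- data.frame(
        group = g,
        dx = if (g == "hc") "CN" else "AD",
        age = age,
        sex = ifelse(stats::runif(n) < d$pct_female / 100, "F", "M"),
        education = round_clamp(stats::rnorm(n, d$edu_mean, d$edu_sd), 6, 20),
        mmse = round_clamp(stats::rnorm(n, d$mmse_mean, d$mmse_sd), 0, 30),
        cdr = pmax(stats::rnorm(n, d$cdr_mean, max(d$cdr_sd, 1e-12)), 0),
        apoe4 = as.integer(stats::runif(n) < d$apoe4_pct / 100),
        csf_ab_abn = as.integer(stats::runif(n) < d$csf_ab_pct / 100),
        csf_tau_abn = as.integer(stats::runif(n) < d$csf_tau_pct / 100)
      )
      # ratings
      if (g == "hc") {
        thr <- mta_cutoff(out$age)
        comp <- vapply(thr, function(t) {
          gr <- mta_grid_for(FALSE, t)
          gr[sample.int(length(gr), 1L)]
        }, numeric(1))
        rat <- cbind(split_composite(comp),
                     data.frame(pa = ifelse(stats::runif(n) < 0.1, 1L, 0L),
                                gca_f = ifelse(stats::runif(n) < 0.1, 1L, 0L)))
      } else {
        rat <- sample_ratings_for_label(g, out$age)
      }
      out <- cbind(out, rat)
      # AVLT raw items: component shift applied to each contributing item
      av <- spec$avlt
      sh <- av$shifts[g, ]
      # learning is the sum of 5 trials: a per-trial shift of s SD moves the
      # sum by s*sqrt(5) of its own SD, so scale down to keep the component
      # shift equal to the configured value
      item_shift <- c(rep(sh[["learning"]] / sqrt(5), 5), sh[["interference"]],
                      sh[["immediate"]], sh[["delayed"]], sh[["recognition"]])
      avlt <- vapply(seq_along(av$items), function(k) {
        it <- av$items[k]
        round_clamp(
          stats::rnorm(n, av$hc_means[[it]] - item_shift[k] * av$hc_sds[[it]],
                       av$hc_sds[[it]]),
          0, 15)
      }, numeric(n))
      if (n == 1) avlt <- matrix(avlt, nrow = 1)
      colnames(avlt) <- paste0("avlt_", av$items)
      out <- cbind(out, as.data.frame(avlt))
      # non-memory battery (z scale, higher = better)
      bt <- spec$battery
      p <- length(bt$tests)
      sigma <- matrix(bt$rho, p, p); diag(sigma) <- 1
      z <- rmvn_std(n, sigma)
      z <- sweep(z, 2, bt$shifts[g, ], `+`)
      colnames(z) <- bt$tests
      out <- cbind(out, as.data.frame(z))

      # couple delayed recall to its within-group predictors (Table-4-style
      # standardized coefficient structure on the latent z scale)
      ms <- spec$memory_structure
      if (!is.null(ms) && g %in% rownames(ms) && n >= 2) {
        b <- ms[g, ]
        zb <- sweep(z, 2, bt$shifts[g, ], `-`)  # unit-variance within group
        learning <- rowSums(out[paste0("avlt_t", 1:5)])
        sl <- stats::sd(learning)
        zl <- if (is.na(sl) || sl == 0) rep(0, n)
              else (learning - mean(learning)) / sl
        eta <- drop(zb[, setdiff(colnames(ms), "learning"), drop = FALSE] %*%
                      b[setdiff(colnames(ms), "learning")]) +
          b[["learning"]] * zl
        resid_var <- max(1 - stats::var(eta), 0.05)
        del_z <- eta + stats::rnorm(n, 0, sqrt(resid_var))
        mu_del <- av$hc_means[["del"]] - sh[["delayed"]] * av$hc_sds[["del"]]
        out$avlt_del <- round_clamp(mu_del + av$hc_sds[["del"]] * del_z, 0, 15)
      }
      out
    })
    res <- do.call(rbind, rows)
    res$id <- sprintf("S%04d", seq_len(nrow(res)))
    res[c("id", setdiff(names(res), "id"))]
  })
}

#' Generate a regression test bed with known standardized coefficients
#'
#' Draws `n` standardized predictor vectors from a zero-mean, unit-variance
#' joint distribution with correlation `sigma_xx`, and sets the outcome to
#' `X beta + e` with residual variance `1 - t(beta) sigma_xx beta`, so the
#' population standardized regression coefficients equal `beta` and the
#' outcome has unit variance. Optionally rescales outcome and predictors to
#' test-score units.
#'
#' @param n Sample size.
#' @param beta Named numeric vector of true standardized coefficients.
#' @param sigma_xx Predictor correlation matrix (default identity).
#' @param mean_y,sd_y Affine map applied to the standardized outcome.
#' @param seed Integer seed.
#' @return Data frame with column `y` and one column per predictor.
#' @export
generate_memory_battery <- function(n, beta, sigma_xx = diag(length(beta)),
                                    mean_y = 0, sd_y = 1, seed = 1L) {
  nmx <- names(beta)
  b <- as.numeric(beta)
  p <- length(b)
  stopifnot(n > p, nrow(sigma_xx) == p, ncol(sigma_xx) == p)
  expl <- drop(t(b) %*% sigma_xx %*% b)
  if (expl >= 1)
    stop("invalid structure: implied explained variance ", round(expl, 3),
         " >= 1")
  with_seed(seed, {
    x <- rmvn_std(n, sigma_xx)
    y <- drop(x %*% b) + stats::rnorm(n, sd = sqrt(1 - expl))
    if (is.null(nmx)) nmx <- paste0("x", seq_len(p))
    out <- data.frame(y = mean_y + sd_y * y)
    out[nmx] <- as.data.frame(x)
    out
  })
}

#' Generate longitudinal CDR and MMSE visit records
#'
#' Simulates `y_ij = alpha_g + b_i + beta_g t_ij + gamma_g t_ij^2 + e_ij`
#' per outcome, with subject random intercepts `b_i ~ N(0, sigma_b^2)` and
#' residuals `e_ij ~ N(0, sigma^2)`, on the visit schedule of the spec.
#' Follow-up visits are independently retained with probability
#' `spec$retention` (baseline always kept), to mimic attrition.
#'
#' @param spec A [cohort_spec()].
#' @param subjects Optional data frame with columns `id` and `group`; by
#'   default a subject list is built from `spec$group_sizes`.
#' @return Long-format data frame `id`, `group`, `time`, `cdr`, `mmse`.
#' @export
generate_longitudinal <- function(spec, subjects = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(subjects)) {
    subjects <- data.frame(
      id = sprintf("S%04d", seq_len(sum(spec$group_sizes))),
      group = rep(names(spec$group_sizes), spec$group_sizes)
    )
  }
  with_seed(sub_seed(spec$seed, "longitudinal"), {
    n <- nrow(subjects)
    tt <- spec$visit_times
    long <- data.frame(
      id = rep(subjects$id, each = length(tt)),
      group = rep(subjects$group, each = length(tt)),
      time = rep(tt, times = n)
    )
    for (oc in c("cdr", "mmse")) {
      tr <- spec$trajectory[[oc]]
      b_i <- stats::rnorm(n, 0, tr$sigma_b)
      g <- long$group
      long[[oc]] <- tr$intercept[g] + rep(b_i, each = length(tt)) +
        tr$slope[g] * long$time + tr$quad[g] * long$time^2 +
        stats::rnorm(nrow(long), 0, tr$sigma)
    }
    if (spec$retention < 1) {
      keep <- long$time == min(tt) | stats::runif(nrow(long)) < spec$retention
      long <- long[keep, ]
    }
    rownames(long) <- NULL
    long
  })
}

#' Generate longitudinal ordinal rating trajectories
#'
#' Starting from each subject's baseline ratings, every scale independently
#' increases by one step at each follow-up visit with its configured
#' transition probability, capped at the scale maximum (4 for MTA sides, 3
#' for PA and GCA-F). Ratings are monotone non-decreasing over visits.
#'
#' @param spec A [cohort_spec()].
#' @param cross_section Output of [generate_cross_section()] (baseline
#'   ratings).
#' @return Long-format data frame `id`, `group`, `time`, `mta_l`, `mta_r`,
#'   `pa`, `gca_f`.
#' @export
generate_rating_progression <- function(spec, cross_section) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("id", "mta_l", "mta_r", "pa", "gca_f") %in%
                  names(cross_section)))
  with_seed(sub_seed(spec$seed, "ratings"), {
    tt <- spec$visit_times
    n <- nrow(cross_section)
    p <- spec$rating_step_prob
    scales <- c(mta_l = "mta", mta_r = "mta", pa = "pa", gca_f = "gca_f")
    maxes <- c(mta_l = 4L, mta_r = 4L, pa = 3L, gca_f = 3L)
    cur <- cross_section[names(scales)]
    out <- vector("list", length(tt))
    for (k in seq_along(tt)) {
      if (k > 1) {
        for (sc in names(scales)) {
          step <- stats::runif(n) < p[[scales[[sc]]]]
          cur[[sc]] <- pmin(cur[[sc]] + as.integer(step), maxes[[sc]])
        }
      }
      out[[k]] <- data.frame(id = cross_section$id,
                             group = cross_section$group,
                             time = tt[k], cur)
    }
    res <- do.call(rbind, out)
    res <- res[order(res$id, res$time), ]
    rownames(res) <- NULL
    res
  })
}

#' Generate a full synthetic cohort
#'
#' Runs the cross-sectional, longitudinal and rating-progression generators
#' under one spec and merges the rating trajectories into the visit table.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cross_section`, `longitudinal` (visits with CDR, MMSE
#'   and ratings) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  cs <- generate_cross_section(spec)
  long <- generate_longitudinal(spec, subjects = cs[c("id", "group")])
  rat <- generate_rating_progression(spec, cs)
  long <- merge(long, rat, by = c("id", "group", "time"), all.x = TRUE)
  long <- long[order(long$id, long$time), ]
  rownames(long) <- NULL
  list(cross_section = cs, longitudinal = long, spec = spec)
}
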