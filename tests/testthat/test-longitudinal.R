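make_long <- function(seed, sizes = c(hc = 80, typical = 80,
                                      limbic_predominant = 80,
                                      hippocampal_sparing = 80,
                                      no_atrophy = 80), ...) {
  generate_longitudinal(cohort_spec(group_sizes = sizes, seed = seed, ...))
}

test_that("noise-free mixed-model recovery is exact", {
  long <- generate_longitudinal(small_spec(seed = 1,
                                           trajectory = noise_free_trajectory()))
  fit <- suppressWarnings(fit_lmm(long, "cdr", ref_group = "hc"))
  sl <- group_slopes(fit)
  truth <- noise_free_trajectory()$cdr$slope
  expect_lt(max(abs(sl$slope - truth[sl$group])), 1e-8)
})

test_that("slopes resolve as reference plus interaction offsets", {
  tr <- noise_free_trajectory(c(hc = 0.03, typical = 0.29,
                                limbic_predominant = 0.29,
                                hippocampal_sparing = 0.29, no_atrophy = 0.29))
  long <- generate_longitudinal(small_spec(seed = 2, trajectory = tr))
  fit <- suppressWarnings(fit_lmm(long, "cdr", ref_group = "hc"))
  sl <- group_slopes(fit)
  expect_equal(sl$slope[sl$group == "typical"], 0.29, tolerance = 1e-8)
  # interaction of zero: group slope equals the reference slope
  tr0 <- noise_free_trajectory(setNames(rep(0.1, 5),
                                        c("hc", subtype_levels())))
  long0 <- generate_longitudinal(small_spec(seed = 3, trajectory = tr0))
  sl0 <- group_slopes(suppressWarnings(fit_lmm(long0, "cdr", ref_group = "hc")))
  expect_true(all(abs(sl0$slope - 0.1) < 1e-8))
})

test_that("slopes are shift-invariant and scale-equivariant", {
  long <- make_long(seed = 4)
  f1 <- fit_lmm(long, "cdr")
  long$cdr_shift <- long$cdr + 100
  long$cdr_scale <- long$cdr * 3
  f2 <- fit_lmm(long, "cdr_shift")
  f3 <- fit_lmm(long, "cdr_scale")
  expect_equal(group_slopes(f1)$slope, group_slopes(f2)$slope,
               tolerance = 1e-6)
  expect_equal(3 * group_slopes(f1)$slope, group_slopes(f3)$slope,
               tolerance = 1e-6)
})

test_that("MMSE slopes are negative in all AD groups on synthetic data", {
  long <- make_long(seed = 5)
  sl <- group_slopes(fit_lmm(long, "mmse"))
  ad <- sl$group != "hc"
  expect_true(all(sl$slope[ad] < 0))
})

test_that("subjects with a single visit are retained in the fit", {
  long <- make_long(seed = 6)
  solo <- long$id %in% unique(long$id)[1:20] & long$time > 0
  long2 <- long[!solo, ]
  fit <- fit_lmm(long2, "cdr")
  expect_true(fit$converged)
  expect_equal(length(unique(fit$data$id)), length(unique(long$id)))
})

test_that("slope contrasts behave: self-pair, unknown group, BH monotone", {
  long <- make_long(seed = 7)
  fit <- fit_lmm(long, "cdr")
  ct <- slope_contrasts(fit)
  expect_equal(nrow(ct), choose(5, 2))
  expect_true(all(ct$p_adj >= ct$p - 1e-12))
  # BH monotone: ordering by raw p is preserved in adjusted p
  o <- order(ct$p)
  expect_true(all(diff(ct$p_adj[o]) >= -1e-12))

  self <- slope_contrasts(fit, pairs = list(c("typical", "typical")))
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)
  expect_error(slope_contrasts(fit, pairs = list(c("typical", "nope"))),
               "unknown group")
})

test_that("slope contrasts reject at the nominal rate under the null", {
  set.seed(8)
  n_sim <- 100
  rej <- numeric(0)
  for (s in seq_len(n_sim)) {
    tr <- default_trajectory()
    tr$cdr$slope[] <- 0.1  # identical groups
    long <- generate_longitudinal(
      cohort_spec(group_sizes = c(hc = 30, typical = 30), trajectory = tr,
                  seed = 1000 + s))
    fit <- fit_lmm(long, "cdr")
    ct <- slope_contrasts(fit, pairs = list(c("hc", "typical")))
    rej <- c(rej, ct$p <= 0.05)
  }
  expect_lt(abs(mean(rej) - 0.05), 0.06)
})

test_that("a true slope difference of 0.15 is detected with high power", {
  set.seed(9)
  hits <- replicate(30, {
    tr <- default_trajectory()
    tr$cdr$slope <- c(hc = 0.1, typical = 0.25, limbic_predominant = 0.1,
                      hippocampal_sparing = 0.1, no_atrophy = 0.1)
    long <- generate_longitudinal(
      cohort_spec(group_sizes = c(hc = 100, typical = 100), trajectory = tr,
                  seed = sample.int(1e6, 1)))
    fit <- fit_lmm(long, "cdr")
    slope_contrasts(fit, pairs = list(c("hc", "typical")))$p <= 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("with vanishing random-intercept variance the fit matches pooled OLS", {
  tr <- default_trajectory()
  tr$cdr$sigma_b <- 1e-8
  long <- generate_longitudinal(small_spec(seed = 10, trajectory = tr))
  fit <- fit_lmm(long, "cdr", ref_group = "hc")
  long$group <- relevel(factor(long$group), ref = "hc")
  ols <- lm(cdr ~ group * time, data = long)
  expect_lt(max(abs(lme4::fixef(fit$model) - coef(ols))), 1e-4)
})

test_that("the quadratic test is calibrated and powered", {
  # null: generated linear, LRT p should not be extreme systematically
  long <- make_long(seed = 11)
  res <- test_quadratic(long, "cdr")
  expect_equal(res$df, 5)  # time^2 plus 4 group interactions
  expect_gt(res$p, 0.001)

  # injected curvature is detected
  tr <- default_trajectory()
  tr$cdr$quad[] <- 0.3
  longq <- generate_longitudinal(small_spec(seed = 12, trajectory = tr))
  resq <- test_quadratic(longq, "cdr")
  expect_lt(resq$p, 1e-6)

  # two time points: unidentifiable
  long2 <- long[long$time < 2, ]
  expect_error(test_quadratic(long2, "cdr"), "3 distinct time points")
})

test_that("rating trajectories average MTA sides and track the step process", {
  spec <- small_spec(seed = 13,
                     rating_step_prob = c(mta = 0, pa = 0, gca_f = 0))
  cs <- generate_cross_section(spec)
  rat <- generate_rating_progression(spec, cs)
  tr <- rating_trajectories(rat)
  for (g in unique(tr$group)) {
    m <- tr$mta[tr$group == g]
    expect_true(all(abs(m - m[1]) < 1e-12))  # flat when nothing progresses
  }

  spec2 <- cohort_spec(group_sizes = c(hc = 4000), visit_times = c(0, 1, 2),
                       rating_step_prob = c(mta = 0.5, pa = 0.5, gca_f = 0.5),
                       seed = 14)
  cs2 <- generate_cross_section(spec2)
  cs2$pa <- 0L
  rat2 <- generate_rating_progression(spec2, cs2)
  tr2 <- rating_trajectories(rat2)
  inc <- diff(tr2$pa[order(tr2$time)])
  expect_lt(max(abs(inc - 0.5)), 0.05)

  # baseline-only input yields a baseline-only table
  tr0 <- rating_trajectories(rat[rat$time == 0, ])
  expect_equal(unique(tr0$time), 0)
})
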