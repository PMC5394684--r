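test_that("backward elimination keeps an exact linear signal in full", {
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5))  # no noise
  fit <- suppressWarnings(backward_select(y, X))  # perfect-fit warning
  expect_setequal(fit$retained, c("a", "b", "c"))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("backward elimination recovers a single true coefficient", {
  d <- generate_memory_battery(1e4, c(learning = 0.744, n1 = 0, n2 = 0,
                                      n3 = 0, n4 = 0), seed = 5)
  fit <- backward_select(d$y, d[, -1])
  expect_true("learning" %in% fit$retained)
  expect_lt(abs(fit$beta_std[["learning"]] - 0.744), 0.02)
})

test_that("pure-noise predictors can leave an empty model without error", {
  d <- generate_memory_battery(500, c(a = 0, b = 0, c = 0), seed = 6)
  fit <- backward_select(d$y, d[, -1], alpha = 0.10)
  expect_true(length(fit$retained) <= 3)
  if (!length(fit$retained)) {
    expect_equal(fit$r2, 0)
    expect_true(is.na(fit$fstat$F))
  }
  # per-step retention under the null happens at roughly the alpha order
  set.seed(61)
  kept <- replicate(200, {
    dd <- data.frame(y = rnorm(60), a = rnorm(60), b = rnorm(60))
    length(backward_select(dd$y, dd[, -1], alpha = 0.10)$retained) > 0
  })
  expect_gt(mean(kept), 0.05)
  expect_lt(mean(kept), 0.40)
})

test_that("backward elimination rejects rank-deficient designs", {
  set.seed(7)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(backward_select(rnorm(50), X), "rank-deficient")
  expect_error(backward_select(rnorm(4), X[1:4, ]), "n > p")
})

test_that("a single predictor's dominance weight is its squared correlation", {
  set.seed(8)
  x <- rnorm(200)
  y <- 0.5 * x + rnorm(200)
  dom <- dominance_decompose(y, cbind(x = x))
  expect_equal(unname(dom$weights), cor(y, x)^2, tolerance = 1e-12)
  expect_equal(sum(dom$weights), dom$r2, tolerance = 1e-12)
})

test_that("under exact orthogonality each weight is the marginal r-squared", {
  set.seed(9)
  # orthogonalize against the intercept too, so centering is preserved
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, -1]
  colnames(Q) <- c("a", "b", "c")
  y <- drop(Q %*% c(3, -2, 1)) + rnorm(200)
  dom <- dominance_decompose(y, Q)
  marg <- apply(Q, 2, function(x) cor(y, x)^2)
  expect_equal(dom$weights, marg, tolerance = 1e-8)
})

test_that("dominance weights are non-negative and sum to the full-model R2", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 80
    X <- matrix(rnorm(n * 4), n, 4)
    X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8  # correlated pair
    y <- drop(X %*% rnorm(4)) + rnorm(n)
    dom <- dominance_decompose(y, X)
    expect_true(all(dom$weights >= -1e-12))
    expect_lt(abs(sum(dom$weights) - dom$r2), 1e-10)
  }
})

test_that("all-subsets weights equal the Shapley-ordering oracle", {
  for (p in 3:4) {
    set.seed(200 + p)
    n <- 60
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + 0.5 * X[, p]
    y <- drop(X %*% seq_len(p)) + rnorm(n, sd = 2)
    dom <- dominance_decompose(y, X)
    oracle <- shapley_dominance_oracle(y, X)
    expect_equal(unname(dom$weights), oracle, tolerance = 1e-10)
  }
})

test_that("p is capped for all-subsets enumeration", {
  X <- matrix(rnorm(30 * 21), 30, 21)
  expect_error(dominance_decompose(rnorm(30), X), "pre-screen")
})

test_that("bootstrap stability separates strong from null predictors", {
  d <- generate_memory_battery(500, c(strong = 0.7, null = 0), seed = 10)
  stab <- bootstrap_stability(d$y, d[, -1], B = 200, seed = 11)
  s <- stab$summary
  expect_true(s$stable[s$predictor == "strong"])
  expect_false(s$stable[s$predictor == "null"])
  expect_true(all(s$lower <= s$upper))

  # B = 1: interval collapses to the single replicate, no crash
  st1 <- bootstrap_stability(d$y, d[, -1], B = 1, seed = 12)
  expect_equal(st1$summary$lower, st1$summary$upper)

  expect_error(bootstrap_stability(d$y[1:5], d[1:5, -1], B = 10), "n >= 10")
})

test_that("bootstrap resampling is seeded and reproducible", {
  d <- generate_memory_battery(200, c(a = 0.5, b = 0.2), seed = 13)
  s1 <- bootstrap_stability(d$y, d[, -1], B = 50, seed = 14)
  s2 <- bootstrap_stability(d$y, d[, -1], B = 50, seed = 14)
  expect_identical(s1$summary, s2$summary)
})

test_that("reconcile reports the retained-and-stable intersection", {
  d <- generate_memory_battery(400, c(strong = 0.7, weak = 0.10, null = 0),
                               seed = 15)
  fit <- backward_select(d$y, d[, -1])
  stab <- bootstrap_stability(d$y, d[, -1], B = 200, seed = 16)
  rec <- reconcile(fit, stab)
  expect_true(all(rec$reported$predictor %in% fit$retained))
  expect_true(all(rec$reported$predictor %in%
                    stab$summary$predictor[stab$summary$stable]))
  expect_setequal(c(rec$reported$predictor, rec$rejected$predictor),
                  fit$retained)

  # empty retained set reconciles to an empty report
  fit0 <- fit; fit0$retained <- character(0); fit0$beta_std <- numeric(0)
  rec0 <- reconcile(fit0, stab)
  expect_equal(nrow(rec0$reported), 0)
})

test_that("standardized-beta recovery holds at the study's design point", {
  # two-predictor structure with the published no-atrophy coefficients
  d <- generate_memory_battery(2000, c(learning = 0.725, ds = -0.336),
                               seed = 17)
  fit <- backward_select(d$y, d[, -1])
  expect_setequal(fit$retained, c("learning", "ds"))
  expect_lt(abs(fit$beta_std[["learning"]] - 0.725), 0.05)
  expect_lt(abs(fit$beta_std[["ds"]] + 0.336), 0.05)
})
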