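# Small cohorts and oracle implementations shared across tests.

small_spec <- function(seed = 1L, n = c(hc = 60, typical = 40,
                                        limbic_predominant = 25,
                                        hippocampal_sparing = 25,
                                        no_atrophy = 25), ...) {
  cohort_spec(group_sizes = n, seed = seed, ...)
}

# noise-free trajectory spec: deterministic lines per group
noise_free_trajectory <- function(cdr_slopes = c(hc = 0.03, typical = 0.29,
                                                 limbic_predominant = 0.28,
                                                 hippocampal_sparing = 0.16,
                                                 no_atrophy = 0.14)) {
  tr <- default_trajectory()
  tr$cdr$slope <- cdr_slopes
  tr$cdr$sigma_b <- 0
  tr$cdr$sigma <- 0
  tr$mmse$sigma_b <- 0
  tr$mmse$sigma <- 0
  tr
}

# Shapley-ordering oracle for general dominance: average, over all p!
# predictor orderings, of the sequential R^2 increment attributed to each
# predictor. Independent of the all-subsets path in the package.
shapley_dominance_oracle <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))))
  }
  orderings <- perms(seq_len(p))
  acc <- numeric(p)
  for (ord in orderings) {
    prev <- 0
    used <- integer(0)
    for (j in ord) {
      used <- c(used, j)
      r2 <- r2_of(used)
      acc[j] <- acc[j] + (r2 - prev)
      prev <- r2
    }
  }
  acc / length(orderings)
}

# Step-up BH oracle, written directly from the procedure's arithmetic.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Weighted-kappa oracle from an explicit confusion-table double loop.
kappa_oracle <- function(tab, scheme = "linear") {
  k <- nrow(tab)
  n <- sum(tab)
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- if (scheme == "linear") abs(i - j) else (i - j)^2
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    num <- num + w * tab[i, j]
    den <- den + w * e
  }
  1 - num / den
}
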