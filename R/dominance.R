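as_model_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

drop_incomplete <- function(y, X) {
  ok <- stats::complete.cases(y, X)
  list(y = y[ok], X = X[ok, , drop = FALSE], n_dropped = sum(!ok))
}

# R^2 of the OLS fit of y on the columns of X indexed by `cols`, computed
# from the joint cross-product matrix. Empty subset -> 0.
subset_r2 <- function(cxx, cxy, syy, cols) {
  if (!length(cols)) return(0)
  b <- solve(cxx[cols, cols, drop = FALSE], cxy[cols])
  drop(crossprod(cxy[cols], b)) / syy
}

#' Backward p-value elimination for multiple linear regression
#'
#' Starting from the full model, repeatedly removes the predictor with the
#' largest coefficient p-value while that p-value is at or above the removal
#' alpha, then refits. Reports the retained predictors with standardized
#' coefficients (outcome and predictors z-scored before the final fit), the
#' final model's F statistic, degrees of freedom, p-value, and R-squared /
#' adjusted R-squared. The model may end up empty if nothing survives.
#'
#' @param y Numeric outcome.
#' @param X Numeric matrix or data frame of predictors.
#' @param alpha Removal threshold: a predictor leaves the model when its
#'   p-value is >= `alpha` (default 0.10).
#' @return Object of class `backward_fit`: list with `retained`,
#'   `beta_std`, `fstat` (`F`, `df1`, `df2`, `p`), `r2`, `adj_r2`,
#'   `removed` (in removal order), `n`.
#' @export
backward_select <- function(y, X, alpha = 0.10) {
  stopifnot(alpha > 0, alpha < 1)
  X <- as_model_matrix(X)
  cc <- drop_incomplete(y, X)
  y <- cc$y; X <- cc$X
  n <- length(y)
  if (n <= ncol(X) + 1) stop("need n > p + 1 complete cases")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("rank-deficient design; check collinear columns: ",
         paste(colnames(X), collapse = ", "))
  }

  active <- colnames(X)
  removed <- character(0)
  repeat {
    if (!length(active)) break
    fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, active, drop = FALSE]))
    pv <- summary(fit)$coefficients[-1, 4]
    worst <- which.max(pv)
    if (pv[worst] >= alpha) {
      removed <- c(removed, active[worst])
      active <- active[-worst]
    } else break
  }

  if (length(active)) {
    zd <- data.frame(y = scale(y)[, 1],
                     scale(X[, active, drop = FALSE]))
    names(zd) <- c("y", active)
    fit <- stats::lm(y ~ ., data = zd)
    sm <- summary(fit)
    beta_std <- stats::coef(fit)[-1]
    fstat <- list(F = unname(sm$fstatistic[1]),
                  df1 = unname(sm$fstatistic[2]),
                  df2 = unname(sm$fstatistic[3]),
                  p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                sm$fstatistic[3], lower.tail = FALSE))
    r2 <- sm$r.squared
    adj_r2 <- sm$adj.r.squared
  } else {
    beta_std <- numeric(0)
    fstat <- list(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
    r2 <- 0
    adj_r2 <- 0
  }

  structure(list(retained = active, beta_std = beta_std, fstat = fstat,
                 r2 = r2, adj_r2 = adj_r2, removed = removed, n = n,
                 alpha = alpha),
            class = "backward_fit")
}

#' @export
print.backward_fit <- function(x, ...) {
  cat("Backward-eliminated linear model (removal alpha =", x$alpha, ")\n")
  if (length(x$retained)) {
    cat("Retained:", paste(sprintf("%s (beta = %.3f)", x$retained,
                                   x$beta_std), collapse = ", "), "\n")
    cat(sprintf("F(%g, %g) = %.3f; p = %.3g; R2 = %.3f; adj R2 = %.3f\n",
                x$fstat$df1, x$fstat$df2, x$fstat$F, x$fstat$p, x$r2,
                x$adj_r2))
  } else cat("No predictor retained.\n")
  if (length(x$removed)) cat("Removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' General dominance decomposition of R-squared
#'
#' Decomposes the full-model R-squared into one non-negative weight per
#' predictor by all-subsets averaging: the weight of predictor j is the mean,
#' over subset sizes k = 0..p-1, of the average incremental R-squared from
#' adding j to each size-k subset that excludes j. The weights sum exactly to
#' the full-model R-squared (this is the Shapley value of the R-squared
#' game). All 2^p subset OLS fits are enumerated, so p is capped at 20.
#'
#' @param y Numeric outcome.
#' @param X Predictor matrix or data frame (p <= 20).
#' @return Object of class `dominance`: list with `weights` (named), `r2`,
#'   `n`, `subset_r2` (named by comma-separated subsets, for inspection).
#' @export
dominance_decompose <- function(y, X) {
  X <- as_model_matrix(X)
  p <- ncol(X)
  if (p > 20) stop("p = ", p, " too large for all-subsets enumeration; ",
                   "pre-screen predictors to 20 or fewer")
  cc <- drop_incomplete(y, X)
  y <- cc$y; X <- cc$X
  n <- length(y)
  if (n <= p + 1) stop("need n > p + 1 complete cases")

  yc <- y - mean(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  cxx <- crossprod(Xc)
  cxy <- drop(crossprod(Xc, yc))
  syy <- sum(yc^2)
  if (syy == 0) stop("outcome has zero variance")

  nsub <- 2^p
  r2 <- numeric(nsub)  # subset encoded by bitmask + 1
  for (m in seq_len(nsub) - 1L) {
    cols <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    r2[m + 1L] <- subset_r2(cxx, cxy, syy, cols)
  }

  weights <- numeric(p)
  for (j in seq_len(p)) {
    jbit <- bitwShiftL(1L, j - 1L)
    inc_by_size <- vector("list", p)
    for (m in seq_len(nsub) - 1L) {
      if (bitwAnd(m, jbit) > 0) next
      k <- sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
      inc <- r2[m + jbit + 1L] - r2[m + 1L]
      inc_by_size[[k + 1L]] <- c(inc_by_size[[k + 1L]], inc)
    }
    weights[j] <- mean(vapply(inc_by_size[seq_len(p)], mean, numeric(1)))
  }
  names(weights) <- colnames(X)

  structure(list(weights = weights, r2 = r2[nsub], n = n),
            class = "dominance")
}

#' @export
print.dominance <- function(x, ...) {
  cat("General dominance decomposition (n =", x$n, ")\n")
  cat(sprintf("Explained variance R2 = %.1f%%\n", 100 * x$r2))
  print(round(100 * x$weights, 1))
  invisible(x)
}

#' Bootstrap stability of dominance weights
#'
#' Resamples subjects (rows) with replacement B times, recomputes the general
#' dominance weights on each replicate, and summarizes each predictor's
#' weight by a percentile interval. A predictor is flagged *stable* when the
#' lower bound of its interval exceeds the stability floor (a minimum
#' variance fraction, default 0.01). Replicates on which the decomposition is
#' degenerate (for instance a resampled constant column) are skipped and
#' counted.
#'
#' @param y Numeric outcome.
#' @param X Predictor matrix or data frame.
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed for the resampling.
#' @param level Percentile-interval coverage (default 0.95).
#' @param floor Stability floor in variance-fraction units (default 0.01).
#' @return Object of class `dominance_boot`: data.frame `summary`
#'   (`predictor`, `weight`, `lower`, `upper`, `stable`) plus `B`,
#'   `n_skipped`, `seed`, `level`, `floor`, and the replicate matrix
#'   `replicates` (B x p, skipped rows NA).
#' @export
bootstrap_stability <- function(y, X, B = 1000, seed = 1L, level = 0.95,
                                floor = 0.01) {
  stopifnot(B >= 1, level > 0, level < 1)
  X <- as_model_matrix(X)
  cc <- drop_incomplete(y, X)
  y <- cc$y; X <- cc$X
  n <- length(y)
  if (n < 10) stop("need n >= 10 for bootstrap stability")
  point <- dominance_decompose(y, X)

  p <- ncol(X)
  reps <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(dominance_decompose(y[idx], X[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(res)) n_skipped <- n_skipped + 1L
      else reps[b, ] <- res$weights
    }
  })

  alpha <- (1 - level) / 2
  lower <- apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  summary <- data.frame(
    predictor = colnames(X),
    weight = unname(point$weights),
    lower = unname(lower),
    upper = unname(upper),
    stable = unname(lower > floor),
    row.names = NULL
  )
  structure(list(summary = summary, r2 = point$r2, B = B,
                 n_skipped = n_skipped, seed = seed, level = level,
                 floor = floor, replicates = reps),
            class = "dominance_boot")
}

#' @export
print.dominance_boot <- function(x, ...) {
  cat(sprintf("Bootstrap dominance stability (B = %d, %d skipped, %.0f%% PI, floor %.2g)\n",
              x$B, x$n_skipped, 100 * x$level, x$floor))
  print(transform(x$summary, weight = round(weight, 3),
                  lower = round(lower, 3), upper = round(upper, 3)))
  invisible(x)
}

#' Reconcile backward selection with dominance stability
#'
#' The reported predictor set is the intersection of the predictors retained
#' by backward elimination and those whose dominance weight is
#' bootstrap-stable; retained-but-unstable predictors are rejected with an
#' explicit reason, mirroring the asterisk convention of the source
#' analysis's regression table.
#'
#' @param fit A `backward_fit` from [backward_select()].
#' @param stab A `dominance_boot` from [bootstrap_stability()] on the same
#'   data.
#' @return List with `reported` (data.frame `predictor`, `beta_std`,
#'   `weight`) and `rejected` (data.frame `predictor`, `reason`).
#' @export
reconcile <- function(fit, stab) {
  stopifnot(inherits(fit, "backward_fit"), inherits(stab, "dominance_boot"))
  stable <- stab$summary$predictor[stab$summary$stable]
  keep <- intersect(fit$retained, stable)
  rejected <- setdiff(fit$retained, stable)
  list(
    reported = data.frame(
      predictor = keep,
      beta_std = unname(fit$beta_std[keep]),
      weight = stab$summary$weight[match(keep, stab$summary$predictor)],
      row.names = NULL
    ),
    rejected = if (length(rejected)) {
      data.frame(predictor = rejected,
                 reason = "retained by backward elimination but dominance weight unstable under bootstrap",
                 row.names = NULL)
    } else data.frame(predictor = character(0), reason = character(0))
  )
}

#' Per-group regression/dominance table for one memory outcome
#'
#' Convenience wrapper reproducing the layout of the source analysis: for
#' each group, backward-eliminate the non-memory predictors, decompose the
#' full-model R-squared by general dominance with bootstrap stability, and
#' reconcile the two.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Outcome column name.
#' @param predictors Predictor column names.
#' @param group Optional grouping column name; `NULL` fits one model.
#' @param alpha,B,seed,floor Passed to the component operations.
#' @return Named list (per group) of lists `fit`, `dominance`, `stability`,
#'   `reported`.
#' @export
dominance_table <- function(data, outcome, predictors, group = NULL,
                            alpha = 0.10, B = 1000, seed = 1L, floor = 0.01) {
  splits <- if (is.null(group)) list(all = data)
            else split(data, data[[group]])
  lapply(splits, function(d) {
    y <- d[[outcome]]
    X <- d[predictors]
    fit <- backward_select(y, X, alpha = alpha)
    dom <- dominance_decompose(y, X)
    stab <- bootstrap_stability(y, X, B = B, seed = seed, floor = floor)
    rec <- reconcile(fit, stab)
    list(fit = fit, dominance = dom, stability = stab, reported = rec)
  })
}
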