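#' Analytic chance-level classification error
#'
#' For G groups weighted equally, a chance classifier errs with probability
#' `1 - 1/G`; with five study groups this is 80 percent.
#'
#' @param n_groups Number of groups G >= 2.
#' @return Chance error in percent.
#' @examples
#' chance_error(5) # 80
#' @export
chance_error <- function(n_groups) {
  stopifnot(n_groups >= 2)
  100 * (1 - 1 / n_groups)
}

#' Random-forest group discriminability screening
#'
#' Fits a bagged decision-tree ensemble (500 trees by default, other
#' hyperparameters at package defaults: sqrt(p) candidate features per
#' split, unlimited depth) and reports the per-group out-of-bag
#' classification error next to the analytic chance error, the screening
#' used to ask whether any variable set separates the study groups better
#' than chance. Rows with missing features are dropped (complete-case).
#'
#' @param features Data frame or matrix of predictor columns.
#' @param labels Group labels (factor or character), one per row.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Object of class `rf_screen`: list with `per_group_error` (named,
#'   percent), `overall_error` (percent), `chance_error` (percent),
#'   `confusion`, `importance`, `n_trees`, `seed`, `n`.
#' @export
rf_group_error <- function(features, labels, n_trees = 500, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) < 2)) stop("every group needs n >= 2")
  features <- as.data.frame(features)
  ok <- stats::complete.cases(features) & !is.na(labels)
  features <- features[ok, , drop = FALSE]
  labels <- droplevels(labels[ok])
  fit <- with_seed(seed, randomForest::randomForest(
    x = features, y = labels, ntree = n_trees, importance = TRUE))
  conf <- fit$confusion
  per_group <- 100 * conf[, "class.error"]
  oob <- 100 * mean(fit$predicted != labels)
  structure(list(per_group_error = per_group,
                 overall_error = oob,
                 chance_error = chance_error(nlevels(labels)),
                 confusion = conf[, seq_len(nlevels(labels)), drop = FALSE],
                 importance = randomForest::importance(fit),
                 n_trees = n_trees, seed = seed, n = length(labels)),
            class = "rf_screen")
}

#' @export
print.rf_screen <- function(x, ...) {
  cat(sprintf("Random-forest screening (%d trees, n = %d)\n", x$n_trees, x$n))
  cat(sprintf("Error by chance = %.0f%%\n", x$chance_error))
  cat("Classification error (OOB):\n")
  print(round(x$per_group_error, 1))
  invisible(x)
}

#' Weighted Cohen's kappa for ordinal rating agreement
#'
#' Chance-corrected agreement between two raters on the same ordinal scale:
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed confusion
#' table, `E` the expected table from the marginal products, and the
#' disagreement weights are `w_ij = |i - j|` (linear, default) or
#' `(i - j)^2` (quadratic). Kappa is 1 under perfect agreement and about 0
#' when ratings are independent.
#'
#' @param ratings_a,ratings_b Equal-length integer vectors of ratings.
#' @param scheme `"linear"` or `"quadratic"` disagreement weighting.
#' @param categories Full ordered category set; defaults to the union of the
#'   observed values (supply explicitly when some scale levels are unused).
#' @return Object of class `weighted_kappa`: list with `kappa`, `scheme`,
#'   `confusion`, `n`.
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           scheme = c("linear", "quadratic"),
                           categories = NULL) {
  scheme <- match.arg(scheme)
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length")
  ok <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- ratings_a[ok]; b <- ratings_b[ok]
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  if (!all(c(a, b) %in% categories))
    stop("ratings outside the declared category set")
  a <- factor(a, levels = categories)
  b <- factor(b, levels = categories)
  O <- table(a, b)
  n <- sum(O)
  if (n == 0) stop("no complete rating pairs")
  E <- outer(rowSums(O), colSums(O)) / n
  idx <- seq_along(categories)
  w <- if (scheme == "linear") abs(outer(idx, idx, "-"))
       else outer(idx, idx, "-")^2
  denom <- sum(w * E)
  kappa <- if (denom == 0) 1 else 1 - sum(w * O) / denom
  structure(list(kappa = kappa, scheme = scheme, confusion = O, n = n),
            class = "weighted_kappa")
}

#' @export
print.weighted_kappa <- function(x, ...) {
  cat(sprintf("Weighted kappa (%s weights, n = %d): %.3f\n",
              x$scheme, x$n, x$kappa))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values for one family of tests (via
#' `stats::p.adjust(method = "BH")`), with validation that the inputs are
#' probabilities.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
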