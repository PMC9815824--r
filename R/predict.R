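#' Balanced (rank-stratified) cross-validation folds
#'
#' Ranks subjects on the outcome and deals consecutive rank blocks of size
#' `k` across folds, one subject per fold per block in seeded random order.
#' This keeps the outcome distribution comparable across folds while fold
#' sizes differ by at most one.
#'
#' @param y Numeric outcome, one value per subject.
#' @param k Number of folds (default 4).
#' @param seed Integer RNG seed.
#' @return Integer vector of fold indices (1..k) in subject order.
#' @examples
#' table(balanced_folds(rnorm(28), k = 4, seed = 1))
#' @export
balanced_folds <- function(y, k = 4L, seed = 1L) {
  stopifnot(is.numeric(y))
  assert_scalar_number(k, "k", lower = 2)
  k <- as.integer(k)
  n <- length(y)
  if (n < k) abort(sprintf("Need at least k = %d subjects, got %d.", k, n))

  with_seed(seed, .balanced_folds_raw(y, k))
}

# fold assignment using the current RNG state (no re-seeding)
.balanced_folds_raw <- function(y, k) {
  n <- length(y)
  ord <- order(y)
  folds <- integer(n)
  n_blocks <- ceiling(n / k)
  for (b in seq_len(n_blocks)) {
    idx <- ord[((b - 1L) * k + 1L):min(b * k, n)]
    folds[idx] <- sample.int(k)[seq_along(idx)]
  }
  folds
}

# Fast inner CV loop: per fold, simple linear regression fit on the
# training subjects, prediction for the held-out subjects; returns the
# Pearson correlation between pooled predictions and observed y.
.cv_r <- function(x, y, folds, k) {
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    xt <- x[!test]
    yt <- y[!test]
    mx <- mean(xt)
    vx <- sum((xt - mx)^2)
    if (vx == 0) abort("Zero-variance predictor in a training fold.")
    slope <- sum((xt - mx) * (yt - mean(yt))) / vx
    pred[test] <- mean(yt) + slope * (x[test] - mx)
  }
  if (sd(pred) == 0) return(0)
  cor(pred, y)
}

#' Cross-validated prediction correlation
#'
#' Builds a simple linear regression on three of four balanced folds,
#' predicts the held-out fold, repeats over folds, and correlates the
#' pooled predictions with the observed outcome, yielding
#' r(predicted, observed).
#'
#' @param x Predictor (one value per subject).
#' @param y Outcome (one value per subject).
#' @param k Number of folds.
#' @param seed Integer RNG seed (fold assignment).
#' @return A `prediction_result` with elements `r`, `k`, `n`, `seed`
#'   (`p_perm`/`n_perm` are `NA` until [permutation_p()] is used).
#' @examples
#' x <- rnorm(28); y <- 2 * x
#' cv_predict_r(x, y, seed = 1)$r
#' @export
cv_predict_r <- function(x, y, k = 4L, seed = 1L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  k <- as.integer(k)
  if (length(y) < 2 * k) {
    abort(sprintf("Need at least 2k = %d subjects.", 2 * k))
  }
  folds <- balanced_folds(y, k = k, seed = seed)
  r <- .cv_r(x, y, folds, k)
  new_prediction_result(r = r, p_perm = NA_real_, n_perm = NA_integer_,
                        k = k, n = length(y), seed = seed)
}

#' Permutation test for the cross-validated prediction correlation
#'
#' Recomputes the cross-validated r(predicted, observed) on `n_perm`
#' label-shuffled surrogates (outcome values permuted across subjects, with
#' folds re-balanced on each shuffled outcome) and reports the proportion
#' of surrogate correlations strictly greater than the observed one. The
#' default matches the published convention (`p = #{r_perm > r_obs} /
#' n_perm`, one-sided, minimum attainable p of 0); `add_one = TRUE` gives
#' the conservative `(1 + #)/(1 + n_perm)` variant, and
#' `alternative = "two.sided"` compares absolute values.
#'
#' @inheritParams cv_predict_r
#' @param n_perm Number of label shuffles (default 1000).
#' @param add_one Use the add-one permutation p.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `prediction_result` with `r`, `p_perm`, `n_perm`, `k`, `n`,
#'   `seed` and the vector of surrogate correlations in `r_perm`.
#' @export
permutation_p <- function(x, y, k = 4L, n_perm = 1000L, seed = 1L,
                          add_one = FALSE,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  assert_scalar_number(n_perm, "n_perm", lower = 1)
  n_perm <- as.integer(n_perm)
  k <- as.integer(k)
  stopifnot(length(x) == length(y))
  if (length(y) < 2 * k) abort(sprintf("Need at least 2k = %d subjects.", 2 * k))

  r_perm <- numeric(n_perm)
  r_obs <- NA_real_
  with_seed(seed, {
    r_obs <- .cv_r(x, y, .balanced_folds_raw(y, k), k)
    for (i in seq_len(n_perm)) {
      y_perm <- sample(y)
      r_perm[i] <- .cv_r(x, y_perm, .balanced_folds_raw(y_perm, k), k)
    }
  })

  exceed <- if (alternative == "greater") {
    sum(r_perm > r_obs)
  } else {
    sum(abs(r_perm) > abs(r_obs))
  }
  p <- if (add_one) (1 + exceed) / (1 + n_perm) else exceed / n_perm

  out <- new_prediction_result(r = r_obs, p_perm = p, n_perm = n_perm,
                               k = k, n = length(y), seed = seed)
  out$r_perm <- r_perm
  out
}

new_prediction_result <- function(r, p_perm, n_perm, k, n, seed) {
  structure(list(r = r, p_perm = p_perm, n_perm = n_perm, k = k, n = n,
                 seed = seed),
            class = "prediction_result")
}

#' @exportS3Method base::print
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result: r(predicted, observed) = %.3f, n = %d, %d-fold>\n",
              x$r, x$n, x$k))
  if (!is.na(x$p_perm)) {
    cat(sprintf("  permutation p = %.4g (%d shuffles)\n", x$p_perm, x$n_perm))
  }
  invisible(x)
}

#' @rdname cv_predict_r
#' @param x A `prediction_result` (for the `tidy`/`glance` methods).
#' @param ... Unused.
#' @export
tidy.prediction_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_perm = x$p_perm, n_perm = x$n_perm,
                 k = x$k, n = x$n)
}

#' @rdname cv_predict_r
#' @export
glance.prediction_result <- function(x, ...) tidy.prediction_result(x)

#' Steiger's test for dependent, non-overlapping correlations
#'
#' Compares two correlations measured on the same subjects that share no
#' variable (e.g. r(x1, y1) vs r(x2, y2)), using the Fisher-z difference
#' divided by its standard error. The covariance of the two correlations is
#' computed by the Pearson-Filon expression with the two compared
#' correlations replaced by their pooled mean.
#'
#' @param r1,r2 The two correlations to compare: `r1 = cor(v1, v2)`,
#'   `r2 = cor(v3, v4)`.
#' @param aux_corrs The four cross correlations as a named list or vector
#'   with entries `r13`, `r14`, `r23`, `r24` (variable order v1, v2, v3,
#'   v4); alternatively a full 4x4 correlation matrix.
#' @param n Number of subjects (`> 3`).
#' @return A `steiger_result`: one-row tibble `z`, `p.value`, `r1`, `r2`,
#'   `n`.
#' @examples
#' steiger_z(0.5, 0.1, c(r13 = 0.3, r14 = 0.2, r23 = 0.2, r24 = 0.3), n = 28)
#' @export
steiger_z <- function(r1, r2, aux_corrs, n) {
  assert_scalar_number(n, "n", lower = 4)
  if (is.matrix(aux_corrs)) {
    stopifnot(all(dim(aux_corrs) == c(4, 4)))
    R <- aux_corrs
    R[1, 2] <- R[2, 1] <- r1
    R[3, 4] <- R[4, 3] <- r2
  } else {
    a <- as.list(aux_corrs)
    need <- c("r13", "r14", "r23", "r24")
    if (!all(need %in% names(a))) {
      abort("`aux_corrs` must supply r13, r14, r23, r24.")
    }
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- r1
    R[3, 4] <- R[4, 3] <- r2
    R[1, 3] <- R[3, 1] <- a$r13
    R[1, 4] <- R[4, 1] <- a$r14
    R[2, 3] <- R[3, 2] <- a$r23
    R[2, 4] <- R[4, 2] <- a$r24
  }
  if (any(abs(R[upper.tri(R)]) >= 1)) {
    abort("All correlations must have absolute value < 1.")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("Supplied correlations form an inconsistent (non-PSD) matrix.")
  }

  r13 <- R[1, 3]; r14 <- R[1, 4]; r23 <- R[2, 3]; r24 <- R[2, 4]
  rbar <- (r1 + r2) / 2
  # Pearson-Filon covariance term with pooled rbar in place of r1, r2.
  psi <- 0.5 * rbar * rbar * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    (rbar * r13 * r14 + rbar * r23 * r24 +
     rbar * r13 * r23 + rbar * r14 * r24)
  cbar <- psi / (1 - rbar^2)^2
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * cbar))
  structure(
    tibble::tibble(z = z,
                   p.value = 2 * pnorm(abs(z), lower.tail = FALSE),
                   r1 = r1, r2 = r2, n = n),
    class = c("steiger_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Steiger's test from raw data columns
#'
#' Convenience wrapper computing all pairwise correlations from data and
#' calling [steiger_z()] on `cor(v1, v2)` vs `cor(v3, v4)`.
#'
#' @param data Data frame of numeric columns.
#' @param v1,v2,v3,v4 Column names; the compared correlations are
#'   `cor(v1, v2)` and `cor(v3, v4)`.
#' @return A `steiger_result` tibble.
#' @export
steiger_test <- function(data, v1, v2, v3, v4) {
  m <- as.matrix(data[, c(v1, v2, v3, v4)])
  R <- cor(m)
  steiger_z(R[1, 2], R[3, 4],
            c(r13 = R[1, 3], r14 = R[1, 4], r23 = R[2, 3], r24 = R[2, 4]),
            n = nrow(m))
}
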