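#' Deconvolve neural activity from a seed BOLD series
#'
#' Estimates the latent neural series whose convolution with the canonical
#' HRF best reproduces the observed seed series, by ridge-regularized
#' least-squares inversion of the (lower-triangular Toeplitz) convolution
#' operator at TR resolution. `ridge_lambda = "gcv"` selects the penalty by
#' generalized cross-validation on the seed itself.
#'
#' @param seed_ts Numeric seed BOLD series.
#' @param tr Repetition time in seconds.
#' @param ridge_lambda Non-negative penalty, or `"gcv"`.
#' @param hrf Optional `hrf_kernel`; defaults to `canonical_hrf(tr, 1)`.
#' @return Numeric neural series (attribute `lambda` records the penalty
#'   used).
#' @examples
#' neural <- c(rep(0, 5), 1, rep(0, 30))
#' bold <- convolve_hrf(neural, canonical_hrf(2, 1)$values)
#' est <- deconvolve_neural(bold, tr = 2, ridge_lambda = 1e-8)
#' @export
deconvolve_neural <- function(seed_ts, tr, ridge_lambda = "gcv",
                              hrf = NULL) {
  stopifnot(is.numeric(seed_ts), all(is.finite(seed_ts)))
  n <- length(seed_ts)
  kernel <- (hrf %||% canonical_hrf(tr, 1L))$values
  C <- conv_matrix(kernel, n)

  if (identical(ridge_lambda, "gcv")) {
    sv <- svd(C)
    uty <- crossprod(sv$u, seed_ts)
    d2 <- sv$d^2
    grid <- 10^seq(-8, 2, length.out = 40)
    gcv <- vapply(grid, function(lam) {
      shrink <- d2 / (d2 + lam)
      rss <- sum(((1 - shrink) * uty)^2)
      edf <- sum(shrink)
      n * rss / (n - edf)^2
    }, numeric(1))
    lam <- grid[which.min(gcv)]
    coefs <- sv$v %*% ((sv$d * uty) / (d2 + lam))
    out <- as.numeric(coefs)
  } else {
    if (!is.numeric(ridge_lambda) || length(ridge_lambda) != 1 ||
        ridge_lambda < 0) {
      abort("`ridge_lambda` must be a single non-negative number or 'gcv'.")
    }
    lam <- ridge_lambda
    A <- crossprod(C)
    diag(A) <- diag(A) + lam
    out <- as.numeric(solve(A, crossprod(C, seed_ts)))
  }
  attr(out, "lambda") <- lam
  out
}

# n x n causal convolution operator for a kernel sampled at TR resolution.
conv_matrix <- function(kernel, n) {
  k <- length(kernel)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    len <- min(k, n - j + 1)
    C[j:(j + len - 1), j] <- kernel[seq_len(len)]
  }
  C
}

#' Build a generalized PPI design matrix
#'
#' Forms, for each task cell (condition, or condition-by-memory-status),
#' the psychophysiological interaction regressor: estimated neural seed
#' activity multiplied by the cell's stimulus boxcar and convolved with the
#' canonical HRF. The HRF-convolved psychological boxcars and the seed
#' physiological series are included to absorb common task activation and
#' driving input; optional nuisance columns and a constant complete the
#' design.
#'
#' @param neural Estimated neural seed series (TR resolution), e.g. from
#'   [deconvolve_neural()].
#' @param boxcars Matrix (`n_volumes` x cells) of 0/1 cell indicators with
#'   column names; cells must not overlap in time.
#' @param seed_ts Observed seed BOLD series (physiological regressor).
#' @param tr Repetition time in seconds.
#' @param nuisance Optional matrix of nuisance series.
#' @param hrf Optional `hrf_kernel` (default `canonical_hrf(tr, 1)`).
#' @return A `design_matrix` whose `ppi_*` columns are the regressors of
#'   interest.
#' @export
build_gppi_design <- function(neural, boxcars, seed_ts, tr,
                              nuisance = NULL, hrf = NULL) {
  boxcars <- as.matrix(boxcars)
  n <- length(neural)
  stopifnot(length(seed_ts) == n, nrow(boxcars) == n)
  cells <- colnames(boxcars) %||% paste0("cell", seq_len(ncol(boxcars)))
  colnames(boxcars) <- cells

  empty <- colSums(boxcars != 0) == 0
  if (any(empty)) {
    abort(paste0("Cell(s) with an all-zero boxcar: ",
                 paste(cells[empty], collapse = ", "), "."))
  }
  if (any(rowSums(boxcars != 0) > 1)) {
    abort("Cell boxcars overlap in time; cells must be disjoint.")
  }

  kernel <- (hrf %||% canonical_hrf(tr, 1L))$values
  cols <- list()
  roles <- character(0)
  for (cell in cells) {
    nm <- paste0("ppi_", cell)
    cols[[nm]] <- convolve_hrf(neural * boxcars[, cell], kernel)
    roles[nm] <- "interest"
  }
  for (cell in cells) {
    nm <- paste0("psych_", cell)
    cols[[nm]] <- convolve_hrf(boxcars[, cell], kernel)
    roles[nm] <- "nuisance"
  }
  cols[["physio"]] <- seed_ts
  roles["physio"] <- "nuisance"
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n)
    nms <- colnames(nuisance) %||% paste0("nuisance_", seq_len(ncol(nuisance)))
    for (j in seq_len(ncol(nuisance))) {
      cols[[nms[j]]] <- nuisance[, j]
      roles[nms[j]] <- "nuisance"
    }
  }
  cols[["constant"]] <- rep(1, n)
  roles["constant"] <- "constant"

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(X, frame_times = (seq_len(n) - 1) * tr, roles = roles, tr = tr,
            class = c("design_matrix", "matrix"))
}

#' Fit a gPPI model and evaluate a coupling contrast
#'
#' OLS fit of a target series on a gPPI design; the contrast (default
#' aversive minus neutral over the `ppi_*` columns) measures
#' condition-specific modulation of seed-target coupling.
#'
#' @param target_ts Target BOLD series.
#' @param ppi_design Design from [build_gppi_design()].
#' @param contrast_weights Named numeric vector of weights over the
#'   `ppi_*` columns; default `+1` on `ppi_aversive`, `-1` on
#'   `ppi_neutral`.
#' @return A `connectivity_estimate`: list with per-cell PPI `beta`,
#'   `contrast`, `se`, `statistic`, `df`, `p.value`, `weights`.
#' @export
fit_gppi_contrast <- function(target_ts, ppi_design,
                              contrast_weights = NULL) {
  X <- unclass(ppi_design)
  attr(X, "roles") <- NULL; attr(X, "frame_times") <- NULL; attr(X, "tr") <- NULL
  ppi_terms <- grep("^ppi_", colnames(X), value = TRUE)
  if (length(ppi_terms) == 0) abort("Design has no `ppi_*` columns.")

  if (is.null(contrast_weights)) {
    if (!all(c("ppi_aversive", "ppi_neutral") %in% ppi_terms)) {
      abort("Supply `contrast_weights` when cells are not aversive/neutral.")
    }
    contrast_weights <- c(ppi_aversive = 1, ppi_neutral = -1)
  }
  if (is.null(names(contrast_weights)) ||
      !all(names(contrast_weights) %in% colnames(X))) {
    abort("`contrast_weights` must be named after design columns.")
  }

  fit <- fit_glm(target_ts, ppi_design)
  w <- setNames(numeric(ncol(X)), colnames(X))
  w[names(contrast_weights)] <- contrast_weights
  xtx_inv <- chol2inv(chol(crossprod(X)))
  est <- sum(w * fit$beta[, 1])
  se <- sqrt(fit$sigma2[1] * drop(t(w) %*% xtx_inv %*% w))
  tstat <- est / se

  structure(
    list(beta = setNames(fit$beta[ppi_terms, 1], ppi_terms),
         contrast = est, se = se, statistic = tstat, df = fit$df,
         p.value = 2 * pt(abs(tstat), fit$df, lower.tail = FALSE),
         weights = contrast_weights, fit = fit),
    class = "connectivity_estimate"
  )
}

#' @exportS3Method base::print
print.connectivity_estimate <- function(x, ...) {
  cat("<connectivity_estimate>\n  PPI betas:\n")
  for (nm in names(x$beta)) cat(sprintf("    %-28s %8.4f\n", nm, x$beta[nm]))
  cat(sprintf("  contrast = %.4f (t = %.2f, df = %d, p = %.4g)\n",
              x$contrast, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @rdname fit_gppi_contrast
#' @param x A `connectivity_estimate`.
#' @param ... Unused.
#' @export
tidy.connectivity_estimate <- function(x, ...) {
  tibble::tibble(term = c(names(x$beta), "contrast"),
                 estimate = c(unname(x$beta), x$contrast),
                 statistic = c(rep(NA_real_, length(x$beta)), x$statistic),
                 p.value = c(rep(NA_real_, length(x$beta)), x$p.value))
}

#' Run a gPPI analysis on one simulated (or supplied) task run
#'
#' Convenience wrapper: deconvolves the run's seed, builds condition (or
#' memory-cell) boxcars from its design, assembles the gPPI design with the
#' run's confounds, and fits the target.
#'
#' @param run One element of a `ts_bundle` (a task run).
#' @param ridge_lambda Penalty for [deconvolve_neural()].
#' @param cells Optional boxcar matrix overriding the run's condition
#'   boxcars (e.g. from [memory_cell_boxcars()]).
#' @param contrast_weights Passed to [fit_gppi_contrast()].
#' @return A `connectivity_estimate`.
#' @export
gppi_run <- function(run, ridge_lambda = "gcv", cells = NULL,
                     contrast_weights = NULL) {
  stopifnot(!is.null(run$design))
  neural <- deconvolve_neural(run$seed_ts, tr = run$tr,
                              ridge_lambda = ridge_lambda)
  box <- cells %||% condition_boxcars(run$design, run$tr, run$n_volumes)
  des <- build_gppi_design(neural, box, run$seed_ts, tr = run$tr,
                           nuisance = run$confounds)
  fit_gppi_contrast(run$target_ts, des, contrast_weights = contrast_weights)
}

#' Condition-by-memory cell boxcars for the four-regressor gPPI variant
#'
#' Builds disjoint boxcars for the cells forgotten/remembered-with-high-
#' confidence crossed with aversive/neutral; trials remembered with low
#' confidence are omitted from the cells, matching the memory-status gPPI
#' model.
#'
#' @param design A `trial_design`.
#' @param behavior Behavioural tibble with `pair_id`, `confidence`,
#'   `chosen_correct`.
#' @param tr Repetition time (s).
#' @param n_volumes Volumes in the run.
#' @return Matrix `n_volumes` x 4 with names like
#'   `remembered_hc_aversive`.
#' @export
memory_cell_boxcars <- function(design, behavior, tr, n_volumes) {
  events <- tibble::as_tibble(design)
  stim <- dplyr::filter(events, !.data$event_kind %in% c("cue", "rating"))
  b <- behavior[match(stim$pair_id, behavior$pair_id), ]
  status <- dplyr::case_when(
    b$chosen_correct & b$confidence >= 3 ~ "remembered_hc",
    !b$chosen_correct ~ "forgotten",
    TRUE ~ NA_character_
  )
  cells <- paste(status, stim$condition, sep = "_")
  cells[is.na(status)] <- NA
  labs <- as.vector(outer(c("remembered_hc", "forgotten"),
                          c("aversive", "neutral"), paste, sep = "_"))
  t_vol <- (seq_len(n_volumes) - 1) * tr
  out <- matrix(0, n_volumes, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(nrow(stim))) {
    if (is.na(cells[i])) next
    on <- t_vol >= stim$onset[i] & t_vol < stim$onset[i] + stim$duration[i]
    out[on, cells[i]] <- 1
  }
  out
}
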