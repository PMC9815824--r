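#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style canonical HRF: difference of two gamma densities with response
#' peak at 6 s, undershoot peak at 16 s, unit dispersions, peak:undershoot
#' ratio 6:1, 32 s support, normalized to unit peak.
#'
#' @param tr Repetition time in seconds (`> 0`).
#' @param oversampling Samples per TR (microtime resolution). Default 16.
#' @return An `hrf_kernel`: list with `values`, `times` (s), `tr`,
#'   `oversampling`, `peak_delay`, `undershoot_delay`, `duration`.
#' @examples
#' h <- canonical_hrf(2)
#' h$times[which.max(h$values)]
#' @export
canonical_hrf <- function(tr, oversampling = 16L) {
  if (!is.numeric(tr) || length(tr) != 1 || !is.finite(tr) || tr <= 0) {
    abort("`tr` must be a single positive number.")
  }
  assert_scalar_number(oversampling, "oversampling", lower = 1)
  dt <- tr / oversampling
  times <- seq(0, 32, by = dt)
  vals <- stats::dgamma(times, shape = 6, rate = 1) -
    stats::dgamma(times, shape = 16, rate = 1) / 6
  vals <- vals / max(vals)
  structure(
    list(values = vals, times = times, tr = tr,
         oversampling = as.integer(oversampling),
         peak_delay = 6, undershoot_delay = 16, duration = 32),
    class = "hrf_kernel"
  )
}

#' @exportS3Method base::print
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel: TR %.2f s, dt %.3f s, %d samples over %g s>\n",
              x$tr, x$tr / x$oversampling, length(x$values), x$duration))
  invisible(x)
}

#' Causal convolution of a stimulus vector with an HRF kernel
#'
#' Discrete convolution truncated to the stimulus length (samples share the
#' kernel's resolution).
#'
#' @param x Numeric stimulus/neural vector.
#' @param kernel_values Kernel samples, e.g. `canonical_hrf(tr, 1)$values`.
#' @return Numeric vector of `length(x)`.
#' @export
convolve_hrf <- function(x, kernel_values) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel_values), type = "open")[seq_len(n)]
  out
}

#' Discrete-cosine drift basis
#'
#' High-pass filtering is implemented as a set of low-frequency DCT
#' regressors up to a cutoff period (default 128 s), entered as nuisance
#' columns.
#'
#' @param n_volumes Number of volumes.
#' @param tr Repetition time (s).
#' @param cutoff Cutoff period in seconds.
#' @return Matrix with `n_volumes` rows (possibly 0 columns).
#' @export
dct_basis <- function(n_volumes, tr, cutoff = 128) {
  n <- as.integer(n_volumes)
  k_max <- floor(2 * n * tr / cutoff)
  if (k_max < 1) return(matrix(numeric(0), n, 0))
  v <- seq_len(n) - 1L
  cols <- vapply(seq_len(k_max),
                 function(k) cos(pi * (2 * v + 1) * k / (2 * n)),
                 numeric(n))
  colnames(cols) <- paste0("drift_", seq_len(k_max))
  cols
}

#' Build a first-level design matrix
#'
#' Creates HRF-convolved regressors from a trial design. In `condition`
#' mode, one regressor per condition models the stimulus events (2 s from
#' onset, the window used for both phases); in `trial` mode each pair id
#' gets its own regressor, spanning every presentation of that pair so
#' repeated viewings collapse into a single estimate (set
#' `collapse_repetitions = FALSE` for one column per presentation). Face-cue
#' events are appended as nuisance regressors: per condition in `condition`
#' mode, a single column in `trial` mode. An optional DCT drift basis,
#' user-supplied nuisance columns and a constant complete the matrix.
#' Boxcars are built at microtime resolution, convolved with
#' [canonical_hrf()], and sampled at volume acquisition times.
#'
#' @param design A `trial_design` (or a tibble of events with the same
#'   columns).
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes in the run.
#' @param mode `"condition"` or `"trial"`.
#' @param extra_regressors Optional matrix/data frame of nuisance series
#'   with `n_volumes` rows (e.g. motion parameters).
#' @param hpf_cutoff High-pass cutoff period in seconds, or `NULL` to skip
#'   the drift basis. Default 128.
#' @param stim_duration Modelled duration (s) of each stimulus event.
#' @param collapse_repetitions Collapse repeated presentations of a pair
#'   into one trial regressor (trial mode only).
#' @param oversampling Microtime samples per TR.
#' @return A `design_matrix`: numeric matrix with attributes `frame_times`,
#'   `roles` (`"interest"`, `"nuisance"`, `"drift"`, `"constant"`), `tr`.
#' @export
build_design_matrix <- function(design, tr, n_volumes,
                                mode = c("condition", "trial"),
                                extra_regressors = NULL,
                                hpf_cutoff = 128,
                                stim_duration = 2,
                                collapse_repetitions = TRUE,
                                oversampling = 16L) {
  mode <- match.arg(mode)
  assert_scalar_number(tr, "tr", lower = 1e-6)
  assert_scalar_number(n_volumes, "n_volumes", lower = 1)
  n_volumes <- as.integer(n_volumes)
  events <- tibble::as_tibble(design)

  dt <- tr / oversampling
  n_micro <- n_volumes * as.integer(oversampling)
  scan_end <- n_volumes * tr

  micro_box <- function(onsets, durations) {
    x <- numeric(n_micro)
    for (i in seq_along(onsets)) {
      a <- floor(onsets[i] / dt) + 1
      if (a > n_micro) next
      b <- min(ceiling((onsets[i] + durations[i]) / dt), n_micro)
      x[a:b] <- 1
    }
    x
  }
  kernel <- canonical_hrf(tr, oversampling)$values
  vol_idx <- (seq_len(n_volumes) - 1L) * as.integer(oversampling) + 1L
  make_col <- function(onsets, durations) {
    convolve_hrf(micro_box(onsets, durations), kernel)[vol_idx]
  }

  cols <- list()
  roles <- character(0)

  if (nrow(events) > 0) {
    stim <- dplyr::filter(events,
                          !.data$event_kind %in% c("cue", "rating"))
    cues <- dplyr::filter(events, .data$event_kind == "cue")
    stim$mod_duration <- pmin(stim$duration, stim_duration)

    too_late <- stim$onset + stim$mod_duration > scan_end + 1e-9
    if (any(too_late)) {
      bad <- stim[which(too_late)[1], ]
      abort(sprintf(
        "Event '%s' (pair %s) at onset %.1f s extends beyond the %d-volume scan (%.1f s).",
        bad$event_kind, bad$pair_id, bad$onset, n_volumes, scan_end))
    }

    if (mode == "condition") {
      for (cond in sort(unique(stim$condition))) {
        e <- stim[stim$condition == cond, ]
        cols[[cond]] <- make_col(e$onset, e$mod_duration)
        roles[cond] <- "interest"
      }
    } else {
      ids <- sort(unique(stim$pair_id))
      for (id in ids) {
        e <- stim[stim$pair_id == id, ]
        if (collapse_repetitions || nrow(e) == 1) {
          nm <- paste0("trial_", id)
          cols[[nm]] <- make_col(e$onset, e$mod_duration)
          roles[nm] <- "interest"
        } else {
          for (j in seq_len(nrow(e))) {
            nm <- paste0("trial_", id, "_rep", j)
            cols[[nm]] <- make_col(e$onset[j], e$mod_duration[j])
            roles[nm] <- "interest"
          }
        }
      }
    }

    if (nrow(cues) > 0) {
      if (mode == "condition") {
        for (cond in sort(unique(cues$condition))) {
          e <- cues[cues$condition == cond, ]
          nm <- paste0("cue_", cond)
          cols[[nm]] <- make_col(e$onset, e$duration)
          roles[nm] <- "nuisance"
        }
      } else {
        cols[["cue"]] <- make_col(cues$onset, cues$duration)
        roles["cue"] <- "nuisance"
      }
    }
  }

  if (!is.null(hpf_cutoff)) {
    dctb <- dct_basis(n_volumes, tr, hpf_cutoff)
    for (j in seq_len(ncol(dctb))) {
      cols[[colnames(dctb)[j]]] <- dctb[, j]
      roles[colnames(dctb)[j]] <- "drift"
    }
  }

  if (!is.null(extra_regressors)) {
    extra <- as.matrix(extra_regressors)
    if (nrow(extra) != n_volumes) {
      abort("`extra_regressors` must have `n_volumes` rows.")
    }
    nms <- colnames(extra) %||% paste0("nuisance_", seq_len(ncol(extra)))
    for (j in seq_len(ncol(extra))) {
      cols[[nms[j]]] <- extra[, j]
      roles[nms[j]] <- "nuisance"
    }
  }

  cols[["constant"]] <- rep(1, n_volumes)
  roles["constant"] <- "constant"

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyDuplicated(colnames(X))) abort("Design matrix labels must be unique.")
  structure(X,
            frame_times = (seq_len(n_volumes) - 1) * tr,
            roles = roles, tr = tr, class = c("design_matrix", "matrix"))
}

#' Fit an ordinary-least-squares GLM
#'
#' Fits `y = X b + e` by OLS and returns per-regressor betas and t values
#' with `df = n - rank(X)`. `y` may be a matrix (e.g. voxels in columns), in
#' which case each column is fitted with the shared design.
#'
#' @param y Numeric vector or matrix of responses (`n_volumes` rows).
#' @param design_matrix Design matrix from [build_design_matrix()] or any
#'   full-column-rank numeric matrix with column names.
#' @return A `glm_fit`: list with `beta`, `se`, `t` (regressors x series),
#'   `sigma2`, `df`, `terms`, `roles`.
#' @examples
#' X <- cbind(x = rnorm(40), constant = 1)
#' fit <- fit_glm(2 * X[, 1] + 1, X)
#' tidy(fit)
#' @export
fit_glm <- function(y, design_matrix) {
  X <- unclass(design_matrix)
  attr(X, "roles") <- NULL
  attr(X, "frame_times") <- NULL
  attr(X, "tr") <- NULL
  y <- as.matrix(y)
  if (nrow(y) != nrow(X)) {
    abort("`y` and the design matrix must have the same number of rows.")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", "), "."))
  }
  df <- nrow(X) - qx$rank
  if (df <= 0) abort("No residual degrees of freedom.")

  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- beta / se

  structure(
    list(beta = beta, se = se, t = tval, sigma2 = sigma2, df = df,
         terms = colnames(X),
         roles = attr(design_matrix, "roles"), residuals = res),
    class = "glm_fit"
  )
}

#' @exportS3Method base::print
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit: %d regressors, %d series, df = %d>\n",
              length(x$terms), ncol(x$beta), x$df))
  invisible(x)
}

#' @rdname fit_glm
#' @param x A `glm_fit`.
#' @param ... Unused.
#' @export
tidy.glm_fit <- function(x, ...) {
  k <- ncol(x$beta)
  tibble::tibble(
    term = rep(x$terms, k),
    series = rep(colnames(x$beta) %||% as.character(seq_len(k)),
                 each = length(x$terms)),
    estimate = as.numeric(x$beta),
    std.error = as.numeric(x$se),
    statistic = as.numeric(x$t),
    df = x$df,
    p.value = 2 * pt(abs(as.numeric(x$t)), x$df, lower.tail = FALSE)
  )
}

#' @rdname fit_glm
#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_terms = length(x$terms), n_series = ncol(x$beta),
                 df.residual = x$df, sigma2 = mean(x$sigma2))
}

#' Extract t-patterns of the regressors of interest
#'
#' Convenience accessor returning the matrix of t values for `interest`
#' regressors (trials or conditions in rows, series/voxels in columns).
#'
#' @param fit A `glm_fit`.
#' @return Numeric matrix of t values.
#' @export
t_patterns <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  keep <- if (is.null(fit$roles)) {
    seq_along(fit$terms)
  } else {
    which(fit$roles[fit$terms] == "interest")
  }
  fit$t[keep, , drop = FALSE]
}
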