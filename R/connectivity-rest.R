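#' Band-pass filter and confound-regress a resting-state series
#'
#' Zero-phase (forward-backward) Butterworth band-pass of the data and of
#' the confound series, followed by regression of the filtered data on the
#' filtered confounds. Filtering the confounds with the same band prevents
#' the regression from reintroducing out-of-band energy. The returned
#' residuals have mean (approximately) zero.
#'
#' @param ts Numeric series, or a matrix with one series per column.
#' @param confounds Matrix of nuisance series (e.g. six motion + CSF + WM),
#'   or `NULL` for filtering only.
#' @param band Pass band in Hz, default `c(0.008, 0.10)`.
#' @param tr Repetition time in seconds.
#' @param order Butterworth design order (default 4).
#' @return Filtered, confound-regressed series (same shape as `ts`).
#' @export
preprocess_rest <- function(ts, confounds = NULL, band = c(0.008, 0.10),
                            tr = 2, order = 4L) {
  nyq <- 1 / (2 * tr)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= nyq) {
    abort(sprintf("`band` must satisfy 0 < low < high < Nyquist (%.3f Hz).",
                  nyq))
  }
  bf <- signal::butter(order, band / nyq, type = "pass")
  filt <- function(v) signal::filtfilt(bf, v - mean(v))

  ts <- as.matrix(ts)
  tf <- apply(ts, 2, filt)
  if (!is.null(confounds)) {
    cf <- apply(as.matrix(confounds), 2, filt)
    tf <- apply(tf, 2, function(v) resid(lm(v ~ cf)))
  }
  tf <- scale(tf, center = TRUE, scale = FALSE)
  if (ncol(tf) == 1) as.numeric(tf) else tf
}

#' Seed-based resting connectivity
#'
#' Fisher-transformed Pearson correlation between a preprocessed seed
#' series and each preprocessed target series (correlations clipped at
#' `|r| = 1 - 1e-7` before the transform).
#'
#' @param seed_res Preprocessed seed series.
#' @param target_res Preprocessed target series: vector, or matrix with
#'   targets in columns.
#' @return Tibble `target`, `r`, `z` (one row per target).
#' @export
seed_connectivity <- function(seed_res, target_res) {
  target_res <- as.matrix(target_res)
  stopifnot(nrow(target_res) == length(seed_res))
  r <- as.numeric(cor(seed_res, target_res))
  tibble::tibble(
    target = colnames(target_res) %||% as.character(seq_len(ncol(target_res))),
    r = r,
    z = fisher_z(r)
  )
}

#' Difference of two connectivity maps
#'
#' Element-wise subtraction of an earlier connectivity map from a later
#' one, in Fisher-z space (late minus early, e.g. post-learning rest minus
#' pre-learning rest).
#'
#' @param map_late,map_early Numeric vectors/arrays of identical shape, or
#'   tibbles from [seed_connectivity()] (matched on `target`).
#' @return Same shape as the inputs (tibble input yields a tibble with a
#'   `z_diff` column).
#' @export
rest_difference <- function(map_late, map_early) {
  if (is.data.frame(map_late) && is.data.frame(map_early)) {
    stopifnot(identical(map_late$target, map_early$target))
    return(tibble::tibble(target = map_late$target,
                          z_diff = map_late$z - map_early$z))
  }
  if (!identical(dim(map_late), dim(map_early)) ||
      length(map_late) != length(map_early)) {
    abort("Maps must have identical shape.")
  }
  map_late - map_early
}

#' Group regression of connectivity change on condition-wise memory
#'
#' Regresses per-subject connectivity-change values on memory accuracy in
#' the aversive and neutral conditions (two covariates of interest plus an
#' intercept) and tests the difference of the two regression coefficients
#' -- the interaction between connectivity change and emotional condition.
#'
#' @param diff_values Numeric vector (one value per subject) or matrix
#'   (subjects x targets) of connectivity differences.
#' @param mem_aversive,mem_neutral Memory accuracy per subject in each
#'   condition.
#' @return Tibble (one row per target): `target`, `coef_aversive`,
#'   `coef_neutral`, `contrast`, `se`, `statistic`, `df`, `p.value`.
#' @export
group_interaction_regression <- function(diff_values, mem_aversive,
                                         mem_neutral) {
  dv <- as.matrix(diff_values)
  n <- nrow(dv)
  stopifnot(length(mem_aversive) == n, length(mem_neutral) == n)
  if (n - 3 < 4) abort("Need at least 4 more subjects than regressors.")
  if (sd(mem_aversive) == 0 || sd(mem_neutral) == 0 ||
      abs(cor(mem_aversive, mem_neutral)) > 0.999) {
    abort("Memory covariates are collinear (|r| > 0.999 or constant).")
  }

  X <- cbind(intercept = 1, memA = mem_aversive, memN = mem_neutral)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, dv)
  rownames(beta) <- colnames(X)
  res <- dv - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  cw <- c(0, 1, -1)
  cvar <- drop(t(cw) %*% xtx_inv %*% cw)
  est <- drop(crossprod(cw, beta))
  se <- sqrt(sigma2 * cvar)
  tstat <- est / se

  tibble::tibble(
    target = colnames(dv) %||% as.character(seq_len(ncol(dv))),
    coef_aversive = beta["memA", ],
    coef_neutral = beta["memN", ],
    contrast = est, se = se, statistic = tstat, df = df,
    p.value = 2 * pt(abs(tstat), df, lower.tail = FALSE)
  )
}
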