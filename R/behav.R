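#' Chance level of a position-dependent matching test
#'
#' In the associative memory test, several cues are matched to the same set
#' of options without replacement, so chance accuracy depends on response
#' position: the k-th response (out of `n`) is chosen from `n - k + 1`
#' remaining options. Chance level is the mean of `1/(n - k + 1)` over
#' positions; with 4 options this is `(1/4 + 1/3 + 1/2 + 1)/4 = 0.5208`,
#' i.e. 52% to the nearest percent.
#'
#' @param n_options Number of options matched per screen (`>= 1`).
#' @return Chance proportion correct.
#' @examples
#' chance_level(4)
#' @export
chance_level <- function(n_options) {
  assert_scalar_number(n_options, "n_options", lower = 1)
  n <- as.integer(n_options)
  mean(1 / seq_len(n))
}

#' Bin memory accuracy by confidence or vividness ratings
#'
#' Sorts trials into a high bin (ratings 3-4) and a low bin (ratings 1-2)
#' and computes the proportion correct per subject, condition and bin. An
#' optional restriction (e.g. high-confidence trials only, before binning
#' on vividness) is applied first. Empty bins are kept with `NA` proportion
#' and flagged, never treated as zero accuracy.
#'
#' @param data Behavioural tibble with columns `subject`, `condition`,
#'   `chosen_correct` and the rating to bin on.
#' @param bin_on `"confidence"` or `"vividness"`.
#' @param restrict Optional unquoted filtering expression evaluated in
#'   `data`, applied before binning.
#' @return Tibble `subject`, `condition`, `bin`, `n_trials`,
#'   `prop_correct`, `empty`.
#' @examples
#' bt <- tibble::tibble(subject = 1, condition = rep(c("aversive", "neutral"), 3),
#'                      confidence = c(4, 4, 1, 2, 3, 1),
#'                      chosen_correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
#' bin_accuracy(bt, "confidence")
#' @export
bin_accuracy <- function(data, bin_on = c("confidence", "vividness"),
                         restrict = NULL) {
  bin_on <- match.arg(bin_on)
  restrict <- rlang::enquo(restrict)
  if (!rlang::quo_is_null(restrict)) {
    data <- dplyr::filter(data, !!restrict)
  }
  rating <- data[[bin_on]]
  if (is.null(rating)) abort(sprintf("Column '%s' not found.", bin_on))
  if (!all(rating %in% 1:4)) abort("Ratings must be in {1, 2, 3, 4}.")

  data$bin <- ifelse(rating >= 3, "high", "low")
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$subject, .data$condition, .data$bin),
    n_trials = dplyr::n(),
    prop_correct = mean(.data$chosen_correct),
    .groups = "drop")
  out <- tidyr::complete(
    out, .data$subject, .data$condition, bin = c("high", "low"),
    fill = list(n_trials = 0L))
  dplyr::mutate(out, empty = .data$n_trials == 0L,
                prop_correct = ifelse(.data$empty, NA_real_,
                                      .data$prop_correct))
}

#' One-sample t test against a fixed value
#'
#' Two-tailed Student t test of the mean of `values` against `mu0`, with
#' Cohen's d (`(mean - mu0) / SD`).
#'
#' @param values Numeric vector, length `>= 2`.
#' @param mu0 Null value.
#' @return One-row tibble `estimate`, `mu0`, `statistic`, `df`, `p.value`,
#'   `cohen_d`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 2, all(is.finite(values)))
  assert_scalar_number(mu0, "mu0")
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    tstat <- if (m == mu0) 0 else sign(m - mu0) * Inf
  } else {
    tstat <- (m - mu0) / (s / sqrt(n))
  }
  tibble::tibble(
    estimate = m, mu0 = mu0, statistic = tstat, df = n - 1,
    p.value = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
    cohen_d = if (s == 0) NA_real_ else (m - mu0) / s
  )
}

#' Paired t test with the d_av effect size
#'
#' Two-tailed paired t test of `x` against `y`. The effect size `d_av`
#' divides the mean difference by the average of the two conditions'
#' standard deviations, rather than by the SD of the differences.
#'
#' @param x,y Paired numeric vectors of equal length `>= 2`.
#' @return One-row tibble `estimate` (mean difference), `statistic`, `df`,
#'   `p.value`, `d_av`.
#' @export
paired_t_dav <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be paired vectors of equal length >= 2.")
  }
  d <- x - y
  n <- length(d)
  sd_av <- (sd(x) + sd(y)) / 2
  if (sd_av == 0) abort("Both measures are constant; d_av is undefined.")
  sdd <- sd(d)
  tstat <- if (sdd == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    mean(d) / (sdd / sqrt(n))
  }
  tibble::tibble(
    estimate = mean(d), statistic = tstat, df = n - 1,
    p.value = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
    d_av = mean(d) / sd_av
  )
}

#' 2x2 repeated-measures ANOVA via within-subject contrasts
#'
#' Tests the two main effects and the interaction of a fully within-subject
#' 2x2 design. Each effect is evaluated through its per-subject contrast
#' (difference score): without covariates, the effect F equals the squared
#' paired t of the contrast and `partial eta^2 = F / (F + df_error)`. With
#' covariates (the repeated-measures ANCOVA convention of mainstream
#' statistics packages), each contrast is regressed on the mean-centered
#' covariates and the regression intercept is tested.
#'
#' @param data Long tibble with one row per subject x cell.
#' @param subject,f1,f2,value Names of the subject, the two within-subject
#'   factor and the outcome columns.
#' @param covariates Optional data frame (or matrix) of subject-level
#'   covariates, one row per subject in sorted subject order.
#' @return Tibble with rows for both main effects and the interaction:
#'   `effect`, `statistic` (F), `df1`, `df2`, `p.value`, `partial_eta_sq`.
#' @examples
#' d <- tidyr::expand_grid(subject = 1:8, emotion = c("aversive", "neutral"),
#'                         confidence = c("high", "low"))
#' d$acc <- runif(nrow(d))
#' rm_anova_2x2(d, f1 = "emotion", f2 = "confidence", value = "acc")
#' @export
rm_anova_2x2 <- function(data, subject = "subject", f1 = "emotion",
                         f2 = "confidence", value = "value",
                         covariates = NULL) {
  need <- c(subject, f1, f2, value)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  l1 <- sort(unique(data[[f1]]))
  l2 <- sort(unique(data[[f2]]))
  if (length(l1) != 2 || length(l2) != 2) {
    abort("Both factors must have exactly 2 levels.")
  }

  wide <- tidyr::pivot_wider(
    data[, need],
    names_from = dplyr::all_of(c(f1, f2)),
    values_from = dplyr::all_of(value), names_sep = ".")
  wide <- dplyr::arrange(wide, .data[[subject]])
  cell_names <- as.vector(outer(l1, l2, paste, sep = "."))
  if (!all(cell_names %in% names(wide)) ||
      anyNA(wide[cell_names])) {
    bad <- wide[[subject]][!complete.cases(wide[intersect(cell_names,
                                                          names(wide))])]
    abort(paste0("Incomplete 2x2 cells for subject(s): ",
                 paste(unique(bad), collapse = ", "), "."))
  }
  c11 <- wide[[paste(l1[1], l2[1], sep = ".")]]
  c12 <- wide[[paste(l1[1], l2[2], sep = ".")]]
  c21 <- wide[[paste(l1[2], l2[1], sep = ".")]]
  c22 <- wide[[paste(l1[2], l2[2], sep = ".")]]
  n <- nrow(wide)

  contrasts <- list(
    (c11 + c12 - c21 - c22) / 2,   # main effect of f1
    (c11 - c12 + c21 - c22) / 2,   # main effect of f2
    c11 - c12 - c21 + c22          # interaction
  )
  names(contrasts) <- c(f1, f2, paste0(f1, ":", f2))

  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) abort("`covariates` must have one row per subject.")
    if (any(apply(cv, 2, sd) == 0)) {
      abort("Zero-variance covariate supplied.")
    }
    cv <- scale(cv, center = TRUE, scale = FALSE)
  }

  rows <- purrr::imap(contrasts, function(con, eff) {
    if (is.null(covariates)) {
      tt <- one_sample_t(con, 0)
      f_stat <- tt$statistic^2
      df2 <- n - 1
      p <- tt$p.value
    } else {
      fit <- lm(con ~ cv)
      sm <- summary(fit)$coefficients
      tstat <- sm["(Intercept)", "t value"]
      f_stat <- tstat^2
      df2 <- n - 1 - ncol(cv)
      p <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
    }
    tibble::tibble(effect = eff, statistic = f_stat, df1 = 1, df2 = df2,
                   p.value = p,
                   partial_eta_sq = f_stat / (f_stat + df2))
  })
  dplyr::bind_rows(rows)
}

#' Trial-level slope from a random-intercept mixed model
#'
#' Fits `y ~ x + (1 | subject)` with \pkg{lme4} across all trials of all
#' participants and reports the fixed slope with its Wald 95% confidence
#' interval, as used to relate encoding vividness to memory confidence at
#' the trial level.
#'
#' @param data Trial-level tibble.
#' @param x,y Names of the predictor and outcome columns.
#' @param subject Name of the grouping column.
#' @return One-row tibble `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `statistic`, `p.value`, `ranef_var`, `n_subjects`, `n_obs`.
#' @export
mixed_slope <- function(data, x, y, subject = "subject") {
  for (col in c(x, y, subject)) {
    if (!col %in% names(data)) abort(sprintf("Column '%s' not found.", col))
  }
  if (length(unique(data[[subject]])) < 2) {
    abort("Need at least 2 subjects for a mixed model.")
  }
  if (sd(data[[x]]) == 0) abort(sprintf("Predictor '%s' is constant.", x))

  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", y, x, subject))
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  est <- lme4::fixef(fit)[[x]]
  se <- sqrt(diag(as.matrix(vcov(fit))))[[2]]
  zc <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(
    estimate = est, std.error = se,
    conf.low = est - zc * se, conf.high = est + zc * se,
    statistic = est / se,
    p.value = 2 * pnorm(abs(est / se), lower.tail = FALSE),
    ranef_var = vc$vcov[vc$grp == subject][1],
    n_subjects = length(unique(data[[subject]])),
    n_obs = nrow(data)
  )
}

#' Mean skin conductance level in post-onset windows
#'
#' Averages a skin conductance trace over `[onset, onset + window_s)` for
#' each stimulus onset; windows extending past the end of the trace give
#' `NA` with a warning.
#'
#' @param trace Numeric conductance samples (microsiemens).
#' @param onsets Stimulus onsets in seconds.
#' @param window_s Window length in seconds (default 6).
#' @param sample_rate Sampling rate in Hz.
#' @param condition,phase Optional per-onset labels carried through.
#' @return Tibble `trial`, `onset`, `condition`, `phase`, `mean_scl`.
#' @export
scl_mean <- function(trace, onsets, window_s = 6, sample_rate,
                     condition = NULL, phase = NULL) {
  stopifnot(is.numeric(trace), is.numeric(onsets))
  assert_scalar_number(window_s, "window_s", lower = 1e-9)
  assert_scalar_number(sample_rate, "sample_rate", lower = 1e-9)

  vals <- vapply(onsets, function(on) {
    a <- floor(on * sample_rate) + 1
    b <- floor((on + window_s) * sample_rate)
    if (a < 1 || b > length(trace)) return(NA_real_)
    mean(trace[a:b])
  }, numeric(1))
  if (anyNA(vals)) {
    warn(sprintf("%d window(s) extend beyond the trace; returned NA.",
                 sum(is.na(vals))))
  }
  tibble::tibble(
    trial = seq_along(onsets), onset = onsets,
    condition = condition %||% NA_character_,
    phase = phase %||% NA_character_,
    mean_scl = vals
  )
}

#' Condition-by-phase SCL means
#'
#' Aggregates per-trial SCL means (from [scl_mean()]) into condition x
#' phase cell means.
#'
#' @param scl_trials Tibble from [scl_mean()].
#' @return Tibble `condition`, `phase`, `mean_scl`, `n_trials`.
#' @export
scl_condition_means <- function(scl_trials) {
  dplyr::summarise(
    dplyr::group_by(scl_trials, .data$condition, .data$phase),
    mean_scl = mean(.data$mean_scl, na.rm = TRUE),
    n_trials = dplyr::n(), .groups = "drop")
}
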