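#' Z-score a multivoxel pattern across voxels
#'
#' Removes the mean activation from a pattern and scales it to unit SD, so
#' later correlations reflect the spatial pattern rather than overall
#' amplitude.
#'
#' @param x Numeric vector with at least 2 elements and nonzero variance.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
normalize_pattern <- function(x) {
  if (!is.numeric(x) || length(x) < 2 || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector of length >= 2.")
  }
  s <- sd(x)
  if (s == 0) abort("Cannot normalize a constant (zero-variance) pattern.")
  (x - mean(x)) / s
}

# Fisher transform with clipping so identical patterns stay finite.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Fisher-transformed Pearson similarity of two patterns
#'
#' Computes `z = atanh(r)` for the Pearson correlation of two patterns,
#' with `r` clipped at `1 - 1e-7` in absolute value so that identical
#' patterns map to a finite maximum.
#'
#' @param x,y Numeric vectors of equal length `>= 2` with nonzero variance.
#' @return Fisher z value.
#' @examples
#' similarity_z(1:5, c(2, 4, 5, 4, 9))
#' @export
similarity_z <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2.")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("Inputs must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for zero-variance input.")
  }
  fisher_z(cor(x, y))
}

# Rows of `m` z-scored; correlations between all row pairs of a and b are
# then crossprod(za, zb) / (v - 1).
.row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  if (any(s == 0)) abort("Pattern with zero variance across voxels.")
  (m - mu) / s
}

.row_cor <- function(a, b) {
  tcrossprod(.row_standardize(a), .row_standardize(b)) / (ncol(a) - 1)
}

#' Trial-level pattern-similarity (reinstatement) measures
#'
#' Computes, per condition, the Fisher-z similarity measures used to
#' dissociate trial-specific reinstatement from category-level
#' representation:
#'
#' * `pair_specific` - correlation of each emotional-phase pattern with the
#'   initial-phase pattern of the *same* pair (trial-specific
#'   reinstatement);
#' * `across_pair_within` - mean correlation with all *other* pairs'
#'   initial patterns from the same condition;
#' * `across_pair_between` - mean correlation with other pairs' initial
#'   patterns from the other condition;
#' * `across_pair_combined` - mean over all other pairs regardless of
#'   condition (category-level representation);
#' * `within_encoding` - mean correlation among same-condition
#'   initial-phase patterns (phase consistency);
#' * `within_arousal` - the same among emotional-phase patterns.
#'
#' The pair's own initial pattern is excluded from every across-pair and
#' within-phase measure. By default, correlations are averaged on the r
#' scale and the mean is then Fisher-transformed
#' (`transform = "after_averaging"`); set `transform = "before_averaging"`
#' to Fisher-transform each correlation first.
#'
#' @param set_init,set_emo [pattern_set()]s with matching pair ids.
#' @param measures Character vector of measures (default: all).
#' @param transform When to apply the Fisher transform relative to
#'   trial averaging.
#' @return Tibble with columns `condition`, `measure`, `z`, `n_trials`.
#' @examples
#' s <- generate_session(sim_params(n_pairs = 12, n_aversive = 6, seed = 5))
#' p <- sim_params(n_pairs = 12, n_aversive = 6, n_voxels = 60, seed = 5)
#' ps <- simulate_pattern_sets(s$design_init1, s$design_emo, p)
#' trial_measures(ps$init, ps$emo)
#' @export
trial_measures <- function(set_init, set_emo,
                           measures = c("pair_specific",
                                        "across_pair_within",
                                        "across_pair_between",
                                        "across_pair_combined",
                                        "within_encoding",
                                        "within_arousal"),
                           transform = c("after_averaging",
                                         "before_averaging")) {
  transform <- match.arg(transform)
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(inherits(set_init, "pattern_set"), inherits(set_emo, "pattern_set"))

  oi <- order(set_init$meta$pair_id)
  oe <- order(set_emo$meta$pair_id)
  Pi <- set_init$patterns[oi, , drop = FALSE]
  Pe <- set_emo$patterns[oe, , drop = FALSE]
  ci <- set_init$meta$condition[oi]
  ce <- set_emo$meta$condition[oe]
  if (!identical(set_init$meta$pair_id[oi], set_emo$meta$pair_id[oe])) {
    abort("Pattern sets must share the same pair ids.")
  }
  if (ncol(Pi) != ncol(Pe)) abort("Pattern sets must share the same voxels.")
  cond <- ce
  n <- nrow(Pe)

  needs_cross <- any(measures %in% c("pair_specific", "across_pair_within",
                                     "across_pair_between",
                                     "across_pair_combined"))
  C <- if (needs_cross) .row_cor(Pe, Pi) else NULL
  Ci <- if ("within_encoding" %in% measures) .row_cor(Pi, Pi) else NULL
  Ce <- if ("within_arousal" %in% measures) .row_cor(Pe, Pe) else NULL

  maybe_z <- function(r) if (transform == "before_averaging") fisher_z(r) else r

  per_trial <- function(measure) {
    vapply(seq_len(n), function(i) {
      same <- cond == cond[i]
      sel <- switch(measure,
        pair_specific = i,
        across_pair_within = which(same & seq_len(n) != i),
        across_pair_between = which(!same),
        across_pair_combined = which(seq_len(n) != i),
        within_encoding = which(same & seq_len(n) != i),
        within_arousal = which(same & seq_len(n) != i)
      )
      if (measure != "pair_specific" && length(sel) < 1) {
        abort(sprintf(
          "Condition '%s' has too few trials for measure '%s'.",
          cond[i], measure))
      }
      M <- switch(measure, within_encoding = Ci, within_arousal = Ce, C)
      mean(maybe_z(M[i, sel]))
    }, numeric(1))
  }

  out <- tidyr::expand_grid(measure = measures,
                            condition = sort(unique(cond)))
  rows <- purrr::pmap(out, function(measure, condition) {
    idx <- cond == condition
    if (measure != "pair_specific" && sum(idx) < 2) {
      abort(sprintf("Condition '%s' needs >= 2 trials for '%s'.",
                    condition, measure))
    }
    vals <- per_trial(measure)[idx]
    z <- if (transform == "after_averaging") fisher_z(mean(vals)) else mean(vals)
    tibble::tibble(condition = condition, measure = measure,
                   z = z, n_trials = sum(idx))
  })
  dplyr::bind_rows(rows)[, c("condition", "measure", "z", "n_trials")]
}

#' Per-subject similarity table
#'
#' Wraps [trial_measures()] with subject and ROI identifiers, producing the
#' tidy long table used by group-level analyses.
#'
#' @inheritParams trial_measures
#' @param subject Subject identifier.
#' @return Tibble `subject`, `roi`, `condition`, `measure`, `z`, `n_trials`.
#' @export
similarity_table <- function(set_init, set_emo, subject = 1L,
                             measures = c("pair_specific",
                                          "across_pair_within",
                                          "across_pair_between",
                                          "across_pair_combined",
                                          "within_encoding",
                                          "within_arousal"),
                             transform = c("after_averaging",
                                           "before_averaging")) {
  out <- trial_measures(set_init, set_emo, measures = measures,
                        transform = transform)
  dplyr::mutate(out, subject = subject, roi = set_init$roi,
                .before = 1)
}

#' Condition-level reactivation similarity
#'
#' Fisher-z similarity between one condition's initial-phase t-pattern and
#' its emotional-phase t-pattern (from condition-mode GLMs). Accepts either
#' two numeric pattern vectors, or two [fit_glm()] results together with the
#' condition (and presentation: the face-voice association regressor, or
#' the cue nuisance regressor) to extract.
#'
#' @param init,emo Numeric t-pattern vectors, or `glm_fit` objects fitted to
#'   multi-voxel data with condition-mode designs.
#' @param condition Condition label (required for `glm_fit` inputs).
#' @param presentation `"association"` or `"cue"` (which emotional-phase
#'   regressor to use for `glm_fit` inputs).
#' @return Fisher z value.
#' @export
condition_level_similarity <- function(init, emo, condition = NULL,
                                       presentation = c("association",
                                                        "cue")) {
  presentation <- match.arg(presentation)
  get_pattern <- function(fit, term) {
    if (!term %in% fit$terms) {
      abort(sprintf("Regressor '%s' not found in GLM fit.", term))
    }
    as.numeric(fit$t[term, ])
  }
  if (inherits(init, "glm_fit")) {
    if (is.null(condition)) abort("`condition` is required for glm_fit input.")
    init <- get_pattern(init, condition)
  }
  if (inherits(emo, "glm_fit")) {
    term <- if (presentation == "cue") paste0("cue_", condition) else condition
    emo <- get_pattern(emo, term)
  }
  if (length(init) != length(emo)) {
    abort("Patterns come from mismatched ROIs (different voxel counts).")
  }
  similarity_z(init, emo)
}
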