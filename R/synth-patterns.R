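#' Construct a pattern set
#'
#' A pattern set holds one multivoxel t-pattern per trial for one ROI and
#' phase, keyed by pair id.
#'
#' @param patterns Numeric matrix, trials in rows, voxels in columns.
#' @param meta Tibble with one row per trial; must contain `pair_id` and
#'   `condition`.
#' @param roi ROI label.
#' @param phase Phase label.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(patterns, meta, roi = "roi", phase = "initial") {
  patterns <- as.matrix(patterns)
  stopifnot(is.numeric(patterns), nrow(patterns) == nrow(meta),
            all(c("pair_id", "condition") %in% names(meta)))
  if (anyDuplicated(meta$pair_id)) {
    abort("`pair_id` must be unique within a pattern set.")
  }
  structure(list(patterns = patterns, meta = tibble::as_tibble(meta),
                 roi = roi, phase = phase),
            class = "pattern_set")
}

#' @exportS3Method base::print
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %s / %s, %d trials x %d voxels>\n",
              x$roi, x$phase, nrow(x$patterns), ncol(x$patterns)))
  invisible(x)
}

#' Simulate paired initial- and emotional-phase pattern sets
#'
#' Generates trial-wise multivoxel patterns with the structure the
#' reinstatement analyses assume. Each pair `p` has a unit-norm face
#' component `f_p` (present in both phases) and a unit-norm object component
#' `o_p`; each condition `c` has a shared unit-norm category component
#' `g_c`. The generative model is
#' \deqn{init(p) = f_p + o_p + \gamma g_c + \epsilon}
#' \deqn{emo(p) = f_p + \rho_c o_p + \gamma g_c + \epsilon}
#' with i.i.d. Gaussian voxel noise of SD `sigma_noise`. `rho_c` is the
#' condition's reinstatement gain: how strongly the initial object pattern
#' is re-expressed when the face is cued during emotional learning.
#'
#' @param design_init,design_emo `trial_design`s sharing the same pair ids.
#' @param params A [sim_params()] object (uses `n_voxels`, `rho_*`, `gamma`,
#'   `sigma_noise`, `seed`).
#' @return List with elements `init` and `emo`, both [pattern_set()]s with
#'   rows ordered by pair id.
#' @examples
#' s <- generate_session(sim_params(n_pairs = 12, n_aversive = 6, seed = 2))
#' ps <- simulate_pattern_sets(s$design_init1, s$design_emo,
#'                             sim_params(n_pairs = 12, n_aversive = 6,
#'                                        n_voxels = 40, seed = 2))
#' ps$emo
#' @export
simulate_pattern_sets <- function(design_init, design_emo,
                                  params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_voxels < 2) abort("Need at least 2 voxels per pattern.")

  meta_of <- function(d) dplyr::distinct(tibble::as_tibble(d)[c("pair_id", "condition")])
  mi <- dplyr::arrange(meta_of(design_init), .data$pair_id)
  me <- dplyr::arrange(meta_of(design_emo), .data$pair_id)
  if (!identical(mi$pair_id, me$pair_id) ||
      !identical(mi$condition, me$condition)) {
    abort("Initial and emotional designs must share pair ids and conditions.")
  }

  n <- nrow(mi)
  v <- params$n_voxels
  unitize <- function(m) m / sqrt(rowSums(m^2))

  with_seed(params$seed, {
    f <- unitize(matrix(rnorm(n * v), n, v))
    o <- unitize(matrix(rnorm(n * v), n, v))
    g <- unitize(matrix(rnorm(2 * v), 2, v))
    rownames(g) <- c("aversive", "neutral")
    gc <- g[mi$condition, , drop = FALSE]
    rho <- ifelse(mi$condition == "aversive",
                  params$rho_aversive, params$rho_neutral)
    init <- f + o + params$gamma * gc +
      params$sigma_noise * matrix(rnorm(n * v), n, v)
    emo <- f + rho * o + params$gamma * gc +
      params$sigma_noise * matrix(rnorm(n * v), n, v)
    rownames(init) <- rownames(emo) <- as.character(mi$pair_id)
  })

  list(
    init = pattern_set(init, mi, roi = "sim", phase = "initial"),
    emo = pattern_set(emo, me, roi = "sim", phase = "emotional")
  )
}

#' Simulate trial-level behaviour linked to reinstatement
#'
#' Memory accuracy follows a logistic link on pair-level reinstatement,
#' `P(correct) = plogis(beta0 + beta1 * reinstatement)`. Vividness and
#' confidence ratings are obtained by thresholding latent standard normals
#' correlated (`latent_cor`) with standardized reinstatement at the
#' equal-width cut points -1, 0, 1, giving ratings 1-4.
#'
#' @param design A `trial_design` providing pair ids and conditions.
#' @param reinstatement Numeric vector, one value per pair, in design pair
#'   order after sorting by `pair_id` (or named by pair id).
#' @param params A [sim_params()] object (`beta0`, `beta1`, `latent_cor`,
#'   `seed`).
#' @param subject Subject identifier stored in the table.
#' @return Tibble with columns `subject`, `pair_id`, `condition`,
#'   `vividness`, `confidence`, `chosen_correct`, `reinstatement`.
#' @export
simulate_behavior <- function(design, reinstatement, params = sim_params(),
                              subject = 1L) {
  stopifnot(inherits(params, "sim_params"))
  meta <- dplyr::arrange(
    dplyr::distinct(tibble::as_tibble(design)[c("pair_id", "condition")]),
    .data$pair_id)
  n <- nrow(meta)
  if (!is.null(names(reinstatement))) {
    reinstatement <- reinstatement[as.character(meta$pair_id)]
  }
  if (length(reinstatement) != n || anyNA(reinstatement)) {
    abort("`reinstatement` must supply one finite value per pair.")
  }

  p_correct <- plogis(params$beta0 + params$beta1 * reinstatement)
  r_std <- if (sd(reinstatement) > 0) {
    as.numeric(scale(reinstatement))
  } else {
    rep(0, n)
  }
  lc <- params$latent_cor
  cut_latent <- function(z) {
    as.integer(cut(z, breaks = c(-Inf, -1, 0, 1, Inf), labels = FALSE))
  }

  with_seed(params$seed, {
    correct <- rbinom(n, 1, p_correct) == 1
    lat_v <- lc * r_std + sqrt(1 - lc^2) * rnorm(n)
    lat_c <- lc * r_std + sqrt(1 - lc^2) * rnorm(n)
  })

  tibble::tibble(
    subject = subject,
    pair_id = meta$pair_id,
    condition = meta$condition,
    vividness = cut_latent(lat_v),
    confidence = cut_latent(lat_c),
    chosen_correct = correct,
    reinstatement = unname(reinstatement)
  )
}

#' Simulate a subject-level table from a serial path model
#'
#' Generates `X -> M1 -> M2 -> Y` data with all lower-order paths:
#' `X ~ N(0,1)`, `M1 = a1 X + e`, `M2 = a2 X + d21 M1 + e`,
#' `Y = cp X + b1 M1 + b2 M2 + e`, errors i.i.d. `N(0, noise^2)`.
#'
#' @param n_subjects Number of rows.
#' @param paths Named list of path coefficients `a1`, `a2`, `d21`, `b1`,
#'   `b2`, `cp`; missing entries default to 0.
#' @param noise Error SD (applied to each equation).
#' @param seed Integer RNG seed.
#' @param standardize If `TRUE`, z-score each column.
#' @return Tibble with columns `subject`, `X`, `M1`, `M2`, `Y`.
#' @examples
#' simulate_subject_table(5, list(a1 = 0.5, d21 = 0.4, b2 = 0.5), seed = 9)
#' @export
simulate_subject_table <- function(n_subjects, paths = list(), noise = 1,
                                   seed = 1L, standardize = FALSE) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  assert_scalar_number(noise, "noise", lower = 0)
  p <- utils::modifyList(
    list(a1 = 0, a2 = 0, d21 = 0, b1 = 0, b2 = 0, cp = 0), paths)
  n <- as.integer(n_subjects)
  dat <- with_seed(seed, {
    X <- rnorm(n)
    M1 <- p$a1 * X + noise * rnorm(n)
    M2 <- p$a2 * X + p$d21 * M1 + noise * rnorm(n)
    Y <- p$cp * X + p$b1 * M1 + p$b2 * M2 + noise * rnorm(n)
    tibble::tibble(subject = seq_len(n), X = X, M1 = M1, M2 = M2, Y = Y)
  })
  if (standardize) {
    dat <- dplyr::mutate(dat, dplyr::across(c("X", "M1", "M2", "Y"),
                                            ~ as.numeric(scale(.x))))
  }
  dat
}
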