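#' Simulate seed/target BOLD time series for a session
#'
#' Generates, per run, a seed series driven by HRF-convolved task boxcars
#' plus noise and a target series coupled to the seed with a
#' condition-dependent gain, matching the generative structure the gPPI
#' analysis estimates. At the neural level the seed is a stimulus boxcar
#' plus white fluctuations `n(t)`; the target's neural signal is
#' `coupling_baseline * n(t)` plus `coupling_c * n(t)` restricted to
#' condition-`c` stimulus epochs. Both are convolved with the canonical HRF
#' and observed with white measurement noise. Rest runs are generated as
#' Gaussian pairs with population correlation `rest_r`; confound series
#' (six motion-like + CSF + WM) are slow sinusoidal drifts plus white
#' noise.
#'
#' @param session A session list from [generate_session()] (or a list with
#'   any subset of `design_init1`, `design_init2`, `design_emo`, `rest`).
#' @param params A [sim_params()] object.
#' @param n_volumes Named volumes per task run; defaults
#'   `c(init1 = 365, init2 = 365, emo = 508)`, the scan lengths the design
#'   emulates.
#' @param noise_sd Measurement noise SD on seed and target.
#' @param neural_sd SD of the neural fluctuations multiplied into the PPI
#'   coupling. Fluctuations are temporally smooth (Gaussian-filtered white
#'   noise, 2-TR width), so they survive the haemodynamic low-pass and can
#'   be recovered by deconvolution.
#' @return A `ts_bundle`: named list of runs, each with `run`, `phase`,
#'   `seed_ts`, `target_ts`, `confounds` (matrix), `design` (or `NULL`),
#'   `tr`, `n_volumes`.
#' @export
simulate_timeseries <- function(session, params = sim_params(),
                                n_volumes = c(init1 = 365, init2 = 365,
                                              emo = 508),
                                noise_sd = 0.3, neural_sd = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (any(n_volumes < 0)) abort("`n_volumes` must be non-negative.")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(neural_sd, "neural_sd", lower = 0)
  tr <- params$tr
  kernel <- canonical_hrf(tr, oversampling = 1L)$values

  task_runs <- list(init1 = session$design_init1,
                    init2 = session$design_init2,
                    emo = session$design_emo)
  task_runs <- task_runs[!vapply(task_runs, is.null, logical(1))]
  seeds <- derive_seeds(params$seed + 7L, length(task_runs) + 3L)
  runs <- list()

  for (i in seq_along(task_runs)) {
    nm <- names(task_runs)[i]
    design <- task_runs[[i]]
    nv <- as.integer(if (nm %in% names(n_volumes)) n_volumes[[nm]] else
                       ceiling(total_duration(design) / tr))
    if (total_duration(design) > nv * tr + 1e-9) {
      abort(sprintf("Run '%s' (%g s) exceeds %d volumes at TR %g s.",
                    nm, total_duration(design), nv, tr))
    }
    box <- condition_boxcars(design, tr, nv)
    box_all <- as.numeric(rowSums(box) > 0)

    runs[[nm]] <- with_seed(seeds[i], {
      neural <- box_all + neural_sd * smooth_noise(nv)
      seed_bold <- convolve_hrf(neural, kernel)
      coup <- c(aversive = params$coupling_aversive,
                neutral = params$coupling_neutral)
      target_neural <- params$coupling_baseline * neural
      for (cond in colnames(box)) {
        target_neural <- target_neural + coup[[cond]] * neural * box[, cond]
      }
      list(run = nm,
           phase = attr(design, "phase"),
           seed_ts = seed_bold + noise_sd * rnorm(nv),
           target_ts = convolve_hrf(target_neural, kernel) +
             noise_sd * rnorm(nv),
           confounds = sim_confounds(nv, tr),
           design = design, tr = tr, n_volumes = nv)
    })
  }

  rest_tbl <- session$rest
  if (!is.null(rest_tbl)) {
    for (j in seq_len(nrow(rest_tbl))) {
      nm <- rest_tbl$run[j]
      nv <- as.integer(rest_tbl$n_volumes[j])
      if (nv < 0) abort("`n_volumes` must be non-negative.")
      runs[[nm]] <- with_seed(seeds[length(task_runs) + j], {
        u <- rnorm(nv)
        v <- rnorm(nv)
        list(run = nm, phase = "rest",
             seed_ts = u,
             target_ts = params$rest_r * u + sqrt(1 - params$rest_r^2) * v,
             confounds = sim_confounds(nv, tr),
             design = NULL, tr = tr, n_volumes = nv)
      })
    }
  }

  structure(runs, class = "ts_bundle")
}

# Unit-SD temporally smooth noise: white noise filtered with a Gaussian FIR
# kernel (SD in samples). Neural fluctuations below the haemodynamic
# low-pass would be unidentifiable; smooth fluctuations keep the gPPI
# ground truth recoverable.
smooth_noise <- function(n, sd_samples = 2) {
  if (n == 0) return(numeric(0))
  k <- dnorm(seq(-3 * sd_samples, 3 * sd_samples), sd = sd_samples)
  k <- k / sum(k)
  pad <- length(k)
  x <- stats::filter(rnorm(n + 2 * pad), k, sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, n))
  as.numeric((x - mean(x)) / s)
}

# Condition-wise stimulus boxcars at TR resolution (n_volumes x conditions).
condition_boxcars <- function(design, tr, n_volumes) {
  events <- tibble::as_tibble(design)
  stim <- dplyr::filter(events, !.data$event_kind %in% c("cue", "rating"))
  conds <- sort(unique(stim$condition))
  out <- matrix(0, n_volumes, length(conds),
                dimnames = list(NULL, conds))
  t_vol <- (seq_len(n_volumes) - 1) * tr
  for (ci in seq_along(conds)) {
    e <- stim[stim$condition == conds[ci], ]
    for (r in seq_len(nrow(e))) {
      on <- t_vol >= e$onset[r] & t_vol < e$onset[r] + e$duration[r]
      out[on, ci] <- 1
    }
  }
  out
}

# Eight nuisance series: slow sinusoidal drifts plus white noise, labelled
# like a motion + CSF + WM confound set.
sim_confounds <- function(n_volumes, tr) {
  t <- (seq_len(n_volumes) - 1) * tr
  labs <- c(paste0("motion_", 1:6), "csf", "wm")
  m <- vapply(labs, function(l) {
    f <- runif(1, 0.003, 0.015)
    amp <- runif(1, 0.2, 1)
    amp * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
      0.1 * rnorm(n_volumes)
  }, numeric(n_volumes))
  colnames(m) <- labs
  m
}

#' @exportS3Method base::print
print.ts_bundle <- function(x, ...) {
  cat(sprintf("<ts_bundle: %d runs>\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-6s %-9s %4d volumes (TR %.1f s)\n",
                r$run, r$phase, r$n_volumes, r$tr))
  }
  invisible(x)
}
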