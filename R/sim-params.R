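#' Simulation parameters for the synthetic study generator
#'
#' Collects the free parameters of the synthetic-data generator in one
#' validated object. Defaults reproduce the study design the generator
#' emulates: 72 face-object pairs, half assigned to an aversive and half to a
#' neutral condition, with stronger reinstatement of the initial object
#' pattern during emotional learning in the aversive condition.
#'
#' @param n_pairs Number of stimulus pairs (trials per phase). Default 72.
#' @param n_aversive Number of pairs in the aversive condition. Default 36.
#' @param n_voxels Voxels per simulated ROI pattern. Default 120.
#' @param rho_aversive,rho_neutral Reinstatement gain in `[0, 1]`: the weight
#'   with which the initial-phase object component is re-expressed in the
#'   emotional-phase pattern, per condition. Defaults 0.8 / 0.2.
#' @param gamma Loading of the condition-shared (category) component, `>= 0`.
#' @param sigma_noise Standard deviation of i.i.d. Gaussian voxel noise.
#' @param coupling_aversive,coupling_neutral Condition-specific seed-to-target
#'   coupling gains used by [simulate_timeseries()].
#' @param coupling_baseline Condition-independent seed-to-target coupling.
#' @param beta0,beta1 Intercept and slope of the logistic link from
#'   pair-level reinstatement to memory accuracy in [simulate_behavior()].
#' @param latent_cor Correlation between reinstatement and the latent normal
#'   that is thresholded into vividness/confidence ratings, in `[-1, 1]`.
#' @param tr Repetition time in seconds. Default 2.
#' @param rest_volumes Volumes per rest run. Default 240 (8 min at TR 2 s).
#' @param rest_r Population seed-target correlation during rest runs.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_voxels = 50, seed = 1)
#' p$rho_aversive
#' @export
sim_params <- function(n_pairs = 72L,
                       n_aversive = 36L,
                       n_voxels = 120L,
                       rho_aversive = 0.8,
                       rho_neutral = 0.2,
                       gamma = 0.5,
                       sigma_noise = 0.25,
                       coupling_aversive = 0.7,
                       coupling_neutral = 0.2,
                       coupling_baseline = 0.3,
                       beta0 = 0,
                       beta1 = 2,
                       latent_cor = 0.4,
                       tr = 2,
                       rest_volumes = 240L,
                       rest_r = 0.3,
                       seed = 1L) {
  assert_scalar_number(n_pairs, "n_pairs", lower = 1)
  assert_scalar_number(n_aversive, "n_aversive", lower = 0)
  if (n_aversive > n_pairs) abort("`n_aversive` must not exceed `n_pairs`.")
  assert_scalar_number(n_voxels, "n_voxels", lower = 2)
  assert_scalar_number(rho_aversive, "rho_aversive", 0, 1)
  assert_scalar_number(rho_neutral, "rho_neutral", 0, 1)
  assert_scalar_number(gamma, "gamma", lower = 0)
  assert_scalar_number(sigma_noise, "sigma_noise", lower = 0)
  assert_scalar_number(coupling_aversive, "coupling_aversive")
  assert_scalar_number(coupling_neutral, "coupling_neutral")
  assert_scalar_number(coupling_baseline, "coupling_baseline")
  assert_scalar_number(beta0, "beta0")
  assert_scalar_number(beta1, "beta1")
  assert_scalar_number(latent_cor, "latent_cor", -1, 1)
  assert_scalar_number(tr, "tr", lower = 1e-6)
  assert_scalar_number(rest_volumes, "rest_volumes", lower = 1)
  assert_scalar_number(rest_r, "rest_r", -1, 1)
  assert_scalar_number(seed, "seed")

  structure(
    list(
      n_pairs = as.integer(n_pairs), n_aversive = as.integer(n_aversive),
      n_voxels = as.integer(n_voxels),
      rho_aversive = rho_aversive, rho_neutral = rho_neutral,
      gamma = gamma, sigma_noise = sigma_noise,
      coupling_aversive = coupling_aversive,
      coupling_neutral = coupling_neutral,
      coupling_baseline = coupling_baseline,
      beta0 = beta0, beta1 = beta1, latent_cor = latent_cor,
      tr = tr, rest_volumes = as.integer(rest_volumes), rest_r = rest_r,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @exportS3Method base::print
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  pairs: %d (%d aversive / %d neutral), %d voxels\n",
              x$n_pairs, x$n_aversive, x$n_pairs - x$n_aversive, x$n_voxels))
  cat(sprintf("  reinstatement rho: aversive %.2f, neutral %.2f; gamma %.2f; noise SD %.2f\n",
              x$rho_aversive, x$rho_neutral, x$gamma, x$sigma_noise))
  cat(sprintf("  coupling: baseline %.2f, aversive %.2f, neutral %.2f\n",
              x$coupling_baseline, x$coupling_aversive, x$coupling_neutral))
  cat(sprintf("  memory link: logit(p) = %.2f + %.2f * reinstatement\n",
              x$beta0, x$beta1))
  cat(sprintf("  TR %.1f s, %d rest volumes, seed %d\n", x$tr, x$rest_volumes, x$seed))
  invisible(x)
}
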