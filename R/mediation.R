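#' Fit the serial two-mediator path model
#'
#' Fits the recursive OLS system `M1 ~ X`, `M2 ~ X + M1`,
#' `Y ~ X + M1 + M2` (plus `Y ~ X` for the total effect), by default on
#' standardized variables so coefficients are path weights. The model is
#' the serial topology used to ask whether seed-amygdala coupling acts on
#' memory through seed-neocortex couplings: indirect effects `a1*b1`
#' (through M1), `a2*b2` (through M2) and the serial product `a1*d21*b2`
#' are returned, and the total effect decomposes exactly as
#' `c = c' + a1*b1 + a2*b2 + a1*d21*b2`.
#'
#' @param data Data frame containing the four variables.
#' @param x,m1,m2,y Column names (defaults `"X"`, `"M1"`, `"M2"`, `"Y"`).
#' @param standardize Standardize variables before fitting (default TRUE).
#' @return A `path_model`: list with `coefficients` (a1, a2, d21, b1, b2,
#'   cp, c), `indirect` (m1, m2, serial, total), `r_squared`, `n`,
#'   `standardized`.
#' @examples
#' d <- simulate_subject_table(200, list(a1 = .5, d21 = .4, b2 = .5), seed = 2)
#' fit_paths(d)
#' @export
fit_paths <- function(data, x = "X", m1 = "M1", m2 = "M2", y = "Y",
                      standardize = TRUE) {
  cols <- c(x, m1, m2, y)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  M <- as.matrix(data[, cols])
  if (nrow(M) < 10) abort("Need at least 10 observations.")
  if (anyNA(M) || any(!is.finite(M))) abort("Data must be finite.")
  if (any(apply(M, 2, sd) == 0)) abort("Zero-variance variable supplied.")

  out <- .fit_paths_mat(M, standardize)
  out$n <- nrow(M)
  out$standardized <- standardize
  out$variables <- setNames(cols, c("x", "m1", "m2", "y"))
  class(out) <- "path_model"
  out
}

# Core fit from an n x 4 matrix (X, M1, M2, Y) via its (co)variance matrix.
.fit_paths_mat <- function(M, standardize = TRUE) {
  S <- if (standardize) cor(M) else cov(M)
  a1 <- S[1, 2] / S[1, 1]
  cf2 <- solve(S[1:2, 1:2], S[1:2, 3])
  cf3 <- solve(S[1:3, 1:3], S[1:3, 4])
  ctot <- S[1, 4] / S[1, 1]
  coefs <- c(a1 = a1, a2 = cf2[[1]], d21 = cf2[[2]],
             cp = cf3[[1]], b1 = cf3[[2]], b2 = cf3[[3]], c = ctot)
  r2 <- c(
    m1 = (a1 * S[1, 2]) / S[2, 2],
    m2 = sum(cf2 * S[1:2, 3]) / S[3, 3],
    y = sum(cf3 * S[1:3, 4]) / S[4, 4]
  )
  indirect <- c(
    m1 = coefs[["a1"]] * coefs[["b1"]],
    m2 = coefs[["a2"]] * coefs[["b2"]],
    serial = coefs[["a1"]] * coefs[["d21"]] * coefs[["b2"]]
  )
  indirect["total"] <- sum(indirect)
  list(coefficients = coefs, indirect = indirect, r_squared = r2)
}

#' @exportS3Method base::print
print.path_model <- function(x, ...) {
  cat(sprintf("<path_model: serial X -> M1 -> M2 -> Y, n = %d%s>\n", x$n,
              if (x$standardized) ", standardized" else ""))
  cf <- x$coefficients
  cat(sprintf("  a1 (X->M1) = %.3f   a2 (X->M2) = %.3f   d21 (M1->M2) = %.3f\n",
              cf["a1"], cf["a2"], cf["d21"]))
  cat(sprintf("  b1 (M1->Y) = %.3f   b2 (M2->Y) = %.3f   c' = %.3f   c = %.3f\n",
              cf["b1"], cf["b2"], cf["cp"], cf["c"]))
  cat(sprintf("  indirect: via M1 %.3f, via M2 %.3f, serial %.3f, total %.3f\n",
              x$indirect["m1"], x$indirect["m2"], x$indirect["serial"],
              x$indirect["total"]))
  invisible(x)
}

#' @rdname fit_paths
#' @param x A `path_model`.
#' @param ... Unused.
#' @export
tidy.path_model <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    term = c("a1", "a2", "d21", "b1", "b2", "cp", "c",
             paste0("indirect_", names(x$indirect))),
    estimate = c(unname(cf[c("a1", "a2", "d21", "b1", "b2", "cp", "c")]),
                 unname(x$indirect))
  )
}

#' @rdname fit_paths
#' @export
glance.path_model <- function(x, ...) {
  tibble::tibble(r.squared.m1 = x$r_squared[["m1"]],
                 r.squared.m2 = x$r_squared[["m2"]],
                 r.squared.y = x$r_squared[["y"]],
                 n = x$n, standardized = x$standardized)
}

#' Bias-corrected bootstrap confidence intervals for indirect effects
#'
#' Case-resampling bootstrap of [fit_paths()]. For each indirect effect the
#' bias-corrected (BC, not accelerated) percentile interval is returned:
#' `z0` is the normal quantile of the proportion of bootstrap estimates
#' below the point estimate, and the interval endpoints are the bootstrap
#' quantiles at `pnorm(2*z0 +/- qnorm(1 - alpha/2))`. Resamples in which a
#' variable degenerates to zero variance are redrawn and counted.
#'
#' @inheritParams fit_paths
#' @param n_boot Number of bootstrap resamples (`>= 100`).
#' @param seed Integer RNG seed.
#' @param level Confidence level (default 0.95).
#' @return An `indirect_effects` tibble: `effect`, `estimate`, `ci_lower`,
#'   `ci_upper`, `z0`, `excludes_zero`, with attributes `n_boot`, `seed`,
#'   `n_redrawn` and the bootstrap draws in `attr(, "boot")`.
#' @examples
#' d <- simulate_subject_table(60, list(a1 = .5, d21 = .4, b2 = .5), seed = 3)
#' bootstrap_indirect(d, n_boot = 200, seed = 1)
#' @export
bootstrap_indirect <- function(data, n_boot = 1000L, seed = 1L,
                               x = "X", m1 = "M1", m2 = "M2", y = "Y",
                               standardize = TRUE, level = 0.95) {
  assert_scalar_number(n_boot, "n_boot", lower = 100)
  assert_scalar_number(level, "level", lower = 0.5, upper = 1 - 1e-9)
  n_boot <- as.integer(n_boot)
  point <- fit_paths(data, x, m1, m2, y, standardize = standardize)
  M <- as.matrix(data[, c(x, m1, m2, y)])
  n <- nrow(M)

  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("m1", "m2", "serial", "total")))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n, replace = TRUE)
        Mb <- M[idx, , drop = FALSE]
        if (all(apply(Mb, 2, sd) > 0)) break
        n_redrawn <- n_redrawn + 1L
        if (attempt == 100L) abort("Could not draw a non-degenerate resample.")
      }
      boot[b, ] <- .fit_paths_mat(Mb, standardize)$indirect
    }
  })

  alpha <- 1 - level
  zc <- qnorm(1 - alpha / 2)
  rows <- purrr::map(colnames(boot), function(eff) {
    est <- point$indirect[[eff]]
    bvals <- boot[, eff]
    prop <- mean(bvals < est)
    prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
    z0 <- qnorm(prop)
    probs <- pnorm(c(2 * z0 - zc, 2 * z0 + zc))
    ci <- unname(quantile(bvals, probs))
    tibble::tibble(effect = eff, estimate = est,
                   ci_lower = ci[1], ci_upper = ci[2], z0 = z0,
                   excludes_zero = ci[1] > 0 | ci[2] < 0)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "boot") <- boot
  class(out) <- c("indirect_effects", class(out))
  out
}
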