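test_that("balanced folds are rank-stratified with near-equal sizes", {
  withr::with_seed(41, y <- rnorm(28))
  f <- balanced_folds(y, k = 4, seed = 1)
  expect_equal(sort(as.vector(table(f))), rep(7L, 4))
  expect_identical(f, balanced_folds(y, k = 4, seed = 1))

  f8 <- balanced_folds(rnorm(8), k = 4, seed = 2)
  expect_equal(as.vector(table(f8)), rep(2L, 4))

  # uneven n: sizes differ by at most one
  f10 <- balanced_folds(rnorm(10), k = 4, seed = 3)
  expect_lte(diff(range(table(f10))), 1)
  expect_error(balanced_folds(rnorm(3), k = 4), "at least")
})

test_that("rank-stratified folds balance the outcome better than random folds", {
  withr::with_seed(42, y <- rnorm(28))
  spread <- function(f) diff(range(tapply(y, f, mean)))
  strat <- vapply(1:200, function(s) spread(balanced_folds(y, 4, seed = s)),
                  numeric(1))
  rand <- vapply(1:200, function(s) {
    spread(withr::with_seed(s, sample(rep(1:4, 7))))
  }, numeric(1))
  expect_lt(mean(strat), mean(rand))
})

test_that("cross-validated prediction is exact on perfect linear signal", {
  withr::with_seed(43, x <- rnorm(28))
  expect_gte(cv_predict_r(x, 2 * x, seed = 1)$r, 0.999)
  expect_gte(cv_predict_r(x, -x, seed = 1)$r, 0.999)  # sign is learned
  expect_error(cv_predict_r(rep(1, 28), rnorm(28), seed = 1),
               "Zero-variance")
  expect_error(cv_predict_r(rnorm(6), rnorm(6), k = 4), "at least")
})

test_that("cv prediction r is invariant to affine transforms of the predictor", {
  withr::with_seed(44, {
    x <- rnorm(28)
    y <- 0.5 * x + rnorm(28)
  })
  r1 <- cv_predict_r(x, y, seed = 9)$r
  r2 <- cv_predict_r(3.2 * x - 7, y, seed = 9)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("under the null the cv correlation is slightly negative, not inflated", {
  # r(predicted, observed) from refit-per-fold regression is negatively
  # biased under independence; it must never be systematically positive
  rs <- vapply(1:500, function(sd_) {
    withr::with_seed(sd_, {
      x <- rnorm(28); y <- rnorm(28)
    })
    cv_predict_r(x, y, seed = sd_)$r
  }, numeric(1))
  expect_lt(mean(rs), 0.02)
  expect_gt(mean(rs), -0.2)
})

test_that("permutation inference is deterministic and detects strong signal", {
  withr::with_seed(45, x <- rnorm(28))
  y <- 2 * x
  p1 <- permutation_p(x, y, n_perm = 1000, seed = 3)
  p2 <- permutation_p(x, y, n_perm = 1000, seed = 3)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_identical(p1$r_perm, p2$r_perm)
  expect_lte(p1$p_perm, 0.01)
  expect_equal(p1$n_perm, 1000)

  # add-one variant is bounded away from zero
  p3 <- permutation_p(x, y, n_perm = 100, seed = 3, add_one = TRUE)
  expect_gte(p3$p_perm, 1 / 101)
  expect_error(permutation_p(x, y, n_perm = 0), "must be in")
})

test_that("null permutation p values are stochastically uniform", {
  ps <- vapply(1:400, function(sd_) {
    withr::with_seed(sd_ + 9000, {
      x <- rnorm(28); y <- rnorm(28)
    })
    permutation_p(x, y, n_perm = 100, seed = sd_)$p_perm
  }, numeric(1))
  # p values sit on the 1/n_perm lattice; KS tie warning is expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Steiger's z is zero at equality and antisymmetric", {
  aux <- c(r13 = 0.3, r14 = 0.2, r23 = 0.25, r24 = 0.35)
  eq <- steiger_z(0.4, 0.4, aux, n = 28)
  expect_equal(eq$z, 0)
  expect_equal(eq$p.value, 1)

  a <- steiger_z(0.5, 0.2, aux, n = 28)
  b <- steiger_z(0.2, 0.5, aux, n = 28)
  expect_equal(a$z, -b$z)
  expect_equal(a$p.value, b$p.value)

  expect_error(steiger_z(1, 0.2, aux, n = 28), "absolute value")
  bad <- c(r13 = 0.99, r14 = -0.99, r23 = 0.99, r24 = 0.99)
  expect_error(steiger_z(0.9, -0.9, bad, n = 28), "non-PSD")
})

test_that("Steiger's test is calibrated for equal population correlations", {
  skip_if_not_installed("MASS")
  rho <- 0.4
  Sigma <- diag(4)
  Sigma[1, 2] <- Sigma[2, 1] <- rho
  Sigma[3, 4] <- Sigma[4, 3] <- rho
  Sigma[1, 3] <- Sigma[3, 1] <- 0.3
  Sigma[2, 4] <- Sigma[4, 2] <- 0.3
  Sigma[1, 4] <- Sigma[4, 1] <- 0.2
  Sigma[2, 3] <- Sigma[3, 2] <- 0.2
  withr::with_seed(46, {
    rej <- replicate(10000, {
      m <- MASS::mvrnorm(60, rep(0, 4), Sigma)
      R <- cor(m)
      steiger_z(R[1, 2], R[3, 4],
                c(r13 = R[1, 3], r14 = R[1, 4],
                  r23 = R[2, 3], r24 = R[2, 4]), n = 60)$p.value < 0.05
    })
  })
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("steiger_test computes its correlations from data columns", {
  withr::with_seed(47, {
    d <- tibble::tibble(x1 = rnorm(40))
    d$y1 <- 0.6 * d$x1 + rnorm(40)
    d$x2 <- rnorm(40)
    d$y2 <- rnorm(40)
  })
  st <- steiger_test(d, "x1", "y1", "x2", "y2")
  expect_equal(st$r1, cor(d$x1, d$y1))
  expect_equal(st$r2, cor(d$x2, d$y2))
  expect_gt(st$z, 0)
})
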