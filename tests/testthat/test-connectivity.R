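test_that("deconvolution inverts the HRF on noise-free input", {
  tr <- 2
  n <- 120
  withr::with_seed(51, {
    neural <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4),
                                       sides = 2))
  })
  neural[is.na(neural)] <- 0
  neural[(n - 16):n] <- 0  # HRF starts at zero: the tail is unobservable
  bold <- convolve_hrf(neural, canonical_hrf(tr, 1)$values)
  est <- deconvolve_neural(bold, tr, ridge_lambda = 1e-8)
  rms <- sqrt(mean((est - neural)^2)) / sd(neural)
  expect_lt(rms, 0.01)

  expect_equal(deconvolve_neural(rep(0, 50), tr, ridge_lambda = 1e-4),
               rep(0, 50), ignore_attr = TRUE)
  expect_error(deconvolve_neural(rnorm(20), tr, ridge_lambda = -1),
               "non-negative")
})

test_that("ridge shrinkage is monotone in lambda and the round trip closes", {
  tr <- 2
  withr::with_seed(52, seed_ts <- rnorm(100))
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    sum(deconvolve_neural(seed_ts, tr, ridge_lambda = l)^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))

  # deconvolve then convolve reproduces a haemodynamic (in-range) series
  # as lambda -> 0
  kernel <- canonical_hrf(tr, 1)$values
  bold <- convolve_hrf(seed_ts, kernel)
  err <- vapply(c(1, 1e-2, 1e-4, 1e-6), function(l) {
    est <- deconvolve_neural(bold, tr, ridge_lambda = l)
    sqrt(mean((convolve_hrf(est, kernel) - bold)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[4] / sd(bold), 0.01)
})

test_that("gPPI designs contain the published column structure", {
  n <- 60
  withr::with_seed(53, {
    neural <- rnorm(n)
    seed_ts <- rnorm(n)
  })
  box <- matrix(0, n, 2, dimnames = list(NULL, c("aversive", "neutral")))
  box[5:10, 1] <- 1
  box[20:25, 2] <- 1
  des <- build_gppi_design(neural, box, seed_ts, tr = 2)
  expect_setequal(colnames(des),
                  c("ppi_aversive", "ppi_neutral", "psych_aversive",
                    "psych_neutral", "physio", "constant"))

  box4 <- cbind(box, m1 = 0, m2 = 0)
  box4[30:35, "m1"] <- 1
  box4[40:45, "m2"] <- 1
  des4 <- build_gppi_design(neural, box4, seed_ts, tr = 2)
  expect_equal(sum(grepl("^ppi_", colnames(des4))), 4)

  empty <- box; empty[, 2] <- 0
  expect_error(build_gppi_design(neural, empty, seed_ts, tr = 2),
               "all-zero.*neutral")
  overlap <- box; overlap[5:10, 2] <- 1
  expect_error(build_gppi_design(neural, overlap, seed_ts, tr = 2),
               "overlap")
})

test_that("planted coupling differences are recovered by the gPPI fit", {
  contrasts <- vapply(1:30, function(sd_) {
    p <- small_params(seed = sd_, n_pairs = 24L, n_aversive = 12L,
                      coupling_aversive = 0.7, coupling_neutral = 0.2)
    s <- generate_session(p)
    b <- simulate_timeseries(s["design_emo"], p, n_volumes = c(emo = 172))
    gppi_run(b$emo, ridge_lambda = "gcv")$contrast
  }, numeric(1))
  expect_gte(mean(contrasts > 0), 0.95)
  expect_lt(abs(mean(contrasts) - 0.5), 0.125)  # within 25 % of the truth
})

test_that("equal condition couplings give an unbiased null contrast", {
  contrasts <- vapply(1:60, function(sd_) {
    p <- small_params(seed = sd_ + 300, n_pairs = 24L, n_aversive = 12L,
                      coupling_aversive = 0.4, coupling_neutral = 0.4)
    s <- generate_session(p)
    b <- simulate_timeseries(s["design_emo"], p, n_volumes = c(emo = 172))
    gppi_run(b$emo, ridge_lambda = "gcv")$contrast
  }, numeric(1))
  expect_lt(abs(mean(contrasts)),
            2 * sd(contrasts) / sqrt(length(contrasts)))
})

test_that("memory-cell gPPI reproduces a planted cell ordering", {
  p <- small_params(seed = 57, n_pairs = 24L, n_aversive = 12L)
  s <- generate_session(p)
  nv <- 180
  tr <- 2
  design <- s$design_emo
  withr::with_seed(57, {
    behavior <- tibble::tibble(
      pair_id = 1:24,
      confidence = rep(c(4, 1), 12),
      chosen_correct = rep(c(TRUE, FALSE), 12))
    box <- memory_cell_boxcars(design, behavior, tr, nv)
    neural <- as.numeric(rowSums(box) > 0) + rnorm(nv)
    kernel <- canonical_hrf(tr, 1)$values
    gains <- c(remembered_hc_aversive = 0.9, forgotten_aversive = 0.5,
               remembered_hc_neutral = 0.3, forgotten_neutral = 0.1)
    tn <- 0.2 * neural
    for (cell in colnames(box)) {
      tn <- tn + gains[[cell]] * neural * box[, cell]
    }
    target <- convolve_hrf(tn, kernel) + 0.1 * rnorm(nv)
  })
  des <- build_gppi_design(neural, box, convolve_hrf(neural, kernel),
                           tr = tr)
  w <- setNames(c(1, -1, 0, 0) / 1,
                paste0("ppi_", c("remembered_hc_aversive",
                                 "forgotten_aversive",
                                 "remembered_hc_neutral",
                                 "forgotten_neutral")))
  est <- fit_gppi_contrast(target, des, contrast_weights = w)
  expect_equal(names(sort(est$beta, decreasing = TRUE)),
               paste0("ppi_", names(sort(gains, decreasing = TRUE))))
  expect_equal(nrow(memory_cell_boxcars(design, behavior, tr, nv)), nv)
})

test_that("the rest band-pass keeps in-band and removes out-of-band signal", {
  tr <- 2
  t <- (0:239) * tr
  in_band <- sin(2 * pi * 0.05 * t)
  out_band <- sin(2 * pi * 0.2 * t)
  f_in <- preprocess_rest(in_band, NULL, tr = tr)
  f_out <- preprocess_rest(out_band, NULL, tr = tr)
  expect_gte(sd(f_in) / sd(in_band), 0.9)
  expect_lte(sd(f_out) / sd(out_band), 0.1)

  f_const <- preprocess_rest(rep(3, 240), NULL, tr = tr)
  expect_lt(max(abs(f_const)), 1e-8)
  expect_error(preprocess_rest(rnorm(100), NULL, band = c(0.05, 0.3),
                               tr = tr), "Nyquist")
  expect_error(preprocess_rest(rnorm(100), NULL, band = c(0, 0.1),
                               tr = tr), "Nyquist")
})

test_that("confound regression removes filtered nuisance signal", {
  tr <- 2
  withr::with_seed(58, {
    conf <- matrix(rnorm(240 * 2), 240, 2)
    ts <- 0.8 * conf[, 1] + rnorm(240, 0, 0.1)
  })
  clean <- preprocess_rest(ts, conf, tr = tr)
  fc <- preprocess_rest(conf[, 1], NULL, tr = tr)
  expect_lt(abs(cor(clean, fc)), 0.05)
  expect_lt(abs(mean(clean)), 1e-8)
})

test_that("seed connectivity reports clipped Fisher z per target", {
  withr::with_seed(59, x <- rnorm(200))
  self <- seed_connectivity(x, x)
  expect_equal(self$z, atanh(1 - 1e-7))

  t2 <- (0:199) / 10
  a <- sin(2 * pi * t2 / 20)
  b <- cos(2 * pi * t2 / 20)
  expect_equal(seed_connectivity(a, b)$z, 0, tolerance = 1e-10)

  zs <- vapply(1:60, function(sd_) {
    withr::with_seed(sd_, {
      u <- rnorm(240)
      v <- 0.6 * u + sqrt(1 - 0.36) * rnorm(240)
    })
    seed_connectivity(u, v)$z
  }, numeric(1))
  expect_gte(mean(abs(zs - atanh(0.6)) <= 2 / sqrt(240 - 3)), 0.9)
})

test_that("rest difference maps subtract element-wise and are antisymmetric", {
  a <- c(x = 0.5, y = -0.2, z = 0.1)
  b <- c(x = 0.1, y = 0.1, z = 0.1)
  expect_equal(rest_difference(a, b), c(x = 0.4, y = -0.3, z = 0))
  expect_equal(rest_difference(a, b), -rest_difference(b, a))
  expect_equal(rest_difference(a, a), c(x = 0, y = 0, z = 0))
  expect_error(rest_difference(a, b[1:2]), "identical shape")

  ta <- tibble::tibble(target = c("p", "q"), r = c(0.4, 0.1),
                       z = atanh(c(0.4, 0.1)))
  tb <- tibble::tibble(target = c("p", "q"), r = c(0.2, 0.1),
                       z = atanh(c(0.2, 0.1)))
  expect_equal(rest_difference(ta, tb)$z_diff,
               atanh(c(0.4, 0.1)) - atanh(c(0.2, 0.1)))
})

test_that("group regression recovers a planted memory-condition interaction", {
  hits <- vapply(1:60, function(sd_) {
    withr::with_seed(sd_, {
      memA <- runif(28, 0.4, 0.9)
      memN <- runif(28, 0.4, 0.9)
      d <- 0.5 * memA - 0.5 * memN + rnorm(28, 0, 0.05)
    })
    group_interaction_regression(d, memA, memN)$contrast > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group regression is calibrated under independence", {
  rej <- vapply(1:1000, function(sd_) {
    withr::with_seed(sd_ + 4000, {
      memA <- rnorm(28)
      memN <- rnorm(28)
      d <- rnorm(28)
    })
    group_interaction_regression(d, memA, memN)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("group regression guards its preconditions and absorbs constants", {
  mem <- rnorm(28)
  expect_error(group_interaction_regression(rnorm(28), mem, mem),
               "collinear")
  expect_error(group_interaction_regression(rnorm(5), rnorm(5), rnorm(5)),
               "4 more")
  withr::with_seed(60, {
    memA <- rnorm(28); memN <- rnorm(28); d <- rnorm(28)
  })
  g1 <- group_interaction_regression(d, memA, memN)
  g2 <- group_interaction_regression(d + 100, memA, memN)
  expect_equal(g1$contrast, g2$contrast, tolerance = 1e-9)
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-9)
})
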