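test_that("chance level reproduces the position-dependent formula", {
  expect_equal(chance_level(4), (1 / 4 + 1 / 3 + 1 / 2 + 1) / 4)
  expect_equal(round(chance_level(4) * 100), 52)
  expect_equal(chance_level(1), 1)
  expect_equal(chance_level(2), 0.75)
  expect_error(chance_level(0), "must be in")
  # strictly decreasing in the number of options
  cl <- vapply(1:10, chance_level, numeric(1))
  expect_true(all(diff(cl) < 0))
})

test_that("binning splits ratings at 3/4 vs 1/2 and flags empty bins", {
  bt <- tibble::tibble(
    subject = 1, condition = "aversive",
    confidence = c(4, 4, 4), vividness = c(4, 3, 2),
    chosen_correct = c(TRUE, TRUE, FALSE))
  out <- bin_accuracy(bt, "confidence")
  high <- out[out$bin == "high", ]
  expect_equal(high$prop_correct, 2 / 3)
  expect_true(out$empty[out$bin == "low"])
  expect_true(is.na(out$prop_correct[out$bin == "low"]))

  # counts conserved
  bt2 <- dplyr::bind_rows(bt, dplyr::mutate(bt, confidence = c(1, 2, 1)))
  out2 <- bin_accuracy(bt2, "confidence")
  expect_equal(sum(out2$n_trials), nrow(bt2))
})

test_that("a hand-built 12-row table bins to hand-computed proportions", {
  bt <- tibble::tibble(
    subject = rep(1:2, each = 6),
    condition = rep(rep(c("aversive", "neutral"), each = 3), 2),
    confidence = c(4, 3, 1, 4, 2, 2, 3, 3, 3, 1, 1, 4),
    vividness = c(4, 1, 3, 2, 4, 4, 3, 2, 1, 1, 2, 3),
    chosen_correct = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                       TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  out <- bin_accuracy(bt, "confidence")
  pick <- function(s, cd, b) {
    out$prop_correct[out$subject == s & out$condition == cd & out$bin == b]
  }
  expect_equal(pick(1, "aversive", "high"), 1 / 2)   # conf 4,3 -> T,F
  expect_equal(pick(1, "aversive", "low"), 1)        # conf 1 -> T
  expect_equal(pick(1, "neutral", "high"), 1)        # conf 4 -> T
  expect_equal(pick(1, "neutral", "low"), 1 / 2)     # conf 2,2 -> F,T
  expect_equal(pick(2, "aversive", "high"), 2 / 3)
  expect_equal(pick(2, "neutral", "high"), 1)
  expect_equal(pick(2, "neutral", "low"), 0)

  # restriction mirrors high-confidence-only vividness binning
  hv <- bin_accuracy(bt, "vividness", restrict = confidence >= 3)
  expect_equal(sum(hv$n_trials), sum(bt$confidence >= 3))
})

test_that("one-sample t agrees with stats::t.test", {
  withr::with_seed(21, v <- rnorm(5, 0.6, 1))
  mine <- one_sample_t(v, 0.52)
  ref <- t.test(v, mu = 0.52)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  expect_equal(mine$df, unname(ref$parameter))

  same <- one_sample_t(rep(0.3, 4), 0.3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(one_sample_t(c(0.52 - 0.1, 0.52 + 0.1), 0.52)$statistic, 0)
})

test_that("one-sample t keeps its nominal type-I rate", {
  withr::with_seed(22, {
    p <- replicate(10000, one_sample_t(rnorm(12), 0)$p.value)
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("paired t with d_av matches t.test and the d_av definition", {
  withr::with_seed(23, {
    x <- rnorm(6, 1, 1)
    y <- rnorm(6, 0.5, 2)
  })
  mine <- paired_t_dav(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  expect_equal(mine$d_av, mean(x - y) / ((sd(x) + sd(y)) / 2))

  expect_equal(paired_t_dav(x, x)$statistic, 0)
  expect_equal(paired_t_dav(x, x)$d_av, 0)
  shift <- paired_t_dav(x, x + 2)
  expect_equal(shift$d_av, -2 / sd(x))
  expect_error(paired_t_dav(rep(1, 4), rep(1, 4)), "constant")
})

test_that("rm-ANOVA effects equal squared paired t tests", {
  withr::with_seed(24, {
    d <- tidyr::expand_grid(subject = 1:20,
                            emotion = c("aversive", "neutral"),
                            confidence = c("high", "low"))
    d$value <- rnorm(nrow(d))
  })
  res <- rm_anova_2x2(d, f1 = "emotion", f2 = "confidence", value = "value")
  wide <- tidyr::pivot_wider(d, names_from = c("emotion", "confidence"),
                             values_from = "value")
  t_emo <- t.test((wide$aversive_high + wide$aversive_low) / 2,
                  (wide$neutral_high + wide$neutral_low) / 2,
                  paired = TRUE)$statistic
  expect_equal(res$statistic[res$effect == "emotion"], unname(t_emo)^2,
               tolerance = 1e-8)
  t_int <- t.test(wide$aversive_high - wide$aversive_low,
                  wide$neutral_high - wide$neutral_low,
                  paired = TRUE)$statistic
  expect_equal(res$statistic[res$effect == "emotion:confidence"],
               unname(t_int)^2, tolerance = 1e-8)
})

test_that("rm-ANOVA reproduces the aov sum-of-squares decomposition", {
  withr::with_seed(25, {
    d <- tidyr::expand_grid(subject = factor(1:8),
                            f1 = c("a", "b"), f2 = c("x", "y"))
    d$value <- rnorm(nrow(d))
  })
  res <- rm_anova_2x2(d, f1 = "f1", f2 = "f2", value = "value")
  ref <- summary(stats::aov(value ~ f1 * f2 + Error(subject / (f1 * f2)),
                            data = d))
  f_of <- function(stratum, term) {
    tab <- ref[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(res$statistic[res$effect == "f1"], f_of("Error: subject:f1", "f1"),
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "f2"], f_of("Error: subject:f2", "f2"),
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "f1:f2"],
               f_of("Error: subject:f1:f2", "f1:f2"), tolerance = 1e-8)
})

test_that("identical cell values give zero F throughout", {
  d <- tidyr::expand_grid(subject = 1:6, emotion = c("a", "n"),
                          confidence = c("h", "l"))
  d$value <- 0.7
  res <- rm_anova_2x2(d, f1 = "emotion", f2 = "confidence", value = "value")
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$partial_eta_sq, rep(0, 3))
})

test_that("ANCOVA covariates adjust the error df and reject degenerate input", {
  withr::with_seed(26, {
    d <- tidyr::expand_grid(subject = 1:15, emotion = c("a", "n"),
                            confidence = c("h", "l"))
    d$value <- rnorm(nrow(d))
    cv <- data.frame(act_init = rnorm(15), act_emo = rnorm(15))
  })
  res <- rm_anova_2x2(d, f1 = "emotion", f2 = "confidence", value = "value",
                      covariates = cv)
  expect_equal(unique(res$df2), 15 - 1 - 2)
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
  expect_error(
    rm_anova_2x2(d, f1 = "emotion", f2 = "confidence", value = "value",
                 covariates = data.frame(z = rep(1, 15))),
    "Zero-variance")
})

test_that("missing cells are reported with the offending subjects", {
  d <- tidyr::expand_grid(subject = 1:5, emotion = c("a", "n"),
                          confidence = c("h", "l"))
  d$value <- 1:nrow(d)
  d <- d[-3, ]
  expect_error(rm_anova_2x2(d, f1 = "emotion", f2 = "confidence",
                            value = "value"), "Incomplete")
})

test_that("the mixed-model slope recovers a planted trial-level effect", {
  gen <- function(sd_, beta = 0.2, n_sub = 30, n_tr = 72) {
    withr::with_seed(sd_, {
      tibble::tibble(
        subject = rep(seq_len(n_sub), each = n_tr),
        x = rnorm(n_sub * n_tr),
        int = rep(rnorm(n_sub, 0, 0.5), each = n_tr)
      ) |>
        dplyr::mutate(y = beta * x + int + rnorm(n_sub * n_tr, 0, 1))
    })
  }
  est <- vapply(1:25, function(sd_) mixed_slope(gen(sd_), "x", "y")$estimate,
                numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.05)

  covered <- vapply(1:150, function(sd_) {
    m <- mixed_slope(gen(sd_ + 500, beta = 0, n_sub = 20, n_tr = 30),
                     "x", "y")
    m$conf.low <= 0 && m$conf.high >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)

  d <- gen(1)
  d$x <- 1
  expect_error(mixed_slope(d, "x", "y"), "constant")
  expect_error(mixed_slope(dplyr::filter(gen(1), subject == 1), "x", "y"),
               "2 subjects")
})

test_that("SCL means integrate the 6-s post-onset window", {
  sr <- 10
  trace <- rep(2.5, 200)
  out <- scl_mean(trace, c(0, 5, 10), window_s = 6, sample_rate = sr)
  expect_equal(out$mean_scl, rep(2.5, 3))

  step <- c(rep(0, 50), rep(1, 150))
  expect_equal(scl_mean(step, 5, 6, sr)$mean_scl, 1)

  # linear ramp: mean over [a, a+6) matches the analytic midpoint
  ramp <- seq(0, by = 0.1, length.out = 200) # 1 microsiemens per second
  got <- scl_mean(ramp, 4, 6, sr)$mean_scl
  expect_equal(got, mean(ramp[41:100]))
  expect_equal(got, (4.0 + 9.9) / 2)  # mean of a linear ramp over the window

  expect_warning(out2 <- scl_mean(trace, 18, 6, sr), "beyond")
  expect_true(is.na(out2$mean_scl))

  trials <- scl_mean(trace, c(0, 6), 6, sr,
                     condition = c("aversive", "neutral"),
                     phase = c("emotional", "emotional"))
  agg <- scl_condition_means(trials)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$mean_scl, c(2.5, 2.5))
})
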