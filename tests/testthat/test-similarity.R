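test_that("pattern normalization is exact, idempotent and guarded", {
  z <- normalize_pattern(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(normalize_pattern(z), z, tolerance = 1e-12)
  expect_error(normalize_pattern(c(5, 5, 5)), "constant")
  expect_error(normalize_pattern(3), "length")
})

test_that("similarity_z matches the Fisher transform closed form", {
  # construct vectors with exactly r = 0.5
  x <- c(1, 1, -1, -1)
  e <- c(1, -1, 1, -1)
  y <- 0.5 * x + sqrt(0.75) * e
  expect_equal(similarity_z(x, y), atanh(0.5), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  expect_equal(similarity_z(x, x), atanh(1 - 1e-7))
  expect_equal(similarity_z(x, e), 0, tolerance = 1e-12)   # orthogonal
  expect_equal(similarity_z(x, y), similarity_z(y, x))     # symmetric
  expect_error(similarity_z(x, rep(1, 4)), "zero-variance")
  expect_error(similarity_z(x, y[1:3]), "equal length")
})

test_that("identical pattern sets give the clipped maximum pair similarity", {
  ps <- small_pattern_sets(seed = 3)
  tm <- trial_measures(ps$init, ps$init, measures = "pair_specific")
  expect_equal(tm$z, rep(atanh(1 - 1e-7), 2))
})

test_that("the aversive reinstatement effect concentrates in pair-specific similarity", {
  hits <- vapply(1:40, function(sd_) {
    ps <- small_pattern_sets(seed = sd_, n_pairs = 72L, n_aversive = 36L,
                             n_voxels = 120L)
    tm <- trial_measures(ps$init, ps$emo,
                         measures = c("pair_specific",
                                      "across_pair_combined"))
    g <- function(m, cd) tm$z[tm$measure == m & tm$condition == cd]
    d_ps <- g("pair_specific", "aversive") - g("pair_specific", "neutral")
    d_ap <- g("across_pair_combined", "aversive") -
      g("across_pair_combined", "neutral")
    d_ps > 0 && d_ps > d_ap
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("shuffling pair labels collapses pair-specific onto across-pair-within", {
  ps <- small_pattern_sets(seed = 8, n_pairs = 36L, n_aversive = 18L)
  diffs <- vapply(1:200, function(i) {
    emo <- ps$emo
    meta <- emo$meta
    perm <- withr::with_seed(i, {
      out <- seq_len(nrow(meta))
      for (cd in unique(meta$condition)) {
        idx <- which(meta$condition == cd)
        out[idx] <- sample(idx)
      }
      out
    })
    emo_shuf <- pattern_set(emo$patterns[perm, , drop = FALSE],
                            meta, roi = emo$roi, phase = emo$phase)
    tm <- trial_measures(ps$init, emo_shuf,
                         measures = c("pair_specific",
                                      "across_pair_within"))
    mean(tm$z[tm$measure == "pair_specific"] -
           tm$z[tm$measure == "across_pair_within"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("combined across-pair similarity lies between its two components", {
  for (sd_ in 1:10) {
    ps <- small_pattern_sets(seed = sd_, n_pairs = 24L, n_aversive = 12L)
    tm <- trial_measures(ps$init, ps$emo,
                         measures = c("across_pair_within",
                                      "across_pair_between",
                                      "across_pair_combined"))
    for (cd in c("aversive", "neutral")) {
      g <- function(m) tm$z[tm$measure == m & tm$condition == cd]
      lo <- min(g("across_pair_within"), g("across_pair_between"))
      hi <- max(g("across_pair_within"), g("across_pair_between"))
      expect_gte(g("across_pair_combined"), lo - 1e-10)
      expect_lte(g("across_pair_combined"), hi + 1e-10)
    }
  }
})

test_that("across-pair and within-phase measures are null-calibrated without signal", {
  zs <- vapply(1:200, function(sd_) {
    ps <- small_pattern_sets(seed = sd_, rho_aversive = 0, rho_neutral = 0,
                             gamma = 0)
    tm <- trial_measures(ps$init, ps$emo,
                         measures = c("across_pair_within",
                                      "across_pair_between",
                                      "within_encoding", "within_arousal"))
    mean(tm$z)
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2 * sd(zs) / sqrt(length(zs)))
})

test_that("similarity measures are invariant to per-pattern affine rescaling", {
  ps <- small_pattern_sets(seed = 12)
  scales <- withr::with_seed(1, runif(12, 0.5, 3))
  shifts <- withr::with_seed(2, rnorm(12, 0, 5))
  rescale <- function(set) {
    pattern_set(set$patterns * scales + shifts, set$meta,
                roi = set$roi, phase = set$phase)
  }
  tm1 <- trial_measures(ps$init, ps$emo)
  tm2 <- trial_measures(rescale(ps$init), rescale(ps$emo))
  expect_equal(tm1$z, tm2$z, tolerance = 1e-10)
  # and to explicit normalization
  normed <- pattern_set(t(apply(ps$emo$patterns, 1, normalize_pattern)),
                        ps$emo$meta, roi = ps$emo$roi, phase = ps$emo$phase)
  tm3 <- trial_measures(ps$init, normed)
  expect_equal(tm1$z, tm3$z, tolerance = 1e-10)
})

test_that("conditions need enough trials for across-pair measures", {
  meta <- tibble::tibble(pair_id = 1:2, condition = c("aversive", "neutral"))
  m <- withr::with_seed(1, matrix(rnorm(2 * 10), 2, 10))
  si <- pattern_set(m, meta, phase = "initial")
  se <- pattern_set(m + 0.1, meta, phase = "emotional")
  expect_error(trial_measures(si, se, measures = "across_pair_within"),
               "trials")
})

test_that("condition-level similarity works on patterns and GLM fits", {
  expect_equal(condition_level_similarity(c(1, 2, 3, 5), c(1, 2, 3, 5)),
               atanh(1 - 1e-7))
  expect_error(condition_level_similarity(1:4, 1:5), "mismatched")

  # emotion-specific reinstatement shows up at condition level
  hits <- vapply(1:40, function(sd_) {
    # no category component so condition means isolate reinstatement;
    # condition-level noise is low because a condition GLM pools all of a
    # condition's trials (trial noise 0.25 / sqrt(36) < 0.1)
    ps <- small_pattern_sets(seed = sd_, n_pairs = 36L, n_aversive = 18L,
                             n_voxels = 120L, gamma = 0, sigma_noise = 0.1,
                             rho_aversive = 0.9, rho_neutral = 0)
    cond_pattern <- function(set, cd) {
      colMeans(set$patterns[set$meta$condition == cd, , drop = FALSE])
    }
    za <- condition_level_similarity(cond_pattern(ps$init, "aversive"),
                                     cond_pattern(ps$emo, "aversive"))
    zn <- condition_level_similarity(cond_pattern(ps$init, "neutral"),
                                     cond_pattern(ps$emo, "neutral"))
    za > zn
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null: mean z of independent patterns is within the Fisher sampling band
  nulls <- vapply(1:1000, function(i) {
    withr::with_seed(i, similarity_z(rnorm(40), rnorm(40)))
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 4 / sqrt(40 - 3) / sqrt(1000))
})

test_that("similarity_table attaches subject and ROI identifiers", {
  ps <- small_pattern_sets(seed = 2)
  st <- similarity_table(ps$init, ps$emo, subject = 7L,
                         measures = "pair_specific")
  expect_equal(unique(st$subject), 7L)
  expect_equal(unique(st$roi), "sim")
  expect_equal(nrow(st), 2)
})
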