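#' Generate a condition sequence with a run-length constraint
#'
#' Draws a pseudo-random ordering of two condition labels with exact counts
#' and no more than `max_run_len` consecutive trials from the same condition,
#' mirroring presentation constraints in which no more than two voices from
#' the same condition may appear in a row.
#'
#' Sampling is by seeded rejection: uniform permutations are drawn until one
#' satisfies the run-length constraint. For very tight constraints where
#' rejection is hopeless (e.g. strict alternation), a feasibility-preserving
#' sequential sampler is used instead; the result is still deterministic
#' given `seed`.
#'
#' @param n_trials Total number of trials.
#' @param n_per_condition Number of aversive trials (the neutral count is
#'   `n_trials - n_per_condition`).
#' @param max_run_len Longest allowed run of a single condition (`>= 1`).
#' @param seed Integer RNG seed.
#' @param labels Length-2 character vector of condition labels.
#'
#' @return Character vector of length `n_trials`.
#' @examples
#' s <- generate_condition_sequence(72, 36, max_run_len = 2, seed = 7)
#' table(s)
#' max(rle(s)$lengths)
#' @export
generate_condition_sequence <- function(n_trials, n_per_condition,
                                        max_run_len = 2L, seed = 1L,
                                        labels = c("aversive", "neutral")) {
  assert_scalar_number(n_trials, "n_trials", lower = 0)
  assert_scalar_number(n_per_condition, "n_per_condition", lower = 0,
                       upper = n_trials)
  assert_scalar_number(max_run_len, "max_run_len", lower = 1)
  stopifnot(length(labels) == 2, is.character(labels))
  n_trials <- as.integer(n_trials)
  a <- as.integer(n_per_condition)
  b <- n_trials - a
  L <- as.integer(max_run_len)

  if (n_trials == 0L) return(character(0))
  # A valid sequence exists iff neither condition must exceed the run cap:
  # the a copies of one label fit into at most (b + 1) gaps of size <= L.
  if (a > (b + 1L) * L || b > (a + 1L) * L) {
    abort(sprintf(
      "No sequence of %d/%d trials satisfies max_run_len = %d.", a, b, L))
  }

  base <- rep(labels, times = c(a, b))
  with_seed(seed, {
    for (i in seq_len(10000L)) {
      cand <- sample(base)
      if (max(rle(cand)$lengths) <= L) return(cand)
    }
    # Constraint too tight for rejection; build sequentially, only taking
    # steps that keep the remaining counts feasible.
    remaining <- c(a, b)
    out <- character(n_trials)
    run_lab <- 0L
    run_len <- 0L
    for (i in seq_len(n_trials)) {
      ok <- logical(2)
      for (j in 1:2) {
        if (remaining[j] == 0L) next
        if (j == run_lab && run_len >= L) next
        rem <- remaining
        rem[j] <- rem[j] - 1L
        new_len <- if (j == run_lab) run_len + 1L else 1L
        # Other label must absorb the rest without overlong runs; the label
        # just placed can still extend its current run by L - new_len.
        cap_j <- (rem[3 - j] + 1L) * L - new_len
        ok[j] <- rem[j] <= cap_j && rem[3 - j] <= (rem[j] + 1L) * L
      }
      if (!any(ok)) abort("Internal error: sequential sampler got stuck.")
      cand <- which(ok)
      pick <- if (length(cand) == 1) cand else sample(cand, 1, prob = remaining[cand])
      out[i] <- labels[pick]
      run_len <- if (pick == run_lab) run_len + 1L else 1L
      run_lab <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    out
  })
}

# Event timings (seconds) per phase. Stimulus events are the ones later
# modelled in the GLM; the ITI menu is counterbalanced so its realized mean
# is exactly the design's nominal mean.
.phase_timing <- function(phase) {
  switch(phase,
    initial = list(
      events = c(pair = 4, rating = 2),
      itis = c(2, 4, 6)
    ),
    emotional = list(
      events = c(cue = 2, face_voice = 2, rating = 2),
      itis = c(6, 8, 10)
    ),
    abort(sprintf("Unknown phase '%s'; use 'initial' or 'emotional'.", phase))
  )
}

#' Generate a trial design for one learning run
#'
#' Builds an ordered event table for an initial-learning run (4 s pair
#' presentation + 2 s vividness rating, ITIs of 2/4/6 s averaging exactly
#' 4 s) or an emotional-learning run (2 s face cue + 2 s face-voice pairing +
#' 2 s rating, ITIs of 6/8/10 s averaging exactly 8 s). ITIs are
#' counterbalanced -- each jitter value occurs equally often, in seeded
#' shuffled order -- so total run duration is an exact closed form:
#' `n_trials * (sum(event durations) + mean ITI)`. With 72 trials this gives
#' 720 s (12 min) for an initial run and 1008 s (16.8 min) for the emotional
#' run.
#'
#' @param phase `"initial"` or `"emotional"`.
#' @param n_trials Number of trials; must be a multiple of the ITI menu size
#'   (3) so the jitters counterbalance exactly.
#' @param seed Integer RNG seed.
#' @param tr Repetition time in seconds (recorded on the design).
#' @param pair_conditions Optional tibble with columns `pair_id` and
#'   `condition` fixing the pair-to-condition map (shared across phases of
#'   one session). When `NULL`, pairs `1:n_trials` are split half/half and
#'   assigned at random.
#' @param max_run_len Run-length cap passed to
#'   [generate_condition_sequence()].
#'
#' @return A `trial_design`: a tibble of events (`trial`, `onset`,
#'   `duration`, `event_kind`, `condition`, `pair_id`) with attributes
#'   `phase`, `tr` and `total_duration` (seconds).
#' @examples
#' d <- generate_design("emotional", 72, seed = 3)
#' total_duration(d) / 60
#' @export
generate_design <- function(phase, n_trials, seed = 1L, tr = 2,
                            pair_conditions = NULL, max_run_len = 2L) {
  timing <- .phase_timing(phase)
  assert_scalar_number(n_trials, "n_trials", lower = 0)
  n_trials <- as.integer(n_trials)

  if (n_trials == 0L) {
    events <- tibble::tibble(
      trial = integer(0), onset = numeric(0), duration = numeric(0),
      event_kind = character(0), condition = character(0),
      pair_id = integer(0)
    )
    return(new_trial_design(events, phase, tr, total_duration = 0))
  }

  n_cells <- length(timing$itis)
  if (n_trials %% n_cells != 0L) {
    abort(sprintf(
      paste("n_trials = %d is not divisible by the %d ITI jitter values;",
            "choose a multiple of %d so the jitters counterbalance exactly."),
      n_trials, n_cells, n_cells))
  }

  if (is.null(pair_conditions)) {
    if (n_trials %% 2L != 0L) {
      abort("With `pair_conditions = NULL`, `n_trials` must be even.")
    }
    pair_conditions <- assign_pair_conditions(n_trials, n_trials %/% 2L,
                                              seed = seed + 1L)
  }
  stopifnot(all(c("pair_id", "condition") %in% names(pair_conditions)))
  if (nrow(pair_conditions) != n_trials) {
    abort("`pair_conditions` must have one row per trial.")
  }

  counts <- table(factor(pair_conditions$condition,
                         levels = c("aversive", "neutral")))
  cond_seq <- generate_condition_sequence(
    n_trials, counts[["aversive"]], max_run_len = max_run_len, seed = seed)

  with_seed(seed + 2L, {
    order_within <- lapply(split(pair_conditions$pair_id,
                                 pair_conditions$condition),
                           function(x) x[sample.int(length(x))])
    slots <- integer(n_trials)
    for (cond in names(order_within)) {
      slots[cond_seq == cond] <- order_within[[cond]]
    }
    itis <- sample(rep(timing$itis, each = n_trials %/% n_cells))
  })

  ev_dur <- timing$events
  trial_len <- sum(ev_dur) + itis
  trial_starts <- c(0, cumsum(trial_len))[seq_len(n_trials)]
  offsets <- unname(c(0, cumsum(ev_dur))[seq_along(ev_dur)])

  events <- tibble::tibble(
    trial = rep(seq_len(n_trials), each = length(ev_dur)),
    onset = rep(trial_starts, each = length(ev_dur)) +
      rep(offsets, times = n_trials),
    duration = rep(unname(ev_dur), times = n_trials),
    event_kind = rep(names(ev_dur), times = n_trials),
    condition = rep(cond_seq, each = length(ev_dur)),
    pair_id = rep(slots, each = length(ev_dur))
  )

  total <- n_trials * (sum(ev_dur) + mean(timing$itis))
  stopifnot(abs(total - (sum(trial_len))) < 1e-9)
  new_trial_design(events, phase, tr, total_duration = total)
}

new_trial_design <- function(events, phase, tr, total_duration) {
  out <- tibble::new_tibble(events, phase = phase, tr = tr,
                            total_duration = total_duration,
                            class = "trial_design")
  out
}

#' @exportS3Method base::print
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design: %s phase, %d trials, %.1f s (TR %.1f s)>\n",
              attr(x, "phase"), length(unique(x$trial)),
              attr(x, "total_duration"), attr(x, "tr")))
  NextMethod()
}

#' Total duration of a trial design in seconds
#' @param design A `trial_design`.
#' @return Duration in seconds.
#' @export
total_duration <- function(design) {
  attr(design, "total_duration")
}

#' Assign pairs to emotional conditions
#'
#' Randomly splits `n_pairs` pair ids into aversive and neutral conditions
#' with exact counts. The map is shared across the phases of one session.
#'
#' @param n_pairs Number of pairs.
#' @param n_aversive Number assigned to the aversive condition.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `pair_id`, `condition`.
#' @export
assign_pair_conditions <- function(n_pairs, n_aversive, seed = 1L) {
  assert_scalar_number(n_pairs, "n_pairs", lower = 0)
  assert_scalar_number(n_aversive, "n_aversive", lower = 0, upper = n_pairs)
  cond <- with_seed(seed, sample(rep(c("aversive", "neutral"),
                                     times = c(n_aversive,
                                               n_pairs - n_aversive))))
  tibble::tibble(pair_id = seq_len(n_pairs), condition = cond)
}

#' Generate all designs of one scanning session
#'
#' One session comprises two initial-learning runs (every pair viewed once
#' per run), one emotional-learning run, and three rest runs, sharing a
#' single pair-to-condition assignment.
#'
#' @param params A [sim_params()] object.
#' @return List with `pair_conditions`, `design_init1`, `design_init2`,
#'   `design_emo`, and `rest` (a tibble of rest-run lengths).
#' @export
generate_session <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  seeds <- derive_seeds(params$seed, 4)
  pc <- assign_pair_conditions(params$n_pairs, params$n_aversive, seeds[1])
  list(
    pair_conditions = pc,
    design_init1 = generate_design("initial", params$n_pairs, seed = seeds[2],
                                   tr = params$tr, pair_conditions = pc),
    design_init2 = generate_design("initial", params$n_pairs, seed = seeds[3],
                                   tr = params$tr, pair_conditions = pc),
    design_emo = generate_design("emotional", params$n_pairs, seed = seeds[4],
                                 tr = params$tr, pair_conditions = pc),
    rest = tibble::tibble(
      run = c("rest1", "rest2", "rest3"),
      n_volumes = rep(params$rest_volumes, 3),
      duration = rep(params$rest_volumes * params$tr, 3)
    )
  )
}
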