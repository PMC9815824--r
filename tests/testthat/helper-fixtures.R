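# Small reusable fixtures, all generated in code.

small_params <- function(seed = 1L, ...) {
  defaults <- list(n_pairs = 12L, n_aversive = 6L, n_voxels = 40L,
                   seed = seed)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

small_session <- function(seed = 1L, ...) {
  generate_session(small_params(seed = seed, ...))
}

small_pattern_sets <- function(seed = 1L, ...) {
  p <- small_params(seed = seed, ...)
  s <- generate_session(p)
  simulate_pattern_sets(s$design_init1, s$design_emo, p)
}

# independent run-length validator for condition sequences
valid_sequence <- function(x, n_aversive, max_run) {
  sum(x == "aversive") == n_aversive && max(rle(x)$lengths) <= max_run
}

# minimal design-like event table (one stimulus event per pair)
bare_design <- function(n_pairs, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- rep(c("aversive", "neutral"), length.out = n_pairs)
  }
  tibble::tibble(
    trial = seq_len(n_pairs),
    onset = (seq_len(n_pairs) - 1) * 10,
    duration = 2,
    event_kind = "face_voice",
    condition = conditions,
    pair_id = seq_len(n_pairs)
  )
}
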