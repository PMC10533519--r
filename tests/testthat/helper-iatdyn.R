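# Hand-built toy trial table: one participant, the standard dual
# blocks, with explicit RT values per (pair, compatibility) cell.
toy_trials <- function(practice_inc = c(900, 1000),
                       practice_com = c(700, 800),
                       test_inc = c(850, 950, 900, 1000),
                       test_com = c(650, 750, 700, 800),
                       pid = "P1", correct = TRUE) {
  block <- function(b, run, compat, rts, offset) {
    tibble::tibble(
      participant_id = pid, iat_type = "generic", block_index = b,
      run_index = run, trial_index = offset + seq_along(rts),
      compatibility = compat, stimulus_class = "word", rt_ms = rts,
      correct = correct, condition_order = "compatible_first")
  }
  df <- rbind(
    block(3L, 1L, "compatible", practice_com, 0L),
    block(4L, 1L, "compatible", test_com, length(practice_com)),
    block(6L, 2L, "incompatible", practice_inc, 0L),
    block(7L, 2L, "incompatible", test_inc, length(practice_inc)))
  iat_trials(df, validate = FALSE)
}

# Small simulated dataset cached across tests in one run
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 12, seed = 77, ...) {
    extra <- list(...)
    key <- paste(n, seed,
                 paste(names(extra), vapply(extra, paste,
                                            collapse = ",",
                                            character(1)),
                       collapse = "|"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_iat(
        iat_sim_config(n_participants = n, seed = seed, ...))
    }
    cache[[key]]
  }
})

# Lean recovery spec matching the generator's structure
recovery_spec <- function(run2_on_asym = TRUE) {
  iat_model_spec(
    start = c("intercept", "incomp"),
    rate = c("intercept", "incomp"),
    asym = if (run2_on_asym) c("intercept", "incomp", "run2")
           else c("intercept", "incomp"),
    gauss_mean = c("intercept", "word_vs_face"),
    random = list(participant = list(
      start = c("intercept", "incomp"),
      rate = c("intercept", "incomp"),
      asym = c("intercept", "incomp"),
      gauss_mean = "intercept")))
}

recovery_truth <- function(config, run2_on_asym = TRUE) {
  tr <- c(config$mean_log_start, config$effect_compat_start,
          config$mean_log_rate, config$effect_compat_rate,
          config$mean_log_asym, config$effect_compat_asym)
  if (run2_on_asym) tr <- c(tr, config$effect_order_asym)
  c(tr, config$mean_log_gauss, config$effect_word_vs_face,
    log(config$gauss_sd_ms))
}
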