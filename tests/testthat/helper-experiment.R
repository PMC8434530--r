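# The scaled end-to-end study used by the acceptance tests: 40 synthetic
# records of 30 min (28 train / 4 validation / 8 test), well-separated
# apnea (envelope x0.05) and hypopnea (x0.5) events, both networks at
# reduced size (32 LSTM units, 10/15 epochs). Episode counts vary across
# records so REI spans the severity classes. Run once per session and
# memoized, since several tests inspect its outputs.

.e2e_cache <- new.env(parent = emptyenv())

e2e_corpus <- function(seed = 1L, n_records = 40L, duration_s = 1800) {
  base <- sim_config(duration_s = duration_s, seed = seed)
  generate_corpus(n_records, base, seed = seed,
                  config_sampler = function(i) {
                    cfg <- base
                    # deterministic severity spread: 2..9 events per record
                    cfg$n_apnea <- 1L + (i * 3L) %% 5L
                    cfg$n_hypopnea <- 1L + (i * 5L) %% 5L
                    cfg
                  })
}

e2e_experiment <- function(seed = 1L) {
  key <- paste0("exp_", seed)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  corpus <- e2e_corpus(seed)
  exp <- run_sdb_experiment(
    corpus,
    net1 = net_config(lstm_units = 32, epochs = 10, batch_size = 128,
                      learning_rate = 3e-3, seed = seed),
    net2 = net_config(lstm_units = 32, epochs = 15, batch_size = 128,
                      learning_rate = 3e-3, seed = seed + 1L),
    max_per_class = 3000, seed = seed)
  .e2e_cache[[key]] <- exp
  exp
}
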