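# Shared fixtures. Heavy objects are built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small calibrated PWM trained against the motif oracle
small_pwm <- function() {
  memo("small_pwm", function() {
    lab <- generate_labeled_set(motif_oracle(), 30000, seed = 101)
    calibrate_pwm(build_pwm(lab), lab)
  })
}

# tiny pretrained model + structures for model/dpo unit tests
tiny_world <- function() {
  memo("tiny_world", function() {
    structures <- lapply(1:6, function(i)
      generate_backbone(50, "mixed", noise_sigma = 0.2, seed = 400 + i))
    seqs <- vapply(seq_along(structures), function(i)
      generate_native_sequence(structures[[i]], seed = 500 + i), character(1))
    base <- init_design_model(model_config(feature_dim = 32, n_neighbors = 8),
                              seed = 5)
    base <- train_supervised(base, structures, seqs, epochs = 15, lr = 1e-3,
                             seed = 6)
    list(structures = structures, seqs = seqs, base = base)
  })
}

# the full desk-scale alignment experiment: motif oracle -> PWM pipeline,
# 20 length-60 synthetic backbones with structure-dependent native sequences,
# supervised base-model fitting, then 12 epochs of DPO with refresh every 2.
# All seeds fixed; every consumer reads the same cached run.
e2e_experiment <- function() {
  memo("e2e_experiment", function() {
    oracle <- motif_oracle()
    lab <- generate_labeled_set(oracle, 60000, seed = 101)
    pwm <- calibrate_pwm(build_pwm(lab), lab)
    topo <- rep(c("helix", "mixed"), 10)
    structures <- lapply(1:20, function(i)
      generate_backbone(60, topo[i], noise_sigma = 0.2, seed = 200 + i))
    seqs <- vapply(seq_along(structures), function(i)
      generate_native_sequence(structures[[i]], seed = 300 + i), character(1))
    base <- init_design_model(model_config(), seed = 11)
    base <- train_supervised(base, structures, seqs, epochs = 40, lr = 1e-3,
                             seed = 12)
    fit <- dpo_align(base, structures, pwm, total_epochs = 12,
                     epochs_per_refresh = 2, checkpoint_epochs = c(2, 6, 10),
                     seed = 77)
    set.seed(500)
    base_designs <- vapply(structures, function(st)
      sample_sequence(base, st, temperature = 1)$sequence, character(1))
    measure <- function(model) {
      ev <- deimmune:::checkpoint_vis_recovery(
        model, structures, as.list(seqs), pwm,
        seed = 900, samples_per_structure = 3)
      set.seed(600)
      rec_vs_base <- mean(vapply(rep(seq_along(structures), 3), function(i)
        sequence_recovery(
          sample_sequence(model, structures[[i]], temperature = 1)$sequence,
          base_designs[i]), numeric(1)))
      list(vis = ev$mean_visibility, rec = ev$mean_recovery,
           rec_vs_base = rec_vs_base)
    }
    list(oracle = oracle, pwm = pwm, structures = structures, seqs = seqs,
         base = base, fit = fit, base_designs = base_designs,
         eval_base = measure(base), eval_tuned = measure(fit$model),
         measure = measure)
  })
}
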