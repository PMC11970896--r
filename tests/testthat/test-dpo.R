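test_that("the DPO loss has its analytic values and monotonicity", {
  # identity policy: loss is exactly log 2 for any beta
  for (b in c(1e-3, 0.0343, 0.2, 5)) {
    expect_equal(dpo_loss(-10, -20, -10, -20, beta = b), log(2),
                 tolerance = 1e-12)
  }
  # closed form at a unit preference margin
  expect_equal(dpo_loss(-9, -20, -10, -20, beta = 0.1),
               log(1 + exp(-0.1)), tolerance = 1e-12)
  # strictly decreasing in the preference margin
  margins <- seq(-5, 5, by = 0.25)
  losses <- vapply(margins, function(d)
    dpo_loss(d, 0, 0, 0, beta = 0.3), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(dpo_loss(Inf, 0, 0, 0, 1), "finite")
  expect_error(dpo_loss(0, 0, 0, 0, beta = 0), "> 0")
})

test_that("preference pairs prefer the less visible candidate and drop ties", {
  w <- tiny_world()
  pwm <- small_pwm()
  # ordering + reference log-probs over a batch of seeded pairs
  vis_w <- c(); vis_l <- c()
  for (i in seq_along(w$structures)) {
    for (rep in 1:5) {
      pr <- generate_preference_pair(w$base, w$base, w$structures[[i]], pwm,
                                     temperature = 0.8, seed = 100 * i + rep)
      if (is.null(pr)) next
      expect_lt(pr$visibility_w, pr$visibility_l)
      vis_w <- c(vis_w, pr$visibility_w); vis_l <- c(vis_l, pr$visibility_l)
    }
  }
  expect_gt(length(vis_w), 10)
  expect_lt(mean(vis_w), mean(vis_l))

  # a constant predictor makes every draw a tie: no pair
  expect_null(generate_preference_pair(
    w$base, w$base, w$structures[[1]],
    function(p) rep(FALSE, length(p)), seed = 1))

  # mismatched configurations are rejected
  other <- init_design_model(model_config(feature_dim = 16, n_neighbors = 8))
  expect_error(generate_preference_pair(w$base, other, w$structures[[1]], pwm),
               "configuration")
})

test_that("one DPO step increases the preference margin", {
  w <- tiny_world()
  pwm <- small_pwm()
  st <- w$structures[[1]]
  pr <- generate_preference_pair(w$base, w$base, st, pwm, temperature = 0.7,
                                 seed = 3)
  expect_false(is.null(pr))
  margin <- function(m) {
    (sequence_log_prob(m, st, pr$y_w, pr$order_w) - pr$ref_log_prob_w) -
      (sequence_log_prob(m, st, pr$y_l, pr$order_l) - pr$ref_log_prob_l)
  }
  expect_equal(margin(w$base), 0)
  flat <- deimmune:::flatten_params(w$base$dec)
  state <- deimmune:::adam_init(flat)
  pr$enc <- encode_backbone(w$base, st)
  stp <- deimmune:::dpo_batch_step(w$base, flat, state, list(pr),
                                   beta = 0.05, lr = 1e-3)
  expect_equal(stp$loss, log(2), tolerance = 1e-12)  # starting at identity
  m2 <- w$base
  m2$dec <- deimmune:::unflatten_params(m2$dec, stp$flat)
  expect_gt(margin(m2), 0)
})

test_that("a zero learning rate leaves the model untouched", {
  w <- tiny_world()
  pwm <- small_pwm()
  fit <- dpo_align(w$base, w$structures[1:3], pwm, lr = 0,
                   total_epochs = 2, seed = 5)
  expect_identical(fit$model$dec, w$base$dec)
})

test_that("the reference policy stays frozen across refresh cycles", {
  e <- e2e_experiment()
  fit <- e$fit
  # recompute a stored pair's reference log-likelihood with the base model:
  # identical after 12 epochs of tuning
  st <- e$structures[[1]]
  pr <- generate_preference_pair(fit$model, e$base, st, e$pwm,
                                 temperature = 0.759, seed = 404)
  if (!is.null(pr)) {
    expect_equal(pr$ref_log_prob_w,
                 sequence_log_prob(e$base, st, pr$y_w, pr$order_w),
                 tolerance = 1e-12)
  }
  expect_identical(fit$base_model$dec, e$base$dec)
})

test_that("alignment reduces visibility and larger beta anchors the policy", {
  w <- tiny_world()
  pwm <- small_pwm()
  kl_from_base <- function(m) {
    bb <- w$structures[[1]]
    enc_b <- encode_backbone(w$base, bb)
    enc_m <- encode_backbone(m, bb)
    set.seed(9); ord <- sample.int(50)
    tok <- deimmune:::tokens_from_sequence(w$seqs[[1]])
    fb <- deimmune:::decoder_forward(w$base, enc_b, tok, ord)
    fm <- deimmune:::decoder_forward(m, enc_m, tok, ord)
    mean(colSums(exp(fb$log_p) * (fb$log_p - fm$log_p)))
  }
  # coarse check over order-of-magnitude-spaced beta values: the divergence
  # penalty needs enough steps to saturate before the ordering shows
  kls <- vapply(c(0.02, 0.5, 5), function(b) {
    fit <- dpo_align(w$base, w$structures, pwm, beta = b,
                     total_epochs = 12, seed = 33)
    kl_from_base(fit$model)
  }, numeric(1))
  expect_true(all(kls > 0))
  expect_true(all(diff(kls) < 0))  # beta up -> divergence from base down
})

test_that("checkpoints are emitted at the requested epochs and reloadable", {
  e <- e2e_experiment()
  expect_setequal(names(e$fit$checkpoints),
                  c("epoch_2", "epoch_6", "epoch_10"))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(e$fit$checkpoints$epoch_2, f)
  back <- read_model(f)
  st <- e$structures[[1]]
  set.seed(2); ord <- sample.int(60)
  expect_equal(
    sequence_log_prob(back, st, e$seqs[[1]], ord),
    sequence_log_prob(e$fit$checkpoints$epoch_2, st, e$seqs[[1]], ord),
    tolerance = 1e-12)
  expect_equal(nrow(e$fit$history), 12L)
})

test_that("visibility reduction trades off against recovery along the tuning trajectory", {
  e <- e2e_experiment()
  models <- c(list(base = e$base), e$fit$checkpoints, list(final = e$fit$model))
  traj <- t(vapply(models, function(m) {
    ev <- e$measure(m)
    c(vis = ev$vis, rec = ev$rec)
  }, numeric(2)))
  # visibility falls monotonically across checkpoints ...
  expect_true(all(diff(traj[, "vis"]) < 0))
  # ... and lower visibility goes with lower recovery (frontier direction)
  expect_gt(stats::cor(traj[, "vis"], traj[, "rec"]), 0)
  expect_lt(traj["final", "rec"], traj["base", "rec"])
})

test_that("hyperparameter sampling follows the sweep distributions", {
  expect_equal(nrow(dpo_sweep(NULL, NULL, NULL, n_runs = 0)), 0L)
  hp <- sample_dpo_hyperparams(1000, seed = 17)
  expect_true(all(hp$beta >= 0.001 & hp$beta <= 0.2))
  expect_true(all(hp$temperature >= 0.01 & hp$temperature <= 1.0))
  expect_true(all(hp$lr >= 1e-7 & hp$lr <= 1e-3))
  # log-uniform marginals (Kolmogorov-Smirnov)
  expect_gt(stats::ks.test(log(hp$beta), "punif",
                           log(0.001), log(0.2))$p.value, 0.01)
  expect_gt(stats::ks.test(log(hp$lr), "punif",
                           log(1e-7), log(1e-3))$p.value, 0.01)
  expect_gt(stats::ks.test(hp$temperature, "punif", 0.01, 1.0)$p.value, 0.01)
})

test_that("the named hyperparameter presets carry their published values", {
  ps <- dpo_presets()
  expect_identical(ps[["458340e4"]],
                   list(beta = 3.43e-2, temperature = 0.759, lr = 2.86e-6))
  expect_identical(ps[["e32b8ed0"]],
                   list(beta = 4.48e-3, temperature = 0.500, lr = 4.62e-7))
})

test_that("a mini sweep records per-checkpoint metrics and survives failures", {
  w <- tiny_world()
  pwm <- small_pwm()
  sw <- dpo_sweep(w$base, w$structures, pwm, n_runs = 3, total_epochs = 2,
                  checkpoint_epochs = 2,
                  eval_sequences = as.list(w$seqs), seed = 21)
  expect_true(all(sw$status %in% c("ok", "failed")))
  ok <- sw[sw$status == "ok", ]
  expect_true(all(is.finite(ok$mean_visibility)))
  expect_true(all(ok$mean_recovery >= 0 & ok$mean_recovery <= 1))
  expect_true(all(ok$beta >= 0.001 & ok$beta <= 0.2))
})

test_that("preference pairs round-trip through JSON lines", {
  w <- tiny_world()
  pwm <- small_pwm()
  prs <- list()
  for (i in 1:3) {
    pr <- generate_preference_pair(w$base, w$base, w$structures[[i]], pwm,
                                   temperature = 0.8, seed = 50 + i)
    if (!is.null(pr)) prs[[length(prs) + 1]] <- pr
  }
  expect_gt(length(prs), 0)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_preference_pairs(prs, f)
  back <- read_preference_pairs(f)
  expect_equal(length(back), length(prs))
  expect_identical(back[[1]]$y_w, prs[[1]]$y_w)
  expect_identical(back[[1]]$order_w, prs[[1]]$order_w)
  expect_equal(back[[1]]$ref_log_prob_w, prs[[1]]$ref_log_prob_w,
               tolerance = 1e-12)
  expect_equal(back[[1]]$visibility_w, prs[[1]]$visibility_w)
})
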