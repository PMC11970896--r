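# Direct-preference-optimization alignment of the design model.
#
# Preference pairs are built by letting the *current* tuned model propose two
# designs per backbone; the PWM classifier scores their immune visibility and
# the less visible design is preferred. Reference log-likelihoods come from
# the frozen base model. Training minimizes
#   L = -E[ log sigmoid( beta * (Delta_w - Delta_l) ) ],
# Delta = log pi_theta(y|x) - log pi_ref(y|x), and the preference dataset is
# refreshed from the current model every `epochs_per_refresh` epochs while
# pi_ref stays the base model throughout.

#' DPO loss for one preference pair
#'
#' `-log sigmoid(beta * ((policy_w - ref_w) - (policy_l - ref_l)))`. At the
#' identity policy (policy == reference) the loss is `log 2`; it is strictly
#' decreasing in the preference margin. Batch losses are means over pairs.
#'
#' @param policy_log_prob_w,policy_log_prob_l Log-probabilities of the
#'   preferred / dispreferred sequence under the tuned policy.
#' @param ref_log_prob_w,ref_log_prob_l Same under the frozen reference.
#' @param beta Deviation-control coefficient (> 0).
#' @return Scalar loss (vectorizes over pairs).
#' @export
dpo_loss <- function(policy_log_prob_w, policy_log_prob_l,
                     ref_log_prob_w, ref_log_prob_l, beta) {
  vals <- c(policy_log_prob_w, policy_log_prob_l, ref_log_prob_w, ref_log_prob_l)
  if (!all(is.finite(vals))) stop("log-probabilities must be finite")
  if (any(beta <= 0)) stop("`beta` must be > 0")
  z <- beta * ((policy_log_prob_w - ref_log_prob_w) -
               (policy_log_prob_l - ref_log_prob_l))
  # -log sigmoid(z) = log(1 + exp(-z)), computed stably
  ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))
}

#' Generate one preference pair for a backbone
#'
#' Samples two candidate designs from the current model, scores their
#' absolute immune visibility with the (fast) PWM predictor, and prefers the
#' less visible one. Reference log-probabilities are computed with the frozen
#' base model under each candidate's own decoding order (fixed at pair
#' creation). Ties in visibility yield no pair (`NULL`): DPO needs a strict
#' preference and a random assignment would inject label noise.
#'
#' @param current_model The current tuned `design_model`.
#' @param base_model The frozen base `design_model` (same config).
#' @param structure A [backbone_structure()] (or `encoding`s precomputed).
#' @param predictor Presentation predictor (typically a calibrated PWM).
#' @param temperature Sampling temperature for the two candidates.
#' @param seed Optional integer seed.
#' @param encoding,base_encoding Optional precomputed encodings for
#'   `current_model` / `base_model`.
#' @return A `preference_pair` list (sequences, orders, reference log-probs,
#'   visibilities) or `NULL` on a visibility tie.
#' @export
generate_preference_pair <- function(current_model, base_model, structure,
                                     predictor, temperature = 0.5,
                                     seed = NULL, encoding = NULL,
                                     base_encoding = NULL) {
  if (!identical(current_model$config, base_model$config))
    stop("current and base models must share a configuration")
  if (!is.null(seed)) set.seed(seed)
  enc <- if (is.null(encoding)) encode_backbone(current_model, structure)
         else encoding
  benc <- if (is.null(base_encoding)) encode_backbone(base_model, structure)
          else base_encoding
  s1 <- sample_sequence(current_model, temperature = temperature, encoding = enc)
  s2 <- sample_sequence(current_model, temperature = temperature, encoding = enc)
  v1 <- absolute_visibility(s1$sequence, predictor)$absolute_visibility
  v2 <- absolute_visibility(s2$sequence, predictor)$absolute_visibility
  if (v1 == v2) return(NULL)
  w <- if (v1 < v2) s1 else s2
  l <- if (v1 < v2) s2 else s1
  out <- list(
    y_w = w$sequence, y_l = l$sequence,
    order_w = w$order, order_l = l$order,
    ref_log_prob_w = sequence_log_prob(base_model, sequence = w$sequence,
                                       order = w$order, encoding = benc),
    ref_log_prob_l = sequence_log_prob(base_model, sequence = l$sequence,
                                       order = l$order, encoding = benc),
    visibility_w = min(v1, v2), visibility_l = max(v1, v2)
  )
  class(out) <- "preference_pair"
  out
}

# one Adam step on the mean DPO loss over `pairs` (list of preference_pair,
# each carrying $enc, the current-model encoding of its backbone)
dpo_batch_step <- function(model, flat, state, pairs, beta, lr) {
  agg <- NULL
  loss <- 0
  for (pr in pairs) {
    gw <- grad_sequence_log_prob(model, pr$enc, tokens_from_sequence(pr$y_w),
                                 pr$order_w)
    gl <- grad_sequence_log_prob(model, pr$enc, tokens_from_sequence(pr$y_l),
                                 pr$order_l)
    z <- beta * ((gw$log_prob - pr$ref_log_prob_w) -
                 (gl$log_prob - pr$ref_log_prob_l))
    loss <- loss + dpo_loss(gw$log_prob, gl$log_prob,
                            pr$ref_log_prob_w, pr$ref_log_prob_l, beta)
    # dL/dz = -sigmoid(-z)
    coefw <- -beta * stats::plogis(-z)
    g <- Map(function(a, b) coefw * a - coefw * b, gw$grad, gl$grad)
    agg <- if (is.null(agg)) g else Map(`+`, agg, g)
  }
  n <- length(pairs)
  agg <- lapply(agg, function(x) x / n)
  st <- adam_step(flat, agg, state, lr)
  list(flat = st$flat, state = st$state, loss = loss / n)
}

#' Align the design model toward low immune visibility with DPO
#'
#' The iterative loop: (1) from each training backbone, draw one preference
#' pair with the *current* model ([generate_preference_pair()]); (2) train
#' for `epochs_per_refresh` epochs of Adam on the mean DPO loss; (3) refresh
#' the preference dataset from the newly tuned model; repeat until
#' `total_epochs`. The reference policy is the frozen base model throughout.
#' Non-finite losses abort with a diagnostic (the divergence mode of
#' too-aggressive hyperparameters), as does a collapse of sampled sequences
#' to >90% single-amino-acid composition.
#'
#' @param base_model The frozen base `design_model`; tuning starts from it.
#' @param structures List of training [backbone_structure()]s.
#' @param predictor Presentation predictor used for the preference feedback
#'   (the fast PWM classifier in the intended workflow).
#' @param beta DPO deviation coefficient (> 0).
#' @param temperature Preference-sampling temperature (distinct from the 0.1
#'   design-generation temperature).
#' @param lr Adam learning rate.
#' @param total_epochs Total tuning epochs (>= 1).
#' @param epochs_per_refresh Epochs between preference-dataset refreshes
#'   (default 2).
#' @param checkpoint_epochs Epochs after which to store a model snapshot
#'   (default `c(2, 10, 20)`, clipped to `total_epochs`).
#' @param batch_size Pairs per Adam step (default 8).
#' @param max_tokens_per_batch Token budget per step; batches are split
#'   so that `2 * sum(sequence lengths) <= max_tokens_per_batch`.
#' @param seed Integer seed.
#' @return A `dpo_fit`: list with `model` (final tuned model), `base_model`,
#'   `checkpoints` (named list of models), `history` (per-epoch data frame
#'   with loss and mean pair visibilities), `hyperparams`, `diverged`.
#' @export
dpo_align <- function(base_model, structures, predictor,
                      beta = 0.0343, temperature = 0.759, lr = 1e-3,
                      total_epochs = 12L, epochs_per_refresh = 2L,
                      checkpoint_epochs = c(2L, 10L, 20L),
                      batch_size = 8L, max_tokens_per_batch = 10000L,
                      seed = 1L) {
  stopifnot(total_epochs >= 1, epochs_per_refresh >= 1, beta > 0, lr >= 0)
  set.seed(seed)
  model <- base_model
  base_encs <- lapply(structures, function(s) encode_backbone(base_model, s))
  flat <- flatten_params(model$dec)
  state <- adam_init(flat)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mean_vis_w = numeric(0), mean_vis_l = numeric(0),
                        n_pairs = integer(0))
  checkpoints <- list()
  checkpoint_epochs <- checkpoint_epochs[checkpoint_epochs <= total_epochs]
  diverged <- FALSE
  pairs <- list()
  ep <- 0L
  while (ep < total_epochs) {
    # refresh the preference dataset from the current model
    model$dec <- unflatten_params(model$dec, flat)
    encs <- lapply(structures, function(s) encode_backbone(model, s))
    pairs <- list()
    collapse <- 0L
    for (i in seq_along(structures)) {
      pr <- generate_preference_pair(model, base_model, predictor = predictor,
                                     temperature = temperature,
                                     encoding = encs[[i]],
                                     base_encoding = base_encs[[i]])
      if (!is.null(pr)) {
        pr$enc_index <- i
        for (sq in c(pr$y_w, pr$y_l)) {
          comp <- max(table(strsplit(sq, "")[[1]])) / nchar(sq)
          if (comp > 0.9) collapse <- collapse + 1L
        }
        pairs[[length(pairs) + 1L]] <- pr
      }
    }
    if (length(pairs) > 0 && collapse >= length(pairs)) {
      stop("alignment diverged: sampled sequences collapsed to near-constant ",
           "chains (lower the learning rate or beta)")
    }
    mvw <- mean(vapply(pairs, `[[`, numeric(1), "visibility_w"))
    mvl <- mean(vapply(pairs, `[[`, numeric(1), "visibility_l"))
    for (sub in seq_len(epochs_per_refresh)) {
      ep <- ep + 1L
      ep_loss <- 0; nb <- 0L
      if (length(pairs) > 0) {
        idx <- sample(seq_along(pairs))
        batches <- make_batches(pairs, idx, batch_size, max_tokens_per_batch)
        for (b in batches) {
          bp <- lapply(b, function(j) {
            pr <- pairs[[j]]
            pr$enc <- encs[[pr$enc_index]]
            pr
          })
          model$dec <- unflatten_params(model$dec, flat)
          st <- dpo_batch_step(model, flat, state, bp, beta, lr)
          if (!is.finite(st$loss)) {
            stop("alignment diverged: non-finite DPO loss at epoch ", ep,
                 " (likely too-high beta or learning rate)")
          }
          flat <- st$flat; state <- st$state
          ep_loss <- ep_loss + st$loss; nb <- nb + 1L
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = if (nb) ep_loss / nb else NA_real_,
        mean_vis_w = mvw, mean_vis_l = mvl, n_pairs = length(pairs)))
      if (ep %in% checkpoint_epochs) {
        model$dec <- unflatten_params(model$dec, flat)
        checkpoints[[paste0("epoch_", ep)]] <- model
      }
      if (ep >= total_epochs) break
    }
  }
  model$dec <- unflatten_params(model$dec, flat)
  structure(list(model = model, base_model = base_model,
                 checkpoints = checkpoints, history = history,
                 hyperparams = list(beta = beta, temperature = temperature,
                                    lr = lr,
                                    epochs_per_refresh = epochs_per_refresh),
                 diverged = diverged, seed = seed),
            class = "dpo_fit")
}

# split pair indices into batches respecting both the pair-count and the
# token budget (each pair contributes both its sequences)
make_batches <- function(pairs, idx, batch_size, max_tokens) {
  batches <- list(); cur <- integer(0); tok <- 0L
  for (j in idx) {
    tj <- nchar(pairs[[j]]$y_w) + nchar(pairs[[j]]$y_l)
    if (length(cur) > 0 &&
        (length(cur) >= batch_size || tok + tj > max_tokens)) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); tok <- 0L
    }
    cur <- c(cur, j); tok <- tok + tj
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  batches
}

#' @export
print.dpo_fit <- function(x, ...) {
  hp <- x$hyperparams
  cat("DPO alignment fit\n")
  cat(sprintf("  beta %.4g | temperature %.3g | lr %.3g | refresh every %d epochs\n",
              hp$beta, hp$temperature, hp$lr, hp$epochs_per_refresh))
  cat(sprintf("  epochs: %d | checkpoints: %s\n", nrow(x$history),
              if (length(x$checkpoints)) paste(names(x$checkpoints), collapse = ", ")
              else "none"))
  h <- x$history
  cat(sprintf("  final loss %.4f | preferred/dispreferred visibility %.2f / %.2f\n",
              h$loss[nrow(h)], h$mean_vis_w[nrow(h)], h$mean_vis_l[nrow(h)]))
  invisible(x)
}

#' @export
plot.dpo_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "DPO loss",
                 main = "training loss", ...)
  graphics::abline(h = log(2), lty = 2)
  graphics::matplot(h$epoch, cbind(h$mean_vis_w, h$mean_vis_l), type = "b",
                    pch = c(1, 2), xlab = "epoch", ylab = "mean visibility",
                    main = "preference-pair visibility")
  graphics::legend("topright", c("preferred", "dispreferred"), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Named DPO hyperparameter presets
#'
#' The two selected fine-tuning configurations of the trade-off analysis,
#' keyed by their run identifiers.
#'
#' @return Named list; each entry has `beta`, `temperature`, `lr`.
#' @export
dpo_presets <- function() {
  list(
    `458340e4` = list(beta = 3.43e-2, temperature = 0.759, lr = 2.86e-6),
    `e32b8ed0` = list(beta = 4.48e-3, temperature = 0.500, lr = 4.62e-7)
  )
}

#' Sample DPO hyperparameters from the sweep distributions
#'
#' `beta ~ log-uniform(0.001, 0.2)`, `temperature ~ uniform(0.01, 1.0)`,
#' `lr ~ log-uniform(1e-7, 1e-3)`.
#'
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Data frame with columns `beta`, `temperature`, `lr`.
#' @export
sample_dpo_hyperparams <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    beta = exp(stats::runif(n, log(0.001), log(0.2))),
    temperature = stats::runif(n, 0.01, 1.0),
    lr = exp(stats::runif(n, log(1e-7), log(1e-3)))
  )
}

#' Random hyperparameter sweep of DPO alignment runs
#'
#' Runs `n_runs` alignments with hyperparameters drawn from
#' [sample_dpo_hyperparams()] and evaluates each stored checkpoint's mean
#' absolute visibility and mean sequence recovery on the evaluation set.
#' Diverged runs are recorded (status `"failed"`) and do not abort the sweep.
#'
#' @param base_model Frozen base `design_model`.
#' @param structures Training backbones.
#' @param predictor Presentation predictor for preference feedback and
#'   evaluation.
#' @param n_runs Number of alignment runs.
#' @param total_epochs Epochs per run.
#' @param checkpoint_epochs Checkpoint epochs to evaluate.
#' @param eval_structures,eval_sequences Evaluation backbones and their
#'   native sequences (defaults: the training set).
#' @param seed Integer seed.
#' @return Data frame with one row per (run, checkpoint): hyperparameters,
#'   status, mean visibility, mean recovery.
#' @export
dpo_sweep <- function(base_model, structures, predictor, n_runs,
                      total_epochs = 4L, checkpoint_epochs = c(2L, 4L),
                      eval_structures = structures, eval_sequences = NULL,
                      seed = 1L) {
  if (n_runs == 0)
    return(data.frame(run = integer(0), beta = numeric(0),
                      temperature = numeric(0), lr = numeric(0),
                      checkpoint = character(0), status = character(0),
                      mean_visibility = numeric(0),
                      mean_recovery = numeric(0)))
  hp <- sample_dpo_hyperparams(n_runs, seed = seed)
  out <- list()
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      dpo_align(base_model, structures, predictor, beta = hp$beta[r],
                temperature = hp$temperature[r], lr = hp$lr[r],
                total_epochs = total_epochs,
                checkpoint_epochs = checkpoint_epochs,
                seed = seed + r),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out[[length(out) + 1L]] <- data.frame(
        run = r, beta = hp$beta[r], temperature = hp$temperature[r],
        lr = hp$lr[r], checkpoint = NA_character_, status = "failed",
        mean_visibility = NA_real_, mean_recovery = NA_real_)
      next
    }
    for (nm in names(fit$checkpoints)) {
      ev <- checkpoint_vis_recovery(fit$checkpoints[[nm]], eval_structures,
                                    eval_sequences, predictor,
                                    seed = seed + 1000L + r)
      out[[length(out) + 1L]] <- data.frame(
        run = r, beta = hp$beta[r], temperature = hp$temperature[r],
        lr = hp$lr[r], checkpoint = nm, status = "ok",
        mean_visibility = ev$mean_visibility,
        mean_recovery = ev$mean_recovery)
    }
  }
  do.call(rbind, out)
}

# mean visibility / recovery of single samples per evaluation structure
checkpoint_vis_recovery <- function(model, structures, sequences, predictor,
                                    seed = 1L, temperature = 1.0,
                                    samples_per_structure = 1L) {
  set.seed(seed)
  vis <- numeric(0); rec <- numeric(0)
  for (i in seq_along(structures)) {
    enc <- encode_backbone(model, structures[[i]])
    for (s in seq_len(samples_per_structure)) {
      sm <- sample_sequence(model, temperature = temperature, encoding = enc)
      vis <- c(vis, absolute_visibility(sm$sequence, predictor)$absolute_visibility)
      if (!is.null(sequences))
        rec <- c(rec, sequence_recovery(sm$sequence, sequences[[i]]))
    }
  }
  list(mean_visibility = mean(vis),
       mean_recovery = if (length(rec)) mean(rec) else NA_real_)
}

#' Write / read preference-pair datasets (JSON lines)
#'
#' One pair per line: sequences, decoding orders, reference log-probs,
#' visibilities and the backbone identifier.
#'
#' @param pairs List of `preference_pair` objects.
#' @param path Output path.
#' @return `read_preference_pairs` returns a list of `preference_pair`s.
#' @export
write_preference_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pr in pairs) {
    keep <- pr[c("y_w", "y_l", "order_w", "order_l", "ref_log_prob_w",
                 "ref_log_prob_l", "visibility_w", "visibility_l")]
    keep$structure_ref <- if (is.null(pr$structure_ref)) NA else pr$structure_ref
    writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_preference_pairs
#' @export
read_preference_pairs <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    obj$order_w <- as.integer(obj$order_w)
    obj$order_l <- as.integer(obj$order_l)
    class(obj) <- "preference_pair"
    obj
  })
}
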