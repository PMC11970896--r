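# Miniature structure-conditioned sequence-design model.
#
# The architecture follows the message-passing encoder / arbitrary-order
# autoregressive decoder contract of fixed-backbone inverse-folding models:
# residues are nodes of a k-nearest-neighbor graph (CA-CA distances), node and
# edge features are rigid-motion invariant (distances and chain offsets only),
# the encoder message-passes over the graph, and the decoder emits one amino
# acid per step in a random decoding order, conditioning on the backbone
# embedding and the already-decoded neighbors.
#
# The encoder weights are seeded at initialization and frozen; the trainable
# parameters are the decoder (token-embedding context, tanh MLP, output
# layer). This keeps every gradient analytic in base R matrix algebra while
# preserving the interface of the full-scale models. The output layer is
# zero-initialized, so a fresh model emits the uniform distribution over the
# 21-token vocabulary (20 amino acids + 'X').

RBF_CENTERS <- seq(2, 22, length.out = 8)
RBF_SIGMA <- 2.5
N_EDGE_FEAT <- length(RBF_CENTERS) + 2L  # RBF(d) + offset sign + scaled offset
N_NODE_FEAT <- 7L

#' Model configuration
#'
#' @param feature_dim Embedding width `D` (default 64; 128 matches the
#'   full-scale preset).
#' @param n_neighbors Neighbors per residue in the k-NN graph (default 16;
#'   48 matches the full-scale preset). Clamped to `L - 1` for short chains.
#' @param encoder_layers,decoder_layers Number of message-passing /
#'   decoder-MLP layers (default 2 + 2).
#' @return A `model_config` list. The vocabulary size is fixed at 21
#'   (20 amino acids plus the unknown token `'X'`, which is input-only:
#'   its logit is masked when sampling).
#' @export
model_config <- function(feature_dim = 64L, n_neighbors = 16L,
                         encoder_layers = 2L, decoder_layers = 2L) {
  stopifnot(feature_dim >= 1, n_neighbors >= 1,
            encoder_layers >= 1, decoder_layers >= 1)
  structure(list(vocab = 21L, feature_dim = as.integer(feature_dim),
                 n_neighbors = as.integer(n_neighbors),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = as.integer(decoder_layers)),
            class = "model_config")
}

#' Initialize a design model
#'
#' Encoder weights are drawn from seeded Gaussians (scaled by fan-in) and are
#' fixed thereafter; decoder hidden layers are seeded Gaussians and the output
#' layer starts at zero, so the untrained model is exactly uniform over the
#' vocabulary.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `design_model` object.
#' @export
init_design_model <- function(config = model_config(), seed = 1L) {
  set.seed(seed)
  D <- config$feature_dim
  V <- config$vocab
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  enc <- list(W_in = rnd(D, N_NODE_FEAT), layers = vector("list", config$encoder_layers))
  for (l in seq_len(config$encoder_layers)) {
    enc$layers[[l]] <- list(S = rnd(D, D), A = rnd(D, D + N_EDGE_FEAT),
                            b = stats::rnorm(D, sd = 0.01))
  }
  dec <- list(E = rnd(D, V), Wh = vector("list", config$decoder_layers),
              bh = vector("list", config$decoder_layers),
              W_out = matrix(0, V, D), b_out = numeric(V))
  for (l in seq_len(config$decoder_layers)) {
    nc <- if (l == 1L) 2L * D else D
    dec$Wh[[l]] <- rnd(D, nc)
    dec$bh[[l]] <- stats::rnorm(D, sd = 0.01)
  }
  structure(list(config = config, enc = enc, dec = dec, seed = seed),
            class = "design_model")
}

#' @export
print.design_model <- function(x, ...) {
  cfg <- x$config
  cat("Structure-conditioned sequence-design model\n")
  cat(sprintf("  vocab %d | D=%d | k-NN=%d | enc layers %d | dec layers %d\n",
              cfg$vocab, cfg$feature_dim, cfg$n_neighbors,
              cfg$encoder_layers, cfg$decoder_layers))
  cat("  trainable parameters:", n_trainable(x), "\n")
  invisible(x)
}

n_trainable <- function(model) {
  sum(vapply(flatten_params(model$dec), length, numeric(1)))
}

flatten_params <- function(dec) {
  out <- list(E = dec$E, W_out = dec$W_out, b_out = dec$b_out)
  for (l in seq_along(dec$Wh)) {
    out[[paste0("Wh", l)]] <- dec$Wh[[l]]
    out[[paste0("bh", l)]] <- dec$bh[[l]]
  }
  out
}

unflatten_params <- function(dec, flat) {
  dec$E <- flat$E; dec$W_out <- flat$W_out; dec$b_out <- flat$b_out
  for (l in seq_along(dec$Wh)) {
    dec$Wh[[l]] <- flat[[paste0("Wh", l)]]
    dec$bh[[l]] <- flat[[paste0("bh", l)]]
  }
  dec
}

# ---------------------------------------------------------------------------
# Featurization and encoder

node_features <- function(structure) {
  co <- structure$coords
  L <- dim(co)[1]
  ca <- matrix(co[, "CA", ], nrow = L)
  dist_to <- function(a, b) sqrt(rowSums((a - b)^2))
  f <- matrix(0, N_NODE_FEAT, L)
  f[1, ] <- dist_to(matrix(co[, "N", ], L), ca)
  f[2, ] <- dist_to(matrix(co[, "C", ], L), ca)
  f[3, ] <- dist_to(matrix(co[, "C", ], L), matrix(co[, "O", ], L))
  shift_d <- function(k) {
    d <- rep(0, L)
    idx <- seq_len(L)
    ok <- idx + k >= 1 & idx + k <= L
    d[ok] <- sqrt(rowSums((ca[idx[ok], , drop = FALSE] -
                           ca[idx[ok] + k, , drop = FALSE])^2))
    d
  }
  f[4, ] <- shift_d(-1); f[5, ] <- shift_d(1)
  f[6, ] <- shift_d(-2); f[7, ] <- shift_d(2)
  f / 10  # keep features O(1)
}

rbf_encode <- function(d) {
  # d: vector -> matrix length(RBF_CENTERS) x length(d)
  vapply(d, function(x) exp(-((x - RBF_CENTERS)^2) / (2 * RBF_SIGMA^2)),
         numeric(length(RBF_CENTERS)))
}

#' Encode a backbone structure
#'
#' Runs the frozen featurization and message-passing encoder. Node and edge
#' features are built from pairwise distances and chain offsets only, so the
#' embeddings are exactly invariant under rigid motions of the coordinates.
#'
#' @param model A [init_design_model()] model.
#' @param structure A [backbone_structure()].
#' @return A `backbone_encoding`: list with `H` (`D x L` node embeddings),
#'   `nbr` (`k x L` neighbor indices) and `L`.
#' @export
encode_backbone <- function(model, structure) {
  stopifnot(inherits(model, "design_model"),
            inherits(structure, "backbone_structure"))
  if (!all(is.finite(structure$coords)))
    stop("backbone coordinates must be finite")
  L <- n_residues(structure)
  k <- min(model$config$n_neighbors, L - 1L)
  if (k < 1L) k <- 0L
  ca <- matrix(structure$coords[, "CA", ], nrow = L)
  dm <- as.matrix(stats::dist(ca))
  diag(dm) <- Inf
  nbr <- matrix(0L, max(k, 0L), L)
  if (k > 0L)
    for (i in seq_len(L)) nbr[, i] <- order(dm[, i])[seq_len(k)]

  f <- node_features(structure)
  H <- model$enc$W_in %*% f
  if (k > 0L) {
    # edge features per neighbor slot: RBF distance + sequence offset
    edge <- vector("list", k)
    for (s in seq_len(k)) {
      j <- nbr[s, ]
      d <- dm[cbind(j, seq_len(L))]
      off <- j - seq_len(L)
      edge[[s]] <- rbind(rbf_encode(d), sign(off), pmin(abs(off), 32) / 32)
    }
    for (lay in model$enc$layers) {
      M <- matrix(0, nrow(H), L)
      for (s in seq_len(k))
        M <- M + lay$A %*% rbind(H[, nbr[s, ], drop = FALSE], edge[[s]])
      H <- tanh(lay$S %*% H + M / k + lay$b)
    }
  } else {
    for (lay in model$enc$layers) H <- tanh(lay$S %*% H + lay$b)
  }
  out <- list(H = H, nbr = nbr, L = L, k = k)
  class(out) <- "backbone_encoding"
  out
}

# ---------------------------------------------------------------------------
# Decoder

tokens_from_sequence <- function(sequence) {
  tok <- match(strsplit(sequence, "")[[1]], aa_alphabet_x())
  if (anyNA(tok)) stop("sequence contains non-amino-acid characters")
  tok
}

sequence_from_tokens <- function(tokens) {
  paste(aa_alphabet_x()[tokens], collapse = "")
}

# context-normalization matrix: entry [j, i] = 1/n_i if j is a neighbor of i
# already decoded when i is emitted
context_matrix <- function(enc, order) {
  L <- enc$L
  rank <- integer(L); rank[order] <- seq_len(L)
  M <- matrix(0, L, L)
  if (enc$k > 0L) {
    for (s in seq_len(enc$k)) {
      j <- enc$nbr[s, ]
      sel <- rank[j] < rank[seq_len(L)]
      M[cbind(j[sel], which(sel))] <- 1
    }
    n <- colSums(M)
    n[n == 0] <- 1
    M <- sweep(M, 2, n, "/")
  }
  M
}

# full decoder forward for a known token sequence; returns caches for backprop
decoder_forward <- function(model, enc, tokens, order) {
  L <- enc$L
  dec <- model$dec
  V <- model$config$vocab
  M <- context_matrix(enc, order)
  Tok <- matrix(0, V, L)
  Tok[cbind(tokens, seq_len(L))] <- 1
  TM <- Tok %*% M                      # V x L
  C <- dec$E %*% TM                    # D x L
  Zs <- vector("list", length(dec$Wh) + 1L)
  Zs[[1]] <- rbind(enc$H, C)
  for (l in seq_along(dec$Wh))
    Zs[[l + 1L]] <- tanh(dec$Wh[[l]] %*% Zs[[l]] + dec$bh[[l]])
  logits <- dec$W_out %*% Zs[[length(Zs)]] + dec$b_out
  mx <- apply(logits, 2, max)
  lse <- mx + log(colSums(exp(sweep(logits, 2, mx))))
  log_p <- sweep(logits, 2, lse)       # V x L log-softmax
  list(log_p = log_p, Zs = Zs, TM = TM, logits = logits)
}

#' Next-token distribution of the arbitrary-order decoder
#'
#' Probability vector over the 21-token vocabulary for the residue decoded at
#' `step` of `order`, conditioning on the backbone encoding and the tokens
#' already placed at `order[1..step-1]`. Probabilities are nonnegative and sum
#' to 1; a freshly initialized model returns the uniform 1/21 vector.
#'
#' @param model A `design_model`.
#' @param encoding A [encode_backbone()] result.
#' @param partial_tokens Integer vector (length `L`) of vocabulary indices;
#'   only the entries at `order[1..step-1]` are read and they must be set.
#' @param order Decoding order (permutation of `1..L`).
#' @param step Step being decoded (1-based).
#' @return Numeric vector of 21 probabilities.
#' @export
next_token_distribution <- function(model, encoding, partial_tokens, order, step) {
  L <- encoding$L
  if (step < 1L || step > L) stop("`step` out of range")
  if (!setequal(order, seq_len(L))) stop("`order` must be a permutation of 1..L")
  decoded <- order[seq_len(step - 1L)]
  if (anyNA(partial_tokens[decoded]))
    stop("partial sequence is missing tokens decoded before `step`")
  i <- order[step]
  dec <- model$dec
  if (encoding$k > 0L) {
    nb <- encoding$nbr[, i]
    ctx <- intersect(nb, decoded)
  } else ctx <- integer(0)
  C <- if (length(ctx)) rowMeans(dec$E[, partial_tokens[ctx], drop = FALSE])
       else numeric(model$config$feature_dim)
  z <- c(encoding$H[, i], C)
  for (l in seq_along(dec$Wh)) z <- tanh(dec$Wh[[l]] %*% z + dec$bh[[l]])
  logits <- as.numeric(dec$W_out %*% z + dec$b_out)
  p <- exp(logits - max(logits))
  p / sum(p)
}

#' Sample a sequence for a backbone
#'
#' Draws a uniformly random decoding order, then samples each residue from
#' the temperature-scaled next-token distribution. The `'X'` token is masked
#' at the draw (it is an input-only vocabulary entry). The returned per-token
#' log-probabilities are the *untempered* model log-probabilities of the
#' realized tokens (full 21-way softmax), so their sum equals
#' [sequence_log_prob()] of the sampled sequence under the same order;
#' temperature shapes the draw only.
#'
#' @param model A `design_model`.
#' @param structure A [backbone_structure()], or a precomputed encoding via
#'   `encoding`.
#' @param temperature Sampling temperature (> 0). Low values approach greedy
#'   argmax decoding.
#' @param seed Optional integer seed.
#' @param order Optional fixed decoding order (default: sampled uniformly).
#' @param encoding Optional precomputed [encode_backbone()] result.
#' @return List with `sequence` (string), `tokens`, `order`, and `log_probs`
#'   (per sequence position).
#' @export
sample_sequence <- function(model, structure = NULL, temperature = 1.0,
                            seed = NULL, order = NULL, encoding = NULL) {
  if (temperature <= 0) stop("`temperature` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  enc <- if (is.null(encoding)) encode_backbone(model, structure) else encoding
  L <- enc$L
  dec <- model$dec
  D <- model$config$feature_dim
  if (is.null(order)) order <- sample.int(L)
  tokens <- integer(L)
  logp <- numeric(L)
  x_tok <- model$config$vocab  # 'X' is the last vocabulary entry
  for (step in seq_len(L)) {
    i <- order[step]
    if (enc$k > 0L) {
      decoded <- order[seq_len(step - 1L)]
      ctx <- intersect(enc$nbr[, i], decoded)
    } else ctx <- integer(0)
    C <- if (length(ctx)) rowMeans(dec$E[, tokens[ctx], drop = FALSE])
         else numeric(D)
    z <- c(enc$H[, i], C)
    for (l in seq_along(dec$Wh)) z <- tanh(dec$Wh[[l]] %*% z + dec$bh[[l]])
    logits <- as.numeric(dec$W_out %*% z + dec$b_out)
    log_p_full <- logits - (max(logits) + log(sum(exp(logits - max(logits)))))
    masked <- logits
    masked[x_tok] <- -Inf
    scaled <- (masked - max(masked)) / temperature
    p <- exp(scaled)
    p <- p / sum(p)
    tok <- sample.int(model$config$vocab, 1L, prob = p)
    tokens[i] <- tok
    logp[i] <- log_p_full[tok]
  }
  list(sequence = sequence_from_tokens(tokens), tokens = tokens,
       order = order, log_probs = logp)
}

#' Log-probability of a sequence under the model
#'
#' Sum over decoding steps of the log-probability of the realized token under
#' the full 21-way next-token softmax, conditioned on the given decoding
#' order: `log pi(y | x, order)`. For fixed order the probabilities over all
#' vocabulary^L sequences sum to 1.
#'
#' @inheritParams sample_sequence
#' @param sequence Amino-acid string of length `L`.
#' @param order Decoding order (permutation of `1..L`).
#' @return Scalar log-probability.
#' @export
sequence_log_prob <- function(model, structure = NULL, sequence, order,
                              encoding = NULL) {
  enc <- if (is.null(encoding)) encode_backbone(model, structure) else encoding
  tokens <- tokens_from_sequence(sequence)
  if (length(tokens) != enc$L)
    stop("sequence length does not match the structure")
  fw <- decoder_forward(model, enc, tokens, order)
  sum(fw$log_p[cbind(tokens, seq_len(enc$L))])
}

# gradient of log pi(sequence | structure, order) w.r.t. decoder parameters
grad_sequence_log_prob <- function(model, enc, tokens, order) {
  dec <- model$dec
  L <- enc$L
  V <- model$config$vocab
  D <- model$config$feature_dim
  fw <- decoder_forward(model, enc, tokens, order)
  P <- exp(fw$log_p)
  dlogits <- -P
  dlogits[cbind(tokens, seq_len(L))] <- dlogits[cbind(tokens, seq_len(L))] + 1
  Zs <- fw$Zs
  nh <- length(dec$Wh)
  g <- list(E = NULL, W_out = dlogits %*% t(Zs[[nh + 1L]]),
            b_out = rowSums(dlogits))
  dZ <- t(dec$W_out) %*% dlogits
  for (l in rev(seq_len(nh))) {
    dA <- dZ * (1 - Zs[[l + 1L]]^2)
    g[[paste0("Wh", l)]] <- dA %*% t(Zs[[l]])
    g[[paste0("bh", l)]] <- rowSums(dA)
    dZ <- t(dec$Wh[[l]]) %*% dA
  }
  dC <- dZ[(D + 1L):(2L * D), , drop = FALSE]
  g$E <- dC %*% t(fw$TM)
  list(grad = g, log_prob = sum(fw$log_p[cbind(tokens, seq_len(L))]))
}

# ---------------------------------------------------------------------------
# Optimizer and supervised training

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(flat, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1.0) {
  # global gradient-norm clipping for stability
  gnorm <- sqrt(sum(vapply(grad, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip)
    grad <- lapply(grad, function(g) g * (clip / gnorm))
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

#' Supervised (cross-entropy) fitting of the design model
#'
#' Maximizes the arbitrary-order autoregressive log-likelihood of native
#' sequences given their backbones: at every visit a fresh uniform decoding
#' order is drawn and one Adam step is taken on the categorical
#' cross-entropy. This is how the package builds its own base model for the
#' alignment experiments (an analogue, at desk scale, of the
#' native-sequence-recovery training of full-scale inverse-folding models).
#'
#' @param model A `design_model`.
#' @param structures List of [backbone_structure()]s.
#' @param sequences Character vector of native sequences (same length/order).
#' @param epochs Passes over the structure set.
#' @param lr Adam learning rate.
#' @param seed Integer seed (decoding orders and example shuffling).
#' @return The fitted `design_model` (attribute `"nll_trace"` holds the mean
#'   per-residue negative log-likelihood per epoch).
#' @export
train_supervised <- function(model, structures, sequences, epochs = 20L,
                             lr = 1e-3, seed = 1L) {
  stopifnot(length(structures) == length(sequences))
  set.seed(seed)
  encs <- lapply(structures, function(s) encode_backbone(model, s))
  toks <- lapply(sequences, tokens_from_sequence)
  flat <- flatten_params(model$dec)
  state <- adam_init(flat)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample(seq_along(structures))
    nll <- 0; ntok <- 0
    for (i in idx) {
      model$dec <- unflatten_params(model$dec, flat)
      ord <- sample.int(encs[[i]]$L)
      gr <- grad_sequence_log_prob(model, encs[[i]], toks[[i]], ord)
      # minimize NLL = ascend log-likelihood
      neg <- lapply(gr$grad, function(g) -g)
      st <- adam_step(flat, neg, state, lr)
      flat <- st$flat; state <- st$state
      nll <- nll - gr$log_prob; ntok <- ntok + encs[[i]]$L
    }
    trace[ep] <- nll / ntok
  }
  model$dec <- unflatten_params(model$dec, flat)
  attr(model, "nll_trace") <- trace
  model
}

# ---------------------------------------------------------------------------
# Serialization

#' Save / load a design model checkpoint
#'
#' JSON checkpoints store the configuration, all encoder and decoder weights
#' (better than 1e-12 relative precision), and the initialization seed.
#'
#' @param model A `design_model`.
#' @param path Checkpoint path (JSON).
#' @return `read_model` returns the `design_model`.
#' @export
write_model <- function(model, path) {
  pack <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else if (is.numeric(x)) list(dim = length(x), data = as.numeric(x))
    else lapply(x, pack)
  }
  obj <- list(config = unclass(model$config), seed = model$seed,
              enc = pack(model$enc), dec = pack(model$dec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- do.call(model_config, obj$config[c("feature_dim", "n_neighbors",
                                            "encoder_layers", "decoder_layers")])
  unpack <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      d <- as.integer(unlist(x$dim))
      v <- as.numeric(unlist(x$data))
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    } else lapply(x, unpack)
  }
  structure(list(config = cfg, enc = unpack(obj$enc), dec = unpack(obj$dec),
                 seed = obj$seed),
            class = "design_model")
}
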