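# The attribute selection hybrid network: CNN post encoder, four attribute
# encoders (part-of-speech GRU, sentiment GRU, symptom-matrix similarity,
# ruminative dot-product relevance), softmax attribute fusion, post-level
# attention and the output classifier, plus the bidirectional-GRU baseline.

#' Model configuration
#'
#' Hyperparameters of the network and its training loop. Defaults are the
#' published full-scale assignment (50 epochs, batch size 64, gradient-norm
#' clip 8.0, pre-encode feedforward 3 x 232 with tanh, encoder hidden size
#' 93 with 2 layers, integrator 337 x 3 with dropout 0.1, output network
#' 3 x 384 with dropout 0.2, learning rate 1e-4, embedding dropout 0.2 for
#' the attribute model and 0.3 for the bidirectional baseline). For desk-scale
#' experiments see [ashn_config_demo()].
#'
#' @param architecture `"ashn"` (attribute network) or `"birnn"` (baseline).
#' @param embedding_dim Word-embedding dimension.
#' @param embedding_dropout Dropout rate on embeddings during training;
#'   defaults to 0.2 for `"ashn"`, 0.3 for `"birnn"`.
#' @param pre_encode_layers,pre_encode_hidden,pre_encode_activation,pre_encode_dropout
#'   Feedforward network applied token-wise to embeddings before encoding
#'   (`pre_encode_layers = 0` disables it).
#' @param encoder_hidden,encoder_layers GRU hidden size and stacked layers
#'   for the sequence encoders.
#' @param integrator_hidden,integrator_layers,integrator_dropout The fusion
#'   (integrator) feedforward network producing the five attribute weights.
#' @param output_layers,output_hidden,output_dropout The output classifier
#'   network.
#' @param pool_size Pooling length from the published assignment; the post
#'   encoder pools max-over-time (a global maximum), which subsumes any
#'   segment pooling length, so this value is recorded but inert.
#' @param conv_width Convolution window width of the CNN post encoder (must
#'   not exceed the minimum post token count, 5).
#' @param post_dim Number of convolution filters (the post-encoding
#'   dimension).
#' @param attr_dim Attribute-vector dimension `d_a`.
#' @param a4_len Fixed length the rumination relevance distribution is
#'   right-padded/truncated to (default 245, the per-user training sample
#'   size).
#' @param grad_clip Global gradient-norm clip.
#' @param epochs,batch_size,learning_rate,l2 Training-loop settings (Adam
#'   optimizer; `l2` is the L2 regularization rate).
#' @param sample_posts Number of posts sampled per user for training.
#' @param threshold Classification threshold on the depressed-class
#'   probability.
#' @param seed Seed for parameter initialization and training shuffles.
#' @return A validated list of class `"ashn_config"`.
#' @export
ashn_config <- function(architecture = c("ashn", "birnn"),
                        embedding_dim = 100L,
                        embedding_dropout = NULL,
                        pre_encode_layers = 3L, pre_encode_hidden = 232L,
                        pre_encode_activation = c("tanh", "relu"),
                        pre_encode_dropout = 0,
                        encoder_hidden = 93L, encoder_layers = 2L,
                        integrator_hidden = 337L, integrator_layers = 3L,
                        integrator_dropout = 0.1,
                        output_layers = 3L, output_hidden = 384L,
                        output_dropout = 0.2,
                        pool_size = 6L, conv_width = 3L,
                        post_dim = 100L, attr_dim = 64L, a4_len = 245L,
                        grad_clip = 8.0,
                        epochs = 50L, batch_size = 64L,
                        learning_rate = 1e-4, l2 = 1e-4,
                        sample_posts = 245L,
                        threshold = 0.5, seed = 42L) {
  architecture <- match.arg(architecture)
  if (is.null(embedding_dropout)) {
    embedding_dropout <- if (architecture == "birnn") 0.3 else 0.2
  }
  cfg <- list(architecture = architecture,
              embedding_dim = as.integer(embedding_dim),
              embedding_dropout = embedding_dropout,
              pre_encode_layers = as.integer(pre_encode_layers),
              pre_encode_hidden = as.integer(pre_encode_hidden),
              pre_encode_activation = match.arg(pre_encode_activation),
              pre_encode_dropout = pre_encode_dropout,
              encoder_hidden = as.integer(encoder_hidden),
              encoder_layers = as.integer(encoder_layers),
              integrator_hidden = as.integer(integrator_hidden),
              integrator_layers = as.integer(integrator_layers),
              integrator_dropout = integrator_dropout,
              output_layers = as.integer(output_layers),
              output_hidden = as.integer(output_hidden),
              output_dropout = output_dropout,
              pool_size = as.integer(pool_size),
              conv_width = as.integer(conv_width),
              post_dim = as.integer(post_dim),
              attr_dim = as.integer(attr_dim),
              a4_len = as.integer(a4_len),
              grad_clip = grad_clip,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, l2 = l2,
              sample_posts = as.integer(sample_posts),
              threshold = threshold, seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  sizes <- c("embedding_dim", "pre_encode_hidden", "encoder_hidden",
             "encoder_layers", "integrator_hidden", "integrator_layers",
             "output_layers", "output_hidden", "pool_size", "conv_width",
             "post_dim", "attr_dim", "a4_len", "batch_size")
  for (s in sizes) if (cfg[[s]] < 1L) stop(s, " must be >= 1")
  drops <- c("embedding_dropout", "pre_encode_dropout", "integrator_dropout",
             "output_dropout")
  for (d in drops) if (cfg[[d]] < 0 || cfg[[d]] >= 1) stop(d, " must lie in [0, 1)")
  if (cfg$threshold <= 0 || cfg$threshold >= 1) stop("threshold must lie in (0, 1)")
  if (cfg$epochs < 0L) stop("epochs must be >= 0")
  if (cfg$conv_width > 5L) stop("conv_width must not exceed the minimum post length (5 tokens)")
  structure(cfg, class = "ashn_config")
}

#' Desk-scale model configuration
#'
#' A small configuration for simulation experiments, examples and tests:
#' 16-dimensional embeddings, single-layer 16-unit feedforward blocks,
#' 12-unit GRUs, 20 convolution filters, 12-dimensional attributes, 10
#' epochs at learning rate 0.01 with batch size 8 and 50 posts sampled per
#' user. Architectural form is identical to [ashn_config()].
#'
#' @param ... Overrides passed on to [ashn_config()].
#' @return An `"ashn_config"` object.
#' @export
ashn_config_demo <- function(...) {
  args <- list(embedding_dim = 16L, embedding_dropout = NULL,
               pre_encode_layers = 1L, pre_encode_hidden = 16L,
               encoder_hidden = 12L, encoder_layers = 1L,
               integrator_hidden = 16L, integrator_layers = 2L,
               integrator_dropout = 0,
               output_layers = 2L, output_hidden = 16L, output_dropout = 0,
               conv_width = 3L, post_dim = 20L, attr_dim = 12L,
               a4_len = 50L, epochs = 10L, batch_size = 8L,
               learning_rate = 0.01, l2 = 1e-5, sample_posts = 50L)
  user <- list(...)
  args[names(user)] <- user
  do.call(ashn_config, args)
}

#' Read a model configuration from YAML
#'
#' Field names mirror [ashn_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return An `"ashn_config"` object.
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  do.call(ashn_config, yaml::yaml.load_file(path))
}

# ---------------------------------------------------------------------------
# parameter initialization (seeded uniform Glorot ranges)

.glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

.make_linear <- function(n_in, n_out) {
  list(W = ad_param(.glorot(n_in, n_out)), b = ad_param(matrix(0, 1L, n_out)))
}

# an n_layers feedforward net: (n_layers - 1) hidden layers of width `hidden`
.make_mlp <- function(n_in, hidden, n_out, n_layers) {
  sizes <- if (n_layers <= 1L) c(n_in, n_out) else
    c(n_in, rep(hidden, n_layers - 1L), n_out)
  lapply(seq_len(length(sizes) - 1L),
         function(i) .make_linear(sizes[i], sizes[i + 1L]))
}

.make_gru <- function(n_in, n_h) {
  list(Wz = ad_param(.glorot(n_in, n_h)), Uz = ad_param(.glorot(n_h, n_h)),
       bz = ad_param(matrix(0, 1L, n_h)),
       Wr = ad_param(.glorot(n_in, n_h)), Ur = ad_param(.glorot(n_h, n_h)),
       br = ad_param(matrix(0, 1L, n_h)),
       Wn = ad_param(.glorot(n_in, n_h)), Un = ad_param(.glorot(n_h, n_h)),
       bn = ad_param(matrix(0, 1L, n_h)))
}

.make_gru_stack <- function(n_in, n_h, n_layers) {
  lapply(seq_len(n_layers), function(l) .make_gru(if (l == 1L) n_in else n_h, n_h))
}

#' Initialize model parameters
#'
#' Creates all trainable arrays of the network with a seeded uniform
#' Glorot-style scheme (seed taken from the configuration).
#'
#' @param config An `"ashn_config"` object.
#' @param vocab_size Number of vocabulary ids (including `UNK` and `PAD`).
#' @return A nested named list of parameter nodes of class
#'   `"ashn_parameters"`.
#' @export
ashn_parameters <- function(config, vocab_size) {
  cfg <- config
  withr_seed(cfg$seed, {
    enc_in <- if (cfg$pre_encode_layers > 0L) cfg$pre_encode_hidden else cfg$embedding_dim
    p <- list(
      emb = ad_param(.glorot(vocab_size, cfg$embedding_dim)),
      pre = if (cfg$pre_encode_layers > 0L)
        .make_mlp(cfg$embedding_dim, cfg$pre_encode_hidden,
                  cfg$pre_encode_hidden, cfg$pre_encode_layers) else list(),
      conv = list(W = lapply(seq_len(cfg$conv_width),
                             function(j) ad_param(.glorot(enc_in, cfg$post_dim))),
                  b = ad_param(matrix(0, 1L, cfg$post_dim))),
      proj0 = .make_linear(cfg$post_dim, cfg$attr_dim),
      gru_pos = .make_gru_stack(48L, cfg$encoder_hidden, cfg$encoder_layers),
      proj1 = .make_linear(cfg$encoder_hidden, cfg$attr_dim),
      gru_sent = .make_gru_stack(3L, cfg$encoder_hidden, cfg$encoder_layers),
      proj2 = .make_linear(cfg$encoder_hidden, cfg$attr_dim),
      W_sym = ad_param(.glorot(cfg$post_dim, cfg$embedding_dim)),
      mlp3 = .make_linear(9L, cfg$attr_dim),
      mlp4 = .make_linear(cfg$a4_len, cfg$attr_dim),
      fusion = .make_mlp(cfg$post_dim, cfg$integrator_hidden, 5L,
                         cfg$integrator_layers),
      W_att = ad_param(.glorot(cfg$attr_dim, cfg$attr_dim)),
      v_ctx = ad_param(.glorot(cfg$attr_dim, 1L)),
      out = .make_mlp(cfg$attr_dim, cfg$output_hidden, 1L, cfg$output_layers),
      gru_fwd = .make_gru_stack(enc_in, cfg$encoder_hidden, cfg$encoder_layers),
      gru_bwd = .make_gru_stack(enc_in, cfg$encoder_hidden, cfg$encoder_layers),
      projb = .make_linear(2L * cfg$encoder_hidden, cfg$attr_dim)
    )
    structure(p, class = "ashn_parameters", vocab_size = vocab_size)
  })
}

# flatten the nested parameter list into a flat list of parameter nodes
flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.environment(x)) {
      out[[prefix]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(x[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  walk(unclass(p), "p")
  out
}

# ---------------------------------------------------------------------------
# forward building blocks (autodiff nodes in, autodiff nodes out)

.act_fun <- function(name) switch(name, tanh = ad_tanh, relu = ad_relu)

.mlp_fwd <- function(x, layers, activation = "tanh", dropout = 0,
                     training = FALSE) {
  act <- .act_fun(activation)
  n <- length(layers)
  for (i in seq_len(n)) {
    x <- ad_add_bias(ad_matmul(x, layers[[i]]$W), layers[[i]]$b)
    if (i < n) {
      x <- act(x)
      if (training && dropout > 0) x <- ad_dropout(x, dropout)
    }
  }
  x
}

# one GRU layer over a list of step inputs (each B x in); masks: list of
# B x h matrices (1 while the sequence is live, 0 on padding)
.gru_layer <- function(steps, masks, g, B, n_h, return_sequence = FALSE) {
  H <- ad_const(matrix(0, B, n_h))
  seq_out <- if (return_sequence) vector("list", length(steps)) else NULL
  for (t in seq_along(steps)) {
    Xt <- steps[[t]]
    z <- ad_sigmoid(ad_add_bias(ad_add(ad_matmul(Xt, g$Wz), ad_matmul(H, g$Uz)), g$bz))
    r <- ad_sigmoid(ad_add_bias(ad_add(ad_matmul(Xt, g$Wr), ad_matmul(H, g$Ur)), g$br))
    n <- ad_tanh(ad_add_bias(ad_add(ad_matmul(Xt, g$Wn),
                                    ad_matmul(ad_mul(r, H), g$Un)), g$bn))
    Hn <- ad_add(ad_sub(n, ad_mul(z, n)), ad_mul(z, H))
    m <- masks[[t]]
    H <- ad_add(ad_mulc(Hn, m), ad_mulc(H, 1 - m))
    if (return_sequence) seq_out[[t]] <- H
  }
  if (return_sequence) list(final = H, seq = seq_out) else list(final = H)
}

# stacked GRU: layer l consumes the step outputs of layer l - 1
.gru_stack_fwd <- function(steps, masks, stack, B, n_h) {
  for (l in seq_along(stack)) {
    res <- .gru_layer(steps, masks, stack[[l]], B, n_h,
                      return_sequence = l < length(stack))
    if (l < length(stack)) steps <- res$seq
  }
  res$final
}

# single-step GRU on plain numeric matrices (exposed for oracle testing)
gru_cell_step <- function(x, h, g) {
  val <- function(p) if (is.environment(p)) p$val else p
  z <- 1 / (1 + exp(-(x %*% val(g$Wz) + h %*% val(g$Uz) + rep(val(g$bz), each = nrow(x)))))
  r <- 1 / (1 + exp(-(x %*% val(g$Wr) + h %*% val(g$Ur) + rep(val(g$br), each = nrow(x)))))
  n <- tanh(x %*% val(g$Wn) + (r * h) %*% val(g$Un) + rep(val(g$bn), each = nrow(x)))
  (1 - z) * n + z * h
}

# CNN post encoder on one post: token embedding rows -> pre-encode
# feedforward -> convolution (width w) -> tanh -> max-over-time
.encode_post_node <- function(ids, params, cfg, training = FALSE) {
  H <- ad_rows(params$emb, ids)
  if (training && cfg$embedding_dropout > 0) H <- ad_dropout(H, cfg$embedding_dropout)
  if (cfg$pre_encode_layers > 0L) {
    H <- .act_fun(cfg$pre_encode_activation)(
      .mlp_fwd(H, params$pre, cfg$pre_encode_activation,
               cfg$pre_encode_dropout, training))
  }
  Tn <- length(ids)
  w <- cfg$conv_width
  if (Tn < w) stop("post shorter than the convolution window")
  Tp <- Tn - w + 1L
  conv <- NULL
  for (j in seq_len(w)) {
    term <- ad_matmul(ad_rows(H, j:(Tp + j - 1L)), params$conv$W[[j]])
    conv <- if (is.null(conv)) term else ad_add(conv, term)
  }
  conv <- ad_tanh(ad_add_bias(conv, params$conv$b))
  ad_maxcol(conv)
}

# symptom matrix node: unit-normalized elementwise product of each
# category's keyword-embedding rows (9 x embedding_dim), built from the
# current embeddings so it tracks them during training
.symptom_matrix_node <- function(emb, keyword_rows) {
  rows <- lapply(keyword_rows, function(idx) {
    p <- ad_rows(emb, idx[1L])
    for (j in seq_along(idx)[-1L]) p <- ad_mul(p, ad_rows(emb, idx[j]))
    p
  })
  ad_unit_rows(ad_vcat(rows))
}

# ---------------------------------------------------------------------------
# full forward pass over one user's encoded posts

# enc: output of encode_user() below
.forward_user <- function(enc, params, cfg, training = FALSE) {
  M <- enc$M
  # per-post CNN encodings
  xs <- vector("list", M)
  for (m in seq_len(M)) {
    xs[[m]] <- .encode_post_node(enc$tok_ids[[m]], params, cfg, training)
  }
  X <- ad_vcat(xs)                                   # M x post_dim

  if (cfg$architecture == "birnn") {
    P <- .baseline_post_vectors(enc, params, cfg, training)
    fusion_w <- matrix(NA_real_, M, 5L)
  } else {
    n_h <- cfg$encoder_hidden
    masks <- lapply(seq_len(enc$Tmax), function(t) {
      matrix(rep(enc$mask[t, ], n_h), M, n_h)
    })
    pos_steps <- lapply(seq_len(enc$Tmax), function(t) {
      m <- matrix(0, M, 48L)
      live <- which(enc$mask[t, ] == 1)
      m[cbind(live, enc$tag_idx[t, live])] <- 1
      ad_const(m)
    })
    sent_steps <- lapply(seq_len(enc$Tmax), function(t) {
      m <- matrix(0, M, 3L)
      live <- which(enc$mask[t, ] == 1)
      m[cbind(live, enc$sent_idx[t, live])] <- 1
      ad_const(m)
    })
    a0 <- ad_add_bias(ad_matmul(X, params$proj0$W), params$proj0$b)
    h1 <- .gru_stack_fwd(pos_steps, masks, params$gru_pos, M, n_h)
    a1 <- ad_add_bias(ad_matmul(h1, params$proj1$W), params$proj1$b)
    h2 <- .gru_stack_fwd(sent_steps, masks, params$gru_sent, M, n_h)
    a2 <- ad_add_bias(ad_matmul(h2, params$proj2$W), params$proj2$b)
    # A3: bilinear similarity against the symptom matrix
    E <- .symptom_matrix_node(params$emb, enc$keyword_rows)
    Y <- ad_softmax_rows(ad_matmul(ad_matmul(X, params$W_sym), ad_t(E)))
    a3 <- ad_tanh(ad_add_bias(ad_matmul(Y, params$mlp3$W), params$mlp3$b))
    # A4: relevance to the user's other posts
    S <- ad_matmul(X, ad_t(X))
    S <- ad_addc(S, diag(-1e9, M))
    # the relevance profile is sorted descending so the attribute does not
    # depend on the storage order of the user's posts
    f4 <- ad_pad_cols(ad_sort_rows_desc(ad_softmax_rows(S)), cfg$a4_len)
    a4 <- ad_tanh(ad_add_bias(ad_matmul(f4, params$mlp4$W), params$mlp4$b))
    # attribute fusion
    wl <- .mlp_fwd(X, params$fusion, "tanh", cfg$integrator_dropout, training)
    w <- ad_softmax_rows(wl)                         # M x 5
    attrs <- list(a0, a1, a2, a3, a4)
    P <- NULL
    for (i in seq_len(5L)) {
      term <- ad_cmul(attrs[[i]], ad_cols(w, i))
      P <- if (is.null(P)) term else ad_add(P, term)
    }
    fusion_w <- w$val
  }

  # post-level attention
  scores <- ad_t(ad_matmul(ad_matmul(P, params$W_att), params$v_ctx))  # 1 x M
  att <- ad_softmax_rows(scores)
  o <- ad_matmul(att, P)                                               # 1 x d_a
  logit <- .mlp_fwd(o, params$out, "tanh", cfg$output_dropout, training)
  list(logit = logit, prob = 1 / (1 + exp(-logit$val[1L])),
       attention = as.vector(att$val), fusion = fusion_w,
       post_vectors = P$val, output = as.vector(o$val))
}

# baseline: bidirectional GRU over (pre-encoded) word embeddings, batched
# across the user's posts; concatenated final states projected to attr_dim
.baseline_post_vectors <- function(enc, params, cfg, training) {
  M <- enc$M
  n_h <- cfg$encoder_hidden
  embed_step <- function(t) {
    H <- ad_rows(params$emb, enc$tok_mat[t, ])
    if (training && cfg$embedding_dropout > 0) H <- ad_dropout(H, cfg$embedding_dropout)
    if (cfg$pre_encode_layers > 0L) {
      H <- .act_fun(cfg$pre_encode_activation)(
        .mlp_fwd(H, params$pre, cfg$pre_encode_activation,
                 cfg$pre_encode_dropout, training))
    }
    H
  }
  steps <- lapply(seq_len(enc$Tmax), embed_step)
  masks <- lapply(seq_len(enc$Tmax), function(t) {
    matrix(rep(enc$mask[t, ], n_h), M, n_h)
  })
  h_f <- .gru_stack_fwd(steps, masks, params$gru_fwd, M, n_h)
  h_b <- .gru_stack_fwd(rev(steps), rev(masks), params$gru_bwd, M, n_h)
  ad_add_bias(ad_matmul(ad_hcat(h_f, h_b), params$projb$W), params$projb$b)
}

# ---------------------------------------------------------------------------
# cohort encoding: turn a user's posts into the integer/index arrays the
# forward pass consumes

encode_user <- function(user, vocab, symptom_lexicon, cfg) {
  posts <- user$posts
  M <- length(posts)
  if (M == 0L) stop("user has no posts")
  tok_ids <- lapply(posts, function(p) encode_tokens(p$tokens, vocab) + 1L)
  lens <- lengths(tok_ids)
  Tmax <- max(lens)
  pad_row <- 2L  # PAD id 1 -> row 2
  tok_mat <- matrix(pad_row, Tmax, M)
  tag_idx <- matrix(1L, Tmax, M)
  sent_idx <- matrix(1L, Tmax, M)
  mask <- matrix(0, Tmax, M)
  for (m in seq_len(M)) {
    l <- lens[m]
    tok_mat[seq_len(l), m] <- tok_ids[[m]]
    ti <- match(posts[[m]]$tags, ASHN_POS_TAGS)
    si <- match(posts[[m]]$sentiments, ASHN_SENTIMENTS)
    if (anyNA(ti) || anyNA(si)) stop("post carries unknown tags or sentiment labels")
    tag_idx[seq_len(l), m] <- ti
    sent_idx[seq_len(l), m] <- si
    mask[seq_len(l), m] <- 1
  }
  keyword_rows <- lapply(unclass(symptom_lexicon), function(kw) {
    encode_tokens(tolower(kw), vocab) + 1L
  })
  list(user_id = user$user_id, y = as.integer(user$group == "depressed"),
       post_ids = vapply(posts, function(p) p$post_id, character(1)),
       M = M, Tmax = Tmax, tok_ids = tok_ids, tok_mat = tok_mat,
       tag_idx = tag_idx, sent_idx = sent_idx, mask = mask,
       keyword_rows = keyword_rows)
}

# ---------------------------------------------------------------------------
# exported single-operation surfaces (plain numeric in / numeric out);
# used for inspection and for oracle comparison in the tests

.as_linear <- function(p) {
  if (is.environment(p$W)) p else list(W = ad_param(p$W), b = ad_param(p$b))
}

#' Encode one post with the CNN post encoder
#'
#' Embeds the token sequence, applies the pre-encode feedforward network,
#' convolves with the configured window width and max-pools over time.
#' Deterministic given parameters (dropout is inference-off).
#'
#' @param tokens Character vector of tokens (out-of-vocabulary tokens map to
#'   `UNK`).
#' @param vocab An `"ashn_vocabulary"`.
#' @param params An `"ashn_parameters"` object.
#' @param config The matching `"ashn_config"`.
#' @return Numeric vector of length `config$post_dim`.
#' @export
encode_post <- function(tokens, vocab, params, config) {
  if (length(tokens) == 0L) stop("cannot encode an empty post")
  ids <- encode_tokens(tokens, vocab) + 1L
  ad_reset_tape()
  as.vector(.encode_post_node(ids, params, config)$val)
}

.run_gru_attr <- function(onehots, stack, proj, n_h) {
  if (!is.matrix(onehots) || nrow(onehots) == 0L) stop("empty input sequence")
  B <- 1L
  steps <- lapply(seq_len(nrow(onehots)), function(t) ad_const(onehots[t, , drop = FALSE]))
  masks <- rep(list(matrix(1, 1L, n_h)), nrow(onehots))
  h <- .gru_stack_fwd(steps, masks, stack, B, n_h)
  as.vector(ad_add_bias(ad_matmul(h, proj$W), proj$b)$val)
}

#' Attribute encoders
#'
#' `attribute_a1_psycholinguistic()` encodes a post's part-of-speech one-hot
#' sequence with a GRU and projects the final hidden state to the attribute
#' dimension; `attribute_a2_sentiment()` does the same over the 3-way
#' sentiment one-hot alphabet.
#'
#' @param pos_onehots A `T x 48` one-hot matrix (see [encode_pos_onehot()]).
#' @param sent_onehots A `T x 3` one-hot matrix.
#' @param params An `"ashn_parameters"` object.
#' @param config The matching `"ashn_config"`.
#' @return Numeric attribute vector of length `config$attr_dim`.
#' @export
attribute_a1_psycholinguistic <- function(pos_onehots, params, config) {
  ad_reset_tape()
  .run_gru_attr(pos_onehots, params$gru_pos, params$proj1, config$encoder_hidden)
}

#' @rdname attribute_a1_psycholinguistic
#' @export
attribute_a2_sentiment <- function(sent_onehots, params, config) {
  ad_reset_tape()
  .run_gru_attr(sent_onehots, params$gru_sent, params$proj2, config$encoder_hidden)
}

#' Build the symptom matrix
#'
#' For each of the nine symptom categories, combines the keyword word
#' vectors by elementwise multiplication and unit-normalizes the result,
#' giving one representative row per category.
#'
#' @param lexicon An `"ashn_symptom_lexicon"`.
#' @param embeddings A word-embedding matrix with rownames, or a function
#'   `word -> numeric vector`.
#' @return A `9 x d` matrix, one unit-norm row per category.
#' @export
build_symptom_matrix <- function(lexicon, embeddings) {
  get_vec <- if (is.function(embeddings)) embeddings else {
    function(w) {
      i <- match(w, rownames(embeddings))
      if (is.na(i)) stop("no embedding for keyword: ", w)
      embeddings[i, ]
    }
  }
  E <- t(vapply(unclass(lexicon), function(kw) {
    if (length(kw) == 0L) stop("empty symptom category")
    v <- Reduce(`*`, lapply(kw, get_vec))
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }, numeric(length(get_vec(lexicon[[1]][1])))))
  rownames(E) <- names(lexicon)
  E
}

#' Symptom-similarity attribute (A3)
#'
#' Nine bilinear similarity scores `f_i = x' W E_i`, softmax-normalized to a
#' category distribution `Y`, projected through an MLP and squashed with
#' tanh.
#'
#' @param x Post-encoding vector (length `config$post_dim`).
#' @param E Symptom matrix (`9 x config$embedding_dim`).
#' @param params,config Model parameters and configuration.
#' @return List with `attribute` (length `config$attr_dim`, components in
#'   (-1, 1)) and `Y` (the length-9 category distribution).
#' @export
attribute_a3_symptom <- function(x, E, params, config) {
  ad_reset_tape()
  xn <- ad_const(matrix(x, 1L))
  Yn <- ad_softmax_rows(ad_matmul(ad_matmul(xn, params$W_sym), ad_t(ad_const(E))))
  a3 <- ad_tanh(ad_add_bias(ad_matmul(Yn, params$mlp3$W), params$mlp3$b))
  list(attribute = as.vector(a3$val), Y = as.vector(Yn$val))
}

#' Rumination attribute (A4)
#'
#' Softmax relevance of a post to each of the user's other posts by dot
#' product. The relevance profile is sorted into descending order (so it
#' does not depend on how the user's posts happen to be stored), then
#' right-padded/truncated to the configured fixed length, projected through
#' an MLP and squashed with tanh.
#'
#' @param x Post-encoding vector.
#' @param others Matrix of the user's other post encodings (one per row;
#'   at least one row).
#' @param params,config Model parameters and configuration.
#' @return List with `attribute` (components in (-1, 1)) and `relevance`
#'   (the softmax distribution over the other posts).
#' @export
attribute_a4_rumination <- function(x, others, params, config) {
  if (is.null(dim(others)) || nrow(others) < 1L) {
    stop("a4 needs at least one other post")
  }
  ad_reset_tape()
  s <- matrix(others %*% x, 1L)
  f <- ad_softmax_rows(ad_const(s))
  fp <- ad_pad_cols(ad_sort_rows_desc(f), config$a4_len)
  a4 <- ad_tanh(ad_add_bias(ad_matmul(fp, params$mlp4$W), params$mlp4$b))
  list(attribute = as.vector(a4$val), relevance = as.vector(f$val))
}

#' Attribute fusion
#'
#' Computes the five softmax fusion weights from the raw post encoding and
#' returns the weighted sum of the five attribute vectors.
#'
#' @param x Post-encoding vector.
#' @param attrs List of five attribute vectors (`a0` to `a4`), common length.
#' @param params,config Model parameters and configuration.
#' @return List with `post_vector` (length `config$attr_dim`) and `weights`
#'   (five non-negative values summing to 1).
#' @export
fuse_attributes <- function(x, attrs, params, config) {
  if (length(attrs) != 5L) stop("fuse_attributes expects five attribute vectors")
  d <- unique(lengths(attrs))
  if (length(d) != 1L) stop("attribute vectors must share one dimension")
  ad_reset_tape()
  xn <- ad_const(matrix(x, 1L))
  w <- ad_softmax_rows(.mlp_fwd(xn, params$fusion, "tanh"))
  wv <- as.vector(w$val)
  p <- colSums(do.call(rbind, attrs) * wv)
  list(post_vector = p, weights = wv)
}

#' Post-level attention
#'
#' Bilinear attention of every post vector against a context vector:
#' `a = softmax(p' W v)`, `o = sum_i a_i p'_i`.
#'
#' @param post_vectors `M x d` matrix of fused post vectors (`M >= 1`).
#' @param v Context vector (length `d`).
#' @param W Bilinear form (`d x d` matrix).
#' @return List with `attention` (length `M`, sums to 1) and `output`
#'   (length `d`).
#' @export
post_level_attention <- function(post_vectors, v, W) {
  if (is.null(dim(post_vectors)) || nrow(post_vectors) < 1L) {
    stop("attention needs at least one post vector")
  }
  s <- as.vector(post_vectors %*% W %*% matrix(v, ncol = 1L))
  e <- exp(s - max(s))
  a <- e / sum(e)
  list(attention = a, output = as.vector(crossprod(post_vectors, a)))
}

#' Classify a user from the attended output vector
#'
#' Runs the output MLP on the user vector and thresholds the sigmoid
#' probability of the depressed class.
#'
#' @param o User output vector (length `config$attr_dim`).
#' @param params,config Model parameters and configuration.
#' @param threshold Classification threshold (default from the config).
#' @return List with `probability`, `label` (`"depressed"`/`"control"`).
#' @export
classify_user <- function(o, params, config, threshold = config$threshold) {
  ad_reset_tape()
  z <- .mlp_fwd(ad_const(matrix(o, 1L)), params$out, "tanh")$val[1L]
  p <- 1 / (1 + exp(-z))
  list(probability = p,
       label = if (p >= threshold) "depressed" else "control")
}
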