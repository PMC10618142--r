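# model blocks: zero-weight identities, hand-computed toys, softmax
# normalization, and permutation/determinism contracts

test_that("configuration validation enforces the stated ranges", {
  expect_s3_class(ashn_config(), "ashn_config")
  expect_identical(ashn_config()$grad_clip, 8.0)
  expect_identical(ashn_config()$epochs, 50L)
  expect_identical(ashn_config()$batch_size, 64L)
  expect_identical(ashn_config()$learning_rate, 1e-4)
  expect_identical(ashn_config()$embedding_dropout, 0.2)
  expect_identical(ashn_config(architecture = "birnn")$embedding_dropout, 0.3)
  expect_error(ashn_config(threshold = 0), "threshold")
  expect_error(ashn_config(embedding_dropout = 1), "dropout")
  expect_error(ashn_config(attr_dim = 0L), "attr_dim")
})

test_that("the CNN post encoder has the configured dimension and zero identity", {
  cfg <- tiny_config()
  v <- build_vocabulary(list(rep(c("a", "b", "c"), 4L)), 0L)
  params <- tiny_params(cfg, length(v))
  x <- encode_post(c("a", "b", "c", "b", "a"), v, params, cfg)
  expect_length(x, cfg$post_dim)
  expect_true(all(is.finite(x)))
  # deterministic
  expect_identical(x, encode_post(c("a", "b", "c", "b", "a"), v, params, cfg))
  # all-zero convolution weights give the zero vector (tanh(0) pooled)
  pz <- zero_params(tiny_params(cfg, length(v)))
  expect_identical(encode_post(c("a", "b", "c"), v, pz, cfg),
                   rep(0, cfg$post_dim))
  expect_error(encode_post(character(0), v, params, cfg), "empty")
})

test_that("single-token encoding reproduces the embedding transform", {
  # width-1 convolution on a 1-token post is exactly W' (pre-encoded e) + b
  cfg <- tiny_config(conv_width = 1L, pre_encode_layers = 0L,
                     embedding_dim = 2L, post_dim = 3L)
  v <- build_vocabulary(list(rep("w", 6L)), 0L)
  params <- tiny_params(cfg, length(v))
  e <- params$emb$val[unname(unclass(v)["w"]) + 1L, ]
  oracle <- tanh(e %*% params$conv$W[[1]]$val + params$conv$b$val)
  expect_equal(encode_post("w", v, params, cfg), as.vector(oracle),
               tolerance = 1e-12)
})

test_that("attribute GRU encoders satisfy the single-step oracle and zero identity", {
  cfg <- tiny_config(encoder_layers = 1L)
  params <- tiny_params(cfg)
  onehot <- encode_pos_onehot("NN")
  a1 <- attribute_a1_psycholinguistic(onehot, params, cfg)
  h <- ashn:::gru_cell_step(onehot, matrix(0, 1, cfg$encoder_hidden),
                            params$gru_pos[[1]])
  oracle <- h %*% params$proj1$W$val + params$proj1$b$val
  expect_equal(a1, as.vector(oracle), tolerance = 1e-12)
  s1 <- encode_sentiment_onehot("negative")
  a2 <- attribute_a2_sentiment(s1, params, cfg)
  h2 <- ashn:::gru_cell_step(s1, matrix(0, 1, cfg$encoder_hidden),
                             params$gru_sent[[1]])
  expect_equal(a2, as.vector(h2 %*% params$proj2$W$val + params$proj2$b$val),
               tolerance = 1e-12)
  pz <- zero_params(tiny_params(cfg))
  expect_identical(attribute_a1_psycholinguistic(onehot, pz, cfg),
                   rep(0, cfg$attr_dim))
  expect_error(attribute_a1_psycholinguistic(onehot[0, , drop = FALSE],
                                             params, cfg), "empty")
})

test_that("the symptom matrix is the normalized elementwise keyword product", {
  lex <- builtin_symptom_lexicon()
  kws <- unique(unlist(unclass(lex)))
  set.seed(20)
  emb <- matrix(rnorm(length(kws) * 3), ncol = 3,
                dimnames = list(kws, NULL))
  E <- build_symptom_matrix(lex, emb)
  expect_identical(dim(E), c(9L, 3L))
  expect_equal(unname(rowSums(E^2)), rep(1, 9), tolerance = 1e-12)
  # two-keyword, three-dim hand computation (padding another category to
  # keep the 76-keyword structural contract)
  toy <- unclass(lex)
  toy[[1]] <- c("alpha", "beta")
  toy[[2]] <- c(toy[[2]], paste0("pad", seq_len(76L - sum(lengths(toy)))))
  toy <- validate_symptom_lexicon(toy)
  e2 <- rbind(alpha = c(1, 2, -1), beta = c(0.5, -1, 2))
  pads <- matrix(1, sum(grepl("^pad", unlist(toy))), 3,
                 dimnames = list(grep("^pad", unlist(toy), value = TRUE), NULL))
  emb2 <- rbind(e2, pads, emb)
  prod <- c(0.5, -2, -2)
  expect_equal(unname(build_symptom_matrix(toy, emb2)[1, ]),
               prod / sqrt(sum(prod^2)), tolerance = 1e-12)
  # a single-keyword category is that keyword's normalized embedding
  toy2 <- unclass(lex); toy2[[2]] <- "solo"
  toy2[[1]] <- paste0("pad", seq_len(76L - sum(lengths(toy2[-1]))))
  toy2 <- validate_symptom_lexicon(toy2)
  emb3 <- rbind(solo = c(3, 0, 4),
                matrix(1, length(unique(unlist(toy2))), 3,
                       dimnames = list(unique(unlist(toy2)), NULL)))
  expect_equal(unname(build_symptom_matrix(toy2, emb3)[2, ]),
               c(0.6, 0, 0.8), tolerance = 1e-12)
})

test_that("the symptom attribute gives a softmax distribution and tanh range", {
  cfg <- tiny_config(post_dim = 9L, embedding_dim = 9L)
  params <- tiny_params(cfg)
  E <- diag(9)
  # W identity, x aligned with E_1 and orthogonal to the rest
  params$W_sym$val <- diag(9)
  x <- c(5, rep(0, 8))
  res <- attribute_a3_symptom(x, E, params, cfg)
  expect_equal(sum(res$Y), 1, tolerance = 1e-12)
  expect_identical(which.max(res$Y), 1L)
  expect_equal(res$Y, as.vector(exp(c(5, rep(0, 8))) / sum(exp(c(5, rep(0, 8))))),
               tolerance = 1e-12)
  expect_true(all(abs(res$attribute) < 1))
  # all scores equal: uniform category distribution
  params$W_sym$val[] <- 0
  res0 <- attribute_a3_symptom(rnorm(9), E, params, cfg)
  expect_equal(res0$Y, rep(1 / 9, 9), tolerance = 1e-12)
  # zero MLP weights: a3 = tanh(0) = 0
  pz <- zero_params(tiny_params(cfg))
  expect_identical(attribute_a3_symptom(x, E, pz, cfg)$attribute,
                   rep(0, cfg$attr_dim))
})

test_that("the rumination attribute is a softmax over dot-product relevance", {
  cfg <- tiny_config(a4_len = 5L)
  params <- tiny_params(cfg)
  # one other post: the relevance distribution is (1)
  r1 <- attribute_a4_rumination(c(1, 2), rbind(c(3, 4)), params,
                                tiny_config(a4_len = 5L, post_dim = 2L))
  expect_identical(r1$relevance, 1)
  # identical other posts: uniform
  r2 <- attribute_a4_rumination(c(1, 2), rbind(c(3, 4), c(3, 4), c(3, 4)),
                                params, cfg)
  expect_equal(r2$relevance, rep(1 / 3, 3), tolerance = 1e-12)
  # three-post two-dim hand computation
  x <- c(1, -1)
  others <- rbind(c(2, 0), c(0, 1), c(1, 1))
  s <- as.vector(others %*% x)
  r3 <- attribute_a4_rumination(x, others, params, cfg)
  expect_equal(r3$relevance, exp(s) / sum(exp(s)), tolerance = 1e-12)
  expect_true(all(abs(r3$attribute) < 1))
  expect_error(attribute_a4_rumination(x, others[0, , drop = FALSE], params, cfg),
               "other post")
})

test_that("attribute fusion weights are softmax and the sum is exact", {
  cfg <- tiny_config()
  set.seed(21)
  attrs <- lapply(0:4, function(i) rnorm(cfg$attr_dim))
  # zero fusion network: uniform weights 0.2
  pz <- zero_params(tiny_params(cfg))
  fz <- fuse_attributes(rnorm(cfg$post_dim), attrs, pz, cfg)
  expect_equal(fz$weights, rep(0.2, 5), tolerance = 1e-12)
  expect_equal(fz$post_vector, colMeans(do.call(rbind, attrs)), tolerance = 1e-12)
  # near-one-hot weights select the matching attribute
  ps <- tiny_params(cfg)
  last <- length(ps$fusion)
  ps$fusion[[last]]$W$val[] <- 0
  ps$fusion[[last]]$b$val <- matrix(c(-40, -40, 40, -40, -40), 1)
  fs <- fuse_attributes(rnorm(cfg$post_dim), attrs, ps, cfg)
  expect_equal(fs$post_vector, attrs[[3]], tolerance = 1e-10)
  # random instances match the brute-force weighted sum
  pr <- tiny_params(cfg)
  for (i in 1:100) {
    attrs <- lapply(0:4, function(i) rnorm(cfg$attr_dim))
    x <- rnorm(cfg$post_dim)
    f <- fuse_attributes(x, attrs, pr, cfg)
    expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    brute <- Reduce(`+`, Map(function(w, a) w * a, f$weights, attrs))
    expect_equal(f$post_vector, brute, tolerance = 1e-9)
  }
  expect_error(fuse_attributes(rnorm(3), attrs[1:4], pr, cfg), "five")
})

test_that("post-level attention matches the bilinear hand computation", {
  # single post: all attention on it
  one <- post_level_attention(rbind(c(1, 2)), c(1, 1), diag(2))
  expect_identical(one$attention, 1)
  expect_identical(one$output, c(1, 2))
  # identical posts: uniform attention
  same <- post_level_attention(rbind(c(1, 2), c(1, 2), c(1, 2)), c(0.3, -1), diag(2))
  expect_equal(same$attention, rep(1 / 3, 3), tolerance = 1e-12)
  # M = 3, d = 2 toy against the closed form
  P <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- rbind(c(2, -1), c(0.5, 1))
  v <- c(1, 2)
  s <- as.vector(P %*% W %*% v)
  a <- exp(s - max(s)) / sum(exp(s - max(s)))
  res <- post_level_attention(P, v, W)
  expect_equal(res$attention, a, tolerance = 1e-12)
  expect_equal(res$output, as.vector(crossprod(P, a)), tolerance = 1e-12)
  expect_error(post_level_attention(P[0, , drop = FALSE], v, W), "at least one")
})

test_that("the classifier is a sigmoid probability, monotone in the logit", {
  cfg <- tiny_config()
  pz <- zero_params(tiny_params(cfg))
  res <- classify_user(rnorm(cfg$attr_dim), pz, cfg)
  expect_identical(res$probability, 0.5)
  expect_identical(res$label, "depressed")   # 0.5 >= threshold 0.5
  # sweep the final-layer bias (the logit) upward: probability is monotone
  ps <- tiny_params(cfg)
  o <- rnorm(cfg$attr_dim)
  last <- length(ps$out)
  probs <- vapply(seq(-4, 4, length.out = 17), function(b) {
    ps$out[[last]]$b$val[] <- b
    classify_user(o, ps, cfg)$probability
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("every softmax in the forward pass normalizes and tanh ranges hold", {
  corp <- tiny_corpus(n_users = 2L, posts = 10L)
  cfg <- tiny_config()
  toks <- unlist(lapply(corp$cohort, function(u) lapply(u$posts, `[[`, "tokens")),
                 recursive = FALSE)
  v <- build_vocabulary(toks, 0L)
  set.seed(30)
  for (i in 1:25) {
    cfg_i <- tiny_config(seed = sample.int(1e6, 1))
    params <- ashn_parameters(cfg_i, length(v))
    enc <- ashn:::encode_user(corp$cohort[[1]], v, builtin_symptom_lexicon(), cfg_i)
    ad_reset_tape()
    fwd <- ashn:::.forward_user(enc, params, cfg_i, training = FALSE)
    expect_equal(sum(fwd$attention), 1, tolerance = 1e-6)
    expect_equal(unname(rowSums(fwd$fusion)), rep(1, enc$M), tolerance = 1e-6)
    expect_true(all(fwd$attention >= 0))
    expect_true(all(fwd$fusion >= 0))
    expect_gte(fwd$prob, 0); expect_lte(fwd$prob, 1)
  }
})

test_that("the forward pass is deterministic and permutation-equivariant", {
  corp <- tiny_corpus(n_users = 2L, posts = 10L)
  cfg <- tiny_config()
  toks <- unlist(lapply(corp$cohort, function(u) lapply(u$posts, `[[`, "tokens")),
                 recursive = FALSE)
  v <- build_vocabulary(toks, 0L)
  params <- ashn_parameters(cfg, length(v))
  u <- corp$cohort[[1]]
  enc <- ashn:::encode_user(u, v, builtin_symptom_lexicon(), cfg)
  ad_reset_tape()
  f1 <- ashn:::.forward_user(enc, params, cfg, training = FALSE)
  ad_reset_tape()
  f2 <- ashn:::.forward_user(enc, params, cfg, training = FALSE)
  expect_identical(f1$prob, f2$prob)
  expect_identical(f1$attention, f2$attention)
  # permute the stored posts: o and the probability are unchanged, the
  # attention weights permute along
  perm <- sample(seq_along(u$posts))
  u2 <- u; u2$posts <- u$posts[perm]
  enc2 <- ashn:::encode_user(u2, v, builtin_symptom_lexicon(), cfg)
  ad_reset_tape()
  f3 <- ashn:::.forward_user(enc2, params, cfg, training = FALSE)
  expect_equal(f3$prob, f1$prob, tolerance = 1e-9)
  expect_equal(f3$output, f1$output, tolerance = 1e-6)
  expect_equal(f3$attention, f1$attention[perm], tolerance = 1e-9)
})

test_that("the bidirectional baseline shares the output contract", {
  corp <- tiny_corpus(n_users = 4L, posts = 10L)
  cfg_b <- tiny_config(architecture = "birnn", epochs = 1L)
  fit_b <- ashn(corp$cohort, cfg_b)
  preds <- predict(fit_b, corp$cohort)
  expect_length(preds, 4L)
  expect_true(all(vapply(preds, function(p) p$probability >= 0 &&
                           p$probability <= 1, logical(1))))
  expect_equal(sum(preds[[1]]$attention), 1, tolerance = 1e-6)
  expect_true(all(is.na(preds[[1]]$fusion)))   # no attribute fusion in the baseline
})

test_that("forward and backward GRU states swap under input reversal", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  params$gru_bwd <- params$gru_fwd   # tie the two directions
  set.seed(31)
  n_h <- cfg$encoder_hidden
  n_in <- cfg$pre_encode_hidden
  steps <- lapply(1:4, function(t) ashn:::ad_const(matrix(rnorm(n_in), 1)))
  masks <- rep(list(matrix(1, 1, n_h)), 4)
  ad_reset_tape()
  # with tied weights the backward state on x equals the forward state on
  # reversed x, and the pair swaps when the input is reversed
  hf_x <- ashn:::.gru_stack_fwd(steps, masks, params$gru_fwd, 1L, n_h)$val
  hb_x <- ashn:::.gru_stack_fwd(rev(steps), rev(masks), params$gru_bwd, 1L, n_h)$val
  hf_rev <- ashn:::.gru_stack_fwd(rev(steps), rev(masks), params$gru_fwd, 1L, n_h)$val
  hb_rev <- ashn:::.gru_stack_fwd(steps, masks, params$gru_bwd, 1L, n_h)$val
  expect_equal(hf_rev, hb_x, tolerance = 1e-12)
  expect_equal(hb_rev, hf_x, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(hf_x, hf_rev)))
})
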