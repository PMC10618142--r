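# shared fixtures: everything is generated in code at test time

# a tiny architecture so forward passes and fits stay fast
tiny_config <- function(...) {
  ashn_config_demo(embedding_dim = 6L, pre_encode_layers = 1L,
                   pre_encode_hidden = 5L, encoder_hidden = 4L,
                   encoder_layers = 1L, integrator_hidden = 5L,
                   integrator_layers = 2L, output_layers = 2L,
                   output_hidden = 5L, conv_width = 2L, post_dim = 7L,
                   attr_dim = 5L, a4_len = 8L, epochs = 2L,
                   batch_size = 4L, sample_posts = 10L, seed = 7L, ...)
}

tiny_corpus <- function(n_users = 6L, posts = 10L, seed = 7L, ...) {
  simulate_corpus(simulate_config(
    n_users = n_users, posts_per_user_mean = posts, posts_per_user_sd = 0,
    tokens_min = 6L, tokens_max = 12L, seed = seed, ...))
}

tiny_params <- function(cfg = tiny_config(), vocab_size = 30L) {
  ashn_parameters(cfg, vocab_size)
}

# set every parameter array of a fit/params object to zero
zero_params <- function(params) {
  for (p in ashn:::flatten_params(params)) p$val <- p$val * 0
  params
}

# a post record as the pipeline sees it
make_post <- function(text, id = "p1", user = "u1") {
  list(user_id = user, post_id = id, title = NA_character_, text = text,
       timestamp = NA_character_, tokens = tokenize(clean_text(text)))
}

random_words <- function(n, seed_pool = c("baby", "sleep", "sad", "walk",
                                          "park", "happy", "tired", "day",
                                          "home", "cry")) {
  sample(seed_pool, n, replace = TRUE)
}
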