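# Synthetic corpus generator: labeled user/post collections with the
# statistical structure the classifier assumes (elevated negative-polarity
# rates, injected symptom keywords, ruminative repetition, first-person and
# verb-rate elevation), with exact per-token injection logs for auditing.

# background word inventory; kept disjoint from the sentiment lexicon and
# the symptom lexicon so lexicon-based recounts identify injections exactly
.bg_nouns <- c("morning", "evening", "dinner", "kitchen", "garden", "window",
               "stroller", "blanket", "bottle", "diaper", "doctor", "visit",
               "weather", "coffee", "neighbour", "sister", "grandma", "photo",
               "song", "story", "walk", "nap", "park", "house", "room",
               "laundry", "recipe", "market", "weekend", "holiday")
.bg_verbs_past <- c("walked", "cooked", "visited", "watched", "played",
                    "washed", "folded", "called", "opened", "carried")
.bg_verbs_pres <- c("walk", "cook", "visit", "watch", "play", "wash",
                    "fold", "call", "open", "carry")
.first_person <- c("i", "me", "my", "myself")

.make_fillers <- function(n) {
  syll <- c("ba", "do", "fe", "gu", "ka", "lo", "mi", "na", "po", "ra",
            "se", "ti", "vu", "wa", "ye", "zo")
  grid <- expand.grid(a = syll, b = syll, c = syll, stringsAsFactors = FALSE)
  words <- paste0(grid$a, grid$b, grid$c)
  words[seq_len(min(n, length(words)))]
}

#' Configuration of the synthetic corpus generator
#'
#' Defines the simulated study conditions. Rates are per word token (the
#' generator draws each word token from a mixture: symptom keyword,
#' negative-polarity word, first-person pronoun, verb, background word) so
#' every knob has an exact binomial audit. Depressed users' rates apply only
#' to a configurable minority of their posts (the signal-bearing posts);
#' their remaining posts, and all control posts, use the control rates.
#'
#' @param n_users Number of users (default 100).
#' @param depressed_fraction Fraction of depressed users; the allocation is
#'   exact (`round(n_users * depressed_fraction)`).
#' @param posts_per_user_mean,posts_per_user_sd,min_posts Posts per user:
#'   normal draw rounded and clipped below at `min_posts` (>= 10 so every
#'   generated user survives the cohort filters).
#' @param tokens_min,tokens_max Word tokens per post (range inside 5--100
#'   after sentence punctuation; `tokens_max` <= 80).
#' @param neg_rate,symptom_rate,pronoun_rate,verb_rate Named length-2 rates
#'   `c(depressed =, control =)` per word token.
#' @param symptom_mix Length-9 category mixture for symptom injections
#'   (defaults uniform).
#' @param rumination_rate Probability (per group) that a post repeats the
#'   core (first) sentence of one of the user's earlier posts.
#' @param signal_post_fraction Fraction of a depressed user's posts that
#'   carry the depressed-group rates.
#' @param background_vocab_size Number of filler background words.
#' @param seed Seed; the corpus is a pure function of the configuration.
#' @return Validated list of class `"ashn_sim_config"`.
#' @export
simulate_config <- function(n_users = 100L, depressed_fraction = 0.5,
                            posts_per_user_mean = 50, posts_per_user_sd = 10,
                            min_posts = 10L,
                            tokens_min = 8L, tokens_max = 30L,
                            neg_rate = c(depressed = 0.40, control = 0.10),
                            symptom_rate = c(depressed = 0.15, control = 0.01),
                            pronoun_rate = c(depressed = 0.30, control = 0.15),
                            verb_rate = c(depressed = 0.25, control = 0.15),
                            symptom_mix = rep(1 / 9, 9),
                            rumination_rate = c(depressed = 0.30, control = 0.05),
                            signal_post_fraction = 0.4,
                            background_vocab_size = 150L,
                            seed = 1L) {
  cfg <- list(n_users = as.integer(n_users),
              depressed_fraction = depressed_fraction,
              posts_per_user_mean = posts_per_user_mean,
              posts_per_user_sd = posts_per_user_sd,
              min_posts = as.integer(min_posts),
              tokens_min = as.integer(tokens_min),
              tokens_max = as.integer(tokens_max),
              neg_rate = neg_rate, symptom_rate = symptom_rate,
              pronoun_rate = pronoun_rate, verb_rate = verb_rate,
              symptom_mix = symptom_mix,
              rumination_rate = rumination_rate,
              signal_post_fraction = signal_post_fraction,
              background_vocab_size = as.integer(background_vocab_size),
              seed = as.integer(seed))
  for (r in c("neg_rate", "symptom_rate", "pronoun_rate", "verb_rate",
              "rumination_rate")) {
    v <- cfg[[r]]
    if (length(v) != 2L || !all(c("depressed", "control") %in% names(v))) {
      stop(r, " must be a named length-2 vector (depressed, control)")
    }
    if (any(v < 0 | v > 1)) stop(r, " must lie in [0, 1]")
    if (v[["depressed"]] > 0 && v[["depressed"]] < v[["control"]]) {
      stop(r, ": the depressed rate must be >= the control rate when the knob is on")
    }
  }
  if (cfg$min_posts < 10L) stop("min_posts must be >= 10 (cohort filter)")
  if (cfg$tokens_min < 5L || cfg$tokens_max > 80L ||
      cfg$tokens_min > cfg$tokens_max) {
    stop("tokens_min/tokens_max must satisfy 5 <= min <= max <= 80")
  }
  if (length(cfg$symptom_mix) != 9L || any(cfg$symptom_mix < 0) ||
      abs(sum(cfg$symptom_mix) - 1) > 1e-8) {
    stop("symptom_mix must be a length-9 probability vector")
  }
  if (cfg$signal_post_fraction <= 0 || cfg$signal_post_fraction > 1) {
    stop("signal_post_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "ashn_sim_config")
}

# injection pools, pairwise disjoint so recounts are exact:
#   negative pool = negative lexicon words that are not symptom keywords
#   symptom pools = per-category keywords that are not sentiment-labelled
.injection_pools <- function(symptom_lexicon, sentiment_lexicon) {
  kw <- unlist(unclass(symptom_lexicon), use.names = FALSE)
  lex <- unclass(sentiment_lexicon)
  negs <- names(lex)[lex == "negative"]
  list(negative = setdiff(negs, kw),
       symptom = lapply(unclass(symptom_lexicon),
                        function(k) setdiff(k, names(lex))))
}

# draw the word tokens of one post from the mixture defined by `rates`
.draw_words <- function(n, rates, pools, fillers, cfg) {
  u <- stats::runif(n)
  p_sym <- rates$symptom
  p_neg <- rates$neg
  p_pro <- rates$pronoun
  p_verb <- rates$verb
  words <- character(n)
  kind <- character(n)
  cat_idx <- integer(n)
  for (j in seq_len(n)) {
    if (u[j] < p_sym) {
      ci <- sample.int(9L, 1L, prob = cfg$symptom_mix)
      pool <- pools$symptom[[ci]]
      words[j] <- pool[sample.int(length(pool), 1L)]
      kind[j] <- "symptom"; cat_idx[j] <- ci
    } else if (u[j] < p_sym + p_neg) {
      words[j] <- pools$negative[sample.int(length(pools$negative), 1L)]
      kind[j] <- "negative"
    } else if (u[j] < p_sym + p_neg + p_pro) {
      words[j] <- .first_person[sample.int(4L, 1L, prob = c(0.6, 0.1, 0.2, 0.1))]
      kind[j] <- "pronoun"
    } else if (u[j] < p_sym + p_neg + p_pro + p_verb) {
      vb <- c(.bg_verbs_past, .bg_verbs_pres)
      words[j] <- vb[sample.int(length(vb), 1L)]
      kind[j] <- "verb"
    } else {
      bg <- c(.bg_nouns, fillers)
      words[j] <- bg[sample.int(length(bg), 1L)]
      kind[j] <- "background"
    }
  }
  list(words = words, kind = kind, category = cat_idx)
}

# assemble words into text with sentence punctuation every 6-10 words
.words_to_text <- function(words) {
  n <- length(words)
  out <- character(0)
  at <- 1L
  while (at <= n) {
    len <- min(sample(6:10, 1L), n - at + 1L)
    out <- c(out, paste(words[at:(at + len - 1L)], collapse = " "),
             sample(c(".", ".", ".", "!"), 1L))
    at <- at + len
  }
  paste0(paste(out[seq(1L, length(out), 2L)],
               out[seq(2L, length(out), 2L)], sep = ""), collapse = " ")
}

.first_sentence <- function(text) {
  split_sentences(text)[[1]][1]
}

#' Generate one synthetic user
#'
#' Draws a PDSS score consistent with the group (control: 0--10, depressed:
#' 30--63), a post count, and the user's posts from the configured token
#' mixture, with ruminative repetition of earlier core sentences.
#'
#' @param group `"control"` or `"depressed"`.
#' @param config An `"ashn_sim_config"`.
#' @param seed Seed for this user's draws.
#' @param user_id User identifier.
#' @return List with `user` (a user record whose posts carry `tokens`,
#'   `tags`, `sentiments`) and `flags` (the per-post injection log).
#' @export
generate_user <- function(group, config, seed, user_id = "u1") {
  stopifnot(group %in% c("control", "depressed"))
  cfg <- config
  pools <- .injection_pools(builtin_symptom_lexicon(), builtin_sentiment_lexicon())
  fillers <- .make_fillers(cfg$background_vocab_size)
  withr_seed(seed, {
    score <- if (group == "control") sample(0:10, 1L) else sample(30:63, 1L)
    n_posts <- max(cfg$min_posts,
                   round(stats::rnorm(1L, cfg$posts_per_user_mean,
                                      cfg$posts_per_user_sd)))
    signal_post <- if (group == "depressed") {
      k <- max(1L, round(cfg$signal_post_fraction * n_posts))
      seq_len(n_posts) %in% sample.int(n_posts, k)
    } else rep(FALSE, n_posts)
    posts <- vector("list", n_posts)
    flags <- vector("list", n_posts)
    texts <- character(n_posts)
    for (m in seq_len(n_posts)) {
      grp_rates <- if (signal_post[m]) "depressed" else "control"
      rates <- list(symptom = cfg$symptom_rate[[grp_rates]],
                    neg = cfg$neg_rate[[grp_rates]],
                    pronoun = cfg$pronoun_rate[[grp_rates]],
                    verb = cfg$verb_rate[[grp_rates]])
      rum_p <- cfg$rumination_rate[[group]]
      ruminated <- m > 1L && stats::runif(1L) < rum_p
      n_words <- sample(cfg$tokens_min:cfg$tokens_max, 1L)
      drawn <- .draw_words(n_words, rates, pools, fillers, cfg)
      if (ruminated) {
        src <- sample.int(m - 1L, 1L)
        core <- .first_sentence(texts[src])
        text <- paste0(core, ". ", .words_to_text(drawn$words))
      } else {
        src <- NA_integer_
        text <- .words_to_text(drawn$words)
      }
      texts[m] <- text
      post_id <- sprintf("%s_p%03d", user_id, m)
      posts[[m]] <- list(user_id = user_id, post_id = post_id,
                         title = NA_character_, text = text,
                         timestamp = NA_character_)
      flags[[m]] <- list(post_id = post_id, carries_signal = signal_post[m],
                         ruminated = ruminated,
                         source_post = if (is.na(src)) NA_character_ else
                           sprintf("%s_p%03d", user_id, src),
                         n_words = n_words,
                         n_negative = sum(drawn$kind == "negative"),
                         n_symptom = sum(drawn$kind == "symptom"),
                         n_pronoun = sum(drawn$kind == "pronoun"),
                         n_verb = sum(drawn$kind == "verb"),
                         symptom_categories = tabulate(drawn$category[drawn$category > 0L], 9L))
    }
    posts <- lapply(posts, function(p) {
      p$tokens <- tokenize(p$text)
      p$tags <- pos_tag(p$tokens)
      p$sentiments <- label_sentiment(p$tokens)
      p
    })
    list(user = list(user_id = user_id, age = sample(19:35, 1L),
                     pdss_score = score, group = group, posts = posts),
         flags = flags)
  })
}

#' Generate a labeled synthetic corpus
#'
#' Seeded and reproducible: the same configuration yields a byte-identical
#' corpus. Group allocation is exact. Every generated user survives the
#' full cohort pipeline by construction (posts have 5--100 tokens, at least
#' two words, under 3000 characters; users have at least `min_posts`
#' posts; scores match groups).
#'
#' @param config An `"ashn_sim_config"`.
#' @return Object of class `"ashn_corpus"`: list with `cohort` (an
#'   `"ashn_cohort"` ready for [ashn()]), `posts` (raw post records),
#'   `scores` (data frame `user_id`, `age`, `pdss_score`), `flags`
#'   (per-user injection logs) and `config`.
#' @export
simulate_corpus <- function(config = simulate_config()) {
  cfg <- config
  n_dep <- round(cfg$n_users * cfg$depressed_fraction)
  groups <- rep(c("depressed", "control"),
                c(n_dep, cfg$n_users - n_dep))
  users <- vector("list", cfg$n_users)
  flags <- vector("list", cfg$n_users)
  for (i in seq_len(cfg$n_users)) {
    uid <- sprintf("u%04d", i)
    useed <- as.integer((as.numeric(cfg$seed) * 100003 + i) %% 2147483647)
    g <- generate_user(groups[i], cfg, seed = useed, user_id = uid)
    users[[i]] <- g$user
    flags[[i]] <- g$flags
  }
  cohort <- users
  class(cohort) <- c("ashn_cohort", "list")
  posts <- unlist(lapply(users, function(u) {
    lapply(u$posts, function(p) p[c("user_id", "post_id", "title", "text", "timestamp")])
  }), recursive = FALSE)
  scores <- data.frame(user_id = vapply(users, `[[`, character(1), "user_id"),
                       age = vapply(users, `[[`, numeric(1), "age"),
                       pdss_score = vapply(users, `[[`, numeric(1), "pdss_score"),
                       stringsAsFactors = FALSE)
  structure(list(cohort = cohort, posts = posts, scores = scores,
                 flags = stats::setNames(flags, scores$user_id), config = cfg),
            class = "ashn_corpus")
}

#' @export
print.ashn_corpus <- function(x, ...) {
  print(x$cohort)
  invisible(x)
}

#' Audit a generated corpus against its injection log
#'
#' Recounts, from the generated text itself, the negative-polarity tokens,
#' symptom keywords (total and per category), first-person pronouns and
#' repeated (ruminative) posts, and compares them with the injection log and
#' the configured rates. Recounts use the injection pools (which are
#' pairwise disjoint from the background vocabulary), so log and recount
#' must agree exactly. Rates are reported per word token over the posts to
#' which each group's configured rates applied (the signal-bearing posts of
#' depressed users; all posts of controls).
#'
#' @param corpus An `"ashn_corpus"`.
#' @return Data frame with one row per group: empirical and configured
#'   negative/symptom/pronoun/verb token rates, repetition rate, and the
#'   logical `log_matches_recount`.
#' @export
signal_audit <- function(corpus) {
  if (is.null(corpus$flags)) stop("corpus carries no signal flags")
  cfg <- corpus$config
  pools <- .injection_pools(builtin_symptom_lexicon(), builtin_sentiment_lexicon())
  rows <- lapply(c("depressed", "control"), function(g) {
    uids <- vapply(corpus$cohort, `[[`, character(1), "user_id")
    sel <- vapply(corpus$cohort, function(u) u$group == g, logical(1))
    tot <- c(words = 0, neg = 0, sym = 0, pro = 0, verb = 0)
    sym_cat <- numeric(9L)
    n_posts_eligible <- 0L
    n_rum <- 0L
    n_posts_rum_eligible <- 0L
    match_ok <- TRUE
    for (ui in which(sel)) {
      u <- corpus$cohort[[ui]]
      fl <- corpus$flags[[uids[ui]]]
      for (m in seq_along(u$posts)) {
        f <- fl[[m]]
        # recount from text over the freshly drawn words (exclude the
        # repeated core sentence, which belongs to its source post's log)
        toks <- u$posts[[m]]$tokens
        if (f$ruminated) {
          core <- tokenize(paste0(.first_sentence(
            corpus$cohort[[ui]]$posts[[match(f$source_post,
              vapply(u$posts, `[[`, character(1), "post_id"))]]$text), "."))
          toks <- toks[-seq_along(core)]
        }
        words <- toks[grepl("\\p{L}", toks, perl = TRUE)]
        n_neg <- sum(words %in% pools$negative)
        n_sym <- sum(words %in% unlist(pools$symptom))
        n_pro <- sum(words %in% .first_person)
        match_ok <- match_ok && n_neg == f$n_negative &&
          n_sym == f$n_symptom && n_pro == f$n_pronoun &&
          length(words) == f$n_words
        in_stratum <- if (g == "depressed") f$carries_signal else TRUE
        if (in_stratum) {
          tot <- tot + c(length(words), n_neg, n_sym, n_pro, f$n_verb)
          sym_cat <- sym_cat + f$symptom_categories
          n_posts_eligible <- n_posts_eligible + 1L
        }
        if (m > 1L) {
          n_posts_rum_eligible <- n_posts_rum_eligible + 1L
          if (f$ruminated) n_rum <- n_rum + 1L
        }
      }
    }
    data.frame(group = g,
               negative_rate = tot[["neg"]] / tot[["words"]],
               negative_rate_configured = cfg$neg_rate[[g]],
               symptom_rate = tot[["sym"]] / tot[["words"]],
               symptom_rate_configured = cfg$symptom_rate[[g]],
               pronoun_rate = tot[["pro"]] / tot[["words"]],
               pronoun_rate_configured = cfg$pronoun_rate[[g]],
               verb_rate = tot[["verb"]] / tot[["words"]],
               verb_rate_configured = cfg$verb_rate[[g]],
               repetition_rate = if (n_posts_rum_eligible > 0)
                 n_rum / n_posts_rum_eligible else NA_real_,
               repetition_rate_configured = cfg$rumination_rate[[g]],
               n_word_tokens = tot[["words"]],
               log_matches_recount = match_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "symptom_category_counts") <- NULL
  out
}

#' Write a corpus in the pipeline's input formats
#'
#' Writes `posts.jsonl`, `scores.csv` and `flags.jsonl` under `dir`.
#'
#' @param corpus An `"ashn_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "posts.jsonl"), "wt", encoding = "UTF-8")
  for (p in corpus$posts) {
    writeLines(jsonlite::toJSON(p, auto_unbox = TRUE, na = "null"), con)
  }
  close(con)
  utils::write.csv(corpus$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "flags.jsonl"), "wt", encoding = "UTF-8")
  for (uid in names(corpus$flags)) {
    for (f in corpus$flags[[uid]]) {
      writeLines(jsonlite::toJSON(c(list(user_id = uid), f),
                                  auto_unbox = TRUE, na = "null"), con)
    }
  }
  close(con)
  invisible(dir)
}
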