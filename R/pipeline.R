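# Cohort construction: character cleaning, length filters, screening-score
# grouping, per-user sampling, and descriptive cohort statistics.

#' Punctuation marks retained by [clean_text()]
#'
#' The fixed set of sentence punctuation marks that survive text cleaning.
#' Everything that is not a letter, whitespace, or one of these marks is
#' treated as a stray character (digits, `@`, `#`, currency and math symbols,
#' control characters, emoji) and removed. The set deliberately excludes
#' symbol-like ASCII punctuation such as `@` so that obfuscated words
#' (`"b@by"`) lose the stray character rather than keeping it.
#'
#' @format A length-one character string containing every retained mark.
#' @export
ASHN_PUNCTUATION <- ".,;:!?'\"()[]{}-–—…‘’“”/"

.punct_class <- function() {
  # character class for the retained punctuation set, metacharacters escaped
  chars <- strsplit(ASHN_PUNCTUATION, "")[[1]]
  paste0(vapply(chars, function(ch) {
    if (grepl("[][\\^-]", ch)) paste0("\\", ch) else ch
  }, character(1)), collapse = "")
}

#' Clean raw post text
#'
#' Removes every character that is not a letter, whitespace, or a punctuation
#' mark from [ASHN_PUNCTUATION], then collapses runs of whitespace to single
#' spaces and trims the ends. The operation is idempotent and never increases
#' the character count.
#'
#' @param text Character vector of raw post texts (may be empty strings).
#' @return Character vector of cleaned texts, same length as `text`.
#' @examples
#' clean_text("b@by cry1ng!!")   # "bby cryng!!"
#' @export
clean_text <- function(text) {
  stopifnot(is.character(text))
  keep <- paste0("[^\\p{L}\\s", .punct_class(), "]")
  out <- gsub(keep, "", text, perl = TRUE)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Assign a screening group from a PDSS score
#'
#' Maps a Postpartum Depression Screening Scale score (0--63) to a cohort
#' group: scores below 11 are `"control"`, scores above 29 are `"depressed"`,
#' and everything in between is `"excluded"` from the two-group analysis.
#'
#' @param pdss_score Integer vector of screening scores in `[0, 63]`.
#' @return Character vector with values in
#'   `c("control", "excluded", "depressed")`.
#' @examples
#' assign_group(c(10, 20, 30))
#' @export
assign_group <- function(pdss_score) {
  stopifnot(is.numeric(pdss_score), !anyNA(pdss_score))
  if (any(pdss_score < 0 | pdss_score > 63)) {
    stop("pdss_score must lie in [0, 63]")
  }
  ifelse(pdss_score < 11, "control",
         ifelse(pdss_score > 29, "depressed", "excluded"))
}

# whitespace-delimited word count (pre-tokenization, used by the 2-word rule)
.word_count <- function(text) {
  lengths(regmatches(text, gregexpr("\\S+", text, perl = TRUE)))
}

#' Filter posts by cleaned length
#'
#' Keeps posts whose cleaned text has at least `min_words` whitespace-delimited
#' words and at most `max_chars` characters; relative order is preserved.
#' Boundary values (exactly `min_words` words, exactly `max_chars` characters)
#' are retained.
#'
#' @param posts List of post records, each with a `text` field (cleaned).
#' @param min_words Minimum word count (default 2).
#' @param max_chars Maximum character count (default 3000).
#' @return The surviving sublist of `posts`.
#' @export
filter_post_length <- function(posts, min_words = 2L, max_chars = 3000L) {
  if (length(posts) == 0L) return(posts)
  txt <- vapply(posts, function(p) p$text, character(1))
  keep <- .word_count(txt) >= min_words & nchar(txt) <= max_chars
  posts[keep]
}

#' Filter posts by token count
#'
#' Keeps posts whose token sequence length lies in
#' `[min_tokens, max_tokens]` (both bounds inclusive; defaults 5 and 100).
#'
#' @param posts List of post records, each with a `tokens` field.
#' @param min_tokens,max_tokens Inclusive bounds on token count.
#' @return The surviving sublist of `posts`.
#' @export
filter_token_length <- function(posts, min_tokens = 5L, max_tokens = 100L) {
  if (min_tokens > max_tokens) {
    stop("min_tokens must not exceed max_tokens")
  }
  if (length(posts) == 0L) return(posts)
  n <- vapply(posts, function(p) length(p$tokens), integer(1))
  posts[n >= min_tokens & n <= max_tokens]
}

#' Drop users with too few posts
#'
#' Keeps users whose post list, after per-post filtering, has at least
#' `min_posts` entries (default 10; the boundary is retained).
#'
#' @param users List of user records, each with a `posts` field.
#' @param min_posts Minimum number of surviving posts per user.
#' @return The surviving sublist of `users`.
#' @export
filter_user_min_posts <- function(users, min_posts = 10L) {
  if (length(users) == 0L) return(users)
  n <- vapply(users, function(u) length(u$posts), integer(1))
  users[n >= min_posts]
}

#' Sample a user's training posts
#'
#' Draws `min(n, number of posts)` distinct posts uniformly without
#' replacement. The draw is a pure function of `(user, n, seed)`.
#'
#' @param user A user record with a `posts` list.
#' @param n Target sample size (default 245 posts per user).
#' @param seed Integer seed controlling the draw.
#' @return A list of sampled post records.
#' @export
sample_training_posts <- function(user, n = 245L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  m <- length(user$posts)
  if (m <= n) return(user$posts)
  idx <- withr_seed(seed, sample.int(m, n))
  user$posts[sort(idx)]
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split cleaned text into sentences
#'
#' Sentences end at runs of `.`, `!` or `?` followed by whitespace or the end
#' of the text. Empty fragments are dropped.
#'
#' @param text Character vector of cleaned texts.
#' @return A list of character vectors, one per input element.
#' @export
split_sentences <- function(text) {
  lapply(strsplit(text, "[.!?]+(\\s+|$)", perl = TRUE), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
}

.mean_sd <- function(x) {
  if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) == 1L) 0 else stats::sd(x))
}

#' Descriptive cohort statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of posts per user,
#' words per user, sentences per user, words per post, words per sentence and
#' sentences per post. Per-user quantities are computed over users; per-post
#' and per-sentence quantities over the pooled posts/sentences. When a
#' quantity has a single observation its standard deviation is reported as 0
#' and flagged.
#'
#' @param users Non-empty list of user records whose posts carry `text` (and,
#'   if available, `tokens`; otherwise words are whitespace-delimited).
#' @return An object of class `"ashn_cohort_stats"`: a data frame with columns
#'   `quantity`, `mean`, `sd`, `n`, `single_observation`, plus attribute
#'   `n_users`.
#' @export
cohort_statistics <- function(users) {
  if (length(users) == 0L) stop("cohort_statistics needs at least one user")
  per_user_posts <- vapply(users, function(u) length(u$posts), numeric(1))
  post_words <- numeric(0)
  post_sents <- numeric(0)
  sent_words <- numeric(0)
  user_words <- numeric(length(users))
  user_sents <- numeric(length(users))
  for (i in seq_along(users)) {
    u <- users[[i]]
    txt <- vapply(u$posts, function(p) p$text, character(1))
    w <- .word_count(txt)
    sents <- split_sentences(txt)
    ns <- lengths(sents)
    sw <- unlist(lapply(sents, .word_count), use.names = FALSE)
    post_words <- c(post_words, w)
    post_sents <- c(post_sents, ns)
    sent_words <- c(sent_words, sw)
    user_words[i] <- sum(w)
    user_sents[i] <- sum(ns)
  }
  rows <- list(
    posts_per_user = per_user_posts,
    words_per_user = user_words,
    sentences_per_user = user_sents,
    words_per_post = post_words,
    words_per_sentence = sent_words,
    sentences_per_post = post_sents
  )
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    x <- rows[[nm]]
    ms <- .mean_sd(x)
    data.frame(quantity = nm, mean = ms[["mean"]], sd = ms[["sd"]],
               n = length(x), single_observation = length(x) == 1L,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_users") <- length(users)
  class(out) <- c("ashn_cohort_stats", class(out))
  out
}

#' Read posts from a JSON-lines file
#'
#' One JSON object per line with keys `user_id`, `post_id`, optional `title`,
#' `text`, optional `timestamp`.
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @return A list of raw post records.
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    p <- jsonlite::fromJSON(l)
    if (is.null(p$user_id) || !nzchar(p$user_id)) stop("post without user_id")
    if (is.null(p$post_id) || !nzchar(p$post_id)) stop("post without post_id")
    list(user_id = as.character(p$user_id), post_id = as.character(p$post_id),
         title = if (is.null(p$title)) NA_character_ else as.character(p$title),
         text = if (is.null(p$text)) "" else as.character(p$text),
         timestamp = if (is.null(p$timestamp)) NA_character_ else as.character(p$timestamp))
  })
}

#' Read screening scores from CSV
#'
#' Expects a header `user_id,age,pdss_score`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with character `user_id`, numeric `age` and integer
#'   `pdss_score`.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  need <- c("user_id", "pdss_score")
  if (!all(need %in% names(df))) stop("scores CSV must have user_id and pdss_score columns")
  if (!"age" %in% names(df)) df$age <- NA_real_
  df$pdss_score <- as.integer(df$pdss_score)
  df[, c("user_id", "age", "pdss_score")]
}

#' Build the analysis cohort from raw posts and screening scores
#'
#' Runs the full preparation pipeline: text cleaning, word/character post
#' filter, tokenization, token-count filter, minimum-post user filter and
#' screening-score grouping; users assigned to the `excluded` band are
#' dropped. Each surviving post carries `tokens`, `tags` (part-of-speech) and
#' `sentiments` sequences.
#'
#' @param posts List of raw post records (see [read_posts_jsonl()]).
#' @param scores Data frame as returned by [read_scores_csv()].
#' @param min_words,max_chars Post length bounds (defaults 2 words, 3000
#'   characters).
#' @param min_tokens,max_tokens Token-count bounds (defaults 5 and 100).
#' @param min_posts Minimum surviving posts per user (default 10).
#' @param sentiment_lexicon Sentiment lexicon used for per-token labels
#'   (default the built-in lexicon).
#' @return A list of user records of class `"ashn_cohort"`.
#' @export
prepare_cohort <- function(posts, scores,
                           min_words = 2L, max_chars = 3000L,
                           min_tokens = 5L, max_tokens = 100L,
                           min_posts = 10L,
                           sentiment_lexicon = builtin_sentiment_lexicon()) {
  by_user <- split(posts, vapply(posts, function(p) p$user_id, character(1)))
  users <- vector("list", 0L)
  for (uid in scores$user_id) {
    ps <- by_user[[uid]]
    if (is.null(ps)) next
    row <- scores[match(uid, scores$user_id), ]
    group <- assign_group(row$pdss_score)
    if (group == "excluded") next
    ps <- lapply(ps, function(p) { p$text <- clean_text(p$text); p })
    ps <- filter_post_length(ps, min_words, max_chars)
    ps <- lapply(ps, function(p) {
      p$tokens <- tokenize(p$text)
      p
    })
    ps <- filter_token_length(ps, min_tokens, max_tokens)
    ps <- lapply(ps, function(p) {
      p$tags <- pos_tag(p$tokens)
      p$sentiments <- label_sentiment(p$tokens, sentiment_lexicon)
      p
    })
    users[[length(users) + 1L]] <- list(
      user_id = uid, age = row$age, pdss_score = row$pdss_score,
      group = group, posts = ps)
  }
  users <- filter_user_min_posts(users, min_posts)
  class(users) <- c("ashn_cohort", "list")
  users
}

#' @export
print.ashn_cohort <- function(x, ...) {
  groups <- vapply(x, function(u) u$group, character(1))
  nposts <- vapply(x, function(u) length(u$posts), integer(1))
  cat(sprintf("ashn cohort: %d users (%d depressed, %d control), %d posts\n",
              length(x), sum(groups == "depressed"), sum(groups == "control"),
              sum(nposts)))
  invisible(x)
}

#' Write a cohort to JSON-lines
#'
#' One JSON object per user holding the user record and its posts.
#'
#' @param cohort A cohort list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (u in cohort) {
    writeLines(jsonlite::toJSON(u, auto_unbox = TRUE, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort_jsonl()]
#'
#' @param path Path to the JSON-lines cohort file.
#' @return A cohort list of class `"ashn_cohort"`.
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  users <- lapply(lines, function(l) {
    u <- jsonlite::fromJSON(l, simplifyDataFrame = FALSE, simplifyVector = TRUE)
    u$posts <- lapply(u$posts, function(p) {
      p$tokens <- as.character(p$tokens)
      if (!is.null(p$tags)) p$tags <- as.character(p$tags)
      if (!is.null(p$sentiments)) p$sentiments <- as.character(p$sentiments)
      p
    })
    u
  })
  class(users) <- c("ashn_cohort", "list")
  users
}
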