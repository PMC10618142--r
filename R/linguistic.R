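# Linguistic feature extraction: tokenizer, part-of-speech tagging over a
# fixed 48-tag inventory, three-way sentiment labelling, the nine-category
# depressive-symptom lexicon, vocabulary construction and frequency tables.

#' The fixed 48-tag part-of-speech inventory
#'
#' Penn-Treebank-style tag set: the 36 word-level tags plus 12
#' punctuation/bracket/symbol tags, in a fixed order that defines the
#' dimension order of the one-hot encoding. The inventory is frozen at
#' exactly 48 unique symbols.
#'
#' @format Character vector of length 48.
#' @export
ASHN_POS_TAGS <- c(
  # word-level tags
  "CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
  "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$",
  "RB", "RBR", "RBS", "RP", "SYM", "TO", "UH",
  "VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "WDT", "WP", "WP$", "WRB",
  # punctuation / bracket / symbol tags
  "#", "$", "``", "''", "-LRB-", "-RRB-", ",", ".", ":", "HYPH", "NFP", "ADD"
)

#' Sentiment label space
#'
#' Fixed order of the three sentiment polarities; defines the dimension order
#' of the sentiment one-hot encoding.
#' @format Character vector of length 3.
#' @export
ASHN_SENTIMENTS <- c("positive", "neutral", "negative")

#' Tokenize cleaned text
#'
#' Lowercases and splits cleaned text into word tokens (runs of letters,
#' apostrophes kept inside words) and single-character punctuation tokens.
#'
#' @param text A single cleaned text string.
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' tokenize("I am sad.")  # c("i", "am", "sad", ".")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- tolower(text)
  m <- gregexpr("\\p{L}+(?:'\\p{L}+)*|[^\\p{L}\\s]", text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0L) character(0) else toks
}

# ---------------------------------------------------------------------------
# lightweight part-of-speech tagger: closed-class lexicon + suffix rules,
# noun fallback.  An external tagger can be plugged in via the `tagger`
# argument of pos_tag().

.pos_lexicon <- local({
  lex <- c(
    the = "DT", a = "DT", an = "DT", this = "DT", that = "DT",
    these = "DT", those = "DT", every = "DT", each = "DT", no = "DT",
    i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP",
    we = "PRP", they = "PRP", me = "PRP", him = "PRP", us = "PRP",
    them = "PRP", myself = "PRP", herself = "PRP", himself = "PRP",
    my = "PRP$", your = "PRP$", his = "PRP$", its = "PRP$",
    our = "PRP$", their = "PRP$", hers = "PRP$",
    "in" = "IN", on = "IN", at = "IN", of = "IN", "for" = "IN",
    with = "IN", from = "IN", about = "IN", into = "IN", over = "IN",
    under = "IN", after = "IN", before = "IN", by = "IN", since = "IN",
    through = "IN", during = "IN", without = "IN", like = "IN",
    and = "CC", or = "CC", but = "CC", nor = "CC", yet = "CC",
    can = "MD", could = "MD", will = "MD", would = "MD", shall = "MD",
    should = "MD", may = "MD", might = "MD", must = "MD",
    to = "TO", there = "EX",
    not = "RB", never = "RB", always = "RB", often = "RB", very = "RB",
    really = "RB", just = "RB", too = "RB", also = "RB", again = "RB",
    still = "RB", now = "RB", then = "RB", here = "RB",
    oh = "UH", wow = "UH", hey = "UH", please = "UH",
    which = "WDT", who = "WP", whom = "WP", what = "WP", whose = "WP$",
    when = "WRB", where = "WRB", why = "WRB", how = "WRB",
    one = "CD", two = "CD", three = "CD", four = "CD", five = "CD",
    six = "CD", seven = "CD", eight = "CD", nine = "CD", ten = "CD",
    be = "VB", am = "VBP", is = "VBZ", are = "VBP", was = "VBD",
    were = "VBD", been = "VBN", being = "VBG",
    have = "VBP", has = "VBZ", had = "VBD", having = "VBG",
    do = "VBP", does = "VBZ", did = "VBD", done = "VBN",
    go = "VBP", goes = "VBZ", went = "VBD", gone = "VBN",
    say = "VBP", says = "VBZ", said = "VBD",
    get = "VBP", got = "VBD", gets = "VBZ",
    feel = "VBP", feels = "VBZ", felt = "VBD",
    see = "VBP", saw = "VBD", seen = "VBN",
    know = "VBP", knew = "VBD", known = "VBN",
    think = "VBP", thought = "VBD",
    make = "VBP", made = "VBD", take = "VBP", took = "VBD",
    come = "VBP", came = "VBD", keep = "VBP", kept = "VBD",
    leave = "VBP", left = "VBD", tell = "VBP", told = "VBD",
    sit = "VBP", sat = "VBD", sleep = "VBP", slept = "VBD",
    wake = "VBP", woke = "VBD", eat = "VBP", ate = "VBD",
    cry = "VBP", cried = "VBD", want = "VBP", need = "VBP",
    cannot = "MD",
    good = "JJ", bad = "JJ", new = "JJ", little = "JJ", own = "JJ",
    other = "JJ", same = "JJ", whole = "JJ", sad = "JJ", happy = "JJ",
    tired = "JJ", alone = "JJ", empty = "JJ", awake = "JJ"
  )
  lex
})

.punct_tag <- function(tok) {
  switch(tok,
         "." = ".", "!" = ".", "?" = ".",
         "," = ",",
         ":" = ":", ";" = ":", "…" = ":",
         "‘" = "``", "“" = "``",
         "'" = "''", "\"" = "''", "’" = "''", "”" = "''",
         "(" = "-LRB-", "[" = "-LRB-", "{" = "-LRB-",
         ")" = "-RRB-", "]" = "-RRB-", "}" = "-RRB-",
         "-" = "HYPH", "–" = "HYPH", "—" = "HYPH",
         "#" = "#", "$" = "$",
         "NFP")
}

.suffix_tag <- function(word) {
  if (grepl("ing$", word) && nchar(word) > 4L) return("VBG")
  if (grepl("ed$", word) && nchar(word) > 3L) return("VBD")
  if (grepl("ly$", word) && nchar(word) > 3L) return("RB")
  if (grepl("est$", word) && nchar(word) > 4L) return("JJS")
  if (grepl("(ous|ful|ive|able|ible|less|ish)$", word)) return("JJ")
  if (grepl("(ness|ment|tion|sion|ity|ance|ence)$", word)) return("NN")
  if (grepl("[^s]s$", word) && nchar(word) > 3L) return("NNS")
  "NN"
}

#' Part-of-speech tagging over the 48-tag inventory
#'
#' The default tagger is a shipped lightweight rule tagger: a closed-class
#' word lexicon, then suffix rules, then the noun fallback `NN`; punctuation
#' tokens map to the matching punctuation tag. An external tagger can be
#' plugged in as a function `tokens -> tags`; its output is validated against
#' [ASHN_POS_TAGS].
#'
#' @param tokens Character vector of (lowercased) tokens.
#' @param tagger Optional replacement tagger function.
#' @return Character vector of tags, one per token, all in [ASHN_POS_TAGS].
#' @examples
#' pos_tag(c("the", "cat", "sat"))  # c("DT", "NN", "VBD")
#' @export
pos_tag <- function(tokens, tagger = NULL) {
  stopifnot(is.character(tokens))
  if (length(tokens) == 0L) return(character(0))
  if (!is.null(tagger)) {
    tags <- tagger(tokens)
    if (length(tags) != length(tokens) || !all(tags %in% ASHN_POS_TAGS)) {
      stop("external tagger returned an invalid tag sequence")
    }
    return(tags)
  }
  vapply(tokens, function(tok) {
    if (!grepl("\\p{L}", tok, perl = TRUE)) return(.punct_tag(tok))
    hit <- unname(.pos_lexicon[tok])
    if (!is.na(hit)) hit else .suffix_tag(tok)
  }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# sentiment lexicon

#' Built-in three-way sentiment lexicon
#'
#' A small packaged word-to-polarity table (no download needed) covering
#' common affect vocabulary; out-of-lexicon words are labelled neutral at
#' lookup time. An external lexicon can replace it via
#' [read_sentiment_lexicon()].
#'
#' @return A named character vector (word -> label) of class
#'   `"ashn_sentiment_lexicon"` with attribute `provenance = "builtin"`.
#' @export
builtin_sentiment_lexicon <- function() {
  negative <- c(
    "hopeless", "sleepless", "tired", "hurting", "anxious", "overeating",
    "panic", "crying", "sad", "unhappy", "miserable", "worthless", "guilty",
    "exhausted", "afraid", "fear", "lonely", "alone", "empty", "depressed",
    "awful", "terrible", "horrible", "bad", "worse", "worst", "pain",
    "angry", "upset", "stressed", "suicidal", "numb", "drained", "helpless",
    "restless", "insomnia", "failure", "useless", "burden", "shame",
    "nightmare", "ashamed", "despair", "gloomy", "weary", "hurt", "cry",
    "sick", "weak", "agitated", "overwhelmed", "tearful", "joyless",
    "fatigued", "sluggish", "listless", "unfocused", "forgetful")
  positive <- c(
    "medication", "planning", "happy", "joy", "love", "loved", "great",
    "good", "wonderful", "amazing", "excited", "grateful", "thankful",
    "hopeful", "calm", "peaceful", "proud", "smile", "laugh", "fun",
    "beautiful", "support", "better", "best", "glad", "sweet", "warm",
    "cheerful", "delighted", "relaxed", "blessed", "lovely")
  lex <- c(stats::setNames(rep("negative", length(negative)), negative),
           stats::setNames(rep("positive", length(positive)), positive))
  structure(lex, class = "ashn_sentiment_lexicon", provenance = "builtin")
}

#' Read an external sentiment lexicon
#'
#' Accepts a TSV with either two columns (`word<TAB>label`, label one of
#' positive/neutral/negative) or three columns
#' (`word<TAB>pos_score<TAB>neg_score`). Scored entries are mapped to hard
#' labels by strict majority: positive iff the positive score strictly
#' exceeds the negative score and exceeds 0; negative symmetrically;
#' otherwise neutral.
#'
#' @param path Path to the TSV file (no header).
#' @return A named character vector of class `"ashn_sentiment_lexicon"` with
#'   attribute `provenance = "external"`.
#' @export
read_sentiment_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    lab <- df[[2]]
    if (!all(lab %in% ASHN_SENTIMENTS)) stop("invalid sentiment labels in lexicon")
  } else if (ncol(df) >= 3L) {
    pos <- as.numeric(df[[2]]); neg <- as.numeric(df[[3]])
    lab <- ifelse(pos > neg & pos > 0, "positive",
                  ifelse(neg > pos & neg > 0, "negative", "neutral"))
  } else stop("sentiment lexicon must have 2 or 3 columns")
  lex <- stats::setNames(lab, tolower(df[[1]]))
  structure(lex, class = "ashn_sentiment_lexicon", provenance = "external")
}

#' Label tokens with sentiment polarity
#'
#' Case-insensitive lexicon lookup; words absent from the lexicon are
#' neutral.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon A sentiment lexicon (default the built-in one).
#' @return Character vector of labels in [ASHN_SENTIMENTS].
#' @export
label_sentiment <- function(tokens, lexicon = builtin_sentiment_lexicon()) {
  if (length(tokens) == 0L) return(character(0))
  lab <- unname(unclass(lexicon)[tolower(tokens)])
  lab[is.na(lab)] <- "neutral"
  lab
}

# ---------------------------------------------------------------------------
# symptom lexicon: nine DSM-5 major-depression symptom domains, 76 keywords.

#' Built-in depressive-symptom keyword lexicon
#'
#' A reconstruction of a nine-category symptom keyword dictionary over the
#' DSM-5 major-depression symptom domains (depressed mood, anhedonia,
#' appetite/weight change, sleep disturbance, psychomotor change, fatigue,
#' worthlessness/guilt, impaired concentration, suicidality), 76 keywords in
#' total. The category structure (9 categories, 76 unique-per-category
#' keywords) is frozen; the content is synthetic/reconstructed and fully
#' replaceable via [read_symptom_lexicon()].
#'
#' @return Named list of 9 character vectors, class `"ashn_symptom_lexicon"`.
#' @export
builtin_symptom_lexicon <- function() {
  lex <- list(
    depressed_mood = c("sad", "hopeless", "empty", "tearful", "crying",
                       "miserable", "down", "unhappy", "despair", "gloomy"),
    anhedonia = c("uninterested", "joyless", "unmotivated", "bored", "numb",
                  "indifferent", "apathetic", "detached"),
    appetite_weight = c("appetite", "overeating", "undereating", "weight",
                        "skinny", "bingeing", "hungry", "craving"),
    sleep = c("insomnia", "sleepless", "oversleeping", "awake", "nightmare",
              "restless", "drowsy", "tossing", "unrested"),
    psychomotor = c("agitated", "slowed", "sluggish", "fidgety", "pacing",
                    "restlessness", "lethargic"),
    fatigue = c("tired", "exhausted", "fatigued", "drained", "weary", "weak",
                "listless", "burnout"),
    worthlessness_guilt = c("worthless", "guilty", "shame", "failure",
                            "burden", "useless", "inadequate", "blame",
                            "regret"),
    concentration = c("unfocused", "indecisive", "forgetful", "distracted",
                      "confused", "foggy", "scattered", "absentminded"),
    suicidality = c("suicidal", "suicide", "die", "death", "overdose",
                    "selfharm", "harming", "ending", "lifeless")
  )
  validate_symptom_lexicon(lex)
}

#' Validate a symptom lexicon
#'
#' Checks the frozen structural contract: exactly 9 non-empty categories, 76
#' keywords in total, keywords unique within each category.
#'
#' @param lex Named list of character vectors.
#' @return The lexicon with class `"ashn_symptom_lexicon"`.
#' @export
validate_symptom_lexicon <- function(lex) {
  if (!is.list(lex) || length(lex) != 9L) stop("symptom lexicon must have 9 categories")
  if (any(!nzchar(names(lex))) || anyDuplicated(names(lex))) {
    stop("symptom lexicon categories must be uniquely named")
  }
  if (any(lengths(lex) == 0L)) stop("symptom lexicon categories must be non-empty")
  if (any(vapply(lex, anyDuplicated, integer(1)) > 0L)) {
    stop("keywords must be unique within a category")
  }
  if (sum(lengths(lex)) != 76L) stop("symptom lexicon must hold 76 keywords in total")
  structure(lex, class = c("ashn_symptom_lexicon", "list"))
}

#' Read a symptom lexicon from JSON
#'
#' Expects `{"category": ["keyword", ...], ...}`; validated with
#' [validate_symptom_lexicon()].
#'
#' @param path Path to the JSON file.
#' @return A validated symptom lexicon.
#' @export
read_symptom_lexicon <- function(path) {
  validate_symptom_lexicon(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# ---------------------------------------------------------------------------
# one-hot encodings

#' One-hot encode a part-of-speech tag sequence
#'
#' @param tags Character vector of tags, all in [ASHN_POS_TAGS].
#' @return A `length(tags) x 48` 0/1 matrix; column order is the tag-set
#'   order.
#' @export
encode_pos_onehot <- function(tags) {
  idx <- match(tags, ASHN_POS_TAGS)
  if (anyNA(idx)) stop("unknown part-of-speech tag: ",
                       paste(unique(tags[is.na(idx)]), collapse = ", "))
  m <- matrix(0, nrow = length(tags), ncol = length(ASHN_POS_TAGS),
              dimnames = list(NULL, ASHN_POS_TAGS))
  if (length(tags)) m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a part-of-speech one-hot matrix back to tags
#' @param onehot Matrix produced by [encode_pos_onehot()].
#' @return Character vector of tags.
#' @export
decode_pos_onehot <- function(onehot) {
  if (nrow(onehot) == 0L) return(character(0))
  ASHN_POS_TAGS[max.col(onehot)]
}

#' One-hot encode a sentiment label sequence
#'
#' Column order is fixed: positive, neutral, negative.
#'
#' @param labels Character vector of labels in [ASHN_SENTIMENTS].
#' @return A `length(labels) x 3` 0/1 matrix.
#' @export
encode_sentiment_onehot <- function(labels) {
  idx <- match(labels, ASHN_SENTIMENTS)
  if (anyNA(idx)) stop("unknown sentiment label")
  m <- matrix(0, nrow = length(labels), ncol = 3L,
              dimnames = list(NULL, ASHN_SENTIMENTS))
  if (length(labels)) m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a sentiment one-hot matrix back to labels
#' @param onehot Matrix produced by [encode_sentiment_onehot()].
#' @return Character vector of labels.
#' @export
decode_sentiment_onehot <- function(onehot) {
  if (nrow(onehot) == 0L) return(character(0))
  ASHN_SENTIMENTS[max.col(onehot)]
}

# ---------------------------------------------------------------------------
# vocabulary

#' Build a vocabulary from a token corpus
#'
#' Words are retained iff they occur strictly more than `min_count` times in
#' the corpus (default 5); all other words map to the reserved `UNK` token at
#' encoding time. Ids are stable: `UNK = 0`, `PAD = 1`, then retained words
#' by decreasing count with lexicographic tie-break.
#'
#' @param corpus List of token character vectors.
#' @param min_count Retention threshold (kept iff count > `min_count`).
#' @return Object of class `"ashn_vocabulary"`: a named integer vector
#'   (word -> id) including `UNK` and `PAD`, with attribute `min_count`.
#' @export
build_vocabulary <- function(corpus, min_count = 5L) {
  toks <- unlist(corpus, use.names = FALSE)
  counts <- if (length(toks)) table(toks) else table(character(0))
  keep <- counts[counts > min_count]
  ord <- order(-as.integer(keep), names(keep))
  words <- names(keep)[ord]
  words <- setdiff(words, c("UNK", "PAD"))
  ids <- stats::setNames(c(0L, 1L, seq_along(words) + 1L),
                         c("UNK", "PAD", words))
  structure(ids, class = "ashn_vocabulary", min_count = min_count)
}

#' Map tokens to vocabulary ids
#'
#' Out-of-vocabulary tokens receive the `UNK` id (0).
#'
#' @param tokens Character vector of tokens.
#' @param vocab An `"ashn_vocabulary"` object.
#' @return Integer vector of ids.
#' @export
encode_tokens <- function(tokens, vocab) {
  ids <- unclass(vocab)[tokens]
  ids[is.na(ids)] <- 0L
  unname(ids)
}

#' Write / read a vocabulary as TSV (word<TAB>id)
#' @param vocab An `"ashn_vocabulary"` object.
#' @param path File path.
#' @return `path` (write) or the vocabulary (read).
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(data.frame(word = names(vocab), id = as.integer(vocab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  structure(stats::setNames(as.integer(df[[2]]), df[[1]]),
            class = "ashn_vocabulary", min_count = NA_integer_)
}

# ---------------------------------------------------------------------------
# frequency tables (word-cloud style summaries)

#' Word-frequency table with sentiment polarity
#'
#' Counts word tokens (punctuation tokens are skipped) over the chosen field
#' of a post collection and returns the `top_k` words by count, ties broken
#' lexicographically, with each word's lexicon polarity.
#'
#' @param posts List of post records carrying `tokens` (field `"text"`) and
#'   optionally `title`.
#' @param lexicon Sentiment lexicon for the polarity column.
#' @param top_k Number of rows to return (default 50).
#' @param field `"text"` (uses the stored token sequences) or `"title"`
#'   (titles are cleaned and tokenized on the fly).
#' @return Data frame with columns `word`, `count`, `polarity`, sorted by
#'   decreasing count.
#' @export
frequency_table <- function(posts, lexicon = builtin_sentiment_lexicon(),
                            top_k = 50L, field = c("text", "title")) {
  if (top_k < 1L) stop("top_k must be >= 1")
  field <- match.arg(field)
  toks <- unlist(lapply(posts, function(p) {
    if (field == "text") p$tokens else {
      t <- p$title
      if (is.null(t) || is.na(t)) character(0) else tokenize(clean_text(t))
    }
  }), use.names = FALSE)
  toks <- toks[grepl("\\p{L}", toks, perl = TRUE)]
  if (length(toks) == 0L) {
    return(data.frame(word = character(0), count = integer(0),
                      polarity = character(0), stringsAsFactors = FALSE))
  }
  counts <- table(toks)
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord][seq_len(min(top_k, length(counts)))]
  data.frame(word = names(counts), count = as.integer(counts),
             polarity = label_sentiment(names(counts), lexicon),
             stringsAsFactors = FALSE, row.names = NULL)
}
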