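# Model fitting: the ashn() entry point (Adam, L2, gradient-norm clipping,
# seeded and deterministic), prediction, and the usual S3 methods.

#' Fit an attribute selection hybrid network
#'
#' Trains the depression classifier on a prepared cohort: posts are sampled
#' per user, a vocabulary is built (words kept iff they occur more than five
#' times), and the network is trained with Adam under L2 regularization and
#' global gradient-norm clipping, minimizing binary cross-entropy on the
#' user-level depressed-class probability. The run is deterministic given
#' `(cohort, config)`: the same seed yields identical loss traces and final
#' parameters.
#'
#' @param cohort An `"ashn_cohort"` (see [prepare_cohort()] or
#'   [simulate_corpus()]) with at least two users in each group.
#' @param config An `"ashn_config"`; `config$architecture` selects the
#'   attribute network (`"ashn"`) or the bidirectional-GRU baseline
#'   (`"birnn"`).
#' @param vocab Optional pre-built `"ashn_vocabulary"`; by default built from
#'   the sampled training posts with the `count > 5` rule.
#' @param symptom_lexicon Symptom lexicon for the A3 encoder.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `"ashn"`: a list with elements `config`,
#'   `params`, `vocab`, `symptom_lexicon`, `loss_trace` (mean training loss
#'   per epoch), `train_ids` and the fitted training predictions
#'   (`fitted`).
#' @seealso [predict.ashn()], [evaluate()], [simulate_corpus()]
#' @export
ashn <- function(cohort, config = ashn_config(), vocab = NULL,
                 symptom_lexicon = builtin_symptom_lexicon(),
                 verbose = FALSE) {
  stopifnot(inherits(config, "ashn_config"))
  groups <- vapply(cohort, function(u) u$group, character(1))
  if (length(unique(groups)) < 2L ||
      any(table(factor(groups, c("control", "depressed"))) < 2L)) {
    stop("training needs at least two users in each group")
  }
  # per-user training sample, seeded off the run seed
  sampled <- lapply(seq_along(cohort), function(i) {
    u <- cohort[[i]]
    u$posts <- sample_training_posts(u, config$sample_posts,
                                     seed = config$seed + i)
    u
  })
  if (is.null(vocab)) {
    toks <- unlist(lapply(sampled, function(u) lapply(u$posts, `[[`, "tokens")),
                   recursive = FALSE)
    vocab <- build_vocabulary(toks, min_count = 5L)
  }
  params <- ashn_parameters(config, vocab_size = length(vocab))
  encs <- lapply(sampled, encode_user, vocab = vocab,
                 symptom_lexicon = symptom_lexicon, cfg = config)
  fp <- flatten_params(params)
  state <- .adam_new_state(fp)
  n <- length(encs)
  loss_trace <- numeric(config$epochs)
  withr_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, n)]
        ad_zero_grads(fp)
        for (i in batch) {
          ad_reset_tape()
          fwd <- .forward_user(encs[[i]], params, config, training = TRUE)
          loss <- ad_bce_with_logit(fwd$logit, encs[[i]]$y)
          ad_backward(loss)
          total <- total + loss$val[1L]
        }
        ad_reset_tape()
        .adam_apply(fp, state, config, batch_n = length(batch))
      }
      loss_trace[epoch] <- total / n
      if (verbose) message(sprintf("epoch %d  loss %.4f", epoch, loss_trace[epoch]))
    }
  })
  fit <- structure(list(config = config, params = params, vocab = vocab,
                        symptom_lexicon = symptom_lexicon,
                        loss_trace = loss_trace,
                        train_ids = vapply(cohort, `[[`, character(1), "user_id"),
                        call = match.call()),
                   class = "ashn")
  fit$fitted <- predict(fit, cohort)
  fit
}

# ---------------------------------------------------------------------------
# Adam optimizer (with L2 term and global gradient-norm clipping)

.adam_new_state <- function(fp) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- lapply(fp, function(p) p$val * 0)
  e$v <- lapply(fp, function(p) p$val * 0)
  e
}

.adam_apply <- function(fp, state, config, batch_n = 1L,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  grads <- lapply(fp, function(p) {
    g <- if (is.null(p$grad)) p$val * 0 else p$grad / batch_n
    g + config$l2 * p$val
  })
  if (is.finite(config$grad_clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gn > config$grad_clip) {
      grads <- lapply(grads, function(g) g * (config$grad_clip / gn))
    }
  }
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in seq_along(fp)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    fp[[k]]$val <- fp[[k]]$val -
      config$learning_rate * (state$m[[k]] / c1) /
      (sqrt(state$v[[k]] / c2) + eps)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# prediction

#' Predict depression risk for a cohort
#'
#' Runs the full forward pass (dropout disabled) on every user and returns
#' per-user probabilities, hard labels at the configured threshold, per-post
#' attention weights and (for the attribute architecture) the per-post
#' five-way attribute fusion weights.
#'
#' @param object A fitted `"ashn"` model.
#' @param newdata A cohort list.
#' @param threshold Classification threshold (default from the fit's
#'   config).
#' @param ... Unused.
#' @return An object of class `"ashn_predictions"`: a list of per-user
#'   records with fields `user_id`, `group` (truth, if present),
#'   `probability`, `label`, `attention` (named by post id) and `fusion`
#'   (`M x 5` matrix, rows named by post id). `as.data.frame()` gives the
#'   flat per-user table.
#' @export
predict.ashn <- function(object, newdata,
                         threshold = object$config$threshold, ...) {
  preds <- lapply(newdata, function(u) {
    enc <- encode_user(u, object$vocab, object$symptom_lexicon, object$config)
    ad_reset_tape()
    fwd <- .forward_user(enc, object$params, object$config, training = FALSE)
    ad_reset_tape()
    att <- stats::setNames(fwd$attention, enc$post_ids)
    fus <- fwd$fusion
    rownames(fus) <- enc$post_ids
    colnames(fus) <- paste0("a", 0:4)
    list(user_id = u$user_id,
         group = if (is.null(u$group)) NA_character_ else u$group,
         probability = fwd$prob,
         label = if (fwd$prob >= threshold) "depressed" else "control",
         attention = att, fusion = fus)
  })
  structure(preds, class = c("ashn_predictions", "list"))
}

#' @export
as.data.frame.ashn_predictions <- function(x, ...) {
  data.frame(user_id = vapply(x, `[[`, character(1), "user_id"),
             group = vapply(x, `[[`, character(1), "group"),
             probability = vapply(x, `[[`, numeric(1), "probability"),
             label = vapply(x, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}

#' @export
print.ashn <- function(x, ...) {
  cat(sprintf("Attribute selection hybrid network (%s)\n",
              if (x$config$architecture == "ashn") "attribute model" else "BiGRU baseline"))
  cat(sprintf("  users: %d   vocabulary: %d ids   epochs: %d\n",
              length(x$train_ids), length(x$vocab), x$config$epochs))
  if (length(x$loss_trace)) {
    cat(sprintf("  training loss: %.4f -> %.4f\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  }
  invisible(x)
}

#' @export
summary.ashn <- function(object, ...) {
  df <- as.data.frame(object$fitted)
  cc <- confusion_counts(df$label, df$group)
  mets <- compute_metrics(cc)
  out <- list(config = object$config, loss_trace = object$loss_trace,
              train_confusion = cc, train_metrics = mets)
  class(out) <- "summary.ashn"
  out
}

#' @export
print.summary.ashn <- function(x, ...) {
  cat(sprintf("ashn fit (%s), %d epochs\n", x$config$architecture,
              x$config$epochs))
  if (length(x$loss_trace)) {
    cat(sprintf("training loss: first %.4f, last %.4f\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  }
  cat(sprintf("training confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$train_confusion["TP"], x$train_confusion["FP"],
              x$train_confusion["FN"], x$train_confusion["TN"]))
  with(x$train_metrics, cat(sprintf(
    "precision %.3f  recall %.3f  accuracy %.3f  F1 %.3f\n",
    precision, recall, accuracy, f1)))
  invisible(x)
}

#' @export
coef.ashn <- function(object, ...) {
  lapply(flatten_params(object$params), function(p) p$val)
}

#' @export
plot.ashn <- function(x, ...) {
  if (!length(x$loss_trace)) {
    warning("no loss trace to plot (0 epochs)")
    return(invisible(x))
  }
  plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
       xlab = "epoch", ylab = "mean training loss",
       main = "ashn training loss", ...)
  invisible(x)
}

#' @export
residuals.ashn <- function(object, ...) {
  df <- as.data.frame(object$fitted)
  stats::setNames((df$group == "depressed") - df$probability, df$user_id)
}

# ---------------------------------------------------------------------------
# checkpointing (text JSON: parameter arrays + config + vocabulary)

#' Save / load a fitted model as a JSON checkpoint
#'
#' The checkpoint is one JSON document holding the configuration, every
#' parameter array keyed by its flattened name, the vocabulary, the two
#' lexicons, and md5 content hashes of the vocabulary and lexicons.
#'
#' @param fit A fitted `"ashn"` object.
#' @param path Output path.
#' @return `path` (save) or the restored `"ashn"` object (load).
#' @export
save_ashn <- function(fit, path) {
  arrays <- lapply(flatten_params(fit$params), function(p) p$val)
  hash_of <- function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(jsonlite::toJSON(x, digits = NA), tf)
    unname(tools::md5sum(tf))
  }
  doc <- list(config = unclass(fit$config),
              params = arrays,
              vocab = list(words = names(fit$vocab), ids = as.integer(fit$vocab)),
              symptom_lexicon = unclass(fit$symptom_lexicon),
              loss_trace = fit$loss_trace,
              train_ids = fit$train_ids,
              hashes = list(vocab = hash_of(as.integer(fit$vocab)),
                            symptom_lexicon = hash_of(unclass(fit$symptom_lexicon))))
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_ashn
#' @export
load_ashn <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg_args <- doc$config
  cfg <- do.call(ashn_config, cfg_args)
  vocab <- structure(stats::setNames(as.integer(doc$vocab$ids), doc$vocab$words),
                     class = "ashn_vocabulary", min_count = 5L)
  params <- ashn_parameters(cfg, vocab_size = length(vocab))
  fp <- flatten_params(params)
  for (nm in names(fp)) {
    arr <- doc$params[[nm]]
    fp[[nm]]$val <- matrix(as.numeric(arr), nrow = nrow(fp[[nm]]$val))
  }
  structure(list(config = cfg, params = params, vocab = vocab,
                 symptom_lexicon = validate_symptom_lexicon(doc$symptom_lexicon),
                 loss_trace = as.numeric(doc$loss_trace),
                 train_ids = doc$train_ids, call = NULL, fitted = NULL),
            class = "ashn")
}

# ---------------------------------------------------------------------------
# splits and cross-validation

#' Stratified user-level train/test split
#'
#' @param cohort A cohort list.
#' @param test_fraction Fraction of users per group held out (default 0.2).
#' @param seed Seed for the draw.
#' @return List with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, seed = 1L) {
  groups <- vapply(cohort, `[[`, character(1), "group")
  test_idx <- withr_seed(seed, {
    unlist(lapply(unique(groups), function(g) {
      idx <- which(groups == g)
      k <- max(1L, round(length(idx) * test_fraction))
      sample(idx, k)
    }))
  })
  train <- cohort[-test_idx]; class(train) <- class(cohort)
  test <- cohort[test_idx]; class(test) <- class(cohort)
  list(train = train, test = test)
}

#' K-fold cross-validation of the classifier
#'
#' Stratified user-level folds; each fold is held out once, the model is
#' refit on the remainder and evaluated on the fold. Reported as mean and
#' sample standard deviation per metric.
#'
#' @param cohort A cohort list.
#' @param config An `"ashn_config"`.
#' @param folds Number of folds (default 5).
#' @param seed Seed for fold assignment.
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
ashn_cross_validate <- function(cohort, config, folds = 5L, seed = 1L) {
  groups <- vapply(cohort, `[[`, character(1), "group")
  fold_of <- integer(length(cohort))
  withr_seed(seed, {
    for (g in unique(groups)) {
      idx <- sample(which(groups == g))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  rows <- lapply(seq_len(folds), function(f) {
    train <- cohort[fold_of != f]; class(train) <- class(cohort)
    test <- cohort[fold_of == f]; class(test) <- class(cohort)
    fit <- ashn(train, config)
    evaluate(fit, test)
  })
  mets <- c("precision", "recall", "accuracy", "f1", "auc")
  do.call(rbind, lapply(mets, function(m) {
    x <- vapply(rows, function(r) r[[m]], numeric(1))
    data.frame(metric = m, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0)
  }))
}
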