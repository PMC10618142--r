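# Evaluation metrics (precision/recall/accuracy/F1, rank-based AUC) and the
# attention-based interpretation reports.  "depressed" is the positive class
# throughout.

.as_binary <- function(x) {
  if (is.character(x)) {
    if (!all(x %in% c("depressed", "control"))) stop("labels must be depressed/control")
    as.integer(x == "depressed")
  } else as.integer(x)
}

#' Confusion counts
#'
#' Tabulates true/false positives and negatives with `depressed` as the
#' positive class.
#'
#' @param predictions Predicted labels: `"depressed"`/`"control"` or 1/0.
#' @param labels True labels in the same encoding, same length.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  p <- .as_binary(predictions)
  y <- .as_binary(labels)
  c(TP = sum(p == 1L & y == 1L), FP = sum(p == 1L & y == 0L),
    FN = sum(p == 0L & y == 1L), TN = sum(p == 0L & y == 0L))
}

#' Classification metrics from confusion counts
#'
#' Recall `TP / (TP + FN)`, precision `TP / (TP + FP)`, accuracy
#' `(TP + TN) / n`, and F1 as the harmonic mean of precision and recall.
#' Zero-denominator cases return 0 and are flagged in `degenerate`.
#'
#' @param counts Named vector from [confusion_counts()].
#' @return List with `precision`, `recall`, `accuracy`, `f1` and the
#'   character vector `degenerate` naming any zero-denominator metrics.
#' @export
compute_metrics <- function(counts) {
  counts <- counts[c("TP", "FP", "FN", "TN")]
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("empty evaluation: all counts are zero")
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  list(precision = precision, recall = recall,
       accuracy = (tp + counts[["TN"]]) / n, f1 = f1, degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Rank (concordance) formulation with tie correction: the probability that
#' a randomly chosen positive outscores a randomly chosen negative, ties
#' counted one half.
#'
#' @param scores Numeric scores (higher = more depressed).
#' @param labels True labels (`"depressed"`/`"control"` or 1/0).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  y <- .as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC is undefined for a single-class input")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted model on a cohort
#'
#' @param fit A fitted `"ashn"` model.
#' @param cohort Cohort with true `group` labels.
#' @param threshold Classification threshold (default from the fit).
#' @return List with `precision`, `recall`, `accuracy`, `f1`, `auc`,
#'   `counts`, and the `"ashn_predictions"` used (`predictions`).
#' @export
evaluate <- function(fit, cohort, threshold = fit$config$threshold) {
  preds <- predict(fit, cohort, threshold = threshold)
  df <- as.data.frame(preds)
  cc <- confusion_counts(df$label, df$group)
  mets <- compute_metrics(cc)
  mets$auc <- compute_auc(df$probability, df$group)
  mets$counts <- cc
  mets$predictions <- preds
  mets
}

#' Write a metrics table as CSV
#'
#' Columns `metric`, `mean`, `sd` (sd 0 for a single run).
#'
#' @param metrics Either an [evaluate()] result or a data frame from
#'   [ashn_cross_validate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- if (is.data.frame(metrics)) metrics else {
    data.frame(metric = c("precision", "recall", "accuracy", "f1", "auc"),
               mean = c(metrics$precision, metrics$recall, metrics$accuracy,
                        metrics$f1, metrics$auc),
               sd = 0)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# interpretation

#' Rank a user's posts by attention weight
#'
#' Posts sorted by attention descending, ties broken by post id; returns the
#' top `k` posts or, if `fraction` is given, the top `floor(fraction * M)`
#' posts (at least one).
#'
#' @param prediction One element of an `"ashn_predictions"` object (carries
#'   the per-post attention).
#' @param k Number of posts to return.
#' @param fraction Alternative to `k`: fraction of the user's posts.
#' @return Named numeric vector of attention weights for the selected posts,
#'   in rank order.
#' @export
rank_posts_by_attention <- function(prediction, k = NULL, fraction = NULL) {
  att <- prediction$attention
  if (is.null(k)) {
    if (is.null(fraction)) stop("give k or fraction")
    k <- max(1L, floor(fraction * length(att)))
  }
  if (k < 1L) stop("k must be >= 1")
  ord <- order(-att, names(att))
  att[ord][seq_len(min(k, length(att)))]
}

#' Attention overlap between two post rankings
#'
#' Number of shared post ids between two lists.
#'
#' @param list_a,list_b Character vectors of post ids (or named vectors as
#'   returned by [rank_posts_by_attention()]).
#' @return Integer overlap count.
#' @export
attention_overlap <- function(list_a, list_b) {
  a <- if (is.character(list_a)) list_a else names(list_a)
  b <- if (is.character(list_b)) list_b else names(list_b)
  length(intersect(a, b))
}

#' Per-attribute fusion-weight report by outcome and attention stratum
#'
#' For each outcome class (TP, TN, FP, FN of the hard labels against the
#' truth) and each attention stratum (each user's top-k and bottom-k posts
#' by attention weight, k defaulting to 20% of the user's posts), reports
#' the mean fusion weight of each of the five attributes. Empty strata are
#' absent from the table rather than reported as zero.
#'
#' @param predictions An `"ashn_predictions"` object carrying fusion
#'   weights.
#' @param labels Optional truth labels (defaults to the `group` carried by
#'   the predictions).
#' @param k Posts per stratum and user; default `NULL` means
#'   `max(1, floor(fraction * M))` per user.
#' @param fraction Fraction for the default `k` (0.2).
#' @return Data frame with columns `outcome`, `attention`, `attribute`,
#'   `mean_weight`, `n_posts`.
#' @export
attribute_weight_report <- function(predictions, labels = NULL, k = NULL,
                                    fraction = 0.2) {
  truth <- if (is.null(labels)) {
    vapply(predictions, `[[`, character(1), "group")
  } else labels
  pred <- vapply(predictions, `[[`, character(1), "label")
  outcome <- ifelse(pred == "depressed" & truth == "depressed", "TP",
             ifelse(pred == "control" & truth == "control", "TN",
             ifelse(pred == "depressed" & truth == "control", "FP", "FN")))
  acc <- list()
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    if (all(is.na(p$fusion))) next  # baseline carries no fusion weights
    M <- length(p$attention)
    ki <- if (is.null(k)) max(1L, floor(fraction * M)) else min(k, M)
    ord <- order(-p$attention, names(p$attention))
    strata <- list(high = ord[seq_len(ki)], low = rev(ord)[seq_len(ki)])
    for (s in names(strata)) {
      key <- paste(outcome[i], s)
      w <- p$fusion[strata[[s]], , drop = FALSE]
      acc[[key]] <- if (is.null(acc[[key]])) w else rbind(acc[[key]], w)
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(outcome = character(0), attention = character(0),
                      attribute = character(0), mean_weight = numeric(0),
                      n_posts = integer(0)))
  }
  do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, " ")[[1]]
    w <- acc[[key]]
    data.frame(outcome = parts[1], attention = parts[2],
               attribute = colnames(w), mean_weight = colMeans(w),
               n_posts = nrow(w), row.names = NULL)
  }))
}

#' Write an attribution report as CSV
#' @param report Data frame from [attribute_weight_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
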