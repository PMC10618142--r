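# evaluation metrics and interpretation reports against brute-force oracles

test_that("confusion counts follow the four outcome definitions", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(cc, c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  cc2 <- confusion_counts(c("depressed", "control"), c("depressed", "control"))
  expect_identical(unname(cc2[c("FP", "FN")]), c(0L, 0L))
  set.seed(40)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    p <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    expect_identical(sum(confusion_counts(p, y)), n)
  }
  expect_error(confusion_counts(c(1, 0), 1), "equal length")
})

test_that("precision, recall, accuracy and F1 follow their definitions", {
  perfect <- compute_metrics(c(TP = 1L, FP = 0L, FN = 0L, TN = 1L))
  expect_equal(unlist(perfect[c("precision", "recall", "accuracy", "f1")]),
               c(precision = 1, recall = 1, accuracy = 1, f1 = 1))
  m <- compute_metrics(c(TP = 3L, FP = 1L, FN = 3L, TN = 3L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.6)
  expect_equal(m$accuracy, 0.6)
  # zero-denominator convention: 0 with a degeneracy flag
  d <- compute_metrics(c(TP = 0L, FP = 0L, FN = 2L, TN = 3L))
  expect_identical(d$precision, 0)
  expect_true("precision" %in% d$degenerate)
  expect_error(compute_metrics(c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)), "empty")
})

test_that("metric formulas match brute-force recomputation on random instances", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    p <- rbinom(n, 1, runif(1)); y <- rbinom(n, 1, runif(1))
    cc <- confusion_counts(p, y)
    m <- compute_metrics(cc)
    tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y)
    expect_identical(m$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_identical(m$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    expect_identical(m$accuracy, mean(p == y))
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall), tolerance = 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("AUC equals pairwise concordance with half-weight ties", {
  expect_identical(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(compute_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)   # coarse scores so ties occur
    pos <- s[y == 1]; neg <- s[y == 0]
    grid <- expand.grid(p = pos, n = neg)
    oracle <- mean(ifelse(grid$p > grid$n, 1, ifelse(grid$p == grid$n, 0.5, 0)))
    expect_equal(compute_auc(s, y), oracle, tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(compute_auc(exp(2 * s), y), oracle, tolerance = 1e-12)
  }
  expect_error(compute_auc(c(1, 2), c(1, 1)), "single-class")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(compute_auc(s, y), ref, tolerance = 1e-12)
})

test_that("attention ranking sorts descending with id tie-breaks", {
  pred <- list(attention = c(p3 = 0.2, p1 = 0.5, p2 = 0.2, p4 = 0.1))
  r <- rank_posts_by_attention(pred, k = 3L)
  expect_identical(names(r), c("p1", "p2", "p3"))   # tie 0.2 broken by id
  expect_identical(names(rank_posts_by_attention(pred, k = 10L)),
                   c("p1", "p2", "p3", "p4"))
  expect_identical(names(rank_posts_by_attention(pred, fraction = 0.5)),
                   c("p1", "p2"))
  # uniform attention: pure id order
  u <- list(attention = setNames(rep(0.25, 4), c("b", "d", "a", "c")))
  expect_identical(names(rank_posts_by_attention(u, k = 2L)), c("a", "b"))
  expect_error(rank_posts_by_attention(pred, k = 0L), "k must be")
  # matches a brute-force sort on random weights
  set.seed(44)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    att <- setNames(runif(n), paste0("p", sample(100, n)))
    k <- sample(n, 1)
    r <- rank_posts_by_attention(list(attention = att), k = k)
    oracle <- att[order(-att, names(att))][seq_len(k)]
    expect_identical(r, oracle)
  }
})

test_that("attention overlap is the post-id intersection size", {
  expect_identical(attention_overlap(paste0("p", 1:100), paste0("p", 1:100)), 100L)
  expect_identical(attention_overlap(paste0("a", 1:10), paste0("b", 1:10)), 0L)
  set.seed(45)
  for (i in 1:50) {
    a <- sample(paste0("p", 1:40), sample(5:20, 1))
    b <- sample(paste0("p", 1:40), sample(5:20, 1))
    expect_identical(attention_overlap(a, b), length(intersect(a, b)))
  }
})

test_that("the attribute weight report stratifies by outcome and attention", {
  mk_pred <- function(uid, label, group, M, fus = NULL) {
    att <- setNames(seq_len(M) / sum(seq_len(M)), paste0(uid, "_p", seq_len(M)))
    if (is.null(fus)) fus <- matrix(0.2, M, 5)
    rownames(fus) <- names(att); colnames(fus) <- paste0("a", 0:4)
    list(user_id = uid, group = group, probability = 0.5, label = label,
         attention = att, fusion = fus)
  }
  preds <- structure(list(
    mk_pred("u1", "depressed", "depressed", 10L),
    mk_pred("u2", "control", "control", 10L)),
    class = c("ashn_predictions", "list"))
  rep1 <- attribute_weight_report(preds)
  expect_true(all(abs(rep1$mean_weight - 0.2) < 1e-12))
  expect_setequal(unique(rep1$outcome), c("TP", "TN"))
  expect_setequal(unique(rep1$attention), c("high", "low"))
  # single user, k = all posts: high and low strata coincide
  one <- structure(list(mk_pred("u1", "depressed", "depressed", 6L)),
                   class = c("ashn_predictions", "list"))
  r_all <- attribute_weight_report(one, k = 6L)
  hi <- r_all[r_all$attention == "high", "mean_weight"]
  lo <- r_all[r_all$attention == "low", "mean_weight"]
  expect_equal(hi, lo, tolerance = 1e-12)
  # random instance vs a brute-force group-by mean
  set.seed(46)
  M <- 10L
  fus <- matrix(runif(M * 5), M); fus <- fus / rowSums(fus)
  p <- mk_pred("u9", "depressed", "depressed", M, fus)
  preds2 <- structure(list(p), class = c("ashn_predictions", "list"))
  k <- 3L
  r <- attribute_weight_report(preds2, k = k)
  ord <- order(-p$attention, names(p$attention))
  top <- fus[ord[1:k], ]; bot <- fus[rev(ord)[1:k], ]
  expect_equal(r$mean_weight[r$attention == "high"], unname(colMeans(top)),
               tolerance = 1e-12)
  expect_equal(r$mean_weight[r$attention == "low"], unname(colMeans(bot)),
               tolerance = 1e-12)
})
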