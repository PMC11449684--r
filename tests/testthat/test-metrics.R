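test_that("confusion matrices tally (true, predicted) pairs", {
  cm <- confusion(c(1, 2), c(1, 2), k = 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 0L, 1L), 2, 2,
               dimnames = dimnames(cm)), ignore_attr = TRUE)
  cm2 <- confusion(c(1, 1, 2), c(2, 1, 2), k = 2)
  expect_equal(as.vector(unclass(cm2)), c(1L, 0L, 1L, 1L))
  expect_error(confusion(c(1, 5), c(1, 1), k = 4), "labels")
})

test_that("confusion matches a brute-force tally on random labelings", {
  set.seed(202)
  for (rep in 1:3) {
    k <- sample(3:6, 1)
    y <- sample(k, 1000, replace = TRUE)
    p <- sample(k, 1000, replace = TRUE)
    cm <- confusion(y, p, k = k)
    brute <- matrix(0L, k, k)
    for (i in seq_along(y)) brute[y[i], p[i]] <- brute[y[i], p[i]] + 1L
    expect_equal(unclass(cm), brute, ignore_attr = TRUE)
    # row sums are the class supports; diagonal sums to total tp
    expect_equal(rowSums(cm), as.numeric(table(factor(y, levels = 1:k))),
                 ignore_attr = TRUE)
    for (kk in 1:k) {
      pc <- per_class(cm, kk)
      expect_equal(pc$tp + pc$fp + pc$fn + pc$tn, 1000)
    }
  }
})

test_that("sensitivity percentages reproduce the worked count pairs", {
  # recall = tp / support, printed to one decimal with round-half-up
  cases <- list(c(254, 300, "84.7"), c(281, 300, "93.7"),
                c(233, 300, "77.7"), c(270, 300, "90"))
  for (cs in cases) {
    tp <- as.numeric(cs[1]); n <- as.numeric(cs[2])
    cm <- confusion(rep(c(1, 2), c(n, n)),
                    c(rep(1, tp), rep(2, n - tp), rep(2, n)), k = 2)
    expect_equal(per_class(cm, 1)$recall, tp / n)
    expect_equal(format_pct(per_class(cm, 1)$recall), cs[3])
  }
})

test_that("accuracy, F1 and macro F1 follow their formulas", {
  cm <- confusion(rep(1:3, each = 4), rep(1:3, each = 4), k = 3)
  expect_equal(accuracy(cm), 1)
  expect_equal(macro_f1(cm), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)    # harmonic mean of equal values
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_true(is.na(f1_score(0, 0)))
  # brute-force macro F1 on random 4x4 matrices
  set.seed(77)
  for (rep in 1:3) {
    y <- sample(4, 400, replace = TRUE)
    p <- sample(4, 400, replace = TRUE)
    cm <- confusion(y, p, k = 4)
    brute <- mean(vapply(1:4, function(k) {
      tp <- sum(y == k & p == k)
      prec <- tp / sum(p == k); rec <- tp / sum(y == k)
      2 * prec * rec / (prec + rec)
    }, numeric(1)), na.rm = TRUE)
    expect_equal(macro_f1(cm), brute)
    expect_equal(accuracy(cm), mean(y == p))
  }
})

test_that("zero denominators yield NA, never zero", {
  cm <- confusion(c(1, 1, 2), c(1, 1, 1), k = 3)
  expect_true(is.na(per_class(cm, 2)$precision))  # nothing predicted as 2
  expect_true(is.na(per_class(cm, 3)$recall))     # no true 3s
})

test_that("ROC endpoints, AUC extremes and tie handling are correct", {
  r <- roc_and_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0))
  # all-tied scores give the chance diagonal
  r2 <- roc_and_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r2$auc, 0.5)
  expect_error(roc_and_auc(1:3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("AUC equals the normalized Mann-Whitney U with tie correction", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 200
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    # coarse scores force ties
    scores <- round(rnorm(n, mean = as.numeric(labels)), 1)
    a <- roc_and_auc(scores, labels)$auc
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(a, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(100)
  labels <- runif(100) < plogis(scores)
  if (any(labels) && !all(labels)) {
    a0 <- roc_and_auc(scores, labels)$auc
    expect_equal(roc_and_auc(exp(scores), labels)$auc, a0)
    expect_equal(roc_and_auc(2 * scores - 7, labels)$auc, a0)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(150)
  labels <- runif(150) < plogis(2 * scores)
  a <- roc_and_auc(scores, labels)$auc
  b <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<")))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("one-vs-rest multiclass ROC yields one curve per class", {
  set.seed(3)
  probs <- matrix(runif(80), 20, 4)
  probs <- probs / rowSums(probs)
  labels <- sample(4, 20, replace = TRUE)
  if (length(unique(labels)) == 4) {
    rocs <- multiclass_roc(probs, labels)
    expect_length(rocs, 4)
    for (r in rocs) expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("percent formatting rounds half up to one decimal", {
  expect_equal(format_pct(254 / 300), "84.7")
  expect_equal(format_pct(0.92845), "92.8")  # 92.845 -> 92.8 (floor at 3rd dp)
  expect_equal(format_pct(0.92850), "92.9")  # exact half rounds up
  expect_equal(format_pct(0.9), "90")
  expect_equal(format_pct(1), "100")
})
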