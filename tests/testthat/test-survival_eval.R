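test_that("confusion metrics match hand arithmetic and flag degeneracies", {
  # counts tp=3 fp=1 tn=4 fn=2
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- confusionMetrics(pred, truth)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 4, 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  # perfect prediction
  p2 <- confusionMetrics(truth, truth)
  expect_equal(c(p2$accuracy, p2$precision, p2$recall, p2$specificity, p2$f1),
               rep(1, 5))
  # all-negative predictions: recall 0, precision flagged undefined
  p3 <- confusionMetrics(rep(0, 10), truth)
  expect_equal(p3$recall, 0)
  expect_true(is.nan(p3$precision))
  expect_true("precision" %in% p3$undefined)
  expect_error(confusionMetrics(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("ROC/AUC equals the concordance oracle and is monotone-invariant", {
  oracle_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)   # ties included
    r <- rocAuc(s, y)
    expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(rocAuc(exp(3 * s), y)$auc, r$auc, tolerance = 1e-12)
  }
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  set.seed(32)
  y <- rbinom(1000, 1, 0.5); s <- runif(1000)
  expect_lt(abs(rocAuc(s, y)$auc - 0.5), 0.06)
  expect_error(rocAuc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC/AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  y <- rbinom(80, 1, 0.4); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  s <- rnorm(80)
  expect_equal(rocAuc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))),
               tolerance = 1e-10)
})

test_that("K-M estimator matches hand-computed product-limit values", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))
  # worked 6-record case with censoring: times 1,2+,3,4+,5,6
  km2 <- kmEstimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
  # steps at 1,3,5,6: S = 5/6, 5/6*3/4, 5/6*3/4*1/2, 0
  expect_equal(km2$time, c(1, 3, 5, 6))
  expect_equal(km2$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0),
               tolerance = 1e-12)
  # all censored: survival stays 1 (no steps)
  km3 <- kmEstimate(c(2, 4, 6), c(0, 0, 0))
  expect_length(km3$time, 0L)
  expect_true(all(km3$fit$surv == 1))
  # no censoring: equals the empirical survival fraction
  set.seed(9)
  tt <- sample(1:20, 12, TRUE)
  km4 <- kmEstimate(tt, rep(1, 12))
  for (i in seq_along(km4$time))
    expect_equal(km4$surv[i], mean(tt > km4$time[i]))
  # monotone non-increasing within [0, 1]
  expect_true(all(diff(km4$surv) <= 0))
  expect_true(all(km4$surv >= 0 & km4$surv <= 1))
})

test_that("log-rank test: null identity, extreme separation, and oracle", {
  t0 <- c(1, 2, 3, 4, 5)
  lr0 <- logrankTest(t0, rep(1, 5), t0, rep(1, 5))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  lr1 <- logrankTest(rep(1, 10), rep(1, 10), rep(10, 10), rep(0, 10))
  expect_gt(lr1$chi_square, 6.63)   # p < 0.01
  expect_lt(lr1$p_value, 0.01)
  # symmetry in group order
  set.seed(21)
  ta <- rexp(20, 0.1); ea <- rbinom(20, 1, 0.8)
  tb <- rexp(25, 0.2); eb <- rbinom(25, 1, 0.8)
  expect_equal(logrankTest(ta, ea, tb, eb)$chi_square,
               logrankTest(tb, eb, ta, ea)$chi_square, tolerance = 1e-10)
  # independently coded observed-minus-expected accumulation
  oracle_logrank <- function(ta, ea, tb, eb) {
    tall <- c(ta, tb); eall <- c(ea, eb)
    grp <- rep(c(0, 1), c(length(ta), length(tb)))
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(tall[eall == 1]))) {
      at <- tall >= t
      n <- sum(at); n1 <- sum(at & grp == 1)
      d <- sum(tall == t & eall == 1)
      d1 <- sum(tall == t & eall == 1 & grp == 1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  expect_equal(logrankTest(ta, ea, tb, eb)$chi_square,
               oracle_logrank(ta, ea, tb, eb), tolerance = 1e-8)
  # degenerate: no events at all
  lrd <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(lrd$degenerate)
})
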