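test_that("forward stepwise finds an exact linear predictor first", {
  set.seed(1)
  d <- data.frame(x = rnorm(60), n1 = rnorm(60), n2 = rnorm(60))
  d$y <- 2 * d$x + 1
  fit <- suppressWarnings(  # lm warns about the essentially perfect fit
    forward_stepwise(d, "y", c("n1", "x", "n2"), family = "linear"))
  expect_equal(fit$selected[1], "x")
  expect_equal(fit$diagnostics$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["x"]]), 2, tolerance = 1e-9)
})

test_that("pure-noise candidates leave essentially nothing explained", {
  set.seed(2)
  d <- data.frame(y = rnorm(500), a = rnorm(500), b = rnorm(500),
                  c = rnorm(500))
  fit <- forward_stepwise(d, "y", c("a", "b", "c"), family = "linear")
  expect_lte(length(fit$selected), 2)
  expect_lt(abs(fit$diagnostics$adjusted_r2), 0.03)
})

test_that("stepwise selection is deterministic given candidate order", {
  set.seed(3)
  d <- data.frame(y = rnorm(80))
  d$x1 <- d$y + rnorm(80, sd = 0.8)
  d$x2 <- d$y + rnorm(80, sd = 0.8)
  f1 <- forward_stepwise(d, "y", c("x1", "x2"), family = "linear")
  f2 <- forward_stepwise(d, "y", c("x1", "x2"), family = "linear")
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$coefficients, f2$coefficients)
})

test_that("adding predictors never lowers raw R2 though adjusted R2 may drop", {
  set.seed(4)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40),
                  x3 = rnorm(40))
  r2 <- vapply(1:3, function(k) {
    summary(lm(reformulate(paste0("x", 1:k), "y"), d))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  adj <- vapply(1:3, function(k) {
    summary(lm(reformulate(paste0("x", 1:k), "y"), d))$adj.r.squared
  }, numeric(1))
  expect_true(any(diff(adj) < 0))  # noise terms are penalized
})

test_that("degenerate designs are rejected", {
  d <- data.frame(y = rep(1, 20), x = rnorm(20))
  expect_error(forward_stepwise(d, "y", "x", family = "linear"),
               class = "rehabElo_input_error")
  expect_error(forward_stepwise(d, "y", character(0), family = "linear"),
               class = "rehabElo_input_error")
  expect_error(forward_stepwise(d, "y", "missing_col", family = "linear"),
               class = "rehabElo_input_error")
})

test_that("VIF is 1 for orthogonal designs and follows the two-predictor closed form", {
  # exactly orthogonal, mean-zero columns via QR of a centred matrix
  set.seed(5)
  q <- qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE)))
  vt <- vif_tolerance(as.data.frame(q))
  expect_equal(vt$vif, rep(1, 3), tolerance = 1e-9)
  expect_equal(vt$tolerance, 1 / vt$vif)
  # construct correlation exactly 0.6: vif = 1/(1-0.36) = 1.5625
  x1 <- as.numeric(scale(rnorm(50)))
  e <- residuals(lm(rnorm(50) ~ x1))
  e <- as.numeric(scale(e))
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * e
  vt2 <- vif_tolerance(data.frame(x1, x2))
  expect_equal(vt2$vif, rep(1.5625, 2), tolerance = 1e-9)
  # duplicated predictor: infinite VIF, zero tolerance
  vt3 <- suppressWarnings(vif_tolerance(data.frame(a = x1, b = x1)))
  expect_true(all(is.infinite(vt3$vif)))
  expect_equal(vt3$tolerance, c(0, 0))
})

test_that("Durbin-Watson matches hand arithmetic and is near 2 for white noise", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(rep(2, 10)), 0)
  set.seed(6)
  expect_equal(durbin_watson(rnorm(10000)), 2, tolerance = 0.05 / 2)
})

test_that("classification metrics are exact on separable cases and ~0.5 under independence", {
  m <- classification_metrics(c(0.9, 0.8, 0.4, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  set.seed(7)
  scores <- runif(4000); labels <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  m2 <- classification_metrics(scores, labels)
  expect_equal(m2$auc, 0.5, tolerance = 0.05)
  expect_true(m2$auc_ci[1] < 0.5 && m2$auc_ci[2] > 0.5)
  # AUC invariant under strictly monotone transforms of the scores
  m3 <- classification_metrics(qlogis(scores), labels)
  expect_equal(m3$auc, m2$auc)
  expect_error(classification_metrics(scores, rep(TRUE, 4000)),
               class = "rehabElo_input_error")
})

test_that("AUC and its CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(200)
  labels <- runif(200) < scores  # informative scores
  ours <- classification_metrics(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$auc_ci, ref_ci[c(1, 3)], tolerance = 1e-6)
})

test_that("Durbin-Watson agrees with the lmtest statistic on a fitted model", {
  skip_if_not_installed("lmtest")
  set.seed(9)
  d <- data.frame(x = rnorm(100)); d$y <- d$x + rnorm(100)
  m <- lm(y ~ x, d)
  expect_equal(durbin_watson(residuals(m)),
               as.numeric(lmtest::dwtest(m)$statistic), tolerance = 1e-9)
})

test_that("logistic stepwise reports AUC, confusion metrics and tolerances", {
  set.seed(10)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- as.numeric(runif(n) < plogis(1.5 * d$x))
  fit <- forward_stepwise(d, "y", c("x", "z"), family = "logistic")
  expect_equal(fit$selected[1], "x")
  expect_gt(fit$diagnostics$auc, 0.7)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in%
                    names(fit$diagnostics)))
  expect_true(all(fit$diagnostics$tolerance > 0 &
                    fit$diagnostics$tolerance <= 1))
  expect_output(summary(fit), "AUC")
})

test_that("ablation delta is zero for identical fits and positive for a real effect", {
  set.seed(11)
  n <- 250
  d <- data.frame(rating = rnorm(n), age = rnorm(n))
  d$y <- 0.8 * d$rating + 0.3 * d$age + rnorm(n)
  with_r <- forward_stepwise(d, "y", c("rating", "age"), family = "linear")
  without_r <- forward_stepwise(d, "y", "age", family = "linear")
  expect_equal(ablation_compare(with_r, with_r)$delta, 0)
  expect_gt(ablation_compare(with_r, without_r)$delta, 0)
  # permuted rating carries no information: delta ~ 0
  d$rating_perm <- sample(d$rating)
  with_p <- forward_stepwise(d, "y", c("rating_perm", "age"), family = "linear")
  expect_lt(abs(ablation_compare(with_p, without_r)$delta), 0.02)
})

test_that("cross-validated criterion is available for internal validation", {
  set.seed(12)
  d <- data.frame(x = rnorm(120), junk = rnorm(120))
  d$y <- d$x + rnorm(120)
  fit <- forward_stepwise(d, "y", c("x", "junk"), family = "linear",
                          cv_folds = 5)
  expect_true("x" %in% fit$selected)
  expect_false("junk" %in% fit$selected)
})
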