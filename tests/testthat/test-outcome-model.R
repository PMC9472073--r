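# Logistic outcome model, cutoff optimizer, ROC, efficiency model.

test_that("predicted probabilities follow the closed form exactly", {
  fm <- randomFeatureMatrix(60, seed = 20, b = 0.4)
  fit <- suppressWarnings(fitOutcomeModel(fm))
  # hand-computed linear predictor agrees to 1e-12
  p <- predictProbability(fit, fm)
  pHand <- 1 / (1 + exp(-(fit@intercept + fm@X %*% fit@coef)))
  expect_equal(p, drop(pHand), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  # all-zero feature row reduces to sigmoid(b)
  zero <- stats::setNames(rep(0, 21), featureColumns())
  expect_equal(predictProbability(fit, zero),
               stats::plogis(fit@intercept), tolerance = 1e-12)
  # column-version mismatch is refused
  fmBad <- fm; fmBad@columnsVersion <- "other/0"
  expect_error(predictProbability(fit, fmBad), "version mismatch")
})

test_that("degenerate label sets are class errors", {
  fm <- randomFeatureMatrix(40, seed = 21)
  fm@y <- rep(0L, 40)
  expect_error(fitOutcomeModel(fm), "both outcome classes")
  expect_error(optimalCutoff(rep(1, 5), runif(5)), "both classes")
  expect_error(rocAuc(rep(0, 5), runif(5)), "both classes")
})

test_that("a separable training set reaches AUC 1 under the penalty", {
  # single informative feature, perfectly separated labels
  X <- matrix(0, 60, 21, dimnames = list(NULL, featureColumns()))
  X[, "rasa"] <- withSeed(22, stats::runif(60))
  fm <- methods::new("FeatureMatrix", X = X,
                     y = as.integer(X[, "rasa"] > 0.5),
                     recordId = sprintf("r%02d", 1:60),
                     dates = as.Date(rep("2015-06-01", 60)),
                     efficiency = rep(NA_real_, 60),
                     columnsVersion = featureColumnsVersion())
  fit <- suppressWarnings(fitOutcomeModel(fm, lambda = 1.0))
  expect_equal(fit@metrics$auc, 1.0)
})

test_that("coefficients recover the generative truth within 3 SE", {
  sim <- fixtureDbLarge()
  fit <- suppressWarnings(fitOutcomeModel(sim$features, lambda = 1e-6))
  truth <- c(sim$model$b, sim$model$k)
  est <- c(fit@intercept, fit@coef)
  z <- abs(est - truth) / fit@se
  expect_lt(max(z), 3)
})

test_that("the fit agrees with an unpenalized glm oracle at tiny lambda", {
  fm <- randomFeatureMatrix(400, seed = 23, b = 0.5,
                            k = c(0.5, 1, rep(0, 19)))
  fit <- suppressWarnings(fitOutcomeModel(fm, lambda = 1e-8))
  oracle <- stats::glm.fit(cbind(1, fm@X), fm@y,
                           family = stats::binomial())
  expect_equal(c(fit@intercept, unname(fit@coef)),
               unname(oracle$coefficients), tolerance = 1e-5)
})

test_that("ridge shrinkage matches the glmnet oracle", {
  skip_if_not_installed("glmnet")
  fm <- randomFeatureMatrix(300, seed = 24, b = 0.3,
                            k = c(0.4, 0.8, rep(0, 19)))
  lambda <- 5
  fit <- suppressWarnings(fitOutcomeModel(fm, lambda = lambda))
  g <- glmnet::glmnet(fm@X, fm@y, family = "binomial", alpha = 0,
                      lambda = lambda / nrow(fm@X), standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit@coef), as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(fit@intercept, unname(g$a0), tolerance = 1e-3)
})

test_that("the cutoff optimizer matches brute-force scans", {
  # hand examples
  co <- optimalCutoff(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(co$sensitivity, 1); expect_equal(co$specificity, 1)
  co2 <- optimalCutoff(c(1, 0), c(0.5, 0.5))
  expect_equal(co2$cutoff, 0)    # smallest candidate under total ties
  expect_equal(co2$sensitivity + co2$specificity, 1)
  # random instances: achieved objective equals exhaustive enumeration and
  # is never beaten by a dense 10,001-point grid
  withSeed(25, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      y <- c(0, 1, stats::rbinom(n, 1, 0.5))
      p <- round(stats::runif(n + 2), sample(c(1, 2, 6), 1))
      co <- optimalCutoff(y, p)
      j <- co$sensitivity + co$specificity
      expect_equal(j, oracleCutoffEnumeration(y, p), tolerance = 1e-12)
      expect_gte(j + 1e-12, oracleCutoffGrid(y, p, 1001))
      # reported metrics are consistent with the p >= cutoff rule
      expect_equal(co$accuracy,
                   mean((p >= co$cutoff) == (y == 1)), tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the exhaustive pairwise oracle and handles ties", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  withSeed(26, {
    for (i in 1:50) {
      y <- c(0, 1, stats::rbinom(48, 1, 0.4))
      p <- round(stats::runif(50), sample(c(1, 3, 8), 1))
      a <- rocAuc(y, p)$auc
      expect_equal(a, oracleAucPairwise(y, p), tolerance = 1e-12)
      # invariance under strictly monotone transforms
      expect_equal(rocAuc(y, p^2)$auc, a, tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with the pROC oracle", {
  skip_if_not_installed("pROC")
  withSeed(27, {
    y <- c(0, 1, stats::rbinom(80, 1, 0.6))
    p <- stats::runif(82)
    a <- rocAuc(y, p)$auc
    o <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
    expect_equal(a, o, tolerance = 1e-12)
  })
})

test_that("the efficiency model transforms, recovers and clamps", {
  fmE <- randomFeatureMatrix(600, seed = 28, efficiency = TRUE,
                             k = c(0.5, 1, rep(0, 19)), sdLog = 0.05)
  fit <- fitEfficiencyModel(fmE, lambda = 1e-8)
  pred <- predictEfficiency(fit, fmE)
  expect_true(all(pred >= 0))
  expect_gt(stats::cor(pred, fmE@efficiency), 0.9)
  # hand evaluation of the inverse transform
  zero <- stats::setNames(rep(0, 21), featureColumns())
  expect_equal(predictEfficiency(fit, zero),
               max(0, exp(fit@intercept) - 1), tolerance = 1e-12)
  # linear predictor below 0 clamps to 0
  fit2 <- fit; fit2@intercept <- -1; fit2@coef[] <- 0
  expect_equal(predictEfficiency(fit2, zero), 0)
  # E = 0 maps to transformed target log(1) = 0 (fit passes through)
  fm0 <- fmE; fm0@efficiency[] <- 0
  fit0 <- fitEfficiencyModel(fm0, lambda = 1e-8)
  expect_equal(unname(c(fit0@intercept, fit0@coef)), rep(0, 22),
               tolerance = 1e-8)
  fmNeg <- fmE; fmNeg@efficiency[1] <- -0.1
  expect_error(fitEfficiencyModel(fmNeg), "negative")
  fmFew <- featureRows(fmE, 1:10)
  expect_error(fitEfficiencyModel(fmFew), "at least 25")
})

test_that("model JSON serialization round-trips", {
  fm <- randomFeatureMatrix(80, seed = 29, b = 1)
  fit <- suppressWarnings(fitOutcomeModel(fm, standardize = TRUE))
  f <- tempfile(fileext = ".json")
  writeModelJSON(fit, f)
  fit2 <- readModelJSON(f)
  expect_equal(fit2@intercept, fit@intercept, tolerance = 1e-12)
  expect_equal(fit2@coef, fit@coef, tolerance = 1e-12)
  expect_equal(fit2@center, fit@center, tolerance = 1e-12)
  expect_equal(fit2@cutoff, fit@cutoff, tolerance = 1e-12)
  p1 <- predictProbability(fit, fm)
  p2 <- predictProbability(fit2, fm)
  expect_equal(p1, p2, tolerance = 1e-12)
})
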