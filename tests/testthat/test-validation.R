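# Validation battery: repeated holdout/balanced, timesplit, PCA,
# Mann-Whitney.

test_that("repeated validation is deterministic and seed-order invariant", {
  fm <- randomFeatureMatrix(250, seed = 30, b = 1,
                            k = c(0.8, 1.2, rep(0, 19)))
  r1 <- runRepeatedValidation(fm, "holdout", seeds = 0:9)
  r2 <- runRepeatedValidation(fm, "holdout", seeds = 0:9)
  expect_identical(r1@rounds, r2@rounds)
  r3 <- runRepeatedValidation(fm, "holdout", seeds = 9:0)
  expect_equal(r1@aggregate, r3@aggregate, tolerance = 1e-12)
  expect_identical(nrow(r1@rounds), 10L)
})

test_that("balanced rounds have equal class counts each time", {
  fm <- randomFeatureMatrix(300, seed = 31, b = 1.6)
  for (s in 0:4) {
    idx <- uaaScreen:::balancedIndices(fm@y, s)
    expect_identical(sum(fm@y[idx] == 1), sum(fm@y[idx] == 0))
  }
  rep <- runRepeatedValidation(fm, "balanced", seeds = 0:4)
  expect_identical(nrow(rep@rounds), 5L)
})

test_that("separable data yields mean AUC 1 with zero spread", {
  X <- matrix(0, 200, 21, dimnames = list(NULL, featureColumns()))
  X[, "entropy"] <- withSeed(32, stats::runif(200, 0, 3))
  fm <- methods::new("FeatureMatrix", X = X,
                     y = as.integer(X[, "entropy"] > 1.5),
                     recordId = sprintf("r%03d", 1:200),
                     dates = as.Date(rep("2015-06-01", 200)),
                     efficiency = rep(NA_real_, 200),
                     columnsVersion = featureColumnsVersion())
  rep <- runRepeatedValidation(fm, "holdout", seeds = 0:9)
  expect_equal(unname(rep@aggregate$auc["mean"]), 1.0)
  expect_equal(unname(rep@aggregate$auc["sd"]), 0.0)
})

test_that("timesplit on a stationary process keeps train and test AUC close", {
  sim <- cached("dbTimesplit", function() {
    w <- fixtureWorld()
    simulateDatabase(w$profiles, w$chem, n = 4000, seed = 33,
                     prevalence = 0.75)
  })
  fm <- sim$features
  rep <- runTimesplitValidation(fm, "2012-01-01")
  expect_lt(abs(rep@rounds$auc - rep@details$trainAuc), 0.05)
  expect_identical(rep@rounds$nTrain + rep@rounds$nTest, 4000L)
  expect_error(runTimesplitValidation(fm, "2050-01-01"), "empty partition")
})

test_that("PCA summary matches an eigendecomposition oracle", {
  X <- withSeed(34, matrix(stats::rnorm(50 * 21), 50, 21,
                           dimnames = list(NULL, featureColumns())))
  ps <- pcaSummary(X)
  expect_gte(ps$evr1, ps$evr2)
  expect_lte(ps$evr1 + ps$evr2, 1)
  # oracle: eigenvectors of the correlation matrix
  ev <- eigen(stats::cor(X))
  evr <- ev$values / sum(ev$values)
  expect_equal(ps$evr1, evr[1], tolerance = 1e-10)
  expect_equal(ps$evr2, evr[2], tolerance = 1e-10)
  sc <- scale(X) %*% ev$vectors[, 1:2]
  for (j in 1:2)
    expect_equal(abs(stats::cor(ps$scores[, j], sc[, j])), 1,
                 tolerance = 1e-8)
  # component scores are uncorrelated
  expect_lt(abs(stats::cov(ps$scores[, 1], ps$scores[, 2])), 1e-8)
  # rank-1 data concentrates all variance on component 1
  v <- withSeed(35, stats::rnorm(50))
  X1 <- outer(v, c(1, -2, 0.5))
  colnames(X1) <- c("a", "b", "c")
  ps1 <- pcaSummary(X1)
  expect_equal(ps1$evr1, 1, tolerance = 1e-12)
  expect_equal(ps1$evr2, 0, tolerance = 1e-12)
  suppressWarnings(
    expect_error(pcaSummary(matrix(1, 10, 3)), "constant|non-constant"))
})

test_that("Mann-Whitney matches exact enumeration and rank identities", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$twoSidedP, 0.1, tolerance = 1e-12)
  expect_equal(mw$U, 0)
  # same multiset: no shift, p near 1
  mwSame <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(mwSame$twoSidedP, 0.99)
  # U1 + U2 = n1 * n2 for arbitrary inputs
  withSeed(36, {
    for (i in 1:10) {
      a <- stats::runif(sample(3:12, 1)); b <- stats::runif(sample(3:12, 1))
      u1 <- mannWhitneyU(a, b)$U
      u2 <- mannWhitneyU(b, a)$U
      expect_equal(u1 + u2, length(a) * length(b))
    }
  })
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("probability quartiles and report serialization work", {
  y <- rep(c(1, 0), each = 20)
  p <- c(seq(0.5, 0.9, length.out = 20), seq(0.1, 0.5, length.out = 20))
  q <- probabilityQuartiles(y, p)
  expect_equal(unname(q$success[2]), stats::median(p[y == 1]))
  fm <- randomFeatureMatrix(150, seed = 37, b = 0.8,
                            k = c(1, 0.5, rep(0, 19)))
  rep <- runRepeatedValidation(fm, "holdout", seeds = 0:3)
  d <- tempfile()
  writeValidationReport(rep, d)
  expect_true(file.exists(file.path(d, "holdout_summary.json")))
  rounds <- utils::read.csv(file.path(d, "holdout_rounds.csv"))
  expect_equal(rounds$auc, rep@rounds$auc, tolerance = 1e-12)
})
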