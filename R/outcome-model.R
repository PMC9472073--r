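# The substitution-outcome model: ridge-penalized logistic regression of
# success/failure on the 21 feature columns, probability prediction, cutoff
# optimization by maximum sensitivity + specificity, ROC/AUC; plus the
# log(E + 1) generalized linear model for incorporation efficiency.

clampProb <- function(p) pmin(1 - 1e-15, pmax(1e-15, p))

#' Fit the substitution-outcome logistic model
#'
#' Maximum penalized likelihood fit of
#' `log(P / (1 - P)) = b + sum_i k_i V_i` by iteratively reweighted least
#' squares (Newton's method).  A ridge penalty `lambda/2 * ||k||^2` on the
#' coefficients (never the intercept) stabilizes the fit; the default
#' strength 1.0 on unstandardized features mirrors common machine-learning
#' toolchain defaults.  The optimal probability cutoff on the training
#' predictions and the training metrics are stored in the fit.
#'
#' @param fm a [FeatureMatrix-class] containing both outcome classes and at
#'   least 25 rows.
#' @param lambda ridge penalty strength (>= 0).
#' @param standardize center and scale columns before fitting (parameters
#'   are stored and re-applied at prediction time).
#' @param maxIter,tol Newton iteration controls.
#' @return an [OutcomeModelFit-class].
#' @export
fitOutcomeModel <- function(fm, lambda = 1.0, standardize = FALSE,
                            maxIter = 100, tol = 1e-10) {
  X <- fm@X; y <- as.numeric(fm@y)
  n <- nrow(X)
  if (length(unique(fm@y)) < 2)
    stopf("both outcome classes are required to fit the model")
  if (n < 25) stopf("at least 25 records are required (got %d)", n)
  ctr <- scl <- numeric(0)
  if (standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  Z <- cbind(`(Intercept)` = 1, X)
  p1 <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p1 - 1)))
  beta <- numeric(p1)
  beta[1] <- stats::qlogis(clampProb(mean(y)))
  devOld <- Inf
  converged <- FALSE
  penDev <- function(b) {
    mu <- clampProb(stats::plogis(drop(Z %*% b)))
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) + drop(t(b) %*% pen %*% b)
  }
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% beta)
    mu <- clampProb(stats::plogis(eta))
    w <- mu * (1 - mu)
    grad <- drop(crossprod(Z, y - mu)) - pen %*% beta
    H <- crossprod(Z * w, Z) + pen
    step <- tryCatch(drop(solve(H, grad)), error = function(e)
      stopf("singular system in the logistic fit: %s", conditionMessage(e)))
    # Newton step with backtracking on the penalized deviance
    fac <- 1
    repeat {
      cand <- beta + fac * step
      dev <- penDev(cand)
      if (dev <= devOld + 1e-8 || fac < 1e-6) break
      fac <- fac / 2
    }
    beta <- cand
    if (is.finite(devOld) && abs(devOld - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE; break
    }
    devOld <- dev
  }
  if (!converged && maxIter > 1)
    stopf("logistic fit did not converge in %d iterations (last deviance change %.3g)",
          maxIter, abs(devOld - dev))
  eta <- drop(Z %*% beta)
  mu <- clampProb(stats::plogis(eta))
  H <- crossprod(Z * (mu * (1 - mu)), Z) + pen
  se <- sqrt(diag(solve(H)))
  k <- beta[-1]; names(k) <- colnames(X)
  fit <- methods::new("OutcomeModelFit", intercept = unname(beta[1]),
                      coef = k, se = unname(se), center = ctr, scale = scl,
                      cutoff = 0.5, metrics = list(),
                      provenance = list(n = n, lambda = lambda,
                                        standardize = standardize,
                                        iterations = it),
                      columnsVersion = fm@columnsVersion)
  p <- predictProbability(fit, fm)
  co <- optimalCutoff(fm@y, p)
  fit@cutoff <- co$cutoff
  fit@metrics <- list(accuracy = co$accuracy, sensitivity = co$sensitivity,
                      specificity = co$specificity, auc = rocAuc(fm@y, p)$auc)
  fit
}

setMethod("show", "OutcomeModelFit", function(object) {
  m <- object@metrics
  cat(sprintf(paste0("OutcomeModelFit: n=%s, lambda=%s, cutoff=%.3f, ",
                     "training accuracy=%.3f, AUC=%.3f\n"),
              object@provenance$n %||% "?", object@provenance$lambda %||% "?",
              object@cutoff, m$accuracy %||% NA, m$auc %||% NA))
})

# resolve a FeatureMatrix / matrix / single row to a conformable matrix
asFeatureInput <- function(rows, columnsVersion) {
  if (methods::is(rows, "FeatureMatrix")) {
    if (!identical(rows@columnsVersion, columnsVersion))
      stopf("feature-encoding version mismatch: fit has %s, data has %s",
            columnsVersion, rows@columnsVersion)
    return(rows@X)
  }
  if (is.null(dim(rows))) rows <- matrix(rows, 1,
                                         dimnames = list(NULL, names(rows)))
  if (!identical(colnames(rows), featureColumns()))
    stopf("feature columns do not match the fit's column order")
  rows
}

#' Predict substitution success probabilities
#'
#' `P = 1 / (1 + exp(-(b + sum_i k_i V_i)))`, applying the fit's stored
#' standardization when present.  Results are strictly inside (0, 1).
#'
#' @param fit an [OutcomeModelFit-class].
#' @param rows a [FeatureMatrix-class], numeric matrix, or single named row.
#' @return numeric probability vector.
#' @export
predictProbability <- function(fit, rows) {
  X <- asFeatureInput(rows, fit@columnsVersion)
  if (length(fit@center))
    X <- sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
  clampProb(stats::plogis(fit@intercept + drop(X %*% fit@coef)))
}

#' Optimal probability cutoff by maximum sensitivity + specificity
#'
#' Scans the candidate thresholds (midpoints between adjacent distinct
#' sorted probabilities, plus 0 and 1) and returns the one maximizing
#' sensitivity + specificity; ties resolve to the smallest threshold.  The
#' decision rule is success iff `p >= cutoff`.
#'
#' @param y 0/1 labels (both classes required).
#' @param p predicted probabilities in \[0, 1\].
#' @return list with `cutoff`, `accuracy`, `sensitivity`, `specificity`.
#' @export
optimalCutoff <- function(y, p) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes are required")
  u <- sort(unique(p))
  cand <- sort(unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # vectorized confusion counts per candidate via cumulative class counts
  sens <- vapply(cand, function(t) sum(p >= t & y == 1L) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(p < t & y == 0L) / n0, numeric(1))
  j <- sens + spec
  best <- which(j == max(j))[1]
  t <- cand[best]
  list(cutoff = t,
       accuracy = (sum(p >= t & y == 1L) + sum(p < t & y == 0L)) / length(y),
       sensitivity = sens[best], specificity = spec[best])
}

#' ROC curve and area under it
#'
#' Threshold-sweep ROC with trapezoid AUC; tied probabilities contribute
#' half, so the AUC equals the probability that a random success outranks a
#' random failure (the Mann-Whitney statistic scaled by n1*n0).
#'
#' @param y 0/1 labels (both classes required).
#' @param p predicted probabilities.
#' @return list with `curve` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
rocAuc <- function(y, p) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("both classes are required")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(p >= t & y == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(p >= t & y == 0L) / n0, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Fit the incorporation-efficiency model
#'
#' Ridge-penalized least squares of `log(E + 1)` on the 21 feature columns,
#' using only rows that carry an efficiency value.  E is the expression of
#' the UAA-bearing protein relative to wild-type (>= 0).
#'
#' @param fm a [FeatureMatrix-class] whose `efficiency` slot is populated
#'   for the training rows (NA rows are dropped).
#' @param lambda ridge penalty strength.
#' @param standardize center/scale columns before fitting.
#' @return an [EfficiencyModelFit-class].
#' @export
fitEfficiencyModel <- function(fm, lambda = 1.0, standardize = FALSE) {
  keep <- which(!is.na(fm@efficiency))
  E <- fm@efficiency[keep]
  if (any(E < 0)) stopf("negative efficiency value(s)")
  n <- length(keep)
  if (n < 25) stopf("at least 25 efficiency records are required (got %d)", n)
  X <- fm@X[keep, , drop = FALSE]
  yt <- log(E + 1)
  ctr <- scl <- numeric(0)
  if (standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  Z <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, ncol(X))))
  beta <- drop(solve(crossprod(Z) + pen, crossprod(Z, yt)))
  resid <- yt - drop(Z %*% beta)
  k <- beta[-1]; names(k) <- colnames(X)
  methods::new("EfficiencyModelFit", intercept = unname(beta[1]), coef = k,
               residualScale = stats::sd(resid), center = ctr, scale = scl,
               provenance = list(n = n, lambda = lambda,
                                 standardize = standardize),
               columnsVersion = fm@columnsVersion)
}

#' Predict incorporation efficiencies
#'
#' `E = max(0, exp(b + sum_i k_i V_i) - 1)` on the fit's scale.
#'
#' @param fit an [EfficiencyModelFit-class].
#' @param rows a [FeatureMatrix-class], matrix, or single named row.
#' @return non-negative predicted efficiencies.
#' @export
predictEfficiency <- function(fit, rows) {
  X <- asFeatureInput(rows, fit@columnsVersion)
  if (length(fit@center))
    X <- sweep(sweep(X, 2, fit@center), 2, fit@scale, "/")
  pmax(0, exp(fit@intercept + drop(X %*% fit@coef)) - 1)
}

setMethod("show", "EfficiencyModelFit", function(object) {
  cat(sprintf("EfficiencyModelFit: n=%s, lambda=%s, residual scale %.4f\n",
              object@provenance$n %||% "?", object@provenance$lambda %||% "?",
              object@residualScale))
})

#' Serialize / restore a fitted outcome model as JSON
#'
#' Round-trip safe; stores the feature-encoding version, intercept,
#' coefficients, standardization parameters, cutoff, metrics and provenance.
#'
#' @param fit an [OutcomeModelFit-class].
#' @param path JSON file path.
#' @return `path` (write) or an [OutcomeModelFit-class] (read).
#' @export
writeModelJSON <- function(fit, path) {
  jsonlite::write_json(list(
    columns_version = fit@columnsVersion, columns = featureColumns(),
    intercept = fit@intercept, coef = as.list(fit@coef), se = fit@se,
    center = fit@center, scale = fit@scale, cutoff = fit@cutoff,
    metrics = fit@metrics, provenance = fit@provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(unlist(j$columns), featureColumns()))
    stopf("model file %s uses an incompatible feature-column order", path)
  ctr <- as.numeric(j$center); scl <- as.numeric(j$scale)
  if (length(ctr)) names(ctr) <- featureColumns()
  if (length(scl)) names(scl) <- featureColumns()
  methods::new("OutcomeModelFit", intercept = j$intercept,
               coef = unlist(j$coef)[featureColumns()],
               se = as.numeric(j$se),
               center = ctr, scale = scl,
               cutoff = j$cutoff, metrics = as.list(j$metrics),
               provenance = as.list(j$provenance),
               columnsVersion = j$columns_version)
}
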