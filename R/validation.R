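# The validation battery: repeated holdout, repeated balanced-subset
# evaluation, timesplit validation, PCA summary, Mann-Whitney comparison
# of predicted probabilities, and report serialization.

#' Repeated holdout / balanced-subset validation
#'
#' Holdout mode: per seed, split the rows 80/20 (round half up on the
#' training size), fit on the training rows and evaluate optimal cutoff,
#' accuracy and AUC on the test rows.  Balanced mode: per seed, build a
#' balanced subset (all minority-class rows plus an equal-size sample of
#' the majority class), fit on it and evaluate on the same subset
#' (in-sample, the reporting convention for balanced panels); an
#' out-of-sample variant is available via `outOfSample = TRUE`, which
#' holds out 20 percent of the balanced subset.  Rounds whose test panel
#' contains a single class are skipped and logged.
#'
#' @param fm a [FeatureMatrix-class].
#' @param mode "holdout" or "balanced".
#' @param seeds integer seeds, one round each (default 0:99).
#' @param trainFraction holdout training fraction.
#' @param cutoffFrom evaluate accuracy at the cutoff recomputed on the
#'   test panel ("test", the reporting default) or frozen from the
#'   training fit ("train").
#' @param outOfSample balanced mode only: hold out part of each subset.
#' @param lambda,standardize model configuration (see [fitOutcomeModel()]).
#' @return a [ValidationReport-class].
#' @export
runRepeatedValidation <- function(fm, mode = c("holdout", "balanced"),
                                  seeds = 0:99, trainFraction = 0.8,
                                  cutoffFrom = c("test", "train"),
                                  outOfSample = FALSE,
                                  lambda = 1.0, standardize = FALSE) {
  mode <- match.arg(mode)
  cutoffFrom <- match.arg(cutoffFrom)
  rounds <- vector("list", length(seeds))
  skipped <- integer(0)
  for (s in seq_along(seeds)) {
    seed <- seeds[s]
    if (mode == "holdout") {
      idx <- holdoutIndices(nrow(fm@X), trainFraction, seed)
      trainIdx <- idx$train; testIdx <- idx$test
    } else {
      bal <- balancedIndices(fm@y, seed)
      if (outOfSample) {
        idx <- holdoutIndices(length(bal), trainFraction, seed)
        trainIdx <- bal[idx$train]; testIdx <- bal[idx$test]
      } else trainIdx <- testIdx <- bal
    }
    if (length(unique(fm@y[trainIdx])) < 2 ||
        length(unique(fm@y[testIdx])) < 2) {
      skipped <- c(skipped, seed); next
    }
    fit <- fitOutcomeModel(featureRows(fm, trainIdx), lambda = lambda,
                           standardize = standardize)
    p <- predictProbability(fit, featureRows(fm, testIdx))
    yT <- fm@y[testIdx]
    co <- if (cutoffFrom == "test") optimalCutoff(yT, p) else {
      t <- fit@cutoff
      list(cutoff = t,
           accuracy = (sum(p >= t & yT == 1L) + sum(p < t & yT == 0L)) /
             length(yT))
    }
    rounds[[s]] <- data.frame(seed = seed, cutoff = co$cutoff,
                              accuracy = co$accuracy,
                              auc = rocAuc(yT, p)$auc)
  }
  rounds <- do.call(rbind, rounds)
  if (is.null(rounds) || nrow(rounds) == 0)
    stopf("no valid validation rounds")
  agg <- list(cutoff = c(mean = mean(rounds$cutoff), sd = stats::sd(rounds$cutoff)),
              accuracy = c(mean = mean(rounds$accuracy), sd = stats::sd(rounds$accuracy)),
              auc = c(mean = mean(rounds$auc), sd = stats::sd(rounds$auc)))
  methods::new("ValidationReport", mode = mode, rounds = rounds,
               aggregate = agg,
               details = list(skippedSeeds = skipped,
                              validRounds = nrow(rounds),
                              config = list(trainFraction = trainFraction,
                                            cutoffFrom = cutoffFrom,
                                            outOfSample = outOfSample,
                                            lambda = lambda,
                                            standardize = standardize)))
}

#' Timesplit validation
#'
#' Fits the model on rows published strictly before `splitDate` and
#' evaluates on the rest: reports the training-derived optimal cutoff, the
#' test accuracy at that cutoff, and the test AUC, together with the PCA
#' summary, probability quartiles and Mann-Whitney comparison of the test
#' panel.
#'
#' @param fm a [FeatureMatrix-class] with dates.
#' @param splitDate split date.
#' @param lambda,standardize model configuration.
#' @return a [ValidationReport-class] with a single round.
#' @export
runTimesplitValidation <- function(fm, splitDate, lambda = 1.0,
                                   standardize = FALSE) {
  d <- fm@dates
  if (anyNA(d)) {
    warnf("excluding %d row(s) without dates from the timesplit", sum(is.na(d)))
    fm <- featureRows(fm, which(!is.na(d)))
    d <- fm@dates
  }
  splitDate <- as.Date(splitDate)
  trainIdx <- which(d < splitDate); testIdx <- which(d >= splitDate)
  if (length(trainIdx) == 0 || length(testIdx) == 0)
    stopf("timesplit at %s leaves an empty partition", splitDate)
  if (length(unique(fm@y[trainIdx])) < 2)
    stopf("training side of the timesplit has a single class")
  fit <- fitOutcomeModel(featureRows(fm, trainIdx), lambda = lambda,
                         standardize = standardize)
  pTest <- predictProbability(fit, featureRows(fm, testIdx))
  pTrain <- predictProbability(fit, featureRows(fm, trainIdx))
  yT <- fm@y[testIdx]
  t <- fit@cutoff
  acc <- (sum(pTest >= t & yT == 1L) + sum(pTest < t & yT == 0L)) / length(yT)
  aucTest <- rocAuc(yT, pTest)$auc
  extras <- list(trainAuc = rocAuc(fm@y[trainIdx], pTrain)$auc,
                 quartiles = probabilityQuartiles(yT, pTest))
  if (length(unique(yT)) == 2)
    extras$mannWhitney <- mannWhitneyU(pTest[yT == 1], pTest[yT == 0])
  rounds <- data.frame(splitDate = splitDate, cutoff = t, accuracy = acc,
                       auc = aucTest, nTrain = length(trainIdx),
                       nTest = length(testIdx))
  methods::new("ValidationReport", mode = "timesplit", rounds = rounds,
               aggregate = list(accuracy = c(mean = acc, sd = 0),
                                auc = c(mean = aucTest, sd = 0)),
               details = c(extras, list(config = list(lambda = lambda,
                                                      standardize = standardize))))
}

#' PCA summary of a feature matrix
#'
#' Standardizes the columns (constant columns are dropped with a warning)
#' and returns the top-2 principal component scores and explained-variance
#' ratios.
#'
#' @param x a [FeatureMatrix-class] or numeric matrix.
#' @return list with `scores` (n x 2), `evr1`, `evr2`.
#' @export
pcaSummary <- function(x) {
  X <- if (methods::is(x, "FeatureMatrix")) x@X else x
  if (nrow(X) < 3) stopf("PCA needs at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant column(s) before PCA", sum(sds == 0))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stopf("PCA needs at least 2 non-constant columns")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, 1:2, drop = FALSE], evr1 = evr[1], evr2 = evr[2])
}

#' Mann-Whitney comparison of two probability groups
#'
#' Rank-sum U statistic with tie correction; the two-sided p-value is exact
#' (full enumeration) when `n1 * n2 <= 400` and there are no ties, and uses
#' the normal approximation with continuity and tie correction otherwise.
#'
#' @param pSuccess,pFailure numeric vectors (both non-empty).
#' @return list with `U` (statistic of the first group) and `twoSidedP`.
#' @export
mannWhitneyU <- function(pSuccess, pFailure) {
  if (length(pSuccess) == 0 || length(pFailure) == 0)
    stopf("both groups must be non-empty")
  n1 <- length(pSuccess); n2 <- length(pFailure)
  ranks <- rank(c(pSuccess, pFailure))
  U1 <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(pSuccess, pFailure)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    pSuccess, pFailure, exact = (n1 * n2 <= 400) && !ties,
    correct = TRUE, alternative = "two.sided"))
  list(U = unname(U1), twoSidedP = unname(wt$p.value))
}

#' Quartiles of predicted probability per outcome class
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities.
#' @return list with `success` and `failure`, each the 25/50/75 percent
#'   quartiles.
#' @export
probabilityQuartiles <- function(y, p) {
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = TRUE)
  list(success = q(p[y == 1]), failure = q(p[y == 0]))
}

setMethod("show", "ValidationReport", function(object) {
  a <- object@aggregate
  cat(sprintf("ValidationReport (%s): %d round(s)\n", object@mode,
              nrow(object@rounds)))
  for (nm in names(a))
    cat(sprintf("  %s: mean %.4f, sd %.4f\n", nm, a[[nm]]["mean"],
                a[[nm]]["sd"]))
  if (length(object@details$skippedSeeds))
    cat(sprintf("  skipped seeds: %s\n",
                paste(object@details$skippedSeeds, collapse = ",")))
})

#' Write a validation report (JSON summary + per-round CSV)
#'
#' @param report a [ValidationReport-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return the JSON path, invisibly.
#' @export
writeValidationReport <- function(report, dir, name = report@mode) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_rounds.csv"))
  utils::write.csv(report@rounds, csv, row.names = FALSE)
  js <- file.path(dir, paste0(name, "_summary.json"))
  jsonlite::write_json(list(mode = report@mode,
                            aggregate = report@aggregate,
                            details = report@details,
                            rounds_csv = basename(csv)),
                       js, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(js)
}
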