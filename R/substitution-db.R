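# The substitution-record database: loading with inclusion rules, named
# subsets, balanced resampling and train/test splitting.

RECORD_COLUMNS <- c("protein_id", "chain", "position", "naa", "uaa", "cdtype",
                    "outcome", "prooflv", "pub_date", "efficiency",
                    "efficiency_quality", "viral", "structure_predicted",
                    "source")

#' Construct a record set from a data.frame
#'
#' @param records data.frame with the record CSV schema (see
#'   [loadRecords()]); missing optional columns are filled with defaults.
#' @param label provenance label.
#' @return a [RecordSet-class].
#' @export
recordSet <- function(records, label = "unlabelled") {
  if (is.null(records$efficiency)) records$efficiency <- NA_real_
  if (is.null(records$efficiency_quality)) records$efficiency_quality <- "none"
  if (is.null(records$viral)) records$viral <- FALSE
  if (is.null(records$structure_predicted)) records$structure_predicted <- FALSE
  if (is.null(records$source)) records$source <- "unspecified"
  records$position <- as.character(records$position)
  records$pub_date <- as.Date(records$pub_date)
  rownames(records) <- NULL
  methods::new("RecordSet", records = records[, RECORD_COLUMNS], label = label)
}

#' Number of records
#' @param rs a [RecordSet-class].
#' @return integer count.
#' @export
nRecords <- function(rs) nrow(rs@records)

#' Records as a data.frame
#' @param rs a [RecordSet-class].
#' @return the underlying data.frame.
#' @export
records <- function(rs) rs@records

#' Outcome labels as 0/1
#' @param rs a [RecordSet-class].
#' @return integer vector, success = 1.
#' @export
outcomeLabels <- function(rs) as.integer(rs@records$outcome == "success")

setMethod("show", "RecordSet", function(object) {
  r <- object@records
  cat(sprintf("RecordSet '%s': %d records (%d success, %d failure)\n",
              object@label, nrow(r), sum(r$outcome == "success"),
              sum(r$outcome == "failure")))
})

setMethod("[", "RecordSet", function(x, i, j, ..., drop = FALSE) {
  methods::new("RecordSet",
               records = {
                 r <- x@records[i, , drop = FALSE]; rownames(r) <- NULL; r
               },
               label = x@label)
})

#' Load and validate substitution records
#'
#' Reads the record CSV (header
#' `protein_id,chain,position,naa,uaa,cdtype,outcome,prooflv,pub_date,efficiency,efficiency_quality,viral,structure_predicted,source`,
#' empty efficiency allowed) and applies the database inclusion rules:
#' records on proteins shorter than 50 residues, records with D-form UAAs,
#' and records whose NAA disagrees with the registered structure are
#' rejected; the itemized rejections are attached as attribute
#' `"rejected"`.
#'
#' @param path record CSV file.
#' @param proteins optional protein registry used for validation: a named
#'   list of [SiteFeatureProfile-class] objects (names = protein ids).
#' @param chem optional [AminoAcidLibrary-class]; referenced UAAs must be
#'   registered and must not be D-form.
#' @param label provenance label for the resulting set.
#' @return a [RecordSet-class] of accepted records; rejected rows (with a
#'   `reason` column) in `attr(, "rejected")`.
#' @export
loadRecords <- function(path, proteins = NULL, chem = NULL,
                        label = basename(path)) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(position = "character"))
  miss <- setdiff(RECORD_COLUMNS, names(r))
  if (length(miss))
    stopf("record CSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(chem)) {
    unknown <- setdiff(unique(r$uaa), chem@specs$code)
    if (length(unknown))
      stopf("unregistered UAA code(s) in %s: %s", path,
            paste(unknown, collapse = ", "))
  }
  if (!is.null(proteins)) {
    unknown <- setdiff(unique(r$protein_id), names(proteins))
    if (length(unknown))
      stopf("unregistered protein(s) in %s: %s", path,
            paste(unknown, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(r))
  if (!is.null(proteins)) {
    for (i in seq_len(nrow(r))) {
      prof <- proteins[[r$protein_id[i]]]
      d <- prof@data
      if (sum(d$chain == r$chain[i]) < 50) {
        reason[i] <- "protein shorter than 50 residues"
        next
      }
      j <- which(d$chain == r$chain[i] & d$position == r$position[i])
      if (length(j) == 0) reason[i] <- "site absent from structure"
      else if (d$aa[j[1]] != r$naa[i])
        reason[i] <- sprintf("NAA mismatch: expected %s, found %s",
                             d$aa[j[1]], r$naa[i])
    }
  }
  if (!is.null(chem)) {
    dform <- r$uaa %in% chem@specs$code[chem@specs$chirality == "D"]
    reason[is.na(reason) & dform] <- "D-form UAA"
  }
  rejected <- cbind(r[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  if (nrow(rejected))
    message(sprintf("loadRecords: rejected %d of %d records (%s)",
                    nrow(rejected), nrow(r),
                    paste(unique(rejected$reason), collapse = "; ")))
  rs <- recordSet(r[is.na(reason), , drop = FALSE], label = label)
  attr(rs, "rejected") <- rejected
  rs
}

#' Substitution outcome from an incorporation efficiency
#'
#' Efficiency strictly greater than 0.01 (1 percent of wild-type
#' expression) counts as a successful incorporation.
#'
#' @param efficiency non-negative efficiency value(s).
#' @return "success" or "failure" per value.
#' @export
outcomeFromEfficiency <- function(efficiency) {
  if (any(!is.finite(efficiency)) || any(efficiency < 0))
    stopf("efficiency must be finite and >= 0")
  ifelse(efficiency > 0.01, "success", "failure")
}

#' Select a named subset of the database
#'
#' Named filters: `direct_proof` (prooflv == "direct"), `amber`
#' (cdtype == "TAG"), `non_predicted_pdb` (structure_predicted == FALSE),
#' `non_viral` (viral == FALSE), `coarse_yield` / `exact_yield`
#' (efficiency present at that quality tier), `non_redundant`
#' (deduplication on protein/chain/position/uaa, keeping the earliest
#' record).  A function predicate over the records data.frame is also
#' accepted.
#'
#' @param rs a [RecordSet-class].
#' @param filter filter name or predicate function.
#' @return the filtered [RecordSet-class] with an updated label.
#' @export
selectSubset <- function(rs, filter) {
  r <- rs@records
  if (is.function(filter)) {
    keep <- filter(r)
    name <- "predicate"
  } else {
    name <- match.arg(filter, c("direct_proof", "amber", "non_predicted_pdb",
                                "non_viral", "coarse_yield", "exact_yield",
                                "non_redundant"))
    keep <- switch(name,
      direct_proof = r$prooflv == "direct",
      amber = r$cdtype == "TAG",
      non_predicted_pdb = !r$structure_predicted,
      non_viral = !r$viral,
      coarse_yield = !is.na(r$efficiency) &
        r$efficiency_quality %in% c("coarse", "exact"),
      exact_yield = !is.na(r$efficiency) & r$efficiency_quality == "exact",
      non_redundant = {
        ord <- order(r$pub_date)
        first <- !duplicated(r[ord, c("protein_id", "chain", "position", "uaa")])
        keep <- logical(nrow(r)); keep[ord[first]] <- TRUE; keep
      })
  }
  if (!any(keep)) warnf("subset '%s' is empty", name)
  out <- rs[which(keep)]
  out@label <- paste0(rs@label, ":", name)
  out
}

# index helpers shared by RecordSet operations and matrix-level validation --

balancedIndices <- function(y, seed) {
  stopifnot(all(y %in% c(0L, 1L)))
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  if (length(i1) == 0 || length(i0) == 0)
    stopf("both outcome classes are required for a balanced subset")
  if (length(i0) <= length(i1)) { minor <- i0; major <- i1 }
  else { minor <- i1; major <- i0 }
  picked <- withSeed(seed, sampleExact(major, length(minor)))
  sort(c(minor, picked))
}

holdoutIndices <- function(n, trainFraction, seed) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stopf("trainFraction must lie strictly between 0 and 1")
  k <- roundHalfUp(trainFraction * n)
  train <- withSeed(seed, sort(sample.int(n, k)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Balanced subset by resampling the majority class
#'
#' All minority-class records plus an equal-size uniform sample (without
#' replacement) of the majority class; deterministic per seed.
#'
#' @param rs a [RecordSet-class] containing both outcome classes.
#' @param seed integer seed.
#' @return a balanced [RecordSet-class].
#' @export
balancedSubset <- function(rs, seed) {
  idx <- balancedIndices(outcomeLabels(rs), seed)
  out <- rs[idx]
  out@label <- sprintf("%s:balanced(seed=%d)", rs@label, as.integer(seed))
  out
}

#' Split records for validation
#'
#' Holdout mode picks `round(trainFraction * n)` records (round half up)
#' uniformly at random as training data; timesplit mode assigns records
#' published strictly before `splitDate` to training and the rest to
#' testing.  Records with missing publication dates are excluded from a
#' timesplit with a warning.
#'
#' @param rs a [RecordSet-class].
#' @param mode "holdout" or "timesplit".
#' @param trainFraction holdout training fraction in (0, 1).
#' @param seed holdout seed.
#' @param splitDate timesplit date (anything `as.Date()` accepts).
#' @return list with [RecordSet-class] elements `train` and `test`.
#' @export
splitRecords <- function(rs, mode = c("holdout", "timesplit"),
                         trainFraction = 0.8, seed = 0, splitDate = NULL) {
  mode <- match.arg(mode)
  if (mode == "holdout") {
    idx <- holdoutIndices(nRecords(rs), trainFraction, seed)
    train <- rs[idx$train]; test <- rs[idx$test]
  } else {
    if (is.null(splitDate)) stopf("timesplit requires a splitDate")
    d <- rs@records$pub_date
    if (anyNA(d)) {
      warnf("excluding %d record(s) without pub_date from the timesplit",
            sum(is.na(d)))
      rs <- rs[which(!is.na(d))]
      d <- rs@records$pub_date
    }
    splitDate <- as.Date(splitDate)
    if (splitDate <= min(d) || splitDate > max(d))
      stopf("splitDate %s lies outside the record date range [%s, %s]",
            splitDate, min(d), max(d))
    train <- rs[which(d < splitDate)]
    test <- rs[which(d >= splitDate)]
  }
  train@label <- paste0(rs@label, ":train")
  test@label <- paste0(rs@label, ":test")
  list(train = train, test = test)
}
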