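# Assembly of the 21-column numeric feature encoding per record.

# one-hot helpers; the reference level maps to all zeros
ssDummies <- function(sstype)
  cbind(isHelix = as.numeric(sstype == "helix"),
        isStrand = as.numeric(sstype == "strand"),
        isTurn = as.numeric(sstype == "turn"))
codonDummies <- function(cdtype)
  cbind(isAmber = as.numeric(cdtype == "TAG"),
        isOchre = as.numeric(cdtype == "TAA"),
        isOpal = as.numeric(cdtype == "TGA"))
proofDummies <- function(prooflv)
  cbind(isDirect = as.numeric(prooflv == "direct"),
        isIndirect = as.numeric(prooflv == "indirect"))

#' Assemble one feature row
#'
#' Builds the 21-column numeric row for one substitution record from its
#' site features (entropy, rasa, hsebup, hsebdn, sstype), the descriptor
#' deltas and fingerprint similarity between its UAA and NAA, and the codon
#' and proof-level dummies.  Reference levels (coil / non-stop codon /
#' other proof) encode as all-zero dummy groups.
#'
#' @param record one-row data.frame or named list with `naa`, `uaa`,
#'   `cdtype`, `prooflv`.
#' @param site named list or one-row data.frame with `entropy`, `rasa`,
#'   `hsebup`, `hsebdn`, `sstype`.
#' @param chem an [AminoAcidLibrary-class].
#' @param absoluteDeltas use |delta| preprocessing for the physiochemical
#'   changes (optional mode; default signed).
#' @return named numeric vector of length 21 in [featureColumns()] order.
#' @export
assembleRow <- function(record, site, chem, absoluteDeltas = FALSE) {
  record <- as.list(record); site <- as.list(site)
  for (f in c("entropy", "rasa", "hsebup", "hsebdn"))
    if (is.null(site[[f]]) || is.na(site[[f]]))
      stopf("missing site feature '%s' for record at %s", f,
            paste(record$protein_id, record$chain, record$position,
                  collapse = " "))
  naa3 <- record$naa
  delta <- descriptorDelta(record$uaa, naa3, library = chem)
  if (absoluteDeltas) delta <- abs(delta)
  simi <- fingerprintSimilarity(record$uaa, naa3, library = chem)
  v <- c(entropy = site$entropy, rasa = site$rasa,
         hsebup = site$hsebup, hsebdn = site$hsebdn,
         ssDummies(site$sstype)[1, ],
         uaasimi = simi, delta,
         codonDummies(record$cdtype)[1, ],
         proofDummies(record$prooflv)[1, ])
  v[featureColumns()]
}

#' Assemble the feature matrix of a record set
#'
#' Vectorized assembly of all records against a registry of site feature
#' profiles and the amino-acid library.  Any record whose site features or
#' chemistry cannot be resolved makes the whole call fail with a
#' consolidated list of offenders (missing features are never imputed).
#' Warns when n is below 10 rows per feature column.
#'
#' @param rs a [RecordSet-class].
#' @param profiles named list of [SiteFeatureProfile-class] objects
#'   (names = protein ids).
#' @param chem an [AminoAcidLibrary-class].
#' @param absoluteDeltas use |delta| preprocessing (default signed).
#' @return a [FeatureMatrix-class] with labels (success = 1), record ids,
#'   dates and efficiencies aligned to the rows.
#' @export
assembleMatrix <- function(rs, profiles, chem, absoluteDeltas = FALSE) {
  r <- rs@records
  if (nrow(r) == 0) stopf("cannot assemble a feature matrix from 0 records")
  siteTab <- do.call(rbind, lapply(names(profiles), function(pid)
    cbind(protein_id = pid, profiles[[pid]]@data,
          stringsAsFactors = FALSE)))
  skey <- paste(siteTab$protein_id, siteTab$chain, siteTab$position, sep = "\r")
  i <- match(paste(r$protein_id, r$chain, r$position, sep = "\r"), skey)
  problems <- character()
  bad <- which(is.na(i))
  if (length(bad))
    problems <- c(problems, sprintf("record %d: no site features for %s %s:%s",
                                    bad, r$protein_id[bad], r$chain[bad],
                                    r$position[bad]))
  site <- siteTab[ifelse(is.na(i), 1L, i), , drop = FALSE]
  mism <- which(!is.na(i) & site$aa != r$naa)
  if (length(mism))
    problems <- c(problems,
                  sprintf("record %d: NAA mismatch (structure %s, record %s)",
                          mism, site$aa[mism], r$naa[mism]))
  incomplete <- which(!is.na(i) &
    (is.na(site$entropy) | is.na(site$rasa) |
       is.na(site$hsebup) | is.na(site$hsebdn)))
  if (length(incomplete))
    problems <- c(problems, sprintf("record %d: incomplete site features",
                                    incomplete))
  aa <- unique(c(r$naa, r$uaa))
  unknown <- setdiff(aa, chem@specs$code)
  if (length(unknown))
    problems <- c(problems, sprintf("unregistered amino acid: %s", unknown))
  if (length(problems))
    stopf("cannot assemble %d record(s):\n  %s", length(problems),
          paste(problems, collapse = "\n  "))
  sp <- chem@specs
  iu <- match(r$uaa, sp$code); inn <- match(r$naa, sp$code)
  plain <- c("AlogP", "Estate", "PSA", "Polar", "HBA", "HBD", "RB")
  deltas <- sapply(plain, function(d) sp[[d]][iu] - sp[[d]][inn])
  if (nrow(r) == 1) deltas <- matrix(deltas, 1, dimnames = list(NULL, plain))
  colnames(deltas) <- paste0("d", plain)
  dMW <- (sp$MW[iu] - sp$MW[inn]) / sp$MW[inn]
  if (absoluteDeltas) { deltas <- abs(deltas); dMW <- abs(dMW) }
  pairKey <- paste(r$uaa, r$naa)
  simi <- vapply(unique(pairKey), function(k) {
    parts <- strsplit(k, " ")[[1]]
    fingerprintSimilarity(parts[1], parts[2], library = chem)
  }, numeric(1))[pairKey]
  X <- cbind(entropy = site$entropy, rasa = site$rasa,
             hsebup = site$hsebup, hsebdn = site$hsebdn,
             ssDummies(site$sstype), uaasimi = unname(simi),
             deltas, dMW = dMW,
             codonDummies(r$cdtype), proofDummies(r$prooflv))
  X <- X[, featureColumns(), drop = FALSE]
  rownames(X) <- NULL
  n <- nrow(X)
  if (n < 10 * ncol(X))
    warnf(paste("sample size %d is below 10 rows per feature column (%d);",
                "estimates may be unstable"), n, 10 * ncol(X))
  methods::new("FeatureMatrix", X = X,
               y = as.integer(r$outcome == "success"),
               recordId = sprintf("%s:%s:%s:%s:%d", r$protein_id, r$chain,
                                  r$position, r$uaa, seq_len(n)),
               dates = as.Date(r$pub_date),
               efficiency = as.numeric(r$efficiency),
               columnsVersion = featureColumnsVersion())
}

#' Decode dummy groups back to categorical levels
#'
#' Inverse of the one-hot encoding used in [assembleRow()]; exact on valid
#' rows (each dummy group sums to at most 1).
#'
#' @param row named numeric feature row (or matrix row).
#' @return list with `sstype`, `cdtype`, `prooflv`.
#' @export
decodeDummies <- function(row) {
  pick <- function(vals, levels, ref) {
    i <- which(vals == 1)
    if (length(i) > 1) stopf("invalid dummy group (sum > 1)")
    if (length(i) == 0) ref else levels[i]
  }
  list(
    sstype = pick(row[c("isHelix", "isStrand", "isTurn")],
                  c("helix", "strand", "turn"), "coil"),
    cdtype = pick(row[c("isAmber", "isOchre", "isOpal")],
                  c("TAG", "TAA", "TGA"), "other"),
    prooflv = pick(row[c("isDirect", "isIndirect")],
                   c("direct", "indirect"), "other"))
}

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d records x %d features (%d success, %d failure)\n",
              nrow(object@X), ncol(object@X), sum(object@y == 1),
              sum(object@y == 0)))
})

#' Subset a feature matrix by row index
#' @param fm a [FeatureMatrix-class].
#' @param i integer row indices.
#' @return the row-subset [FeatureMatrix-class].
#' @export
featureRows <- function(fm, i) {
  methods::new("FeatureMatrix", X = fm@X[i, , drop = FALSE], y = fm@y[i],
               recordId = fm@recordId[i], dates = fm@dates[i],
               efficiency = fm@efficiency[i],
               columnsVersion = fm@columnsVersion)
}

#' Write / read a feature matrix CSV
#'
#' Header is the fixed 21-column order plus `label` and `record_id`.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path CSV path.
#' @return `path` (write) or a [FeatureMatrix-class] (read).
#' @export
writeFeatureMatrix <- function(fm, path) {
  d <- cbind(as.data.frame(fm@X), label = fm@y, record_id = fm@recordId)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  X <- as.matrix(d[, featureColumns()])
  methods::new("FeatureMatrix", X = X, y = as.integer(d$label),
               recordId = as.character(d$record_id),
               dates = as.Date(rep(NA, nrow(X))),
               efficiency = rep(NA_real_, nrow(X)),
               columnsVersion = featureColumnsVersion())
}
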