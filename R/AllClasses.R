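# S4 classes for the central data objects.

DESCRIPTOR_NAMES <- c("AlogP", "Estate", "PSA", "Polar", "HBA", "HBD", "RB", "MW")

#' Amino-acid library
#'
#' Registry of natural (NAA) and unnatural (UAA) amino acids with eight
#' physiochemical descriptors (AlogP, Estate, PSA in square Angstrom, Polar
#' in cubic Angstrom, HBA/HBD/RB counts, MW in Dalton), optional binary
#' fingerprints (sets of on-bit indices) and an optional precomputed
#' fingerprint similarity matrix.  Imported similarity values always take
#' precedence over live Tanimoto computation.
#'
#' @slot specs data.frame with one row per amino acid; columns
#'   `code`, `kind` ("NAA"/"UAA"), `one_letter`, the eight descriptor
#'   columns and `chirality` ("L", "D" or "achiral").
#' @slot fingerprints named list of integer vectors (on-bit indices).
#' @slot similarity square numeric matrix of pairwise similarities in
#'   \[0, 1\] with codes as dimnames, or a 0 x 0 matrix when absent.
#' @export
setClass("AminoAcidLibrary",
  representation(specs = "data.frame", fingerprints = "list",
                 similarity = "matrix"))

setValidity("AminoAcidLibrary", function(object) {
  sp <- object@specs
  msg <- character()
  need <- c("code", "kind", DESCRIPTOR_NAMES, "chirality")
  miss <- setdiff(need, names(sp))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(sp$code)) msg <- c(msg, "duplicate amino-acid codes")
  d <- as.matrix(sp[, DESCRIPTOR_NAMES])
  if (!all(is.finite(d))) msg <- c(msg, "non-finite descriptor values")
  else {
    if (any(sp$MW <= 0)) msg <- c(msg, "MW must be positive")
    cnt <- as.matrix(sp[, c("HBA", "HBD", "RB")])
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "HBA/HBD/RB must be non-negative integers")
  }
  if (!all(sp$kind %in% c("NAA", "UAA"))) msg <- c(msg, "kind must be NAA or UAA")
  if (any(sp$kind == "UAA" & sp$chirality == "D"))
    msg <- c(msg, "D-form UAAs are excluded from the library")
  if (length(object@fingerprints) &&
      !all(names(object@fingerprints) %in% sp$code))
    msg <- c(msg, "fingerprint codes not present in specs")
  s <- object@similarity
  if (length(s)) {
    if (nrow(s) != ncol(s) || is.null(dimnames(s)))
      msg <- c(msg, "similarity must be a named square matrix")
    else if (any(s < -1e-9 | s > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "similarity values outside [0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Protein structure model
#'
#' Per-atom coordinate model of one protein (or assembly), restricted to
#' polymer ATOM records, first model of multi-model files, highest-occupancy
#' alternate conformers.  Residues keep the author numbering of the source
#' file; insertion codes are part of the position key.
#'
#' @slot proteinId identifier string (conventionally 4 lowercase characters).
#' @slot atoms data.frame with columns `chain`, `resno` (integer), `insert`
#'   (string, "" when absent), `resid` (3-letter residue code), `elety`
#'   (atom name), `element`, `x`, `y`, `z` (Angstrom).
#' @slot provenance "experimental" or "predicted".
#' @export
setClass("StructureModel",
  representation(proteinId = "character", atoms = "data.frame",
                 provenance = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (anyDuplicated(a[, c("chain", "resno", "insert", "elety")]))
    return("duplicate atom records (chain, resno, insert, elety)")
  if (!object@provenance %in% c("experimental", "predicted"))
    return("provenance must be 'experimental' or 'predicted'")
  TRUE
})

#' Per-residue site feature profile
#'
#' The per-protein table of evolutional and steric site features consumed by
#' feature assembly and screening: one row per residue with alignment column
#' entropy, relative accessible surface area, half-sphere exposure counts and
#' 3-class secondary structure.
#'
#' @slot proteinId protein identifier.
#' @slot data data.frame with columns `chain`, `position` (author numbering,
#'   insertion code appended when present), `aa` (3-letter NAA code),
#'   `entropy`, `rasa`, `hsebup`, `hsebdn`, `sstype`
#'   ("helix", "strand", "turn" or "coil").
#' @export
setClass("SiteFeatureProfile",
  representation(proteinId = "character", data = "data.frame"))

setValidity("SiteFeatureProfile", function(object) {
  d <- object@data
  need <- c("chain", "position", "aa", "entropy", "rasa",
            "hsebup", "hsebdn", "sstype")
  miss <- setdiff(need, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  ok <- is.na(d$rasa) | (d$rasa >= 0 & d$rasa <= 1)
  if (!all(ok)) return("rasa outside [0, 1]")
  if (!all(is.na(d$entropy) | d$entropy >= 0)) return("negative entropy")
  if (!all(d$sstype %in% c("helix", "strand", "turn", "coil")))
    return("invalid sstype")
  TRUE
})

#' Substitution record set
#'
#' An ordered collection of experimentally verified NAA to UAA substitution
#' records with a provenance label.  See [loadRecords()] for the CSV schema.
#'
#' @slot records data.frame, one row per record.
#' @slot label provenance label string.
#' @export
setClass("RecordSet",
  representation(records = "data.frame", label = "character"))

setValidity("RecordSet", function(object) {
  r <- object@records
  need <- c("protein_id", "chain", "position", "naa", "uaa", "cdtype",
            "outcome", "prooflv", "pub_date", "efficiency",
            "efficiency_quality", "viral", "structure_predicted", "source")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(r)) {
    if (!all(r$outcome %in% c("success", "failure"))) return("invalid outcome")
    if (!all(r$cdtype %in% c("TAG", "TAA", "TGA", "other"))) return("invalid cdtype")
    if (!all(r$prooflv %in% c("direct", "indirect", "other"))) return("invalid prooflv")
    if (!all(r$efficiency_quality %in% c("exact", "coarse", "none")))
      return("invalid efficiency_quality")
    if (any(!is.na(r$efficiency) & r$efficiency_quality == "none"))
      return("efficiency present but efficiency_quality is 'none'")
    pos <- suppressWarnings(as.integer(sub("[A-Za-z]$", "", r$position)))
    if (any(is.na(pos)) || any(pos < 1)) return("positions must be >= 1")
    key <- r[, c("protein_id", "chain", "position", "uaa", "cdtype", "source")]
    if (anyDuplicated(key)) return("duplicate (protein, chain, position, uaa, cdtype, source)")
  }
  TRUE
})

#' Feature matrix
#'
#' The fixed 21-column numeric encoding of the model variables for a record
#' set, with the binary outcome labels (success = 1) and row-aligned record
#' identifiers.  Column order is fixed and versioned; see [featureColumns()].
#'
#' @slot X numeric matrix, n x 21.
#' @slot y integer labels in \{0, 1\}.
#' @slot recordId character row identifiers.
#' @slot dates publication dates (`Date`, may contain NA).
#' @slot efficiency incorporation efficiencies (NA when unreported).
#' @slot columnsVersion feature-encoding version string.
#' @export
setClass("FeatureMatrix",
  representation(X = "matrix", y = "integer", recordId = "character",
                 dates = "Date", efficiency = "numeric",
                 columnsVersion = "character"))

setValidity("FeatureMatrix", function(object) {
  if (!identical(colnames(object@X), featureColumns()))
    return("feature columns do not match the versioned column order")
  if (anyNA(object@X)) return("feature matrix contains missing values")
  if (length(object@y) != nrow(object@X)) return("label length mismatch")
  if (!all(object@y %in% c(0L, 1L))) return("labels must be 0/1")
  if (length(object@recordId) != nrow(object@X)) return("recordId length mismatch")
  TRUE
})

#' Fitted substitution-outcome model
#'
#' Ridge-penalized logistic regression of the substitution outcome on the 21
#' feature columns: `log(P/(1-P)) = b + sum_i k_i V_i`.  Carries the optimal
#' probability cutoff (maximizing sensitivity + specificity on the training
#' panel) and training metrics.
#'
#' @slot intercept fitted intercept b.
#' @slot coef named coefficient vector (length 21).
#' @slot se asymptotic standard errors (intercept first, then coefficients).
#' @slot center,scale standardization parameters (length-0 when unused).
#' @slot cutoff optimal probability cutoff in (0, 1).
#' @slot metrics list with accuracy, sensitivity, specificity, auc.
#' @slot provenance list (subset label, n, fit date, config).
#' @slot columnsVersion feature-encoding version string.
#' @export
setClass("OutcomeModelFit",
  representation(intercept = "numeric", coef = "numeric", se = "numeric",
                 center = "numeric", scale = "numeric", cutoff = "numeric",
                 metrics = "list", provenance = "list",
                 columnsVersion = "character"))

setValidity("OutcomeModelFit", function(object) {
  if (!identical(names(object@coef), featureColumns()))
    return("coefficient names do not match the versioned column order")
  if (!is.finite(object@intercept)) return("non-finite intercept")
  if (!all(is.finite(object@coef))) return("non-finite coefficients")
  if (length(object@cutoff) && (object@cutoff <= 0 || object@cutoff >= 1))
    return("cutoff must lie in (0, 1)")
  TRUE
})

#' Fitted incorporation-efficiency model
#'
#' Ridge-penalized linear model of log(E + 1) on the 21 feature columns,
#' where E is the incorporation efficiency (expression relative to
#' wild-type).  Predictions are mapped back by exp(eta) - 1 and clamped at 0.
#'
#' @slot intercept,coef model parameters on the log(E + 1) scale.
#' @slot residualScale residual standard deviation on the transformed scale.
#' @slot center,scale standardization parameters (length-0 when unused).
#' @slot provenance list describing the training subset.
#' @slot columnsVersion feature-encoding version string.
#' @export
setClass("EfficiencyModelFit",
  representation(intercept = "numeric", coef = "numeric",
                 residualScale = "numeric", center = "numeric",
                 scale = "numeric", provenance = "list",
                 columnsVersion = "character"))

#' UAA-by-site probability matrix
#'
#' Full virtual-screening result for one protein: predicted probability of
#' successful substitution for every registered UAA at every site with
#' complete features, under an assumed prediction context (codon type and
#' proof level).
#'
#' @slot P numeric matrix, UAAs x sites, values in \[0, 1\].
#' @slot sites data.frame describing the site columns (chain, position, aa).
#' @slot context list with the assumed `cdtype` and `prooflv`.
#' @slot provenance list (protein id, model provenance, omitted sites).
#' @export
setClass("ProbabilityMatrix",
  representation(P = "matrix", sites = "data.frame", context = "list",
                 provenance = "list"))

setValidity("ProbabilityMatrix", function(object) {
  if (any(object@P < 0 | object@P > 1)) return("probabilities outside [0, 1]")
  if (ncol(object@P) != nrow(object@sites)) return("site dimension mismatch")
  TRUE
})

#' Validation report
#'
#' Per-round and aggregate results of a validation battery run (repeated
#' holdout, repeated balanced resampling, or timesplit).
#'
#' @slot mode "holdout", "balanced" or "timesplit".
#' @slot rounds data.frame with one row per evaluated round.
#' @slot aggregate named list of mean/sd per reported index.
#' @slot details list (skipped rounds, config, extras such as PCA and
#'   Mann-Whitney summaries).
#' @export
setClass("ValidationReport",
  representation(mode = "character", rounds = "data.frame",
                 aggregate = "list", details = "list"))
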