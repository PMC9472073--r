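# Virtual screening: the full UAA-by-site probability matrix, the fixed-UAA
# and fixed-site ranking strategies, and the heatmap / CSV reports.

#' Predict the full UAA-by-site probability matrix
#'
#' For every registered UAA and every site of the protein with complete
#' features, assembles the feature row (using the site's own NAA and an
#' assumed prediction context for the codon type and proof level, which are
#' properties of the planned experiment rather than of the site) and
#' predicts the probability of successful substitution.  Sites with
#' incomplete features are omitted and listed in the provenance.
#'
#' @param profile a [SiteFeatureProfile-class].
#' @param chem an [AminoAcidLibrary-class]; rows are its registered UAAs.
#' @param fit an [OutcomeModelFit-class].
#' @param context assumed `cdtype` (default "TAG", amber suppression being
#'   the overwhelmingly common system) and `prooflv` (default "direct");
#'   always recorded in the output provenance.
#' @param uaas optional subset of UAA codes to screen.
#' @return a [ProbabilityMatrix-class].
#' @export
predictFullMatrix <- function(profile, chem, fit,
                              context = list(cdtype = "TAG",
                                             prooflv = "direct"),
                              uaas = NULL) {
  d <- profile@data
  complete <- !is.na(d$entropy) & !is.na(d$rasa) & !is.na(d$hsebup) &
    !is.na(d$hsebdn) & d$aa %in% chem@specs$code
  omitted <- d[!complete, c("chain", "position", "aa")]
  d <- d[complete, , drop = FALSE]
  if (nrow(d) == 0)
    stopf("protein %s has no sites with complete features", profile@proteinId)
  uaas <- uaas %||% aaCodes(chem, "UAA")
  if (length(uaas) == 0) stopf("no UAAs registered")
  nS <- nrow(d); nU <- length(uaas)
  # site-level block (same for every UAA)
  siteBlock <- cbind(entropy = d$entropy, rasa = d$rasa, hsebup = d$hsebup,
                     hsebdn = d$hsebdn, ssDummies(d$sstype))
  ctxBlock <- cbind(codonDummies(context$cdtype %||% "TAG"),
                    proofDummies(context$prooflv %||% "direct"))
  sp <- chem@specs
  plain <- c("AlogP", "Estate", "PSA", "Polar", "HBA", "HBD", "RB")
  P <- matrix(NA_real_, nU, nS,
              dimnames = list(uaas, paste0(d$chain, ":", d$position)))
  for (u in seq_len(nU)) {
    iu <- match(uaas[u], sp$code); inn <- match(d$aa, sp$code)
    deltas <- sapply(plain, function(dd) sp[[dd]][iu] - sp[[dd]][inn])
    if (nS == 1) deltas <- matrix(deltas, 1, dimnames = list(NULL, plain))
    colnames(deltas) <- paste0("d", plain)
    simi <- vapply(unique(d$aa), function(naa)
      fingerprintSimilarity(uaas[u], naa, library = chem), numeric(1))[d$aa]
    X <- cbind(siteBlock, uaasimi = unname(simi), deltas,
               dMW = (sp$MW[iu] - sp$MW[inn]) / sp$MW[inn],
               ctxBlock[rep(1, nS), , drop = FALSE])
    P[u, ] <- predictProbability(fit, X[, featureColumns(), drop = FALSE])
  }
  methods::new("ProbabilityMatrix", P = P,
               sites = data.frame(chain = d$chain, position = d$position,
                                  aa = d$aa, stringsAsFactors = FALSE),
               context = list(cdtype = context$cdtype %||% "TAG",
                              prooflv = context$prooflv %||% "direct"),
               provenance = list(proteinId = profile@proteinId,
                                 model = fit@provenance,
                                 cutoff = fit@cutoff,
                                 omittedSites = omitted))
}

setMethod("show", "ProbabilityMatrix", function(object) {
  cat(sprintf(
    "ProbabilityMatrix '%s': %d UAAs x %d sites (context %s/%s), P in [%.3f, %.3f]\n",
    object@provenance$proteinId, nrow(object@P), ncol(object@P),
    object@context$cdtype, object@context$prooflv, min(object@P),
    max(object@P)))
})

#' Rank screening candidates
#'
#' Fixed-UAA strategy: rank all sites for one UAA; fixed-site strategy:
#' rank all UAAs for one site.  Candidates are sorted by probability
#' descending with deterministic tie-breaks (site order, then UAA code),
#' optionally filtered to `P >= threshold`.
#'
#' @param pm a [ProbabilityMatrix-class].
#' @param strategy "fixed_uaa" or "fixed_site".
#' @param key UAA code (fixed_uaa) or site key "chain:position" (fixed_site).
#' @param threshold optional probability threshold (e.g. the training
#'   cutoff, or a stricter 0.90 / 0.95 for high confidence).
#' @return data.frame `uaa, chain, position, naa, P`, best candidate first.
#' @export
rankCandidates <- function(pm, strategy = c("fixed_uaa", "fixed_site"),
                           key, threshold = NULL) {
  strategy <- match.arg(strategy)
  s <- pm@sites
  if (strategy == "fixed_uaa") {
    i <- match(key, rownames(pm@P))
    if (is.na(i)) stopf("UAA '%s' is not a row of the matrix", key)
    out <- data.frame(uaa = key, chain = s$chain, position = s$position,
                      naa = s$aa, P = pm@P[i, ], stringsAsFactors = FALSE)
    ord <- order(-out$P, seq_len(nrow(out)))
  } else {
    j <- match(key, colnames(pm@P))
    if (is.na(j)) stopf("site '%s' is not a column of the matrix", key)
    out <- data.frame(uaa = rownames(pm@P), chain = s$chain[j],
                      position = s$position[j], naa = s$aa[j], P = pm@P[, j],
                      stringsAsFactors = FALSE)
    ord <- order(-out$P, out$uaa)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(threshold)) out <- out[out$P >= threshold, , drop = FALSE]
  out
}

#' Export a screening report (CSV + optional heatmap)
#'
#' Writes the long-format CSV (one row per UAA/site pair:
#' `uaa,chain,position,naa,P`) and, optionally, a heatmap image with UAAs
#' on rows, residue positions on columns and a fixed color scale \[0, 1\],
#' into the given predictions directory.
#'
#' @param pm a [ProbabilityMatrix-class].
#' @param dir output directory (created if needed).
#' @param heatmap also render the heatmap image (PNG).
#' @return named character vector of the written paths, invisibly.
#' @export
writeScreeningReport <- function(pm, dir, heatmap = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- pm@provenance$proteinId
  s <- pm@sites
  long <- do.call(rbind, lapply(rownames(pm@P), function(u)
    data.frame(uaa = u, chain = s$chain, position = s$position, naa = s$aa,
               P = pm@P[u, ], stringsAsFactors = FALSE)))
  csv <- file.path(dir, sprintf("%s_probability_matrix.csv", pid))
  utils::write.csv(long, csv, row.names = FALSE, quote = FALSE)
  paths <- c(csv = csv)
  meta <- file.path(dir, sprintf("%s_provenance.json", pid))
  jsonlite::write_json(c(pm@provenance[c("proteinId", "model", "cutoff")],
                         list(context = pm@context,
                              omitted = nrow(pm@provenance$omittedSites))),
                       meta, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(paths, provenance = meta)
  if (heatmap) {
    png <- file.path(dir, sprintf("%s_probability_heatmap.png", pid))
    grDevices::png(png, width = max(480, 12 * ncol(pm@P) + 160),
                   height = max(360, 12 * nrow(pm@P) + 120))
    pheatmap::pheatmap(pm@P, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(0, 1, length.out = 101),
                       main = sprintf("%s (%s/%s)", pid, pm@context$cdtype,
                                      pm@context$prooflv))
    grDevices::dev.off()
    paths <- c(paths, heatmap = png)
  }
  invisible(paths)
}
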