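# Evolutional tolerance: per-site alignment columns and Shannon entropy.

STANDARD_AA <- names(AA_ONE_TO_THREE)

#' Build per-site alignment columns
#'
#' Collects, for every query position, the multiset of amino-acid letters
#' aligned to it across the query and all hits.  Input is either NCBI BLAST
#' XML output (pairwise local alignments) or an aligned FASTA whose first
#' sequence is the query.  Insertions relative to the query (gap characters
#' in the query row) create no columns; positions never covered by a hit
#' yield a singleton column holding the query residue.
#'
#' @param path BLAST XML file or aligned FASTA.
#' @param querySeq the ungapped query sequence (required to place singleton
#'   columns; for aligned FASTA it defaults to the first record, degapped).
#' @param format "auto" (sniffed), "blastxml" or "fasta".
#' @param bestHspOnly keep only the best-scoring HSP per hit (default FALSE:
#'   all HSPs are counted).
#' @return named list: query position (1-based, as character) -> character
#'   vector of aligned symbols (query residue first; gaps excluded).
#' @export
buildSiteAlignment <- function(path, querySeq = NULL,
                               format = c("auto", "blastxml", "fasta"),
                               bestHspOnly = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^<\\?xml|^<BlastOutput", first)) "blastxml" else "fasta"
  }
  if (format == "blastxml") {
    if (is.null(querySeq))
      stopf("querySeq is required for BLAST XML input")
    aln <- parseBlastXML(path, bestHspOnly = bestHspOnly)
  } else {
    seqs <- as.character(Biostrings::readAAStringSet(path))
    if (length(seqs) == 0) stopf("empty alignment file %s", path)
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1)
      stopf("aligned FASTA rows have unequal widths")
    if (is.null(querySeq)) querySeq <- gsub("-", "", seqs[[1]])
    aln <- list(list(qseq = seqs[[1]], hseq = NULL, qfrom = 1L))
    if (length(seqs) > 1)
      aln <- lapply(seqs[-1], function(h)
        list(qseq = seqs[[1]], hseq = h, qfrom = 1L))
  }
  qres <- strsplit(toupper(querySeq), "")[[1]]
  L <- length(qres)
  cols <- lapply(seq_len(L), function(i) qres[i])
  for (block in aln) {
    if (is.null(block$hseq)) next
    qs <- strsplit(toupper(block$qseq), "")[[1]]
    hs <- strsplit(toupper(block$hseq), "")[[1]]
    if (length(qs) != length(hs))
      stopf("aligned strings of unequal length in an alignment block")
    qpos <- block$qfrom - 1L
    for (k in seq_along(qs)) {
      if (qs[k] == "-") next        # insertion in hit: no query column
      qpos <- qpos + 1L
      if (hs[k] == "-") next        # deletion: nothing aligned here
      if (qpos >= 1L && qpos <= L) cols[[qpos]] <- c(cols[[qpos]], hs[k])
    }
  }
  names(cols) <- as.character(seq_len(L))
  cols
}

# parse NCBI BLAST XML: list of blocks (qseq, hseq, qfrom)
parseBlastXML <- function(path, bestHspOnly = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed BLAST XML %s: %s", path,
                                            conditionMessage(e)))
  hits <- xml2::xml_find_all(doc, ".//Hit")
  out <- list()
  for (h in hits) {
    hsps <- xml2::xml_find_all(h, ".//Hsp")
    if (length(hsps) == 0) next
    if (bestHspOnly && length(hsps) > 1) {
      scores <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(hsps, "Hsp_bit-score")))
      hsps <- hsps[which.max(scores)]
    }
    for (p in hsps) {
      out[[length(out) + 1]] <- list(
        qseq = xml2::xml_text(xml2::xml_find_first(p, "Hsp_qseq")),
        hseq = xml2::xml_text(xml2::xml_find_first(p, "Hsp_hseq")),
        qfrom = as.integer(xml2::xml_text(
          xml2::xml_find_first(p, "Hsp_query-from"))))
    }
  }
  out
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum p_a log(p_a)` over the observed amino-acid frequencies of the
#' column, natural log by default.  Gap characters and ambiguous symbols
#' (X, B, Z, J, U, O, *) are excluded from the counts before normalization;
#' a single-symbol column has entropy 0.
#'
#' @param column character vector of aligned symbols.
#' @param base logarithm base; `exp(1)` (default) or 2.
#' @return non-negative entropy; 0 (with a warning) for a column that is
#'   empty after exclusions.
#' @export
siteEntropy <- function(column, base = exp(1)) {
  s <- toupper(column)
  s <- s[s %in% STANDARD_AA]
  if (length(s) == 0) {
    warnf("alignment column empty after excluding gaps/ambiguity codes")
    return(0)
  }
  p <- table(s) / length(s)
  -sum(p * log(p, base = base))
}

#' Entropy for every site of an alignment
#'
#' @param columns site alignment as returned by [buildSiteAlignment()].
#' @param base logarithm base.
#' @return named numeric vector (query position -> entropy).
#' @export
siteEntropyProfile <- function(columns, base = exp(1)) {
  vapply(columns, siteEntropy, numeric(1), base = base)
}
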