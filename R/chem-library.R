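# Amino-acid registry: descriptor import, descriptor deltas, fingerprint
# similarity.  The primary path is CSV import; an optional Open Babel backend
# (ChemmineOB) can compute a subset of descriptors and FP2 fingerprints from
# SMILES, but imported tables always take precedence.

#' Load an amino-acid descriptor table
#'
#' Reads a descriptor CSV with header
#' `code,kind,one_letter,AlogP,Estate,PSA,Polar,HBA,HBD,RB,MW,chirality`
#' (UTF-8, dot decimal).  The `kind` column may be omitted when
#' `kindColumnPresent = FALSE`, in which case every row is taken as a UAA
#' unless its code is a standard 3-letter NAA code.
#'
#' @param path CSV file path.
#' @param kindColumnPresent does the file carry a `kind` column?
#' @return data.frame of validated amino-acid specs.
#' @export
loadDescriptorTable <- function(path, kindColumnPresent = TRUE) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp$code <- trimws(sp$code)
  need <- DESCRIPTOR_NAMES
  miss <- setdiff(need, names(sp))
  if (length(miss))
    stopf("descriptor table %s lacks required column(s): %s", path,
          paste(miss, collapse = ", "))
  if (!"code" %in% names(sp)) stopf("descriptor table lacks a 'code' column")
  for (col in need) {
    v <- suppressWarnings(as.numeric(sp[[col]]))
    bad <- which(is.na(v) & !is.na(sp[[col]]))
    if (length(bad))
      stopf("non-numeric value in descriptor column '%s' at row %d", col, bad[1])
    if (anyNA(v))
      stopf("missing value in descriptor column '%s' at row %d", col,
            which(is.na(v))[1])
    sp[[col]] <- v
  }
  dup <- sp$code[duplicated(sp$code)]
  if (length(dup))
    stopf("duplicate amino-acid code(s): %s", paste(unique(dup), collapse = ", "))
  if (!kindColumnPresent || !"kind" %in% names(sp))
    sp$kind <- ifelse(sp$code %in% names(AA_THREE_TO_ONE), "NAA", "UAA")
  if (!"one_letter" %in% names(sp))
    sp$one_letter <- unname(AA_THREE_TO_ONE[sp$code])
  if (!"chirality" %in% names(sp)) sp$chirality <- "L"
  sp$chirality[is.na(sp$chirality) | sp$chirality == ""] <- "L"
  rownames(sp) <- sp$code
  sp
}

#' Load a fingerprint table
#'
#' CSV with columns `code,bits`; `bits` is a space-separated list of on-bit
#' indices of a binary fingerprint.
#'
#' @param path CSV file path.
#' @return named list of sorted integer vectors.
#' @export
loadFingerprints <- function(path) {
  fp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "bits") %in% names(fp)))
    stopf("fingerprint table needs columns 'code' and 'bits'")
  out <- lapply(strsplit(as.character(fp$bits), "[[:space:]]+"),
                function(b) sort(unique(as.integer(b[nzchar(b)]))))
  names(out) <- trimws(fp$code)
  out
}

#' Load a precomputed similarity matrix
#'
#' Square CSV matrix; first column and header row carry the amino-acid codes,
#' values must lie in \[0, 1\] and the matrix must be symmetric with unit
#' diagonal.
#'
#' @param path CSV file path.
#' @return numeric matrix with code dimnames.
#' @export
loadSimilarityTable <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  codes <- trimws(m[[1]])
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- codes
  colnames(m) <- trimws(colnames(m))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m)))
    stopf("similarity table is not a square code-by-code matrix")
  m <- m[, rownames(m), drop = FALSE]
  if (any(m < 0 | m > 1)) stopf("similarity values outside [0, 1]")
  if (max(abs(m - t(m))) > 1e-6) stopf("similarity table is not symmetric")
  if (max(abs(diag(m) - 1)) > 1e-6) stopf("similarity diagonal must be 1")
  m
}

#' Construct an amino-acid library
#'
#' @param specs descriptor data.frame as returned by [loadDescriptorTable()].
#' @param fingerprints optional named list of on-bit index vectors.
#' @param similarity optional precomputed similarity matrix.
#' @return an [AminoAcidLibrary-class] object.
#' @export
aminoAcidLibrary <- function(specs, fingerprints = list(), similarity = NULL) {
  methods::new("AminoAcidLibrary", specs = specs,
               fingerprints = fingerprints,
               similarity = similarity %||% matrix(numeric(), 0, 0))
}

#' Packaged synthetic amino-acid library
#'
#' Loads the descriptor table, linear-path fingerprints (2048 bits, path
#' length <= 7) and Tanimoto similarity matrix shipped with the package:
#' the 20 natural amino acids plus 12 representative UAAs used in genetic
#' code expansion.  The tables are a synthetic stand-in for a laboratory
#' UAA registry, generated once from structure line notation and frozen.
#'
#' @return an [AminoAcidLibrary-class] object with 32 registered amino acids.
#' @export
syntheticChemLibrary <- function() {
  p <- function(f) system.file("extdata", f, package = "uaaScreen", mustWork = TRUE)
  aminoAcidLibrary(loadDescriptorTable(p("aa_descriptors_synthetic.csv")),
                   loadFingerprints(p("aa_fingerprints_synthetic.csv")),
                   loadSimilarityTable(p("aa_similarity_synthetic.csv")))
}

#' @describeIn aminoAcidLibrary registered codes, optionally one kind only.
#' @param x an `AminoAcidLibrary`.
#' @param kind optional "NAA" or "UAA".
#' @export
aaCodes <- function(x, kind = NULL) {
  stopifnot(methods::is(x, "AminoAcidLibrary"))
  sp <- x@specs
  if (!is.null(kind)) sp <- sp[sp$kind == kind, , drop = FALSE]
  sp$code
}

#' @describeIn aminoAcidLibrary one spec as a named list.
#' @param code amino-acid code.
#' @export
aaSpec <- function(x, code) {
  stopifnot(methods::is(x, "AminoAcidLibrary"))
  i <- match(code, x@specs$code)
  if (is.na(i)) stopf("amino acid '%s' is not registered", code)
  as.list(x@specs[i, ])
}

setMethod("show", "AminoAcidLibrary", function(object) {
  sp <- object@specs
  cat(sprintf("AminoAcidLibrary: %d specs (%d NAA, %d UAA), %d fingerprints%s\n",
              nrow(sp), sum(sp$kind == "NAA"), sum(sp$kind == "UAA"),
              length(object@fingerprints),
              if (length(object@similarity)) ", similarity table" else ""))
})

#' Physiochemical descriptor differences between a UAA and an NAA
#'
#' Seven plain differences (UAA minus NAA) for AlogP, Estate, PSA, Polar,
#' HBA, HBD and RB, and the relative molecular-weight difference
#' `dMW = (MW_UAA - MW_NAA) / MW_NAA`.
#'
#' @param uaa,naa amino-acid codes (resolved in `library`) or named lists /
#'   one-row data.frames carrying the eight descriptors.
#' @param library optional [AminoAcidLibrary-class] for code resolution.
#' @return named numeric vector
#'   `dAlogP, dEstate, dPSA, dPolar, dHBA, dHBD, dRB, dMW`.
#' @export
descriptorDelta <- function(uaa, naa, library = NULL) {
  res <- function(s) {
    if (is.character(s)) {
      if (is.null(library)) stopf("a library is required to resolve code '%s'", s)
      aaSpec(library, s)
    } else as.list(s)
  }
  u <- res(uaa); n <- res(naa)
  for (d in DESCRIPTOR_NAMES) {
    if (is.null(u[[d]]) || is.null(n[[d]]) || !is.finite(u[[d]]) || !is.finite(n[[d]]))
      stopf("descriptor '%s' missing or non-finite", d)
  }
  if (n$MW <= 0) stopf("NAA molecular weight must be positive")
  plain <- c("AlogP", "Estate", "PSA", "Polar", "HBA", "HBD", "RB")
  out <- vapply(plain, function(d) u[[d]] - n[[d]], numeric(1))
  names(out) <- paste0("d", plain)
  c(out, dMW = (u$MW - n$MW) / n$MW)
}

#' Fingerprint similarity between two amino acids
#'
#' Returns the pairwise similarity in \[0, 1\].  A precomputed similarity
#' table (the library's imported matrix, or one passed via `table`) takes
#' precedence; otherwise the Tanimoto coefficient |A&B| / |A|B| of the two
#' binary fingerprints is computed.
#'
#' @param a,b amino-acid codes or integer vectors of fingerprint on-bits.
#' @param library optional [AminoAcidLibrary-class] supplying fingerprints
#'   and/or a similarity table.
#' @param table optional explicit similarity matrix overriding the library's.
#' @return similarity value in \[0, 1\].
#' @export
fingerprintSimilarity <- function(a, b, library = NULL, table = NULL) {
  tab <- table %||% (if (!is.null(library) && length(library@similarity))
    library@similarity else NULL)
  if (is.character(a) && is.character(b) && !is.null(tab) &&
      a %in% rownames(tab) && b %in% colnames(tab))
    return(unname(tab[a, b]))
  bits <- function(s) {
    if (is.numeric(s)) return(as.integer(s))
    if (!is.null(library) && s %in% names(library@fingerprints))
      return(library@fingerprints[[s]])
    NULL
  }
  fa <- bits(a); fb <- bits(b)
  if (is.null(fa) || is.null(fb))
    stopf("no similarity table entry and no fingerprints for pair (%s, %s)",
          paste(a, collapse = ","), paste(b, collapse = ","))
  if (length(fa) == 0 && length(fb) == 0)
    stopf("both fingerprints are empty; Tanimoto similarity undefined")
  length(intersect(fa, fb)) / length(union(fa, fb))
}

#' Compute descriptors and fingerprints from SMILES (optional backend)
#'
#' Uses Open Babel (via the ChemmineOB package, if installed) to compute the
#' descriptor subset Open Babel supports (AlogP, PSA, Polar via molar
#' refractivity, HBA, HBD, MW) and FP2 linear-path fingerprints (1024 bits,
#' path length <= 7).  Estate and RB are returned as NA; imported descriptor
#' tables always take precedence over this backend.
#'
#' @param smiles named character vector of SMILES (names become codes).
#' @return list with elements `specs` (data.frame, NA where the backend
#'   cannot compute a descriptor) and `fingerprints`.
#' @export
computeDescriptorsOB <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stopf("the optional cheminformatics backend requires the ChemmineOB package")
  if (is.null(names(smiles)) || any(!nzchar(names(smiles))))
    stopf("'smiles' must be a named character vector")
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  pr <- do.call(rbind, lapply(mols, ChemmineOB::prop_OB))
  fpm <- ChemmineOB::fingerprint_OB(mols, "FP2")
  if (is.null(dim(fpm))) fpm <- matrix(fpm, nrow = 1)
  fps <- lapply(seq_len(nrow(fpm)), function(i) which(fpm[i, ] != 0))
  names(fps) <- names(smiles)
  specs <- data.frame(code = names(smiles), kind = NA_character_,
                      one_letter = NA_character_,
                      AlogP = pr$logP, Estate = NA_real_, PSA = pr$TPSA,
                      Polar = pr$MR, HBA = pr$HBA2, HBD = pr$HBD,
                      RB = NA_real_, MW = pr$MW, chirality = "L",
                      stringsAsFactors = FALSE)
  rownames(specs) <- specs$code
  list(specs = specs, fingerprints = fps)
}
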