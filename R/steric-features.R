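# Per-residue steric features: Shrake-Rupley accessible surface area,
# half-sphere exposure (beta variant, 12 A radius), and 3-class secondary
# structure from backbone hydrogen-bond patterns or an external DSSP file.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent accessible surface area: each atom is covered with a
#' deterministic Fibonacci lattice of `nPoints` test points on its solvated
#' sphere (van der Waals radius + probe radius); points falling inside any
#' other atom's solvated sphere are occluded and
#' `ASA = 4 pi (r + probe)^2 * accessible / nPoints`.
#'
#' @param model a [StructureModel-class]; all chains are used (assembly-wide
#'   burial), so supply a complex to get complex-context accessibility.
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints test points per atom; 960 is the production default, use
#'   more for a high-resolution reference.
#' @param radii named van der Waals radii (Angstrom) by element; defaults to
#'   Bondi-style values.
#' @param defaultRadius fallback radius for unlisted elements; `NULL` (the
#'   default) makes an unknown element an error.
#' @return numeric vector of per-atom ASA (Angstrom^2), aligned with
#'   `model@atoms` rows.
#' @export
shrakeRupleyASA <- function(model, probeRadius = 1.4, nPoints = 960,
                            radii = VDW_RADII, defaultRadius = NULL) {
  a <- model@atoms
  rv <- radii[a$element]
  if (anyNA(rv)) {
    if (is.null(defaultRadius))
      stopf("no van der Waals radius for element(s): %s",
            paste(unique(a$element[is.na(rv)]), collapse = ", "))
    rv[is.na(rv)] <- defaultRadius
  }
  rs <- rv + probeRadius
  xyz <- cbind(a$x, a$y, a$z)
  pts <- fibonacciSphere(nPoints)
  n <- nrow(a)
  out <- numeric(n)
  # neighbor candidates via cell lists would be overkill at fixture scale;
  # simple distance screening per atom
  maxr <- max(rs)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    p <- pts * rs[i]
    p <- cbind(p[, 1] + xyz[i, 1], p[, 2] + xyz[i, 2], p[, 3] + xyz[i, 3])
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 > rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(acc) / nPoints
  }
  out
}

#' Relative accessible surface area per residue
#'
#' Sums atomic ASA per residue and divides by the theoretical maximum for
#' the residue type (Tien et al. 2013 values by default), clamped to
#' \[0, 1\] (0 fully buried, 1 fully exposed).
#'
#' @param model a [StructureModel-class].
#' @param asa optional precomputed per-atom ASA from [shrakeRupleyASA()].
#' @param maxAsa named per-residue-type maxima (Angstrom^2); override via a
#'   CSV of `resid,max_asa` read by the caller.
#' @param ... passed to [shrakeRupleyASA()] when `asa` is NULL.
#' @return data.frame `chain, resno, insert, resid, rasa`.
#' @export
relativeASA <- function(model, asa = NULL, maxAsa = MAX_ASA_TIEN2013, ...) {
  if (is.null(asa)) asa <- shrakeRupleyASA(model, ...)
  a <- model@atoms
  res <- residueTable(model)
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  tot <- tapply(asa, factor(key, levels = res$key), sum)
  mx <- maxAsa[res$resid]
  if (anyNA(mx))
    stopf("no maximum-ASA reference for residue type(s): %s",
          paste(unique(res$resid[is.na(mx)]), collapse = ", "))
  data.frame(chain = res$chain, resno = res$resno, insert = res$insert,
             resid = res$resid, rasa = pmin(1, pmax(0, as.numeric(tot) / mx)),
             stringsAsFactors = FALSE)
}

# direction of the side chain at each residue: CB - CA, or a virtual CB
# direction from tetrahedral N/CA/C geometry when CB is absent (glycine)
sideChainDirections <- function(model) {
  ca <- atomCoords(model, "CA"); cb <- atomCoords(model, "CB")
  nn <- atomCoords(model, "N");  cc <- atomCoords(model, "C")
  dir <- cb - ca
  missing <- is.na(dir[, 1])
  if (any(missing)) {
    # virtual CB: opposite the bisector of the N and C bond directions
    b1 <- nn[missing, , drop = FALSE] - ca[missing, , drop = FALSE]
    b2 <- cc[missing, , drop = FALSE] - ca[missing, , drop = FALSE]
    nrm <- function(v) v / sqrt(rowSums(v^2))
    dir[missing, ] <- -nrm(nrm(b1) + nrm(b2))
  }
  list(ca = ca, dir = dir)
}

#' Half-sphere exposure (beta variant)
#'
#' Counts the C-alpha atoms of all other residues in the assembly within
#' `radius` of each residue's C-alpha and partitions them by the plane
#' through the C-alpha perpendicular to the CA->CB direction (real CB when
#' present, virtual CB from backbone geometry for glycine): `hsebup` counts
#' the side-chain hemisphere (positive dot product), `hsebdn` the complement
#' (a boundary dot product of exactly 0 counts as down).
#'
#' @param model a [StructureModel-class].
#' @param radius neighborhood radius in Angstrom (default 12).
#' @return data.frame `chain, resno, insert, resid, hsebup, hsebdn`.
#' @export
halfSphereExposure <- function(model, radius = 12) {
  res <- residueTable(model)
  sc <- sideChainDirections(model)
  ca <- sc$ca
  if (anyNA(ca)) stopf("residue(s) without CA atom: %s",
                       paste(res$key[is.na(ca[, 1])], collapse = "; "))
  if (anyNA(sc$dir))
    stopf("cannot determine side-chain direction (missing backbone atoms)")
  n <- nrow(res)
  up <- dn <- integer(n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    d <- cbind(ca[, 1] - ca[i, 1], ca[, 2] - ca[i, 2], ca[, 3] - ca[i, 3])
    within <- which(rowSums(d^2) <= r2 & seq_len(n) != i)
    if (length(within)) {
      dot <- d[within, , drop = FALSE] %*% sc$dir[i, ]
      up[i] <- sum(dot > 0)
      dn[i] <- length(within) - up[i]
    }
  }
  data.frame(chain = res$chain, resno = res$resno, insert = res$insert,
             resid = res$resid, hsebup = up, hsebdn = dn,
             stringsAsFactors = FALSE)
}

# DSSP-style backbone hydrogen bond energies.  Returns n x n logical matrix:
# bond[i, j] = TRUE when the N-H of residue i donates to the C=O of residue j.
backboneHBonds <- function(model, cutoff = -0.5) {
  res <- residueTable(model)
  n <- nrow(res)
  N <- atomCoords(model, "N"); CA <- atomCoords(model, "CA")
  C <- atomCoords(model, "C"); O <- atomCoords(model, "O")
  # amide H: along the previous residue's O->C direction, 1.01 A from N
  H <- matrix(NA_real_, n, 3)
  same <- c(FALSE, res$chain[-1] == res$chain[-n])
  prev <- which(same)
  d <- C[prev - 1, , drop = FALSE] - O[prev - 1, , drop = FALSE]
  d <- d / sqrt(rowSums(d^2))
  H[prev, ] <- N[prev, , drop = FALSE] + 1.01 * d
  bond <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  donors <- which(!is.na(H[, 1]) & res$resid != "PRO")
  for (i in donors) {
    js <- which(abs(seq_len(n) - i) >= 2 & !is.na(O[, 1]) & !is.na(C[, 1]))
    if (!length(js)) next
    rON <- sqrt(rowSums((O[js, , drop = FALSE] -
                           matrix(N[i, ], length(js), 3, TRUE))^2))
    rCH <- sqrt(rowSums((C[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, TRUE))^2))
    rOH <- sqrt(rowSums((O[js, , drop = FALSE] -
                           matrix(H[i, ], length(js), 3, TRUE))^2))
    rCN <- sqrt(rowSums((C[js, , drop = FALSE] -
                           matrix(N[i, ], length(js), 3, TRUE))^2))
    E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    bond[i, js[E < cutoff]] <- TRUE
  }
  bond
}

#' Assign 3-class secondary structure
#'
#' With an external DSSP output file, parses its 8-state letters and reduces
#' them (H,G,I -> helix; E,B -> strand; T,S -> turn; else coil).  Otherwise
#' assigns internally from backbone hydrogen bonds (electrostatic energy
#' model, bond when E < -0.5 kcal/mol): runs of i->i+4 (and i->i+3, i->i+5)
#' turns make helices, bridge patterns make strands, isolated turns make
#' turns, everything else is coil.  Residues with missing backbone atoms
#' default to coil with a warning.
#'
#' @param model a [StructureModel-class].
#' @param dsspFile optional path to a classic DSSP output file.
#' @param includeBend treat DSSP state "S" (bend) as turn (default TRUE).
#' @return data.frame `chain, resno, insert, resid, sstype`.
#' @export
assignSecondaryStructure <- function(model, dsspFile = NULL,
                                     includeBend = TRUE) {
  res <- residueTable(model)
  n <- nrow(res)
  if (!is.null(dsspFile)) {
    st8 <- parseDSSP(dsspFile)
    i <- match(paste(res$chain, res$resno, res$insert, sep = "\r"),
               paste(st8$chain, st8$resno, st8$insert, sep = "\r"))
    letter <- ifelse(is.na(i), " ", st8$ss[i])
    turnStates <- if (includeBend) c("T", "S") else "T"
    sstype <- ifelse(letter %in% c("H", "G", "I"), "helix",
              ifelse(letter %in% c("E", "B"), "strand",
              ifelse(letter %in% turnStates, "turn", "coil")))
    return(cbind(res[c("chain", "resno", "insert", "resid")],
                 sstype = sstype, stringsAsFactors = FALSE))
  }
  bb <- list(N = atomCoords(model, "N"), CA = atomCoords(model, "CA"),
             C = atomCoords(model, "C"), O = atomCoords(model, "O"))
  incomplete <- Reduce(`|`, lapply(bb, function(m) is.na(m[, 1])))
  if (any(incomplete))
    warnf("%d residue(s) missing backbone atoms; defaulting to coil",
          sum(incomplete))
  hbAll <- backboneHBonds(model)          # inter-chain bonds kept for bridges
  sameChain <- outer(res$chain, res$chain, `==`)
  hb <- hbAll & sameChain                 # turns and helices are intra-chain
  # turn(k) at i: C=O of i accepts from N-H of i+k
  turnAt <- function(k) {
    t <- rep(FALSE, n)
    i <- seq_len(n - k)
    t[i] <- hb[cbind(i + k, i)] & res$chain[i] == res$chain[i + k]
    t
  }
  t3 <- turnAt(3); t4 <- turnAt(4); t5 <- turnAt(5)
  helix <- rep(FALSE, n)
  markRun <- function(t, k) {
    for (i in which(t)) if (i > 1 && t[i - 1])
      helix[i:min(n, i + k - 1)] <<- TRUE
  }
  markRun(t4, 4); markRun(t3, 3); markRun(t5, 5)
  # bridges (parallel and antiparallel) -> strand
  strand <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (res$chain[i] == res$chain[j] && j - i < 3) next
      inner <- i > 1 && i < n && j > 1 && j < n
      par <- inner && ((hbAll[i, j - 1] && hbAll[j + 1, i]) ||
                       (hbAll[j, i - 1] && hbAll[i + 1, j]))
      anti <- (hbAll[i, j] && hbAll[j, i]) ||
              (inner && hbAll[i - 1, j + 1] && hbAll[j - 1, i + 1])
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }
  turn <- rep(FALSE, n)
  for (k in 3:5) {
    tk <- list(t3, t4, t5)[[k - 2]]
    for (i in which(tk)) turn[i:min(n, i + k)] <- TRUE
  }
  sstype <- ifelse(helix, "helix",
            ifelse(strand, "strand",
            ifelse(turn, "turn", "coil")))
  sstype[incomplete] <- "coil"
  cbind(res[c("chain", "resno", "insert", "resid")], sstype = sstype,
        stringsAsFactors = FALSE)
}

# classic DSSP output parser (the per-residue block after the '  #  RESIDUE'
# header line); returns chain, resno, insert, ss letter
parseDSSP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1)
    stopf("%s does not look like a DSSP output file", path)
  body <- lines[(start + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  data.frame(chain = trimws(substr(body, 12, 12)),
             resno = as.integer(substr(body, 6, 10)),
             insert = trimws(substr(body, 11, 11)),
             ss = substr(body, 17, 17), stringsAsFactors = FALSE)
}

#' Build the per-residue site feature profile of a protein
#'
#' Combines the steric features (relative ASA, half-sphere exposure,
#' secondary structure) with per-site alignment entropy into the standard
#' per-protein site table.  Entropy is mapped from sequence positions to
#' author numbering via the chain sequence: the offset between the
#' structure's residues and the supplied query sequence is found by exact
#' window matching.
#'
#' @param model a [StructureModel-class].
#' @param entropy optional named numeric vector of per-sequence-position
#'   entropies (names = 1-based query positions) as produced by
#'   [siteEntropyProfile()], or NULL for NA entropy.
#' @param querySeq the query sequence the entropy positions refer to;
#'   required when `entropy` is given and numbering must be reconciled.
#' @param chain chain to map entropy onto (default: first chain).
#' @param dsspFile optional external DSSP file for secondary structure.
#' @param nPoints sphere points for the ASA computation.
#' @return a [SiteFeatureProfile-class].
#' @export
siteFeatureProfile <- function(model, entropy = NULL, querySeq = NULL,
                               chain = NULL, dsspFile = NULL, nPoints = 960) {
  ras <- relativeASA(model, nPoints = nPoints)
  hse <- halfSphereExposure(model)
  ss <- assignSecondaryStructure(model, dsspFile = dsspFile)
  d <- data.frame(chain = ras$chain,
                  position = paste0(ras$resno, ras$insert),
                  aa = ras$resid, entropy = NA_real_, rasa = ras$rasa,
                  hsebup = hse$hsebup, hsebdn = hse$hsebdn,
                  sstype = ss$sstype, stringsAsFactors = FALSE)
  if (!is.null(entropy)) {
    ch <- chain %||% d$chain[1]
    seqStruct <- chainSequence(model, ch)
    off <- 0L
    if (!is.null(querySeq)) {
      off <- sequenceOffset(seqStruct, querySeq)
      if (is.na(off))
        stopf("cannot reconcile chain %s sequence with the query sequence", ch)
    }
    inChain <- which(d$chain == ch)
    qpos <- seq_along(inChain) + off
    v <- entropy[as.character(qpos)]
    d$entropy[inChain] <- as.numeric(v)
  }
  methods::new("SiteFeatureProfile", proteinId = model@proteinId, data = d)
}

# offset o such that structure residue i corresponds to query position i + o
sequenceOffset <- function(structSeq, querySeq) {
  s <- strsplit(structSeq, "")[[1]]
  q <- strsplit(querySeq, "")[[1]]
  if (length(s) > length(q)) return(NA_integer_)
  for (o in 0:(length(q) - length(s))) {
    m <- q[seq_along(s) + o]
    if (all(s == m | s == "X" | m == "X")) return(o)
  }
  NA_integer_
}

setMethod("show", "SiteFeatureProfile", function(object) {
  d <- object@data
  cat(sprintf(
    "SiteFeatureProfile '%s': %d sites (%d with entropy), sstype: %s\n",
    object@proteinId, nrow(d), sum(!is.na(d$entropy)),
    paste(sprintf("%s=%d", names(table(d$sstype)), table(d$sstype)),
          collapse = " ")))
})

#' Write / read the per-protein site feature CSV
#'
#' Column layout `protein_id,chain,position,aa,entropy,rasa,hsebup,hsebdn,sstype`.
#'
#' @param profile a [SiteFeatureProfile-class].
#' @param path CSV path.
#' @return `path` (write) or a [SiteFeatureProfile-class] (read).
#' @export
writeSiteFeatures <- function(profile, path) {
  d <- cbind(protein_id = profile@proteinId, profile@data)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSiteFeatures
#' @export
readSiteFeatures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(position = "character"))
  pid <- unique(d$protein_id)
  if (length(pid) != 1) stopf("site feature file must describe one protein")
  methods::new("SiteFeatureProfile", proteinId = pid,
               data = d[, setdiff(names(d), "protein_id")])
}
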