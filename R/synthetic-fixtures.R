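# Deterministic synthetic generators: ideal helices and sheets with full
# backbone geometry, simulated alignments with controlled per-site
# conservation, and substitution databases drawn from a known logistic
# ground-truth model.

# Natural extension reference frame: place atom D given A, B, C with bond
# |CD|, angle B-C-D (degrees) and torsion A-B-C-D (degrees).
nerfPlace <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone internal coordinates (Engh-Huber style averages)
BB_GEOM <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231, cacb = 1.521,
                angNCAC = 111.2, angCACN = 116.2, angCNCA = 121.7,
                angCACO = 120.8, angNCACB = 110.4, impCB = 122.5)

# build one chain with given per-residue (phi, psi), omega = 180
buildBackbone <- function(sequence3, phi, psi, chain = "A", startRes = 1L) {
  n <- length(sequence3)
  g <- BB_GEOM
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$nca, 0, 0)
  a <- g$angNCAC * pi / 180
  C[1, ] <- CA[1, ] + g$cac * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], g$cn, g$angCACN, psi[i])
      CA[i + 1, ] <- nerfPlace(CA[i, ], C[i, ], N[i + 1, ], g$nca, g$angCNCA, 180)
      C[i + 1, ] <- nerfPlace(C[i, ], N[i + 1, ], CA[i + 1, ], g$cac,
                              g$angNCAC, phi[i + 1])
    }
    O[i, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], g$co, g$angCACO, psi[i] + 180)
    if (sequence3[i] != "GLY")
      CB[i, ] <- nerfPlace(C[i, ], N[i, ], CA[i, ], g$cacb, g$angNCACB, g$impCB)
  }
  rows <- list()
  for (i in seq_len(n)) {
    at <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (!is.na(CB[i, 1])) at$CB <- CB[i, ]
    for (nm in names(at))
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, resno = startRes + i - 1L, insert = "",
        resid = sequence3[i], elety = nm,
        element = substr(nm, 1, 1), x = at[[nm]][1], y = at[[nm]][2],
        z = at[[nm]][3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

seqToThree <- function(n, sequence = NULL) {
  if (is.null(sequence)) return(rep("ALA", n))
  one <- strsplit(toupper(sequence), "")[[1]]
  if (length(one) != n) stopf("sequence length %d != n %d", length(one), n)
  three <- AA_ONE_TO_THREE[one]
  if (anyNA(three)) stopf("unknown residue letter(s): %s",
                          paste(unique(one[is.na(three)]), collapse = ","))
  unname(three)
}

#' Ideal alpha-helix fixture
#'
#' Poly-alanine (or a given sequence) helix with phi/psi = (-57, -47)
#' degrees, ideal bond geometry, N/CA/C/O/CB atoms (no CB for glycine).
#' Fully deterministic.
#'
#' @param n number of residues (>= 4).
#' @param sequence optional one-letter sequence of length `n`.
#' @param proteinId identifier for the resulting model.
#' @return a [StructureModel-class] with one chain A.
#' @export
makeIdealHelix <- function(n, sequence = NULL, proteinId = "hlx1") {
  if (n < 4) stopf("an ideal helix needs at least 4 residues")
  three <- seqToThree(n, sequence)
  atoms <- buildBackbone(three, phi = rep(-57, n), psi = rep(-47, n))
  structureModel(atoms, proteinId = proteinId, provenance = "predicted")
}

#' Ideal antiparallel two-strand sheet fixture
#'
#' Two extended strands (phi/psi = (-139, 135) degrees) in chains A and B;
#' chain B is the 180-degree rotation of chain A about the axis
#' perpendicular to the strand direction, rigidly placed by a deterministic
#' grid search maximizing the number of inter-strand backbone hydrogen
#' bonds under the package's electrostatic bond model.
#'
#' @param nPerStrand residues per strand (>= 4).
#' @param sequence optional one-letter sequence for each strand.
#' @param proteinId identifier.
#' @return a [StructureModel-class] with chains A and B.
#' @export
makeIdealSheet <- function(nPerStrand = 8, sequence = NULL,
                           proteinId = "sht1") {
  if (nPerStrand < 4) stopf("a strand needs at least 4 residues")
  three <- seqToThree(nPerStrand, sequence)
  a <- buildBackbone(three, phi = rep(-139, nPerStrand),
                     psi = rep(135, nPerStrand), chain = "A")
  b <- buildBackbone(three, phi = rep(-139, nPerStrand),
                     psi = rep(135, nPerStrand), chain = "B")
  modelA <- structureModel(a, proteinId = "tmpA")
  bbA <- list(N = atomCoords(modelA, "N"), C = atomCoords(modelA, "C"),
              O = atomCoords(modelA, "O"), CA = atomCoords(modelA, "CA"))
  amideH <- function(bb) {
    n <- nrow(bb$N)
    H <- matrix(NA_real_, n, 3)
    d <- bb$C[-n, , drop = FALSE] - bb$O[-n, , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    H[-1, ] <- bb$N[-1, , drop = FALSE] + 1.01 * d
    H
  }
  HA <- amideH(bbA)
  q <- 0.084 * 332
  bondEnergy <- function(Nd, Hd, Ca, Oa) {
    dist <- function(P, Q) sqrt(pmax(1e-6,
      outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)))
    q * (1 / dist(Nd, Oa) + 1 / dist(Hd, Ca) - 1 / dist(Hd, Oa) -
           1 / dist(Nd, Ca))
  }
  # strand axis and perpendicular frame
  u <- stats::prcomp(bbA$CA)$rotation[, 1]
  v <- c(-u[2], u[1], 0); v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  g <- colMeans(bbA$CA)
  okA <- which(!is.na(HA[, 1]))
  # the antiparallel partner is a 2-fold rotation about an axis
  # perpendicular to the strand, placed by exhaustive search over the axis
  # orientation, inter-strand separation and register shift
  apply2fold <- function(M, theta, sep, reg, lift) {
    ax <- cos(theta) * v + sin(theta) * w
    R <- 2 * ax %o% ax - diag(3)
    t(R %*% (t(M) - g) + g) +
      matrix(sep * ax + reg * u + lift * (u), nrow(M), 3, byrow = TRUE) -
      matrix(0, nrow(M), 3)
  }
  score <- function(theta, sep, reg) {
    CAB <- apply2fold(bbA$CA, theta, sep, reg, 0)
    # reject sterically clashing placements outright
    d2 <- outer(rowSums(bbA$CA^2), rowSums(CAB^2), `+`) -
      2 * bbA$CA %*% t(CAB)
    if (min(d2) < 4.0^2) return(c(-1, Inf))
    NB <- apply2fold(bbA$N, theta, sep, reg, 0)
    CB2 <- apply2fold(bbA$C, theta, sep, reg, 0)
    OB <- apply2fold(bbA$O, theta, sep, reg, 0)
    HB <- amideH(list(N = NB, C = CB2, O = OB))
    okB <- which(!is.na(HB[, 1]))
    e1 <- bondEnergy(bbA$N[okA, , drop = FALSE], HA[okA, , drop = FALSE],
                     CB2, OB)
    e2 <- bondEnergy(NB[okB, , drop = FALSE], HB[okB, , drop = FALSE],
                     bbA$C, bbA$O)
    c(sum(e1 < -0.5) + sum(e2 < -0.5), sum(pmin(e1, 0)) + sum(pmin(e2, 0)))
  }
  grid <- expand.grid(theta = seq(0, pi, pi / 18),
                      sep = seq(4, 6, 0.2), reg = seq(-3.5, 3.5, 0.25))
  best <- c(-1, Inf); bestPar <- c(0, 5, 0)
  for (i in seq_len(nrow(grid))) {
    pr <- as.numeric(grid[i, ])
    sc <- score(pr[1], pr[2], pr[3])
    if (sc[1] > best[1] || (sc[1] == best[1] && sc[2] < best[2])) {
      best <- sc; bestPar <- pr
    }
  }
  # local refinement around the best cell
  ref <- expand.grid(theta = bestPar[1] + seq(-0.1, 0.1, 0.05),
                     sep = bestPar[2] + seq(-0.2, 0.2, 0.05),
                     reg = bestPar[3] + seq(-0.25, 0.25, 0.05))
  for (i in seq_len(nrow(ref))) {
    pr <- as.numeric(ref[i, ])
    sc <- score(pr[1], pr[2], pr[3])
    if (sc[1] > best[1] || (sc[1] == best[1] && sc[2] < best[2])) {
      best <- sc; bestPar <- pr
    }
  }
  xyzB <- apply2fold(as.matrix(b[, c("x", "y", "z")]), bestPar[1],
                     bestPar[2], bestPar[3], 0)
  b$x <- xyzB[, 1]; b$y <- xyzB[, 2]; b$z <- xyzB[, 3]
  structureModel(rbind(a, b), proteinId = proteinId,
                 provenance = "predicted")
}

#' Simulate a multiple sequence alignment
#'
#' Generates `depth` homolog sequences for a query: at each site, the query
#' residue is kept with probability `conservation[i]`, otherwise a residue
#' is drawn uniformly from the other 19.  Deterministic per seed.
#'
#' @param query one-letter query sequence.
#' @param depth number of homolog sequences (>= 1).
#' @param conservation per-site retention probabilities in \[0, 1\]
#'   (length = query length; a scalar is recycled).
#' @param seed integer seed.
#' @return named character vector: the query first, then the homologs.
#' @export
simulateAlignment <- function(query, depth, conservation, seed) {
  if (depth < 1) stopf("depth must be >= 1")
  qres <- strsplit(toupper(query), "")[[1]]
  L <- length(qres)
  if (length(conservation) == 1) conservation <- rep(conservation, L)
  if (length(conservation) != L)
    stopf("conservation vector length %d != query length %d",
          length(conservation), L)
  if (any(conservation < 0 | conservation > 1))
    stopf("conservation values must lie in [0, 1]")
  withSeed(seed, {
    seqs <- vapply(seq_len(depth), function(h) {
      keep <- stats::runif(L) < conservation
      out <- qres
      sub <- which(!keep)
      for (i in sub)
        out[i] <- sample(setdiff(names(AA_ONE_TO_THREE), qres[i]), 1)
      paste(out, collapse = "")
    }, character(1))
    c(query = paste(qres, collapse = ""),
      stats::setNames(seqs, paste0("hit", seq_len(depth))))
  })
}

#' Write sequences as (aligned) FASTA
#'
#' @param seqs named character vector of equal-width sequences.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Build the full site profile of a synthetic protein
#'
#' Convenience wrapper chaining the simulated alignment, entropy and steric
#' features of a generated structure into a [SiteFeatureProfile-class].
#'
#' @param model a [StructureModel-class] (e.g. from [makeIdealHelix()]).
#' @param conservation per-site conservation for the simulated alignment
#'   (scalar or per-chain-A-residue vector).
#' @param depth alignment depth.
#' @param seed integer seed.
#' @param nPoints ASA sphere points.
#' @return a [SiteFeatureProfile-class].
#' @export
syntheticProteinProfile <- function(model, conservation = 0.8, depth = 30,
                                    seed = 1, nPoints = 960) {
  chains <- unique(model@atoms$chain)
  entAll <- NULL
  prof <- siteFeatureProfile(model, nPoints = nPoints)
  d <- prof@data
  for (ch in chains) {
    qs <- chainSequence(model, ch)
    aln <- simulateAlignment(qs, depth = depth, conservation = conservation,
                             seed = seed + match(ch, chains) - 1)
    f <- tempfile(fileext = ".fasta")
    writeAlignedFasta(aln, f)
    cols <- buildSiteAlignment(f, querySeq = qs)
    unlink(f)
    ent <- siteEntropyProfile(cols)
    inCh <- which(d$chain == ch)
    d$entropy[inCh] <- as.numeric(ent[seq_along(inCh)])
  }
  methods::new("SiteFeatureProfile", proteinId = model@proteinId, data = d)
}

#' Default ground-truth generative model
#'
#' The fixed intercept/coefficient vector used by the simulated database:
#' tolerant sites (high entropy, high exposure) and chemically conservative
#' substitutions (high similarity, small deltas) favor success.
#'
#' @return list with `b` and named coefficient vector `k` (21 columns).
#' @export
defaultGenerativeModel <- function() {
  k <- c(entropy = 0.8, rasa = 1.6, hsebup = -0.06, hsebdn = -0.06,
         isHelix = -0.3, isStrand = -0.4, isTurn = 0.1,
         uaasimi = 1.2, dAlogP = -0.15, dEstate = -0.02, dPSA = -0.004,
         dPolar = -0.01, dHBA = -0.12, dHBD = -0.12, dRB = -0.05,
         dMW = -0.8, isAmber = 0.3, isOchre = 0.0, isOpal = -0.1,
         isDirect = 0.4, isIndirect = -0.2)
  list(b = 0.5, k = k[featureColumns()])
}

#' Simulate a substitution database with known ground truth
#'
#' Samples `n` records over the sites of the supplied protein profiles, the
#' registered UAAs, codon types and proof levels; assembles their feature
#' rows; optionally calibrates the intercept by root finding so the mean
#' success probability hits `prevalence` (the coefficients are never
#' altered); and draws outcomes as Bernoulli(sigmoid(b + k . V)).
#' Publication dates are sampled uniformly (independent of the features, so
#' the generative process is stationary in time).  Deterministic per seed.
#'
#' @param profiles named list of [SiteFeatureProfile-class] objects.
#' @param chem an [AminoAcidLibrary-class].
#' @param n number of records.
#' @param model list with `b` and `k` (default [defaultGenerativeModel()]).
#' @param prevalence target success fraction in (0, 1), or NULL to use `b`
#'   as given.
#' @param codonProbs,proofProbs named sampling weights.
#' @param dateRange two dates for uniform pub_date sampling.
#' @param efficiencyModel optional list `(b, k, sdLog)`: attaches a
#'   simulated efficiency `E = max(0, exp(b + k . V + noise) - 1)` to every
#'   record (quality "exact"), with lognormal-scale noise sd `sdLog`.
#' @param seed integer seed.
#' @return list with `records` ([RecordSet-class]), `features`
#'   ([FeatureMatrix-class] with realized outcomes), `trueProb`,
#'   `bayesAuc` (realized AUC of the generative probabilities),
#'   `model` (with the calibrated intercept) and `seed`.
#' @export
simulateDatabase <- function(profiles, chem, n,
                             model = defaultGenerativeModel(),
                             prevalence = 0.87,
                             codonProbs = c(TAG = 0.8, TAA = 0.1,
                                            TGA = 0.05, other = 0.05),
                             proofProbs = c(direct = 0.6, indirect = 0.3,
                                            other = 0.1),
                             dateRange = as.Date(c("2002-01-01",
                                                   "2021-12-31")),
                             efficiencyModel = NULL, seed = 0) {
  if (n < 1) stopf("n must be >= 1")
  sites <- do.call(rbind, lapply(names(profiles), function(pid) {
    d <- profiles[[pid]]@data
    ok <- !is.na(d$entropy) & !is.na(d$rasa) & d$aa %in%
      chem@specs$code[chem@specs$kind == "NAA"]
    cbind(protein_id = pid, d[ok, c("chain", "position", "aa"),
                              drop = FALSE])
  }))
  if (nrow(sites) == 0) stopf("profiles contain no usable sites")
  uaas <- aaCodes(chem, "UAA")
  sim <- withSeed(seed, {
    si <- sample.int(nrow(sites), n, replace = TRUE)
    r <- data.frame(
      protein_id = sites$protein_id[si], chain = sites$chain[si],
      position = sites$position[si], naa = sites$aa[si],
      uaa = sample(uaas, n, replace = TRUE),
      cdtype = sample(names(codonProbs), n, TRUE, prob = codonProbs),
      outcome = "success",
      prooflv = sample(names(proofProbs), n, TRUE, prob = proofProbs),
      pub_date = dateRange[1] +
        sample.int(as.integer(dateRange[2] - dateRange[1]) + 1L, n,
                   replace = TRUE) - 1L,
      efficiency = NA_real_, efficiency_quality = "none", viral = FALSE,
      structure_predicted = FALSE,
      source = sprintf("sim%06d", seq_len(n)), stringsAsFactors = FALSE)
    rs0 <- recordSet(r, label = sprintf("simulated(seed=%d)", seed))
    fm <- suppressWarnings(assembleMatrix(rs0, profiles, chem))
    eta0 <- drop(fm@X %*% model$k[featureColumns()])
    b <- model$b
    if (!is.null(prevalence)) {
      f <- function(bb) mean(stats::plogis(bb + eta0)) - prevalence
      b <- tryCatch(stats::uniroot(f, c(-60, 60), tol = 1e-10)$root,
                    error = function(e) {
                      warnf("prevalence %.2f unreachable; keeping b = %.2f",
                            prevalence, model$b)
                      model$b
                    })
    }
    p <- stats::plogis(b + eta0)
    y <- stats::rbinom(n, 1, p)
    r$outcome <- ifelse(y == 1, "success", "failure")
    if (!is.null(efficiencyModel)) {
      etaE <- efficiencyModel$b +
        drop(fm@X %*% efficiencyModel$k[featureColumns()])
      E <- pmax(0, exp(etaE + stats::rnorm(n, 0, efficiencyModel$sdLog)) - 1)
      r$efficiency <- E
      r$efficiency_quality <- "exact"
    }
    list(r = r, p = p, y = y, b = b)
  })
  rs <- recordSet(sim$r, label = sprintf("simulated(seed=%d)", seed))
  fm <- suppressWarnings(assembleMatrix(rs, profiles, chem))
  bayes <- if (length(unique(sim$y)) == 2) rocAuc(sim$y, sim$p)$auc
           else NA_real_
  list(records = rs, features = fm, trueProb = sim$p, bayesAuc = bayes,
       model = list(b = sim$b, k = model$k[featureColumns()]), seed = seed)
}

#' Write the generative sidecar of a simulated database
#'
#' Emits a JSON description of the generative parameters (ground-truth
#' model, realized prevalence, Bayes AUC, seed) so downstream tests never
#' hard-code hidden numbers.
#'
#' @param sim result of [simulateDatabase()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeGenerativeSidecar <- function(sim, path) {
  jsonlite::write_json(list(
    seed = sim$seed, n = nRecords(sim$records),
    intercept = sim$model$b, coefficients = as.list(sim$model$k),
    realized_prevalence = mean(outcomeLabels(sim$records)),
    bayes_auc = sim$bayesAuc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
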