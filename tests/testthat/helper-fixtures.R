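# Shared fixtures, built once per test session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

fixtureChem <- function() cached("chem", syntheticChemLibrary)

fixtureHelix20 <- function() cached("helix20", function() makeIdealHelix(20))

fixtureHelix4 <- function() cached("helix4", function()
  makeIdealHelix(4, proteinId = "tet1"))

fixtureSheet <- function() cached("sheet", function() makeIdealSheet(8))

# a central alanine surrounded by a tight shell of alanines (steric burial)
fixtureCluster <- function() cached("cluster", function() {
  base <- makeIdealHelix(4)@atoms
  res1 <- base[base$resno == 2, ]
  shell <- list()
  k <- 0L
  for (dx in c(-5, 0, 5)) for (dy in c(-5, 0, 5)) for (dz in c(-5, 0, 5)) {
    k <- k + 1L
    r <- res1
    r$resno <- k
    r$x <- r$x + dx; r$y <- r$y + dy; r$z <- r$z + dz
    shell[[k]] <- r
  }
  atoms <- do.call(rbind, shell)
  structureModel(atoms, proteinId = "clu1")
})

# the standard synthetic world: a 60-residue helix covering all 20 NAAs and
# an 8+8 antiparallel sheet, both with simulated alignments
fixtureWorld <- function() cached("world", function() {
  chem <- fixtureChem()
  seq60 <- paste(rep(names(AA_ONE_TO_THREE), 3), collapse = "")
  helix <- makeIdealHelix(60, sequence = seq60, proteinId = "hel6")
  sheet <- makeIdealSheet(8, sequence = "ARNDCEQG", proteinId = "she8")
  profHelix <- syntheticProteinProfile(
    helix, conservation = withSeed(101, stats::runif(60, 0.4, 1)),
    depth = 30, seed = 11)
  profSheet <- syntheticProteinProfile(sheet, conservation = 0.7,
                                       depth = 30, seed = 12)
  list(chem = chem,
       profiles = list(hel6 = profHelix, she8 = profSheet),
       helix = helix, sheet = sheet)
})

# paper-scale simulated database (n = 1221, prevalence 0.87)
fixtureDbSmall <- function() cached("dbSmall", function() {
  w <- fixtureWorld()
  simulateDatabase(w$profiles, w$chem, n = 1221, seed = 42)
})

# large simulated database for recovery checks
fixtureDbLarge <- function() cached("dbLarge", function() {
  w <- fixtureWorld()
  simulateDatabase(w$profiles, w$chem, n = 5000, seed = 7)
})

# independent oracles ------------------------------------------------------

# pairwise-comparison AUC: P(p_success > p_failure) with ties counting 1/2
oracleAucPairwise <- function(y, p) {
  p1 <- p[y == 1]; p0 <- p[y == 0]
  s <- 0
  for (a in p1) s <- s + sum(a > p0) + 0.5 * sum(a == p0)
  s / (length(p1) * length(p0))
}

# brute-force best sensitivity+specificity over every candidate threshold
oracleCutoffEnumeration <- function(y, p) {
  cand <- sort(unique(c(0, 1, p, p - 1e-9, p + 1e-9)))
  best <- -Inf
  for (t in cand) {
    sens <- sum(p >= t & y == 1) / sum(y == 1)
    spec <- sum(p < t & y == 0) / sum(y == 0)
    if (sens + spec > best) best <- sens + spec
  }
  best
}

# dense-grid scan of sensitivity+specificity (10,001 thresholds)
oracleCutoffGrid <- function(y, p, nGrid = 10001) {
  ts <- seq(0, 1, length.out = nGrid)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  best <- -Inf
  for (t in ts) {
    j <- sum(p >= t & y == 1) / n1 + sum(p < t & y == 0) / n0
    if (j > best) best <- j
  }
  best
}

# brute-force half-sphere exposure from raw coordinates
oracleHSE <- function(model, radius = 12) {
  a <- model@atoms
  key <- paste(a$chain, a$resno, a$insert)
  resKeys <- unique(key)
  ca <- t(vapply(resKeys, function(k) {
    r <- a[key == k & a$elety == "CA", ]
    c(r$x[1], r$y[1], r$z[1])
  }, numeric(3)))
  dir <- t(vapply(resKeys, function(k) {
    r <- a[key == k, ]
    caR <- unlist(r[r$elety == "CA", c("x", "y", "z")])
    if ("CB" %in% r$elety) {
      unlist(r[r$elety == "CB", c("x", "y", "z")]) - caR
    } else {
      nR <- unlist(r[r$elety == "N", c("x", "y", "z")]) - caR
      cR <- unlist(r[r$elety == "C", c("x", "y", "z")]) - caR
      nR <- nR / sqrt(sum(nR^2)); cR <- cR / sqrt(sum(cR^2))
      b <- nR + cR
      -b / sqrt(sum(b^2))
    }
  }, numeric(3)))
  up <- dn <- integer(length(resKeys))
  for (i in seq_along(resKeys)) {
    for (j in seq_along(resKeys)) {
      if (i == j) next
      d <- ca[j, ] - ca[i, ]
      if (sum(d^2) <= radius^2) {
        if (sum(d * dir[i, ]) > 0) up[i] <- up[i] + 1L else dn[i] <- dn[i] + 1L
      }
    }
  }
  data.frame(key = resKeys, hsebup = up, hsebdn = dn)
}

# tiny feature matrix generator for model-level tests (no structures needed)
randomFeatureMatrix <- function(n, seed, b = 0, k = NULL,
                                efficiency = FALSE, sdLog = 0.05) {
  withSeed(seed, {
    cols <- featureColumns()
    X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
    X[, "entropy"] <- stats::runif(n, 0, 3)
    X[, "rasa"] <- stats::runif(n)
    X[, "hsebup"] <- stats::rpois(n, 6)
    X[, "hsebdn"] <- stats::rpois(n, 8)
    ss <- sample(c("helix", "strand", "turn", "coil"), n, TRUE)
    X[, "isHelix"] <- ss == "helix"
    X[, "isStrand"] <- ss == "strand"
    X[, "isTurn"] <- ss == "turn"
    X[, "uaasimi"] <- stats::runif(n)
    X[, "dAlogP"] <- stats::rnorm(n, 0, 1.5)
    X[, "dEstate"] <- stats::rnorm(n, 0, 10)
    X[, "dPSA"] <- stats::rnorm(n, 0, 40)
    X[, "dPolar"] <- stats::rnorm(n, 0, 15)
    X[, "dHBA"] <- sample(-2:4, n, TRUE)
    X[, "dHBD"] <- sample(-2:2, n, TRUE)
    X[, "dRB"] <- sample(0:8, n, TRUE)
    X[, "dMW"] <- stats::runif(n, -0.2, 2)
    cd <- sample(c("TAG", "TAA", "TGA", "other"), n, TRUE)
    X[, "isAmber"] <- cd == "TAG"
    X[, "isOchre"] <- cd == "TAA"
    X[, "isOpal"] <- cd == "TGA"
    pf <- sample(c("direct", "indirect", "other"), n, TRUE)
    X[, "isDirect"] <- pf == "direct"
    X[, "isIndirect"] <- pf == "indirect"
    if (is.null(k)) k <- rep(0, length(cols))
    eta <- b + drop(X %*% k)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    eff <- if (efficiency)
      pmax(0, exp(0.2 + 0.5 * drop(X %*% k) +
                    stats::rnorm(n, 0, sdLog)) - 1)
    else rep(NA_real_, n)
    methods::new("FeatureMatrix", X = X, y = as.integer(y),
                 recordId = sprintf("r%04d", seq_len(n)),
                 dates = as.Date("2010-01-01") + sample.int(3650, n, TRUE),
                 efficiency = eff, columnsVersion = featureColumnsVersion())
  })
}

# small record table for database-level tests
demoRecords <- function(n = 40, seed = 1) {
  withSeed(seed, {
    data.frame(
      protein_id = "hel6", chain = "A",
      position = as.character(sample(1:60, n, TRUE)),
      naa = sample(names(AA_THREE_TO_ONE), n, TRUE),
      uaa = sample(c("NAEK", "BocK", "pAcF"), n, TRUE),
      cdtype = sample(c("TAG", "TAA", "TGA", "other"), n, TRUE),
      outcome = sample(c("success", "failure"), n, TRUE, prob = c(0.8, 0.2)),
      prooflv = sample(c("direct", "indirect", "other"), n, TRUE),
      pub_date = as.character(as.Date("2005-01-01") +
                                sample.int(5000, n, TRUE)),
      efficiency = NA_real_, efficiency_quality = "none", viral = FALSE,
      structure_predicted = FALSE,
      source = sprintf("demo%03d", seq_len(n)), stringsAsFactors = FALSE)
  })
}
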