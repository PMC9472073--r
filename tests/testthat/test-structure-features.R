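# Structure parsing and the steric feature stack.

test_that("structures round-trip through PDB and mmCIF", {
  h <- fixtureHelix20()
  pdb <- tempfile(fileext = ".pdb"); writeStructurePDB(h, pdb)
  cif <- tempfile(fileext = ".cif"); writeStructureCIF(h, cif)
  h2 <- readStructure(pdb)
  h3 <- suppressWarnings(readStructure(cif))
  for (m in list(h2, h3)) {
    expect_identical(nrow(m@atoms), nrow(h@atoms))
    expect_identical(m@atoms$resno, h@atoms$resno)
    expect_identical(m@atoms$elety, h@atoms$elety)
    expect_lt(max(abs(as.matrix(m@atoms[, c("x", "y", "z")]) -
                        as.matrix(h@atoms[, c("x", "y", "z")]))), 1e-3)
  }
  expect_error(readStructure(pdb, chain = "Z"), "chain selection")
  noAtoms <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), noAtoms)
  expect_error(readStructure(noAtoms), "ATOM|parse")
})

test_that("Shrake-Rupley handles the no-occlusion and full-occlusion limits", {
  # two atoms far apart: each gets the full solvated-sphere area
  atoms <- data.frame(chain = "A", resno = 1:2, insert = "",
                      resid = "GLY", elety = c("CA", "CA"), element = "C",
                      x = c(0, 50), y = 0, z = 0)
  m <- structureModel(atoms)
  asa <- shrakeRupleyASA(m)
  expect_equal(asa, rep(4 * pi * (1.70 + 1.4)^2, 2), tolerance = 1e-9)
  # an atom enclosed by a tight shell is fully occluded
  shell <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(shell)), insert = "",
                      resid = "GLY", elety = "CA", element = "C",
                      x = shell$x, y = shell$y, z = shell$z)
  m <- structureModel(atoms)
  asa <- shrakeRupleyASA(m)
  center <- which(shell$x == 0 & shell$y == 0 & shell$z == 0)
  expect_equal(asa[center], 0)
  expect_error(
    shrakeRupleyASA(structureModel(transform(atoms, element = "XX"))),
    "radius")
})

test_that("960-point ASA agrees with the 10,000-point oracle within 2%", {
  for (model in list(fixtureHelix20(), fixtureHelix4(), fixtureSheet(),
                     fixtureCluster())) {
    a960 <- sum(shrakeRupleyASA(model, nPoints = 960))
    a10k <- sum(shrakeRupleyASA(model, nPoints = 10000))
    expect_lt(abs(a960 - a10k) / a10k, 0.02, label = model@proteinId)
  }
})

test_that("relative ASA is clamped, buried in clusters, exposed when solitary", {
  m <- fixtureHelix4()
  r <- relativeASA(m)
  expect_true(all(r$rasa >= 0 & r$rasa <= 1))
  # middle residue of a short solitary peptide is well exposed (vs oracle)
  r10k <- relativeASA(m, nPoints = 10000)
  expect_gt(r10k$rasa[2], 0.5)
  expect_equal(r$rasa, r10k$rasa, tolerance = 0.05)
  # central residue of the packed cluster is nearly fully buried
  clu <- fixtureCluster()
  rc <- relativeASA(clu, nPoints = 10000)
  central <- which.min(rowSums(scale(as.matrix(
    aggregate(cbind(x, y, z) ~ resno, clu@atoms, mean)[, -1]),
    scale = FALSE)^2))
  expect_lt(rc$rasa[central], 0.1)
  # clamping: a tiny reference maximum forces rasa to 1
  tiny <- stats::setNames(rep(1e-3, 20), names(AA_THREE_TO_ONE))
  expect_equal(unique(relativeASA(m, maxAsa = tiny)$rasa), 1)
  expect_error(relativeASA(structureModel(transform(m@atoms, resid = "UNK"))),
               "reference")
})

test_that("half-sphere exposure matches the brute-force oracle", {
  for (model in list(fixtureHelix20(), fixtureSheet())) {
    hse <- halfSphereExposure(model)
    orc <- oracleHSE(model)
    expect_identical(hse$hsebup, orc$hsebup)
    expect_identical(hse$hsebdn, orc$hsebdn)
    # partition conservation against a plain distance count
    a <- model@atoms
    ca <- a[a$elety == "CA", c("x", "y", "z")]
    for (i in seq_len(nrow(ca))) {
      d2 <- rowSums(sweep(as.matrix(ca), 2, as.numeric(ca[i, ]))^2)
      expect_identical(hse$hsebup[i] + hse$hsebdn[i],
                       as.integer(sum(d2 <= 144) - 1L))
    }
  }
})

test_that("an isolated residue has an empty half-sphere neighborhood", {
  m <- fixtureHelix4()
  one <- structureModel(m@atoms[m@atoms$resno == 2, ])
  hse <- halfSphereExposure(one)
  expect_identical(hse$hsebup, 0L)
  expect_identical(hse$hsebdn, 0L)
})

test_that("secondary structure recovers ideal helix and sheet geometry", {
  ss <- assignSecondaryStructure(fixtureHelix20())
  interior <- 3:18
  expect_gte(mean(ss$sstype[interior] == "helix"), 0.8)
  # chain termini without qualifying hydrogen bonds stay non-helix
  expect_true(ss$sstype[1] != "helix")
  sh <- assignSecondaryStructure(fixtureSheet())
  expect_gte(mean(sh$sstype == "strand"), 0.6)
})

test_that("external DSSP letters reduce to the 3-class scheme", {
  m <- fixtureHelix4()
  dssp <- tempfile(fileext = ".dssp")
  hdr <- c("==== Secondary Structure Definition ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  rows <- sprintf("%5d%5d %s %s  %s", 1:4, 1:4, "A",
                  c("A", "A", "A", "A"), c("H", "E", "T", " "))
  writeLines(c(hdr, rows), dssp)
  ss <- assignSecondaryStructure(m, dsspFile = dssp)
  expect_identical(ss$sstype, c("helix", "strand", "turn", "coil"))
  bad <- tempfile(); writeLines("not a dssp file", bad)
  expect_error(assignSecondaryStructure(m, dsspFile = bad), "DSSP")
})

test_that("site profiles assemble, map entropy and round-trip as CSV", {
  w <- fixtureWorld()
  prof <- w$profiles$hel6
  d <- prof@data
  expect_identical(nrow(d), 60L)
  expect_true(all(!is.na(d$entropy)))
  expect_true(all(d$rasa >= 0 & d$rasa <= 1))
  f <- tempfile(fileext = ".csv")
  writeSiteFeatures(prof, f)
  prof2 <- readSiteFeatures(f)
  expect_identical(prof2@proteinId, prof@proteinId)
  expect_equal(prof2@data$entropy, d$entropy, tolerance = 1e-12)
  expect_identical(prof2@data$sstype, d$sstype)
  # entropy mapping respects an author-numbering offset
  m <- w$helix
  shifted <- m@atoms; shifted$resno <- shifted$resno + 99L
  ms <- structureModel(shifted, proteinId = "off1")
  qs <- chainSequence(m, "A")
  ent <- stats::setNames(seq(0, 1, length.out = 60), as.character(1:60))
  ps <- siteFeatureProfile(ms, entropy = ent, querySeq = qs, nPoints = 96)
  expect_equal(ps@data$entropy, as.numeric(ent), tolerance = 1e-12)
})
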