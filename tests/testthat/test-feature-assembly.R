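# The 21-column feature encoding.

test_that("assembleRow encodes dummies and chemistry as specified", {
  chem <- fixtureChem()
  site <- list(entropy = 1.2, rasa = 0.5, hsebup = 4, hsebdn = 9,
               sstype = "helix")
  rec <- list(protein_id = "hel6", chain = "A", position = "5",
              naa = "LYS", uaa = "NAEK", cdtype = "TAG", prooflv = "direct")
  v <- assembleRow(rec, site, chem)
  expect_identical(names(v), featureColumns())
  expect_equal(v[["isAmber"]], 1); expect_equal(v[["isOchre"]], 0)
  expect_equal(v[["isOpal"]], 0)
  expect_equal(v[["isDirect"]], 1); expect_equal(v[["isIndirect"]], 0)
  expect_equal(v[["isHelix"]], 1)
  expect_equal(v[["dMW"]],
               descriptorDelta("NAEK", "LYS", library = chem)[["dMW"]])
  # reference levels are all-zero dummy groups
  rec2 <- modifyList(rec, list(cdtype = "other", prooflv = "other"))
  site2 <- modifyList(site, list(sstype = "coil"))
  v2 <- assembleRow(rec2, site2, chem)
  expect_equal(unname(v2[c("isHelix", "isStrand", "isTurn", "isAmber",
                           "isOchre", "isOpal", "isDirect", "isIndirect")]),
               rep(0, 8))
  # self-substitution: zero deltas, unit similarity
  rec3 <- modifyList(rec, list(naa = "LYS", uaa = "LYS"))
  v3 <- assembleRow(rec3, site, chem)
  expect_equal(unname(v3[paste0("d", c("AlogP", "Estate", "PSA", "Polar",
                                       "HBA", "HBD", "RB", "MW"))]),
               rep(0, 8))
  expect_equal(v3[["uaasimi"]], 1)
  # absolute-delta preprocessing mode
  vAbs <- assembleRow(rec, site, chem, absoluteDeltas = TRUE)
  expect_equal(vAbs[["dAlogP"]], abs(v[["dAlogP"]]))
  # missing site features are a hard error, never imputed
  expect_error(assembleRow(rec, modifyList(site, list(rasa = NA)), chem),
               "missing site feature")
})

test_that("dummy encoding is injective over all categorical levels", {
  chem <- fixtureChem()
  site <- list(entropy = 0.3, rasa = 0.9, hsebup = 2, hsebdn = 3,
               sstype = "turn")
  for (ss in c("helix", "strand", "turn", "coil"))
    for (cd in c("TAG", "TAA", "TGA", "other"))
      for (pf in c("direct", "indirect", "other")) {
        v <- assembleRow(list(naa = "ALA", uaa = "AHA", cdtype = cd,
                              prooflv = pf),
                         modifyList(site, list(sstype = ss)), chem)
        dec <- decodeDummies(v)
        expect_identical(dec$sstype, ss)
        expect_identical(dec$cdtype, cd)
        expect_identical(dec$prooflv, pf)
      }
})

test_that("assembleMatrix matches row-wise assembly and labels counts", {
  sim <- fixtureDbSmall()
  fm <- sim$features
  expect_identical(dim(fm@X), c(1221L, 21L))
  expect_identical(colnames(fm@X), featureColumns())
  expect_false(anyNA(fm@X))
  expect_identical(sum(fm@y), sum(records(sim$records)$outcome == "success"))
  # spot-check consistency with assembleRow
  w <- fixtureWorld()
  r <- records(sim$records)
  idx <- withSeed(3, sample.int(nrow(r), 12))
  for (i in idx) {
    prof <- w$profiles[[r$protein_id[i]]]@data
    j <- which(prof$chain == r$chain[i] & prof$position == r$position[i])
    v <- assembleRow(r[i, ], prof[j, ], w$chem)
    expect_equal(unname(v), unname(fm@X[i, ]), tolerance = 1e-12)
  }
})

test_that("assembly fails fast with a consolidated offender list", {
  w <- fixtureWorld()
  r <- demoRecords(6, seed = 10)
  prof <- w$profiles$hel6@data
  r$naa <- prof$aa[match(r$position, prof$position)]
  r$position[2] <- "999"           # site absent
  r$naa[4] <- setdiff(names(AA_THREE_TO_ONE), r$naa[4])[1]  # mismatch
  err <- tryCatch(
    assembleMatrix(recordSet(r), w$profiles, w$chem),
    error = conditionMessage)
  expect_match(err, "record 2")
  expect_match(err, "record 4")
  empty <- recordSet(demoRecords(5, seed = 10))[integer(0)]
  expect_error(assembleMatrix(empty, w$profiles, w$chem), "0 records")
})

test_that("small samples trigger the 10-rows-per-column warning", {
  w <- fixtureWorld()
  r <- demoRecords(30, seed = 11)
  prof <- w$profiles$hel6@data
  r$naa <- prof$aa[match(r$position, prof$position)]
  r <- r[!is.na(r$naa), ]
  expect_warning(assembleMatrix(recordSet(r), w$profiles, w$chem),
                 "10 rows per feature column")
})

test_that("feature matrices round-trip through CSV", {
  fm <- randomFeatureMatrix(40, seed = 12)
  f <- tempfile(fileext = ".csv")
  writeFeatureMatrix(fm, f)
  fm2 <- readFeatureMatrix(f)
  expect_equal(fm2@X, fm@X, tolerance = 1e-10)
  expect_identical(fm2@y, fm@y)
  expect_identical(fm2@recordId, fm@recordId)
})
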