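# Record database: loading rules, subsets, balancing, splitting.

test_that("inclusion rules reject short proteins, D-form UAAs and NAA mismatches", {
  w <- fixtureWorld()
  # she8 has 8 residues per chain -> shorter than 50 -> rejected
  r <- demoRecords(10, seed = 2)
  prof <- w$profiles$hel6
  d <- prof@data
  r$naa <- d$aa[match(r$position, d$position)]   # consistent NAAs
  r <- r[!is.na(r$naa), ]
  short <- r[1, ]; short$protein_id <- "she8"; short$chain <- "A"
  short$position <- "2"; short$naa <- "ARG"; short$source <- "short1"
  mism <- r[2, ]
  mism$naa <- setdiff(names(AA_THREE_TO_ONE), mism$naa)[1]
  mism$source <- "mism1"
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rbind(r, short, mism), f, row.names = FALSE)
  rs <- suppressMessages(loadRecords(f, proteins = w$profiles, chem = w$chem))
  rej <- attr(rs, "rejected")
  expect_identical(nRecords(rs), nrow(r))
  expect_setequal(rej$source, c("short1", "mism1"))
  expect_match(rej$reason[rej$source == "short1"], "50 residues")
  expect_match(rej$reason[rej$source == "mism1"], "mismatch")
  # D-form UAA rejection
  chemD <- w$chem
  chemD@specs$chirality[chemD@specs$code == "pAcF"] <- "D"  # bypass validity
  rD <- r; rD$uaa <- "pAcF"; rD$source <- paste0("D", seq_len(nrow(rD)))
  utils::write.csv(rD, f, row.names = FALSE)
  rsD <- suppressMessages(loadRecords(f, proteins = w$profiles, chem = chemD))
  expect_identical(nRecords(rsD), 0L)
  expect_true(all(attr(rsD, "rejected")$reason == "D-form UAA"))
  # unregistered references are hard errors
  rU <- r; rU$uaa[1] <- "NOPE"
  utils::write.csv(rU, f, row.names = FALSE)
  expect_error(loadRecords(f, chem = w$chem), "NOPE")
})

test_that("the efficiency threshold rule is strict at 0.01", {
  expect_identical(outcomeFromEfficiency(0.02), "success")
  expect_identical(outcomeFromEfficiency(0.01), "failure")
  expect_identical(outcomeFromEfficiency(0), "failure")
  expect_identical(outcomeFromEfficiency(c(0.5, 0.001)),
                   c("success", "failure"))
  expect_error(outcomeFromEfficiency(-0.1), ">= 0")
})

test_that("named subsets filter correctly and idempotently", {
  rs <- recordSet(demoRecords(60, seed = 3), label = "demo")
  amber <- selectSubset(rs, "amber")
  expect_true(all(records(amber)$cdtype == "TAG"))
  expect_identical(records(selectSubset(amber, "amber")), records(amber))
  nonviral <- selectSubset(rs, "non_viral")
  expect_true(all(!records(nonviral)$viral))
  expect_warning(empty <- selectSubset(rs, "exact_yield"), "empty")
  expect_identical(nRecords(empty), 0L)
  expect_error(selectSubset(rs, "no_such_subset"))
  # non-redundant keeps the earliest record per (protein, chain, pos, uaa)
  r <- records(rs)
  nr <- selectSubset(rs, "non_redundant")
  key <- function(d) paste(d$protein_id, d$chain, d$position, d$uaa)
  expect_false(anyDuplicated(key(records(nr))) > 0)
  expect_true(all(key(records(nr)) %in% key(r)))
})

test_that("balanced subsets equalize classes deterministically", {
  rs <- recordSet(demoRecords(200, seed = 4), label = "demo")
  y <- outcomeLabels(rs)
  b1 <- balancedSubset(rs, seed = 0)
  b2 <- balancedSubset(rs, seed = 0)
  expect_identical(records(b1), records(b2))
  yb <- outcomeLabels(b1)
  expect_identical(sum(yb == 1), sum(yb == 0))
  expect_identical(nRecords(b1), 2L * min(table(y)))
  # 1064/157-style imbalance gives 157 + 157
  big <- demoRecords(200, seed = 5)
  big$outcome <- rep(c("success", "failure"), c(170, 30))
  bb <- balancedSubset(recordSet(big), seed = 1)
  expect_identical(nRecords(bb), 60L)
  # over 100 seeds every majority record is drawn at least once
  drawn <- unique(unlist(lapply(0:99, function(s)
    records(balancedSubset(rs, s))$source)))
  expect_setequal(drawn, records(rs)$source)
  oneClass <- recordSet(transform(demoRecords(20, 6), outcome = "success"))
  expect_error(balancedSubset(oneClass, 0), "both")
})

test_that("holdout splits partition exactly with round-half-up sizing", {
  rs <- recordSet(demoRecords(100, seed = 7), label = "demo")
  sp <- splitRecords(rs, "holdout", trainFraction = 0.8, seed = 0)
  expect_identical(nRecords(sp$train), 80L)
  expect_identical(nRecords(sp$test), 20L)
  expect_length(intersect(records(sp$train)$source,
                          records(sp$test)$source), 0)
  expect_setequal(c(records(sp$train)$source, records(sp$test)$source),
                  records(rs)$source)
  sp2 <- splitRecords(rs, "holdout", trainFraction = 0.8, seed = 0)
  expect_identical(records(sp2$train), records(sp$train))
  sp3 <- splitRecords(rs, "holdout", trainFraction = 0.8, seed = 1)
  expect_false(identical(records(sp3$train), records(sp$train)))
  # round half up: 0.805 * 31 = 24.955 -> 25; 0.85*30 = 25.5 -> 26
  expect_identical(nRecords(splitRecords(rs[1:30], "holdout",
                                         trainFraction = 0.85,
                                         seed = 0)$train), 26L)
  # random partitions always reunite to the input
  for (s in 1:5) {
    spr <- splitRecords(rs, "holdout", trainFraction = 0.37, seed = s)
    expect_setequal(c(records(spr$train)$source, records(spr$test)$source),
                    records(rs)$source)
  }
})

test_that("timesplit respects the strict date rule and range checks", {
  r <- demoRecords(50, seed = 8)
  r$pub_date <- as.character(as.Date("2015-01-01") + seq(0, 2000,
                                                         length.out = 50))
  r$pub_date[3] <- "2017-12-31"
  rs <- recordSet(r)
  sp <- splitRecords(rs, "timesplit", splitDate = "2018-01-01")
  expect_true("2017-12-31" %in% as.character(records(sp$train)$pub_date))
  expect_true(all(records(sp$train)$pub_date < as.Date("2018-01-01")))
  expect_true(all(records(sp$test)$pub_date >= as.Date("2018-01-01")))
  expect_identical(nRecords(sp$train) + nRecords(sp$test), nRecords(rs))
  expect_error(splitRecords(rs, "timesplit", splitDate = "2030-01-01"),
               "outside")
  rNA <- r; rNA$pub_date[5] <- NA
  expect_warning(spNA <- splitRecords(recordSet(rNA), "timesplit",
                                      splitDate = "2018-01-01"),
                 "without pub_date")
  expect_identical(nRecords(spNA$train) + nRecords(spNA$test), 49L)
})
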