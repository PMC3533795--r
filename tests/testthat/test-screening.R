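test_that("normalization does background subtraction and percent-of-control", {
  scr <- PLDScreen(tinyWells())
  norm <- normalizeWells(scr)
  # background mean 50, control mean 150: raw 250 -> 200, raw 150 -> 100
  expect_equal(norm$percent_of_control[norm$compound_id == "drugA"],
               c(200, 200))
  expect_equal(norm$percent_of_control[norm$compound_id == "drugB"],
               c(100, 100))

  # raw equal to control mean with zero background -> 100; raw = background -> 0
  w <- percentScaleWells(c(100, 0), compound = c("atCtrl", "atBg"))
  norm <- normalizeWells(PLDScreen(w))
  expect_equal(norm$percent_of_control[norm$compound_id == "atCtrl"], 100)
  expect_equal(norm$percent_of_control[norm$compound_id == "atBg"], 0)
})

test_that("normalization errors name the offending plate", {
  w <- tinyWells()
  expect_error(normalizeWells(PLDScreen(w[w$role != "background", ])),
               "background.*P1")
  expect_error(normalizeWells(PLDScreen(w[w$role != "control", ])),
               "control.*P1")
  # control mean at/below background mean: uninterpretable plate
  w2 <- tinyWells()
  w2$fluorescence[w2$role == "control"] <- c(40, 60)
  expect_error(normalizeWells(PLDScreen(w2)), "uninterpretable")
})

test_that("sub-background wells are clamped to zero with a warning", {
  w <- tinyWells()
  w$fluorescence[w$compound_id == "drugB"] <- c(10, 20)  # below bg mean 50
  expect_warning(norm <- normalizeWells(PLDScreen(w)), "clamped")
  expect_equal(norm$percent_of_control[norm$compound_id == "drugB"], c(0, 0))
})

test_that("normalization is invariant to rescaling a whole plate", {
  base <- tinyWells()
  for (k in c(0.25, 3, 1700)) {
    w <- base
    w$fluorescence <- w$fluorescence * k
    expect_equal(normalizeWells(PLDScreen(w))$percent_of_control,
                 normalizeWells(PLDScreen(base))$percent_of_control,
                 tolerance = 1e-12)
  }
})

test_that("plates and channels are normalized independently", {
  w1 <- tinyWells()
  w2 <- tinyWells()
  w2$plate_id <- "P2"
  w2$fluorescence <- w2$fluorescence * 10  # different gain, same percentages
  norm <- normalizeWells(PLDScreen(rbind(w1, w2)))
  a <- norm[norm$compound_id == "drugA", ]
  expect_equal(a$percent_of_control[a$plate_id == "P1"],
               a$percent_of_control[a$plate_id == "P2"], tolerance = 1e-12)
})

test_that("replicate summaries use the mean and the sample (n-1) SD", {
  summ <- summarizeScreen(PLDScreen(percentScaleWells(
    rep(100, 4), compound = rep("flat", 4))))
  tab <- screenTable(summ)
  expect_equal(tab$percent_of_control, 100)
  expect_equal(tab$sd, 0)
  expect_equal(tab$cv, 0)
  expect_false(tab$pld_active)

  summ <- summarizeScreen(PLDScreen(percentScaleWells(
    c(90, 100, 110, 100), compound = rep("mid", 4))))
  tab <- screenTable(summ)
  expect_equal(tab$percent_of_control, 100)
  expect_equal(tab$sd, 8.164966, tolerance = 1e-6)
  expect_equal(tab$cv, 0.08164966, tolerance = 1e-6)
  expect_equal(tab$n, 4L)
})

test_that("a single replicate reports undefined dispersion, not zero", {
  summ <- summarizeScreen(PLDScreen(percentScaleWells(150, compound = "solo")))
  tab <- screenTable(summ)
  expect_equal(tab$n, 1L)
  expect_true(is.na(tab$sd))
  expect_true(is.na(tab$cv))
})

test_that("a noiseless strong inducer is summarized and called active", {
  # quadruplicate at 740.5% with zero noise, tamoxifen-like
  summ <- summarizeScreen(PLDScreen(percentScaleWells(
    rep(740.5, 4), compound = rep("strong", 4))))
  tab <- screenTable(summ)
  expect_equal(tab$percent_of_control, 740.5)
  expect_true(tab$pld_active)
})

test_that("activity calls are strict at the threshold", {
  expect_identical(classifyPld(c(200, 900.2, 114, 200.0001)),
                   c(FALSE, TRUE, FALSE, TRUE))
  expect_error(classifyPld(-1), ">= 0")
  expect_false(classifyPld(250, threshold = 300))
})

test_that("raising the threshold never enlarges the active set", {
  set.seed(4)
  pct <- runif(300, 0, 1000)
  thresholds <- c(150, 200, 250, 300, 500)
  for (i in seq_len(length(thresholds) - 1)) {
    lo <- classifyPld(pct, thresholds[i])
    hi <- classifyPld(pct, thresholds[i + 1])
    expect_true(all(lo | !hi))  # active(hi) subset of active(lo)
  }
})

test_that("DAPI wells feed the summary's dapi_percent", {
  w <- rbind(percentScaleWells(rep(300, 2), compound = rep("x", 2)),
             percentScaleWells(c(90, 110), compound = rep("x", 2),
                               channel = "dapi"))
  tab <- screenTable(summarizeScreen(PLDScreen(w)))
  expect_equal(tab$dapi_percent, 100)
  # no DAPI wells at all -> NA
  tab2 <- screenTable(summarizeScreen(PLDScreen(percentScaleWells(300))))
  expect_true(is.na(tab2$dapi_percent))
})

test_that("consistency report compares the two concentrations", {
  # identical effects at both concentrations
  scr <- quadScreen(rep(300, 4), rep(300, 4))
  rep0 <- consistencyReport(summarizeScreen(scr))
  expect_identical(rep0@inclusionViolations, character(0))
  expect_equal(rep0@meanEffectIncrease, 0)
  expect_equal(rep0@nIncreasing, 0L)

  # tamoxifen-like pair: 740.5 -> 900.2 is an increase of 159.7 points
  scr <- quadScreen(rep(740.5, 4), rep(900.2, 4))
  rep1 <- consistencyReport(summarizeScreen(scr))
  expect_equal(rep1@meanEffectIncrease, 159.7, tolerance = 1e-9)
  expect_equal(rep1@nIncreasing, 1L)
  expect_equal(rep1@nActiveHigh, 1L)

  # ratio scale is available as an alternative reading
  rep2 <- consistencyReport(summarizeScreen(scr), scale = "ratio")
  expect_equal(rep2@meanEffectIncrease, 900.2 / 740.5, tolerance = 1e-9)

  # active at low but not high concentration is an inclusion violation
  scr <- quadScreen(rep(300, 4), rep(150, 4))
  rep3 <- consistencyReport(summarizeScreen(scr))
  expect_identical(rep3@inclusionViolations, "drugA")
})

test_that("consistency report refuses mismatched compound sets", {
  w <- rbind(percentScaleWells(300, compound = "onlyLow"),
             data.frame(plate_id = "P1", compound_id = "other",
                        concentration_uM = 5, channel = "lipidtox",
                        replicate = 1, role = "test", fluorescence = 300,
                        stringsAsFactors = FALSE))
  expect_error(consistencyReport(summarizeScreen(PLDScreen(w))), "onlyLow")
})

test_that("DAPI QC flags losses and reports group means", {
  w <- rbind(percentScaleWells(c(300, 120), compound = c("act", "inact")),
             percentScaleWells(c(100, 100), compound = c("act", "inact"),
                               channel = "dapi"))
  qc <- dapiQc(summarizeScreen(PLDScreen(w)))
  expect_equal(nrow(qc@dapiFlags), 0L)
  gm <- qc@dapiGroupMeans
  expect_setequal(gm$group, c("active", "inactive", "total"))
  expect_equal(gm$mean, rep(100, 3))

  # a compound at 40% of control cells is flagged at the default threshold
  w$fluorescence[w$channel == "dapi" & w$compound_id == "inact"] <- 40
  qc2 <- dapiQc(summarizeScreen(PLDScreen(w)))
  expect_equal(qc2@dapiFlags$compound_id, "inact")
  # missing DAPI data is an error naming the compound
  w3 <- percentScaleWells(300, compound = "noDapi")
  expect_error(dapiQc(summarizeScreen(PLDScreen(w3))), "noDapi")
})

test_that("well tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tinyWells(), path, row.names = FALSE)
  scr <- readWellTable(path)
  expect_s4_class(scr, "PLDScreen")
  expect_equal(nrow(wells(scr)), 8L)
  out <- withr::local_tempfile(fileext = ".csv")
  writeSummaryTable(summarizeScreen(scr), out)
  back <- utils::read.csv(out)
  expect_equal(back$percent_of_control[back$compound_id == "drugA"], 200)
})

test_that("screen validity catches malformed well tables", {
  w <- tinyWells()
  w$fluorescence[1] <- -5
  expect_error(PLDScreen(w), ">= 0")
  w <- tinyWells()
  w$concentration_uM[w$role == "test"] <- 0
  expect_error(PLDScreen(w), "concentration")
  w <- tinyWells()
  w$replicate <- 1  # duplicate replicate ids
  expect_error(PLDScreen(w), "unique")
})
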