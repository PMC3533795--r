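test_that("the generator is a pure function of its configuration", {
  s1 <- simulateScreen(syntheticConfig(seed = 5, nCompounds = 60))
  s2 <- simulateScreen(syntheticConfig(seed = 5, nCompounds = 60))
  expect_identical(wells(s1$screen), wells(s2$screen))
  expect_identical(s1$properties, s2$properties)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulateScreen(syntheticConfig(seed = 6, nCompounds = 60))
  expect_false(identical(wells(s1$screen), wells(s3$screen)))
})

test_that("an empty screen configuration yields empty tables", {
  comp <- genCompounds(syntheticConfig(nCompounds = 0))
  expect_equal(nrow(comp$properties), 0L)
  expect_length(comp$labels, 0L)
})

test_that("the planted active count follows the configured fraction", {
  comp <- genCompounds(syntheticConfig(seed = 2))
  expect_equal(sum(comp$trueLabels), 55L)  # floor(55/297 * 297)
  expect_equal(length(comp$trueLabels), 297L)
  # label noise flips the requested fraction
  compN <- genCompounds(syntheticConfig(seed = 2, labelNoise = 0.1))
  expect_equal(sum(compN$labels != compN$trueLabels), round(0.1 * 297))
})

test_that("a noiseless screen reproduces latent effects exactly", {
  cfg <- syntheticConfig(seed = 9, nCompounds = 80, cvLow = 0, cvHigh = 0,
                         dapiSd = 0)
  sim <- simulateScreen(cfg)
  tab <- screenTable(summarizeScreen(sim$screen))
  inact <- names(sim$trueLabels)[!sim$trueLabels]
  # inactive compounds sit exactly at 100% of control
  expect_equal(tab$percent_of_control[tab$compound_id %in% inact],
               rep(100, 2 * length(inact)), tolerance = 1e-9)
  # recovered active set equals the planted set at both concentrations
  for (conc in c(2.5, 5)) {
    act <- pldActive(summarizeScreen(sim$screen), conc)
    expect_identical(unname(act[names(sim$trueLabels)]),
                     unname(sim$trueLabels))
  }
})

test_that("replicate noise calibration is recovered from quadruplicates", {
  # two seeds here; the full 20-seed 3-standard-error check is in the
  # acceptance suite
  cvs <- vapply(1:2, function(s) {
    sim <- simulateScreen(syntheticConfig(seed = s))
    tab <- screenTable(summarizeScreen(sim$screen))
    inact <- names(sim$trueLabels)[!sim$trueLabels]
    mean(tab$cv[tab$compound_id %in% inact & tab$concentration_uM == 2.5])
  }, numeric(1))
  expect_gt(mean(cvs), 0.06)
  expect_lt(mean(cvs), 0.095)
})

test_that("zero concentration-doubling effect gives a flat consistency report", {
  cfg <- syntheticConfig(seed = 10, nCompounds = 80, deltaMean = 0,
                         deltaSd = 0, cvLow = 0, cvHigh = 0)
  rep0 <- consistencyReport(summarizeScreen(simulateScreen(cfg)$screen))
  expect_equal(rep0@meanEffectIncrease, 0, tolerance = 1e-9)
})

test_that("plates respect the round-robin capacity", {
  sim <- simulateScreen(syntheticConfig(seed = 4))
  w <- wells(sim$screen)
  perPlate <- tapply(w$compound_id[w$role == "test"],
                     w$plate_id[w$role == "test"],
                     function(x) length(unique(x)))
  expect_true(all(perPlate <= 80))
  expect_equal(length(perPlate), 4L)  # ceiling(297 / 80)
})

test_that("annotation concordance controls association strength", {
  # perfect concordance gives the strongest attainable association
  cfg1 <- syntheticConfig(seed = 11, annotationConcordance = 1)
  sim <- simulateScreen(cfg1)
  asm <- stats::setNames(sim$annotations$asm_inhibitor,
                         sim$annotations$compound_id)
  expect_identical(unname(asm[names(sim$trueLabels)]),
                   unname(sim$trueLabels))
  r <- associate(sim$trueLabels, asm)
  expect_lt(pValue(r), 1e-10)

  # 0.5 concordance is the null: mostly non-significant
  hits <- vapply(1:20, function(s) {
    sim <- simulateScreen(syntheticConfig(seed = s, nCompounds = 150,
                                          annotationConcordance = 0.5))
    asm <- stats::setNames(sim$annotations$asm_inhibitor,
                           sim$annotations$compound_id)
    pValue(associate(sim$trueLabels, asm)) < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("ATC classes are enriched for actives where designed", {
  sim <- simulateScreen(syntheticConfig(seed = 12))
  act <- sim$trueLabels
  cls <- atcSecondLevel(vapply(strsplit(sim$annotations$atc_codes, ";"),
                               `[`, character(1), 1))
  inN0 <- cls %in% c("N05", "N06")
  expect_gt(mean(inN0[act[sim$annotations$compound_id]]),
            mean(inN0[!act[sim$annotations$compound_id]]))
})

test_that("generated wells always satisfy the container invariants", {
  for (s in 1:3) {
    sim <- simulateScreen(syntheticConfig(seed = s, nCompounds = 50))
    expect_true(validObject(sim$screen))
    w <- wells(sim$screen)
    expect_true(all(w$fluorescence >= 0))
    expect_equal(sort(unique(w$role)), c("background", "control", "test"))
  }
})
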