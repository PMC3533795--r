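# small planted-signal fixture: one informative descriptor among noise
plantedMatrix <- function(n = 100, p = 12, seed = 41) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n,
              dimnames = list(NULL, sprintf("noise%02d", seq_len(p))))
  x <- cbind(signal = rnorm(n), x)
  list(x = x, y = x[, "signal"] > 0.25)
}

test_that("prefilter ranks separating descriptors first and prunes", {
  pm <- plantedMatrix()
  x <- cbind(pm$x, label_copy = as.numeric(pm$y))
  xf <- prefilterDescriptors(x, pm$y, k = 5)
  expect_identical(colnames(xf)[1], "label_copy")
  expect_true("signal" %in% colnames(xf))

  # duplicated column: exactly one member of the pair survives
  x2 <- cbind(pm$x, signal_dup = pm$x[, "signal"])
  xf2 <- prefilterDescriptors(x2, pm$y, k = ncol(x2))
  expect_true(xor("signal" %in% colnames(xf2),
                  "signal_dup" %in% colnames(xf2)))

  # constant columns are dropped; an all-constant matrix errors
  x3 <- cbind(pm$x, flat = 1)
  expect_false("flat" %in% colnames(prefilterDescriptors(x3, pm$y, k = 20)))
  expect_error(prefilterDescriptors(matrix(1, 10, 2,
    dimnames = list(NULL, c("a", "b"))), rep(c(TRUE, FALSE), 5)), "constant")
})

test_that("prefilter recovers planted descriptors among many noise columns", {
  set.seed(42)
  n <- 100
  noise <- matrix(rnorm(n * 500), n,
                  dimnames = list(NULL, sprintf("r%03d", 1:500)))
  s1 <- rnorm(n); s2 <- rnorm(n)
  y <- (s1 + s2) > 0
  x <- cbind(noise, planted1 = s1, planted2 = s2)
  xf <- prefilterDescriptors(x, y, k = 113)
  expect_true(all(c("planted1", "planted2") %in% colnames(xf)))
})

test_that("forest training is deterministic and fits separable data", {
  pm <- plantedMatrix()
  f1 <- trainRf(pm$x, pm$y, "signal", rfConfig(seed = 9))
  f2 <- trainRf(pm$x, pm$y, "signal", rfConfig(seed = 9))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$accuracyResub, f2$accuracyResub)
  f3 <- trainRf(pm$x, pm$y, "signal", rfConfig(seed = 10))
  # a single thresholded descriptor is realized by a depth-bounded tree
  expect_equal(f1$accuracyResub, 1.0)
  expect_equal(f3$accuracyResub, 1.0)

  # degenerate but defined: constant labels
  expect_equal(trainRf(pm$x, rep(TRUE, nrow(pm$x)), "signal",
                       rfConfig())$accuracyResub, 1.0)
  expect_error(trainRf(pm$x, pm$y, character(0)), "empty")
  expect_error(trainRf(pm$x, pm$y, "nope"), "nope")
})

test_that("forest predictions agree with an independent implementation", {
  # ranger with identical hyperparameters is the cross-check, not the engine
  pm <- plantedMatrix(n = 150)
  fit <- trainRf(pm$x, pm$y, c("signal", "noise01"), rfConfig(seed = 2))
  rf <- ranger::ranger(x = as.data.frame(pm$x[, c("signal", "noise01")]),
                       y = factor(pm$y), num.trees = 5, max.depth = 8,
                       mtry = 2, num.threads = 1, seed = 2)
  rpred <- predict(rf, as.data.frame(pm$x[, c("signal", "noise01")]),
                   num.threads = 1)$predictions == "TRUE"
  # both memorize the separable training set near-perfectly
  expect_gt(mean(fit$predictions == pm$y), 0.97)
  expect_gt(mean(rpred == pm$y), 0.97)
  expect_gt(mean(fit$predictions == rpred), 0.95)
})

test_that("beam search recovers a planted threshold rule and stops", {
  pm <- plantedMatrix()
  cands <- beamSearch(pm$x, pm$y, rfConfig(), maxSize = 4, seeds = 1)
  expect_true(length(cands) >= 1)
  top <- cands[[1]]
  expect_true("signal" %in% modelSubset(top))
  expect_equal(top@accuracyResub, 1.0)  # the stop rule fired
  # a size-1 or size-2 subset suffices for a single threshold rule
  expect_lte(length(modelSubset(top)), 2L)
})

test_that("beam search unions candidates across seeds with seeds recorded", {
  pm <- plantedMatrix(n = 60, p = 6)
  cands <- beamSearch(pm$x, pm$y, rfConfig(), maxSize = 2, seeds = c(1, 2))
  expect_true(all(vapply(cands, function(x) x@seed %in% c(1, 2), logical(1))))
  keys <- vapply(cands, function(x) paste(sort(modelSubset(x)), collapse = ";"),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("pure-noise searches still return best-found candidates", {
  set.seed(43)
  n <- 50
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, sprintf("n%d", 1:6)))
  y <- rep(c(TRUE, FALSE), n / 2)
  cands <- beamSearch(x, y, rfConfig(), maxSize = 3, seeds = 1)
  expect_true(length(cands) >= 1)
  expect_true(all(vapply(cands, function(cc) cc@accuracyResub <= 1, logical(1))))
})

test_that("out-of-bootstrap scoring never sees training compounds", {
  pm <- plantedMatrix()
  cand <- beamSearch(pm$x, pm$y, rfConfig(), maxSize = 2, seeds = 1)[[1]]
  v <- bootstrapValidate(pm$x, pm$y, cand, nBoot = 30, seed = 5,
                         keepIndices = TRUE)
  its <- attr(v, "iterations")
  expect_length(its, 30)
  for (it in its) {
    expect_length(intersect(it$train, it$test), 0)
    expect_setequal(union(it$train, it$test), seq_len(nrow(pm$x)))
  }
  # planted signal validates far above chance
  expect_gt(validatedAccuracy(v), 0.9)
  # the out-of-bootstrap fraction hovers near exp(-1)
  expect_gt(v@oobFraction, 0.30)
  expect_lt(v@oobFraction, 0.44)
})

test_that("bootstrap validation is reproducible and guards bad input", {
  pm <- plantedMatrix(n = 60, p = 4)
  cand <- beamSearch(pm$x, pm$y, rfConfig(), maxSize = 1, seeds = 1)[[1]]
  v1 <- bootstrapValidate(pm$x, pm$y, cand, nBoot = 1, seed = 7)
  v2 <- bootstrapValidate(pm$x, pm$y, cand, nBoot = 1, seed = 7)
  expect_identical(validatedAccuracy(v1), validatedAccuracy(v2))
  expect_error(bootstrapValidate(pm$x, pm$y, cand, nBoot = 0), "nBoot")
})

test_that("permuted labels validate near the majority-class rate", {
  pm <- plantedMatrix(n = 120, p = 4, seed = 44)
  set.seed(45)
  yperm <- sample(pm$y)
  cand <- new("ModelCandidate", subset = "signal", nTrees = 5L,
              maxDepth = 8L, seed = 1, accuracyResub = NA_real_)
  v <- bootstrapValidate(pm$x, yperm, cand, nBoot = 100, seed = 8)
  base <- max(mean(yperm), 1 - mean(yperm))
  # within 3 binomial SDs (per-iteration test-set size) of the
  # no-information rate
  se <- sqrt(base * (1 - base) / (nrow(pm$x) * v@oobFraction))
  expect_lt(abs(validatedAccuracy(v) - base), 3 * se)
})

test_that("ranking orders by validated accuracy, then size, then names", {
  mk <- function(sub, acc) {
    cand <- new("ModelCandidate", subset = sub, nTrees = 5L, maxDepth = 8L,
                seed = 1, accuracyResub = 1)
    cand@accuracyValidated <- acc
    cand@accuracySd <- 0.01
    cand@nBoot <- 10L
    cand
  }
  rk <- rankModels(list(mk(c("a", "b", "c", "d"), 0.847),
                        mk(c("a", "b", "c"), 0.863),
                        mk(c("x", "y", "z"), 0.847)))
  expect_equal(validatedAccuracy(rk[[1]]), 0.863)
  # tie at 0.847: the size-3 subset precedes the size-4 one
  expect_length(modelSubset(rk[[2]]), 3L)
  expect_true(rk[[1]]@bestOfSize)       # best three-descriptor model
  expect_false(rk[[2]]@bestOfSize)      # second-best of its size
  expect_true(rk[[3]]@bestOfSize)       # best (only) four-descriptor model
  expect_error(rankModels(list(mk("a", NA_real_))), "validated")
  expect_identical(rankModels(list()), list())
})
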