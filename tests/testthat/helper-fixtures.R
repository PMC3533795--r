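# Fixtures are built in code: a minimal one-plate screen and small helpers
# shared across test files.

# One plate, one channel, explicit numbers chosen for hand-checkable
# normalization: background mean 50, control mean 150, span 100.
tinyWells <- function() {
  data.frame(
    plate_id = "P1",
    compound_id = c("drugA", "drugA", "drugB", "drugB", "CTRL", "CTRL", "BG", "BG"),
    concentration_uM = c(2.5, 2.5, 2.5, 2.5, 0, 0, 0, 0),
    channel = "lipidtox",
    replicate = c(1, 2, 1, 2, 1, 2, 1, 2),
    role = c("test", "test", "test", "test", "control", "control",
             "background", "background"),
    fluorescence = c(250, 250, 150, 150, 140, 160, 40, 60),
    stringsAsFactors = FALSE)
}

# wells already on the percent scale: background 0, control 100, so
# normalized percent equals the raw test-well value
percentScaleWells <- function(values, concentration = 2.5,
                              compound = sprintf("c%02d", seq_along(values)),
                              channel = "lipidtox") {
  rbind(
    data.frame(plate_id = "P1", compound_id = compound,
               concentration_uM = concentration, channel = channel,
               replicate = seq_along(values), role = "test",
               fluorescence = values, stringsAsFactors = FALSE),
    data.frame(plate_id = "P1", compound_id = c("CTRL", "BG"),
               concentration_uM = 0, channel = channel, replicate = 1,
               role = c("control", "background"), fluorescence = c(100, 0),
               stringsAsFactors = FALSE))
}

# quadruplicate screen for one compound at both concentrations, exact values
quadScreen <- function(lowValues, highValues, compound = "drugA") {
  w <- rbind(
    percentScaleWells(lowValues, 2.5, rep(compound, length(lowValues))),
    percentScaleWells(highValues, 5.0, rep(compound, length(highValues))))
  w <- w[!duplicated(w[c("compound_id", "concentration_uM", "channel",
                         "replicate", "role")]), ]
  PLDScreen(w)
}

# exhaustive margin-preserving enumeration oracle for the two-sided Fisher
# p-value, written with binomial coefficients only (independent of dhyper)
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  as <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, as) * choose(r2, c1 - as) / choose(N, c1)
  pobs <- choose(r1, a) * choose(r2, c) / choose(N, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# descriptor table rows for rule tests
propRow <- function(logp = 2, pka = 8, mw = 300, hbd = 1, hba = 3,
                    id = "cpd") {
  data.frame(compound_id = id, logp = logp, pka_basic_max = pka, mw = mw,
             hbd = hbd, hba = hba, stringsAsFactors = FALSE)
}
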