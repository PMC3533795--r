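# unbiasing constant for the sample SD at n replicates: E[S] = c4 * sigma
.c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

# raw-unit anchors for mapping percent-of-control back to fluorescence
.BG_LEVEL <- 400
.SPAN <- 4000
.N_REPLICATES <- 4L
.N_CONTROL <- 8L
.N_BACKGROUND <- 4L

#' Build a synthetic screen configuration
#'
#' See [SyntheticConfig-class] for the meaning and provenance of every
#' parameter; arguments override the defaults, which encode the study
#' conditions the generator emulates.
#'
#' @param nCompounds,activeFraction,cvLow,cvHigh,effectLowRange,deltaMean,deltaSd
#'   screen structure and noise; see [SyntheticConfig-class].
#' @param activePkaMean,activePkaSd,activeLogpMean,activeLogpSd,inactivePkaMean,inactivePkaSd,inactiveLogpMean,inactiveLogpSd
#'   property distributions.
#' @param nNoiseDescriptors,labelNoise,annotationConcordance,concLow,concHigh,dapiMean,dapiSd,compoundsPerPlate,seed
#'   remaining knobs; see [SyntheticConfig-class].
#' @return a [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nCompounds = 297, activeFraction = 55 / 297,
                            cvLow = 0.077, cvHigh = 0.080,
                            effectLowRange = c(210, 750),
                            deltaMean = 178.1, deltaSd = 76.4,
                            activePkaMean = 9.04, activePkaSd = 1.38,
                            activeLogpMean = 5.08, activeLogpSd = 1.53,
                            inactivePkaMean = 7.0, inactivePkaSd = 2.0,
                            inactiveLogpMean = 2.5, inactiveLogpSd = 1.5,
                            nNoiseDescriptors = 150, labelNoise = 0,
                            annotationConcordance = 0.85,
                            concLow = 2.5, concHigh = 5.0,
                            dapiMean = 96, dapiSd = 25,
                            compoundsPerPlate = 80, seed = 1) {
  new("SyntheticConfig", nCompounds = as.integer(nCompounds),
      activeFraction = activeFraction, cvLow = cvLow, cvHigh = cvHigh,
      effectLowRange = effectLowRange, deltaMean = deltaMean,
      deltaSd = deltaSd, activePkaMean = activePkaMean,
      activePkaSd = activePkaSd, activeLogpMean = activeLogpMean,
      activeLogpSd = activeLogpSd, inactivePkaMean = inactivePkaMean,
      inactivePkaSd = inactivePkaSd, inactiveLogpMean = inactiveLogpMean,
      inactiveLogpSd = inactiveLogpSd,
      nNoiseDescriptors = as.integer(nNoiseDescriptors),
      labelNoise = labelNoise, annotationConcordance = annotationConcordance,
      concLow = concLow, concHigh = concHigh, dapiMean = dapiMean,
      dapiSd = dapiSd, compoundsPerPlate = as.integer(compoundsPerPlate),
      seed = seed)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nCompounds, "compounds,",
      floor(object@activeFraction * object@nCompounds), "planted actives,",
      "seed", object@seed, "\n")
  cat(sprintf("  concentrations %g / %g uM, replicate CV %.3f / %.3f\n",
              object@concLow, object@concHigh, object@cvLow, object@cvHigh))
  cat(sprintf("  active effects U[%g, %g]%% + doubling increase N(%g, %g)\n",
              object@effectLowRange[1], object@effectLowRange[2],
              object@deltaMean, object@deltaSd))
  cat(sprintf("  active pKa N(%g, %g), logP N(%g, %g); %d noise descriptors\n",
              object@activePkaMean, object@activePkaSd,
              object@activeLogpMean, object@activeLogpSd,
              object@nNoiseDescriptors))
})

#' Generate synthetic compounds with molecular properties
#'
#' Plants \code{floor(activeFraction * n)} active compounds and draws each
#' group's highest basic pKa and logP from its configured normal
#' distribution (actives are CAD-like by construction, so rule-based
#' classifiers recover an elevated CAD rate among actives). Molecular
#' weight, H-bond donor and acceptor counts come from broad drug-like
#' ranges. Two informative descriptors - noisy monotone transforms of logP
#' and pKa with 5 percent relative noise - and
#' \code{nNoiseDescriptors} standard-normal columns are appended, so
#' subset-selection methods face a planted-signal recovery problem.
#' \code{labelNoise > 0} flips that fraction of activity labels (the flipped
#' labels are what the screen "observes"; the planted truth is also
#' returned).
#'
#' @param config a [SyntheticConfig-class] object.
#' @return list with elements \code{properties} (data.frame: compound_id,
#'   logp, pka_basic_max, mw, hbd, hba, lipophilicity_index,
#'   basicity_index, rnd_* columns), \code{labels} (named logical, after
#'   label noise) and \code{trueLabels} (named logical, planted).
#' @export
genCompounds <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.deriveSeed(config@seed, 1))
  n <- config@nCompounds
  ids <- sprintf("CPD%04d", seq_len(n))
  if (n == 0L) {
    empty <- stats::setNames(logical(0), character(0))
    return(list(properties = data.frame(compound_id = character(0)),
                labels = empty, trueLabels = empty))
  }
  nActive <- floor(config@activeFraction * n)
  active <- stats::setNames(rep(FALSE, n), ids)
  active[sample.int(n, nActive)] <- TRUE
  pka <- ifelse(active,
                stats::rnorm(n, config@activePkaMean, config@activePkaSd),
                stats::rnorm(n, config@inactivePkaMean, config@inactivePkaSd))
  logp <- ifelse(active,
                 stats::rnorm(n, config@activeLogpMean, config@activeLogpSd),
                 stats::rnorm(n, config@inactiveLogpMean,
                              config@inactiveLogpSd))
  props <- data.frame(
    compound_id = ids, logp = logp, pka_basic_max = pka,
    mw = stats::runif(n, 150, 650),
    hbd = sample(0:5, n, replace = TRUE),
    hba = sample(0:10, n, replace = TRUE),
    lipophilicity_index = exp(logp / 2) * (1 + 0.05 * stats::rnorm(n)),
    basicity_index = exp(pka / 3) * (1 + 0.05 * stats::rnorm(n)),
    stringsAsFactors = FALSE)
  if (config@nNoiseDescriptors > 0L) {
    noise <- matrix(stats::rnorm(n * config@nNoiseDescriptors), nrow = n,
                    dimnames = list(NULL,
                      sprintf("rnd_%03d", seq_len(config@nNoiseDescriptors))))
    props <- cbind(props, as.data.frame(noise))
  }
  labels <- active
  nFlip <- round(config@labelNoise * n)
  if (nFlip > 0L) {
    flip <- sample.int(n, nFlip)
    labels[flip] <- !labels[flip]
  }
  list(properties = props, labels = labels, trueLabels = active)
}

# truncated-normal draw by redraw; lower bound is vectorized
.rtruncnorm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  for (i in which(out < lower)) {
    repeat {
      out[i] <- stats::rnorm(1, mean, sd)
      if (out[i] >= lower[i]) break
    }
  }
  out
}

#' Generate well-level plate fluorescence for a compound set
#'
#' Emulates the screen's plate reads. Each compound gets 4 LipidTOX test
#' wells per concentration: inactives fluctuate around 100 percent of
#' control; actives draw a latent effect uniformly from
#' \code{effectLowRange} at the low concentration and add a
#' \code{Normal(deltaMean, deltaSd)} percent-point increase at the high
#' concentration, truncated below so the high-concentration effect stays
#' above 110 percent of control. Replicate noise is proportional to the
#' latent effect with the configured CV; its SD is scaled by 1/c4(4) so the
#' sample-SD-based CV computed from quadruplicates is unbiased for the
#' configured value. DAPI wells draw from
#' \code{Normal(dapiMean, dapiSd)} floored at 0. Latent percentages are
#' mapped to raw fluorescence through simulated per-plate background and
#' control levels; each plate carries 8 control and 4 background wells per
#' channel (noise proportional to \code{cvLow}, so a zero-CV configuration
#' is exactly noiseless). Compounds are dealt to plates round-robin at 80
#' per plate.
#'
#' @param compounds data.frame with a \code{compound_id} column (as from
#'   [genCompounds()]).
#' @param labels logical planted activity named by compound id.
#' @param config a [SyntheticConfig-class] object.
#' @return a [PLDScreen-class] object.
#' @export
genPlateData <- function(compounds, labels, config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.deriveSeed(config@seed, 2))
  ids <- as.character(compounds$compound_id)
  n <- length(ids)
  act <- as.logical(labels[ids])
  if (anyNA(act)) stop("labels must cover every compound")
  nPlates <- max(1L, ceiling(n / config@compoundsPerPlate))
  plate <- sprintf("P%02d", ((seq_len(n) - 1L) %% nPlates) + 1L)
  c4 <- .c4(.N_REPLICATES)

  # latent per-compound effects (percent of control)
  effLow <- ifelse(act,
                   stats::runif(n, config@effectLowRange[1],
                                config@effectLowRange[2]), 100)
  delta <- rep(0, n)
  if (any(act))
    delta[act] <- .rtruncnorm(sum(act), config@deltaMean, config@deltaSd,
                              lower = 110 - effLow[act])
  effHigh <- ifelse(act, effLow + delta, 100)

  concs <- c(config@concLow, config@concHigh)
  cvs <- c(config@cvLow, config@cvHigh)
  rows <- vector("list", 0L)
  for (k in 1:2) {
    eff <- if (k == 1L) effLow else effHigh
    pct <- stats::rnorm(n * .N_REPLICATES,
                        mean = rep(eff, each = .N_REPLICATES),
                        sd = rep(eff * cvs[k] / c4, each = .N_REPLICATES))
    raw <- pmax(0, .BG_LEVEL + pct / 100 * .SPAN)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = rep(plate, each = .N_REPLICATES),
      compound_id = rep(ids, each = .N_REPLICATES),
      concentration_uM = concs[k], channel = "lipidtox",
      replicate = rep(seq_len(.N_REPLICATES), n), role = "test",
      fluorescence = raw, stringsAsFactors = FALSE)
    dapi <- pmax(0, stats::rnorm(n * .N_REPLICATES, config@dapiMean,
                                 config@dapiSd))
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = rep(plate, each = .N_REPLICATES),
      compound_id = rep(ids, each = .N_REPLICATES),
      concentration_uM = concs[k], channel = "dapi",
      replicate = rep(seq_len(.N_REPLICATES), n), role = "test",
      fluorescence = pmax(0, .BG_LEVEL + dapi / 100 * .SPAN),
      stringsAsFactors = FALSE)
  }
  # shared control and background wells per plate and channel
  plates <- sort(unique(plate))
  for (pl in plates) {
    for (ch in c("lipidtox", "dapi")) {
      ctrl <- .BG_LEVEL + .SPAN *
        (1 + config@cvLow * stats::rnorm(.N_CONTROL))
      bg <- pmax(0, .BG_LEVEL * (1 + config@cvLow * stats::rnorm(.N_BACKGROUND)))
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = pl, compound_id = "CTRL", concentration_uM = 0,
        channel = ch, replicate = seq_len(.N_CONTROL), role = "control",
        fluorescence = pmax(0, ctrl), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = pl, compound_id = "BG", concentration_uM = 0,
        channel = ch, replicate = seq_len(.N_BACKGROUND),
        role = "background", fluorescence = bg, stringsAsFactors = FALSE)
    }
  }
  PLDScreen(do.call(rbind, rows))
}

#' Generate compound annotations (ATC codes, ASM and BBB flags)
#'
#' The acid-sphingomyelinase-inhibitor and blood-brain-barrier-permeability
#' flags copy the compound's activity label with probability
#' \code{annotationConcordance} (independently per compound and per flag)
#' and are flipped otherwise, emulating the strong overlap between PLD
#' inducers and those annotation sets. Second-level ATC classes are sampled
#' from the bundled class list with the psychotropic classes (N05, N06)
#' up-weighted sixfold for actives, so active compounds cluster there; a
#' random tenth of compounds carries a second code.
#'
#' @inheritParams genPlateData
#' @return data.frame with columns \code{compound_id}, \code{atc_codes}
#'   (semicolon-separated), \code{asm_inhibitor}, \code{bbb_permeable}.
#' @export
genAnnotations <- function(compounds, labels, config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(.deriveSeed(config@seed, 3))
  ids <- as.character(compounds$compound_id)
  n <- length(ids)
  act <- as.logical(labels[ids])
  if (anyNA(act)) stop("labels must cover every compound")
  keep <- stats::runif(n) < config@annotationConcordance
  asm <- ifelse(keep, act, !act)
  keep <- stats::runif(n) < config@annotationConcordance
  bbb <- ifelse(keep, act, !act)
  classes <- names(.atcClassNames)
  wActive <- ifelse(classes %in% c("N05", "N06"), 6, 1)
  drawCode <- function(w) {
    cls <- sample(classes, 1L, prob = w)
    sprintf("%sA%02d", cls, sample.int(99, 1L))
  }
  codes <- vapply(seq_len(n), function(i)
    drawCode(if (act[i]) wActive else rep(1, length(classes))), character(1))
  second <- stats::runif(n) < 0.10
  codes[second] <- paste(codes[second],
                         vapply(seq_len(sum(second)), function(i)
                           drawCode(rep(1, length(classes))), character(1)),
                         sep = ";")
  data.frame(compound_id = ids, atc_codes = codes, asm_inhibitor = asm,
             bbb_permeable = bbb, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic screen
#'
#' Convenience wrapper running [genCompounds()], [genPlateData()] and
#' [genAnnotations()] with one configuration. Every output is a pure
#' function of the configuration (including its seed).
#'
#' @param config a [SyntheticConfig-class] object (default
#'   \code{syntheticConfig()}).
#' @return list with elements \code{screen} ([PLDScreen-class]),
#'   \code{properties}, \code{labels}, \code{trueLabels},
#'   \code{annotations} and \code{config}.
#' @export
simulateScreen <- function(config = syntheticConfig()) {
  comp <- genCompounds(config)
  screen <- genPlateData(comp$properties, comp$labels, config)
  ann <- genAnnotations(comp$properties, comp$labels, config)
  list(screen = screen, properties = comp$properties, labels = comp$labels,
       trueLabels = comp$trueLabels, annotations = ann, config = config)
}
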