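#' @import methods
NULL

.WELL_COLUMNS <- c("plate_id", "compound_id", "concentration_uM", "channel",
                   "replicate", "role", "fluorescence")
.CHANNELS <- c("lipidtox", "dapi")
.ROLES <- c("test", "control", "background")

#' Well-level plate screen container
#'
#' Holds one raw fluorescence measurement per row: plate, compound,
#' concentration (micromolar; 0 for control and background wells), channel
#' (\code{"lipidtox"} for the phospholipid stain, \code{"dapi"} for the
#' nuclear counterstain), replicate index, well role and raw fluorescence in
#' arbitrary units. Validity enforces nonnegative fluorescence, positive
#' concentrations on test wells and replicate uniqueness within
#' (compound, concentration, channel, plate).
#'
#' @slot wells data.frame with columns \code{plate_id}, \code{compound_id},
#'   \code{concentration_uM}, \code{channel}, \code{replicate}, \code{role},
#'   \code{fluorescence}.
#' @seealso [readWellTable()], [normalizeWells()], [summarizeScreen()]
#' @export
setClass("PLDScreen", representation(wells = "data.frame"))

setValidity("PLDScreen", function(object) {
  w <- object@wells
  miss <- setdiff(.WELL_COLUMNS, names(w))
  if (length(miss))
    return(paste("missing well columns:", paste(miss, collapse = ", ")))
  if (!is.numeric(w$fluorescence) || anyNA(w$fluorescence) ||
      any(w$fluorescence < 0))
    return("fluorescence must be numeric, non-missing and >= 0")
  if (!all(w$channel %in% .CHANNELS))
    return(paste("channel must be one of:", paste(.CHANNELS, collapse = ", ")))
  if (!all(w$role %in% .ROLES))
    return(paste("role must be one of:", paste(.ROLES, collapse = ", ")))
  if (any(w$role == "test" & !(w$concentration_uM > 0)))
    return("test wells must have concentration_uM > 0")
  key <- paste(w$compound_id, w$concentration_uM, w$channel, w$plate_id,
               w$replicate, sep = "\r")
  if (anyDuplicated(key))
    return("replicate indices must be unique within (compound, concentration, channel, plate)")
  TRUE
})

#' Per-compound screen summary
#'
#' One row per compound x concentration: mean percent-of-control LipidTOX
#' signal, sample standard deviation and coefficient of variation over
#' replicates, replicate count, mean DAPI percent-of-control (NA when no DAPI
#' wells were measured) and the activity call at the stored threshold.
#'
#' @slot table data.frame with columns \code{compound_id},
#'   \code{concentration_uM}, \code{percent_of_control}, \code{sd}, \code{cv},
#'   \code{n}, \code{dapi_percent}, \code{pld_active}.
#' @slot threshold numeric(1), percent-of-control activity threshold.
#' @seealso [summarizeScreen()], [consistencyReport()], [dapiQc()]
#' @export
setClass("ScreenSummary",
         representation(table = "data.frame", threshold = "numeric"))

setValidity("ScreenSummary", function(object) {
  need <- c("compound_id", "concentration_uM", "percent_of_control", "sd",
            "cv", "n", "dapi_percent", "pld_active")
  miss <- setdiff(need, names(object@table))
  if (length(miss))
    return(paste("missing summary columns:", paste(miss, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold < 0)
    return("threshold must be a single nonnegative number")
  if (any(object@table$n < 1L))
    return("each summary row needs at least one replicate")
  TRUE
})

#' Screen quality-control report
#'
#' Produced by [consistencyReport()] (concentration-consistency fields) and
#' [dapiQc()] (cell-count fields); fields not computed by the producing
#' operation are left empty.
#'
#' @slot inclusionViolations character: compounds active at the low but not
#'   the high concentration.
#' @slot meanEffectIncrease,sdEffectIncrease numeric(1): mean and SD, over
#'   compounds active at the high concentration, of the high-minus-low
#'   percent-of-control difference (or the high/low ratio, per \code{scale}).
#' @slot nIncreasing integer(1): high-concentration actives whose effect is
#'   larger at the high concentration.
#' @slot nActiveHigh,nActiveLow integer(1): active-set sizes.
#' @slot scale character(1): \code{"points"} or \code{"ratio"}.
#' @slot dapiGroupMeans data.frame: per concentration and activity group
#'   (active / inactive / total) the n, mean and SD of DAPI percent.
#' @slot dapiFlags data.frame: compound x concentration rows whose DAPI
#'   percent fell below the loss threshold.
#' @export
setClass("ScreenQCReport",
         representation(inclusionViolations = "character",
                        meanEffectIncrease = "numeric",
                        sdEffectIncrease = "numeric",
                        nIncreasing = "integer",
                        nActiveHigh = "integer",
                        nActiveLow = "integer",
                        scale = "character",
                        dapiGroupMeans = "data.frame",
                        dapiFlags = "data.frame"),
         prototype(inclusionViolations = character(0),
                   meanEffectIncrease = NA_real_,
                   sdEffectIncrease = NA_real_,
                   nIncreasing = NA_integer_,
                   nActiveHigh = NA_integer_,
                   nActiveLow = NA_integer_,
                   scale = NA_character_,
                   dapiGroupMeans = data.frame(),
                   dapiFlags = data.frame()))

#' Result of a 2x2 association test
#'
#' @slot table 2x2 integer matrix of observed counts.
#' @slot testUsed \code{"g_test"} (likelihood-ratio chi-squared, no continuity
#'   correction) or \code{"fisher"}.
#' @slot statistic numeric(1): the G statistic (NA for Fisher).
#' @slot df numeric(1): degrees of freedom (1 for a 2x2 table; NA for Fisher).
#' @slot pValue numeric(1).
#' @slot significant logical(1): \code{pValue < alpha}.
#' @slot alpha numeric(1): significance level (default 0.05).
#' @slot n numeric(1): number of observations behind the table.
#' @seealso [gTest()], [fisherExact()], [associate()]
#' @export
setClass("AssociationResult",
         representation(table = "matrix", testUsed = "character",
                        statistic = "numeric", df = "numeric",
                        pValue = "numeric", significant = "logical",
                        alpha = "numeric", n = "numeric"))

setValidity("AssociationResult", function(object) {
  if (!all(dim(object@table) == c(2L, 2L)))
    return("table must be 2x2")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (!object@testUsed %in% c("g_test", "fisher"))
    return("testUsed must be 'g_test' or 'fisher'")
  TRUE
})

#' A descriptor-subset model candidate
#'
#' One candidate from the beam search: the descriptor subset, the forest
#' hyperparameters, its resubstitution accuracy, and (after
#' [bootstrapValidate()]) the out-of-bootstrap validated accuracy.
#'
#' @slot subset character: descriptor names.
#' @slot nTrees,maxDepth integer(1): forest size and depth bound.
#' @slot seed numeric(1): search/training seed.
#' @slot accuracyResub numeric(1): accuracy on the training compounds.
#' @slot accuracyValidated numeric(1): mean out-of-bootstrap accuracy
#'   (NA before validation).
#' @slot accuracySd numeric(1): SD of the out-of-bootstrap accuracies.
#' @slot nBoot integer(1): bootstrap iterations (0 before validation).
#' @slot sampleRatio numeric(1): resample size as a fraction of n.
#' @slot oobFraction numeric(1): mean fraction of compounds left out of the
#'   resample per iteration (about exp(-1) at sampleRatio 1).
#' @slot bestOfSize logical(1): flagged by [rankModels()] for the best
#'   candidate at each subset size.
#' @seealso [beamSearch()], [bootstrapValidate()], [rankModels()]
#' @export
setClass("ModelCandidate",
         representation(subset = "character", nTrees = "integer",
                        maxDepth = "integer", seed = "numeric",
                        accuracyResub = "numeric",
                        accuracyValidated = "numeric", accuracySd = "numeric",
                        nBoot = "integer", sampleRatio = "numeric",
                        oobFraction = "numeric", bestOfSize = "logical"),
         prototype(accuracyValidated = NA_real_, accuracySd = NA_real_,
                   nBoot = 0L, sampleRatio = NA_real_,
                   oobFraction = NA_real_, bestOfSize = FALSE))

setValidity("ModelCandidate", function(object) {
  if (length(object@subset) < 1L) return("subset must contain >= 1 descriptor")
  ok <- function(a) is.na(a) || (a >= 0 && a <= 1)
  if (!ok(object@accuracyResub) || !ok(object@accuracyValidated))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' Synthetic screen configuration
#'
#' Parameters of the synthetic-screen generator. Defaults emulate a
#' 297-compound screen measured in quadruplicate at 2.5 and 5.0 uM: 55 planted
#' actives, replicate coefficients of variation 0.077 / 0.080 at the two
#' concentrations, active effect sizes uniform on 210--750 percent of control
#' at the low concentration with a Normal(178.1, 76.4) percent-point increase
#' on doubling, active compounds drawn with basic pKa 9.04 +/- 1.38 and logP
#' 5.08 +/- 1.53. Inactive property distributions, DAPI noise and the
#' annotation concordance are free parameters (no measured values exist);
#' their defaults are documented in the methods vignette.
#'
#' @slot nCompounds integer(1), screen size (default 297).
#' @slot activeFraction numeric(1), fraction of planted actives
#'   (default 55/297; the planted count is \code{floor(activeFraction * n)}).
#' @slot cvLow,cvHigh numeric(1), replicate CV at the low / high
#'   concentration (defaults 0.077, 0.080).
#' @slot effectLowRange numeric(2), percent-of-control interval the low
#'   concentration active effects are drawn from (default c(210, 750)).
#' @slot deltaMean,deltaSd numeric(1), percent-point effect increase on
#'   concentration doubling (defaults 178.1, 76.4).
#' @slot activePkaMean,activePkaSd,activeLogpMean,activeLogpSd numeric(1),
#'   property distributions of actives (defaults 9.04/1.38 and 5.08/1.53).
#' @slot inactivePkaMean,inactivePkaSd,inactiveLogpMean,inactiveLogpSd
#'   numeric(1), free parameters (defaults 7.0/2.0 and 2.5/1.5).
#' @slot nNoiseDescriptors integer(1), uninformative standard-normal
#'   descriptor columns (default 150).
#' @slot labelNoise numeric(1), fraction of activity labels flipped
#'   (default 0).
#' @slot annotationConcordance numeric(1), probability that the ASM and BBB
#'   flags copy the activity label (default 0.85, free parameter).
#' @slot concLow,concHigh numeric(1), tested concentrations in uM
#'   (defaults 2.5, 5.0).
#' @slot dapiMean,dapiSd numeric(1), DAPI percent-of-control distribution
#'   (defaults 96, 25, free parameters).
#' @slot compoundsPerPlate integer(1), plate capacity for the round-robin
#'   plate assignment (default 80).
#' @slot seed numeric(1), master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @seealso [syntheticConfig()], [genCompounds()], [genPlateData()],
#'   [genAnnotations()], [simulateScreen()]
#' @export
setClass("SyntheticConfig",
         representation(nCompounds = "integer", activeFraction = "numeric",
                        cvLow = "numeric", cvHigh = "numeric",
                        effectLowRange = "numeric",
                        deltaMean = "numeric", deltaSd = "numeric",
                        activePkaMean = "numeric", activePkaSd = "numeric",
                        activeLogpMean = "numeric", activeLogpSd = "numeric",
                        inactivePkaMean = "numeric", inactivePkaSd = "numeric",
                        inactiveLogpMean = "numeric",
                        inactiveLogpSd = "numeric",
                        nNoiseDescriptors = "integer", labelNoise = "numeric",
                        annotationConcordance = "numeric",
                        concLow = "numeric", concHigh = "numeric",
                        dapiMean = "numeric", dapiSd = "numeric",
                        compoundsPerPlate = "integer", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  frac <- c(object@activeFraction, object@labelNoise,
            object@annotationConcordance)
  if (any(frac < 0 | frac > 1)) return("fractions must lie in [0, 1]")
  if (object@cvLow < 0 || object@cvHigh < 0) return("CVs must be >= 0")
  if (object@deltaSd < 0) return("deltaSd must be >= 0")
  if (length(object@effectLowRange) != 2L ||
      diff(object@effectLowRange) < 0)
    return("effectLowRange must be an increasing interval")
  if (object@nCompounds < 0L) return("nCompounds must be >= 0")
  TRUE
})
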