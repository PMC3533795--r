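#' Extract the well table from a screen
#' @param x a [PLDScreen-class] object.
#' @return data.frame of well records.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' Extract the per-compound summary table
#' @param x a [ScreenSummary-class] object.
#' @return data.frame, one row per compound x concentration.
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' Activity threshold of a summary
#' @param x a [ScreenSummary-class] object.
#' @return numeric(1), percent-of-control threshold used for activity calls.
#' @export
setGeneric("activityThreshold", function(x) standardGeneric("activityThreshold"))

#' Activity calls of a summary
#' @param x a [ScreenSummary-class] object.
#' @param concentration optional concentration (uM) to restrict to.
#' @return named logical vector of PLD activity calls.
#' @export
setGeneric("pldActive",
           function(x, concentration = NULL) standardGeneric("pldActive"))

#' p-value of an association test
#' @param x an [AssociationResult-class] object.
#' @return numeric(1).
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Which test an association result used
#' @param x an [AssociationResult-class] object.
#' @return \code{"g_test"} or \code{"fisher"}.
#' @export
setGeneric("testUsed", function(x) standardGeneric("testUsed"))

#' Descriptor subset of a model candidate
#' @param x a [ModelCandidate-class] object.
#' @return character vector of descriptor names.
#' @export
setGeneric("modelSubset", function(x) standardGeneric("modelSubset"))

#' Validated accuracy of a model candidate
#' @param x a [ModelCandidate-class] object.
#' @return numeric(1), mean out-of-bootstrap accuracy (NA before validation).
#' @export
setGeneric("validatedAccuracy", function(x) standardGeneric("validatedAccuracy"))
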