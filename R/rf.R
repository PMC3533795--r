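#' Random forest configuration
#'
#' Hyperparameters of the compact depth-bounded random forest used as the
#' fitness model of the descriptor-subset search: 5 trees of depth at most 8
#' by default, each grown on a bootstrap resample of the compounds with
#' \code{ceiling(sqrt(d))} candidate features per split.
#'
#' @param nTrees number of trees (default 5).
#' @param maxDepth maximum tree depth (default 8).
#' @param seed training seed; the fit is a pure function of
#'   (data, configuration, seed).
#' @return a list of class \code{"rfConfig"}.
#' @export
rfConfig <- function(nTrees = 5, maxDepth = 8, seed = 1) {
  stopifnot(nTrees >= 1, maxDepth >= 1)
  structure(list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
                 seed = as.numeric(seed)), class = "rfConfig")
}

.checkMatrix <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (is.null(colnames(x))) stop("x must have descriptor column names")
  if (anyDuplicated(colnames(x))) stop("descriptor names must be unique")
  if (anyNA(x)) stop("x must not contain missing values")
  if (length(labels) != nrow(x))
    stop("labels must have one entry per compound row")
  if (anyNA(labels)) stop("labels must not be missing")
  invisible(TRUE)
}

#' Train the forest on a descriptor subset
#'
#' Fits the depth-bounded random forest on the given descriptor subset and
#' reports the resubstitution (training-set) accuracy, the fitness measure
#' of the beam search. Each tree is grown on a with-replacement resample of
#' the compounds; predictions are by majority vote over trees, with ties
#' broken toward the active class.
#'
#' @param x numeric compound x descriptor matrix with column names.
#' @param labels logical PLD activity per compound.
#' @param subset character vector of descriptor names (default all columns).
#' @param config an [rfConfig()] list.
#' @return a list of class \code{"rfFit"} with elements \code{forest},
#'   \code{subset}, \code{config}, \code{accuracyResub} and
#'   \code{predictions} (logical, training compounds).
#' @export
trainRf <- function(x, labels, subset = colnames(x), config = rfConfig()) {
  .checkMatrix(x, labels)
  if (!length(subset)) stop("the descriptor subset must not be empty")
  if (length(bad <- setdiff(subset, colnames(x))))
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "))
  xs <- x[, subset, drop = FALSE]
  y <- as.integer(as.logical(labels))
  mtry <- ceiling(sqrt(length(subset)))
  forest <- .rf_train(xs, y, config$nTrees, config$maxDepth, mtry,
                      config$seed)
  pred <- .rf_predict(forest, xs) == 1L
  structure(list(forest = forest, subset = subset, config = config,
                 accuracyResub = mean(pred == as.logical(labels)),
                 predictions = pred),
            class = "rfFit")
}

#' Predict activity with a trained forest
#'
#' @param fit an \code{"rfFit"} object from [trainRf()].
#' @param x numeric matrix containing at least the fitted descriptor columns.
#' @return logical vector of predicted activity.
#' @export
predictRf <- function(fit, x) {
  stopifnot(inherits(fit, "rfFit"))
  .rf_predict(fit$forest, x[, fit$subset, drop = FALSE]) == 1L
}
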