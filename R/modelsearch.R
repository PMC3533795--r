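.subsetKey <- function(subset) paste(sort(subset), collapse = ";")

#' Prefilter a descriptor matrix
#'
#' Reduces a raw descriptor matrix to the \code{k} most promising columns
#' before the subset search: drops descriptors with near-zero variance,
#' drops the later member of any pair of columns with absolute Pearson
#' correlation above \code{corMax}, then ranks the survivors by absolute
#' point-biserial correlation with the activity label (a univariate
#' class-separation score) and keeps the top \code{k}. The result is
#' deterministic given the input column order; returned columns are ordered
#' by decreasing score.
#'
#' @param x numeric compound x descriptor matrix with column names.
#' @param labels logical activity label per compound.
#' @param k number of descriptors to keep (default 113; clipped to the
#'   number available).
#' @param varTol variance threshold below which a descriptor is considered
#'   constant (default 1e-12).
#' @param corMax absolute-correlation threshold for the redundancy prune
#'   (default 0.98).
#' @return the filtered matrix; attribute \code{"score"} carries the
#'   per-column scores.
#' @export
prefilterDescriptors <- function(x, labels, k = 113, varTol = 1e-12,
                                 corMax = 0.98) {
  .checkMatrix(x, labels)
  v <- apply(x, 2, stats::var)
  keep <- which(v >= varTol)
  if (!length(keep)) stop("all descriptors are constant")
  x <- x[, keep, drop = FALSE]
  if (ncol(x) > 1L) {
    cm <- abs(stats::cor(x))
    drop <- logical(ncol(x))
    for (j in 2:ncol(x))
      if (any(cm[j, 1:(j - 1)][!drop[1:(j - 1)]] > corMax)) drop[j] <- TRUE
    x <- x[, !drop, drop = FALSE]
  }
  y <- as.numeric(as.logical(labels))
  if (stats::var(y) == 0)
    stop("labels contain a single class; no separation score is defined")
  score <- abs(as.numeric(stats::cor(x, y)))
  ord <- order(-score)  # stable: ties keep input order
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- x[, ord, drop = FALSE]
  attr(out, "score") <- stats::setNames(score[ord], colnames(out))
  out
}

.newCandidate <- function(subset, acc, config, seed) {
  new("ModelCandidate", subset = subset, nTrees = config$nTrees,
      maxDepth = config$maxDepth, seed = seed, accuracyResub = acc)
}

#' Beam search over descriptor subsets
#'
#' Breadth-limited greedy search for small descriptor subsets that classify
#' PLD activity: level 1 evaluates every single descriptor with the
#' random-forest resubstitution accuracy as fitness; each subsequent level
#' keeps the \code{beamWidth} best subsets (ties broken by higher accuracy,
#' then smaller subset, then lexicographic descriptor order) and extends
#' each by one unused descriptor. The search stops at the first level where
#' any subset reaches accuracy 1.0 - returning every evaluated subset that
#' achieved it - or at \code{maxSize}, returning the best subsets found.
#' The whole search is repeated for each seed and the de-duplicated union
#' returned, with the seed recorded per candidate.
#'
#' @inheritParams trainRf
#' @param config an [rfConfig()] list; its seed is replaced by each search
#'   seed in turn.
#' @param beamWidth beam width (default: the number of descriptors).
#' @param maxSize largest subset size (default 4).
#' @param seeds integer vector of search seeds (default 1).
#' @return list of [ModelCandidate-class] objects, ordered by the search's
#'   tie rules.
#' @export
beamSearch <- function(x, labels, config = rfConfig(),
                       beamWidth = ncol(x), maxSize = 4, seeds = 1) {
  .checkMatrix(x, labels)
  desc <- colnames(x)
  out <- list()
  for (seed in seeds) {
    cfg <- rfConfig(config$nTrees, config$maxDepth, seed)
    acc <- new.env(parent = emptyenv())   # key -> accuracy
    members <- new.env(parent = emptyenv())
    evalLevel <- function(subsets) {
      for (s in subsets) {
        key <- .subsetKey(s)
        if (is.null(acc[[key]])) {
          acc[[key]] <- trainRf(x, labels, s, cfg)$accuracyResub
          members[[key]] <- s
        }
      }
    }
    orderKeys <- function(keys) {
      a <- vapply(keys, function(k) acc[[k]], numeric(1))
      sz <- lengths(lapply(keys, function(k) members[[k]]))
      keys[order(-a, sz, keys)]
    }
    level <- as.list(desc)
    evalLevel(level)
    levelKeys <- vapply(level, .subsetKey, character(1))
    repeat {
      hits <- Filter(function(k) acc[[k]] >= 1, ls(acc))
      if (length(hits) || lengths(level[1]) >= maxSize) break
      beam <- orderKeys(unique(levelKeys))
      beam <- beam[seq_len(min(beamWidth, length(beam)))]
      nxt <- list()
      for (k in beam) {
        s <- members[[k]]
        for (d in setdiff(desc, s)) nxt[[length(nxt) + 1L]] <- c(s, d)
      }
      keys <- vapply(nxt, .subsetKey, character(1))
      dup <- duplicated(keys) | !vapply(keys, function(k)
        is.null(acc[[k]]), logical(1))
      level <- nxt[!dup]
      levelKeys <- keys[!dup]
      if (!length(level)) break
      evalLevel(level)
    }
    hits <- Filter(function(k) acc[[k]] >= 1, ls(acc))
    pick <- if (length(hits)) orderKeys(hits)
            else {
              best <- orderKeys(ls(acc))
              best[seq_len(min(beamWidth, length(best)))]
            }
    for (k in pick)
      out[[length(out) + 1L]] <- .newCandidate(members[[k]], acc[[k]], cfg,
                                               seed)
  }
  keys <- vapply(out, function(cand) .subsetKey(cand@subset), character(1))
  out[!duplicated(keys)]
}

#' Out-of-bootstrap validation of a model candidate
#'
#' Validates a descriptor subset by bootstrapping: in each of \code{nBoot}
#' iterations a with-replacement resample of \code{sampleRatio * n}
#' compounds is drawn, the forest is trained on the resample, and accuracy
#' is measured on the compounds the resample missed (the out-of-bootstrap
#' set, on average a fraction \eqn{(1 - 1/n)^n \approx e^{-1}} of the
#' screen at ratio 1). Iterations with an empty out-of-bootstrap set or
#' single-class training labels are redrawn, at most 10 times each. The
#' validated accuracy is the mean over iterations, with its SD.
#'
#' @inheritParams trainRf
#' @param candidate a [ModelCandidate-class] from [beamSearch()].
#' @param nBoot bootstrap iterations (default 100).
#' @param sampleRatio resample size as a fraction of n (default 1.0).
#' @param seed resampling seed (default: the candidate's seed).
#' @param keepIndices record per-iteration train/test index sets in the
#'   \code{"iterations"} attribute (default FALSE).
#' @return the candidate with \code{accuracyValidated}, \code{accuracySd},
#'   \code{nBoot}, \code{sampleRatio} and \code{oobFraction} filled in.
#' @export
bootstrapValidate <- function(x, labels, candidate, nBoot = 100,
                              sampleRatio = 1.0, seed = candidate@seed,
                              keepIndices = FALSE) {
  .checkMatrix(x, labels)
  stopifnot(is(candidate, "ModelCandidate"))
  if (nBoot < 1) stop("nBoot must be at least 1")
  n <- nrow(x)
  m <- max(1L, round(sampleRatio * n))
  labels <- as.logical(labels)
  set.seed(.deriveSeed(seed, 911))
  accs <- oobf <- rep(NA_real_, nBoot)
  iterations <- if (keepIndices) vector("list", nBoot) else NULL
  for (b in seq_len(nBoot)) {
    for (try in 0:10) {
      idx <- sample.int(n, m, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) && length(unique(labels[idx])) == 2L) break
      if (try == 10L) stop("could not draw a usable bootstrap resample ",
                           "after 10 redraws (iteration ", b, ")")
    }
    cfg <- rfConfig(candidate@nTrees, candidate@maxDepth,
                    .deriveSeed(seed, b))
    fit <- trainRf(x[idx, , drop = FALSE], labels[idx], candidate@subset, cfg)
    pred <- predictRf(fit, x[oob, , drop = FALSE])
    accs[b] <- mean(pred == labels[oob])
    oobf[b] <- length(oob) / n
    if (keepIndices) iterations[[b]] <- list(train = idx, test = oob)
  }
  candidate@accuracyValidated <- mean(accs)
  candidate@accuracySd <- stats::sd(accs)
  candidate@nBoot <- as.integer(nBoot)
  candidate@sampleRatio <- sampleRatio
  candidate@oobFraction <- mean(oobf)
  if (keepIndices) attr(candidate, "iterations") <- iterations
  candidate
}

#' Rank validated model candidates
#'
#' Sorts candidates by validated accuracy (descending), breaking ties by
#' fewer descriptors and then lexicographic subset order, and flags the
#' best candidate of each subset size.
#'
#' @param candidates list of validated [ModelCandidate-class] objects.
#' @return the reordered list (empty input gives an empty list).
#' @export
rankModels <- function(candidates) {
  if (!length(candidates)) return(list())
  if (any(vapply(candidates, function(cand) is.na(cand@accuracyValidated),
                 logical(1))))
    stop("all candidates must be validated before ranking")
  av <- vapply(candidates, function(cand) cand@accuracyValidated, numeric(1))
  sz <- vapply(candidates, function(cand) length(cand@subset), integer(1))
  keys <- vapply(candidates, function(cand) .subsetKey(cand@subset),
                 character(1))
  ord <- order(-av, sz, keys)
  candidates <- candidates[ord]
  sz <- sz[ord]
  seen <- logical(0)
  for (i in seq_along(candidates)) {
    first <- !as.character(sz[i]) %in% names(seen)[seen]
    candidates[[i]]@bestOfSize <- first
    seen[as.character(sz[i])] <- TRUE
  }
  candidates
}

#' Export model candidates as a table
#'
#' @param candidates list of [ModelCandidate-class] objects.
#' @return data.frame with one row per candidate.
#' @export
candidateTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(subset = character(0), size = integer(0),
                      accuracy_resub = numeric(0),
                      accuracy_validated_mean = numeric(0),
                      accuracy_validated_sd = numeric(0),
                      n_boot = integer(0), seed = numeric(0),
                      best_of_size = logical(0)))
  data.frame(
    subset = vapply(candidates, function(x) paste(x@subset, collapse = ";"),
                    character(1)),
    size = vapply(candidates, function(x) length(x@subset), integer(1)),
    accuracy_resub = vapply(candidates, function(x) x@accuracyResub,
                            numeric(1)),
    accuracy_validated_mean = vapply(candidates,
                                     function(x) x@accuracyValidated,
                                     numeric(1)),
    accuracy_validated_sd = vapply(candidates, function(x) x@accuracySd,
                                   numeric(1)),
    n_boot = vapply(candidates, function(x) x@nBoot, integer(1)),
    seed = vapply(candidates, function(x) x@seed, numeric(1)),
    best_of_size = vapply(candidates, function(x) x@bestOfSize, logical(1)),
    stringsAsFactors = FALSE)
}

#' @describeIn beamSearch descriptor-subset accessor
#' @export
setMethod("modelSubset", "ModelCandidate", function(x) x@subset)

#' @describeIn bootstrapValidate validated-accuracy accessor
#' @export
setMethod("validatedAccuracy", "ModelCandidate",
          function(x) x@accuracyValidated)

setMethod("show", "ModelCandidate", function(object) {
  cat("ModelCandidate:", paste(object@subset, collapse = " + "), "\n")
  cat(sprintf("  forest: %d trees, depth <= %d, seed %g\n", object@nTrees,
              object@maxDepth, object@seed))
  cat(sprintf("  resubstitution accuracy: %.3f\n", object@accuracyResub))
  if (!is.na(object@accuracyValidated))
    cat(sprintf("  validated accuracy: %.3f +/- %.3f (%d bootstraps, ratio %g)\n",
                object@accuracyValidated, object@accuracySd, object@nBoot,
                object@sampleRatio))
})
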