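#' Additive prediction for a drug combination
#'
#' Predicts the percent-of-control phospholipid effect of a combination from
#' its single-agent effects at the combination's per-component
#' concentrations, assuming additivity on the percent-excess-over-control
#' scale:
#' \deqn{100 + \sum_i (e_i - 100).}
#' The prediction is permutation-invariant and associative, and a component
#' with effect exactly 100 (no effect) leaves it unchanged.
#'
#' @param effects numeric vector of single-agent percent-of-control effects
#'   (nonnegative, nonempty).
#' @return numeric(1), predicted percent of control.
#' @examples
#' additivePrediction(c(134, 144))                 # 178
#' additivePrediction(c(114, 102, 134, 144, 128))  # 222
#' @export
additivePrediction <- function(effects) {
  if (!length(effects)) stop("at least one component effect is required")
  if (anyNA(effects)) stop("component effects must not be missing")
  if (any(effects < 0)) stop("component effects must be >= 0")
  100 + sum(effects - 100)
}

#' Compare an observed combination effect with the additive prediction
#'
#' Computes the additive prediction from the single-agent effects and
#' reports the observed/predicted ratio and the excess ratio
#' \code{(observed - 100) / (predicted - 100)} (NA when the prediction is
#' exactly 100, where the excess scale is undefined). The interaction is
#' classified as additive when the observed effect matches the prediction
#' within the observed SD (exact equality when no SD is supplied), else
#' super-additive when the excess over control exceeds the predicted excess
#' and sub-additive otherwise.
#'
#' @param componentEffects numeric vector of single-agent percent-of-control
#'   effects.
#' @param observed observed percent-of-control effect of the combination.
#' @param observedSd SD of the observed effect (optional).
#' @return one-row data.frame with columns \code{predicted}, \code{observed},
#'   \code{observed_sd}, \code{ratio}, \code{excess_ratio},
#'   \code{classification}.
#' @examples
#' compareCombination(c(114, 102, 134, 144, 128), observed = 380,
#'                    observedSd = 40)  # super-additive
#' @export
compareCombination <- function(componentEffects, observed,
                               observedSd = NA_real_) {
  if (length(observed) != 1L || is.na(observed))
    stop("a single observed effect is required")
  predicted <- additivePrediction(componentEffects)
  ratio <- observed / predicted
  excess <- if (predicted == 100) NA_real_
            else (observed - 100) / (predicted - 100)
  tol <- if (is.na(observedSd)) 0 else observedSd
  classification <-
    if (abs(observed - predicted) <= tol) "additive"
    else if (observed > predicted) "super-additive"
    else "sub-additive"
  data.frame(predicted = predicted, observed = observed,
             observed_sd = observedSd, ratio = ratio, excess_ratio = excess,
             classification = classification, stringsAsFactors = FALSE)
}

#' Additivity analysis for a table of combination experiments
#'
#' Joins single-agent effects from a screen summary onto a combination
#' table and runs [compareCombination()] per row.
#'
#' @param combinations data.frame with columns \code{combination_id},
#'   \code{component_ids} (semicolon-separated compound ids),
#'   \code{concentration_each_uM}, \code{observed_effect},
#'   \code{observed_sd}.
#' @param summary a [ScreenSummary-class] object holding the single-agent
#'   effects at the matching concentration.
#' @return data.frame, one row per combination, with the prediction, ratios
#'   and classification.
#' @export
compareCombinations <- function(combinations, summary) {
  stopifnot(is.data.frame(combinations), is(summary, "ScreenSummary"))
  tab <- screenTable(summary)
  out <- vector("list", nrow(combinations))
  for (i in seq_len(nrow(combinations))) {
    row <- combinations[i, ]
    ids <- trimws(strsplit(as.character(row$component_ids), ";",
                           fixed = TRUE)[[1]])
    sel <- tab$compound_id %in% ids &
      tab$concentration_uM == row$concentration_each_uM
    found <- tab$compound_id[sel]
    if (length(miss <- setdiff(ids, found)))
      stop("no single-agent effect at ", row$concentration_each_uM,
           " uM for: ", paste(miss, collapse = ", "))
    cmp <- compareCombination(tab$percent_of_control[sel],
                              row$observed_effect, row$observed_sd)
    out[[i]] <- cbind(data.frame(combination_id = row$combination_id,
                                 n_components = length(ids),
                                 stringsAsFactors = FALSE), cmp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
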