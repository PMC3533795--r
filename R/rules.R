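#' Read a compound descriptor table
#'
#' Reads a comma-separated descriptor table with columns \code{compound_id},
#' \code{logp}, \code{pka_basic_max_calc} (optionally
#' \code{pka_basic_max_exp}), \code{mw}, \code{hbd}, \code{hba} and any
#' further named numeric descriptor columns. When an experimental pKa is
#' present it overrides the calculated one: measured values take precedence
#' over predictions for compounds near the classification boundary. The
#' returned table carries the resolved value in \code{pka_basic_max}
#' (NA encodes a compound with no basic center).
#'
#' @param file path to a CSV file.
#' @return data.frame keyed by \code{compound_id}.
#' @export
readDescriptorTable <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("compound_id", "logp", "mw", "hbd", "hba")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("descriptor table ", file, " is missing columns: ",
         paste(miss, collapse = ", "))
  if ("pka_basic_max" %in% names(d)) {
    pka <- d$pka_basic_max
  } else if ("pka_basic_max_calc" %in% names(d)) {
    pka <- d$pka_basic_max_calc
  } else {
    stop("descriptor table ", file,
         " needs a pka_basic_max or pka_basic_max_calc column")
  }
  if ("pka_basic_max_exp" %in% names(d)) {
    exp_ <- d$pka_basic_max_exp
    pka <- ifelse(is.na(exp_), pka, exp_)
  }
  d$pka_basic_max <- pka
  d$pka_basic_max_calc <- NULL
  d$pka_basic_max_exp <- NULL
  d
}

.ruleColumns <- function(props, need) {
  miss <- setdiff(need, names(props))
  if (length(miss))
    stop("descriptor table is missing required field(s): ",
         paste(miss, collapse = ", "))
  for (f in setdiff(need, "pka_basic_max"))
    if (anyNA(props[[f]]))
      stop("missing values in required field: ", f)
  invisible(props)
}

#' Cationic amphiphilic drug (CAD) rule
#'
#' Classifies compounds as cationic amphiphilic drugs: a protonatable basic
#' center (highest basic pKa strictly above \code{pkaCut}, default 7.4, so
#' the compound is predominantly charged at physiological pH) combined with
#' high lipophilicity (logP strictly above \code{logpCut}, default 3.0,
#' which for a charged species implies amphiphilic character). A missing
#' \code{pka_basic_max} encodes a compound with no basic center and is
#' classified non-CAD.
#'
#' @param props data.frame with columns \code{logp} and \code{pka_basic_max}
#'   (see [readDescriptorTable()]).
#' @param pkaCut,logpCut strict lower cut-offs (defaults 7.4 and 3.0).
#' @return logical vector, named by \code{compound_id} when present.
#' @examples
#' isCad(data.frame(logp = c(5.08, 4.0, 10), pka_basic_max = c(9.04, 6.85, 7.4)))
#' @export
isCad <- function(props, pkaCut = 7.4, logpCut = 3.0) {
  .ruleColumns(props, c("logp", "pka_basic_max"))
  out <- !is.na(props$pka_basic_max) & props$pka_basic_max > pkaCut &
    props$logp > logpCut
  if ("compound_id" %in% names(props)) names(out) <- props$compound_id
  out
}

#' Count Lipinski rule-of-five violations
#'
#' Counts, per compound, how many of Lipinski's bounds are exceeded
#' (strictly): molecular weight > 500 Da, logP > 5, more than 5 hydrogen-bond
#' donors, more than 10 hydrogen-bond acceptors. A compound sitting exactly
#' on a bound does not violate it.
#'
#' @param props data.frame with columns \code{mw}, \code{logp}, \code{hbd},
#'   \code{hba}.
#' @return integer vector in 0..4, named by \code{compound_id} when present.
#' @export
lo5Violations <- function(props) {
  .ruleColumns(props, c("mw", "logp", "hbd", "hba"))
  out <- (props$mw > 500) + (props$logp > 5) + (props$hbd > 5) +
    (props$hba > 10)
  out <- as.integer(out)
  if ("compound_id" %in% names(props)) names(out) <- props$compound_id
  out
}

#' Lipinski rule-of-five violator flag
#'
#' Flags compounds violating the rule of five. By default a single violation
#' counts (compounds exceeding any bound are the less drug-like set);
#' \code{minViolations = 2} gives the classical multi-violation criterion.
#'
#' @inheritParams lo5Violations
#' @param minViolations minimum number of violated bounds (default 1).
#' @return logical vector.
#' @export
violatesLo5 <- function(props, minViolations = 1) {
  lo5Violations(props) >= minViolations
}
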