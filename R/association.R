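.asTable2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (anyNA(tab) || any(tab < 0)) stop("counts must be nonnegative")
  if (any(tab != round(tab))) stop("counts must be integers")
  storage.mode(tab) <- "double"
  tab
}

.associationResult <- function(tab, testUsed, statistic, df, p, alpha, n) {
  new("AssociationResult", table = tab, testUsed = testUsed,
      statistic = statistic, df = df, pValue = p,
      significant = p < alpha, alpha = alpha, n = n)
}

#' Likelihood-ratio chi-squared (G) test for a 2x2 table
#'
#' Computes the likelihood-ratio statistic
#' \deqn{G = 2 \sum_{cells: O > 0} O \ln(O/E)}
#' with expected counts \eqn{E} from the table margins, no continuity
#' correction, and compares it with the chi-squared distribution on 1 degree
#' of freedom. Cells with an observed count of zero contribute 0 (the
#' \eqn{x \ln x \to 0} limit). The test is undefined when a row or column
#' margin is zero.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.05).
#' @return an [AssociationResult-class] object.
#' @examples
#' gTest(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))  # G = 20.93, p = 4.8e-06
#' @export
gTest <- function(table, alpha = 0.05) {
  tab <- .asTable2x2(table)
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  if (any(rm == 0) || any(cm == 0))
    stop("G test undefined: a row or column margin is zero")
  E <- outer(rm, cm) / N
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  G <- max(G, 0)  # guard tiny negative rounding on exact independence
  p <- stats::pchisq(G, df = 1, lower.tail = FALSE)
  .associationResult(tab, "g_test", G, 1, p, alpha, N)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided exact test using the probability-mass definition: the p-value
#' sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (with a relative tolerance of 1e-7 on the comparison, so ties are counted
#' despite floating-point rounding). A table with a zero row or column
#' margin admits a single configuration and yields p = 1.
#'
#' @inheritParams gTest
#' @return an [AssociationResult-class] object (statistic is NA).
#' @examples
#' fisherExact(matrix(c(10, 0, 0, 10), 2))  # p = 2 / choose(20, 10)
#' @export
fisherExact <- function(table, alpha = 0.05) {
  tab <- .asTable2x2(table)
  N <- sum(tab)
  if (N < 1) stop("the table must contain at least one observation")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- tab[1, 1]
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  pr <- stats::dhyper(support, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  .associationResult(tab, "fisher", NA_real_, NA_real_, p, alpha, N)
}

#' Select the association test for a 2x2 table
#'
#' Fisher's exact test is used for small or unbalanced tables - whenever any
#' observed cell count is below 5 - and the likelihood-ratio chi-squared
#' test otherwise.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return \code{"fisher"} or \code{"g_test"}.
#' @export
chooseTest <- function(table) {
  tab <- .asTable2x2(table)
  if (min(tab) < 5) "fisher" else "g_test"
}

#' Test association between two binary compound labels
#'
#' Builds the 2x2 contingency table cross-classifying two binary labels on
#' their shared compound set (labels observed for only part of the screen
#' are intersected by name), selects the test by the small-count rule of
#' [chooseTest()], and runs it.
#'
#' @param labelsA,labelsB logical vectors named by compound id.
#' @param labelA,labelB display names for the two properties.
#' @param alpha significance level (default 0.05).
#' @return an [AssociationResult-class] object; the table rows are
#'   \code{labelsA} (+/-), columns \code{labelsB} (+/-), and \code{n} records
#'   the intersection size.
#' @export
associate <- function(labelsA, labelsB, labelA = "A", labelB = "B",
                      alpha = 0.05) {
  if (is.null(names(labelsA)) || is.null(names(labelsB)))
    stop("labels must be named by compound id")
  ids <- intersect(names(labelsA), names(labelsB))
  ids <- ids[!is.na(labelsA[ids]) & !is.na(labelsB[ids])]
  if (!length(ids))
    stop("no shared compounds between the two label sets")
  a <- labelsA[ids]; b <- labelsB[ids]
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(stats::setNames(c("+", "-"), NULL),
                                c("+", "-")))
  names(dimnames(tab)) <- c(labelA, labelB)
  res <- if (chooseTest(tab) == "fisher") fisherExact(tab, alpha)
         else gTest(tab, alpha)
  res@n <- length(ids)
  res
}

#' @describeIn associate p-value accessor
#' @param x an AssociationResult object.
#' @export
setMethod("pValue", "AssociationResult", function(x) x@pValue)

#' @describeIn associate accessor for the test that was applied
#' @export
setMethod("testUsed", "AssociationResult", function(x) x@testUsed)

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult (%s, n = %g)\n",
              if (object@testUsed == "g_test")
                "likelihood-ratio chi-squared, no continuity correction"
              else "Fisher's exact test, two-sided", object@n))
  print(object@table)
  if (object@testUsed == "g_test")
    cat(sprintf("  G = %.4g, df = %g, p = %.4g%s\n", object@statistic,
                object@df, object@pValue,
                if (object@significant) " (significant)" else ""))
  else
    cat(sprintf("  p = %.4g%s\n", object@pValue,
                if (object@significant) " (significant)" else ""))
})
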