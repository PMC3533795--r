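# Display names for the second-level ATC classes the screen populates;
# unknown classes print their code only.
.atcClassNames <- c(
  A03 = "Agents for functional gastrointestinal disorders",
  C01 = "Cardiac therapy",
  C04 = "Peripheral vasodilators",
  C07 = "Beta-blocking agents",
  C08 = "Calcium channel blockers",
  D04 = "Antipruritics including antihistamines, anesthetics, etc.",
  G03 = "Sex hormones and modulators of the genital system",
  J01 = "Antibacterials for systemic use",
  L02 = "Endocrine therapy",
  N05 = "Psycholeptics",
  N06 = "Psychoanaleptics",
  P01 = "Antiprotozoals",
  P02 = "Anthelmintics",
  R06 = "Antihistamines for systemic use")

#' Second-level ATC class of a code
#'
#' Truncates full WHO Anatomical Therapeutic Chemical codes to their
#' second level - the anatomical main group letter plus the two-digit
#' therapeutic subgroup (e.g. \code{"N05AD01"} to \code{"N05"}) - and
#' validates the letter-digit-digit pattern.
#'
#' @param codes character vector of ATC codes (length >= 3 each).
#' @return character vector of 3-character class codes.
#' @examples
#' atcSecondLevel(c("N05AD01", "C08"))
#' @export
atcSecondLevel <- function(codes) {
  codes <- as.character(codes)
  if (any(is.na(codes) | nchar(codes) < 3L))
    stop("ATC codes must have at least 3 characters: ",
         paste(codes[is.na(codes) | nchar(codes) < 3L], collapse = ", "))
  cls <- toupper(substr(codes, 1L, 3L))
  bad <- !grepl("^[A-Z][0-9][0-9]$", cls)
  if (any(bad))
    stop("malformed ATC code(s): ", paste(codes[bad], collapse = ", "))
  cls
}

#' ATC class enrichment table
#'
#' Groups compounds by second-level ATC class and tabulates, per class, the
#' number of PLD-active and PLD-inactive compounds and the active ratio
#' \code{n_active / (n_active + n_inactive)}. A compound carrying several
#' codes counts once in each distinct class (duplicate codes mapping to the
#' same class are de-duplicated). Only classes containing at least one
#' active and one inactive compound are listed; rows are sorted by class
#' code. Compounds with an activity call but no ATC code are skipped and
#' recorded in the \code{"skipped"} attribute of the result.
#'
#' @param annotations data.frame with columns \code{compound_id} and
#'   \code{atc_codes} (semicolon-separated full codes; empty or NA for
#'   unannotated compounds).
#' @param activity logical vector of PLD activity named by compound id;
#'   must cover every annotated compound.
#' @return data.frame with columns \code{atc_class}, \code{class_name},
#'   \code{n_active}, \code{n_inactive}, \code{ratio} (exact) and
#'   \code{ratio_display} (half-up rounded to 2 decimals, as conventionally
#'   printed).
#' @export
enrichmentTable <- function(annotations, activity) {
  stopifnot(is.data.frame(annotations),
            all(c("compound_id", "atc_codes") %in% names(annotations)))
  if (is.null(names(activity))) stop("activity must be named by compound id")
  codes <- as.character(annotations$atc_codes)
  has <- !is.na(codes) & nzchar(trimws(codes))
  skipped <- as.character(annotations$compound_id[!has])
  ann <- annotations[has, , drop = FALSE]
  unknown <- setdiff(ann$compound_id, names(activity))
  if (length(unknown))
    stop("no activity call for annotated compound(s): ",
         paste(unknown, collapse = ", "))
  pieces <- strsplit(as.character(ann$atc_codes), ";", fixed = TRUE)
  long <- data.frame(
    compound_id = rep(as.character(ann$compound_id), lengths(pieces)),
    atc_class = atcSecondLevel(trimws(unlist(pieces))),
    stringsAsFactors = FALSE)
  long <- unique(long)  # one count per compound per class
  long$active <- activity[long$compound_id]
  nA <- tapply(long$active, long$atc_class, sum)
  nT <- tapply(long$active, long$atc_class, length)
  out <- data.frame(atc_class = names(nA),
                    n_active = as.integer(nA),
                    n_inactive = as.integer(nT - nA),
                    stringsAsFactors = FALSE)
  out <- out[out$n_active >= 1L & out$n_inactive >= 1L, , drop = FALSE]
  out <- out[order(out$atc_class), , drop = FALSE]
  out$class_name <- ifelse(out$atc_class %in% names(.atcClassNames),
                           .atcClassNames[out$atc_class], out$atc_class)
  out$ratio <- out$n_active / (out$n_active + out$n_inactive)
  out$ratio_display <- roundHalfUp(out$ratio, 2)
  out <- out[c("atc_class", "class_name", "n_active", "n_inactive",
               "ratio", "ratio_display")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
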