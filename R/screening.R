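#' Construct a PLDScreen from a well table
#'
#' @param wells data.frame with columns \code{plate_id}, \code{compound_id},
#'   \code{concentration_uM}, \code{channel} (\code{"lipidtox"} or
#'   \code{"dapi"}), \code{replicate}, \code{role} (\code{"test"},
#'   \code{"control"} or \code{"background"}) and \code{fluorescence}
#'   (raw units, nonnegative).
#' @return a [PLDScreen-class] object.
#' @examples
#' wells <- data.frame(plate_id = "P1", compound_id = c("A", "A", "CTRL", "BG"),
#'                     concentration_uM = c(2.5, 2.5, 0, 0),
#'                     channel = "lipidtox", replicate = c(1, 2, 1, 1),
#'                     role = c("test", "test", "control", "background"),
#'                     fluorescence = c(900, 950, 500, 100))
#' PLDScreen(wells)
#' @export
PLDScreen <- function(wells) {
  wells <- as.data.frame(wells)
  wells$channel <- as.character(wells$channel)
  wells$role <- as.character(wells$role)
  wells$compound_id <- as.character(wells$compound_id)
  wells$plate_id <- as.character(wells$plate_id)
  new("PLDScreen", wells = wells)
}

#' Read a well table from delimited text
#'
#' Expects a comma-separated file with a header row and exactly the columns
#' described in [PLDScreen()].
#'
#' @param file path to a CSV file.
#' @return a [PLDScreen-class] object.
#' @export
readWellTable <- function(file) {
  w <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(.WELL_COLUMNS, names(w))
  if (length(miss))
    stop("well table ", file, " is missing columns: ",
         paste(miss, collapse = ", "))
  PLDScreen(w[.WELL_COLUMNS])
}

#' @describeIn PLDScreen well table accessor
#' @param x a PLDScreen object.
#' @export
setMethod("wells", "PLDScreen", function(x) x@wells)

setMethod("show", "PLDScreen", function(object) {
  w <- object@wells
  cat("PLDScreen:", nrow(w), "wells,",
      length(unique(w$compound_id[w$role == "test"])), "test compounds,",
      length(unique(w$plate_id)), "plate(s)\n")
  cat("  channels:", paste(sort(unique(w$channel)), collapse = ", "), "\n")
  cat("  test concentrations (uM):",
      paste(sort(unique(w$concentration_uM[w$role == "test"])),
            collapse = ", "), "\n")
})

#' Normalize well fluorescence to percent of control
#'
#' Per plate and per channel, subtracts the mean background-well fluorescence
#' and expresses each test well as a percentage of the background-subtracted
#' control-well mean:
#' \deqn{100 (raw - \bar{B}) / (\bar{C} - \bar{B}).}
#' Control wells therefore map to mean 100 by construction, and the result is
#' invariant to rescaling all raw values on a plate by a common factor.
#' Normalized values below 0 (raw fluorescence under the background mean,
#' i.e. measurement noise) are clamped to 0 with a warning.
#'
#' @param x a [PLDScreen-class] object or a well data.frame.
#' @return data.frame with columns \code{plate_id}, \code{compound_id},
#'   \code{concentration_uM}, \code{channel}, \code{replicate},
#'   \code{percent_of_control}; one row per test well.
#' @examples
#' scr <- PLDScreen(data.frame(
#'   plate_id = "P1", compound_id = c("A", "CTRL", "BG"),
#'   concentration_uM = c(2.5, 0, 0), channel = "lipidtox",
#'   replicate = 1, role = c("test", "control", "background"),
#'   fluorescence = c(250, 150, 50)))
#' normalizeWells(scr)  # 100 * (250 - 50) / (150 - 50) = 200
#' @export
normalizeWells <- function(x) {
  if (is(x, "PLDScreen")) w <- x@wells else w <- wells(PLDScreen(x))
  grp <- interaction(w$plate_id, w$channel, drop = TRUE, sep = " / channel ")
  out <- vector("list", nlevels(grp))
  clamped <- 0L
  for (i in seq_len(nlevels(grp))) {
    g <- w[grp == levels(grp)[i], , drop = FALSE]
    bg <- g$fluorescence[g$role == "background"]
    ctrl <- g$fluorescence[g$role == "control"]
    where <- paste0("plate '", g$plate_id[1L], "', channel '", g$channel[1L], "'")
    if (!length(bg)) stop("no background wells on ", where)
    if (!length(ctrl)) stop("no control wells on ", where)
    span <- mean(ctrl) - mean(bg)
    if (span <= 0)
      stop("control mean <= background mean on ", where,
           ": plate is uninterpretable")
    tw <- g[g$role == "test", , drop = FALSE]
    pct <- 100 * (tw$fluorescence - mean(bg)) / span
    neg <- pct < 0
    if (any(neg)) {
      clamped <- clamped + sum(neg)
      pct[neg] <- 0
    }
    out[[i]] <- data.frame(plate_id = tw$plate_id,
                           compound_id = tw$compound_id,
                           concentration_uM = tw$concentration_uM,
                           channel = tw$channel, replicate = tw$replicate,
                           percent_of_control = pct,
                           stringsAsFactors = FALSE)
  }
  if (clamped > 0L)
    warning(clamped, " test well(s) below the background mean clamped to 0")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call PLD activity from percent-of-control values
#'
#' A compound is a PLD inducer when its percent-of-control phospholipid
#' signal strictly exceeds the threshold; the default 200 corresponds to a
#' doubling of the cellular phospholipid stain over control. Boundary
#' equality is inactive.
#'
#' @param percent numeric vector of percent-of-control values (>= 0).
#' @param threshold numeric(1), default 200.
#' @return logical vector.
#' @examples
#' classifyPld(c(114, 200, 740.5))  # FALSE FALSE TRUE
#' @export
classifyPld <- function(percent, threshold = 200) {
  if (anyNA(percent)) stop("percent-of-control values must not be missing")
  if (any(percent < 0)) stop("percent-of-control values must be >= 0")
  percent > threshold
}

#' Summarize a screen per compound and concentration
#'
#' Averages normalized replicates per compound x concentration: the
#' percent-of-control mean over LipidTOX replicates, the sample standard
#' deviation (n-1 denominator; NA for a single replicate), the coefficient
#' of variation sd/mean, the mean DAPI percent (NA when no DAPI wells exist)
#' and the activity call via [classifyPld()].
#'
#' @param x a [PLDScreen-class] object, a raw well data.frame, or an
#'   already-normalized data.frame as returned by [normalizeWells()].
#' @param threshold percent-of-control activity threshold (default 200).
#' @return a [ScreenSummary-class] object.
#' @export
summarizeScreen <- function(x, threshold = 200) {
  norm <- if (is.data.frame(x) && "percent_of_control" %in% names(x)) x
          else normalizeWells(x)
  lt <- norm[norm$channel == "lipidtox", , drop = FALSE]
  if (!nrow(lt)) stop("no LipidTOX test wells to summarize")
  da <- norm[norm$channel == "dapi", , drop = FALSE]
  key <- paste(lt$compound_id, lt$concentration_uM, sep = "\r")
  sp <- split(lt$percent_of_control, key)
  first <- lt[match(names(sp), key), c("compound_id", "concentration_uM")]
  m <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
              numeric(1))
  n <- vapply(sp, length, integer(1))
  cv <- ifelse(!is.na(s) & m > 0, s / m, NA_real_)
  dapi <- rep(NA_real_, length(sp))
  if (nrow(da)) {
    dk <- paste(da$compound_id, da$concentration_uM, sep = "\r")
    dm <- vapply(split(da$percent_of_control, dk), mean, numeric(1))
    dapi <- dm[match(names(sp), names(dm))]
  }
  tab <- data.frame(compound_id = first$compound_id,
                    concentration_uM = first$concentration_uM,
                    percent_of_control = unname(m), sd = unname(s),
                    cv = unname(cv), n = unname(n),
                    dapi_percent = unname(dapi),
                    pld_active = classifyPld(unname(m), threshold),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$compound_id, tab$concentration_uM), , drop = FALSE]
  rownames(tab) <- NULL
  new("ScreenSummary", table = tab, threshold = threshold)
}

#' @describeIn summarizeScreen summary table accessor
#' @export
setMethod("screenTable", "ScreenSummary", function(x) x@table)

#' @describeIn summarizeScreen threshold accessor
#' @export
setMethod("activityThreshold", "ScreenSummary", function(x) x@threshold)

#' @describeIn summarizeScreen activity calls, optionally at one concentration
#' @param concentration optional concentration (uM) to restrict to.
#' @export
setMethod("pldActive", "ScreenSummary", function(x, concentration = NULL) {
  tab <- x@table
  if (!is.null(concentration))
    tab <- tab[tab$concentration_uM == concentration, , drop = FALSE]
  stats::setNames(tab$pld_active, tab$compound_id)
})

setMethod("show", "ScreenSummary", function(object) {
  tab <- object@table
  cat("ScreenSummary:", nrow(tab), "compound x concentration rows",
      sprintf("(threshold %g%% of control)\n", object@threshold))
  for (cc in sort(unique(tab$concentration_uM))) {
    sub <- tab[tab$concentration_uM == cc, ]
    cat(sprintf("  %g uM: %d compounds, %d active\n", cc, nrow(sub),
                sum(sub$pld_active)))
  }
})

#' Write a screen summary as delimited text
#'
#' @param summary a [ScreenSummary-class] object.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeSummaryTable <- function(summary, file) {
  stopifnot(is(summary, "ScreenSummary"))
  utils::write.csv(screenTable(summary), file, row.names = FALSE)
  invisible(file)
}

#' Concentration-consistency report
#'
#' Compares activity calls and effect sizes between a low and a high test
#' concentration. Compounds active at the low but not the high concentration
#' are listed as inclusion violations (none are expected when effects grow
#' with concentration). Over the compounds active at the high concentration,
#' the report gives the mean and SD of the effect increase - by default the
#' difference \code{percent_high - percent_low} in percent points of control
#' (\code{scale = "ratio"} reports \code{percent_high / percent_low} instead)
#' - and the count of those actives whose effect is larger at the high
#' concentration.
#'
#' @param summary a [ScreenSummary-class] object covering both concentrations.
#' @param concLow,concHigh the two concentrations (uM; defaults 2.5 and 5).
#' @param scale \code{"points"} (default) or \code{"ratio"}.
#' @return a [ScreenQCReport-class] object.
#' @export
consistencyReport <- function(summary, concLow = 2.5, concHigh = 5,
                              scale = c("points", "ratio")) {
  stopifnot(is(summary, "ScreenSummary"))
  scale <- match.arg(scale)
  tab <- screenTable(summary)
  lo <- tab[tab$concentration_uM == concLow, , drop = FALSE]
  hi <- tab[tab$concentration_uM == concHigh, , drop = FALSE]
  onlyLo <- setdiff(lo$compound_id, hi$compound_id)
  onlyHi <- setdiff(hi$compound_id, lo$compound_id)
  if (length(onlyLo) || length(onlyHi))
    stop("compound sets differ between concentrations; missing at high: ",
         paste(onlyLo, collapse = ", "), "; missing at low: ",
         paste(onlyHi, collapse = ", "))
  hi <- hi[match(lo$compound_id, hi$compound_id), , drop = FALSE]
  viol <- lo$compound_id[lo$pld_active & !hi$pld_active]
  act <- hi$pld_active
  d <- if (scale == "points") hi$percent_of_control - lo$percent_of_control
       else hi$percent_of_control / lo$percent_of_control
  new("ScreenQCReport",
      inclusionViolations = viol,
      meanEffectIncrease = if (any(act)) mean(d[act]) else NA_real_,
      sdEffectIncrease = if (sum(act) > 1L) stats::sd(d[act]) else NA_real_,
      nIncreasing = sum(act &
        hi$percent_of_control > lo$percent_of_control),
      nActiveHigh = sum(act), nActiveLow = sum(lo$pld_active),
      scale = scale)
}

#' DAPI cell-count quality control
#'
#' Flags compound x concentration rows whose mean DAPI percent-of-control
#' (a proxy for adherent cell number) fell below \code{lossThreshold}, and
#' tabulates the mean and SD of the DAPI percent for PLD-active compounds,
#' inactive compounds and all compounds at each concentration.
#'
#' @param summary a [ScreenSummary-class] object with DAPI data.
#' @param lossThreshold percent-of-control cell-loss cut-off (default 50).
#' @return a [ScreenQCReport-class] object.
#' @export
dapiQc <- function(summary, lossThreshold = 50) {
  stopifnot(is(summary, "ScreenSummary"))
  tab <- screenTable(summary)
  if (anyNA(tab$dapi_percent))
    stop("dapi_percent missing for: ",
         paste(unique(tab$compound_id[is.na(tab$dapi_percent)]),
               collapse = ", "))
  flags <- tab[tab$dapi_percent < lossThreshold,
               c("compound_id", "concentration_uM", "dapi_percent"),
               drop = FALSE]
  rownames(flags) <- NULL
  rows <- list()
  for (cc in sort(unique(tab$concentration_uM))) {
    sub <- tab[tab$concentration_uM == cc, , drop = FALSE]
    pick <- list(active = sub$pld_active, inactive = !sub$pld_active,
                 total = rep(TRUE, nrow(sub)))
    for (g in names(pick)) {
      v <- sub$dapi_percent[pick[[g]]]
      if (!length(v)) next  # empty groups reported as absent
      rows[[length(rows) + 1L]] <- data.frame(
        concentration_uM = cc, group = g, n = length(v), mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  new("ScreenQCReport",
      dapiGroupMeans = do.call(rbind, rows), dapiFlags = flags)
}

setMethod("show", "ScreenQCReport", function(object) {
  cat("ScreenQCReport\n")
  if (!is.na(object@nActiveHigh)) {
    cat(sprintf("  actives: %d (high conc), %d (low conc); inclusion violations: %d\n",
                object@nActiveHigh, object@nActiveLow,
                length(object@inclusionViolations)))
    cat(sprintf("  effect increase (%s): %.1f +/- %.1f; increasing: %d of %d\n",
                object@scale, object@meanEffectIncrease,
                object@sdEffectIncrease, object@nIncreasing,
                object@nActiveHigh))
  }
  if (nrow(object@dapiGroupMeans)) {
    cat("  DAPI group means:\n")
    print(object@dapiGroupMeans, row.names = FALSE)
    cat(sprintf("  DAPI loss flags: %d\n", nrow(object@dapiFlags)))
  }
})
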