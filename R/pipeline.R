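.readOrPass <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the screening pipeline end to end
#'
#' Orchestrates the stages in dependency order - simulate (or ingest
#' user-supplied tables), summarize, rules, associate, enrich, train, combos
#' - writing every stage output as comma-separated text under \code{outdir}
#' plus a JSON run manifest (configuration snapshot, seeds, file digests,
#' per-stage row counts, package version, timestamp). Re-running with the
#' same inputs and configuration reproduces every stage output byte for
#' byte; only the manifest timestamp differs.
#'
#' @param config a [SyntheticConfig-class] used when no well table is
#'   supplied (default \code{syntheticConfig()}).
#' @param outdir output directory (created if needed).
#' @param threshold percent-of-control activity threshold (default 200).
#' @param stages character vector of stages to run, in any order; dependency
#'   order is enforced internally. Default: all except \code{"combos"},
#'   which needs a combination table.
#' @param wellTable,descriptorTable,annotationTable optional user-supplied
#'   inputs (paths to CSV files or data.frames); when \code{wellTable} is
#'   NULL the synthetic generator provides all three.
#' @param combinations optional combination table (path or data.frame, see
#'   [compareCombinations()]); required by the \code{"combos"} stage.
#' @param trainControl model-search settings, either a list or the path to
#'   a JSON key-value file with the same fields: \code{k} (prefilter
#'   size, default 113), \code{nTrees} (5), \code{maxDepth} (8),
#'   \code{maxSize} (4), \code{beamWidth} (default: descriptor count),
#'   \code{seeds} (default: the configuration seed), \code{nBoot} (100),
#'   \code{sampleRatio} (1.0), \code{nValidate} (how many top candidates to
#'   bootstrap-validate, default all).
#' @param quiet suppress per-stage messages (default FALSE).
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config = syntheticConfig(), outdir,
                        threshold = 200,
                        stages = c("simulate", "summarize", "rules",
                                   "associate", "enrich", "train"),
                        wellTable = NULL, descriptorTable = NULL,
                        annotationTable = NULL, combinations = NULL,
                        trainControl = list(), quiet = FALSE) {
  order_ <- c("simulate", "summarize", "rules", "associate", "enrich",
              "train", "combos")
  stages <- order_[order_ %in% match.arg(stages, order_, several.ok = TRUE)]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pldscreen] ", ...)
  counts <- list()
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    counts[[name]] <<- nrow(df)
    path
  }

  # --- inputs: synthetic generation or user files -------------------------
  truth <- NULL
  if (is.null(wellTable)) {
    if (!"simulate" %in% stages)
      stop("stage 'simulate' is required when no well table is supplied")
    sim <- simulateScreen(config)
    screen <- sim$screen
    props <- sim$properties
    ann <- sim$annotations
    truth <- data.frame(compound_id = names(sim$trueLabels),
                        true_active = unname(sim$trueLabels),
                        label = unname(sim$labels[names(sim$trueLabels)]),
                        stringsAsFactors = FALSE)
    put(wells(screen), "wells.csv")
    put(props, "descriptors.csv")
    put(ann, "annotations.csv")
    put(truth, "truth.csv")
    say("simulate: ", nrow(wells(screen)), " wells, ",
        nrow(props), " compounds")
  } else {
    screen <- if (is.character(wellTable)) readWellTable(wellTable)
              else PLDScreen(wellTable)
    props <- .readOrPass(descriptorTable, readDescriptorTable)
    ann <- .readOrPass(annotationTable,
                       function(f) utils::read.csv(f, stringsAsFactors = FALSE))
  }

  # --- summarize ----------------------------------------------------------
  summary <- NULL
  if ("summarize" %in% stages) {
    summary <- summarizeScreen(screen, threshold = threshold)
    put(screenTable(summary), "summary.csv")
    say("summarize: ", nrow(screenTable(summary)),
        " compound x concentration rows")
  }

  highConc <- max(wells(screen)$concentration_uM)
  activeHigh <- if (!is.null(summary)) pldActive(summary, highConc) else NULL

  # --- rules --------------------------------------------------------------
  rules <- NULL
  if ("rules" %in% stages) {
    if (is.null(props)) stop("stage 'rules' failed: no descriptor table")
    rules <- data.frame(compound_id = props$compound_id,
                        is_cad = unname(isCad(props)),
                        lo5_violations = unname(lo5Violations(props)),
                        violates_lo5 = unname(violatesLo5(props)),
                        stringsAsFactors = FALSE)
    put(rules, "rules.csv")
    say("rules: ", sum(rules$is_cad), " CADs, ", sum(rules$violates_lo5),
        " rule-of-five violators")
  }

  # --- associations -------------------------------------------------------
  if ("associate" %in% stages) {
    if (is.null(activeHigh) || is.null(rules) || is.null(ann))
      stop("stage 'associate' failed: needs summary, rules and annotations")
    lab <- function(v, ids) stats::setNames(as.logical(v), ids)
    pairs <- list(
      asm_inhibitor = lab(ann$asm_inhibitor, ann$compound_id),
      bbb_permeable = lab(ann$bbb_permeable, ann$compound_id),
      is_cad = lab(rules$is_cad, rules$compound_id),
      violates_lo5 = lab(rules$violates_lo5, rules$compound_id))
    res <- lapply(names(pairs), function(nm) {
      r <- associate(activeHigh, pairs[[nm]], labelA = "pld_active",
                     labelB = nm)
      data.frame(property = nm, n = r@n,
                 a = r@table[1, 1], b = r@table[1, 2],
                 c = r@table[2, 1], d = r@table[2, 2],
                 test = testUsed(r), statistic = r@statistic, df = r@df,
                 p_value = pValue(r), significant = r@significant,
                 stringsAsFactors = FALSE)
    })
    put(do.call(rbind, res), "associations.csv")
    say("associate: ", length(pairs), " property pairs tested")
  }

  # --- ATC enrichment -----------------------------------------------------
  if ("enrich" %in% stages) {
    if (is.null(activeHigh) || is.null(ann))
      stop("stage 'enrich' failed: needs summary and annotations")
    enr <- enrichmentTable(ann[c("compound_id", "atc_codes")], activeHigh)
    put(enr, "enrichment.csv")
    say("enrich: ", nrow(enr), " ATC classes with both groups present")
  }

  # --- model search -------------------------------------------------------
  if ("train" %in% stages) {
    if (is.null(activeHigh) || is.null(props))
      stop("stage 'train' failed: needs summary and descriptors")
    if (is.character(trainControl))  # path to a JSON key-value file
      trainControl <- jsonlite::read_json(trainControl, simplifyVector = TRUE)
    tc <- utils::modifyList(
      list(k = 113, nTrees = 5, maxDepth = 8, maxSize = 4, beamWidth = NULL,
           seeds = config@seed, nBoot = 100, sampleRatio = 1.0,
           nValidate = Inf), trainControl)
    num <- vapply(props, is.numeric, logical(1))
    x <- as.matrix(props[num])
    rownames(x) <- props$compound_id
    keep <- !is.na(activeHigh[rownames(x)])
    x <- x[keep, , drop = FALSE]
    y <- as.logical(activeHigh[rownames(x)])
    xf <- prefilterDescriptors(x, y, k = tc$k)
    bw <- if (is.null(tc$beamWidth)) ncol(xf) else tc$beamWidth
    cands <- beamSearch(xf, y, rfConfig(tc$nTrees, tc$maxDepth),
                        beamWidth = bw, maxSize = tc$maxSize,
                        seeds = tc$seeds)
    nv <- min(length(cands), tc$nValidate)
    cands <- cands[seq_len(nv)]
    cands <- lapply(cands, function(cand)
      bootstrapValidate(xf, y, cand, nBoot = tc$nBoot,
                        sampleRatio = tc$sampleRatio))
    cands <- rankModels(cands)
    put(candidateTable(cands), "models.csv")
    say("train: ", length(cands), " validated candidates; best ",
        sprintf("%.3f", if (length(cands))
          cands[[1]]@accuracyValidated else NA))
  }

  # --- combinations -------------------------------------------------------
  if ("combos" %in% stages) {
    comb <- .readOrPass(combinations,
                        function(f) utils::read.csv(f, stringsAsFactors = FALSE))
    if (is.null(comb) || is.null(summary))
      stop("stage 'combos' failed: needs a combination table and summary")
    put(compareCombinations(comb, summary), "combinations.csv")
    say("combos: ", nrow(comb), " combinations compared")
  }

  manifest <- list(
    package = "pldscreen",
    version = as.character(utils::packageVersion("pldscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config@seed,
    threshold = threshold,
    stages = stages,
    config = .configAsList(config),
    row_counts = counts,
    file_digests = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}
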