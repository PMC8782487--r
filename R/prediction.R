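#' Construct a FunctionalTable
#'
#' @param scores numeric matrix (positions x 20 amino acids; columns
#'   may be in any order but must be named with one-letter codes).
#' @param positions integer sequence positions (defaults to the
#'   rownames of `scores`).
#' @param wtAa wild-type one-letter code per position.
#' @return a [FunctionalTable].
#' @export
functionalTable <- function(scores, positions = NULL, wtAa) {
  if (is.null(positions)) positions <- as.integer(rownames(scores))
  scores <- as.matrix(scores[, AA1, drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- positions
  new("FunctionalTable", scores = scores, positions = as.integer(positions),
      wtAa = as.character(wtAa))
}

#' Read a functional-score CSV
#'
#' Expected columns: `position`, `wt_aa`, then the 20 one-letter
#' amino-acid columns; empty cells are missing measurements.
#'
#' @param path CSV file path.
#' @return a [FunctionalTable].
#' @export
readFunctionalTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("position", "wt_aa", AA1) %in% names(d)))
    stop("functional CSV must have columns position, wt_aa and the 20 amino acids")
  functionalTable(as.matrix(d[, AA1]), positions = d$position,
                  wtAa = d$wt_aa)
}

#' Write a FunctionalTable as CSV
#'
#' @param func a [FunctionalTable].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeFunctionalTable <- function(func, path) {
  d <- data.frame(position = func@positions, wt_aa = func@wtAa,
                  func@scores, check.names = FALSE)
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Mean functional score per position
#'
#' Averages the available (non-missing) mutation scores at each
#' position, excluding the synonymous cell (mutation to the wild-type
#' amino acid is not a mutation). Positions with no data are dropped.
#'
#' @param func a [FunctionalTable].
#' @return named numeric vector (names = positions).
#' @export
positionMeans <- function(func) {
  sc <- func@scores
  for (i in seq_along(func@positions)) sc[i, func@wtAa[i]] <- NA
  m <- rowMeans(sc, na.rm = TRUE)
  m[!is.nan(m)]
}

.selectByMean <- function(func, percent, decreasing) {
  if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
  m <- positionMeans(func)
  if (length(m) == 0) stop("no scored positions")
  k <- floor(length(m) * percent / 100)
  if (k == 0) stop("selection is empty: floor(n * percent / 100) = 0")
  pos <- as.integer(names(m))
  ord <- order(if (decreasing) -m else m, pos)
  sort(pos[ord][seq_len(k)])
}

#' Functionally sensitive positions (FSPs)
#'
#' The `floor(n * percent / 100)` positions with the lowest mean
#' functional score (strongest loss of function). Ties at the boundary
#' are broken by the lower position number.
#'
#' @param func a [FunctionalTable].
#' @param percent percentage of positions to select (default 40).
#' @return sorted integer vector of positions.
#' @export
selectFSPs <- function(func, percent = 40) {
  .selectByMean(func, percent, decreasing = FALSE)
}

#' Functionally robust positions (FRPs)
#'
#' The `floor(n * percent / 100)` positions with the highest mean
#' functional score (weakest loss of function). Ties are broken by the
#' lower position number.
#'
#' @inheritParams selectFSPs
#' @return sorted integer vector of positions.
#' @export
selectFRPs <- function(func, percent = 40) {
  .selectByMean(func, percent, decreasing = TRUE)
}

#' Construct PredictionParams
#'
#' Defaults reproduce the balanced setting (threshold 9 Angstroms,
#' cutoff vector (1.5, 1.5, 1.5) over nodes/edges/weight, minimum
#' count 2, 40% functional positions). The diameter is computed and
#' reported throughout but excluded from prediction by default.
#'
#' @param thresholdT distance threshold in Angstroms.
#' @param cutoffs per-measure cutoffs in standard deviations; either a
#'   named vector or a single value recycled over `measures`.
#' @param minCount minimum number of measures for which a position
#'   must have a sensitive mutation.
#' @param measures measures used for prediction.
#' @param functionalPercent percentage of positions called FSPs.
#' @return a [PredictionParams].
#' @examples
#' predictionParams()
#' predictionParams(cutoffs = 1, minCount = 1)
#' @export
predictionParams <- function(thresholdT = 9,
                             cutoffs = c(nodes = 1.5, edges = 1.5,
                                         weight = 1.5),
                             minCount = 2,
                             measures = c("nodes", "edges", "weight"),
                             functionalPercent = 40) {
  if (is.null(names(cutoffs))) {
    if (length(cutoffs) == 1) cutoffs <- rep(cutoffs, length(measures))
    names(cutoffs) <- measures
  }
  new("PredictionParams", thresholdT = as.numeric(thresholdT),
      cutoffs = cutoffs, minCount = as.integer(minCount),
      measures = measures,
      functionalPercent = as.numeric(functionalPercent))
}

# Internal classifier core: works from an explicit cutoff vector so
# ROC sweeps can use cutoffs outside the constructor's (0, Inf)
# constraint.
.sensitiveMutations <- function(table, thresholdT, cutoffs, measures) {
  s <- table@scores
  if (!any(abs(s$threshold - thresholdT) < 1e-8))
    stop("threshold ", thresholdT, " absent from the score table")
  out <- lapply(measures, function(m) {
    d <- .tableAt(table, m, thresholdT)
    d <- d[!is.na(d$zscore) & d$zscore > cutoffs[[m]], , drop = FALSE]
    data.frame(position = d$position, mut_aa = d$mut_aa,
               stringsAsFactors = FALSE)
  })
  names(out) <- measures
  out
}

.sensitivePositions <- function(table, thresholdT, cutoffs, measures,
                                minCount) {
  sm <- .sensitiveMutations(table, thresholdT, cutoffs, measures)
  posSets <- lapply(sm, function(d) unique(d$position))
  counts <- table(unlist(posSets))
  sort(as.integer(names(counts))[counts >= minCount])
}

#' Sensitive mutations per measure
#'
#' A mutation is sensitive for a measure when its standardized
#' perturbation score is strictly above that measure's cutoff.
#'
#' @param table a [MutationScoreTable].
#' @param params a [PredictionParams].
#' @return named list (one element per measure used) of data.frames
#'   with columns `position`, `mut_aa`.
#' @export
sensitiveMutations <- function(table, params = predictionParams()) {
  .sensitiveMutations(table, params@thresholdT, params@cutoffs,
                      params@measures)
}

#' Structurally sensitive positions (SSPs)
#'
#' A position is sensitive for a measure when it has at least one
#' sensitive mutation for that measure; it is an SSP when it is
#' sensitive for at least `minCount` of the measures used.
#'
#' @inheritParams sensitiveMutations
#' @return sorted integer vector of positions.
#' @export
sensitivePositions <- function(table, params = predictionParams()) {
  .sensitivePositions(table, params@thresholdT, params@cutoffs,
                      params@measures, params@minCount)
}

#' Structurally robust positions (SRPs)
#'
#' The complement of the SSPs within the scored positions at the
#' prediction threshold.
#'
#' @inheritParams sensitiveMutations
#' @return sorted integer vector of positions.
#' @export
robustPositions <- function(table, params = predictionParams()) {
  setdiff(scoredPositions(table, params@thresholdT),
          sensitivePositions(table, params))
}

#' Write a prediction table as CSV
#'
#' One row per scored position with the per-measure sensitivity flags,
#' the count of sensitive measures and the SSP call.
#'
#' @param table a [MutationScoreTable].
#' @param params a [PredictionParams].
#' @param path output CSV path.
#' @return invisibly, the data.frame written.
#' @export
writePredictions <- function(table, params, path) {
  pos <- scoredPositions(table, params@thresholdT)
  sm <- sensitiveMutations(table, params)
  flags <- vapply(sm, function(d) pos %in% d$position,
                  logical(length(pos)))
  flags <- matrix(flags, nrow = length(pos),
                  dimnames = list(NULL, paste0("sensitive_",
                                               params@measures)))
  count <- rowSums(flags)
  d <- data.frame(position = pos, flags, count = count,
                  is_ssp = count >= params@minCount)
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}
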