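#' Evaluate a predicted position set against a reference set
#'
#' True positives are the intersection of the predicted (SSP) and
#' reference (FSP) sets. Precision and recall are reported as
#' percentages; the null scores are those expected from random
#' prediction of the same number of positions (null precision = the
#' functional percentage, null recall = the prediction percentage);
#' the improvement factor is precision/nullPrecision =
#' recall/nullRecall = tp * total / (|reference| * |predicted|).
#'
#' @param predicted integer vector of predicted positions.
#' @param reference integer vector of reference (functionally
#'   sensitive) positions.
#' @param totalPositions size of the scored-position universe.
#' @return an [EvaluationReport]. Precision and improvement are NA
#'   when nothing is predicted.
#' @examples
#' evaluatePrediction(c(1, 2, 3, 4), c(1, 2, 3, 5), 10)
#' @export
evaluatePrediction <- function(predicted, reference, totalPositions) {
  if (totalPositions <= 0) stop("totalPositions must be positive")
  predicted <- unique(predicted)
  reference <- unique(reference)
  tp <- length(intersect(predicted, reference))
  fp <- length(setdiff(predicted, reference))
  fn <- length(setdiff(reference, predicted))
  nPred <- length(predicted)
  nRef <- length(reference)
  precision <- if (nPred > 0) 100 * tp / nPred else NA_real_
  recall <- if (nRef > 0) 100 * tp / nRef else NA_real_
  predPct <- 100 * nPred / totalPositions
  funcPct <- 100 * nRef / totalPositions
  improvement <- if (nPred > 0 && nRef > 0)
    tp * totalPositions / (nRef * nPred) else NA_real_
  new("EvaluationReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), totalPositions = as.integer(totalPositions),
      precision = precision, recall = recall,
      predictionPercentage = predPct, functionalPercentage = funcPct,
      nullPrecision = funcPct, nullRecall = predPct,
      improvement = improvement)
}

#' ROC curve of the cutoff-vector classifier
#'
#' Sweeps a common cutoff over all measures used (keeping the minimum
#' count fixed), predicting SSPs at each cutoff and scoring them
#' against the FSPs of the functional table. TPR = recall; FPR = false
#' positives / (total scored positions - |FSPs|). The AUC is the
#' trapezoid area under the curve augmented with the (0,0) and (1,1)
#' endpoints.
#'
#' @param table a [MutationScoreTable].
#' @param func a [FunctionalTable].
#' @param params a [PredictionParams] providing the threshold,
#'   measures, minimum count and functional percentage.
#' @param cutoffs ascending numeric grid of cutoffs; default 100
#'   evenly spaced values from 0.03 to 3.
#' @return list with `points` (data.frame `cutoff`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocCurve <- function(table, func, params = predictionParams(),
                     cutoffs = seq(0.03, 3, length.out = 100)) {
  if (length(cutoffs) == 0) stop("cutoff grid must be non-empty")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoff grid must be strictly ascending")
  universe <- scoredPositions(table, params@thresholdT)
  ref <- intersect(selectFSPs(func, params@functionalPercent), universe)
  total <- length(universe)
  if (length(ref) == 0 || length(ref) == total)
    stop("degenerate reference: all or no positions are functionally sensitive")
  pts <- do.call(rbind, lapply(cutoffs, function(cc) {
    cv <- setNames(rep(cc, length(params@measures)), params@measures)
    ssp <- .sensitivePositions(table, params@thresholdT, cv,
                               params@measures, params@minCount)
    tp <- length(intersect(ssp, ref))
    fp <- length(setdiff(ssp, ref))
    data.frame(cutoff = cc, fpr = fp / (total - length(ref)),
               tpr = tp / length(ref))
  }))
  curve <- rbind(data.frame(fpr = 0, tpr = 0),
                 pts[order(pts$fpr, pts$tpr), c("fpr", "tpr")],
                 data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Spearman correlation between per-position structural and
#' functional means
#'
#' Rank correlation over the positions shared by the two maps,
#' reported as an absolute value (structural perturbation and
#' functional loss are expected to be antimonotone) with a two-sided
#' p-value. Ties are handled by average ranks.
#'
#' @param structMeans named numeric vector, e.g. from
#'   [positionMean()].
#' @param funcMeans named numeric vector, e.g. from
#'   [positionMeans()].
#' @return list with `rho` (absolute value) and `p.value`.
#' @export
spearmanByPosition <- function(structMeans, funcMeans) {
  shared <- intersect(names(structMeans), names(funcMeans))
  if (length(shared) < 3) stop("need at least 3 shared positions")
  x <- structMeans[shared]
  y <- funcMeans[shared]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = abs(unname(ct$estimate)), p.value = ct$p.value)
}

#' Default perturbation-cutoff grid
#'
#' 51 cutoffs from 1 to 2 in steps of 0.02, applied identically to all
#' measures used.
#'
#' @param from,to,by grid endpoints and step (standard deviations).
#' @return numeric vector of cutoffs.
#' @export
cutoffGrid <- function(from = 1, to = 2, by = 0.02) {
  round(seq(from, to, by = by), 10)
}

#' Sweep perturbation cutoffs and minimum counts
#'
#' Evaluates the classifier over a grid of common cutoffs and minimum
#' counts against the FSPs of the functional table.
#'
#' @param table a [MutationScoreTable].
#' @param func a [FunctionalTable].
#' @param minCounts integer vector of minimum counts.
#' @param cutoffs numeric vector of common cutoffs; default
#'   [cutoffGrid()].
#' @param params base [PredictionParams] (threshold, measures,
#'   functional percentage).
#' @return data.frame with one row per (minCount, cutoff) holding the
#'   [EvaluationReport] fields.
#' @export
sweepCutoffs <- function(table, func, minCounts = 1:3,
                         cutoffs = cutoffGrid(),
                         params = predictionParams()) {
  universe <- scoredPositions(table, params@thresholdT)
  ref <- intersect(selectFSPs(func, params@functionalPercent), universe)
  rows <- list()
  for (mc in minCounts) {
    for (cc in cutoffs) {
      cv <- setNames(rep(cc, length(params@measures)), params@measures)
      ssp <- .sensitivePositions(table, params@thresholdT, cv,
                                 params@measures, as.integer(mc))
      rep_ <- evaluatePrediction(ssp, ref, length(universe))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(minCount = mc, cutoff = cc),
              as.data.frame(rep_))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep distance thresholds
#'
#' For each threshold present in the score table: the absolute
#' Spearman correlation (and p-value) between per-position structural
#' and functional means for each measure, plus the evaluation report
#' of the classifier at that threshold.
#'
#' @param table a multi-threshold [MutationScoreTable].
#' @param func a [FunctionalTable].
#' @param params a [PredictionParams]; its `thresholdT` is replaced by
#'   each grid threshold in turn.
#' @return data.frame with one row per threshold: `threshold`,
#'   `rho_<measure>` and `p_<measure>` for the four measures (NA where
#'   undefined), and the report fields.
#' @export
sweepThresholds <- function(table, func, params = predictionParams()) {
  ts <- sort(unique(table@scores$threshold))
  fm <- positionMeans(func)
  meas <- c("nodes", "edges", "weight", "diameter")
  rows <- lapply(ts, function(t) {
    cors <- lapply(meas, function(m) {
      sm <- positionMean(table, m, t)
      tryCatch(spearmanByPosition(sm, fm),
               error = function(e) list(rho = NA_real_,
                                        p.value = NA_real_))
    })
    p <- new("PredictionParams", thresholdT = t, cutoffs = params@cutoffs,
             minCount = params@minCount, measures = params@measures,
             functionalPercent = params@functionalPercent)
    universe <- scoredPositions(table, t)
    rep_ <- if (length(universe) > 0) {
      evaluatePrediction(
        sensitivePositions(table, p),
        intersect(selectFSPs(func, params@functionalPercent), universe),
        length(universe))
    } else {
      new("EvaluationReport", tp = 0L, fp = 0L, fn = 0L,
          totalPositions = 0L, precision = NA_real_, recall = NA_real_,
          predictionPercentage = NA_real_, functionalPercentage = NA_real_,
          nullPrecision = NA_real_, nullRecall = NA_real_,
          improvement = NA_real_)
    }
    cbind(data.frame(threshold = t),
          setNames(as.data.frame(lapply(cors, `[[`, "rho")),
                   paste0("rho_", meas)),
          setNames(as.data.frame(lapply(cors, `[[`, "p.value")),
                   paste0("p_", meas)),
          as.data.frame(rep_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
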