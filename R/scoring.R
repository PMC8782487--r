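#' Average raw perturbation scores over chains
#'
#' For proteins with multiple (identical) chains the same mutation is
#' modelled once per chain; the per-chain measures are averaged to give
#' a single score per sequence position. A mutation present in only
#' some chains is averaged over the chains where it is available.
#' Single-chain input passes through unchanged (minus the chain
#' column).
#'
#' @param raw data.frame as returned by [scoreMutantSet()] (columns
#'   `chain`, `position`, `wt_aa`, `mut_aa`, `threshold`, plus the four
#'   measures).
#' @return data.frame keyed by (`position`, `wt_aa`, `mut_aa`,
#'   `threshold`) with chain-averaged measures.
#' @export
averageOverChains <- function(raw) {
  meas <- c("nodes", "edges", "weight", "diameter")
  out <- aggregate(raw[meas],
                   by = raw[c("position", "wt_aa", "mut_aa", "threshold")],
                   FUN = mean)
  out <- out[order(out$position, out$mut_aa, out$threshold), ]
  rownames(out) <- NULL
  out
}

#' Standardize a numeric column to z-scores
#'
#' Centers by the mean and divides by the population standard
#' deviation (divide by N). Missing values are excluded from the mean
#' and sd and stay missing in the output.
#'
#' @param x numeric vector with at least two non-missing values and
#'   non-zero spread.
#' @return numeric vector of z-scores, same length as `x`.
#' @examples
#' zstandardize(c(2, 4, 6))
#' @export
zstandardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) stop("need at least two non-missing values")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("degenerate distribution: zero spread")
  (x - mu) / sigma
}

#' Standardize a chain-averaged score table
#'
#' Converts the chain-averaged measures to tidy long format, removes
#' synonymous entries (mutation to the wild-type amino acid, whose
#' perturbation is null by construction), and z-scores each
#' (threshold, measure) column with the population standard deviation.
#' A degenerate column (zero spread, e.g. the diameter at a very low
#' threshold where no mutation perturbs anything) yields NA z-scores
#' with a warning rather than an error, so a full threshold sweep can
#' proceed.
#'
#' @param avg data.frame from [averageOverChains()] (or
#'   [scoreMutantSet()] output for a single chain).
#' @return a [MutationScoreTable].
#' @export
standardizeScores <- function(avg) {
  meas <- c("nodes", "edges", "weight", "diameter")
  avg <- avg[avg$wt_aa != avg$mut_aa, , drop = FALSE]
  if (nrow(avg) == 0) stop("no non-synonymous mutations to standardize")
  long <- do.call(rbind, lapply(meas, function(m) {
    data.frame(position = avg$position, wt_aa = avg$wt_aa,
               mut_aa = avg$mut_aa, threshold = avg$threshold,
               measure = m, raw = avg[[m]], stringsAsFactors = FALSE)
  }))
  long$zscore <- NA_real_
  degenerate <- character(0)
  for (g in split(seq_len(nrow(long)),
                  paste(long$threshold, long$measure))) {
    z <- tryCatch(zstandardize(long$raw[g]), error = function(e) NULL)
    if (is.null(z)) {
      degenerate <- c(degenerate,
                      paste0(long$measure[g[1]], "@", long$threshold[g[1]]))
    } else {
      long$zscore[g] <- z
    }
  }
  if (length(degenerate))
    warning("degenerate score column(s), z-scores set to NA: ",
            paste(degenerate, collapse = ", "))
  long <- long[order(long$threshold, long$measure, long$position,
                     long$mut_aa), ]
  rownames(long) <- NULL
  new("MutationScoreTable", scores = long)
}

.tableAt <- function(table, measure, t) {
  s <- table@scores
  s[s$measure == measure & abs(s$threshold - t) < 1e-8, , drop = FALSE]
}

#' Positions with standardized scores at a threshold
#'
#' @param table a [MutationScoreTable].
#' @param t distance threshold.
#' @return sorted integer vector of positions having at least one
#'   non-missing z-score at `t`.
#' @export
scoredPositions <- function(table, t) {
  s <- table@scores
  s <- s[abs(s$threshold - t) < 1e-8 & !is.na(s$zscore), , drop = FALSE]
  sort(unique(s$position))
}

#' Mean standardized score per position
#'
#' Averages the z-scores of the available mutant amino acids at each
#' position, for one measure and threshold. Positions with no
#' non-missing score are absent from the result.
#'
#' @param table a [MutationScoreTable].
#' @param measure one of `"nodes"`, `"edges"`, `"weight"`,
#'   `"diameter"`.
#' @param t distance threshold.
#' @return named numeric vector (names = positions).
#' @export
positionMean <- function(table, measure, t) {
  s <- .tableAt(table, measure, t)
  s <- s[!is.na(s$zscore), , drop = FALSE]
  if (nrow(s) == 0) return(setNames(numeric(0), character(0)))
  m <- tapply(s$zscore, s$position, mean)
  setNames(as.numeric(m), names(m))
}

#' Per-position sign consensus of standardized scores
#'
#' For each position, the percentage of its non-zero-sign scores that
#' share the majority sign: 100 * max(#positive, #negative) / (#positive
#' + #negative). High values mean most mutations at the position
#' perturb in the same direction regardless of the mutant amino acid.
#' Zero scores count toward neither sign; positions with no non-zero
#' score are excluded.
#'
#' @param x a [MutationScoreTable] (uses z-scores) or a
#'   [FunctionalTable] (uses the functional entries).
#' @param measure,t measure and threshold (score tables only).
#' @return list with `perPosition` (data.frame `position`,
#'   `consensus`), `mean` and `sd` over positions.
#' @export
signConsensus <- function(x, measure = "nodes", t = 9) {
  if (is(x, "MutationScoreTable")) {
    s <- .tableAt(x, measure, t)
    vals <- split(s$zscore[!is.na(s$zscore)],
                  s$position[!is.na(s$zscore)])
  } else if (is(x, "FunctionalTable")) {
    sc <- x@scores
    for (i in seq_along(x@positions)) sc[i, x@wtAa[i]] <- NA
    vals <- setNames(lapply(seq_len(nrow(sc)),
                            function(i) sc[i, !is.na(sc[i, ])]),
                     x@positions)
  } else stop("x must be a MutationScoreTable or FunctionalTable")
  cons <- vapply(vals, function(v) {
    np <- sum(v > 0); nn <- sum(v < 0)
    if (np + nn == 0) return(NA_real_)
    100 * max(np, nn) / (np + nn)
  }, numeric(1))
  keep <- !is.na(cons)
  per <- data.frame(position = as.integer(names(cons))[keep],
                    consensus = as.numeric(cons)[keep])
  per <- per[order(per$position), ]
  rownames(per) <- NULL
  list(perPosition = per, mean = mean(per$consensus),
       sd = stats::sd(per$consensus))
}
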