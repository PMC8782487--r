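#' Residue identifiers of an object
#'
#' Residues are labelled "chain:resno" (plus the insertion code when
#' present); these labels are the node names of amino-acid networks.
#'
#' @param x a [ProteinStructure] or network object.
#' @return character vector of residue identifiers, in residue order.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' Chains present in a structure
#'
#' @param x a [ProteinStructure].
#' @return character vector of unique chain identifiers, in file order.
#' @examples
#' s <- generateStructure(syntheticSpec(nResidues = 4, seed = 1))
#' listChains(s)
#' @export
setGeneric("listChains", function(x) standardGeneric("listChains"))

#' Number of residues
#' @param x a [ProteinStructure] object.
#' @return integer count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Topology measures of a perturbation network
#'
#' @param x a [PerturbationNetwork].
#' @return named numeric vector with elements `nodes`, `edges`,
#'   `weight`, `diameter`.
#' @export
setGeneric("measures", function(x) standardGeneric("measures"))

#' Edge table of a network
#' @param x an [AminoAcidNetwork] or [PerturbationNetwork].
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Distance threshold of a network
#' @param x an [AminoAcidNetwork] or [PerturbationNetwork].
#' @return numeric threshold in Angstroms.
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' Tidy data.frame of scores
#' @param x a [MutationScoreTable].
#' @return the underlying tidy data.frame.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

setMethod("residueIds", "ProteinStructure", function(x) {
  a <- x@atoms
  if (nrow(a) == 0) return(character(0))
  key <- paste0(a$chain, ":", a$resno, a$insert)
  ord <- order(a$chain[!duplicated(key)],
               a$resno[!duplicated(key)],
               a$insert[!duplicated(key)])
  unique(key)[ord]
})

setMethod("listChains", "ProteinStructure", function(x) {
  unique(x@atoms$chain)
})

setMethod("nResidues", "ProteinStructure", function(x) {
  length(residueIds(x))
})

setMethod("measures", "PerturbationNetwork", function(x) x@measures)

setMethod("edgeTable", "AminoAcidNetwork", function(x) x@edges)
setMethod("edgeTable", "PerturbationNetwork", function(x) x@edges)
setMethod("networkThreshold", "AminoAcidNetwork", function(x) x@threshold)
setMethod("networkThreshold", "PerturbationNetwork", function(x) x@threshold)
setMethod("scoreTable", "MutationScoreTable", function(x) x@scores)

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure:", nResidues(object), "residues,",
      nrow(object@atoms), "atoms, chains:",
      paste(listChains(object), collapse = ","), "\n")
})

setMethod("show", "AminoAcidNetwork", function(object) {
  cat(sprintf("AminoAcidNetwork (t = %.2f A): %d nodes, %d edges, total weight %d\n",
              object@threshold, length(object@nodes), nrow(object@edges),
              as.integer(sum(object@edges$weight))))
})

setMethod("show", "PerturbationNetwork", function(object) {
  m <- object@measures
  cat(sprintf("PerturbationNetwork (t = %.2f A): %d nodes, %d edges, weight %d, diameter %d\n",
              object@threshold, as.integer(m[["nodes"]]),
              as.integer(m[["edges"]]), as.integer(m[["weight"]]),
              as.integer(m[["diameter"]])))
})

setMethod("show", "MutationScoreTable", function(object) {
  s <- object@scores
  cat("MutationScoreTable:", length(unique(s$position)), "positions,",
      length(unique(s$threshold)), "thresholds,",
      nrow(s), "rows\n")
})

setMethod("show", "FunctionalTable", function(object) {
  cat("FunctionalTable:", length(object@positions), "positions,",
      sum(!is.na(object@scores)), "scored entries\n")
})

setMethod("show", "PredictionParams", function(object) {
  cat(sprintf("PredictionParams: t = %.1f A, cutoffs (%s), min count %d, functional %% = %g\n",
              object@thresholdT,
              paste(sprintf("%s=%g", object@measures,
                            object@cutoffs[object@measures]), collapse = ", "),
              object@minCount, object@functionalPercent))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: tp=%d fp=%d fn=%d (n=%d)\n",
              object@tp, object@fp, object@fn, object@totalPositions))
  cat(sprintf("  precision %.1f%% (null %.1f%%), recall %.1f%% (null %.1f%%), improvement %.2f\n",
              object@precision, object@nullPrecision, object@recall,
              object@nullRecall, object@improvement))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d residues x %d atoms, spacing %.1f A, jitter %.1f A, displacement %.2f A, seed %d\n",
              object@nResidues, object@atomsPerResidue,
              object@backboneSpacing, object@atomJitterSd,
              object@mutationDisplacement, object@seed))
})

#' Coerce an EvaluationReport to a one-row data.frame
#'
#' @param x an [EvaluationReport].
#' @param row.names,optional,... ignored; present for the generic.
#' @return one-row data.frame with the confusion counts and scores.
#' @export
as.data.frame.EvaluationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(tp = x@tp, fp = x@fp, fn = x@fn,
             totalPositions = x@totalPositions,
             precision = x@precision, recall = x@recall,
             predictionPercentage = x@predictionPercentage,
             functionalPercentage = x@functionalPercentage,
             nullPrecision = x@nullPrecision, nullRecall = x@nullRecall,
             improvement = x@improvement)
}
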