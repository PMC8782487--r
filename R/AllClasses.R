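#' @import methods
#' @importFrom stats sd cor.test rnorm rlnorm aggregate setNames
#' @importFrom utils read.csv write.csv
NULL

# The 20 standard amino acids; column order of functional tables.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
         "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
         "TRP", "TYR")
names(AA3) <- AA1
AA_321 <- setNames(AA1, AA3)

#' ProteinStructure: residues with atom coordinates
#'
#' Holds the atoms of a protein chain set after filtering: one row per
#' atom with its chain, residue number, insertion code, residue type
#' (3-letter code), atom name and coordinates in Angstroms. A residue is
#' identified by (chain, resno, insert); the residue order is the
#' lexicographic order of these identifiers.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `x`, `y`, `z`.
#' @seealso [readStructure()], [proteinStructure()], [buildNetwork()]
#' @exportClass ProteinStructure
setClass("ProteinStructure", representation(atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0 && !all(is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  TRUE
})

#' AminoAcidNetwork: weighted residue contact graph at threshold t
#'
#' Nodes are residue identifiers ("chain:resno\[insert\]"); an edge between
#' two residues carries the number of inter-residue atom pairs at
#' Euclidean distance strictly less than the threshold. Residue pairs
#' with zero atom pairs have no edge; there are no self-edges.
#'
#' @slot threshold distance threshold t in Angstroms.
#' @slot nodes character vector of residue identifiers (all residues of
#'   the structure, including isolated ones), in residue order.
#' @slot edges data.frame with columns `from`, `to`, `weight`; `from`
#'   precedes `to` in the node order.
#' @seealso [buildNetwork()], [perturbationNetwork()], [adjacencyMatrix()]
#' @exportClass AminoAcidNetwork
setClass("AminoAcidNetwork",
         representation(threshold = "numeric", nodes = "character",
                        edges = "data.frame"))

.validEdges <- function(edges, nodes, selfOk = FALSE) {
  if (!all(c("from", "to", "weight") %in% names(edges)))
    return("edges must have columns from, to, weight")
  if (nrow(edges) == 0) return(TRUE)
  if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes))
    return("edge endpoints must be nodes")
  if (any(edges$from == edges$to)) return("self-edges are not allowed")
  if (any(edges$weight <= 0)) return("edge weights must be positive")
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) return("duplicate edges")
  TRUE
}

setValidity("AminoAcidNetwork", function(object) {
  if (length(object@threshold) != 1 || object@threshold <= 0)
    return("threshold must be a single positive number")
  .validEdges(object@edges, object@nodes)
})

#' PerturbationNetwork: pruned |A - B| difference graph
#'
#' The entrywise absolute difference of the wild-type and mutant
#' adjacency matrices, with all-zero rows/columns removed: only residue
#' pairs whose weight changed survive as edges, and only residues
#' incident to a surviving edge remain as nodes. Summarised by four
#' topology measures: number of nodes, number of edges, total weight,
#' and diameter (longest shortest path in hops, computed on the largest
#' connected component; 0 for an empty network).
#'
#' @slot threshold distance threshold t in Angstroms.
#' @slot nodes surviving residue identifiers.
#' @slot edges data.frame `from`, `to`, `weight` (absolute differences).
#' @slot measures named numeric vector `nodes`, `edges`, `weight`,
#'   `diameter`.
#' @seealso [perturbationNetwork()], [measures()]
#' @exportClass PerturbationNetwork
setClass("PerturbationNetwork",
         representation(threshold = "numeric", nodes = "character",
                        edges = "data.frame", measures = "numeric"))

setValidity("PerturbationNetwork", function(object) {
  m <- object@measures
  if (!identical(names(m), c("nodes", "edges", "weight", "diameter")))
    return("measures must be named nodes, edges, weight, diameter")
  ok <- .validEdges(object@edges, object@nodes)
  if (!isTRUE(ok)) return(ok)
  if (m[["nodes"]] != length(object@nodes)) return("nodes measure mismatch")
  if (m[["edges"]] != nrow(object@edges)) return("edges measure mismatch")
  if (m[["weight"]] != sum(object@edges$weight)) return("weight measure mismatch")
  if (nrow(object@edges) == 0 && any(m != 0))
    return("empty network must have all-zero measures")
  if (nrow(object@edges) > 0 &&
      any(table(c(object@edges$from, object@edges$to))[object@nodes] < 1,
          na.rm = TRUE))
    return("no degree-zero nodes allowed")
  TRUE
})

#' MutationScoreTable: standardized per-mutation perturbation scores
#'
#' A tidy table of perturbation scores after chain averaging, removal of
#' synonymous entries and standardization: one row per (position, mutant
#' amino acid, threshold, measure), holding the raw (chain-averaged)
#' value and its z-score. Within each (threshold, measure) group the
#' z-scores have mean 0 and population standard deviation 1 (NA for
#' degenerate groups with zero spread).
#'
#' @slot scores data.frame with columns `position`, `wt_aa`, `mut_aa`,
#'   `threshold`, `measure`, `raw`, `zscore`.
#' @seealso [standardizeScores()], [sensitivePositions()], [positionMean()]
#' @exportClass MutationScoreTable
setClass("MutationScoreTable", representation(scores = "data.frame"))

setValidity("MutationScoreTable", function(object) {
  s <- object@scores
  need <- c("position", "wt_aa", "mut_aa", "threshold", "measure",
            "raw", "zscore")
  if (!all(need %in% names(s)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) == 0) return(TRUE)
  if (any(s$wt_aa == s$mut_aa))
    return("synonymous entries must not appear in standardized scores")
  grp <- split(s$zscore, paste(s$threshold, s$measure))
  for (z in grp) {
    z <- z[!is.na(z)]
    if (length(unique(z)) < 2) next
    n <- length(z)
    if (abs(mean(z)) > 1e-9) return("zscore group mean must be 0")
    if (abs(sqrt(mean((z - mean(z))^2)) - 1) > 1e-9)
      return("zscore group population sd must be 1")
  }
  TRUE
})

#' FunctionalTable: deep-mutational-scanning scores per position
#'
#' A positions x 20 matrix of functional scores (negative = loss of
#' function, positive = gain), with the wild-type amino acid of each
#' position. Missing measurements are NA. The synonymous cell (mutation
#' to the wild-type amino acid) is not a mutation and is ignored by
#' [positionMeans()].
#'
#' @slot scores numeric matrix, rows = positions, columns = the 20
#'   amino acids in alphabetical one-letter order.
#' @slot positions integer vector of sequence positions (row labels).
#' @slot wtAa character vector of wild-type one-letter codes.
#' @seealso [functionalTable()], [readFunctionalTable()], [selectFSPs()]
#' @exportClass FunctionalTable
setClass("FunctionalTable",
         representation(scores = "matrix", positions = "integer",
                        wtAa = "character"))

setValidity("FunctionalTable", function(object) {
  if (ncol(object@scores) != 20 || !identical(colnames(object@scores), AA1))
    return("scores must have the 20 amino-acid columns in order")
  if (nrow(object@scores) != length(object@positions))
    return("one row per position required")
  if (length(object@wtAa) != length(object@positions))
    return("one wild-type amino acid per position required")
  if (anyDuplicated(object@positions)) return("duplicate positions")
  if (!all(object@wtAa %in% AA1)) return("invalid wild-type amino acid")
  TRUE
})

#' PredictionParams: cutoff-vector classifier settings
#'
#' Parameters of the structural-sensitivity classifier: the distance
#' threshold at which standardized scores are read, the per-measure
#' perturbation cutoff vector (in standard deviations above the mean),
#' the minimum count of measures for which a position must have at
#' least one sensitive mutation, the measures used, and the percentage
#' of positions called functionally sensitive.
#'
#' @slot thresholdT distance threshold in Angstroms (default 9).
#' @slot cutoffs named positive numeric vector of per-measure cutoffs.
#' @slot minCount integer, 1..length(measures).
#' @slot measures character subset of nodes/edges/weight/diameter.
#' @slot functionalPercent percentage of positions taken as FSPs.
#' @seealso [predictionParams()], [sensitivePositions()]
#' @exportClass PredictionParams
setClass("PredictionParams",
         representation(thresholdT = "numeric", cutoffs = "numeric",
                        minCount = "integer", measures = "character",
                        functionalPercent = "numeric"))

setValidity("PredictionParams", function(object) {
  allM <- c("nodes", "edges", "weight", "diameter")
  if (!length(object@measures) || !all(object@measures %in% allM))
    return("measures must be a non-empty subset of nodes/edges/weight/diameter")
  if (anyDuplicated(object@measures)) return("duplicate measures")
  if (!all(object@measures %in% names(object@cutoffs)))
    return("cutoffs must name every measure used")
  if (any(object@cutoffs <= 0)) return("cutoff entries must be > 0")
  if (object@minCount < 1L || object@minCount > length(object@measures))
    return("minCount must be in 1..length(measures)")
  if (object@thresholdT <= 0) return("thresholdT must be positive")
  if (object@functionalPercent <= 0 || object@functionalPercent >= 100)
    return("functionalPercent must be in (0, 100)")
  TRUE
})

#' EvaluationReport: scores of a position prediction
#'
#' Confusion counts and derived scores of a predicted position set
#' against a reference (functionally sensitive) set: precision and
#' recall as percentages, the prediction and functional percentages,
#' the null scores expected from random prediction, and the improvement
#' factor over random prediction.
#'
#' @slot tp,fp,fn integer confusion counts.
#' @slot totalPositions integer size of the scored-position universe.
#' @slot precision,recall percentages (precision NA when nothing is
#'   predicted).
#' @slot predictionPercentage,functionalPercentage percentages.
#' @slot nullPrecision,nullRecall percentages (equal to the functional
#'   and prediction percentages, respectively).
#' @slot improvement ratio of real to null precision (equivalently,
#'   real to null recall); NA when nothing is predicted.
#' @seealso [evaluatePrediction()]
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(tp = "integer", fp = "integer", fn = "integer",
                        totalPositions = "integer",
                        precision = "numeric", recall = "numeric",
                        predictionPercentage = "numeric",
                        functionalPercentage = "numeric",
                        nullPrecision = "numeric", nullRecall = "numeric",
                        improvement = "numeric"))

#' SyntheticSpec: parameters of the synthetic data generator
#'
#' Describes a synthetic "protein": residues placed along a
#' self-avoiding 3D walk with a fixed backbone step, atoms jittered
#' around each residue center, coordinate-displacement "mutants", and a
#' functional table with position-dependent mean effects plus noise.
#' The seed fixes all randomness end-to-end.
#'
#' @slot nResidues number of residues.
#' @slot atomsPerResidue atoms per residue (first atom is the CA center).
#' @slot backboneSpacing distance between consecutive residue centers
#'   (Angstroms).
#' @slot atomJitterSd sd of atom placement around the center (Angstroms).
#' @slot mutationDisplacement typical atom displacement of a mutant
#'   (Angstroms).
#' @slot seed integer master seed.
#' @slot functionalEffect named numeric vector: mean functional effect
#'   per position (names = positions).
#' @slot functionalNoiseSd sd of the noise added to functional entries.
#' @seealso [syntheticSpec()], [generateStructure()], [generateMutant()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(nResidues = "integer", atomsPerResidue = "integer",
                        backboneSpacing = "numeric", atomJitterSd = "numeric",
                        mutationDisplacement = "numeric", seed = "integer",
                        functionalEffect = "numeric",
                        functionalNoiseSd = "numeric"))

setValidity("SyntheticSpec", function(object) {
  if (object@nResidues < 1L) return("nResidues must be >= 1")
  if (object@atomsPerResidue < 1L) return("atomsPerResidue must be >= 1")
  if (object@backboneSpacing <= 0) return("backboneSpacing must be > 0")
  if (object@atomJitterSd <= 0) return("atomJitterSd must be > 0")
  if (object@mutationDisplacement < 0)
    return("mutationDisplacement must be >= 0")
  if (object@functionalNoiseSd < 0) return("functionalNoiseSd must be >= 0")
  TRUE
})
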