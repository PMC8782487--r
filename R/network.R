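#' @importFrom igraph graph_from_data_frame components induced_subgraph
#'   diameter V
NULL

# Inter-residue atom-pair distances below maxDist.
# Returns a data.frame (i, j, d): i, j are residue indices into `ids`
# (i < j in residue order), one row per atom pair.
.residuePairDistances <- function(structure, maxDist) {
  a <- structure@atoms
  ids <- residueIds(structure)
  key <- paste0(a$chain, ":", a$resno, a$insert)
  ridx <- match(key, ids)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(list(ids = ids, pairs = data.frame(i = integer(0),
                                                       j = integer(0),
                                                       d = numeric(0))))
  D <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(D) & D < maxDist, arr.ind = TRUE)
  if (nrow(sel) > 0) {
    ri <- ridx[sel[, 1]]
    rj <- ridx[sel[, 2]]
    keep <- ri != rj
    ri <- ri[keep]; rj <- rj[keep]
    d <- D[sel][keep]
    swap <- ri > rj
    tmp <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmp
    pairs <- data.frame(i = ri, j = rj, d = d)
  } else {
    pairs <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  }
  list(ids = ids, pairs = pairs)
}

# Edge weights at threshold t from a pair-distance list: named integer
# vector keyed "i|j" (residue indices).
.edgeWeightsAt <- function(pd, t) {
  keep <- pd$pairs$d < t
  if (!any(keep)) return(integer(0))
  key <- paste(pd$pairs$i[keep], pd$pairs$j[keep], sep = "|")
  tab <- table(key)
  setNames(as.integer(tab), names(tab))
}

.edgesFromWeights <- function(w, ids) {
  if (length(w) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  ij <- do.call(rbind, strsplit(names(w), "|", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  ord <- order(i, j)
  data.frame(from = ids[i][ord], to = ids[j][ord],
             weight = as.numeric(w)[ord], stringsAsFactors = FALSE)
}

#' Build a weighted amino-acid network
#'
#' Nodes are the residues of the structure; two residues are connected
#' when at least one pair of atoms, one in each residue, lies at
#' Euclidean distance strictly less than `t`, and the edge weight is
#' the number of such atom pairs. Sequence-adjacent residues are
#' treated like any other pair.
#'
#' @param structure a [ProteinStructure].
#' @param t distance threshold in Angstroms (strictly positive; pairs
#'   at distance exactly `t` are excluded).
#' @return an [AminoAcidNetwork].
#' @examples
#' s <- generateStructure(syntheticSpec(nResidues = 6, seed = 1))
#' buildNetwork(s, 9)
#' @export
buildNetwork <- function(structure, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0)
    stop("threshold t must be a single positive number")
  if (nResidues(structure) == 0) stop("structure is empty")
  pd <- .residuePairDistances(structure, t)
  new("AminoAcidNetwork", threshold = t, nodes = pd$ids,
      edges = .edgesFromWeights(.edgeWeightsAt(pd, t), pd$ids))
}

#' Construct an AminoAcidNetwork directly from an edge list
#'
#' Used for worked examples and fixtures where the network, not a
#' structure, is the starting point.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param nodes node identifiers; defaults to the endpoints.
#' @param t nominal distance threshold.
#' @return an [AminoAcidNetwork].
#' @export
aminoAcidNetwork <- function(edges, nodes = NULL, t = 5) {
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  swap <- match(edges$from, nodes) > match(edges$to, nodes)
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  new("AminoAcidNetwork", threshold = t, nodes = nodes, edges = edges)
}

#' Adjacency matrix of a network
#'
#' @param net an [AminoAcidNetwork] or [PerturbationNetwork].
#' @param nodeOrder ordered node identifiers defining the matrix rows
#'   and columns; must contain every node of the network. Defaults to
#'   the network's own node order.
#' @return symmetric numeric matrix with zero diagonal; entry (i, j)
#'   is the edge weight, or 0 when the pair has no edge.
#' @export
adjacencyMatrix <- function(net, nodeOrder = NULL) {
  if (is.null(nodeOrder)) nodeOrder <- net@nodes
  if (!all(net@nodes %in% nodeOrder))
    stop("nodeOrder must contain every node of the network")
  n <- length(nodeOrder)
  A <- matrix(0, n, n, dimnames = list(nodeOrder, nodeOrder))
  e <- net@edges
  if (nrow(e) > 0) {
    i <- match(e$from, nodeOrder)
    j <- match(e$to, nodeOrder)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  A
}

# Hop-count diameter of the largest connected component of an edge
# list (ties in component size broken by the first component found).
.hopDiameter <- function(edges) {
  if (nrow(edges) == 0) return(0L)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.integer(igraph::diameter(sub, weights = NA))
}

# Perturbation edges/measures from two "i|j"-keyed weight vectors.
.perturbFromWeights <- function(wWt, wMut, ids, t) {
  keys <- union(names(wWt), names(wMut))
  a <- rep(0, length(keys)); names(a) <- keys
  b <- a
  a[names(wWt)] <- wWt
  b[names(wMut)] <- wMut
  dw <- abs(a - b)
  edges <- .edgesFromWeights(dw[dw > 0], ids)
  nodes <- unique(c(edges$from, edges$to))
  nodes <- ids[sort(match(nodes, ids))]
  m <- c(nodes = length(nodes), edges = nrow(edges),
         weight = sum(edges$weight), diameter = .hopDiameter(edges))
  new("PerturbationNetwork", threshold = t, nodes = nodes, edges = edges,
      measures = m)
}

#' Perturbation network of a mutation
#'
#' Given the wild-type and mutant amino-acid networks at the same
#' threshold, forms the entrywise absolute difference of their
#' adjacency matrices (C = |A - B|) over the union of their node sets,
#' removes all-zero rows and columns, and returns the resulting graph
#' together with its four measures. A residue pair with an edge in
#' only one of the two networks contributes that full weight. The
#' diameter is the unweighted longest shortest path on the largest
#' connected component (0 for an empty network).
#'
#' @param wt,mut [AminoAcidNetwork] objects at the same threshold;
#'   nodes are matched by residue identifier, so the mutated residue
#'   (same chain/number, different amino acid) matches itself.
#' @return a [PerturbationNetwork].
#' @examples
#' fx <- fig7Fixture()
#' measures(perturbationNetwork(fx$wt, fx$mut))
#' @export
perturbationNetwork <- function(wt, mut) {
  if (abs(wt@threshold - mut@threshold) > 1e-9)
    stop("wild-type and mutant networks must share the same threshold")
  ids <- union(wt@nodes, mut@nodes)
  toW <- function(net) {
    e <- net@edges
    if (nrow(e) == 0) return(numeric(0))
    i <- match(e$from, ids); j <- match(e$to, ids)
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    setNames(e$weight, paste(i, j, sep = "|"))
  }
  .perturbFromWeights(toW(wt), toW(mut), ids, wt@threshold)
}

#' Score a set of mutant structures over a threshold grid
#'
#' For each mutation and each threshold, builds the wild-type and
#' mutant amino-acid networks (the wild-type atom-pair distances are
#' computed once and reused across thresholds) and records the four
#' perturbation-network measures.
#'
#' @param wt wild-type [ProteinStructure].
#' @param mutants list of mutant [ProteinStructure] objects.
#' @param mutations data.frame with one row per mutant: columns
#'   `chain`, `position`, `wt_aa`, `mut_aa`.
#' @param thresholds ascending numeric vector of distance thresholds
#'   (Angstroms); defaults to [thresholdGrid()].
#' @return data.frame with columns `chain`, `position`, `wt_aa`,
#'   `mut_aa`, `threshold`, `nodes`, `edges`, `weight`, `diameter`.
#' @export
scoreMutantSet <- function(wt, mutants, mutations,
                           thresholds = thresholdGrid()) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (length(mutants) != nrow(mutations))
    stop("one mutations row per mutant structure required")
  tmax <- max(thresholds)
  pdWt <- .residuePairDistances(wt, tmax)
  wtW <- lapply(thresholds, function(t) .edgeWeightsAt(pdWt, t))
  wtIds <- pdWt$ids
  out <- vector("list", length(mutants))
  for (k in seq_along(mutants)) {
    mutS <- mutants[[k]]
    if (!any(residueIds(mutS) %in% wtIds))
      stop("mutant ", k, " shares no residues with the wild type")
    pdMut <- .residuePairDistances(mutS, tmax)
    ids <- union(wtIds, pdMut$ids)
    # remap mutant pair keys onto the union index space
    remapW <- function(w, fromIds) {
      if (length(w) == 0) return(w)
      ij <- do.call(rbind, strsplit(names(w), "|", fixed = TRUE))
      i <- match(fromIds[as.integer(ij[, 1])], ids)
      j <- match(fromIds[as.integer(ij[, 2])], ids)
      swap <- i > j
      tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
      setNames(as.integer(w), paste(i, j, sep = "|"))
    }
    rows <- lapply(seq_along(thresholds), function(ti) {
      p <- .perturbFromWeights(remapW(wtW[[ti]], wtIds),
                               remapW(.edgeWeightsAt(pdMut, thresholds[ti]),
                                      pdMut$ids),
                               ids, thresholds[ti])
      m <- p@measures
      data.frame(chain = mutations$chain[k],
                 position = mutations$position[k],
                 wt_aa = mutations$wt_aa[k], mut_aa = mutations$mut_aa[k],
                 threshold = thresholds[ti],
                 nodes = m[["nodes"]], edges = m[["edges"]],
                 weight = m[["weight"]], diameter = m[["diameter"]],
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default distance-threshold grid
#'
#' 71 thresholds from 3 to 10 Angstroms in steps of 0.1.
#'
#' @param from,to,by grid endpoints and step in Angstroms.
#' @return numeric vector of thresholds.
#' @export
thresholdGrid <- function(from = 3, to = 10, by = 0.1) {
  round(seq(from, to, by = by), 10)
}
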