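#' @importFrom withr with_seed
NULL

#' Construct a SyntheticSpec
#'
#' Defaults describe a compact 30-residue toy protein: residue centers
#' on a self-avoiding walk with a 3.8 Angstrom step (the typical
#' C-alpha to C-alpha distance), 4 atoms per residue jittered with sd
#' 1 Angstrom around the center, mutant atoms displaced by about
#' 2 Angstroms, and functional scores equal to a per-position mean
#' effect plus Gaussian noise (sd 0.1).
#'
#' @param nResidues,atomsPerResidue residue and atom counts.
#' @param backboneSpacing,atomJitterSd,mutationDisplacement geometric
#'   scales in Angstroms (see [SyntheticSpec]).
#' @param seed integer master seed fixing all randomness.
#' @param functionalEffect named numeric vector of per-position mean
#'   effects (names = positions); empty by default.
#' @param functionalNoiseSd sd of functional-score noise.
#' @return a [SyntheticSpec].
#' @export
syntheticSpec <- function(nResidues = 30, atomsPerResidue = 4,
                          backboneSpacing = 3.8, atomJitterSd = 1.0,
                          mutationDisplacement = 2.0, seed = 1,
                          functionalEffect = numeric(0),
                          functionalNoiseSd = 0.1) {
  new("SyntheticSpec", nResidues = as.integer(nResidues),
      atomsPerResidue = as.integer(atomsPerResidue),
      backboneSpacing = backboneSpacing, atomJitterSd = atomJitterSd,
      mutationDisplacement = mutationDisplacement, seed = as.integer(seed),
      functionalEffect = functionalEffect,
      functionalNoiseSd = functionalNoiseSd)
}

#' Worked-example fixture: one mutation on a 3-residue network
#'
#' A wild-type network on residues a, b, c with edge weights
#' (a,b) = 4, (b,c) = 1, (a,c) = 2, and the network of a mutation in
#' b in which a and b lose three atom pairs and the b-c edge
#' disappears. The resulting perturbation network has 3 nodes, 2
#' edges, weight 4, and diameter 2.
#'
#' @return list with elements `wt` and `mut`, both
#'   [AminoAcidNetwork].
#' @examples
#' fx <- fig7Fixture()
#' measures(perturbationNetwork(fx$wt, fx$mut))
#' @export
fig7Fixture <- function() {
  nodes <- c("a", "b", "c")
  wt <- aminoAcidNetwork(data.frame(from = c("a", "b", "a"),
                                    to = c("b", "c", "c"),
                                    weight = c(4, 1, 2)),
                         nodes = nodes, t = 5)
  mut <- aminoAcidNetwork(data.frame(from = c("a", "a"),
                                     to = c("b", "c"),
                                     weight = c(1, 2)),
                          nodes = nodes, t = 5)
  list(wt = wt, mut = mut)
}

# Self-avoiding walk of n points with fixed step; rejects steps closer
# than 0.9 * step to any previous point.
.backboneWalk <- function(n, step) {
  pts <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    for (try in 1:500) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pts[i - 1, ] + step * u
      d2 <- rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                       matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (all(d2 > (0.9 * step)^2)) break
    }
    pts[i, ] <- cand
  }
  pts
}

#' Generate a synthetic protein structure
#'
#' Places residue centers along a self-avoiding 3D walk with the
#' spec's backbone spacing; the first atom of each residue ("CA") sits
#' at the center and the remaining atoms are jittered around it with
#' sd `atomJitterSd`. Residue types are drawn uniformly from the 20
#' amino acids. Deterministic under the spec's seed.
#'
#' @param spec a [SyntheticSpec].
#' @return a [ProteinStructure] with chain "A" and residues numbered
#'   from 1.
#' @export
generateStructure <- function(spec) {
  extra <- c("CB", "CG", "CD", "CE", "CZ", "NZ", "OG", "SD")
  withr::with_seed(spec@seed, {
    centers <- .backboneWalk(spec@nResidues, spec@backboneSpacing)
    seqAa <- sample(AA1, spec@nResidues, replace = TRUE)
    rows <- lapply(seq_len(spec@nResidues), function(i) {
      k <- spec@atomsPerResidue
      xyz <- matrix(rep(centers[i, ], k), k, 3, byrow = TRUE)
      if (k > 1)
        xyz[-1, ] <- xyz[-1, , drop = FALSE] +
          matrix(rnorm(3 * (k - 1), sd = spec@atomJitterSd), k - 1, 3)
      data.frame(chain = "A", resno = i, insert = "",
                 resid = AA3[[seqAa[i]]],
                 elety = c("CA", rep_len(extra, k - 1))[seq_len(k)],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    })
    proteinStructure(do.call(rbind, rows))
  })
}

#' Generate a synthetic mutant structure
#'
#' Displaces the atoms of one residue by independent Gaussian vectors
#' and leaves every other residue untouched, standing in for the
#' structural relaxation around a point mutation. The per-mutant
#' displacement scale is `displacement` times a lognormal severity
#' factor (sdlog 0.5), so mutants at the same position differ in how
#' strongly they perturb the structure. Residue identifiers are
#' unchanged, so wild-type/mutant node matching works as for real
#' mutant files.
#'
#' @param wt wild-type [ProteinStructure].
#' @param position residue number to perturb (chain "A" convention of
#'   the generator; any chain with that residue number is displaced).
#' @param spec a [SyntheticSpec] (supplies the default displacement).
#' @param displacement typical atom displacement in Angstroms; 0
#'   returns an unchanged copy.
#' @param seed seed for this mutant (defaults to the spec seed).
#' @return a [ProteinStructure].
#' @export
generateMutant <- function(wt, position, spec,
                           displacement = spec@mutationDisplacement,
                           seed = spec@seed) {
  a <- wt@atoms
  hit <- a$resno == position
  if (!any(hit)) stop("position ", position, " not present in structure")
  if (displacement > 0) {
    withr::with_seed(as.integer(seed), {
      sdm <- displacement * rlnorm(1, 0, 0.5)
      n <- sum(hit)
      a$x[hit] <- a$x[hit] + rnorm(n, sd = sdm)
      a$y[hit] <- a$y[hit] + rnorm(n, sd = sdm)
      a$z[hit] <- a$z[hit] + rnorm(n, sd = sdm)
    })
  }
  proteinStructure(a)
}

#' Generate the full mutant set of a synthetic protein
#'
#' For every requested position, generates one mutant structure per
#' non-wild-type amino acid (19 mutants), each with its own derived
#' seed, plus one synonymous record (the unchanged wild type) flagged
#' by `wt_aa == mut_aa`.
#'
#' @param wt wild-type [ProteinStructure].
#' @param spec a [SyntheticSpec].
#' @param positions positions to mutate (default: all residues).
#' @param displacementMap optional named numeric vector overriding the
#'   displacement per position (names = positions).
#' @param includeSynonymous also emit the synonymous record per
#'   position (default FALSE).
#' @return list with `structures` (list of [ProteinStructure]) and
#'   `mutations` (data.frame `chain`, `position`, `wt_aa`, `mut_aa`).
#' @export
syntheticMutagenesis <- function(wt, spec, positions = NULL,
                                 displacementMap = NULL,
                                 includeSynonymous = FALSE) {
  seqAa <- structureSequence(wt)
  a <- wt@atoms
  resno <- a$resno[!duplicated(paste0(a$chain, ":", a$resno, a$insert))]
  if (is.null(positions)) positions <- sort(unique(resno))
  structures <- list()
  rows <- list()
  for (p in positions) {
    wtAa <- unname(seqAa[match(p, sort(unique(resno)))])
    disp <- if (!is.null(displacementMap)) {
      if (is.na(displacementMap[as.character(p)]))
        spec@mutationDisplacement else displacementMap[[as.character(p)]]
    } else spec@mutationDisplacement
    for (ai in seq_along(AA1)) {
      mutAa <- AA1[ai]
      if (mutAa == wtAa && !includeSynonymous) next
      seed <- (spec@seed + p * 997L + ai * 31L) %% 2147483647L
      s <- if (mutAa == wtAa) wt else
        generateMutant(wt, p, spec, displacement = disp, seed = seed)
      structures[[length(structures) + 1L]] <- s
      rows[[length(rows) + 1L]] <-
        data.frame(chain = "A", position = p, wt_aa = wtAa,
                   mut_aa = mutAa, stringsAsFactors = FALSE)
    }
  }
  list(structures = structures, mutations = do.call(rbind, rows))
}

#' Generate a synthetic functional table
#'
#' Every entry is the position's mean effect plus Gaussian noise; the
#' synonymous cell is 0. The effect structure is position-dependent
#' and independent of the mutant amino acid, emulating the dominant
#' pattern of deep-mutational-scanning data.
#'
#' @param spec a [SyntheticSpec] whose `functionalEffect` covers all
#'   requested positions.
#' @param positions integer positions (rows of the table).
#' @param wtSequence wild-type one-letter codes, one per position.
#' @return a [FunctionalTable].
#' @export
generateFunctionalTable <- function(spec, positions, wtSequence) {
  eff <- spec@functionalEffect[as.character(positions)]
  if (any(is.na(eff)))
    stop("functionalEffect must cover all positions")
  withr::with_seed(spec@seed + 7L, {
    m <- matrix(rep(eff, each = 20), nrow = length(positions), ncol = 20,
                byrow = TRUE)
    m <- m + matrix(rnorm(length(m), sd = spec@functionalNoiseSd),
                    nrow = nrow(m))
    colnames(m) <- AA1
    for (i in seq_along(positions)) m[i, wtSequence[i]] <- 0
    functionalTable(m, positions = positions, wtAa = wtSequence)
  })
}
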