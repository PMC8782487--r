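# The end-to-end recovery dataset: a 30-residue synthetic protein in
# which the designated 40% of positions (1..12) respond strongly to
# mutation (displacement 2 A) and the rest barely move (0.02 A), with
# a matching functional table (-2 effect at designated positions).
# Built once per test run and cached.
.recoveryCache <- new.env(parent = emptyenv())

recoveryDataset <- function(seed = 11) {
  key <- as.character(seed)
  if (!is.null(.recoveryCache[[key]])) return(.recoveryCache[[key]])
  n <- 30
  designated <- 1:12
  effect <- setNames(ifelse(seq_len(n) %in% designated, -2, 0),
                     as.character(seq_len(n)))
  spec <- syntheticSpec(nResidues = n, seed = seed,
                        functionalEffect = effect)
  wt <- generateStructure(spec)
  disp <- setNames(ifelse(effect < 0, spec@mutationDisplacement, 0.02),
                   names(effect))
  ms <- syntheticMutagenesis(wt, spec, displacementMap = disp)
  raw <- scoreMutantSet(wt, ms$structures, ms$mutations, thresholds = 9)
  std <- standardizeScores(averageOverChains(raw))
  func <- generateFunctionalTable(spec, seq_len(n), structureSequence(wt))
  out <- list(spec = spec, wt = wt, mutants = ms, raw = raw, std = std,
              func = func, designated = designated)
  .recoveryCache[[key]] <- out
  out
}

# A small standardized score table from random raw measures, for
# classifier property tests.
randomScoreTable <- function(nPos = 15, nMut = 5, t = 9) {
  raw <- expand.grid(position = seq_len(nPos),
                     mut_aa = c("G", "P", "W", "D", "K")[seq_len(nMut)],
                     stringsAsFactors = FALSE)
  raw$chain <- "A"
  raw$wt_aa <- "A"
  raw$threshold <- t
  raw$nodes <- rpois(nrow(raw), 8)
  raw$edges <- rpois(nrow(raw), 12)
  raw$weight <- rpois(nrow(raw), 30)
  raw$diameter <- rpois(nrow(raw), 3)
  standardizeScores(averageOverChains(raw))
}
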