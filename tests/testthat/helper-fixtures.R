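# Hand-written PDB fixture: chain A with
#   res 1 ALA: N, CA, CB + hydrogen HB1   (heavy: 3, all: 4)
#   res 2 GLY: N, CA                      (2 atoms)
#   res 3 SER: N, CA altloc A+B, OG       (after altloc dedup: 3 atoms)
# plus one water (HOH) and one HETATM ligand record, both always excluded.
pdbAtomLine <- function(serial, name, alt, resn, chain, resno, icode,
                        x, y, z, elem, record = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, icode,
          x, y, z, 1, 0, elem)
}

writeFixturePdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdbAtomLine(1, "N",   " ", "ALA", "A", 1, " ", 0.0, 0.0, 0.0, "N"),
    pdbAtomLine(2, "CA",  " ", "ALA", "A", 1, " ", 1.5, 0.0, 0.0, "C"),
    pdbAtomLine(3, "CB",  " ", "ALA", "A", 1, " ", 2.0, 1.0, 0.0, "C"),
    pdbAtomLine(4, "HB1", " ", "ALA", "A", 1, " ", 2.5, 1.5, 0.5, "H"),
    pdbAtomLine(5, "N",   " ", "GLY", "A", 2, " ", 3.0, 0.0, 0.0, "N"),
    pdbAtomLine(6, "CA",  " ", "GLY", "A", 2, " ", 4.5, 0.5, 0.0, "C"),
    pdbAtomLine(7, "N",   " ", "SER", "A", 3, " ", 6.0, 0.0, 0.0, "N"),
    pdbAtomLine(8, "CA",  "A", "SER", "A", 3, " ", 7.2, 0.4, 0.0, "C"),
    pdbAtomLine(9, "CA",  "B", "SER", "A", 3, " ", 7.4, 0.6, 0.1, "C"),
    pdbAtomLine(10, "OG", " ", "SER", "A", 3, " ", 8.0, 1.2, 0.3, "O"),
    pdbAtomLine(11, "O",  " ", "HOH", "A", 4, " ", 20.0, 20.0, 20.0, "O"),
    pdbAtomLine(12, "C1", " ", "LIG", "A", 5, " ", 25.0, 25.0, 25.0, "C",
                record = "HETATM"),
    "END")
  writeLines(lines, path)
  path
}

writeTwoChainPdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdbAtomLine(1, "CA", " ", "ALA", "A", 1, " ", 0, 0, 0, "C"),
    pdbAtomLine(2, "CA", " ", "GLY", "A", 2, " ", 3.8, 0, 0, "C"),
    pdbAtomLine(3, "CA", " ", "ALA", "B", 1, " ", 0, 8, 0, "C"),
    pdbAtomLine(4, "CA", " ", "GLY", "B", 2, " ", 3.8, 8, 0, "C"),
    "END")
  writeLines(lines, path)
  path
}

# Random toy structure: nRes residues, each with 1..maxAtoms atoms at
# uniform coordinates in a box.
randomToyStructure <- function(nRes, maxAtoms = 10, box = 12) {
  rows <- lapply(seq_len(nRes), function(i) {
    k <- sample(maxAtoms, 1)
    data.frame(chain = "A", resno = i, resid = "ALA",
               elety = paste0("C", seq_len(k)),
               x = runif(k, 0, box), y = runif(k, 0, box),
               z = runif(k, 0, box))
  })
  proteinStructure(do.call(rbind, rows))
}

# Independent brute-force oracle: double loop over residues and atoms.
bruteForceNetwork <- function(structure, t) {
  a <- structure@atoms
  ids <- residueIds(structure)
  key <- paste0(a$chain, ":", a$resno, a$insert)
  weights <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ai <- a[key == ids[i], ]
      aj <- a[key == ids[j], ]
      w <- 0L
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                      (ai$z[p] - aj$z[q])^2)
          if (d < t) w <- w + 1L
        }
      }
      if (w > 0) weights[[paste(ids[i], ids[j], sep = "->")]] <- w
    }
  }
  weights
}

# Named edge-weight map of an AminoAcidNetwork for oracle comparison.
edgeWeightMap <- function(net) {
  e <- edgeTable(net)
  if (nrow(e) == 0) return(list())
  setNames(as.list(e$weight), paste(e$from, e$to, sep = "->"))
}

# Simple two-residue structures from explicit atom coordinate lists.
twoResidueStructure <- function(atoms1, atoms2) {
  mk <- function(m, resno) {
    data.frame(chain = "A", resno = resno, resid = "ALA",
               elety = paste0("C", seq_len(nrow(m))),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }
  proteinStructure(rbind(mk(atoms1, 1), mk(atoms2, 2)))
}
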