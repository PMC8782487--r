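#' Construct a ProteinStructure from an atom table
#'
#' Low-level constructor used by the reader and the synthetic
#' generator. The table is kept as-is apart from type normalisation;
#' use [readStructure()] to apply the atom-filtering policy to a PDB
#' file.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `elety`, `x`, `y`, `z` (insert may be omitted; defaults
#'   to "").
#' @return a [ProteinStructure].
#' @examples
#' atoms <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
#'                     elety = "CA", x = c(0, 3.8), y = 0, z = 0)
#' proteinStructure(atoms)
#' @export
proteinStructure <- function(atoms) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  atoms <- atoms[, c("chain", "resno", "insert", "resid", "elety",
                     "x", "y", "z")]
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms)
}

.isHydrogen <- function(elety, elesy = NULL) {
  h <- grepl("^[0-9]*H", elety)
  if (!is.null(elesy)) {
    known <- !is.na(elesy) & elesy != ""
    h[known] <- toupper(elesy[known]) == "H"
  }
  h
}

#' Read a PDB file into a ProteinStructure
#'
#' Parses ATOM records of a PDB file (via bio3d) and applies the
#' filtering policy: only the 20 standard amino acids are kept (waters
#' and hetero records are always excluded), only the first model of a
#' multi-model file is read, and for alternate locations only the
#' first-listed conformer of each atom is retained.
#'
#' @param path path to a PDB file.
#' @param atomPolicy one of `"heavy"` (default; exclude hydrogens),
#'   `"all"` (keep all atoms), `"calpha"` (CA atoms only). The policy
#'   determines which atoms enter network pair counts, so it must be
#'   identical for wild-type and mutant files.
#' @param chains optional character vector restricting the chains read;
#'   all requested chains must exist.
#' @return a [ProteinStructure].
#' @examples
#' s <- generateStructure(syntheticSpec(nResidues = 5, seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePdb(s, f)
#' readStructure(f)
#' @export
readStructure <- function(path, atomPolicy = c("heavy", "all", "calpha"),
                          chains = NULL) {
  atomPolicy <- match.arg(atomPolicy)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch({
    out <- utils::capture.output(
      p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                            verbose = FALSE)))
    p
  }, error = function(e) stop("failed to parse PDB file '", path, "': ",
                              conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$resid %in% AA3, , drop = FALSE]
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(a$chain))
    if (length(missing))
      stop("requested chain(s) not present: ", paste(missing, collapse = ","))
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  if (nrow(a) > 0) {
    if (atomPolicy == "heavy") {
      a <- a[!.isHydrogen(a$elety, a$elesy), , drop = FALSE]
    } else if (atomPolicy == "calpha") {
      a <- a[a$elety == "CA", , drop = FALSE]
    }
  }
  if (nrow(a) > 0) {
    # first-listed conformer: keep the first record per (residue, atom name)
    ins <- ifelse(is.na(a$insert), "", a$insert)
    key <- paste(a$chain, a$resno, ins, a$elety)
    a <- a[!duplicated(key), , drop = FALSE]
  }
  if (nrow(a) == 0)
    stop("no residues survive filtering in '", path, "'")
  proteinStructure(data.frame(chain = a$chain, resno = a$resno,
                              insert = ifelse(is.na(a$insert), "", a$insert),
                              resid = a$resid, elety = a$elety,
                              x = a$x, y = a$y, z = a$z,
                              stringsAsFactors = FALSE))
}

#' Write a ProteinStructure as a PDB file
#'
#' Emits standard ATOM records so that generated structures round-trip
#' through [readStructure()].
#'
#' @param structure a [ProteinStructure].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructurePdb <- function(structure, path) {
  a <- structure@atoms
  if (nrow(a) == 0) stop("cannot write an empty structure")
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = a$insert,
    elesy = substr(a$elety, 1, 1)))
  invisible(path)
}

#' One-letter sequence of a structure
#'
#' @param structure a [ProteinStructure].
#' @return named character vector of one-letter codes, one per residue
#'   (names = residue identifiers).
#' @export
structureSequence <- function(structure) {
  a <- structure@atoms
  ids <- residueIds(structure)
  key <- paste0(a$chain, ":", a$resno, a$insert)
  res <- a$resid[match(ids, key)]
  setNames(unname(AA_321[res]), ids)
}

#' Parse a mutation code of the form "KA10G"
#'
#' The code concatenates wild-type amino acid, chain, position and
#' mutant amino acid (the convention of FoldX individual-mutation
#' lists). Used to recover the mutation from mutant file names.
#'
#' @param code character vector of codes, e.g. `"KA10G"`.
#' @return data.frame with columns `chain`, `position`, `wt_aa`,
#'   `mut_aa`.
#' @examples
#' parseMutationCode(c("KA10G", "LB7A"))
#' @export
parseMutationCode <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([A-Za-z0-9])([0-9]+)([A-Z])$", code))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("unparseable mutation code(s): ", paste(code[bad], collapse = ", "))
  data.frame(chain = vapply(m, `[`, "", 3L),
             position = as.integer(vapply(m, `[`, "", 4L)),
             wt_aa = vapply(m, `[`, "", 2L),
             mut_aa = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Read a directory of mutant PDB files
#'
#' Each file must be named `<code>.pdb` where `<code>` parses with
#' [parseMutationCode()].
#'
#' @param dir directory containing mutant PDB files.
#' @param atomPolicy,chains passed to [readStructure()].
#' @return list with elements `structures` (list of
#'   [ProteinStructure]) and `mutations` (data.frame with one row per
#'   structure: `chain`, `position`, `wt_aa`, `mut_aa`).
#' @export
readMutantDirectory <- function(dir, atomPolicy = "heavy", chains = NULL) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  if (length(files) == 0) stop("no .pdb files found in ", dir)
  codes <- sub("\\.pdb$", "", basename(files))
  mutations <- parseMutationCode(codes)
  structures <- lapply(files, readStructure, atomPolicy = atomPolicy,
                       chains = chains)
  list(structures = structures, mutations = mutations)
}
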