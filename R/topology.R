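# Topology: atom table plus chain->molecule partition.
#
# Atoms are kept in file order.  Residue identity is (chain, resno, insert)
# so insertion-coded residues survive round trips; all reporting uses the
# file's own numbering.

#' Construct a topology
#'
#' A topology is the static bookkeeping behind a trajectory: an ordered atom
#' table and a partition of chains into named molecules.  Most users obtain
#' one via [read_topology()]; the constructor is exported so synthetic
#' systems can be assembled in code.
#'
#' @param atoms data.frame with columns `serial` (integer), `name`, `element`,
#'   `chain`, `resno` (integer), `insert` (use `""` when absent), `resname`.
#' @param molecules named character vector mapping chain id to molecule name;
#'   default: each chain is its own molecule.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, molecules = NULL) {
  need <- c("serial", "name", "element", "chain", "resno", "insert", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    mdccr_stop(paste0("atom table is missing column(s): ",
                      paste(miss, collapse = ", ")), "mdccr_validation_error")
  }
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- toupper(trimws(atoms$element))

  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    mdccr_stop(paste0("duplicate atom identity (chain|resno|insert|name): ", dup),
               "mdccr_validation_error")
  }

  chains <- unique(atoms$chain)
  if (is.null(molecules)) {
    molecules <- setNames(chains, chains)
  } else {
    molecules <- setNames(as.character(molecules), names(molecules))
    absent <- setdiff(chains, names(molecules))
    if (length(absent) > 0) {
      mdccr_stop(paste0("chains without molecule assignment: ",
                        paste(absent, collapse = ", ")), "mdccr_validation_error")
    }
  }

  rkey <- residue_keys(atoms)
  atoms$residue <- match(rkey, unique(rkey))  # 1-based residue index, file order

  structure(list(atoms = atoms, molecules = molecules),
            class = "topology")
}

residue_keys <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno, atoms$insert, ":", atoms$resname)
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d chains, %d molecules\n",
              nrow(a), length(unique(a$residue)), length(unique(a$chain)),
              length(unique(x$molecules))))
  cat("  molecules:",
      paste(sprintf("%s (chain %s)", x$molecules, names(x$molecules)),
            collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Residue table of a topology
#'
#' @param top a `"topology"`.
#' @return data.frame with one row per residue: `residue` (index), `key`
#'   (`chain:resno:resname` label), `chain`, `resno`, `insert`, `resname`,
#'   `molecule`.
#' @export
residue_table <- function(top) {
  a <- top$atoms
  first <- !duplicated(a$residue)
  data.frame(residue = a$residue[first],
             key = residue_keys(a)[first],
             chain = a$chain[first],
             resno = a$resno[first],
             insert = a$insert[first],
             resname = a$resname[first],
             molecule = unname(top$molecules[a$chain[first]]),
             stringsAsFactors = FALSE)
}

# element guess from a PDB atom name when the element column is blank:
# strip digits/primes, take the leading alphabetic character(s); two-letter
# elements are only recognised for common hetero cases.
guess_element <- function(name) {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA")
  # atom names like "CA" (C-alpha) are carbon in amino acids; the two-letter
  # table is only consulted when the full stripped name matches exactly and
  # the original name was right-justified (a heuristic PDB writers follow) --
  # here we keep it simple and treat 1st char as element unless name == "CL" etc.
  el <- substr(nm, 1L, 1L)
  hit <- nm %in% setdiff(two, c("CA", "NA"))  # never mistake CA/NA protein atoms
  el[hit] <- nm[hit]
  el
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), reconstructs the chain/residue
#' hierarchy, preserves serials, residue numbers and insertion codes, and
#' partitions chains into molecules (default: one molecule per chain).
#'
#' @param path PDB file path.
#' @param format only `"pdb"` is supported.
#' @param molecules optional named character vector chain -> molecule name.
#' @return A `"topology"`.
#' @export
read_topology <- function(path, format = "pdb", molecules = NULL) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) {
    mdccr_stop(paste0("file not found: ", path), "mdccr_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
    error = function(e) {
      mdccr_stop(paste0("cannot parse '", path, "' as PDB: ",
                        conditionMessage(e)), "mdccr_format_error")
    })
  at <- pdb$atom
  el <- at$elesy
  blank <- is.na(el) | trimws(el) == ""
  el[blank] <- guess_element(at$elety[blank])
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  ins <- at$insert
  ins[is.na(ins)] <- ""
  topology(data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = el, chain = chain, resno = at$resno,
                      insert = ins, resname = trimws(at$resid),
                      stringsAsFactors = FALSE),
           molecules = molecules)
}
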