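# Three-letter -> one-letter code map for the 20 standard amino acids.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Phospho-residue codes and their canonical parents.
.PHOSPHO_PARENT <- c(SEP = "SER", TPO = "THR", PTR = "TYR")

#' Phospho-residue codes handled by the pipeline
#' @return Character vector `c("SEP", "TPO", "PTR")`.
#' @export
phospho_codes <- function() names(.PHOSPHO_PARENT)

#' Map residue codes to their canonical parents
#'
#' SEP, TPO and PTR map to SER, THR and TYR; every other code maps to
#' itself.
#'
#' @param code3 Character vector of three-letter residue codes.
#' @return Character vector of parent codes.
#' @export
parent_code <- function(code3) {
  out <- code3
  hit <- code3 %in% names(.PHOSPHO_PARENT)
  out[hit] <- .PHOSPHO_PARENT[code3[hit]]
  out
}

#' Residue codes excluded from the non-polymer scan
#'
#' The shipped list contains the 20 standard amino acids plus the water,
#' ion, nucleotide and common-ligand codes screened out before searching
#' for non-canonical residues.
#'
#' @param category One of `"all"`, `"standard_aa"`, `"non_polymer"`.
#' @return Character vector of residue codes.
#' @export
exclusion_codes <- function(category = c("all", "standard_aa", "non_polymer")) {
  category <- match.arg(category)
  path <- system.file("extdata", "exclusion_codes.tsv", package = "ptmlocal")
  tab <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  if (category != "all") tab <- tab[tab$category == category, , drop = FALSE]
  tab$code
}

#' Construct a chain model
#'
#' A `chain_model` holds one polymer chain of one PDB entry: an ordered
#' residue table and an atom table keyed into it. Residue indices are
#' 1-based and contiguous over the observed residues.
#'
#' @param pdb_id Four-character entry identifier (free-form for synthetic
#'   chains).
#' @param chain_id Single-character chain identifier.
#' @param residues Data frame with columns `code3`, `seqnum`, `icode`.
#' @param atoms Data frame with columns `res_index`, `name`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `altloc`.
#' @param ss_records Optional data frame of HELIX/SHEET annotations with
#'   columns `type` ("H"/"E"), `start`, `end` (author numbering).
#' @param n_source_chains Number of distinct chain identifiers the model
#'   was built from (1 unless chains were deliberately merged).
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(pdb_id, chain_id, residues, atoms,
                        ss_records = NULL, n_source_chains = 1L) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (is.null(residues$icode)) residues$icode <- ""
  residues$parent_code3 <- parent_code(residues$code3)
  residues$is_phospho <- residues$code3 %in% phospho_codes()
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]  # stable within residue
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  structure(
    list(pdb_id = pdb_id, chain_id = chain_id,
         residues = residues, atoms = atoms,
         ss_records = ss_records, n_source_chains = as.integer(n_source_chains)),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s chain %s: %d residues, %d atoms, %d phospho site(s)\n",
              x$pdb_id, x$chain_id, n_residues(x), nrow(x$atoms),
              sum(x$residues$is_phospho)))
  invisible(x)
}

#' Number of residues in a chain model
#' @param chain A `chain_model`.
#' @return Integer count.
#' @export
n_residues <- function(chain) nrow(chain$residues)

#' One-letter sequence of a chain over parent codes
#'
#' Phospho-residues contribute their parent letter (SEP -> S, TPO -> T,
#' PTR -> Y); any residue without a standard parent contributes `"X"`.
#'
#' @param chain A `chain_model`.
#' @return Single character string.
#' @export
chain_sequence <- function(chain) {
  one <- .AA3TO1[chain$residues$parent_code3]
  one[is.na(one)] <- "X"
  paste0(one, collapse = "")
}

#' C-alpha coordinates of a chain
#'
#' @param chain A `chain_model`.
#' @param indices Residue indices (1-based); default all.
#' @return Numeric matrix with one row per requested residue (rows of
#'   `NA` where a residue lacks a CA atom, which cleaning removes).
#' @export
ca_coords <- function(chain, indices = seq_len(n_residues(chain))) {
  at <- chain$atoms
  ca <- at[at$name == "CA" & !at$is_hydrogen, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(indices), ncol = 3)
  m <- match(indices, ca$res_index)
  ok <- !is.na(m)
  out[ok, ] <- as.matrix(ca[m[ok], c("x", "y", "z")])
  out
}

# Atom table restricted to a set of residue indices.
atoms_of <- function(chain, indices) {
  chain$atoms[chain$atoms$res_index %in% indices, , drop = FALSE]
}

#' Author-numbering locus label for residue indices
#' @param chain A `chain_model`.
#' @param indices Residue indices.
#' @return Character vector like `"160"` or `"27A"`.
#' @export
residue_locus <- function(chain, indices) {
  r <- chain$residues[indices, , drop = FALSE]
  paste0(r$seqnum, ifelse(r$icode == "", "", r$icode))
}

# Guess the element symbol from a PDB atom name when the element column
# is blank. Leading digits are stripped (e.g. "1HB" -> H); two-letter
# elements relevant here are handled explicitly.
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("FE", "ZN", "MG", "CL", "BR", "SE", "HG", "CU", "MN", "NA")] <-
    two[two %in% c("FE", "ZN", "MG", "CL", "BR", "SE", "HG", "CU", "MN", "NA")]
  el
}

#' Parse PDB-format content into chain models
#'
#' Reads fixed-column ATOM/HETATM records through bio3d. One
#' `chain_model` is returned per chain identifier. HETATM residues that
#' carry a CA atom (this is how SEP/TPO/PTR and other modified residues
#' appear) are retained as polymer residues; water, ions and ligands
#' survive parsing and are removed later by [clean_structure()]. Only
#' the first MODEL of multi-model (NMR) files is read.
#'
#' @param text PDB-format content as a single string or character vector
#'   of lines. Exactly one of `text`/`file` must be given.
#' @param file Path to a PDB file.
#' @param pdb_id Entry identifier to stamp on the chains; defaults to the
#'   file base name.
#' @return List of `chain_model`, named by chain identifier.
#' @export
parse_pdb <- function(text = NULL, file = NULL, pdb_id = NULL) {
  if (is.null(file)) {
    stopifnot(!is.null(text))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(if (length(text) == 1L) strsplit(text, "\n")[[1]] else text, file)
    if (is.null(pdb_id)) pdb_id <- "XXXX"
  }
  if (is.null(pdb_id)) {
    pdb_id <- sub("\\.(pdb|ent)$", "", basename(file), ignore.case = TRUE)
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no polymer chain in '", pdb_id, "'")
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- guess_element(at$elety[is.na(at$elesy) | at$elesy == ""])

  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    key <- paste(sub$resno, sub$insert, sub$resid, sep = "|")
    ukey <- unique(key)
    first <- match(ukey, key)
    res <- data.frame(
      code3 = sub$resid[first],
      seqnum = sub$resno[first],
      icode = sub$insert[first],
      stringsAsFactors = FALSE
    )
    ord <- order(res$seqnum, res$icode)
    res <- res[ord, , drop = FALSE]
    res_index <- match(key, ukey[ord])
    atoms <- data.frame(
      res_index = res_index,
      name = sub$elety,
      element = toupper(sub$elesy),
      x = sub$x, y = sub$y, z = sub$z,
      occupancy = sub$o,
      altloc = sub$alt,
      stringsAsFactors = FALSE
    )
    atoms <- atoms[order(atoms$res_index, seq_len(nrow(atoms))), , drop = FALSE]
    ss <- .chain_ss_records(pdb, ch)
    chains[[ch]] <- chain_model(pdb_id, ch, res, atoms, ss_records = ss)
  }
  # A file is only useful if at least one chain has a CA-bearing residue.
  has_ca <- vapply(chains, function(c) any(c$atoms$name == "CA" & c$atoms$element == "C"),
                   logical(1))
  if (!any(has_ca)) stop("no polymer chain in '", pdb_id, "'")
  chains
}

# Extract HELIX/SHEET records for one chain from a bio3d pdb object.
.chain_ss_records <- function(pdb, ch) {
  recs <- NULL
  if (!is.null(pdb$helix) && length(pdb$helix$start)) {
    keep <- pdb$helix$chain == ch
    if (any(keep)) {
      recs <- data.frame(type = "H", start = unname(pdb$helix$start[keep]),
                         end = unname(pdb$helix$end[keep]))
    }
  }
  if (!is.null(pdb$sheet) && length(pdb$sheet$start)) {
    keep <- pdb$sheet$chain == ch
    if (any(keep)) {
      recs <- rbind(recs, data.frame(type = "E", start = unname(pdb$sheet$start[keep]),
                                     end = unname(pdb$sheet$end[keep])))
    }
  }
  recs
}

#' Clean a parsed chain for geometric analysis
#'
#' Removes water/ion/ligand residues (the shipped non-polymer code list
#' by default), strips hydrogen atoms, resolves alternate locations by
#' keeping the highest-occupancy conformer of each atom (ties go to file
#' order), and drops residues that lack a CA atom. Residue indices are
#' re-packed to stay contiguous.
#'
#' @param chain A `chain_model`.
#' @param exclusion_list Residue codes to remove outright.
#' @param verbose Emit a message for each dropped CA-less residue.
#' @return A cleaned `chain_model`.
#' @export
clean_structure <- function(chain,
                            exclusion_list = exclusion_codes("non_polymer"),
                            verbose = FALSE) {
  res <- chain$residues
  at <- chain$atoms

  keep_res <- !(res$code3 %in% exclusion_list)
  at <- at[keep_res[at$res_index], , drop = FALSE]
  at <- at[!at$is_hydrogen, , drop = FALSE]

  # Alternate locations: per residue and atom name keep the
  # highest-occupancy record; stable order breaks ties by file order.
  if (any(at$altloc != "")) {
    key <- paste(at$res_index, at$name, sep = "|")
    ord <- order(key, -at$occupancy, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$res_index, at$name, sep = "|")), , drop = FALSE]
    at <- at[order(at$res_index, seq_len(nrow(at))), , drop = FALSE]
    at$altloc <- ""
  }

  has_ca <- sort(unique(at$res_index[at$name == "CA" & at$element == "C"]))
  dropped <- setdiff(unique(at$res_index), has_ca)
  if (verbose && length(dropped)) {
    message("dropping ", length(dropped), " residue(s) without CA in ",
            chain$pdb_id, " chain ", chain$chain_id)
  }
  at <- at[at$res_index %in% has_ca, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no polymer chain left after cleaning '", chain$pdb_id, "' chain ",
         chain$chain_id)
  }
  new_index <- match(at$res_index, has_ca)
  res <- res[has_ca, , drop = FALSE]
  at$res_index <- new_index
  out <- chain_model(chain$pdb_id, chain$chain_id,
                     res[, c("code3", "seqnum", "icode")], at,
                     ss_records = chain$ss_records,
                     n_source_chains = chain$n_source_chains)
  attr(out, "cleaned") <- TRUE
  out
}

#' Locate phospho-residues in a chain
#'
#' @param chain A cleaned `chain_model`.
#' @return Data frame with one row per SEP/TPO/PTR residue, in sequence
#'   order: `index` (1-based), `ptm_code`, `seqnum`, `icode`, `locus`.
#' @export
find_phospho_sites <- function(chain) {
  idx <- which(chain$residues$is_phospho)
  data.frame(
    index = idx,
    ptm_code = chain$residues$code3[idx],
    seqnum = chain$residues$seqnum[idx],
    icode = chain$residues$icode[idx],
    locus = residue_locus(chain, idx),
    stringsAsFactors = FALSE
  )
}

#' Write a chain model as PDB-format records
#'
#' Residues whose code is not one of the 20 standard amino acids
#' (including SEP/TPO/PTR) are emitted as HETATM. Coordinates round-trip
#' through [parse_pdb()] to 3 decimals.
#'
#' @param chain A non-empty `chain_model`.
#' @param file Destination path, or `NULL` to return the lines.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(chain, file = NULL) {
  if (n_residues(chain) == 0L || nrow(chain$atoms) == 0L) {
    stop("cannot write an empty chain")
  }
  at <- chain$atoms
  res <- chain$residues
  type <- ifelse(res$code3[at$res_index] %in% names(.AA3TO1), "ATOM", "HETATM")
  dest <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    pdb = NULL, file = dest,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = type,
    resno = res$seqnum[at$res_index],
    resid = res$code3[at$res_index],
    insert = res$icode[at$res_index],
    chain = rep(substr(chain$chain_id, 1, 1), nrow(at)),
    eleno = seq_len(nrow(at)),
    elety = at$name,
    o = at$occupancy,
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  lines <- readLines(dest)
  if (is.null(file)) unlink(dest)
  invisible(lines)
}

#' Merge chain models into one unsplit model
#'
#' Represents a structure whose chains were not separated (used to
#' exercise the per-chain curation rule; analysis functions expect
#' single-chain models).
#'
#' @param chains List of `chain_model` from the same entry.
#' @return A `chain_model` with `n_source_chains > 1`.
#' @export
merge_chains <- function(chains) {
  stopifnot(length(chains) >= 1)
  res <- do.call(rbind, lapply(chains, function(c) c$residues[, c("code3", "seqnum", "icode")]))
  offs <- cumsum(c(0L, vapply(chains, n_residues, integer(1))))
  at <- do.call(rbind, lapply(seq_along(chains), function(i) {
    a <- chains[[i]]$atoms
    a$res_index <- a$res_index + offs[i]
    a
  }))
  chain_model(chains[[1]]$pdb_id,
              paste(vapply(chains, function(c) c$chain_id, character(1)), collapse = ""),
              res, at, n_source_chains = length(chains))
}
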