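# Segmentation of pairs into groups N1/N2/N3 by global and window RMSD,
# and secondary-structure context of modification sites.

#' Classify a pair by global and window RMSD
#'
#' * N1 — global RMSD above the threshold: the forms differ over the
#'   whole chain and local comparison is not meaningful.
#' * N2 — globally similar, but at least one neighborhood's window RMSD
#'   exceeds the threshold: a local rearrangement at the site.
#' * N3 — globally and locally similar.
#'
#' A value exactly at the threshold counts as "not exceeding" (strict
#' inequality detects difference).
#'
#' @param rmsd_global Global CA RMSD in Angstrom.
#' @param rmsd_windows Non-empty numeric vector of per-k window RMSDs.
#' @param threshold Decision threshold in Angstrom (default 2.0).
#' @return List of class `group_label`: `label` ("N1"/"N2"/"N3"),
#'   `rmsd_global`, `rmsd_windows`, `threshold`.
#' @export
classify_pair <- function(rmsd_global, rmsd_windows, threshold = 2.0) {
  stopifnot(length(rmsd_windows) >= 1)
  label <- if (rmsd_global > threshold) {
    "N1"
  } else if (max(rmsd_windows) > threshold) {
    "N2"
  } else {
    "N3"
  }
  structure(list(label = label, rmsd_global = rmsd_global,
                 rmsd_windows = rmsd_windows, threshold = threshold),
            class = "group_label")
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Backbone phi/psi angles per residue (NA at chain ends or where N/CA/C
# atoms are missing).
backbone_dihedrals <- function(chain) {
  n <- n_residues(chain)
  get_atom <- function(i, name) {
    a <- chain$atoms[chain$atoms$res_index == i & chain$atoms$name == name, ]
    if (nrow(a) == 0L) return(NULL)
    as.numeric(a[1, c("x", "y", "z")])
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- get_atom(i, "N"); CA <- get_atom(i, "CA"); C <- get_atom(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1) {
      Cp <- get_atom(i - 1, "C")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < n) {
      Nn <- get_atom(i + 1, "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  data.frame(phi = phi, psi = psi)
}

# Classify one residue from its phi/psi pair.
.ss_from_phipsi <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("C")
  if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) return("H")
  if (phi >= -180 && phi <= -90 &&
      ((psi >= 90 && psi <= 180) || (psi >= -180 && psi <= -170))) return("E")
  "C"
}

# Revert H runs shorter than min_h and E runs shorter than min_e to C.
.enforce_run_lengths <- function(ss, min_h = 4L, min_e = 3L) {
  r <- rle(ss)
  short <- (r$values == "H" & r$lengths < min_h) |
           (r$values == "E" & r$lengths < min_e)
  r$values[short] <- "C"
  inverse.rle(r)
}

#' Assign per-residue secondary structure
#'
#' Three sources are supported:
#' * `"records"` — HELIX/SHEET records carried from the PDB header are
#'   mapped onto residues by author numbering; everything else is coil.
#' * `"dihedral"` — a phi/psi-region heuristic (helix: phi in
#'   \[-100, -30\], psi in \[-80, -5\]; strand: phi in \[-180, -90\],
#'   psi in \[90, 180\] or \[-180, -170\]); helix runs shorter than 4
#'   and strand runs shorter than 3 are reverted to coil.
#' * `"external"` — a two-column TSV (`index`, `ss`) of precomputed
#'   per-residue annotations (e.g. exported from DSSP/STRIDE); never
#'   invoked as a subprocess.
#'
#' `"auto"` uses records when any are present, else the dihedral
#' heuristic.
#'
#' @param chain A cleaned `chain_model`.
#' @param source One of `"auto"`, `"records"`, `"dihedral"`, `"external"`.
#' @param file Annotation file for `source = "external"`.
#' @return Character string over `{H, E, C}`, one letter per residue.
#' @export
assign_secondary_structure <- function(chain,
                                       source = c("auto", "records",
                                                  "dihedral", "external"),
                                       file = NULL) {
  source <- match.arg(source)
  n <- n_residues(chain)
  if (source == "auto") {
    source <- if (!is.null(chain$ss_records) && nrow(chain$ss_records) > 0)
      "records" else "dihedral"
  }
  if (source == "records") {
    ss <- rep("C", n)
    recs <- chain$ss_records
    if (!is.null(recs)) {
      for (i in seq_len(nrow(recs))) {
        hit <- chain$residues$seqnum >= recs$start[i] &
               chain$residues$seqnum <= recs$end[i]
        ss[hit] <- recs$type[i]
      }
    }
    return(paste0(ss, collapse = ""))
  }
  if (source == "external") {
    stopifnot(!is.null(file))
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    ss <- rep("C", n)
    ss[tab$index] <- tab$ss
    return(paste0(ss, collapse = ""))
  }
  # dihedral
  if (n < 3) {
    warning("chain too short for dihedral assignment; returning all-coil")
    return(paste0(rep("C", n), collapse = ""))
  }
  ang <- backbone_dihedrals(chain)
  ss <- mapply(.ss_from_phipsi, ang$phi, ang$psi)
  ss <- .enforce_run_lengths(ss)
  paste0(ss, collapse = "")
}

#' Secondary-structure context of a site
#'
#' Maps the site's assignment to one of four categories: `alpha-helix`,
#' `beta-strand`, `coil-middle` (unstructured, no regular element within
#' `edge_margin` positions) or `coil-edge` (unstructured but adjacent to
#' a helix or strand — the border-zone case).
#'
#' @param ss Per-residue secondary-structure string over `{H, E, C}`.
#' @param site_index 1-based position of the site.
#' @param edge_margin Number of flanking positions scanned for a regular
#'   element (default 2).
#' @return One of `"alpha-helix"`, `"beta-strand"`, `"coil-middle"`,
#'   `"coil-edge"`.
#' @export
site_context <- function(ss, site_index, edge_margin = 2L) {
  letters <- strsplit(ss, "")[[1]]
  n <- length(letters)
  if (site_index < 1 || site_index > n) stop("site index out of range")
  s <- letters[site_index]
  if (s == "H") return("alpha-helix")
  if (s == "E") return("beta-strand")
  if (edge_margin > 0) {
    lo <- max(1L, site_index - edge_margin)
    hi <- min(n, site_index + edge_margin)
    if (any(letters[lo:hi] %in% c("H", "E"))) return("coil-edge")
  }
  "coil-middle"
}

#' Group and site-context report for a set of pairs
#'
#' @param records List of `pair_record`.
#' @param geometries List of [pair_geometry()] tables, parallel to
#'   `records`.
#' @param threshold RMSD decision threshold (Angstrom).
#' @param edge_margin Passed to [site_context()].
#' @param ss_source Passed to [assign_secondary_structure()] (applied to
#'   the intact chain).
#' @return Data frame: `pair_id`, `uniprot_id`, `label`, `rmsd_global`,
#'   one `rmsd_k<k>` column per half-width, `site_context` of the first
#'   site.
#' @export
segment_pairs <- function(records, geometries, threshold = 2.0,
                          edge_margin = 2L, ss_source = "auto") {
  stopifnot(length(records) == length(geometries))
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    wr <- pair_window_rmsd(geometries[[i]])
    lab <- classify_pair(rec$rmsd_global, wr, threshold)
    ss <- assign_secondary_structure(rec$intact, source = ss_source)
    site_mod <- rec$sites$index[1]
    m <- rec$correspondence[rec$correspondence$modified_index == site_mod, ]
    ctx <- if (nrow(m) == 1L) site_context(ss, m$intact_index, edge_margin)
           else NA_character_
    row <- data.frame(pair_id = rec$pair_id, uniprot_id = rec$uniprot_id,
                      label = lab$label, rmsd_global = rec$rmsd_global,
                      site_context = ctx, stringsAsFactors = FALSE)
    for (k in names(wr)) row[[paste0("rmsd_k", k)]] <- wr[[k]]
    row
  })
  do.call(rbind, rows)
}

#' Tabulate site contexts by group
#'
#' @param segments Data frame from [segment_pairs()].
#' @return Contingency table of `site_context` by `label`.
#' @export
context_table <- function(segments) {
  table(context = segments$site_context, group = segments$label)
}
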