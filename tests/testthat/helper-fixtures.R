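# Fixtures and independent oracles shared across the test files. All
# fixtures are built in code; nothing is read from disk.

# --- independent RMSD oracle: quaternion search -----------------------
# For a fixed rotation the optimal translation matches the centroids,
# so the oracle scans rotations only. A random quaternion sweep seeds a
# derivative-free polish; no SVD anywhere.

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rmsd_given_rotation <- function(rot, a, b) {
  br <- b %*% t(rot)
  br <- sweep(br, 2, colMeans(a) - colMeans(br), "+")
  sqrt(mean(rowSums((br - a)^2)))
}

brute_force_rmsd <- function(a, b, n_grid = 1000L) {
  qs <- matrix(stats::rnorm(n_grid * 4), ncol = 4)
  vals <- apply(qs, 1, function(q) rmsd_given_rotation(quat_to_rot(q), a, b))
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, function(q) rmsd_given_rotation(quat_to_rot(q), a, b),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# --- synthetic pair records -------------------------------------------

fixture_record <- function(kind, seed = 1L, ...) {
  pr <- make_pair(scenario(kind, seed = seed, ...))
  build_pair_record(candidate_pair(pr$intact, pr$modified, "SYNTEST"))
}

# Identical "pair": the same chain as intact and modified, with the site
# residue phosphorylated on the modified side only in name (no phosphate,
# no perturbation, no noise) so every geometric delta must be exactly zero.
identical_record <- function(length = 60L, site = 30L) {
  intact <- make_backbone(length, "mixed", site_indices = site,
                          site_codes = "SER", pdb_id = "idnt")
  res <- intact$residues[, c("code3", "seqnum", "icode")]
  res$code3[site] <- "SEP"
  at <- intact$atoms
  at$is_hydrogen <- NULL
  modified <- chain_model("idnm", "A", res, at)
  build_pair_record(candidate_pair(intact, modified, "IDENT"))
}

# Re-key a chain model (new pdb_id), optionally jittering coordinates.
rekey_chain <- function(chain, pdb_id, jitter_sd = 0, jitter_seed = 99L) {
  at <- chain$atoms
  at$is_hydrogen <- NULL
  if (jitter_sd > 0) {
    set.seed(jitter_seed)
    at$x <- at$x + stats::rnorm(nrow(at), sd = jitter_sd)
    at$y <- at$y + stats::rnorm(nrow(at), sd = jitter_sd)
    at$z <- at$z + stats::rnorm(nrow(at), sd = jitter_sd)
  }
  chain_model(pdb_id, chain$chain_id,
              chain$residues[, c("code3", "seqnum", "icode")], at)
}

# Swap residue codes at given positions (e.g. to plant a non-canonical
# residue in an intact chain).
recode_residues <- function(chain, indices, codes) {
  res <- chain$residues[, c("code3", "seqnum", "icode")]
  res$code3[indices] <- codes
  at <- chain$atoms
  at$is_hydrogen <- NULL
  chain_model(chain$pdb_id, chain$chain_id, res, at)
}

# A chain with several phospho-residues (phosphates attached), used for
# the phospho-count criterion.
multi_phospho_chain <- function(length = 120L, sites = c(40L, 50L, 60L, 70L),
                                pdb_id = "mphs") {
  ch <- make_backbone(length, "mixed", site_indices = sites,
                      site_codes = "SER", pdb_id = pdb_id)
  res <- ch$residues[, c("code3", "seqnum", "icode")]
  res$code3[sites] <- "SEP"
  at <- ch$atoms
  at$is_hydrogen <- NULL
  for (s in sites) at <- ptmlocal:::.attach_phosphate(at, s)
  chain_model(pdb_id, "A", res, at)
}

# --- tiny hand-written PDB text fixtures ------------------------------

pdb_line <- function(type, serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = "", elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# Minimal two-residue helix-like fragment with a SEP HETATM residue, a
# water, hydrogens and an altloc pair; exercises parsing and cleaning.
messy_pdb_text <- function() {
  paste(c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.46, 0, 0, elem = "C"),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 2.0, 1.4, 0, elem = "C"),
    pdb_line("ATOM", 4, "HA", "ALA", "A", 1, 1.5, -1.0, 0, elem = "H"),
    pdb_line("ATOM", 5, "CB", "ALA", "A", 1, 1.9, -0.9, 1.1, occ = 0.6,
             alt = "A", elem = "C"),
    pdb_line("ATOM", 6, "CB", "ALA", "A", 1, 1.8, -1.0, 1.2, occ = 0.4,
             alt = "B", elem = "C"),
    pdb_line("HETATM", 7, "N", "SEP", "A", 2, 3.3, 1.5, 0, elem = "N"),
    pdb_line("HETATM", 8, "CA", "SEP", "A", 2, 4.3, 2.5, 0, elem = "C"),
    pdb_line("HETATM", 9, "C", "SEP", "A", 2, 5.7, 1.9, 0, elem = "C"),
    pdb_line("HETATM", 10, "P", "SEP", "A", 2, 5.0, 4.5, 1.5, elem = "P"),
    pdb_line("HETATM", 11, "O", "HOH", "A", 101, 9, 9, 9, elem = "O"),
    pdb_line("HETATM", 12, "ZN", "ZN", "A", 102, 8, 8, 8, elem = "ZN"),
    "END"), collapse = "\n")
}
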