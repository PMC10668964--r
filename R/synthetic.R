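# Synthetic intact/modified chain pairs with controlled structural-change
# scenarios. Backbones are grown by natural-extension (NeRF) placement
# from phi/psi torsions with ideal bond geometry, so secondary-structure
# ground truth is known by construction; the modified member carries a
# phospho-residue and a backbone perturbation that is absent ("null"),
# confined to a window around the site ("local"), or chain-wide
# ("global").

# Ideal backbone geometry (Angstrom / degrees).
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  omega = 180
)

# Torsion pairs by secondary-structure letter. Coil alternates two
# irregular conformers so coils are classified C by the dihedral
# heuristic without forming regular runs.
.TORSIONS <- list(
  H = list(phi = -57, psi = -47),
  E = list(phi = -130, psi = 135),
  C = list(phi = c(-75, -60), psi = c(145, 30))
)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D at distance `bond` from C, angle B-C-D and torsion
# A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         -bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Default mixed secondary-structure pattern: coil / helix / coil /
# strand blocks tiled to the requested length.
.mixed_ss <- function(length) {
  unit <- c(rep("C", 4), rep("H", 10), rep("C", 5), rep("E", 6))
  paste0(rep(unit, length.out = length), collapse = "")
}

#' Generate a synthetic backbone chain
#'
#' Grows an N/CA/C/CB backbone residue by residue from ideal bond
#' geometry and per-residue phi/psi torsions. `"helix"` and
#' `"extended"` chains use a single canonical torsion pair; `"mixed"`
#' tiles coil/helix/coil/strand blocks and stores the ground-truth
#' secondary-structure string as `attr(chain, "ss_truth")`. Residues are
#' alanine except at `site_indices`, which get `site_codes` (with a
#' side-chain oxygen for SER/THR/TYR so a phosphate can be attached).
#'
#' @param length Number of residues (>= 4).
#' @param geometry `"helix"`, `"extended"` or `"mixed"`.
#' @param site_indices 1-based positions of designated sites.
#' @param site_codes Parent codes at those positions (`"SER"`, `"THR"`,
#'   `"TYR"`), recycled.
#' @param pdb_id,chain_id Identifiers stamped on the model.
#' @return A `chain_model` (construction is deterministic).
#' @export
make_backbone <- function(length, geometry = c("helix", "extended", "mixed"),
                          site_indices = integer(0), site_codes = "SER",
                          pdb_id = "SYNT", chain_id = "A") {
  geometry <- match.arg(geometry)
  if (length < 4) stop("chain length must be at least 4")
  ss <- switch(geometry,
               helix = strrep("H", length),
               extended = strrep("E", length),
               mixed = .mixed_ss(length))
  letters_ss <- strsplit(ss, "")[[1]]
  phi <- psi <- numeric(length)
  coil_toggle <- 0L
  for (i in seq_len(length)) {
    t <- .TORSIONS[[letters_ss[i]]]
    if (letters_ss[i] == "C") {
      coil_toggle <- coil_toggle + 1L
      j <- 1L + coil_toggle %% 2L
      phi[i] <- t$phi[j]; psi[i] <- t$psi[j]
    } else {
      phi[i] <- t$phi; psi[i] <- t$psi
    }
  }
  if (geometry == "extended") { phi[] <- -150; psi[] <- 150 }

  n_xyz <- ca_xyz <- c_xyz <- matrix(0, length, 3)
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(.BB$n_ca, 0, 0)
  c_xyz[1, ] <- place_atom(c(0, 1, 0), n_xyz[1, ], ca_xyz[1, ],
                           .BB$ca_c, .BB$ang_n_ca_c, phi[1] + 60)
  for (i in 2:length) {
    n_xyz[i, ] <- place_atom(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                             .BB$c_n, .BB$ang_ca_c_n, psi[i - 1])
    ca_xyz[i, ] <- place_atom(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                              .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
    c_xyz[i, ] <- place_atom(c_xyz[i - 1, ], n_xyz[i, ], ca_xyz[i, ],
                             .BB$ca_c, .BB$ang_n_ca_c, phi[i])
  }

  codes <- rep("ALA", length)
  if (length(site_indices)) {
    codes[site_indices] <- rep(site_codes, length.out = length(site_indices))
  }
  side_o_name <- c(SER = "OG", THR = "OG1", TYR = "OH")

  rows <- list()
  for (i in seq_len(length)) {
    cb <- place_atom(c_xyz[i, ], n_xyz[i, ], ca_xyz[i, ], 1.53, 110.4, 122.5)
    at <- data.frame(
      res_index = i,
      name = c("N", "CA", "C", "CB"),
      element = c("N", "C", "C", "C"),
      x = c(n_xyz[i, 1], ca_xyz[i, 1], c_xyz[i, 1], cb[1]),
      y = c(n_xyz[i, 2], ca_xyz[i, 2], c_xyz[i, 2], cb[2]),
      z = c(n_xyz[i, 3], ca_xyz[i, 3], c_xyz[i, 3], cb[3]),
      occupancy = 1, altloc = "", stringsAsFactors = FALSE
    )
    if (codes[i] %in% names(side_o_name)) {
      og <- place_atom(n_xyz[i, ], ca_xyz[i, ], cb, 1.42, 110.0, 180)
      at <- rbind(at, data.frame(res_index = i, name = side_o_name[[codes[i]]],
                                 element = "O", x = og[1], y = og[2], z = og[3],
                                 occupancy = 1, altloc = "",
                                 stringsAsFactors = FALSE))
    }
    rows[[i]] <- at
  }
  res <- data.frame(code3 = codes, seqnum = seq_len(length), icode = "",
                    stringsAsFactors = FALSE)
  out <- chain_model(pdb_id, chain_id, res, do.call(rbind, rows))
  attr(out, "ss_truth") <- ss
  out
}

#' Define a structural-change scenario
#'
#' @param kind `"null"` (chemical change only), `"local"` (backbone
#'   perturbation confined to a window around the site) or `"global"`
#'   (chain-wide low-frequency deformation).
#' @param chain_length Residues; >= 31 keeps +/-15 windows untruncated.
#' @param site_index Site position (default: chain center).
#' @param ptm_code `"SEP"`, `"TPO"` or `"PTR"`.
#' @param amplitude Peak backbone displacement in Angstrom; defaults to
#'   0 / 3 / 4 for null / local / global.
#' @param perturb_halfwidth Support half-width of the local bump
#'   (residues).
#' @param geometry Backbone geometry passed to [make_backbone()].
#' @param noise_sd Isotropic coordinate noise added to the modified
#'   form (Angstrom).
#' @param seed Integer seed controlling all randomness.
#' @return List of class `scenario`.
#' @export
scenario <- function(kind = c("null", "local", "global"),
                     chain_length = 120L,
                     site_index = as.integer(ceiling(chain_length / 2)),
                     ptm_code = "SEP",
                     amplitude = c(null = 0, local = 3, global = 4)[[kind]],
                     perturb_halfwidth = 6L,
                     geometry = "mixed",
                     noise_sd = 0.05,
                     seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, site_index >= 1, site_index <= chain_length,
            chain_length >= 4)
  structure(list(kind = kind, chain_length = as.integer(chain_length),
                 site_index = as.integer(site_index), ptm_code = ptm_code,
                 amplitude = amplitude,
                 perturb_halfwidth = as.integer(perturb_halfwidth),
                 geometry = geometry, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario")
}

# Smooth taper over residue offsets: 1 on the inner half of the support,
# cosine rolloff to exactly 0 at the declared half-width (C1-smooth,
# support exactly +/-halfwidth).
.bump_taper <- function(offsets, halfwidth) {
  a <- abs(offsets)
  inner <- halfwidth / 2
  t <- numeric(length(a))
  t[a <= inner] <- 1
  mid <- a > inner & a < halfwidth
  t[mid] <- cos((a[mid] - inner) / (halfwidth - inner) * pi / 2)
  t
}

# Attach an idealized phosphate (P + O1P/O2P/O3P, P-O 1.6 A,
# tetrahedral) to the side-chain oxygen of the site residue.
.attach_phosphate <- function(atoms, site_index) {
  side <- atoms[atoms$res_index == site_index &
                atoms$name %in% c("OG", "OG1", "OH"), ]
  cb <- atoms[atoms$res_index == site_index & atoms$name == "CB", ]
  stopifnot(nrow(side) == 1L, nrow(cb) == 1L)
  o <- as.numeric(side[1, c("x", "y", "z")])
  cbx <- as.numeric(cb[1, c("x", "y", "z")])
  u <- o - cbx; u <- u / sqrt(sum(u^2))
  p <- o + 1.6 * u
  # orthonormal frame perpendicular to the P-O axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(u, ref); v <- v / sqrt(sum(v^2))
  w <- cross3(u, v)
  ang <- 109.5 * pi / 180
  op <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th) {
    p + 1.52 * (cos(ang) * u + sin(ang) * (cos(th) * v + sin(th) * w))
  })
  extra <- data.frame(
    res_index = site_index,
    name = c("P", "O1P", "O2P", "O3P"),
    element = c("P", "O", "O", "O"),
    x = c(p[1], op[[1]][1], op[[2]][1], op[[3]][1]),
    y = c(p[2], op[[1]][2], op[[2]][2], op[[3]][2]),
    z = c(p[3], op[[1]][3], op[[2]][3], op[[3]][3]),
    occupancy = 1, altloc = "", stringsAsFactors = FALSE
  )
  rbind(atoms, extra)
}

#' Generate an intact/modified pair for a scenario
#'
#' The modified member is the intact chain with the site residue swapped
#' for its phospho form (phosphate atoms attached at idealized
#' geometry), the scenario's backbone perturbation applied, and Gaussian
#' coordinate noise (`noise_sd`) added everywhere. All randomness is
#' driven by the scenario seed, so regeneration is bit-stable.
#'
#' @param scn A [scenario()].
#' @return List `intact`, `modified` (both `chain_model`) and `truth`
#'   (scenario parameters plus `expected_label`).
#' @export
make_pair <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  parent <- c(SEP = "SER", TPO = "THR", PTR = "TYR")[[scn$ptm_code]]
  if (scn$kind == "local" &&
      (scn$site_index - scn$perturb_halfwidth < 1 ||
       scn$site_index + scn$perturb_halfwidth > scn$chain_length)) {
    stop("site too close to a terminus for the requested half-width")
  }
  intact <- make_backbone(scn$chain_length, scn$geometry,
                          site_indices = scn$site_index, site_codes = parent,
                          pdb_id = sprintf("w%03d", scn$seed %% 1000))
  ss_truth <- attr(intact, "ss_truth")

  set.seed(scn$seed)
  at <- intact$atoms
  at$is_hydrogen <- NULL
  res <- intact$residues[, c("code3", "seqnum", "icode")]
  res$code3[scn$site_index] <- scn$ptm_code
  at <- .attach_phosphate(at, scn$site_index)

  L <- scn$chain_length
  disp <- matrix(0, L, 3)
  if (scn$kind == "local" && scn$amplitude > 0) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(u, ref); v <- v / sqrt(sum(v^2))
    offs <- seq_len(L) - scn$site_index
    t <- .bump_taper(offs, scn$perturb_halfwidth)
    # direction rotates along the window (period 3 residues), so the
    # deformation is smooth but far from any rigid-body motion
    th <- 2 * pi * offs / 3
    disp <- scn$amplitude * t * (cos(th) %o% u + sin(th) %o% v)
  } else if (scn$kind == "global" && scn$amplitude > 0) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- cross3(u, ref); v <- v / sqrt(sum(v^2))
    i <- seq_len(L)
    disp <- (scn$amplitude / sqrt(2)) *
      (sin(2 * pi * 2 * i / L) %o% u + cos(2 * pi * 3 * i / L) %o% v)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  xyz <- xyz + disp[at$res_index, , drop = FALSE]
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = scn$noise_sd), ncol = 3)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  modified <- chain_model(sprintf("m%03d", scn$seed %% 1000), intact$chain_id,
                          res, at)
  attr(modified, "ss_truth") <- ss_truth
  truth <- c(unclass(scn),
             list(expected_label = c(null = "N3", local = "N2",
                                     global = "N1")[[scn$kind]],
                  ss_truth = ss_truth))
  list(intact = intact, modified = modified, truth = truth)
}

#' Write a cohort of synthetic pairs to disk
#'
#' Generates `n_per_scenario` pairs for each scenario kind, writes every
#' chain as a PDB file, and writes `manifest.tsv` (consumable by
#' [load_candidates()]) plus `truth.tsv` with the generating parameters
#' and expected group label.
#'
#' @param dir Output directory (created if needed).
#' @param n_per_scenario Pairs per scenario kind.
#' @param kinds Scenario kinds to include.
#' @param base_seed Seeds are `base_seed + 0:(n-1)` per kind offset.
#' @param site_cycle Site loci cycled over replicates, so a cohort
#'   samples different secondary-structure contexts (the defaults hit
#'   coil, helix and strand positions of the mixed backbone).
#' @param ... Further arguments passed to [scenario()].
#' @return Invisibly, the manifest data frame.
#' @export
make_cohort <- function(dir, n_per_scenario = 5L,
                        kinds = c("null", "local", "global"),
                        base_seed = 1L,
                        site_cycle = c(52L, 60L, 68L, 45L, 75L), ...) {
  stopifnot(n_per_scenario >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); truth <- list()
  serial <- 0L
  for (kind in kinds) {
    for (r in seq_len(n_per_scenario)) {
      serial <- serial + 1L
      scn <- scenario(kind, seed = base_seed + serial - 1L,
                      site_index = site_cycle[(r - 1L) %% length(site_cycle) + 1L],
                      ...)
      pr <- make_pair(scn)
      pr$intact$pdb_id <- sprintf("w%03d", serial)
      pr$modified$pdb_id <- sprintf("m%03d", serial)
      fi <- file.path(dir, sprintf("w%03d.pdb", serial))
      fm <- file.path(dir, sprintf("m%03d.pdb", serial))
      write_pdb(pr$intact, fi)
      write_pdb(pr$modified, fm)
      manifest[[serial]] <- data.frame(
        intact_pdb = basename(fi), intact_chain = "A",
        modified_pdb = basename(fm), modified_chain = "A",
        uniprot_id = sprintf("SYN%04d", serial), stringsAsFactors = FALSE)
      truth[[serial]] <- data.frame(
        uniprot_id = sprintf("SYN%04d", serial), kind = kind,
        seed = scn$seed, site_index = scn$site_index,
        amplitude = scn$amplitude,
        expected_label = pr$truth$expected_label, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
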