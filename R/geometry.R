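# Numeric core: rigid-body superposition, radius of gyration, and
# solvent-accessible surface area on heavy atoms.

# Standard atomic masses (u) for the elements that occur in cleaned
# protein chains; used by the mass-weighted radius of gyration.
.ATOMIC_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845)

#' Default van der Waals radii for heavy-atom SASA
#'
#' Bondi-style set; elements outside the table fall back to
#' `fallback` (with a warning at computation time).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

element_masses <- function(elements, default = 12.011) {
  m <- .ATOMIC_MASS[elements]
  m[is.na(m)] <- default
  unname(m)
}

#' SASA parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (water, 1.4).
#' @param mesh_points Sphere mesh points per atom.
#' @param radii_table Named element -> radius vector.
#' @param fallback_radius Radius used for elements missing from the table.
#' @return List of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, mesh_points = 960,
                        radii_table = default_vdw_radii(),
                        fallback_radius = 1.8) {
  stopifnot(probe_radius > 0, mesh_points >= 2)
  structure(list(probe_radius = probe_radius, mesh_points = mesh_points,
                 radii_table = radii_table, fallback_radius = fallback_radius),
            class = "sasa_params")
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation of `coords_b` that minimize
#' the (weighted) least-squares deviation from `coords_a`, via singular
#' value decomposition of the cross-covariance with the usual sign
#' correction so that the rotation is never a reflection.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom) with
#'   row-wise correspondence, N >= 3.
#' @param weights Optional non-negative per-point weights.
#' @return List of class `superposition` with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3; the fit maps `b` to
#'   `b %*% t(rotation) + translation`), and `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(coords_a, coords_b, weights = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    stop("coordinate sets must both be N x 3")
  }
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 corresponding points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)

  cen_a <- colSums(coords_a * w)
  cen_b <- colSums(coords_b * w)
  ac <- sweep(coords_a, 2, cen_a)
  bc <- sweep(coords_b, 2, cen_b)

  h <- t(bc * w) %*% ac              # cross-covariance, moving -> fixed
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  rot <- sv$v %*% s %*% t(sv$u)      # applied as b %*% t(rot)

  fitted <- bc %*% t(rot)
  resid2 <- rowSums((fitted - ac)^2)
  rmsd <- sqrt(sum(w * resid2))
  structure(list(rotation = rot,
                 translation = as.numeric(cen_a - rot %*% cen_b),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup A `superposition`.
#' @param coords N x 3 matrix in the moving frame.
#' @return N x 3 matrix in the fixed frame.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Per-residue C-alpha displacement profile
#'
#' Superposes the pair once, globally, on all corresponding CA atoms and
#' reports the residual distance per corresponding residue, indexed by
#' the intact chain. Residues without a counterpart get `NA`.
#'
#' @param pair A `pair_record` (see [curate_pairs()]).
#' @return Data frame `intact_index`, `modified_index`, `displacement`
#'   with one row per intact residue.
#' @export
ca_displacement_profile <- function(pair) {
  corr <- pair$correspondence
  if (nrow(corr) < 3) stop("need at least 3 corresponding residues")
  a <- ca_coords(pair$intact, corr$intact_index)
  b <- ca_coords(pair$modified, corr$modified_index)
  sup <- kabsch_superpose(a, b)
  d <- sqrt(rowSums((apply_superposition(sup, b) - a)^2))
  out <- data.frame(intact_index = seq_len(n_residues(pair$intact)),
                    modified_index = NA_integer_,
                    displacement = NA_real_)
  out$modified_index[corr$intact_index] <- corr$modified_index
  out$displacement[corr$intact_index] <- d
  out
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))` with `rbar` the
#' (mass-)centroid. Computed in Angstrom; divide by 10 for nm.
#'
#' @param atoms Atom data frame with `x`, `y`, `z` and `element` columns
#'   (a `chain_model$atoms` table), or an N x 3 coordinate matrix.
#' @param mass_weighted Use standard atomic masses (default); otherwise
#'   uniform weights.
#' @param unit `"angstrom"` or `"nm"`.
#' @return Non-negative scalar.
#' @export
radius_of_gyration <- function(atoms, mass_weighted = TRUE,
                               unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (is.data.frame(atoms)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    m <- if (mass_weighted) element_masses(atoms$element) else rep(1, nrow(xyz))
  } else {
    xyz <- as.matrix(atoms)
    m <- rep(1, nrow(xyz))
  }
  if (nrow(xyz) == 0L) stop("radius of gyration of an empty atom set")
  m <- m / sum(m)
  cen <- colSums(xyz * m)
  rg <- sqrt(sum(m * rowSums(sweep(xyz, 2, cen)^2)))
  if (unit == "nm") rg / 10 else rg
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolling-ball SASA on heavy atoms: each atom is wrapped in a
#' quasi-uniform Fibonacci mesh at radius `r_vdw + probe`; the accessible
#' fraction of mesh points not buried inside any neighbouring atom's
#' expanded sphere gives the atom's exposed area.
#'
#' @param atoms Atom data frame (`x`, `y`, `z`, `element`, optionally
#'   `res_index`); hydrogens must already be removed.
#' @param params A [sasa_params()] object.
#' @return List with `atom_area` (per input atom, Angstrom^2),
#'   `residue_area` (named by `res_index`, if present), `total`.
#' @export
shrake_rupley_sasa <- function(atoms, params = sasa_params()) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 0L) stop("SASA of an empty atom set")
  radii <- params$radii_table[atoms$element]
  if (anyNA(radii)) {
    missing <- unique(atoms$element[is.na(radii)])
    if (is.null(params$fallback_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(missing, collapse = ", "))
    }
    warning("using fallback radius ", params$fallback_radius,
            " A for element(s): ", paste(missing, collapse = ", "))
    radii[is.na(radii)] <- params$fallback_radius
  }
  radii <- unname(radii)
  probe <- params$probe_radius
  ext <- radii + probe
  mesh <- fibonacci_sphere(params$mesh_points)

  # Neighbour lists from the pairwise distance matrix; two atoms can
  # occlude each other only within the sum of their expanded radii.
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      pts <- sweep(mesh * ext[i], 2, xyz[i, ], "+")
      free <- rep(TRUE, nrow(pts))
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
        free[free] <- dj2 > ext[j]^2
      }
      frac <- mean(free)
    }
    area[i] <- 4 * pi * ext[i]^2 * frac
  }
  out <- list(atom_area = area, total = sum(area))
  if (!is.null(atoms$res_index)) {
    out$residue_area <- tapply(area, atoms$res_index, sum)
  }
  out
}

#' Whole-chain per-residue SASA
#'
#' Convenience wrapper computing Shrake-Rupley SASA on a cleaned chain
#' and returning the per-residue sums as a plain vector aligned with the
#' residue table.
#'
#' @param chain A cleaned `chain_model`.
#' @param params A [sasa_params()].
#' @return Numeric vector, one value per residue (Angstrom^2).
#' @export
chain_residue_sasa <- function(chain, params = sasa_params()) {
  res <- shrake_rupley_sasa(chain$atoms, params)
  out <- numeric(n_residues(chain))
  idx <- as.integer(names(res$residue_area))
  out[idx] <- as.numeric(res$residue_area)
  out
}
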