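# Sequence-window neighborhoods of modification sites: per-window
# re-superposition RMSD, radius of gyration and SASA deltas, and
# boundary-distance statistics.

#' Default neighborhood half-widths
#' @return `c(3, 6, 9, 12, 15)`.
#' @export
default_neighborhoods <- function() c(3L, 6L, 9L, 12L, 15L)

#' Extract a +/-k residue window around a site
#'
#' The window covers `k` residues on either side of the site along the
#' sequence, clamped at the chain termini; an untruncated window holds
#' `L_surr = 2k + 1` residues.
#'
#' @param chain A `chain_model`.
#' @param site_index 1-based residue index of the modification site.
#' @param k Half-width; one of [default_neighborhoods()] unless
#'   `allow_any_k`.
#' @param allow_any_k Permit non-standard half-widths.
#' @return List of class `site_window`: `site_index`, `k`, `start`,
#'   `end`, `l_surr`, `truncated`.
#' @export
extract_window <- function(chain, site_index, k, allow_any_k = FALSE) {
  n <- n_residues(chain)
  stopifnot(site_index >= 1, site_index <= n)
  if (!allow_any_k && !(k %in% default_neighborhoods())) {
    stop("half-width k must be one of ", paste(default_neighborhoods(), collapse = ", "))
  }
  start <- max(1L, site_index - k)
  end <- min(n, site_index + k)
  structure(list(site_index = site_index, k = as.integer(k),
                 start = start, end = end,
                 l_surr = end - start + 1L,
                 truncated = (end - start + 1L) != (2L * k + 1L)),
            class = "site_window")
}

#' Normalized Rg and SASA deltas between two scopes
#'
#' `delta_rg_percent = (rg_ptm - rg_wt) / rg_wt * 100 + 100`, so an
#' unchanged scope scores 100%. `delta_sasa_per_residue =
#' (sasa_ptm - sasa_wt) / l_surr`, the SASA change per residue of the
#' neighborhood (for the whole protein, per residue of the chain).
#'
#' @param rg_wt,rg_ptm Radius of gyration of the intact/modified scope.
#' @param sasa_wt,sasa_ptm Summed SASA of the intact/modified scope.
#' @param l_surr Residue count of the scope.
#' @return List of class `delta_metrics`.
#' @export
delta_metrics <- function(rg_wt, rg_ptm, sasa_wt, sasa_ptm, l_surr) {
  stopifnot(rg_wt > 0, l_surr >= 1)
  structure(list(
    rg_wt = rg_wt, rg_ptm = rg_ptm,
    delta_rg_percent = (rg_ptm - rg_wt) / rg_wt * 100 + 100,
    sasa_wt = sasa_wt, sasa_ptm = sasa_ptm,
    l_surr = l_surr,
    delta_sasa_per_residue = (sasa_ptm - sasa_wt) / l_surr
  ), class = "delta_metrics")
}

#' Distance to the most remote window residue
#'
#' Maximum Euclidean CA distance from the site to any residue of its
#' +/-k window (the site itself contributes 0).
#'
#' @inheritParams extract_window
#' @return Distance in Angstrom.
#' @export
boundary_distance <- function(chain, site_index, k, allow_any_k = FALSE) {
  w <- extract_window(chain, site_index, k, allow_any_k)
  xyz <- ca_coords(chain, w$start:w$end)
  site <- ca_coords(chain, site_index)
  max(sqrt(rowSums(sweep(xyz, 2, as.numeric(site))^2)), na.rm = TRUE)
}

#' Descriptive statistics of boundary distances
#'
#' @param values Numeric vector (one boundary distance per pair).
#' @param sample_sd Use the sample (n-1) standard deviation (default);
#'   otherwise population.
#' @return Named vector `min`, `max`, `mean`, `median`, `sd`.
#' @export
summarize_boundary_distances <- function(values, sample_sd = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no boundary distances to summarize")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  if (!sample_sd && length(values) > 1L) {
    s <- s * sqrt((length(values) - 1) / length(values))
  }
  c(min = min(values), max = max(values), mean = mean(values),
    median = stats::median(values), sd = s)
}

# Correspondence rows whose modified-chain index falls in [start, end].
.window_pairs <- function(corr, start, end) {
  corr[corr$modified_index >= start & corr$modified_index <= end, , drop = FALSE]
}

#' Window geometry for one site and half-width
#'
#' The window is anchored on the modified chain and mapped through the
#' pair's residue correspondence; the pair is re-superposed on the
#' window's CA atoms alone (not the global fit). Rg is computed over all
#' atoms of the matched window residues of each form. Window SASA is the
#' sum of whole-chain per-residue SASA over the matched residues — the
#' neighborhood is never excised and recomputed in isolation.
#'
#' @param pair A `pair_record`.
#' @param site_index Site position on the modified chain (1-based).
#' @param k Half-width.
#' @param sasa_intact,sasa_modified Whole-chain per-residue SASA vectors
#'   (see [chain_residue_sasa()]).
#' @param allow_any_k Permit non-standard half-widths.
#' @return List of class `window_geometry` (`window`, `rmsd_window`,
#'   `delta`, `boundary_distance`, `n_pairs`), or `NULL` with a message
#'   when fewer than 3 corresponding residues fall in the window.
#' @export
window_geometry <- function(pair, site_index, k, sasa_intact, sasa_modified,
                            allow_any_k = FALSE) {
  w <- extract_window(pair$modified, site_index, k, allow_any_k)
  wp <- .window_pairs(pair$correspondence, w$start, w$end)
  if (nrow(wp) < 3) {
    message("window k=", k, " at site ", site_index, " of ", pair$pair_id,
            " has fewer than 3 corresponding residues; skipped")
    return(NULL)
  }
  a <- ca_coords(pair$intact, wp$intact_index)
  b <- ca_coords(pair$modified, wp$modified_index)
  sup <- kabsch_superpose(a, b)

  rg_wt <- radius_of_gyration(atoms_of(pair$intact, wp$intact_index))
  rg_ptm <- radius_of_gyration(atoms_of(pair$modified, wp$modified_index))
  sasa_wt <- sum(sasa_intact[wp$intact_index])
  sasa_ptm <- sum(sasa_modified[wp$modified_index])
  delta <- delta_metrics(rg_wt, rg_ptm, sasa_wt, sasa_ptm, w$l_surr)

  site_row <- pair$correspondence[pair$correspondence$modified_index == site_index, ]
  bd <- if (nrow(site_row) == 1L) {
    site_i <- site_row$intact_index
    xyz <- ca_coords(pair$intact, wp$intact_index)
    site_xyz <- ca_coords(pair$intact, site_i)
    max(sqrt(rowSums(sweep(xyz, 2, as.numeric(site_xyz))^2)), na.rm = TRUE)
  } else NA_real_

  structure(list(window = w, rmsd_window = sup$rmsd, delta = delta,
                 boundary_distance = bd, n_pairs = nrow(wp)),
            class = "window_geometry")
}

#' Full geometry table for one pair
#'
#' Computes, for every modification site and half-width, the re-fit
#' window RMSD, Rg and SASA deltas and boundary distance, plus one
#' whole-protein row per site set (`k = NA`) where `L_surr` is the
#' modified-chain length.
#'
#' @param pair A `pair_record`.
#' @param ks Half-widths (default [default_neighborhoods()]).
#' @param params A [sasa_params()].
#' @param sasa_intact,sasa_modified Optional precomputed per-residue
#'   SASA vectors; computed here when missing.
#' @return Data frame with columns `pair_id`, `site_locus`, `k`,
#'   `rmsd_global`, `rmsd_window`, `rg_wt`, `rg_ptm`, `delta_rg_percent`,
#'   `sasa_wt`, `sasa_ptm`, `delta_sasa_per_residue`,
#'   `boundary_distance`, `truncated`.
#' @export
pair_geometry <- function(pair, ks = default_neighborhoods(),
                          params = sasa_params(),
                          sasa_intact = NULL, sasa_modified = NULL) {
  if (is.null(sasa_intact)) sasa_intact <- chain_residue_sasa(pair$intact, params)
  if (is.null(sasa_modified)) sasa_modified <- chain_residue_sasa(pair$modified, params)

  rows <- list()
  # Whole-protein scope: full chains, L_surr = modified chain length.
  rg_wt <- radius_of_gyration(pair$intact$atoms)
  rg_ptm <- radius_of_gyration(pair$modified$atoms)
  whole <- delta_metrics(rg_wt, rg_ptm, sum(sasa_intact), sum(sasa_modified),
                         n_residues(pair$modified))
  rows[[1]] <- data.frame(
    pair_id = pair$pair_id, site_locus = "whole", k = NA_integer_,
    rmsd_global = pair$rmsd_global, rmsd_window = NA_real_,
    rg_wt = whole$rg_wt, rg_ptm = whole$rg_ptm,
    delta_rg_percent = whole$delta_rg_percent,
    sasa_wt = whole$sasa_wt, sasa_ptm = whole$sasa_ptm,
    delta_sasa_per_residue = whole$delta_sasa_per_residue,
    boundary_distance = NA_real_, truncated = NA,
    stringsAsFactors = FALSE
  )
  for (s in seq_len(nrow(pair$sites))) {
    for (k in ks) {
      wg <- window_geometry(pair, pair$sites$index[s], k,
                            sasa_intact, sasa_modified)
      if (is.null(wg)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pair$pair_id, site_locus = pair$sites$locus[s], k = k,
        rmsd_global = pair$rmsd_global, rmsd_window = wg$rmsd_window,
        rg_wt = wg$delta$rg_wt, rg_ptm = wg$delta$rg_ptm,
        delta_rg_percent = wg$delta$delta_rg_percent,
        sasa_wt = wg$delta$sasa_wt, sasa_ptm = wg$delta$sasa_ptm,
        delta_sasa_per_residue = wg$delta$delta_sasa_per_residue,
        boundary_distance = wg$boundary_distance, truncated = wg$window$truncated,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Per-k window RMSD of a pair, aggregated over sites
#'
#' For classification, a pair's window RMSD at each half-width is the
#' maximum over its modification sites (most sensitive to any local
#' change).
#'
#' @param geometry Data frame from [pair_geometry()].
#' @return Named numeric vector indexed by `k`.
#' @export
pair_window_rmsd <- function(geometry) {
  g <- geometry[!is.na(geometry$k), , drop = FALSE]
  if (nrow(g) == 0L) return(numeric(0))
  out <- tapply(g$rmsd_window, g$k, max)
  stats::setNames(as.numeric(out), names(out))
}
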