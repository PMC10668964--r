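# Distribution summaries of the geometric indicators: Gaussian KDE
# curves with Scott's bandwidth, histograms, and per-group medians.

#' Gaussian kernel density estimate with Scott's bandwidth
#'
#' Bandwidth is Scott's rule, `sd(x) * n^(-1/5)`; the curve is evaluated
#' on `n_grid` points spanning the data range extended by four
#' bandwidths on each side, so the trapezoidal integral is ~1. No
#' clipping at physical bounds is applied; any probability mass below an
#' expected lower bound is the caller's to inspect.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param n_grid Number of grid points (default 500).
#' @return List of class `kde_curve`: `grid`, `density`, `bandwidth`.
#' @export
kde_curve <- function(values, n_grid = 500L) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L) {
    stop("KDE needs at least 2 distinct values (degenerate bandwidth)")
  }
  bw <- stats::sd(values) * length(values)^(-1 / 5)
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = min(values) - 4 * bw, to = max(values) + 4 * bw,
                      n = n_grid)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "kde_curve")
}

#' Trapezoidal integral of a KDE curve
#' @param curve A `kde_curve`.
#' @return Scalar (close to 1 for a well-resolved curve).
#' @export
kde_integral <- function(curve) {
  sum(diff(curve$grid) * (utils::head(curve$density, -1) +
                          utils::tail(curve$density, -1)) / 2)
}

#' Histogram counts for a metric
#'
#' @param values Numeric vector.
#' @param breaks Passed to [graphics::hist()] breaks logic via
#'   [base::cut()]-compatible `hist(plot = FALSE)`.
#' @return Data frame `mid`, `count`.
#' @export
metric_histogram <- function(values, breaks = "Sturges") {
  h <- graphics::hist(values[!is.na(values)], breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Per-group, per-neighborhood medians of a metric
#'
#' @param geometry Combined [pair_geometry()] table with a `label`
#'   column (group assignment merged in).
#' @param metric Column to summarize (e.g. `"rmsd_window"`,
#'   `"delta_rg_percent"`, `"delta_sasa_per_residue"`).
#' @param group Group label to select (`"N1"`, `"N2"`, `"N3"`), or
#'   `NULL` for all rows.
#' @return Data frame `k`, `median`, `n`; window rows only.
#' @export
group_medians <- function(geometry, metric, group = NULL) {
  g <- geometry[!is.na(geometry$k), , drop = FALSE]
  if (!is.null(group)) g <- g[g$label == group, , drop = FALSE]
  if (nrow(g) == 0L) {
    message("no rows for group ", group)
    return(data.frame(k = integer(0), median = numeric(0), n = integer(0)))
  }
  ks <- sort(unique(g$k))
  data.frame(
    k = ks,
    median = vapply(ks, function(k) stats::median(g[[metric]][g$k == k],
                                                  na.rm = TRUE), numeric(1)),
    n = vapply(ks, function(k) sum(g$k == k), integer(1))
  )
}

#' KDE table for a metric by group and neighborhood
#'
#' Produces the long-format backing table of the distribution figures:
#' one KDE curve per (group, k) cell with enough data.
#'
#' @inheritParams group_medians
#' @param n_grid Grid size per curve.
#' @return Data frame `label`, `k`, `grid`, `density`, `bandwidth`.
#' @export
kde_table <- function(geometry, metric, n_grid = 500L) {
  g <- geometry[!is.na(geometry$k), , drop = FALSE]
  rows <- list()
  for (lab in unique(g$label)) {
    for (k in sort(unique(g$k))) {
      v <- g[[metric]][g$label == lab & g$k == k]
      v <- v[!is.na(v)]
      if (length(unique(v)) < 2L) next
      cur <- kde_curve(v, n_grid)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, k = k, grid = cur$grid, density = cur$density,
        bandwidth = cur$bandwidth, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(label = character(0), k = integer(0), grid = numeric(0),
                      density = numeric(0), bandwidth = numeric(0)))
  }
  do.call(rbind, rows)
}
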