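# Orchestration: scan a directory of structures for phospho-sites,
# build candidates from a pair manifest, and run the full
# curate -> analyze -> classify -> summarize workflow.

#' Pipeline configuration
#'
#' @param manifest Path to a pair-manifest TSV (columns `intact_pdb`,
#'   `intact_chain`, `modified_pdb`, `modified_chain`, `uniprot_id`), or
#'   a data frame of the same shape.
#' @param output_dir Directory for result tables (`NULL` = don't write).
#' @param neighborhoods Window half-widths, ascending.
#' @param rmsd_threshold Group-decision threshold, Angstrom.
#' @param sasa [sasa_params()].
#' @param curation [curation_config()].
#' @param edge_margin Site-context border width, residues.
#' @param ss_source Secondary-structure source (see
#'   [assign_secondary_structure()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, output_dir = NULL,
                            neighborhoods = default_neighborhoods(),
                            rmsd_threshold = 2.0,
                            sasa = sasa_params(),
                            curation = curation_config(),
                            edge_margin = 2L,
                            ss_source = "auto") {
  stopifnot(rmsd_threshold >= 0, !is.unsorted(neighborhoods))
  structure(list(manifest = manifest, output_dir = output_dir,
                 neighborhoods = as.integer(neighborhoods),
                 rmsd_threshold = rmsd_threshold, sasa = sasa,
                 curation = curation, edge_margin = as.integer(edge_margin),
                 ss_source = ss_source),
            class = "pipeline_config")
}

#' Scan structures for phospho-sites
#'
#' Parses and cleans every `.pdb` file in a directory (or an explicit
#' file list) and catalogues SEP/TPO/PTR occurrences per chain.
#' Unreadable files are skipped with a message.
#'
#' @param path Directory containing PDB files, or a character vector of
#'   file paths.
#' @return Data frame: `file`, `pdb_id`, `chain`, `n_res`, `n_SEP`,
#'   `n_TPO`, `n_PTR`, `loci` (comma-joined author loci).
#' @export
run_scan <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  } else path[file.exists(path)]
  if (length(files) == 0L) {
    warning("no PDB files found to scan")
  }
  rows <- list()
  for (f in files) {
    chains <- tryCatch(parse_pdb(file = f), error = function(e) {
      message("skipping ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(chains)) next
    for (ch in chains) {
      cl <- tryCatch(clean_structure(ch), error = function(e) NULL)
      if (is.null(cl)) next
      sites <- find_phospho_sites(cl)
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, pdb_id = cl$pdb_id, chain = cl$chain_id,
        n_res = n_residues(cl),
        n_SEP = sum(sites$ptm_code == "SEP"),
        n_TPO = sum(sites$ptm_code == "TPO"),
        n_PTR = sum(sites$ptm_code == "PTR"),
        loci = paste(paste0(sites$locus, sites$ptm_code), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(file = character(0), pdb_id = character(0),
                      chain = character(0), n_res = integer(0),
                      n_SEP = integer(0), n_TPO = integer(0),
                      n_PTR = integer(0), loci = character(0)))
  }
  do.call(rbind, rows)
}

#' Build candidate pairs from a manifest
#'
#' @param manifest Manifest TSV path or data frame (columns
#'   `intact_pdb`, `intact_chain`, `modified_pdb`, `modified_chain`,
#'   `uniprot_id`; paths relative to `dir` if given).
#' @param dir Base directory for relative paths; defaults to the
#'   manifest's own directory when `manifest` is a path.
#' @return List of `candidate_pair`.
#' @export
load_candidates <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  need <- c("intact_pdb", "intact_chain", "modified_pdb", "modified_chain",
            "uniprot_id")
  stopifnot(all(need %in% names(manifest)))
  resolve <- function(p) {
    if (!is.null(dir) && !startsWith(p, "/")) file.path(dir, p) else p
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    ic <- parse_pdb(file = resolve(manifest$intact_pdb[i]))
    mc <- parse_pdb(file = resolve(manifest$modified_pdb[i]))
    intact <- clean_structure(ic[[manifest$intact_chain[i]]])
    modified <- clean_structure(mc[[manifest$modified_chain[i]]])
    up <- manifest$uniprot_id[i]
    if (is.null(up) || is.na(up) || up == "") up <- NA_character_
    candidate_pair(intact, modified, up, up)
  })
}

#' Run the full analysis workflow
#'
#' Curates the manifest's candidate pairs, computes whole-protein and
#' windowed geometry for every accepted pair, classifies pairs into
#' N1/N2/N3, and produces boundary-distance summaries, per-group
#' medians and KDE tables. When `config$output_dir` is set, every table
#' is written as TSV plus a `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return List: `verdicts`, `records`, `geometry` (combined table with
#'   group labels), `segments`, `group_counts`, `boundary_summary`,
#'   `medians`, `kde`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  candidates <- load_candidates(config$manifest)
  cur <- curate_pairs(candidates, config$curation)
  if (length(cur$records) == 0L) {
    stop("no candidate pair passed curation; see the verdict table for ",
         "per-criterion reject reasons")
  }
  geoms <- lapply(cur$records, pair_geometry,
                  ks = config$neighborhoods, params = config$sasa)
  segments <- segment_pairs(cur$records, geoms,
                            threshold = config$rmsd_threshold,
                            edge_margin = config$edge_margin,
                            ss_source = config$ss_source)
  geometry <- do.call(rbind, geoms)
  geometry$label <- segments$label[match(geometry$pair_id, segments$pair_id)]
  rownames(geometry) <- NULL

  wins <- geometry[!is.na(geometry$k), , drop = FALSE]
  boundary_summary <- do.call(rbind, lapply(sort(unique(wins$k)), function(k) {
    s <- summarize_boundary_distances(wins$boundary_distance[wins$k == k])
    data.frame(k = k, t(s))
  }))

  medians <- do.call(rbind, lapply(intersect(c("N2", "N3"), segments$label),
    function(g) {
      do.call(rbind, lapply(c("rmsd_window", "delta_rg_percent",
                              "delta_sasa_per_residue"), function(m) {
        gm <- group_medians(geometry, m, g)
        if (nrow(gm)) cbind(label = g, metric = m, gm) else NULL
      }))
    }))

  kde <- kde_table(geometry, "rmsd_window")
  group_counts <- table(factor(segments$label, levels = c("N1", "N2", "N3")))

  out <- list(verdicts = cur$verdicts, records = cur$records,
              geometry = geometry, segments = segments,
              group_counts = group_counts,
              boundary_summary = boundary_summary,
              medians = medians, kde = kde)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) utils::write.table(
      x, file.path(config$output_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(cur$verdicts, "verdicts.tsv")
    wt(geometry, "window_metrics.tsv")
    wt(segments[, setdiff(names(segments), "site_context")], "groups.tsv")
    wt(segments[, c("pair_id", "uniprot_id", "label", "site_context")],
       "site_context.tsv")
    wt(boundary_summary, "boundary_summary.tsv")
    if (!is.null(medians)) wt(medians, "group_medians.tsv")
    wt(kde, "kde_rmsd_window.tsv")
    jsonlite::write_json(
      list(n_candidates = nrow(cur$verdicts),
           n_accepted = length(cur$records),
           group_counts = as.list(group_counts)),
      file.path(config$output_dir, "summary.json"), auto_unbox = TRUE)
  }
  out
}
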