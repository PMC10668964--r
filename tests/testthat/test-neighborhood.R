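test_that("window extraction clamps at termini and tracks truncation", {
  ch <- make_backbone(40, "helix")
  w <- extract_window(ch, 20, 3)
  expect_equal(w$l_surr, 7)
  expect_false(w$truncated)
  expect_equal(c(w$start, w$end), c(17, 23))

  ch10 <- make_backbone(10, "helix")
  w2 <- extract_window(ch10, 2, 3)
  expect_equal(c(w2$start, w2$end, w2$l_surr), c(1, 5, 5))
  expect_true(w2$truncated)

  ch12 <- make_backbone(12, "helix")
  w3 <- extract_window(ch12, 6, 15)
  expect_equal(w3$l_surr, 12)
  expect_true(w3$truncated)

  expect_error(extract_window(ch, 20, 4), "half-width")
  expect_equal(extract_window(ch, 20, 4, allow_any_k = TRUE)$l_surr, 9)
})

test_that("delta formulas are identities on identical scopes", {
  d <- delta_metrics(rg_wt = 10, rg_ptm = 10.8, sasa_wt = 100, sasa_ptm = 100,
                     l_surr = 7)
  expect_equal(d$delta_rg_percent, 108)
  expect_equal(d$delta_sasa_per_residue, 0)
  expect_error(delta_metrics(0, 1, 0, 0, 7), "rg_wt")
})

test_that("identical pairs give zero window RMSD, 100% dRg, 0 dSASA at every k", {
  rec <- identical_record()
  g <- pair_geometry(rec)
  expect_true(all(abs(g$rmsd_window[!is.na(g$k)]) < 1e-9))
  expect_equal(g$delta_rg_percent, rep(100, nrow(g)), tolerance = 1e-9)
  expect_equal(g$delta_sasa_per_residue, rep(0, nrow(g)), tolerance = 1e-9)
  # whole-protein normalization uses the chain length
  whole <- g[is.na(g$k), ]
  expect_equal(nrow(whole), 1)
})

test_that("local perturbation inflates window RMSD above the global value", {
  rec <- fixture_record("local", seed = 21)
  g <- pair_geometry(rec, sasa_intact = numeric(n_residues(rec$intact)),
                     sasa_modified = numeric(n_residues(rec$modified)))
  wr <- pair_window_rmsd(g)
  expect_gt(wr[["6"]], rec$rmsd_global)
})

test_that("window re-fit can never beat the globally superposed residuals", {
  for (kind in c("null", "local", "global")) {
    rec <- fixture_record(kind, seed = 22)
    sup_global <- kabsch_superpose(
      ca_coords(rec$intact, rec$correspondence$intact_index),
      ca_coords(rec$modified, rec$correspondence$modified_index))
    for (k in c(3, 9, 15)) {
      for (s in rec$sites$index) {
        w <- extract_window(rec$modified, s, k)
        wp <- rec$correspondence[rec$correspondence$modified_index >= w$start &
                                 rec$correspondence$modified_index <= w$end, ]
        a <- ca_coords(rec$intact, wp$intact_index)
        b <- ca_coords(rec$modified, wp$modified_index)
        local_fit <- kabsch_superpose(a, b)$rmsd
        global_resid <- sqrt(mean(rowSums(
          (apply_superposition(sup_global, b) - a)^2)))
        expect_lte(local_fit, global_resid + 1e-9)
      }
    }
  }
})

test_that("boundary distance is non-decreasing in k", {
  ch <- make_backbone(80, "mixed", site_indices = 40, site_codes = "SER")
  vals <- vapply(default_neighborhoods(), function(k)
    boundary_distance(ch, 40, k), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # pathological single-residue window
  ch1 <- parse_pdb(text = paste(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, elem = "C"), "END",
    sep = "\n"))[["A"]]
  expect_equal(boundary_distance(ch1, 1, 3), 0)
})

test_that("boundary-distance summaries match hand computation", {
  s <- summarize_boundary_distances(5)
  expect_equal(unname(s), c(5, 5, 5, 5, 0))
  s2 <- summarize_boundary_distances(c(1, 2, 3))
  expect_equal(s2[["mean"]], 2)
  expect_equal(s2[["median"]], 2)
  expect_equal(s2[["sd"]], 1)
  expect_equal(summarize_boundary_distances(c(1, 2, 3), sample_sd = FALSE)[["sd"]],
               sqrt(2 / 3))
  # three synthetic helical chains with sites at different loci
  vals <- vapply(c(20, 30, 40), function(s) {
    boundary_distance(make_backbone(60, "helix"), s, 3)
  }, numeric(1))
  s3 <- summarize_boundary_distances(vals)
  expect_equal(s3[["min"]], min(vals))
  expect_equal(s3[["max"]], max(vals))
  expect_equal(s3[["mean"]], mean(vals))
  expect_error(summarize_boundary_distances(numeric(0)), "no boundary")
})

test_that("degenerate windows are skipped with a message", {
  rec <- identical_record(length = 60, site = 30)
  # restrict the correspondence to starve the window below 3 pairs
  rec$correspondence <- rec$correspondence[c(1, 2, 30), ]
  expect_message(
    out <- window_geometry(rec, 30, 3, numeric(60), numeric(60)),
    "fewer than 3")
  expect_null(out)
})
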