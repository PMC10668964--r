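test_that("sequence identity uses alignment-length denominator", {
  a <- strrep("A", 100)
  expect_equal(sequence_identity(a, a), 1.0)
  # 2 mismatches in 20, no gaps: 18/20 (hand-counted alignment)
  b20 <- "ACDEFGHIKLMNPQRSTVWY"
  b20_mut <- "ACDEFGHIKLMNPQRSTVAA"
  expect_equal(sequence_identity(b20, b20_mut), 0.90)
  expect_error(sequence_identity("", "ACD"), "empty")
})

test_that("phospho-residues compare equal to their parents after mapping", {
  rec <- fixture_record("null", seed = 5)
  expect_equal(rec$identity, 1.0)
  # correspondence is injective and order-preserving
  corr <- rec$correspondence
  expect_false(any(duplicated(corr$intact_index)))
  expect_false(any(duplicated(corr$modified_index)))
  expect_true(all(diff(corr$intact_index) > 0))
  expect_true(all(diff(corr$modified_index) > 0))
})

test_that("phospho groups are counted as phospho-residues", {
  pr <- make_pair(scenario("null", seed = 2))
  expect_equal(count_phospho_groups(pr$modified), 1)
  expect_equal(count_phospho_groups(pr$intact), 0)
  expect_equal(count_phospho_groups(multi_phospho_chain(sites = c(30L, 50L, 70L))), 3)
  # histone-like extreme: 14 phospho residues are countable
  expect_equal(count_phospho_groups(
    multi_phospho_chain(sites = as.integer(seq(10, 114, by = 8)))), 14)
})

test_that("per-pair filters report every violated criterion, unordered", {
  pr <- make_pair(scenario("null", seed = 3, chain_length = 14L,
                           site_index = 7L))
  short <- candidate_pair(pr$intact, pr$modified, "U1")
  v <- apply_pair_filters(short)
  expect_false(v$accepted)
  expect_equal(v$reasons, "C1")

  # no UniProt accession: rejected with C2, not an exception
  pr2 <- make_pair(scenario("null", seed = 3))
  v2 <- apply_pair_filters(candidate_pair(pr2$intact, pr2$modified))
  expect_equal(v2$reasons, "C2")

  # several violations at once are all reported (no short-circuit)
  v3 <- apply_pair_filters(candidate_pair(pr$intact, pr$modified))
  expect_setequal(v3$reasons, c("C1", "C2"))
})

test_that("length-difference and identity thresholds reject at the boundary", {
  big <- make_pair(scenario("null", seed = 4, chain_length = 120L))
  small6 <- make_pair(scenario("null", seed = 4, chain_length = 114L,
                               site_index = 57L))
  v <- apply_pair_filters(candidate_pair(big$intact, small6$modified, "U"))
  expect_equal(v$reasons, "C4")
  # exactly 5 apart is allowed
  small5 <- make_pair(scenario("null", seed = 4, chain_length = 115L,
                               site_index = 57L))
  v5 <- apply_pair_filters(candidate_pair(big$intact, small5$modified, "U"))
  expect_true(v5$accepted)
})

test_that("best modified candidate is the lowest-RMSD one, ties by key", {
  pr_null <- make_pair(scenario("null", seed = 6))
  pr_glob <- make_pair(scenario("global", seed = 6))
  best <- select_best_modified(pr_null$intact,
                               list(pr_glob$modified, pr_null$modified))
  expect_identical(best$pdb_id, pr_null$modified$pdb_id)
  expect_identical(select_best_modified(pr_null$intact,
                                        list(pr_null$modified))$pdb_id,
                   pr_null$modified$pdb_id)
  # two rigid copies tie at RMSD ~0: lexicographically smaller id wins
  copy_b <- rekey_chain(pr_null$modified, "zzzz")
  copy_a <- rekey_chain(pr_null$modified, "aaaa")
  expect_identical(select_best_modified(pr_null$intact,
                                        list(copy_b, copy_a))$pdb_id, "aaaa")
  expect_error(select_best_modified(pr_null$intact, list()), "no candidates")
})

test_that("dedupe keeps one record per accession and locus set", {
  r1 <- fixture_record("null", seed = 7)
  r2 <- fixture_record("local", seed = 7)   # same accession, same locus
  kept <- dedupe_pairs(list(r1, r2))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$rmsd_global, min(r1$rmsd_global, r2$rmsd_global))
  # different locus survives
  r3 <- make_pair(scenario("null", seed = 8, site_index = 40L))
  r3 <- build_pair_record(candidate_pair(r3$intact, r3$modified, "SYNTEST"))
  expect_length(dedupe_pairs(list(r1, r3)), 2)
  expect_length(dedupe_pairs(list()), 0)
  # idempotence
  expect_identical(dedupe_pairs(kept), kept)
})

test_that("an identical pair differing only by the phosphate is accepted", {
  pr <- make_pair(scenario("null", seed = 9))
  v <- apply_pair_filters(candidate_pair(pr$intact, pr$modified, "U9"))
  expect_true(v$accepted)
  expect_length(v$reasons, 0)
})
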