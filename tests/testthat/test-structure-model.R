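test_that("parsing retains CA-bearing HETATM residues and splits chains", {
  chains <- parse_pdb(text = messy_pdb_text())
  expect_named(chains, "A")
  ch <- chains[["A"]]
  # ALA + SEP + HOH + ZN before cleaning
  expect_equal(n_residues(ch), 4)
  sep <- ch$residues[ch$residues$code3 == "SEP", ]
  expect_true(sep$is_phospho)
  expect_equal(sep$parent_code3, "SER")

  two_chain <- paste(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, elem = "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0, elem = "C"),
    pdb_line("ATOM", 3, "CA", "GLY", "B", 1, 0, 5, 0, elem = "C"),
    "END"), collapse = "\n")
  cs <- parse_pdb(text = two_chain)
  expect_setequal(names(cs), c("A", "B"))
  expect_equal(n_residues(cs[["A"]]), 2)
  expect_equal(n_residues(cs[["B"]]), 1)
})

test_that("a file with only solvent and ions is not a polymer chain", {
  only_het <- paste(c(
    pdb_line("HETATM", 1, "O", "HOH", "A", 1, 0, 0, 0, elem = "O"),
    pdb_line("HETATM", 2, "ZN", "ZN", "A", 2, 1, 1, 1, elem = "ZN"),
    "END"), collapse = "\n")
  expect_error(parse_pdb(text = only_het), "no polymer chain")
})

test_that("cleaning removes waters, ions, hydrogens and resolves altlocs", {
  ch <- parse_pdb(text = messy_pdb_text())[["A"]]
  cl <- clean_structure(ch)
  expect_equal(n_residues(cl), 2)          # ALA + SEP survive
  expect_false(any(cl$atoms$is_hydrogen))
  expect_false(any(cl$residues$code3 %in% c("HOH", "ZN")))
  # altloc: highest occupancy CB retained, exactly one
  cb <- cl$atoms[cl$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$occupancy, 0.6)
  # idempotence
  expect_identical(clean_structure(cl)$atoms, cl$atoms)
})

test_that("cleaning drops residues without CA and errors on empty chains", {
  txt <- paste(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, elem = "C"),
    pdb_line("ATOM", 2, "N", "GLY", "A", 2, 3.8, 0, 0, elem = "N"),
    "END"), collapse = "\n")
  ch <- parse_pdb(text = txt)[["A"]]
  cl <- clean_structure(ch)
  expect_equal(n_residues(cl), 1)

  het_only <- paste(c(
    pdb_line("HETATM", 1, "O", "HOH", "A", 1, 0, 0, 0, elem = "O"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 1, 1, 1, elem = "C"),
    "END"), collapse = "\n")
  ch2 <- parse_pdb(text = het_only)[["A"]]
  expect_error(clean_structure(ch2, exclusion_list = c("HOH", "GLY")),
               "no polymer chain")
})

test_that("only the first MODEL of a multi-model file is read", {
  model_txt <- paste(c(
    "MODEL        1",
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, elem = "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3.8, 0, 0, elem = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 10, 0, 0, elem = "C"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 13.8, 0, 0, elem = "C"),
    "ENDMDL",
    "END"), collapse = "\n")
  ch <- parse_pdb(text = model_txt)[["A"]]
  expect_equal(n_residues(ch), 2)
  expect_equal(ch$atoms$x[1], 0)
})

test_that("phospho-site detection matches a brute-force residue scan", {
  ch <- make_backbone(50, "mixed", site_indices = c(10, 20, 35),
                      site_codes = c("SER", "TYR", "THR"))
  ch <- recode_residues(ch, c(10, 20), c("SEP", "PTR"))
  sites <- find_phospho_sites(ch)
  expect_equal(sites$index, c(10, 20))
  expect_equal(sites$ptm_code, c("SEP", "PTR"))
  # brute-force oracle over the residue table
  expect_equal(nrow(sites), sum(ch$residues$code3 %in% c("SEP", "TPO", "PTR")))
  # a chain of canonical residues has no sites
  expect_equal(nrow(find_phospho_sites(make_backbone(50, "helix"))), 0)
})

test_that("write/parse round-trip preserves codes, order and coordinates", {
  pr <- make_pair(scenario("local", seed = 11))
  lines <- write_pdb(pr$modified)
  expect_true(any(grepl("^HETATM", lines) & grepl("SEP", lines)))
  back <- parse_pdb(text = paste(lines, collapse = "\n"))[["A"]]
  expect_equal(back$residues$code3, pr$modified$residues$code3)
  expect_equal(back$atoms$name, pr$modified$atoms$name)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(pr$modified$atoms[, c("x", "y", "z")]))), 1e-3)
  # parse . write . parse is idempotent
  again <- parse_pdb(text = paste(write_pdb(back), collapse = "\n"))[["A"]]
  expect_identical(again$atoms, back$atoms)
  expect_error(write_pdb(structure(list(residues = data.frame(),
                                        atoms = data.frame()),
                                   class = "chain_model")),
               "empty")
})

test_that("the shipped exclusion list carries the scan codes", {
  std <- exclusion_codes("standard_aa")
  het <- exclusion_codes("non_polymer")
  expect_length(std, 20)
  expect_length(het, 25)
  expect_true(all(c("HOH", "ZN", "SO4", "DT", "UNK", "NA") %in% het))
  expect_false(any(c("SEP", "TPO", "PTR") %in% exclusion_codes()))
})
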