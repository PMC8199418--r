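# Structure and pathway-map input: SDF/SMILES parsing, format
# equivalence, charge handling, and pathway filtering.

write_sdf_from_smiles <- function(smiles_named, path) {
  # multi-record SDF via OpenBabel, one record per named SMILES
  txt <- vapply(names(smiles_named), function(id) {
    rec <- ChemmineOB::convertFormat("SMI", "SDF",
                                     paste0(smiles_named[[id]], "\n"))
    sub("^[^\n]*", id, rec)  # put the id on the name line
  }, character(1))
  writeLines(paste(txt, collapse = ""), path)
  path
}

test_that("SMILES and SDF routes give identical fragment sets", {
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_from_smiles(as.list(oracle_panel_smiles), f)
  from_sdf <- read_sdf(f)
  expect_length(from_sdf, length(oracle_panel_smiles))
  for (id in names(oracle_panel_smiles)) {
    m_smi <- parse_smiles(oracle_panel_smiles[[id]], id)
    expect_identical(molecule_fragments(from_sdf[[id]]),
                     molecule_fragments(m_smi), label = id)
  }
})

test_that("SDF reader handles minimal, multi-record and corrupt input", {
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_from_smiles(list(methane = "C", ethanol = "CCO",
                             benzene = "c1ccccc1"), f)
  mols <- read_sdf(f)
  expect_identical(attr(mols, "skipped"), 0L)
  expect_identical(nrow(mols$methane$atoms), 1L)
  expect_identical(nrow(mols$methane$bonds), 0L)
  expect_identical(nrow(mols$ethanol$atoms), 3L)
  expect_identical(nrow(mols$benzene$atoms), 6L)

  # corrupt the middle record's counts line
  lines <- readLines(f)
  cl <- grep("V2000", lines)[2]
  lines[cl] <- "garbage counts line"
  f2 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(lines, f2)
  expect_warning(mols2 <- read_sdf(f2), "skipping")
  expect_length(mols2, 2L)
  expect_identical(attr(mols2, "skipped"), 1L)

  f3 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), f3)
  expect_error(read_sdf(f3), "empty")
})

test_that("explicit hydrogens are stripped before fragmentation", {
  # ethanol with explicit hydrogens, hand-written V2000
  rec <- c("ethanol_H", " test", "",
           "  5  4  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "  2  3  1  0  0  0  0",
           "  1  4  1  0  0  0  0",
           "  3  5  1  0  0  0  0",
           "M  END", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(rec, f)
  mol <- read_sdf(f)[[1]]
  expect_identical(nrow(mol$atoms), 3L)
  expect_identical(molecule_fragments(mol),
                   molecule_fragments(parse_smiles("CCO", "ethanol")))
})

test_that("parse_smiles builds the expected graphs and rejects bad input", {
  eth <- parse_smiles("CCO", "ethanol")
  expect_identical(eth$atoms$element, c("C", "C", "O"))
  expect_identical(nrow(eth$bonds), 2L)
  expect_true(all(eth$bonds$order == 1L))

  benz <- parse_smiles("c1ccccc1", "benzene")
  expect_identical(nrow(benz$atoms), 6L)
  expect_identical(nrow(benz$bonds), 6L)
  expect_true(all(benz$bonds$order == 4L))
  expect_true(all(benz$atoms$aromatic))

  expect_error(parse_smiles("C(", "bad"), "C\\(")
  expect_error(parse_smiles("C1CC", "bad_ring"), "invalid SMILES")
})

test_that("kekulized and aromatic ring encodings give identical fragments", {
  pairs <- list(c("c1ccccc1", "C1=CC=CC=C1"),
                c("c1ccncc1", "C1=CC=NC=C1"),
                c("Cc1ccccc1", "CC1=CC=CC=C1"))
  for (p in pairs) {
    expect_identical(molecule_fragments(parse_smiles(p[1], "a")),
                     molecule_fragments(parse_smiles(p[2], "k")),
                     label = p[1])
  }
  # saturated ring must NOT be marked aromatic
  chx <- parse_smiles("C1CCCCC1", "cyclohexane")
  expect_true(all(chx$bonds$order == 1L))
})

test_that("formal charges reach atom labels, M CHG superseding", {
  rec <- c("acetate", " test", "",
           "  4  3  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "    1.0000    1.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "  2  3  2  0  0  0  0",
           "  2  4  1  0  0  0  0",
           "M  CHG  1   4  -1",
           "M  END", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(rec, f)
  mol <- read_sdf(f)[[1]]
  expect_identical(mol$atoms$charge, c(0L, 0L, 0L, -1L))
  expect_true("C-O-" %in% enumerate_linear_fragments(mol))
  # matches the SMILES route with the bracket charge
  expect_identical(molecule_fragments(mol),
                   molecule_fragments(parse_smiles("CC(=O)[O-]", "ac")))
  # charges can be ignored by configuration
  expect_false(any(grepl("O-$", enumerate_linear_fragments(mol, charges = FALSE))))
})

test_that("pathway map has set semantics and both directions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tc1", "P1\tc2", "P2\tc1", "P1\tc1"), f)
  map <- read_pathway_map(f)
  expect_identical(map$pathways$P1, c("c1", "c2"))
  expect_identical(map$compounds$c1, c("P1", "P2"))
  expect_identical(map$compounds$c2, "P1")

  # header detection
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tcompound_id", "P1\tc1", "P1\tc2"), f2)
  expect_identical(read_pathway_map(f2)$pathways$P1, c("c1", "c2"))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f3)
  expect_error(read_pathway_map(f3), "empty")
})

test_that("pathway size filter keeps the boundary and is idempotent", {
  mk <- function(n, p) data.frame(pathway_id = p,
                                  compound_id = sprintf("%s_c%02d", p, 1:n))
  map <- pathway_map(rbind(mk(9, "small"), mk(10, "boundary"), mk(15, "big")))
  filt <- filter_pathways(map, 10)
  expect_identical(names(filt$pathways), c("big", "boundary"))
  # compounds of the dropped pathway leave the reverse map
  expect_false(any(grepl("^small", names(filt$compounds))))
  expect_identical(filter_pathways(filt, 10), filt)
  expect_identical(filter_pathways(map, 1)$pathways, map$pathways)
})

test_that("map/structure mismatches are reported by validation", {
  map <- pathway_map(data.frame(pathway_id = c("P1", "P1"),
                                compound_id = c("c1", "c2")))
  v <- validate_compounds(map, c("c2", "c3"))
  expect_identical(v$missing_structure, "c1")
  expect_identical(v$unmapped, "c3")
})
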