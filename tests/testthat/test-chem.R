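# structure module: level-1 scaffold assignment, PAINS alerting, analog scores

test_that("single-ring and acyclic molecules get the expected scaffolds", {
  sc <- level1_scaffold(c("benzene", "propane"), c("c1ccccc1", "CCC"))
  expect_equal(sc[sc$compound_id == "benzene", ]$level1_scaffold, "c1ccccc1")
  expect_equal(sc[sc$compound_id == "propane", ]$level1_scaffold, "")
  expect_equal(sc[sc$compound_id == "propane", ]$n_rings, 0L)
})

test_that("side chains never change the scaffold assignment", {
  sc <- level1_scaffold(c("biphenyl", "methylbiphenyl"),
                        c("c1ccc(-c2ccccc2)cc1", "Cc1ccc(-c2ccccc2)cc1"))
  expect_equal(length(unique(sc$level1_scaffold)), 1L)
  # property: random decoration of library cores maps into the core scaffold
  cores <- c("c1ccc(-c2ccccc2)cc1", "c1ccc2ccccc2c1", "c1ccccc1")
  subs <- c("", "C", "CC", "CCO", "N", "O", "Cl", "CN", "FC(F)(F)")
  grid <- expand.grid(core = cores, sub = subs, stringsAsFactors = FALSE)
  sc2 <- chem_properties(paste0("m", seq_len(nrow(grid))),
                         paste0(grid$sub, grid$core))
  base <- chem_properties(c("b1", "b2", "b3"), cores)
  expect_equal(sc2$level1_scaffold,
               base$level1_scaffold[match(grid$core, base$smiles)])
})

test_that("scaffold assignment is invariant to atom ordering", {
  # same molecule (4-methylbiphenyl) written three different ways
  sc <- level1_scaffold(
    c("w1", "w2", "w3"),
    c("Cc1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccc(C)cc2)cc1",
      "c1cc(C)ccc1-c1ccccc1"))
  expect_equal(length(unique(sc$level1_scaffold)), 1L)
})

test_that("multi-ring frameworks reduce deterministically to two rings", {
  sc <- chem_properties(
    c("terphenyl", "acridine", "benzamide_pip"),
    c("c1ccc(-c2ccccc2-c2ccccc2)cc1",   # 3 linked phenyls
      "c1ccc2nc3ccccc3cc2c1",           # fused, N-containing middle ring
      "O=C(c1ccccc1)N1CCN(Cc2ccncc2)CC1"))
  expect_equal(sc[sc$compound_id == "terphenyl", ]$level1_scaffold,
               "c1ccc(-c2ccccc2)cc1")
  # heteroatom-rich rings are retained: quinoline survives from acridine
  expect_equal(sc[sc$compound_id == "acridine", ]$level1_scaffold,
               "c1ccc2ncccc2c1")
  expect_equal(sc[sc$compound_id == "acridine", ]$n_rings, 3L)
  # repeated runs agree (determinism)
  sc2 <- chem_properties("benzamide_pip", "O=C(c1ccccc1)N1CCN(Cc2ccncc2)CC1")
  expect_equal(sc[sc$compound_id == "benzamide_pip", ]$level1_scaffold,
               sc2$level1_scaffold)
})

test_that("PAINS matching flags known interference motifs", {
  pr <- pains_score(c("methane", "catechol", "catechol2"),
                    c("C", "Oc1ccccc1O", "Oc1ccccc1O"))
  expect_equal(pr[pr$compound_id == "methane", ]$pains_score, 1L)
  expect_equal(pr[pr$compound_id == "catechol", ]$pains_score, 0L)
  expect_match(pr[pr$compound_id == "catechol", ]$alerts, "catechol")
  # duplicate submissions give identical results
  expect_equal(pr[pr$compound_id == "catechol", -"compound_id"],
               pr[pr$compound_id == "catechol2", -"compound_id"])
  # pains_score = 0 iff alerts non-empty
  expect_equal(pr$pains_score == 0L, nzchar(pr$alerts))
})

test_that("a custom SMARTS pattern file replaces the built-in catalog", {
  pf <- withr::local_tempfile(fileext = ".smarts")
  writeLines(c("# test patterns", "c1ccccc1\tany_benzene"), pf)
  pr <- pains_score(c("b", "m"), c("c1ccccc1", "C"), pains_smarts = pf)
  expect_equal(pr[pr$compound_id == "b", ]$pains_score, 0L)
  expect_equal(pr[pr$compound_id == "b", ]$alerts, "any_benzene")
  expect_equal(pr[pr$compound_id == "m", ]$pains_score, 1L)
})

test_that("unparseable structures default to PAINS 1, excluded from scaffolds", {
  expect_warning(cp <- chem_properties(c("ok", "bad"),
                                       c("c1ccccc1", "not_a_smiles((")),
                 "could not be parsed")
  bad <- cp[cp$compound_id == "bad", ]
  expect_false(bad$parse_ok)
  expect_equal(bad$pains_score, 1L)
  expect_equal(bad$level1_scaffold, "")
})

test_that("salts reduce to the largest covalent fragment", {
  cp <- chem_properties(c("salt", "free"),
                        c("Cc1ccc(-c2ccccc2)cc1.Cl", "Cc1ccc(-c2ccccc2)cc1"))
  expect_equal(cp$level1_scaffold[1], cp$level1_scaffold[2])
})

test_that("SAR needs same scaffold, same publication, and an active analog", {
  mk <- function(pub2 = "P1", val2 = 100) ingest_rows(
    raw_row("A", "T1", 100, pubmed = "P1", smiles = "c1ccc(-c2ccccc2)cc1"),
    raw_row("B", "T1", val2, pubmed = pub2, smiles = "Cc1ccc(-c2ccccc2)cc1"))
  score_pair <- function(m) {
    res <- score_dataset(m)
    res$scores[order(res$scores$compound_id), ]
  }
  s <- score_pair(mk())                      # same pub, both active
  expect_equal(s$sar, c(1L, 1L))             # symmetric
  s2 <- score_pair(mk(pub2 = "P2"))          # different publications
  expect_equal(s2$sar, c(0L, 0L))
  s3 <- score_pair(ingest_rows(              # analog inactive: SAR 0, IA 1
    raw_row("A", "T1", 100, pubmed = "P1", smiles = "c1ccc(-c2ccccc2)cc1"),
    raw_row("B", "T1", 50000, pubmed = "P1", smiles = "Cc1ccc(-c2ccccc2)cc1")))
  expect_equal(s3$sar, 0L)
  expect_equal(s3$inactive_analog, 1L)       # only A is scored (B inactive)
  # compound alone in its publication scores 0
  s4 <- score_pair(ingest_rows(
    raw_row("A", "T1", 100, pubmed = "P1", smiles = "c1ccc(-c2ccccc2)cc1")))
  expect_equal(s4$sar, 0L)
})

test_that("inactive-analog matching ignores publications; analogs are symmetric", {
  m <- ingest_rows(
    raw_row("A", "T1", 10, pubmed = "P1", smiles = "c1ccc(-c2ccccc2)cc1"),
    raw_row("B", "T1", 20, pubmed = "P1", smiles = "Cc1ccc(-c2ccccc2)cc1"),
    raw_row("C", "T1", 50000, pubmed = "P9", smiles = "CCc1ccc(-c2ccccc2)cc1"))
  res <- score_dataset(m)
  s <- res$scores[order(res$scores$compound_id), ]
  expect_equal(s$inactive_analog, c(1L, 1L))  # A and B both see C
  # standalone operations agree with the pipeline
  expect_equal(
    inactive_analog_score("A", "T1", res$aggregates, res$chem, m), 1L)
  expect_equal(sar_score("A", "T1", res$aggregates, res$chem, m), 1L)
  # active analog at 10 nM only (no inactive analog around)
  m2 <- ingest_rows(
    raw_row("A", "T1", 10, smiles = "c1ccc(-c2ccccc2)cc1"),
    raw_row("B", "T1", 10, smiles = "Cc1ccc(-c2ccccc2)cc1"))
  res2 <- score_dataset(m2)
  expect_equal(res2$scores$inactive_analog, c(0L, 0L))
})

test_that("acyclic compounds are excluded from analog matching", {
  m <- ingest_rows(
    raw_row("A", "T1", 10, pubmed = "P1", smiles = "CCCC"),
    raw_row("B", "T1", 20, pubmed = "P1", smiles = "CCCCC"))
  res <- score_dataset(m)
  expect_equal(res$scores$sar, c(0L, 0L))
  expect_equal(res$scores$inactive_analog, c(0L, 0L))
})

test_that("SDF input maps molecule titles to compound ids", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  # minimal single-record SDF for ethylbenzene
  writeLines(c(
    "CPD_X", "  probescore", "",
    "  8  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "  1  2  4  0", "  2  3  4  0", "  3  4  4  0", "  4  5  4  0",
    "  5  6  4  0", "  6  1  4  0", "  1  7  1  0", "  7  8  1  0",
    "M  END", "$$$$"), sdf)
  out <- read_sdf_file(sdf)
  expect_equal(out$compound_id, "CPD_X")
  expect_equal(out$smiles, "CCc1ccccc1")
})
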