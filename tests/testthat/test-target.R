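# target-level assessment: Information Richness, icons, minimum standard,
# proteome summary

test_that("Information Richness sums tested-panel sizes over active compounds", {
  # 2 active compounds, tested against 3 and 5 targets -> IR = 8
  rows <- c(
    lapply(paste0("T", 1:3), function(t) raw_row("A", t, 10)),
    lapply(paste0("T", 1:5), function(t) raw_row("B", t, 10))
  )
  agg <- aggregate_pairs(do.call(ingest_rows, rows))
  ir <- information_richness(agg)
  expect_equal(ir[ir$target_accession == "T1", ]$information_richness, 8L)
  # untested accessions raise a lookup error
  expect_error(information_richness(agg, targets = "T99"), "unknown target")
})

test_that("IR is 0 without active compounds; 1 per exclusively-tested active", {
  agg <- aggregate_pairs(ingest_rows(
    raw_row("A", "T1", 50000),   # inactive
    raw_row("B", "T2", 10),      # active, tested only here
    raw_row("C", "T2", 10)))
  ir <- information_richness(agg)
  expect_equal(ir[ir$target_accession == "T1", ]$information_richness, 0L)
  expect_equal(ir[ir$target_accession == "T2", ]$information_richness, 2L)
})

test_that("IR matches the compounds-plus-other-targets decomposition (property)", {
  set.seed(77)
  for (i in 1:5) {
    ls <- generate_landscape(landscape_spec(
      n_targets = 10, n_compounds = 40, seed = 500 + i))
    tf <- withr::local_tempfile(fileext = ".tsv")
    data.table::fwrite(ls$measurements, tf, sep = "\t")
    agg <- aggregate_pairs(parse_bioactivity_table(tf))
    ir <- information_richness(agg)
    for (t in ir$target_accession) {
      expect_equal(ir[ir$target_accession == t, ]$information_richness,
                   oracle_ir_decomposed(agg, t))
    }
  }
})

test_that("IR percentile anchors max at 100, min at 0, ties share values", {
  expect_equal(information_richness_percentile(c(10, 20, 30)), c(0, 50, 100))
  expect_equal(information_richness_percentile(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(information_richness_percentile(42), 100)
  expect_equal(information_richness_percentile(c(1, 1, 7)), c(0, 0, 100))
  expect_equal(information_richness_percentile(numeric()), numeric())
})

test_that("minimum standard needs potency >= 7, cell activity, full selectivity", {
  expect_true(minimum_standard(8, 1, 3, 3))
  expect_false(minimum_standard(8, 1, 3, 2))   # one unselective off-target
  expect_false(minimum_standard(6.5, 1, 3, 3)) # below 100 nM potency
  expect_false(minimum_standard(8, 0, 3, 3))   # no cell activity
  expect_false(minimum_standard(8, 1, 0, 0))   # never screened off-target
  expect_true(minimum_standard(7, 1, 1, 1))    # boundary potency included
})

test_that("minimum standard implies no danger flag (property)", {
  set.seed(88)
  n_off <- sample(0:10, 200, replace = TRUE)
  n_sel <- vapply(n_off, function(k) sample(0:k, 1), 1L)
  ms <- minimum_standard(runif(200, 5, 10), sample(0:1, 200, TRUE),
                         n_off, n_sel)
  expect_true(all(!danger_flag(n_off, n_sel)[ms]))
})

test_that("target icons use the any-off-target selectivity reading", {
  toy <- worked_toy_target("five_compound_kinase")
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(toy$measurements, tf, sep = "\t")
  res <- score_dataset(parse_bioactivity_table(tf))
  a <- assess_targets(res$scores, res$aggregates)
  a <- a[order(a$target_accession), ]
  expect_equal(a$target_accession, paste0("KIN", 1:4))
  expect_equal(a$selectivity, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$potency, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(a$cell, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$minimum_standard, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$sar, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(a$inactive_analog, c(TRUE, FALSE, FALSE, FALSE))
  # KIN3's only active compound is a PAINS hit -> icon stays grey
  expect_equal(a$non_pains, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$n_minimum_standard_compounds, c(1L, 1L, 0L, 0L))
  expect_equal(a$minimum_standard, a$n_minimum_standard_compounds >= 1L)
  expect_equal(a$information_richness,
               unname(toy$expected$information_richness[a$target_accession]))
  expect_equal(a$information_richness_percentile,
               unname(toy$expected$ir_percentile[a$target_accession]))
})

test_that("proteome summary counts nested target classes", {
  toy <- worked_toy_target("five_compound_kinase")
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(toy$measurements, tf, sep = "\t")
  res <- score_dataset(parse_bioactivity_table(tf))
  ps <- proteome_summary(res$scores, res$aggregates)
  exp <- toy$expected$proteome
  expect_equal(ps$n_targets_liganded, exp$liganded)
  expect_equal(ps$n_targets_potent, exp$potent)
  expect_equal(ps$n_targets_potent_selective, exp$potent_selective)
  expect_equal(ps$n_targets_minimum_standard, exp$minimum_standard)
  expect_equal(ps$fraction_liganded, exp$liganded / 20171)
  # configurable proteome size; too-small sizes warn but still report
  ps2 <- proteome_summary(res$scores, res$aggregates, proteome_size = 100)
  expect_equal(ps2$fraction_liganded, exp$liganded / 100)
  expect_warning(proteome_summary(res$scores, res$aggregates,
                                  proteome_size = 2), "smaller")
})

test_that("empty dataset summarizes to zero everywhere", {
  m <- ingest_rows(raw_row("A", "T1", 50000))  # nothing active
  res <- suppressWarnings(score_dataset(m))
  ps <- proteome_summary(res$scores, res$aggregates)
  expect_equal(ps$n_targets_liganded, 0L)
  expect_equal(ps$n_targets_minimum_standard, 0L)
  expect_equal(ps$n_compounds_minimum_standard, 0L)
})
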