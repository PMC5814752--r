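# potency, cell, global scores; ranking; the full scoring pipeline against
# the hand-computed worked fixture

test_that("potency score maps pActivity linearly from 5 to 10", {
  expect_equal(potency_score(10), 1)
  expect_equal(potency_score(5), 0)
  expect_equal(potency_score(7.5), 0.5)
  expect_equal(potency_score(12), 1)   # defensive clamp
  expect_error(potency_score(8, active = FALSE), "active pairs")
  # exactly linear on [5, 10] and monotone
  p <- seq(5, 10, by = 0.25)
  expect_equal(potency_score(p), (p - 5) / 5)
  expect_true(all(diff(potency_score(sort(runif(100, 4, 11)))) >= 0))
})

test_that("cell score requires sub-10-uM activity in some cell line", {
  one_line <- function(value_nM) {
    aggregate_pairs(ingest_rows(
      raw_row("A", NA, value_nM, kind = "cell", cell_line = "CL1")),
      kind = "cell")
  }
  expect_equal(cell_score(one_line(1000)), 1L)      # 1 uM
  expect_equal(cell_score(one_line(10000)), 0L)     # exactly 10 uM: strict
  expect_equal(cell_score(one_line(50000)), 0L)
  expect_equal(cell_score(NULL), 0L)                # never tested in cells
})

test_that("global score is the weighted mean, scale-invariant in weights", {
  w <- probe_weights()
  expect_equal(global_score(1, 1, 1, 1, 1, 1, w), 1)
  expect_equal(global_score(0, 0, 0, 0, 0, 0, w), 0)
  expect_equal(global_score(1, 1, 1, 0, 0, 0, w), 14 / 17)
  set.seed(5)
  s <- runif(6)
  g1 <- global_score(s[1], s[2], s[3], s[4], s[5], s[6], probe_weights())
  g2 <- global_score(s[1], s[2], s[3], s[4], s[5], s[6],
                     probe_weights(8 * 3.7, 4 * 3.7, 2 * 3.7, 3.7, 3.7, 3.7))
  expect_equal(g1, g2)
  expect_error(probe_weights(0, 0, 0, 0, 0, 0), "positive")
  expect_error(probe_weights(-1), "non-negative")
})

test_that("ranking is descending by key with ascending-id tie-break", {
  scored <- data.table::data.table(
    compound_id = c("B", "A", "C"), target_accession = "T1",
    global = c(0.5, 0.5, 0.9), potency = c(0.2, 0.9, 0.5))
  r <- rank_compounds(scored, "T1", order_key = "global")
  expect_equal(r$compound_id, c("C", "A", "B"))
  expect_equal(r$rank, 1:3)
  r2 <- rank_compounds(scored, "T1", order_key = "potency")
  expect_equal(r2$compound_id, c("A", "C", "B"))
  expect_equal(rank_compounds(scored[3, ])$rank, 1L)
  expect_error(rank_compounds(scored, "T1", order_key = "bogus"))
  expect_error(rank_compounds(scored[0, ]), "no scored compounds")
})

test_that("the five-compound worked fixture reproduces every hand-computed score", {
  toy <- worked_toy_target("five_compound_kinase")
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(toy$measurements, tf, sep = "\t")
  res <- score_dataset(parse_bioactivity_table(tf))
  expect_equal(res$liganded_target_count, toy$expected$liganded_target_count)
  exp <- toy$expected$scores
  got <- merge(res$scores, exp, by = c("compound_id", "target_accession"),
               suffixes = c("", ".exp"))
  expect_equal(nrow(got), nrow(exp))
  for (col in c("median_pactivity", "potency", "first_factor", "sic",
                "second_factor_raw", "second_factor_norm", "third_factor",
                "selectivity", "global")) {
    expect_equal(got[[col]], got[[paste0(col, ".exp")]],
                 info = col, tolerance = 1e-12)
  }
  for (col in c("cell", "sar", "inactive_analog", "pains", "rank")) {
    expect_equal(as.integer(got[[col]]), as.integer(got[[paste0(col, ".exp")]]),
                 info = col)
  }
  expect_equal(got$danger_flag, got$danger_flag.exp)
  expect_equal(got$minimum_standard, got$minimum_standard.exp)
})

test_that("a compound with no off-target data scores selectivity 0", {
  toy <- worked_toy_target("no_offtarget")
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(toy$measurements, tf, sep = "\t")
  res <- suppressWarnings(score_dataset(parse_bioactivity_table(tf)))
  expect_equal(res$scores$selectivity, 0)
  expect_equal(res$scores$n_off_targets, 0L)
  expect_false(res$scores$danger_flag)
})

test_that("missing structures degrade to SAR/IA/PAINS = 0 with a warning", {
  m <- ingest_rows(raw_row("A", "T1", 10), raw_row("A", "T2", 5000))
  expect_warning(res <- score_dataset(m), "no structures")
  expect_true(all(res$scores$sar == 0L))
  expect_true(all(res$scores$inactive_analog == 0L))
  expect_true(all(res$scores$pains == 0L))
  expect_true(all(res$scores$global > 0))  # other factors still scored
})

test_that("all scores stay in range on a random landscape (property)", {
  ls <- generate_landscape(landscape_spec(n_targets = 8, n_compounds = 60,
                                          seed = 33))
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(ls$measurements, tf, sep = "\t")
  res <- score_dataset(suppressMessages(parse_bioactivity_table(tf)))
  s <- res$scores
  for (col in c("potency", "selectivity", "first_factor",
                "second_factor_norm", "third_factor", "global")) {
    expect_true(all(s[[col]] >= 0 & s[[col]] <= 1), info = col)
  }
  expect_true(all(s$cell %in% 0:1 & s$sar %in% 0:1 &
                    s$inactive_analog %in% 0:1 & s$pains %in% 0:1))
  # self-consistency: global always equals the weighted mean of components
  expect_equal(s$global,
               global_score(s$selectivity, s$potency, s$cell, s$sar,
                            s$inactive_analog, s$pains, res$weights))
  # selectivity breakdown invariants
  expect_true(all(s$n_selective_off_targets <= s$n_off_targets))
  expect_equal(s[s$n_off_targets == 0, ]$selectivity,
               rep(0, sum(s$n_off_targets == 0)))
})
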