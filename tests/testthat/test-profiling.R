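reg <- default_enzymes()

test_that("protein profiling reports every occurrence with coordinates", {
  cat_ae <- peptide_catalogue(data.frame(
    id = "c1", sequence = "AE", activity = "DPP-IV inhibitor",
    stringsAsFactors = FALSE))
  pr <- profile_protein("AEAE", cat_ae)
  expect_equal(pr$hits$start, c(1L, 3L))
  expect_equal(pr$hits$end, c(2L, 4L))
  expect_equal(pr$counts, c("DPP-IV inhibitor" = 2L))

  # overlapping hits are both reported
  pr2 <- profile_protein("AAEA", tiny_catalogue())
  expect_equal(pr2$hits$peptide, c("AE", "EA"))
  expect_equal(pr2$hits$start, c(2L, 3L))

  # hits always equal the protein substring at their coordinates
  expect_true(all(substring("AAEA", pr2$hits$start, pr2$hits$end) ==
                  pr2$hits$peptide))

  # empty intersection -> empty profile
  none <- peptide_catalogue(data.frame(id = "x", sequence = "WW",
                                       activity = "antioxidative",
                                       stringsAsFactors = FALSE))
  pr3 <- profile_protein("AEAE", none)
  expect_equal(nrow(pr3$hits), 0L)
  expect_length(pr3$counts, 0L)
})

test_that("profiling equals the brute-force all-substrings oracle", {
  set.seed(13)
  for (i in 1:40) {
    s <- random_sequence(sample(10:300, 1))
    cat <- random_catalogue(sample(5:50, 1))
    pr <- profile_protein(s, cat)
    want <- oracle_profile_hits(s, cat)
    expect_equal(pr$hits, want, ignore_attr = TRUE)
    norm <- function(v) {
      nm <- as.character(if (is.null(names(v))) character(0) else names(v))
      stats::setNames(as.integer(v), nm)[order(nm)]
    }
    expect_equal(norm(pr$counts), norm(table(want$activity)))
  }
})

test_that("distinct counting collapses repeated peptides", {
  cat_ae <- peptide_catalogue(data.frame(
    id = "c1", sequence = "AE", activity = "DPP-IV inhibitor",
    stringsAsFactors = FALSE))
  expect_equal(profile_protein("AEAEAE", cat_ae)$counts[["DPP-IV inhibitor"]], 3L)
  expect_equal(profile_protein("AEAEAE", cat_ae, distinct = TRUE)$counts[["DPP-IV inhibitor"]], 1L)
})

test_that("active fragments use whole-released-peptide matching", {
  frags <- digest("AFAVALAEA", reg$pepsin_ph_gt2)  # AF AVAL AE A
  rep <- active_fragments(frags, tiny_catalogue(), enzyme_name = "pepsin_ph_gt2")
  expect_equal(nrow(rep$active_hits), 1L)
  expect_equal(rep$active_hits$sequence, "AE")
  expect_equal(rep$counts, c("DPP-IV inhibitor" = 1L))
  expect_equal(rep$ruleset_version, RULESET_VERSION)

  # a long fragment merely containing AE is NOT a hit
  rep2 <- active_fragments(digest("WAEW", reg$trypsin), tiny_catalogue())
  expect_equal(nrow(rep2$active_hits), 0L)

  # instance counting: a peptide released twice counts twice
  toy <- enzyme("toyase", rules = cleavage_rule(p1_allow = "E"))
  rep3 <- active_fragments(digest("AEAE", toy), tiny_catalogue())
  expect_equal(rep3$counts, c("DPP-IV inhibitor" = 2L))

  # empty digest -> empty report
  rep4 <- active_fragments(digest("AAAA", reg$trypsin)[0, ], tiny_catalogue())
  expect_equal(nrow(rep4$active_hits), 0L)
})

test_that("released active peptides are a subset of full-profile occurrences", {
  set.seed(19)
  cat <- load_catalogue(demo_catalogue_path())
  for (i in 1:10) {
    s <- random_sequence(sample(50:200, 1))
    pr <- profile_protein(s, cat)
    for (nm in c("pepsin_ph_gt2", "trypsin", "papain")) {
      rep <- active_fragments(digest(s, reg[[nm]]), cat, enzyme_name = nm)
      for (a in names(rep$counts)) {
        expect_lte(rep$counts[[a]],
                   if (a %in% names(pr$counts)) pr$counts[[a]] else 0L)
      }
    }
  }
})

test_that("enzyme ranking aggregates counts and groups other activities", {
  cat <- peptide_catalogue(data.frame(
    id = c("c1", "c2"), sequence = c("AE", "YY"),
    activity = c("DPP-IV inhibitor", "antioxidative"),
    stringsAsFactors = FALSE))
  # pepsin releases AE from FAEA; toyase (cuts after W) releases nothing
  toy <- enzyme("toyase", rules = cleavage_rule(p1_allow = "W"))
  prots <- protein_records("p1", "GFAEAG")
  rk <- rank_enzymes(prots, list(reg$pepsin_ph_gt2, toy), cat)
  expect_equal(names(rk$totals)[1], "pepsin_ph_gt2")
  expect_equal(rk$totals[["toyase"]], 0)
  tab <- rk$table
  expect_setequal(unique(tab$activity),
                  c("ACE inhibitor", "DPP-IV inhibitor", "other activities"))
  expect_equal(tab$count[tab$enzyme == "pepsin_ph_gt2" &
                         tab$activity == "DPP-IV inhibitor"], 1L)
  # empty enzyme list -> empty table
  rk0 <- rank_enzymes(prots, list(), cat)
  expect_equal(nrow(rk0$table), 0L)
})

test_that("frequency of occurrence is count over residue length", {
  cat_ae <- peptide_catalogue(data.frame(
    id = "c1", sequence = "AE", activity = "DPP-IV inhibitor",
    stringsAsFactors = FALSE))
  pr <- profile_protein("AEAE", cat_ae)
  expect_equal(frequency_of_occurrence(pr), c("DPP-IV inhibitor" = 0.5))
  # 2 hits on a length-100 protein -> 0.02
  long <- paste0(strrep("G", 96), "AEAE")
  expect_equal(frequency_of_occurrence(profile_protein(long, cat_ae)),
               c("DPP-IV inhibitor" = 0.02))
  # empty profile -> no nonzero frequencies
  none <- peptide_catalogue(data.frame(id = "x", sequence = "WW",
                                       activity = "antioxidative",
                                       stringsAsFactors = FALSE))
  expect_length(frequency_of_occurrence(profile_protein("AEAE", none)), 0L)
})

test_that("identical inputs give byte-identical reports", {
  cat <- load_catalogue(demo_catalogue_path())
  prots <- random_proteins(2, c(60, 80), seed = 5)
  out1 <- tempfile(fileext = ".tsv"); out2 <- tempfile(fileext = ".tsv")
  rk1 <- rank_enzymes(prots, c("pepsin_ph_gt2", "papain"), cat)
  rk2 <- rank_enzymes(prots, c("pepsin_ph_gt2", "papain"), cat)
  write_table(rk1$table, out1, "tsv"); write_table(rk2$table, out2, "tsv")
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(rk1, rk2)
})
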