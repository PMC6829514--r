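reg <- default_enzymes()

test_that("rule construction enforces alphabet and allow/block disjointness", {
  expect_error(cleavage_rule(p1_allow = "K1"), "non-canonical")
  expect_error(cleavage_rule(p1_allow = "K", p1_block = "K"), "overlap")
  expect_error(cleavage_rule(p1_allow = "K", p1prime_allow = "P",
                             p1prime_block = "P"), "overlap")
  r <- cleavage_rule(p1_allow = c("K", "R"), p1prime_block = "P")
  expect_setequal(r$p1_allow, c("K", "R"))
})

test_that("enzyme config merges user definitions over bundled defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("enzymes:",
               "  toyase:",
               "    ec: '0.0.0.0'",
               "    p1_allow: K"), f)
  regc <- parse_enzyme_config(f)
  expect_true("toyase" %in% names(regc))
  expect_true(all(names(default_enzymes()) %in% names(regc)))
  expect_equal(digest("AKAKA", regc$toyase)$sequence, c("AK", "AK", "A"))

  writeLines(c("enzymes:", "  t2:", "    p1_allow: K", "    p1_block: K"), f)
  expect_error(parse_enzyme_config(f), "overlap")
  writeLines(c("enzymes:", "  t3:", "    q9_allow: K"), f)
  expect_error(parse_enzyme_config(f), "unknown key")
  writeLines("enzymes: {}", f)
  expect_equal(names(parse_enzyme_config(f)), names(default_enzymes()))
  expect_equal(names(parse_enzyme_config(NULL)), names(default_enzymes()))
})

test_that("bundled registry covers the standard proteases", {
  expect_true(all(c("pepsin_ph_gt2", "bromelain_stem", "papain", "trypsin",
                    "chymotrypsin_a", "lys_c") %in% names(reg)))
  expect_equal(reg$pepsin_ph_gt2$ec, "3.4.23.1")
  expect_equal(reg$trypsin$ec, "3.4.21.4")
})

test_that("cleavage sites follow the P1/P1'/P2 rule semantics", {
  # hand enumeration: A F A V A L A E A -> cut after F(2), L(6), E(8)
  expect_equal(cleavage_sites("AFAVALAEA", reg$pepsin_ph_gt2), c(2L, 6L, 8L))
  # Keil exception: no tryptic cut of K-P bonds
  expect_equal(cleavage_sites("AKPA", reg$trypsin), integer(0))
  expect_equal(cleavage_sites("AKAA", reg$trypsin), 2L)
  # a never-firing enzyme yields no sites
  dead <- enzyme("dead", rules = cleavage_rule())
  expect_equal(cleavage_sites("AKRFLEWY", dead), integer(0))
  # papain's P2 = F alternative trigger: cut after the residue following F
  expect_equal(cleavage_sites("AFGA", reg$papain), 3L)
})

test_that("complete digestion partitions the parent", {
  frags <- digest("AFAVALAEA", reg$pepsin_ph_gt2)
  expect_equal(frags$sequence, c("AF", "AVAL", "AE", "A"))
  expect_equal(frags$start, c(1L, 3L, 7L, 9L))
  expect_equal(frags$end, c(2L, 6L, 8L, 9L))
  expect_true(all(frags$n_missed == 0L))
  # no cleavable site -> the whole protein is the single fragment
  expect_equal(digest("AAAA", reg$trypsin)$sequence, "AAAA")
})

test_that("missed cleavages enumerate runs of consecutive fragments", {
  toy <- enzyme("toyase", rules = cleavage_rule(p1_allow = "K"))
  f1 <- digest("AKAKA", toy, max_missed = 1L)
  expect_equal(f1$sequence, c("AK", "AKAK", "AK", "AKA", "A"))
  expect_equal(f1$n_missed, c(0L, 1L, 0L, 1L, 0L))
  # against subset enumeration on random sequences with <= 8 sites
  set.seed(42)
  for (i in 1:25) {
    s <- random_sequence(sample(10:60, 1))
    enz <- reg[[sample(names(reg), 1)]]
    sites <- cleavage_sites(s, enz)
    if (length(sites) > 8) next
    m <- sample(0:3, 1)
    got <- digest(s, enz, max_missed = m)
    want <- oracle_fragments(s, sites, m)
    expect_equal(got[c("start", "end", "sequence", "n_missed")], want,
                 ignore_attr = TRUE)
  }
})

test_that("digest agrees with the per-bond brute-force oracle", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_sequence(sample(2:200, 1))
    for (enz in reg) {
      expect_equal(cleavage_sites(s, enz), oracle_sites(s, enz),
                   info = sprintf("enzyme %s on %s", enz$name, s))
    }
  }
})

test_that("sequential digestion cuts at the union of site sets", {
  # trypsin sites are a superset of Lys-C sites here
  expect_equal(digest_sequential("AKARA", list(reg$lys_c, reg$trypsin))$sequence,
               c("AK", "AR", "A"))
  # unit law: one enzyme behaves exactly like digest(..., max_missed = 0)
  s <- "MKWLVAEPRAGKY"
  expect_equal(digest_sequential(s, list(reg$trypsin)),
               digest(s, reg$trypsin))
  # monotonicity: union site set contains each enzyme's own sites
  set.seed(11)
  for (i in 1:20) {
    s <- random_sequence(sample(20:150, 1))
    pair <- sample(names(reg), 2)
    both <- digest_sequential(s, reg[pair])
    union_sites <- setdiff(both$end, nchar(s))
    for (nm in pair) {
      expect_true(all(cleavage_sites(s, reg[[nm]]) %in% union_sites))
    }
    # partition, and no zero-length fragments
    expect_equal(paste(both$sequence, collapse = ""), s)
    expect_true(all(nchar(both$sequence) >= 1))
  }
})
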