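test_that("canonical pairs sort endpoints, allow self-pairs, and are idempotent", {
  expect_equal(unname(canonical_pair("YBR001C", "YAL002W")[1, ]),
               c("YAL002W", "YBR001C"))
  expect_equal(unname(canonical_pair("YAL002W", "YAL002W")[1, ]),
               c("YAL002W", "YAL002W"))
  expect_error(canonical_pair("", "YAL002W"), "non-empty")
  set.seed(7)
  for (i in 1:20) {
    a <- paste0(sample(LETTERS, 5), collapse = "")
    b <- paste0(sample(letters, 5), collapse = "")
    once <- canonical_pair(a, b)
    twice <- canonical_pair(once[1, 1], once[1, 2])
    expect_identical(once, twice)
  }
})

test_that("dataset construction merges duplicate rows and counts distinct pairs", {
  ds <- interaction_dataset(c("B", "A", "A"), c("A", "B", "C"),
                            evidence_codes = list("Two-hybrid", "FRET", "PCA"),
                            pub_ids = c("P1", "P2", "P3"),
                            pub_years = c(1999L, 2001L, 1995L))
  expect_equal(ds_size(ds), 2L)
  i <- which(ds$pairs$key == "A|B")
  expect_setequal(ds$evidence[[i]], c("Two-hybrid", "FRET"))
  expect_setequal(ds$pub_ids[[i]], c("P1", "P2"))
  # every stored pair is canonical; re-canonicalizing is a no-op
  expect_identical(ds$pairs$key, pair_key(ds$pairs$a, ds$pairs$b))
})

test_that("publication throughput classification uses a strict pair-count threshold", {
  raw <- throughput_fixture()
  cls <- classify_publication_throughput(raw, ht_paper_threshold = 100)
  expect_equal(unname(cls[c("PUB5", "PUB100", "PUB101", "PUB2000")]),
               c("low", "low", "high", "high"))
})

test_that("curation keeps whitelisted low-throughput rows merged per pair", {
  raw <- raw_filter_fixture()
  ds <- filter_binary_physical_low_throughput(raw, ht_paper_threshold = 2)
  expect_equal(ds_size(ds), 4L)
  expect_setequal(ds$pairs$key, c("P1|P2", "P3|P4", "P10|P9", "P7|P8"))
  # the pair with both an HT row and low rows keeps only the low pubs
  i <- which(ds$pairs$key == "P1|P2")
  expect_setequal(ds$pub_ids[[i]], c("L3", "L4"))
  # genetic evidence never passes the whitelist
  expect_false(any(vapply(ds$evidence,
                          function(e) "Synthetic Lethality" %in% e,
                          logical(1))))
  expect_error(filter_binary_physical_low_throughput(raw,
                                                     evidence_whitelist = character(0)),
               "whitelist")
})

test_that("pre-2000 restriction requires at least one strictly earlier publication", {
  ds <- interaction_dataset(
    paste0("A", 1:6), paste0("B", 1:6),
    pub_ids = list("q1", "q2", "q3", "q4", c("q5", "q6"), c("q7", "q8")),
    pub_years = list(1995L, 1999L, 2000L, 2001L, c(1998L, 2003L),
                     c(2000L, 2008L)))
  kept <- restrict_before_year(ds, 2000)
  expect_equal(ds_size(kept), 3L)
  expect_setequal(kept$pairs$a, c("A1", "A2", "A5"))
  # nesting in the year bound
  for (y in c(1996, 1999, 2002)) {
    expect_true(all(ds_keys(restrict_before_year(ds, y)) %in%
                      ds_keys(restrict_before_year(ds, y + 1))))
  }
})

test_that("well-studied set has an inclusive boundary and is nested in the cutoff", {
  expect_equal(well_studied_set(study_levels(c(A = 125)), 125), "A")
  expect_equal(well_studied_set(study_levels(c(A = 124)), 125), character(0))
  set.seed(11)
  lv <- study_levels(stats::setNames(rpois(50, 100), paste0("G", 1:50)))
  for (i in 1:5) {
    c1 <- sample(50:150, 1)
    c2 <- c1 + sample(1:50, 1)
    expect_true(all(well_studied_set(lv, c2) %in% well_studied_set(lv, c1)))
  }
})

test_that("well-studied restriction honours any/both endpoint modes", {
  ds <- interaction_dataset(c("A", "C"), c("B", "D"))
  expect_equal(ds_size(restrict_well_studied(ds, "A", "any")), 1L)
  expect_equal(ds_size(restrict_well_studied(ds, "A", "both")), 0L)
  set.seed(5)
  for (i in 1:5) {
    r <- random_dataset(40)
    ws <- sample(sprintf("R%03d", 1:30), 8)
    both <- restrict_well_studied(r, ws, "both")
    any_ <- restrict_well_studied(r, ws, "any")
    expect_true(all(ds_keys(both) %in% ds_keys(any_)))
    expect_true(all(ds_keys(any_) %in% ds_keys(r)))
  }
})

test_that("single-paper unique subset drops multi-paper and HT-shared pairs", {
  lc <- interaction_dataset(
    paste0("A", 1:5), paste0("B", 1:5),
    pub_ids = list("p1", c("p2", "p3"), "p4", "p5", c("p6", "p7")))
  ht <- interaction_dataset("A1", "B1")
  u <- single_paper_unique(lc, ht)
  expect_equal(ds_size(u), 2L)
  expect_setequal(u$pairs$a, c("A3", "A4"))
})

test_that("set algebra obeys identities and inclusion-exclusion", {
  set.seed(3)
  empty <- interaction_dataset(character(0), character(0))
  for (i in 1:10) {
    a <- random_dataset(30)
    b <- random_dataset(30)
    expect_setequal(ds_keys(intersect_datasets(a, a)), ds_keys(a))
    expect_setequal(ds_keys(union_datasets(a, empty)), ds_keys(a))
    expect_equal(ds_size(union_datasets(a, b)),
                 ds_size(a) + ds_size(b) - ds_size(intersect_datasets(a, b)))
    # commutativity on keys
    expect_setequal(ds_keys(union_datasets(a, b)),
                    ds_keys(union_datasets(b, a)))
  }
})

test_that("study levels load as distinct paper counts with zero default", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tp1", "g1\tp1", "g1\tp2", "g2\tp1",
               "g3\tp9", "g3\tp8", "g3\tp7", "g4\tp1", "g5\tp2"), tmp)
  lv <- load_study_levels(tmp)
  expect_equal(study_level_of(lv, c("G1", "G2", "G3", "G4", "G5", "G6")),
               c(2L, 1L, 3L, 1L, 1L, 0L))
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(study_level_of(load_study_levels(empty), "ANY"), 0L)
})

test_that("BioGRID loader round-trips the exported dialect and skips bad rows", {
  tmp <- withr::local_tempfile(fileext = ".tab")
  write_micro_biogrid(tmp)
  raw <- load_biogrid_tab(tmp)
  fx <- micro_fixture()
  expect_setequal(unique(raw$key), ds_keys(fx$lc))
  expect_equal(sort(unique(raw$pub_year)),
               sort(unique(unlist(fx$lc$pub_years))))
  # header-only file loads as an empty record set
  head_only <- withr::local_tempfile(fileext = ".tab")
  writeLines(paste(c("INTERACTOR_A", "INTERACTOR_B", "EXPERIMENTAL_SYSTEM",
                     "SOURCE", "PUBMED_ID"), collapse = "\t"), head_only)
  expect_equal(nrow(load_biogrid_tab(head_only)), 0L)
  # a row with a missing interactor is skipped with a warning
  bad <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(paste(c("INTERACTOR_A", "INTERACTOR_B", "EXPERIMENTAL_SYSTEM",
                       "SOURCE", "PUBMED_ID"), collapse = "\t"),
               "YAL001C\tYBR002C\tTwo-hybrid\tAuthor A (1999)\t123",
               "-\tYBR002C\tTwo-hybrid\tAuthor A (1999)\t124"), bad)
  expect_warning(raw2 <- load_biogrid_tab(bad), "malformed")
  expect_equal(nrow(raw2), 1L)
  expect_equal(raw2$pub_year, 1999L)
  expect_error(load_biogrid_tab(file.path(tempdir(), "nope.tab")), "cannot read")
})
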