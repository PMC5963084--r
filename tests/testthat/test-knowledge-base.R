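test_that("a KB loads from CSV and answers role queries", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug,gene,role,evidence",
               "paclitaxel,ABCC1,export,efflux",
               "Paclitaxel,CYP3A4,metabolize,",
               "gemcitabine,CMPK1,activate,prodrug"), path)
  kb <- read_kb(path)
  expect_s3_class(kb, "pk_kb")
  expect_true("ABCC1" %in% genes_for(kb, "paclitaxel", "export"))
  expect_equal(genes_for(kb, "paclitaxel", "metabolize"), "CYP3A4")
  expect_equal(genes_for(kb, "gemcitabine", "activate"), "CMPK1")
  # absent drug and non-drug token: empty, not an error
  expect_identical(genes_for(kb, "radiotherapy", "export"), character(0))
  expect_identical(genes_for(kb, "nosuchdrug", "target"), character(0))
})

test_that("an empty KB (header only) is valid and all queries are empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("drug,gene,role,evidence", path)
  kb <- read_kb(path)
  expect_equal(nrow(kb$relations), 0L)
  expect_identical(genes_for(kb, "paclitaxel", "export"), character(0))
})

test_that("malformed KB rows fail with the offending line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug,gene,role", "paclitaxel,ABCC1,export",
               "paclitaxel,ABCB1,exporter"), path)
  expect_error(read_kb(path), "line 3")
  writeLines(c("drug,gene,role", ",ABCC1,export"), path)
  expect_error(read_kb(path), "line 2")
  writeLines(c("drug,gene", "paclitaxel,ABCC1"), path)
  expect_error(read_kb(path), "header")
})

test_that("duplicate triples collapse with a warning and round-trip survives", {
  df <- data.frame(drug = c("a", "a", "b"), gene = c("G1", "G1", "G2"),
                   role = c("export", "export", "target"))
  expect_warning(kb <- as_pk_kb(df), "duplicate")
  expect_equal(nrow(kb$relations), 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kb(kb, path)
  kb2 <- read_kb(path)
  expect_identical(kb$relations[, c("drug", "gene", "role")],
                   kb2$relations[, c("drug", "gene", "role")])
})

test_that("genes_for is pure and the union over roles covers the drug", {
  kb <- read_kb(example_kb_path())
  for (drug in c("paclitaxel", "gemcitabine", "carboplatin")) {
    per_role <- lapply(PK_ROLES, function(r) genes_for(kb, drug, r))
    again <- lapply(PK_ROLES, function(r) genes_for(kb, drug, r))
    expect_identical(per_role, again)
    expect_setequal(unlist(per_role),
                    kb$relations$gene[kb$relations$drug == drug])
  }
})

test_that("the bundled KB holds the established PK relationships", {
  kb <- read_kb(example_kb_path())
  triples <- list(
    c("paclitaxel", "ABCC1", "export"),
    c("doxorubicin", "ABCC1", "export"),
    c("paclitaxel", "CYP3A4", "metabolize"),
    c("fluorouracil", "DPYD", "metabolize"),
    c("gemcitabine", "NT5C", "metabolize"),
    c("carboplatin", "SLC31A1", "import"),
    c("cisplatin", "SLC31A1", "import"),
    c("carboplatin", "HMGB1", "target"),
    c("lapatinib", "EGFR", "target"),
    c("cetuximab", "EGFR", "target"),
    c("tamoxifen", "ESR2", "target"),
    c("paclitaxel", "TUBB1", "target"),
    c("paclitaxel", "MAP2", "target"),
    c("paclitaxel", "MAP4", "target"),
    c("paclitaxel", "MAPT", "target"),
    c("docetaxel", "TUBB1", "target"),
    c("docetaxel", "MAP2", "target"),
    c("docetaxel", "MAP4", "target"),
    c("docetaxel", "MAPT", "target"))
  for (tr in triples)
    expect_true(tr[2] %in% genes_for(kb, tr[1], tr[3]),
                info = paste(tr, collapse = "-"))
  # expected gene families from the literature behind the fixture
  expect_true(all(c("CYP3A4", "CYP2C8", "NR1I2") %in%
                    genes_for(kb, "paclitaxel", "metabolize")))
})

test_that("therapy names normalize through the map, case-insensitively", {
  nm <- read_name_map(example_name_map_path())
  expect_setequal(normalize_therapy("Macdonald", nm),
                  c("fluorouracil", "leucovorin", "radiotherapy"))
  expect_identical(normalize_therapy("Paclitaxel", nm,
                                     kb = read_kb(example_kb_path())),
                   "paclitaxel")
  expect_identical(normalize_therapy("  taxol  ", nm), "paclitaxel")
  err <- tryCatch(normalize_therapy("xyzzy-unknown", nm), error = identity)
  expect_s3_class(err, "pktem_unknown_therapy")
  expect_equal(err$raw_name, "xyzzy-unknown")
  expect_match(conditionMessage(err), "xyzzy-unknown")
})
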