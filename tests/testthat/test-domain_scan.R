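# Constellation scanner: planted-domain recovery, degenerate domains,
# false-positive control and coordinate conventions.

reg <- load_motif_registry()

test_that("an intact planted cassette yields one covering WELL_FORMED domain", {
  withr::with_seed(8, {
    cass <- ptpscan:::build_cassette(reg)
    seq <- paste0(random_seq(100), cass$seq, random_seq(100))
  })
  truth_start <- 101L
  truth_end <- 100L + 245L
  ann <- scan_protein(protein_record("SYNINT01-PA", seq), reg)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$presence, "WELL_FORMED")
  expect_lte(abs(ann$start - truth_start), 30L)
  expect_lte(abs(ann$end - truth_end), 30L)
  expect_identical(ann$m8_status, "ACTIVE")
  expect_identical(ann$m9_status, "ACTIVE")
  expect_identical(ann$m10_status, "ACTIVE")
})

test_that("a domain losing its P-loop cysteine and WPD aspartate is still
           found, with motif 9 INACTIVE", {
  withr::with_seed(7, {
    cass <- ptpscan:::build_cassette(reg, lesions = c(8L, 9L))
    seq <- paste0(random_seq(100), cass$seq, random_seq(100))
  })
  ann <- scan_protein(protein_record("SYNLES01-PA", seq), reg)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$m9_status, "INACTIVE")
  expect_identical(ann$m8_status, "INACTIVE")
})

test_that("random proteins without a planted cassette rarely contain domains", {
  withr::with_seed(4242, {
    n_empty <- 0L
    for (i in 1:1000) {
      ann <- scan_protein(protein_record("RND00001-PA", random_seq(300)), reg)
      n_empty <- n_empty + (nrow(ann) == 0L)
    }
    expect_gte(n_empty / 1000, 0.99)
  })
})

test_that("the table1 fixture yields 13 domains with the expected layout", {
  fx <- table1_fixture_records()
  ann <- scan_proteome(fx$records, reg)
  expect_identical(nrow(ann), 13L)
  counts <- table(ann$accession)
  expect_identical(as.integer(counts[c("AAEL001046", "AAEL008528-PA",
                                       "AAEL008528-PB")]), c(2L, 2L, 2L))
  expect_true(all(counts[setdiff(names(counts),
                                 c("AAEL001046", "AAEL008528-PA",
                                   "AAEL008528-PB"))] == 1L))
  expect_identical(sum(ann$presence == "DEGENERATE"), 4L)
})

test_that("scan output is deterministic and ordered by start", {
  fx <- table1_fixture_records()
  a1 <- scan_proteome(fx$records, reg)
  a2 <- scan_proteome(fx$records, reg)
  expect_identical(a1, a2)
  expect_true(all(diff(order(a1$accession, a1$start)) > 0 |
                  !is.unsorted(a1$start[a1$accession == a1$accession[1]])))
  for (acc in unique(a1$accession)) {
    expect_false(is.unsorted(a1$start[a1$accession == acc]))
  }
})

test_that("domain presence recall and per-motif agreement against generator
           truth stay above 0.95", {
  planted <- 0L; found <- 0L; agree <- 0L; cells <- 0L
  for (s in 1:200) {
    px <- make_proteome(n_proteins = 1, seed = s)
    tr <- px$truth$domains
    if (nrow(tr) == 0L) next
    ann <- scan_protein(protein_record(names(px$sequences)[1],
                                       px$sequences[[1]]), reg)
    for (i in seq_len(nrow(tr))) {
      planted <- planted + 1L
      hit <- which(ann$start <= tr$end[i] & ann$end >= tr$start[i])
      if (!length(hit)) next
      found <- found + 1L
      h <- hit[1L]
      for (m in c(1, 8, 9, 10)) {
        cells <- cells + 1L
        agree <- agree +
          (ann[[sprintf("m%d_status", m)]][h] ==
             tr[[sprintf("m%d_truth", m)]][i])
      }
    }
  }
  expect_gte(found / planted, 0.95)
  expect_gte(agree / cells, 0.95)
})

test_that("duplicate accessions are a validation error", {
  fx <- table1_fixture_records()
  expect_error(scan_proteome(c(fx$records, fx$records[1])),
               "duplicate accession")
})

test_that("empty input and empty registry are handled per contract", {
  expect_identical(nrow(scan_proteome(list(), reg)), 0L)
  expect_error(scan_protein(protein_record("A-PA", "MKV"),
                            reg[0, , drop = FALSE]), "empty motif registry")
})

test_that("1-based inclusive <-> 0-based half-open conversion round-trips", {
  for (i in 1:20) {
    s <- sample(1:500, 1); e <- s + sample(0:300, 1)
    z <- coords_to_base0(s, e)
    back <- coords_to_base1(z$start, z$end)
    expect_identical(back$start, s)
    expect_identical(back$end, e)
  }
})

test_that("annotation reports round-trip through TSV", {
  fx <- table1_fixture_records()
  ann <- classify_annotations(scan_proteome(fx$records, reg))
  tf <- tempfile(fileext = ".tsv")
  write_annotations(ann, tf)
  back <- read_annotations(tf)
  expect_equal(back, ann, ignore_attr = TRUE)
})

test_that("proteins with illegal residues are rejected with coordinates", {
  expect_error(protein_record("BAD00001-PA", "MKVO"),
               "invalid residue 'O' at position 4 in BAD00001-PA")
})
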