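# Table parsing, validation diagnostics, candidate round-trips.

write_lines <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

regions_header <- paste(c("protein_acc", "family_acc", "clan_acc",
                          "ali_start", "ali_end", "hmm_start", "hmm_end",
                          "model_length", "evalue"), collapse = "\t")

test_that("regions TSV parses, sorts, and maps empty clans to NA", {
  path <- write_lines(c(
    regions_header,
    "P1\tFAM2\t\t150\t240\t1\t90\t90\t1e-20",
    "P1\tFAM1\tCL0001\t10\t100\t5\t95\t100\t1e-30",
    "P2\tFAM1\tCL0001\t1\t80\t21\t100\t100\t"))
  hits <- read_domain_hits(path, "regions_tsv")
  expect_identical(nrow(hits), 3L)
  # sorted by protein then ali_start
  expect_identical(hits$family_acc, c("FAM1", "FAM2", "FAM1"))
  expect_identical(hits$clan_acc, c("CL0001", NA, "CL0001"))
  expect_identical(hits$evalue, c(1e-30, 1e-20, NA))
  expect_identical(hits$ali_start, c(10L, 150L, 1L))
})

test_that("rows violating coordinate invariants are rejected with row-addressed diagnostics", {
  bad_order <- write_lines(c(regions_header,
                             "P1\tFAM1\t\t50\t40\t1\t90\t90\t1e-5"))
  expect_error(read_domain_hits(bad_order), "row 1.*ali_start.*ordering",
               class = "atrophy_validation_error")
  bad_hmm <- write_lines(c(regions_header,
                           "P1\tFAM1\t\t10\t100\t1\t120\t90\t1e-5"))
  expect_error(read_domain_hits(bad_hmm), "exceeds model length",
               class = "atrophy_validation_error")
  bad_int <- write_lines(c(regions_header,
                           "P1\tFAM1\t\tten\t100\t1\t90\t90\t1e-5"))
  expect_error(read_domain_hits(bad_int), "row 1.*ali_start")
  inconsistent_L <- write_lines(c(
    regions_header,
    "P1\tFAM1\t\t10\t100\t1\t90\t90\t1e-5",
    "P2\tFAM1\t\t10\t100\t1\t90\t100\t1e-5"))
  expect_error(read_domain_hits(inconsistent_L), "inconsistent model lengths")
})

test_that("protein metadata validates PE levels, flags and duplicates", {
  ok <- write_lines(c("protein_acc\tseq_length\tpe_level\tis_fragment",
                      "P1\t400\t1\tfalse"))
  recs <- read_protein_metadata(ok)
  expect_identical(nrow(recs), 1L)
  expect_false(recs$is_fragment)

  bad_pe <- write_lines(c("protein_acc\tseq_length\tpe_level\tis_fragment",
                          "P1\t400\t6\tfalse"))
  expect_error(read_protein_metadata(bad_pe), "pe_level",
               class = "atrophy_validation_error")

  dup <- write_lines(c("protein_acc\tseq_length\tpe_level\tis_fragment",
                       "P1\t400\t1\tfalse", "P1\t300\t1\tfalse"))
  expect_error(read_protein_metadata(dup), "duplicate protein accession: P1")
})

test_that("hmmsearch domtblout parses with qlen as the model length", {
  path <- system.file("extdata", "synthetic_scan.domtblout",
                      package = "atrophyscan")
  hits <- read_domain_hits(path, "domtblout")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$protein_acc, "SYNPROT1")
  expect_identical(hits$family_acc, "TOYFAM")
  expect_identical(hits$model_length, 120L)
  expect_identical(hits$hmm_start, 32L)
  expect_identical(hits$hmm_end, 120L)
  expect_identical(hits$ali_start, 22L)
  expect_identical(hits$ali_end, 110L)
  expect_equal(hits$evalue, 6.4e-57)
  # the scanned domain is N-truncated: 31 missing leading states, partly
  # credited by the 21-residue flank -> positive N-terminal score 10/120
  expect_equal(atrophy_score(unmatched_states_n(hits$hmm_start),
                             interval_n(hits$ali_start, 0),
                             hits$model_length), 10 / 120)
})

test_that("domtblout hits round-trip through the candidate writer", {
  path <- system.file("extdata", "synthetic_scan.domtblout",
                      package = "atrophyscan")
  hits <- read_domain_hits(path, "domtblout")
  res <- detect_atrophy(hits, mk_protein("SYNPROT1", seq_length = 130))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(res$calls, out)
  back <- read_candidates(out)
  expect_identical(back$ali_start, res$calls$ali_start)
  expect_identical(back$ali_end, res$calls$ali_end)
  expect_identical(back$hmm_start, res$calls$hmm_start)
  expect_identical(back$hmm_end, res$calls$hmm_end)
})

test_that("candidate tables round-trip exactly at the documented precision", {
  pr <- generate_proteome(default_scenario(), seed = 7)
  res <- detect_atrophy(pr$hits, pr$proteins)
  calls <- utils::head(res$calls, 50)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(calls, out)
  back <- read_candidates(out)
  expect_identical(back$call_id, calls$call_id)
  expect_identical(back$score, as.numeric(sprintf("%.6f", calls$score)))
  for (col in c("D", "d", "L", "ali_start", "ali_end", "hmm_start",
                "hmm_end", "ali_start2", "ali_end2", "hmm_start2",
                "hmm_end2")) {
    expect_identical(back[[col]], calls[[col]])
  }
  expect_identical(back$filter_flags, calls$filter_flags)
  expect_identical(back$candidate, calls$candidate)
})

test_that("an empty call list writes a header-only file; scores use 6 decimals", {
  out <- withr::local_tempfile(fileext = ".tsv")
  empty <- detect_atrophy(
    read_domain_hits(write_lines(regions_header)),
    mk_protein("P1"))$calls
  write_candidates(empty, out)
  expect_identical(length(readLines(out)), 1L)

  one <- mk_hit(ali_start = 1, ali_end = 134, hmm_start = 67, hmm_end = 200,
                model_length = 200)
  res <- detect_atrophy(one, mk_protein("P1", seq_length = 200))
  write_candidates(res$calls, out)
  expect_true(any(grepl("\t0\\.330000\t", readLines(out))))
})

test_that("every generated fixture table parses without diagnostics", {
  pr <- generate_proteome(default_scenario(), seed = 3)
  dir <- withr::local_tempdir()
  write_proteome(pr, dir)
  hits <- read_domain_hits(file.path(dir, "hits.tsv"))
  proteins <- read_protein_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(nrow(hits), nrow(pr$hits))
  expect_identical(nrow(proteins), nrow(pr$proteins))
  # every hit joins to a protein record
  expect_true(all(hits$protein_acc %in% proteins$protein_acc))
  # parsed tables reproduce the in-memory coordinates
  expect_identical(hits$ali_start, pr$hits$ali_start)
  expect_identical(hits$hmm_end, pr$hits$hmm_end)
})
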