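# Readers/writers for GENEPOP, FASTA and site metadata, study assembly, and
# the genotyping error-rate arithmetic.

test_that("GENEPOP parsing: missing codes, block structure, ragged rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("toy", "locA", "locB", "POP",
               "p1:a , 0102 0000",
               "p1:b , 0103 0405",
               "p1:c , 0102 0405",
               "Pop",
               "p2:d , 0102 0404",
               "p2:e , 0103 0505"), f)
  tab <- read_genepop(f)
  expect_equal(length(tab$individual_id), 5)
  expect_equal(as.integer(table(tab$site_id)[c("p1", "p2")]), c(3L, 2L))
  expect_true(is.na(tab$a1["a", "locB"]) && is.na(tab$a2["a", "locB"]))
  expect_equal(unname(tab$a1["b", "locB"]), 4L)

  writeLines(c("toy", "locA", "locB", "POP", "x , 0102"), f)
  expect_error(read_genepop(f), "ragged.*x")
})

test_that("GENEPOP round-trip is the identity on random tables", {
  for (seed in 1:5) {
    tab <- random_gt(n = 18, L = 13, n_sites = 3, seed = seed)
    f <- withr::local_tempfile(fileext = ".txt")
    write_genepop(tab, NULL, f)
    back <- read_genepop(f)
    expect_identical(back$a1, tab$a1)
    expect_identical(back$a2, tab$a2)
    expect_identical(back$site_id, tab$site_id)
    expect_identical(back$individual_id, tab$individual_id)
    expect_identical(back$locus_names, tab$locus_names)
  }
})

test_that("GENEPOP writing: 3-digit bound, empty and single-site layouts", {
  tab <- gt_from("s1", matrix(1000L, 1, 1), matrix(1000L, 1, 1))
  f <- withr::local_tempfile(fileext = ".txt")
  expect_error(write_genepop(tab, NULL, f), "999")

  empty <- genotype_table(character(), character(),
                          matrix(integer(), 0, 2), matrix(integer(), 0, 2),
                          c("locA", "locB"))
  write_genepop(empty, NULL, f)
  expect_identical(readLines(f)[-1], c("locA", "locB"))  # header-only

  one <- random_gt(n = 6, n_sites = 1, seed = 3)
  write_genepop(one, NULL, f)
  expect_equal(sum(grepl("^POP$", readLines(f))), 1)
})

test_that("FASTA reading: ids, case, duplicates, alignment length", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a extra header words", "ACGTACGTAA", ">b", "acgtacgtcc"), f)
  h <- read_fasta(f)
  expect_equal(h$individual_id, c("a", "b"))
  expect_equal(h$sequence[2], "ACGTACGTCC")  # upper-cased

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">a", "ACGT", ">b", "ACGTT"), f)
  expect_error(read_fasta(f), "b")
})

test_that("STRUCTURE export has two columns per locus and -9 for missing", {
  tab <- random_gt(n = 8, L = 4, seed = 5, miss_rate = 0.3)
  f <- withr::local_tempfile(fileext = ".str")
  write_structure(tab, f)
  m <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(m), 8)
  expect_equal(ncol(m), 2 + 2 * 4)
  g <- as.matrix(m[, -(1:2)])
  expect_true(all(g[g < 0] == -9))
  expect_equal(sum(g == -9), 2 * sum(is.na(tab$a1)))
})

test_that("load_study validates, pools member locations, and round-trips the simulator", {
  fx <- make_fixture("tiny")
  p <- write_study(fx$study, withr::local_tempdir())
  st <- load_study(p["genotypes"], p["fasta"], p["metadata"])
  expect_identical(st$genotypes$a1, fx$study$genotypes$a1)
  expect_identical(st$haplotypes$sequence, fx$study$haplotypes$sequence)
  expect_equal(nrow(st$sites), 2)

  # paper-shape fixture: 15 sampling locations pool to 11 analysis sites
  fp <- make_fixture("paper_shape")
  expect_equal(length(fp$study$genotypes$individual_id), 260)
  expect_equal(nrow(fp$study$sites), 15)
  pp <- write_study(fp$study, withr::local_tempdir())
  stp <- load_study(pp["genotypes"], pp["fasta"], pp["metadata"])
  expect_equal(length(unique(stp$genotypes$site_id)), 11)
  expect_equal(length(stp$genotypes$individual_id), 260)  # nothing dropped

  # unknown site in the genotype file is an error naming the site
  md <- fx$study$sites
  expect_error(load_study(fx$study$genotypes, fx$study$haplotypes,
                          md[md$site_id != "pure_east", ]),
               "pure_east")

  # cis site with equal banks is a metadata error
  bad <- md
  bad$role[1] <- "cis"; bad$latitude_group[1] <- "north"
  expect_error(read_site_metadata(bad), "cis")
})

test_that("genotype table invariants are enforced", {
  expect_error(gt_from("s", matrix(c(1L, NA), 1, 2), matrix(c(1L, 2L), 1, 2)),
               "half-missing")
  expect_error(genotype_table(c("a", "a"), c("s", "s"),
                              matrix(1L, 2, 1), matrix(1L, 2, 1), "L1"),
               "duplicate")
  expect_error(gt_from("s", matrix(-3L, 1, 1), matrix(2L, 1, 1)), "positive")
  a <- random_gt(6, 3, seed = 1); b <- random_gt(6, 3, seed = 2)
  b$individual_id <- paste0("x", b$individual_id)
  expect_equal(length(gt_bind(a, b)$individual_id), 12)
})

test_that("genotyping error rate matches the published re-genotyping arithmetic", {
  expect_equal(genotyping_error_rate(0, 76), 0)
  expect_equal(round(genotyping_error_rate(2, 16 * 13), 4), 0.0096)
  expect_equal(round(genotyping_error_rate(2, 16 * 13 + 76), 4), 0.0070)
  # scale invariance
  for (c_ in c(2, 5, 11)) {
    expect_equal(genotyping_error_rate(3 * c_, 80 * c_), genotyping_error_rate(3, 80))
  }
  expect_error(genotyping_error_rate(1, 0), "positive")
  expect_error(genotyping_error_rate(5, 3), "n_mismatch")
})
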