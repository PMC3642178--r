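# Private-allele discovery, diagnostic filtering, design construction, the
# mixed-logit channel models, and the AIC comparison.

# small study with known private alleles: locus L01 has allele 3 private to
# the west pure site at frequency 0.25, locus L02 is shared
toy_study <- function() {
  a1 <- rbind(matrix(c(3L, 5L), 4, 2, byrow = TRUE),   # pure west
              matrix(c(4L, 5L), 4, 2, byrow = TRUE),   # pure east
              matrix(c(3L, 5L), 4, 2, byrow = TRUE),   # cis
              matrix(c(4L, 5L), 4, 2, byrow = TRUE))   # control
  a2 <- rbind(matrix(c(4L, 6L), 4, 2, byrow = TRUE),
              matrix(c(4L, 6L), 4, 2, byrow = TRUE),
              matrix(c(4L, 6L), 4, 2, byrow = TRUE),
              matrix(c(4L, 6L), 4, 2, byrow = TRUE))
  a1[2:4, 1] <- 4L  # allele 3 only in individual 1 of pure west and cis
  a1[9, 1] <- 3L
  tab <- gt_from(rep(c("pure_west", "pure_east", "cis1", "control1"), each = 4),
                 a1, a2)
  md <- data.frame(
    site_id = c("pure_west", "pure_east", "cis1", "control1"),
    role = c("pure", "pure", "cis", "control"),
    latitude_group = c("none", "none", "north", "north"),
    bank_current = c("west", "east", "east", "west"),
    bank_historical = c("west", "east", "west", "west"))
  structure(list(genotypes = tab,
                 haplotypes = haplotype_set(character(), character()),
                 sites = read_site_metadata(md)),
            class = "study_dataset")
}

test_that("private alleles: identity case, frequency bookkeeping, filters", {
  # identical allele sets give an empty record list
  same <- gt_from(rep(c("pw", "pe"), each = 3),
                  matrix(1L, 6, 1), matrix(2L, 6, 1))
  expect_equal(nrow(find_private_alleles(same, "pw", "pe")), 0)

  st <- toy_study()
  rec <- find_private_alleles(st$genotypes, "pure_west", "pure_east")
  r3 <- rec[rec$allele == 3 & rec$locus == "L01", ]
  expect_equal(r3$origin, "west")
  expect_equal(r3$freq_pure, 1 / 8)
  expect_false(r3$passed_prevalence)  # 0.125 < 0.15

  # threshold boundaries are inclusive
  rec2 <- rec
  rec2$freq_pure <- 0.15; rec2$freq_overall <- 0.10
  rec2$passed_prevalence <- TRUE; rec2$passed_overall <- TRUE
  out <- filter_diagnostic(rec2)
  expect_true(all(out$selected))

  # one allele per locus: highest overall frequency wins, ties to lower code
  multi <- data.frame(locus = "L01", allele = c(10L, 12L, 11L), origin = "west",
                      freq_pure = 0.3, freq_overall = c(0.2, 0.3, 0.3),
                      passed_prevalence = TRUE, passed_overall = TRUE,
                      selected = FALSE)
  sel <- filter_diagnostic(multi)
  expect_equal(sel$allele[sel$selected], 11L)
  expect_equal(unname(attr(sel, "cascade")), c(3L, 3L, 1L))
})

test_that("deep-split simulation recovers every fixed difference as private", {
  tab <- gt_from(rep(c("pw", "pe"), each = 6),
                 cbind(rep(c(2L, 9L), each = 6), rep(c(4L, 7L), each = 6)),
                 cbind(rep(c(2L, 9L), each = 6), rep(c(4L, 7L), each = 6)))
  rec <- find_private_alleles(tab, "pw", "pe")
  expect_equal(nrow(rec), 4)  # two fixed differences per locus
  expect_true(all(rec$freq_pure == 1))
  expect_true(all(filter_diagnostic(rec)$selected ==
                    c(TRUE, TRUE, TRUE, TRUE) |
                    sum(filter_diagnostic(rec)$selected) == 2))
})

test_that("mtDNA pseudo-alleles mirror the haplogroup split", {
  asg <- data.frame(individual_id = sprintf("i%03d", 1:16),
                    haplogroup = rep(c("west", "east"), c(10, 6)),
                    dist_west = 0, dist_east = 0.06)
  mt <- add_mtdna_pseudoalleles(asg)
  expect_equal(mt$origin, c("west", "east"))
  expect_equal(unique(mt$allele_group), "mtDNA")
  mt2 <- add_mtdna_pseudoalleles(asg, shared_group = FALSE)
  expect_equal(length(unique(mt2$allele_group)), 2)
  expect_error(add_mtdna_pseudoalleles(
    data.frame(individual_id = "x", haplogroup = "unassigned")), "unassigned")

  st <- toy_study()
  asg2 <- data.frame(individual_id = st$genotypes$individual_id,
                     haplogroup = rep(c("west", "east", "west", "west"), each = 4))
  rec <- filter_diagnostic(find_private_alleles(st$genotypes, "pure_west", "pure_east"))
  rows <- build_design(rec, st, mtdna = add_mtdna_pseudoalleles(asg2))
  mtrows <- rows[rows$locus == "mtDNA", ]
  # mirrored rows: k_west + k_east = n assigned, per site
  for (s in unique(mtrows$site_id)) {
    ks <- mtrows$k[mtrows$site_id == s]
    expect_equal(sum(ks), mtrows$n[mtrows$site_id == s][1])
  }
})

test_that("design rows: completeness, native flags, k = 0 retained", {
  st <- toy_study()
  rec <- find_private_alleles(st$genotypes, "pure_west", "pure_east")
  rec$selected <- TRUE  # score both alleles regardless of the filters
  rows <- build_design(rec, st)
  expect_equal(nrow(rows), 4 * nrow(rec))  # sites x allele groups
  cis_west <- rows[rows$site_id == "cis1" & rows$origin == "west", ]
  expect_equal(cis_west$native_historical, rep(1L, nrow(cis_west)))
  expect_equal(cis_west$native_current, rep(0L, nrow(cis_west)))
  expect_true(any(rows$k == 0))
  # non-cis sites agree between the two channels
  other <- rows[rows$site_id != "cis1", ]
  expect_equal(other$native_historical, other$native_current)
})

test_that("null data give an odds ratio near 1 and a flagged separation case", {
  rows <- glmm_rows(seed = 1, beta = 0, sd_re = 0.2)
  f <- fit_mixed_logit(rows, "historical")
  expect_lt(abs(f$beta), 0.05)
  expect_equal(f$odds_ratio, 1, tolerance = 0.06)
  expect_equal(f$n_par, 4)  # intercept, slope, two variances

  sep <- glmm_rows(seed = 2, beta = 0)
  sep$k[sep$native == 1] <- 0
  fs <- fit_mixed_logit(sep, "historical")
  expect_true(any(grepl("separation", fs$flags)))

  one <- glmm_rows(seed = 3)
  one$latitude_group <- "L1"
  expect_error(fit_mixed_logit(one, "historical"), ">= 2 levels")
})

test_that("Laplace fit matches the adaptive-quadrature oracle within 1e-3", {
  skip_if_not_installed("pracma")
  for (seed in 1:3) {
    rows <- glmm_rows(seed = seed, beta = 0.8, nlat = 2, ngrp = 2, nn = 200)
    f <- fit_mixed_logit(rows, "historical")
    lnq <- oracle_glmm_lnl(rows, "historical", f$intercept, f$beta,
                           sqrt(f$re_variance[1]), sqrt(f$re_variance[2]))
    expect_lt(abs(f$loglik - lnq), 1e-3)
  }
})

test_that("a true odds ratio of 2.67 is recovered across seeds", {
  ors <- vapply(1:25, function(sd) {
    # native sites carry the allele at 0.4, non-native at 0.2
    rows <- glmm_rows(seed = 300 + sd, beta = log((0.4 / 0.6) / (0.2 / 0.8)),
                      intercept = qlogis(0.2), nlat = 3, ngrp = 4, nn = 40,
                      reps_per = 1, sd_re = 0.15)
    fit_mixed_logit(rows, "historical")$odds_ratio
  }, numeric(1))
  expect_gt(median(ors), 2.0)
  expect_lt(median(ors), 3.5)
  expect_gt(mean(ors >= 2.0 & ors <= 3.5), 0.6)
})

test_that("channel comparison: exact tie without cis sites, msats-only branch", {
  st <- toy_study()
  rec <- find_private_alleles(st$genotypes, "pure_west", "pure_east")
  rec$selected <- TRUE
  asg <- data.frame(individual_id = st$genotypes$individual_id,
                    haplogroup = rep(c("west", "east", "west", "west"), each = 4))
  rows <- build_design(rec, st, mtdna = add_mtdna_pseudoalleles(asg))
  rows$latitude_group[rows$site_id %in% c("pure_west", "pure_east")] <-
    rep(c("none1", "none2"), each = sum(rows$site_id == "pure_west"))
  # removing the cis rows makes the two designs identical: delta-AIC is 0
  nocis <- rows[rows$site_id != "cis1", ]
  cmp0 <- compare_channels(nocis)
  expect_identical(cmp0$delta_aic, 0)
  expect_equal(cmp0$preferred, "tie")
})

test_that("swapping west and east everywhere leaves delta-AIC unchanged", {
  sim <- compact_sim()
  st <- sim$study
  tab <- st$genotypes
  ids <- function(s) tab$individual_id[tab$site_id == s]
  seqs <- function(s) st$haplotypes$sequence[st$haplotypes$individual_id %in% ids(s)]
  asg <- assign_haplogroups(st$haplotypes, seqs("pure_west"), seqs("pure_east"))
  rec <- filter_diagnostic(find_private_alleles(tab, "pure_west", "pure_east"))
  rows <- build_design(rec, st, mtdna = add_mtdna_pseudoalleles(asg))
  rows$latitude_group[rows$latitude_group == "none"] <-
    ifelse(rows$site_id[rows$latitude_group == "none"] == "pure_west", "nw", "ne")
  cmp <- compare_channels(rows)
  # the msats-only branch is fit whenever mtDNA pseudo-allele rows exist
  expect_false(is.null(cmp$msat_only))

  flip <- function(x) ifelse(x == "west", "east", ifelse(x == "east", "west", x))
  st2 <- st
  st2$sites$bank_current <- flip(st2$sites$bank_current)
  st2$sites$bank_historical <- flip(st2$sites$bank_historical)
  asg2 <- asg; asg2$haplogroup <- flip(asg2$haplogroup)
  # in the flipped world the west-bank reference is the site named pure_east
  rec2 <- filter_diagnostic(find_private_alleles(tab, "pure_east", "pure_west"))
  rows2 <- build_design(rec2, st2, mtdna = add_mtdna_pseudoalleles(asg2))
  rows2$latitude_group[rows2$latitude_group == "none"] <-
    ifelse(rows2$site_id[rows2$latitude_group == "none"] == "pure_west", "nw", "ne")
  cmp2 <- compare_channels(rows2)
  expect_equal(cmp$delta_aic, cmp2$delta_aic, tolerance = 1e-6)
})
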