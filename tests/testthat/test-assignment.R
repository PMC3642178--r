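# mtDNA haplogroup assignment and admixture-model clustering with K
# selection.

test_that("haplogroup assignment: exact match, tie rule, reference checks", {
  q <- haplotype_set(c("q1", "q2"), c("ACGTACGTAC", "AAAAAAAAAA"))
  west <- c("ACGTACGTAC", "ACGTACGTAA")
  east <- c("TTTTTTTTTT", "TTTTTTTTAC")
  asg <- assign_haplogroups(q, west, east)
  expect_equal(asg$haplogroup[1], "west")
  expect_equal(asg$dist_west[1], 0)

  # exactly equidistant: unassigned
  tie <- haplotype_set("t", "AACC")
  a2 <- assign_haplogroups(tie, "AATT", "GGCC")  # both at distance 2/4
  expect_equal(a2$haplogroup, "unassigned")

  expect_error(assign_haplogroups(q, character(0), east), "non-empty")
  expect_error(assign_haplogroups(q, "ACG", east), "length")
})

test_that("simulated pure sites are assigned 100% to their own bank", {
  sim <- compact_sim()
  st <- sim$study
  ids <- function(s) st$genotypes$individual_id[st$genotypes$site_id == s]
  seqs <- function(s) st$haplotypes$sequence[st$haplotypes$individual_id %in% ids(s)]
  asg <- assign_haplogroups(st$haplotypes, seqs("pure_west"), seqs("pure_east"))
  comp <- haplogroup_site_composition(
    asg, stats::setNames(st$genotypes$site_id, st$genotypes$individual_id))
  expect_equal(comp$frac_west[comp$site_id == "pure_west"], 1)
  expect_equal(comp$frac_east[comp$site_id == "pure_east"], 1)
  # composition fractions account for every individual
  expect_equal(comp$frac_west + comp$frac_east + comp$frac_unassigned,
               rep(1, nrow(comp)))
  # invariant to individual ordering
  perm <- sample(nrow(asg))
  comp2 <- haplogroup_site_composition(
    asg[perm, ], stats::setNames(st$genotypes$site_id, st$genotypes$individual_id))
  expect_equal(comp2[match(comp$site_id, comp2$site_id), -1], comp[, -1],
               ignore_attr = TRUE)
})

two_pop_tab <- function(n = 20, L = 12) {
  # fixed allele differences at every locus
  gt_from(rep(c("p1", "p2"), each = n),
          rbind(matrix(2L, n, L), matrix(8L, n, L)),
          rbind(matrix(2L, n, L), matrix(8L, n, L)))
}

test_that("admixture model: K=1 degeneracy, fixed-difference recovery, determinism", {
  tab <- two_pop_tab()
  r1 <- admixture_mcmc(tab, K = 1, n_sweeps = 120, burnin = 40, seed = 1)
  expect_equal(unname(r1$Q[, 1]), rep(1, 40))

  refs <- tab$individual_id[tab$site_id == "p1"]
  r2 <- admixture_mcmc(tab, K = 2, n_sweeps = 400, burnin = 100, seed = 2,
                       ref_ids = refs)
  sm <- site_mean_ancestry(r2)
  expect_gt(sm["p1", 1], 0.95)
  expect_gt(sm["p2", 2], 0.95)
  expect_equal(unname(rowSums(r2$Q)), rep(1, 40), tolerance = 1e-9)

  # seeded determinism
  r2b <- admixture_mcmc(tab, K = 2, n_sweeps = 400, burnin = 100, seed = 2,
                        ref_ids = refs)
  expect_identical(r2$Q, r2b$Q)
  expect_identical(r2$loglik, r2b$loglik)
})

test_that("relabeling clusters leaves the data likelihood unchanged", {
  tab <- two_pop_tab(n = 10, L = 4)
  r <- admixture_mcmc(tab, K = 2, n_sweeps = 200, burnin = 50, seed = 3)
  # direct data log-likelihood at the posterior-mean parameters
  cp <- oxbowflow:::gt_copies(tab)
  flat <- (cp$loc - 1L) * cp$jmax + cp$allele
  lnl <- function(Q, P) {
    w <- 0
    for (k in seq_len(ncol(Q))) w <- w + Q[cp$ind, k] * P[[k]][flat]
    sum(log(w))
  }
  expect_equal(lnl(r$Q, r$P), lnl(r$Q[, 2:1], r$P[2:1]), tolerance = 1e-9)
})

test_that("duplicating every individual leaves ancestry essentially unchanged", {
  sim <- compact_sim()
  tab <- gt_sites(sim$study$genotypes, c("north_cis", "pure_west", "pure_east"))
  refs <- tab$individual_id[tab$site_id == "pure_west"]
  dup <- tab
  dup$individual_id <- c(tab$individual_id, paste0(tab$individual_id, "_b"))
  dup$site_id <- c(tab$site_id, tab$site_id)
  dup <- genotype_table(dup$individual_id, dup$site_id,
                        rbind(tab$a1, tab$a1), rbind(tab$a2, tab$a2),
                        tab$locus_names)
  r1 <- admixture_mcmc(tab, K = 2, n_sweeps = 600, burnin = 200, seed = 9,
                       ref_ids = refs)
  r2 <- admixture_mcmc(dup, K = 2, n_sweeps = 600, burnin = 200, seed = 9,
                       ref_ids = refs)
  dq <- mean(abs(r1$Q - r2$Q[seq_len(nrow(r1$Q)), ]))
  expect_lt(dq, 0.05)
})

test_that("K selection: likelihood favors K=1 under panmixia, delta-K finds K=2", {
  # single panmictic population
  pan <- random_gt(n = 40, L = 8, n_sites = 1, seed = 17, miss_rate = 0,
                   alleles = 1:6)
  runs <- list()
  for (K in 1:3) for (r in 1:3) {
    runs[[length(runs) + 1L]] <- admixture_mcmc(pan, K, n_sweeps = 600,
                                                burnin = 200, seed = 10 * K + r)
  }
  sel <- select_k(runs)
  expect_equal(sel$best_k_likelihood, 1)

  # deep two-population split
  tab <- two_pop_tab(n = 15, L = 6)
  runs2 <- list()
  for (K in 1:3) for (r in 1:3) {
    # (K = 3 exceeds the two distinct multilocus genotypes: warned, allowed)
    runs2[[length(runs2) + 1L]] <- suppressWarnings(
      admixture_mcmc(tab, K, n_sweeps = 600, burnin = 200, seed = 100 + 10 * K + r))
  }
  sel2 <- select_k(runs2)
  expect_equal(sel2$best_k_delta, 2)
  expect_equal(sel2$best_k_likelihood, 2)

  # K range of length 2: delta-K unavailable, likelihood ranking still returned
  short <- runs2[vapply(runs2, function(r) r$K <= 2, logical(1))]
  sel3 <- select_k(short)
  expect_true(is.na(sel3$best_k_delta))
  expect_true(sel3$best_k_likelihood %in% 1:2)
})
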