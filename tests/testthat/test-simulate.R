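# Forward-time simulator: determinism, conservation, divergence limits,
# fixtures, and the realized-migration truth tables.

test_that("identical configurations reproduce identical studies", {
  cfg <- sim_config(deme_size = 20, pool_size = 20, t_split = 60, t_local = 20,
                    t_cutoff = 6, t_iso = 3, n_msat_loci = 4, mtdna_length = 100,
                    sample_sizes = c(cis = 8, trans = 8, control = 8, pure = 8),
                    seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study$genotypes, b$study$genotypes)
  expect_identical(a$study$haplotypes, b$study$haplotypes)
  cfg2 <- cfg; cfg2$seed <- 6
  expect_false(identical(simulate_study(cfg2)$study$genotypes$a1, a$study$genotypes$a1))
})

test_that("conservation: sampled counts equal the configured sample sizes", {
  sim <- compact_sim()
  cnt <- table(sim$study$genotypes$site_id)
  expect_equal(as.integer(cnt[c("north_cis", "north_trans", "north_control")]),
               rep(15L, 3))
  expect_equal(as.integer(cnt[c("pure_west", "pure_east")]), rep(12L, 2))
  expect_equal(length(sim$truth$individual_id), sum(cnt))
})

test_that("no divergence when the banks never split", {
  cfg <- sim_config(t_split = 0, t_local = 0, cutoff = FALSE,
                    deme_size = 100, pool_size = 100,
                    sample_sizes = c(cis = 20, trans = 20, control = 20, pure = 20),
                    seed = 31)
  sim <- simulate_study(cfg)
  th <- pairwise_fst(sim$study$genotypes, "pure_west", "pure_east")$theta
  expect_lt(abs(th), 0.02)
})

test_that("complete isolation sorts mtDNA haplogroups perfectly by bank", {
  cfg <- sim_config(deme_size = 30, pool_size = 30, t_split = 300, t_local = 30,
                    cutoff = FALSE, m_cross = 0, mtdna_mut_rate = 2e-4,
                    sample_sizes = c(cis = 10, trans = 10, control = 10, pure = 10),
                    seed = 12)
  sim <- simulate_study(cfg)
  st <- sim$study
  ids <- function(s) st$genotypes$individual_id[st$genotypes$site_id == s]
  seqs <- function(s) st$haplotypes$sequence[st$haplotypes$individual_id %in% ids(s)]
  asg <- assign_haplogroups(st$haplotypes, seqs("pure_west"), seqs("pure_east"))
  site <- st$genotypes$site_id[match(asg$individual_id, st$genotypes$individual_id)]
  # no cutoff: every site keeps its historical bank, and haplogroups sort by it
  west_sites <- st$sites$site_id[st$sites$bank_historical == "west"]
  expect_true(all(asg$haplogroup[site %in% west_sites] == "west"))
  expect_true(all(asg$haplogroup[!(site %in% west_sites)] == "east"))
})

test_that("canned fixtures have the documented shapes", {
  tn <- make_fixture("tiny")
  expect_equal(length(tn$study$genotypes$individual_id), 16)
  expect_equal(length(tn$study$genotypes$locus_names), 3)

  fp <- make_fixture("paper_shape")
  expect_equal(length(fp$study$genotypes$individual_id), 260)
  expect_equal(nrow(fp$study$sites), 15)
  expect_equal(fp$truths$north$transferred_deme, "north_cis")

  nl <- make_fixture("no_cutoff_null")
  expect_true(is.na(nl$truths$north$transferred_deme))
  expect_error(make_fixture("bogus"), "tiny")
})

test_that("realized migration truth: row-stochastic, cross-bank zeros, transfer window", {
  sim <- compact_sim()
  tm <- truth_migration_matrix(sim$truth, window = 40)
  expect_equal(unname(rowSums(tm)), rep(1, nrow(tm)))
  # m_cross = 0: no west<->east exchange after the isolation window
  cfgG <- dim(sim$truth$immigrant_counts)[1]
  post <- truth_migration_matrix(sim$truth, window = sim$truth$config$t_cutoff -
                                   sim$truth$config$t_iso)
  west <- paste0("W", 1:3); east <- paste0("E", 1:3)
  expect_equal(sum(post[west, east]) + sum(post[east, west]), 0)
  # the loop reconnects to trans (E2) only, after the isolation window
  expect_gt(post["loop", "E2"], 0)
  expect_equal(sum(post["loop", c(west, "E1", "E3")]), 0)
  # window covering only the isolation phase: the loop deme is 100% itself
  iso <- apply(sim$truth$immigrant_counts[
    seq(cfgG - sim$truth$config$t_cutoff + 1,
        cfgG - sim$truth$config$t_cutoff + sim$truth$config$t_iso), , ,
    drop = FALSE], c(2, 3), sum)
  loop <- which(sim$truth$deme_labels == "loop")
  expect_equal(iso[loop, loop] / sum(iso[loop, ]), 1)
  expect_error(truth_migration_matrix(sim$truth, 0), "empty")
  expect_error(truth_migration_matrix(sim$truth, cfgG + 1), "exceeds")
})

test_that("within-bank realized migration is symmetric under symmetric rates", {
  sim <- compact_sim()
  tm <- truth_migration_matrix(sim$truth, window = 40)
  # adjacent west demes exchange symmetrically within binomial noise
  n_events <- 40 * sim$truth$config$deme_size
  se <- 2 * sqrt(sim$truth$config$m_along / n_events)
  expect_lt(abs(tm["W1", "W2"] - tm["W2", "W1"]), 4 * se)
})

test_that("cross-bank divergence increases with split time", {
  mean_fst <- vapply(c(50, 125, 200, 275, 350), function(ts) {
    mean(vapply(1:8, function(sd) {
      cfg <- sim_config(deme_size = 80, pool_size = 80, t_split = ts,
                        t_local = 20, cutoff = FALSE, n_msat_loci = 8,
                        msat_mut_rate = 1e-3, mtdna_length = 50,
                        sample_sizes = c(cis = 0, trans = 0, control = 0, pure = 15),
                        seed = 1000 * ts + sd)
      sim <- simulate_study(cfg)
      pairwise_fst(sim$study$genotypes, "pure_west", "pure_east")$theta
    }, numeric(1)))
  }, numeric(1))
  rho <- cor(seq_along(mean_fst), mean_fst, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("pure-site haplogroups sit near the target 6% divergence", {
  sim <- compact_sim()
  st <- sim$study
  ids <- function(s) st$genotypes$individual_id[st$genotypes$site_id == s]
  sw <- st$haplotypes$sequence[st$haplotypes$individual_id %in% ids("pure_west")]
  se <- st$haplotypes$sequence[st$haplotypes$individual_id %in% ids("pure_east")]
  pd <- function(a, b) mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  between <- mean(outer(sw[1:8], se[1:8], Vectorize(pd)))
  expect_gt(between, 0.04)
  expect_lt(between, 0.08)
})

test_that("configuration invariants are rejected before any simulation", {
  expect_error(sim_config(m_along = -0.1), "rates")
  expect_error(sim_config(t_cutoff = 50, t_local = 40), "t_iso <= t_cutoff <= t_local")
  expect_error(sim_config(t_local = 500, t_split = 400), "t_local")
  expect_error(sim_config(m_along = 0.3, m_loop = 0.5), "sum to < 1")
  expect_error(sim_config(sample_sizes = c(cis = 500, trans = 5, control = 5, pure = 5)),
               "exceed")
})
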