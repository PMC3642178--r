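#!/usr/bin/env Rscript
# mtDNA haplogroup assignment against the pure-site references, and
# admixture-model clustering per oxbow (K = 2 ancestry plus likelihood /
# delta-K selection over K = 1..3, three replicate runs each).
#
# Reads results/data/, writes results/assignment/.

library(oxbowflow)

inp <- file.path("results", "data")
out <- file.path("results", "assignment")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

study <- load_study(file.path(inp, "study.genepop.txt"),
                    file.path(inp, "study.cytb.fasta"),
                    file.path(inp, "study.sites.tsv"))
tab <- study$genotypes
md <- study$sites

ids <- function(s) tab$individual_id[tab$site_id == s]
refseq <- function(s) study$haplotypes$sequence[
  study$haplotypes$individual_id %in% ids(s)]
asg <- assign_haplogroups(study$haplotypes, refseq("pure_west"), refseq("pure_east"))
write.table(asg, file.path(out, "haplogroups.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
comp <- haplogroup_site_composition(
  asg, stats::setNames(tab$site_id, tab$individual_id))
write.table(comp, file.path(out, "haplogroup_composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-site haplogroup composition (fraction western):\n")
print(comp[order(comp$site_id), c("site_id", "frac_west", "n")], digits = 2)

for (lat in c("north", "central", "south")) {
  ss <- c(md$site_id[md$latitude_group == lat], "pure_west", "pure_east")
  sub <- gt_sites(tab, ss)
  refs <- ids("pure_west")
  run2 <- admixture_mcmc(sub, K = 2, n_sweeps = 2000, burnin = 500,
                         seed = seed + 10, ref_ids = refs)
  sm <- site_mean_ancestry(run2)
  write.table(round(run2$Q, 4), file.path(out, sprintf("Q_%s_K2.tsv", lat)),
              sep = "\t", quote = FALSE)
  cat(sprintf("\n%s oxbow, K = 2 mean western ancestry by site:\n", lat))
  print(round(sm[, 1], 3))

  runs <- list()
  for (K in 1:3) for (r in 1:3) {
    runs[[length(runs) + 1L]] <- admixture_mcmc(
      sub, K, n_sweeps = 1500, burnin = 400,
      seed = seed + 100 * K + r, ref_ids = refs)
  }
  sel <- select_k(runs)
  write.table(sel$table, file.path(out, sprintf("kselect_%s.tsv", lat)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: likelihood-best K = %d, delta-K best K = %s\n",
              lat, sel$best_k_likelihood, sel$best_k_delta))
}
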