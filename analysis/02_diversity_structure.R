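#!/usr/bin/env Rscript
# Per-site diversity (Table-1 style), Hardy-Weinberg and linkage
# disequilibrium with Bonferroni correction, and pairwise divergence
# (theta, G'ST, Jost's D) within each oxbow.
#
# Reads results/data/ (01_simulate_study.R), writes results/stats/.

library(oxbowflow)

inp <- file.path("results", "data")
out <- file.path("results", "stats")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- load_study(file.path(inp, "study.genepop.txt"),
                    file.path(inp, "study.cytb.fasta"),
                    file.path(inp, "study.sites.tsv"))
tab <- study$genotypes
md <- study$sites

# pooling check for the member locations merged at load (unpooled reload)
raw <- load_study(file.path(inp, "study.genepop.txt"), NULL,
                  file.path(inp, "study.sites.tsv"), pool = FALSE)
members <- split(raw$sites$site_id[!is.na(raw$sites$parent_id)],
                 raw$sites$parent_id[!is.na(raw$sites$parent_id)])
for (parent in names(members)) {
  locs <- c(parent, members[[parent]])
  chk <- amova_pooling_check(raw$genotypes, locs, n_perm = 199, seed = 2)
  cat(sprintf("pooling %s (%s): theta = %.4f, p = %.3f -> %s\n",
              parent, paste(locs, collapse = "+"), chk$theta, chk$p_value,
              if (chk$pool) "pool" else "keep separate"))
}

dsum <- diversity_summary(study)
write.table(dsum, file.path(out, "diversity_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nper-site diversity (mean over loci):\n")
print(dsum, digits = 3)

# HWE exact tests per site x locus, Bonferroni over the whole family
hwe <- do.call(rbind, lapply(unique(tab$site_id), function(s) {
  do.call(rbind, lapply(tab$locus_names, function(l) {
    p <- tryCatch(
      suppressWarnings(hwe_exact_test(tab, s, l, mc_reps = 5000, seed = 7)$p_value),
      error = function(e) NA_real_)
    data.frame(site_id = s, locus = l, p_value = p)
  }))
}))
hwe <- hwe[!is.na(hwe$p_value), ]
bf <- bonferroni(hwe$p_value, 0.05)
hwe$significant <- bf$significant
write.table(hwe, file.path(out, "hwe_tests.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nHWE: %d of %d tests significant after Bonferroni (threshold %.2g)\n",
            bf$n_significant, bf$m, bf$threshold))

# pairwise LD at each site over locus pairs (permutation G-test)
prs <- utils::combn(tab$locus_names, 2)
ld_p <- unlist(lapply(unique(tab$site_id), function(s) {
  vapply(seq_len(ncol(prs)), function(j) {
    tryCatch(ld_permutation_test(tab, s, prs[, j], n_perm = 199, seed = j)$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
}))
ld_p <- ld_p[!is.na(ld_p)]
bf_ld <- bonferroni(ld_p, 0.05)
cat(sprintf("LD: %d of %d tests significant after Bonferroni\n",
            bf_ld$n_significant, bf_ld$m))

# pairwise divergence within each oxbow
for (lat in c("north", "central", "south")) {
  ss <- md$site_id[md$latitude_group == lat]
  dv <- divergence_matrix(tab, ss, n_perm = 99, seed = 3)
  write.table(dv, file.path(out, sprintf("divergence_%s.tsv", lat)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s oxbow divergence:\n", lat))
  print(dv, digits = 3)
}
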