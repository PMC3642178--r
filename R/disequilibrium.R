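## Hardy-Weinberg exact tests (Monte-Carlo with exhaustive enumeration for
## two-allele tables), a G-statistic linkage-disequilibrium permutation test,
## and Bonferroni flagging.

## Variable part of log P(genotype table | allele counts) under HWE:
## h*log(2) - sum(log n_ij!), h = number of heterozygous individuals.
hwe_log_kernel <- function(x1, x2) {
  g <- paste(pmin(x1, x2), pmax(x1, x2))
  sum((x1 != x2)) * log(2) - sum(lgamma(table(g) + 1))
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype table given allele counts with the
#' probability-ordering rejection region. For two-allele tables the
#' heterozygote-count distribution (Levene) is enumerated exhaustively;
#' otherwise a Monte-Carlo test repeatedly re-pairs the sampled gene copies
#' at random.
#'
#' @param tab a [genotype_table()].
#' @param site site id.
#' @param locus locus name.
#' @param mc_reps Monte-Carlo replicates (default 1e5 in spirit, 2e4 here for
#'   routine use; raise for publication runs).
#' @param seed RNG seed.
#' @param method `"auto"` (enumeration for two-allele tables, Monte-Carlo
#'   otherwise), or force one of the two.
#' @return List with `p_value`, `method` (`"enumeration"` or `"monte-carlo"`),
#'   `n_alleles`.
#' @export
hwe_exact_test <- function(tab, site, locus, mc_reps = 20000, seed = 1,
                           method = c("auto", "enumeration", "monte-carlo")) {
  method <- match.arg(method)
  ii <- tab$site_id == site & !is.na(tab$a1[, locus])
  x1 <- tab$a1[ii, locus]; x2 <- tab$a2[ii, locus]
  n <- length(x1)
  if (n < 3) stop("need >= 3 typed individuals")
  alleles <- sort(unique(c(x1, x2)))
  k <- length(alleles)
  if (k < 2) {
    warning("monomorphic locus ", locus, " at ", site, ": p = 1")
    return(list(p_value = 1, method = "monomorphic", n_alleles = 1L))
  }
  if (method == "enumeration" && k > 2)
    stop("exhaustive enumeration is implemented for two-allele tables only")
  if (k == 2 && method != "monte-carlo") {
    # Levene's exact distribution of the heterozygote count
    mA <- sum(c(x1, x2) == alleles[1])
    het_obs <- sum(x1 != x2)
    hs <- seq(mA %% 2, min(mA, 2 * n - mA), by = 2)
    logp <- vapply(hs, function(h) {
      nAA <- (mA - h) / 2; naa <- n - nAA - h
      h * log(2) + lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1)
    }, numeric(1))
    pr <- exp(logp - logsumexp(logp))
    p <- sum(pr[pr <= pr[match(het_obs, hs)] + 1e-12])
    return(list(p_value = p, method = "enumeration", n_alleles = 2L))
  }
  local_rng(seed)
  pool <- c(x1, x2)
  obs <- hwe_log_kernel(x1, x2)
  hits <- 0L
  for (b in seq_len(mc_reps)) {
    perm <- sample(pool)
    y1 <- perm[seq_len(n)]; y2 <- perm[n + seq_len(n)]
    if (hwe_log_kernel(y1, y2) <= obs + 1e-12) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (mc_reps + 1), method = "monte-carlo", n_alleles = k)
}

#' Linkage-disequilibrium permutation test for a locus pair
#'
#' G statistic on the two-locus genotype contingency table; the null is built
#' by permuting one locus's genotypes across individuals.
#'
#' @param tab a [genotype_table()].
#' @param site site id.
#' @param locus_pair character vector of two locus names.
#' @param n_perm permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `p_value`, `g_obs`, `n_perm`.
#' @export
ld_permutation_test <- function(tab, site, locus_pair, n_perm = 999, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  stopifnot(length(locus_pair) == 2)
  ii <- tab$site_id == site & !is.na(tab$a1[, locus_pair[1]]) & !is.na(tab$a1[, locus_pair[2]])
  gcode <- function(l) {
    paste(pmin(tab$a1[ii, l], tab$a2[ii, l]), pmax(tab$a1[ii, l], tab$a2[ii, l]))
  }
  g1 <- gcode(locus_pair[1]); g2 <- gcode(locus_pair[2])
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop("both loci must be polymorphic at the site")
  gstat <- function(a, b) {
    tb <- table(a, b)
    e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    nz <- tb > 0
    2 * sum(tb[nz] * log(tb[nz] / e[nz]))
  }
  obs <- gstat(g1, g2)
  local_rng(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) if (gstat(g1, sample(g2)) >= obs - 1e-12) hits <- hits + 1L
  list(p_value = (1 + hits) / (n_perm + 1), g_obs = obs, n_perm = n_perm)
}

#' Bonferroni significance flags
#'
#' Flags `p <= alpha / m` (inclusive at the boundary), `m` = family size.
#'
#' @param pvals numeric vector of p-values (the test family).
#' @param alpha family-wise error rate in (0, 1).
#' @return List with `threshold`, `significant` (logical vector), `m`,
#'   `n_significant`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty test family")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- length(pvals)
  thr <- alpha / m
  sig <- pvals <= thr
  list(threshold = thr, significant = sig, m = m, n_significant = sum(sig))
}
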