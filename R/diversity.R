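## Per-site diversity indices (allele frequencies, Nei unbiased gene
## diversity, observed heterozygosity, Weir-Cockerham F_IS, rarefied allelic
## richness) and the Table-1-style per-site summary.

#' Allele counts per locus at a site
#'
#' @param tab a [genotype_table()].
#' @param site site id.
#' @param loci optional subset of locus names.
#' @return Named list (by locus) of named integer allele-count vectors;
#'   missing genotypes are excluded locus-wise.
#' @export
allele_counts <- function(tab, site, loci = tab$locus_names) {
  ii <- tab$site_id == site
  if (!any(ii)) stop("no individuals at site ", site)
  out <- lapply(loci, function(l) {
    x <- c(tab$a1[ii, l], tab$a2[ii, l])
    x <- x[!is.na(x)]
    if (!length(x)) stop("locus ", l, " is entirely missing at site ", site)
    tb <- table(x)
    stats::setNames(as.integer(tb), names(tb))
  })
  stats::setNames(out, loci)
}

#' Allele frequencies per locus at a site
#'
#' @inheritParams allele_counts
#' @return Named list (by locus) of frequency vectors summing to 1.
#' @export
allele_frequencies <- function(tab, site, loci = tab$locus_names) {
  lapply(allele_counts(tab, site, loci), function(ct) ct / sum(ct))
}

#' Nei's unbiased gene diversity
#'
#' \eqn{H_E = \frac{n}{n-1}\,(1 - \sum_i p_i^2)} with \eqn{n} the number of
#' gene copies sampled.
#'
#' @param freqs numeric vector of allele frequencies (sums to 1).
#' @param n_genes number of gene copies (2 x typed individuals); must be >= 2.
#' @return Unbiased expected heterozygosity.
#' @export
nei_unbiased_diversity <- function(freqs, n_genes) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  (n_genes / (n_genes - 1)) * (1 - sum(freqs^2))
}

#' Observed heterozygosity per locus and mean
#'
#' @param tab a [genotype_table()].
#' @param site site id.
#' @return List with `per_locus` (named vector) and `mean`.
#' @export
observed_heterozygosity <- function(tab, site) {
  ii <- tab$site_id == site
  if (!any(ii)) stop("no individuals at site ", site)
  per <- vapply(tab$locus_names, function(l) {
    ok <- ii & !is.na(tab$a1[, l])
    if (!sum(ok)) return(NA_real_)
    mean(tab$a1[ok, l] != tab$a2[ok, l])
  }, numeric(1))
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

## Weir-Cockerham (1984) variance components for one locus across r
## populations. Returns the per-allele sums of components a (among
## populations), b (among individuals within populations) and c (within
## individuals). For r = 1 the a component is undefined and returned as 0.
wc_components <- function(tab, sites, locus) {
  comp <- list(a = 0, b = 0, c = 0, polymorphic = FALSE)
  ni <- c(); pmat <- list(); hmat <- list()
  for (s in sites) {
    ii <- tab$site_id == s & !is.na(tab$a1[, locus])
    if (!sum(ii)) next
    x1 <- tab$a1[ii, locus]; x2 <- tab$a2[ii, locus]
    ni <- c(ni, sum(ii))
    pmat[[length(pmat) + 1L]] <- c(x1, x2)
    hmat[[length(hmat) + 1L]] <- cbind(x1, x2)
  }
  r <- length(ni)
  if (!r) return(comp)
  alleles <- sort(unique(unlist(pmat)))
  if (length(alleles) < 2) return(comp)
  comp$polymorphic <- TRUE
  nbar <- mean(ni)
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    p_i <- vapply(seq_len(r), function(i) mean(pmat[[i]] == al), numeric(1))
    h_i <- vapply(seq_len(r), function(i) {
      g <- hmat[[i]]; mean((g[, 1] == al) != (g[, 2] == al))
    }, numeric(1))
    pbar <- sum(ni * p_i) / (r * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    s2 <- if (r > 1) sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
    b <- (nbar / (nbar - 1)) * (inner - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a <- if (r > 1) (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1)) else 0
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  list(a = a_sum, b = b_sum, c = c_sum, polymorphic = TRUE)
}

#' Weir-Cockerham inbreeding coefficient F_IS
#'
#' Small-sample estimator \eqn{\hat f = 1 - \sum c / \sum(b + c)} from the
#' Weir-Cockerham variance components, per locus and multilocus (components
#' summed across loci). Monomorphic loci are undefined per locus and excluded
#' from the multilocus sums.
#'
#' @param tab a [genotype_table()].
#' @param sites one site id or a character vector of sites (components are
#'   then pooled across populations).
#' @return List with `per_locus` and `multilocus`.
#' @export
fis_weir_cockerham <- function(tab, sites) {
  if (sum(tab$site_id %in% sites) < 2) stop("need >= 2 individuals")
  B <- C <- 0
  per <- stats::setNames(rep(NA_real_, length(tab$locus_names)), tab$locus_names)
  for (l in tab$locus_names) {
    cp <- wc_components(tab, sites, l)
    if (!cp$polymorphic) next
    per[l] <- 1 - cp$c / (cp$b + cp$c)
    B <- B + cp$b; C <- C + cp$c
  }
  if (B + C == 0) stop("all loci monomorphic; F_IS undefined")
  list(per_locus = per, multilocus = 1 - C / (B + C))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies:
#' \eqn{A_R = \sum_a [1 - \binom{N-N_a}{g} / \binom{N}{g}]}.
#'
#' @param counts named allele-count vector for one locus, or a list of such
#'   vectors (one per locus; the mean across loci is then returned as `mean`).
#' @param g rarefaction depth in gene copies; `1 <= g <= N` for every locus.
#' @return For a single vector, the rarefied richness; for a list, a list
#'   with `per_locus` and `mean`.
#' @export
allelic_richness_rarefied <- function(counts, g) {
  one <- function(ct) {
    N <- sum(ct)
    if (g < 1) stop("g must be >= 1")
    if (g > N) stop("rarefaction depth g = ", g, " exceeds available gene copies (", N, ")")
    sum(1 - exp(lchoose(N - ct, g) - lchoose(N, g)))
  }
  if (is.list(counts)) {
    per <- vapply(counts, one, numeric(1))
    list(per_locus = per, mean = mean(per))
  } else one(counts)
}

#' Table-1-style per-site diversity summary
#'
#' For every site: sample size N, mean allele number A_N, rarefied richness
#' A_R at depth `g_r`, richness A_R* at the global minimum depth, mean Nei
#' unbiased gene diversity H_E, mean observed heterozygosity H_O, and the
#' multilocus Weir-Cockerham F_IS.
#'
#' @param study a `study_dataset` (or a `genotype_table` plus `sites` vector).
#' @param g_r rarefaction depth (gene copies) for A_R; default 40, capped at
#'   the global minimum if smaller.
#' @param exclude_loci loci to drop before summarising.
#' @return A data frame with one row per site.
#' @export
diversity_summary <- function(study, g_r = 40, exclude_loci = character()) {
  tab <- if (inherits(study, "study_dataset")) study$genotypes else study
  if (length(exclude_loci)) tab <- gt_subset(tab, loci = setdiff(tab$locus_names, exclude_loci))
  sites <- unique(tab$site_id)
  cts <- lapply(sites, function(s) allele_counts(tab, s))
  g_min <- min(vapply(cts, function(cl) min(vapply(cl, sum, numeric(1))), numeric(1)))
  g_r <- min(g_r, g_min)
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[i]; ct <- cts[[i]]
    he <- mean(vapply(ct, function(x) nei_unbiased_diversity(x / sum(x), sum(x)), numeric(1)))
    data.frame(
      site_id = s,
      N = sum(tab$site_id == s),
      A_N = mean(vapply(ct, length, numeric(1))),
      A_R = allelic_richness_rarefied(ct, g_r)$mean,
      A_R_star = allelic_richness_rarefied(ct, g_min)$mean,
      H_E = he,
      H_O = observed_heterozygosity(tab, s)$mean,
      F_IS = fis_weir_cockerham(tab, s)$multilocus)
  })
  out <- do.call(rbind, rows)
  attr(out, "g_r") <- g_r
  attr(out, "g_min") <- g_min
  out
}
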