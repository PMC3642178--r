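## Recent immigration rates by a Bayesian first-generation-migrant assignment
## model (Metropolis-within-Gibbs over latent origins, row-stochastic
## migrant fractions, per-population inbreeding F and allele frequencies),
## and the equilibrium private-alleles Nm estimator.

prep_migration <- function(tab) {
  n <- n_individuals(tab); L <- length(tab$locus_names)
  codes <- lapply(seq_len(L), function(l) sort(unique(c(tab$a1[, l], tab$a2[, l]))))
  jmax <- max(vapply(codes, length, integer(1)))
  idx <- function(A) {
    m <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) m[, l] <- match(A[, l], codes[[l]])
    m
  }
  i1 <- idx(tab$a1); i2 <- idx(tab$a2)
  flat <- function(i) {
    f <- ifelse(is.na(i), NA_integer_, (col(i) - 1L) * jmax + i)
    storage.mode(f) <- "integer"
    f
  }
  list(n = n, L = L, jmax = jmax, codes = codes,
       n_alleles = vapply(codes, length, integer(1)),
       flat1 = flat(i1), flat2 = flat(i2),
       hom = i1 == i2)
}

## Leave-one-out Dirichlet-multinomial predictive genotype log-likelihood of
## individual i under every candidate source, given the allele counts C
## ((L*jmax) x R, excluding i) and per-locus gene-copy totals Tt (L x R),
## with a per-source inbreeding coefficient F:
## hom aa: p^2 (1-F) + p F ; het ab: 2 a b (1-F), p the posterior predictive
## frequency (lambda = 1 prior per allele).
loo_logliks <- function(prep, i, C, Tt, F) {
  f1 <- prep$flat1[i, ]; f2 <- prep$flat2[i, ]
  ok <- !is.na(f1)
  f1 <- f1[ok]; f2 <- f2[ok]
  hom <- prep$hom[i, ok]
  J <- prep$n_alleles[ok]
  denom <- J + Tt[ok, , drop = FALSE]          # L' x R
  p1 <- (1 + C[f1, , drop = FALSE]) / denom
  p2 <- (1 + C[f2, , drop = FALSE]) / denom
  Fm <- matrix(F, nrow = nrow(p1), ncol = length(F), byrow = TRUE)
  Hm <- matrix(hom, nrow = nrow(p1), ncol = ncol(p1))
  ll <- ifelse(Hm, log(p1 * p1 * (1 - Fm) + p1 * Fm),
               log(2 * p1 * p2 * (1 - Fm)))
  colSums(ll)
}

#' Recent asymmetric immigration rates among sites (MCMC)
#'
#' First-generation-migrant assignment model: each individual sampled at site
#' r is an immigrant from site s with prior probability `m[r, s]` (the self
#' term is the non-immigrant fraction); its genotype likelihood uses the
#' origin population's allele frequencies with a per-population inbreeding
#' parameter F that accommodates within-site heterozygote deficits. The
#' sampler (a compiled Metropolis-within-Gibbs kernel) collapses the allele
#' frequencies: latent origins are updated by random-scan Gibbs under the
#' leave-one-out Dirichlet-multinomial predictive likelihood (Dirichlet(1)
#' frequency prior), the rows of m by conjugate Dirichlet Gibbs (with the
#' Rao-Blackwellized conditional mean accumulated as the posterior mean),
#' and each F by random-walk Metropolis on the logit scale with a Beta(1, 5)
#' prior. Each row of m sums to 1 at every sweep; 95%
#' highest-posterior-density intervals are computed per entry by the
#' shortest-interval method from the sampled draws.
#'
#' @param tab a [genotype_table()].
#' @param sites character vector (>= 2) of site ids, each with >= 5
#'   individuals.
#' @param n_samples post-burnin sweeps.
#' @param burnin burn-in sweeps.
#' @param thin keep every `thin`-th sweep.
#' @param seed RNG seed.
#' @return A `migration_estimate`: `sites`, `m_mean` (row-stochastic matrix
#'   of posterior means), `hpdi_low`/`hpdi_high`, `F_mean`, `traces` (kept
#'   draws, columns `r<-s`), `n_kept`.
#' @export
recent_migration_mcmc <- function(tab, sites, n_samples = 2000, burnin = 500,
                                  thin = 1, seed = 1) {
  if (length(sites) < 2) stop("need >= 2 sites")
  sub <- gt_sites(tab, sites)
  nr <- vapply(sites, function(s) sum(sub$site_id == s), numeric(1))
  if (any(nr < 5)) stop("every site needs >= 5 individuals")
  for (l in sub$locus_names) for (s in sites)
    if (all(is.na(sub$a1[sub$site_id == s, l])))
      stop("locus ", l, " entirely missing at site ", s)
  local_rng(seed)
  prep <- prep_migration(sub)
  R <- length(sites)
  home <- match(sub$site_id, sites)
  out <- .migration_chain_cpp(prep$flat1, prep$flat2, prep$n_alleles,
                              as.integer(home), R, prep$jmax,
                              as.integer(n_samples), as.integer(burnin),
                              as.integer(thin))
  m_mean <- out$m_mean
  dimnames(m_mean) <- list(sites, sites)
  hp <- apply(out$traces, 2, hpdi)
  structure(list(sites = sites,
                 m_mean = m_mean,
                 hpdi_low = matrix(hp[1, ], R, R, dimnames = list(sites, sites)),
                 hpdi_high = matrix(hp[2, ], R, R, dimnames = list(sites, sites)),
                 F_mean = as.numeric(out$F_mean),
                 traces = out$traces, n_kept = out$n_kept),
            class = "migration_estimate")
}

#' @export
print.migration_estimate <- function(x, ...) {
  cat("migration_estimate over", length(x$sites), "sites; posterior mean m:\n")
  print(round(x$m_mean, 3))
  invisible(x)
}

#' Across-replicate convergence check for migration chains
#'
#' @param replicates list (>= 2) of `migration_estimate`s from independent
#'   chains on the same data.
#' @param tol maximum allowed across-replicate standard deviation of any
#'   posterior-mean entry.
#' @return List with `spread` (matrix of per-entry sds), `max_spread`,
#'   `pass`.
#' @export
check_convergence <- function(replicates, tol = 0.05) {
  if (length(replicates) < 2) stop("need >= 2 replicate chains")
  ms <- lapply(replicates, `[[`, "m_mean")
  d <- dim(ms[[1]])
  arr <- array(unlist(ms), dim = c(d, length(ms)))
  spread <- apply(arr, c(1, 2), stats::sd)
  dimnames(spread) <- dimnames(ms[[1]])
  list(spread = spread, max_spread = max(spread), pass = max(spread) < tol)
}

## Barton & Slatkin (1986) log-linear calibration of the conditional mean
## private-allele frequency: ln p(1) = a + b ln(Nm), tabulated for reference
## sample sizes of 10, 25 and 50 diploids per deme.
.barton_slatkin <- data.frame(
  n = c(10, 25, 50),
  a = c(-2.440, -2.609, -2.585),
  b = c(-0.505, -0.576, -0.612))

bs_coeffs <- function(n_mean) {
  bs <- .barton_slatkin
  if (n_mean <= bs$n[1]) return(bs[1, c("a", "b")])
  if (n_mean >= bs$n[3]) return(bs[3, c("a", "b")])
  i <- if (n_mean <= bs$n[2]) 1L else 2L
  w <- (log(n_mean) - log(bs$n[i])) / (log(bs$n[i + 1]) - log(bs$n[i]))
  data.frame(a = (1 - w) * bs$a[i] + w * bs$a[i + 1],
             b = (1 - w) * bs$b[i] + w * bs$b[i + 1])
}

#' Effective number of migrants (Nm) by the private-alleles method
#'
#' Computes the mean within-site frequency of alleles private to one of the
#' two sites and inverts the Barton-Slatkin log-linear calibration
#' `ln p(1) = a + b ln(Nm)`, with the published (a, b) pairs for reference
#' sample sizes 10/25/50 interpolated log-linearly at the observed mean
#' sample size.
#'
#' @param tab a [genotype_table()].
#' @param site_a,site_b site ids.
#' @return An `nm_estimate`: `p1_bar`, `mean_n`, `nm`, `n_private`,
#'   `status` (`"ok"` or `"no-private-alleles"`, in which case `nm` is `NA`).
#' @export
private_allele_nm <- function(tab, site_a, site_b) {
  fa <- allele_frequencies(tab, site_a)
  fb <- allele_frequencies(tab, site_b)
  pf <- c()
  for (l in tab$locus_names) {
    pa <- fa[[l]]; pb <- fb[[l]]
    only_a <- setdiff(names(pa), names(pb))
    only_b <- setdiff(names(pb), names(pa))
    pf <- c(pf, unname(pa[only_a]), unname(pb[only_b]))
  }
  n_mean <- mean(c(sum(tab$site_id == site_a), sum(tab$site_id == site_b)))
  if (!length(pf)) {
    return(structure(list(p1_bar = NA_real_, mean_n = n_mean, nm = NA_real_,
                          n_private = 0L, status = "no-private-alleles"),
                     class = "nm_estimate"))
  }
  p1 <- mean(pf)
  cf <- bs_coeffs(n_mean)
  nm <- exp((log(p1) - cf$a) / cf$b)
  structure(list(p1_bar = p1, mean_n = n_mean, nm = nm,
                 n_private = length(pf), status = "ok"),
            class = "nm_estimate")
}
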