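# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# small deterministic genotype table from explicit vectors
gt_from <- function(site, a1, a2, loci = sprintf("L%02d", seq_len(ncol(a1)))) {
  n <- length(site)
  genotype_table(sprintf("i%03d", seq_len(n)), site, a1, a2, loci)
}

# random valid genotype table (allele codes 5..60), lexically ordered ids
# within sites so GENEPOP round-trips preserve row order
random_gt <- function(n = 20, L = 13, n_sites = 2, seed = 1, miss_rate = 0.05,
                      alleles = 5:60) {
  set.seed(seed)
  site <- sort(rep_len(sprintf("site%d", seq_len(n_sites)), n))
  a1 <- matrix(sample(alleles, n * L, TRUE), n, L)
  a2 <- matrix(sample(alleles, n * L, TRUE), n, L)
  drop <- matrix(runif(n * L) < miss_rate, n, L)
  a1[drop] <- NA; a2[drop] <- NA
  gt_from(site, a1, a2)
}

# one compact cutoff study shared by several tests (built lazily, cached)
compact_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(deme_size = 60, pool_size = 60, t_split = 250,
                        t_local = 60, t_cutoff = 15, t_iso = 8,
                        mtdna_mut_rate = 1.2e-4,
                        sample_sizes = c(cis = 15, trans = 15, control = 15, pure = 12),
                        seed = 77)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# ---- independent oracles ----------------------------------------------------

# Weir-Cockerham theta for two populations, written directly from the 1984
# variance-component definitions (independent of the package implementation)
oracle_theta <- function(tab, sa, sb) {
  num <- den <- 0
  for (l in tab$locus_names) {
    pops <- lapply(c(sa, sb), function(s) {
      ii <- tab$site_id == s & !is.na(tab$a1[, l])
      cbind(tab$a1[ii, l], tab$a2[ii, l])
    })
    alleles <- sort(unique(unlist(pops)))
    if (length(alleles) < 2) next
    r <- 2
    ni <- vapply(pops, nrow, numeric(1))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      p <- vapply(pops, function(g) mean(g == al), numeric(1))
      h <- vapply(pops, function(g) mean((g[, 1] == al) != (g[, 2] == al)), numeric(1))
      pbar <- sum(ni * p) / sum(ni)
      hbar <- sum(ni * h) / sum(ni)
      s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

# Nei-Chesser unbiased Hs/Ht per locus for two sites (independent coding)
oracle_hs_ht <- function(tab, sa, sb, l) {
  dat <- lapply(c(sa, sb), function(s) {
    ii <- tab$site_id == s & !is.na(tab$a1[, l])
    cbind(tab$a1[ii, l], tab$a2[ii, l])
  })
  ni <- vapply(dat, nrow, numeric(1))
  ntil <- 2 / sum(1 / ni)
  ho <- mean(vapply(dat, function(g) mean(g[, 1] != g[, 2]), numeric(1)))
  alleles <- sort(unique(unlist(dat)))
  pm <- vapply(dat, function(g) vapply(alleles, function(al) mean(g == al), numeric(1)),
               numeric(length(alleles)))
  pm <- matrix(pm, nrow = length(alleles))
  hs <- ntil / (ntil - 1) * (1 - mean(colSums(pm^2)) - ho / (2 * ntil))
  ht <- 1 - sum(rowMeans(pm)^2) + hs / (2 * ntil) - ho / (4 * ntil)
  list(hs = hs, ht = ht)
}

# adaptive Gauss-Hermite marginal log-likelihood of the channel mixed-logit
# model at given parameters (brute-force quadrature over all crossed random
# intercepts jointly)
oracle_glmm_lnl <- function(rows, channel, b0, b1, s_lat, s_grp, nodes = 13) {
  nat <- if (channel == "historical") rows$native_historical else rows$native_current
  lats <- unique(rows$latitude_group); grps <- unique(rows$allele_group)
  d <- length(lats) + length(grps)
  lat_i <- match(rows$latitude_group, lats)
  grp_i <- match(rows$allele_group, grps) + length(lats)
  sds <- c(rep(max(s_lat, 1e-6), length(lats)), rep(max(s_grp, 1e-6), length(grps)))
  k <- rows$k; n <- rows$n; nr <- nrow(rows)
  joint <- function(b) {
    sum(dbinom(k, n, plogis(b0 + b1 * nat + b[lat_i] + b[grp_i]), log = TRUE)) +
      sum(dnorm(b, 0, sds, log = TRUE))
  }
  opt <- stats::optim(rep(0, d), function(b) -joint(b), method = "BFGS", hessian = TRUE)
  Sig <- solve(opt$hessian)
  L <- t(chol(Sig))
  gh <- pracma::gaussHermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(gh$x), d)))
  lw <- rowSums(as.matrix(expand.grid(rep(list(log(gh$w)), d))))
  B <- sweep(sqrt(2) * grid %*% t(L), 2, opt$par, "+")
  ETA <- matrix(b0 + b1 * nat, nrow(B), nr, byrow = TRUE) + B[, lat_i] + B[, grp_i]
  LL <- matrix(dbinom(rep(k, each = nrow(B)), rep(n, each = nrow(B)), plogis(ETA),
                      log = TRUE), nrow(B), nr)
  gj <- rowSums(LL) +
    rowSums(matrix(dnorm(B, 0, rep(sds, each = nrow(B)), log = TRUE), nrow(B), d))
  z2 <- rowSums(grid^2)
  m <- max(gj + z2 + lw)
  (d / 2) * log(2) + sum(log(diag(L))) + m + log(sum(exp(gj + z2 + lw - m)))
}

# design-row fixture for mixed-logit tests: crossed latitude x allele-group
# binomial rows with a known native effect
glmm_rows <- function(seed, beta = 0.8, nlat = 2, ngrp = 2, nn = 200,
                      reps_per = 3, sd_re = 0.5, intercept = -0.4) {
  set.seed(seed)
  lats <- paste0("L", seq_len(nlat)); grps <- paste0("g", seq_len(ngrp))
  base <- expand.grid(latitude_group = lats, allele_group = grps, native = c(0, 1),
                      rep = seq_len(reps_per), stringsAsFactors = FALSE)
  u <- rnorm(nlat, 0, sd_re); v <- rnorm(ngrp, 0, sd_re)
  eta <- intercept + beta * base$native +
    u[match(base$latitude_group, lats)] + v[match(base$allele_group, grps)]
  base$n <- nn
  base$k <- rbinom(nrow(base), nn, plogis(eta))
  base$native_historical <- base$native
  base$native_current <- base$native
  base$locus <- base$allele_group
  base$site_id <- paste0("s", seq_len(nrow(base)))
  base
}

# independent 4-island Wright-Fisher generator for the private-alleles Nm
# check (written apart from the package simulator)
island_gt <- function(N = 50, D = 4, m = 0.02, mu = 5e-4, L = 13,
                      gens = 2000, n_samp = 25, seed = 1) {
  set.seed(seed)
  n <- D * N
  A1 <- matrix(sample(20:40, n * L, TRUE), n, L)
  A2 <- matrix(sample(20:40, n * L, TRUE), n, L)
  deme <- rep(seq_len(D), each = N)
  for (g in seq_len(gens)) {
    mig <- runif(n) < m
    src <- deme
    src[mig] <- 1 + (deme[mig] - 1 + sample(D - 1, sum(mig), TRUE)) %% D
    p1 <- (src - 1) * N + floor(runif(n) * N) + 1
    p2 <- (src - 1) * N + floor(runif(n) * N) + 1
    sw1 <- matrix(runif(n * L) < 0.5, n, L); sw2 <- matrix(runif(n * L) < 0.5, n, L)
    g1 <- ifelse(sw1, A1[p1, ], A2[p1, ]); g2 <- ifelse(sw2, A1[p2, ], A2[p2, ])
    mut <- function(x) {
      mm <- runif(length(x)) < mu
      x[mm] <- x[mm] + sample(c(-1, 1), sum(mm), TRUE)
      pmax(pmin(x, 60), 5)
    }
    A1 <- mut(g1); A2 <- mut(g2)
  }
  s1 <- sample(seq_len(N), n_samp); s2 <- N + sample(seq_len(N), n_samp)
  gt_from(rep(c("a", "b"), each = n_samp),
          rbind(A1[s1, ], A1[s2, ]), rbind(A2[s1, ], A2[s2, ]))
}
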