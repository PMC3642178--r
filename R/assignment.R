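## mtDNA haplogroup assignment by nearest pure-site reference (uncorrected
## p-distance) and admixture-model Bayesian clustering (Gibbs sampler over
## allele-copy origins) with likelihood and Evanno delta-K model choice.

seq_char_matrix <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Assign individuals to mtDNA haplogroups
#'
#' Each query is assigned to the side (west/east) of its nearest reference
#' haplotype by uncorrected p-distance with pairwise deletion of gaps and
#' `N`s; an exact tie between the two nearest references leaves the
#' individual unassigned.
#'
#' @param haps a [haplotype_set()] of query sequences.
#' @param west_refs,east_refs `haplotype_set`s (or character vectors of
#'   sequences) of pure-site reference haplotypes; non-empty, same alignment
#'   length as the queries.
#' @return Data frame: `individual_id`, `haplogroup`
#'   (`west`/`east`/`unassigned`), `dist_west`, `dist_east`.
#' @export
assign_haplogroups <- function(haps, west_refs, east_refs) {
  getseq <- function(x) if (inherits(x, "haplotype_set")) x$sequence else as.character(x)
  ws <- getseq(west_refs); es <- getseq(east_refs)
  if (!length(ws) || !length(es)) stop("both reference sets must be non-empty")
  if (any(nchar(c(ws, es)) != haps$length)) stop("reference alignment length mismatch")
  all_seq <- c(haps$sequence, ws, es)
  m <- seq_char_matrix(all_seq)
  m <- matrix(tolower(m), nrow(m))  # DNAbin wants lowercase; n/- are handled
  bin <- ape::as.DNAbin(m)
  d <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  nq <- length(haps$sequence)
  dw <- apply(d[seq_len(nq), nq + seq_along(ws), drop = FALSE], 1, min)
  de <- apply(d[seq_len(nq), nq + length(ws) + seq_along(es), drop = FALSE], 1, min)
  grp <- ifelse(dw < de, "west", ifelse(de < dw, "east", "unassigned"))
  data.frame(individual_id = haps$individual_id, haplogroup = grp,
             dist_west = unname(dw), dist_east = unname(de))
}

#' Per-site haplogroup composition
#'
#' @param assignments data frame from [assign_haplogroups()].
#' @param site_id character vector of site ids named by individual id (or a
#'   `study_dataset`, whose genotype table supplies the mapping).
#' @return Data frame per site: `frac_west`, `frac_east`, `frac_unassigned`,
#'   `n`.
#' @export
haplogroup_site_composition <- function(assignments, site_id) {
  if (inherits(site_id, "study_dataset"))
    site_id <- stats::setNames(site_id$genotypes$site_id, site_id$genotypes$individual_id)
  s <- site_id[assignments$individual_id]
  if (anyNA(s)) stop("individual(s) without a site mapping")
  agg <- function(site) {
    g <- assignments$haplogroup[s == site]
    data.frame(site_id = site, frac_west = mean(g == "west"),
               frac_east = mean(g == "east"),
               frac_unassigned = mean(g == "unassigned"), n = length(g))
  }
  do.call(rbind, lapply(unique(s), agg))
}

## ---- admixture model -------------------------------------------------------

## Long-format allele copies for the sampler.
gt_copies <- function(tab) {
  n <- n_individuals(tab); L <- length(tab$locus_names)
  codes <- lapply(seq_len(L), function(l) sort(unique(c(tab$a1[, l], tab$a2[, l]))))
  jmax <- max(vapply(codes, length, integer(1)))
  ind <- rep(seq_len(n), 2L * L)
  loc <- rep(rep(seq_len(L), each = n), 2L)
  al <- c(tab$a1, tab$a2)  # column-major: locus blocks
  aidx <- integer(length(al))
  for (l in seq_len(L)) {
    sel <- loc == l
    aidx[sel] <- match(al[sel], codes[[l]])
  }
  ok <- !is.na(aidx)
  list(ind = ind[ok], loc = loc[ok], allele = aidx[ok],
       n = n, L = L, jmax = jmax,
       n_alleles = vapply(codes, length, integer(1)), codes = codes)
}

#' Admixture-model Bayesian clustering (one MCMC run)
#'
#' Gibbs sampler for the no-admixture-prior ("admixture model with
#' uncorrelated frequencies") clustering model: allele-copy origins Z,
#' cluster allele frequencies P with Dirichlet(1) prior, and per-individual
#' ancestry Q with Dirichlet(alpha) prior. `alpha` is sampled by a
#' Metropolis step by default (standard practice for the admixture model),
#' or fixed at `alpha_fixed`. The model log-likelihood is estimated as
#' `mean(lnL) - var(lnL)/2` over post-burnin sweeps. Cluster labels are
#' canonically ordered by mean ancestry among `ref_ids` (descending) when
#' given, making replicate runs comparable.
#'
#' @param tab a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param n_sweeps,burnin sweep counts (`n_sweeps > burnin`).
#' @param seed RNG seed; identical inputs and seed give identical chains.
#' @param alpha_mode `"sample"` (default) or `"fixed"`.
#' @param alpha_fixed value of alpha under `"fixed"` (default 1).
#' @param ref_ids individual ids used to orient cluster labels (typically the
#'   west pure site).
#' @return An `ancestry_result`: `K`, `Q` (posterior mean, rows sum to 1),
#'   `P` (mean cluster allele frequencies), `loglik`, `lnl_trace`, `alpha`.
#' @export
admixture_mcmc <- function(tab, K, n_sweeps = 2000, burnin = 500, seed = 1,
                           alpha_mode = c("sample", "fixed"), alpha_fixed = 1,
                           ref_ids = NULL) {
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(K >= 1, n_sweeps > burnin)
  cp <- gt_copies(tab)
  n_distinct <- nrow(unique(cbind(tab$a1, tab$a2)))
  if (K > n_distinct)
    warning("K exceeds the number of distinct multilocus genotypes (",
            n_distinct, "); surplus clusters will be empty")
  local_rng(seed)
  M <- length(cp$ind)
  n <- cp$n
  flat <- (cp$loc - 1L) * cp$jmax + cp$allele  # index into t(P[k, , ]) slices
  alpha <- alpha_fixed
  z <- sample.int(K, M, replace = TRUE)
  Q <- matrix(1 / K, n, K)
  Pk <- vector("list", K)
  draw_P <- function() {
    for (k in seq_len(K)) {
      cnt <- numeric(cp$L * cp$jmax)
      sel <- z == k
      if (any(sel)) {
        tb <- tabulate(flat[sel], cp$L * cp$jmax)
        cnt <- cnt + tb
      }
      g <- stats::rgamma(cp$L * cp$jmax, shape = 1 + cnt, rate = 1)
      gm <- matrix(g, nrow = cp$jmax)  # jmax x L
      for (l in seq_len(cp$L)) {
        j <- cp$n_alleles[l]
        gm[seq_len(j), l] <- gm[seq_len(j), l] / sum(gm[seq_len(j), l])
        if (j < cp$jmax) gm[seq(j + 1L, cp$jmax), l] <- 0
      }
      Pk[[k]] <<- gm  # jmax x L, columns are per-locus frequency vectors
    }
  }
  qsum <- matrix(0, n, K); psum <- lapply(seq_len(K), function(k) matrix(0, cp$jmax, cp$L))
  lnl <- numeric(n_sweeps)
  kept <- 0L
  for (sw in seq_len(n_sweeps)) {
    draw_P()
    ## Z update + data log-likelihood
    W <- matrix(0, M, K)
    for (k in seq_len(K)) W[, k] <- Q[cp$ind, k] * Pk[[k]][flat]
    tot <- rowSums(W)
    lnl[sw] <- sum(log(tot))
    u <- stats::runif(M) * tot
    cum <- W[, 1]
    znew <- rep(1L, M)
    if (K > 1) for (k in 2:K) { znew[u > cum] <- k; cum <- cum + W[, k] }
    z <- znew
    ## Q update
    nik <- matrix(0, n, K)
    for (k in seq_len(K)) nik[, k] <- tabulate(cp$ind[z == k], n)
    g <- matrix(stats::rgamma(n * K, shape = alpha + nik, rate = 1), n, K)
    Q <- g / rowSums(g)
    ## alpha update (Metropolis on log scale, uniform(0, 10] prior)
    if (alpha_mode == "sample" && K > 1) {
      prop <- alpha * exp(stats::rnorm(1, 0, 0.3))
      if (prop <= 10) {
        slq <- sum(log(pmax(Q, 1e-300)))
        lp <- function(a) n * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * slq
        lacc <- lp(prop) - lp(alpha) + log(prop) - log(alpha)
        if (is.finite(lacc) && log(stats::runif(1)) < lacc) alpha <- prop
      }
    }
    if (sw > burnin) {
      kept <- kept + 1L
      qsum <- qsum + Q
      for (k in seq_len(K)) psum[[k]] <- psum[[k]] + Pk[[k]]
    }
  }
  Qm <- qsum / kept
  Pm <- lapply(psum, function(x) x / kept)
  rownames(Qm) <- tab$individual_id
  ord <- seq_len(K)
  if (!is.null(ref_ids) && K > 1) {
    ii <- match(intersect(ref_ids, tab$individual_id), tab$individual_id)
    if (length(ii)) ord <- order(colMeans(Qm[ii, , drop = FALSE]), decreasing = TRUE)
  }
  keep_lnl <- lnl[seq(burnin + 1L, n_sweeps)]
  structure(list(K = K, Q = Qm[, ord, drop = FALSE],
                 P = Pm[ord],
                 loglik = mean(keep_lnl) - stats::var(keep_lnl) / 2,
                 lnl_trace = lnl, alpha = alpha,
                 site_id = tab$site_id),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("ancestry_result: K =", x$K, ", ln L estimate =", round(x$loglik, 1), "\n")
  invisible(x)
}

#' Per-site mean ancestry
#' @param res an `ancestry_result`.
#' @return Matrix sites x clusters of mean Q.
#' @export
site_mean_ancestry <- function(res) {
  sites <- unique(res$site_id)
  m <- t(vapply(sites, function(s) colMeans(res$Q[res$site_id == s, , drop = FALSE]),
                numeric(res$K)))
  rownames(m) <- sites
  m
}

#' Select the number of clusters from replicate runs
#'
#' Groups replicate `ancestry_result`s by K, ranks K by mean model
#' log-likelihood, and computes the Evanno second-order statistic
#' `delta_K = mean(|L_r(K+1) - 2 L_r(K) + L_r(K-1)|) / sd(L(K))` across
#' paired replicates for interior K of a contiguous range of length >= 3.
#'
#' @param runs list of `ancestry_result` objects (replicates across a K
#'   range).
#' @return List: `table` (K, n_runs, mean_lnl, sd_lnl, delta_k),
#'   `best_k_likelihood`, `best_k_delta` (NA when delta-K is unavailable).
#' @export
select_k <- function(runs) {
  ks <- vapply(runs, `[[`, integer(1), "K")
  ll <- vapply(runs, `[[`, numeric(1), "loglik")
  kk <- sort(unique(ks))
  tab <- data.frame(K = kk,
                    n_runs = vapply(kk, function(k) sum(ks == k), integer(1)),
                    mean_lnl = vapply(kk, function(k) mean(ll[ks == k]), numeric(1)),
                    sd_lnl = vapply(kk, function(k) stats::sd(ll[ks == k]), numeric(1)))
  tab$delta_k <- NA_real_
  contiguous <- length(kk) >= 3 && all(diff(kk) == 1)
  if (contiguous) {
    nrep <- min(tab$n_runs)
    lmat <- vapply(kk, function(k) ll[ks == k][seq_len(nrep)], numeric(nrep))
    lmat <- matrix(lmat, nrow = nrep)
    for (j in seq_along(kk)[-c(1, length(kk))]) {
      sdk <- tab$sd_lnl[j]
      if (is.na(sdk) || sdk == 0) next  # flagged: delta-K undefined
      tab$delta_k[j] <- mean(abs(lmat[, j + 1] - 2 * lmat[, j] + lmat[, j - 1])) / sdk
    }
  }
  best_delta <- if (all(is.na(tab$delta_k))) NA_integer_
    else tab$K[which.max(tab$delta_k)]
  list(table = tab,
       best_k_likelihood = tab$K[which.max(tab$mean_lnl)],
       best_k_delta = best_delta)
}
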