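## Pairwise differentiation: Weir-Cockerham theta (F_ST) with permutation
## tests, Nei-Chesser unbiased H_S/H_T, Hedrick's G'_ST, Jost's D_est, and a
## one-level AMOVA-style pooling check for member sampling locations.

theta_from_components <- function(tab, sites) {
  A <- B <- C <- 0
  per <- stats::setNames(rep(NA_real_, length(tab$locus_names)), tab$locus_names)
  for (l in tab$locus_names) {
    cp <- wc_components(tab, sites, l)
    if (!cp$polymorphic) next
    denom <- cp$a + cp$b + cp$c
    per[l] <- if (denom != 0) cp$a / denom else NA_real_
    A <- A + cp$a; B <- B + cp$b; C <- C + cp$c
  }
  if (A + B + C == 0) return(list(per_locus = per, multilocus = NA_real_))
  list(per_locus = per, multilocus = A / (A + B + C))
}

#' Pairwise F_ST (Weir-Cockerham theta) with permutation test
#'
#' Multilocus theta sums the among-population (a), among-individual (b) and
#' within-individual (c) variance components over loci and alleles:
#' \eqn{\hat\theta = \sum a / \sum (a+b+c)}. The p-value permutes individuals
#' between the two sites.
#'
#' @param tab a [genotype_table()].
#' @param site_a,site_b site ids (each with >= 2 individuals).
#' @param n_perm number of permutations (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @return List with `per_locus`, `theta` (multilocus) and `p_value`.
#' @export
pairwise_fst <- function(tab, site_a, site_b, n_perm = 0, seed = 1) {
  sub <- gt_sites(tab, c(site_a, site_b))
  if (sum(sub$site_id == site_a) < 2 || sum(sub$site_id == site_b) < 2)
    stop("both sites need >= 2 individuals")
  est <- theta_from_components(sub, c(site_a, site_b))
  if (is.na(est$multilocus)) stop("theta undefined: no polymorphic locus across the pair")
  p <- NA_real_
  if (n_perm > 0) {
    rng <- local_rng(seed)
    obs <- est$multilocus
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sub
      perm$site_id <- sample(sub$site_id)
      t_b <- theta_from_components(perm, c(site_a, site_b))$multilocus
      if (!is.na(t_b) && t_b >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(per_locus = est$per_locus, theta = est$multilocus, p_value = p)
}

## Nei & Chesser (1983) unbiased H_S and H_T for one locus over r sites, with
## the harmonic-mean sample size correction.
nei_chesser_hs_ht <- function(tab, sites, locus) {
  ps <- list(); ho <- c(); ni <- c()
  for (s in sites) {
    ii <- tab$site_id == s & !is.na(tab$a1[, locus])
    if (!sum(ii)) next
    x1 <- tab$a1[ii, locus]; x2 <- tab$a2[ii, locus]
    tb <- table(c(x1, x2))
    ps[[length(ps) + 1L]] <- tb / sum(tb)
    ho <- c(ho, mean(x1 != x2))
    ni <- c(ni, sum(ii))
  }
  r <- length(ni)
  if (r < 2) return(NULL)
  ntilde <- r / sum(1 / ni)
  alleles <- sort(unique(unlist(lapply(ps, names))))
  pm <- vapply(ps, function(p) {
    v <- stats::setNames(rep(0, length(alleles)), alleles)
    v[names(p)] <- p
    v
  }, numeric(length(alleles)))
  pm <- matrix(pm, nrow = length(alleles))
  ho_bar <- mean(ho)
  hs <- (ntilde / (ntilde - 1)) * (1 - mean(colSums(pm^2)) - ho_bar / (2 * ntilde))
  pbar <- rowMeans(pm)
  ht <- 1 - sum(pbar^2) + hs / (ntilde * r) - ho_bar / (2 * ntilde * r)
  list(hs = hs, ht = ht, r = r)
}

#' Hedrick's standardized G'_ST for a site pair
#'
#' \eqn{G'_{ST} = G_{ST} / G_{ST(max)}} with
#' \eqn{G_{ST(max)} = (k-1)(1-H_S)/(k-1+H_S)}, k = 2, using Nei-Chesser
#' unbiased \eqn{H_S}, \eqn{H_T} with harmonic-mean sample size. Global value
#' from mean \eqn{H_S}, \eqn{H_T} across loci.
#'
#' @inheritParams pairwise_fst
#' @return List with `per_locus` and `global`.
#' @export
gst_hedrick <- function(tab, site_a, site_b) {
  hh <- lapply(tab$locus_names, function(l) nei_chesser_hs_ht(tab, c(site_a, site_b), l))
  ok <- !vapply(hh, is.null, logical(1))
  if (!any(ok)) stop("no locus typed in both sites")
  hs <- vapply(hh[ok], `[[`, numeric(1), "hs")
  ht <- vapply(hh[ok], `[[`, numeric(1), "ht")
  gprime <- function(hs, ht, k = 2) {
    if (any(hs >= 1)) stop("G'_ST undefined: H_S = 1")
    gst <- (ht - hs) / ht
    gst_max <- (k - 1) * (1 - hs) / (k - 1 + hs)
    gst / gst_max
  }
  per <- stats::setNames(rep(NA_real_, length(tab$locus_names)), tab$locus_names)
  per[tab$locus_names[ok]] <- vapply(seq_along(hs), function(i) {
    if (ht[i] <= 0) return(NA_real_)
    gprime(hs[i], ht[i])
  }, numeric(1))
  list(per_locus = per, global = gprime(mean(hs), mean(ht)))
}

#' Jost's D_est for a site pair
#'
#' Per locus \eqn{D = \frac{H_T - H_S}{1 - H_S}\cdot\frac{k}{k-1}} (k = 2)
#' with Nei-Chesser unbiased estimators. The global value is the
#' variance-corrected harmonic mean of per-locus values with negative values
#' floored at 0 before averaging; the arithmetic mean is also reported.
#'
#' @inheritParams pairwise_fst
#' @return List with `per_locus`, `global` (harmonic) and `global_arithmetic`.
#' @export
d_est_jost <- function(tab, site_a, site_b) {
  hh <- lapply(tab$locus_names, function(l) nei_chesser_hs_ht(tab, c(site_a, site_b), l))
  ok <- !vapply(hh, is.null, logical(1))
  if (!any(ok)) stop("no locus typed in both sites")
  per <- stats::setNames(rep(NA_real_, length(tab$locus_names)), tab$locus_names)
  vals <- vapply(hh[ok], function(x) {
    if (x$hs >= 1) return(NA_real_)
    ((x$ht - x$hs) / (1 - x$hs)) * 2
  }, numeric(1))
  per[tab$locus_names[ok]] <- vals
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("D_est undefined: all loci monomorphic across both sites")
  v <- pmax(vals, 0)
  mu <- mean(v)
  glob <- if (mu == 0) 0 else 1 / (1 / mu + stats::var(v) / mu^3)
  list(per_locus = per, global = glob, global_arithmetic = mean(vals))
}

#' All pairwise divergence metrics among sites
#'
#' @param tab a [genotype_table()].
#' @param sites character vector of site ids (default: all).
#' @param n_perm permutations for the F_ST test (0 = none).
#' @param seed RNG seed.
#' @return Data frame with one row per unordered site pair: `theta`, `gst_h`
#'   (Hedrick global), `d_est` (Jost global, harmonic), `fst_p`.
#' @export
divergence_matrix <- function(tab, sites = unique(tab$site_id), n_perm = 0, seed = 1) {
  prs <- utils::combn(sites, 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    fst <- pairwise_fst(tab, a, b, n_perm = n_perm, seed = seed + j)
    data.frame(site_a = a, site_b = b,
               theta = fst$theta,
               gst_h = gst_hedrick(tab, a, b)$global,
               d_est = d_est_jost(tab, a, b)$global,
               fst_p = fst$p_value)
  })
  do.call(rbind, rows)
}

#' One-level AMOVA-style pooling check for member sampling locations
#'
#' Tests differentiation among the member locations of a parent site by the
#' multilocus Weir-Cockerham theta with a permutation null (individuals
#' shuffled among locations). Pooling is recommended iff p > 0.05.
#'
#' @param tab a [genotype_table()] whose `site_id` holds the member location
#'   ids (i.e. an unpooled table).
#' @param locations character vector (>= 2) of member location ids.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `theta`, `p_value`, `pool` (logical recommendation).
#' @export
amova_pooling_check <- function(tab, locations, n_perm = 199, seed = 1) {
  if (length(locations) < 2) stop("pooling check needs >= 2 member locations")
  n_loc <- vapply(locations, function(s) sum(tab$site_id == s), numeric(1))
  if (any(n_loc == 0)) stop("member location with 0 individuals: ",
                            paste(locations[n_loc == 0], collapse = ", "))
  sub <- gt_sites(tab, locations)
  obs <- theta_from_components(sub, locations)$multilocus
  if (is.na(obs)) stop("theta undefined among locations")
  rng <- local_rng(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sub
    perm$site_id <- sample(sub$site_id)
    t_b <- theta_from_components(perm, locations)$multilocus
    if (!is.na(t_b) && t_b >= obs - 1e-12) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(theta = obs, p_value = p, pool = p > 0.05)
}
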