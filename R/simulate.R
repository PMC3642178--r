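## Forward-time Wright-Fisher simulator of a two-bank river metapopulation
## with a meander-loop-cutoff transfer event.
##
## Demography: two "pure" bank pools diverge in isolation from a common
## ancestor starting t_split generations before present. t_local generations
## before present, a local river neighbourhood is founded from the pools: L
## stepping-stone demes per bank plus one meander-loop deme (the future cis
## deme) attached to the west bank. t_cutoff generations before present the
## loop deme is transferred to the east bank, exchanges no migrants for t_iso
## generations, and then exchanges with its new east-bank neighbour (trans).
## Microsatellites mutate by a strict single-step model with reflecting
## bounds; mtDNA is copied from one uniformly chosen parent with per-site
## substitution.

#' Simulation configuration
#'
#' @param deme_size diploids per river deme.
#' @param demes_per_bank stepping-stone demes per bank (excluding the loop
#'   deme and the distal pure pools).
#' @param pool_size diploids in each distal bank pool (the pure populations).
#' @param t_split generations before present at which the two banks split
#'   from the common ancestor.
#' @param t_local generations before present at which the river neighbourhood
#'   is founded from the bank pools.
#' @param t_cutoff generations before present of the cutoff transfer event
#'   (must satisfy `t_iso <= t_cutoff <= t_local < t_split`).
#' @param t_iso generations the transferred deme exchanges no migrants after
#'   the cutoff.
#' @param m_along per-generation migration fraction between adjacent
#'   same-bank demes.
#' @param m_loop pre-cutoff migration fraction between the meander-loop deme
#'   and its bank neighbour. Before the cutoff the loop is continuous
#'   riverside habitat connected by a wide neck, so its coupling to the bank
#'   is stronger than between distance-separated stepping-stone demes; after
#'   the cutoff the oxbow reconnects to its new bank at `m_along` only.
#' @param m_cross across-river fraction between facing demes (default 0).
#' @param n_msat_loci number of microsatellite loci.
#' @param msat_mut_rate stepwise mutation rate per allele copy per generation.
#' @param msat_bounds reflecting bounds for allele repeat codes.
#' @param mtdna_length aligned mtDNA length in bp.
#' @param mtdna_mut_rate substitution rate per site per generation. The
#'   default, with `t_split = 400`, yields ~6% uncorrected divergence between
#'   the two bank haplogroups.
#' @param sample_sizes named vector: diploids sampled per role
#'   (`cis`, `trans`, `control`, `pure`); a role of 0 is not sampled.
#' @param cutoff logical: simulate the transfer event (FALSE = no cutoff).
#' @param null_river_mixing logical: found the river demes from an even
#'   mixture of the two pools and connect facing demes at `m_along`. Used
#'   for the no-cutoff null in which the cis/trans/control labels carry no
#'   information.
#' @param latitude latitude label for the emitted river sites.
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(deme_size = 100, demes_per_bank = 3, pool_size = 100,
                       t_split = 400, t_local = 100, t_cutoff = 20, t_iso = 10,
                       m_along = 0.02, m_loop = 0.1, m_cross = 0,
                       n_msat_loci = 13, msat_mut_rate = 5e-3,
                       msat_bounds = c(5L, 60L),
                       mtdna_length = 809, mtdna_mut_rate = 7.5e-5,
                       sample_sizes = c(cis = 25, trans = 25, control = 25, pure = 15),
                       cutoff = TRUE, null_river_mixing = FALSE,
                       latitude = "north", seed = 1) {
  cfg <- as.list(environment())
  rates <- c(m_along, m_loop, m_cross, msat_mut_rate, mtdna_mut_rate)
  if (any(rates < 0) || any(rates > 1)) stop("all rates must lie in [0, 1]")
  if (cutoff && !(t_iso <= t_cutoff && t_cutoff <= t_local))
    stop("need t_iso <= t_cutoff <= t_local")
  if (t_local > t_split) stop("need t_local <= t_split (t_cutoff < t_split)")
  if (cutoff && t_cutoff >= t_split) stop("need t_cutoff < t_split")
  if (2 * m_along + m_loop + 2 * m_cross >= 1)
    stop("migration fractions out of a deme must sum to < 1")
  if (deme_size < 2 || pool_size < 2) stop("deme sizes must be >= 2")
  need <- c("cis", "trans", "control", "pure")
  if (!all(need %in% names(sample_sizes)))
    stop("sample_sizes must be named with roles: ", paste(need, collapse = ", "))
  if (any(sample_sizes > c(cis = deme_size, trans = deme_size,
                           control = deme_size, pure = pool_size)[names(sample_sizes)]))
    stop("sample sizes cannot exceed deme sizes")
  structure(cfg, class = "sim_config")
}

## ---- mtDNA haplotype registry ---------------------------------------------

.acgt <- c("A", "C", "G", "T")

reg_new <- function(len) {
  e <- new.env(parent = emptyenv())
  e$root <- sample(.acgt, len, replace = TRUE)
  e$n <- 0L
  e$cap <- 1024L
  e$parent <- integer(1024L)
  e$site <- vector("list", 1024L)
  e$base <- vector("list", 1024L)
  e$len <- len
  e
}

## A mutation node stores the hit sites and, per site, which of the three
## alternative bases is substituted (resolved lazily against the base carried
## at that point of the lineage, so reconstruction is root-to-leaf).
reg_add <- function(reg, parent, k) {
  if (reg$n == reg$cap) {  # amortized growth
    reg$cap <- reg$cap * 2L
    length(reg$parent) <- reg$cap
    length(reg$site) <- reg$cap
    length(reg$base) <- reg$cap
  }
  id <- reg$n + 1L
  reg$n <- id
  reg$parent[id] <- parent
  reg$site[[id]] <- sample.int(reg$len, k)
  reg$base[[id]] <- floor(stats::runif(k) * 3) + 1L  # 1-of-3 alternative pick
  id
}

hap_sequence <- function(reg, id) {
  path <- integer(0)
  while (id > 0L) { path <- c(path, id); id <- reg$parent[id] }
  s <- reg$root
  for (nd in rev(path)) {
    sites <- reg$site[[nd]]; pick <- reg$base[[nd]]
    for (j in seq_along(sites)) {
      cur <- s[sites[j]]
      s[sites[j]] <- .acgt[.acgt != cur][pick[j]]
    }
  }
  paste(s, collapse = "")
}

## ---- Wright-Fisher engine --------------------------------------------------

## state: list(A1, A2 (n x L integer), hap (int n), deme (int n)); deme sizes
## are constant. mig is a row-stochastic D x D source matrix (mig[d, s] =
## probability an offspring born in d draws its parent pair from s).
wf_generations <- function(state, mig, gens, cfg, reg, record = FALSE) {
  n <- length(state$deme)
  D <- nrow(mig)
  sizes <- tabulate(state$deme, D)
  starts <- cumsum(c(0L, sizes[-D]))
  L <- ncol(state$A1)
  lo <- cfg$msat_bounds[1]; hi <- cfg$msat_bounds[2]
  cm <- t(apply(mig, 1, cumsum))
  pmut_tot <- cfg$mtdna_length * cfg$mtdna_mut_rate
  counts <- if (record) array(0L, dim = c(gens, D, D)) else NULL
  for (g in seq_len(gens)) {
    u <- stats::runif(n)
    src <- rowSums(u > cm[state$deme, , drop = FALSE]) + 1L
    if (record) counts[g, , ] <- as.matrix(table(factor(state$deme, 1:D), factor(src, 1:D)))
    p1 <- starts[src] + floor(stats::runif(n) * sizes[src]) + 1L
    p2 <- starts[src] + floor(stats::runif(n) * sizes[src]) + 1L
    pick1 <- matrix(stats::runif(n * L) < 0.5, n, L)
    pick2 <- matrix(stats::runif(n * L) < 0.5, n, L)
    A1 <- ifelse(pick1, state$A1[p1, , drop = FALSE], state$A2[p1, , drop = FALSE])
    A2 <- ifelse(pick2, state$A1[p2, , drop = FALSE], state$A2[p2, , drop = FALSE])
    if (cfg$msat_mut_rate > 0) {
      for (nm in c("A1", "A2")) {
        X <- get(nm)
        mut <- matrix(stats::runif(n * L) < cfg$msat_mut_rate, n, L)
        if (any(mut)) {
          step <- ifelse(stats::runif(sum(mut)) < 0.5, -1L, 1L)
          X[mut] <- X[mut] + step
          X[X < lo] <- 2L * lo - X[X < lo]
          X[X > hi] <- 2L * hi - X[X > hi]
          assign(nm, X)
        }
      }
    }
    hap <- state$hap[p1]  # maternal parent = first uniformly drawn parent
    if (pmut_tot > 0) {
      k <- stats::rbinom(n, cfg$mtdna_length, cfg$mtdna_mut_rate)
      for (i in which(k > 0L)) hap[i] <- reg_add(reg, hap[i], k[i])
    }
    state$A1 <- A1; state$A2 <- A2; state$hap <- hap
  }
  list(state = state, counts = counts)
}

## Ancestral microsatellite pool: per-locus discretized-normal allele
## distributions (a rough stand-in for a stationary stepwise-mutation allele
## frequency profile).
init_msats <- function(n, cfg) {
  L <- cfg$n_msat_loci
  lo <- cfg$msat_bounds[1]; hi <- cfg$msat_bounds[2]
  centers <- sample(seq(lo + 15L, hi - 15L), L, replace = TRUE)
  sds <- stats::runif(L, 2, 5)
  draw <- function() {
    x <- round(matrix(stats::rnorm(n * L, rep(centers, each = n), rep(sds, each = n)), n, L))
    x[x < lo] <- lo; x[x > hi] <- hi
    storage.mode(x) <- "integer"
    x
  }
  list(A1 = draw(), A2 = draw())
}

## ---- study assembly --------------------------------------------------------

#' Simulate a cutoff study (one oxbow plus the two pure populations)
#'
#' Runs the demographic model of the package (see `sim_config`) and emits a
#' `study_dataset` (genotypes + mtDNA + site metadata) together with a
#' `simulation_truth` object: the configuration echo, each sampled
#' individual's true deme and pre-cutoff bank, the per-generation realized
#' immigrant counts among river demes, and the identity of the transferred
#' deme. Identical configurations (including seed) reproduce identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return List with `study` and `truth`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(cfg$seed)
  sim_core(cfg, lat_prefix = cfg$latitude, include_pures = TRUE)
}

## Internal single-oxbow core; assumes RNG already seeded. pools may be
## supplied (shared across latitudes) as a snapshot list.
sim_core <- function(cfg, lat_prefix, include_pures = TRUE, shared = NULL) {
  L <- cfg$demes_per_bank
  reg <- if (is.null(shared)) reg_new(cfg$mtdna_length) else shared$reg

  if (is.null(shared)) {
    npool <- 2L * cfg$pool_size
    ms <- init_msats(npool, cfg)
    pools <- list(A1 = ms$A1, A2 = ms$A2, hap = rep(0L, npool),
                  deme = rep(1:2, each = cfg$pool_size))
    mig2 <- diag(2)
    pools <- wf_generations(pools, mig2, cfg$t_split - cfg$t_local, cfg, reg)$state
    snapshot <- pools
    pools <- wf_generations(pools, mig2, cfg$t_local, cfg, reg)$state
  } else {
    snapshot <- shared$snapshot
    pools <- shared$pools
  }

  ## river neighbourhood: demes 1..L west, L+1..2L east, 2L+1 = loop deme
  D <- 2L * L + 1L
  jmid <- ceiling(L / 2)
  cis_d <- D
  ctrl_d <- jmid
  trans_d <- L + jmid
  nriv <- D * cfg$deme_size
  west_pool <- which(snapshot$deme == 1L)
  east_pool <- which(snapshot$deme == 2L)
  founder_of <- function(d) {
    west <- d <= L || d == cis_d
    if (cfg$null_river_mixing) {
      pick <- stats::runif(cfg$deme_size) < 0.5
      ifelse(pick, sample(west_pool, cfg$deme_size, replace = TRUE),
             sample(east_pool, cfg$deme_size, replace = TRUE))
    } else {
      sample(if (west) west_pool else east_pool, cfg$deme_size, replace = TRUE)
    }
  }
  fid <- unlist(lapply(1:D, founder_of))
  river <- list(A1 = snapshot$A1[fid, , drop = FALSE],
                A2 = snapshot$A2[fid, , drop = FALSE],
                hap = snapshot$hap[fid],
                deme = rep(1:D, each = cfg$deme_size))

  mig_river <- function(loop_attached_to) {
    M <- matrix(0, D, D)
    link <- function(a, b, m) { M[a, b] <<- M[a, b] + m; M[b, a] <<- M[b, a] + m }
    if (cfg$null_river_mixing) {
      # exchangeable null: complete graph with equal weights, so every
      # permutation of river demes is an automorphism and all direction
      # statistics are symmetric by construction
      M[] <- 0.4 / (D - 1)
    } else {
      for (i in seq_len(L - 1)) { link(i, i + 1, cfg$m_along); link(L + i, L + i + 1, cfg$m_along) }
      for (i in seq_len(L)) link(i, L + i, cfg$m_cross)
      if (!is.na(loop_attached_to[1])) {
        for (d in loop_attached_to) link(cis_d, d, cfg$m_loop)
        if (cfg$m_cross > 0) link(cis_d, trans_d, cfg$m_cross)
      }
    }
    diag(M) <- 0
    diag(M) <- 1 - rowSums(M)
    M
  }

  counts <- array(0L, dim = c(cfg$t_local, D, D))
  gen_at <- 0L
  run_epoch <- function(st, M, gens) {
    if (gens == 0L) return(st)
    out <- wf_generations(st, M, gens, cfg, reg, record = TRUE)
    counts[gen_at + seq_len(gens), , ] <<- out$counts
    gen_at <<- gen_at + gens
    out$state
  }
  if (cfg$cutoff && !cfg$null_river_mixing) {
    river <- run_epoch(river, mig_river(ctrl_d), cfg$t_local - cfg$t_cutoff)
    river <- run_epoch(river, mig_river(NA), cfg$t_iso)            # isolation
    river <- run_epoch(river, {M <- mig_river(NA); i <- cis_d; j <- trans_d
                               M[i, j] <- M[j, i] <- cfg$m_along
                               diag(M) <- 0; diag(M) <- 1 - rowSums(M); M},
                       cfg$t_cutoff - cfg$t_iso)
  } else {
    river <- run_epoch(river, mig_river(ctrl_d), cfg$t_local)
  }

  ## sampling
  ss <- cfg$sample_sizes
  roles <- list()
  if (ss["cis"] > 0)     roles[[paste0(lat_prefix, "_cis")]]     <- list(deme = cis_d,  src = "river", role = "cis")
  if (ss["trans"] > 0)   roles[[paste0(lat_prefix, "_trans")]]   <- list(deme = trans_d, src = "river", role = "trans")
  if (ss["control"] > 0) roles[[paste0(lat_prefix, "_control")]] <- list(deme = ctrl_d, src = "river", role = "control")
  if (include_pures && ss["pure"] > 0) {
    roles[["pure_west"]] <- list(deme = 1L, src = "pool", role = "pure")
    roles[["pure_east"]] <- list(deme = 2L, src = "pool", role = "pure")
  }
  ids <- sites <- character(0); a1 <- a2 <- NULL; seqs <- character(0)
  true_deme <- character(0)
  for (nm in names(roles)) {
    r <- roles[[nm]]
    st <- if (r$src == "river") river else pools
    pool_ii <- which(st$deme == r$deme)
    take <- sample(pool_ii, ss[[if (r$role == "pure") "pure" else r$role]])
    id_new <- sprintf("%s-%02d", nm, seq_along(take))
    ids <- c(ids, id_new); sites <- c(sites, rep(nm, length(take)))
    a1 <- rbind(a1, st$A1[take, , drop = FALSE]); a2 <- rbind(a2, st$A2[take, , drop = FALSE])
    seqs <- c(seqs, vapply(st$hap[take], function(h) hap_sequence(reg, h), character(1)))
    true_deme <- c(true_deme, rep(nm, length(take)))
  }
  loci <- sprintf("L%02d", seq_len(cfg$n_msat_loci))
  tab <- genotype_table(ids, sites, a1, a2, loci)
  haps <- haplotype_set(ids, seqs)

  md <- do.call(rbind, lapply(names(roles), function(nm) {
    r <- roles[[nm]]
    bank_cur <- switch(r$role,
      cis = "east", trans = "east", control = "west",
      pure = if (nm == "pure_west") "west" else "east")
    bank_hist <- if (r$role == "cis") "west" else bank_cur
    data.frame(site_id = nm, role = r$role,
               latitude_group = if (r$role == "pure") "none" else lat_prefix,
               bank_current = bank_cur, bank_historical = bank_hist,
               oxbow_id = if (r$role == "pure") NA_character_ else lat_prefix,
               parent_id = NA_character_)
  }))
  study <- structure(list(genotypes = tab, haplotypes = haps,
                          sites = read_site_metadata(md)),
                     class = "study_dataset")
  truth <- structure(list(
    config = cfg,
    individual_id = ids,
    true_deme = true_deme,
    pre_cutoff_bank = ifelse(grepl("_cis$", true_deme) & cfg$cutoff & !cfg$null_river_mixing,
                             "west",
                             ifelse(grepl("_control$|pure_west", true_deme), "west", "east")),
    transferred_deme = if (cfg$cutoff && !cfg$null_river_mixing) paste0(lat_prefix, "_cis") else NA_character_,
    immigrant_counts = counts,
    deme_labels = c(paste0("W", 1:L), paste0("E", 1:L), "loop"),
    river_roles = stats::setNames(c("control", "trans", "cis"),
                                  c(paste0("W", jmid), paste0("E", jmid), "loop"))),
    class = "simulation_truth")
  list(study = study, truth = truth,
       shared = list(reg = reg, snapshot = snapshot, pools = pools))
}

#' Simulate a three-latitude study sharing one deep bank split
#'
#' Runs the bank-divergence phase once, then founds and evolves an
#' independent river neighbourhood per latitude (three oxbows as three
#' replicate local histories), sampling one shared pair of pure sites.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives everything.
#' @param latitudes character vector of latitude labels.
#' @return List with combined `study`, and `truths` (one per latitude).
#' @export
simulate_oxbow_study <- function(cfg, latitudes = c("north", "central", "south")) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(cfg$seed)
  shared <- NULL
  tabs <- list(); hap_ids <- character(0); hap_seq <- character(0)
  mds <- list(); truths <- list()
  for (i in seq_along(latitudes)) {
    lat <- latitudes[i]
    out <- sim_core(cfg, lat_prefix = lat, include_pures = (i == 1L), shared = shared)
    shared <- out$shared
    tabs[[lat]] <- out$study$genotypes
    hap_ids <- c(hap_ids, out$study$haplotypes$individual_id)
    hap_seq <- c(hap_seq, out$study$haplotypes$sequence)
    mds[[lat]] <- out$study$sites
    truths[[lat]] <- out$truth
  }
  tab <- do.call(gt_bind, unname(tabs))
  md <- unique(do.call(rbind, mds))
  study <- structure(list(genotypes = tab,
                          haplotypes = haplotype_set(hap_ids, hap_seq),
                          sites = read_site_metadata(md)),
                     class = "study_dataset")
  validate_study(study)
  list(study = study, truths = truths)
}

#' Realized migration matrix from simulation truth
#'
#' Per-deme-pair realized immigrant fractions over the last `window`
#' generations of the river phase; rows sum to 1 over source demes including
#' self.
#'
#' @param truth a `simulation_truth`.
#' @param window number of generations before present (>= 1, at most the
#'   river phase length).
#' @return Row-stochastic matrix with deme labels.
#' @export
truth_migration_matrix <- function(truth, window) {
  G <- dim(truth$immigrant_counts)[1]
  if (window < 1) stop("empty window")
  if (window > G) stop("window exceeds simulated river generations (", G, ")")
  m <- apply(truth$immigrant_counts[seq(G - window + 1L, G), , , drop = FALSE], c(2, 3), sum)
  m <- m / rowSums(m)
  dimnames(m) <- list(truth$deme_labels, truth$deme_labels)
  m
}

#' Mean expected heterozygosity under pure drift in one isolated deme
#'
#' Utility for checking the drift law: with no mutation, E[H] declines by a
#' factor (1 - 1/(2N)) per generation.
#'
#' @param N diploid deme size.
#' @param generations generations to run.
#' @param n_loci independent loci to average over.
#' @param seed RNG seed.
#' @return Numeric vector of mean expected heterozygosity (1 - sum p^2),
#'   one value per generation.
#' @export
drift_heterozygosity_trace <- function(N, generations, n_loci = 20, seed = 1) {
  local_rng(seed)
  cfg <- sim_config(deme_size = N, n_msat_loci = n_loci, msat_mut_rate = 0,
                    mtdna_mut_rate = 0, mtdna_length = 1, seed = seed)
  ms <- init_msats(N, cfg)
  st <- list(A1 = ms$A1, A2 = ms$A2, hap = rep(0L, N), deme = rep(1L, N))
  reg <- reg_new(1L)
  he <- numeric(generations)
  for (g in seq_len(generations)) {
    st <- wf_generations(st, matrix(1, 1, 1), 1L, cfg, reg)$state
    he[g] <- mean(vapply(seq_len(n_loci), function(l) {
      p <- table(c(st$A1[, l], st$A2[, l]))
      1 - sum((p / sum(p))^2)
    }, numeric(1)))
  }
  he
}

#' Canned simulation fixtures
#'
#' `tiny`: 2 pure sites x 8 individuals x 3 loci for unit tests.
#' `paper_shape`: 15 sampling locations / 13 loci / 260 individuals in
#' cis-trans-control triplets at three latitudes plus two distal pure sites
#' (the geometry of the motivating field study), with member locations that
#' pool to 11 analysis sites.
#' `no_cutoff_null`: the same geometry with no transfer event and an
#' exchangeable river region (the cis/trans/control labels are arbitrary),
#' for false-positive testing.
#'
#' @param name one of `"tiny"`, `"paper_shape"`, `"no_cutoff_null"`.
#' @param seed RNG seed (fixed defaults per fixture).
#' @return List with `study` and `truth` (or `truths` for the multi-latitude
#'   fixtures).
#' @export
make_fixture <- function(name, seed = NULL) {
  opts <- c("tiny", "paper_shape", "no_cutoff_null")
  if (!name %in% opts)
    stop("unknown fixture '", name, "'; options: ", paste(opts, collapse = ", "))
  if (name == "tiny") {
    cfg <- sim_config(deme_size = 12, demes_per_bank = 1, pool_size = 12,
                      t_split = 40, t_local = 10, t_cutoff = 4, t_iso = 2,
                      n_msat_loci = 3, mtdna_length = 120, mtdna_mut_rate = 5e-4,
                      sample_sizes = c(cis = 0, trans = 0, control = 0, pure = 8),
                      seed = if (is.null(seed)) 42 else seed)
    return(simulate_study(cfg))
  }
  null <- name == "no_cutoff_null"
  cfg <- sim_config(cutoff = !null, null_river_mixing = null,
                    seed = if (is.null(seed)) (if (null) 1402 else 1401) else seed)
  sizes <- list(
    north   = c(cis = 30, trans = 22, control = 29),
    central = c(cis = 28, trans = 28, control = 21),
    south   = c(cis = 25, trans = 25, control = 25))
  pures <- c(pure_west = 15, pure_east = 12)
  shared <- NULL
  tabs <- list(); hap_ids <- hap_seq <- character(0); mds <- list(); truths <- list()
  local_rng(cfg$seed)
  for (i in seq_along(sizes)) {
    lat <- names(sizes)[i]
    ci <- cfg
    ci$sample_sizes <- c(sizes[[i]], pure = if (i == 1L) 15 else 0)
    out <- sim_core(ci, lat_prefix = lat, include_pures = (i == 1L), shared = shared)
    shared <- out$shared
    if (i == 1L) {
      # pure_east should have 12 (not 15) individuals: trim deterministically
      keep <- !(out$study$genotypes$site_id == "pure_east" &
                  seq_along(out$study$genotypes$site_id) %in%
                  utils::tail(which(out$study$genotypes$site_id == "pure_east"), 3))
      out$study$genotypes <- gt_subset(out$study$genotypes, keep)
      hkeep <- out$study$haplotypes$individual_id %in% out$study$genotypes$individual_id
      out$study$haplotypes <- haplotype_set(
        out$study$haplotypes$individual_id[hkeep], out$study$haplotypes$sequence[hkeep])
    }
    tabs[[lat]] <- out$study$genotypes
    hap_ids <- c(hap_ids, out$study$haplotypes$individual_id)
    hap_seq <- c(hap_seq, out$study$haplotypes$sequence)
    mds[[lat]] <- out$study$sites
    truths[[lat]] <- out$truth
  }
  tab <- do.call(gt_bind, unname(tabs))
  md <- unique(do.call(rbind, mds))
  split_site <- function(tab, md, site, parts) {
    ii <- which(tab$site_id == site)
    # the first member location keeps the parent id, extra locations pool into it
    sub_ids <- c(site, paste0(site, "_loc", seq_along(parts)[-1]))
    at <- rep(sub_ids, parts)
    tab$site_id[ii] <- at
    row <- md[md$site_id == site, ]
    new <- row[rep(1, length(parts)), ]
    new$site_id <- sub_ids
    new$parent_id <- c(NA_character_, rep(site, length(parts) - 1L))
    md <- rbind(md[md$site_id != site, ], new)
    list(tab = tab, md = md)
  }
  # 15 sampling locations: north cis split 15+15; south sites split 13+12
  for (sp in list(list("north_cis", c(15, 15)), list("south_cis", c(13, 12)),
                  list("south_trans", c(13, 12)), list("south_control", c(13, 12)))) {
    out <- split_site(tab, md, sp[[1]], sp[[2]])
    tab <- out$tab; md <- out$md
  }
  study <- structure(list(genotypes = tab,
                          haplotypes = haplotype_set(hap_ids, hap_seq),
                          sites = read_site_metadata(md)),
                     class = "study_dataset")
  validate_study(study)
  list(study = study, truths = truths)
}
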