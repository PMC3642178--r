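## The seven-prediction scoreboard for cutoff-mediated gene flow, the
## pipeline orchestrator, and a compact per-seed mechanism check used for
## Monte-Carlo calibration.

role_site <- function(md, role, lat = NULL) {
  sel <- md$role == role & is.na(md$parent_id)
  if (!is.null(lat)) sel <- sel & md$latitude_group == lat
  s <- md$site_id[sel]
  if (!length(s)) NA_character_ else s[1]
}

div_lookup <- function(div, a, b, metric) {
  i <- which((div$site_a == a & div$site_b == b) | (div$site_a == b & div$site_b == a))
  if (!length(i)) return(NA_real_)
  div[[metric]][i[1]]
}

#' Score the seven predictions of cutoff-mediated gene flow
#'
#' Evaluates each prediction x marker x latitude cell from upstream results
#' only (the battery never touches raw genotypes): haplogroup site
#' composition, pairwise divergence, admixture ancestry, migration-rate
#' posteriors, private-allele Nm, and the channel-model AIC comparison. A
#' cell whose upstream input is missing is `n/a` with a reason, never an
#' error. Trends score the direction of point estimates; the evidence column
#' retains the numbers so stricter rules can be applied downstream.
#'
#' @param bundle list with elements `sites` (metadata), `latitudes`, and any
#'   of `hap_composition`, `divergence` (per-latitude list of
#'   [divergence_matrix()] frames), `ancestry` (per-latitude list:
#'   `site_mean` west-oriented matrix, optional `select` and
#'   `best_site_mean`), `migration` (per-latitude `migration_estimate`),
#'   `nm` (per-latitude list `control_cis`, `cis_trans`), `channel`
#'   ([compare_channels()] output).
#' @return A `prediction_report` data frame: `prediction`, `marker`,
#'   `latitude`, `trend`, `evidence`.
#' @export
evaluate_predictions <- function(bundle) {
  md <- bundle$sites
  lats <- bundle$latitudes
  cells <- list()
  emit <- function(pred, marker, lat, trend, evidence) {
    cells[[length(cells) + 1L]] <<- data.frame(
      prediction = pred, marker = marker, latitude = lat,
      trend = trend, evidence = evidence)
  }
  na_cell <- function(pred, marker, lat, why) emit(pred, marker, lat, "n/a", why)
  wrong_side <- function(hc, site) {
    i <- which(hc$site_id == site)
    if (!length(i)) return(NA_real_)
    bank <- md$bank_current[md$site_id == site][1]
    if (bank == "west") hc$frac_east[i] else hc$frac_west[i]
  }
  for (lat in lats) {
    cis <- role_site(md, "cis", lat); trn <- role_site(md, "trans", lat)
    ctl <- role_site(md, "control", lat)
    ## P1: cis more similar to control than to trans
    if (!is.null(bundle$hap_composition)) {
      hc <- bundle$hap_composition
      wf <- function(s) { i <- which(hc$site_id == s); if (length(i)) hc$frac_west[i] else NA }
      d_ctl <- abs(wf(cis) - wf(ctl)); d_trn <- abs(wf(cis) - wf(trn))
      emit(1, "mtDNA", lat,
           if (anyNA(c(d_ctl, d_trn))) "n/a" else if (d_ctl < d_trn) "expected" else "unexpected",
           sprintf("|west%%(cis)-west%%(control)|=%.3f vs |west%%(cis)-west%%(trans)|=%.3f", d_ctl, d_trn))
    } else na_cell(1, "mtDNA", lat, "no haplogroup composition")
    if (!is.null(bundle$divergence[[lat]])) {
      dv <- bundle$divergence[[lat]]
      dirs <- vapply(c("d_est", "theta", "gst_h"), function(mt)
        div_lookup(dv, cis, ctl, mt) < div_lookup(dv, cis, trn, mt), logical(1))
      trend <- if (anyNA(dirs)) "n/a" else if (all(dirs)) "expected"
        else if (!any(dirs)) "unexpected" else "ambiguous"
      emit(1, "msats", lat, trend,
           sprintf("D_est %.3f vs %.3f; theta %.3f vs %.3f; G'ST %.3f vs %.3f",
                   div_lookup(dv, cis, ctl, "d_est"), div_lookup(dv, cis, trn, "d_est"),
                   div_lookup(dv, cis, ctl, "theta"), div_lookup(dv, cis, trn, "theta"),
                   div_lookup(dv, cis, ctl, "gst_h"), div_lookup(dv, cis, trn, "gst_h")))
    } else na_cell(1, "msats", lat, "no divergence results")
    ## P2: more wrong-side individuals at cis than control
    if (!is.null(bundle$hap_composition)) {
      a <- wrong_side(bundle$hap_composition, cis); b <- wrong_side(bundle$hap_composition, ctl)
      emit(2, "mtDNA", lat,
           if (anyNA(c(a, b))) "n/a" else if (a > b) "expected" else "unexpected",
           sprintf("wrong-side haplotype fraction cis=%.3f control=%.3f", a, b))
    } else na_cell(2, "mtDNA", lat, "no haplogroup composition")
    anc <- bundle$ancestry[[lat]]
    if (!is.null(anc)) {
      nn <- function(s) {
        q <- anc$site_mean[s, 1]  # column 1 = west-oriented cluster
        bank <- md$bank_current[md$site_id == s][1]
        if (bank == "east") q else 1 - q
      }
      a <- nn(cis); b <- nn(ctl)
      emit(2, "msats", lat, if (a > b) "expected" else "unexpected",
           sprintf("non-native mean ancestry cis=%.3f control=%.3f", a, b))
    } else na_cell(2, "msats", lat, "no ancestry results")
    ## P3/P4: asymmetric immigration
    mg <- bundle$migration[[lat]]
    if (!is.null(mg)) {
      m <- mg$m_mean
      emit(3, "msats", lat,
           if (m[cis, ctl] > m[ctl, cis]) "expected" else "unexpected",
           sprintf("m[cis<-control]=%.3f m[control<-cis]=%.3f", m[cis, ctl], m[ctl, cis]))
      emit(4, "msats", lat,
           if (m[trn, ctl] > m[ctl, trn]) "expected" else "unexpected",
           sprintf("m[trans<-control]=%.3f m[control<-trans]=%.3f", m[trn, ctl], m[ctl, trn]))
    } else { na_cell(3, "msats", lat, "no migration results")
             na_cell(4, "msats", lat, "no migration results") }
    ## P5: Nm higher across the river than along the bank
    nm <- bundle$nm[[lat]]
    if (!is.null(nm) && nm$control_cis$status == "ok" && nm$cis_trans$status == "ok") {
      emit(5, "msats", lat,
           if (nm$control_cis$nm > nm$cis_trans$nm) "expected" else "unexpected",
           sprintf("Nm(control-cis)=%.2f Nm(cis-trans)=%.2f",
                   nm$control_cis$nm, nm$cis_trans$nm))
    } else na_cell(5, "msats", lat, "no private-allele Nm results")
    ## P7: divergence of the cis site is evident
    p7a <- NA; p7b <- NA; ev7 <- character(0)
    if (!is.null(anc) && !is.null(anc$best_site_mean)) {
      bm <- anc$best_site_mean
      own <- vapply(seq_len(ncol(bm)), function(k)
        rownames(bm)[which.max(bm[, k])] == cis && max(bm[, k]) >= 0.5, logical(1))
      p7a <- any(own)
      ev7 <- c(ev7, sprintf("own-cluster at best K: %s", p7a))
    }
    if (!is.null(bundle$divergence[[lat]])) {
      dv <- bundle$divergence[[lat]]
      top <- dv[which.max(dv$d_est), ]
      p7b <- cis %in% c(top$site_a, top$site_b)
      ev7 <- c(ev7, sprintf("highest D_est pair %s-%s (%.3f)", top$site_a, top$site_b, top$d_est))
    }
    if (all(is.na(c(p7a, p7b)))) na_cell(7, "msats", lat, "no clustering or divergence results")
    else emit(7, "msats", lat,
              if (isTRUE(p7a) || isTRUE(p7b)) "expected" else "unexpected",
              paste(ev7, collapse = "; "))
  }
  ## P6: historical channel predicts private alleles better (all latitudes)
  if (!is.null(bundle$channel)) {
    ch <- bundle$channel
    emit(6, "msats+mtDNA", "all",
         if (ch$delta_aic > 0) "expected" else "unexpected",
         sprintf("dAIC(current-historical)=%.2f; OR hist=%.2f cur=%.2f%s",
                 ch$delta_aic, ch$fit_historical$odds_ratio, ch$fit_current$odds_ratio,
                 if (!is.null(ch$msat_only))
                   sprintf("; msat-only dAIC=%.2f", ch$msat_only$delta_aic) else ""))
  } else na_cell(6, "msats+mtDNA", "all", "no channel-model results")
  out <- do.call(rbind, cells)
  out <- out[order(out$prediction, out$marker, out$latitude), ]
  rownames(out) <- NULL
  class(out) <- c("prediction_report", class(out))
  out
}

#' Render a prediction report as a human-readable grid
#'
#' @param report a `prediction_report` from [evaluate_predictions()].
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(report) {
  labels <- c("1 cis closer to control than trans",
              "2 more wrong-side individuals at cis than control",
              "3 immigration higher control->cis than cis->control",
              "4 immigration higher control->trans than trans->control",
              "5 Nm higher control<->cis than cis<->trans",
              "6 historical channel predicts private alleles better",
              "7 divergence of cis sites is evident")
  mark <- function(tr) switch(tr, expected = "Yes", unexpected = "No",
                              ambiguous = "Yes/No", "n/a")
  lines <- sprintf("%-55s %-12s %-8s %-7s", "Prediction", "Marker", "Latitude", "Trend")
  if (nrow(report)) for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf("%-55s %-12s %-8s %-7s",
                              labels[r$prediction], r$marker, r$latitude, mark(r$trend)))
  }
  lines <- c(lines, "", "Evidence:")
  if (nrow(report)) for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf("  P%d %s %s: %s", r$prediction, r$marker, r$latitude, r$evidence))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

## ---- orchestration ---------------------------------------------------------

default_chains <- function() {
  list(admix_sweeps = 800, admix_burnin = 200, k_range = 1:3, k_reps = 3,
       run_kselect = TRUE, mig_samples = 800, mig_burnin = 250, thin = 1)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate/load, summary
#' statistics, haplogroup + admixture assignment, migration estimation, the
#' channel test, and the prediction report — writing tab-delimited artifacts
#' under `out`. Reruns with the same configuration are deterministic. Stage
#' errors are recorded (dependent cells degrade to `n/a`) rather than
#' aborting the run.
#'
#' @param config list or YAML file path. Recognized keys: `seed`, `out`,
#'   `stages` (subset of simulate/stats/assign/migrate/channel/report),
#'   `fixture` (name for [make_fixture()]), `sim` (explicit [sim_config()]
#'   arguments for a three-latitude simulation; overrides `fixture`),
#'   `input` (list with `genotypes`, `fasta`, `metadata` paths for field
#'   data), `chains` (chain-length overrides), `exclude_loci`.
#' @return List: `bundle` (upstream results), `report`
#'   (`prediction_report` or NULL), `dir`, `errors` (named list of stage
#'   error messages).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out %||% file.path("results", "pipeline")
  stages <- config$stages %||% c("simulate", "stats", "assign", "migrate", "channel", "report")
  chains <- utils::modifyList(default_chains(), config$chains %||% list())
  excl <- config$exclude_loci %||% character(0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- list()
  logit <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s (seed=%s, %.1fs elapsed)", stage, sprintf(fmt, ...),
                    seed, as.numeric(Sys.time()) - t0))
  }
  t0 <- as.numeric(Sys.time())
  wtsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  try_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      logit(stage, "ERROR: %s (dependent stages degrade)", conditionMessage(e))
      NULL
    })
  }

  ## ---- data
  study <- NULL; truths <- NULL
  if (!is.null(config$input)) {
    study <- try_stage("load", load_study(config$input$genotypes,
                                          config$input$fasta, config$input$metadata))
    if (!is.null(study)) logit("load", "loaded %d individuals", n_individuals(study$genotypes))
  } else if ("simulate" %in% stages) {
    fx <- try_stage("simulate", {
      if (!is.null(config$sim)) {
        sim_args <- config$sim
        # YAML turns named vectors into lists; flatten them back
        for (v in c("sample_sizes", "msat_bounds"))
          if (!is.null(sim_args[[v]])) sim_args[[v]] <- unlist(sim_args[[v]])
        cfg <- do.call(sim_config, utils::modifyList(sim_args, list(seed = seed)))
        simulate_oxbow_study(cfg)
      } else {
        make_fixture(config$fixture %||% "paper_shape", seed = seed)
      }
    })
    if (!is.null(fx)) {
      study <- fx$study; truths <- fx$truths
      write_study(study, out_dir, "simulated")
      logit("simulate", "simulated %d individuals at %d sites",
            n_individuals(study$genotypes), nrow(study$sites))
      ## pooling mirrors the load path
      study <- load_study(study$genotypes, study$haplotypes, study$sites)
    }
  }
  if (is.null(study)) stop("no study data: simulate failed or no input given")
  if (length(excl))
    study$genotypes <- gt_subset(study$genotypes,
                                 loci = setdiff(study$genotypes$locus_names, excl))
  md <- study$sites
  lats <- setdiff(unique(md$latitude_group), "none")
  bundle <- list(sites = md, latitudes = lats)
  pw <- role_site(md, "pure"); pures <- md$site_id[md$role == "pure"]
  west_pure <- md$site_id[md$role == "pure" & md$bank_current == "west"][1]
  east_pure <- md$site_id[md$role == "pure" & md$bank_current == "east"][1]
  tab <- study$genotypes

  ## ---- stats
  if ("stats" %in% stages) {
    dsum <- try_stage("stats", diversity_summary(study))
    if (!is.null(dsum)) { bundle$diversity <- dsum; wtsv(dsum, "diversity.tsv") }
    dvl <- try_stage("stats", {
      out <- list()
      for (lat in lats) {
        ss <- md$site_id[md$latitude_group == lat]
        out[[lat]] <- divergence_matrix(tab, ss)
      }
      out
    })
    if (!is.null(dvl)) {
      bundle$divergence <- dvl
      wtsv(do.call(rbind, Map(function(d, l) cbind(latitude = l, d), dvl, names(dvl))),
           "divergence.tsv")
      logit("stats", "diversity + divergence done")
    }
  }

  ## ---- assignment
  asg <- NULL
  if ("assign" %in% stages && !is.na(west_pure) && !is.na(east_pure)) {
    hap_ok <- length(study$haplotypes$individual_id) > 0
    if (hap_ok) {
      asg <- try_stage("assign", {
        ids <- function(s) tab$individual_id[tab$site_id == s]
        keep <- function(s) study$haplotypes$individual_id %in% ids(s)
        wr <- study$haplotypes$sequence[keep(west_pure)]
        er <- study$haplotypes$sequence[keep(east_pure)]
        assign_haplogroups(study$haplotypes, wr, er)
      })
      if (!is.null(asg)) {
        bundle$assignments <- asg
        bundle$hap_composition <- haplogroup_site_composition(
          asg, stats::setNames(tab$site_id, tab$individual_id))
        wtsv(asg, "haplogroups.tsv")
        wtsv(bundle$hap_composition, "haplogroup_composition.tsv")
        logit("assign", "haplogroups assigned")
      }
    }
    anc <- try_stage("assign", {
      res <- list()
      for (li in seq_along(lats)) {
        lat <- lats[li]
        ss <- c(md$site_id[md$latitude_group == lat], pures)
        sub <- gt_sites(tab, ss)
        refs <- tab$individual_id[tab$site_id == west_pure]
        run <- admixture_mcmc(sub, K = 2, n_sweeps = chains$admix_sweeps,
                              burnin = chains$admix_burnin,
                              seed = child_seeds(seed, 1, salt = 100 + li), ref_ids = refs)
        entry <- list(site_mean = site_mean_ancestry(run), run = run)
        if (isTRUE(chains$run_kselect)) {
          runs <- list()
          for (K in chains$k_range) for (r in seq_len(chains$k_reps)) {
            runs[[length(runs) + 1L]] <- admixture_mcmc(
              sub, K = K, n_sweeps = chains$admix_sweeps, burnin = chains$admix_burnin,
              seed = child_seeds(seed, 1, salt = 1000 + 100 * li + 10 * K + r),
              ref_ids = refs)
          }
          entry$select <- select_k(runs)
          bk <- entry$select$best_k_delta
          if (is.na(bk)) bk <- entry$select$best_k_likelihood
          best_run <- runs[[which(vapply(runs, `[[`, integer(1), "K") == bk)[1]]]
          entry$best_site_mean <- site_mean_ancestry(best_run)
        }
        res[[lat]] <- entry
      }
      res
    })
    if (!is.null(anc)) {
      bundle$ancestry <- anc
      for (lat in names(anc)) {
        wtsv(data.frame(individual_id = rownames(anc[[lat]]$run$Q),
                        round(anc[[lat]]$run$Q, 4)),
             paste0("ancestry_Q_", lat, ".tsv"))
        if (!is.null(anc[[lat]]$select))
          wtsv(anc[[lat]]$select$table, paste0("kselect_", lat, ".tsv"))
      }
      logit("assign", "admixture clustering done")
    }
  }

  ## ---- migration
  if ("migrate" %in% stages) {
    mig <- try_stage("migrate", {
      res <- list()
      for (li in seq_along(lats)) {
        lat <- lats[li]
        ss <- c(md$site_id[md$latitude_group == lat], pures)
        res[[lat]] <- recent_migration_mcmc(tab, ss, n_samples = chains$mig_samples,
                                            burnin = chains$mig_burnin, thin = chains$thin,
                                            seed = child_seeds(seed, 1, salt = 200 + li))
      }
      res
    })
    if (!is.null(mig)) {
      bundle$migration <- mig
      rows <- list()
      for (lat in names(mig)) {
        m <- mig[[lat]]
        for (r in m$sites) for (s in m$sites) if (r != s)
          rows[[length(rows) + 1L]] <- data.frame(
            latitude = lat, to = r, from = s, mean = m$m_mean[r, s],
            hpdi_low = m$hpdi_low[r, s], hpdi_high = m$hpdi_high[r, s])
      }
      wtsv(do.call(rbind, rows), "migration_rates.tsv")
      logit("migrate", "recent-migration MCMC done")
    }
    nm <- try_stage("migrate", {
      res <- list()
      for (lat in lats) {
        cis <- role_site(md, "cis", lat); trn <- role_site(md, "trans", lat)
        ctl <- role_site(md, "control", lat)
        res[[lat]] <- list(control_cis = private_allele_nm(tab, ctl, cis),
                           cis_trans = private_allele_nm(tab, cis, trn))
      }
      res
    })
    if (!is.null(nm)) {
      bundle$nm <- nm
      wtsv(do.call(rbind, lapply(names(nm), function(lat) data.frame(
        latitude = lat,
        pair = c("control-cis", "cis-trans"),
        nm = c(nm[[lat]]$control_cis$nm, nm[[lat]]$cis_trans$nm),
        p1_bar = c(nm[[lat]]$control_cis$p1_bar, nm[[lat]]$cis_trans$p1_bar)))),
        "nm_private_alleles.tsv")
    }
  }

  ## ---- channel test
  if ("channel" %in% stages && !is.na(west_pure) && !is.na(east_pure)) {
    ch <- try_stage("channel", {
      rec <- filter_diagnostic(find_private_alleles(tab, west_pure, east_pure))
      rec$allele_group <- paste0(rec$locus, ".", rec$allele)
      mt <- if (!is.null(asg)) add_mtdna_pseudoalleles(asg) else NULL
      rows <- build_design(rec, study, mtdna = mt)
      list(records = rec, rows = rows, cmp = compare_channels(rows))
    })
    if (!is.null(ch)) {
      bundle$private_alleles <- ch$records
      bundle$design <- ch$rows
      bundle$channel <- ch$cmp
      wtsv(ch$records, "private_alleles.tsv")
      wtsv(ch$rows, "channel_design.tsv")
      casc <- attr(ch$records, "cascade")
      logit("channel", "cascade %d -> %d -> %d; dAIC=%.2f",
            casc["total"], casc["prevalence"], casc["selected"], ch$cmp$delta_aic)
    }
  }

  ## ---- report
  report <- NULL
  if ("report" %in% stages) {
    report <- try_stage("report", evaluate_predictions(bundle))
    if (!is.null(report)) {
      wtsv(as.data.frame(report), "predictions.tsv")
      writeLines(utils::capture.output(render_report(report)),
                 file.path(out_dir, "prediction_report.txt"))
      logit("report", "prediction battery done")
    }
  }
  list(bundle = bundle, report = report, dir = out_dir, errors = errors,
       truths = truths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compact per-seed mechanism check
#'
#' Simulates one compact three-latitude cutoff study (or its exchangeable
#' no-cutoff null) and evaluates the four core direction tests of the
#' transfer mechanism: P1 (D_est(cis, control) < D_est(cis, trans)) and P2
#' (non-native admixture ancestry cis > control) at `lat`, P3 (the
#' study-level posterior-mean immigration asymmetry control->cis minus
#' cis->control, averaged over the three oxbows, is positive) and P6 (AIC
#' prefers the historical channel) on the whole study. Chain lengths are
#' reduced for Monte-Carlo use.
#'
#' @param seed integer seed for the replicate.
#' @param null simulate the exchangeable no-cutoff null instead.
#' @param lat latitude evaluated for P1-P3.
#' @return Named list: logicals `p1`, `p2`, `p3`, `p6` and the numeric
#'   evidence behind them.
#' @export
mlc_mechanism_check <- function(seed, null = FALSE, lat = "north") {
  cfg <- sim_config(deme_size = 60, pool_size = 60, t_split = 250, t_local = 60,
                    t_cutoff = 15, t_iso = 8, mtdna_mut_rate = 1.2e-4,
                    sample_sizes = c(cis = 15, trans = 15, control = 15, pure = 12),
                    cutoff = !null, null_river_mixing = null, seed = seed)
  sim <- simulate_oxbow_study(cfg)
  study <- sim$study
  tab <- study$genotypes
  md <- study$sites
  cis <- paste0(lat, "_cis"); trn <- paste0(lat, "_trans"); ctl <- paste0(lat, "_control")
  ## P1
  d_ctl <- d_est_jost(tab, cis, ctl)$global
  d_trn <- d_est_jost(tab, cis, trn)$global
  ## P2 (admixture, K = 2, oriented by the west pure site)
  ss <- c(cis, trn, ctl, "pure_west", "pure_east")
  sub <- gt_sites(tab, ss)
  refs <- tab$individual_id[tab$site_id == "pure_west"]
  run <- admixture_mcmc(sub, K = 2, n_sweeps = 500, burnin = 150,
                        seed = child_seeds(seed, 1, salt = 11), ref_ids = refs)
  sm <- site_mean_ancestry(run)
  nn_cis <- sm[cis, 1]        # cis is currently an east-bank site
  nn_ctl <- 1 - sm[ctl, 1]    # control is a west-bank site
  ## P3: study-level asymmetry, averaged over the three oxbows
  lat_margin <- function(l2, salt) {
    s2 <- c(paste0(l2, c("_cis", "_trans", "_control")), "pure_west", "pure_east")
    mm <- recent_migration_mcmc(tab, s2, n_samples = 1000, burnin = 300,
                                seed = child_seeds(seed, 1, salt = salt))$m_mean
    mm[s2[1], s2[3]] - mm[s2[3], s2[1]]
  }
  lats <- setdiff(unique(md$latitude_group), "none")
  margins <- vapply(seq_along(lats), function(i) lat_margin(lats[i], 12 + i), numeric(1))
  mg <- recent_migration_mcmc(tab, ss, n_samples = 1000, burnin = 300,
                              seed = child_seeds(seed, 1, salt = 12))
  ## P6
  rec <- filter_diagnostic(find_private_alleles(tab, "pure_west", "pure_east"))
  refseq <- function(s) {
    ids <- tab$individual_id[tab$site_id == s]
    study$haplotypes$sequence[study$haplotypes$individual_id %in% ids]
  }
  asg <- assign_haplogroups(study$haplotypes, refseq("pure_west"), refseq("pure_east"))
  rows <- build_design(rec, study, mtdna = add_mtdna_pseudoalleles(asg))
  cmp <- compare_channels(rows)
  list(p1 = d_ctl < d_trn,
       p2 = unname(nn_cis > nn_ctl),
       p3 = mean(margins) > 0,
       p6 = cmp$delta_aic > 0,
       d_est_cis_control = d_ctl, d_est_cis_trans = d_trn,
       nonnative_cis = nn_cis, nonnative_control = nn_ctl,
       m_cis_from_control = mg$m_mean[cis, ctl],
       m_control_from_cis = mg$m_mean[ctl, cis],
       m_margins = margins,
       delta_aic = cmp$delta_aic)
}
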