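# The seven-prediction scoreboard and the pipeline orchestrator.

fake_bundle <- function() {
  md <- data.frame(
    site_id = c("north_cis", "north_trans", "north_control", "pure_west", "pure_east"),
    role = c("cis", "trans", "control", "pure", "pure"),
    latitude_group = c("north", "north", "north", "none", "none"),
    bank_current = c("east", "east", "west", "west", "east"),
    bank_historical = c("west", "east", "west", "west", "east"),
    parent_id = NA_character_)
  hc <- data.frame(site_id = md$site_id,
                   frac_west = c(0.9, 0.2, 0.95, 1, 0),
                   frac_east = c(0.1, 0.8, 0.05, 0, 1),
                   frac_unassigned = 0, n = 20)
  dv <- data.frame(site_a = c("north_cis", "north_cis", "north_trans"),
                   site_b = c("north_control", "north_trans", "north_control"),
                   theta = c(0.05, 0.30, 0.28),
                   gst_h = c(0.10, 0.55, 0.50),
                   d_est = c(0.08, 0.45, 0.40),
                   fst_p = NA_real_)
  sm <- matrix(c(0.85, 0.15, 0.1, 0.9, 0.92, 0.08, 0.98, 0.02, 0.03, 0.97),
               ncol = 2, byrow = TRUE,
               dimnames = list(md$site_id, NULL))
  m <- matrix(0.05, 5, 5, dimnames = list(md$site_id, md$site_id))
  diag(m) <- 0.8
  m["north_cis", "north_control"] <- 0.15
  m["north_trans", "north_control"] <- 0.12
  mg <- structure(list(sites = md$site_id, m_mean = m / rowSums(m)),
                  class = "migration_estimate")
  nm_ok <- function(x) structure(list(nm = x, status = "ok"), class = "nm_estimate")
  ch <- list(delta_aic = 5.2,
             fit_historical = list(odds_ratio = 1.3),
             fit_current = list(odds_ratio = 1.4),
             msat_only = list(delta_aic = 0.4))
  list(sites = md, latitudes = "north",
       hap_composition = hc,
       divergence = list(north = dv),
       ancestry = list(north = list(site_mean = sm, best_site_mean = sm)),
       migration = list(north = mg),
       nm = list(north = list(control_cis = nm_ok(3.1), cis_trans = nm_ok(1.2))),
       channel = ch)
}

test_that("a complete bundle fills every applicable cell in the expected direction", {
  rep <- evaluate_predictions(fake_bundle())
  expect_s3_class(rep, "prediction_report")
  expect_false(any(rep$trend == "n/a"))
  # this bundle is constructed to support the transfer hypothesis throughout
  expect_true(all(rep$trend == "expected"))
  expect_equal(sort(unique(rep$prediction)), 1:7)
})

test_that("missing upstream results degrade to n/a cells, never errors", {
  b <- fake_bundle()
  b$migration <- NULL
  b$nm <- NULL
  rep <- evaluate_predictions(b)
  expect_true(all(rep$trend[rep$prediction %in% 3:5] == "n/a"))
  expect_true(all(rep$trend[rep$prediction %in% c(1, 2, 6, 7)] != "n/a"))
  # metric disagreement marks the msat similarity cell ambiguous
  b2 <- fake_bundle()
  b2$divergence$north$theta <- c(0.30, 0.05, 0.28)  # theta disagrees with D_est
  rep2 <- evaluate_predictions(b2)
  expect_equal(rep2$trend[rep2$prediction == 1 & rep2$marker == "msats"], "ambiguous")
})

test_that("the rendered grid agrees with the machine-readable report", {
  rep <- evaluate_predictions(fake_bundle())
  lines <- utils::capture.output(txt <- render_report(rep))
  expect_equal(sum(grepl("Yes", lines)), sum(rep$trend == "expected"))
  expect_equal(length(grep("^  P[0-9]", lines)), nrow(rep))
})

test_that("the pipeline runs end to end and reruns byte-identically", {
  cfgl <- list(
    seed = 11,
    out = file.path(withr::local_tempdir(), "run1"),
    sim = list(deme_size = 40, pool_size = 40, t_split = 150, t_local = 30,
               t_cutoff = 10, t_iso = 5, n_msat_loci = 8, mtdna_length = 300,
               mtdna_mut_rate = 2e-4,
               sample_sizes = c(cis = 10, trans = 10, control = 10, pure = 8)),
    chains = list(admix_sweeps = 200, admix_burnin = 60, run_kselect = FALSE,
                  mig_samples = 200, mig_burnin = 60))
  out1 <- suppressMessages(run_pipeline(cfgl))
  expect_equal(length(out1$errors), 0)
  expect_true(file.exists(file.path(out1$dir, "predictions.tsv")))
  expect_true(file.exists(file.path(out1$dir, "diversity.tsv")))
  # every prediction appears; P7's clustering route is absent without
  # K-selection but the divergence route still scores the cell
  expect_equal(sort(unique(out1$report$prediction)), 1:7)

  cfgl$out <- file.path(withr::local_tempdir(), "run2")
  out2 <- suppressMessages(run_pipeline(cfgl))
  for (f in c("diversity.tsv", "divergence.tsv", "migration_rates.tsv",
              "predictions.tsv")) {
    expect_identical(readLines(file.path(out1$dir, f)),
                     readLines(file.path(out2$dir, f)),
                     info = f)
  }

  # a YAML configuration is accepted
  yml <- file.path(withr::local_tempdir(), "cfg.yaml")
  sim_yaml <- cfgl$sim
  sim_yaml$sample_sizes <- as.list(sim_yaml$sample_sizes)  # YAML map, not sequence
  yaml::write_yaml(list(seed = 11, stages = c("simulate", "stats"),
                        out = file.path(dirname(yml), "run3"),
                        sim = sim_yaml), yml)
  out3 <- suppressMessages(run_pipeline(yml))
  expect_true(file.exists(file.path(out3$dir, "diversity.tsv")))
  # stats-only run: battery cells without upstream results are n/a
  expect_true(all(out3$report$trend[out3$report$prediction %in% 3:5] == "n/a"))
})
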