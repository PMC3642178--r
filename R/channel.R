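## Private-allele channel test: find alleles diagnostic of one river side,
## score sites as native/non-native under the historical vs current river
## channel, fit binomial mixed-logit models (crossed random intercepts for
## latitude and allele group) and compare the two channel hypotheses by AIC.

#' Find alleles private to one of the two pure sites
#'
#' An allele is private when observed in exactly one of the two pure
#' (reference) sites. Records carry the allele's frequency within its pure
#' site of origin and in the whole dataset, plus the two filter flags used to
#' select diagnostic alleles.
#'
#' @param tab a [genotype_table()].
#' @param west_pure,east_pure pure-site ids.
#' @param prevalence_min pure-site frequency threshold (inclusive).
#' @param overall_min whole-dataset frequency threshold (inclusive).
#' @return Data frame ordered by (locus, allele code): `locus`, `allele`,
#'   `origin`, `freq_pure`, `freq_overall`, `passed_prevalence`,
#'   `passed_overall`, `selected` (all FALSE; see [filter_diagnostic()]).
#' @export
find_private_alleles <- function(tab, west_pure, east_pure,
                                 prevalence_min = 0.15, overall_min = 0.10) {
  rows <- list()
  for (l in tab$locus_names) {
    fw <- tryCatch(allele_frequencies(tab, west_pure, l)[[1]], error = function(e) NULL)
    fe <- tryCatch(allele_frequencies(tab, east_pure, l)[[1]], error = function(e) NULL)
    if (is.null(fw) || is.null(fe)) {
      warning("locus ", l, " has no data at a pure site; skipped")
      next
    }
    all_copies <- c(tab$a1[, l], tab$a2[, l])
    all_copies <- all_copies[!is.na(all_copies)]
    ft <- table(all_copies) / length(all_copies)
    rec <- function(al, origin, fp) {
      fo <- as.numeric(ft[as.character(al)])
      if (is.na(fo)) fo <- 0
      data.frame(locus = l, allele = as.integer(al), origin = origin,
                 freq_pure = fp, freq_overall = fo,
                 passed_prevalence = fp >= prevalence_min,
                 passed_overall = fo >= overall_min,
                 selected = FALSE)
    }
    for (al in setdiff(names(fw), names(fe)))
      rows[[length(rows) + 1L]] <- rec(al, "west", unname(fw[al]))
    for (al in setdiff(names(fe), names(fw)))
      rows[[length(rows) + 1L]] <- rec(al, "east", unname(fe[al]))
  }
  if (!length(rows))
    return(data.frame(locus = character(), allele = integer(), origin = character(),
                      freq_pure = numeric(), freq_overall = numeric(),
                      passed_prevalence = logical(), passed_overall = logical(),
                      selected = logical()))
  out <- do.call(rbind, rows)
  out[order(out$locus, out$allele), , drop = FALSE]
}

#' Select the diagnostic private-allele set
#'
#' Applies the pure-site prevalence filter, then the whole-dataset frequency
#' filter (both inclusive), then keeps at most one allele per locus (highest
#' whole-dataset frequency; ties broken by the lower allele code).
#'
#' @param records output of [find_private_alleles()].
#' @param one_per_locus keep only one allele per locus (independent loci).
#' @return `records` with `selected` set; attribute `cascade` holds the
#'   filter-cascade sizes (total, prevalence-passing, selected).
#' @export
filter_diagnostic <- function(records, one_per_locus = TRUE) {
  sel <- records$passed_prevalence & records$passed_overall
  if (one_per_locus && any(sel)) {
    for (l in unique(records$locus[sel])) {
      ii <- which(sel & records$locus == l)
      if (length(ii) > 1) {
        best <- ii[order(-records$freq_overall[ii], records$allele[ii])][1]
        sel[setdiff(ii, best)] <- FALSE
      }
    }
  }
  records$selected <- sel
  attr(records, "cascade") <- c(total = nrow(records),
                                prevalence = sum(records$passed_prevalence),
                                selected = sum(sel))
  records
}

#' Add the mtDNA haplogroups as mirrored private pseudo-alleles
#'
#' Scores the bi-allelic mtDNA marker as two mirrored pseudo-alleles (one
#' private to each side) sharing one allele-group id for random-effect
#' purposes (configurable to two).
#'
#' @param assignments data frame from [assign_haplogroups()].
#' @param shared_group logical: one shared allele group (default) or one per
#'   haplogroup.
#' @return Data frame of pseudo-allele records with `allele_group`, `origin`,
#'   and the assignment table attached as attribute `assignments`.
#' @export
add_mtdna_pseudoalleles <- function(assignments, shared_group = TRUE) {
  assigned <- assignments$haplogroup %in% c("west", "east")
  if (!any(assigned)) stop("all individuals unassigned; no mtDNA pseudo-alleles")
  out <- data.frame(
    locus = "mtDNA",
    allele = c("mtDNA-west", "mtDNA-east"),
    origin = c("west", "east"),
    allele_group = if (shared_group) c("mtDNA", "mtDNA") else c("mtDNA-west", "mtDNA-east"))
  attr(out, "assignments") <- assignments
  out
}

#' Build the channel-test design table
#'
#' One row per site x allele group: `k` individuals possessing >= 1 copy of
#' the allele (haplogroup membership for mtDNA), `n` individuals scored,
#' native flags under the historical and current channel (site bank vs the
#' allele's origin side), and the site's latitude group. Rows with `k = 0`
#' are data and are retained; rows with `n = 0` are dropped.
#'
#' @param records [filter_diagnostic()] output (only `selected` rows are
#'   used).
#' @param study a `study_dataset` (site metadata + genotypes).
#' @param mtdna optional output of [add_mtdna_pseudoalleles()].
#' @param include_pure include the two pure sites as rows (default TRUE).
#' @return Data frame of design rows.
#' @export
build_design <- function(records, study, mtdna = NULL, include_pure = TRUE) {
  sel <- records[records$selected, , drop = FALSE]
  if (!nrow(sel) && is.null(mtdna)) stop("no selected alleles to score")
  md <- study$sites
  if (!include_pure) md <- md[md$role != "pure", , drop = FALSE]
  tab <- study$genotypes
  rows <- list()
  add_row <- function(site, group, locus, allele, origin, k, n) {
    i <- which(md$site_id == site)
    if (n == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      site_id = site, allele_group = group, locus = locus, allele = as.character(allele),
      origin = origin, k = k, n = n,
      native_historical = as.integer(md$bank_historical[i] == origin),
      native_current = as.integer(md$bank_current[i] == origin),
      latitude_group = md$latitude_group[i])
  }
  for (site in md$site_id) {
    ii <- tab$site_id == site
    for (j in seq_len(nrow(sel))) {
      l <- sel$locus[j]; al <- sel$allele[j]
      scored <- ii & !is.na(tab$a1[, l])
      k <- sum((tab$a1[scored, l] == al) | (tab$a2[scored, l] == al))
      add_row(site, paste0(l, ".", al), l, al, sel$origin[j], k, sum(scored))
    }
    if (!is.null(mtdna)) {
      asg <- attr(mtdna, "assignments")
      ids <- tab$individual_id[ii]
      g <- asg$haplogroup[match(ids, asg$individual_id)]
      n_assigned <- sum(g %in% c("west", "east"), na.rm = TRUE)
      for (j in seq_len(nrow(mtdna))) {
        add_row(site, mtdna$allele_group[j], "mtDNA", mtdna$allele[j],
                mtdna$origin[j], sum(g == mtdna$origin[j], na.rm = TRUE), n_assigned)
      }
    }
  }
  do.call(rbind, rows)
}

#' Fit the channel mixed-logit model (one hypothesis)
#'
#' Binomial-logit model of `k` carriers out of `n` scored per design row with
#' the native flag of the chosen channel as the fixed effect and crossed
#' random intercepts for latitude and allele group, fit by maximum
#' likelihood with the Laplace approximation. AIC counts 4 parameters
#' (intercept, slope, two variances). The odds ratio and its standard-error
#' interval come from the native coefficient on the log-odds scale.
#'
#' @param rows design table from [build_design()].
#' @param channel `"historical"` or `"current"`.
#' @param random_effects character vector among `"latitude_group"`,
#'   `"allele_group"`.
#' @return A `channel_model_fit`: coefficients, `odds_ratio` with
#'   `or_low`/`or_high`, `z`, `p`, `aic`, `loglik`, random-intercept
#'   variances, `flags`, and the underlying `lme4` fit.
#' @export
fit_mixed_logit <- function(rows, channel = c("historical", "current"),
                            random_effects = c("latitude_group", "allele_group")) {
  channel <- match.arg(channel)
  rows$native <- if (channel == "historical") rows$native_historical else rows$native_current
  if (length(unique(rows$native)) < 2)
    stop("both predictor levels (native/non-native) must be present")
  for (re in random_effects)
    if (length(unique(rows[[re]])) < 2)
      stop("random effect ", re, " needs >= 2 levels")
  flags <- character(0)
  for (lev in unique(rows$native)) {
    kk <- rows$k[rows$native == lev]; nn <- rows$n[rows$native == lev]
    if (all(kk == 0) || all(kk == nn))
      flags <- c(flags, paste0("separation: native=", lev, " level is all-0 or all-n"))
  }
  form <- stats::as.formula(paste("cbind(k, n - k) ~ native +",
    paste(sprintf("(1 | %s)", random_effects), collapse = " + ")))
  quietly <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {  # e.g. boundary (singular) fit
      flags <<- c(flags, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  fit <- quietly(lme4::glmer(form, data = rows, family = stats::binomial()))
  co <- quietly(summary(fit)$coefficients)
  beta <- co["native", "Estimate"]; se <- co["native", "Std. Error"]
  vc <- lme4::VarCorr(fit)
  vars <- vapply(random_effects, function(re) as.numeric(vc[[re]]), numeric(1))
  structure(list(channel = channel,
                 intercept = co["(Intercept)", "Estimate"],
                 beta = beta, se = se,
                 z = co["native", "z value"], p = co["native", "Pr(>|z|)"],
                 odds_ratio = exp(beta),
                 or_low = exp(beta - se), or_high = exp(beta + se),
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 n_par = attr(stats::logLik(fit), "df"),
                 re_variance = vars,
                 flags = flags, fit = fit),
            class = "channel_model_fit")
}

#' @export
print.channel_model_fit <- function(x, ...) {
  cat(sprintf("channel_model_fit [%s]: OR = %.3f (SE interval %.3f-%.3f), AIC = %.2f\n",
              x$channel, x$odds_ratio, x$or_low, x$or_high, x$aic))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Compare the historical and current channel hypotheses
#'
#' Fits both channel models on the same design rows and reports
#' `delta_aic = AIC(current) - AIC(historical)` (positive favors the
#' historical channel). When mtDNA pseudo-allele rows are present the
#' microsatellite-only branch is fit as well.
#'
#' @param rows design table from [build_design()].
#' @param random_effects passed to [fit_mixed_logit()].
#' @return List: `fit_historical`, `fit_current`, `delta_aic`, `preferred`
#'   (`"historical"`/`"current"`/`"tie"`), and `msat_only` (same structure,
#'   or NULL when no mtDNA rows exist).
#' @export
compare_channels <- function(rows, random_effects = c("latitude_group", "allele_group")) {
  fh <- fit_mixed_logit(rows, "historical", random_effects)
  fc <- fit_mixed_logit(rows, "current", random_effects)
  delta <- fc$aic - fh$aic
  out <- list(fit_historical = fh, fit_current = fc, delta_aic = delta,
              preferred = if (delta > 0) "historical" else if (delta < 0) "current" else "tie",
              msat_only = NULL)
  if (any(rows$locus == "mtDNA")) {
    sub <- rows[rows$locus != "mtDNA", , drop = FALSE]
    if (nrow(sub) && length(unique(sub$allele_group)) >= 2)
      out$msat_only <- compare_channels(sub, random_effects)
  }
  out
}
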