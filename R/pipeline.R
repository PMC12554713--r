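#' Descriptive characteristics of reports for one drug (or all reports)
#'
#' Counts and percentages by sex (Female/Male/Unknown), display age bin
#' (<18, 18-64.9, 65-85, >85, Unknown) and outcome code (CA, DE, DS, HO, LT,
#' OT, RI, Unknown). A case reporting several outcome codes contributes to
#' each listed code; a case with no outcome row counts as outcome Unknown.
#' Sex and age counts each sum to the drug's total.
#'
#' @param cases A `faers_cases` object.
#' @param drug Canonical drug name, or `NULL` for all cases.
#' @return data.frame `drug, dimension, level, n, pct` (pct of the drug's
#'   total report count).
#' @export
pv_descriptives <- function(cases, drug = NULL) {
  ids <- cases$demo$primaryid
  if (!is.null(drug)) {
    ps <- filter_primary_suspect(cases$drugs)
    ids <- intersect(ids, unique(ps$primaryid[!is.na(ps$canonical) &
                                                ps$canonical == drug]))
  }
  d <- cases$demo[cases$demo$primaryid %in% ids]
  total <- nrow(d)
  label <- drug %||% "ALL"

  sex_lv <- c(F = "Female", M = "Male", UNK = "Unknown")
  sex_n <- vapply(names(sex_lv), function(s) sum(d$sex == s), integer(1))

  age_bin <- cut(d$age_years, breaks = c(-Inf, 18, 65, 85, Inf), right = FALSE,
                 labels = c("<18", "18-64.9", "65-85", ">85"))
  age_lv <- c("<18", "18-64.9", "65-85", ">85", "Unknown")
  age_n <- c(vapply(levels(age_bin), function(b)
    sum(!is.na(age_bin) & age_bin == b), integer(1)),
    Unknown = sum(is.na(age_bin)))

  out_lv <- c("CA", "DE", "DS", "HO", "LT", "OT", "RI")
  ou <- cases$outcomes[cases$outcomes$primaryid %in% ids]
  out_n <- vapply(out_lv, function(oc)
    length(unique(ou$primaryid[ou$outc_cod == oc])), integer(1))
  out_n <- c(out_n, Unknown = total - length(unique(ou$primaryid)))

  rows <- rbind(
    data.frame(dimension = "total", level = "Number of Events", n = total),
    data.frame(dimension = "sex", level = unname(sex_lv), n = unname(sex_n)),
    data.frame(dimension = "age", level = age_lv, n = unname(age_n)),
    data.frame(dimension = "outcome", level = c(out_lv, "Unknown"),
               n = unname(out_n)))
  rows$drug <- label
  rows$pct <- if (total > 0) round(100 * rows$n / total, 1) else 0
  rows[, c("drug", "dimension", "level", "n", "pct")]
}

# core signal computation shared by overall and subgroup runs: one row per
# drug, all four statistics within the given case set
signal_table <- function(cases, drugs, events, thresholds, universe,
                         refit_prior = TRUE) {
  cells <- tryCatch(drug_event_cells(cases, universe), error = function(e) NULL)
  prior <- if (refit_prior && !is.null(cells) && nrow(cells) >= 2L)
    mgps_fit_prior(cells$o, cells$e) else mgps_prior()
  rows <- lapply(drugs, function(dg) {
    t <- tryCatch(build_contingency(cases, dg, events, universe),
                  error = function(e) NULL)
    if (is.null(t) || (t$a + t$b) == 0L) {
      return(data.frame(drug = dg, a = if (is.null(t)) 0L else t$a,
                        b = 0L, c = if (is.null(t)) NA_integer_ else t$c,
                        d = if (is.null(t)) NA_integer_ else t$d,
                        expected = NA_real_, ror = NA_real_, ror_lo = NA_real_,
                        ror_hi = NA_real_, prr = NA_real_, chi2 = NA_real_,
                        ic = NA_real_, ic025 = NA_real_, ebgm = NA_real_,
                        ebgm05 = NA_real_, p_raw = NA_real_,
                        ror_pos = NA, prr_pos = NA, ic_pos = NA, ebgm_pos = NA,
                        min_case_ok = FALSE, signal = FALSE, defined = FALSE))
    }
    ror <- ror_stats(t)
    prr <- prr_stats(t)
    ic <- ic_stats(t)
    eb <- ebgm_score(t$a, max(ic$expected, .Machine$double.eps), prior)
    p <- fisher_p(t)
    cls <- classify_signal(ror$ror_lo, prr$prr, prr$chi2, ic$ic025, eb$ebgm05,
                           t$a, thresholds)
    data.frame(drug = dg, a = t$a, b = t$b, c = t$c, d = t$d,
               expected = ic$expected,
               ror = ror$ror, ror_lo = ror$ror_lo, ror_hi = ror$ror_hi,
               prr = prr$prr, chi2 = prr$chi2, ic = ic$ic, ic025 = ic$ic025,
               ebgm = eb$ebgm, ebgm05 = eb$ebgm05, p_raw = p,
               ror_pos = cls$ror_pos, prr_pos = cls$prr_pos,
               ic_pos = cls$ic_pos, ebgm_pos = cls$ebgm_pos,
               min_case_ok = cls$min_case_ok, signal = cls$overall,
               defined = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "prior") <- prior
  out
}

#' Overall disproportionality signal table (one row per drug)
#'
#' For each drug: the 2x2 cells, ROR with 95% CI, PRR with Yates chi-square,
#' shrunken IC with IC025, EBGM with EBGM05 (prior fitted on the full
#' drug x PT grid of the universe), the two-sided Fisher exact p-value, its
#' Bonferroni-adjusted version, and the positivity verdict. Deterministic
#' given inputs and config. Drugs absent from the data yield an `N = 0` row
#' with undefined statistics, flagged via `defined = FALSE`.
#'
#' @param cases A `faers_cases` object.
#' @param drugs Canonical drug names to screen (default: the bundled
#'   vocabulary's 12 drugs).
#' @param events Target event set.
#' @param thresholds Positivity thresholds; `bonferroni_m = "auto"` uses the
#'   number of drugs with a defined p-value in this run.
#' @param universe Background universe, as in [build_contingency()].
#' @return data.frame, one row per drug, with attribute `prior` (the fitted
#'   `mgps_prior`).
#' @export
pv_run_overall <- function(cases, drugs = names(load_drug_vocab()),
                           events = load_target_events(),
                           thresholds = default_thresholds(),
                           universe = "all_ingested") {
  out <- signal_table(cases, drugs, events, thresholds, universe)
  m <- thresholds$bonferroni_m
  m <- if (identical(m, "auto") || is.null(m)) max(1L, sum(!is.na(out$p_raw))) else m
  out$p_adj <- bonferroni(out$p_raw, m)
  out$signal <- out$signal & !is.na(out$p_raw)
  attr(out, "bonferroni_m") <- m
  out
}

#' Subgroup signal tables (drug x stratum)
#'
#' Re-runs the full statistic set within each stratum's case subset: both the
#' 2x2 tables and the MGPS expected counts (and refitted prior) are
#' stratum-internal. Sex strata are F and M; age strata are younger
#' (< 60 years) and older (>= 60 years); cases with unknown sex or age are
#' excluded from the corresponding dimension (but remain in the overall
#' analysis). Strata where a drug has no co-reports keep the row with
#' undefined statistics, mirroring the dashes of published subgroup tables.
#'
#' @inheritParams pv_run_overall
#' @param age_cutoff Years separating younger from older (default 60).
#' @return data.frame with columns `dimension, stratum` prepended to the
#'   overall-table columns.
#' @export
pv_run_subgroups <- function(cases, drugs = names(load_drug_vocab()),
                             events = load_target_events(),
                             thresholds = default_thresholds(),
                             universe = "all_ingested", age_cutoff = 60) {
  d <- cases$demo
  strata <- list(
    sex = list(Female = d$primaryid[d$sex == "F"],
               Male   = d$primaryid[d$sex == "M"]),
    age = list(Younger = d$primaryid[!is.na(d$age_years) & d$age_years < age_cutoff],
               Older   = d$primaryid[!is.na(d$age_years) & d$age_years >= age_cutoff]))
  res <- list()
  for (dim_name in names(strata)) {
    for (st_name in names(strata[[dim_name]])) {
      sub <- subset_cases(cases, strata[[dim_name]][[st_name]])
      tab <- if (nrow(sub$demo) == 0L) {
        # empty stratum: keep the rows, undefined stats (a dash in print)
        data.frame(drug = drugs, a = 0L, b = 0L, c = NA_integer_,
                   d = NA_integer_, expected = NA_real_, ror = NA_real_,
                   ror_lo = NA_real_, ror_hi = NA_real_, prr = NA_real_,
                   chi2 = NA_real_, ic = NA_real_, ic025 = NA_real_,
                   ebgm = NA_real_, ebgm05 = NA_real_, p_raw = NA_real_,
                   ror_pos = NA, prr_pos = NA, ic_pos = NA, ebgm_pos = NA,
                   min_case_ok = FALSE, signal = FALSE, defined = FALSE)
      } else signal_table(sub, drugs, events, thresholds, universe)
      tab$dimension <- dim_name
      tab$stratum <- st_name
      res[[paste(dim_name, st_name)]] <- tab
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  m <- thresholds$bonferroni_m
  m <- if (identical(m, "auto") || is.null(m)) max(1L, sum(!is.na(out$p_raw))) else m
  out$p_adj <- bonferroni(out$p_raw, m)
  out$signal <- out$signal & !is.na(out$p_raw)
  attr(out, "bonferroni_m") <- m
  out[, c("dimension", "stratum", setdiff(names(out), c("dimension", "stratum")))]
}

#' System-organ-class summary of reaction terms per drug
#'
#' Counts reaction PT occurrences (case-PT pairs) of each drug's
#' primary-suspect reports, aggregated by SOC through the hierarchy. Rows are
#' sorted by descending count within drug; the UNMAPPED sentinel, if present,
#' is placed last. SOC counts sum to the drug's total PT occurrences.
#'
#' @param cases A `faers_cases` object.
#' @param drugs Canonical drug names.
#' @param hierarchy An [load_event_hierarchy()] object.
#' @return data.frame `drug, soc, n`.
#' @export
pv_soc_summary <- function(cases, drugs = names(load_drug_vocab()),
                           hierarchy = load_event_hierarchy()) {
  ps <- filter_primary_suspect(cases$drugs)
  ps <- ps[!is.na(ps$canonical) & ps$canonical %in% drugs,
           c("primaryid", "canonical")]
  ps <- unique(data.table::as.data.table(ps))
  re <- data.table::as.data.table(cases$reactions)
  x <- merge(ps, re, by = "primaryid", allow.cartesian = TRUE)
  if (!nrow(x)) {
    return(data.frame(drug = character(), soc = character(), n = integer()))
  }
  x$soc <- map_pt(x$pt, hierarchy)$soc
  agg <- x[, .(n = .N), by = .(drug = canonical, soc)]
  agg <- agg[order(drug, soc == "UNMAPPED", -n, soc)]
  as.data.frame(agg)
}

#' Run the full analysis and write its output files
#'
#' Orchestrates descriptives, the overall signal table, the subgroup tables
#' and the SOC summary, writing `descriptives.csv`, `signals_overall.csv`,
#' `signals_subgroup.csv`, `soc_summary.csv` and `run_report.json` (the run
#' report carries the config hash, universe, thresholds, fitted MGPS prior
#' and ingest counters, so every output is auditable). Outputs contain no
#' timestamps: identical inputs and config give byte-identical files.
#'
#' @param cases A `faers_cases` object.
#' @param out_dir Output directory (created if needed).
#' @param drugs,events,thresholds,universe As in [pv_run_overall()].
#' @param hierarchy SOC hierarchy for the summary.
#' @return Invisibly, a list of the four tables and the run report.
#' @export
pv_analyze <- function(cases, out_dir, drugs = names(load_drug_vocab()),
                       events = load_target_events(),
                       thresholds = default_thresholds(),
                       universe = "all_ingested",
                       hierarchy = load_event_hierarchy()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  desc <- do.call(rbind, c(list(pv_descriptives(cases)),
                           lapply(drugs, pv_descriptives, cases = cases)))
  overall <- pv_run_overall(cases, drugs, events, thresholds, universe)
  subgrp <- pv_run_subgroups(cases, drugs, events, thresholds, universe)
  soc <- pv_soc_summary(cases, drugs, hierarchy)

  config <- list(drugs = drugs, events = events, thresholds = thresholds,
                 universe = universe)
  prior <- attr(overall, "prior")
  report <- list(
    config_hash = config_hash(config),
    universe = universe,
    target_events = events,
    thresholds = thresholds,
    bonferroni_m = attr(overall, "bonferroni_m"),
    mgps_prior = prior[c("w", "alpha1", "beta1", "alpha2", "beta2")],
    mgps_prior_loglik = attr(prior, "loglik"),
    ingest = cases$ingest,
    n_signals = sum(overall$signal, na.rm = TRUE))

  data.table::fwrite(desc, file.path(out_dir, "descriptives.csv"))
  data.table::fwrite(overall, file.path(out_dir, "signals_overall.csv"))
  data.table::fwrite(subgrp, file.path(out_dir, "signals_subgroup.csv"))
  data.table::fwrite(soc, file.path(out_dir, "soc_summary.csv"))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "run_report.json"))
  invisible(list(descriptives = desc, overall = overall, subgroups = subgrp,
                 soc = soc, report = report))
}
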