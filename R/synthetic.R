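#' Specification of a synthetic FAERS-like dataset
#'
#' Fully describes the generative model for a simulated spontaneous-report
#' dataset: drug and event reporting marginals, injected drug-event
#' reporting-rate multipliers (optionally stratum-specific), demographic
#' marginals, duplicate-report rate, and the mandatory seed. Defaults emulate
#' a large antiepileptic-drug pharmacovigilance extract: the 12 study drugs
#' share 40% of reports in proportion to their published report volumes, the
#' remainder goes to a background drug pool; sex, age-bin and outcome
#' marginals follow the descriptive distribution of such extracts (50.0/33.0/
#' 16.9% F/M/unknown; 9.8/38.3/12.4/1.4% in the display age bins among a
#' 61.8% known-age fraction; ~34% of cases without an outcome code).
#'
#' @param n_reports Number of distinct cases to simulate.
#' @param seed Integer seed (mandatory; the generator is deterministic).
#' @param drug_marginals Named probabilities of each named drug being the
#'   primary suspect; the remainder is spread uniformly over
#'   `n_background_drugs` background drugs.
#' @param event_marginals Named per-draw probabilities for specific PTs; the
#'   remainder is spread over the hierarchy's other PTs (weighted by
#'   `background_pt_weights` where named, else uniformly).
#' @param signal_multipliers data.frame with columns `drug, pt, multiplier`
#'   and optional `sex` (`"F"`/`"M"`) and `age_group`
#'   (`"Younger"`/`"Older"`); a multiplier scales P(that PT per draw) for
#'   reports whose PS drug (and stratum, if given) matches, renormalized.
#' @param sex_probs,age_known_probs,age_missing_rate,outcome_probs
#'   Demographic marginals; `outcome_probs` must contain a `NONE` mass for
#'   cases without an outcome row.
#' @param duplicate_rate Probability that a case also emits an earlier-dated
#'   extra report version (same caseid, lower primaryid).
#' @param n_drugs_probs,n_pts_probs Distributions of the number of drug rows
#'   (1-3; the first is PS, the rest concomitant/secondary/interacting) and
#'   of PT draws per report (1-5).
#' @param n_background_drugs Size of the background ("OTHER") drug pool.
#' @param hierarchy Event hierarchy supplying the PT pool.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 20000L,
                             seed,
                             drug_marginals = default_drug_marginals(),
                             event_marginals = c(OSTEOPENIA = 8e-4),
                             signal_multipliers = NULL,
                             sex_probs = c(F = 0.500, M = 0.330, UNK = 0.169),
                             age_known_probs = c("<18" = 0.098, "18-64.9" = 0.383,
                                                 "65-85" = 0.124, ">85" = 0.014),
                             age_missing_rate = 0.382,
                             outcome_probs = c(CA = 0.022, DE = 0.066, DS = 0.016,
                                               HO = 0.198, LT = 0.038, OT = 0.320,
                                               RI = 0.001, NONE = 0.338),
                             duplicate_rate = 0.05,
                             n_drugs_probs = c(0.6, 0.3, 0.1),
                             n_pts_probs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                             n_background_drugs = 20L,
                             hierarchy = load_event_hierarchy()) {
  if (missing(seed) || !is_number(seed)) stop("a numeric seed is mandatory")
  stopifnot(n_reports >= 1, duplicate_rate >= 0, duplicate_rate < 1,
            age_missing_rate >= 0, age_missing_rate < 1)
  if (sum(drug_marginals) > 1 + 1e-9)
    stop("drug_marginals sum to more than 1")
  if (sum(event_marginals) > 1 + 1e-9)
    stop("event_marginals sum to more than 1")
  if (!is.null(signal_multipliers)) {
    signal_multipliers <- as.data.frame(signal_multipliers)
    need <- c("drug", "pt", "multiplier")
    if (!all(need %in% names(signal_multipliers)))
      stop("signal_multipliers needs columns drug, pt, multiplier")
    if (any(signal_multipliers$multiplier < 0))
      stop("multipliers must be >= 0")
    if (!"sex" %in% names(signal_multipliers))
      signal_multipliers$sex <- NA_character_
    if (!"age_group" %in% names(signal_multipliers))
      signal_multipliers$age_group <- NA_character_
  }

  bg_drugs <- sprintf("OTHER DRUG %02d", seq_len(n_background_drugs))
  drug_p <- c(drug_marginals,
              stats::setNames(rep((1 - sum(drug_marginals)) / n_background_drugs,
                                  n_background_drugs), bg_drugs))

  pts <- hierarchy$pt
  named <- intersect(names(event_marginals), pts)
  if (length(named) < length(event_marginals))
    stop("event_marginals name PTs absent from the hierarchy: ",
         paste(setdiff(names(event_marginals), pts), collapse = ", "))
  other <- setdiff(pts, named)
  event_p <- stats::setNames(numeric(length(pts)), pts)
  event_p[named] <- event_marginals[named]
  event_p[other] <- (1 - sum(event_marginals)) * default_background_pt_weights(other)

  structure(list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    drug_probs = drug_p, event_probs = event_p,
    signal_multipliers = signal_multipliers,
    sex_probs = sex_probs / sum(sex_probs),
    age_known_probs = age_known_probs / sum(age_known_probs),
    age_missing_rate = age_missing_rate,
    outcome_probs = outcome_probs / sum(outcome_probs),
    duplicate_rate = duplicate_rate,
    n_drugs_probs = n_drugs_probs / sum(n_drugs_probs),
    n_pts_probs = n_pts_probs / sum(n_pts_probs),
    background_drugs = bg_drugs), class = "synthetic_config")
}

# the 12 study drugs at 40% of all reports, split in proportion to their
# published report volumes in a 2005-2025 antiepileptic extract
default_drug_marginals <- function(study_share = 0.4) {
  counts <- c(CARBAMAZEPINE = 15199, ETHOSUXIMIDE = 478, PHENYTOIN = 7844,
              `VALPROIC ACID` = 8149, GABAPENTIN = 54126, LAMOTRIGINE = 33937,
              LEVETIRACETAM = 47801, OXCARBAZEPINE = 6159, TOPIRAMATE = 17567,
              ZONISAMIDE = 2451, ESLICARBAZEPINE = 59, LACOSAMIDE = 13617)
  study_share * counts / sum(counts)
}

# background PT weights: nervous-system and general-disorder terms dominate
# spontaneous reporting for CNS drugs; everything else uniform
default_background_pt_weights <- function(pts) {
  w <- stats::setNames(rep(1, length(pts)), pts)
  heavy <- c("SEIZURE", "DIZZINESS", "SOMNOLENCE", "HEADACHE", "TREMOR",
             "FATIGUE", "DRUG INEFFECTIVE", "MALAISE")
  w[intersect(heavy, pts)] <- 6
  medium <- c("NAUSEA", "VOMITING", "RASH", "MEMORY IMPAIRMENT", "PYREXIA")
  w[intersect(medium, pts)] <- 3
  w / sum(w)
}

# age group of a numeric age under the analysis cutoff (60y)
age_group_of <- function(age_years, cutoff = 60) {
  ifelse(is.na(age_years), NA_character_,
         ifelse(age_years < cutoff, "Younger", "Older"))
}

# per-draw PT distribution for one (drug, sex, age_group) combination
adjusted_event_probs <- function(config, drug, sex = NA, age_group = NA) {
  p <- config$event_probs
  sm <- config$signal_multipliers
  if (!is.null(sm)) {
    hit <- sm$drug == drug &
      (is.na(sm$sex) | (!is.na(sex) & sm$sex == sex)) &
      (is.na(sm$age_group) | (!is.na(age_group) & sm$age_group == age_group))
    for (i in which(hit)) p[sm$pt[i]] <- p[sm$pt[i]] * sm$multiplier[i]
  }
  p / sum(p)
}

#' Generate a synthetic spontaneous-report dataset in memory
#'
#' Draws `n_reports` cases from the generative model in [synthetic_config()]:
#' each case gets a primary-suspect drug from the drug marginals, sex/age/
#' outcome from the demographic marginals, 1-3 drug rows (one PS), and 1-5 PT
#' draws whose per-draw distribution is the event marginal scaled by any
#' matching injected multipliers and renormalized (reactions are the
#' deduplicated set of draws). With probability `duplicate_rate` a case also
#' emits an earlier-dated report version with a lower primaryid. Byte-stable:
#' the same config always produces the same tables; the caller's RNG state is
#' left untouched.
#'
#' @param config A `synthetic_config`.
#' @return List of raw FAERS-dialect tables `demo, drug, reac, outc`
#'   (data.tables), plus `truth` (the ground-truth bookkeeping: configured
#'   multipliers, per-case PS drug, number of injected duplicates).
#' @export
synthetic_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reports
  caseid <- sprintf("C%08d", seq_len(n))
  primaryid <- as.character(seq_len(n) * 10L + 2L)

  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  age_known <- stats::runif(n) >= config$age_missing_rate
  bin <- sample(names(config$age_known_probs), n, TRUE, config$age_known_probs)
  lo <- c("<18" = 0, "18-64.9" = 18, "65-85" = 65, ">85" = 85)[bin]
  hi <- c("<18" = 18, "18-64.9" = 65, "65-85" = 85, ">85" = 100)[bin]
  age_years <- ifelse(age_known, round(lo + stats::runif(n) * (hi - lo), 1), NA_real_)

  dates <- seq(as.Date("2005-01-01"), as.Date("2025-03-31"), by = "day")
  date_idx <- sample(length(dates), n, TRUE)
  fda_dt <- as.integer(format(dates[date_idx], "%Y%m%d"))
  quarter <- paste0(format(dates[date_idx], "%Y"), "Q",
                    (as.integer(format(dates[date_idx], "%m")) - 1L) %/% 3L + 1L)

  drug_pool <- names(config$drug_probs)
  ps_drug <- sample(drug_pool, n, TRUE, config$drug_probs)

  # PT draws: group reports sharing the same per-draw distribution
  k <- sample(seq_along(config$n_pts_probs), n, TRUE, config$n_pts_probs)
  ag <- age_group_of(age_years)
  sm <- config$signal_multipliers
  mod_drugs <- if (is.null(sm)) character() else unique(sm$drug)
  grp <- ifelse(ps_drug %in% mod_drugs,
                paste(ps_drug, sex, ifelse(is.na(ag), "UNK", ag), sep = "\r"),
                "\rBASE")
  pts <- names(config$event_probs)
  reac_pid <- vector("list", length(unique(grp)))
  reac_pt <- vector("list", length(unique(grp)))
  gi <- 0L
  for (g in sort(unique(grp))) {
    gi <- gi + 1L
    idx <- which(grp == g)
    pvec <- if (g == "\rBASE") config$event_probs / sum(config$event_probs) else {
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      adjusted_event_probs(config, parts[1],
                           sex = parts[2],
                           age_group = if (parts[3] == "UNK") NA else parts[3])
    }
    draws <- sample(pts, sum(k[idx]), TRUE, pvec)
    owner <- rep(idx, k[idx])
    keep <- !duplicated(paste0(owner, "\r", draws))
    reac_pid[[gi]] <- primaryid[owner[keep]]
    reac_pt[[gi]] <- draws[keep]
  }
  reac <- data.table::data.table(primaryid = unlist(reac_pid),
                                 pt = unlist(reac_pt))
  data.table::setorder(reac, primaryid, pt)

  # drug rows: PS first, then concomitant/secondary/interacting extras
  n_drugs <- sample(seq_along(config$n_drugs_probs), n, TRUE, config$n_drugs_probs)
  n_extra <- n_drugs - 1L
  extra_owner <- rep(seq_len(n), n_extra)
  extra_name <- sample(drug_pool, length(extra_owner), TRUE, config$drug_probs)
  extra_role <- sample(c("C", "SS", "I"), length(extra_owner), TRUE,
                       c(0.6, 0.3, 0.1))
  drug <- data.table::data.table(
    primaryid = c(primaryid, primaryid[extra_owner]),
    drug_seq = c(rep(1L, n), unlist(lapply(n_extra[n_extra > 0L], seq_len)) + 1L),
    drugname = c(ps_drug, extra_name),
    prod_ai = c(ps_drug, extra_name),
    role_cod = c(rep("PS", n), extra_role))
  data.table::setorder(drug, primaryid, drug_seq)

  outc_draw <- sample(names(config$outcome_probs), n, TRUE, config$outcome_probs)
  has_outc <- outc_draw != "NONE"
  outc <- data.table::data.table(primaryid = primaryid[has_outc],
                                 outc_cod = outc_draw[has_outc])
  data.table::setorder(outc, primaryid, outc_cod)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt, sex = sex,
    age = ifelse(is.na(age_years), "", format(age_years, trim = TRUE)),
    age_cod = ifelse(is.na(age_years), "", "YR"),
    reporting_quarter = quarter)

  # duplicate case versions: same caseid, earlier date, lower primaryid
  is_dup <- stats::runif(n) < config$duplicate_rate
  if (any(is_dup)) {
    di <- which(is_dup)
    dup_demo <- demo[di]
    dup_demo[, primaryid := as.character(di * 10L + 1L)]
    back <- sample(30:400, length(di), TRUE)
    dup_demo[, fda_dt := as.integer(format(
      pmax(dates[pmax(date_idx[di] - back, 1L)], dates[1L]), "%Y%m%d"))]
    remap <- stats::setNames(dup_demo$primaryid, primaryid[di])
    dup_child <- function(x) {
      y <- x[x$primaryid %in% names(remap)]
      y[, primaryid := unname(remap[primaryid])]
      y
    }
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, dup_child(drug))
    reac <- rbind(reac, dup_child(reac))
    outc <- rbind(outc, dup_child(outc))
    data.table::setorder(demo, caseid, primaryid)
    data.table::setorder(drug, primaryid, drug_seq)
    data.table::setorder(reac, primaryid, pt)
    data.table::setorder(outc, primaryid, outc_cod)
  }

  truth <- list(
    signal_multipliers = config$signal_multipliers,
    ps_drug = stats::setNames(ps_drug, primaryid),
    n_cases = n,
    n_duplicates = sum(is_dup),
    seed = config$seed)
  list(demo = demo, drug = drug, reac = reac, outc = outc, truth = truth)
}

#' Write a synthetic dataset as FAERS-format quarterly files
#'
#' Materializes [synthetic_reports()] as `$`-delimited DEMO.txt, DRUG.txt,
#' REAC.txt and OUTC.txt in the exact dialect [read_faers_table()] reads,
#' plus `ground_truth.json` recording the injected multipliers and duplicate
#' bookkeeping. Identical config (including seed) produces byte-identical
#' files.
#'
#' @param config A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; the generated tables as attribute `reports`.
#' @export
generate_faers <- function(config, dir) {
  sim <- synthetic_reports(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, file) data.table::fwrite(
    x, file.path(dir, file), sep = "$", quote = FALSE, eol = "\n")
  wr(sim$demo, "DEMO.txt")
  wr(sim$drug, "DRUG.txt")
  wr(sim$reac, "REAC.txt")
  wr(sim$outc, "OUTC.txt")
  truth <- sim$truth
  truth$ps_drug <- NULL   # per-case assignment stays in-memory; file stays small
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", dataframe = "rows"),
             file.path(dir, "ground_truth.json"))
  invisible(structure(dir, reports = sim))
}

#' Link a synthetic dataset straight into a `faers_cases` object
#'
#' Convenience path for simulation studies: applies the same deduplication
#' and linking as file-based ingestion without the file round-trip.
#'
#' @param config A `synthetic_config`.
#' @param vocab Drug dictionary used for normalization.
#' @return A `faers_cases` object (with `ingest$duplicates_removed`).
#' @export
synthetic_cases <- function(config, vocab = load_drug_vocab()) {
  sim <- synthetic_reports(config)
  demo <- deduplicate_demo(sim$demo)
  demo[, age_years := convert_age(age, age_cod)]
  cases <- link_cases(demo, sim$drug, sim$reac, sim$outc, vocab = vocab)
  cases$ingest$duplicates_removed <- attr(demo, "n_removed")
  cases$ingest$n_demo_rows_raw <- nrow(sim$demo)
  cases
}

#' Expected 2x2 cell proportions implied by a synthetic config
#'
#' Closed-form expectation of the contingency table for one drug against a
#' target event set under the generative model (before duplicate injection,
#' which deduplication removes again): a report's probability of containing a
#' target PT is 1 - E_K[(1 - q)^K] where q is the per-draw target mass of its
#' PS drug's (stratum-averaged) adjusted event distribution. Used as the
#' ground-truth oracle in calibration tests.
#'
#' @param config A `synthetic_config`.
#' @param drug Drug label (canonical or background name).
#' @param events Target event set (list with `pts`, or character vector).
#' @return List with `props` (expected a,b,c,d proportions summing to 1),
#'   `ror` and `prr` (the values implied by those proportions).
#' @export
expected_table <- function(config, drug, events) {
  pts <- if (is.list(events)) events$pts else toupper(trimws(events))
  kp <- config$n_pts_probs
  # stratum weights: sex x age-group (incl. unknown age via missing rate)
  p_young_known <- unname(config$age_known_probs["<18"] +
                            config$age_known_probs["18-64.9"] * (60 - 18) / (65 - 18))
  age_w <- c(Younger = (1 - config$age_missing_rate) * p_young_known,
             Older = (1 - config$age_missing_rate) * (1 - p_young_known),
             UNK = config$age_missing_rate)
  p_event_report <- function(d) {
    tot <- 0
    for (sx in names(config$sex_probs)) {
      for (agn in names(age_w)) {
        pvec <- adjusted_event_probs(config, d, sex = sx,
                                     age_group = if (agn == "UNK") NA else agn)
        q <- sum(pvec[pts], na.rm = TRUE)
        pe <- sum(kp * (1 - (1 - q)^seq_along(kp)))
        tot <- tot + config$sex_probs[[sx]] * age_w[[agn]] * pe
      }
    }
    tot
  }
  pd <- config$drug_probs
  pe <- vapply(names(pd), p_event_report, numeric(1))
  a <- pd[[drug]] * pe[[drug]]
  b <- pd[[drug]] * (1 - pe[[drug]])
  cc <- sum(pd[names(pd) != drug] * pe[names(pd) != drug])
  dd <- 1 - a - b - cc
  props <- c(a = unname(a), b = unname(b), c = unname(cc), d = unname(dd))
  list(props = props,
       ror = (a * dd) / (b * cc),
       prr = (a / (a + b)) / (cc / (cc + dd)))
}
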