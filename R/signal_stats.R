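#' Construct a 2x2 drug-event contingency table
#'
#' Cell layout for one drug-event pair within one analysis universe:
#' `a` = reports with the target drug and the target event, `b` = target drug
#' & other events, `c` = other drugs & target event, `d` = neither.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class `contingency_table`: list `a,b,c,d,n`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  structure(as.list(c(cells, n = sum(cells))), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one drug against a target event set
#'
#' A case counts in the "target drug" row iff the drug is among its
#' primary-suspect drugs after name normalization, and in the "target event"
#' column iff any of its reaction PTs belongs to the target set. Each case is
#' counted once per table (set semantics, so a drug listed twice as PS still
#' counts once).
#'
#' @param cases A `faers_cases` object (deduplicated and normalized).
#' @param drug Canonical drug name.
#' @param events Target event set (from [load_target_events()], or a
#'   character vector of PTs).
#' @param universe `"all_ingested"` (all loaded cases form the background) or
#'   `"study_drugs_only"` (only cases whose PS drugs include a vocabulary
#'   drug).
#' @return A `contingency_table`.
#' @export
build_contingency <- function(cases, drug, events,
                              universe = c("all_ingested", "study_drugs_only")) {
  universe <- match.arg(universe)
  pts <- if (is.list(events)) events$pts else toupper(trimws(events))
  ps <- filter_primary_suspect(cases$drugs)
  uni_ids <- if (universe == "all_ingested") cases$demo$primaryid else
    intersect(cases$demo$primaryid, unique(ps$primaryid[!is.na(ps$canonical)]))
  if (!length(uni_ids)) stop("empty analysis universe")
  drug_ids <- unique(ps$primaryid[!is.na(ps$canonical) & ps$canonical == drug])
  event_ids <- unique(cases$reactions$primaryid[cases$reactions$pt %in% pts])
  in_drug <- uni_ids %in% drug_ids
  in_event <- uni_ids %in% event_ids
  contingency_table(a = sum(in_drug & in_event),
                    b = sum(in_drug & !in_event),
                    c = sum(!in_drug & in_event),
                    d = sum(!in_drug & !in_event))
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); the interval is exp(ln ROR +/- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d)). When any cell is zero, 0.5 is added to all four cells for
#' this computation (Haldane-Anscombe correction), so the estimate is always
#' finite.
#'
#' @param t A `contingency_table`.
#' @return List `ror, ror_lo, ror_hi`.
#' @export
ror_stats <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) cells <- cells + 0.5
  ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = ror,
       ror_lo = exp(log(ror) - 1.96 * se),
       ror_hi = exp(log(ror) + 1.96 * se))
}

#' Proportional reporting ratio with Yates-corrected chi-square
#'
#' PRR = (a/(a+b)) / (c/(c+d)); the companion statistic is the
#' continuity-corrected chi-square n(|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d)),
#' floored at 0 when |ad - bc| <= n/2. A zero margin makes both undefined
#' (`NA`), flagged via attribute `undefined`; undefined results are never
#' called positive.
#'
#' @param t A `contingency_table`.
#' @return List `prr, chi2` (NA when undefined).
#' @export
prr_stats <- function(t) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    out <- list(prr = NA_real_, chi2 = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  chi2 <- if (dev <= n / 2) 0 else n * (dev - n / 2)^2 / prod(margins)
  list(prr = prr, chi2 = chi2)
}

#' Information component with shrinkage (BCPNN)
#'
#' IC = log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/n the expected count
#' under row-column independence. The lower credibility bound uses the
#' standard approximation IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2).
#'
#' @param t A `contingency_table`.
#' @return List `ic, ic025, expected`.
#' @export
ic_stats <- function(t) {
  if (t$n == 0) stop("ic_stats requires a non-empty table")
  e <- (t$a + t$b) * (t$a + t$c) / t$n
  ic <- log2((t$a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2 * (t$a + 0.5)^(-1.5)
  list(ic = ic, ic025 = ic025, expected = e)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' @param t A `contingency_table`.
#' @return The two-sided exact probability of independence.
#' @export
fisher_p <- function(t) {
  m <- matrix(c(t$a, t$c, t$b, t$d), 2L, 2L)
  stats::fisher.test(m)$p.value
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving. `m` must be at least the number
#' of p-values supplied.
#'
#' @param p Vector of raw p-values.
#' @param m Family size (number of hypotheses).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, m >= sum(!is.na(p)))
  pmin(1, m * p)
}

#' Default signal-positivity thresholds
#'
#' @param path Optional YAML file overriding the bundled defaults.
#' @return Named list of thresholds (see the bundled `thresholds.yaml`).
#' @export
default_thresholds <- function(path = system.file("extdata", "thresholds.yaml",
                                                  package = "pvsignal")) {
  yaml::read_yaml(path)
}

#' Apply the positivity rule to one drug-event pair
#'
#' Method criteria (defaults): ROR CI lower bound > 1; PRR >= 2 with
#' chi-square >= 4; IC025 > 0; EBGM05 > 2. A pair needs at least
#' `min_cases` co-reports before any call. Under the `"any"` rule (the
#' default) a pair is a signal when any method fires; `"all"` requires all
#' four. Undefined statistics (NA) count as negative.
#'
#' @param ror_lo,prr,chi2,ic025,ebgm05 Statistics for the pair.
#' @param a Co-report count (cell a).
#' @param thresholds Threshold list ([default_thresholds()]).
#' @return List of logicals `ror_pos, prr_pos, ic_pos, ebgm_pos, min_case_ok,
#'   overall`.
#' @export
classify_signal <- function(ror_lo, prr, chi2, ic025, ebgm05, a,
                            thresholds = default_thresholds()) {
  th <- thresholds
  pos <- function(x) !is.na(x) & x
  ror_pos  <- pos(ror_lo > th$ror_lo_gt)
  prr_pos  <- pos(prr >= th$prr_ge & chi2 >= th$chi2_ge)
  ic_pos   <- pos(ic025 > th$ic025_gt)
  ebgm_pos <- pos(ebgm05 > th$ebgm05_gt)
  min_case_ok <- !is.na(a) & a >= th$min_cases
  rule <- th$rule %||% "any"
  fired <- if (identical(rule, "all"))
    ror_pos & prr_pos & ic_pos & ebgm_pos
  else ror_pos | prr_pos | ic_pos | ebgm_pos
  list(ror_pos = ror_pos, prr_pos = prr_pos, ic_pos = ic_pos,
       ebgm_pos = ebgm_pos, min_case_ok = min_case_ok,
       overall = min_case_ok & fired)
}
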