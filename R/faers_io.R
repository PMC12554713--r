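#' Read one FAERS-format quarterly table
#'
#' FAERS quarterly ASCII files are `$`-delimited text with a header row and no
#' quoting. Column names are matched case-insensitively. Rows with an empty
#' report key (`primaryid`) are counted as malformed and dropped; the read
#' fails hard if the malformed fraction exceeds `max_error_rate`. Files are
#' read as UTF-8 with a Latin-1 fallback.
#'
#' @param path File path.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"indi"`,
#'   `"ther"`; selects required columns and field normalization.
#' @param max_error_rate Malformed-line fraction above which reading aborts.
#' @return A data.table of raw records, with attributes `n_malformed` and
#'   `warnings` (character vector of per-file issues, e.g. invalid dates).
#' @export
read_faers_table <- function(path, kind = c("demo", "drug", "reac", "outc",
                                            "indi", "ther"),
                             max_error_rate = 0.05) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FAERS file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "$", quote = "", header = TRUE,
                      colClasses = "character", encoding = "UTF-8",
                      fill = TRUE, showProgress = FALSE),
    error = function(e)
      data.table::fread(path, sep = "$", quote = "", header = TRUE,
                        colClasses = "character", encoding = "Latin-1",
                        fill = TRUE, showProgress = FALSE)
  )
  data.table::setnames(dt, tolower(names(dt)))

  required <- switch(kind,
    demo = c("primaryid", "caseid", "fda_dt"),
    drug = c("primaryid", "drugname", "role_cod"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    indi = "primaryid",
    ther = "primaryid")
  # older FAERS layouts: gndr_cod instead of sex
  if (kind == "demo" && !"sex" %in% names(dt) && "gndr_cod" %in% names(dt))
    data.table::setnames(dt, "gndr_cod", "sex")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("FAERS ", toupper(kind), " file ", path,
         " is missing required column(s): ", paste(miss, collapse = ", "))
  }

  warnings <- character()
  bad <- is.na(dt$primaryid) | !nzchar(trimws(dt$primaryid))
  n_malformed <- sum(bad)
  if (nrow(dt) > 0L && n_malformed / nrow(dt) > max_error_rate) {
    stop("FAERS ", toupper(kind), " file ", path, ": ", n_malformed, "/",
         nrow(dt), " malformed lines exceeds max_error_rate = ", max_error_rate)
  }
  if (n_malformed > 0L) {
    warnings <- c(warnings, sprintf("%d malformed line(s) dropped", n_malformed))
    dt <- dt[!bad]
  }
  dt[, primaryid := trimws(primaryid)]

  if (kind == "demo") {
    dt[, caseid := trimws(caseid)]
    d <- parse_fda_dt(dt$fda_dt)
    n_bad_dt <- sum(!is.na(dt$fda_dt) & nzchar(trimws(dt$fda_dt)) & is.na(d))
    if (n_bad_dt > 0L)
      warnings <- c(warnings,
                    sprintf("%d invalid fda_dt value(s) flagged missing", n_bad_dt))
    dt[, fda_dt := d]
    if ("sex" %in% names(dt)) {
      dt[, sex := toupper(trimws(sex))]
      dt[!sex %in% c("F", "M"), sex := "UNK"]
    } else dt[, sex := "UNK"]
    if ("age_cod" %in% names(dt)) dt[, age_cod := toupper(trimws(age_cod))]
  }
  if (kind == "drug") {
    dt[, role_cod := toupper(trimws(role_cod))]
    n_bad_role <- sum(!dt$role_cod %in% c("PS", "SS", "C", "I"))
    if (n_bad_role > 0L) {
      warnings <- c(warnings,
                    sprintf("%d drug row(s) with unknown role_cod flagged UNK", n_bad_role))
      dt[!role_cod %in% c("PS", "SS", "C", "I"), role_cod := "UNK"]
    }
  }
  if (kind == "reac") {
    dt[, pt := toupper(trimws(pt))]
    dt <- dt[nzchar(pt)]
  }
  if (kind == "outc") dt[, outc_cod := toupper(trimws(outc_cod))]

  data.table::setattr(dt, "n_malformed", n_malformed)
  data.table::setattr(dt, "warnings", warnings)
  dt
}

# YYYYMMDD integer-style strings -> integer; invalid calendar dates -> NA
parse_fda_dt <- function(x) {
  s <- trimws(as.character(x))
  ok <- grepl("^[0-9]{8}$", s)
  d <- rep(NA_integer_, length(s))
  if (any(ok)) {
    parsed <- as.Date(s[ok], format = "%Y%m%d")
    d[ok] <- ifelse(is.na(parsed), NA_integer_, as.integer(s[ok]))
  }
  d
}

#' Convert reported ages to years
#'
#' FAERS reports age together with a unit code. Decades are multiplied by 10,
#' months divided by 12, weeks by the mean Gregorian weeks per year
#' (52.1775), days by 365.25, hours by 8766. An age with a missing or
#' unrecognized unit code is conservatively treated as missing rather than
#' assumed to be years; negative ages become missing.
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Character vector of unit codes
#'   (`DEC`, `YR`, `MON`, `WK`, `DY`, `HR`).
#' @return Numeric vector of ages in years (`NA` where not convertible).
#' @export
convert_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[toupper(trimws(as.character(age_cod)))]
  out <- age * unname(f)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

#' Deduplicate case versions
#'
#' A FAERS case (CASEID) can appear as several report versions (PRIMARYID).
#' Within each case the record with the latest FDA receipt date (`fda_dt`)
#' survives; ties are broken by the higher PRIMARYID (numeric comparison when
#' all ids in the tie are numeric, lexicographic otherwise). Records with a
#' missing `fda_dt` sort below any dated record. Output is sorted by caseid;
#' the operation is idempotent.
#'
#' @param demo data.table/data.frame of demographic records with columns
#'   `primaryid`, `caseid`, `fda_dt` (integer YYYYMMDD or NA).
#' @return One surviving record per caseid, with attribute `n_removed`.
#' @export
deduplicate_demo <- function(demo) {
  dt <- data.table::as.data.table(demo)
  if (!nrow(dt)) {
    data.table::setattr(dt, "n_removed", 0L)
    return(dt)
  }
  pid_num <- suppressWarnings(as.numeric(dt$primaryid))
  # rank primaryid: numeric value when parseable, else lexicographic rank
  # placed after all numeric ids (FAERS ids are numeric in practice)
  lex <- rank(dt$primaryid, ties.method = "min")
  pid_rank <- ifelse(is.na(pid_num), max(pid_num, 0, na.rm = TRUE) + lex, pid_num)
  ord <- order(dt$caseid,
               ifelse(is.na(dt$fda_dt), -Inf, dt$fda_dt),
               pid_rank)
  dt <- dt[ord]
  keep <- !duplicated(dt$caseid, fromLast = TRUE)   # last = max date, max pid
  out <- dt[keep]
  data.table::setorder(out, caseid)
  data.table::setattr(out, "n_removed", sum(!keep))
  out[]
}

#' Link deduplicated demographics with drug, reaction and outcome tables
#'
#' Joins child tables to the surviving report versions by `primaryid`. Child
#' rows referencing an eliminated or unknown report version are dropped and
#' counted. Reaction PTs are uppercased, trimmed, and deduplicated per case
#' (set semantics); drug names are normalized against the vocabulary. Cases
#' with zero reactions are retained but flagged.
#'
#' @param demo Deduplicated demographics ([deduplicate_demo()]).
#' @param drugs,reactions,outcomes Raw child tables ([read_faers_table()]).
#' @param vocab Drug dictionary for name normalization.
#' @return An object of class `faers_cases`: list of data.tables `demo`
#'   (with `age_years`, `has_reactions`), `drugs` (with `canonical`),
#'   `reactions`, `outcomes`, plus an `ingest` report list.
#' @export
link_cases <- function(demo, drugs, reactions, outcomes = NULL,
                       vocab = load_drug_vocab()) {
  demo <- data.table::as.data.table(demo)
  keep_ids <- demo$primaryid

  take <- function(x, cols) {
    x <- data.table::as.data.table(x)
    orphan <- !x$primaryid %in% keep_ids
    list(kept = x[!orphan, intersect(cols, names(x)), with = FALSE],
         n_orphan = sum(orphan))
  }
  dr <- take(drugs, c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"))
  re <- take(reactions, c("primaryid", "pt"))
  ou <- if (is.null(outcomes)) {
    list(kept = data.table::data.table(primaryid = character(),
                                       outc_cod = character()), n_orphan = 0L)
  } else take(outcomes, c("primaryid", "outc_cod"))

  re$kept[, pt := toupper(trimws(pt))]
  re$kept <- unique(re$kept[nzchar(pt)], by = c("primaryid", "pt"))
  ou$kept <- unique(ou$kept, by = c("primaryid", "outc_cod"))
  dr$kept[, canonical := normalize_drug(drugname, vocab)]
  if ("prod_ai" %in% names(dr$kept)) {
    # fall back to the active-ingredient field when the verbatim name misses
    miss <- is.na(dr$kept$canonical) & !is.na(dr$kept$prod_ai)
    if (any(miss))
      dr$kept[miss, canonical := normalize_drug(prod_ai, vocab)]
  }

  if (!"age_years" %in% names(demo)) {
    demo[, age_years := if (all(c("age", "age_cod") %in% names(demo)))
      convert_age(age, age_cod) else NA_real_]
  }
  if (!"sex" %in% names(demo)) demo[, sex := "UNK"]
  demo[, has_reactions := primaryid %in% re$kept$primaryid]

  structure(
    list(demo = demo, drugs = dr$kept, reactions = re$kept, outcomes = ou$kept,
         ingest = list(
           n_cases = nrow(demo),
           n_drug_rows = nrow(dr$kept),
           n_reaction_rows = nrow(re$kept),
           n_outcome_rows = nrow(ou$kept),
           orphans_dropped = c(drug = dr$n_orphan, reac = re$n_orphan,
                               outc = ou$n_orphan),
           n_cases_without_reactions = sum(!demo$has_reactions),
           n_unmatched_drug_rows = sum(is.na(dr$kept$canonical)))),
    class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " cases, ", nrow(x$drugs),
      " drug rows, ", nrow(x$reactions), " reaction rows, ",
      nrow(x$outcomes), " outcome rows\n", sep = "")
  invisible(x)
}

#' Ingest a directory (or explicit file set) of FAERS quarterly files
#'
#' Reads DEMO/DRUG/REAC/OUTC files (multiple quarters are concatenated),
#' deduplicates case versions, and links the tables into a `faers_cases`
#' object. Files are discovered by name prefix (`DEMO*`, `DRUG*`, ...).
#'
#' @param dir Directory containing the `$`-delimited quarterly files.
#' @param vocab Drug dictionary.
#' @param max_error_rate Passed to [read_faers_table()].
#' @return A `faers_cases` object; its `ingest` element also records raw row
#'   counts and the number of duplicate case versions removed.
#' @export
ingest_faers <- function(dir, vocab = load_drug_vocab(), max_error_rate = 0.05) {
  find <- function(prefix) {
    f <- list.files(dir, pattern = paste0("^", prefix), full.names = TRUE,
                    ignore.case = TRUE)
    if (!length(f)) stop("no ", prefix, "* file found in ", dir)
    sort(f)
  }
  read_all <- function(prefix, kind) {
    data.table::rbindlist(
      lapply(find(prefix), read_faers_table, kind = kind,
             max_error_rate = max_error_rate),
      use.names = TRUE, fill = TRUE)
  }
  demo <- read_all("DEMO", "demo")
  drug <- read_all("DRUG", "drug")
  reac <- read_all("REAC", "reac")
  outc_files <- list.files(dir, pattern = "^OUTC", full.names = TRUE,
                           ignore.case = TRUE)
  outc <- if (length(outc_files)) read_all("OUTC", "outc") else NULL

  n_raw <- nrow(demo)
  demo2 <- deduplicate_demo(demo)
  cases <- link_cases(demo2, drug, reac, outc, vocab = vocab)
  cases$ingest$n_demo_rows_raw <- n_raw
  cases$ingest$duplicates_removed <- attr(demo2, "n_removed")
  cases
}

#' Write linked cases to the flat intermediate format
#'
#' One CSV row per case; the drug, reaction and outcome sets are pipe-joined
#' list columns (`drugs` entries are `CANONICAL_OR_RAW:ROLE`). The format
#' round-trips exactly through [read_case_table()].
#'
#' @param cases A `faers_cases` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(cases, path) {
  stopifnot(inherits(cases, "faers_cases"))
  d <- cases$demo
  join <- function(child, fmt) {
    if (!nrow(child)) return(rep("", nrow(d)))
    s <- split(fmt(child), child$primaryid)
    v <- vapply(s, function(z) paste(sort(z), collapse = "|"), character(1))
    out <- unname(v[d$primaryid])
    out[is.na(out)] <- ""
    out
  }
  flat <- data.table::data.table(
    primaryid = d$primaryid, caseid = d$caseid, fda_dt = d$fda_dt,
    sex = d$sex, age_years = d$age_years,
    drugs = join(cases$drugs, function(z)
      paste0(ifelse(is.na(z$canonical), z$drugname, z$canonical), ":", z$role_cod)),
    reactions = join(cases$reactions, function(z) z$pt),
    outcomes = join(cases$outcomes, function(z) z$outc_cod))
  data.table::fwrite(flat, path)
  invisible(path)
}

#' Read the flat intermediate case format back into a `faers_cases` object
#'
#' @param path CSV written by [write_case_table()].
#' @return A `faers_cases` object.
#' @export
read_case_table <- function(path) {
  flat <- data.table::fread(path, colClasses = list(
    character = c("primaryid", "caseid", "sex", "drugs", "reactions", "outcomes")))
  unjoin <- function(col) {
    items <- lapply(strsplit(col, "|", fixed = TRUE), function(z) z[nzchar(z)])
    data.table::data.table(
      primaryid = rep(flat$primaryid, lengths(items)),
      value = as.character(unlist(items)))
  }
  dr <- unjoin(flat$drugs)
  parts <- regmatches(dr$value, regexpr(":[^:]*$", dr$value))
  dr_name <- substr(dr$value, 1L, nchar(dr$value) - nchar(parts))
  drugs <- data.table::data.table(
    primaryid = dr$primaryid, drugname = dr_name,
    role_cod = sub("^:", "", parts))
  drugs[, canonical := ifelse(drugname %in% names(load_drug_vocab()),
                              drugname, NA_character_)]
  re <- unjoin(flat$reactions)
  ou <- unjoin(flat$outcomes)
  demo <- flat[, .(primaryid, caseid, fda_dt, sex, age_years)]
  demo[, has_reactions := primaryid %in% re$primaryid]
  structure(
    list(demo = demo,
         drugs = drugs,
         reactions = data.table::setnames(re, "value", "pt"),
         outcomes = data.table::setnames(ou, "value", "outc_cod"),
         ingest = list(n_cases = nrow(demo))),
    class = "faers_cases")
}

#' Subset a `faers_cases` object to a set of report ids
#'
#' @param cases A `faers_cases` object.
#' @param primaryids Report ids to keep.
#' @return A `faers_cases` object restricted to those cases.
#' @export
subset_cases <- function(cases, primaryids) {
  structure(
    list(demo = cases$demo[cases$demo$primaryid %in% primaryids],
         drugs = cases$drugs[cases$drugs$primaryid %in% primaryids],
         reactions = cases$reactions[cases$reactions$primaryid %in% primaryids],
         outcomes = cases$outcomes[cases$outcomes$primaryid %in% primaryids],
         ingest = list(n_cases = sum(cases$demo$primaryid %in% primaryids))),
    class = "faers_cases")
}
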