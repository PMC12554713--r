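#' Load a drug synonym dictionary
#'
#' Reads a YAML file mapping each canonical study-drug name to its synonyms
#' (generic spellings, salt forms, brand names). Every canonical name is
#' implicitly its own synonym. Synonym sets must be pairwise disjoint across
#' canonicals; overlap is a hard error raised at load time, not per lookup.
#'
#' @param path YAML file, `canonical: [synonym, ...]`. Defaults to the
#'   dictionary bundled with the package (the 12 antiepileptic study drugs).
#' @return An object of class `drug_vocab`: a named list of uppercase synonym
#'   character vectors, with a precomputed synonym-to-canonical lookup table
#'   in attribute `lookup`.
#' @export
load_drug_vocab <- function(path = system.file("extdata", "drug_vocab.yaml",
                                               package = "pvsignal")) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("drug vocabulary is empty: ", path)
  canon <- toupper(trimws(names(raw)))
  vocab <- lapply(seq_along(raw), function(i) {
    unique(c(canon[i], toupper(trimws(unlist(raw[[i]])))))
  })
  names(vocab) <- canon
  syns <- unlist(vocab, use.names = FALSE)
  if (anyDuplicated(syns)) {
    stop("drug vocabulary synonym sets overlap across canonicals: ",
         paste(unique(syns[duplicated(syns)]), collapse = ", "))
  }
  lookup <- stats::setNames(rep(canon, lengths(vocab)), syns)
  structure(vocab, lookup = lookup, class = "drug_vocab")
}

#' @export
print.drug_vocab <- function(x, ...) {
  cat("<drug_vocab> ", length(x), " canonical drugs, ",
      length(attr(x, "lookup")), " synonyms\n", sep = "")
  invisible(x)
}

# Trailing tokens stripped before synonym lookup: dosage forms, routes,
# salts and bare numbers as they appear in free-text FAERS drug names.
default_drug_stoplist <- function() {
  c("SODIUM", "HCL", "HYDROCHLORIDE", "ACETATE", "TABLET", "TABLETS",
    "CAPSULE", "CAPSULES", "ER", "XR", "CR", "DR", "SR", "ORAL", "INJECTION",
    "SOLUTION", "SUSPENSION", "SYRUP", "MG", "ML", "MG/ML", "UNKNOWN")
}

#' Normalize free-text drug names to canonical study drugs
#'
#' Uppercases and trims the input, strips trailing dosage/form/salt tokens
#' from a configurable stop-list (including bare numbers such as "100" or
#' "100MG"), and performs an exact synonym lookup. No fuzzy matching.
#' Idempotent on its own outputs: a canonical name always maps to itself.
#'
#' @param raw_name Character vector of reported drug names.
#' @param vocab A [load_drug_vocab()] dictionary.
#' @param stoplist Trailing tokens to strip before lookup.
#' @return Character vector of canonical names, `NA` where out of vocabulary.
#' @export
normalize_drug <- function(raw_name, vocab = load_drug_vocab(),
                           stoplist = default_drug_stoplist()) {
  stopifnot(inherits(vocab, "drug_vocab"))
  lookup <- attr(vocab, "lookup")
  x <- gsub("\\s+", " ", trimws(toupper(raw_name)))
  out <- unname(lookup[x])
  todo <- unique(x[is.na(out) & !is.na(x) & nzchar(x)])
  if (length(todo)) {
    stripped <- vapply(todo, function(nm) {
      toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
      while (length(toks) > 1L) {
        last <- toks[length(toks)]
        if (!(last %in% stoplist ||
              grepl("^[0-9]+(\\.[0-9]+)?(MG|MCG|G|ML)?$", last)))
          break
        toks <- toks[-length(toks)]
        if (!is.na(lookup[paste(toks, collapse = " ")])) break
      }
      unname(lookup[paste(toks, collapse = " ")])
    }, character(1))
    hit <- !is.na(stripped)
    if (any(hit)) {
      idx <- is.na(out) & x %in% todo[hit]
      out[idx] <- stripped[match(x[idx], todo)]
    }
  }
  out
}

#' Keep only primary-suspect drug entries
#'
#' Spontaneous reports label each drug with a role code: PS (primary
#' suspect), SS (secondary suspect), C (concomitant), I (interaction).
#' Signal analysis here attributes a report to a drug only when that drug is
#' the primary suspect.
#'
#' @param drugs data.frame with at least a `role_cod` column.
#' @return The rows with `role_cod == "PS"`.
#' @export
filter_primary_suspect <- function(drugs) {
  drugs[!is.na(drugs$role_cod) & drugs$role_cod == "PS", , drop = FALSE]
}

#' Load a PT/HLT/HLGT/SOC event hierarchy
#'
#' Reads a CSV with columns `pt,hlt,hlgt,soc` describing a MedDRA-like
#' four-level term hierarchy. The mapping must be a function on PT: each PT
#' appears exactly once. The bundled mock hierarchy covers the terms used by
#' the synthetic generator and tests; a user-supplied full hierarchy in the
#' same format is accepted anywhere this object is.
#'
#' @param path CSV path; defaults to the bundled mock hierarchy.
#' @return Object of class `event_hierarchy` (a data.table keyed by PT).
#' @export
load_event_hierarchy <- function(path = system.file("extdata", "event_hierarchy.csv",
                                                    package = "pvsignal")) {
  h <- data.table::fread(path, colClasses = "character")
  need <- c("pt", "hlt", "hlgt", "soc")
  miss <- setdiff(need, tolower(names(h)))
  if (length(miss)) stop("event hierarchy missing column(s): ",
                         paste(miss, collapse = ", "))
  data.table::setnames(h, tolower(names(h)))
  h <- h[, need, with = FALSE]
  for (cl in need) data.table::set(h, j = cl, value = toupper(trimws(h[[cl]])))
  if (anyDuplicated(h$pt)) {
    stop("event hierarchy maps these PTs more than once: ",
         paste(unique(h$pt[duplicated(h$pt)]), collapse = ", "))
  }
  structure(h, class = c("event_hierarchy", class(h)))
}

#' Map preferred terms to their HLT/HLGT/SOC path
#'
#' Exact case-insensitive lookup. PTs absent from the hierarchy are routed to
#' the sentinel SOC `"UNMAPPED"` (and sentinel HLT/HLGT), never dropped.
#'
#' @param pt Character vector of preferred terms.
#' @param hierarchy An [load_event_hierarchy()] object.
#' @return data.frame with columns `pt, hlt, hlgt, soc`, one row per input.
#' @export
map_pt <- function(pt, hierarchy = load_event_hierarchy()) {
  key <- toupper(trimws(pt))
  idx <- match(key, hierarchy$pt)
  out <- data.frame(
    pt   = key,
    hlt  = ifelse(is.na(idx), "UNMAPPED", hierarchy$hlt[idx]),
    hlgt = ifelse(is.na(idx), "UNMAPPED", hierarchy$hlgt[idx]),
    soc  = ifelse(is.na(idx), "UNMAPPED", hierarchy$soc[idx]),
    stringsAsFactors = FALSE
  )
  out
}

#' Load named target adverse-event sets
#'
#' @param path YAML file, `set name: [PT, ...]`. Defaults to the bundled
#'   file whose first entry is the single-PT osteopenia set.
#' @param name Which set to return; default the first in the file.
#' @return List with `name` and `pts` (uppercase character vector).
#' @export
load_target_events <- function(path = system.file("extdata", "target_events.yaml",
                                                  package = "pvsignal"),
                               name = NULL) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("target event file is empty: ", path)
  name <- name %||% names(raw)[1L]
  if (!name %in% names(raw)) stop("no target event set named '", name, "' in ", path)
  pts <- unique(toupper(trimws(unlist(raw[[name]]))))
  if (!length(pts)) stop("target event set '", name, "' is empty")
  list(name = name, pts = pts)
}
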