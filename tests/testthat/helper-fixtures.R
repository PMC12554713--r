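# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read except the package's bundled vocabulary/hierarchy.

# demographic rows in the raw (pre-dedup) layout
demo_rows <- function(primaryid, caseid, fda_dt, sex = "UNK", age_years = NA) {
  data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    fda_dt = as.integer(fda_dt), sex = sex, age_years = as.numeric(age_years))
}

drug_rows <- function(primaryid, drugname, role_cod = "PS") {
  data.table::data.table(primaryid = as.character(primaryid),
                         drugname = drugname, role_cod = role_cod)
}

reac_rows <- function(primaryid, pt) {
  data.table::data.table(primaryid = as.character(primaryid), pt = pt)
}

outc_rows <- function(primaryid, outc_cod) {
  data.table::data.table(primaryid = as.character(primaryid),
                         outc_cod = outc_cod)
}

# assemble a linked faers_cases object from raw fixture tables
fixture_cases <- function(demo, drugs, reacs, outcs = NULL) {
  link_cases(deduplicate_demo(demo), drugs, reacs, outcs)
}

# the canonical six-case 2x2 fixture: 2 drug&event, 1 drug only,
# 1 event only, 2 neither -> (a,b,c,d) = (2,1,1,2)
six_case_fixture <- function(drug = "GABAPENTIN", event = "OSTEOPENIA") {
  demo <- demo_rows(1:6, paste0("C", 1:6), 20200101)
  drugs <- drug_rows(c(1, 2, 3, 4, 5, 6),
                     c(drug, drug, drug, "OTHERX", "OTHERX", "OTHERX"))
  reacs <- reac_rows(c(1, 2, 4), rep(event, 3))
  fixture_cases(demo, drugs, reacs)
}

# write a small $-delimited FAERS-format table
write_faers_file <- function(lines, file) {
  writeLines(lines, file)
  file
}

# independent direct-formula oracles for the disproportionality statistics
oracle_ror <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, lo = exp(log(ror) - 1.96 * se), hi = exp(log(ror) + 1.96 * se))
}

oracle_prr <- function(a, b, c, d) {
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  chi2 <- if (dev <= n / 2) 0 else
    n * (dev - n / 2)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  c(prr = prr, chi2 = chi2)
}

oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  c(ic = ic, ic025 = ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5))
}

# two-sided Fisher exact by full hypergeometric enumeration via choose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(m, k)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  p0 <- choose(m, a) * choose(n2, c) / choose(m + n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# quadrature oracles for the gamma-Poisson posterior over lambda
mix_prior_density <- function(l, pr) {
  pr$w * stats::dgamma(l, pr$alpha1, rate = pr$beta1) +
    (1 - pr$w) * stats::dgamma(l, pr$alpha2, rate = pr$beta2)
}

oracle_ebgm_quadrature <- function(o, e, pr) {
  post_unnorm <- function(l) mix_prior_density(l, pr) * stats::dpois(o, l * e)
  z <- stats::integrate(post_unnorm, 0, Inf, rel.tol = 1e-10,
                        abs.tol = 0)$value
  elog <- stats::integrate(function(l) log(l) * post_unnorm(l), 0, Inf,
                           rel.tol = 1e-10, abs.tol = 0)$value / z
  # the 5% point lies between the two posterior component 5% quantiles
  lo <- min(stats::qgamma(0.05, pr$alpha1 + o, rate = pr$beta1 + e),
            stats::qgamma(0.05, pr$alpha2 + o, rate = pr$beta2 + e)) * 0.5
  hi <- max(stats::qgamma(0.05, pr$alpha1 + o, rate = pr$beta1 + e),
            stats::qgamma(0.05, pr$alpha2 + o, rate = pr$beta2 + e)) * 2
  q05 <- stats::uniroot(function(x)
    stats::integrate(post_unnorm, 0, x, rel.tol = 1e-10,
                     abs.tol = 0)$value / z - 0.05,
    interval = c(lo, hi), tol = 1e-11)$root
  c(ebgm = exp(elog), ebgm05 = q05)
}

# sample cells from a known gamma(-mixture) prior
simulate_cells <- function(n, pr, seed) {
  set.seed(seed)
  comp1 <- stats::runif(n) < pr$w
  lambda <- ifelse(comp1,
                   stats::rgamma(n, pr$alpha1, rate = pr$beta1),
                   stats::rgamma(n, pr$alpha2, rate = pr$beta2))
  e <- stats::runif(n, 0.1, 10)
  list(o = stats::rpois(n, lambda * e), e = e)
}
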