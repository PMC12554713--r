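#' Gamma-mixture prior for the gamma-Poisson shrinker
#'
#' DuMouchel's model for a grid of drug-event cells: the observed count O of
#' each cell is Poisson(lambda E) with E the expected count under
#' independence, and the relative reporting rate lambda is drawn from a
#' two-component gamma mixture w Gamma(alpha1, beta1) + (1 - w)
#' Gamma(alpha2, beta2) (shape/rate parameterization).
#'
#' @param w Mixture weight in (0, 1).
#' @param alpha1,beta1,alpha2,beta2 Positive gamma shape/rate parameters.
#' @return Object of class `mgps_prior`.
#' @export
mgps_prior <- function(w = 1 / 3, alpha1 = 0.2, beta1 = 0.1,
                       alpha2 = 2, beta2 = 4) {
  stopifnot(is_number(w), w > 0, w < 1,
            is_number(alpha1), alpha1 > 0, is_number(beta1), beta1 > 0,
            is_number(alpha2), alpha2 > 0, is_number(beta2), beta2 > 0)
  structure(list(w = w, alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf("<mgps_prior> w = %.4f | Gamma(%.4g, %.4g) / Gamma(%.4g, %.4g)\n",
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2))
  if (!is.null(attr(x, "converged")) && !attr(x, "converged"))
    cat("  (optimizer did not report convergence; best point found)\n")
  invisible(x)
}

# log negative-binomial marginal of O when lambda ~ Gamma(alpha, beta), O ~ Poi(lambda E):
# NB(size = alpha, prob = beta / (beta + E))
nb_logpmf <- function(o, alpha, beta, e) {
  stats::dnbinom(o, size = alpha, prob = beta / (beta + e), log = TRUE)
}

#' Marginal log-likelihood of the gamma-Poisson mixture
#'
#' Sum over cells of log[w NB(O; alpha1, beta1/(beta1+E)) + (1-w) NB(O;
#' alpha2, beta2/(beta2+E))], evaluated in log space so that counts up to
#' 1e6 do not underflow.
#'
#' @param prior An `mgps_prior`.
#' @param o,e Vectors of observed and expected counts (E > 0).
#' @return The scalar log-likelihood.
#' @export
mgps_marginal_loglik <- function(prior, o, e) {
  stopifnot(length(o) == length(e), all(e > 0))
  l1 <- log(prior$w) + nb_logpmf(o, prior$alpha1, prior$beta1, e)
  l2 <- log1p(-prior$w) + nb_logpmf(o, prior$alpha2, prior$beta2, e)
  ll <- log_add(l1, l2)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1L]
    stop(sprintf("non-finite marginal likelihood at cell %d (O = %g, E = %g)",
                 bad, o[bad], e[bad]))
  }
  sum(ll)
}

# parameter transform: shapes/rates on log scale, weight on logit scale
mgps_pack <- function(p) c(log(p$alpha1), log(p$beta1), log(p$alpha2),
                           log(p$beta2), stats::qlogis(p$w))
mgps_unpack <- function(th) mgps_prior(
  w = stats::plogis(th[5]), alpha1 = exp(th[1]), beta1 = exp(th[2]),
  alpha2 = exp(th[3]), beta2 = exp(th[4]))

#' Fit the mixture prior by maximum marginal likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) ascent on the marginal log-likelihood over
#' the full cell grid, on log/logit-transformed parameters with shapes and
#' rates constrained to [1e-4, 1e4]. A small fixed multi-start grid guards
#' against the known bimodality of the mixture likelihood; the returned prior
#' never has lower log-likelihood than the supplied init (ascent property).
#'
#' @param o,e Observed and expected counts over all grid cells.
#' @param init Starting prior; the classic MGPS init is the default.
#' @param extra_starts Number of additional grid starts (0 disables).
#' @return The fitted `mgps_prior` with attributes `loglik`, `converged`,
#'   and `init_loglik`. A warning is raised below 50 cells.
#' @export
mgps_fit_prior <- function(o, e, init = mgps_prior(), extra_starts = 6L) {
  stopifnot(length(o) == length(e))
  if (length(o) < 50L)
    warning("fitting an MGPS prior on fewer than 50 cells is unreliable")
  lim <- log(c(1e-4, 1e4))
  wlim <- stats::qlogis(c(1e-4, 1 - 1e-4))
  negll <- function(th) {
    p <- tryCatch(mgps_unpack(th), error = function(err) NULL)
    if (is.null(p)) return(1e12)
    v <- tryCatch(-mgps_marginal_loglik(p, o, e), error = function(err) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  # analytic gradient on the transformed scale (responsibilities x per-
  # component NB score, chain-ruled through log/logit)
  negll_grad <- function(th) {
    p <- tryCatch(mgps_unpack(th), error = function(err) NULL)
    if (is.null(p)) return(rep(0, 5))
    l1 <- log(p$w) + nb_logpmf(o, p$alpha1, p$beta1, e)
    l2 <- log1p(-p$w) + nb_logpmf(o, p$alpha2, p$beta2, e)
    r1 <- 1 / (1 + exp(l2 - l1))   # responsibility of component 1
    r2 <- 1 - r1
    score_a <- function(alpha, beta)
      digamma(o + alpha) - digamma(alpha) + log(beta / (beta + e))
    score_b <- function(alpha, beta)
      alpha * (1 / beta - 1 / (beta + e)) - o / (beta + e)
    g <- c(p$alpha1 * sum(r1 * score_a(p$alpha1, p$beta1)),
           p$beta1  * sum(r1 * score_b(p$alpha1, p$beta1)),
           p$alpha2 * sum(r2 * score_a(p$alpha2, p$beta2)),
           p$beta2  * sum(r2 * score_b(p$alpha2, p$beta2)),
           sum(r1 - p$w))
    if (any(!is.finite(g))) return(rep(0, 5))
    -g
  }
  starts <- list(init)
  if (extra_starts > 0L) {
    grid <- list(
      mgps_prior(w = 0.1, alpha1 = 0.1, beta1 = 0.1, alpha2 = 1, beta2 = 1),
      mgps_prior(w = 0.5, alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1),
      mgps_prior(w = 0.5, alpha1 = 0.5, beta1 = 0.25, alpha2 = 4, beta2 = 4),
      mgps_prior(w = 0.2, alpha1 = 2, beta1 = 4, alpha2 = 0.2, beta2 = 0.1),
      mgps_prior(w = 0.9, alpha1 = 1, beta1 = 1, alpha2 = 0.1, beta2 = 0.05),
      mgps_prior(w = 0.5, alpha1 = 10, beta1 = 10, alpha2 = 0.5, beta2 = 0.5))
    starts <- c(starts, grid[seq_len(min(extra_starts, length(grid)))])
  }
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(mgps_pack(s), negll, gr = negll_grad, method = "L-BFGS-B",
                   lower = c(rep(lim[1], 4), wlim[1]),
                   upper = c(rep(lim[2], 4), wlim[2]),
                   control = list(maxit = 500)),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0L
    }
  }
  init_ll <- mgps_marginal_loglik(init, o, e)
  if (is.null(best) || -best$value < init_ll) {
    out <- init   # optimizer failed to improve; keep the start point
    ll <- init_ll
    converged <- FALSE
  } else {
    out <- mgps_unpack(best$par)
    ll <- -best$value
  }
  attr(out, "loglik") <- ll
  attr(out, "init_loglik") <- init_ll
  attr(out, "converged") <- converged
  out
}

#' EBGM and EBGM05 scores for drug-event cells
#'
#' Given the fitted prior, the posterior on each cell's relative reporting
#' rate lambda is again a two-component gamma mixture, Gamma(alpha1 + O,
#' beta1 + E) and Gamma(alpha2 + O, beta2 + E), with component-1 weight Q
#' equal to the posterior probability that the cell came from component 1.
#' EBGM = exp(E[ln lambda]) (the empirical Bayes geometric mean) and EBGM05
#' is the posterior 5th percentile, located by bisection on the mixture CDF
#' to 1e-10 relative precision.
#'
#' @param o,e Observed and expected counts (vectors; E > 0).
#' @param prior An `mgps_prior`.
#' @return data.frame with columns `ebgm, ebgm05`.
#' @export
ebgm_score <- function(o, e, prior) {
  stopifnot(length(o) == length(e), all(e > 0))
  l1 <- log(prior$w) + nb_logpmf(o, prior$alpha1, prior$beta1, e)
  l2 <- log1p(-prior$w) + nb_logpmf(o, prior$alpha2, prior$beta2, e)
  q <- 1 / (1 + exp(l2 - l1))
  s1 <- prior$alpha1 + o; r1 <- prior$beta1 + e
  s2 <- prior$alpha2 + o; r2 <- prior$beta2 + e
  elog <- q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2))
  ebgm05 <- vapply(seq_along(o), function(i)
    mixture_gamma_quantile(0.05, q[i], s1[i], r1[i], s2[i], r2[i]),
    numeric(1))
  data.frame(ebgm = exp(elog), ebgm05 = ebgm05)
}

# p-quantile of q Gamma(s1, r1) + (1 - q) Gamma(s2, r2) by bisection.
# The mixture quantile lies between the two component quantiles.
mixture_gamma_quantile <- function(p, q, s1, r1, s2, r2, tol = 1e-10) {
  cdf <- function(x) q * stats::pgamma(x, s1, rate = r1) +
    (1 - q) * stats::pgamma(x, s2, rate = r2)
  q1 <- stats::qgamma(p, s1, rate = r1)
  q2 <- stats::qgamma(p, s2, rate = r2)
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (hi - lo < tol * max(hi, 1)) return((lo + hi) / 2)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
    if (hi - lo < tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

#' Observed/expected cell grid over the full drug x PT matrix
#'
#' Builds the cell grid the MGPS prior is fitted on: for every combination of
#' primary-suspect drug label and reaction PT occurring in the universe,
#' O = number of cases reporting that PS drug and that PT, and E = (row
#' margin x column margin) / n from the case-count margins (so the cell of a
#' target drug-event pair has exactly the 2x2 table's a and (a+b)(a+c)/n).
#' Drug labels are canonical names where the vocabulary matches, otherwise
#' the raw uppercase name, so shrinkage borrows strength across the whole
#' reporting background.
#'
#' @param cases A `faers_cases` object.
#' @param universe As in [build_contingency()].
#' @return data.table with columns `drug, pt, o, e` (all cells of the cross
#'   grid whose margins are positive).
#' @export
drug_event_cells <- function(cases, universe = c("all_ingested", "study_drugs_only")) {
  universe <- match.arg(universe)
  ps <- filter_primary_suspect(cases$drugs)
  ps <- data.table::as.data.table(ps)
  ps[, drug := ifelse(is.na(canonical), toupper(trimws(drugname)), canonical)]
  uni_ids <- if (universe == "all_ingested") cases$demo$primaryid else
    intersect(cases$demo$primaryid, unique(ps$primaryid[!is.na(ps$canonical)]))
  n <- length(uni_ids)
  if (!n) stop("empty analysis universe")
  ps <- unique(ps[primaryid %in% uni_ids, .(primaryid, drug)])
  re <- unique(data.table::as.data.table(
    cases$reactions)[primaryid %in% uni_ids, .(primaryid, pt)])
  row_margin <- ps[, .(r = data.table::uniqueN(primaryid)), by = drug]
  col_margin <- re[, .(s = data.table::uniqueN(primaryid)), by = pt]
  obs <- merge(ps, re, by = "primaryid", allow.cartesian = TRUE)[
    , .(o = .N), by = .(drug, pt)]
  grid <- data.table::CJ(drug = row_margin$drug, pt = col_margin$pt)
  grid <- merge(grid, obs, by = c("drug", "pt"), all.x = TRUE)
  grid[is.na(o), o := 0L]
  grid <- merge(grid, row_margin, by = "drug")
  grid <- merge(grid, col_margin, by = "pt")
  grid[, e := r * s / n]
  data.table::setorder(grid, drug, pt)
  grid[, .(drug, pt, o, e)]
}
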