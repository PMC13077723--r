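# Multi-item gamma-Poisson shrinker (MGPS).
#
# Model: for pair i with observed count a_i and expected count
# E_i = (a_i + b_i)(a_i + c_i) / n_i, the relative reporting ratio lambda
# has the two-component gamma mixture prior
#
#   lambda ~ P Gamma(alpha1, rate = beta1) + (1 - P) Gamma(alpha2, rate = beta2)
#
# and a_i | lambda ~ Poisson(lambda E_i). The marginal of a_i is then a
# mixture of negative binomials, the posterior is again a two-component
# gamma mixture with component j updated to Gamma(alpha_j + a, beta_j + E)
# and weights proportional to the component marginals. EBGM is the
# posterior geometric mean 2^{E[log2 lambda]}; EBGM05 is the 5th
# percentile of the posterior mixture. Hyperparameters are either fixed or
# fitted by maximizing the product of negative-binomial marginals over the
# corpus of pairs (deterministic quasi-Newton from the conventional start
# (0.2, 0.1, 2, 4, 1/3)).

#' MGPS prior hyperparameters
#'
#' @param alpha1,beta1 shape and rate of the first gamma component.
#' @param alpha2,beta2 shape and rate of the second gamma component.
#' @param P mixing weight of the first component, in (0, 1].
#' @return named list of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                       P = 1 / 3) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0))
    stop_config("mgps_prior: shapes and rates must be > 0")
  if (P <= 0 || P > 1) stop_config("mgps_prior: P must lie in (0, 1]")
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, P = P), class = "mgps_prior")
}

# log marginal density of each count under one gamma component:
# negative binomial with size = alpha, prob = beta / (beta + E)
lnb <- function(a, E, alpha, beta) {
  stats::dnbinom(a, size = alpha, prob = beta / (beta + E), log = TRUE)
}

#' Negative log marginal likelihood of an MGPS prior
#'
#' @param theta an [mgps_prior()].
#' @param a observed counts.
#' @param E expected counts (same length, > 0).
#' @return scalar negative log-likelihood.
#' @export
mgps_negloglik <- function(theta, a, E) {
  l1 <- log(theta$P) + lnb(a, E, theta$alpha1, theta$beta1)
  l2 <- log1p(-min(theta$P, 1 - 1e-15)) + lnb(a, E, theta$alpha2, theta$beta2)
  m <- pmax(l1, l2)
  -sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Fit the MGPS prior by maximum marginal likelihood
#'
#' Deterministic quasi-Newton optimization (\code{\link[stats]{nlminb}} on
#' log/logit-transformed hyperparameters) from the conventional start
#' `(0.2, 0.1, 2, 4, 1/3)`. Pairs with `E = 0` or missing counts are
#' dropped from the fit.
#'
#' @param a observed counts over the corpus of pairs.
#' @param E expected counts.
#' @param start starting [mgps_prior()].
#' @return fitted `mgps_prior` with attribute `negloglik`.
#' @export
fit_mgps_prior <- function(a, E, start = mgps_prior()) {
  keep <- !is.na(a) & !is.na(E) & E > 0
  a <- a[keep]; E <- E[keep]
  if (length(a) < 2)
    stop_config("fit_mgps_prior: need at least two pairs with E > 0")
  if (all(a == 0))
    stop_config("fit_mgps_prior: degenerate corpus (all counts zero); ",
                "supply a fixed prior instead")
  par0 <- c(log(start$alpha1), log(start$beta1), log(start$alpha2),
            log(start$beta2), stats::qlogis(start$P))
  obj <- function(p) {
    th <- mgps_prior(exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]),
                     stats::plogis(p[5]))
    mgps_negloglik(th, a, E)
  }
  fit <- stats::nlminb(par0, obj, control = list(iter.max = 500, eval.max = 1000))
  out <- mgps_prior(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]),
                    exp(fit$par[4]), stats::plogis(fit$par[5]))
  attr(out, "negloglik") <- fit$objective
  out
}

# posterior mixture weights (first component) for each (a, E)
posterior_weight <- function(a, E, theta) {
  l1 <- log(theta$P) + lnb(a, E, theta$alpha1, theta$beta1)
  l2 <- log1p(-min(theta$P, 1 - 1e-15)) + lnb(a, E, theta$alpha2, theta$beta2)
  1 / (1 + exp(l2 - l1))
}

#' EBGM and EBGM05 scores
#'
#' Posterior geometric mean of the relative reporting ratio,
#' `EBGM = 2^{E[log2 lambda | a]} = exp(E[ln lambda | a])`, and the 5th
#' percentile of the posterior gamma mixture (`EBGM05`), found by
#' root-finding on the mixture CDF to absolute tolerance 1e-10. Pairs with
#' `E = 0` or missing values return NA.
#'
#' @param a observed counts.
#' @param E expected counts.
#' @param theta an [mgps_prior()].
#' @param quantile lower posterior quantile to report (default 0.05).
#' @return data frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm_scores <- function(a, E, theta, quantile = 0.05) {
  stopifnot(inherits(theta, "mgps_prior"))
  n <- length(a)
  ebgm <- rep(NA_real_, n)
  eb05 <- rep(NA_real_, n)
  ok <- !is.na(a) & !is.na(E) & E > 0
  if (any(ok)) {
    ai <- a[ok]; Ei <- E[ok]
    w <- posterior_weight(ai, Ei, theta)
    s1 <- theta$alpha1 + ai; r1 <- theta$beta1 + Ei
    s2 <- theta$alpha2 + ai; r2 <- theta$beta2 + Ei
    mean_ln <- w * (digamma(s1) - log(r1)) + (1 - w) * (digamma(s2) - log(r2))
    ebgm[ok] <- exp(mean_ln)
    cdf <- function(x, i) {
      w[i] * stats::pgamma(x, s1[i], rate = r1[i]) +
        (1 - w[i]) * stats::pgamma(x, s2[i], rate = r2[i])
    }
    q <- numeric(length(ai))
    for (i in seq_along(ai)) {
      lo <- min(stats::qgamma(quantile, s1[i], rate = r1[i]),
                stats::qgamma(quantile, s2[i], rate = r2[i]))
      hi <- max(stats::qgamma(quantile, s1[i], rate = r1[i]),
                stats::qgamma(quantile, s2[i], rate = r2[i]))
      if (hi - lo < 1e-14) {
        q[i] <- lo
      } else {
        q[i] <- stats::uniroot(function(x) cdf(x, i) - quantile,
                               lower = lo * 0.5, upper = hi * 2,
                               extendInt = "upX", tol = 1e-10)$root
      }
    }
    eb05[ok] <- q
  }
  data.frame(ebgm = ebgm, ebgm05 = eb05)
}
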