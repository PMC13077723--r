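# Shared fixtures and independent oracles.

# Build a minimal raw-table list accepted by assemble_cases(). `spec` is a
# data frame with one row per case: caseid, drugs (list of name vectors),
# roles (list of role vectors), pts (list of PT vectors), and optional
# demographic overrides.
raw_fixture <- function(caseid, drugs, roles, pts,
                        caseversion = rep(1L, length(caseid)),
                        fda_dt = rep(20100101, length(caseid)),
                        event_dt = fda_dt,
                        start_dt = rep(NA_real_, length(caseid)),
                        sex = rep(NA_character_, length(caseid))) {
  primaryid <- paste0(caseid, caseversion)
  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     caseversion = caseversion, fda_dt = fda_dt,
                     event_dt = event_dt, sex = sex,
                     age = NA_real_, age_cod = NA_character_,
                     wt = NA_real_, wt_cod = NA_character_,
                     occp_cod = NA_character_, occr_country = NA_character_,
                     stringsAsFactors = FALSE)
  drug <- do.call(rbind, lapply(seq_along(caseid), function(i) {
    data.frame(primaryid = primaryid[i], drug_seq = seq_along(drugs[[i]]),
               role_cod = roles[[i]], drugname = drugs[[i]],
               route = NA_character_, stringsAsFactors = FALSE)
  }))
  reac <- do.call(rbind, lapply(seq_along(caseid), function(i) {
    if (length(pts[[i]]) == 0) return(NULL)
    data.frame(primaryid = primaryid[i], pt = pts[[i]], stringsAsFactors = FALSE)
  }))
  has_start <- !is.na(start_dt)
  ther <- data.frame(primaryid = primaryid[has_start],
                     dsg_drug_seq = rep(1, sum(has_start)),
                     start_dt = start_dt[has_start],
                     stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac,
       outc = data.frame(primaryid = character(0), outc_cod = character(0)),
       rpsr = data.frame(primaryid = character(0), rpsr_cod = character(0)),
       ther = ther)
}

# Brute-force per-case double loop over the generator ledger.
loop_contingency <- function(report_set, drug_id, event_id) {
  cases <- report_set$truth$cases
  reac <- report_set$truth$reactions
  a <- b <- c <- d <- 0
  for (i in seq_len(nrow(cases))) {
    exposed <- cases$ps_drug_id[i] == drug_id
    with_event <- FALSE
    for (j in seq_len(nrow(reac))) {
      if (reac$caseid[j] == cases$caseid[i] && reac$event_id[j] == event_id) {
        with_event <- TRUE
        break
      }
    }
    if (exposed && with_event) a <- a + 1
    else if (exposed) b <- b + 1
    else if (with_event) c <- c + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c, d = d)
}

# Random strictly positive 2x2 tables.
random_tables <- function(n, max_cell = 500, seed = 101) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, replace = TRUE),
             b = sample.int(max_cell, n, replace = TRUE),
             c = sample.int(max_cell, n, replace = TRUE),
             d = sample.int(max_cell, n, replace = TRUE))
}

# Independent BCPNN evaluation: same printed formulas transcribed on the
# log scale, term by term, with gamma exponentiated from a sum of logs.
bcpnn_oracle <- function(a, b, c, d, a1 = 1, b1 = 1, al = 2, be = 2, g11 = 1) {
  C <- a + b + c + d; Cx <- a + b; Cy <- a + c; Cxy <- a
  g <- exp(log(g11) + log(C + al) + log(C + be) - log(Cx + a1) - log(Cy + b1))
  eic <- (log(Cxy + g11) + log(C + al) + log(C + be) -
            log(C + g) - log(Cx + a1) - log(Cy + b1)) / log(2)
  vic <- (1 / log(2)^2) * (
    (C - Cxy + g - g11) / ((Cxy + g11) * (1 + C + g)) +
      (C - Cx + al - a1) / ((Cx + a1) * (1 + C + al)) +
      (C - Cy + be - b1) / ((Cy + b1) * (1 + C + be)))
  c(ic = eic, v_ic = vic, ic_minus_2sd = eic - 2 * sqrt(vic))
}

# Independent EBGM oracle by numerical quadrature of the posterior of
# lambda: density proportional to prior(lambda) * dpois(a, lambda * E).
ebgm_quadrature_oracle <- function(a, E, theta, q = 0.05) {
  # integrate on the log scale: u = ln(lambda) removes the origin
  # singularity of the log moment; the integrand is assembled from log
  # densities so the tails underflow to 0 instead of producing NaN
  g <- function(u) {
    l <- exp(u)
    lp1 <- log(theta$P) + dgamma(l, theta$alpha1, rate = theta$beta1, log = TRUE)
    lp2 <- log1p(-min(theta$P, 1 - 1e-15)) +
      dgamma(l, theta$alpha2, rate = theta$beta2, log = TRUE)
    m <- pmax(lp1, lp2)
    lg <- m + log(exp(lp1 - m) + exp(lp2 - m)) +
      dpois(a, l * E, log = TRUE) + u
    out <- exp(lg)
    out[!is.finite(out)] <- 0
    out
  }
  Z <- integrate(g, -Inf, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  mean_ln <- integrate(function(u) u * g(u), -Inf, Inf, rel.tol = 1e-10,
                       subdivisions = 500L)$value / Z
  cdf <- function(x) integrate(g, -Inf, log(x), rel.tol = 1e-10,
                               subdivisions = 500L)$value / Z
  lo <- 0; hi <- (a + 10) / max(E, 1e-6) + 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < q) lo <- mid else hi <- mid
  }
  c(ebgm = exp(mean_ln), ebgm05 = (lo + hi) / 2)
}
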