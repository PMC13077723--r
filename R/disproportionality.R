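# Disproportionality statistics on 2x2 contingency tables.
#
# Four estimators are provided, all comparing the observed reporting
# frequency of a (drug, event) pair against the background of all other
# reports: the reporting odds ratio (ROR), the proportional reporting
# ratio (PRR) with a Yates-corrected chi-square, the BCPNN information
# component (IC) with its lower two-standard-deviation bound, and the
# empirical-Bayes gamma-Poisson EBGM (see ebgm.R).
#
# Cells with zeros make ROR/PRR/chi-square undefined; those return NA
# rather than applying a silent continuity correction (a Haldane +0.5
# correction is available behind an explicit flag). The BCPNN and EBGM are
# regularized by their priors and remain defined for zero cells.

cells <- function(table) {
  if (!inherits(table, "contingency_table") && !is.data.frame(table))
    stop_config("expected a contingency_table or a data frame with a,b,c,d")
  # doubles throughout: products of margins overflow 32-bit integers
  list(a = as.numeric(table$a), b = as.numeric(table$b),
       c = as.numeric(table$c), d = as.numeric(table$d))
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d) / (b c)` with the log-scale Wald interval
#' `exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. Undefined (NA) when any
#' cell is zero, unless `haldane = TRUE` adds 0.5 to every cell first.
#'
#' @param table a [contingency_table()] or data frame with columns a,b,c,d
#'   (vectorized).
#' @param conf confidence level (default 0.95).
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables instead of returning NA.
#' @return data frame with columns `ror`, `ci_low`, `ci_high`.
#' @export
ror <- function(table, conf = 0.95, haldane = FALSE) {
  x <- cells(table)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  undef <- a == 0 | b == 0 | c == 0 | d == 0
  if (haldane) {
    a <- a + 0.5 * undef; b <- b + 0.5 * undef
    c <- c + 0.5 * undef; d <- d + 0.5 * undef
    undef <- rep(FALSE, length(a))
  }
  est <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- data.frame(ror = est,
                    ci_low = exp(log(est) - z * se),
                    ci_high = exp(log(est) + z * se))
  out[undef, ] <- NA_real_
  out
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' `PRR = (a / (a + b)) / (c / (c + d))`. The interval uses the standard
#' log-Wald standard error `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#' Undefined (NA) when `a = 0` or `c = 0`.
#'
#' @inheritParams ror
#' @return data frame with columns `prr`, `ci_low`, `ci_high`.
#' @export
prr <- function(table, conf = 0.95, haldane = FALSE) {
  x <- cells(table)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  undef <- a == 0 | c == 0
  if (haldane) {
    a <- a + 0.5 * undef; b <- b + 0.5 * undef
    c <- c + 0.5 * undef; d <- d + 0.5 * undef
    undef <- rep(FALSE, length(a))
  }
  est <- (a * (c + d)) / (c * (a + b))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  out <- data.frame(prr = est,
                    ci_low = exp(log(est) - z * se),
                    ci_high = exp(log(est) + z * se))
  out[undef, ] <- NA_real_
  out
}

#' Yates continuity-corrected chi-square statistic
#'
#' `chi^2 = n (|ad - bc| - n/2)^2 / ((a+b)(a+c)(c+d)(b+d))`, with the
#' correction term `|ad - bc| - n/2` floored at zero before squaring (the
#' standard Yates convention). Undefined (NA) when any margin is zero.
#'
#' @inheritParams ror
#' @return numeric vector of statistics.
#' @export
chisq_yates <- function(table) {
  x <- cells(table)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  n <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  undef <- m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0
  corr <- pmax(abs(a * d - b * c) - n / 2, 0)
  out <- n * corr^2 / (m1 * m2 * m3 * m4)
  out[undef] <- NA_real_
  out
}

#' BCPNN prior hyperparameters
#'
#' Defaults are the conventional uninformative choice
#' `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`; `gamma` itself
#' is derived inside [bcpnn()] so that the prior information component is
#' centred at zero.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 positive hyperparameters.
#' @return named list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  v <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
         gamma11 = gamma11)
  if (any(v <= 0)) stop_config("bcpnn_priors: all hyperparameters must be > 0")
  structure(as.list(v), class = "bcpnn_priors")
}

#' BCPNN information component
#'
#' Closed-form Bayesian shrinkage estimate of the log2 observed-to-expected
#' reporting ratio. Writing `C = n`, `Cx = a + b`, `Cy = a + c`,
#' `Cxy = a`, and with `gamma = gamma11 (C+alpha)(C+beta) /
#' ((Cx+alpha1)(Cy+beta1))`:
#'
#' `E(IC) = log2[ (Cxy+gamma11)(C+alpha)(C+beta) /
#'               ((C+gamma)(Cx+alpha1)(Cy+beta1)) ]`
#'
#' `V(IC) = (1/ln^2 2) [ (C-Cxy+gamma-gamma11)/((Cxy+gamma11)(1+C+gamma))
#'        + (C-Cx+alpha-alpha1)/((Cx+alpha1)(1+C+alpha))
#'        + (C-Cy+beta-beta1)/((Cy+beta1)(1+C+beta)) ]`
#'
#' and `IC - 2SD = E(IC) - 2 sqrt(V(IC))`. The priors regularize empty
#' cells, so the statistic is defined for every nonnegative table; on the
#' empty table the default priors give `E(IC) = 0`.
#'
#' @inheritParams ror
#' @param priors a [bcpnn_priors()] object.
#' @return data frame with columns `ic`, `v_ic`, `ic_minus_2sd`.
#' @export
bcpnn <- function(table, priors = bcpnn_priors()) {
  x <- cells(table)
  a <- x$a
  C <- x$a + x$b + x$c + x$d
  Cx <- x$a + x$b
  Cy <- x$a + x$c
  p <- priors
  g <- p$gamma11 * (C + p$alpha) * (C + p$beta) /
    ((Cx + p$alpha1) * (Cy + p$beta1))
  ic <- log2((a + p$gamma11) * (C + p$alpha) * (C + p$beta) /
               ((C + g) * (Cx + p$alpha1) * (Cy + p$beta1)))
  v_ic <- (1 / log(2)^2) * (
    (C - a + g - p$gamma11) / ((a + p$gamma11) * (1 + C + g)) +
      (C - Cx + p$alpha - p$alpha1) / ((Cx + p$alpha1) * (1 + C + p$alpha)) +
      (C - Cy + p$beta - p$beta1) / ((Cy + p$beta1) * (1 + C + p$beta)))
  data.frame(ic = ic, v_ic = v_ic, ic_minus_2sd = ic - 2 * sqrt(v_ic))
}

#' Signal criteria thresholds
#'
#' The conventional printed thresholds: a pair signals under ROR when
#' `a >= 3`, `ROR >= 2` and the lower 95% bound exceeds 1; under PRR when
#' `a >= 3`, `PRR >= 2` and `chi^2 >= 4`; under BCPNN when `a >= 3` and
#' `IC - 2SD > 0`; under EBGM when `a >= 3` and `EBGM05 > 2` (no printed
#' convention exists for EBGM05; 2 is the customary cut and overridable).
#' Ratio thresholds are inclusive (`>=`); bound thresholds are strict
#' (`>`).
#'
#' @param min_a minimum case count gate shared by all four algorithms.
#' @param ror_min,prr_min,chisq_min,ebgm05_min,ic025_min thresholds.
#' @return named list of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_min = 2, prr_min = 2, chisq_min = 4,
                            ic025_min = 0, ebgm05_min = 2) {
  structure(list(min_a = min_a, ror_min = ror_min, prr_min = prr_min,
                 chisq_min = chisq_min, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min), class = "signal_criteria")
}

#' Apply signal criteria to computed statistics
#'
#' Adds per-algorithm logical flags and the combined `all_of` / `any_of`
#' columns. An undefined (NA) statistic never signals.
#'
#' @param results data frame with columns `case_reports`, `ror`,
#'   `ror_ci_low`, `prr`, `chisq`, `ic025`, `ebgm05` (as produced by
#'   [disproportionality()]).
#' @param criteria a [signal_criteria()] object.
#' @return `results` with flag columns appended/replaced.
#' @export
evaluate_signals <- function(results, criteria = signal_criteria()) {
  gate <- !is.na(results$case_reports) & results$case_reports >= criteria$min_a
  flag <- function(x) !is.na(x) & x
  results$ror_signal <- gate & flag(results$ror >= criteria$ror_min &
                                      results$ror_ci_low > 1)
  results$prr_signal <- gate & flag(results$prr >= criteria$prr_min &
                                      results$chisq >= criteria$chisq_min)
  results$bcpnn_signal <- gate & flag(results$ic025 > criteria$ic025_min)
  results$ebgm_signal <- gate & flag(results$ebgm05 > criteria$ebgm05_min)
  results$all_of <- results$ror_signal & results$prr_signal &
    results$bcpnn_signal & results$ebgm_signal
  results$any_of <- results$ror_signal | results$prr_signal |
    results$bcpnn_signal | results$ebgm_signal
  results
}

#' Rank results by signal intensity
#'
#' Descending by `key` (default `ebgm`); ties broken by `case_reports`
#' descending then event label ascending, so the order is deterministic
#' for any input permutation. NA keys sort last.
#'
#' @param results a results data frame.
#' @param key column to rank on.
#' @param top_n optionally keep only the first `top_n` rows.
#' @return reordered (and possibly truncated) results.
#' @export
rank_results <- function(results, key = "ebgm", top_n = NULL) {
  if (!key %in% names(results))
    stop_config("rank_results: unknown ranking key '", key, "'")
  o <- order(-xtfrm(results[[key]]), -results$case_reports, results$event,
             na.last = TRUE)
  out <- results[o, , drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Full disproportionality analysis over a set of contingency tables
#'
#' Computes ROR, PRR, Yates chi-square, the BCPNN information component and
#' the gamma-Poisson EBGM for every event, then applies the signal
#' criteria. The EBGM prior is either fitted to the corpus by maximum
#' marginal likelihood (`mgps = "fit"`, the default) or supplied as a
#' fixed [mgps_prior()].
#'
#' @param tables data frame from [build_contingency_tables()].
#' @param priors BCPNN priors.
#' @param mgps `"fit"` or a fixed [mgps_prior()].
#' @param criteria signal thresholds.
#' @param conf confidence level for the ROR/PRR intervals.
#' @return data frame with columns `event`, `case_reports`, `ror`,
#'   `ror_ci_low`, `ror_ci_high`, `prr`, `prr_ci_low`, `prr_ci_high`,
#'   `chisq`, `ic`, `ic025`, `ebgm`, `ebgm05` and the signal flags.
#' @export
disproportionality <- function(tables, priors = bcpnn_priors(), mgps = "fit",
                               criteria = signal_criteria(), conf = 0.95) {
  r1 <- ror(tables, conf = conf)
  r2 <- prr(tables, conf = conf)
  x2 <- chisq_yates(tables)
  bc <- bcpnn(tables, priors)
  expected <- (tables$a + tables$b) * (tables$a + tables$c) / tables$n
  theta <- if (identical(mgps, "fit")) fit_mgps_prior(tables$a, expected) else mgps
  eb <- ebgm_scores(tables$a, expected, theta)
  out <- data.frame(
    event = tables$event, case_reports = tables$a,
    ror = r1$ror, ror_ci_low = r1$ci_low, ror_ci_high = r1$ci_high,
    prr = r2$prr, prr_ci_low = r2$ci_low, prr_ci_high = r2$ci_high,
    chisq = x2, ic = bc$ic, ic025 = bc$ic_minus_2sd,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
    stringsAsFactors = FALSE)
  attr(out, "mgps_prior") <- theta
  evaluate_signals(out, criteria)
}
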