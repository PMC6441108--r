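## exact single-hit binomial log-likelihood and its derivative in log f
.singleHitLl <- function(lf, agg) {
  p <- pmin(pmax(1 - exp(-exp(lf) * agg$dose), 1e-300), 1 - 1e-15)
  sum(stats::dbinom(agg$n_positive, agg$n_tested, p, log = TRUE))
}

.singleHitScore <- function(lf, agg) {
  f <- exp(lf)
  p <- 1 - exp(-f * agg$dose)
  p <- pmin(pmax(p, 1e-300), 1)
  sum(agg$n_positive * agg$dose * f * exp(-f * agg$dose) / p -
        (agg$n_tested - agg$n_positive) * agg$dose * f)
}

## MLE of log f for aggregated non-boundary data. A binomial GLM with
## complementary log-log link and offset log(dose) is the standard route;
## its IRLS can run away on data that contradict the dose response, so the
## solution is accepted only if it actually zeroes the score, with a direct
## root-find of the score as fallback.
.fitLogF <- function(agg) {
  frac <- pmin(pmax(agg$n_positive / agg$n_tested, 1 / (2 * agg$n_tested)),
               1 - 1 / (2 * agg$n_tested))
  lf0 <- stats::weighted.mean(log(-log(1 - frac) / agg$dose), agg$n_tested)
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      cbind(n_positive, n_tested - n_positive) ~ 1 + offset(log(dose)),
      family = stats::binomial(link = "cloglog"), data = agg, start = lf0)),
    error = function(e) NULL)
  log_f <- if (!is.null(fit)) unname(stats::coef(fit)[1]) else NA_real_
  use_glm <- is.finite(log_f) && abs(log_f) < 30 &&
    abs(.singleHitScore(log_f, agg)) < 1e-6
  if (!use_glm) {
    log_f <- stats::uniroot(.singleHitScore, c(-50, 10), agg = agg,
                            tol = 1e-12)$root
  }
  se <- if (use_glm) sqrt(stats::vcov(fit)[1, 1]) else {
    eps <- 1e-4
    info <- -(.singleHitLl(log_f + eps, agg) - 2 * .singleHitLl(log_f, agg) +
                .singleHitLl(log_f - eps, agg)) / eps^2
    if (info > 0) 1 / sqrt(info) else NA_real_
  }
  frac_obs <- agg$n_positive / agg$n_tested
  ll_sat <- sum(stats::dbinom(agg$n_positive, agg$n_tested, frac_obs,
                              log = TRUE))
  list(log_f = log_f, se = se, ll = .singleHitLl(log_f, agg),
       deviance = 2 * (ll_sat - .singleHitLl(log_f, agg)),
       converged = if (use_glm) isTRUE(fit$converged) else TRUE)
}

#' Fit the single-hit Poisson model to limiting-dilution data
#'
#' Under the single-hit model a well (or injection) is positive iff it
#' received at least one initiating cell, so P(positive | dose d) =
#' 1 - exp(-f d) where f is the per-cell initiating frequency. The MLE of
#' log f is obtained as the intercept of a binomial GLM with a
#' complementary log-log link and offset log(dose); the 95% CI is Wald on
#' log f, reported on the familiar "1 in N" scale. Data positive (or
#' negative) in every well sit on the likelihood boundary and yield a
#' flagged one-sided exact-binomial bound instead of a point estimate.
#'
#' @param observations data.frame with columns dose, n_tested, n_positive
#'   (and optionally group); rows with equal dose are aggregated.
#' @param group label stored on the fit (defaults to the table's group
#'   column if single-valued).
#' @return an [LDAFit-class].
#' @examples
#' obs <- data.frame(dose = c(1000, 100, 10, 1), n_tested = 24,
#'                   n_positive = c(24, 10, 2, 0))
#' fitSingleHit(obs, group = "control")
#' @export
fitSingleHit <- function(observations, group = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("dose", "n_tested", "n_positive") %in% names(observations)))
  if (!nrow(observations)) stop("empty limiting-dilution table")
  if (any(observations$n_positive < 0 |
          observations$n_positive > observations$n_tested))
    stop("n_positive must lie in [0, n_tested]")
  if (any(observations$dose < 1)) stop("doses must be >= 1")
  if (is.null(group)) {
    group <- if ("group" %in% names(observations) &&
                 length(unique(observations$group)) == 1L)
      as.character(observations$group[1]) else "group"
  }
  agg <- stats::aggregate(cbind(n_tested, n_positive) ~ dose,
                          data = observations, FUN = sum)
  agg <- agg[order(agg$dose), , drop = FALSE]
  totpos <- sum(agg$n_positive)
  tottest <- sum(agg$n_tested)

  if (totpos == 0L || totpos == tottest) {
    ## boundary: one-sided exact bound at the 0.025 tail
    if (totpos == 0L) {
      ## P(all negative | f) = exp(-f * sum(n d)) = 0.025
      f <- -log(0.025) / sum(agg$n_tested * agg$dose)
      boundary <- "all_negative"
    } else {
      ## P(all positive | f) = prod (1 - exp(-f d))^n = 0.025
      g <- function(lf) {
        sum(agg$n_tested * log1p(-exp(-exp(lf) * agg$dose))) - log(0.025)
      }
      lf <- stats::uniroot(g, lower = -40, upper = 5, tol = 1e-12)$root
      f <- exp(lf)
      boundary <- "all_positive"
    }
    return(new("LDAFit", group = group, log_f = log(f), se_log_f = NA_real_,
               frequency = f, one_in = 1 / f,
               ci95_one_in = c(lower = NA_real_, upper = NA_real_),
               deviance = NA_real_, df = NA_integer_, converged = TRUE,
               boundary = boundary, observations = agg))
  }

  mle <- .fitLogF(agg)
  log_f <- mle$log_f
  se <- mle$se
  z <- stats::qnorm(0.975)
  f <- exp(log_f)
  if (f > 1)
    warning("estimated frequency exceeds 1 per cell; single-hit model strained")
  new("LDAFit", group = group, log_f = log_f, se_log_f = se,
      frequency = f, one_in = 1 / f,
      ci95_one_in = c(lower = 1 / exp(log_f + z * se),
                      upper = 1 / exp(log_f - z * se)),
      deviance = mle$deviance, df = nrow(agg) - 1L,
      converged = mle$converged, boundary = "none",
      observations = agg)
}

#' Compare initiating-cell frequencies between two groups
#'
#' Likelihood-ratio test (1 df) of a single shared frequency against
#' per-group frequencies, with the frequency ratio f_a / f_b and its Wald
#' 95% CI from the difference of log frequencies.
#'
#' @param fit_a,fit_b non-boundary [LDAFit-class] objects.
#' @return an [LDAComparison-class].
#' @export
compareGroups <- function(fit_a, fit_b) {
  stopifnot(is(fit_a, "LDAFit"), is(fit_b, "LDAFit"))
  if (fit_a@boundary != "none" || fit_b@boundary != "none")
    stop("cannot compare boundary fits (all wells positive or negative in ",
         "one group); collect informative doses first")
  oa <- fit_a@observations
  ob <- fit_b@observations
  pooled <- rbind(oa, ob)
  ll_sep <- .singleHitLl(fit_a@log_f, oa) + .singleHitLl(fit_b@log_f, ob)
  ll_pooled <- .fitLogF(pooled)$ll
  lrt <- max(0, 2 * (ll_sep - ll_pooled))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  d <- fit_a@log_f - fit_b@log_f
  sed <- sqrt(fit_a@se_log_f^2 + fit_b@se_log_f^2)
  z <- stats::qnorm(0.975)
  new("LDAComparison",
      groups = c(fit_a@group, fit_b@group),
      frequency_ratio = exp(d),
      ratio_ci95 = c(lower = exp(d - z * sed), upper = exp(d + z * sed)),
      lrt_statistic = lrt, lrt_df = 1L, p = p)
}

#' Single-hit model adequacy check
#'
#' Compares the residual deviance of an [LDAFit-class] against a
#' chi-square with (number of doses - 1) degrees of freedom; warns when
#' the tail probability falls below 0.05 or when the observed positive
#' fraction is non-monotone in dose.
#'
#' @param fit an [LDAFit-class] from at least two distinct doses.
#' @return list with `applicable`, `deviance`, `df`, `p`.
#' @export
goodnessOfFit <- function(fit) {
  stopifnot(is(fit, "LDAFit"))
  agg <- fit@observations
  if (nrow(agg) < 2L || fit@boundary != "none")
    return(list(applicable = FALSE, deviance = NA_real_, df = NA_integer_,
                p = NA_real_))
  frac <- agg$n_positive / agg$n_tested
  o <- order(agg$dose)
  if (any(diff(frac[o]) < 0))
    warning("positive fraction decreases with dose; single-hit model suspect")
  p <- stats::pchisq(fit@deviance, df = fit@df, lower.tail = FALSE)
  if (p < 0.05)
    warning("single-hit model fits poorly (deviance p = ",
            format(p, digits = 3), ")")
  list(applicable = TRUE, deviance = fit@deviance, df = fit@df, p = p)
}

#' Read a limiting-dilution outcome table
#'
#' @param path TSV with header columns group, dose, n_tested, n_positive.
#' @return data.frame.
#' @export
readLdaTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("group", "dose", "n_tested", "n_positive")
  if (!all(need %in% names(tab)))
    stop("LDA table needs columns: ", paste(need, collapse = ", "))
  tab
}
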