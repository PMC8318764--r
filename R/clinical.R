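# Early neurological deterioration (END) after intravenous thrombolysis:
# the NIHSS-based diagnostic rule, 2x2 contingency statistics, and logistic
# regression by IRLS.

#' NIHSS trajectory
#'
#' Scores at the five assessment timepoints: 4 hours before thrombolysis
#' (baseline), immediately after, and 4 h / 24 h / 1 week after. All scores
#' must be integers in \[0, 42\] (the NIHSS range).
#'
#' @param baseline,post_thrombolysis,h4,h24,week1 integer scores.
#' @return object of class `nihss_trajectory`.
#' @export
nihss_trajectory <- function(baseline, post_thrombolysis, h4, h24, week1) {
  sc <- c(baseline = baseline, post_thrombolysis = post_thrombolysis,
          h4 = h4, h24 = h24, week1 = week1)
  if (any(!is.finite(sc)) || any(sc != round(sc)) || any(sc < 0 | sc > 42))
    stop_param("NIHSS scores must be integers in [0, 42]")
  structure(as.list(stats::setNames(as.integer(sc), names(sc))),
            class = "nihss_trajectory")
}

#' Classify early neurological deterioration
#'
#' Baseline-dependent rule (the study's diagnostic criterion): END iff the
#' 24-hour increase over baseline is at least 2 points when the baseline
#' NIHSS is below 6, or at least 4 points when the baseline is 6 or more.
#' General rule: END iff the increase is at least 4 points regardless of
#' baseline. Thresholds are inclusive.
#'
#' @param trajectory an [nihss_trajectory()], or a list/data.frame row with
#'   `baseline` and `h24`.
#' @param rule `"baseline-dependent"` (default) or `"general-delta4"`.
#' @return logical.
#' @export
classify_end <- function(trajectory, rule = c("baseline-dependent", "general-delta4")) {
  rule <- match.arg(rule)
  b <- trajectory$baseline; h24 <- trajectory$h24
  if (any(!is.finite(c(b, h24))) || any(c(b, h24) < 0 | c(b, h24) > 42))
    stop_param("scores must lie in [0, 42]")
  delta <- h24 - b
  if (rule == "general-delta4") delta >= 4
  else ifelse(b < 6, delta >= 2, delta >= 4)
}

#' Percentage of a count over a total
#'
#' @param count integer in `[0, total]`. @param total positive integer.
#' @param digits decimals to round to (default 2, the usual printed
#'   precision; use `NULL` for the unrounded value).
#' @return percentage on the 0-100 scale.
#' @export
proportion_pct <- function(count, total, digits = 2) {
  if (total <= 0) stop_param("undefined rate: total must be > 0")
  if (count < 0 || count > total) stop_param("need 0 <= count <= total")
  p <- 100 * count / total
  if (is.null(digits)) p else round(p, digits)
}

#' 2x2 contingency table
#'
#' Exposure x outcome counts: `a` exposed/outcome+, `b` exposed/outcome-,
#' `c` unexposed/outcome+, `d` unexposed/outcome-.
#' @param a,b,c,d non-negative integer counts, total > 0.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop_param("counts must be non-negative integers")
  if (sum(cnt) == 0) stop_param("table total must be > 0")
  structure(as.list(cnt), class = "contingency_2x2")
}

as_matrix_2x2 <- function(tab) matrix(c(tab$a, tab$c, tab$b, tab$d), 2, 2)

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)` with a log-normal (Woolf) interval. If any cell is
#' zero, the Haldane-Anscombe 0.5 correction is added to every cell and the
#' output is flagged.
#'
#' @param table a [contingency_2x2()]. @param ci_level coverage in (0, 1).
#' @return list with `or`, `ci_low`, `ci_high`, `ci_level`, `corrected`.
#' @export
odds_ratio <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (ci_level <= 0 || ci_level >= 1) stop_param("ci_level must be in (0, 1)")
  x <- c(table$a, table$b, table$c, table$d)
  corrected <- any(x == 0)
  if (corrected) {
    # degenerate even after correction: a full zero margin carries no signal
    if ((table$a + table$b == 0) || (table$c + table$d == 0) ||
        (table$a + table$c == 0) || (table$b + table$d == 0))
      stop_param("degenerate table: a zero margin has no estimable odds ratio")
    x <- x + 0.5
  }
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       ci_level = ci_level, corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default (`yates = TRUE` applies the
#' Yates correction). p-value from the chi-square distribution with 1
#' degree of freedom. An expected cell below 1 sets `small_expected` in the
#' output instead of failing.
#'
#' @param table a [contingency_2x2()]. @param yates logical.
#' @return list with `statistic`, `p`, `df`, `small_expected`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  O <- as_matrix_2x2(table)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) stop_param("degenerate table: zero margin")
  dev <- abs(O - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, small_expected = any(E < 1))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `logit P(outcome) = b0 + X b` (Newton/IRLS,
#' relative coefficient tolerance 1e-8, at most 100 iterations). Reports,
#' per covariate: coefficient B, its standard error, the Wald statistic
#' `(B/SE)^2`, `OR = exp(B)`, the Wald 95\% CI on the OR scale, and the
#' two-sided p-value. Complete or quasi-complete separation is flagged per
#' covariate (`estimable = FALSE`) rather than raised.
#'
#' @param records data.frame of patient records (e.g. from
#'   [simulate_cohort()]).
#' @param covariates character vector of numeric/logical column names.
#' @param outcome outcome column name (logical or 0/1), default
#'   `"end_label"`.
#' @param ci_level Wald CI coverage.
#' @return data.frame with one row per term (intercept first) and columns
#'   `term`, `beta`, `se`, `wald`, `or`, `ci_low`, `ci_high`, `p`,
#'   `estimable`; attributes `converged`, `iterations`, `loglik`.
#' @export
fit_logistic <- function(records, covariates, outcome = "end_label", ci_level = 0.95) {
  records <- as.data.frame(records)
  if (!all(c(covariates, outcome) %in% names(records)))
    stop_param("missing columns in records")
  y <- as.numeric(records[[outcome]])
  if (length(y) < 10 * length(covariates))
    stop_param("need at least 10 records per covariate")
  if (all(y == y[1])) stop_param("outcome has no variation")
  X <- cbind(`(intercept)` = 1,
             as.matrix(as.data.frame(lapply(records[covariates], as.numeric))))
  colnames(X) <- c("(intercept)", covariates)
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(100L)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtW <- t(X * w)
    H <- XtW %*% X
    g <- t(X) %*% (y - mu)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta)) break
    beta <- beta + as.vector(delta)
    if (sqrt(sum(delta^2)) <= 1e-8 * max(1, sqrt(sum(beta^2)))) { converged <- TRUE; break }
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- t(X * w) %*% X
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  # separation heuristic: runaway coefficient or exploding SE
  estimable <- is.finite(se) & se < 1e3 & abs(beta) < 15
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(term = colnames(X), beta = beta, se = se,
                    wald = (beta / se)^2, or = exp(beta),
                    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    estimable = estimable, row.names = NULL)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "loglik") <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  out
}

#' Univariate screening for model entry
#'
#' Screens each candidate covariate in a single-covariate logistic fit and
#' keeps those with `p < threshold` (the conventional lenient entry
#' criterion for multivariate modelling).
#'
#' @param records data.frame. @param candidates covariate names.
#' @param threshold entry p-value threshold (default 0.2).
#' @param outcome outcome column.
#' @return character vector of retained covariate names.
#' @export
screen_covariates <- function(records, candidates, threshold = 0.2, outcome = "end_label") {
  keep <- character(0)
  for (cv in candidates) {
    fit <- fit_logistic(records, cv, outcome = outcome)
    pv <- fit$p[fit$term == cv]
    if (is.finite(pv) && pv < threshold) keep <- c(keep, cv)
  }
  keep
}
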