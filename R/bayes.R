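#' @importFrom stats dcauchy dbeta dt integrate optimize setNames var sd
NULL

# ---------------------------------------------------------------------------
# bayes_result container

new_bayes_result <- function(family, bf10, effect_size, ci95, prior, n_info,
                             rounded_input = FALSE, detail = list()) {
  stopifnot(is.numeric(bf10), bf10 > 0)
  structure(
    list(family = family, bf10 = bf10, bf01 = 1 / bf10,
         effect_size = effect_size, ci95 = ci95, prior = prior,
         n_info = n_info, rounded_input = rounded_input, detail = detail),
    class = "bayes_result"
  )
}

#' @export
print.bayes_result <- function(x, ...) {
  cat("<bayes_result> family:", x$family, "\n")
  cat("  BF10 =", format(x$bf10, digits = 4),
      " (BF01 =", format(x$bf01, digits = 4), ")\n")
  if (!is.null(x$effect_size) && !is.na(x$effect_size)) {
    cat("  effect size =", format(x$effect_size, digits = 3),
        " 95% CI [", format(x$ci95[1], digits = 3), ",",
        format(x$ci95[2], digits = 3), "]\n")
  }
  cat("  prior:", paste(names(x$prior), unlist(x$prior), sep = " = ",
                        collapse = ", "), "\n")
  cat("  n: ", paste(names(x$n_info), unlist(x$n_info), sep = " = ",
                     collapse = ", "),
      if (isTRUE(x$rounded_input)) " [rounded-input summaries]" else "",
      "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JZS t-family machinery

# log prior density of g: inverse-gamma(1/2, r^2/2), the mixing density whose
# marginal over the normal effect prior is a Cauchy(0, r) on delta
log_dinvgamma_g <- function(g, r) {
  0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
}

# log of the conditional Bayes factor BF(g) for the t statistic:
# marginal likelihood ratio of the g-scaled effect model vs the point null
log_bf_t_given_g <- function(g, t, df, neff) {
  -0.5 * log1p(neff * g) -
    (df + 1) / 2 * log1p(t^2 / ((1 + neff * g) * df)) +
    (df + 1) / 2 * log1p(t^2 / df)
}

# JZS Bayes factor by adaptive quadrature over u = log(g); log scale
# throughout so extreme t statistics do not overflow
log_bf10_jzs <- function(t, df, neff, r) {
  stopifnot(df > 0, neff > 0, r > 0)
  logf <- function(u) {
    log_bf_t_given_g(exp(u), t, df, neff) +
      log_dinvgamma_g(exp(u), r) + u
  }
  opt <- optimize(logf, interval = c(-40, 40), maximum = TRUE)
  m <- opt$objective
  val <- integrate(clamped_exp(logf, m), lower = -Inf, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)
  if (val$message != "OK" || !is.finite(val$value) || val$value <= 0) {
    stop("JZS integration failed: ", val$message, " (t = ", t, ", df = ",
         df, ")", call. = FALSE)
  }
  m + log(val$value)
}

# exp(logf(u) - m) with the far-tail Inf - Inf indeterminacies mapped to 0
clamped_exp <- function(logf, m) {
  function(u) {
    v <- exp(logf(u) - m)
    v[!is.finite(v)] <- 0
    v
  }
}

# posterior median and central 95% interval for delta under the Cauchy prior,
# by dense-grid quadrature of prior x noncentral-t likelihood
delta_posterior_summary <- function(t, df, neff, r, n_grid = 4001L) {
  d_hat <- t / sqrt(neff)
  se <- sqrt(1 / neff + d_hat^2 / (2 * max(df, 1)))
  lo <- min(d_hat - 8 * se, -2 * r)
  hi <- max(d_hat + 8 * se, 2 * r)
  delta <- seq(lo, hi, length.out = n_grid)
  logpost <- dcauchy(delta, 0, r, log = TRUE) +
    suppressWarnings(dt(t, df, ncp = delta * sqrt(neff), log = TRUE))
  logpost <- logpost - max(logpost)
  w <- exp(logpost)
  cdf <- cumsum(w) - w / 2
  cdf <- cdf / (sum(w))
  qfun <- stats::approxfun(cdf, delta, rule = 2, ties = "ordered")
  c(median = qfun(0.5), lower = qfun(0.025), upper = qfun(0.975))
}

jzs_result <- function(family, t, df, neff, r, n_info, rounded_input,
                       detail = list()) {
  lbf <- log_bf10_jzs(t, df, neff, r)
  post <- delta_posterior_summary(t, df, neff, r)
  new_bayes_result(
    family = family,
    bf10 = exp(lbf),
    effect_size = unname(post["median"]),
    ci95 = unname(post[c("lower", "upper")]),
    prior = list(cauchy_width = r),
    n_info = n_info,
    rounded_input = rounded_input,
    detail = c(detail, list(t = t, df = df, neff = neff, log_bf10 = lbf))
  )
}

#' Default Bayesian independent-samples t test
#'
#' JZS Bayes factor for a two-group mean difference against the point null,
#' with a Cauchy prior of width `cauchy_width` on the standardized effect
#' size delta. Accepts either raw vectors (`x`, `y`) or the printed summary
#' statistics (`m1, sd1, n1, m2, sd2, n2`); summaries imply the pooled- or
#' Welch-variance t statistic. Effect sizes are reported as the posterior
#' median of delta with its central 95% credible interval; positive delta
#' means the first group is larger.
#'
#' @param x,y Raw value vectors (optional).
#' @param m1,sd1,n1,m2,sd2,n2 Summary statistics (used when `x` is NULL).
#' @param cauchy_width Cauchy prior scale on delta (default 0.707).
#' @param variance_rule `"pooled"` (default) or `"welch"`.
#' @return A `bayes_result`.
#' @examples
#' bf_ttest_independent(m1 = 70.6, sd1 = 14.9, n1 = 36,
#'                      m2 = 68.4, sd2 = 30.3, n2 = 46)
#' @export
bf_ttest_independent <- function(x = NULL, y = NULL,
                                 m1 = NULL, sd1 = NULL, n1 = NULL,
                                 m2 = NULL, sd2 = NULL, n2 = NULL,
                                 cauchy_width = sqrt(2) / 2,
                                 variance_rule = c("pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  rounded <- is.null(x)
  if (!is.null(x)) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    m1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    m2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2)
  if (!is.finite(sd1) || !is.finite(sd2) || (sd1 <= 0 && sd2 <= 0)) {
    stop("degenerate variance: both group SDs are zero", call. = FALSE)
  }
  if (variance_rule == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("degenerate pooled variance", call. = FALSE)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v <- sd1^2 / n1 + sd2^2 / n2
    t <- (m1 - m2) / sqrt(v)
    df <- v^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  neff <- n1 * n2 / (n1 + n2)
  jzs_result("independent_t", t, df, neff, cauchy_width,
             n_info = list(n1 = n1, n2 = n2), rounded_input = rounded,
             detail = list(variance_rule = variance_rule,
                           mean_diff = m1 - m2))
}

#' Default Bayesian paired (one-sample) t test
#'
#' One-sample JZS Bayes factor on within-subject differences, Cauchy prior
#' of width `cauchy_width` on delta. Accepts paired raw vectors or the
#' summary of the differences.
#'
#' @param x,y Paired raw vectors (optional; differences are `x - y`).
#' @param mean_diff,sd_diff,n Summary of the differences (used when `x` is
#'   NULL).
#' @param cauchy_width Cauchy prior scale on delta (default 0.707).
#' @return A `bayes_result`.
#' @examples
#' bf_ttest_paired(mean_diff = -10.25, sd_diff = 4.9, n = 20)
#' @export
bf_ttest_paired <- function(x = NULL, y = NULL,
                            mean_diff = NULL, sd_diff = NULL, n = NULL,
                            cauchy_width = sqrt(2) / 2) {
  rounded <- is.null(x)
  if (!is.null(x)) {
    if (is.null(y)) y <- rep(0, length(x))
    stopifnot(length(x) == length(y))
    d <- x - y
    d <- d[!is.na(d)]
    mean_diff <- mean(d); sd_diff <- sd(d); n <- length(d)
  }
  stopifnot(n >= 2)
  if (!is.finite(sd_diff) || sd_diff <= 0) {
    stop("degenerate variance of the differences", call. = FALSE)
  }
  t <- mean_diff / (sd_diff / sqrt(n))
  jzs_result("paired_t", t, df = n - 1, neff = n, r = cauchy_width,
             n_info = list(n = n), rounded_input = rounded,
             detail = list(mean_diff = mean_diff))
}

# ---------------------------------------------------------------------------
# correlation family

# log Gauss hypergeometric 2F1(a, b; c; z) by power series, valid for
# 0 <= z < 1; with c large (c = n - 1/2) convergence is fast
log_hyp2f1_series <- function(a, b, c, z, tol = 1e-15, max_iter = 10000L) {
  stopifnot(z >= 0, z < 1)
  term <- 1
  total <- 1
  for (k in 0:(max_iter - 1L)) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) break
  }
  log(total)
}

# log exact sampling density of the Pearson correlation r given rho, n
# (Hotelling's form with a single hypergeometric term)
log_dr_given_rho <- function(r, rho, n, hyp2f1 = log_hyp2f1_series) {
  log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r) +
    hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

# stretched-beta prior density on rho in (-1, 1) with width kappa:
# (rho+1)/2 ~ Beta(1/kappa, 1/kappa)
dstretched_beta <- function(rho, kappa) {
  dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
}

#' Default Bayesian Pearson correlation
#'
#' Jeffreys-style two-sided Bayes factor for a Pearson correlation,
#' computed from the sufficiency of (r, n): the exact sampling density of r
#' given rho is integrated against a stretched-beta prior of width
#' `beta_width` (width 1 is uniform on (-1, 1)) and compared with the null
#' density at rho = 0. Accepts raw pairs or (r, n) directly.
#'
#' @param x,y Raw paired vectors (optional).
#' @param r Observed Pearson correlation, |r| < 1 (used when `x` is NULL).
#' @param n Number of pairs (>= 3).
#' @param beta_width Stretched-beta prior width kappa (default 1).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   one-sided tests fold the prior onto positive or negative rho.
#' @return A `bayes_result` with the posterior median of rho and its 95%
#'   credible interval.
#' @examples
#' bf_correlation(r = 0.105, n = 20)
#' @export
bf_correlation <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                           beta_width = 1,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  rounded <- is.null(x)
  if (!is.null(x)) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    r <- stats::cor(x, y)
  }
  stopifnot(is.numeric(r), is.numeric(n), n >= 3)
  if (!is.finite(r) || abs(r) >= 1) {
    stop("|r| must be < 1 (degenerate or perfectly collinear data)",
         call. = FALSE)
  }
  support <- switch(alternative,
                    two.sided = c(-1, 1),
                    greater = c(0, 1),
                    less = c(-1, 0))
  fold <- if (alternative == "two.sided") 1 else 2
  log_null <- log_dr_given_rho(r, 0, n)
  integrand <- function(rho) {
    vapply(rho, function(p) {
      exp(log_dr_given_rho(r, p, n) - log_null) *
        fold * dstretched_beta(p, beta_width)
    }, numeric(1))
  }
  val <- integrate(integrand, lower = support[1], upper = support[2],
                   rel.tol = 1e-10, subdivisions = 500L)
  if (val$message != "OK" || !is.finite(val$value) || val$value <= 0) {
    stop("correlation BF integration failed: ", val$message, call. = FALSE)
  }
  bf10 <- val$value
  # posterior of rho on a dense open grid over the prior's support
  rho <- seq(max(support[1], -1 + 1e-6), min(support[2], 1 - 1e-6),
             length.out = 4001L)
  logpost <- vapply(rho, function(p) log_dr_given_rho(r, p, n), numeric(1)) +
    log(dstretched_beta(rho, beta_width))
  logpost <- logpost - max(logpost)
  w <- exp(logpost)
  cdf <- (cumsum(w) - w / 2) / sum(w)
  qfun <- stats::approxfun(cdf, rho, rule = 2, ties = "ordered")
  new_bayes_result(
    family = "correlation", bf10 = bf10,
    effect_size = qfun(0.5), ci95 = c(qfun(0.025), qfun(0.975)),
    prior = list(beta_width = beta_width, alternative = alternative),
    n_info = list(n = n), rounded_input = rounded,
    detail = list(r = r)
  )
}

# ---------------------------------------------------------------------------
# one-way ANOVA with a default g prior on standardized group effects

# log conditional Bayes factor BF(g) for a one-way layout, from the group
# sizes nj, group sums sj, total sum of squares ssy = sum(y^2).
# Group effects carry a N(0, g sigma^2 I) prior in an orthonormal
# sum-to-zero basis Q (so the implied prior on a two-group standardized
# difference is N(0, 2g)); mean and variance get the Jeffreys prior.
# Everything reduces to (k-1) x (k-1) linear algebra via Woodbury, which
# stays well conditioned for arbitrarily large g.
log_bf_anova_given_g <- function(g, nj, sj, ssy) {
  k <- length(nj)
  N <- sum(nj)
  G <- sum(sj)
  Q <- qr.Q(qr(stats::contr.helmert(k)))   # k x (k-1), orthonormal, 1'Q = 0
  A <- crossprod(Q, nj * Q)                # Q' D Q
  B <- solve(diag(k - 1L) + g * A)
  qn <- drop(crossprod(Q, nj))
  qs <- drop(crossprod(Q, sj))
  one_v_one <- N - g * drop(t(qn) %*% B %*% qn)
  one_v_y <- G - g * drop(t(qn) %*% B %*% qs)
  y_v_y <- ssy - g * drop(t(qs) %*% B %*% qs)
  logdet <- as.numeric(
    determinant(diag(k - 1L) + g * A, logarithm = TRUE)$modulus
  )
  r_g <- y_v_y - one_v_y^2 / one_v_one
  r_0 <- ssy - G^2 / N
  lratio <- if (r_0 <= 0) 0 else log(r_g / r_0)
  -0.5 * (logdet + log(one_v_one / N)) - (N - 1) / 2 * lratio
}

#' Default Bayesian one-way ANOVA
#'
#' Bayes factor for group mean differences against the grand-mean null,
#' with a default g prior on standardized group effects (scale
#' `g_prior_scale` = 0.5 for fixed effects) mixed over an inverse-gamma
#' density, integrated numerically in one dimension. With two balanced
#' groups this is equivalent to the JZS t test at Cauchy width
#' `sqrt(2) * g_prior_scale`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   n >= 2), or a single data vector with `g` a grouping factor.
#' @param g Optional grouping factor when `groups` is a vector.
#' @param g_prior_scale Prior scale on standardized effects (default 0.5).
#' @return A `bayes_result` (no single effect-size summary is reported for
#'   k > 2 designs; the detail slot carries R-squared).
#' @export
bf_anova_oneway <- function(groups, g = NULL, g_prior_scale = 0.5) {
  if (!is.list(groups)) {
    stopifnot(!is.null(g), length(g) == length(groups))
    groups <- split(as.numeric(groups), g)
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  nj <- vapply(groups, length, integer(1))
  if (any(nj < 2L)) stop("every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  sj <- vapply(groups, sum, numeric(1))
  ssy <- sum(y^2)
  N <- sum(nj)
  sst <- ssy - sum(y)^2 / N
  ssb <- sum(sj^2 / nj) - sum(y)^2 / N
  if (sst - ssb <= 1e-12 * max(sst, 1) && ssb > 0) {
    # zero within-group variance with distinct means: the evidence for a
    # group effect is unbounded (perfect separation)
    warning("zero within-group variance with distinct group means; ",
            "Bayes factor is infinite", call. = FALSE)
    return(new_bayes_result(
      family = "anova_oneway", bf10 = Inf,
      effect_size = NA_real_, ci95 = c(NA_real_, NA_real_),
      prior = list(g_prior_scale = g_prior_scale),
      n_info = as.list(setNames(nj, paste0("n", seq_len(k)))),
      detail = list(k = k, r_squared = 1)))
  }
  logf <- function(u) {
    vapply(u, function(ui) {
      log_bf_anova_given_g(exp(ui), nj, sj, ssy) +
        log_dinvgamma_g(exp(ui), g_prior_scale) + ui
    }, numeric(1))
  }
  opt <- optimize(logf, interval = c(-40, 40), maximum = TRUE)
  m <- opt$objective
  val <- integrate(clamped_exp(logf, m), lower = -Inf, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 0, subdivisions = 500L)
  if (val$message != "OK" || !is.finite(val$value) || val$value <= 0) {
    stop("ANOVA BF integration failed: ", val$message, call. = FALSE)
  }
  bf10 <- exp(m + log(val$value))
  new_bayes_result(
    family = "anova_oneway", bf10 = bf10,
    effect_size = NA_real_, ci95 = c(NA_real_, NA_real_),
    prior = list(g_prior_scale = g_prior_scale),
    n_info = as.list(setNames(nj, paste0("n", seq_len(k)))),
    detail = list(k = k, r_squared = if (sst > 0) ssb / sst else NA_real_)
  )
}

# ---------------------------------------------------------------------------
# contingency tables (Gunel-Dickey independent multinomial, rows fixed)

lmbeta <- function(alpha) sum(lgamma(alpha)) - lgamma(sum(alpha))

#' Default Bayesian contingency-table test
#'
#' Gunel-Dickey Bayes factor for association versus independence in an
#' r x k count table under independent-multinomial sampling with row
#' margins fixed (each row a multinomial with a symmetric Dirichlet prior
#' of the given concentration; the matched null prior pools the rows).
#' Closed form in log-gamma functions.
#'
#' @param table Matrix of nonnegative integer counts (>= 2 columns).
#' @param concentration Dirichlet prior concentration a (default 1).
#' @return A `bayes_result`.
#' @examples
#' bf_contingency(matrix(c(24, 35, 12, 11), nrow = 2))
#' @export
bf_contingency <- function(table, concentration = 1) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (ncol(table) < 2L || nrow(table) < 2L) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has an all-zero margin", call. = FALSE)
  }
  a <- concentration
  r <- nrow(table); k <- ncol(table)
  a_row <- rep(a, k)
  a_null <- rep(r * a, k)
  log_m1 <- sum(apply(table, 1, function(y) lmbeta(a_row + y) - lmbeta(a_row)))
  log_m0 <- lmbeta(a_null + colSums(table)) - lmbeta(a_null)
  bf10 <- exp(log_m1 - log_m0)
  new_bayes_result(
    family = "contingency", bf10 = bf10,
    effect_size = NA_real_, ci95 = c(NA_real_, NA_real_),
    prior = list(concentration = a, sampling = "independent_multinomial_rows"),
    n_info = list(n = sum(table)),
    detail = list(dim = dim(table))
  )
}
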