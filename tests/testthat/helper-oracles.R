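# Independent oracles and tiny fixtures shared across the suite.

# the three-token toy table used throughout
toy_table <- function() {
  m <- rbind(cat = c(1, 0, 0), dog = c(0, 1, 0), the = c(0, 0, 1))
  embedding_table(m, case = "lower", source_label = "toy")
}

random_unit_matrix <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# brute-force double-loop oracle for the full-frame mean similarity
oracle_asw_full <- function(seq, pair_mode = "all_pairs") {
  n <- nrow(seq)
  if (n < 2) return(NA_real_)
  if (pair_mode == "adjacent") {
    return(mean(vapply(seq_len(n - 1), function(i) {
      cosine_similarity(seq[i, ], seq[i + 1, ])
    }, numeric(1))))
  }
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, cosine_similarity(seq[i, ], seq[j, ]))
    }
  }
  mean(vals)
}

# enumerate every window position explicitly
oracle_asw_window <- function(seq, window = 10, pair_mode = "all_pairs") {
  n <- nrow(seq)
  if (n < 2) return(NA_real_)
  if (n <= window) return(oracle_asw_full(seq, pair_mode))
  starts <- seq_len(n - window + 1)
  mean(vapply(starts, function(s) {
    oracle_asw_full(seq[s:(s + window - 1), , drop = FALSE], pair_mode)
  }, numeric(1)))
}

# JZS Bayes factor through a mathematically different route than the
# implementation: integrate the noncentral-t likelihood over the Cauchy
# prior on delta (the implementation integrates over the g mixing variable)
oracle_bf_jzs <- function(t, df, neff, r = sqrt(2) / 2) {
  num <- integrate(function(delta) {
    suppressWarnings(dt(t, df, ncp = delta * sqrt(neff))) *
      dcauchy(delta, 0, r)
  }, lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  num / dt(t, df)
}

# Gauss hypergeometric via the Euler integral representation (the
# implementation uses the power series)
euler_hyp2f1 <- function(a, b, c, z) {
  val <- integrate(function(t) {
    t^(b - 1) * (1 - t)^(c - b - 1) * (1 - z * t)^(-a)
  }, lower = 0, upper = 1, rel.tol = 1e-12)$value
  log(val) + lgamma(c) - lgamma(b) - lgamma(c - b)
}

oracle_bf_correlation <- function(r, n, kappa = 1) {
  logd <- function(robs, rho) {
    log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
      ((n - 4) / 2) * log1p(-robs^2) - 0.5 * log(2 * pi) -
      lgamma(n - 0.5) - (n - 1.5) * log1p(-rho * robs) +
      euler_hyp2f1(0.5, 0.5, n - 0.5, (rho * robs + 1) / 2)
  }
  ln0 <- logd(r, 0)
  integrate(function(rho) {
    vapply(rho, function(p) {
      exp(logd(r, p) - ln0) * dbeta((p + 1) / 2, 1 / kappa, 1 / kappa) / 2
    }, numeric(1))
  }, lower = -1, upper = 1, rel.tol = 1e-10)$value
}

# one-way ANOVA Bayes factor on the original k x k algebra (full sum-to-zero
# projection, no reduced basis) and with the integral taken over
# z = g / (1 + g) on (0, 1) instead of log g on the real line
oracle_bf_anova <- function(groups, scale = 0.5) {
  nj <- vapply(groups, length, integer(1))
  sj <- vapply(groups, sum, numeric(1))
  y <- unlist(groups)
  ssy <- sum(y^2)
  k <- length(nj); N <- sum(nj); G <- sum(y)
  log_bf_g <- function(g) {
    P <- diag(k) - matrix(1 / k, k, k)
    D <- diag(nj, k)
    M <- solve(diag(k) + g * D %*% P)
    PM <- P %*% M
    ovo <- N - g * drop(t(nj) %*% PM %*% nj)
    ovy <- G - g * drop(t(nj) %*% PM %*% sj)
    yvy <- ssy - g * drop(t(sj) %*% PM %*% sj)
    ld <- as.numeric(determinant(diag(k) + g * P %*% D, TRUE)$modulus)
    r_g <- yvy - ovy^2 / ovo
    r_0 <- ssy - G^2 / N
    -0.5 * (ld + log(ovo / N)) - (N - 1) / 2 * log(r_g / r_0)
  }
  log_prior <- function(g) {
    0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - scale^2 / (2 * g)
  }
  integrate(function(z) {
    vapply(z, function(zi) {
      g <- zi / (1 - zi)
      exp(log_bf_g(g) + log_prior(g)) / (1 - zi)^2
    }, numeric(1))
  }, lower = 0, upper = 1, rel.tol = 1e-10)$value
}

# 2 x 2 Gunel-Dickey independent-multinomial BF by direct numeric beta
# integrals (the implementation uses the closed log-gamma form). Each row
# has its own theta ~ Beta(a, a) under association; under independence the
# rows share one theta ~ Beta(2a, 2a) (the matched pooled prior). The
# multinomial coefficients cancel between the two marginals.
oracle_bf_contingency_2x2 <- function(tab, a = 1) {
  row_marg <- function(y1, y2, a1, a2) {
    integrate(function(th) th^y1 * (1 - th)^y2 * dbeta(th, a1, a2),
              0, 1, rel.tol = 1e-12)$value
  }
  m1 <- row_marg(tab[1, 1], tab[1, 2], a, a) *
    row_marg(tab[2, 1], tab[2, 2], a, a)
  m0 <- row_marg(sum(tab[, 1]), sum(tab[, 2]), 2 * a, 2 * a)
  m1 / m0
}

# build a tiny deterministic cohort for pipeline tests (returns the loaded
# cohort plus its generator pieces)
tiny_cohort <- function(seed = 11, p_hc = 0.75, p_fes = 0.9,
                        n_FES = 12, n_HC = 10, fu_FES = 6, fu_HC = 5) {
  cfg <- synth_config(n_FES = n_FES, n_HC = n_HC,
                      n_followup_FES = fu_FES, n_followup_HC = fu_HC)
  gen <- synth_embedding(cfg, seed = seed)
  ps <- list(HC = c(baseline = p_hc, followup = p_hc),
             FES = c(baseline = p_fes, followup = min(1, p_fes + 0.05)))
  coh <- synth_cohort(cfg, seed = seed, gen = gen, p_stay = ps)
  cc <- suppressWarnings(suppressMessages(
    load_cohort(coh$metadata, coh$transcripts, gen$table,
                stoplist = gen$stop_tokens)))
  list(cfg = cfg, gen = gen, synth = coh, cohort = cc)
}
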