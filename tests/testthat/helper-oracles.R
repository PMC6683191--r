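# Independent oracles used to cross-check the package's own estimators and
# selection logic. These deliberately take different computational routes
# (lm() fits, explicit loops) from the implementation.

# Weighted least squares through the origin via lm(); returns slope, the
# fixed-effect SE recovered from lm's scaled SE, Cochran's Q, and the
# random-effects SE with the dispersion floored at 1.
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- lm(by ~ 0 + bx, weights = w)
  slope <- unname(coef(fit)[1])
  q <- sum(w * residuals(fit)^2)
  j <- length(bx)
  sigma <- summary(fit)$sigma                   # sqrt(Q/(J-1))
  se_fixed <- unname(summary(fit)$coefficients[1, 2]) / sigma
  se_re <- se_fixed * max(1, sigma)
  list(slope = slope, se_fixed = se_fixed, se = se_re, q = q,
       p = 2 * pnorm(-abs(slope / se_re)))
}

# Weighted least squares with intercept via lm(), after orienting every
# instrument to a positive exposure effect.
oracle_egger <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  x <- s * bx; y <- s * by
  w <- 1 / sy^2
  fit <- lm(y ~ x, weights = w)
  q <- sum(w * residuals(fit)^2)
  j <- length(bx)
  sigma <- summary(fit)$sigma                   # sqrt(Q/(J-2))
  se_fixed <- summary(fit)$coefficients[, 2] / sigma
  mult <- max(1, sigma)
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       slope_se = unname(se_fixed["x"]) * mult,
       intercept_se = unname(se_fixed["(Intercept)"]) * mult,
       q = q)
}

# Interpolated weighted median by explicit scan of the crossing point.
oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  w <- w / sum(w)
  p <- numeric(length(v))
  acc <- 0
  for (i in seq_along(v)) {
    p[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (p[1] >= 0.5) return(v[1])
  if (p[length(p)] <= 0.5) return(v[length(v)])
  for (i in seq_len(length(v) - 1)) {
    if (p[i] < 0.5 && p[i + 1] >= 0.5) {
      return(v[i] + (v[i + 1] - v[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("no crossing found")
}

# Brute-force greedy thinning: visit candidates by ascending p (ties by
# chrom, bp, id), keep unless some kept variant is within the window AND
# correlated above the cutoff. r2 looked up pair-by-pair in a plain
# data.frame.
oracle_greedy_select <- function(df, ld_df, p_threshold = 5e-8,
                                 window_cm = 3, r2_max = 0.05) {
  lookup <- function(a, b) {
    hit <- which((ld_df$a == a & ld_df$b == b) | (ld_df$a == b & ld_df$b == a))
    if (length(hit) == 0) 0 else ld_df$r2[hit[1]]
  }
  cand <- df[df$p < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(cand$p, suppressWarnings(as.numeric(cand$chrom)),
                     cand$chrom, cand$pos_bp, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      kc <- df$pos_cm[df$variant_id == k]
      if (abs(kc - cand$pos_cm[i]) <= window_cm &&
          lookup(k, cand$variant_id[i]) > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, cand$variant_id[i])
  }
  kept
}

# Liability-scale conversion coded directly from the threshold model.
oracle_liability_ve <- function(eaf, beta_logodds, K, P) {
  t <- qnorm(1 - K)
  z <- exp(-t^2 / 2) / sqrt(2 * pi)
  beta_obs <- beta_logodds * P * (1 - P)
  h2_obs <- sum(2 * eaf * (1 - eaf) * beta_obs^2)
  100 * h2_obs * (K * (1 - K))^2 / (z^2 * P * (1 - P))
}
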