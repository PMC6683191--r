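#' Assemble estimator input from per-variant effect estimates
#'
#' Parallel vectors of exposure and outcome association estimates for the
#' selected instruments: exposure effects in phenotype-SD units, outcome
#' effects in log-odds (binary outcome) or SD units.
#'
#' @param bx,sx exposure effect estimates and standard errors.
#' @param by,sy outcome effect estimates and standard errors.
#' @param variant_ids optional variant ids (defaults to `snp_1`, ...).
#' @return An object of class `"mr_input"`.
#' @export
mr_input <- function(bx, sx, by, sy, variant_ids = NULL) {
  n <- length(bx)
  if (n < 1L) stop("at least one instrument is required", call. = FALSE)
  if (length(sx) != n || length(by) != n || length(sy) != n) {
    stop("bx, sx, by, sy must have equal length", call. = FALSE)
  }
  if (is.null(variant_ids)) variant_ids <- sprintf("snp_%d", seq_len(n))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != n) stop("variant_ids length mismatch", call. = FALSE)
  if (any(!is.finite(bx) | !is.finite(by))) {
    stop("effect estimates must be finite", call. = FALSE)
  }
  if (any(!is.finite(sx) | sx <= 0 | !is.finite(sy) | sy <= 0)) {
    stop("all standard errors must be strictly positive", call. = FALSE)
  }
  structure(list(bx = as.numeric(bx), sx = as.numeric(sx),
                 by = as.numeric(by), sy = as.numeric(sy),
                 variant_ids = variant_ids),
            class = "mr_input")
}

#' Extract estimator input from a harmonized pair
#'
#' @param pair a `"harmonized_pair"`.
#' @param instruments optional `"instrument_set"` restricting the rows.
#' @return An `"mr_input"` (exposure on x, outcome on y).
#' @export
as_mr_input <- function(pair, instruments = NULL) {
  stopifnot(inherits(pair, "harmonized_pair"))
  rows <- pair$rows
  if (!is.null(instruments)) {
    stopifnot(inherits(instruments, "instrument_set"))
    idx <- match(instruments$variant_ids, rows$variant_id)
    if (anyNA(idx)) {
      stop("instrument variant(s) absent from harmonized rows: ",
           paste(instruments$variant_ids[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    rows <- rows[idx, , drop = FALSE]
  }
  mr_input(bx = rows$beta_exp, sx = rows$se_exp,
           by = rows$beta_out, sy = rows$se_out,
           variant_ids = rows$variant_id)
}

.new_mr_result <- function(method, slope, slope_se, slope_p, n_snps_used,
                           q_statistic = NA_real_,
                           intercept = NULL, intercept_se = NULL,
                           intercept_p = NULL, excluded_ids = NULL,
                           seed = NULL) {
  structure(list(method = method, slope = slope, slope_se = slope_se,
                 slope_p = slope_p, n_snps_used = n_snps_used,
                 q_statistic = q_statistic,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p,
                 excluded_ids = excluded_ids, seed = seed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  lab <- c(ivw = "Inverse-variance weighted",
           ivw_excl = "IVW, pleiotropic SNPs excluded",
           median = "Weighted median",
           egger = "MR-Egger")[x$method]
  cat(sprintf("%s: slope %.4g (SE %.3g), p = %.3g, %d SNPs\n",
              lab, x$slope, x$slope_se, x$slope_p, x$n_snps_used))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4g (SE %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.null(x$excluded_ids) && length(x$excluded_ids) > 0L) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

.two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Per-variant Wald ratio estimates
#'
#' `ratio_j = by_j / bx_j` with first-order standard error
#' `sy_j / |bx_j|` (uncertainty in the exposure effect ignored).
#'
#' @param input an `"mr_input"`.
#' @return data.frame with `variant_id`, `ratio`, `se`.
#' @export
ratio_estimates <- function(input) {
  stopifnot(inherits(input, "mr_input"))
  zero <- input$bx == 0
  if (any(zero)) {
    stop("degenerate instrument(s) with zero exposure effect: ",
         paste(input$variant_ids[zero], collapse = ", "), call. = FALSE)
  }
  data.frame(variant_id = input$variant_ids,
             ratio = input$by / input$bx,
             se = input$sy / abs(input$bx),
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/sy^2`. The standard error is the fixed-effect SE
#' multiplied by `max(1, sqrt(Q/(J-1)))` (multiplicative random-effects
#' model with the dispersion floored at 1) unless `random_effects = FALSE`.
#' `Q` is Cochran's heterogeneity statistic around the fitted slope.
#'
#' @param input an `"mr_input"` with at least 2 instruments.
#' @param random_effects logical; apply the multiplicative dispersion
#'   inflation (default `TRUE`).
#' @return An `"mr_result"` with method `"ivw"`.
#' @export
mr_ivw <- function(input, random_effects = TRUE) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$bx)
  if (J < 2L) stop("IVW requires at least 2 instruments", call. = FALSE)
  w <- 1 / input$sy^2
  sxx <- sum(w * input$bx^2)
  slope <- sum(w * input$bx * input$by) / sxx
  q <- sum(w * (input$by - slope * input$bx)^2)
  se <- sqrt(1 / sxx)
  if (random_effects) se <- se * max(1, sqrt(q / (J - 1)))
  .new_mr_result("ivw", slope, se, .two_sided_p(slope / se), J, q)
}

#' MR-Egger regression with intercept test
#'
#' Each instrument is first oriented so its exposure effect is positive
#' (outcome effect re-signed with it), then outcome effects are regressed on
#' exposure effects by weighted least squares *with* an intercept, weights
#' `1/sy^2`. A nonzero intercept indicates directional pleiotropy; the slope
#' is a pleiotropy-adjusted causal estimate. Standard errors use the same
#' multiplicative random-effects inflation as [mr_ivw()] (floor 1, `J - 2`
#' residual degrees of freedom); p-values are two-sided normal.
#'
#' @param input an `"mr_input"` with at least 3 instruments.
#' @param random_effects logical; apply the dispersion inflation.
#' @return An `"mr_result"` with method `"egger"` and intercept fields.
#' @export
mr_egger <- function(input, random_effects = TRUE) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$bx)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  s <- ifelse(input$bx < 0, -1, 1)
  x <- s * input$bx
  y <- s * input$by
  w <- 1 / input$sy^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swxx * swy - swx * swxy) / d
  q <- sum(w * (y - intercept - slope * x)^2)
  mult <- if (random_effects) max(1, sqrt(q / (J - 2))) else 1
  slope_se <- sqrt(sw / d) * mult
  int_se <- sqrt(swxx / d) * mult
  .new_mr_result("egger", slope, slope_se, .two_sided_p(slope / slope_se), J, q,
                 intercept = intercept, intercept_se = int_se,
                 intercept_p = .two_sided_p(intercept / int_se))
}

# Interpolated weighted median of `values` under `weights` (need not sum
# to 1): the value at which the running quantity S_j - w_j/2 (S_j the
# cumulative normalized weight in ascending value order) crosses 1/2,
# linearly interpolated between adjacent order statistics.
.weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  pq <- cumsum(w) - w / 2
  if (pq[1] >= 0.5) return(v[1])
  k <- length(v)
  if (pq[k] <= 0.5) return(v[k])
  j <- max(which(pq < 0.5))
  v[j] + (v[j + 1] - v[j]) * (0.5 - pq[j]) / (pq[j + 1] - pq[j])
}

#' Weighted-median estimator
#'
#' The inverse-variance interpolated weighted median of the per-variant Wald
#' ratios: consistent provided at least 50% of the weight comes from valid
#' (non-pleiotropic) instruments. The standard error comes from a parametric
#' bootstrap: effect estimates are resampled as
#' `by* ~ N(by, sy^2)`, `bx* ~ N(bx, sx^2)`, the median recomputed per
#' replicate, and the SE taken as the standard deviation across replicates.
#'
#' @param input an `"mr_input"` with at least 3 instruments.
#' @param n_boot number of bootstrap replicates (default 1000). `n_boot = 0`
#'   skips the bootstrap and returns `NA` for the SE and p-value (useful in
#'   simulation studies that only need the point estimate).
#' @param seed RNG seed for the bootstrap; recorded in the result. The
#'   caller's RNG state is restored on exit.
#' @return An `"mr_result"` with method `"median"`.
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = 1) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$bx)
  if (J < 3L) stop("weighted median requires at least 3 instruments", call. = FALSE)
  rat <- ratio_estimates(input)
  est <- .weighted_median(rat$ratio, 1 / rat$se^2)
  if (n_boot == 0L) {
    return(.new_mr_result("median", est, NA_real_, NA_real_, J, seed = seed))
  }
  boot <- local_seed(seed, {
    by_b <- matrix(stats::rnorm(J * n_boot, input$by, input$sy), nrow = J)
    bx_b <- matrix(stats::rnorm(J * n_boot, input$bx, input$sx), nrow = J)
    r_b <- by_b / bx_b
    vapply(seq_len(n_boot), function(k) {
      se_k <- input$sy / abs(bx_b[, k])
      .weighted_median(r_b[, k], 1 / se_k^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  .new_mr_result("median", est, se, .two_sided_p(est / se), J, seed = seed)
}

#' Flag instruments showing evidence of pleiotropy
#'
#' Fits [mr_ivw()] on all instruments, computes each variant's contribution
#' `Q_j = w_j (by_j - slope * bx_j)^2` to Cochran's Q, refers it to the
#' chi-square distribution with 1 degree of freedom, and flags variants with
#' `p_j < alpha / N`, where `N` is the number of instruments supplied.
#'
#' @param input an `"mr_input"` with at least 3 instruments.
#' @param alpha nominal level before the per-instrument Bonferroni division
#'   (default 0.05).
#' @return Character vector of flagged variant ids (possibly empty).
#' @export
flag_pleiotropic <- function(input, alpha = 0.05) {
  stopifnot(inherits(input, "mr_input"))
  J <- length(input$bx)
  if (J < 3L) stop("pleiotropy flagging requires at least 3 instruments",
                   call. = FALSE)
  fit <- mr_ivw(input)
  w <- 1 / input$sy^2
  q_j <- w * (input$by - fit$slope * input$bx)^2
  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
  input$variant_ids[p_j < alpha / J]
}

#' IVW after excluding pleiotropic instruments
#'
#' Re-runs [mr_ivw()] on the complement of [flag_pleiotropic()]; the excluded
#' variant ids are recorded in the result.
#'
#' @inheritParams flag_pleiotropic
#' @param random_effects passed to [mr_ivw()].
#' @return An `"mr_result"` with method `"ivw_excl"`.
#' @export
mr_ivw_excluding_pleiotropic <- function(input, alpha = 0.05, random_effects = TRUE) {
  excluded <- flag_pleiotropic(input, alpha = alpha)
  keep <- !(input$variant_ids %in% excluded)
  if (sum(keep) < 2L) {
    stop("fewer than 2 instruments remain after pleiotropy exclusion",
         call. = FALSE)
  }
  sub <- mr_input(input$bx[keep], input$sx[keep], input$by[keep], input$sy[keep],
                  input$variant_ids[keep])
  fit <- mr_ivw(sub, random_effects = random_effects)
  .new_mr_result("ivw_excl", fit$slope, fit$slope_se, fit$slope_p,
                 fit$n_snps_used, fit$q_statistic, excluded_ids = excluded)
}

#' Fit the full set of Mendelian randomization analyses
#'
#' The central fitting function: runs inverse-variance weighted regression,
#' IVW after pleiotropy exclusion, the weighted median, and MR-Egger
#' regression (with its intercept test) on one exposure/outcome instrument
#' set, and returns a classed object with the usual accessor methods
#' (`print`, `summary`, `coef`, `confint`, `plot`, `residuals`).
#'
#' @param object an `"mr_input"`, or a `"harmonized_pair"` (optionally with
#'   `instruments` restricting it).
#' @param methods subset of `c("ivw", "ivw_excl", "median", "egger")`.
#' @param n_boot,seed bootstrap settings for the weighted median.
#' @param alpha nominal level for the pleiotropy-exclusion rule.
#' @param random_effects passed to the IVW/Egger fits.
#' @param ... passed between methods.
#' @return An object of class `"mr_fit"`: named list `results` of
#'   `"mr_result"` objects plus the input.
#' @examples
#' inp <- mr_input(bx = c(0.1, 0.12, 0.08, 0.15, 0.11),
#'                 sx = rep(0.01, 5),
#'                 by = c(0.021, 0.025, 0.015, 0.031, 0.020),
#'                 sy = rep(0.005, 5))
#' fit <- mr_fit(inp, seed = 42)
#' coef(fit)
#' confint(fit)
#' @export
mr_fit <- function(object, ...) UseMethod("mr_fit")

#' @rdname mr_fit
#' @export
mr_fit.mr_input <- function(object, methods = c("ivw", "ivw_excl", "median", "egger"),
                            n_boot = 1000, seed = 1, alpha = 0.05,
                            random_effects = TRUE, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  results <- list()
  for (m in methods) {
    results[[m]] <- switch(m,
      ivw = mr_ivw(object, random_effects = random_effects),
      ivw_excl = mr_ivw_excluding_pleiotropic(object, alpha = alpha,
                                              random_effects = random_effects),
      median = mr_weighted_median(object, n_boot = n_boot, seed = seed),
      egger = mr_egger(object, random_effects = random_effects))
  }
  structure(list(results = results, input = object,
                 exposure = attr(object, "exposure"),
                 outcome = attr(object, "outcome")),
            class = "mr_fit")
}

#' @rdname mr_fit
#' @param instruments optional `"instrument_set"` (harmonized-pair method).
#' @export
mr_fit.harmonized_pair <- function(object, instruments = NULL, ...) {
  inp <- as_mr_input(object, instruments)
  attr(inp, "exposure") <- object$exposure_name
  attr(inp, "outcome") <- object$outcome_name
  mr_fit(inp, ...)
}

#' @export
print.mr_fit <- function(x, ...) {
  hdr <- if (!is.null(x$exposure)) {
    sprintf("Mendelian randomization: %s -> %s", x$exposure, x$outcome)
  } else "Mendelian randomization"
  cat(hdr, sprintf("(%d instruments)\n", length(x$input$bx)))
  for (r in x$results) print(r)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$results, function(r) r$slope, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  methods <- names(object$results)
  if (!missing(parm)) methods <- intersect(methods, parm)
  out <- t(vapply(object$results[methods], function(r) {
    c(r$slope - z * r$slope_se, r$slope + z * r$slope_se)
  }, numeric(2)))
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  r <- object$results[[method]]
  if (is.null(r)) stop("method '", method, "' not fitted", call. = FALSE)
  intercept <- if (is.null(r$intercept)) 0 else r$intercept
  bx <- object$input$bx; by <- object$input$by
  if (identical(method, "egger")) {
    s <- ifelse(bx < 0, -1, 1)
    bx <- s * bx; by <- s * by
  }
  stats::setNames(by - intercept - r$slope * bx, object$input$variant_ids)
}

#' @export
summary.mr_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  tab <- data.frame(
    method = names(object$results),
    slope = vapply(object$results, function(r) r$slope, numeric(1)),
    se = vapply(object$results, function(r) r$slope_se, numeric(1)),
    p = vapply(object$results, function(r) r$slope_p, numeric(1)),
    ci_low = ci[, 1], ci_high = ci[, 2],
    n_snps = vapply(object$results, function(r) r$n_snps_used, integer(1)),
    q = vapply(object$results, function(r) r$q_statistic %||% NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  egger <- object$results$egger
  structure(list(table = tab, exposure = object$exposure,
                 outcome = object$outcome,
                 egger_intercept = if (!is.null(egger)) {
                   c(estimate = egger$intercept, se = egger$intercept_se,
                     p = egger$intercept_p)
                 },
                 excluded = object$results$ivw_excl$excluded_ids),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  if (!is.null(x$exposure)) {
    cat(sprintf("Mendelian randomization: %s -> %s\n", x$exposure, x$outcome))
  }
  tab <- x$table
  tab$slope <- signif(tab$slope, 3); tab$se <- signif(tab$se, 3)
  tab$p <- signif(tab$p, 2)
  tab$ci_low <- signif(tab$ci_low, 3); tab$ci_high <- signif(tab$ci_high, 3)
  tab$q <- signif(tab$q, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept: %.4g (SE %.3g), p = %.3g\n",
                x$egger_intercept["estimate"], x$egger_intercept["se"],
                x$egger_intercept["p"]))
  }
  if (!is.null(x$excluded) && length(x$excluded) > 0L) {
    cat("Excluded as pleiotropic:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scatter plot of instrument effects with fitted slopes
#'
#' Plots per-allele outcome effects against exposure effects (both oriented
#' to a positive exposure effect) with one fitted line per estimator.
#'
#' @param x an `"mr_fit"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  s <- ifelse(x$input$bx < 0, -1, 1)
  bx <- s * x$input$bx; by <- s * x$input$by
  cols <- c(ivw = "red", ivw_excl = "orange", median = "darkgreen",
            egger = "blue")
  graphics::plot(bx, by, pch = 19, cex = 0.6,
                 xlab = "Exposure effect (SD per allele)",
                 ylab = "Outcome effect per allele",
                 xlim = range(0, bx), ...)
  graphics::segments(bx, by - 1.96 * x$input$sy,
                     bx, by + 1.96 * x$input$sy, col = "grey70")
  graphics::abline(h = 0)
  for (m in names(x$results)) {
    r <- x$results[[m]]
    graphics::abline(a = r$intercept %||% 0, b = r$slope, col = cols[[m]])
  }
  graphics::legend("topleft", legend = names(x$results),
                   col = cols[names(x$results)], lty = 1, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
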