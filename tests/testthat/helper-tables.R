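# Build small summary-statistic tables in code. P-values are always derived
# from beta/se so the consistency invariant holds by construction.

make_records <- function(ids, beta, se,
                         a1 = "A", a2 = "G",
                         chrom = "1", pos_bp = NULL, pos_cm = NULL,
                         info = 1, n = 1e5, eaf = NA_real_) {
  k <- length(ids)
  if (is.null(pos_bp)) pos_bp <- seq_len(k) * 1000L
  d <- data.frame(
    variant_id = ids,
    chrom = rep_len(chrom, k),
    pos_bp = rep_len(pos_bp, k),
    effect_allele = rep_len(a1, k),
    other_allele = rep_len(a2, k),
    beta = rep_len(beta, k),
    se = rep_len(se, k),
    info = rep_len(info, k),
    n = rep_len(n, k),
    eaf = rep_len(eaf, k),
    stringsAsFactors = FALSE
  )
  if (!is.null(pos_cm)) d$pos_cm <- rep_len(pos_cm, k)
  d$pvalue <- pmax(2 * pnorm(-abs(d$beta / d$se)), 1e-300)
  d
}

make_table <- function(..., trait_name = "trait",
                       trait_type = "quantitative", prevalence = NULL,
                       case_fraction = NULL) {
  sumstat_table(make_records(...), trait_name = trait_name,
                trait_type = trait_type, prevalence = prevalence,
                case_fraction = case_fraction)
}

# Random estimator input of J instruments with roughly GWAS-like scales.
random_mr_input <- function(J, seed) {
  set.seed(seed)
  mr_input(bx = rnorm(J, 0, 0.1) + 0.05 * sample(c(-1, 1), J, TRUE),
           sx = runif(J, 0.002, 0.01),
           by = rnorm(J, 0, 0.02),
           sy = runif(J, 0.005, 0.02),
           variant_ids = sprintf("v%d", seq_len(J)))
}

# Random instrument-selection instance of <= n_max SNPs plus a sparse LD
# table, as plain data.frames for the brute-force oracle.
random_selection_instance <- function(seed, n_max = 12) {
  set.seed(seed)
  k <- sample(2:n_max, 1)
  ids <- sprintf("s%02d", seq_len(k))
  df <- data.frame(
    variant_id = ids,
    chrom = "1",
    pos_bp = sort(sample.int(1e6, k)),
    pos_cm = sort(runif(k, 0, 12)),
    p = 10^runif(k, -12, -5),   # mixes significant and sub-threshold
    stringsAsFactors = FALSE
  )
  n_pairs <- sample(0:(k * (k - 1) / 2), 1)
  ld_df <- NULL
  if (n_pairs > 0) {
    combs <- t(combn(ids, 2))
    pick <- sample.int(nrow(combs), n_pairs)
    ld_df <- data.frame(a = combs[pick, 1], b = combs[pick, 2],
                        r2 = runif(n_pairs), stringsAsFactors = FALSE)
  }
  list(df = df, ld_df = ld_df)
}

# Wrap a selection instance into the package's native objects.
as_native_selection <- function(inst) {
  k <- nrow(inst$df)
  ex <- make_records(inst$df$variant_id, beta = rep(0.1, k), se = rep(0.01, k),
                     chrom = inst$df$chrom, pos_bp = inst$df$pos_bp,
                     pos_cm = inst$df$pos_cm)
  ex$pvalue <- inst$df$p
  ex$beta <- -qnorm(ex$pvalue / 2) * ex$se   # keep p consistent with beta/se
  ou <- ex
  ou$beta <- rnorm(k, 0, 0.01)
  ou$pvalue <- pmax(2 * pnorm(-abs(ou$beta / ou$se)), 1e-300)
  pair <- harmonize(
    sumstat_table(ex, "exp_trait", "quantitative"),
    sumstat_table(ou, "out_trait", "quantitative"))
  ld <- if (is.null(inst$ld_df)) NULL else
    ld_table(inst$ld_df$a, inst$ld_df$b, inst$ld_df$r2)
  list(pair = pair, ld = ld)
}
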