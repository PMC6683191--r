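#' Simulation configuration for paired GWAS summary statistics
#'
#' Describes a two-sample summary-level GWAS experiment with known ground
#' truth: a quantitative exposure (effects in phenotype SDs) measured in a
#' GWAS of `n_exposure` samples and an outcome measured in an independent
#' GWAS of `n_outcome` samples — binary on the log-odds scale when
#' `outcome_type = "binary"`. Defaults mirror large-biobank anthropometric
#' exposures (n ~ 330,000) paired with a case-control depression outcome
#' (n ~ 173,000, case fraction 0.346, population prevalence 15%).
#'
#' True causal SNPs receive exposure association z-scores drawn
#' `N(0, instrument_strength^2)` (so nearly all clear genome-wide
#' significance at these sample sizes); the per-SNP true outcome effect is
#' `theta` times the exposure effect plus, for the designated pleiotropic
#' fraction, a direct effect `N(pleiotropy_mean, pleiotropy_sd^2)` applied
#' on the exposure-increasing allele (so a nonzero mean is *directional*
#' pleiotropy that survives orientation; mean 0 is balanced). Null SNPs
#' affect neither trait.
#'
#' SNPs are organised in LD blocks: within-block pairs share r-squared
#' `block_r2` and sit within 1 cM of each other; consecutive blocks are
#' separated by at least `cm_span` centimorgans. Causal SNPs are spread one
#' per block (cycling). Designated fractions of SNPs receive palindromic
#' (A/T or C/G) allele pairs or sub-0.9 imputation info scores, which the
#' harmonization step is expected to remove.
#'
#' @param n_snps total SNPs per table.
#' @param n_causal number of SNPs causal for the exposure.
#' @param theta true causal effect (outcome units per exposure SD).
#' @param pleiotropy_frac fraction of causal SNPs with direct outcome
#'   effects.
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct effects on
#'   the exposure-increasing allele.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"binary"` (default) or `"quantitative"`.
#' @param case_fraction sample case fraction of the binary outcome GWAS.
#' @param prevalence population prevalence attached to the binary outcome.
#' @param maf_range range the uniform minor-allele frequencies are drawn
#'   from.
#' @param n_blocks number of LD blocks.
#' @param block_r2 within-block squared correlation.
#' @param cm_span minimum centimorgan gap between blocks.
#' @param palindromic_frac,low_info_frac fractions of SNPs given A/T-or-C/G
#'   alleles resp. info scores below 0.9 (assigned disjointly).
#' @param instrument_strength SD of true exposure association z-scores at
#'   `n_exposure`.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 1000, n_causal = 150, theta = 0.2,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.03,
                       n_exposure = 330000, n_outcome = 173000,
                       outcome_type = c("binary", "quantitative"),
                       case_fraction = 0.346, prevalence = 0.15,
                       maf_range = c(0.05, 0.5),
                       n_blocks = 150, block_r2 = 0.9, cm_span = 5,
                       palindromic_frac = 0.05, low_info_frac = 0.05,
                       instrument_strength = 40, seed = 1) {
  outcome_type <- match.arg(outcome_type)
  cfg <- list(n_snps = n_snps, n_causal = n_causal, theta = theta,
              pleiotropy_frac = pleiotropy_frac,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              n_exposure = n_exposure, n_outcome = n_outcome,
              outcome_type = outcome_type, case_fraction = case_fraction,
              prevalence = prevalence, maf_range = maf_range,
              n_blocks = n_blocks, block_r2 = block_r2, cm_span = cm_span,
              palindromic_frac = palindromic_frac,
              low_info_frac = low_info_frac,
              instrument_strength = instrument_strength, seed = seed)
  ok <- n_snps >= 1 && n_causal >= 0 && n_causal <= n_snps &&
    pleiotropy_frac >= 0 && pleiotropy_frac <= 1 && pleiotropy_sd >= 0 &&
    n_exposure >= 1 && n_outcome >= 1 &&
    case_fraction > 0 && case_fraction < 1 &&
    prevalence > 0 && prevalence < 1 &&
    length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
    maf_range[1] <= maf_range[2] &&
    n_blocks >= 1 && block_r2 >= 0 && block_r2 < 1 && cm_span > 0 &&
    palindromic_frac >= 0 && low_info_frac >= 0 &&
    palindromic_frac + low_info_frac <= 1 &&
    instrument_strength > 0
  if (!ok) stop("invalid simulation configuration", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a paired exposure/outcome set of GWAS summary statistics
#'
#' Draws effect estimates directly at the summary level:
#' `beta_hat ~ N(beta_true, se^2)` independently for the two samples, with
#' `se = 1/sqrt(2 p (1-p) n)` for quantitative traits and
#' `se = 1/sqrt(2 p (1-p) n v (1-v))` (v the case fraction, log-odds scale)
#' for the binary outcome. P-values are exact two-sided normal tests,
#' floored at 1e-300 to stay representable.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `exposure` and `outcome`
#'   (`"sumstat_table"`), `ld` (`"ld_table"`), and `truth` — a
#'   `"sim_truth"` ledger: per-SNP true effects, pleiotropy flags, block
#'   assignments and `theta`, satisfying
#'   `beta_outcome_true = theta * beta_exposure_true + direct_effect`
#'   exactly.
#' @export
simulate_pair <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    n <- cfg$n_snps
    ids <- sprintf("snp_%05d", seq_len(n))
    block <- rep(seq_len(cfg$n_blocks), length.out = n)
    block <- sort(block)
    # genetic map: blocks spaced cm_span + 1 apart, members packed in <1 cM
    within_idx <- stats::ave(seq_len(n), block, FUN = seq_along)
    block_size <- stats::ave(seq_len(n), block, FUN = length)
    offset <- 0.9 * (within_idx - 1) / pmax(1, block_size - 1)
    pos_cm <- (block - 1) * (cfg$cm_span + 1) + offset
    pos_bp <- as.integer(round(pos_cm * 1e6)) + seq_len(n)  # strictly increasing
    n_chr <- min(22L, cfg$n_blocks)
    chrom <- as.character(cut(block, breaks = n_chr, labels = FALSE))

    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
    se_y <- if (cfg$outcome_type == "binary") {
      v <- cfg$case_fraction
      1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome * v * (1 - v))
    } else {
      1 / sqrt(2 * maf * (1 - maf) * cfg$n_outcome)
    }

    # causal SNPs: one per block, cycling, so LD thinning keeps them apart
    causal <- integer(0)
    if (cfg$n_causal > 0) {
      # shuffle within blocks so causal positions differ between seeds
      by_block <- lapply(split(seq_len(n), block),
                         function(ix) ix[sample.int(length(ix))])
      ord <- unlist(lapply(seq_len(max(lengths(by_block))), function(k) {
        vapply(by_block, function(ix) if (length(ix) >= k) ix[k] else NA_integer_,
               integer(1))
      }))
      ord <- ord[!is.na(ord)]
      causal <- sort(ord[seq_len(cfg$n_causal)])
    }
    bx_true <- numeric(n)
    bx_true[causal] <- stats::rnorm(length(causal), 0, cfg$instrument_strength) *
      se_x[causal]

    pleio <- rep(FALSE, n)
    direct <- numeric(n)
    n_pleio <- round(cfg$pleiotropy_frac * length(causal))
    if (n_pleio > 0) {
      chosen <- causal[sample.int(length(causal), n_pleio)]
      pleio[chosen] <- TRUE
      # direct effect rides on the exposure-increasing allele
      direct[chosen] <- sign(bx_true[chosen]) *
        stats::rnorm(n_pleio, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }
    by_true <- cfg$theta * bx_true + direct

    # allele assignment: palindromic and low-info sets are disjoint
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    ok_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                      c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    n_pal <- round(cfg$palindromic_frac * n)
    n_low <- round(cfg$low_info_frac * n)
    marked <- sample(n, n_pal + n_low)
    pal_idx <- marked[seq_len(n_pal)]
    low_idx <- setdiff(marked, pal_idx)
    pick <- sample(nrow(ok_pairs), n, replace = TRUE)
    a1 <- ok_pairs[pick, 1]; a2 <- ok_pairs[pick, 2]
    if (n_pal > 0) {
      pick_p <- sample(nrow(pal_pairs), n_pal, replace = TRUE)
      a1[pal_idx] <- pal_pairs[pick_p, 1]; a2[pal_idx] <- pal_pairs[pick_p, 2]
    }
    info_x <- stats::runif(n, 0.95, 1)
    info_y <- stats::runif(n, 0.95, 1)
    if (n_low > 0) {
      # the low-info mark hits the outcome-side record
      info_y[low_idx] <- stats::runif(n_low, 0.5, 0.89)
    }

    bx_hat <- stats::rnorm(n, bx_true, se_x)
    by_hat <- stats::rnorm(n, by_true, se_y)
    p_x <- pmax(2 * stats::pnorm(-abs(bx_hat / se_x)), 1e-300)
    p_y <- pmax(2 * stats::pnorm(-abs(by_hat / se_y)), 1e-300)

    base <- data.frame(variant_id = ids, chrom = chrom, pos_bp = pos_bp,
                       pos_cm = pos_cm, effect_allele = a1, other_allele = a2,
                       stringsAsFactors = FALSE)
    exposure <- sumstat_table(
      cbind(base, data.frame(beta = bx_hat, se = se_x, pvalue = p_x,
                             info = info_x, n = cfg$n_exposure, eaf = maf)),
      trait_name = "exposure", trait_type = "quantitative")
    outcome <- sumstat_table(
      cbind(base, data.frame(beta = by_hat, se = se_y, pvalue = p_y,
                             info = info_y, n = cfg$n_outcome, eaf = maf)),
      trait_name = "outcome",
      trait_type = if (cfg$outcome_type == "binary") "binary" else "quantitative",
      prevalence = if (cfg$outcome_type == "binary") cfg$prevalence,
      case_fraction = if (cfg$outcome_type == "binary") cfg$case_fraction)

    # LD: all within-block pairs at block_r2 (omitted entirely when 0)
    if (cfg$block_r2 > 0) {
      pair_list <- lapply(split(ids, block), function(members) {
        k <- length(members)
        if (k < 2) return(NULL)
        combs <- utils::combn(members, 2)
        data.frame(a = combs[1, ], b = combs[2, ], stringsAsFactors = FALSE)
      })
      pairs <- do.call(rbind, pair_list)
      ld <- if (is.null(pairs)) ld_table() else {
        ld_table(pairs$a, pairs$b, rep(cfg$block_r2, nrow(pairs)))
      }
    } else {
      ld <- ld_table()
    }

    truth <- structure(
      list(theta = cfg$theta,
           snps = data.frame(variant_id = ids, block = block, maf = maf,
                             beta_exposure_true = bx_true,
                             direct_effect = direct,
                             pleiotropic = pleio,
                             beta_outcome_true = by_true,
                             stringsAsFactors = FALSE),
           config = cfg),
      class = "sim_truth")
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: theta = %g, %d SNPs (%d causal, %d pleiotropic)\n",
              x$theta, nrow(x$snps), sum(x$snps$beta_exposure_true != 0),
              sum(x$snps$pleiotropic)))
  invisible(x)
}

#' Write the canonical simulated fixture suite
#'
#' Writes four small exposure/outcome pairs with their LD tables and
#' ground-truth ledgers: `clean` (theta 0.2, no contamination),
#' `palindromic` (theta 0.2 with palindromic and low-info contamination),
#' `directional` (theta 0.2 with directional pleiotropy on 40% of causal
#' SNPs), and `null` (theta 0). Files use the tab-separated summary-statistic
#' and LD dialects of [write_sumstats()] and [write_ld()]; each truth ledger
#' is a TSV of per-SNP true effects with a `theta` column.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base RNG seed; each fixture uses `seed + k`.
#' @param n_snps,n_causal,n_blocks sizes shared by all four fixtures.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, n_snps = 300, n_causal = 60,
                               n_blocks = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- function(...) sim_config(n_snps = n_snps, n_causal = n_causal,
                                   n_blocks = n_blocks, ...)
  cfgs <- list(
    clean = base(theta = 0.2, palindromic_frac = 0, low_info_frac = 0,
                 seed = seed),
    palindromic = base(theta = 0.2, palindromic_frac = 0.15,
                       low_info_frac = 0.10, seed = seed + 1),
    directional = base(theta = 0.2, pleiotropy_frac = 0.4,
                       pleiotropy_mean = 0.05, pleiotropy_sd = 0.03,
                       palindromic_frac = 0, low_info_frac = 0,
                       seed = seed + 2),
    null = base(theta = 0, palindromic_frac = 0, low_info_frac = 0,
                seed = seed + 3)
  )
  written <- character(0)
  for (nm in names(cfgs)) {
    sim <- simulate_pair(cfgs[[nm]])
    paths <- c(
      exposure = file.path(out_dir, paste0(nm, "_exposure.tsv")),
      outcome = file.path(out_dir, paste0(nm, "_outcome.tsv")),
      ld = file.path(out_dir, paste0(nm, "_ld.tsv")),
      truth = file.path(out_dir, paste0(nm, "_truth.tsv")))
    write_sumstats(sim$exposure, paths[["exposure"]])
    write_sumstats(sim$outcome, paths[["outcome"]])
    write_ld(sim$ld, paths[["ld"]])
    tr <- sim$truth$snps
    tr$theta <- sim$truth$theta
    utils::write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    names(paths) <- paste(nm, names(paths), sep = "_")
    written <- c(written, paths)
  }
  invisible(written)
}
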