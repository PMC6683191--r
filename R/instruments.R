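#' Construct a pairwise LD table
#'
#' Stores r-squared values for unordered variant pairs. Pairs absent from
#' the table are treated as unlinked (r-squared 0) by [select_instruments()],
#' which matches how sparse LD references are distributed: only pairs above
#' some reporting floor are listed.
#'
#' @param snp_a,snp_b character vectors of variant ids (parallel).
#' @param r2 numeric vector of squared correlations in \[0,1\].
#' @return An object of class `"ld_table"`.
#' @export
ld_table <- function(snp_a = character(0), snp_b = character(0), r2 = numeric(0)) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  snp_a <- as.character(snp_a); snp_b <- as.character(snp_b)
  if (any(snp_a == snp_b)) {
    stop("LD table may not contain self-pairs", call. = FALSE)
  }
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    stop("r2 values must lie in [0,1]", call. = FALSE)
  }
  key <- paste(pmin(snp_a, snp_b), pmax(snp_a, snp_b), sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    if (any(abs(r2 - r2[match(key, key)]) > 0)) {
      stop("conflicting r2 for duplicated pair(s)", call. = FALSE)
    }
    snp_a <- snp_a[first]; snp_b <- snp_b[first]
    r2 <- r2[first]; key <- key[first]
  }
  index <- r2
  names(index) <- key
  structure(list(pairs = data.frame(snp_a = snp_a, snp_b = snp_b, r2 = r2,
                                    stringsAsFactors = FALSE),
                 index = index),
            class = "ld_table")
}

#' Read a pairwise LD table
#'
#' Tab-separated file with header `SNP_A SNP_B R2`.
#'
#' @param path path to the file.
#' @return An `"ld_table"`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("SNP_A", "SNP_B", "R2"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ld_table(raw$SNP_A, raw$SNP_B, as.numeric(raw$R2))
}

#' Write a pairwise LD table
#' @param x an `"ld_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(x, path) {
  stopifnot(inherits(x, "ld_table"))
  out <- data.frame(SNP_A = x$pairs$snp_a, SNP_B = x$pairs$snp_b,
                    R2 = as.character(x$pairs$r2), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up pairwise r-squared values
#'
#' @param ld an `"ld_table"` or `NULL` (all pairs unlinked).
#' @param a,b character vectors of variant ids (recycled to a common length).
#' @return Numeric vector of r-squared; 0 for pairs absent from the table.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  if (is.null(ld)) return(numeric(n))
  stopifnot(inherits(ld, "ld_table"))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- unname(ld$index[key])
  out[is.na(out)] <- 0
  out
}

#' Instrument-selection configuration
#'
#' Thresholds for genome-wide significance and greedy LD thinning: a
#' candidate instrument must reach `p_threshold` for the selection trait, and
#' no retained pair may lie within `window_cm` centimorgans of each other
#' while having r-squared above `r2_max`. Defaults follow standard practice:
#' p < 5e-8, 3 cM window, r-squared 0.05.
#'
#' @param p_threshold genome-wide significance threshold (strict `<`).
#' @param window_cm genetic-map window in centimorgans (inclusive bound).
#' @param r2_max maximum tolerated squared correlation (strict `>` excludes).
#' @return An object of class `"selection_config"`.
#' @export
selection_config <- function(p_threshold = 5e-8, window_cm = 3.0, r2_max = 0.05) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0,
            is.numeric(window_cm), window_cm > 0,
            is.numeric(r2_max), r2_max > 0, r2_max < 1)
  structure(list(p_threshold = p_threshold, window_cm = window_cm,
                 r2_max = r2_max),
            class = "selection_config")
}

#' Select independent genome-wide significant instruments
#'
#' Greedy thinning of the selection-side association results of a harmonized
#' pair: candidates below `p_threshold` are visited in ascending p-value
#' order (ties broken by chromosome, position, then variant id) and a
#' candidate is retained iff no already-retained variant is simultaneously
#' within `window_cm` of it and correlated with it at r-squared above
#' `r2_max`. Pairs absent from `ld` count as unlinked.
#'
#' @param pair a `"harmonized_pair"`.
#' @param side which side's p-values drive selection: `"exposure"` (default)
#'   or `"outcome"`.
#' @param ld an `"ld_table"`, or `NULL` for no LD information.
#' @param config a [selection_config()].
#' @return An object of class `"instrument_set"`: `variant_ids` in retention
#'   order, `n_instruments`, the selection trait and the configuration used.
#' @export
select_instruments <- function(pair, side = c("exposure", "outcome"), ld = NULL,
                               config = selection_config()) {
  stopifnot(inherits(pair, "harmonized_pair"), inherits(config, "selection_config"))
  side <- match.arg(side)
  rows <- pair$rows
  p <- if (side == "exposure") rows$p_exp else rows$p_out
  trait <- if (side == "exposure") pair$exposure_name else pair$outcome_name
  cand <- which(p < config$p_threshold)
  if (length(cand) == 0L) {
    stop("no genome-wide significant variants for trait '", trait,
         "' at p < ", format(config$p_threshold), call. = FALSE)
  }
  chrom_num <- suppressWarnings(as.numeric(rows$chrom[cand]))
  ord <- order(p[cand], chrom_num, rows$chrom[cand], rows$pos_bp[cand],
               rows$variant_id[cand])
  cand <- cand[ord]

  kept_id <- character(0)
  kept_cm <- numeric(0)
  for (i in cand) {
    id <- rows$variant_id[i]
    cm <- rows$pos_cm[i]
    if (length(kept_id) > 0L) {
      near <- abs(kept_cm - cm) <= config$window_cm
      if (any(near) && any(ld_r2(ld, id, kept_id[near]) > config$r2_max)) next
    }
    kept_id <- c(kept_id, id)
    kept_cm <- c(kept_cm, cm)
  }
  structure(list(selection_trait = trait, variant_ids = kept_id,
                 n_instruments = length(kept_id), config = config,
                 side = side),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d independent genome-wide significant SNPs\n",
              x$selection_trait, x$n_instruments))
  cat(sprintf("  p < %s, window %.2g cM, r2 <= %.2g\n",
              format(x$config$p_threshold), x$config$window_cm, x$config$r2_max))
  invisible(x)
}

#' Approximate phenotypic variance explained by an instrument set
#'
#' For a quantitative trait in SD units the per-variant contribution is
#' `2 p (1 - p) beta^2` with `p` the effect-allele frequency, summed over
#' instruments and reported as a percentage (phenotype variance 1). For a
#' binary trait the log-odds effects are first mapped to the observed 0/1
#' scale via the logistic derivative at the sample case fraction `P`
#' (`beta_obs = beta * P(1-P)`), summed the same way, then converted to the
#' liability scale with the threshold-model factor
#' `K^2 (1-K)^2 / (z^2 P(1-P))`, where `K` is the population prevalence and
#' `z` the standard-normal density at the (1-K) quantile.
#'
#' @param instruments an `"instrument_set"`.
#' @param table the `"sumstat_table"` the instruments were selected for.
#' @param case_fraction sample case fraction override for binary traits;
#'   defaults to the table's `case_fraction` field.
#' @return Percentage of phenotypic (liability for binary) variance explained.
#' @export
variance_explained <- function(instruments, table, case_fraction = NULL) {
  stopifnot(inherits(instruments, "instrument_set"), inherits(table, "sumstat_table"))
  ids <- instruments$variant_ids
  if (length(ids) == 0L) return(0)
  idx <- match(ids, table$data$variant_id)
  if (anyNA(idx)) {
    stop("instrument variant(s) absent from table: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  eaf <- table$data$eaf[idx]
  beta <- table$data$beta[idx]
  if (anyNA(eaf)) {
    stop("effect-allele frequency missing for variant(s): ",
         paste(ids[is.na(eaf)], collapse = ", "), call. = FALSE)
  }
  if (table$trait_type == "quantitative") {
    return(100 * sum(2 * eaf * (1 - eaf) * beta^2))
  }
  K <- table$prevalence
  if (is.null(K)) stop("binary trait requires a prevalence", call. = FALSE)
  P <- if (!is.null(case_fraction)) case_fraction else table$case_fraction
  if (is.null(P)) {
    stop("binary trait requires a sample case fraction (table field or argument)",
         call. = FALSE)
  }
  beta_obs <- beta * P * (1 - P)
  h2_obs <- sum(2 * eaf * (1 - eaf) * beta_obs^2)
  z <- stats::dnorm(stats::qnorm(1 - K))
  100 * h2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}
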