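#' Construct a GWAS summary-statistic table
#'
#' Bundles one trait's per-variant association results with trait-level
#' metadata. Effect sizes are expected in phenotype-SD units for quantitative
#' traits and log-odds for binary traits; `A1`-style effect alleles must be
#' single bases A/C/G/T.
#'
#' @param data data.frame with columns `variant_id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `info`, `n`,
#'   and optionally `pos_cm` (centimorgans) and `eaf` (effect-allele
#'   frequency).
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence population prevalence in (0,1); required for binary
#'   traits (used by the liability-scale conversion).
#' @param case_fraction sample case fraction in (0,1); optional, binary
#'   traits only.
#' @param validate logical; run per-row invariant checks (default `TRUE`).
#'
#' @return An object of class `"sumstat_table"`.
#' @seealso [read_sumstats()], [harmonize()]
#' @export
sumstat_table <- function(data, trait_name, trait_type = c("quantitative", "binary"),
                          prevalence = NULL, case_fraction = NULL, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_name), length(trait_name) == 1L)
  required <- c("variant_id", "chrom", "pos_bp", "effect_allele", "other_allele",
                "beta", "se", "pvalue", "info", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"pos_cm" %in% names(data)) data$pos_cm <- NA_real_
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  data <- data[c(required[1:3], "pos_cm", required[4:10], "eaf")]
  data$variant_id <- as.character(data$variant_id)
  data$chrom <- as.character(data$chrom)
  data$pos_bp <- as.integer(data$pos_bp)
  data$n <- as.integer(data$n)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))

  if (trait_type == "binary") {
    if (is.null(prevalence)) {
      stop("binary trait '", trait_name, "' requires a prevalence", call. = FALSE)
    }
    stopifnot(is.numeric(prevalence), prevalence > 0, prevalence < 1)
    if (!is.null(case_fraction)) {
      stopifnot(is.numeric(case_fraction), case_fraction > 0, case_fraction < 1)
    }
  } else {
    prevalence <- NULL
    case_fraction <- NULL
  }

  dup <- unique(data$variant_id[duplicated(data$variant_id)])
  if (length(dup) > 0L) {
    stop("duplicate variant_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (validate) .validate_sumstat_rows(data)

  rownames(data) <- NULL
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         prevalence = prevalence, case_fraction = case_fraction,
         data = data),
    class = "sumstat_table"
  )
}

# Row-level invariants; failures are fatal and cite 1-based row indices.
.validate_sumstat_rows <- function(d) {
  bases <- c("A", "C", "G", "T")
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      problems <<- c(problems,
                     sprintf("row %d: %s", utils::head(idx, 10L), what))
    }
  }
  bad(!d$effect_allele %in% bases, "effect_allele not one of A/C/G/T")
  bad(!d$other_allele %in% bases, "other_allele not one of A/C/G/T")
  bad(d$effect_allele == d$other_allele, "effect_allele equals other_allele")
  bad(!is.finite(d$pos_bp) | d$pos_bp < 1, "pos_bp not a positive integer")
  bad(!is.finite(d$beta), "beta not finite")
  bad(!is.finite(d$se) | d$se <= 0, "se not strictly positive")
  bad(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1, "pvalue outside (0,1]")
  bad(!is.finite(d$info) | d$info < 0 | d$info > 1, "info outside [0,1]")
  bad(!is.finite(d$n) | d$n < 1, "n not a positive integer")
  bad(!is.na(d$eaf) & (d$eaf <= 0 | d$eaf >= 1), "eaf outside (0,1)")
  # p must agree with the two-sided normal test of beta/se to 10% relative
  # tolerance; skipped where either p-value underflows double precision.
  p_implied <- 2 * stats::pnorm(-abs(d$beta / d$se))
  check <- is.finite(d$se) & d$se > 0 & is.finite(d$pvalue) & d$pvalue > 0 &
    pmin(d$pvalue, p_implied) >= 1e-290
  bad(check & abs(d$pvalue - p_implied) > 0.1 * p_implied,
      "pvalue inconsistent with beta/se (>10% relative difference)")
  if (length(problems) > 0L) {
    stop("summary-statistic validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a GWAS summary-statistic file
#'
#' Reads a tab-separated table with header columns
#' `SNP CHR BP A1 A2 BETA SE P INFO N` (optional `CM`, `EAF`); `A1` is the
#' effect allele. Gzip-compressed files are accepted. Rows violating the
#' per-record invariants (alleles, positive SE, p-value range and its
#' consistency with beta/SE, info in \[0,1\]) raise a validation error citing
#' the offending rows.
#'
#' @param path path to the file.
#' @inheritParams sumstat_table
#' @return A `"sumstat_table"`.
#' @export
read_sumstats <- function(path, trait_name, trait_type = c("quantitative", "binary"),
                          prevalence = NULL, case_fraction = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE,
                           colClasses = NA, comment.char = "")
  required <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "INFO", "N")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    variant_id = as.character(raw$SNP),
    chrom = as.character(raw$CHR),
    pos_bp = as.integer(raw$BP),
    pos_cm = if ("CM" %in% names(raw)) as.numeric(raw$CM) else NA_real_,
    effect_allele = as.character(raw$A1),
    other_allele = as.character(raw$A2),
    beta = as.numeric(raw$BETA),
    se = as.numeric(raw$SE),
    pvalue = as.numeric(raw$P),
    info = as.numeric(raw$INFO),
    n = as.integer(raw$N),
    eaf = if ("EAF" %in% names(raw)) as.numeric(raw$EAF) else NA_real_,
    stringsAsFactors = FALSE
  )
  sumstat_table(d, trait_name = trait_name, trait_type = trait_type,
                prevalence = prevalence, case_fraction = case_fraction)
}

#' Write a summary-statistic table to disk
#'
#' Inverse of [read_sumstats()]: emits the tab-separated dialect with columns
#' `SNP CHR BP [CM] A1 A2 BETA SE P INFO N [EAF]`. Numeric columns are
#' serialized with `as.character()`, so a read/write cycle reproduces the
#' data columns byte-for-byte for files produced by this writer.
#'
#' @param x a `"sumstat_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstat_table"))
  d <- x$data
  out <- data.frame(
    SNP = d$variant_id, CHR = d$chrom, BP = as.character(d$pos_bp),
    stringsAsFactors = FALSE
  )
  if (!all(is.na(d$pos_cm))) out$CM <- as.character(d$pos_cm)
  out$A1 <- d$effect_allele
  out$A2 <- d$other_allele
  out$BETA <- as.character(d$beta)
  out$SE <- as.character(d$se)
  out$P <- as.character(d$pvalue)
  out$INFO <- as.character(d$info)
  out$N <- as.character(d$n)
  if (!all(is.na(d$eaf))) out$EAF <- as.character(d$eaf)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s)\n", x$trait_name, x$trait_type))
  if (x$trait_type == "binary") {
    cat(sprintf("  prevalence %.3f%s\n", x$prevalence,
                if (!is.null(x$case_fraction))
                  sprintf(", case fraction %.3f", x$case_fraction) else ""))
  }
  cat(sprintf("  %d variants, median n = %s\n", nrow(x$data),
              format(stats::median(x$data$n))))
  invisible(x)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

# Vectorized allele alignment. Returns verdict plus a flip indicator for the
# kept rows. Precedence when several rules fire: palindromic > low_info >
# allele_mismatch (affects the verdict/counters only; the row is dropped
# either way).
.align_alleles_vec <- function(ea_x, oa_x, ea_y, oa_y, info_x, info_y,
                               min_info = 0.9) {
  n <- length(ea_x)
  direct <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  comp_direct <- .complement[ea_y] == ea_x & .complement[oa_y] == oa_x
  comp_swapped <- .complement[ea_y] == oa_x & .complement[oa_y] == ea_x
  match_ok <- direct | swapped | comp_direct | comp_swapped
  flip <- (swapped | comp_swapped) & !(direct | comp_direct)
  palindromic <- .is_palindromic(ea_x, oa_x) | .is_palindromic(ea_y, oa_y)
  low_info <- info_x < min_info | info_y < min_info
  verdict <- rep("kept", n)
  verdict[!match_ok] <- "allele_mismatch"
  verdict[low_info] <- "low_info"
  verdict[palindromic] <- "palindromic"
  list(verdict = verdict, flip = flip)
}

#' Align one outcome record onto the exposure's effect allele
#'
#' Applies the variant-level harmonization rules for a single shared variant:
#' palindromic (A/T or C/G) allele pairs and records with imputation info
#' below `min_info` are excluded; otherwise the outcome's effect is re-signed
#' (and its allele frequency complemented) whenever its effect allele matches
#' the exposure's other allele, directly or as the reverse complement.
#'
#' @param exp,out single-row record lists or data.frames with fields
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `info` and
#'   optionally `eaf`.
#' @param min_info minimum acceptable imputation info score (default 0.9),
#'   applied to both records.
#' @return A list with `verdict` (one of `"kept"`, `"palindromic"`,
#'   `"low_info"`, `"allele_mismatch"`) and, when kept, the aligned outcome
#'   `beta` and `eaf`.
#' @export
align_alleles <- function(exp, out, min_info = 0.9) {
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$variant_id), as.character(out$variant_id))) {
    stop("records do not share a variant_id", call. = FALSE)
  }
  al <- .align_alleles_vec(toupper(exp$effect_allele), toupper(exp$other_allele),
                           toupper(out$effect_allele), toupper(out$other_allele),
                           exp$info, out$info, min_info = min_info)
  if (al$verdict != "kept") {
    return(list(verdict = al$verdict, beta = NA_real_, eaf = NA_real_))
  }
  beta <- if (al$flip) -out$beta else out$beta
  eaf <- if (is.null(out$eaf) || is.na(out$eaf)) NA_real_
         else if (al$flip) 1 - out$eaf else out$eaf
  list(verdict = "kept", beta = beta, eaf = eaf)
}

#' Harmonize an exposure/outcome pair of summary-statistic tables
#'
#' Inner-joins the two tables on variant id, aligns outcome effects onto the
#' exposure's effect allele via [align_alleles()], drops palindromic
#' variants and variants with info below `min_info` on either side, and
#' returns the merged rows ordered by (chromosome, position). Missing
#' genetic-map positions are imputed as `pos_bp / 1e6` (1 cM per Mb) with a
#' warning, so downstream cM-window thinning always has coordinates.
#'
#' @param exposure,outcome `"sumstat_table"` objects.
#' @param min_info minimum imputation info score applied to both sides.
#' @return An object of class `"harmonized_pair"`: the retained `rows`
#'   (exposure and outcome beta/SE/p per variant, plus positions and the
#'   exposure allele frequency), the shared-variant count `n_shared`, and
#'   drop counters `n_dropped_palindromic`, `n_dropped_info`,
#'   `n_dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome, min_info = 0.9) {
  stopifnot(inherits(exposure, "sumstat_table"), inherits(outcome, "sumstat_table"))
  ex <- exposure$data
  ou <- outcome$data
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L) {
    stop("no shared variants between '", exposure$trait_name, "' and '",
         outcome$trait_name, "'", call. = FALSE)
  }
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  pos_cm <- ex$pos_cm
  if (anyNA(pos_cm)) {
    warning("imputing missing pos_cm as pos_bp / 1e6 (1 cM per Mb) for ",
            sum(is.na(pos_cm)), " variant(s)", call. = FALSE)
    pos_cm[is.na(pos_cm)] <- ex$pos_bp[is.na(pos_cm)] / 1e6
  }

  al <- .align_alleles_vec(ex$effect_allele, ex$other_allele,
                           ou$effect_allele, ou$other_allele,
                           ex$info, ou$info, min_info = min_info)
  keep <- al$verdict == "kept"
  beta_out <- ifelse(al$flip, -ou$beta, ou$beta)

  rows <- data.frame(
    variant_id = ex$variant_id, chrom = ex$chrom, pos_bp = ex$pos_bp,
    pos_cm = pos_cm,
    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$pvalue, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = ou$se, p_out = ou$pvalue,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(rows$chrom))
  ord <- order(chrom_num, rows$chrom, rows$pos_bp)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL

  structure(
    list(exposure_name = exposure$trait_name, outcome_name = outcome$trait_name,
         rows = rows,
         n_shared = length(shared),
         n_dropped_palindromic = sum(al$verdict == "palindromic"),
         n_dropped_info = sum(al$verdict == "low_info"),
         n_dropped_mismatch = sum(al$verdict == "allele_mismatch"),
         min_info = min_info),
    class = "harmonized_pair"
  )
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %s (exposure) ~ %s (outcome)\n",
              x$exposure_name, x$outcome_name))
  cat(sprintf("  %d shared variants; retained %d\n", x$n_shared, nrow(x$rows)))
  cat(sprintf("  dropped: %d palindromic, %d low info (< %.2g), %d allele mismatch\n",
              x$n_dropped_palindromic, x$n_dropped_info, x$min_info,
              x$n_dropped_mismatch))
  invisible(x)
}
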