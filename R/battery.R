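#' Battery configuration
#'
#' Settings for a bidirectional multi-trait Mendelian randomization battery.
#' `n_tests` is a fixed constant (42 for 21 traits in both directions), not
#' derived from the cells actually run, so that partial runs keep the same
#' Bonferroni threshold.
#'
#' @param alpha family-wise nominal level (default 0.05).
#' @param n_tests number of tests the Bonferroni correction divides by
#'   (default 42).
#' @param directions `"both"`, `"forward"` (trait as exposure) or
#'   `"reverse"` (depression as exposure).
#' @param selection a [selection_config()].
#' @param n_boot,seed weighted-median bootstrap settings.
#' @return An object of class `"battery_config"`.
#' @export
battery_config <- function(alpha = 0.05, n_tests = 42,
                           directions = c("both", "forward", "reverse"),
                           selection = selection_config(),
                           n_boot = 1000, seed = 1) {
  directions <- match.arg(directions)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(n_tests), n_tests >= 1,
            inherits(selection, "selection_config"))
  structure(list(alpha = alpha, n_tests = n_tests, directions = directions,
                 selection = selection, n_boot = n_boot, seed = seed),
            class = "battery_config")
}

#' Absolute z threshold equivalent to the Bonferroni rule
#'
#' The standard-normal quantile at `1 - (alpha/n_tests)/2`: a two-sided test
#' of a slope rejects at the Bonferroni level exactly when
#' `|slope/se|` meets or exceeds this value.
#'
#' @param alpha nominal family-wise level.
#' @param n_tests number of tests.
#' @return The critical |z| value.
#' @examples
#' critical_z(0.05, 1)   # ~1.96
#' critical_z(0.05, 42)  # ~3.24
#' @export
critical_z <- function(alpha = 0.05, n_tests = 1) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  stats::qnorm(1 - (alpha / n_tests) / 2)
}

#' Run one direction of the battery for one trait pair
#'
#' Harmonizes the pair, selects instruments on the exposure side, runs all
#' four estimators on the instrumented rows, and flags significance from the
#' all-SNP IVW slope p-value against `alpha/n_tests`. The sensitivity
#' analyses (exclusion IVW, weighted median, Egger) are reported but never
#' drive the flag.
#'
#' @param exposure,outcome `"sumstat_table"` objects.
#' @param ld an `"ld_table"` or `NULL`.
#' @param config a [battery_config()].
#' @param direction label stored in the cell (`"forward"` or `"reverse"`).
#' @return A `"battery_cell"`: the fitted `"mr_fit"`, instrument count and
#'   significance flag.
#' @export
run_direction <- function(exposure, outcome, ld = NULL,
                          config = battery_config(),
                          direction = "forward") {
  stopifnot(inherits(config, "battery_config"))
  pair <- harmonize(exposure, outcome)
  instruments <- tryCatch(
    select_instruments(pair, side = "exposure", ld = ld,
                       config = config$selection),
    error = function(e) {
      stop(direction, " direction: ", conditionMessage(e), call. = FALSE)
    })
  if (instruments$n_instruments < 3L) {
    stop(direction, " direction: only ", instruments$n_instruments,
         " instrument(s) for '", exposure$trait_name,
         "'; at least 3 required", call. = FALSE)
  }
  fit <- mr_fit(pair, instruments = instruments,
                n_boot = config$n_boot, seed = config$seed)
  structure(list(exposure = exposure$trait_name, outcome = outcome$trait_name,
                 direction = direction, fit = fit,
                 n_instruments = instruments$n_instruments,
                 significant = fit$results$ivw$slope_p <
                   config$alpha / config$n_tests,
                 error = NULL),
            class = "battery_cell")
}

.failed_cell <- function(exposure, outcome, direction, message) {
  structure(list(exposure = exposure, outcome = outcome, direction = direction,
                 fit = NULL, n_instruments = NA_integer_,
                 significant = NA, error = message),
            class = "battery_cell")
}

#' Run the full bidirectional trait battery
#'
#' For each trait: the forward cell uses the trait as exposure and the
#' genome-wide depression table as outcome; the reverse cell uses the
#' depression instrument-source table (the larger GWAS reporting only
#' top SNPs) as exposure and the trait as outcome. Per-cell failures (e.g.
#' too few instruments) are recorded in the report rather than aborting the
#' battery.
#'
#' @param traits named list of `"sumstat_table"` objects (one per trait).
#' @param depression_exposure depression table used as the exposure in the
#'   reverse direction (instrument source; genome-wide coverage not needed).
#' @param depression_outcome depression table used as the outcome in the
#'   forward direction (genome-wide coverage required).
#' @param ld an `"ld_table"` or `NULL`.
#' @param config a [battery_config()].
#' @return A `"battery_report"` with one cell per trait per direction.
#' @export
run_battery <- function(traits, depression_exposure, depression_outcome,
                        ld = NULL, config = battery_config()) {
  stopifnot(is.list(traits), length(traits) >= 1L,
            inherits(config, "battery_config"))
  if (is.null(names(traits))) {
    names(traits) <- vapply(traits, function(t) t$trait_name, character(1))
  }
  dirs <- switch(config$directions, both = c("forward", "reverse"),
                 forward = "forward", reverse = "reverse")
  cells <- list()
  for (nm in names(traits)) {
    trait <- traits[[nm]]
    if ("forward" %in% dirs) {
      cells[[paste(nm, "forward", sep = ".")]] <- tryCatch(
        run_direction(trait, depression_outcome, ld, config, "forward"),
        error = function(e) .failed_cell(trait$trait_name,
                                         depression_outcome$trait_name,
                                         "forward", conditionMessage(e)))
    }
    if ("reverse" %in% dirs) {
      cells[[paste(nm, "reverse", sep = ".")]] <- tryCatch(
        run_direction(depression_exposure, trait, ld, config, "reverse"),
        error = function(e) .failed_cell(depression_exposure$trait_name,
                                         trait$trait_name,
                                         "reverse", conditionMessage(e)))
    }
  }
  structure(list(cells = cells, config = config, trait_names = names(traits)),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  n_fail <- sum(vapply(x$cells, function(c) !is.null(c$error), logical(1)))
  n_sig <- sum(vapply(x$cells, function(c) isTRUE(c$significant), logical(1)))
  cat(sprintf("MR battery: %d traits, %s direction(s), %d cells\n",
              length(x$trait_names), x$config$directions, length(x$cells)))
  cat(sprintf("  significant at p < %.3g/%d: %d cells; failed: %d cells\n",
              x$config$alpha, x$config$n_tests, n_sig, n_fail))
  invisible(x)
}

.fmt_slope <- function(r) {
  if (is.null(r)) return(NA_character_)
  sprintf("%.3g (%.2g)", r$slope, r$slope_se)
}
.fmt_p <- function(p) if (is.null(p) || is.na(p)) NA_character_ else sprintf("%.2g", p)

.cell_columns <- function(cell, prefix) {
  methods <- c("ivw", "ivw_excl", "median", "egger")
  out <- list()
  if (is.null(cell) || !is.null(cell$error)) {
    for (m in methods) {
      out[[paste(prefix, m, sep = "_")]] <- NA_character_
      out[[paste(prefix, m, "p", sep = "_")]] <- NA_character_
    }
    out[[paste(prefix, "egger_intercept_p", sep = "_")]] <- NA_character_
    out[[paste(prefix, "n_snps", sep = "_")]] <- NA_integer_
    out[[paste(prefix, "significant", sep = "_")]] <- NA_character_
  } else {
    for (m in methods) {
      r <- cell$fit$results[[m]]
      out[[paste(prefix, m, sep = "_")]] <- .fmt_slope(r)
      out[[paste(prefix, m, "p", sep = "_")]] <- .fmt_p(r$slope_p)
    }
    eg <- cell$fit$results$egger
    out[[paste(prefix, "egger_intercept_p", sep = "_")]] <-
      .fmt_p(if (is.null(eg)) NA else eg$intercept_p)
    out[[paste(prefix, "n_snps", sep = "_")]] <- cell$n_instruments
    out[[paste(prefix, "significant", sep = "_")]] <-
      if (isTRUE(cell$significant)) "yes" else "no"
  }
  out
}

#' Render a battery report as a tab-separated table
#'
#' One row per trait; forward-direction columns (trait as causal risk factor
#' for the outcome) precede reverse-direction columns. Each group carries the
#' four method slopes formatted `estimate (SE)`, their p-values, the Egger
#' intercept p-value, the instrument count and the Bonferroni significance
#' mark. Failed cells render as `NA` with the failure reason in a `notes`
#' column. Rendering is pure: re-rendering an unchanged report reproduces
#' identical bytes.
#'
#' @param report a `"battery_report"`.
#' @param path output path, or `NULL` to skip writing.
#' @return The rendered data.frame, invisibly (visibly when `path` is
#'   `NULL`).
#' @export
render_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "battery_report"))
  rows <- lapply(report$trait_names, function(nm) {
    fwd <- report$cells[[paste(nm, "forward", sep = ".")]]
    rev <- report$cells[[paste(nm, "reverse", sep = ".")]]
    notes <- c(
      if (!is.null(fwd) && !is.null(fwd$error)) paste0("forward: ", fwd$error),
      if (!is.null(rev) && !is.null(rev$error)) paste0("reverse: ", rev$error))
    as.data.frame(c(list(trait = nm), .cell_columns(fwd, "fwd"),
                    .cell_columns(rev, "rev"),
                    list(notes = if (length(notes)) paste(notes, collapse = "; ")
                         else "")),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(out))
  }
  out
}
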