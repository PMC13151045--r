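#' Compute and write f_u summaries from an assay CSV
#'
#' Reads a dialysis assay table, aggregates replicates and laboratories
#' (see [aggregate_fu()]) and writes a summary CSV with QC flags.
#'
#' @param assay_csv input path in the dialect of [read_assay_table()].
#' @param out output CSV path (`NULL` to skip writing).
#' @param ... passed to [aggregate_fu()].
#' @return the `fu_summary` data.frame, invisibly when `out` is given.
#' @export
run_fu <- function(assay_csv, out = NULL, ...) {
  measurements <- read_assay_table(assay_csv)
  summaries <- aggregate_fu(measurements, ...)
  if (!is.null(out)) {
    utils::write.csv(summaries, out, row.names = FALSE, na = "")
    return(invisible(summaries))
  }
  summaries
}

#' Run the Fish Plasma Model screen and write outputs
#'
#' Screens an API table (a CSV path, an `api_table`, or `"fixture"` for
#' the packaged 44-pharmaceutical panel) through the original and refined
#' model for one fish species, writes the TWC table as CSV, and writes a
#' plain-text prioritisation report of flagged APIs per speciation group
#' with the group denominators stated.
#'
#' @param apis CSV path, `api_table`, or `"fixture"`.
#' @param species target fish species id.
#' @param rfu Rf_u source (see [fpm_screen()]); defaults to the packaged
#'   worst-case column when `apis = "fixture"`.
#' @param rfu_rule `"max"` or `"median"`.
#' @param median_threshold,max_threshold prioritisation thresholds.
#' @param out optional output CSV path for the TWC table.
#' @param report optional output path for the text report.
#' @param denominator group-count denominator policy, see
#'   [speciation_summary()].
#' @return list with `twc` (the [fpm_screen()] result), `flags`
#'   (per-API classification) and `groups` (per-group counts), invisibly
#'   when `out` is given.
#' @export
run_screen <- function(apis, species = "rainbow_trout", rfu = NULL,
                       rfu_rule = c("max", "median"),
                       median_threshold = 3, max_threshold = 10,
                       out = NULL, report = NULL,
                       denominator = "measured_rfu") {
  rfu_rule <- match.arg(rfu_rule)
  if (is.character(apis) && length(apis) == 1L && apis == "fixture") {
    fx <- load_fixture()
    apis <- fx$apis
    if (is.null(rfu)) rfu <- fx$rfu$rfu_trout_max_human_min
  } else if (is.character(apis)) {
    apis <- read_api_table(apis)
  }
  if (is.null(rfu)) {
    stop("an Rf_u source is required (vector or rfu_summary data.frame)",
         call. = FALSE)
  }
  twc <- fpm_screen(apis, species = species, rfu = rfu,
                    rfu_rule = rfu_rule)
  threshold <- if (rfu_rule == "max") max_threshold else median_threshold
  flags <- classify_rfu(data.frame(api_name = twc$api_name,
                                   rfu_max = twc$rfu_used),
                        max_threshold = threshold)
  groups <- speciation_summary(apis, twc$rfu_used, threshold = threshold,
                               denominator = denominator)
  if (!is.null(out)) {
    utils::write.csv(twc, out, row.names = FALSE, na = "")
  }
  if (!is.null(report)) {
    lines <- c(sprintf("FPM prioritisation report: species %s, %s-rule, threshold >= %g",
                       species, rfu_rule, threshold),
               sprintf("denominator policy: %s", denominator),
               "",
               sprintf("%-14s %9s / %-9s", "group", "flagged", "total"))
    for (i in seq_len(nrow(groups))) {
      lines <- c(lines, sprintf("%-14s %9d / %-9d", groups$group[i],
                                groups$n_flagged[i], groups$n_total[i]))
    }
    flagged <- flags$api_name[!is.na(flags$flag_max_ge10) &
                                flags$flag_max_ge10]
    lines <- c(lines, "", "flagged APIs:",
               paste(" ", flagged))
    writeLines(lines, report)
  }
  res <- list(twc = twc, flags = flags, groups = groups)
  if (!is.null(out)) invisible(res) else res
}

#' Fit the molecular-predictor model from a CSV and write a fit report
#'
#' Reads a table with descriptor columns (`mw`, `pka`, a LogD column for
#' the species pH) and a measured `fu` (or `fu_median`) column, fits the
#' additive model (see [fit_fu_gam()]) and writes the fit report as YAML
#' plus a per-term CSV.
#'
#' @param data CSV path or data.frame.
#' @param species species id; selects the LogD column by plasma pH.
#' @param out optional basename for outputs (`<out>.yaml`,
#'   `<out>_terms.csv`).
#' @param ... passed to [fit_fu_gam()].
#' @return the `fu_gam_fit`, invisibly when `out` is given.
#' @export
run_gam <- function(data, species = "rainbow_trout", out = NULL, ...) {
  if (is.character(data)) {
    data <- utils::read.csv(data, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  if (!"fu" %in% names(data)) {
    if ("fu_median" %in% names(data)) {
      data$fu <- data$fu_median
    } else {
      stop("data lacks an 'fu' (or 'fu_median') column", call. = FALSE)
    }
  }
  if (!"logd" %in% names(data)) {
    ctx <- species_contexts()
    ph <- ctx$plasma_ph[ctx$species_id == species]
    if (length(ph) == 0L) {
      stop("unknown species '", species, "'; valid choices: ",
           paste(ctx$species_id, collapse = ", "), call. = FALSE)
    }
    data$logd <- data[[logd_column_for_ph(data, ph)]]
  }
  fit <- fit_fu_gam(data, species = species, ...)
  if (!is.null(out)) {
    basis <- check_basis_dimension(fit)
    yaml::write_yaml(list(species = fit$species_id,
                          n = fit$n,
                          transform = fit$transform_name,
                          family = fit$family,
                          smoothing_selection = fit$smoothing_selection,
                          charge_mapping = fit$charge_mapping,
                          basis_dim_k = fit$basis_dim_k,
                          r2_adj = fit$r2_adj,
                          deviance_explained_pct =
                            fit$deviance_explained_pct,
                          predictor_significance =
                            as.list(fit$predictor_significance),
                          dropped_terms = fit$dropped_terms),
                     paste0(out, ".yaml"))
    terms <- merge(basis,
                   data.frame(term = names(fit$predictor_significance),
                              p_value =
                                as.numeric(fit$predictor_significance)),
                   by = "term", all = TRUE)
    utils::write.csv(terms, paste0(out, "_terms.csv"), row.names = FALSE,
                     na = "")
    return(invisible(fit))
  }
  fit
}

#' Write a synthetic assay CSV
#'
#' Convenience wrapper: generates a panel and its dialysis measurements
#' from a [synthetic_config()] and writes them in the assay CSV dialect,
#' plus the panel descriptor table.
#'
#' @param config a [synthetic_config()].
#' @param assay_out path for the assay CSV.
#' @param panel_out optional path for the panel descriptor CSV.
#' @return list with `panel` and `measurements`, invisibly.
#' @export
run_simulate <- function(config, assay_out, panel_out = NULL) {
  panel <- generate_api_panel(config)
  measurements <- simulate_dialysis(panel, config)
  utils::write.csv(measurements, assay_out, row.names = FALSE)
  if (!is.null(panel_out)) {
    utils::write.csv(panel, panel_out, row.names = FALSE, na = "")
  }
  invisible(list(panel = panel, measurements = measurements))
}
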