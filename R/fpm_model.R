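#' Blood:water partition coefficient from LogD
#'
#' Hydrophobic partitioning of an (ionizable) pharmaceutical between fish
#' blood and the surrounding water, quantified from the pH-dependent
#' octanol-water distribution coefficient:
#' \deqn{P_{Blood:Water} = 10^{0.73 \, LogD_{ow} - 0.88}}
#' The regression coefficients default to the published calibration and
#' are configurable.
#'
#' @param logd LogD_ow at the relevant plasma pH.
#' @param slope,intercept regression coefficients on the log10 scale.
#' @return dimensionless partition coefficient(s).
#' @examples
#' blood_water_partition(1.31)   # ~1.19
#' @export
blood_water_partition <- function(logd, slope = 0.73, intercept = -0.88) {
  10^(slope * logd + intercept)
}

#' Steady-state fish plasma concentration
#'
#' Fish Plasma Model exposure prediction: the steady-state plasma
#' concentration under continuous aqueous exposure is the water
#' concentration scaled by blood:water partitioning.
#'
#' @param water_conc exposure water concentration (mg/L), >= 0.
#' @param p_bw blood:water partition coefficient.
#' @return predicted plasma concentration (mg/L).
#' @export
predict_fss_pc <- function(water_conc, p_bw) {
  if (any(water_conc < 0, na.rm = TRUE)) {
    stop("water concentration must be >= 0", call. = FALSE)
  }
  water_conc * p_bw
}

#' Therapeutic water concentration, original Fish Plasma Model
#'
#' The water concentration predicted to produce a fish plasma level equal
#' to the human therapeutic plasma concentration:
#' \eqn{TWC = C_{max} / P_{Blood:Water}}. A lower TWC means higher priority
#' for in vivo testing.
#'
#' @param cmax human therapeutic plasma concentration (mg/L); `NA` yields
#'   `NA` (absent, never zero).
#' @param p_bw blood:water partition coefficient, > 0.
#' @return TWC (mg/L).
#' @export
twc_original <- function(cmax, p_bw) {
  if (any(p_bw <= 0, na.rm = TRUE)) {
    stop("partition coefficient must be > 0", call. = FALSE)
  }
  if (any(cmax <= 0, na.rm = TRUE)) {
    stop("C_max must be > 0 when present", call. = FALSE)
  }
  cmax / p_bw
}

#' Therapeutic water concentration, refined Fish Plasma Model
#'
#' Refinement accounting for interspecies plasma protein binding: the
#' human therapeutic concentration is first divided by the relative
#' unbound fraction Rf_u (fish:human), then by blood:water partitioning at
#' the fish plasma pH:
#' \eqn{TWC = (C_{max} / Rf_u) / P_{Blood:Water}}.
#' An Rf_u of 10 therefore lowers the TWC tenfold relative to the original
#' model at the same partitioning. Missing or below-quantification
#' (zero) Rf_u yields `NA`.
#'
#' @param cmax human therapeutic plasma concentration (mg/L).
#' @param rfu relative unbound fraction fish:human, > 0 (0 or `NA` gives
#'   `NA`).
#' @param p_bw_fish partition coefficient at the fish plasma pH, > 0.
#' @return refined TWC (mg/L).
#' @export
twc_refined <- function(cmax, rfu, p_bw_fish) {
  if (any(p_bw_fish <= 0, na.rm = TRUE)) {
    stop("partition coefficient must be > 0", call. = FALSE)
  }
  if (any(cmax <= 0, na.rm = TRUE)) {
    stop("C_max must be > 0 when present", call. = FALSE)
  }
  if (any(rfu < 0, na.rm = TRUE)) {
    stop("Rf_u must be >= 0", call. = FALSE)
  }
  rfu <- ifelse(!is.na(rfu) & rfu == 0, NA_real_, rfu)
  (cmax / rfu) / p_bw_fish
}

#' Compare TWC predictions with chronic effect concentrations
#'
#' A screening prediction is conservative when the TWC does not exceed the
#' lowest-observed-effect concentration from chronic fish early-life-stage
#' tests (inclusive: TWC equal to the LOEC counts as conservative). Ratios
#' TWC/LOEC are reported for both model variants; when only a NOEC is
#' available the ratio is computed against it and the conservatism flag is
#' left absent.
#'
#' @param twc data.frame with `twc_original` and `twc_refined` columns
#'   (mg/L), e.g. from [fpm_screen()].
#' @param noec,loec chronic effect concentrations (mg/L), `NA` when not
#'   available.
#' @return `twc` with columns `ratio_orig_to_loec`, `ratio_refined_to_loec`,
#'   `conservative_original`, `conservative_refined` added.
#' @export
assess_conservatism <- function(twc, noec = NA_real_, loec = NA_real_) {
  effect <- ifelse(!is.na(loec), loec, noec)
  twc$ratio_orig_to_loec <- twc$twc_original / effect
  twc$ratio_refined_to_loec <- twc$twc_refined / effect
  twc$conservative_original <-
    ifelse(is.na(loec), NA, twc$twc_original <= loec)
  twc$conservative_refined <-
    ifelse(is.na(loec), NA, twc$twc_refined <= loec)
  twc
}

#' Screen an API table through the original and refined Fish Plasma Model
#'
#' For every API, computes blood:water partition coefficients at the human
#' reference pH (original model, generic "fish") and at the target species
#' plasma pH (refined model), original and refined TWC, their ratio (the
#' TWC reduction factor contributed by the Rf_u correction), and the
#' conservatism assessment against NOEC/LOEC where effect data are
#' present. Rows lacking C_max or a usable Rf_u keep absent TWC fields;
#' output rows follow input order.
#'
#' @param apis `api_table` with LogD columns for both pHs (see
#'   [read_api_table()], [load_fixture()]).
#' @param species target fish species id, matched against `contexts`.
#' @param rfu Rf_u source: a numeric vector parallel to `apis` rows, or a
#'   data.frame from [rfu_summary()]/[classify_rfu()] joined by API name,
#'   in which case `rfu_rule` selects the column.
#' @param rfu_rule `"max"` (worst case, default) or `"median"`.
#' @param human_ph human reference pH for the original model (7.4).
#' @param species_ph plasma pH of the target species; defaults to the
#'   value in `contexts`.
#' @param contexts species context table, see [species_contexts()].
#' @param slope,intercept partitioning coefficients, see
#'   [blood_water_partition()].
#' @return data.frame of class `twc_result`, one row per API, columns
#'   `api_name`, `species_id`, `logd_used_original`, `logd_used_refined`,
#'   `p_bw_original`, `p_bw_refined`, `rfu_used`, `twc_original`,
#'   `twc_refined`, `twc_ratio`, plus the conservatism columns of
#'   [assess_conservatism()].
#' @examples
#' fx <- load_fixture()
#' twc <- fpm_screen(fx$apis, rfu = fx$rfu$rfu_trout_max_human_min)
#' head(twc[, c("api_name", "twc_original", "twc_refined", "twc_ratio")])
#' @export
fpm_screen <- function(apis, species = "rainbow_trout", rfu,
                       rfu_rule = c("max", "median"),
                       human_ph = 7.4, species_ph = NULL,
                       contexts = species_contexts(),
                       slope = 0.73, intercept = -0.88) {
  rfu_rule <- match.arg(rfu_rule)
  if (nrow(apis) == 0L) {
    return(structure(data.frame(), class = c("twc_result", "data.frame")))
  }
  if (!species %in% contexts$species_id) {
    stop("unknown species '", species, "'; valid choices: ",
         paste(contexts$species_id, collapse = ", "), call. = FALSE)
  }
  if (is.null(species_ph)) {
    species_ph <- contexts$plasma_ph[contexts$species_id == species]
  }
  col_h <- logd_column_for_ph(apis, human_ph)
  col_s <- logd_column_for_ph(apis, species_ph)

  if (is.data.frame(rfu)) {
    col <- if (rfu_rule == "max") "rfu_max" else "rfu_median"
    if (!col %in% names(rfu)) {
      stop("rfu data.frame lacks column '", col, "'", call. = FALSE)
    }
    nm <- if ("api_name" %in% names(rfu)) rfu$api_name else rfu$name
    rfu_vec <- rfu[[col]][match(apis$name, nm)]
  } else {
    stopifnot(length(rfu) == nrow(apis))
    rfu_vec <- as.numeric(rfu)
  }

  p_h <- blood_water_partition(apis[[col_h]], slope, intercept)
  p_s <- blood_water_partition(apis[[col_s]], slope, intercept)
  out <- data.frame(api_name = apis$name,
                    species_id = species,
                    speciation = apis$speciation,
                    charge_class = apis$charge_class,
                    logd_used_original = apis[[col_h]],
                    logd_used_refined = apis[[col_s]],
                    p_bw_original = p_h,
                    p_bw_refined = p_s,
                    cmax_mg_per_L = apis$cmax_mg_per_L,
                    rfu_used = rfu_vec,
                    stringsAsFactors = FALSE)
  out$twc_original <- twc_original(apis$cmax_mg_per_L, p_h)
  out$twc_refined <- twc_refined(apis$cmax_mg_per_L, rfu_vec, p_s)
  out$twc_ratio <- out$twc_original / out$twc_refined
  out <- assess_conservatism(out, noec = apis$noec_mg_per_L,
                             loec = apis$loec_mg_per_L)
  class(out) <- c("twc_result", "data.frame")
  out
}
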