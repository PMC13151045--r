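#' Relative unbound fraction, fish:human
#'
#' Point ratio of a fish unbound fraction to the human unbound fraction.
#' Values well above 1 mean the drug is substantially freer in fish plasma
#' than in human plasma, so read-across from human therapeutic levels
#' underestimates the pharmacologically available dose in fish.
#'
#' @param fu_fish,fu_human unbound fractions; `fu_human` must be > 0.
#' @return ratio(s) `fu_fish / fu_human`.
#' @examples
#' rfu_point(0.30, 0.02)   # 15
#' @export
rfu_point <- function(fu_fish, fu_human) {
  if (any(is.na(fu_human)) || any(fu_human <= 0)) {
    stop("human unbound fraction must be > 0: ratio undefined",
         call. = FALSE)
  }
  if (any(fu_fish < 0, na.rm = TRUE)) {
    stop("fish unbound fraction must be >= 0", call. = FALSE)
  }
  fu_fish / fu_human
}

#' Median-based relative unbound fraction
#'
#' Ratio of the fish median f_u to the human median f_u, the central
#' cross-laboratory estimate of the interspecies binding difference.
#'
#' @param fish,human single rows of an `fu_summary` (see
#'   [aggregate_fu()]), or any objects with `fu_median` fields.
#' @return the ratio of medians.
#' @export
rfu_median <- function(fish, human) {
  rfu_point(fish$fu_median, human$fu_median)
}

#' Worst-case relative unbound fraction
#'
#' Ratio of the fish maximum f_u to the human minimum f_u across
#' laboratories: the most precautionary estimate of the interspecies
#' binding difference, always at least as large as the median-based ratio
#' for the same summary pair.
#'
#' @param fish,human single rows of an `fu_summary`, or any objects with
#'   `fu_max` / `fu_min` fields.
#' @return `fish$fu_max / human$fu_min`.
#' @export
rfu_max <- function(fish, human) {
  rfu_point(fish$fu_max, human$fu_min)
}

#' Combine fish and human f_u summaries into Rf_u results
#'
#' Joins per-API fish and human summaries by API name and computes both
#' the median-based and the worst-case Rf_u.
#'
#' @param fish,human `fu_summary` data.frames for one fish species and for
#'   human, one row per API.
#' @return data.frame `api_name`, `species_id`, `rfu_median`, `rfu_max`.
#' @export
rfu_summary <- function(fish, human) {
  idx <- match(fish$api, human$api)
  if (any(is.na(idx))) {
    stop("no human summary for API(s): ",
         paste(fish$api[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  h <- human[idx, , drop = FALSE]
  data.frame(api_name = fish$api,
             species_id = fish$species,
             rfu_median = rfu_point(fish$fu_median, h$fu_median),
             rfu_max = rfu_point(fish$fu_max, h$fu_min),
             stringsAsFactors = FALSE)
}

#' Flag APIs whose interspecies binding difference is substantive
#'
#' Thresholds follow the intercomparison evidence: intra-/inter-laboratory
#' f_u ranges are generally within a factor 3, so a median Rf_u of 3 or
#' more marks a substantive difference, while a worst-case Rf_u of 10 or
#' more implements a generic 10-fold assessment factor. Both thresholds
#' are inclusive and configurable.
#'
#' @param rfu data.frame with `rfu_median` and/or `rfu_max` columns (e.g.
#'   from [rfu_summary()]), or a numeric vector treated as `rfu_max`.
#' @param median_threshold,max_threshold inclusive flag thresholds.
#' @return the input with logical columns `flag_median_ge3` and
#'   `flag_max_ge10` added (`NA` where the ratio is missing).
#' @export
classify_rfu <- function(rfu, median_threshold = 3, max_threshold = 10) {
  if (is.numeric(rfu)) {
    rfu <- data.frame(rfu_max = rfu)
  }
  if ("rfu_median" %in% names(rfu)) {
    rfu$flag_median_ge3 <- rfu$rfu_median >= median_threshold
  }
  if ("rfu_max" %in% names(rfu)) {
    rfu$flag_max_ge10 <- rfu$rfu_max >= max_threshold
  }
  rfu
}

#' Per-speciation-group counts of flagged APIs
#'
#' Counts how many APIs in each charge group exceed the prioritisation
#' threshold, under a configurable denominator policy: `"all"` counts all
#' rows per group; `"measured_rfu"` (default) restricts to rows with a
#' non-missing, non-zero Rf_u (a printed Rf_u of 0 is below
#' quantification); `"with_cmax"` restricts to rows with a known human
#' C_max. The policy used is recorded in the output so the denominators
#' are never ambiguous.
#'
#' @param apis `api_table` with `speciation` (and `cmax_mg_per_L` for the
#'   `with_cmax` policy).
#' @param rfu numeric vector of ratios, parallel to `apis` rows (typically
#'   the worst-case Rf_u; pass the median-based ratio with
#'   `threshold = 3` for median-rule counts).
#' @param grouping speciation-to-group mapping name, see [charge_class()].
#'   The `"group_counts"` default yields anionic / unionized / cationic /
#'   zwitterionic groups.
#' @param threshold inclusive flag threshold (10 for the worst-case rule).
#' @param denominator denominator policy, see Details.
#' @return data.frame `group`, `n_flagged`, `n_total`, `denominator`.
#' @examples
#' fx <- load_fixture()
#' speciation_summary(fx$apis, fx$rfu$rfu_trout_max_human_min)
#' @export
speciation_summary <- function(apis, rfu,
                               grouping = c("group_counts", "default"),
                               threshold = 10,
                               denominator = c("measured_rfu", "with_cmax",
                                               "all")) {
  grouping <- match.arg(grouping)
  denominator <- match.arg(denominator)
  stopifnot(length(rfu) == nrow(apis))
  group <- charge_class(apis$speciation, mapping = grouping)
  keep <- switch(denominator,
    all = rep(TRUE, nrow(apis)),
    measured_rfu = !is.na(rfu) & rfu > 0,
    with_cmax = !is.na(apis$cmax_mg_per_L))
  flagged <- !is.na(rfu) & rfu >= threshold
  groups <- unique(group)
  out <- data.frame(group = groups,
                    n_flagged = vapply(groups, function(g)
                      sum(flagged & keep & group == g), integer(1L)),
                    n_total = vapply(groups, function(g)
                      sum(keep & group == g), integer(1L)),
                    denominator = rep(denominator, length(groups)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
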