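#' Unbound fraction from an equilibrium-dialysis concentration pair
#'
#' At equilibrium only free drug crosses the dialysis membrane, so the
#' buffer-chamber concentration equals the free plasma concentration and
#' the unbound fraction is the buffer:plasma concentration ratio. No
#' clamping is applied: a ratio above 1 (possible under measurement noise)
#' is returned as-is and should be QC-flagged downstream.
#'
#' @param plasma_conc total concentration in the plasma chamber (µM), > 0.
#' @param buffer_conc concentration in the buffer chamber (µM), >= 0.
#' @return unbound fraction(s), `buffer_conc / plasma_conc`.
#' @examples
#' compute_fu(8, 2)   # 0.25
#' @export
compute_fu <- function(plasma_conc, buffer_conc) {
  if (any(is.na(plasma_conc)) || any(plasma_conc <= 0)) {
    stop("plasma concentration must be > 0: unbound fraction undefined",
         call. = FALSE)
  }
  if (any(!is.na(buffer_conc) & buffer_conc < 0)) {
    stop("buffer concentration must be >= 0", call. = FALSE)
  }
  buffer_conc / plasma_conc
}

#' Correct an unbound fraction measured in diluted plasma
#'
#' Plasma diluted D-fold has D-fold fewer binding sites, so the unbound
#' fraction measured in the diluted assay (`fu_diluted`) overestimates the
#' undiluted-plasma value. Under linear (non-saturating) binding the
#' undiluted equivalent is
#' \deqn{f_u = f_{u,D} / (D - (D-1) f_{u,D})}
#' which at D = 10 (10% plasma) reduces to \eqn{f_{u10}/(10 - 9 f_{u10})}.
#'
#' @param fu_diluted unbound fraction measured in diluted plasma, in
#'   \[0, 1\].
#' @param dilution_factor D >= 1; 1 means undiluted (identity).
#' @param allow_above_one retain values > 1 (flag them downstream) instead
#'   of erroring.
#' @return unbound fraction referred to 100% plasma.
#' @seealso [dilute_fu()] for the algebraic inverse.
#' @examples
#' correct_dilution(0.1, 10)   # 0.1 / (10 - 0.9)
#' @export
correct_dilution <- function(fu_diluted, dilution_factor,
                             allow_above_one = FALSE) {
  if (any(dilution_factor < 1, na.rm = TRUE)) {
    stop("dilution factor must be >= 1", call. = FALSE)
  }
  if (!allow_above_one && any(fu_diluted > 1, na.rm = TRUE)) {
    stop("diluted unbound fraction > 1: failed QC ",
         "(set allow_above_one = TRUE to retain and flag)", call. = FALSE)
  }
  if (any(fu_diluted < 0, na.rm = TRUE)) {
    stop("unbound fraction must be >= 0", call. = FALSE)
  }
  fu_diluted / (dilution_factor - (dilution_factor - 1) * fu_diluted)
}

#' Unbound fraction expected in diluted plasma
#'
#' Algebraic inverse of [correct_dilution()]: the unbound fraction that a
#' D-fold diluted assay would measure for a compound whose undiluted-plasma
#' unbound fraction is `fu`.
#'
#' @param fu undiluted-plasma unbound fraction in \[0, 1\].
#' @param dilution_factor D >= 1.
#' @return diluted-assay unbound fraction.
#' @export
dilute_fu <- function(fu, dilution_factor) {
  if (any(dilution_factor < 1, na.rm = TRUE)) {
    stop("dilution factor must be >= 1", call. = FALSE)
  }
  dilution_factor * fu / (1 + (dilution_factor - 1) * fu)
}

#' Total assay recovery and QC class
#'
#' Mass balance after dialysis: the mass recovered from both chambers as a
#' percentage of the nominal spiked mass (spike concentration times plasma
#' chamber volume). Recovery well below 100% indicates non-specific binding
#' to assay plastics or membrane. Classes: `pass` (>= 70%), `caution`
#' (\[50, 70)%), `fail` (< 50%); thresholds configurable.
#'
#' @param plasma_conc,buffer_conc chamber concentrations (µM).
#' @param nominal_spike nominal spike concentration in plasma (µM), 10 in
#'   the standard design.
#' @param plasma_volume,buffer_volume chamber volumes (same units; only the
#'   ratio matters). Equal volumes by default.
#' @param pass,caution lower bounds (%) of the pass and caution bands.
#' @return data.frame with `recovery_pct` and `qc_class`.
#' @examples
#' compute_recovery(5, 5, 10)  # 100% -> pass
#' @export
compute_recovery <- function(plasma_conc, buffer_conc, nominal_spike,
                             plasma_volume = 1, buffer_volume = 1,
                             pass = 70, caution = 50) {
  if (any(c(plasma_volume, buffer_volume) <= 0)) {
    stop("chamber volumes must be positive", call. = FALSE)
  }
  if (any(nominal_spike <= 0)) {
    stop("nominal spike must be positive", call. = FALSE)
  }
  recovery <- 100 * (plasma_conc * plasma_volume +
                     buffer_conc * buffer_volume) /
              (nominal_spike * plasma_volume)
  qc <- ifelse(recovery >= pass, "pass",
               ifelse(recovery >= caution, "caution", "fail"))
  data.frame(recovery_pct = recovery, qc_class = qc,
             stringsAsFactors = FALSE)
}

#' Read a dialysis assay table
#'
#' CSV dialect: header `api,species,lab,replicate,plasma_conc_uM,
#' buffer_conc_uM,nominal_uM,dilution_factor`, one row per replicate
#' measurement.
#'
#' @param path path to the CSV.
#' @return data.frame of measurements.
#' @export
read_assay_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("api", "species", "lab", "replicate", "plasma_conc_uM",
              "buffer_conc_uM", "nominal_uM", "dilution_factor")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop(path, ": assay table is empty", call. = FALSE)
  }
  for (col in c("plasma_conc_uM", "buffer_conc_uM")) {
    bad <- which(is.na(raw[[col]]) | raw[[col]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s: column '%s', row %d: must be a number >= 0",
                   path, col, bad[1L]), call. = FALSE)
    }
  }
  bad <- which(is.na(raw$dilution_factor) | raw$dilution_factor < 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s: column 'dilution_factor', row %d: must be >= 1",
                 path, bad[1L]), call. = FALSE)
  }
  raw
}

#' Aggregate replicate dialysis measurements into f_u summaries
#'
#' Per measurement, the unbound fraction is the buffer:plasma ratio
#' corrected to 100% plasma with the row's dilution factor. Within each
#' laboratory, replicate f_u values are averaged (arithmetic mean); the
#' reported minimum, median and maximum are order statistics of the lab
#' means (for a single lab all three coincide; the median of an even count
#' is the midpoint). Values above 1 are retained and flagged
#' (`fu_above_one`), never truncated; any replicate recovery below the
#' pass threshold raises `low_recovery`. With `strict_qc = TRUE`,
#' replicates with f_u > 1 are excluded from the lab means (the flag is
#' still reported).
#'
#' @param measurements data.frame in the dialect of [read_assay_table()].
#' @param strict_qc exclude f_u > 1 replicates from aggregation.
#' @param recovery_pass,recovery_caution recovery QC bands (%), see
#'   [compute_recovery()].
#' @param plasma_volume,buffer_volume chamber volumes for recovery.
#' @return data.frame of class `fu_summary`: one row per (api, species)
#'   with `fu_min`, `fu_median`, `fu_max`, `n_replicates`, `n_labs`,
#'   `qc_flags` (comma-separated, empty when clean).
#' @examples
#' m <- data.frame(api = "drugA", species = "human", lab = "L1",
#'                 replicate = 1:3, plasma_conc_uM = c(8, 8, 8),
#'                 buffer_conc_uM = c(1.6, 2.4, 3.2), nominal_uM = 10,
#'                 dilution_factor = 1)
#' aggregate_fu(m)   # fu_min = fu_median = fu_max = 0.3
#' @export
aggregate_fu <- function(measurements, strict_qc = FALSE,
                         recovery_pass = 70, recovery_caution = 50,
                         plasma_volume = 1, buffer_volume = 1) {
  m <- measurements
  if (nrow(m) == 0L) {
    stop("no measurements to aggregate", call. = FALSE)
  }
  if (any(is.na(m$dilution_factor))) {
    stop("dilution_factor missing: cannot correct to 100% plasma",
         call. = FALSE)
  }
  fu_raw <- compute_fu(m$plasma_conc_uM, m$buffer_conc_uM)
  m$fu <- correct_dilution(fu_raw, m$dilution_factor,
                           allow_above_one = TRUE)
  m$recovery <- compute_recovery(m$plasma_conc_uM, m$buffer_conc_uM,
                                 m$nominal_uM, plasma_volume, buffer_volume,
                                 pass = recovery_pass,
                                 caution = recovery_caution)$recovery_pct

  key <- interaction(m$api, m$species, drop = TRUE, sep = "\r")
  pieces <- lapply(split(m, key), function(grp) {
    flags <- character(0)
    if (any(grp$fu > 1)) flags <- c(flags, "fu_above_one")
    if (any(grp$recovery < recovery_pass)) flags <- c(flags, "low_recovery")
    used <- if (strict_qc) grp[grp$fu <= 1, , drop = FALSE] else grp
    if (nrow(used) == 0L) {
      stop("api '", grp$api[1L], "', species '", grp$species[1L],
           "': all replicates excluded by strict QC", call. = FALSE)
    }
    lab_means <- tapply(used$fu, used$lab, mean)
    data.frame(api = grp$api[1L], species = grp$species[1L],
               fu_min = min(lab_means),
               fu_median = stats::median(lab_means),
               fu_max = max(lab_means),
               n_replicates = nrow(grp),
               n_labs = length(lab_means),
               qc_flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  # preserve first-appearance order of (api, species)
  out <- out[match(unique(as.character(key)),
                   paste(out$api, out$species, sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fu_summary", "data.frame")
  out
}
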