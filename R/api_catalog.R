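#' @keywords internal
"_PACKAGE"

# Valid speciation codes: predominant charge at plasma pH 7.4-7.9.
# A anion, a anionic (unionized), N neutral, c cationic (unionized),
# C cation, Z zwitterion.
SPECIATION_CODES <- c("A", "a", "N", "c", "C", "Z")

#' Map speciation codes to charge classes
#'
#' Collapses the six speciation codes to a charge factor. Two named
#' mappings are provided. The `"default"` mapping groups by acid/base
#' character (`A`,`a` -> anionic; `C`,`c` -> cationic; `N` -> neutral;
#' `Z` -> zwitterionic) and is the four-level factor used for modelling.
#' The `"group_counts"` mapping groups by ionization state instead
#' (`a`,`N`,`c` -> unionized) and matches how prioritisation counts are
#' reported per group.
#'
#' @param speciation character vector of speciation codes.
#' @param mapping `"default"` or `"group_counts"`.
#' @return character vector of charge classes, same length as `speciation`.
#' @examples
#' charge_class(c("A", "a", "N", "c", "C", "Z"))
#' charge_class(c("A", "a", "N", "c", "C", "Z"), mapping = "group_counts")
#' @export
charge_class <- function(speciation, mapping = c("default", "group_counts")) {
  mapping <- match.arg(mapping)
  bad <- setdiff(unique(speciation), c(SPECIATION_CODES, NA))
  if (length(bad) > 0L) {
    stop("unknown speciation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map <- switch(mapping,
    default = c(A = "anionic", a = "anionic", N = "neutral",
                c = "cationic", C = "cationic", Z = "zwitterionic"),
    group_counts = c(A = "anionic", a = "unionized", N = "unionized",
                     c = "unionized", C = "cationic", Z = "zwitterionic"))
  unname(map[speciation])
}

# Normalise typographic minus signs (en dash U+2013, minus sign U+2212)
# to ASCII hyphen-minus so numeric parsing is locale-independent.
normalize_minus <- function(x) {
  gsub("–|−", "-", x)
}

as_numeric_strict <- function(x, column, path = "<table>") {
  x <- trimws(normalize_minus(as.character(x)))
  x[x %in% c("", "-", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("%s: column '%s', row %d: cannot parse '%s' as a number",
                 path, column, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read an API descriptor table
#'
#' Reads a comma-delimited UTF-8 table of pharmaceutical descriptors with
#' header `name,speciation,mw,pka,logd_ph7.4,...,cmax_mg_per_L,
#' noec_mg_per_L,loec_mg_per_L`. Any column matching `logd_phX.Y` is
#' accepted and carried as LogD at that pH. En-dash/minus-sign glyphs in
#' numeric fields are normalised to ASCII before parsing; empty fields
#' become `NA` (explicit absence, never zero).
#'
#' @param path path to the CSV file.
#' @return a `data.frame` of class `api_table`, one row per API, with a
#'   `charge_class` column derived from `speciation`.
#' @seealso [write_api_table()], [load_fixture()]
#' @export
read_api_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("name", "speciation")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  logd_cols <- grep("^logd_ph[0-9]+(\\.[0-9]+)?$", names(raw), value = TRUE)
  if (length(logd_cols) == 0L) {
    stop(path, ": no logd_phX.Y column found", call. = FALSE)
  }
  out <- data.frame(name = trimws(raw$name),
                    speciation = trimws(raw$speciation),
                    stringsAsFactors = FALSE)
  dup <- out$name[duplicated(out$name)]
  if (length(dup) > 0L) {
    stop(path, ": duplicate API name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out$charge_class <- charge_class(out$speciation)   # validates codes
  for (col in c("mw", "pka", logd_cols,
                "cmax_mg_per_L", "noec_mg_per_L", "loec_mg_per_L")) {
    if (col %in% names(raw)) {
      out[[col]] <- as_numeric_strict(raw[[col]], col, path)
    } else if (!col %in% logd_cols) {
      out[[col]] <- NA_real_
    }
  }
  for (col in c("cmax_mg_per_L", "noec_mg_per_L", "loec_mg_per_L")) {
    bad <- which(!is.na(out[[col]]) & out[[col]] <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s: column '%s', row %d: must be strictly positive",
                   path, col, bad[1L]), call. = FALSE)
    }
  }
  if (all(vapply(logd_cols, function(cl) all(is.na(out[[cl]])), logical(1L)))) {
    stop(path, ": all LogD values missing", call. = FALSE)
  }
  attr(out, "logd_columns") <- logd_cols
  class(out) <- c("api_table", "data.frame")
  out
}

#' Write an API descriptor table
#'
#' Inverse of [read_api_table()]: writes the documented CSV dialect with
#' missing values as empty fields. `read_api_table(write_api_table(x))`
#' is field-identical for valid tables.
#'
#' @param apis an `api_table` (or compatible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_api_table <- function(apis, path) {
  cols <- c("name", "speciation", "mw", "pka", logd_columns(apis),
            "cmax_mg_per_L", "noec_mg_per_L", "loec_mg_per_L")
  cols <- intersect(cols, names(apis))
  utils::write.csv(apis[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' LogD column names of an API table
#'
#' @param apis an `api_table` or any data.frame using the package's column
#'   conventions.
#' @return character vector of `logd_phX.Y` column names present.
#' @export
logd_columns <- function(apis) {
  grep("^logd_ph[0-9]+(\\.[0-9]+)?$", names(apis), value = TRUE)
}

# Column name for LogD at a given pH, erroring when absent.
logd_column_for_ph <- function(apis, ph) {
  col <- sprintf("logd_ph%s", format(ph, trim = TRUE))
  if (!col %in% names(apis)) {
    stop("API table has no LogD column for pH ", ph,
         " (expected column '", col, "')", call. = FALSE)
  }
  col
}

#' Species assay contexts
#'
#' Plasma pH, assay incubation temperature and assay plasma fraction for
#' the species supported out of the box. Human, koi carp and rainbow trout
#' plasma is assayed undiluted; fathead minnow plasma at 10% in pH-matched
#' isotonic buffer (assay plasma fraction 0.1, i.e. dilution factor 10).
#'
#' @param path optional path to a contexts CSV
#'   (`species_id,plasma_ph,assay_temperature_C,assay_plasma_fraction`);
#'   defaults to the packaged table.
#' @return data.frame with one row per species.
#' @export
species_contexts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_contexts.csv",
                        package = "fishplasma", mustWork = TRUE)
  }
  ctx <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species_id", "plasma_ph", "assay_temperature_C",
              "assay_plasma_fraction")
  missing_cols <- setdiff(needed, names(ctx))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(ctx$plasma_ph < 6.5 | ctx$plasma_ph > 8.5)) {
    stop(path, ": plasma_ph outside [6.5, 8.5]", call. = FALSE)
  }
  if (any(ctx$assay_plasma_fraction <= 0 | ctx$assay_plasma_fraction > 1)) {
    stop(path, ": assay_plasma_fraction outside (0, 1]", call. = FALSE)
  }
  ctx
}

#' Load the packaged 44-pharmaceutical screening fixture
#'
#' Loads the packaged rainbow-trout screening table (44 APIs: printed LogD
#' at pH 7.4 and 7.9, human C_max, worst-case Rf_u = trout f_u max / human
#' f_u min, chronic NOEC/LOEC where available, and the printed partition
#' coefficients and TWC columns for cross-checking) together with the
#' species assay contexts. Missing printed values are `NA`; a printed
#' Rf_u of `0` is preserved as zero and treated downstream as below
#' quantification (refined TWC undefined).
#'
#' @param path optional path to an alternative fixture CSV.
#' @return a list with elements
#'   \describe{
#'     \item{apis}{`api_table` of the 44 APIs (name, speciation,
#'       charge_class, LogD at pH 7.4/7.9, C_max, NOEC, LOEC).}
#'     \item{rfu}{data.frame `name`, `rfu_trout_max_human_min`.}
#'     \item{printed}{data.frame of the printed partition/TWC/ratio columns
#'       for validation.}
#'     \item{contexts}{species context table, see [species_contexts()].}
#'   }
#' @examples
#' fx <- load_fixture()
#' nrow(fx$apis)            # 44
#' table(fx$apis$speciation)
#' @export
load_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trout_screen44.csv",
                        package = "fishplasma", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- c("speciation", "name", "logd_ph7.4", "pbw_fish", "logd_ph7.9",
                "pbw_trout", "cmax_mg_per_L", "rfu_trout_max_human_min",
                "twc_original_mg_per_L", "twc_refined_mg_per_L",
                "twc_orig_over_refined", "noec_mg_per_L", "loec_mg_per_L",
                "twc_orig_over_loec", "twc_refined_over_loec")
  missing_cols <- setdiff(expected, names(raw))
  if (length(missing_cols) > 0L) {
    stop("fixture ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$name[i]) || !nzchar(raw$name[i])) {
      stop("fixture ", path, ": row ", i, ": column 'name' is empty",
           call. = FALSE)
    }
    if (!raw$speciation[i] %in% SPECIATION_CODES) {
      stop("fixture ", path, ": row ", i,
           ": column 'speciation' has invalid code '", raw$speciation[i],
           "'", call. = FALSE)
    }
  }
  num <- raw
  for (col in setdiff(expected, c("speciation", "name"))) {
    num[[col]] <- as_numeric_strict(raw[[col]], col, path)
  }
  apis <- data.frame(name = num$name,
                     speciation = num$speciation,
                     charge_class = charge_class(num$speciation),
                     mw = NA_real_, pka = NA_real_,
                     `logd_ph7.4` = num$`logd_ph7.4`,
                     `logd_ph7.9` = num$`logd_ph7.9`,
                     cmax_mg_per_L = num$cmax_mg_per_L,
                     noec_mg_per_L = num$noec_mg_per_L,
                     loec_mg_per_L = num$loec_mg_per_L,
                     check.names = FALSE, stringsAsFactors = FALSE)
  attr(apis, "logd_columns") <- c("logd_ph7.4", "logd_ph7.9")
  class(apis) <- c("api_table", "data.frame")
  list(apis = apis,
       rfu = data.frame(name = num$name,
                        rfu_trout_max_human_min = num$rfu_trout_max_human_min,
                        stringsAsFactors = FALSE),
       printed = num[, c("name", "pbw_fish", "pbw_trout",
                         "twc_original_mg_per_L", "twc_refined_mg_per_L",
                         "twc_orig_over_refined", "twc_orig_over_loec",
                         "twc_refined_over_loec")],
       contexts = species_contexts())
}
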