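# Shared helpers: printed-precision tolerances and small in-code fixtures.

# Tolerance for comparing a recomputed value against a printed one:
# the larger of a relative band, half the resolution of the printed
# representation (a value printed as 0.004 is only known to +-0.0005),
# and a relative slack propagated from the printed precision of an input
# (e.g. an Rf_u printed as an integer).
printed_tolerance <- function(printed_str, rel = 0.05, input_rel = 0) {
  printed <- suppressWarnings(as.numeric(printed_str))
  has_dec <- grepl("\\.", printed_str) & !grepl("[eE]", printed_str)
  dec <- ifelse(has_dec, nchar(sub(".*\\.", "", printed_str)), 0)
  res <- ifelse(grepl("[eE]", printed_str),
                0.01 * abs(printed), 0.51 * 10^(-dec))
  pmax(rel * abs(printed), res, input_rel * abs(printed))
}

# Relative half-resolution of a printed number (e.g. "29" -> 0.5/29).
printed_input_rel <- function(printed_str) {
  printed <- suppressWarnings(as.numeric(printed_str))
  has_dec <- grepl("\\.", printed_str)
  dec <- ifelse(has_dec, nchar(sub(".*\\.", "", printed_str)), 0)
  out <- 0.5 * 10^(-dec) / abs(printed)
  out[is.na(out) | !is.finite(out)] <- 0
  out
}

# The packaged screening table with every cell kept as printed text.
fixture_printed <- function() {
  utils::read.csv(system.file("extdata", "trout_screen44.csv",
                              package = "fishplasma"),
                  colClasses = "character", check.names = FALSE)
}

# Minimal valid API table CSV written to a temp file.
write_tiny_api_csv <- function(path, logd74 = c(-1.12, 0.5, 2.0)) {
  writeLines(c(
    "name,speciation,mw,pka,logd_ph7.4,logd_ph7.9,cmax_mg_per_L,noec_mg_per_L,loec_mg_per_L",
    sprintf("drugA,A,350,4.5,%s,-1.5,0.4,,", logd74[1]),
    sprintf("drugB,C,280,9.1,%s,0.9,0.05,0.1,0.3", logd74[2]),
    sprintf("drugC,N,410,7.0,%s,2.0,1.2,,", logd74[3])
  ), path)
  path
}

# Closed-form free fraction for single-site binding: total ligand Lt,
# total protein Pt, dissociation constant Kd (all same units).
free_fraction_single_site <- function(Lt, Pt, Kd) {
  b <- Pt + Lt + Kd
  complex <- (b - sqrt(b^2 - 4 * Pt * Lt)) / 2
  (Lt - complex) / Lt
}
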