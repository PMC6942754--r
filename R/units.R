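# Unit parsing for config values. Internal computation is strictly SI;
# config files may state values as "6 kV/cm", "300 ns", "10 um", etc.

.pf_unit_table <- c(
  "V/m" = 1, "kV/m" = 1e3, "kV/cm" = 1e5, "V/cm" = 1e2,
  "s" = 1, "ms" = 1e-3, "us" = 1e-6, "ns" = 1e-9, "ps" = 1e-12,
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9,
  "V" = 1, "mV" = 1e-3,
  "S/m" = 1, "mS/m" = 1e-3,
  "K" = 1, "J" = 1, "J/m" = 1, "J/m^2" = 1, "N/V^2" = 1,
  "m^-2" = 1, "1/m^2" = 1, "m^2/s" = 1, "m^-2/s" = 1
)

#' Convert a config value to SI units
#'
#' Accepts a bare number (already SI) or a string of the form
#' `"<number> <unit>"` with a recognised unit (e.g. `"6 kV/cm"`,
#' `"300 ns"`, `"10 um"`).
#'
#' @param x numeric or character scalar.
#' @param key field name used in error messages.
#' @return numeric scalar in SI units.
#' @keywords internal
pf_si <- function(x, key = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("config field '%s': expected a number or '<number> <unit>' string", key))
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(num <- as.numeric(m[2]))))
    stop(sprintf("config field '%s': cannot parse value '%s'", key, x))
  unit <- trimws(m[3])
  if (unit == "") return(num)
  # normalise a few spellings
  unit <- sub("µ", "u", unit)          # micro sign
  unit <- gsub("\\s+", "", unit)
  if (!unit %in% names(.pf_unit_table))
    stop(sprintf("config field '%s': unknown unit '%s'", key, unit))
  num * .pf_unit_table[[unit]]
}
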