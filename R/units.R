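#' Convert a concentration to mol/L
#'
#' All model code in bindfit works in mol/L; unit conversion happens only at
#' I/O boundaries. Units must be declared explicitly — nothing is inferred.
#'
#' @param value numeric vector of concentrations.
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return numeric vector in mol/L.
#' @examples
#' to_molar(17, "mM")
#' to_molar(c(0, 0.5, 1), "uM")
#' @export
to_molar <- function(value, unit) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  if (length(unit) != 1L || !unit %in% names(scale)) {
    stop("unknown concentration unit: ", paste(unit, collapse = ", "),
         " (expected one of ", paste(names(scale), collapse = ", "), ")")
  }
  value * scale[[unit]]
}

#' Convert mol/L back to a named unit
#' @param value numeric vector in mol/L.
#' @inheritParams to_molar
#' @return numeric vector in `unit`.
#' @export
from_molar <- function(value, unit) {
  value / to_molar(1, unit)
}

#' Concentration from an amount loaded in a volume
#'
#' EMSA lanes are typically specified as an amount of nucleosome (pmol) in a
#' load volume (uL); this converts to mol/L. 1.5 pmol in 8 uL is 0.1875 uM,
#' 3 pmol in 8 uL is 0.375 uM.
#'
#' @param pmol amount in picomoles.
#' @param volume_ul load volume in microlitres.
#' @return concentration in mol/L.
#' @examples
#' from_molar(amount_to_molar(3, 8), "uM")  # 0.375
#' @export
amount_to_molar <- function(pmol, volume_ul) {
  if (any(pmol < 0) || any(volume_ul <= 0)) {
    stop("pmol must be >= 0 and volume_ul > 0")
  }
  (pmol * 1e-12) / (volume_ul * 1e-6)
}

# internal: positive, finite scalar check with a named error
check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(name, " must be finite and numeric")
  }
  if (allow_zero) {
    if (any(x < 0)) stop(name, " must be >= 0, got ", min(x))
  } else {
    if (any(x <= 0)) stop(name, " must be > 0, got ", min(x))
  }
  invisible(x)
}
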