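#' Spectrum kinds
#'
#' The four supported one-dimensional techniques. NMR and IR spectra are
#' drawn as line plots, mass spectra as bar (stick) plots.
#'
#' @format Character vector of kind identifiers.
#' @export
SPECTRUM_KINDS <- c("NMR_1H", "NMR_13C", "IR", "MS")

#' Plot layout associated with a spectrum kind
#'
#' @param kind One of `SPECTRUM_KINDS`.
#' @return `"line"` for NMR/IR, `"bar"` for MS.
#' @export
kind_layout <- function(kind) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (kind == "MS") "bar" else "line"
}

#' Construct a spectrum
#'
#' The central container shared by all modules: a decoded x/y trace plus a
#' kind tag and acquisition metadata. The abscissa is ppm for NMR,
#' wavenumber (1/cm) for IR and m/z for MS; it must be strictly monotonic
#' in either direction, and the direction is preserved on write.
#'
#' @param x,y Numeric vectors of equal length (>= 1).
#' @param kind One of `SPECTRUM_KINDS`.
#' @param meta Named list; recognised keys include `observe_freq` (MHz),
#'   `solvent`, `x_units`, `y_units`, `title`, `data_class`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(x, y, kind, meta = list()) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 1L) {
    spk_stop("invalid_spec", "x and y must have equal length >= 1")
  }
  if (length(x) > 1L) {
    d <- diff(x)
    if (!(all(d > 0) || all(d < 0))) {
      spk_stop("invalid_spec", "x must be strictly monotonic")
    }
  }
  if (kind == "MS" && any(y < 0)) {
    spk_stop("invalid_spec", "mass-spectrum intensities must be non-negative")
  }
  structure(list(x = x, y = y, kind = kind, meta = meta), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$x)
  cat(sprintf("<spectrum> kind=%s  n=%d  x: [%g, %g] %s\n",
              x$kind, length(x$x), rng[1], rng[2],
              x$meta$x_units %||% ""))
  if (!is.null(x$meta$observe_freq)) {
    cat(sprintf("  observe frequency: %g MHz\n", x$meta$observe_freq))
  }
  if (!is.null(x$meta$title)) cat("  title:", x$meta$title, "\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) data.frame(x = x$x, y = x$y)

observe_freq <- function(s) {
  f <- s$meta$observe_freq
  if (is.null(f) || !is.finite(f) || f <= 0) {
    spk_stop("invalid_spec",
             "a positive observe frequency (MHz) is required for Hz-based computation")
  }
  f
}

#' Is an IR trace stored as transmittance?
#'
#' Transmittance traces have absorption bands as minima; they are detected
#' from the y-units label, or heuristically from a high baseline
#' (max(y) > 5 with the bulk of the trace near the maximum).
#'
#' @param s A `spectrum` of kind `IR`.
#' @return Logical.
#' @export
is_transmittance <- function(s) {
  if (s$kind != "IR") return(FALSE)
  yu <- toupper(s$meta$y_units %||% "")
  if (grepl("TRANSMITTANCE", yu)) return(TRUE)
  if (grepl("ABSORBANCE", yu)) return(FALSE)
  max(s$y) > 5 && stats::median(s$y) > 0.75 * max(s$y)
}

#' Peak-direction-corrected ordinate
#'
#' Peak logic works on an "effective" intensity in which peaks are maxima:
#' IR transmittance traces are inverted (band depth below the 100% line);
#' all other spectra are used as-is.
#'
#' @param s A `spectrum`.
#' @return Numeric vector, same length as `s$y`.
#' @export
effective_intensity <- function(s) {
  if (is_transmittance(s)) max(s$y) - s$y else s$y
}

.default_threshold_frac <- c(NMR_1H = 0.01, NMR_13C = 0.05, IR = 0.20, MS = 0.05)

#' Default peak-picking threshold for a spectrum
#'
#' Per-kind defaults, as a fraction of the maximum effective intensity:
#' 1% for 1H NMR, 5% for 13C NMR, 20% of the deepest band for IR, and 5% of
#' the base peak for MS. Deterministic for a given spectrum and always
#' strictly inside the effective ordinate range.
#'
#' @param s A `spectrum`.
#' @param config Optional named list overriding the fractions, with keys
#'   `threshold.nmr1h`, `threshold.nmr13c`, `threshold.ir`, `threshold.ms`
#'   (fractions in \[0, 1\]).
#' @return Threshold on the effective-intensity scale.
#' @export
default_threshold <- function(s, config = NULL) {
  eff <- effective_intensity(s)
  lo <- min(eff); hi <- max(eff)
  if (hi <= lo) {
    spk_stop("degenerate_spectrum", "spectrum is constant; no sensible threshold exists")
  }
  key <- c(NMR_1H = "threshold.nmr1h", NMR_13C = "threshold.nmr13c",
           IR = "threshold.ir", MS = "threshold.ms")[[s$kind]]
  frac <- config[[key]] %||% .default_threshold_frac[[s$kind]]
  if (!is.finite(frac) || frac <= 0 || frac >= 1) {
    spk_stop("invalid_spec", sprintf("threshold fraction for %s must be in (0, 1)", s$kind))
  }
  thr <- frac * hi
  if (thr <= lo) thr <- lo + frac * (hi - lo)
  thr
}

#' Detect the spectrum type of a JCAMP-DX document
#'
#' The data-type record is matched first (case-insensitive substring match
#' on "MASS", "INFRARED"/"IR", "NMR"); NMR documents are then split on the
#' observe-nucleus record ("^1H" vs "^13C"). When the data-type record is
#' absent, the x-units record is used as a fallback ("1/CM" -> IR,
#' "M/Z" -> MS, "PPM"/"HZ" -> NMR). If no rule fires an error of class
#' `speckit_unrecognized_type` is raised rather than guessing.
#'
#' @param doc A `jcamp_document` (see [parse_jcamp()]).
#' @return One of `SPECTRUM_KINDS`.
#' @export
detect_type <- function(doc) {
  dt <- toupper(jc_value(doc, "DATATYPE") %||% "")
  xu <- toupper(jc_value(doc, "XUNITS") %||% "")

  nmr_kind <- function() {
    nuc <- toupper(jc_value(doc, ".OBSERVENUCLEUS") %||% "")
    if (grepl("13C", nuc, fixed = TRUE)) return("NMR_13C")
    if (grepl("1H", nuc, fixed = TRUE)) return("NMR_1H")
    spk_stop("unrecognized_type",
             "NMR document without a recognisable observe-nucleus record")
  }

  if (nzchar(dt)) {
    if (grepl("MASS", dt)) return("MS")
    if (grepl("INFRARED", dt) || grepl("\\bIR\\b", dt)) return("IR")
    if (grepl("NMR", dt)) return(nmr_kind())
  }
  if (grepl("1/CM", xu, fixed = TRUE) || grepl("CM-1", xu, fixed = TRUE)) return("IR")
  if (grepl("M/Z", xu, fixed = TRUE)) return("MS")
  if (grepl("PPM", xu) || grepl("\\bHZ\\b", xu)) return(nmr_kind())
  spk_stop("unrecognized_type", sprintf(
    "unsupported technique: data type '%s', x units '%s'", dt, xu))
}
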