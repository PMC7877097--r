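# NMR-specific analysis: residual-solvent referencing, signal integration,
# multiplicity / coupling-constant inference and journal-style reporting.
#
# Multiplicity inference converts peak spacings to Hz (delta-ppm times the
# observe frequency) and matches them against coupling-tree patterns under
# conservative validation rules; anything that fails any rule is reported
# as an unresolved multiplet ("m") rather than a wrong named label.

.multiplet_mults <- list(
  s = integer(0), d = 2L, t = 3L, q = 4L, quint = 5L, sext = 6L, sept = 7L,
  dd = c(2L, 2L), dt = c(2L, 3L), td = c(3L, 2L))

#' Residual-solvent reference shifts
#'
#' The shipped table of the most common deuterated-solvent residual shifts
#' (ppm) for 1H and 13C, loaded from the package's `solvent_shifts.csv`.
#'
#' @return Data frame with columns `solvent`, `nucleus`, `shift_ppm`.
#' @export
solvent_shifts <- function() {
  utils::read.csv(system.file("extdata", "solvent_shifts.csv",
                              package = "speckit"),
                  stringsAsFactors = FALSE)
}

.nucleus_of <- function(s) {
  switch(s$kind, NMR_1H = "1H", NMR_13C = "13C",
         spk_stop("invalid_spec", "not an NMR spectrum"))
}

#' Reference an NMR spectrum to a residual solvent shift
#'
#' Rigidly shifts the ppm axis so that the observed residual-solvent
#' position lands on its tabulated value: every x is shifted by
#' (expected - observed); the ordinate is untouched and the applied shift
#' is recorded in the metadata.
#'
#' @param s An NMR `spectrum`.
#' @param solvent Solvent name as in [solvent_shifts()].
#' @param observed_ppm Observed position of the residual solvent peak.
#' @return The referenced `spectrum`.
#' @export
reference_correct <- function(s, solvent, observed_ppm) {
  nuc <- .nucleus_of(s)
  tab <- solvent_shifts()
  row <- tab[tab$solvent == solvent & tab$nucleus == nuc, ]
  if (!nrow(row)) {
    spk_stop("unknown_solvent", sprintf(
      "no %s reference shift for solvent '%s'", nuc, solvent))
  }
  shift <- row$shift_ppm[1] - observed_ppm
  s$x <- s$x + shift
  s$meta$reference <- list(solvent = solvent, nucleus = nuc,
                           expected_ppm = row$shift_ppm[1],
                           observed_ppm = observed_ppm, shift_ppm = shift)
  s
}

.raw_area <- function(s, lo, hi) {
  sel <- which(s$x >= lo & s$x <= hi)
  if (length(sel) < 2L) {
    spk_stop("empty_range", sprintf("no grid points in range [%g, %g]", lo, hi))
  }
  sel <- sel[order(s$x[sel])]
  x <- s$x[sel]; y <- s$y[sel]
  n <- length(x)
  # anchor the local baseline on the mean of the outermost points of the
  # range (up to 3 per side) so a single noisy endpoint cannot tilt it
  k <- min(3L, n %/% 2L)
  y0 <- mean(y[seq_len(k)]); y1 <- mean(y[(n - k + 1L):n])
  x0 <- mean(x[seq_len(k)]); x1 <- mean(x[(n - k + 1L):n])
  base <- y0 + (y1 - y0) * (x - x0) / (x1 - x0)
  yc <- y - base
  sum(diff(x) * (yc[-1] + yc[-n]) / 2)
}

#' Integrate NMR signal ranges
#'
#' Each raw area is the trapezoidal area of the trace above a local linear
#' baseline through the range endpoints. Areas are normalized so that the
#' reference range integrates exactly to `ref_value`.
#'
#' @param s An NMR `spectrum`.
#' @param ranges List of `c(lo, hi)` ppm pairs (or a 2-column matrix).
#' @param ref_range Reference range; defaults to the first range.
#' @param ref_value Value assigned to the reference range (default 1).
#' @return Data frame with columns `lo`, `hi`, `raw`, `integral`.
#' @export
nmr_integrate <- function(s, ranges, ref_range = NULL, ref_value = 1.0) {
  if (is.matrix(ranges)) ranges <- split(ranges, row(ranges)[, 1])
  if (!is.list(ranges)) ranges <- list(ranges)
  if (ref_value <= 0) spk_stop("invalid_spec", "ref_value must be positive")
  ranges <- lapply(ranges, function(r) sort(as.numeric(r)[1:2]))
  ref_range <- sort(as.numeric(ref_range %||% ranges[[1]])[1:2])
  raw <- vapply(ranges, function(r) .raw_area(s, r[1], r[2]), numeric(1))
  ref_raw <- .raw_area(s, ref_range[1], ref_range[2])
  if (ref_raw <= 0) {
    spk_stop("zero_reference", "reference range has non-positive raw area")
  }
  data.frame(
    lo = vapply(ranges, `[`, numeric(1), 1L),
    hi = vapply(ranges, `[`, numeric(1), 2L),
    raw = raw,
    integral = raw * ref_value / ref_raw)
}

.check_intensities <- function(obs, expected, tol = 0.3) {
  scale <- sum(obs) / sum(expected)
  all(abs(obs / (expected * scale) - 1) <= tol)
}

.j_tol <- function(J) pmax(0.15, 0.05 * J)

.binomial_match <- function(hz, ints) {
  n <- length(hz)
  if (n < 2L || n > 7L) return(NULL)
  spac <- diff(hz)
  J <- mean(spac)
  if (J < 0.5 || J > 25) return(NULL)
  if (any(abs(spac - J) > .j_tol(J))) return(NULL)
  if (!.check_intensities(ints, choose(n - 1L, 0:(n - 1L)))) return(NULL)
  list(label = c("d", "t", "q", "quint", "sext", "sept")[n - 1L], J = J)
}

.dd_match <- function(hz, ints) {
  if (length(hz) != 4L) return(NULL)
  J2 <- mean(c(hz[2] - hz[1], hz[4] - hz[3]))
  J1 <- mean(c(hz[3] - hz[1], hz[4] - hz[2]))
  if (any(c(J1, J2) < 0.5) || any(c(J1, J2) > 25)) return(NULL)
  tol1 <- .j_tol(J1); tol2 <- .j_tol(J2)
  if (abs((hz[2] - hz[1]) - (hz[4] - hz[3])) > tol2) return(NULL)
  if (abs((hz[3] - hz[1]) - (hz[4] - hz[2])) > tol1) return(NULL)
  if (J1 - J2 <= max(tol1, tol2)) return(NULL)   # would be a triplet
  if (!.check_intensities(ints, rep(1, 4))) return(NULL)
  list(label = "dd", J = c(J1, J2))
}

.two_coupling_match <- function(hz, ints, ma, mb) {
  # brute-force fit of a (ma x mb) coupling tree over candidate J pairs
  n <- length(hz)
  if (n != ma * mb) return(NULL)
  gaps <- as.vector(outer(hz, hz, "-"))
  gaps <- sort(unique(round(gaps[gaps > 0.4 & gaps < 26], 3)))
  if (!length(gaps)) return(NULL)
  ctr <- mean(hz)
  width <- hz[n] - hz[1]
  wa <- choose(ma - 1L, 0:(ma - 1L))
  wb <- choose(mb - 1L, 0:(mb - 1L))
  best <- NULL
  for (Ja in gaps) {
    for (Jb in gaps) {
      if ((ma - 1L) * Ja + (mb - 1L) * Jb > width + 1) next
      tol <- .j_tol(min(Ja, Jb))
      if (abs((ma - 1L) * Ja + (mb - 1L) * Jb - width) > 2 * tol) next
      offs <- outer((0:(ma - 1L) - (ma - 1L) / 2) * Ja,
                    (0:(mb - 1L) - (mb - 1L) / 2) * Jb, "+")
      pred <- sort(as.vector(offs)) + ctr
      # coincident predicted lines would merge; require distinct lines
      if (min(diff(pred)) < tol) next
      err <- abs(pred - hz)
      if (any(err > tol)) next
      o <- order(as.vector(offs))
      wpred <- as.vector(outer(wa, wb))[o]
      if (!.check_intensities(ints, wpred)) next
      rms <- sqrt(mean(err^2))
      if (is.null(best) || rms < best$rms) {
        best <- list(Ja = Ja, Jb = Jb, rms = rms)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best
}

#' Infer the multiplicity and coupling constants of one signal
#'
#' Peak spacings are converted to Hz via the observe frequency and matched
#' against coupling-tree patterns (binomial n-line multiplets d..sept, and
#' the two-coupling patterns dd, dt, td). Validation rules: spacings must
#' agree within max(0.15 Hz, 5% of J); line intensities must match the
#' pattern's binomial/tree ratios within 30%; named J values must lie in
#' \[0.5, 25\] Hz; the two J of a dd must differ resolvably. A signal
#' failing any rule is reported as `("m", no J)` - never a wrong named
#' label with fabricated couplings.
#'
#' @param peaks Data frame of the active peaks of one signal (columns `x`
#'   in ppm and `y`), or a `peak_list`.
#' @param observe_freq Observe frequency in MHz.
#' @return List with elements `label` and `J` (Hz, sorted descending).
#' @export
analyze_multiplet <- function(peaks, observe_freq) {
  if (inherits(peaks, "peak_list")) peaks <- active_peaks(peaks)
  if (!is.finite(observe_freq) || observe_freq <= 0) {
    spk_stop("invalid_spec", "observe_freq must be positive (MHz)")
  }
  n <- nrow(peaks)
  fallback <- list(label = "m", J = numeric(0))
  if (n < 1L || n > 16L) return(fallback)
  if (n == 1L) return(list(label = "s", J = numeric(0)))
  o <- order(peaks$x)
  hz <- peaks$x[o] * observe_freq
  ints <- peaks$y[o]

  m <- .binomial_match(hz, ints)
  if (!is.null(m)) return(list(label = m$label, J = round(m$J, 2)))
  if (n == 4L) {
    m <- .dd_match(hz, ints)
    if (!is.null(m)) return(list(label = "dd", J = round(sort(m$J, decreasing = TRUE), 2)))
  }
  if (n == 6L) {
    m <- .two_coupling_match(hz, ints, 2L, 3L)
    if (!is.null(m)) {
      label <- if (m$Ja >= m$Jb) "dt" else "td"
      return(list(label = label,
                  J = round(sort(c(m$Ja, m$Jb), decreasing = TRUE), 2)))
    }
  }
  fallback
}

#' Construct an NMR signal
#'
#' A grouped multiplet: its ppm range, member peaks, multiplicity label,
#' coupling constants and normalized integral.
#'
#' @param range `c(lo, hi)` in ppm.
#' @param peaks Data frame of member peaks (`x`, `y`).
#' @param label Multiplicity label (`s`, `d`, `t`, `q`, `quint`, `sext`,
#'   `sept`, `dd`, `dt`, `td`, `m`).
#' @param J Coupling constants in Hz (empty for `s` and `m`).
#' @param integral Normalized area (>= 0).
#' @param nucleus `"1H"` or `"13C"`.
#' @return An object of class `nmr_signal`.
#' @export
nmr_signal <- function(range, peaks, label, J = numeric(0), integral = NA_real_,
                       nucleus = "1H") {
  label <- match.arg(label, c(names(.multiplet_mults), "m"))
  J <- sort(as.numeric(J), decreasing = TRUE)
  if (label == "s" && length(J)) {
    spk_stop("invalid_spec", "a singlet carries no coupling constants")
  }
  if (label %in% c("s", "m")) J <- numeric(0)
  if (length(J) && (any(J <= 0) || any(J < 0.5 | J > 25))) {
    spk_stop("invalid_spec", "named J values must lie in [0.5, 25] Hz")
  }
  if (is.finite(integral) && integral < 0) {
    spk_stop("invalid_spec", "integral must be >= 0")
  }
  structure(list(range = sort(as.numeric(range)[1:2]), peaks = peaks,
                 label = label, J = J, integral = integral,
                 nucleus = nucleus),
            class = "nmr_signal")
}

#' @export
print.nmr_signal <- function(x, ...) {
  jtxt <- if (length(x$J)) sprintf(", J = %s Hz",
                                   paste(sprintf("%.1f", x$J), collapse = ", ")) else ""
  cat(sprintf("<nmr_signal> %.2f-%.2f ppm (%s%s), integral %.2f\n",
              x$range[1], x$range[2], x$label, jtxt, x$integral))
  invisible(x)
}

.signal_shift <- function(sig) {
  if (nrow(sig$peaks)) mean(sig$peaks$x) else mean(sig$range)
}

.fmt_nH <- function(integral) {
  h <- round(integral * 2) / 2          # nearest 0.5 H
  if (h == round(h)) sprintf("%dH", as.integer(h)) else sprintf("%.1fH", h)
}

#' Journal-style NMR signal report
#'
#' Formats a signal list the way experimental sections print it, e.g.
#' `1H NMR (400 MHz, CDCl3) d = 8.52 (s, 1H), 7.45 (dd, J = 12.0, 4.0 Hz,
#' 1H)`; shifts sorted descending, J values descending, integrals rounded
#' to the nearest 0.5 H. 13C reports omit multiplicity and J.
#'
#' @param signals List of `nmr_signal` objects.
#' @param nucleus `"1H"` or `"13C"`.
#' @param observe_freq Observe frequency in MHz.
#' @param solvent Solvent name.
#' @return A single string.
#' @export
nmr_report <- function(signals, nucleus = "1H", observe_freq = 400,
                       solvent = "CDCl3") {
  stopifnot(length(signals) >= 1L)
  nuc_txt <- if (nucleus == "13C") "\u00b9\u00b3C" else "\u00b9H"
  shifts <- vapply(signals, .signal_shift, numeric(1))
  signals <- signals[order(shifts, decreasing = TRUE)]
  shifts <- sort(shifts, decreasing = TRUE)
  digits <- if (nucleus == "13C") 1L else 2L
  parts <- vapply(seq_along(signals), function(i) {
    sig <- signals[[i]]
    shift <- formatC(round_half_away(shifts[i], digits), format = "f",
                     digits = digits)
    if (nucleus == "13C") return(shift)
    inner <- sig$label
    if (length(sig$J)) {
      inner <- paste0(inner, sprintf(", J = %s Hz",
                                     paste(sprintf("%.1f", sig$J), collapse = ", ")))
    }
    if (is.finite(sig$integral)) {
      inner <- paste0(inner, ", ", .fmt_nH(sig$integral))
    }
    sprintf("%s (%s)", shift, inner)
  }, "")
  sprintf("%s NMR (%.0f MHz, %s) \u03b4 = %s",
          nuc_txt, observe_freq, solvent, paste(parts, collapse = ", "))
}

#' Export NMR signals as CSV rows
#'
#' @param signals List of `nmr_signal` objects.
#' @param path Optional file path.
#' @return Data frame with one row per signal.
#' @export
nmr_signals_csv <- function(signals, path = NULL) {
  df <- data.frame(
    lo = vapply(signals, function(s) s$range[1], numeric(1)),
    hi = vapply(signals, function(s) s$range[2], numeric(1)),
    shift = vapply(signals, .signal_shift, numeric(1)),
    label = vapply(signals, function(s) s$label, ""),
    J = vapply(signals, function(s) paste(sprintf("%.2f", s$J), collapse = ";"), ""),
    integral = vapply(signals, function(s) s$integral, numeric(1)),
    nucleus = vapply(signals, function(s) s$nucleus, ""),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Recover the multiplicity of a single-signal spectrum
#'
#' Convenience wrapper for the standard analysis recipe: pick peaks at a
#' threshold of `threshold_frac` times the maximum effective intensity
#' (high enough to ignore baseline noise, low enough to keep the weak
#' outer lines of a quartet), refine the apex positions by local
#' quadratic interpolation, and run [analyze_multiplet()].
#'
#' @param s An NMR `spectrum` containing one multiplet.
#' @param threshold_frac Picking threshold as a fraction of the maximum
#'   effective intensity.
#' @return See [analyze_multiplet()].
#' @export
recover_multiplet <- function(s, threshold_frac = 0.2) {
  pl <- pick_peaks(s, threshold_frac * max(effective_intensity(s)))
  analyze_multiplet(refine_peaks(pl), observe_freq(s))
}
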