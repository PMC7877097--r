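# Basic FID -> frequency-domain processing.
#
# Pipeline: group-delay handling -> exponential apodization -> zero-fill
# to the next power of two times a factor -> discrete Fourier transform ->
# ppm axis from the spectral width, observe frequency and carrier offset
# -> automatic zero/first-order phase correction (negative-area
# minimization) -> real part -> polynomial baseline correction.

#' Construct an FID record
#'
#' A complex time-domain NMR signal plus the acquisition parameters needed
#' to transform it.
#'
#' @param points Complex vector (length >= 2).
#' @param sw_hz Spectral width in Hz (> 0).
#' @param sf_mhz Observe frequency in MHz (> 0).
#' @param center_ppm Carrier position, i.e. the ppm value of the spectrum
#'   center.
#' @param group_delay Leading digital-filter delay in points (may be
#'   fractional); 0 when absent.
#' @param nucleus `"1H"` or `"13C"`.
#' @param meta Additional acquisition metadata.
#' @return An object of class `fid_record`.
#' @export
fid_record <- function(points, sw_hz, sf_mhz, center_ppm = 5, group_delay = 0,
                       nucleus = "1H", meta = list()) {
  points <- as.complex(points)
  if (length(points) < 2L) {
    spk_stop("invalid_acquisition", "an FID needs at least 2 points")
  }
  if (!is.finite(sw_hz) || sw_hz <= 0 || !is.finite(sf_mhz) || sf_mhz <= 0) {
    spk_stop("invalid_acquisition",
             "spectral width and observe frequency must be positive")
  }
  structure(list(points = points, sw_hz = sw_hz, sf_mhz = sf_mhz,
                 center_ppm = center_ppm, group_delay = group_delay,
                 nucleus = nucleus, meta = meta),
            class = "fid_record")
}

#' @export
print.fid_record <- function(x, ...) {
  cat(sprintf("<fid_record> %d complex points, SW %.1f Hz, SF %.2f MHz, %s\n",
              length(x$points), x$sw_hz, x$sf_mhz, x$nucleus))
  invisible(x)
}

fftshift <- function(v) {
  n <- length(v)
  c(v[(floor(n / 2) + 1L):n], v[1:floor(n / 2)])
}

.default_lb <- c(`1H` = 0.3, `13C` = 1.0)

#' Apply zero- and first-order phase to a complex spectrum
#'
#' @param spec Complex vector.
#' @param ph0 Zero-order phase in degrees.
#' @param ph1 First-order phase in degrees across the full window.
#' @return Phased complex vector.
#' @export
apply_phase <- function(spec, ph0, ph1 = 0) {
  n <- length(spec)
  w <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
  spec * exp(1i * pi / 180 * (ph0 + ph1 * w))
}

.neg_area_obj <- function(spec, w, total, pivot_w) {
  # evaluate only where the spectrum carries amplitude; the near-zero
  # points contribute nothing to the negative-area balance. The first-
  # order term is pivoted on the tallest peak so it cannot stand in for
  # the zero-order phase (the classic single-line degeneracy); a small
  # |ph1| penalty breaks the ties that remain.
  keep <- Mod(spec) >= 1e-3 * max(Mod(spec))
  sre <- Re(spec[keep]); sim <- Im(spec[keep])
  wk <- w[keep] - pivot_w
  function(p0, p1) {
    phi <- pi / 180 * (p0 + p1 * wk)
    re <- sre * cos(phi) - sim * sin(phi)
    sum(pmax(-re, 0)) / total + 0.05 * abs(p1) / 180
  }
}

#' Automatic phase correction by negative-area minimization
#'
#' Searches (ph0, ph1) on a coarse-to-fine grid for the phase pair whose
#' real part has the smallest negative-lobe area (with a small penalty on
#' |ph1| to break the degeneracy of single-line spectra). This is the
#' simplest defensible objective for well-resolved 1D spectra; entropy-
#' based and baseline-aware methods are deliberately out of scope.
#'
#' @param spec Complex frequency-domain vector.
#' @return Numeric `c(ph0, ph1)` in degrees; `c(0, 0)` in the worst case.
#' @export
auto_phase <- function(spec) {
  n <- length(spec)
  w <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
  total <- sum(abs(spec))
  if (!is.finite(total) || total == 0) return(c(ph0 = 0, ph1 = 0))
  pivot_w <- w[which.max(Mod(spec))]
  obj <- .neg_area_obj(spec, w, total, pivot_w)
  best <- c(0, 0); best_val <- obj(0, 0)
  for (p1 in seq(-180, 180, by = 20)) {
    for (p0 in seq(-180, 175, by = 5)) {
      v <- obj(p0, p1)
      if (v < best_val) { best <- c(p0, p1); best_val <- v }
    }
  }
  steps <- list(c(1, 5), c(0.2, 1), c(0.05, 0.2))
  for (st in steps) {
    p0s <- best[1] + seq(-5, 5) * st[1]
    p1s <- best[2] + seq(-5, 5) * st[2]
    for (p1 in p1s) {
      for (p0 in p0s) {
        v <- obj(p0, p1)
        if (v < best_val) { best <- c(p0, p1); best_val <- v }
      }
    }
  }
  # convert from pivot parameterization back to the window convention and
  # wrap ph0 into (-180, 180]
  ph0 <- best[1] - best[2] * pivot_w
  ph0 <- ((ph0 + 180) %% 360) - 180
  c(ph0 = ph0, ph1 = best[2])
}

#' Polynomial baseline correction
#'
#' Fits a low-order polynomial to automatically selected signal-free
#' regions - the lowest-variance quantile of windowed segments - and
#' subtracts it.
#'
#' @param s A real `spectrum`.
#' @param degree Polynomial degree (default 2).
#' @param nseg Number of windows used to find signal-free regions.
#' @return The baseline-corrected `spectrum`.
#' @export
baseline_correct <- function(s, degree = 2L, nseg = 32L) {
  n <- length(s$y)
  if (n < 4L * nseg) nseg <- max(4L, n %/% 16L)
  bounds <- floor(seq(0, n, length.out = nseg + 1L))
  segs <- lapply(seq_len(nseg), function(i) (bounds[i] + 1L):bounds[i + 1L])
  v <- vapply(segs, function(ix) stats::var(s$y[ix]), numeric(1))
  sel <- segs[v <= stats::quantile(v, 0.25, na.rm = TRUE)]
  ix <- unlist(sel)
  if (length(ix) < degree + 2L) return(s)
  xs <- (s$x[ix] - mean(s$x)) / (diff(range(s$x)) / 2)
  X <- stats::poly(xs, degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), s$y[ix])
  xall <- (s$x - mean(s$x)) / (diff(range(s$x)) / 2)
  Xall <- cbind(1, stats::poly(xall, degree, raw = TRUE))
  s$y <- s$y - as.vector(Xall %*% fit$coefficients)
  s
}

#' Process a raw FID into a frequency-domain spectrum
#'
#' See the module header for the pipeline. The ppm axis is
#' `(freq - center) / observe_freq + carrier_offset`; with the default
#' settings the axis spans `center_ppm` plus/minus half the spectral width.
#'
#' @param f An `fid_record`.
#' @param zero_fill Zero-fill factor (>= 1): the FID is padded to the next
#'   power of two times this factor.
#' @param line_broadening Exponential apodization in Hz; defaults to
#'   0.3 Hz for 1H and 1.0 Hz for 13C.
#' @param phase `"auto"` (default) or `"none"`.
#' @param baseline Apply [baseline_correct()] to the result.
#' @return A `spectrum` of kind `NMR_1H` or `NMR_13C` with ascending ppm
#'   axis; the applied phases and processing parameters are recorded in
#'   the metadata.
#' @export
process_fid <- function(f, zero_fill = 2, line_broadening = NULL,
                        phase = c("auto", "none"), baseline = TRUE) {
  stopifnot(inherits(f, "fid_record"))
  phase <- match.arg(phase)
  lb <- line_broadening %||% .default_lb[[f$nucleus]] %||% 0.3
  if (lb < 0) spk_stop("invalid_acquisition", "line broadening must be >= 0")
  pts <- f$points
  n <- length(pts)

  gd <- f$group_delay %||% 0
  ig <- floor(gd)
  frac <- gd - ig
  if (ig > 0 && ig < n) pts <- c(pts[(ig + 1L):n], pts[1:ig])

  t <- (seq_len(n) - 1) / f$sw_hz
  pts <- pts * exp(-pi * lb * t)
  pts[1] <- pts[1] / 2          # half first point: removes the DC offset

  n2 <- 2^ceiling(log2(n)) * max(1L, as.integer(round(zero_fill)))
  spec <- stats::fft(c(pts, complex(real = rep(0, n2 - n))))
  if (frac > 0) {
    spec <- spec * exp(2i * pi * (seq_len(n2) - 1) * frac / n2)
  }
  spec <- fftshift(spec)
  freq <- (seq_len(n2) - 1 - floor(n2 / 2)) * f$sw_hz / n2
  ppm <- freq / f$sf_mhz + f$center_ppm

  ph <- c(ph0 = 0, ph1 = 0)
  if (phase == "auto") {
    ph <- auto_phase(spec)
    spec <- apply_phase(spec, ph[1], ph[2])
  }
  kind <- if (f$nucleus == "13C") "NMR_13C" else "NMR_1H"
  out <- spectrum(ppm, Re(spec), kind,
                  meta = list(observe_freq = f$sf_mhz,
                              x_units = "PPM", y_units = "ARBITRARY UNITS",
                              title = f$meta$title %||% "processed FID",
                              processing = list(zero_fill = zero_fill,
                                                line_broadening = lb,
                                                ph0 = unname(ph[1]),
                                                ph1 = unname(ph[2]),
                                                group_delay = gd)))
  if (isTRUE(baseline)) out <- baseline_correct(out)
  out
}

#' Write a vendor-neutral FID bundle
#'
#' The bundle is a directory (optionally zipped) holding the interleaved
#' real/imaginary points plus a key=value parameter sidecar (`SW_HZ`,
#' `SF_MHZ`, `CENTER_PPM`, `GROUP_DELAY`, `NUCLEUS`).
#'
#' @param f An `fid_record`.
#' @param dir Output directory (created if needed).
#' @param binary Write `fid.bin` (little-endian float64) instead of the
#'   two-column text file `fid.txt`.
#' @return The directory path, invisibly.
#' @export
write_fid_bundle <- function(f, dir, binary = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inter <- as.vector(rbind(Re(f$points), Im(f$points)))
  if (binary) {
    con <- file(file.path(dir, "fid.bin"), "wb")
    writeBin(inter, con, size = 8L, endian = "little")
    close(con)
  } else {
    writeLines(sprintf("%.17g %.17g", Re(f$points), Im(f$points)),
               file.path(dir, "fid.txt"))
  }
  writeLines(c(
    sprintf("SW_HZ=%.10g", f$sw_hz),
    sprintf("SF_MHZ=%.10g", f$sf_mhz),
    sprintf("CENTER_PPM=%.10g", f$center_ppm),
    sprintf("GROUP_DELAY=%.10g", f$group_delay),
    sprintf("NUCLEUS=%s", f$nucleus)
  ), file.path(dir, "params.txt"))
  invisible(dir)
}

#' Read a vendor-neutral FID bundle
#'
#' @param path Bundle directory or a `.zip` containing one.
#' @return An `fid_record`.
#' @export
read_fid_bundle <- function(path) {
  if (grepl("\\.zip$", tolower(path))) {
    exdir <- tempfile("speckit-fid-")
    utils::unzip(path, exdir = exdir)
    hits <- list.files(exdir, pattern = "^params\\.txt$", recursive = TRUE,
                       full.names = TRUE)
    if (!length(hits)) {
      spk_stop("invalid_acquisition", "no params.txt found in FID bundle")
    }
    path <- dirname(hits[1])
  }
  pfile <- file.path(path, "params.txt")
  if (!file.exists(pfile)) {
    spk_stop("invalid_acquisition", sprintf("no params.txt in '%s'", path))
  }
  kv <- utils::read.table(pfile, sep = "=", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  params <- stats::setNames(as.list(kv$V2), kv$V1)
  num <- function(key, default = NA_real_) {
    v <- suppressWarnings(as.numeric(params[[key]]))
    if (length(v) != 1L || is.na(v)) default else v
  }
  bin <- file.path(path, "fid.bin")
  txt <- file.path(path, "fid.txt")
  if (file.exists(bin)) {
    con <- file(bin, "rb")
    inter <- readBin(con, "double", n = file.size(bin) / 8, size = 8L,
                     endian = "little")
    close(con)
  } else if (file.exists(txt)) {
    m <- as.matrix(utils::read.table(txt))
    inter <- as.vector(t(m))
  } else {
    spk_stop("invalid_acquisition", sprintf("no fid.bin or fid.txt in '%s'", path))
  }
  pts <- complex(real = inter[c(TRUE, FALSE)], imaginary = inter[c(FALSE, TRUE)])
  fid_record(pts, sw_hz = num("SW_HZ"), sf_mhz = num("SF_MHZ"),
             center_ppm = num("CENTER_PPM", 5), group_delay = num("GROUP_DELAY", 0),
             nucleus = as.character(params[["NUCLEUS"]] %||% "1H"))
}
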