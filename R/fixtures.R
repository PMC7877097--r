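# Seeded synthetic fixtures with known ground truth: NMR spectra (and
# matching FIDs), IR transmittance traces, and standards-conformant mzML
# text. Noise is additive Gaussian, expressed as a fraction of the
# strongest band amplitude; the seed fully determines the output.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state around seeded generation, so
#' fixture generation never perturbs the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Line positions and weights of a named multiplet
#'
#' Builds the coupling tree: each coupling J with multiplicity m splits
#' every line into m lines J apart with binomial weights; the full pattern
#' is the convolution of its couplings. Coincident lines merge.
#'
#' @param label Multiplicity label (`s`, `d`, `t`, `q`, `quint`, `sext`,
#'   `sept`, `dd`, `dt`, `td`).
#' @param J Coupling constants in Hz, one per coupling of the label.
#' @return Data frame with columns `offset_hz` (centered on 0) and
#'   `weight` (normalized to sum 1).
#' @export
multiplet_lines <- function(label, J = numeric(0)) {
  mults <- .multiplet_mults[[label]]
  if (is.null(mults)) spk_stop("invalid_spec", sprintf("unknown label '%s'", label))
  if (length(J) != length(mults)) {
    spk_stop("invalid_spec", sprintf(
      "label '%s' needs %d coupling constant(s)", label, length(mults)))
  }
  pos <- 0; w <- 1
  for (k in seq_along(mults)) {
    m <- mults[k]
    offs <- (0:(m - 1) - (m - 1) / 2) * J[k]
    bw <- choose(m - 1, 0:(m - 1))
    pos <- as.vector(outer(pos, offs, "+"))
    w <- as.vector(outer(w, bw, "*"))
  }
  key <- round(pos, 6)
  agg <- rowsum(w, key)
  out <- data.frame(offset_hz = as.numeric(rownames(agg)),
                    weight = as.vector(agg))
  out <- out[order(out$offset_hz), ]
  out$weight <- out$weight / sum(out$weight)
  rownames(out) <- NULL
  out
}

.norm_bands <- function(bands) {
  lapply(bands, function(b) {
    list(center = b$center,
         width_hz = b$width_hz %||% 1,
         label = b$label %||% "s",
         J = b$J %||% numeric(0),
         nH = b$nH %||% 1)
  })
}

#' Generate a synthetic NMR spectrum with matching FID and ground truth
#'
#' The frequency-domain trace is a sum of Lorentzians at the coupling-tree
#' line positions with binomial intensities and band areas proportional to
#' nH. The matching FID is the sum of damped complex exponentials whose
#' discrete Fourier transform reproduces the trace (the decay constant is
#' `1 / (pi * FWHM)`).
#'
#' @param bands List of band descriptions: each a list with `center`
#'   (ppm), `width_hz` (Lorentzian FWHM, default 1), `label`
#'   (multiplicity, default `"s"`), `J` (Hz) and `nH` (default 1).
#' @param kind `"NMR_1H"` or `"NMR_13C"`.
#' @param observe_freq Observe frequency in MHz.
#' @param ppm_range Abscissa range `c(lo, hi)`.
#' @param n Number of grid points (>= 16).
#' @param noise Gaussian noise s.d. as a fraction of the maximum clean
#'   amplitude.
#' @param seed Integer seed (fully determines the output).
#' @param solvent Solvent recorded in the metadata.
#' @return List with `spectrum`, `fid` (an `fid_record`), and `truth`
#'   (data frame of every line: band, ppm, hz offset, weight, label, J,
#'   nH, area share).
#' @export
gen_nmr <- function(bands, kind = "NMR_1H", observe_freq = 400,
                    ppm_range = c(0, 10), n = 2^13, noise = 2e-4, seed = 1,
                    solvent = "CDCl3") {
  stopifnot(n >= 16L)
  bands <- .norm_bands(bands)
  sf <- observe_freq
  x <- seq(ppm_range[1], ppm_range[2], length.out = n)
  y <- numeric(n)
  truth <- list()
  sw <- (ppm_range[2] - ppm_range[1]) * sf
  center_ppm <- mean(ppm_range)
  tvec <- (seq_len(n) - 1) / sw
  fid <- complex(real = rep(0, n))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    lines <- multiplet_lines(b$label, b$J)
    gamma_ppm <- b$width_hz / sf
    for (li in seq_len(nrow(lines))) {
      pos <- b$center + lines$offset_hz[li] / sf
      area_ppm <- b$nH * lines$weight[li]      # area in (intensity x ppm)
      amp <- area_ppm * 2 / (pi * gamma_ppm)
      y <- y + amp / (1 + (2 * (x - pos) / gamma_ppm)^2)
      # FID line: a * exp(2*pi*i*f*t) * exp(-t/T2), f relative to carrier
      f_hz <- (pos - center_ppm) * sf
      t2 <- 1 / (pi * b$width_hz)
      a <- amp / (t2 * sw)                     # peak height amp after DFT
      fid <- fid + a * exp((2i * pi * f_hz - 1 / t2) * tvec)
      truth[[length(truth) + 1L]] <- data.frame(
        band = bi, ppm = pos, offset_hz = lines$offset_hz[li],
        weight = lines$weight[li], label = b$label,
        J = paste(sprintf("%.3f", b$J), collapse = ";"),
        nH = b$nH, area = area_ppm)
    }
  }
  ymax <- max(y)
  with_seed(seed, {
    if (noise > 0) {
      y <- y + stats::rnorm(n, sd = noise * ymax)
      fid <- fid + complex(real = stats::rnorm(n, sd = noise * ymax / (2 * sqrt(n))),
                           imaginary = stats::rnorm(n, sd = noise * ymax / (2 * sqrt(n))))
    }
  })
  meta <- list(observe_freq = sf, solvent = solvent,
               x_units = "PPM", y_units = "ARBITRARY UNITS",
               title = sprintf("synthetic %s fixture (seed %d)", kind, seed))
  list(
    spectrum = spectrum(x, y, kind, meta),
    fid = fid_record(fid, sw_hz = sw, sf_mhz = sf, center_ppm = center_ppm,
                     nucleus = if (kind == "NMR_13C") "13C" else "1H",
                     meta = list(title = meta$title)),
    truth = do.call(rbind, truth))
}

#' Generate a synthetic IR transmittance spectrum
#'
#' A 100% baseline minus Gaussian absorption bands, so bands appear as
#' minima, plus seeded Gaussian noise.
#'
#' @param bands List of band descriptions: `center` (1/cm), `depth`
#'   (fraction of full scale in (0, 1\]), `width` (Gaussian sigma, 1/cm,
#'   default 10).
#' @param range Wavenumber range (descending axis is generated).
#' @param n Number of grid points.
#' @param noise Noise s.d. in transmittance percentage points.
#' @param seed Integer seed.
#' @return List with `spectrum` (kind `IR`) and `truth` (band table).
#' @export
gen_ir <- function(bands, range = c(400, 4000), n = 1024, noise = 0.05,
                   seed = 1) {
  x <- seq(max(range), min(range), length.out = n)     # conventional descending axis
  y <- rep(100, n)
  for (b in bands) {
    w <- b$width %||% 10
    y <- y - b$depth * 100 * exp(-(x - b$center)^2 / (2 * w^2))
  }
  with_seed(seed, {
    if (noise > 0) y <- y + stats::rnorm(n, sd = noise)
  })
  truth <- data.frame(
    center = vapply(bands, `[[`, numeric(1), "center"),
    depth = vapply(bands, `[[`, numeric(1), "depth"),
    width = vapply(bands, function(b) b$width %||% 10, numeric(1)))
  meta <- list(x_units = "1/CM", y_units = "TRANSMITTANCE",
               title = sprintf("synthetic IR fixture (seed %d)", seed))
  list(spectrum = spectrum(x, y, "IR", meta), truth = truth)
}

.b64_chunk <- function(raw) gsub("[\r\n ]", "", jsonlite::base64_enc(raw))

.encode_binary_array <- function(values, what, precision = 64L,
                                 compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  raw <- writeBin(as.numeric(values), raw(), size = precision %/% 8L,
                  endian = "little")
  if (compression == "zlib") raw <- memCompress(raw, type = "gzip")
  acc_prec <- if (precision == 64L) .cv$float64 else .cv$float32
  name_prec <- if (precision == 64L) "64-bit float" else "32-bit float"
  acc_comp <- if (compression == "zlib") .cv$zlib else .cv$none
  name_comp <- if (compression == "zlib") "zlib compression" else "no compression"
  acc_what <- if (what == "mz") .cv$mz else .cv$intensity
  name_what <- if (what == "mz") "m/z array" else "intensity array"
  b64 <- .b64_chunk(raw)
  paste0(
    sprintf('      <binaryDataArray encodedLength="%d">\n', nchar(b64)),
    sprintf('        <cvParam cvRef="MS" accession="%s" name="%s"/>\n',
            acc_prec, name_prec),
    sprintf('        <cvParam cvRef="MS" accession="%s" name="%s"/>\n',
            acc_comp, name_comp),
    sprintf('        <cvParam cvRef="MS" accession="%s" name="%s" unitName=""/>\n',
            acc_what, name_what),
    sprintf('        <binary>%s</binary>\n', b64),
    '      </binaryDataArray>')
}

#' Generate a standards-conformant mzML document
#'
#' Writes an mzML file with base64-encoded binary arrays (optionally
#' zlib-compressed, optionally 32-bit) for a list of centroid scans.
#'
#' @param scans List of data frames with columns `mz` (ascending) and
#'   `intensity`, or an integer: that many random scans are generated.
#' @param path Optional output file; the text is always returned.
#' @param compression `"none"` or `"zlib"`.
#' @param precision 64 or 32 (bits per float).
#' @param seed Integer seed used when `scans` is a count.
#' @return List with `text` (the mzML document) and `truth` (the scan
#'   list actually encoded).
#' @export
gen_ms_mzml <- function(scans = 3L, path = NULL,
                        compression = c("none", "zlib"), precision = 64L,
                        seed = 1) {
  compression <- match.arg(compression)
  if (is.numeric(scans) && length(scans) == 1L) {
    n_scans <- as.integer(scans)
    scans <- with_seed(seed, lapply(seq_len(n_scans), function(i) {
      npk <- sample(5:30, 1)
      mz <- sort(stats::runif(npk, 50, 500))
      data.frame(mz = round(mz, 4),
                 intensity = round(stats::runif(npk, 1, 1000), 3))
    }))
  }
  if (precision == 32L) {
    # values must survive the float32 round trip bit-exactly
    scans <- lapply(scans, function(sc) {
      r <- writeBin(as.numeric(sc$mz), raw(), size = 4L, endian = "little")
      sc$mz <- readBin(r, "double", n = nrow(sc), size = 4L, endian = "little")
      r <- writeBin(as.numeric(sc$intensity), raw(), size = 4L, endian = "little")
      sc$intensity <- readBin(r, "double", n = nrow(sc), size = 4L, endian = "little")
      sc
    })
  }
  body <- vapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    paste0(
      sprintf('    <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
              i - 1L, i, nrow(sc)),
      sprintf('      <cvParam cvRef="MS" accession="%s" name="ms level" value="1"/>\n',
              .cv$ms_level),
      sprintf('      <cvParam cvRef="MS" accession="%s" name="centroid spectrum"/>\n',
              .cv$centroid),
      '      <binaryDataArrayList count="2">\n',
      .encode_binary_array(sc$mz, "mz", precision, compression), "\n",
      .encode_binary_array(sc$intensity, "intensity", precision, compression), "\n",
      '      </binaryDataArrayList>\n',
      '    </spectrum>')
  }, "")
  text <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '  </cvList>\n',
    '  <run id="run1">\n',
    sprintf('  <spectrumList count="%d" defaultDataProcessingRef="dp1">\n',
            length(scans)),
    paste(body, collapse = "\n"), "\n",
    '  </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  if (!is.null(path)) writeLines(text, path, sep = "")
  list(text = text, truth = scans)
}

#' Generate the full type-detection fixture corpus
#'
#' A set of JCAMP-DX documents of every kind with known generating kind,
#' used to exercise automatic type detection and round-trip tests.
#'
#' @param per_kind Number of fixtures per kind.
#' @param seed Integer seed.
#' @param n Grid points per NMR/IR fixture.
#' @return List of lists with elements `kind` and `doc`.
#' @export
gen_fixture_corpus <- function(per_kind = 25L, seed = 1, n = 512L) {
  out <- list()
  for (k in seq_len(per_kind)) {
    sk <- as.integer((as.numeric(seed) * 1000 + k) %% 2147483646) + 1L
    nmr1 <- gen_nmr(list(list(center = 2 + (k %% 5), label = "d", J = 8,
                              width_hz = 2)),
                    kind = "NMR_1H", n = n, noise = 0.002, seed = sk)
    nmr2 <- gen_nmr(list(list(center = 60 + (k %% 7) * 10, width_hz = 3)),
                    kind = "NMR_13C", observe_freq = 100.6,
                    ppm_range = c(0, 200), n = n, noise = 0.002, seed = sk)
    ir <- gen_ir(list(list(center = 1000 + 50 * (k %% 10), depth = 0.8),
                      list(center = 2900, depth = 0.4)),
                 n = n, seed = sk)
    ms <- with_seed(sk, {
      npk <- sample(5:20, 1)
      spectrum(sort(stats::runif(npk, 50, 500)), stats::runif(npk, 10, 1000),
               "MS", list(x_units = "M/Z", y_units = "RELATIVE ABUNDANCE",
                          title = sprintf("synthetic MS fixture %d", k)))
    })
    out <- c(out, list(
      list(kind = "NMR_1H", doc = spectrum_to_jcamp(nmr1$spectrum)),
      list(kind = "NMR_13C", doc = spectrum_to_jcamp(nmr2$spectrum)),
      list(kind = "IR", doc = spectrum_to_jcamp(ir$spectrum)),
      list(kind = "MS", doc = spectrum_to_jcamp(ms))))
  }
  out
}

# --- minimal store-mode ZIP writer (deterministic, no compression) -------

.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(raw) {
  crc <- -1L
  b <- as.integer(raw)
  for (i in seq_along(b)) {
    crc <- bitwXor(.crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

.w16 <- function(con, v) writeBin(as.integer(v), con, size = 2L, endian = "little")
.w32 <- function(con, v) {
  v <- as.numeric(v)
  lo <- v %% 65536; hi <- (v - lo) / 65536
  .w16(con, lo); .w16(con, hi)
}

#' Write a store-mode ZIP archive
#'
#' A deterministic, uncompressed (method 0) ZIP writer used to package
#' fixture bundles; readable by any unzip implementation.
#'
#' @param files Character vector of file paths to store.
#' @param zipfile Output archive path.
#' @param names Archive member names (default: basenames of `files`).
#' @return `zipfile`, invisibly.
#' @export
zip_store <- function(files, zipfile, names = basename(files)) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  crcs <- numeric(length(files))
  sizes <- numeric(length(files))
  pos <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", file.size(files[i]))
    nm <- charToRaw(names[i])
    offsets[i] <- pos
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    writeBin(charToRaw("PK\x03\x04"), con)
    .w16(con, 20); .w16(con, 0); .w16(con, 0)      # version, flags, method
    .w16(con, 0); .w16(con, 33)                    # fixed mod time/date
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(nm)); .w16(con, 0)
    writeBin(nm, con)
    writeBin(data, con)
    pos <- pos + 30 + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    nm <- charToRaw(names[i])
    writeBin(charToRaw("PK\x01\x02"), con)
    .w16(con, 20); .w16(con, 20); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 33)
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(nm)); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 0); .w32(con, 0)
    .w32(con, offsets[i])
    writeBin(nm, con)
    pos <- pos + 46 + length(nm)
  }
  writeBin(charToRaw("PK\x05\x06"), con)
  .w16(con, 0); .w16(con, 0)
  .w16(con, length(files)); .w16(con, length(files))
  .w32(con, pos - cd_start); .w32(con, cd_start)
  .w16(con, 0)
  invisible(zipfile)
}

#' Generate the multiplet-recovery study set
#'
#' The seeded fixture set used to measure multiplicity recovery: labels
#' cycle over `labels`, coupling constants are drawn uniformly from
#' `j_range`, lines are 1 Hz wide at 400 MHz, and the noise level is 1%
#' of the tallest line (an amplitude SNR of 100, comfortably above the
#' level where thresholded picking is well posed). For dd fixtures the
#' two couplings are drawn at least two linewidths apart - a dd whose
#' couplings merge is physically indistinguishable from a triplet, so it
#' would not constitute a recoverable ground-truth label.
#'
#' @param n_cases Number of fixtures.
#' @param seed Integer seed (fully determines the set).
#' @param labels Multiplicity labels to cycle through.
#' @param j_range Coupling-constant range in Hz.
#' @param width_hz Lorentzian FWHM in Hz.
#' @param observe_freq Observe frequency in MHz.
#' @param noise Noise s.d. as a fraction of the tallest line.
#' @param n Grid points per fixture.
#' @param ppm_range Spectral window in ppm.
#' @return List of cases, each with `label`, `J`, `seed` and `fixture`
#'   (the [gen_nmr()] output).
#' @export
gen_multiplet_study <- function(n_cases = 500L, seed = 1,
                                labels = c("s", "d", "t", "q", "dd"),
                                j_range = c(2, 18), width_hz = 1,
                                observe_freq = 400, noise = 0.01,
                                n = 4096L, ppm_range = c(4, 6)) {
  with_seed(seed, {
    lapply(seq_len(n_cases), function(r) {
      lab <- labels[(r - 1L) %% length(labels) + 1L]
      nJ <- length(.multiplet_mults[[lab]])
      J <- if (lab == "dd") {
        repeat {
          J <- sort(stats::runif(2, j_range[1], j_range[2]), decreasing = TRUE)
          if (diff(range(J)) >= 2 * width_hz) break
        }
        J
      } else if (nJ == 1L) {
        stats::runif(1, j_range[1], j_range[2])
      } else {
        numeric(0)
      }
      sub <- sample.int(2^30, 1)
      list(label = lab, J = J, seed = sub,
           fixture = gen_nmr(list(list(center = mean(ppm_range),
                                       width_hz = width_hz, label = lab,
                                       J = J, nH = 1)),
                             observe_freq = observe_freq,
                             ppm_range = ppm_range, n = n, noise = noise,
                             seed = sub))
    })
  })
}
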