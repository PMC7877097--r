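# Composing the edited JCAMP-DX document, IR intensity labels, PNG
# rendering, and the output bundle of the embedded workflow: the original
# bytes stay untouched; the composed `<stem>.edit.jdx` carries the peak
# and signal state in private ##$CS... records; two PNG renditions
# (1600x1000 full, 320x240 thumbnail) are regenerated on every edit.

.ir_bins <- c(vs = 0.8, s = 0.6, m = 0.3, w = 0.1)

#' Classify the intensity of an IR band
#'
#' Bands are classified by relative depth d (this band's absorbance-
#' equivalent depth over the deepest band's): vs for d >= 0.8, s for
#' \[0.6, 0.8), m for \[0.3, 0.6), w for \[0.1, 0.3), vw below 0.1.
#'
#' @param peak One row of a `peak_list` (or a list with `x`), for an IR
#'   spectrum.
#' @param s The IR `spectrum`.
#' @return One of `"vw"`, `"w"`, `"m"`, `"s"`, `"vs"`.
#' @export
ir_intensity_label <- function(peak, s) {
  if (s$kind != "IR") spk_stop("not_infrared", "intensity labels are IR-only")
  eff <- effective_intensity(s)
  i <- which.min(abs(s$x - peak$x))
  d <- eff[i] / max(eff)
  if (d >= .ir_bins["vs"]) "vs"
  else if (d >= .ir_bins["s"]) "s"
  else if (d >= .ir_bins["m"]) "m"
  else if (d >= .ir_bins["w"]) "w"
  else "vw"
}

#' IR report: wavenumbers with bracketed intensity labels
#'
#' The reporting-standard style "1700 (vs), 1520 (m)": value first, label
#' in brackets after the corresponding wavenumber, sorted descending.
#'
#' @param pl A `peak_list` over an IR spectrum.
#' @param digits Displayed digits for the wavenumbers.
#' @return A single string.
#' @export
ir_report <- function(pl, digits = 0) {
  s <- attr(pl, "spectrum")
  ap <- active_peaks(pl)
  if (!nrow(ap)) return("")
  o <- order(ap$x, decreasing = TRUE)
  parts <- vapply(o, function(i) {
    sprintf("%s (%s)",
            formatC(round_half_away(ap$x[i], digits), format = "f", digits = digits),
            ir_intensity_label(ap[i, ], s))
  }, "")
  paste(parts, collapse = ", ")
}

.fmt_pair <- function(x, y) sprintf("%.10g,%.10g", x, y)

#' Compose the edited JCAMP-DX document
#'
#' Emits the original records and the full (unmodified) data table plus
#' private records carrying the edit state: `##$CSTHRESHOLD`, `##$CSPEAKS`
#' (active peaks as x,y pairs), `##$CSEDITS` (user additions/removals)
#' and `##$CSSIGNALS` (NMR signals with multiplicity, J and integral).
#' Edits annotate - they never mutate the trace - and re-parsing recovers
#' the peak and signal state losslessly via [cs_peaks()] and
#' [cs_signals()].
#'
#' @param doc The source `jcamp_document`.
#' @param pl The edited `peak_list`.
#' @param signals Optional list of `nmr_signal` objects.
#' @return The composed document text (single string).
#' @export
compose_edited_jcamp <- function(doc, pl, signals = NULL) {
  if (inherits(doc, "spectrum")) doc <- spectrum_to_jcamp(doc)
  s <- attr(pl, "spectrum")
  rng <- range(s$x)
  ap <- active_peaks(pl)
  if (nrow(ap) && (any(ap$x < rng[1]) || any(ap$x > rng[2]))) {
    spk_stop("inconsistent_edit", "peak outside the spectrum's x range")
  }
  extra <- data.frame(label = character(0), value = character(0),
                      stringsAsFactors = FALSE)
  add <- function(label, value) {
    extra[nrow(extra) + 1L, ] <<- c(label, value)
  }
  add("$CSTHRESHOLD", sprintf("%.10g", attr(pl, "threshold")))
  if (nrow(ap)) {
    add("$CSPEAKS", paste(c("(XY..XY)", .fmt_pair(ap$x, ap$y)), collapse = "\n"))
  }
  edits <- character(0)
  user_added <- pl$origin == "user" & pl$status == "active"
  removed <- pl$status == "removed"
  if (any(user_added)) {
    edits <- c(edits, sprintf("ADD,%.10g", pl$x[user_added]))
  }
  if (any(removed)) {
    edits <- c(edits, sprintf("REMOVE,%.10g", pl$x[removed]))
  }
  if (length(edits)) add("$CSEDITS", paste(edits, collapse = "\n"))
  if (length(signals)) {
    lines <- vapply(signals, function(sig) {
      sprintf("%.6g,%.6g,%s,%s,%.6g", sig$range[1], sig$range[2], sig$label,
              paste(sprintf("%.4g", sig$J), collapse = ";"),
              sig$integral)
    }, "")
    add("$CSSIGNALS", paste(lines, collapse = "\n"))
  }
  write_jcamp(doc, extra_records = extra)
}

#' Recover the active peak set from a composed document
#'
#' @param doc A parsed composed document (see [compose_edited_jcamp()]).
#' @return Data frame with columns `x`, `y` (empty if none recorded).
#' @export
cs_peaks <- function(doc) {
  v <- jc_value(doc, "$CSPEAKS")
  if (is.null(v)) return(data.frame(x = numeric(0), y = numeric(0)))
  lines <- strsplit(v, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("XY\\.\\.XY", lines)]
  parts <- do.call(rbind, strsplit(lines, ",", fixed = TRUE))
  data.frame(x = as.numeric(parts[, 1]), y = as.numeric(parts[, 2]))
}

#' Recover the NMR signal list from a composed document
#'
#' @param doc A parsed composed document.
#' @return List of `nmr_signal` objects (empty if none recorded).
#' @export
cs_signals <- function(doc) {
  v <- jc_value(doc, "$CSSIGNALS")
  if (is.null(v)) return(list())
  lines <- strsplit(v, "\n", fixed = TRUE)[[1]]
  lapply(lines, function(ln) {
    p <- strsplit(ln, ",", fixed = TRUE)[[1]]
    J <- if (nzchar(p[4])) as.numeric(strsplit(p[4], ";", fixed = TRUE)[[1]])
         else numeric(0)
    nmr_signal(range = c(as.numeric(p[1]), as.numeric(p[2])),
               peaks = data.frame(x = numeric(0), y = numeric(0)),
               label = p[3], J = J, integral = as.numeric(p[5]))
  })
}

.canvas <- list(full = c(1600L, 1000L), thumbnail = c(320L, 240L))

#' Render a spectrum to PNG bytes
#'
#' Line plot for NMR and IR data, bar (stick) plot for MS data. The NMR
#' (and IR) abscissa is drawn descending left to right; active peaks are
#' annotated. The canvas is fixed - 1600x1000 for `"full"`, 320x240 for
#' `"thumbnail"` - and the output bytes are deterministic for fixed
#' inputs.
#'
#' @param s A `spectrum`.
#' @param pl Optional `peak_list` whose active peaks are annotated.
#' @param size `"full"` or `"thumbnail"`.
#' @param path Optional output file.
#' @return Raw PNG bytes, invisibly when `path` is given.
#' @export
render_png <- function(s, pl = NULL, size = c("full", "thumbnail"),
                       path = NULL) {
  size <- match.arg(size)
  dims <- .canvas[[size]]
  file <- path %||% tempfile(fileext = ".png")
  grDevices::png(file, width = dims[1], height = dims[2], type = "cairo",
                 pointsize = if (size == "thumbnail") 8 else 14)
  on.exit(grDevices::dev.off(), add = TRUE)
  thumb <- size == "thumbnail"
  graphics::par(mar = if (thumb) c(2, 2, 1, 0.5) else c(4.5, 4.5, 3, 1))
  xlim <- range(s$x)
  if (s$kind %in% c("NMR_1H", "NMR_13C", "IR")) xlim <- rev(range(s$x))
  xlab <- switch(s$kind, IR = "wavenumber [1/cm]", MS = "m/z",
                 "chemical shift [ppm]")
  main <- if (thumb) "" else s$meta$title %||% ""
  if (kind_layout(s$kind) == "bar") {
    graphics::plot(NA, xlim = xlim, ylim = c(0, max(s$y) * 1.08),
                   xlab = if (thumb) "" else xlab,
                   ylab = if (thumb) "" else "intensity",
                   main = main, yaxs = "i")
    graphics::segments(s$x, 0, s$x, s$y, lwd = if (thumb) 1 else 2,
                       col = "grey25")
  } else {
    graphics::plot(s$x, s$y, type = "l", xlim = xlim,
                   xlab = if (thumb) "" else xlab,
                   ylab = if (thumb) "" else "intensity",
                   main = main, col = "grey15")
  }
  if (!is.null(pl)) {
    ap <- active_peaks(pl)
    if (nrow(ap)) {
      graphics::points(ap$x, ap$y, pch = 6, col = "red3",
                       cex = if (thumb) 0.5 else 0.9)
      if (!thumb) {
        digits <- switch(s$kind, NMR_1H = 2L, NMR_13C = 1L, 1L)
        graphics::text(ap$x, ap$y, labels = formatC(ap$x, format = "f",
                                                    digits = digits),
                       pos = 3, cex = 0.7, col = "red3", xpd = NA)
      }
    }
  }
  grDevices::dev.off()
  on.exit()
  bytes <- readBin(file, "raw", file.size(file))
  if (is.null(path)) unlink(file)
  if (is.null(path)) bytes else invisible(bytes)
}

#' Build the output bundle of the embedded workflow
#'
#' Assembles the artifact set stored alongside an upload: the untouched
#' original bytes, the composed `<stem>.edit.jdx`, and the two PNG
#' renditions `<stem>.edit.png` (1600x1000) and `<stem>.thumb.png`
#' (320x240). Rebuilding with identical inputs is byte-idempotent; both
#' images are regenerated from the current peak state on every call.
#'
#' @param input Path to the original file, or raw bytes.
#' @param name Original filename (required when `input` is raw).
#' @param doc The parsed `jcamp_document` for the spectrum.
#' @param pl The current `peak_list`.
#' @param signals Optional list of `nmr_signal` objects.
#' @return An object of class `artifact_bundle`.
#' @export
build_bundle <- function(input, name = NULL, doc = NULL, pl = NULL,
                         signals = NULL) {
  if (is.raw(input)) {
    if (is.null(name)) spk_stop("invalid_spec", "raw input needs a name")
    original <- input
  } else {
    name <- name %||% basename(input)
    original <- readBin(input, "raw", file.size(input))
  }
  if (is.null(doc)) {
    if (is.raw(input)) {
      doc <- parse_jcamp(rawToChar(original))
    } else {
      doc <- read_jcamp(input)
    }
  }
  s <- if (!is.null(pl)) attr(pl, "spectrum") else jcamp_to_spectrum(doc)
  pl <- pl %||% pick_peaks(s)
  edited <- compose_edited_jcamp(doc, pl, signals)
  stem <- tools::file_path_sans_ext(name)
  structure(list(
    original = original, original_name = name, stem = stem,
    edited = edited,
    edited_name = paste0(stem, ".edit.jdx"),
    png_full = render_png(s, pl, "full"),
    png_full_name = paste0(stem, ".edit.png"),
    png_thumb = render_png(s, pl, "thumbnail"),
    png_thumb_name = paste0(stem, ".thumb.png")),
    class = "artifact_bundle")
}

#' @export
print.artifact_bundle <- function(x, ...) {
  cat(sprintf("<artifact_bundle> %s\n", x$original_name))
  cat(sprintf("  %s (%d bytes)\n", x$edited_name, nchar(x$edited)))
  cat(sprintf("  %s (%d bytes)\n", x$png_full_name, length(x$png_full)))
  cat(sprintf("  %s (%d bytes)\n", x$png_thumb_name, length(x$png_thumb)))
  invisible(x)
}

#' Write an artifact bundle to a directory
#'
#' @param bundle An `artifact_bundle`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(bundle$original_name, bundle$edited_name,
                            bundle$png_full_name, bundle$png_thumb_name))
  writeBin(bundle$original, paths[1])
  writeLines(bundle$edited, paths[2], sep = "")
  writeBin(bundle$png_full, paths[3])
  writeBin(bundle$png_thumb, paths[4])
  invisible(paths)
}
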