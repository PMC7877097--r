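# mzML reading: binary-data-array decoding (base64, optional zlib,
# 32/64-bit little-endian floats), the scan list, scan selection, and
# conversion of a scan to a JCAMP-DX peak-table document.

.cv <- list(
  float64 = "MS:1000523", float32 = "MS:1000521",
  zlib = "MS:1000574", none = "MS:1000576",
  mz = "MS:1000514", intensity = "MS:1000515",
  ms_level = "MS:1000511", centroid = "MS:1000127", profile = "MS:1000128")

.decode_binary_array <- function(node, idx) {
  params <- xml2::xml_find_all(node, ".//*[local-name()='cvParam']")
  acc <- xml2::xml_attr(params, "accession")
  name <- tolower(xml2::xml_attr(params, "name"))
  has <- function(code, label) any(acc == code, na.rm = TRUE) ||
    any(grepl(label, name), na.rm = TRUE)
  size <- if (has(.cv$float64, "64-bit")) 8L else if (has(.cv$float32, "32-bit")) 4L else 8L
  zlib <- has(.cv$zlib, "zlib")
  none <- has(.cv$none, "no compression")
  known_comp <- c(.cv$zlib, .cv$none)
  comp_acc <- acc[grepl("compression", name)]
  if (!zlib && !none && length(comp_acc) && !any(comp_acc %in% known_comp)) {
    spk_stop("unsupported_encoding", sprintf(
      "unsupported binary-array compression (%s) in spectrum %d",
      paste(comp_acc, collapse = ","), idx))
  }
  what <- if (has(.cv$mz, "m/z array")) "mz"
          else if (has(.cv$intensity, "intensity array")) "intensity"
          else NA_character_
  b64 <- xml2::xml_text(xml2::xml_find_first(node, ".//*[local-name()='binary']"))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  vals <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                  endian = "little")
  list(what = what, values = vals, precision = size * 8L)
}

#' Parse an mzML file
#'
#' Every `spectrum` element becomes one scan, in file order, with paired
#' m/z and intensity arrays of equal length. Decoding is bit-exact for
#' uncompressed 64-bit arrays; 32-bit arrays are widened on read with the
#' original precision recorded per scan. Zlib-compressed arrays are
#' inflated; other compression schemes (e.g. numpress) raise
#' `speckit_unsupported_encoding`.
#'
#' @param input File path or a single string of mzML text.
#' @return An object of class `ms_scan_set`: a list with `scans` (list of
#'   `spectrum` objects of kind `MS`) and `selected` (index of the scan
#'   shown by default, always the first).
#' @export
parse_mzml <- function(input) {
  xml <- tryCatch({
    if (length(input) == 1L && !grepl("<", input, fixed = TRUE) &&
        file.exists(input)) {
      xml2::read_xml(input)
    } else {
      xml2::read_xml(paste(input, collapse = "\n"))
    }
  }, error = function(e) spk_stop("malformed_xml", conditionMessage(e)))
  if (grepl("\\.(mzxml|cdf)$", tolower(if (length(input) == 1L &&
                                           !grepl("<", input, fixed = TRUE))
                                         input else ""))) {
    spk_stop("unsupported_format", "mzXML and CDF inputs are not supported")
  }
  root_name <- xml2::xml_name(xml)
  if (identical(root_name, "mzXML")) {
    spk_stop("unsupported_format", "mzXML input is not supported; supply mzML")
  }
  nodes <- xml2::xml_find_all(xml, "//*[local-name()='spectrum']")
  if (!length(nodes)) {
    spk_stop("malformed_xml", "no spectrum elements found")
  }
  scans <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    params <- xml2::xml_find_all(
      nd, "./*[local-name()='cvParam'] | ./*[local-name()='scanList']//*[local-name()='cvParam']")
    acc <- xml2::xml_attr(params, "accession")
    lvl <- xml2::xml_attr(params, "value")[acc == .cv$ms_level]
    ms_level <- if (length(lvl)) suppressWarnings(as.integer(lvl[1])) else NA_integer_
    mode <- if (any(acc == .cv$profile, na.rm = TRUE)) "profile" else "centroid"
    arrays <- xml2::xml_find_all(nd, ".//*[local-name()='binaryDataArray']")
    mz <- NULL; inten <- NULL; precision <- 64L
    for (k in seq_along(arrays)) {
      dec <- .decode_binary_array(arrays[[k]], i)
      if (identical(dec$what, "mz")) mz <- dec$values
      if (identical(dec$what, "intensity")) {
        inten <- dec$values
        precision <- dec$precision
      }
    }
    if (is.null(mz) || is.null(inten) || length(mz) != length(inten)) {
      spk_stop("malformed_xml", sprintf(
        "spectrum %d lacks paired m/z and intensity arrays", i))
    }
    if (length(mz) > 1L && any(diff(mz) < 0)) {
      o <- order(mz); mz <- mz[o]; inten <- inten[o]
    }
    meta <- list(scan_id = xml2::xml_attr(nd, "id"),
                 ms_level = ms_level, mode = mode,
                 precision = precision, x_units = "M/Z",
                 y_units = "RELATIVE ABUNDANCE")
    scans[[i]] <- if (length(mz)) {
      spectrum(mz, inten, "MS", meta)
    } else {
      structure(list(x = numeric(0), y = numeric(0), kind = "MS", meta = meta),
                class = "spectrum")
    }
  }
  structure(list(scans = scans, selected = 1L), class = "ms_scan_set")
}

#' @export
print.ms_scan_set <- function(x, ...) {
  cat(sprintf("<ms_scan_set> %d scan(s), default selection: scan %d\n",
              length(x$scans), x$selected))
  for (i in seq_along(x$scans)) {
    s <- x$scans[[i]]
    cat(sprintf("  [%d] %s: %d peaks, MS level %s (%s)\n", i,
                s$meta$scan_id %||% "?", length(s$x),
                s$meta$ms_level %||% "?", s$meta$mode %||% "?"))
  }
  invisible(x)
}

#' Select a scan from an mzML scan set
#'
#' @param set An `ms_scan_set`.
#' @param index 1-based scan index; when omitted the first scan is
#'   returned, matching the editor's default.
#' @return A `spectrum` of kind `MS`.
#' @export
select_scan <- function(set, index = NULL) {
  stopifnot(inherits(set, "ms_scan_set"))
  n <- length(set$scans)
  index <- index %||% set$selected
  if (!is.numeric(index) || length(index) != 1L || index < 1L || index > n) {
    spk_stop("index_out_of_range", sprintf(
      "scan index must be in [1, %d]", n))
  }
  set$scans[[as.integer(index)]]
}

#' Convert an MS scan to a JCAMP-DX peak-table document
#'
#' @param scan A `spectrum` of kind `MS`.
#' @return A `jcamp_document` with data type "MASS SPECTRUM" and a
#'   `(XY..XY)` peak table whose NPOINTS equals the peak count. Written
#'   and re-parsed, m/z values survive bit-exactly.
#' @export
scan_to_jcamp <- function(scan) {
  stopifnot(inherits(scan, "spectrum"))
  if (scan$kind != "MS") spk_stop("invalid_spec", "scan must have kind MS")
  if (!length(scan$x)) spk_stop("empty_scan", "scan contains no peaks")
  title <- scan$meta$title %||%
    sprintf("MS scan %s", scan$meta$scan_id %||% "1")
  doc <- spectrum_to_jcamp(scan, title = title)
  doc
}
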