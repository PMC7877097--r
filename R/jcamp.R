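# JCAMP-DX document model, parser and writer.
#
# A document is an ordered list of labeled-data-records (LDRs, lines
# starting "##LABEL="). Labels are matched after normalization (case,
# spaces, dashes, slashes and underscores ignored; "." and "$" prefixes
# kept, so technique records like ##.OBSERVE FREQUENCY and private records
# like ##$CSPEAKS survive). Data tables are decoded through the ASDF codec.

.data_labels <- c("XYDATA", "XYPOINTS", "PEAKTABLE", "PEAKASSIGNMENTS",
                  "DATATABLE")
.regen_labels <- c("XFACTOR", "YFACTOR", "FIRSTX", "LASTX", "NPOINTS",
                   "FIRSTY", "DELTAX", "MAXX", "MINX", "MAXY", "MINY",
                   "XUNITS", "YUNITS",
                   .data_labels, "NTUPLES", "ENDNTUPLES", "PAGE", "END")
.head_labels <- c("TITLE", "JCAMPDX", "DATATYPE", "DATACLASS", "ORIGIN", "OWNER")

norm_label <- function(label) gsub("[ \t/_-]", "", toupper(label))

jc_records <- function(doc) doc$records

#' Look up a record value in a JCAMP-DX document
#'
#' @param doc A `jcamp_document`.
#' @param label Record label; matching is case-insensitive and ignores
#'   spaces, dashes, slashes and underscores.
#' @return The record value (character) or `NULL` if absent.
#' @export
jc_value <- function(doc, label) {
  i <- which(doc$records$norm == norm_label(label))
  if (!length(i)) return(NULL)
  doc$records$value[i[1]]
}

jc_num <- function(doc, label, default = NA_real_) {
  v <- jc_value(doc, label)
  if (is.null(v)) return(default)
  n <- suppressWarnings(as.numeric(sub("^\\s*\\(?([-+0-9.eE]+).*$", "\\1", v)))
  if (is.na(n)) default else n
}

new_jcamp_document <- function(records, data = list(), ntuples = NULL,
                               blocks = list()) {
  structure(list(records = records, data = data, ntuples = ntuples,
                 blocks = blocks),
            class = "jcamp_document")
}

#' @export
print.jcamp_document <- function(x, ...) {
  cat(sprintf("<jcamp_document> '%s' (%s)\n",
              jc_value(x, "TITLE") %||% "?", jc_value(x, "DATATYPE") %||% "?"))
  cat(sprintf("  %d records, %d data table(s), %d nested block(s)\n",
              nrow(x$records), length(x$data), length(x$blocks)))
  invisible(x)
}

.split_ldrs <- function(lines) {
  ldrs <- list()
  cur <- NULL
  push <- function(x) ldrs[[length(ldrs) + 1L]] <<- x
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##")) {
      if (!is.null(cur)) push(cur)
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0L) {
        label <- substr(ln, 3L, nchar(ln)); val <- ""
      } else {
        label <- substr(ln, 3L, eq - 1L)
        val <- substr(ln, eq + 1L, nchar(ln))
      }
      cur <- list(label = trimws(label), norm = norm_label(label),
                  value = trimws(val), lines = character(0), line = i)
    } else if (startsWith(trimws(ln), "$$") &&
               (is.null(cur) || !(cur$norm %in% .data_labels))) {
      # full-line comments outside data tables are records of their own;
      # inside a data table they stay with the table (the tokenizer
      # ignores them)
      if (!is.null(cur)) push(cur)
      push(list(label = "$$", norm = "$$", value = trimws(ln),
                lines = character(0), line = i))
      cur <- NULL
    } else if (!is.null(cur)) {
      cur$lines <- c(cur$lines, ln)
    }
  }
  if (!is.null(cur)) push(cur)
  ldrs
}

.record_row <- function(l) {
  value <- paste(c(l$value, l$lines), collapse = "\n")
  data.frame(label = l$label, norm = l$norm, value = sub("\\s+$", "", value),
             stringsAsFactors = FALSE)
}

.num_from <- function(records, label, default = NA_real_) {
  i <- which(records$norm == norm_label(label))
  if (!length(i)) return(default)
  n <- suppressWarnings(as.numeric(records$value[i[1]]))
  if (is.na(n)) default else n
}

.parse_pairs <- function(lines) {
  txt <- paste(vapply(lines, function(l) sub("\\$\\$.*$", "", l), ""),
               collapse = " ")
  m <- gregexpr("[-+]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][-+]?[0-9]+)?", txt)[[1]]
  nums <- as.numeric(regmatches(txt, list(m))[[1]])
  if (length(nums) %% 2L == 1L) nums <- nums[-length(nums)]
  list(x = nums[c(TRUE, FALSE)], y = nums[c(FALSE, TRUE)])
}

.decode_grid_table <- function(l, records, strict) {
  firstx <- .num_from(records, "FIRSTX")
  lastx <- .num_from(records, "LASTX")
  np <- .num_from(records, "NPOINTS")
  xf <- .num_from(records, "XFACTOR", 1)
  yf <- .num_from(records, "YFACTOR", 1)
  deltax <- if (is.finite(np) && np > 1) (lastx - firstx) / (np - 1) else NA
  y <- decode_asdf(l$lines, npoints = np, yfactor = yf, xfactor = xf,
                   firstx = firstx, deltax = deltax, strict = strict)
  n <- length(y)
  x <- if (is.finite(firstx) && is.finite(deltax) && n > 0) {
    firstx + (seq_len(n) - 1) * deltax
  } else {
    seq_len(n)
  }
  list(form = "XYDATA", variable_list = l$value, x = x, y = y,
       firstx = firstx, lastx = lastx, npoints = np,
       xfactor = xf, yfactor = yf)
}

.parse_ntuples <- function(ldrs, i, strict) {
  nt <- list(header = list(), pages = list())
  nt_records <- data.frame(label = character(0), norm = character(0),
                           value = character(0), stringsAsFactors = FALSE)
  page_attr <- NULL
  n <- length(ldrs)
  while (i <= n) {
    l <- ldrs[[i]]
    if (l$norm == "ENDNTUPLES") { i <- i + 1L; break }
    if (l$norm == "PAGE") {
      page_attr <- l$value
      i <- i + 1L
      next
    }
    if (l$norm == "DATATABLE") {
      sy <- regmatches(l$value, regexpr("\\(X\\+\\+\\(([A-Za-z])\\.\\.[A-Za-z]\\)\\)", l$value))
      sym <- if (length(sy)) sub("^.*\\((.)\\.\\..*$", "\\1", sy) else "Y"
      symbols <- strsplit(nt$header$SYMBOL %||% "", ",")[[1]]
      symbols <- trimws(symbols)
      getv <- function(key, j, default = NA_real_) {
        v <- strsplit(nt$header[[key]] %||% "", ",")[[1]]
        if (length(v) < j) return(default)
        num <- suppressWarnings(as.numeric(trimws(v[j])))
        if (is.na(num)) default else num
      }
      jx <- match("X", symbols, nomatch = 1L)
      jy <- match(sym, symbols, nomatch = 2L)
      firstx <- getv("FIRST", jx); lastx <- getv("LAST", jx)
      np <- getv("VARDIM", jy, getv("VARDIM", jx))
      xf <- getv("FACTOR", jx, 1); yf <- getv("FACTOR", jy, 1)
      deltax <- if (is.finite(np) && np > 1) (lastx - firstx) / (np - 1) else NA
      y <- decode_asdf(l$lines, npoints = np, yfactor = yf, xfactor = xf,
                       firstx = firstx, deltax = deltax, strict = strict)
      x <- if (is.finite(firstx) && is.finite(deltax)) {
        firstx + (seq_along(y) - 1) * deltax
      } else {
        seq_along(y)
      }
      nt$pages[[length(nt$pages) + 1L]] <- list(
        page = page_attr, symbol = sym, variable_list = l$value,
        x = x, y = y, firstx = firstx, lastx = lastx, npoints = np,
        xfactor = xf, yfactor = yf)
      i <- i + 1L
      next
    }
    nt$header[[l$norm]] <- paste(c(l$value, l$lines), collapse = " ")
    nt_records <- rbind(nt_records, .record_row(l))
    i <- i + 1L
  }
  list(ntuples = nt, next_pos = i, records = nt_records)
}

.build_block <- function(ldrs, pos, strict) {
  stopifnot(ldrs[[pos]]$norm == "TITLE")
  records <- .record_row(ldrs[[pos]])
  data <- list()
  ntuples <- NULL
  blocks <- list()
  i <- pos + 1L
  n <- length(ldrs)
  while (i <= n) {
    l <- ldrs[[i]]
    if (l$norm == "TITLE") {
      child <- .build_block(ldrs, i, strict)
      blocks[[length(blocks) + 1L]] <- child$doc
      i <- child$next_pos
      next
    }
    if (l$norm == "END") { i <- i + 1L; break }
    if (l$norm == "NTUPLES") {
      records <- rbind(records, .record_row(list(label = l$label, norm = l$norm,
                                                 value = l$value, lines = character(0))))
      res <- .parse_ntuples(ldrs, i + 1L, strict)
      ntuples <- res$ntuples
      ntuples$name <- l$value
      i <- res$next_pos
      next
    }
    if (l$norm %in% .data_labels) {
      records <- rbind(records, .record_row(list(label = l$label, norm = l$norm,
                                                 value = l$value, lines = character(0))))
      if (grepl("X\\+\\+", l$value)) {
        data[[length(data) + 1L]] <- .decode_grid_table(l, records, strict)
      } else {
        p <- .parse_pairs(l$lines)
        data[[length(data) + 1L]] <- list(
          form = if (l$norm == "XYPOINTS") "XYPOINTS" else "PEAKTABLE",
          variable_list = l$value, x = p$x, y = p$y,
          npoints = .num_from(records, "NPOINTS"))
      }
      i <- i + 1L
      next
    }
    records <- rbind(records, .record_row(l))
    i <- i + 1L
  }
  # expose the real page of an NTUPLES record set as the primary table
  if (!is.null(ntuples) && length(ntuples$pages)) {
    prim <- which(vapply(ntuples$pages, function(p) identical(p$symbol, "R"),
                         logical(1)))
    prim <- if (length(prim)) prim[1] else 1L
    p <- ntuples$pages[[prim]]
    data <- c(data, list(c(p[setdiff(names(p), "page")], list(form = "NTUPLES"))))
  }
  doc <- new_jcamp_document(records, data, ntuples, blocks)
  list(doc = doc, next_pos = i)
}

#' Parse a JCAMP-DX document
#'
#' Accepts single-block, compound (nested block) and NTUPLES documents;
#' XYDATA `(X++(Y..Y))` tables in any ASDF ordinate form, XYPOINTS and
#' PEAK TABLE `(XY..XY)` tables are decoded. All records are preserved in
#' order (private `##$` records verbatim); CRLF and LF line endings are
#' accepted. In the default lenient mode x-sequence/DIF check failures are
#' reported as warnings with line numbers and parsing continues; with
#' `strict = TRUE` they raise errors.
#'
#' @param text A single string or a character vector of lines.
#' @param strict Promote data-check warnings to errors.
#' @return A `jcamp_document`; decoded tables are in `$data` (each with
#'   `x`, `y`, grid parameters), nested blocks in `$blocks`, NTUPLES pages
#'   (e.g. the imaginary NMR page) in `$ntuples$pages`.
#' @export
parse_jcamp <- function(text, strict = FALSE) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\r\n|\n|\r")[[1]]
  } else {
    sub("\r$", "", text)
  }
  ldrs <- .split_ldrs(lines)
  if (!length(ldrs) || ldrs[[1]]$norm != "TITLE") {
    # tolerate leading comments before TITLE
    first_title <- which(vapply(ldrs, function(l) l$norm == "TITLE", logical(1)))
    if (!length(first_title)) {
      spk_stop("malformed_document", "no ##TITLE= record found")
    }
    ldrs <- ldrs[first_title[1]:length(ldrs)]
  }
  if (!any(vapply(ldrs, function(l) l$norm == "END", logical(1)))) {
    spk_stop("malformed_document", "no ##END= record found")
  }
  .build_block(ldrs, 1L, strict)$doc
}

#' Read a JCAMP-DX file
#'
#' Accepts `.jdx`, `.dx` and `.jcamp` files; a `.zip` container holding a
#' single JCAMP file is unpacked transparently.
#'
#' @param path File path.
#' @param strict See [parse_jcamp()].
#' @return A `jcamp_document`.
#' @export
read_jcamp <- function(path, strict = FALSE) {
  if (grepl("\\.zip$", tolower(path))) {
    exdir <- tempfile("speckit-zip-")
    utils::unzip(path, exdir = exdir)
    files <- list.files(exdir, pattern = "\\.(jdx|dx|jcamp)$", ignore.case = TRUE,
                        recursive = TRUE, full.names = TRUE)
    if (length(files) != 1L) {
      spk_stop("malformed_document", sprintf(
        "expected one JCAMP file in '%s', found %d", path, length(files)))
    }
    path <- files[1]
  }
  parse_jcamp(readLines(path, warn = FALSE), strict = strict)
}

.fmt_num <- function(v) sprintf("%.12g", v)

.choose_yfactor <- function(y) {
  if (!length(y) || all(y == 0)) return(1)
  if (all(abs(y - round(y)) < 1e-9 * pmax(1, abs(y)))) return(1)
  max(abs(y)) / 2^23
}

#' Write a JCAMP-DX document
#'
#' Re-emits a parsed (or constructed) document with records in canonical
#' order (TITLE, version, data type, origin/owner, remaining records in
#' original order, grid records, data table, END) and the data table in
#' the requested ordinate form. Grid records are regenerated from the
#' decoded table; the stored ordinates are `round(y / YFACTOR)`, so a
#' re-parse reproduces y within `YFACTOR / 2` (exactly for integer
#' ordinates with `YFACTOR` 1). Lines are limited to 78 characters.
#'
#' @param doc A `jcamp_document`, or a `spectrum` (converted via
#'   [spectrum_to_jcamp()]).
#' @param form `"auto"` (AFFN for tables of <= 64 points, DIFDUP
#'   otherwise), `"AFFN"`, `"SQZ"`, `"DIF"` or `"DIFDUP"`.
#' @param path Optional output file; the text is returned invisibly then.
#' @param extra_records Optional data frame with columns `label`, `value`
#'   inserted before the data table (used for the composed edit records).
#' @return The document text as a single string.
#' @export
write_jcamp <- function(doc, form = c("auto", "AFFN", "SQZ", "DIF", "DIFDUP"),
                        path = NULL, extra_records = NULL) {
  form <- match.arg(form)
  if (inherits(doc, "spectrum")) doc <- spectrum_to_jcamp(doc)
  if (!inherits(doc, "jcamp_document")) {
    spk_stop("unwritable_document", "not a jcamp_document")
  }
  if (!length(doc$data)) {
    spk_stop("unwritable_document", "document has no decoded data table")
  }
  tab <- doc$data[[1]]
  rec <- doc$records

  out <- character(0)
  emit <- function(label, value) {
    txt <- paste0("##", label, "=", value)
    out <<- c(out, strsplit(txt, "\n", fixed = TRUE)[[1]])
  }

  used <- logical(nrow(rec))
  head_emit <- function(norm, default = NULL) {
    i <- which(rec$norm == norm & !used)
    if (length(i)) {
      used[i[1]] <<- TRUE
      emit(rec$label[i[1]], rec$value[i[1]])
    } else if (!is.null(default)) {
      emit(default[[1]], default[[2]])
    }
  }
  head_emit("TITLE", list("TITLE", "speckit export"))
  head_emit("JCAMPDX", list("JCAMP-DX", "5.01"))
  head_emit("DATATYPE")
  head_emit("DATACLASS")
  head_emit("ORIGIN")
  head_emit("OWNER")
  skip <- rec$norm %in% c(.regen_labels, "$$") |
    (rec$norm %in% .head_labels & !used) | used
  for (i in which(!skip)) emit(rec$label[i], rec$value[i])
  # comments are re-emitted verbatim before the data block
  for (i in which(rec$norm == "$$")) out <- c(out, rec$value[i])

  if (!is.null(extra_records)) {
    for (i in seq_len(nrow(extra_records))) {
      emit(extra_records$label[i], extra_records$value[i])
    }
  }

  n <- length(tab$y)
  if (identical(tab$form, "PEAKTABLE") || identical(tab$form, "XYPOINTS")) {
    emit("XUNITS", jc_value(doc, "XUNITS") %||% "M/Z")
    emit("YUNITS", jc_value(doc, "YUNITS") %||% "RELATIVE ABUNDANCE")
    emit("NPOINTS", sprintf("%d", n))
    label <- if (identical(tab$form, "XYPOINTS")) "XYPOINTS" else "PEAK TABLE"
    pair_lines <- sprintf("%.17g,%.10g", tab$x, tab$y)
    emit(label, paste(c("(XY..XY)", pair_lines), collapse = "\n"))
  } else {
    if (n < 2L) spk_stop("unwritable_document", "grid table needs >= 2 points")
    dx <- diff(tab$x)
    if (max(abs(dx - dx[1])) > 1e-6 * max(abs(dx))) {
      spk_stop("unwritable_document",
               "grid table abscissa is not uniformly spaced")
    }
    yfactor <- .choose_yfactor(tab$y)
    ystored <- round(tab$y / yfactor)
    use_form <- if (form == "auto") (if (n <= 64L) "AFFN" else "DIFDUP") else form
    emit("XUNITS", jc_value(doc, "XUNITS") %||% "ARBITRARY UNITS")
    emit("YUNITS", jc_value(doc, "YUNITS") %||% "ARBITRARY UNITS")
    emit("XFACTOR", "1")
    emit("YFACTOR", .fmt_num(yfactor))
    emit("FIRSTX", .fmt_num(tab$x[1]))
    emit("LASTX", .fmt_num(tab$x[n]))
    emit("NPOINTS", sprintf("%d", n))
    emit("FIRSTY", .fmt_num(ystored[1] * yfactor))
    data_lines <- encode_asdf(tab$y, tab$x, form = use_form,
                              yfactor = yfactor, xfactor = 1)
    emit("XYDATA", paste(c("(X++(Y..Y))", data_lines), collapse = "\n"))
  }
  emit("END", "")

  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Convert a decoded JCAMP-DX document to a spectrum
#'
#' Detects the spectrum kind and extracts acquisition metadata (observe
#' frequency, solvent, units, title). For compound documents the first
#' nested block carrying data is used.
#'
#' @param doc A `jcamp_document`.
#' @return A `spectrum`.
#' @export
jcamp_to_spectrum <- function(doc) {
  blk <- doc
  if (!length(blk$data)) {
    for (b in doc$blocks) {
      if (length(b$data)) { blk <- b; break }
    }
  }
  if (!length(blk$data)) {
    spk_stop("malformed_document", "document contains no data table")
  }
  kind <- detect_type(blk)
  tab <- blk$data[[1]]
  meta <- list(
    title = jc_value(blk, "TITLE"),
    x_units = jc_value(blk, "XUNITS"),
    y_units = jc_value(blk, "YUNITS"),
    data_class = jc_value(blk, "DATACLASS"),
    solvent = jc_value(blk, ".SOLVENTNAME")
  )
  of <- jc_num(blk, ".OBSERVEFREQUENCY")
  if (is.finite(of)) meta$observe_freq <- of
  meta <- meta[!vapply(meta, is.null, logical(1))]
  ord <- tab$x
  x <- tab$x; y <- tab$y
  if (length(x) > 1L && any(diff(x) == 0)) {
    keep <- !duplicated(x)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) > 1L && !(all(diff(x) > 0) || all(diff(x) < 0))) {
    o <- order(x); x <- x[o]; y <- y[o]
  }
  spectrum(x, y, kind, meta)
}

#' Build a JCAMP-DX document from a spectrum
#'
#' Constructs the canonical record set for the spectrum's kind (data type,
#' observe nucleus/frequency and solvent for NMR, units records) and
#' attaches the trace as a grid table (NMR/IR) or a peak table (MS).
#'
#' @param s A `spectrum`.
#' @param title Document title (defaults to the spectrum's title).
#' @return A `jcamp_document`.
#' @export
spectrum_to_jcamp <- function(s, title = NULL) {
  title <- title %||% s$meta$title %||% "speckit spectrum"
  rows <- list(c("TITLE", title), c("JCAMP-DX", "5.01"))
  add <- function(label, value) rows[[length(rows) + 1L]] <<- c(label, value)
  xu <- s$meta$x_units %||% switch(s$kind, IR = "1/CM", MS = "M/Z", "PPM")
  yu <- s$meta$y_units %||% switch(s$kind, IR = "TRANSMITTANCE", "ARBITRARY UNITS")
  switch(s$kind,
    NMR_1H = , NMR_13C = {
      add("DATA TYPE", "NMR SPECTRUM")
      add("DATA CLASS", "XYDATA")
      add(".OBSERVE NUCLEUS", if (s$kind == "NMR_1H") "^1H" else "^13C")
      if (!is.null(s$meta$observe_freq)) {
        add(".OBSERVE FREQUENCY", .fmt_num(s$meta$observe_freq))
      }
      if (!is.null(s$meta$solvent)) add(".SOLVENT NAME", s$meta$solvent)
    },
    IR = {
      add("DATA TYPE", "INFRARED SPECTRUM")
      add("DATA CLASS", "XYDATA")
    },
    MS = {
      add("DATA TYPE", "MASS SPECTRUM")
      add("DATA CLASS", "PEAK TABLE")
    })
  add("ORIGIN", "speckit")
  add("OWNER", "speckit")
  add("XUNITS", xu)
  add("YUNITS", yu)
  records <- data.frame(
    label = vapply(rows, `[[`, "", 1L),
    value = vapply(rows, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  records$norm <- norm_label(records$label)
  records <- records[, c("label", "norm", "value")]
  tab <- if (s$kind == "MS") {
    list(form = "PEAKTABLE", variable_list = "(XY..XY)", x = s$x, y = s$y,
         npoints = length(s$x))
  } else {
    list(form = "XYDATA", variable_list = "(X++(Y..Y))", x = s$x, y = s$y,
         firstx = s$x[1], lastx = s$x[length(s$x)], npoints = length(s$x),
         xfactor = 1, yfactor = 1)
  }
  new_jcamp_document(records, list(tab))
}
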