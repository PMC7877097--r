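# ASDF ordinate codec for JCAMP-DX data tables.
#
# Pseudo-digit tables (the character replaces the FIRST digit of an integer):
#   SQZ (absolute):   @ A..I = 0..9     a..i = -1..-9
#   DIF (difference): % J..R = 0..9     j..r = -1..-9
#   DUP (repeat):     S..Z   = 1..8     s    = 9
# AFFN/PAC tokens are plain (optionally signed) decimal numbers.

.sqz_pos <- "@ABCDEFGHI"
.sqz_neg <- "abcdefghi"
.dif_pos <- "%JKLMNOPQR"
.dif_neg <- "jklmnopqr"
.dup_chr <- "STUVWXYZs"

.asdf_token_re <- "[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)|[@A-Ia-i][0-9]*|[%J-Rj-r][0-9]*|[S-Zs][0-9]*|\\?"

.pseudo_value <- function(tok, pos_set, neg_set, offset_pos = 0L, offset_neg = 1L) {
  first <- substr(tok, 1L, 1L)
  rest <- substr(tok, 2L, nchar(tok))
  i <- regexpr(first, pos_set, fixed = TRUE)
  if (i > 0L) {
    digit <- i - 1L + offset_pos
    sign <- 1
  } else {
    i <- regexpr(first, neg_set, fixed = TRUE)
    digit <- i - 1L + offset_neg
    sign <- -1
  }
  sign * as.numeric(paste0(digit, rest))
}

asdf_tokenize <- function(line) {
  line <- sub("\\$\\$.*$", "", line)          # strip in-line comments
  m <- gregexpr(.asdf_token_re, line)[[1]]
  if (m[1] == -1L) return(character(0))
  regmatches(line, list(m))[[1]]
}

.asdf_classify <- function(tokens) {
  first <- substr(tokens, 1L, 1L)
  kind <- character(length(tokens))
  kind[grepl("^[0-9+.-]", first)] <- "affn"
  kind[first == "?"] <- "missing"
  kind[grepl("[@A-Ia-i]", first)] <- "sqz"
  kind[grepl("[%J-Rj-r]", first)] <- "dif"
  kind[grepl("[S-Zs]", first)] <- "dup"
  kind
}

.asdf_values <- function(tokens, kind) {
  v <- numeric(length(tokens))
  for (i in seq_along(tokens)) {
    v[i] <- switch(kind[i],
      affn = as.numeric(tokens[i]),
      missing = NA_real_,
      sqz = .pseudo_value(tokens[i], .sqz_pos, .sqz_neg),
      dif = .pseudo_value(tokens[i], .dif_pos, .dif_neg),
      dup = .pseudo_value(tokens[i], .dup_chr, "", offset_pos = 1L)
    )
  }
  v
}

#' Decode an ASDF-compressed ordinate table
#'
#' Decodes the data lines of a JCAMP-DX `(X++(Y..Y))` table in any of the
#' standard ordinate forms (AFFN, PAC, SQZ, DIF, DUP and mixed DIFDUP).
#' Each line starts with an abscissa value followed by ordinate tokens. In
#' DIF mode the first ordinate of every following line is a check value
#' that repeats the previous line's last ordinate; it is verified and
#' consumed, not emitted.
#'
#' @param lines Character vector of data lines (without the `##XYDATA=` line).
#' @param npoints Expected point count (`NA` to accept any).
#' @param yfactor Ordinate scale factor applied after decoding.
#' @param xfactor,firstx,deltax Abscissa grid parameters used only to verify
#'   the per-line x check values (any may be `NA` to skip the check).
#' @param strict If `TRUE`, check failures raise errors
#'   (`speckit_checksum_mismatch`); otherwise they signal warnings and
#'   decoding continues.
#' @return Numeric vector of `npoints` ordinates (already multiplied by
#'   `yfactor`).
#' @export
decode_asdf <- function(lines, npoints = NA, yfactor = 1, xfactor = 1,
                        firstx = NA, deltax = NA, strict = FALSE) {
  out <- vector("list", length(lines))
  n_emitted <- 0L
  last_y <- NA_real_
  in_dif <- FALSE

  complain <- function(class, msg) {
    if (strict) spk_stop(class, msg) else spk_warning(class, msg)
  }

  for (li in seq_along(lines)) {
    tokens <- asdf_tokenize(lines[li])
    if (length(tokens) == 0L) next
    kind <- .asdf_classify(tokens)
    vals <- .asdf_values(tokens, kind)
    if (any(kind == "")) {
      complain("illegal_character",
               sprintf("illegal character in data line %d", li))
    }
    if (kind[1] != "affn") {
      complain("checksum_mismatch",
               sprintf("data line %d does not start with an abscissa value", li))
    } else {
      if (is.finite(firstx) && is.finite(deltax) && deltax != 0) {
        expect_x <- (firstx + n_emitted * deltax) / xfactor
        if (abs(vals[1] - expect_x) > abs(deltax / xfactor) + 1e-6 * abs(expect_x)) {
          complain("checksum_mismatch", sprintf(
            "x-sequence check failed at line %d: stored %g, expected %g",
            li, vals[1], expect_x))
        }
      }
      tokens <- tokens[-1]; kind <- kind[-1]; vals <- vals[-1]
    }
    if (length(tokens) == 0L) next

    # missing values decode as NA ordinates; treated as absolute entries
    kind[kind == "missing"] <- "affn"

    # expand DUP tokens: a count n repeats the previous token n-1 more times
    dup_at <- which(kind == "dup")
    if (length(dup_at)) {
      if (any(dup_at == 1L)) {
        complain("illegal_character",
                 sprintf("line %d starts with a duplicate count", li))
      }
      reps <- rep(1L, length(kind))
      drop <- logical(length(kind))
      for (j in dup_at) {
        if (j == 1L) { drop[j] <- TRUE; next }
        reps[j - 1L] <- reps[j - 1L] + as.integer(vals[j]) - 1L
        drop[j] <- TRUE
      }
      idx <- rep(seq_along(kind), times = ifelse(drop, 0L, reps))
      kind <- kind[idx]; vals <- vals[idx]
    }

    # consume the DIF-mode check value at the start of a continuation line
    if (in_dif && length(vals) >= 1L && kind[1] %in% c("affn", "sqz")) {
      if (is.finite(last_y) && is.finite(vals[1]) &&
          abs(vals[1] - last_y) > 1e-9 * max(1, abs(last_y))) {
        complain("checksum_mismatch", sprintf(
          "y check value failed at line %d: stored %g, expected %g",
          li, vals[1], last_y))
        last_y <- vals[1]   # lenient: trust the checkpoint
      }
      kind <- kind[-1]; vals <- vals[-1]
    }
    if (length(vals) == 0L) { in_dif <- FALSE; next }

    # absolute anchors + cumulative differences, vectorised per line
    is_abs <- kind %in% c("affn", "sqz")
    if (!is_abs[1] && !is.finite(last_y)) {
      complain("checksum_mismatch",
               sprintf("difference token with no preceding ordinate at line %d", li))
      last_y <- 0
    }
    grp <- cumsum(is_abs)
    danc <- ifelse(is_abs, 0, vals)
    cumd <- cumsum(danc)
    anchors <- c(last_y, vals[is_abs])          # group 0 anchored on carry-in
    anchor_cumd <- c(0, cumd[is_abs])
    y <- anchors[grp + 1L] + cumd - anchor_cumd[grp + 1L]

    out[[li]] <- y
    n_emitted <- n_emitted + length(y)
    last_y <- y[length(y)]
    in_dif <- kind[length(kind)] == "dif"
  }

  y <- unlist(out, use.names = FALSE) %||% numeric(0)
  if (is.finite(npoints)) {
    if (length(y) > npoints) {
      complain("checksum_mismatch", sprintf(
        "decoded %d points but NPOINTS=%d; extra points dropped",
        length(y), npoints))
      y <- y[seq_len(npoints)]
    } else if (length(y) < npoints) {
      complain("checksum_mismatch", sprintf(
        "decoded %d points but NPOINTS=%d", length(y), npoints))
    }
  }
  y * yfactor
}

.sqz_encode <- function(v) {
  # v: integer-valued scalar
  s <- sprintf("%.0f", abs(v))
  d <- as.integer(substr(s, 1L, 1L))
  ch <- if (v < 0) substr(.sqz_neg, d, d) else substr(.sqz_pos, d + 1L, d + 1L)
  paste0(ch, substr(s, 2L, nchar(s)))
}

.dif_encode <- function(v) {
  s <- sprintf("%.0f", abs(v))
  d <- as.integer(substr(s, 1L, 1L))
  ch <- if (v < 0) substr(.dif_neg, d, d) else substr(.dif_pos, d + 1L, d + 1L)
  paste0(ch, substr(s, 2L, nchar(s)))
}

.dup_encode <- function(n) {
  s <- sprintf("%d", n)
  d <- as.integer(substr(s, 1L, 1L))
  paste0(substr(.dup_chr, d, d), substr(s, 2L, nchar(s)))
}

.fmt_x <- function(x) sprintf("%.8g", x)

#' Encode an ordinate table in an ASDF form
#'
#' Inverse of [decode_asdf()]. Ordinates are stored as
#' `round(y / yfactor)`; the quantization error is therefore bounded by
#' `yfactor / 2`. In the DIF-containing forms every continuation line
#' starts with an SQZ check value repeating the previous line's last
#' ordinate, and a final check line carries the last abscissa/ordinate
#' pair, as the standard prescribes.
#'
#' @param y Numeric ordinates.
#' @param x Abscissa values (same length), used for the per-line x values.
#' @param form One of `"AFFN"`, `"SQZ"`, `"DIF"`, `"DIFDUP"`.
#' @param yfactor Ordinate scale factor.
#' @param xfactor Abscissa scale factor (stored x = x / xfactor).
#' @param width Maximum line width in characters.
#' @return Character vector of data lines.
#' @export
encode_asdf <- function(y, x, form = c("DIFDUP", "AFFN", "SQZ", "DIF"),
                        yfactor = 1, xfactor = 1, width = 78) {
  form <- match.arg(form)
  stopifnot(length(x) == length(y))
  ys <- round(y / yfactor)
  xs <- x / xfactor
  n <- length(ys)

  if (form == "AFFN") {
    lines <- character(0)
    i <- 1L
    while (i <= n) {
      parts <- .fmt_x(xs[i])
      j <- i
      while (j <= n) {
        tok <- sprintf("%.0f", ys[j])
        if (nchar(parts) + 1L + nchar(tok) > width && j > i) break
        parts <- paste(parts, tok)
        j <- j + 1L
      }
      lines <- c(lines, parts)
      i <- j
    }
    return(lines)
  }

  if (form == "SQZ") {
    lines <- character(0)
    i <- 1L
    while (i <= n) {
      parts <- .fmt_x(xs[i])
      j <- i
      while (j <= n) {
        tok <- .sqz_encode(ys[j])
        if (nchar(parts) + nchar(tok) > width && j > i) break
        parts <- paste0(parts, tok)
        j <- j + 1L
      }
      lines <- c(lines, parts)
      i <- j
    }
    return(lines)
  }

  # DIF / DIFDUP: token stream of (kind, value, runlen)
  difs <- diff(ys)
  toks <- character(0)
  if (form == "DIF") {
    toks <- vapply(difs, .dif_encode, "")
  } else {
    r <- rle(difs)
    for (k in seq_along(r$values)) {
      toks <- c(toks, .dif_encode(r$values[k]))
      if (r$lengths[k] > 1L) toks <- c(toks, .dup_encode(r$lengths[k]))
    }
  }

  lines <- character(0)
  ti <- 1L          # next token index
  pt <- 1L          # index of last point emitted so far
  # map token -> number of points it emits (DUP n emits n-1)
  emits <- ifelse(grepl("^[S-Zs]", toks),
                  vapply(toks, function(t) .pseudo_value(t, .dup_chr, "", 1L) - 1,
                         numeric(1)),
                  1)
  while (ti <= length(toks) || pt == 1L) {
    # line starts with x of the checkpoint (= last emitted point)
    parts <- paste0(.fmt_x(xs[pt]), .sqz_encode(ys[pt]))
    if (pt == 1L && length(toks) == 0L) { lines <- c(lines, parts); break }
    advanced <- FALSE
    while (ti <= length(toks)) {
      tok <- toks[ti]
      if (nchar(parts) + nchar(tok) > width && advanced) break
      parts <- paste0(parts, tok)
      pt <- pt + emits[ti]
      ti <- ti + 1L
      advanced <- TRUE
    }
    lines <- c(lines, parts)
    if (ti > length(toks)) break
  }
  # final check line: last x and last ordinate in SQZ form
  if (n > 1L) lines <- c(lines, paste0(.fmt_x(xs[n]), .sqz_encode(ys[n])))
  lines
}
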