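# Threshold-based peak picking with an auditable edit history.
#
# Picking operates on the effective (peak-direction-corrected) intensity:
# strict local maxima at or above the threshold. Plateaus (runs of equal
# ordinates strictly above both neighbouring runs) report their central
# grid point, left-of-center for even run lengths. No smoothing is applied;
# noise robustness comes from the threshold alone.

new_peak_list <- function(peaks, threshold, kind, s) {
  structure(peaks,
            threshold = threshold, kind = kind, spectrum = s,
            step = if (length(s$x) > 1L) stats::median(abs(diff(s$x))) else 0,
            class = c("peak_list", "data.frame"))
}

#' Pick peaks above a threshold
#'
#' @param s A `spectrum`.
#' @param threshold Threshold on the effective-intensity scale; defaults to
#'   [default_threshold()] for the spectrum's kind.
#' @return A `peak_list`: a data frame with columns `x`, `y` (ordinate on
#'   the original, non-inverted scale), `origin` (`"auto"`/`"user"`) and
#'   `status` (`"active"`/`"removed"`), carrying the threshold, kind and
#'   source spectrum as attributes.
#' @export
pick_peaks <- function(s, threshold = NULL) {
  stopifnot(inherits(s, "spectrum"))
  eff <- effective_intensity(s)
  if (max(eff) == min(eff)) {
    spk_stop("degenerate_spectrum", "constant trace; no peaks can be picked")
  }
  threshold <- threshold %||% default_threshold(s)
  idx <- integer(0)
  if (length(eff) >= 3L) {
    r <- rle(eff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr <- length(r$values)
    if (nr >= 3L) {
      j <- 2:(nr - 1L)
      is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
      jj <- j[is_max]
      idx <- starts[jj] + (r$lengths[jj] - 1L) %/% 2L
    }
  }
  idx <- idx[eff[idx] >= threshold]
  peaks <- data.frame(
    x = s$x[idx], y = s$y[idx],
    origin = rep("auto", length(idx)),
    status = rep("active", length(idx)),
    stringsAsFactors = FALSE)
  new_peak_list(peaks, threshold, s$kind, s)
}

#' @export
print.peak_list <- function(x, ...) {
  act <- sum(x$status == "active")
  cat(sprintf("<peak_list> %s: %d peaks (%d active), threshold %.4g\n",
              attr(x, "kind"), nrow(x), act, attr(x, "threshold")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

active_peaks <- function(pl) pl[pl$status == "active", , drop = FALSE]

#' Apply user edits to a peak list
#'
#' Additions are inserted with `origin = "user"` and the ordinate
#' interpolated from the trace; removals flip the nearest active peak
#' (within one grid step) to `status = "removed"` but keep it in the list
#' as an auditable edit history. Adds are applied before removes, so
#' adding and then removing the same position leaves no active peak there.
#'
#' @param pl A `peak_list`.
#' @param add,remove Numeric vectors of x positions.
#' @return The edited `peak_list`.
#' @export
apply_edits <- function(pl, add = numeric(0), remove = numeric(0)) {
  s <- attr(pl, "spectrum")
  step <- attr(pl, "step")
  rng <- range(s$x)
  for (xa in add) {
    if (xa < rng[1] || xa > rng[2]) {
      spk_stop("out_of_range", sprintf(
        "added peak at %g outside spectrum range [%g, %g]", xa, rng[1], rng[2]))
    }
    act <- pl$status == "active"
    if (any(act & pl$x == xa)) {
      spk_stop("inconsistent_edit", sprintf("active peak already at %g", xa))
    }
    ya <- stats::approx(s$x, s$y, xout = xa)$y
    pl <- rbind(pl, data.frame(x = xa, y = ya, origin = "user",
                               status = "active", stringsAsFactors = FALSE))
  }
  for (xr in remove) {
    act <- which(pl$status == "active")
    if (!length(act)) {
      spk_stop("no_matching_peak", sprintf("no active peak near %g", xr))
    }
    d <- abs(pl$x[act] - xr)
    i <- act[which.min(d)]
    if (min(d) > step + 1e-12) {
      spk_stop("no_matching_peak", sprintf(
        "no active peak within one grid step (%g) of %g", step, xr))
    }
    pl$status[i] <- "removed"
  }
  attrs <- attributes(pl)
  new_peak_list(as.data.frame(pl), attr(pl, "threshold"), attr(pl, "kind"), s)
}

round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a peak list for the text output panel
#'
#' Active peaks only; x values rounded half-away-from-zero to `digits`,
#' sorted in the requested order, comma-space separated. Values that
#' coincide after rounding collapse to a single entry.
#'
#' @param pl A `peak_list`.
#' @param digits Number of displayed digits.
#' @param order `"descending"` or `"ascending"`.
#' @return A single string (empty for an empty list).
#' @export
format_peak_list <- function(pl, digits = 2, order = c("descending", "ascending")) {
  order <- match.arg(order)
  xs <- active_peaks(pl)$x
  if (!length(xs)) return("")
  xs <- unique(round_half_away(xs, digits))
  xs <- sort(xs, decreasing = (order == "descending"))
  paste(formatC(xs, format = "f", digits = digits), collapse = ", ")
}

#' Refine peak positions by local quadratic interpolation
#'
#' Fits a parabola to the trace around each active peak (on the effective
#' intensity scale) and replaces the grid-point position with the fitted
#' apex. Used by the multiplet analysis to measure line spacings below the
#' grid resolution; the apex is kept only when it falls within the fit
#' window.
#'
#' @param pl A `peak_list`.
#' @param halfwidth Half-width of the fit window in grid points.
#' @return A data frame of active peaks with refined `x` and `y`.
#' @export
refine_peaks <- function(pl, halfwidth = 2L) {
  s <- attr(pl, "spectrum")
  eff <- effective_intensity(s)
  ap <- active_peaks(pl)
  for (k in seq_len(nrow(ap))) {
    i <- which.min(abs(s$x - ap$x[k]))
    lo <- max(1L, i - halfwidth); hi <- min(length(s$x), i + halfwidth)
    if (hi - lo < 2L) next
    xs <- s$x[lo:hi] - s$x[i]
    fit <- stats::lm.fit(cbind(1, xs, xs^2), eff[lo:hi])
    a <- fit$coefficients
    if (!is.finite(a[3]) || a[3] >= 0) next
    apex <- -a[2] / (2 * a[3])
    if (abs(apex) <= abs(s$x[hi] - s$x[lo]) / 2) {
      ap$x[k] <- s$x[i] + apex
      ap$y[k] <- a[1] - a[2]^2 / (4 * a[3])
    }
  }
  ap
}

#' Export a peak list as CSV rows
#'
#' @param pl A `peak_list`.
#' @param path Optional file path; when omitted the data frame is returned.
#' @return Data frame with columns `x`, `y`, `origin`, `status` (invisibly
#'   when written to file).
#' @export
peak_list_csv <- function(pl, path = NULL) {
  df <- as.data.frame(pl)[, c("x", "y", "origin", "status")]
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
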