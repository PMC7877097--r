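# Shared test scaffolding: tiny document builders and the brute-force
# peak oracle used by several files.

minimal_jcamp <- function(data_lines, firstx = 1, lastx = 3, npoints = 3,
                          yfactor = NULL, extra = character(0),
                          data_type = "INFRARED SPECTRUM") {
  c("##TITLE=minimal fixture",
    "##JCAMP-DX=4.24",
    paste0("##DATA TYPE=", data_type),
    extra,
    if (!is.null(yfactor)) paste0("##YFACTOR=", yfactor),
    paste0("##FIRSTX=", firstx),
    paste0("##LASTX=", lastx),
    paste0("##NPOINTS=", npoints),
    "##XYDATA=(X++(Y..Y))",
    data_lines,
    "##END=")
}

# independent oracle: scan testing y[i-1] < y[i] >= y[i+1] and y[i] >= thr
brute_force_peaks <- function(eff, thr) {
  n <- length(eff)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[eff[i - 1L] < eff[i] & eff[i] >= eff[i + 1L] & eff[i] >= thr]
}

# analytic peak table of a named multiplet (no lineshape, no noise)
analytic_multiplet_peaks <- function(label, J, center_ppm, observe_freq,
                                     amp = 1) {
  ml <- multiplet_lines(label, J)
  data.frame(x = center_ppm + ml$offset_hz / observe_freq,
             y = amp * ml$weight / max(ml$weight))
}
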