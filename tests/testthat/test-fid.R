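# FID processing: frequency axis, zero filling, automatic phase and
# baseline correction, energy conservation and bundle IO.

test_that("a damped exponential lands on its analytic ppm position", {
  # +1000 Hz offset at 400 MHz with the carrier at 5.0 ppm -> 7.50 ppm
  sw <- 4000; n <- 8192
  t <- (seq_len(n) - 1) / sw
  pts <- exp((2i * pi * 1000 - 1 / 0.2) * t)
  f <- fid_record(pts, sw_hz = sw, sf_mhz = 400, center_ppm = 5.0)
  s <- process_fid(f)
  rp <- refine_peaks(pick_peaks(s))
  expect_lt(abs(rp$x[which.max(rp$y)] - 7.50), 0.005)
})

test_that("zero filling doubles the grid without moving the peak", {
  g <- gen_nmr(list(list(center = 6.2, width_hz = 2)), n = 4096, noise = 0,
               seed = 1)
  s1 <- process_fid(g$fid, zero_fill = 1)
  s2 <- process_fid(g$fid, zero_fill = 2)
  expect_equal(length(s2$x), 2 * length(s1$x))
  p1 <- s1$x[which.max(s1$y)]
  p2 <- s2$x[which.max(s2$y)]
  expect_lte(abs(p1 - p2), diff(s1$x)[1] / 2)
})

test_that("two resonances 50 Hz apart resolve into two picked peaks", {
  g <- gen_nmr(list(list(center = 5, width_hz = 2),
                    list(center = 5.125, width_hz = 2)),
               n = 8192, noise = 0, seed = 3)
  s <- process_fid(g$fid)
  pl <- pick_peaks(s)
  expect_equal(nrow(pl), 2)
  expect_lt(abs(sort(pl$x)[1] - 5), 0.005)
  expect_lt(abs(sort(pl$x)[2] - 5.125), 0.005)
})

.complex_line <- function(n = 4096, pos = 0.4) {
  # ideal absorption + i*dispersion Lorentzian on an index grid
  u <- (seq_len(n) / n - pos) * 200
  complex(real = 1 / (1 + u^2), imaginary = -u / (1 + u^2))
}

test_that("auto phase is a fixed point on a correctly phased line", {
  ph <- auto_phase(.complex_line())
  expect_lte(abs(ph[["ph0"]]), 2)
})

test_that("auto phase recovers an injected zero-order error against the grid oracle", {
  spec <- .complex_line() * exp(1i * pi / 180 * 30)
  ph <- auto_phase(spec)
  expect_lt(abs(ph[["ph0"]] + 30), 2)
  # exhaustive 0.5-degree zero-order grid search as the independent oracle
  re <- Re(spec); im <- Im(spec)
  grid <- seq(-180, 179.5, by = 0.5)
  neg <- vapply(grid, function(p) {
    phi <- pi / 180 * p
    sum(pmax(-(re * cos(phi) - im * sin(phi)), 0))
  }, numeric(1))
  oracle <- grid[which.min(neg)]
  expect_lt(abs(ph[["ph0"]] - oracle), 1)
  # applying the returned phase leaves a clean absorption line
  phased <- apply_phase(spec, ph[["ph0"]], ph[["ph1"]])
  expect_lte(sum(pmax(-Re(phased), 0)) / sum(abs(Re(phased))), 0.05)
})

test_that("a linear phase ramp across the window is recovered", {
  g <- gen_nmr(list(list(center = 2, width_hz = 2),
                    list(center = 5, width_hz = 2),
                    list(center = 8, width_hz = 2)),
               n = 8192, noise = 0, seed = 5)
  sw <- g$fid$sw_hz
  pts <- g$fid$points
  n <- length(pts)
  t <- (seq_len(n) - 1) / sw
  pts <- pts * exp(-pi * 0.3 * t); pts[1] <- pts[1] / 2
  n2 <- 2 * 2^ceiling(log2(n))
  spec <- stats::fft(c(pts, complex(real = rep(0, n2 - n))))
  spec <- spec[c((n2 / 2 + 1):n2, 1:(n2 / 2))]
  spec <- apply_phase(spec, 20, 90)
  ph <- auto_phase(spec)
  expect_lt(abs(ph[["ph0"]] + 20), 5)
  expect_lt(abs(ph[["ph1"]] + 90), 5)
})

test_that("spectral energy equals time-domain energy before apodization", {
  g <- gen_nmr(list(list(center = 5, width_hz = 2)), n = 4096, noise = 1e-3,
               seed = 2)
  fid <- g$fid$points
  spec <- stats::fft(fid)
  lhs <- sum(Mod(fid)^2)
  rhs <- sum(Mod(spec)^2) / length(fid)
  expect_lt(abs(lhs - rhs) / lhs, 1e-6)
})

test_that("pure tones land on the analytic ppm within one bin", {
  sw <- 5000; n <- 2048; sf <- 400
  for (seed in 1:50) {
    f_hz <- with_seed(seed, stats::runif(1, -2000, 2000))
    t <- (seq_len(n) - 1) / sw
    pts <- exp((2i * pi * f_hz - 20) * t)
    s <- process_fid(fid_record(pts, sw, sf, center_ppm = 5),
                     zero_fill = 1, line_broadening = 0, baseline = FALSE)
    got <- s$x[which.max(s$y)]
    expect_lte(abs(got - (5 + f_hz / sf)), sw / n / sf)
  }
})

test_that("baseline correction removes offsets and tilts, preserving areas", {
  g <- gen_nmr(list(list(center = 5, width_hz = 2, nH = 1)), n = 4096,
               noise = 0, seed = 4)
  s <- g$spectrum
  # constant offset
  s1 <- s; s1$y <- s1$y + 50
  b1 <- baseline_correct(s1)
  edge <- abs(b1$y[s1$x < 2 | s1$x > 8])
  expect_lte(max(edge), 0.5)                   # residual <= 1% of the offset
  # linear tilt
  s2 <- s; s2$y <- s2$y + 3 + 0.5 * s2$x
  b2 <- baseline_correct(s2)
  a <- nmr_integrate(b2, list(c(4.5, 5.5)))$raw
  expect_lt(abs(a - 1), 0.02)                  # area within 2% of pi*A*Gamma/2
})

test_that("group delay is undone by circular rotation", {
  g <- gen_nmr(list(list(center = 6, width_hz = 2)), n = 4096, noise = 0,
               seed = 9)
  pts <- g$fid$points
  gd <- 70L
  shifted <- c(rep(0 + 0i, gd), pts[1:(length(pts) - gd)])
  f <- fid_record(shifted, g$fid$sw_hz, g$fid$sf_mhz, g$fid$center_ppm,
                  group_delay = gd)
  s <- process_fid(f)
  expect_lt(abs(s$x[which.max(s$y)] - 6), 0.005)
})

test_that("FID bundles round trip through text, binary and zip forms", {
  g <- gen_nmr(list(list(center = 4.2, width_hz = 2)), n = 1024, noise = 0,
               seed = 8)
  for (binary in c(FALSE, TRUE)) {
    d <- file.path(tempdir(), paste0("fidbundle", binary))
    write_fid_bundle(g$fid, d, binary = binary)
    f2 <- read_fid_bundle(d)
    expect_equal(f2$points, g$fid$points)
    expect_equal(f2$sw_hz, g$fid$sw_hz)
    expect_equal(f2$sf_mhz, g$fid$sf_mhz)
  }
  d <- file.path(tempdir(), "fidbundleTRUE")
  zp <- file.path(tempdir(), "fidbundle.zip")
  zip_store(list.files(d, full.names = TRUE), zp)
  f3 <- read_fid_bundle(zp)
  expect_equal(f3$points, g$fid$points)
  expect_error(read_fid_bundle(tempdir()),
               class = "speckit_invalid_acquisition")
})

test_that("invalid acquisition parameters are rejected", {
  expect_error(fid_record(complex(real = 1:4), sw_hz = -1, sf_mhz = 400),
               class = "speckit_invalid_acquisition")
  expect_error(fid_record(complex(real = 1), sw_hz = 100, sf_mhz = 400),
               class = "speckit_invalid_acquisition")
})
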