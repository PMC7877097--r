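# NMR analysis: referencing, integration, multiplicity inference and
# reporting.

test_that("the solvent table carries the standard residual shifts", {
  tab <- solvent_shifts()
  need_1h <- c("CDCl3", "DMSO-d6", "CD3OD", "D2O")
  need_13c <- c("CDCl3", "DMSO-d6", "CD3OD")
  expect_true(all(need_1h %in% tab$solvent[tab$nucleus == "1H"]))
  expect_true(all(need_13c %in% tab$solvent[tab$nucleus == "13C"]))
  expect_equal(tab$shift_ppm[tab$solvent == "CDCl3" & tab$nucleus == "1H"], 7.26)
  expect_equal(tab$shift_ppm[tab$solvent == "CDCl3" & tab$nucleus == "13C"], 77.16)
})

test_that("referencing shifts the axis rigidly by expected minus observed", {
  g <- gen_nmr(list(list(center = 7.31)), n = 1024, noise = 0, seed = 1)
  s <- g$spectrum
  s2 <- reference_correct(s, "CDCl3", observed_ppm = 7.31)
  expect_equal(s2$x, s$x - 0.05)
  expect_identical(s2$y, s$y)
  expect_equal(diff(s2$x), diff(s$x))          # rigid shift
  # zero shift at the fixed point, and idempotence there
  s3 <- reference_correct(s, "CDCl3", observed_ppm = 7.26)
  expect_equal(s3$x, s$x)
  s4 <- reference_correct(s2, "CDCl3", observed_ppm = 7.26)
  expect_equal(s4$x, s2$x)
  expect_error(reference_correct(s, "heptane", 1.0),
               class = "speckit_unknown_solvent")
})

test_that("integration recovers a 2:3 area ratio against the closed form", {
  for (seed in 1:10) {
    g <- gen_nmr(list(list(center = 3, nH = 2, width_hz = 1.5),
                      list(center = 7, nH = 3, width_hz = 1.5)),
                 n = 8192, seed = 100 + seed)
    ii <- nmr_integrate(g$spectrum, list(c(2.9, 3.1), c(6.9, 7.1)),
                        ref_value = 2)
    expect_equal(ii$integral[1], 2)            # reference is a fixed point
    expect_lt(abs(ii$integral[2] - 3), 0.06)   # within 2% of the pi*A*Gamma/2 oracle
  }
})

test_that("integration is invariant under ordinate scaling", {
  g <- gen_nmr(list(list(center = 3, nH = 1), list(center = 7, nH = 2)),
               n = 4096, seed = 5)
  s2 <- g$spectrum; s2$y <- s2$y * 17.3
  i1 <- nmr_integrate(g$spectrum, list(c(2.8, 3.2), c(6.8, 7.2)))
  i2 <- nmr_integrate(s2, list(c(2.8, 3.2), c(6.8, 7.2)))
  expect_equal(i1$integral, i2$integral)
})

test_that("baseline-only ranges integrate to about zero", {
  g <- gen_nmr(list(list(center = 3, nH = 1)), n = 4096, seed = 6)
  ii <- nmr_integrate(g$spectrum, list(c(2.8, 3.2), c(8, 9)))
  expect_lt(abs(ii$integral[2]), 0.02)
  expect_error(nmr_integrate(g$spectrum, list(c(11, 12))),
               class = "speckit_empty_range")
  g0 <- gen_nmr(list(list(center = 3, nH = 1)), n = 1024, noise = 0, seed = 6)
  expect_error(nmr_integrate(g0$spectrum, list(c(8, 9))),
               class = "speckit_zero_reference")
})

test_that("analytic doublet and triplet spacings convert to Hz correctly", {
  d <- analyze_multiplet(data.frame(x = c(6.99, 7.01), y = c(1, 1)), 400)
  expect_equal(d$label, "d")
  expect_equal(d$J, 8)                         # 0.02 ppm x 400 MHz
  t <- analyze_multiplet(data.frame(x = c(6.98, 7.00, 7.02), y = c(1, 2, 1)), 400)
  expect_equal(t$label, "t")
  expect_equal(t$J, 8)
  s <- analyze_multiplet(data.frame(x = 8.52, y = 1), 400)
  expect_equal(s$label, "s")
  expect_length(s$J, 0)
})

test_that("a dd decomposes into two couplings, checked by tree enumeration", {
  pk <- analytic_multiplet_peaks("dd", c(12, 4), 7.45, 400)
  m <- analyze_multiplet(pk, 400)
  expect_equal(m$label, "dd")
  expect_equal(m$J, c(12, 4))
  # independent oracle: enumerate all two-coupling trees over the peaks
  hz <- sort(pk$x * 400)
  cands <- expand.grid(J1 = seq(0.5, 25, by = 0.25), J2 = seq(0.5, 25, by = 0.25))
  cands <- cands[cands$J1 > cands$J2, ]
  errs <- apply(cands, 1, function(p) {
    pred <- sort(c(-p[1] - p[2], -p[1] + p[2], p[1] - p[2], p[1] + p[2]) / 2)
    max(abs(pred + mean(hz) - hz))
  })
  best <- cands[which.min(errs), ]
  expect_equal(unname(unlist(best)), m$J, tolerance = 0.26)
})

test_that("the validation rules fall back to m instead of guessing", {
  # unequal intensities break the doublet rule
  m1 <- analyze_multiplet(data.frame(x = c(6.99, 7.01), y = c(1, 3)), 400)
  expect_equal(m1$label, "m")
  expect_length(m1$J, 0)
  # irregular spacings break the triplet rule
  m2 <- analyze_multiplet(data.frame(x = c(6.95, 7.00, 7.02), y = c(1, 2, 1)), 400)
  expect_equal(m2$label, "m")
  # couplings outside [0.5, 25] Hz are not named
  m3 <- analyze_multiplet(data.frame(x = c(6.9, 7.1), y = c(1, 1)), 400)
  expect_equal(m3$label, "m")
  # too many peaks
  m4 <- analyze_multiplet(data.frame(x = seq(1, 2, length.out = 17), y = 1), 400)
  expect_equal(m4$label, "m")
})

test_that("dt and td patterns are distinguished by which coupling is larger", {
  dt <- analyze_multiplet(analytic_multiplet_peaks("dt", c(10, 3), 4, 400), 400)
  expect_equal(dt$label, "dt")
  expect_equal(dt$J, c(10, 3), tolerance = 0.01)
  td <- analyze_multiplet(analytic_multiplet_peaks("td", c(9, 2.5), 4, 400), 400)
  expect_equal(td$label, "td")
  expect_equal(td$J, c(9, 2.5), tolerance = 0.01)
})

test_that("multiplet recovery holds across the seeded study set", {
  cases <- gen_multiplet_study(n_cases = 100L, seed = 11)
  good <- 0; jmax <- 0
  for (cs in cases) {
    m <- recover_multiplet(cs$fixture$spectrum)
    if (identical(m$label, cs$label)) {
      good <- good + 1
      if (length(cs$J)) jmax <- max(jmax, max(abs(m$J - cs$J)))
    }
  }
  expect_gte(good / length(cases), 0.95)
  expect_lte(jmax, 0.2)
})

test_that("reports follow the journal template", {
  sig1 <- nmr_signal(c(8.4, 8.6), data.frame(x = 8.52, y = 1), "s",
                     integral = 1)
  sig2 <- nmr_signal(c(7.3, 7.6), data.frame(x = 7.45, y = 1), "dd",
                     J = c(4, 12), integral = 1)
  txt <- nmr_report(list(sig2, sig1), "1H", 400, "CDCl3")
  expect_match(txt, "¹H NMR \\(400 MHz, CDCl3\\)", fixed = FALSE)
  expect_match(txt, "8.52 \\(s, 1H\\)")
  expect_match(txt, "7.45 \\(dd, J = 12.0, 4.0 Hz, 1H\\)")   # J descending
  # shifts sorted descending
  expect_lt(regexpr("8.52", txt), regexpr("7.45", txt))
  # m signals carry no J clause
  sigm <- nmr_signal(c(1.2, 1.5), data.frame(x = 1.3, y = 1), "m",
                     integral = 2)
  expect_match(nmr_report(list(sigm), "1H", 400, "CDCl3"), "\\(m, 2H\\)")
  # 13C omits multiplicity entirely
  c13 <- nmr_report(list(nmr_signal(c(170, 171), data.frame(x = 170.4, y = 1),
                                    "s", integral = NA, nucleus = "13C")),
                    "13C", 101, "CDCl3")
  expect_match(c13, "¹³C NMR \\(101 MHz, CDCl3\\) δ = 170.4$")
})

test_that("signal invariants are enforced", {
  expect_error(nmr_signal(c(1, 2), data.frame(), "s", J = 5),
               class = "speckit_invalid_spec")
  expect_error(nmr_signal(c(1, 2), data.frame(), "d", J = 30),
               class = "speckit_invalid_spec")
  sig <- nmr_signal(c(1, 2), data.frame(), "dd", J = c(3, 9), integral = 1)
  expect_equal(sig$J, c(9, 3))                 # reported descending
})
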