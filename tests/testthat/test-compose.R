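# Composition of the edited document, IR intensity labels, rendering and
# the artifact bundle.

make_ir_fixture <- function(seed = 1) {
  gen_ir(list(list(center = 1700, depth = 0.9),
              list(center = 2950, depth = 0.45),
              list(center = 3400, depth = 0.08, width = 30)),
         noise = 0, seed = seed)
}

test_that("IR bands are classified by relative depth", {
  g <- make_ir_fixture()
  s <- g$spectrum
  pl <- pick_peaks(s, threshold = 0.05 * max(effective_intensity(s)))
  labels <- vapply(seq_len(nrow(pl)),
                   function(i) ir_intensity_label(pl[i, ], s), "")
  named <- stats::setNames(labels, round(pl$x, -1))
  expect_equal(unname(named[as.character(1700)]), "vs")   # deepest band
  expect_equal(unname(named[as.character(2950)]), "m")    # d = 0.5
  expect_equal(unname(named[as.character(3400)]), "vw")   # d < 0.1
  expect_error(ir_intensity_label(pl[1, ], gen_nmr(list(list(center = 5)),
                                                   n = 256, seed = 1)$spectrum),
               class = "speckit_not_infrared")
})

test_that("the IR report puts the label in brackets after the wavenumber", {
  g <- make_ir_fixture()
  pl <- pick_peaks(g$spectrum, 0.05 * max(effective_intensity(g$spectrum)))
  txt <- ir_report(pl)
  expect_match(txt, "^\\d+ \\(vw\\), \\d+ \\(m\\), \\d+ \\(vs\\)$")
  vals <- as.numeric(regmatches(txt, gregexpr("\\d+", txt))[[1]])
  expect_equal(vals, c(3400, 2950, 1700), tolerance = attr(pl, "step") / 1700)
})

test_that("composed documents recover peaks, edits and signals losslessly", {
  g <- gen_nmr(list(list(center = 7.45, label = "dd", J = c(12, 4), nH = 1),
                    list(center = 3.4, label = "s", nH = 3)),
               n = 2048, seed = 13)
  doc <- spectrum_to_jcamp(g$spectrum)
  pl <- pick_peaks(g$spectrum)
  pl <- apply_edits(pl, add = 5.5, remove = 3.4)
  sig <- nmr_signal(c(7.3, 7.6), data.frame(x = 7.45, y = 1), "dd",
                    J = c(12, 4), integral = 1)
  txt <- compose_edited_jcamp(doc, pl, list(sig))
  d2 <- parse_jcamp(txt)
  # active peak set identical
  ap <- pl[pl$status == "active", ]
  rec <- cs_peaks(d2)
  expect_equal(rec$x, ap$x)
  expect_equal(rec$y, ap$y)
  # signals carry multiplicity and both J values
  sigs <- cs_signals(d2)
  expect_length(sigs, 1)
  expect_equal(sigs[[1]]$label, "dd")
  expect_equal(sigs[[1]]$J, c(12, 4))
  # user edit trail is present
  expect_match(jc_value(d2, "$CSEDITS"), "ADD,5.5")
  expect_match(jc_value(d2, "$CSEDITS"), "REMOVE,3.4")
  # the trace itself is not mutated by the edits
  expect_equal(d2$data[[1]]$y, g$spectrum$y,
               tolerance = max(abs(g$spectrum$y)) / 2^23)
  # composing twice is byte-identical
  expect_identical(compose_edited_jcamp(doc, pl, list(sig)), txt)
})

test_that("inconsistent edits are refused", {
  g <- gen_nmr(list(list(center = 5)), n = 512, seed = 2)
  pl <- pick_peaks(g$spectrum)
  pl$x[1] <- 99
  expect_error(compose_edited_jcamp(spectrum_to_jcamp(g$spectrum), pl),
               class = "speckit_inconsistent_edit")
})

test_that("renditions use the fixed canvases and are byte-deterministic", {
  skip_if_not_installed("png")
  g <- gen_nmr(list(list(center = 5, label = "d", J = 8)), n = 1024, seed = 3)
  pl <- pick_peaks(g$spectrum)
  full <- render_png(g$spectrum, pl, "full")
  thumb <- render_png(g$spectrum, pl, "thumbnail")
  expect_equal(dim(png::readPNG(full))[2:1], c(1600, 1000))
  expect_equal(dim(png::readPNG(thumb))[2:1], c(320, 240))
  expect_identical(render_png(g$spectrum, pl, "full"), full)
  # MS renders too (bar layout)
  ms <- spectrum(c(100, 150, 200), c(10, 50, 30), "MS")
  bar <- render_png(ms, size = "thumbnail")
  expect_equal(dim(png::readPNG(bar))[2:1], c(320, 240))
})

test_that("bundles follow the naming contract and are idempotent", {
  g <- gen_nmr(list(list(center = 7, label = "d", J = 8)), n = 1024, seed = 5)
  jdx <- file.path(tempdir(), "sample.jdx")
  write_jcamp(spectrum_to_jcamp(g$spectrum), path = jdx)
  zipf <- file.path(tempdir(), "sample.zip")
  zip_store(jdx, zipf)

  b <- build_bundle(zipf)
  expect_equal(b$edited_name, "sample.edit.jdx")
  expect_equal(b$png_full_name, "sample.edit.png")
  expect_equal(b$png_thumb_name, "sample.thumb.png")
  # original bytes are untouched
  expect_identical(b$original, readBin(zipf, "raw", file.size(zipf)))
  # the edited member re-parses
  expect_silent(d2 <- parse_jcamp(b$edited))
  expect_gt(nrow(cs_peaks(d2)), 0)
  # rebuilding is byte-idempotent
  b2 <- build_bundle(zipf)
  expect_identical(b2$edited, b$edited)
  expect_identical(b2$png_full, b$png_full)
  expect_identical(b2$png_thumb, b$png_thumb)

  out <- write_bundle(b, file.path(tempdir(), "bundleout"))
  expect_true(all(file.exists(out)))
})

test_that("edits regenerate both images", {
  g <- gen_nmr(list(list(center = 7, label = "d", J = 8)), n = 1024, seed = 5)
  jdx <- file.path(tempdir(), "sample2.jdx")
  write_jcamp(spectrum_to_jcamp(g$spectrum), path = jdx)
  doc <- read_jcamp(jdx)
  pl <- pick_peaks(jcamp_to_spectrum(doc))
  b1 <- build_bundle(jdx, doc = doc, pl = pl)
  b2 <- build_bundle(jdx, doc = doc, pl = apply_edits(pl, add = 2.22))
  expect_false(identical(b1$png_full, b2$png_full))
  expect_false(identical(b1$png_thumb, b2$png_thumb))
  expect_false(identical(b1$edited, b2$edited))
})
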