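# JCAMP-DX parsing and writing: grid decoding, record preservation,
# compound and NTUPLES documents, containers, and round-trip fidelity.

test_that("a minimal AFFN table decodes with the declared grid", {
  d <- parse_jcamp(minimal_jcamp("1.0 10 20 30"))
  expect_equal(d$data[[1]]$x, c(1, 2, 3))
  expect_equal(d$data[[1]]$y, c(10, 20, 30))
})

test_that("stored ordinates are scaled by YFACTOR", {
  d <- parse_jcamp(minimal_jcamp("1.0 5 10 15", yfactor = 2))
  expect_equal(d$data[[1]]$y, c(10, 20, 30))
})

test_that("documents without TITLE or END are rejected", {
  expect_error(parse_jcamp(c("##DATA TYPE=NMR SPECTRUM", "##END=")),
               class = "speckit_malformed_document")
  expect_error(parse_jcamp(c("##TITLE=x", "##NPOINTS=3")),
               class = "speckit_malformed_document")
})

test_that("records, private labels and comments survive a round trip", {
  txt <- minimal_jcamp("1.0 10 20 30",
                       extra = c("##ORIGIN=lab", "##$MYPRIVATE=kept verbatim",
                                 "$$ a free comment line"))
  d1 <- parse_jcamp(txt)
  d2 <- parse_jcamp(write_jcamp(d1))
  expect_equal(jc_value(d2, "$MYPRIVATE"), "kept verbatim")
  expect_equal(jc_value(d2, "ORIGIN"), "lab")
  expect_true(any(d2$records$norm == "$$"))
  # every non-data record's label/value pair is preserved
  keep <- !(d1$records$norm %in% c("$$", "XYDATA", "END", "NPOINTS",
                                   "FIRSTX", "LASTX", "YFACTOR"))
  for (i in which(keep)) {
    expect_equal(jc_value(d2, d1$records$label[i]),
                 d1$records$value[i])
  }
})

test_that("CRLF documents parse identically to LF documents", {
  txt <- minimal_jcamp("1.0 10 20 30")
  lf <- parse_jcamp(paste(txt, collapse = "\n"))
  crlf <- parse_jcamp(paste(txt, collapse = "\r\n"))
  expect_equal(crlf$data[[1]]$y, lf$data[[1]]$y)
  expect_equal(crlf$records$value, lf$records$value)
})

test_that("compound documents expose nested blocks", {
  inner1 <- minimal_jcamp("1.0 1 2 3", data_type = "INFRARED SPECTRUM")
  inner2 <- minimal_jcamp("1.0 4 5 6", data_type = "MASS SPECTRUM")
  txt <- c("##TITLE=compound", "##JCAMP-DX=5.01", "##BLOCKS=2",
           inner1, inner2, "##END=")
  d <- parse_jcamp(txt)
  expect_length(d$blocks, 2)
  expect_equal(d$blocks[[1]]$data[[1]]$y, c(1, 2, 3))
  expect_equal(d$blocks[[2]]$data[[1]]$y, c(4, 5, 6))
  expect_equal(detect_type(d$blocks[[2]]), "MS")
  # conversion picks the first block carrying data
  s <- jcamp_to_spectrum(d)
  expect_equal(s$y, c(1, 2, 3))
})

test_that("NTUPLES documents expose the real page as primary table", {
  re <- c(5, 10, 20, 10, 5)
  im <- c(-2, -1, 0, 1, 2)
  txt <- c(
    "##TITLE=ntuples fixture",
    "##JCAMP-DX=5.01",
    "##DATA TYPE=NMR SPECTRUM",
    "##.OBSERVE NUCLEUS=^1H",
    "##.OBSERVE FREQUENCY=400",
    "##NTUPLES=NMR SPECTRUM",
    "##VAR_NAME=FREQUENCY,SPECTRUM/REAL,SPECTRUM/IMAG",
    "##SYMBOL=X,R,I",
    "##VAR_DIM=5,5,5",
    "##FACTOR=1,1,1",
    "##FIRST=0,5,-2",
    "##LAST=4,5,2",
    "##PAGE=N=1",
    "##DATA TABLE=(X++(R..R)), XYDATA",
    paste("0", paste(re, collapse = " ")),
    "##PAGE=N=2",
    "##DATA TABLE=(X++(I..I)), XYDATA",
    paste("0", paste(im, collapse = " ")),
    "##END NTUPLES=NMR SPECTRUM",
    "##END=")
  d <- parse_jcamp(txt, strict = TRUE)
  expect_equal(d$data[[1]]$y, re)       # NPOINTS (VAR_DIM) honored
  expect_length(d$data[[1]]$y, 5)
  expect_length(d$ntuples$pages, 2)
  expect_equal(d$ntuples$pages[[2]]$symbol, "I")
  expect_equal(d$ntuples$pages[[2]]$y, im)  # imaginary page retained
  expect_equal(detect_type(d), "NMR_1H")
})

test_that("write-parse round trips reproduce the table within YFACTOR/2", {
  corpus <- gen_fixture_corpus(per_kind = 3L, seed = 7, n = 256L)
  for (f in corpus) {
    d1 <- parse_jcamp(write_jcamp(f$doc))
    t0 <- f$doc$data[[1]]; t1 <- d1$data[[1]]
    expect_length(t1$y, length(t0$y))
    yf <- .num_or <- if (!is.null(t1$yfactor)) t1$yfactor else 1
    expect_lte(max(abs(t1$y - t0$y)), yf / 2 + 1e-12)
    # second round trip is exact: ordinates are already quantized
    d2 <- parse_jcamp(write_jcamp(d1))
    expect_identical(d2$data[[1]]$y, d1$data[[1]]$y)
  }
})

test_that("integer ordinates with unit YFACTOR round trip bit-exactly", {
  y <- with_seed(3, round(stats::rnorm(500, 0, 2000)))
  s <- spectrum(seq(0, 10, length.out = 500), y, "NMR_1H",
                list(observe_freq = 400))
  d <- parse_jcamp(write_jcamp(spectrum_to_jcamp(s), form = "DIFDUP"))
  expect_identical(d$data[[1]]$y, as.numeric(y))
})

test_that("peak-table documents preserve m/z bit-exactly", {
  mz <- c(100.123456789012, 250.000000000001, 499.999999999999)
  s <- spectrum(mz, c(5, 10, 2), "MS")
  d <- parse_jcamp(write_jcamp(spectrum_to_jcamp(s)))
  expect_identical(d$data[[1]]$x, mz)
  expect_equal(jc_num(d, "NPOINTS"), 3)
})

test_that("a ZIP container holding one JCAMP file is unpacked transparently", {
  g <- gen_ir(list(list(center = 1600, depth = 0.7)), seed = 2)
  jdx <- file.path(tempdir(), "irfix.jdx")
  write_jcamp(spectrum_to_jcamp(g$spectrum), path = jdx)
  zipf <- file.path(tempdir(), "irfix.zip")
  zip_store(jdx, zipf)
  d <- read_jcamp(zipf)
  expect_equal(detect_type(d), "IR")
  expect_length(d$data[[1]]$y, length(g$spectrum$y))
})

test_that("the writer refuses documents without a decoded table", {
  d <- parse_jcamp(minimal_jcamp("1.0 1 2 3"))
  d$data <- list()
  expect_error(write_jcamp(d), class = "speckit_unwritable_document")
})
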