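test_that("object measurement implements the summed-intensity ratio", {
  # uniform disk with em1 total 100 and em2 total 200 -> R = 0.5
  lab <- matrix(0L, 32, 32); lab[10:19, 10:19] <- 1L
  em1 <- matrix(0, 32, 32); em1[10:19, 10:19] <- 1
  em2 <- matrix(0, 32, 32); em2[10:19, 10:19] <- 2
  tab <- measure_objects(lab, list(em1 = em1, em2 = em2),
                         low_signal_floor = 0)
  expect_equal(tab$em1, 100)
  expect_equal(tab$em2, 200)
  expect_equal(tab$ratio_em1_em2, 0.5)
  expect_equal(tab$area_px, 100L)
  expect_equal(tab$centroid_row, 14.5)

  # zero em2 signal: ratio undefined, low_signal flagged
  tab0 <- measure_objects(lab, list(em1 = em1, em2 = em2 * 0))
  expect_true(is.na(tab0$ratio_em1_em2))
  expect_true(tab0$low_signal)

  # empty label image: empty table, not an error
  empty <- measure_objects(matrix(0L, 16, 16),
                           list(em1 = matrix(0, 16, 16),
                                em2 = matrix(0, 16, 16)))
  expect_identical(nrow(empty), 0L)

  # saturation is flagged from the raw, pre-correction pixels
  raw1 <- em1; raw1[12, 12] <- 4095
  sat <- measure_objects(lab, list(em1 = em1, em2 = em2),
                         raw = list(em1 = raw1, em2 = em2),
                         low_signal_floor = 0)
  expect_true(sat$saturated)
})

test_that("the em1/em2 ratio is invariant under intensity scaling", {
  set.seed(9)
  r <- render_nucleus(c(32, 32), 5, 4e4, 0.737,
                      matrix(0, 64, 64), matrix(0, 64, 64))
  lab <- matrix(0L, 64, 64); lab[r$em2 > 0] <- 1L
  base <- measure_objects(lab, r, low_signal_floor = 0)$ratio_em1_em2
  for (c_mult in c(0.25, 3, 117)) {
    scaled <- measure_objects(lab, list(em1 = r$em1 * c_mult,
                                        em2 = r$em2 * c_mult),
                              low_signal_floor = 0)$ratio_em1_em2
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("monoculture calibration returns sample mean and n-1 sd", {
  mk <- function(ratios) {
    data.frame(object_id = seq_along(ratios), plate_id = "p",
               well_id = "B02", field_index = 0L, day = 0L,
               centroid_row = 1, centroid_col = 1, area_px = 100L,
               em1 = 1, em2 = 1, ratio_em1_em2 = ratios,
               saturated = FALSE, low_signal = FALSE,
               stringsAsFactors = FALSE)
  }
  cal <- calibrate_line(mk(c(0.5, 0.6, 0.7)), "lineA", min_n = 3)
  expect_equal(cal$mu, 0.6)
  expect_equal(cal$sigma, 0.1)
  expect_identical(cal$n, 3L)

  # flagged objects are excluded before averaging
  t2 <- mk(c(0.5, 0.6, 0.7, 9.9, 9.9))
  t2$saturated[4] <- TRUE; t2$low_signal[5] <- TRUE
  cal2 <- calibrate_line(t2, "lineA", min_n = 3)
  expect_equal(cal2$mu, 0.6)

  expect_error(calibrate_line(mk(c(0.5, 0.6)), "lineA", min_n = 500),
               "shortfall")

  # sampling-distribution oracle at n = 1e4
  set.seed(2024)
  big <- mk(rnorm(1e4, 0.560, 0.025))
  cal3 <- calibrate_line(big, "mCherry", min_n = 500)
  expect_lt(abs(cal3$mu - 0.560), 3 * 0.025 / sqrt(1e4))
  expect_lt(abs(cal3$sigma - 0.025), 3 * 0.025 / sqrt(2e4))
})

test_that("windows are mu +/- k sigma and must be pairwise disjoint", {
  # k = 0.5 arithmetic
  w <- make_windows(data.frame(label = "x", mu = 1.0, sigma = 0.1), k = 0.5)
  expect_equal(c(w$lo, w$hi), c(0.95, 1.05))

  # the three-line panel is disjoint at k = 3 (0.635 < 0.644)
  cal3 <- data.frame(label = c("a", "b"), mu = c(0.560, 0.737),
                     sigma = c(0.025, 0.031))
  w3 <- make_windows(cal3, k = 3)
  expect_lt(w3$hi[1], w3$lo[2])

  # overlap is a construction error naming the pair and the maximal k
  err <- tryCatch(make_windows(cal3, k = 4), error = conditionMessage)
  expect_match(err, "overlap")
  expect_match(err, "largest disjoint k is 3.161")  # 0.177 / 0.056

  # degenerate sigma cannot support windows
  expect_error(make_windows(data.frame(label = "x", mu = 0.7, sigma = 0),
                            k = 3),
               "sigma > 0")

  # user override labels straddling objects ambiguous instead
  wo <- make_windows(cal3, k = 4, allow_overlap = TRUE)
  cls <- classify_ratios(c(0.56, 0.66, 2.0, NA), wo)
  expect_identical(cls, c("a", "ambiguous", "other", "excluded"))
})

test_that("calibration tables round-trip through CSV", {
  cal <- make_windows(data.frame(label = c("a", "b"), mu = c(0.56, 1.07),
                                 sigma = c(0.025, 0.045), n = c(600L, 700L)),
                      k = 3)
  p <- file.path(withr::local_tempdir(), "cal.csv")
  write_calibration(cal, p)
  back <- read_calibration(p)
  expect_s3_class(back, "barcode_calibration")
  expect_equal(back$lo, cal$lo)
  expect_equal(back$hi, cal$hi)
  expect_identical(back$label, cal$label)
})

test_that("objects classify into lines, other, and excluded categories", {
  cal <- make_windows(data.frame(label = c("mCherry2", "mPlum2"),
                                 mu = c(0.5544, 1.0626),
                                 sigma = c(0.0236, 0.0539)), k = 3)
  tab <- data.frame(object_id = 1:4, well_id = "E02", field_index = 0L,
                    day = 0L, area_px = 100L, em1 = 1, em2 = 1,
                    ratio_em1_em2 = c(0.55, 0.80, 1.05, 0.56),
                    saturated = c(FALSE, FALSE, FALSE, TRUE),
                    low_signal = FALSE, stringsAsFactors = FALSE)
  res <- classify_objects(tab, cal)
  expect_identical(res$objects$assignment,
                   c("mCherry2", "other", "mPlum2", "excluded"))
  expect_identical(as.integer(res$counts[c("mCherry2", "mPlum2", "other",
                                           "excluded")]),
                   c(1L, 1L, 1L, 1L))
})

test_that("Gaussian in-window coverage approaches 99.73% at k = 3", {
  set.seed(55)
  cal <- make_windows(data.frame(label = "line", mu = 0.737, sigma = 0.031),
                      k = 3)
  n <- 1e5
  draws <- rnorm(n, 0.737, 0.031)
  inside <- mean(classify_ratios(draws, cal) == "line")
  p <- 2 * pnorm(3) - 1
  expect_lt(abs(inside - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("k = 5 windows of well-separated lines see no cross-assignment", {
  # populations >= 10 pooled sd apart: zero misassignment in 1e6 draws
  set.seed(56)
  cal <- make_windows(data.frame(label = c("lo", "hi"), mu = c(0.5, 1.5),
                                 sigma = c(0.04, 0.04)), k = 5)
  cls <- classify_ratios(rnorm(1e6, 1.5, 0.04), cal)
  expect_identical(sum(cls == "lo"), 0L)
})

test_that("spectral ratio prediction matches quadrature oracles", {
  # flat spectrum through equal-width ideal filters: R = d
  flat <- data.frame(wavelength_nm = 550:750, intensity = 1)
  expect_equal(predict_em_ratio_from_spectrum(flat, detector_factor = 1),
               1.0, tolerance = 1e-12)
  expect_equal(predict_em_ratio_from_spectrum(flat), 0.893,
               tolerance = 1e-12)

  # Gaussian emission curve vs closed-form normal-integral oracle
  grid <- seq(500, 800, by = 0.5)
  gauss <- data.frame(wavelength_nm = grid,
                      intensity = dnorm(grid, 649, 30))
  oracle <- 0.893 * (pnorm(675, 649, 30) - pnorm(635, 649, 30)) /
    (pnorm(648, 649, 30) - pnorm(608, 649, 30))
  got <- predict_em_ratio_from_spectrum(gauss)
  expect_lt(abs(got - oracle) / oracle, 1e-4)

  # spectrum must cover the passbands; empty em2 integral is an error
  narrow <- data.frame(wavelength_nm = 640:660, intensity = 1)
  expect_error(predict_em_ratio_from_spectrum(narrow), "cover")
  zero2 <- data.frame(wavelength_nm = 600:700,
                      intensity = as.numeric(600:700 >= 650))
  expect_error(
    predict_em_ratio_from_spectrum(zero2,
                                   filter_em2 = em_filter(lo = 600,
                                                          hi = 640)),
    "zero")
})

test_that("spectra load from two-column CSV", {
  p <- file.path(withr::local_tempdir(), "spec.csv")
  write.csv(data.frame(wavelength_nm = c(700, 600, 650),
                       intensity = c(0.2, 0.1, 1.0)), p, row.names = FALSE)
  sp <- read_emission_spectrum(p)
  expect_equal(sp$wavelength_nm, c(600, 650, 700))
  write.csv(data.frame(w = 1:3, i = c(-1, 1, 1)), p, row.names = FALSE)
  expect_error(read_emission_spectrum(p), "non-negative")
})

test_that("no-FRET mixture prediction is a bounded weighted mediant", {
  # identical FPs return the homogeneous ratio exactly
  expect_equal(predict_mixture_ratio(0.74, 0.74, 2, 5), 0.74)
  # hand-computed example: (1/3 + 1/2) / (2/3 + 1/2) = 5/7
  expect_equal(predict_mixture_ratio(0.5, 1.0), 5 / 7, tolerance = 1e-12)
  # betweenness and monotonicity toward the heavier FP
  set.seed(77)
  for (i in 1:50) {
    r <- sort(runif(2, 0.2, 2)); w <- runif(2, 0.1, 10)
    mix <- predict_mixture_ratio(r[1], r[2], w[1], w[2])
    expect_gt(mix, r[1]); expect_lt(mix, r[2])
    heavier <- predict_mixture_ratio(r[1], r[2], w[1], w[2] * 2)
    expect_gt(heavier, mix)  # more weight on the larger-ratio FP
  }
})
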