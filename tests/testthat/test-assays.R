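mk_objects <- function(well, day, assignments, yfp = NULL, area = 100L) {
  n <- length(assignments)
  df <- data.frame(object_id = seq_len(n), plate_id = "p", well_id = well,
                   field_index = 0L, day = day, area_px = area,
                   em1 = 1, em2 = 1, ratio_em1_em2 = 0.6,
                   saturated = FALSE, low_signal = FALSE,
                   assignment = assignments, stringsAsFactors = FALSE)
  if (!is.null(yfp)) df$yfp <- yfp * area
  df
}

test_that("per-well counts conserve every object in exactly one category", {
  obj <- mk_objects("B02", 0L, c(rep("A", 3), rep("B", 2), "other",
                                 "excluded"))
  counts <- count_per_well(obj)
  get <- function(line) counts$count[counts$line == line]
  expect_identical(get("A"), 3L)
  expect_identical(get("B"), 2L)
  expect_identical(get("other"), 1L)
  expect_identical(get("excluded"), 1L)
  # line counts + other = total; excluded stays out of the total
  expect_identical(get("total"), get("A") + get("B") + get("other"))

  expect_identical(nrow(count_per_well(obj[0, ])), 0L)
  expect_error(count_per_well(obj[, names(obj) != "assignment"]),
               "classify_objects")
})

test_that("growth folds reproduce the published day-4/day-0 arithmetic", {
  counts <- data.frame(
    well_id = rep(c("B02", "B03"), each = 2),
    day = c(0L, 4L, 0L, 4L),
    line = "total",
    count = c(359L, 638L, 314L, 591L))
  # 638/359 and 591/314 print as 1.78 and 1.88 at two decimals
  expect_equal(round(growth_fold(counts, "B02", "total", 4L), 2), 1.78)
  expect_equal(round(growth_fold(counts, "B03", "total", 4L), 2), 1.88)
  # N4 = N0 gives exactly 1
  same <- data.frame(well_id = "X", day = c(0L, 4L), line = "total",
                     count = c(100L, 100L))
  expect_equal(growth_fold(same, "X", "total", 4L), 1.0)
  # zero baseline is undefined and flagged
  zero <- data.frame(well_id = "X", day = c(0L, 4L), line = "total",
                     count = c(0L, 50L))
  expect_warning(g <- growth_fold(zero, "X", "total", 4L), "zero")
  expect_true(is.na(g))

  gt <- growth_table(counts, "total", day_t = 4L)
  expect_equal(sort(round(gt$fold, 2)), c(1.78, 1.88))
})

test_that("the 3-sd false-negative rule scores against the reference", {
  set.seed(41)
  ref <- rnorm(50, 1000, 50)
  tau <- mean(ref) + 3 * sd(ref)
  expect_equal(growth_false_negative_rate(rep(tau * 2, 10), ref), 0.0)
  expect_equal(growth_false_negative_rate(rep(tau / 2, 10), ref), 1.0)
  mixed <- c(tau - 1, tau + 1, tau + 1, tau - 1)
  expect_equal(growth_false_negative_rate(mixed, ref), 0.5)
  expect_warning(growth_false_negative_rate(1:3, c(5, 5)), "degenerate")
  expect_error(growth_false_negative_rate(1:3, 5), "at least 2")
})

test_that("longitudinal scoring beats cross-well scoring on noisy plating", {
  # day-0 plating Normal(1000, cv 15%); true per-well growth 1.5-fold with
  # 5% multiplicative measurement noise; 1e4 replicate wells
  set.seed(90)
  n <- 1e4
  n0 <- rnorm(n, 1000, 150)
  fold_true <- 1.5
  day4 <- n0 * fold_true * rlnorm(n, 0, 0.05)
  # cross-well (Hoechst-style): day-4 counts against the day-0 population
  fn_cross <- growth_false_negative_rate(day4, n0)
  # longitudinal: per-well day4/day0 folds against no-growth folds (~1)
  null_folds <- rlnorm(n, 0, 0.05)
  fn_long <- growth_false_negative_rate(day4 / n0, null_folds)
  expect_gt(fn_cross, fn_long)
  expect_gt(fn_cross, 0.05)   # cross-well scoring loses real growth wells
  expect_lt(fn_long, 0.001)   # longitudinal scoring essentially never does
})

test_that("z_prime matches its closed form and limits", {
  # constructed samples with mu_p=2, sd_p=0.1, mu_n=1, sd_n=0.1 -> Z'=0.4
  z <- z_prime(c(1.9, 2.0, 2.1), c(0.9, 1.0, 1.1))
  expect_equal(z$z_prime, 0.4)
  expect_equal(z_prime(c(2, 2, 2), c(1, 1, 1))$z_prime, 1.0)
  # closed form: separation 12 sigma with equal sds gives Z' -> 0.5
  set.seed(33)
  sig <- 0.5
  zz <- z_prime(rnorm(5000, 12 * sig, sig), rnorm(5000, 0, sig))
  expect_equal(zz$z_prime, 0.5, tolerance = 0.02)
  expect_error(z_prime(c(1, 1), c(1, 1)), "undefined")
  expect_error(z_prime(1, c(1, 2)), "at least 2")
})

test_that("reporter summaries separate lines and respect missingness", {
  obj <- rbind(mk_objects("E02", 0L, rep(c("A", "B"), each = 5),
                          yfp = rep(c(100, 200), each = 5)),
               mk_objects("E03", 0L, rep(c("A", "B"), each = 5),
                          yfp = rep(c(100, 200), each = 5)))
  lay <- plate_layout(data.frame(well_id = c("E02", "E03"), role = "sample",
                                 mixture = "A|B", treatment = "vehicle",
                                 stringsAsFactors = FALSE))
  s <- nuclear_reporter_summary(obj, lay)
  a <- s$conditions[s$conditions$line == "A", ]
  b <- s$conditions[s$conditions$line == "B", ]
  expect_equal(a$mean, 100); expect_equal(a$sd, 0)
  expect_equal(b$mean, 200); expect_equal(b$sd, 0)
  expect_identical(a$n_fields, 2L)
  # a field with no objects of a line yields no row, never a zero
  obj2 <- mk_objects("E04", 0L, rep("A", 4), yfp = 50)
  s2 <- nuclear_reporter_summary(obj2)
  expect_false("B" %in% s2$fields$line)
})

test_that("reporter contrasts survive demultiplexing in simulation", {
  # one line responds 5x to DHT; the other does not
  ph <- list(
    resp = line_phenotype("resp", 0.56, 0.025,
                          reporter_response = c(vehicle = 40, DHT = 200)),
    flat = line_phenotype("flat", 1.067, 0.045,
                          reporter_response = c(vehicle = 40, DHT = 40)))
  cal <- make_windows(data.frame(label = c("resp", "flat"),
                                 mu = c(0.56, 1.067),
                                 sigma = c(0.026, 0.046)), k = 3)
  cfg <- simulation_config(image_size = c(256, 256), debris_rate = 0)
  ref <- 10 * nucbarcode:::vignette_surface(c(256L, 256L), 0.15)
  objs <- list()
  for (treat in c("vehicle", "DHT")) {
    for (f in 0:3) {
      sim <- simulate_field(ph, c(resp = 15, flat = 15), cfg,
                            seed = 7000 + f + 100 * (treat == "DHT"),
                            well_id = paste0("W_", treat), field_index = f,
                            treatment = treat,
                            channels = c("em1", "em2", "yfp"))
      corrected <- lapply(c(em1 = "em1", em2 = "em2", yfp = "yfp"),
                          function(ch)
                            correct_field(sim$field$channels[[ch]]$pixels,
                                          ref, sim$offsets[[ch]]))
      seg <- segment_nuclei(corrected$em1)
      tab <- measure_objects(seg$labels, corrected,
                             meta = list(plate_id = "p",
                                         well_id = paste0("W_", treat),
                                         field_index = f, day = 0L))
      objs[[paste(treat, f)]] <- classify_objects(tab, cal)$objects
    }
  }
  lay <- plate_layout(data.frame(well_id = c("W_vehicle", "W_DHT"),
                                 role = "sample", mixture = "resp|flat",
                                 treatment = c("vehicle", "DHT"),
                                 stringsAsFactors = FALSE))
  s <- nuclear_reporter_summary(objs, lay)$conditions
  fc <- function(line) {
    s$mean[s$line == line & s$treatment == "DHT"] /
      s$mean[s$line == line & s$treatment == "vehicle"]
  }
  expect_gt(fc("resp"), 3.5)   # 5x contrast within sampling error
  expect_lt(fc("flat"), 1.5)   # no contrast for the unresponsive line
})

test_that("the culture-mode ANOVA flags shifts and not identical modes", {
  set.seed(61)
  treatments <- rep(c("veh", "DHT", "actD", "both"), each = 6)
  base <- rep(c(1.5, 2.5, 0.4, 1.0), each = 6) + rnorm(24, 0, 0.05)
  df <- data.frame(value = c(base, base),
                   treatment = rep(treatments, 2),
                   mode = rep(c("mono", "co"), each = 24))
  same <- coculture_equivalence_test(df)
  expect_lt(same$F, 1e-10)
  expect_gt(same$p_value, 0.99)

  df$value[df$mode == "co"] <- df$value[df$mode == "co"] + 5
  shift <- coculture_equivalence_test(df)
  expect_lt(shift$p_value, 1e-6)

  expect_error(coculture_equivalence_test(
    data.frame(value = 1:4, treatment = "a", mode = c("m", "m", "c", "c"))),
    "two treatments")
})
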