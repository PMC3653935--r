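#' Describe one bar-coded cell line for the simulator
#'
#' A phenotype collects everything the simulator needs to emulate a cell
#' line carrying one FP_NLS_FP marker: its characteristic em1/em2
#' emission-ratio distribution (Gaussian across cells of the line),
#' log-normal expression heterogeneity of the total red signal per
#' nucleus, nuclear YFP reporter responses per treatment, a growth rate
#' (fold-change per day) and nucleus size.
#'
#' @param label cell-line label (e.g. `"mCherry_NLS_mCherry"`).
#' @param ratio_mean,ratio_sd mean and sd of the per-cell em1/em2 ratio.
#' @param brightness_logmean,brightness_logsd log-normal parameters of the
#'   total red signal (em1+em2 summed counts) per nucleus.
#' @param reporter_response named numeric vector, treatment -> mean nuclear
#'   YFP intensity (counts per pixel).
#' @param growth_per_day fold-change in cell number per day (> 0).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius in pixels.
#' @return a `line_phenotype` list.
#' @export
line_phenotype <- function(label, ratio_mean, ratio_sd,
                           brightness_logmean = log(1e5),
                           brightness_logsd = 0.35,
                           reporter_response = c(vehicle = 40),
                           growth_per_day = 1.0,
                           nucleus_radius_mean = 5,
                           nucleus_radius_sd = 0.5) {
  stopifnot(ratio_mean > 0, ratio_sd > 0, growth_per_day > 0,
            nucleus_radius_mean > 0, nucleus_radius_sd >= 0)
  structure(list(label = label, ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 brightness_logmean = brightness_logmean,
                 brightness_logsd = brightness_logsd,
                 reporter_response = reporter_response,
                 growth_per_day = growth_per_day,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd),
            class = "line_phenotype")
}

#' Default three-line bar-code panel
#'
#' Three phenotypes whose em1/em2 ratio distributions match the published
#' monoculture calibrations of the three-line co-culture study
#' (0.560 +/- 0.025, 0.737 +/- 0.031, 1.067 +/- 0.045). Growth rates give
#' slow androgen-sensitive growth (about 1.8-fold over four days for the
#' mCherry line). The mCherry line's reporter responds 5x to DHT.
#'
#' @return named list of [line_phenotype()] objects.
#' @export
default_phenotypes <- function() {
  list(
    mCherry_NLS_mCherry = line_phenotype(
      "mCherry_NLS_mCherry", 0.560, 0.025,
      reporter_response = c(vehicle = 40, DHT = 200),
      growth_per_day = 1.155),
    mRaspberry_NLS_mKate2 = line_phenotype(
      "mRaspberry_NLS_mKate2", 0.737, 0.031,
      reporter_response = c(vehicle = 40, DHT = 60),
      growth_per_day = 1.10),
    mPlum_NLS_mPlum = line_phenotype(
      "mPlum_NLS_mPlum", 1.067, 0.045,
      reporter_response = c(vehicle = 40, DHT = 45),
      growth_per_day = 1.12))
}

#' Simulator configuration
#'
#' @param image_size `c(rows, cols)` of each field.
#' @param vignette_amplitude fractional depth `a` of the radially symmetric
#'   multiplicative illumination bowl `1 - a * r^2 / r_max^2`.
#' @param baseline_background flat background level in counts (camera
#'   offset plus media fluorescence) before vignetting.
#' @param per_well_offset_sd sd (counts) of the additive per-well,
#'   per-day, per-channel background offset; the plate-to-plate regime is
#'   a few counts on the 12-bit scale.
#' @param read_noise_sd Gaussian camera read noise sd in counts.
#' @param shot_noise if `TRUE`, Poisson shot noise is applied to the
#'   expected counts before read noise.
#' @param debris_rate expected number of sub-nuclear debris objects per
#'   field (Poisson).
#' @param saturation_fraction fraction of nuclei forced to contain a
#'   saturated (4095) pixel in em1.
#' @param hoechst_negative_fraction fraction of nuclei rendered without
#'   counterstain signal in the hoechst channel.
#' @param quantize if `TRUE` (default) pixel values are rounded to
#'   integers and clipped at 4095, as a camera would; `FALSE` keeps exact
#'   real-valued fields for noise-free oracle checks.
#' @param max_place_attempts rejection-sampling attempts per nucleus when
#'   placing non-overlapping nuclei.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(image_size = c(256L, 256L),
                              vignette_amplitude = 0.15,
                              baseline_background = 10,
                              per_well_offset_sd = 1.5,
                              read_noise_sd = 2,
                              shot_noise = TRUE,
                              debris_rate = 4,
                              saturation_fraction = 0,
                              hoechst_negative_fraction = 0,
                              quantize = TRUE,
                              max_place_attempts = 200L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            vignette_amplitude >= 0, vignette_amplitude < 1,
            baseline_background >= 0, per_well_offset_sd >= 0,
            read_noise_sd >= 0, debris_rate >= 0,
            saturation_fraction >= 0, saturation_fraction <= 1,
            hoechst_negative_fraction >= 0, hoechst_negative_fraction <= 1,
            max_place_attempts >= 1)
  structure(list(image_size = as.integer(image_size),
                 vignette_amplitude = vignette_amplitude,
                 baseline_background = baseline_background,
                 per_well_offset_sd = per_well_offset_sd,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 debris_rate = debris_rate,
                 saturation_fraction = saturation_fraction,
                 hoechst_negative_fraction = hoechst_negative_fraction,
                 quantize = quantize,
                 max_place_attempts = as.integer(max_place_attempts)),
            class = "simulation_config")
}

# Radially symmetric multiplicative illumination surface.
vignette_surface <- function(dim, amplitude) {
  r0 <- (dim[1] + 1) / 2; c0 <- (dim[2] + 1) / 2
  r2 <- outer((seq_len(dim[1]) - r0)^2, (seq_len(dim[2]) - c0)^2, "+")
  1 - amplitude * r2 / max(r2)
}

# Deterministic per-field sub-seed: any field of a plate simulation is
# reproducible in isolation from (master seed, well, field, day).
field_seed <- function(seed, well_id, field_index = 0L, day = 0L) {
  h <- sum(utf8ToInt(well_id) * seq_along(utf8ToInt(well_id))) +
    131L * field_index + 8191L * day
  as.integer(((abs(seed) %% 100000) * 1000003 + h * 97) %% 2147483647L)
}

# Gaussian blob footprint: isotropic 2-D Gaussian with sigma = radius/2,
# truncated at 3 sigma, weights normalized to sum to 1.
gaussian_blob <- function(center, radius, dim) {
  sigma <- radius / 2
  ext <- ceiling(3 * sigma)
  rows <- max(1L, floor(center[1] - ext)):min(dim[1], ceiling(center[1] + ext))
  cols <- max(1L, floor(center[2] - ext)):min(dim[2], ceiling(center[2] + ext))
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > (3 * sigma)^2] <- 0
  list(rows = rows, cols = cols, w = w / sum(w))
}

#' Render one nucleus onto em1/em2 canvases
#'
#' Adds a smooth Gaussian-profile blob to both canvases such that the
#' added integrals satisfy `added_em1 / added_em2 = ratio` exactly (the
#' noise-free emission split of one FP_NLS_FP-marked nucleus).
#'
#' @param center `c(row, col)` in pixels (must lie inside the canvas).
#' @param radius nucleus radius in pixels; the blob is an isotropic
#'   Gaussian with `sigma = radius/2` truncated at 3 sigma.
#' @param total_signal total red signal (em1 + em2 integral), > 0.
#' @param ratio em1/em2 ratio, > 0.
#' @param em1,em2 numeric matrices (canvases) of identical dimensions.
#' @return `list(em1 =, em2 =)` updated canvases.
#' @export
render_nucleus <- function(center, radius, total_signal, ratio, em1, em2) {
  stopifnot(ratio > 0, total_signal > 0, radius > 0)
  dim <- dim(em1)
  if (!identical(dim, dim(em2))) stop("canvases differ in dimensions")
  if (center[1] < 1 || center[1] > dim[1] ||
      center[2] < 1 || center[2] > dim[2])
    stop("nucleus center lies outside the canvas")
  b <- gaussian_blob(center, radius, dim)
  em1[b$rows, b$cols] <- em1[b$rows, b$cols] +
    total_signal * ratio / (1 + ratio) * b$w
  em2[b$rows, b$cols] <- em2[b$rows, b$cols] +
    total_signal / (1 + ratio) * b$w
  list(em1 = em1, em2 = em2)
}

# Rejection placement of non-overlapping centers. Returns matrix of
# centers or signals an error naming the achievable count.
place_centers <- function(n, radii, dim, existing = NULL,
                          existing_radii = numeric(0), max_attempts = 200L) {
  centers <- matrix(numeric(0), ncol = 2)
  all_r <- existing_radii
  if (!is.null(existing) && nrow(existing)) centers_all <- existing
  else centers_all <- matrix(numeric(0), ncol = 2)
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    margin <- 1.5 * radii[i] + 1
    for (a in seq_len(max_attempts)) {
      cand <- c(runif(1, margin, dim[1] - margin),
                runif(1, margin, dim[2] - margin))
      if (nrow(centers_all)) {
        d <- sqrt((centers_all[, 1] - cand[1])^2 +
                  (centers_all[, 2] - cand[2])^2)
        # fully disjoint 3-sigma footprints: centers >= 1.5*(r_i + r_j)
        if (any(d < 1.5 * (all_r + radii[i]))) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place nucleus ", i, " of ", n, " without overlap ",
           "after ", max_attempts, " attempts; achievable count: ", i - 1L)
    centers_all <- rbind(centers_all, cand)
    all_r <- c(all_r, radii[i])
    placed <- rbind(placed, cand)
  }
  placed
}

#' Simulate one multi-channel field with per-nucleus ground truth
#'
#' Renders nuclei drawn from the per-line phenotype distributions on a
#' vignetted background, optionally adds debris, per-well offsets,
#' Poisson shot noise and Gaussian read noise, then rounds and clips at
#' 4095 (unless `config$quantize` is `FALSE`). The returned ground truth
#' records each nucleus's true line, ratio and signal.
#'
#' @param phenotypes named list of [line_phenotype()] objects.
#' @param counts named integer vector, line label -> number of nuclei.
#' @param config a [simulation_config()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param plate_id,well_id,field_index,day field metadata.
#' @param treatment treatment label (selects the reporter response).
#' @param channels channels to render; any of em1, em2, yfp, hoechst.
#' @param offsets optional named numeric per-channel additive background
#'   offsets (counts); default 0 for every channel.
#' @return list with elements `field` ([field_image_set()]), `truth`
#'   (data.frame: object_id, line, centroid, radius, true ratio/signal,
#'   forced-saturation flag), `truth_labels` (integer matrix labelling
#'   each nucleus's footprint) and `offsets`.
#' @export
simulate_field <- function(phenotypes, counts, config = simulation_config(),
                           seed = 1L, plate_id = "simplate",
                           well_id = "A01", field_index = 0L, day = 0L,
                           treatment = "vehicle",
                           channels = c("em1", "em2"),
                           offsets = NULL) {
  stopifnot(all(counts >= 0), all(names(counts) %in% names(phenotypes)))
  channels <- match.arg(channels, CHANNEL_IDS, several.ok = TRUE)
  if (!all(c("em1", "em2") %in% channels))
    stop("em1 and em2 must both be rendered for bar-code analysis")
  set.seed(seed)
  dim <- config$image_size
  if (is.null(offsets)) offsets <- setNames(numeric(length(channels)), channels)
  offsets <- offsets[channels]
  offsets[is.na(offsets)] <- 0
  names(offsets) <- channels

  canv <- setNames(lapply(channels, function(ch) matrix(0, dim[1], dim[2])),
                   channels)
  truth_labels <- matrix(0L, dim[1], dim[2])

  # draw per-nucleus truth
  lines <- rep(names(counts), times = counts)
  n <- length(lines)
  truth <- data.frame(object_id = seq_len(n), line = lines,
                      centroid_row = rep(NA_real_, n),
                      centroid_col = rep(NA_real_, n),
                      radius_px = rep(NA_real_, n),
                      ratio_true = rep(NA_real_, n),
                      signal_true = rep(NA_real_, n),
                      yfp_true = rep(NA_real_, n),
                      hoechst_positive = rep(TRUE, n),
                      forced_saturated = rep(FALSE, n),
                      stringsAsFactors = FALSE)
  if (n) {
    radii <- numeric(n); ratios <- numeric(n); signals <- numeric(n)
    yfp_amp <- numeric(n)
    for (i in seq_len(n)) {
      ph <- phenotypes[[lines[i]]]
      radii[i] <- max(1.5, rnorm(1, ph$nucleus_radius_mean,
                                 ph$nucleus_radius_sd))
      ratios[i] <- max(0.01, rnorm(1, ph$ratio_mean, ph$ratio_sd))
      signals[i] <- rlnorm(1, ph$brightness_logmean, ph$brightness_logsd)
      resp <- ph$reporter_response
      base <- if (treatment %in% names(resp)) resp[[treatment]]
              else if ("vehicle" %in% names(resp)) resp[["vehicle"]]
              else 0
      yfp_amp[i] <- base * rlnorm(1, 0, 0.25)
    }
    centers <- place_centers(n, radii, dim,
                             max_attempts = config$max_place_attempts)
    if (config$hoechst_negative_fraction > 0)
      truth$hoechst_positive <-
        runif(n) >= config$hoechst_negative_fraction
    for (i in seq_len(n)) {
      r <- render_nucleus(centers[i, ], radii[i], signals[i], ratios[i],
                          canv$em1, canv$em2)
      canv$em1 <- r$em1; canv$em2 <- r$em2
      b <- gaussian_blob(centers[i, ], radii[i], dim)
      truth_labels[b$rows, b$cols][b$w > 0] <- i
      if ("yfp" %in% channels)
        canv$yfp[b$rows, b$cols] <- canv$yfp[b$rows, b$cols] +
          yfp_amp[i] * sum(b$w > 0) * b$w
      if ("hoechst" %in% channels && truth$hoechst_positive[i])
        canv$hoechst[b$rows, b$cols] <- canv$hoechst[b$rows, b$cols] +
          800 * sum(b$w > 0) * b$w
    }
    truth$centroid_row <- centers[, 1]; truth$centroid_col <- centers[, 2]
    truth$radius_px <- radii; truth$ratio_true <- ratios
    truth$signal_true <- signals
    truth$yfp_true <- yfp_amp
  }

  # sub-nuclear debris: small dim blobs of arbitrary em1/em2 ratio
  n_debris <- if (config$debris_rate > 0) rpois(1, config$debris_rate) else 0L
  if (n_debris > 0) {
    mean_r <- mean(vapply(phenotypes, `[[`, numeric(1), "nucleus_radius_mean"))
    d_radii <- runif(n_debris, 1, mean_r / 2)  # <= quarter nucleus area
    d_centers <- tryCatch(
      place_centers(n_debris, d_radii, dim,
                    existing = cbind(truth$centroid_row, truth$centroid_col),
                    existing_radii = truth$radius_px,
                    max_attempts = config$max_place_attempts),
      error = function(e) NULL)
    if (!is.null(d_centers)) {
      for (i in seq_len(nrow(d_centers))) {
        r <- render_nucleus(d_centers[i, ], d_radii[i],
                            runif(1, 40, 250), runif(1, 0.3, 1.5),
                            canv$em1, canv$em2)
        canv$em1 <- r$em1; canv$em2 <- r$em2
      }
    }
  }

  v <- vignette_surface(dim, config$vignette_amplitude)
  out <- vector("list", length(channels)); names(out) <- channels
  for (ch in channels) {
    e <- v * (config$baseline_background + canv[[ch]]) + offsets[[ch]]
    e[e < 0] <- 0
    if (config$shot_noise) e <- matrix(rpois(length(e), e), dim[1], dim[2])
    if (config$read_noise_sd > 0)
      e <- e + matrix(rnorm(length(e), 0, config$read_noise_sd),
                      dim[1], dim[2])
    if (config$quantize) e <- pmin(pmax(round(e), 0), MAX_COUNT)
    else e <- pmin(pmax(e, 0), MAX_COUNT)
    out[[ch]] <- e
  }

  if (n && config$saturation_fraction > 0) {
    n_sat <- floor(n * config$saturation_fraction)
    if (n_sat > 0) {
      idx <- sample.int(n, n_sat)
      for (i in idx) {
        out$em1[round(truth$centroid_row[i]), round(truth$centroid_col[i])] <-
          MAX_COUNT
        truth$forced_saturated[i] <- TRUE
      }
    }
  }

  chans <- setNames(lapply(channels, function(ch)
    channel_image(out[[ch]], ch)), channels)
  list(field = field_image_set(plate_id, well_id, field_index, day, chans),
       truth = truth, truth_labels = truth_labels, offsets = offsets)
}

#' Simulate a longitudinal plate experiment
#'
#' Applies per-line exponential growth (and treatment modifiers) to the
#' per-field counts across imaging days, draws one background offset per
#' (well, day, channel), leaves background wells free of nuclei, and
#' simulates every field of every well via [simulate_field()].
#'
#' Per-line counts on day `d` are `round(n0 * growth^d * modifier)` with
#' the treatment modifier applied only after day 0 (treatments are added
#' at day 0).
#'
#' @param layout a [plate_layout()].
#' @param phenotypes named list of [line_phenotype()] objects; every label
#'   referenced by the layout must be present.
#' @param days sorted integer vector of imaging days; must contain 0.
#' @param n0_per_field baseline day-0 nuclei per line per field in
#'   monoculture wells; mixtures share it (`round(n0/`#lines`)` each).
#' @param fields_per_well number of fields imaged per well.
#' @param treatment_effects nested named list,
#'   `treatment -> line -> growth modifier` (fold applied to counts after
#'   day 0); missing entries default to 1.
#' @param config a [simulation_config()].
#' @param seed master seed; per-field sub-seeds are derived
#'   deterministically so any field is reproducible in isolation.
#' @param channels channels to render.
#' @return list with `fields` (list of [simulate_field()] results),
#'   `truth` (combined ground-truth table with well/field/day columns) and
#'   `offsets` (per well/day/channel draws).
#' @export
simulate_plate_experiment <- function(layout, phenotypes, days = 0L,
                                      n0_per_field = 45L,
                                      fields_per_well = 2L,
                                      treatment_effects = list(),
                                      config = simulation_config(),
                                      seed = 1L,
                                      channels = c("em1", "em2")) {
  days <- as.integer(days)
  if (is.unsorted(days)) stop("'days' must be sorted ascending")
  if (days[1] != 0L) stop("day 0 must be present (baseline counts)")
  labels <- unique(unlist(layout$mixture))
  unknown <- setdiff(labels, names(phenotypes))
  if (length(unknown))
    stop("layout references unknown line label(s): ",
         paste(unknown, collapse = ", "))

  fields <- list(); truth_all <- list(); offsets_all <- list()
  for (w in seq_len(nrow(layout))) {
    well <- layout$well_id[w]
    mix <- layout$mixture[[w]]
    treatment <- layout$treatment[w]
    for (day in days) {
      set.seed(field_seed(seed, well, 997L, day))
      offs <- setNames(rnorm(length(channels), 0, config$per_well_offset_sd),
                       channels)
      offsets_all[[paste(well, day, sep = "_")]] <- offs
      counts <- integer(0)
      if (layout$role[w] == "sample" && length(mix)) {
        n0 <- round(n0_per_field / length(mix))
        counts <- setNames(integer(length(mix)), mix)
        for (ln in mix) {
          g <- phenotypes[[ln]]$growth_per_day
          mod <- 1
          if (day > 0 && treatment %in% names(treatment_effects)) {
            te <- treatment_effects[[treatment]]
            if (ln %in% names(te)) mod <- te[[ln]]
          }
          counts[ln] <- as.integer(round(n0 * g^day * mod))
        }
      }
      for (f in seq_len(fields_per_well) - 1L) {
        sim <- simulate_field(phenotypes, counts, config,
                              seed = field_seed(seed, well, f, day),
                              well_id = well, field_index = f, day = day,
                              treatment = treatment, channels = channels,
                              offsets = offs)
        key <- sprintf("%s_f%d_day%d", well, f, day)
        fields[[key]] <- sim
        if (nrow(sim$truth)) {
          tr <- sim$truth
          tr$well_id <- well; tr$field_index <- f; tr$day <- day
          truth_all[[key]] <- tr
        }
      }
    }
  }
  truth <- if (length(truth_all)) do.call(rbind, truth_all)
           else cbind(simulate_field(phenotypes, integer(0),
                                     simulation_config(debris_rate = 0),
                                     seed = 1L)$truth[0, ],
                      well_id = character(0), field_index = integer(0),
                      day = integer(0))
  rownames(truth) <- NULL
  list(fields = fields, truth = truth, offsets = offsets_all)
}
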