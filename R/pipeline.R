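# ---- run plumbing --------------------------------------------------------

open_run_log <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(out_dir, "run.log")
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
  invisible(msg)
}

write_manifest <- function(out_dir, command, params) {
  manifest <- list(command = command,
                   package = "nucbarcode",
                   version = as.character(utils::packageVersion("nucbarcode")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("'config' must be a YAML path or a list")
}

#' Default synthetic three-line plate configuration
#'
#' One plate carrying the default three-line bar-code panel: four
#' media-only background wells, five monoculture wells per line and
#' three wells co-cultured with all three lines, two fields per well at
#' 256 x 256 px, imaged on day 0. This is the study design the package's
#' own end-to-end checks run on; monoculture wells supply roughly 550
#' usable objects per line for calibration.
#'
#' @param seed master seed.
#' @param days imaging days (must include 0).
#' @return a config list consumable by [run_simulate()].
#' @export
default_simulation_config <- function(seed = 1L, days = 0L) {
  lines <- c("mCherry_NLS_mCherry", "mRaspberry_NLS_mKate2",
             "mPlum_NLS_mPlum")
  layout <- list(
    list(well_id = "A01", role = "background"),
    list(well_id = "A02", role = "background"),
    list(well_id = "P23", role = "background"),
    list(well_id = "P24", role = "background"),
    lapply(sprintf("B%02d", 2:6), function(w)
      list(well_id = w, role = "sample", mixture = lines[1])),
    lapply(sprintf("C%02d", 2:6), function(w)
      list(well_id = w, role = "sample", mixture = lines[2])),
    lapply(sprintf("D%02d", 2:6), function(w)
      list(well_id = w, role = "sample", mixture = lines[3])),
    lapply(sprintf("E%02d", 2:4), function(w)
      list(well_id = w, role = "sample",
           mixture = paste(lines, collapse = "|"))))
  layout <- c(layout[1:4], layout[[5]], layout[[6]], layout[[7]],
              layout[[8]])
  list(seed = seed, days = as.list(as.integer(days)),
       n0_per_field = 55L, fields_per_well = 2L,
       channels = c("em1", "em2", "yfp"),
       image = list(size = c(256L, 256L)),
       layout = layout)
}

config_to_layout <- function(cfg_layout) {
  if (is.character(cfg_layout)) return(load_plate_layout(cfg_layout))
  rows <- lapply(cfg_layout, function(r)
    data.frame(well_id = r$well_id, role = r$role,
               mixture = r$mixture %||% "",
               treatment = r$treatment %||% "",
               concentration = r$concentration %||% "",
               stringsAsFactors = FALSE))
  plate_layout(do.call(rbind, rows))
}

config_to_sim <- function(cfg) {
  img <- cfg$image %||% list()
  simulation_config(
    image_size = unlist(img$size %||% c(224L, 224L)),
    vignette_amplitude = img$vignette_amplitude %||% 0.15,
    baseline_background = img$baseline_background %||% 10,
    per_well_offset_sd = img$per_well_offset_sd %||% 1.5,
    read_noise_sd = img$read_noise_sd %||% 2,
    shot_noise = img$shot_noise %||% TRUE,
    debris_rate = img$debris_rate %||% 4,
    saturation_fraction = img$saturation_fraction %||% 0,
    hoechst_negative_fraction = img$hoechst_negative_fraction %||% 0)
}

config_to_phenotypes <- function(cfg) {
  if (is.null(cfg$lines)) return(default_phenotypes())
  phs <- lapply(cfg$lines, function(l)
    line_phenotype(l$label, l$ratio_mean, l$ratio_sd,
                   brightness_logmean = l$brightness_logmean %||% log(2e4),
                   brightness_logsd = l$brightness_logsd %||% 0.4,
                   reporter_response = unlist(l$reporter_response %||%
                                                list(vehicle = 40)),
                   growth_per_day = l$growth_per_day %||% 1.0,
                   nucleus_radius_mean = l$nucleus_radius_mean %||% 4,
                   nucleus_radius_sd = l$nucleus_radius_sd %||% 0.4))
  setNames(phs, vapply(phs, `[[`, character(1), "label"))
}

field_tiff_paths <- function(image_dir, well, field, day, channels) {
  setNames(file.path(image_dir, sprintf("day%d", day),
                     sprintf("%s_f%d_day%d_%s.tif", well, field, day,
                             channels)),
           channels)
}

# Discover the fields present on disk for one well/day.
discover_fields <- function(image_dir, well, day) {
  dd <- file.path(image_dir, sprintf("day%d", day))
  if (!dir.exists(dd)) return(integer(0))
  fs <- list.files(dd, pattern = sprintf("^%s_f[0-9]+_day%d_em1\\.tif$",
                                         well, day))
  if (!length(fs)) return(integer(0))
  sort(as.integer(sub(sprintf("^%s_f([0-9]+)_day%d_em1\\.tif$", well, day),
                      "\\1", fs)))
}

# ---- commands ------------------------------------------------------------

#' Simulate a plate and write it as an image tree (`simulate` command)
#'
#' Runs [simulate_plate_experiment()] from a config (YAML path or list)
#' and writes: `layout.csv`, `images/day<d>/<well>_f<i>_day<d>_<ch>.tif`,
#' `ground_truth.csv`, `manifest.json` and `run.log`. Output is
#' deterministic for a given seed; a missing seed is auto-generated and
#' logged.
#'
#' @param config YAML file path or config list (see
#'   [default_simulation_config()] for the schema).
#' @param out_dir output directory.
#' @return (invisibly) list with `layout`, `truth` and the paths written.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- read_config(config)
  log <- open_run_log(out_dir)
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(.Machine$integer.max, 1)
    log_line(log, "no seed in config; auto-generated seed ", cfg$seed)
  }
  layout <- config_to_layout(cfg$layout)
  phenotypes <- config_to_phenotypes(cfg)
  sim_cfg <- config_to_sim(cfg)
  days <- as.integer(unlist(cfg$days %||% 0L))
  channels <- unlist(cfg$channels %||% c("em1", "em2"))
  log_line(log, "simulate: ", nrow(layout), " wells, days ",
           paste(days, collapse = ","), ", seed ", cfg$seed)
  plate <- simulate_plate_experiment(
    layout, phenotypes, days = days,
    n0_per_field = cfg$n0_per_field %||% 45L,
    fields_per_well = cfg$fields_per_well %||% 2L,
    treatment_effects = cfg$treatment_effects %||% list(),
    config = sim_cfg, seed = cfg$seed, channels = channels)
  img_dir <- file.path(out_dir, "images")
  for (sim in plate$fields) {
    f <- sim$field
    write_field(f, file.path(img_dir, sprintf("day%d", f$day)))
  }
  write_plate_layout(layout, file.path(out_dir, "layout.csv"))
  write.csv(plate$truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "simulate", cfg)
  log_line(log, "simulate: wrote ", length(plate$fields), " fields, ",
           nrow(plate$truth), " ground-truth nuclei")
  invisible(list(layout = layout, truth = plate$truth,
                 image_dir = img_dir, out_dir = out_dir))
}

# Build per-channel reference backgrounds from the layout's media-only
# wells on one day.
build_plate_references <- function(layout, image_dir, day, channels,
                                   log = NULL) {
  bg_wells <- background_wells(layout)
  if (!length(bg_wells))
    stop("the layout has no background (media-only) wells; ",
         "background correction requires at least one")
  fields <- list()
  for (w in bg_wells) {
    for (f in discover_fields(image_dir, w, day)) {
      paths <- field_tiff_paths(image_dir, w, f, day, channels)
      fields[[length(fields) + 1L]] <-
        load_field(paths, well_id = w, field_index = f, day = day)
    }
  }
  if (!length(fields))
    stop("no images found for background wells ",
         paste(bg_wells, collapse = ", "), " on day ", day,
         "; run the simulate (or acquisition) step first")
  refs <- lapply(setNames(channels, channels), function(ch)
    build_reference_background(fields, ch))
  if (!is.null(log))
    log_line(log, "background reference: averaged ",
             refs[[1]]$n_fields_averaged, " media-only fields per channel")
  refs
}

# Correct, segment and measure one field; returns the object table.
# The offset-estimation mask requires small connected components
# (min_obj_area = 3) so that isolated single-pixel noise excursions do
# not bias the background sample low; genuine objects, even faint
# debris, are spatially coherent and remain masked.
measure_field <- function(field, refs, min_area_px = 40L,
                          min_mean_intensity = 10, noise_sd = 2,
                          dilation_px = 3L, offset_mask_min_area = 3L) {
  channels <- intersect(names(refs), names(field$channels))
  corrected <- list()
  for (ch in channels) {
    raw_m <- field$channels[[ch]]$pixels
    mask <- permissive_mask(raw_m, dilation_px = dilation_px,
                            min_obj_area = offset_mask_min_area)
    delta <- estimate_field_offset(raw_m, refs[[ch]], mask)
    corrected[[ch]] <- correct_field(raw_m, refs[[ch]], delta)
  }
  # never threshold below 6 robust sds of the background noise: when the
  # foreground fraction is small, plain Otsu can split the noise instead
  seg <- segment_nuclei(corrected$em1, min_area_px = min_area_px,
                        min_mean_intensity = min_mean_intensity,
                        threshold_floor = 6 * mad(corrected$em1))
  measure_objects(seg$labels, corrected,
                  raw = lapply(field$channels[intersect(c("em1", "em2"),
                                                        channels)],
                               `[[`, "pixels"),
                  meta = list(plate_id = field$plate_id,
                              well_id = field$well_id,
                              field_index = field$field_index,
                              day = field$day),
                  noise_sd = noise_sd)
}

measure_wells <- function(layout, image_dir, wells, day, channels, refs,
                          ...) {
  tabs <- list()
  for (w in wells) {
    for (f in discover_fields(image_dir, w, day)) {
      paths <- field_tiff_paths(image_dir, w, f, day, channels)
      fld <- load_field(paths, well_id = w, field_index = f, day = day)
      tabs[[sprintf("%s_f%d_day%d", w, f, day)]] <-
        measure_field(fld, refs, ...)
    }
  }
  tabs
}

#' Calibrate per-line windows from monoculture wells (`calibrate` command)
#'
#' Builds reference backgrounds from the layout's media-only wells,
#' measures every monoculture well of every line present in the layout,
#' calibrates each line's em1/em2 mean and sd, constructs the +/- k sd
#' windows (which must be disjoint) and writes the calibration CSV.
#'
#' @param layout plate layout (path or [plate_layout()]).
#' @param image_dir image tree root (as written by [run_simulate()]).
#' @param out_dir output directory for `calibration.csv` and the log.
#' @param k sd multiplier for the windows.
#' @param min_n minimum usable objects per line.
#' @param day imaging day to calibrate from.
#' @param channels channels to load.
#' @return (invisibly) the `barcode_calibration`.
#' @export
run_calibrate <- function(layout, image_dir, out_dir, k = 3, min_n = 500L,
                          day = 0L, channels = c("em1", "em2")) {
  if (is.character(layout)) layout <- load_plate_layout(layout)
  log <- open_run_log(out_dir)
  refs <- build_plate_references(layout, image_dir, day, channels, log)
  lines <- unique(unlist(layout$mixture))
  cals <- list()
  for (ln in lines) {
    wells <- monoculture_wells(layout, ln)
    if (!length(wells)) next
    tabs <- measure_wells(layout, image_dir, wells, day, channels, refs)
    tab <- do.call(rbind, tabs)
    log_line(log, "calibrate ", ln, ": ", nrow(tab), " objects segmented, ",
             sum(tab$saturated), " saturated, ", sum(tab$low_signal),
             " low-signal")
    cals[[ln]] <- calibrate_line(tab, ln, min_n = min_n)
  }
  if (!length(cals))
    stop("the layout contains no monoculture wells; calibration needs ",
         "wells carrying a single line")
  cal <- make_windows(do.call(rbind, cals), k = k)
  path <- file.path(out_dir, "calibration.csv")
  write_calibration(cal, path)
  write_manifest(out_dir, "calibrate",
                 list(k = k, min_n = min_n, day = day, lines = lines))
  log_line(log, "calibrate: wrote ", nrow(cal), " disjoint windows to ",
           path)
  invisible(cal)
}

#' Demultiplex sample wells against a calibration (`demux` command)
#'
#' Measures every sample well, classifies each object by its em1/em2
#' ratio, and writes `objects.csv` (per-nucleus records with
#' assignments), `counts.csv` (per well/day/line tallies) and the
#' accounting log (segmented, excluded, assigned, other).
#'
#' @param layout plate layout (path or object).
#' @param image_dir image tree root.
#' @param calibration calibration CSV path or `barcode_calibration`.
#' @param out_dir output directory.
#' @param days days to process (default: every day directory found).
#' @param channels channels to load and measure.
#' @return (invisibly) list with `objects`, `counts`.
#' @export
run_demux <- function(layout, image_dir, calibration, out_dir,
                      days = NULL, channels = c("em1", "em2")) {
  if (is.character(layout)) layout <- load_plate_layout(layout)
  if (is.character(calibration)) {
    if (!file.exists(calibration))
      stop("calibration file not found: ", calibration,
           "; run the calibrate command first")
    calibration <- read_calibration(calibration)
  }
  log <- open_run_log(out_dir)
  if (is.null(days)) {
    dd <- list.dirs(image_dir, recursive = FALSE, full.names = FALSE)
    days <- sort(as.integer(sub("^day", "", grep("^day[0-9]+$", dd,
                                                 value = TRUE))))
  }
  if (!length(days)) stop("no day directories found under ", image_dir,
                          "; run the simulate step first")
  all_objects <- list(); deltas <- list()
  for (day in days) {
    refs <- build_plate_references(layout, image_dir, day, channels, log)
    wells <- layout$well_id[layout$role == "sample"]
    tabs <- measure_wells(layout, image_dir, wells, day, channels, refs)
    for (key in names(tabs)) {
      cls <- classify_objects(tabs[[key]], calibration)
      all_objects[[key]] <- cls$objects
    }
  }
  objects <- do.call(rbind, all_objects)
  rownames(objects) <- NULL
  counts <- count_per_well(objects)
  n_seg <- nrow(objects)
  n_exc <- sum(objects$assignment == "excluded")
  n_oth <- sum(objects$assignment == "other")
  n_asn <- n_seg - n_exc - n_oth
  log_line(log, sprintf(
    "demux: %d objects segmented -> %d excluded (%.2f%%) -> %d assigned -> %d other/debris (%.2f%%)",
    n_seg, n_exc, 100 * n_exc / max(1, n_seg), n_asn, n_oth,
    100 * n_oth / max(1, n_seg)))
  write_object_table(objects, file.path(out_dir, "objects.csv"))
  write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  write_manifest(out_dir, "demux",
                 list(days = days, k = calibration$k[1],
                      lines = calibration$label))
  invisible(list(objects = objects, counts = counts))
}

#' Longitudinal growth, false-negative and Z' reports (`growth` command)
#'
#' From a per-well count table covering at least two days, computes the
#' per-well day-t/day-0 growth folds for each line, a false-negative
#' report (3-sd rule against the chosen reference) and, when a positive
#' and negative treatment are named, the Z'-factor between them.
#'
#' @param counts count table (CSV path or [count_per_well()] data.frame).
#' @param out_dir output directory.
#' @param day_t later day (default: the largest day present).
#' @param day_ref baseline day (default 0).
#' @param layout optional layout for treatment lookup (needed for the
#'   Z' report and the `day_t_vehicle` reference).
#' @param reference false-negative reference: `"day_ref"` (the baseline
#'   count distribution) or `"day_t_vehicle"` (the later-day counts of
#'   vehicle-treated wells).
#' @param pos_treatment,neg_treatment optional treatment labels whose
#'   per-well folds define the Z' positive/negative controls.
#' @return (invisibly) list with `growth`, `false_negative`, `z_prime`.
#' @export
run_growth <- function(counts, out_dir, day_t = NULL, day_ref = 0L,
                       layout = NULL, reference = c("day_ref",
                                                    "day_t_vehicle"),
                       pos_treatment = NULL, neg_treatment = NULL) {
  reference <- match.arg(reference)
  if (is.character(counts)) {
    if (!file.exists(counts))
      stop("count table not found: ", counts,
           "; run the demux command first")
    counts <- read.csv(counts, stringsAsFactors = FALSE)
  }
  if (is.character(layout)) layout <- load_plate_layout(layout)
  log <- open_run_log(out_dir)
  days <- sort(unique(counts$day))
  if (length(days) < 2L)
    stop("growth analysis needs counts from at least two days; got day ",
         paste(days, collapse = ", "))
  if (is.null(day_t)) day_t <- max(days)
  lines <- setdiff(unique(counts$line), c("other", "excluded"))
  growth <- do.call(rbind, lapply(lines, function(ln)
    growth_table(counts, ln, day_t = day_t, day_ref = day_ref)))
  growth <- growth[!is.na(growth$n_t), , drop = FALSE]
  write.csv(growth, file.path(out_dir, "growth.csv"), row.names = FALSE)

  fn <- NULL
  g_tot <- growth[growth$line == "total" & !is.na(growth$fold), ]
  if (nrow(g_tot) >= 2L) {
    if (reference == "day_ref") {
      ref_vals <- counts$count[counts$line == "total" &
                                 counts$day == day_ref]
      vals <- counts$count[counts$line == "total" & counts$day == day_t]
    } else {
      if (is.null(layout)) stop("'day_t_vehicle' reference needs a layout")
      veh <- layout$well_id[layout$treatment %in% c("", "vehicle")]
      ref_vals <- counts$count[counts$line == "total" &
                                 counts$day == day_t &
                                 counts$well_id %in% veh]
      vals <- counts$count[counts$line == "total" & counts$day == day_t &
                             !counts$well_id %in% veh]
    }
    if (length(ref_vals) >= 2L && length(vals)) {
      fn <- growth_false_negative_rate(vals, ref_vals)
      log_line(log, sprintf(
        "growth: cross-well false-negative fraction %.3f (reference %s)",
        fn, reference))
    }
  }

  zp <- NULL
  if (!is.null(pos_treatment) && !is.null(neg_treatment)) {
    if (is.null(layout)) stop("Z' report needs a layout for treatments")
    g_tot2 <- growth[growth$line == "total", ]
    tr <- layout$treatment[match(g_tot2$well_id, layout$well_id)]
    pos <- g_tot2$fold[tr == pos_treatment]
    neg <- g_tot2$fold[tr == neg_treatment]
    if (length(pos) >= 2L && length(neg) >= 2L) {
      zp <- z_prime(pos, neg)
      log_line(log, sprintf("growth: Z' = %.3f (%s vs %s)", zp$z_prime,
                            pos_treatment, neg_treatment))
    }
  }
  report <- list(day_t = day_t, day_ref = day_ref,
                 false_negative_fraction = fn,
                 z_prime = if (!is.null(zp)) zp$z_prime else NULL)
  jsonlite::write_json(report, file.path(out_dir, "growth_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_manifest(out_dir, "growth", report)
  invisible(list(growth = growth, false_negative = fn, z_prime = zp))
}
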