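# Shared fixtures, all built in code at test time.

# Flat image with hard disks of a given value (for segmentation tests).
disk_image <- function(centers, radius, value = 1000, dim = c(96L, 96L),
                       background = 0) {
  m <- matrix(background, dim[1], dim[2])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(dim[1])) {
      d2 <- (i - centers[k, 1])^2 + (seq_len(dim[2]) - centers[k, 2])^2
      m[i, d2 <= radius^2] <- value
    }
  }
  m
}

# Media-only fields for reference-background construction.
media_fields <- function(n, config = simulation_config(debris_rate = 0),
                         seed0 = 9000L) {
  lapply(seq_len(n), function(i)
    simulate_field(default_phenotypes(), integer(0), config,
                   seed = seed0 + i, well_id = "A01")$field)
}

# Match measured objects to ground-truth nuclei by nearest centroid.
# Returns the true line label per object, or NA when unmatched.
match_truth <- function(objects, truth, max_dist = 4) {
  vapply(seq_len(nrow(objects)), function(i) {
    tr <- truth
    if ("well_id" %in% names(truth))
      tr <- truth[truth$well_id == objects$well_id[i] &
                    truth$field_index == objects$field_index[i] &
                    truth$day == objects$day[i], , drop = FALSE]
    if (!nrow(tr)) return(NA_character_)
    d <- sqrt((tr$centroid_row - objects$centroid_row[i])^2 +
                (tr$centroid_col - objects$centroid_col[i])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) tr$line[j] else NA_character_
  }, character(1))
}

# The default synthetic three-line plate, simulated, calibrated and
# demultiplexed once per test session (several files assert against it).
.plate_cache <- new.env(parent = emptyenv())
default_plate_run <- function() {
  if (!is.null(.plate_cache$run)) return(.plate_cache$run)
  out <- file.path(tempdir(), "nucbarcode-default-plate")
  suppressMessages({
    sim <- run_simulate(default_simulation_config(seed = 1L), out)
    cal <- run_calibrate(file.path(out, "layout.csv"), sim$image_dir,
                         file.path(out, "cal"), k = 3, min_n = 500L)
    dmx <- run_demux(file.path(out, "layout.csv"), sim$image_dir,
                     file.path(out, "cal", "calibration.csv"),
                     file.path(out, "demux"))
  })
  .plate_cache$run <- list(out = out, sim = sim, cal = cal, dmx = dmx)
  .plate_cache$run
}
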