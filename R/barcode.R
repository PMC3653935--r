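#' Measure segmented nuclei in corrected channel grids
#'
#' For every labelled object, records the area, centroid and the summed
#' background-corrected intensity in each channel, and computes the
#' bar-code ratio `R = sum(em1) / sum(em2)`. The ratio is emitted only
#' when the em2 sum exceeds the low-signal floor (by default `low_signal_k`
#' times the expected noise sd of the object sum, `noise_sd * sqrt(area)`);
#' otherwise the object carries the `low_signal` flag and an undefined
#' ratio, because a near-zero em2 denominator makes the ratio unreliable.
#' The `saturated` flag is set from the raw (pre-correction) em1/em2
#' images whenever a member pixel equals 4095.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param corrected named list of corrected real-valued grids (must
#'   contain `em1` and `em2`; may contain `yfp`, `hoechst`).
#' @param raw optional named list of raw grids (`em1`, `em2`) for
#'   saturation flagging.
#' @param meta list of provenance fields `plate_id`, `well_id`,
#'   `field_index`, `day`.
#' @param noise_sd per-pixel noise sd (counts) used by the default
#'   low-signal floor.
#' @param low_signal_k floor multiplier (default 5).
#' @param low_signal_floor optional constant floor overriding the
#'   area-scaled default.
#' @return object-table `data.frame`, one row per object (empty when the
#'   label image holds no objects).
#' @export
measure_objects <- function(labels, corrected, raw = NULL,
                            meta = list(plate_id = "plate1", well_id = "A01",
                                        field_index = 0L, day = 0L),
                            noise_sd = 2, low_signal_k = 5,
                            low_signal_floor = NULL) {
  if (!all(c("em1", "em2") %in% names(corrected)))
    stop("'corrected' must contain em1 and em2 grids")
  chans <- names(corrected)
  for (ch in chans)
    if (!identical(dim(as_pixel_matrix(corrected[[ch]])), dim(labels)))
      stop("channel '", ch, "' and label image differ in dimensions")
  n <- max(labels)
  if (n == 0L) {
    tab <- empty_object_table(chans)
    tab$plate_id <- character(0)
    return(tab)
  }
  idx <- which(labels > 0)
  l <- labels[idx]
  ulab <- sort(unique(l))
  area <- tabulate(l, n)[ulab]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  tab <- data.frame(object_id = ulab,
                    plate_id = meta$plate_id %||% "plate1",
                    well_id = meta$well_id %||% "A01",
                    field_index = as.integer(meta$field_index %||% 0L),
                    day = as.integer(meta$day %||% 0L),
                    centroid_row = as.numeric(rowsum(rows, l)[, 1]) / area,
                    centroid_col = as.numeric(rowsum(cols, l)[, 1]) / area,
                    area_px = as.integer(area),
                    stringsAsFactors = FALSE)
  for (ch in chans) {
    m <- as_pixel_matrix(corrected[[ch]])
    tab[[ch]] <- as.numeric(rowsum(m[idx], l)[, 1])
  }
  floor_i <- if (!is.null(low_signal_floor)) rep(low_signal_floor, nrow(tab))
             else low_signal_k * noise_sd * sqrt(tab$area_px)
  tab$ratio_em1_em2 <- ifelse(tab$em2 > floor_i, tab$em1 / tab$em2, NA_real_)
  tab$saturated <- FALSE
  if (!is.null(raw)) {
    for (ch in intersect(c("em1", "em2"), names(raw))) {
      r <- as_pixel_matrix(raw[[ch]])
      sat_max <- as.numeric(tapply(r[idx], l, max))  # sorted-unique order
      tab$saturated <- tab$saturated | (sat_max >= MAX_COUNT)
    }
  }
  tab$low_signal <- !(tab$em2 > floor_i)
  rownames(tab) <- NULL
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate one cell line's em1/em2 ratio from monoculture tables
#'
#' Pools the ratios of all unflagged objects measured in wells containing
#' only this line and returns the sample mean, sample sd (n-1
#' denominator) and the number of objects used. Saturated and low-signal
#' objects are excluded before averaging.
#'
#' @param tables an object table or list of object tables from
#'   monoculture wells of this line.
#' @param label the line label.
#' @param min_n minimum number of usable objects (default 500).
#' @return one-row `data.frame` with `label`, `mu`, `sigma`, `n`.
#' @export
calibrate_line <- function(tables, label, min_n = 500L) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  keep <- !tab$saturated & !tab$low_signal & !is.na(tab$ratio_em1_em2)
  ratios <- tab$ratio_em1_em2[keep]
  if (length(ratios) < min_n)
    stop("calibration of '", label, "' has only ", length(ratios),
         " usable objects; ", min_n, " required (shortfall of ",
         min_n - length(ratios), ")")
  data.frame(label = label, mu = mean(ratios), sigma = sd(ratios),
             n = length(ratios), stringsAsFactors = FALSE)
}

#' Build per-line classification windows `[mu - k*sigma, mu + k*sigma]`
#'
#' Windows of different lines must be pairwise disjoint; otherwise
#' construction fails and the error reports the offending pair together
#' with the largest `k` that would keep all windows disjoint. Users who
#' deliberately override the disjointness check obtain overlapping
#' windows, and objects falling in more than one window are classified
#' `ambiguous`.
#'
#' @param calibrations data.frame from [calibrate_line()] rows (columns
#'   `label`, `mu`, `sigma`, optionally `n`).
#' @param k sd multiplier (> 0); 3 for the three-line panel, 5 in the
#'   two-line study.
#' @param allow_overlap override the disjointness requirement.
#' @return `barcode_calibration` data.frame with columns `label, mu,
#'   sigma, n, k, lo, hi`.
#' @export
make_windows <- function(calibrations, k = 3, allow_overlap = FALSE) {
  stopifnot(is.data.frame(calibrations), k > 0)
  if (any(calibrations$sigma <= 0))
    stop("window construction requires sigma > 0 for every line")
  cal <- calibrations
  if (!"n" %in% names(cal)) cal$n <- NA_integer_
  cal$k <- k
  cal$lo <- cal$mu - k * cal$sigma
  cal$hi <- cal$mu + k * cal$sigma
  if (nrow(cal) > 1L) {
    o <- order(cal$mu)
    s <- cal[o, ]
    for (i in seq_len(nrow(s) - 1L)) {
      if (s$hi[i] >= s$lo[i + 1L]) {
        pair_k <- abs(outer(cal$mu, cal$mu, "-")) /
          outer(cal$sigma, cal$sigma, "+")
        diag(pair_k) <- Inf
        k_max <- min(pair_k)
        if (!allow_overlap)
          stop(sprintf(paste0(
            "windows for '%s' and '%s' overlap at k = %g ",
            "([%.4f, %.4f] vs [%.4f, %.4f]); the largest disjoint k is %.3f"),
            s$label[i], s$label[i + 1L], k, s$lo[i], s$hi[i],
            s$lo[i + 1L], s$hi[i + 1L], k_max))
      }
    }
  }
  class(cal) <- c("barcode_calibration", "data.frame")
  cal
}

#' Classify em1/em2 ratios against calibration windows
#'
#' @param ratios numeric vector (NA allowed).
#' @param calibration a [make_windows()] result.
#' @return character vector: the owning line's label, `"other"` when the
#'   ratio falls in no window, `"ambiguous"` when it falls in several
#'   (only possible with overlapping windows), `"excluded"` for NA.
#' @export
classify_ratios <- function(ratios, calibration) {
  stopifnot(inherits(calibration, "barcode_calibration"))
  out <- rep("other", length(ratios))
  hits <- matrix(FALSE, length(ratios), nrow(calibration))
  for (j in seq_len(nrow(calibration)))
    hits[, j] <- !is.na(ratios) & ratios >= calibration$lo[j] &
      ratios <= calibration$hi[j]
  nh <- rowSums(hits)
  one <- which(nh == 1L)
  if (length(one))
    out[one] <- calibration$label[apply(hits[one, , drop = FALSE], 1, which)]
  out[nh > 1L] <- "ambiguous"
  out[is.na(ratios)] <- "excluded"
  out
}

#' Assign measured objects to bar-coded cell lines
#'
#' Saturated and low-signal objects are excluded outright (their em1/em2
#' characterization is unreliable); the remaining objects are assigned to
#' the line whose window contains their ratio, or to `"other"` (debris)
#' when no window does.
#'
#' @param table object table from [measure_objects()].
#' @param calibration a [make_windows()] result.
#' @return list with `objects` (the table plus an `assignment` column)
#'   and `counts` (named tally over lines, other, ambiguous, excluded).
#' @export
classify_objects <- function(table, calibration) {
  assignment <- classify_ratios(table$ratio_em1_em2, calibration)
  assignment[table$saturated | table$low_signal] <- "excluded"
  table$assignment <- assignment
  cats <- c(calibration$label, "other", "ambiguous", "excluded")
  counts <- setNames(integer(length(cats)), cats)
  tl <- table(assignment)
  counts[names(tl)] <- as.integer(tl)
  list(objects = table, counts = counts)
}

#' Persist a calibration as CSV (`label, mu, sigma, n, k, lo, hi`)
#' @param calibration a `barcode_calibration`.
#' @param path output CSV path.
#' @export
write_calibration <- function(calibration, path) {
  write.csv(as.data.frame(calibration)[, c("label", "mu", "sigma", "n",
                                           "k", "lo", "hi")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration CSV written by [write_calibration()]
#' @param path CSV path.
#' @return a `barcode_calibration` data.frame.
#' @export
read_calibration <- function(path) {
  cal <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mu", "sigma", "k", "lo", "hi")
  miss <- setdiff(need, names(cal))
  if (length(miss)) stop("calibration file missing columns: ",
                         paste(miss, collapse = ", "))
  class(cal) <- c("barcode_calibration", "data.frame")
  cal
}

# ---- spectral prediction -------------------------------------------------

#' Emission passband filter
#'
#' Either a named instrument preset (`"em1"` = 635--675 nm, `"em2"` =
#' 608--648 nm, ideal top-hats) or an explicit band or tabulated
#' transmission curve.
#'
#' @param name preset name, or `NULL` when `lo`/`hi` or `table` is given.
#' @param lo,hi top-hat passband edges in nm.
#' @param table data.frame `wavelength_nm`, `transmission` for a measured
#'   filter curve (linearly interpolated, 0 outside its support).
#' @return an `em_filter` object.
#' @export
em_filter <- function(name = NULL, lo = NULL, hi = NULL, table = NULL) {
  if (!is.null(name)) {
    name <- match.arg(name, c("em1", "em2"))
    band <- switch(name, em1 = c(635, 675), em2 = c(608, 648))
    lo <- band[1]; hi <- band[2]
  }
  if (!is.null(table)) {
    stopifnot(all(c("wavelength_nm", "transmission") %in% names(table)))
    return(structure(list(type = "table", table = table),
                     class = "em_filter"))
  }
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(type = "tophat", lo = lo, hi = hi), class = "em_filter")
}

filter_transmission <- function(filter, wavelengths) {
  if (filter$type == "tophat")
    as.numeric(wavelengths >= filter$lo & wavelengths <= filter$hi)
  else
    approx(filter$table$wavelength_nm, filter$table$transmission,
           xout = wavelengths, yleft = 0, yright = 0)$y
}

# Trapezoid integral of spectrum * transmission. For a top-hat filter the
# integration range is clipped exactly at the band edges (interpolated
# endpoints inserted), so the passband edges carry no O(grid-step) error.
passband_integral <- function(w, s, filter) {
  if (filter$type == "tophat") {
    inside <- w > filter$lo & w < filter$hi
    ww <- c(filter$lo, w[inside], filter$hi)
    ss <- c(approx(w, s, filter$lo)$y, s[inside], approx(w, s, filter$hi)$y)
    pracma::trapz(ww, ss)
  } else {
    pracma::trapz(w, s * filter_transmission(filter, w))
  }
}

filter_range <- function(filter) {
  if (filter$type == "tophat") c(filter$lo, filter$hi)
  else range(filter$table$wavelength_nm)
}

#' Read a two-column emission spectrum CSV
#'
#' @param path CSV with columns `wavelength_nm` and `intensity` (relative
#'   units; any second-column name is accepted).
#' @return data.frame `wavelength_nm`, `intensity`, sorted by wavelength.
#' @export
read_emission_spectrum <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("spectrum file needs two columns: wavelength, intensity")
  names(df)[1:2] <- c("wavelength_nm", "intensity")
  if (any(df$intensity < 0)) stop("emission spectrum must be non-negative")
  df[order(df$wavelength_nm), 1:2]
}

#' Predict the theoretical em1/em2 ratio of one FP from its spectrum
#'
#' Integrates the emission spectrum over both passbands (trapezoid rule
#' on the provided wavelength grid) and applies the detector-efficiency
#' factor for em1 relative to em2:
#' `R = d * integral(S*T_em1) / integral(S*T_em2)`. The default detector
#' factor 0.893 reflects an instrument whose optics/camera detect em1
#' emissions at 89.3\% the efficiency of em2.
#'
#' @param spectrum data.frame `wavelength_nm`, `intensity` covering both
#'   passbands.
#' @param filter_em1,filter_em2 [em_filter()] objects.
#' @param detector_factor em1-vs-em2 detection efficiency `d` (> 0).
#' @return the predicted ratio.
#' @export
predict_em_ratio_from_spectrum <- function(spectrum,
                                           filter_em1 = em_filter("em1"),
                                           filter_em2 = em_filter("em2"),
                                           detector_factor = 0.893) {
  stopifnot(detector_factor > 0)
  w <- spectrum$wavelength_nm
  s <- spectrum$intensity
  if (any(s < 0)) stop("emission spectrum must be non-negative")
  for (f in list(filter_em1, filter_em2)) {
    rng <- filter_range(f)
    if (min(w) > rng[1] || max(w) < rng[2])
      stop("spectrum does not cover the passband [", rng[1], ", ", rng[2],
           "] nm")
  }
  num <- passband_integral(w, s, filter_em1)
  den <- passband_integral(w, s, filter_em2)
  if (den <= 0) stop("em2 passband integral is zero; cannot form a ratio")
  detector_factor * num / den
}

#' Predict the no-FRET em1/em2 ratio of a two-FP fusion marker
#'
#' For a marker fusing FP-N and FP-C, each contributing weight
#' `w_i = excitation_efficiency_i * brightness_i` and homogeneous ratio
#' `R_i`, the expected ratio assuming no energy transfer between the FPs
#' is the brightness-weighted combination of their channel emissions:
#' `e_i_em1 = w_i * R_i / (1 + R_i)`, `e_i_em2 = w_i / (1 + R_i)`,
#' `R = (e_N_em1 + e_C_em1) / (e_N_em2 + e_C_em2)`.
#'
#' @param r_n,r_c homogeneous em1/em2 ratios of the two FPs (> 0).
#' @param w_n,w_c excitation-weighted brightness weights (> 0); only
#'   their relative magnitude matters. Excitation efficiencies default to
#'   1 (they cancel for homogeneous markers and only reweight mixtures).
#' @return predicted em1/em2 ratio; always strictly between
#'   `min(r_n, r_c)` and `max(r_n, r_c)` for distinct inputs.
#' @export
predict_mixture_ratio <- function(r_n, r_c, w_n = 1, w_c = 1) {
  stopifnot(r_n > 0, r_c > 0, w_n > 0, w_c > 0)
  e1 <- w_n * r_n / (1 + r_n) + w_c * r_c / (1 + r_c)
  e2 <- w_n / (1 + r_n) + w_c / (1 + r_c)
  e1 / e2
}
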