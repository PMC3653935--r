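#' @importFrom EBImage bwlabel fillHull distmap watershed dilate otsu Image
NULL

# Exact Euclidean disk structuring element of radius r.
disk_kernel <- function(r) {
  off <- -r:r
  outer(off, off, function(a, b) as.numeric(sqrt(a^2 + b^2) <= r))
}

# Otsu threshold computed in a log-compressed domain. Fluorescent nuclei
# span more than a decade of expression, so on the linear scale Otsu
# lands between dim and bright nuclei instead of between background and
# foreground; log compression restores a two-class histogram. Intensities
# are first normalized by the robust background scale (MAD), which makes
# the resulting mask exactly invariant under multiplication by c > 0.
otsu_threshold <- function(m) {
  scale <- mad(m)
  if (scale <= 0) scale <- 1
  v <- log1p(pmax(m, 0) / scale)
  rng <- range(v)
  if (diff(rng) == 0) return(Inf)  # constant image: nothing to segment
  norm <- (v - rng[1]) / diff(rng)
  t_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  expm1(rng[1] + t_norm * diff(rng)) * scale
}

#' Segment nuclei in a corrected em1 image (stringent mode)
#'
#' Thresholds the background-corrected em1 image (Otsu in a
#' log-compressed domain, robust to the wide per-cell expression range,
#' with an optional absolute floor), fills holes (nucleoli are
#' dimmer than the surrounding nucleoplasm and must not fragment
#' objects), labels connected regions, optionally splits touching nuclei
#' by distance-transform watershed, and discards objects below the area
#' or mean-intensity floors.
#'
#' @param image background-corrected em1 grid ([channel_image()] or
#'   numeric matrix).
#' @param min_area_px minimum object area in pixels (> 0).
#' @param min_mean_intensity minimum mean corrected intensity of an
#'   object, in counts above background (> 0).
#' @param split_touching if `TRUE`, touching blobs are split by watershed
#'   on the distance transform.
#' @param threshold_floor optional absolute lower bound for the Otsu
#'   threshold (counts).
#' @return list with `labels` (integer matrix, background 0, labels
#'   `1..n` consecutive) and `objects` (data.frame: label, area_px,
#'   centroid_row, centroid_col, mean_intensity).
#' @export
segment_nuclei <- function(image, min_area_px = 40L, min_mean_intensity = 10,
                           split_touching = TRUE, threshold_floor = 0) {
  m <- as_pixel_matrix(image)
  if (min_area_px <= 0) stop("'min_area_px' must be positive")
  if (min_mean_intensity <= 0) stop("'min_mean_intensity' must be positive")
  thr <- max(otsu_threshold(m), threshold_floor)
  mask <- m > thr
  if (!any(mask))
    return(list(labels = matrix(0L, nrow(m), ncol(m)),
                objects = data.frame(label = integer(0), area_px = integer(0),
                                     centroid_row = numeric(0),
                                     centroid_col = numeric(0),
                                     mean_intensity = numeric(0))))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
  relabel_filtered(lab, m, min_area_px, min_mean_intensity)
}

# Drop labels failing area/intensity floors and relabel consecutively.
relabel_filtered <- function(lab, m, min_area_px, min_mean_intensity) {
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab,
                objects = data.frame(label = integer(0), area_px = integer(0),
                                     centroid_row = numeric(0),
                                     centroid_col = numeric(0),
                                     mean_intensity = numeric(0))))
  idx <- which(lab > 0)
  l <- lab[idx]
  area <- tabulate(l, n)
  # rowsum orders by sorted unique labels; align into full-length vectors
  mi <- rep(NA_real_, n)
  mi[sort(unique(l))] <- as.numeric(rowsum(m[idx], l)[, 1]) /
    area[sort(unique(l))]
  keep <- which(area >= min_area_px & !is.na(mi) & mi >= min_mean_intensity)
  if (!length(keep))
    return(list(labels = matrix(0L, nrow(m), ncol(m)),
                objects = data.frame(label = integer(0), area_px = integer(0),
                                     centroid_row = numeric(0),
                                     centroid_col = numeric(0),
                                     mean_intensity = numeric(0))))
  map <- integer(n)
  map[keep] <- seq_along(keep)
  new_lab <- matrix(0L, nrow(m), ncol(m))
  new_lab[idx] <- map[l]
  rows <- ((idx - 1) %% nrow(m)) + 1
  cols <- ((idx - 1) %/% nrow(m)) + 1
  keep_mask <- map[l] > 0
  nl <- map[l][keep_mask]
  objects <- data.frame(
    label = seq_along(keep),
    area_px = as.integer(area[keep]),
    centroid_row = as.numeric(rowsum(rows[keep_mask], nl)[, 1]) /
      tabulate(nl, length(keep)),
    centroid_col = as.numeric(rowsum(cols[keep_mask], nl)[, 1]) /
      tabulate(nl, length(keep)),
    mean_intensity = mi[keep])
  list(labels = new_lab, objects = objects)
}

#' All-object mask for background estimation (permissive mode)
#'
#' Detects every fluorescent object, however small or faint, by a low
#' robust threshold (background median + `k_mad` robust sd, via MAD),
#' then dilates by `dilation_px` using an exact Euclidean disk so that
#' faint object fringes are excluded from background sampling. `TRUE`
#' means "excluded from background estimation".
#'
#' @param image raw or reference-subtracted grid.
#' @param dilation_px non-negative dilation radius in pixels (default 3).
#' @param k_mad robust-sd multiplier for the detection threshold.
#' @param min_obj_area optional minimum connected-component area applied
#'   before dilation (0 = keep everything, the permissive default);
#'   useful to ignore single-pixel noise excursions when screening
#'   media-only fields for debris.
#' @return logical matrix mask.
#' @export
permissive_mask <- function(image, dilation_px = 3L, k_mad = 2,
                            min_obj_area = 0L) {
  m <- as_pixel_matrix(image)
  if (dilation_px < 0) stop("'dilation_px' must be non-negative")
  thr <- median(m) + k_mad * mad(m)
  mask <- m > thr
  if (!any(mask)) return(mask)
  if (min_obj_area > 0) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))
    area <- tabulate(lab[lab > 0], max(lab))
    mask <- matrix(lab > 0 & area[pmax(lab, 1L)] >= min_obj_area,
                   nrow(m), ncol(m))
    if (!any(mask)) return(mask)
  }
  if (dilation_px > 0) {
    d <- EBImage::dilate(EBImage::Image(mask * 1), disk_kernel(dilation_px))
    mask <- matrix(as.numeric(EBImage::imageData(d)) > 0.5, nrow(m), ncol(m))
  }
  mask
}

#' Fraction of segmented objects positive for a counterstain
#'
#' Scores each labelled FP_NLS_FP object as counterstained when its mean
#' intensity in the (spatially registered) counterstain channel exceeds
#' `positive_threshold`. Used to verify that the nuclear marker labels
#' genuine (e.g. Hoechst-positive) nuclei rather than debris.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param counterstain counterstain channel grid, same dimensions.
#' @param positive_threshold mean-intensity cutoff for positivity.
#' @return fraction in `[0, 1]`, or `NA_real_` when there are no objects
#'   (distinct from an observed fraction of 0).
#' @export
counterstain_fraction <- function(labels, counterstain, positive_threshold) {
  cs <- as_pixel_matrix(counterstain)
  if (!identical(dim(labels), dim(cs)))
    stop("counterstain image and label image differ in dimensions")
  n <- max(labels)
  if (n == 0L) return(NA_real_)
  idx <- which(labels > 0)
  l <- labels[idx]
  means <- as.numeric(rowsum(cs[idx], l)[, 1]) / tabulate(l, n)[sort(unique(l))]
  mean(means > positive_threshold)
}
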