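#' Build a per-channel reference background image from media-only wells
#'
#' The reference captures camera offset, media fluorescence and the
#' smooth illumination non-uniformity (vignetting) of one channel. Each
#' candidate media-only field is first screened for unusual fluorescent
#' debris: its all-object mask (permissive detection, small components
#' below `min_obj_area` ignored, then dilation) must cover no more than
#' `max_mask_fraction` of pixels. Accepted fields are averaged pixel-wise
#' and the result kept real-valued.
#'
#' @param media_only_fields list of [field_image_set()] from media-only
#'   (no-cell) wells.
#' @param channel channel id to average.
#' @param max_mask_fraction maximum tolerated masked-pixel fraction per
#'   field (default 0.5\%).
#' @param dilation_px,k_mad,min_obj_area debris-screen mask parameters
#'   (see [permissive_mask()]).
#' @return list of class `background_reference` with `reference` (real
#'   matrix), `channel`, `n_fields_averaged` and `rejected` (named reasons).
#' @export
build_reference_background <- function(media_only_fields, channel,
                                       max_mask_fraction = 0.005,
                                       dilation_px = 3L, k_mad = 5,
                                       min_obj_area = 5L) {
  if (length(media_only_fields) < 1L)
    stop("at least one media-only field is required")
  acc <- list(); rejected <- character(0)
  for (i in seq_along(media_only_fields)) {
    fs <- media_only_fields[[i]]
    if (!channel %in% names(fs$channels)) {
      rejected[sprintf("field %d", i)] <- paste0("missing channel ", channel)
      next
    }
    m <- fs$channels[[channel]]$pixels
    msk <- permissive_mask(m, dilation_px = dilation_px, k_mad = k_mad,
                           min_obj_area = min_obj_area)
    frac <- mean(msk)
    if (frac > max_mask_fraction) {
      rejected[sprintf("field %d (%s/%s)", i, fs$well_id, fs$field_index)] <-
        sprintf("debris mask covers %.2f%% of pixels (limit %.2f%%)",
                100 * frac, 100 * max_mask_fraction)
      next
    }
    acc[[length(acc) + 1L]] <- m
  }
  if (!length(acc))
    stop("all candidate background fields were rejected:\n  ",
         paste(names(rejected), rejected, sep = ": ", collapse = "\n  "))
  reference <- Reduce(`+`, acc) / length(acc)
  structure(list(reference = reference, channel = channel,
                 n_fields_averaged = length(acc), rejected = rejected),
            class = "background_reference")
}

ref_matrix <- function(reference) {
  if (inherits(reference, "background_reference")) reference$reference
  else as_pixel_matrix(reference)
}

#' Estimate the per-field residual background offset
#'
#' After subtracting the reference background image, each field still
#' shows a small well-to-well offset (typically +/- 1 to 3 counts on the
#' 12-bit scale, from compound fluorescence or media variation). The
#' offset is the mean of `field - reference` over the pixels outside the
#' dilated all-object exclusion mask; the same mask is applied to both
#' grids so both are sampled in the same cell-free area.
#'
#' @param field_image field grid ([channel_image()] or matrix).
#' @param reference [build_reference_background()] result or matrix.
#' @param exclusion_mask logical matrix from [permissive_mask()] applied
#'   to this field (`TRUE` = excluded).
#' @param min_unmasked_fraction minimum fraction of background pixels
#'   required (default 1\%).
#' @return the scalar offset delta, in counts.
#' @export
estimate_field_offset <- function(field_image, reference, exclusion_mask,
                                  min_unmasked_fraction = 0.01) {
  m <- as_pixel_matrix(field_image)
  ref <- ref_matrix(reference)
  if (!identical(dim(m), dim(ref)))
    stop("field and reference differ in dimensions")
  if (!identical(dim(m), dim(exclusion_mask)))
    stop("field and exclusion mask differ in dimensions")
  free <- !exclusion_mask
  if (mean(free) < min_unmasked_fraction)
    stop("only ", sprintf("%.2f%%", 100 * mean(free)),
         " of pixels are unmasked; too few for offset estimation -- ",
         "sample a denser cell-free background area")
  mean(m[free] - ref[free])
}

#' Apply the two-stage background correction to a field
#'
#' `corrected = field - reference - delta`. Negative values are preserved
#' (not clipped) so that summed object intensities remain unbiased.
#'
#' @param field_image field grid.
#' @param reference reference background (object or matrix).
#' @param delta scalar per-field offset from [estimate_field_offset()].
#' @return real-valued corrected matrix.
#' @export
correct_field <- function(field_image, reference, delta = 0) {
  m <- as_pixel_matrix(field_image)
  ref <- ref_matrix(reference)
  if (!identical(dim(m), dim(ref)))
    stop("field and reference differ in dimensions")
  m - ref - delta
}

#' Warn when edge-row background offsets deviate from the plate
#'
#' Plate walls can reflect background light into edge wells. Given the
#' per-well offsets of one plate/day, flags edge-row/column wells whose
#' offset deviates by more than `k` robust sds from the plate median.
#'
#' @param offsets named numeric vector, well id -> offset.
#' @param k deviation multiplier (default 3).
#' @return (invisibly) character vector of flagged wells; a warning is
#'   emitted when any well is flagged.
#' @export
check_edge_background <- function(offsets, k = 3) {
  wells <- names(offsets)
  rows <- substr(wells, 1, 1)
  cols <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", wells)))
  edge <- rows %in% c(min(rows), max(rows)) |
    cols %in% c(min(cols, na.rm = TRUE), max(cols, na.rm = TRUE))
  s <- mad(offsets)
  if (s == 0) return(invisible(character(0)))
  dev <- abs(offsets - median(offsets)) / s
  flagged <- wells[edge & dev > k]
  if (length(flagged))
    warning("edge-well background offsets deviate by >", k,
            " sd from the plate median (possible plate-wall reflection): ",
            paste(flagged, collapse = ", "))
  invisible(flagged)
}
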