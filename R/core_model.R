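#' @import stats
#' @import utils
NULL

CHANNEL_IDS <- c("em1", "em2", "yfp", "hoechst")
MAX_COUNT <- 4095  # 12-bit data stored in a 16-bit container

#' Construct a single-channel field image
#'
#' A `channel_image` holds one field of one acquisition channel as a
#' numeric pixel matrix on the 12-bit intensity scale (0--4095). Values
#' outside that range are rejected, never clipped, so that acquisition
#' errors surface early. Pixels may be non-integer: simulated fields can
#' be kept unquantized, and background-corrected grids are real-valued.
#'
#' @param pixels numeric matrix, all values in `[0, 4095]`, non-empty.
#' @param channel_id one of `"em1"`, `"em2"`, `"yfp"`, `"hoechst"`.
#' @param exposure_ms optional positive exposure time (metadata only).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_id, exposure_ms = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("'pixels' contains non-finite values")
  if (any(pixels < 0) || any(pixels > MAX_COUNT))
    stop("pixel values outside [0, ", MAX_COUNT,
         "]: images must carry 12-bit data (values are rejected, not clipped)")
  channel_id <- match.arg(channel_id, CHANNEL_IDS)
  if (!is.null(exposure_ms) && (!is.numeric(exposure_ms) || exposure_ms <= 0))
    stop("'exposure_ms' must be a positive number")
  structure(list(pixels = pixels, channel_id = channel_id,
                 exposure_ms = exposure_ms),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s: %d x %d px, range [%.1f, %.1f]>\n",
              x$channel_id, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a channel_image or a bare matrix wherever a pixel grid is
# expected (corrected grids circulate as plain real matrices).
as_pixel_matrix <- function(x) {
  if (inherits(x, "channel_image")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a channel_image or a numeric matrix")
}

#' Bundle the channel images of one imaged field
#'
#' @param plate_id,well_id character identifiers; wells use the standard
#'   384-well "LetterNumber" convention (e.g. `"B03"`).
#' @param field_index non-negative integer field number within the well.
#' @param day non-negative integer imaging day.
#' @param channels named list of [channel_image()] objects; names must match
#'   each element's `channel_id` and all pixel grids must share dimensions.
#' @return an object of class `field_image_set`.
#' @export
field_image_set <- function(plate_id, well_id, field_index, day, channels) {
  stopifnot(is.character(plate_id), is.character(well_id),
            length(well_id) == 1L, field_index >= 0, day >= 0)
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of channel images")
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be named by channel id")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!inherits(ch, "channel_image"))
      stop("channel '", nm, "' is not a channel_image")
    if (!identical(nm, ch$channel_id))
      stop("channel list name '", nm, "' does not match channel_id '",
           ch$channel_id, "'")
  }
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels of a field must share identical pixel dimensions")
  structure(list(plate_id = plate_id, well_id = well_id,
                 field_index = as.integer(field_index), day = as.integer(day),
                 channels = channels),
            class = "field_image_set")
}

#' @export
print.field_image_set <- function(x, ...) {
  cat(sprintf("<field_image_set %s/%s f%d day%d: %s>\n", x$plate_id,
              x$well_id, x$field_index, x$day,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Load a field from single-plane grayscale TIFF files
#'
#' Reads one 16-bit grayscale TIFF per channel and validates the 12-bit
#' contract (all values must lie in 0--4095).
#'
#' @param paths named character vector or list, channel id -> TIFF path.
#' @param plate_id,well_id,field_index,day field metadata.
#' @return a [field_image_set()].
#' @export
load_field <- function(paths, plate_id = "plate1", well_id = "A01",
                       field_index = 0L, day = 0L) {
  paths <- unlist(paths)
  channels <- vector("list", length(paths))
  names(channels) <- names(paths)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p))
      stop("cannot read image for channel '", nm, "': file not found: ", p)
    m <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(m)) != 2L)
      stop("channel '", nm, "': expected a single-plane grayscale TIFF: ", p)
    if (max(m) > MAX_COUNT)
      stop("channel '", nm, "': pixel values exceed ", MAX_COUNT,
           "; the pipeline expects 12-bit data in a 16-bit container")
    channels[[nm]] <- channel_image(m, nm)
  }
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel images have mismatched dimensions: ",
         paste(sprintf("%s=%dx%d", names(channels), dims[1, ], dims[2, ]),
               collapse = ", "))
  field_image_set(plate_id, well_id, field_index, day, channels)
}

#' Write the channels of a field as 16-bit grayscale TIFFs
#'
#' Pixel values are rounded to integers on write; the write-then-read
#' round trip through [load_field()] is then exact.
#'
#' @param field a [field_image_set()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to `well_fN_dayD`.
#' @return named character vector of the written paths (by channel).
#' @export
write_field <- function(field, dir, prefix = NULL) {
  if (is.null(prefix))
    prefix <- sprintf("%s_f%d_day%d", field$well_id, field$field_index,
                      field$day)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    m <- round(field$channels[[nm]]$pixels)
    tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L)
    paths[nm] <- p
  }
  paths
}

# Canonical object-table column order (documented header of the CSV).
OBJECT_TABLE_COLUMNS <- c(
  "object_id", "plate_id", "well_id", "field_index", "day",
  "centroid_row", "centroid_col", "area_px",
  "em1", "em2", "yfp", "hoechst",
  "ratio_em1_em2", "saturated", "low_signal", "assignment")

# An empty but valid object table (intensity channels as requested).
empty_object_table <- function(channels = c("em1", "em2")) {
  df <- data.frame(object_id = integer(0), plate_id = character(0),
                   well_id = character(0), field_index = integer(0),
                   day = integer(0), centroid_row = numeric(0),
                   centroid_col = numeric(0), area_px = integer(0),
                   stringsAsFactors = FALSE)
  for (ch in channels) df[[ch]] <- numeric(0)
  df$ratio_em1_em2 <- numeric(0)
  df$saturated <- logical(0)
  df$low_signal <- logical(0)
  df
}

#' Write an object table to CSV
#'
#' One row per segmented nucleus, in the canonical column order
#' (`object_id, plate_id, well_id, field_index, day, centroid_row,
#' centroid_col, area_px, <channels>, ratio_em1_em2, saturated,
#' low_signal[, assignment]`). Integers round-trip exactly; reals to full
#' double precision.
#'
#' @param table an object table `data.frame` (possibly empty).
#' @param path output CSV path.
#' @export
write_object_table <- function(table, path) {
  if (!is.data.frame(table)) stop("'table' must be a data.frame")
  cols <- intersect(OBJECT_TABLE_COLUMNS, names(table))
  extra <- setdiff(names(table), cols)
  out <- table[, c(cols, extra), drop = FALSE]
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write object table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read an object table written by [write_object_table()]
#' @param path CSV path.
#' @return the object table `data.frame`.
#' @export
read_object_table <- function(path) {
  if (!file.exists(path)) stop("object table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("object_id", "field_index", "day", "area_px"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  for (col in c("saturated", "low_signal"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Load a plate layout from CSV
#'
#' Expected columns: `well_id`, `role` (`sample` or `background`), and
#' optionally `mixture` (cell-line labels separated by `|`), `treatment`
#' and `concentration` (free text, e.g. `"0.2 nM"`). Background
#' ("media only") wells carry no mixture.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `plate_layout` with a list-column
#'   `mixture`.
#' @export
load_plate_layout <- function(path) {
  if (!file.exists(path)) stop("plate layout not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  plate_layout(df)
}

#' Construct and validate a plate layout
#'
#' @param df data.frame with columns `well_id`, `role` and optionally
#'   `mixture` (either a `|`-separated character column or a list-column),
#'   `treatment`, `concentration`.
#' @return validated `plate_layout` data.frame.
#' @export
plate_layout <- function(df) {
  need <- c("well_id", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate layout is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$well_id))
    stop("duplicate well_id in plate layout: ",
         paste(unique(df$well_id[duplicated(df$well_id)]), collapse = ", "))
  bad <- setdiff(unique(df$role), c("sample", "background"))
  if (length(bad)) stop("unknown role in plate layout: ",
                        paste(bad, collapse = ", "))
  if (!"mixture" %in% names(df)) df$mixture <- ""
  if (!is.list(df$mixture)) {
    df$mixture <- lapply(df$mixture, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  if (!"treatment" %in% names(df)) df$treatment <- ""
  if (!"concentration" %in% names(df)) df$concentration <- ""
  df$treatment[is.na(df$treatment)] <- ""
  df$concentration[is.na(df$concentration)] <- ""
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Write a plate layout to CSV (inverse of [load_plate_layout()])
#' @param layout a `plate_layout`.
#' @param path output CSV path.
#' @export
write_plate_layout <- function(layout, path) {
  out <- data.frame(well_id = layout$well_id, role = layout$role,
                    mixture = vapply(layout$mixture, paste,
                                     character(1), collapse = "|"),
                    treatment = layout$treatment,
                    concentration = layout$concentration,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Wells of the layout containing exactly one line (monocultures of `label`).
monoculture_wells <- function(layout, label) {
  sel <- layout$role == "sample" &
    vapply(layout$mixture, function(m)
      length(m) == 1L && m == label, logical(1))
  layout$well_id[sel]
}

background_wells <- function(layout) layout$well_id[layout$role == "background"]
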