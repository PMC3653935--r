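#' Tally assigned objects per well, day and line
#'
#' Sums object counts over the fields of each well. Every segmented
#' object contributes to exactly one category: an assigned line,
#' `"other"` (debris outside all windows) or `"excluded"` (saturated or
#' low-signal). The `"total"` row counts assigned-plus-other objects;
#' excluded objects are tallied separately and never enter line totals.
#'
#' @param objects object table(s) carrying an `assignment` column (from
#'   [classify_objects()]); a data.frame or list of data.frames.
#' @return `data.frame` with columns `well_id, day, line, count`, where
#'   `line` runs over assigned labels plus `"other"`, `"excluded"`,
#'   `"total"`.
#' @export
count_per_well <- function(objects) {
  if (is.data.frame(objects)) objects <- list(objects)
  tab <- do.call(rbind, objects)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(well_id = character(0), day = integer(0),
                      line = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  if (!"assignment" %in% names(tab))
    stop("objects must carry an 'assignment' column; run classify_objects()")
  agg <- aggregate(list(count = rep(1L, nrow(tab))),
                   by = list(well_id = tab$well_id, day = tab$day,
                             line = tab$assignment), FUN = sum)
  counted <- agg[agg$line != "excluded", , drop = FALSE]
  tot <- aggregate(list(count = counted$count),
                   by = list(well_id = counted$well_id, day = counted$day),
                   FUN = sum)
  tot$line <- "total"
  out <- rbind(agg, tot[, c("well_id", "day", "line", "count")])
  out <- out[order(out$well_id, out$day, out$line), ]
  rownames(out) <- NULL
  out
}

count_lookup <- function(counts, well, line, day) {
  hit <- counts$well_id == well & counts$line == line & counts$day == day
  if (!any(hit)) return(NA_integer_)
  sum(counts$count[hit])
}

#' Longitudinal growth fold for one well and line
#'
#' `G = N(day_t) / N(day_ref)` within the same well, the longitudinal
#' measurement that cancels well-to-well plating variability. Undefined
#' (NA, with a warning) when the baseline count is zero or missing.
#'
#' @param counts a [count_per_well()] table.
#' @param well well id.
#' @param line line label, or `"total"`.
#' @param day_t later day.
#' @param day_ref baseline day (default 0).
#' @return the growth fold (numeric scalar).
#' @export
growth_fold <- function(counts, well, line = "total", day_t, day_ref = 0L) {
  n_t <- count_lookup(counts, well, line, day_t)
  n_0 <- count_lookup(counts, well, line, day_ref)
  if (is.na(n_0) || n_0 <= 0) {
    warning("growth fold undefined for well ", well, " line ", line,
            ": baseline day-", day_ref, " count is ",
            if (is.na(n_0)) "missing" else "zero")
    return(NA_real_)
  }
  n_t / n_0
}

#' Growth folds for every well of a line
#'
#' @param counts a [count_per_well()] table.
#' @param line line label or `"total"`.
#' @param day_t later day; `day_ref` baseline day.
#' @return data.frame `well_id, line, day_t, day_ref, n_t, n_ref, fold`.
#' @export
growth_table <- function(counts, line = "total", day_t, day_ref = 0L) {
  wells <- unique(counts$well_id[counts$line == line & counts$day == day_t])
  out <- data.frame(well_id = wells, line = line, day_t = day_t,
                    day_ref = day_ref, n_t = NA_integer_, n_ref = NA_integer_,
                    fold = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(wells)) {
    out$n_t[i] <- count_lookup(counts, wells[i], line, day_t)
    out$n_ref[i] <- count_lookup(counts, wells[i], line, day_ref)
    if (!is.na(out$n_ref[i]) && out$n_ref[i] > 0)
      out$fold[i] <- out$n_t[i] / out$n_ref[i]
  }
  out
}

#' False-negative rate under 3-sd threshold scoring
#'
#' A treated well is scored "no growth" (a false negative when growth is
#' truly present) if its measurement does not exceed
#' `tau = mean(reference) + 3 * sd(reference)`. With cross-well scoring
#' the reference is the day-0 (or day-4 vehicle) count distribution of
#' other wells; with longitudinal scoring both the values and the
#' reference are per-well day-t/day-0 folds, which removes plating
#' variability.
#'
#' @param values numeric measurements of the treated wells (counts or
#'   folds).
#' @param reference numeric reference sample (length >= 2).
#' @param rule scoring rule; only `"3sd_above"` is defined.
#' @return fraction of `values` at or below the threshold, in `[0, 1]`.
#' @export
growth_false_negative_rate <- function(values, reference,
                                       rule = "3sd_above") {
  rule <- match.arg(rule)
  if (length(reference) < 2L)
    stop("reference sample must contain at least 2 wells")
  s <- sd(reference)
  if (s == 0) {
    warning("degenerate reference (sd = 0); threshold equals the mean")
    s <- 0
  }
  tau <- mean(reference) + 3 * s
  mean(values <= tau)
}

#' Z'-factor assay quality statistic
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values above
#' 0.5 indicate well-to-well reproducibility sufficient for
#' high-throughput screening.
#'
#' @param pos_values,neg_values numeric samples (length >= 2 each) of the
#'   positive- and negative-control wells.
#' @return list of class `assay_quality` with `z_prime`, `mu_pos`,
#'   `sd_pos`, `mu_neg`, `sd_neg`.
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    stop("each control sample needs at least 2 wells")
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stop("Z'-factor is undefined when the control means are equal")
  s_p <- sd(pos_values); s_n <- sd(neg_values)
  structure(list(z_prime = 1 - 3 * (s_p + s_n) / abs(mu_p - mu_n),
                 mu_pos = mu_p, sd_pos = s_p, mu_neg = mu_n, sd_neg = s_n),
            class = "assay_quality")
}

#' @export
print.assay_quality <- function(x, ...) {
  cat(sprintf("Z' = %.3f  (pos %.3g +/- %.3g, neg %.3g +/- %.3g)\n",
              x$z_prime, x$mu_pos, x$sd_pos, x$mu_neg, x$sd_neg))
  invisible(x)
}

#' Per-line nuclear reporter summary
#'
#' Averages the per-nucleus reporter intensity (summed corrected signal
#' divided by area, i.e. the mean nuclear intensity) within each field
#' and assigned line, then summarizes each (line, treatment) condition as
#' mean +/- sd across fields. Excluded objects are omitted; a (field,
#' line) cell without objects yields no row (missing, never zero).
#'
#' @param objects classified object table(s) with an `assignment` column
#'   and the reporter channel column.
#' @param layout optional [plate_layout()]; when given, each well's
#'   treatment is joined in, otherwise treatment is `""`.
#' @param channel reporter channel column name (default `"yfp"`).
#' @return list with `fields` (per well/field/day/line field means) and
#'   `conditions` (per line/treatment mean, sd, n_fields).
#' @export
nuclear_reporter_summary <- function(objects, layout = NULL,
                                     channel = "yfp") {
  if (is.data.frame(objects)) objects <- list(objects)
  tab <- do.call(rbind, objects)
  if (!channel %in% names(tab))
    stop("reporter channel '", channel, "' not present in the object table")
  if (!"assignment" %in% names(tab))
    stop("objects must carry an 'assignment' column; run classify_objects()")
  keep <- !(tab$assignment %in% c("excluded", "other", "ambiguous"))
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab))
    return(list(fields = data.frame(), conditions = data.frame()))
  tab$reporter_mean <- tab[[channel]] / tab$area_px
  fields <- aggregate(list(mean_intensity = tab$reporter_mean),
                      by = list(well_id = tab$well_id,
                                field_index = tab$field_index,
                                day = tab$day, line = tab$assignment),
                      FUN = mean)
  fields$treatment <- ""
  if (!is.null(layout)) {
    mt <- match(fields$well_id, layout$well_id)
    fields$treatment <- ifelse(is.na(mt), "", layout$treatment[mt])
  }
  conditions <- aggregate(fields$mean_intensity,
                          by = list(line = fields$line,
                                    treatment = fields$treatment),
                          FUN = function(v) c(mean = mean(v), sd = sd(v),
                                              n = length(v)))
  conditions <- data.frame(line = conditions$line,
                           treatment = conditions$treatment,
                           mean = conditions$x[, "mean"],
                           sd = conditions$x[, "sd"],
                           n_fields = as.integer(conditions$x[, "n"]),
                           stringsAsFactors = FALSE)
  list(fields = fields, conditions = conditions)
}

#' Two-way ANOVA equivalence check between mono- and co-culture
#'
#' Tests whether measurements collected from individually cultured wells
#' and from co-cultured, bar-code-separated wells agree across a
#' treatment panel: a two-way fixed-effects ANOVA with factors treatment
#' and culture mode (type-II sums of squares, so unbalanced designs are
#' handled), returning the culture-mode main effect. A large p-value
#' supports equivalence of the two culture modes.
#'
#' @param data data.frame of per-well (or per-field) measurements.
#' @param value,treatment,mode column names for the measurement, the
#'   treatment factor and the culture-mode factor.
#' @return list with `F` (culture-mode F statistic), `p_value`, and the
#'   full `anova_table`.
#' @export
coculture_equivalence_test <- function(data, value = "value",
                                       treatment = "treatment",
                                       mode = "mode") {
  stopifnot(all(c(value, treatment, mode) %in% names(data)))
  data[[treatment]] <- factor(data[[treatment]])
  data[[mode]] <- factor(data[[mode]])
  if (nlevels(data[[treatment]]) < 2L)
    stop("the equivalence test needs at least two treatments")
  if (nlevels(data[[mode]]) < 2L)
    stop("both culture modes must be present")
  fml <- reformulate(c(treatment, mode), response = value)
  fit <- lm(fml, data = data)
  at <- car::Anova(fit, type = 2)
  row <- which(rownames(at) == mode)
  list(F = at$`F value`[row], p_value = at$`Pr(>F)`[row], anova_table = at)
}
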