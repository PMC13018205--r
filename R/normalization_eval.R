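# Ratiometric normalization evaluation: per-plant and pooled CVs per
# scheme/condition, one-tailed Welch comparisons against an unnormalized
# control, Bonferroni correction, and CV matrices over design factors.

.readouts <- c("green", "red", "green_over_red", "red_over_green")

# per-disk readout values for one condition, NA-dropping per channel
.readout_values <- function(green, red, readout) {
  switch(readout,
    green = green,
    red = red,
    green_over_red = ifelse(!is.na(red) & red > 0, green / red, NA_real_),
    red_over_green = ifelse(!is.na(green) & green > 0, red / green, NA_real_)
  )
}

#' Append a per-disk ratio channel
#'
#' Computes the reporter/normalizer ratio disk by disk (not as a ratio of
#' plant means). Disks whose denominator is missing or zero are dropped and
#' the count is recorded in the provenance filter log.
#'
#' @param table An `assay_table` with both channels present.
#' @param numerator,denominator `"green"` or `"red"`.
#' @return The `assay_table` with an added `ratio` column.
#' @export
disk_ratio <- function(table, numerator = "green", denominator = "red") {
  stopifnot(
    inherits(table, "assay_table"),
    numerator %in% c("green", "red"), denominator %in% c("green", "red"),
    numerator != denominator
  )
  df <- tibble::as_tibble(as.data.frame(table))
  den <- df[[denominator]]
  drop <- is.na(den) | den <= 0
  out <- df[!drop, , drop = FALSE]
  out$ratio <- out[[numerator]] / out[[denominator]]
  .assay_rewrap(out, table, tibble::tibble(
    rule = sprintf("%s/%s ratio: denominator missing or <= 0", numerator, denominator),
    n_removed = sum(drop)
  ))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Scale
#' invariant under positive rescaling.
#'
#' @param values At least two real values with nonzero mean.
#' @return The unitless CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  sd(values) / m
}

#' Summarize a scheme/condition's variability
#'
#' Per-plant CVs are computed from all of a plant's disks regardless of leaf;
#' the pooled CV uses every disk of the condition at once. Plants whose CV is
#' undefined (fewer than 2 usable disks) are skipped and counted.
#'
#' @param table An `assay_table`.
#' @param condition_id Condition to summarize.
#' @param readout One of `"green"`, `"red"`, `"green_over_red"`,
#'   `"red_over_green"`.
#' @return A `scheme_summary` list: `condition_id`, `readout`, `plant_cvs`,
#'   `pooled_cv`, `n_plants`, `n_disks`, `n_skipped_plants`.
#' @export
summarize_scheme <- function(table, condition_id, readout = .readouts) {
  readout <- match.arg(readout)
  stopifnot(inherits(table, "assay_table"))
  df <- tibble::as_tibble(as.data.frame(table))
  df <- df[df$condition_id == condition_id, , drop = FALSE]
  if (nrow(df) == 0) stop("condition not present: ", condition_id, call. = FALSE)
  vals <- .readout_values(df$green, df$red, readout)
  keep <- !is.na(vals)
  df <- df[keep, , drop = FALSE]
  vals <- vals[keep]

  key <- paste(df$batch_id, df$plant_id, sep = "\r")
  per_plant <- split(vals, key)
  cvs <- vapply(per_plant, function(x) {
    if (length(x) < 2 || mean(x) == 0) NA_real_ else sd(x) / mean(x)
  }, numeric(1))
  skipped <- sum(is.na(cvs))
  cvs <- unname(cvs[!is.na(cvs)])

  structure(list(
    condition_id = condition_id,
    readout = readout,
    plant_cvs = cvs,
    pooled_cv = if (length(vals) >= 2 && mean(vals) != 0) sd(vals) / mean(vals) else NA_real_,
    n_plants = length(cvs),
    n_disks = length(vals),
    n_skipped_plants = skipped
  ), class = "scheme_summary")
}

#' One-tailed Welch test for reduced variability
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; the one-tailed p-value for the alternative
#' `mean(sample) < mean(control)`, as used to ask whether a normalization
#' scheme's per-plant CVs are significantly below the unnormalized control's.
#' When both groups are exactly constant the p-value is taken as 0 when the
#' sample mean is below the control mean, 1 when above, and 0.5 on a tie
#' (the sign convention of the limiting test).
#'
#' @param sample,control Numeric vectors of at least 2 values each
#'   (typically per-plant CVs).
#' @return The one-tailed p-value.
#' @export
welch_one_tailed_less <- function(sample, control) {
  sample <- sample[!is.na(sample)]
  control <- control[!is.na(control)]
  if (length(sample) < 2 || length(control) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (var(sample) == 0 && var(control) == 0) {
    d <- mean(sample) - mean(control)
    return(if (d < 0) 0 else if (d > 0) 1 else 0.5)
  }
  stats::t.test(sample, control, alternative = "less", var.equal = FALSE)$p.value
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the family size `m` and capped at 1. The
#' family size is explicit because the set of scheme-vs-control comparisons
#' forming one family depends on the experimental design (17 co-delivery
#' schemes per reporter orientation in the motivating design).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  stats::p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Compare schemes' per-plant CVs against an unnormalized control
#'
#' For each scheme, runs [welch_one_tailed_less()] of the scheme's per-plant
#' CVs (at `readout`) against the control condition's per-plant CVs (at
#' `control_readout`), then applies a Bonferroni correction with family size
#' `m`.
#'
#' @param table An `assay_table`.
#' @param schemes Character vector of scheme condition ids.
#' @param control Control condition id.
#' @param readout Readout for the schemes (default `"green_over_red"`).
#' @param control_readout Readout for the control (default `"green"`).
#' @param m Bonferroni family size (default: number of schemes).
#' @return A tibble with one row per scheme: `scheme`, `control`,
#'   `n_plants`, `mean_plant_cv`, `p_raw`, `p_adjusted`, `m_tests`,
#'   `percent_cv_change` (signed, relative to the control's mean plant CV).
#' @export
compare_scheme_cvs <- function(table, schemes, control,
                               readout = "green_over_red",
                               control_readout = "green",
                               m = length(schemes)) {
  ctrl <- summarize_scheme(table, control, control_readout)
  rows <- lapply(schemes, function(s) {
    sm <- summarize_scheme(table, s, readout)
    p <- welch_one_tailed_less(sm$plant_cvs, ctrl$plant_cvs)
    tibble::tibble(
      scheme = s, control = control,
      n_plants = sm$n_plants,
      mean_plant_cv = mean(sm$plant_cvs),
      p_raw = p,
      percent_cv_change = 100 * (mean(sm$plant_cvs) - mean(ctrl$plant_cvs)) /
        mean(ctrl$plant_cvs)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$m_tests <- m
  out[, c(
    "scheme", "control", "n_plants", "mean_plant_cv",
    "p_raw", "p_adjusted", "m_tests", "percent_cv_change"
  )]
}

#' Pooled-CV matrix over two design factors
#'
#' One pooled CV per combination of two metadata factors (e.g. the OD600 of
#' each co-infiltrated strain, or the two promoters), mirroring grid-style
#' variability summaries. Cells with no data, or too few disks for a CV, are
#' `NA`.
#'
#' @param table An `assay_table`.
#' @param row_factor,col_factor Names of metadata columns present in the
#'   table.
#' @param readout Readout used per disk.
#' @return A numeric matrix with factor levels as dimnames.
#' @export
cv_matrix <- function(table, row_factor, col_factor, readout = "green") {
  readout <- match.arg(readout, .readouts)
  df <- tibble::as_tibble(as.data.frame(table))
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(df)) stop("factor column not present: ", f, call. = FALSE)
  }
  vals <- .readout_values(df$green, df$red, readout)
  rl <- sort(unique(as.character(df[[row_factor]])))
  cl <- sort(unique(as.character(df[[col_factor]])))
  m <- matrix(NA_real_, length(rl), length(cl), dimnames = list(rl, cl))
  for (i in seq_along(rl)) {
    for (j in seq_along(cl)) {
      x <- vals[as.character(df[[row_factor]]) == rl[i] &
        as.character(df[[col_factor]]) == cl[j]]
      x <- x[!is.na(x)]
      if (length(x) >= 2 && mean(x) != 0) m[i, j] <- sd(x) / mean(x)
    }
  }
  m
}
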