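#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats sd var rnorm runif quantile pt qt setNames coef dnorm
#' @importFrom utils head
NULL

# Canonical column set. `green`/`red` are plate-reader fluorescences in
# arbitrary units; `od600_total` is the total inoculum density of the
# infiltration mix. Extra columns (promoter names, delivery method, ...) are
# carried through untouched as metadata.
.assay_key_cols <- c("batch_id", "condition_id", "plant_id", "leaf", "disk_index")
.assay_core_cols <- c(.assay_key_cols, "strain", "green", "red", "od600_total")

.assay_leaves <- c("T4", "T5")

new_assay_table <- function(df, provenance = list()) {
  df <- tibble::as_tibble(df)
  if (is.null(provenance$filter_log)) {
    provenance$filter_log <- tibble::tibble(
      rule = character(), n_removed = integer()
    )
  }
  structure(df,
    class = c("assay_table", class(tibble::tibble())),
    provenance = provenance
  )
}

#' Validate a data frame as an assay table
#'
#' An assay table holds one row per leaf disk of an agroinfiltration
#' fluorescence assay, with the full batch > plant > leaf > disk hierarchy and
#' condition metadata. Validation enforces the structural invariants:
#' `leaf` is `"T4"` or `"T5"`, `disk_index` is 1-4, every row carries at least
#' one nonnegative channel value, the hierarchy key
#' (`batch_id`, `condition_id`, `plant_id`, `leaf`, `disk_index`) is unique,
#' and no plant has more than 8 disks (2 leaves x 4 disks).
#'
#' @param df A data frame with at least the columns `batch_id`, `plant_id`,
#'   `leaf`, `disk_index`, `condition_id`, and one of `green`/`red`. Missing
#'   `strain` or `od600_total` columns are added as `NA`.
#' @param source Provenance label recorded on the result.
#' @param on_invalid `"error"` to fail on rows that violate row-level
#'   invariants, `"drop"` to reject them and record row-level diagnostics in
#'   the provenance (`rejected` element).
#' @return An `assay_table` (a tibble subclass carrying provenance).
#' @export
as_assay_table <- function(df, source = "in-memory", on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- tibble::as_tibble(df)

  missing_cols <- setdiff(c(.assay_key_cols), names(df))
  if (length(missing_cols) > 0) {
    stop("assay table schema error: missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!any(c("green", "red") %in% names(df))) {
    stop("assay table schema error: need at least one channel column ('green' or 'red')",
      call. = FALSE
    )
  }
  for (ch in c("green", "red")) if (!ch %in% names(df)) df[[ch]] <- NA_real_
  if (!"strain" %in% names(df)) df$strain <- NA_character_
  if (!"od600_total" %in% names(df)) df$od600_total <- NA_real_

  df$batch_id <- as.character(df$batch_id)
  df$condition_id <- as.character(df$condition_id)
  df$plant_id <- as.character(df$plant_id)
  df$leaf <- as.character(df$leaf)
  df$disk_index <- as.integer(df$disk_index)
  df$green <- as.numeric(df$green)
  df$red <- as.numeric(df$red)
  df$od600_total <- as.numeric(df$od600_total)
  df$strain <- as.character(df$strain)

  # row-level invariants
  bad_leaf <- !(df$leaf %in% .assay_leaves)
  bad_disk <- is.na(df$disk_index) | df$disk_index < 1L | df$disk_index > 4L
  no_channel <- is.na(df$green) & is.na(df$red)
  neg_channel <- (!is.na(df$green) & df$green < 0) | (!is.na(df$red) & df$red < 0)
  bad <- bad_leaf | bad_disk | no_channel | neg_channel

  rejected <- NULL
  if (any(bad)) {
    reason <- dplyr::case_when(
      bad_leaf ~ "leaf not in {T4, T5}",
      bad_disk ~ "disk_index not in 1..4",
      no_channel ~ "no channel value present",
      neg_channel ~ "negative channel value",
      TRUE ~ NA_character_
    )[bad]
    rejected <- dplyr::mutate(df[bad, , drop = FALSE],
      .row = which(bad), .reason = reason
    )
    if (on_invalid == "error") {
      stop(
        "assay table has ", sum(bad), " invalid row(s); first: row ",
        rejected$.row[1], " (", rejected$.reason[1], ")",
        call. = FALSE
      )
    }
    df <- df[!bad, , drop = FALSE]
  }

  key <- do.call(paste, c(df[.assay_key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), .assay_key_cols][1, ]
    stop(
      "assay table integrity error: duplicated hierarchy key (",
      paste(sprintf("%s=%s", names(dup), unlist(dup)), collapse = ", "), ")",
      call. = FALSE
    )
  }
  plant_key <- paste(df$batch_id, df$condition_id, df$plant_id, sep = "\r")
  sizes <- table(plant_key)
  if (any(sizes > 8L)) {
    stop(
      "assay table integrity error: a plant has ", max(sizes),
      " disks (maximum is 8 = 2 leaves x 4 disks)",
      call. = FALSE
    )
  }

  new_assay_table(df, provenance = list(source = source, rejected = rejected))
}

#' Read an assay table from delimited text
#'
#' Reads a delimited file (comma-separated, UTF-8, header required, by
#' default) whose columns map onto the canonical disk-record fields, and
#' validates it. Rows violating row-level invariants are rejected and
#' reported in the provenance; structural violations (missing mandatory
#' columns, duplicated hierarchy keys) are errors.
#'
#' @param path Path to the delimited file.
#' @param delim Field separator (default `","`).
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(green = "gfp_fluor")`. Columns not
#'   mentioned are taken verbatim. Use this to adapt e.g. control-well flag
#'   columns whose naming the canonical schema does not fix.
#' @return An `assay_table`.
#' @seealso [write_assay_table()], [as_assay_table()]
#' @export
read_assay_table <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, comment = "#"
  )
  if (!is.null(col_map)) {
    absent <- setdiff(unname(col_map), names(df))
    if (length(absent) > 0) {
      stop("assay table schema error: mapped column(s) not in file: ",
        paste(absent, collapse = ", "),
        call. = FALSE
      )
    }
    names(df)[match(col_map, names(df))] <- names(col_map)
  }
  as_assay_table(df, source = path, on_invalid = "drop")
}

#' Write an assay table to delimited text
#'
#' Values round-trip exactly through [read_assay_table()] for
#' text-representable fields (doubles are written with shortest
#' round-trippable representations).
#'
#' @param table An `assay_table`.
#' @param path Output path.
#' @param delim Field separator.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "assay_table"))
  readr::write_delim(tibble::as_tibble(as.data.frame(table)), path, delim = delim)
  invisible(path)
}

#' Retrieve assay-table provenance
#'
#' @param table An `assay_table`.
#' @return A list with at least `source` and `filter_log` (a tibble of QC
#'   rules applied with removal counts); may carry `rejected` rows from
#'   reading and `n_truncated` from synthetic generation.
#' @export
assay_provenance <- function(table) {
  attr(table, "provenance")
}

# Re-wrap a plain tibble as assay_table, carrying provenance forward and
# appending filter-log entries.
.assay_rewrap <- function(df, template, log_entries = NULL) {
  prov <- attr(template, "provenance")
  if (!is.null(log_entries)) {
    prov$filter_log <- dplyr::bind_rows(prov$filter_log, log_entries)
  }
  new_assay_table(df, provenance = prov)
}

#' Apply plate-reader QC exclusion filters
#'
#' Removes disks whose measured fluorescence falls in the range expected of
#' uninfiltrated tissue: disks from a construct carrying the green reporter
#' with `green < green_min`, and disks from a construct carrying the red
#' reporter with `red < red_min`. Thresholds are strict (a value exactly equal
#' to the threshold is retained). Missing channel values are never a reason
#' for exclusion. Which conditions carry which reporter is declared, not
#' inferred from signal; by default a condition is taken to carry a channel
#' if any of its disks has a non-missing value there.
#'
#' @param table An `assay_table`.
#' @param green_min,red_min Exclusion thresholds (arbitrary fluorescence
#'   units, default 1000 and 100); must be nonnegative.
#' @param green_carriers,red_carriers Optional character vectors of
#'   `condition_id` values whose constructs carry the respective reporter.
#'   `NULL` (default) means every condition with any non-missing value in
#'   that channel.
#' @return The filtered `assay_table`; counts removed per rule are appended
#'   to the provenance filter log. Filtering is idempotent.
#' @export
apply_qc_filters <- function(table, green_min = 1000, red_min = 100,
                             green_carriers = NULL, red_carriers = NULL) {
  stopifnot(inherits(table, "assay_table"), green_min >= 0, red_min >= 0)
  df <- tibble::as_tibble(as.data.frame(table))

  carriers <- function(channel, declared) {
    if (!is.null(declared)) {
      return(declared)
    }
    unique(df$condition_id[!is.na(df[[channel]])])
  }
  g_cond <- carriers("green", green_carriers)
  r_cond <- carriers("red", red_carriers)

  drop_green <- df$condition_id %in% g_cond & !is.na(df$green) & df$green < green_min
  drop_red <- df$condition_id %in% r_cond & !is.na(df$red) & df$red < red_min

  out <- df[!(drop_green | drop_red), , drop = FALSE]
  if (nrow(out) == 0) {
    warning("QC filtering removed every record", call. = FALSE)
  }
  .assay_rewrap(out, table, tibble::tibble(
    rule = c(
      sprintf("green < %g (green-carrying conditions)", green_min),
      sprintf("red < %g (red-carrying conditions)", red_min)
    ),
    n_removed = c(sum(drop_green), sum(drop_red & !drop_green))
  ))
}

#' Group disks by plant
#'
#' One group per (`batch_id`, `condition_id`, `plant_id`); a plant's group
#' carries all of its disks' channel values regardless of leaf, matching how
#' per-plant summaries (CVs) are computed downstream.
#'
#' @param table A non-empty `assay_table`.
#' @return A tibble with one row per plant: the key columns, `n_disks`, and
#'   list-columns `green` and `red` of the plant's disk values.
#' @export
per_plant_groups <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  if (nrow(table) == 0) stop("assay table is empty", call. = FALSE)
  df <- tibble::as_tibble(as.data.frame(table))
  dplyr::summarise(
    dplyr::group_by(df, .data$batch_id, .data$condition_id, .data$plant_id),
    n_disks = dplyr::n(),
    green = list(.data$green),
    red = list(.data$red),
    .groups = "drop"
  )
}

#' @export
print.assay_table <- function(x, ...) {
  prov <- assay_provenance(x)
  cat(sprintf(
    "<assay_table> %d disks | %d batches | %d plants | source: %s\n",
    nrow(x),
    length(unique(x$batch_id)),
    nrow(unique(as.data.frame(x)[c("batch_id", "condition_id", "plant_id")])),
    if (is.null(prov$source)) "?" else prov$source
  ))
  if (nrow(prov$filter_log) > 0) {
    cat("QC filter log:\n")
    for (i in seq_len(nrow(prov$filter_log))) {
      cat(sprintf(
        "  - %s: %d removed\n",
        prov$filter_log$rule[i], prov$filter_log$n_removed[i]
      ))
    }
  }
  NextMethod()
}
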