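# Reading, validating, filtering, segmenting and joining long-format
# laboratory result tables. A result table is a data.frame with columns
# person_id, gender, age, analyte, value, date (one row per reading).

#' LOINC codes for the bundled renal analytes
#' @export
LOINC_CREATININE <- "2160-0"
#' @rdname LOINC_CREATININE
#' @export
LOINC_UREA <- "3094-0"

#' Default implausible-value thresholds (mg/dl)
#'
#' Readings above these are treated as potential entry or unit errors:
#' 25 mg/dl for serum creatinine, 150 mg/dl for blood urea nitrogen.
#' @export
default_thresholds <- function() {
  c("2160-0" = 25, "3094-0" = 150)
}

.normalize_gender <- function(g) {
  g <- tolower(trimws(as.character(g)))
  g[g %in% c("m", "male")] <- "male"
  g[g %in% c("f", "female")] <- "female"
  g
}

#' Read a long-format lab result table from CSV
#'
#' Reads a delimited file of de-identified lab results, validates each row
#' (known gender, non-negative integer age within `age_range`, finite numeric
#' value, parseable ISO-8601 date) and drops invalid rows, counting them in a
#' drop report attached as attribute `"drop_report"`.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named character vector mapping the canonical names
#'   `person_id`, `gender`, `age`, `analyte`, `value`, `date` to the file's
#'   column names; defaults to identity.
#' @param age_range allowed age range in years.
#' @return A `data.frame` with canonical columns and attribute
#'   `drop_report` (a named list of drop counts by reason plus `total`).
#' @export
read_results <- function(path, column_map = NULL, age_range = c(0, 120)) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  canonical <- c("person_id", "gender", "age", "analyte", "value", "date")
  cm <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  missing <- setdiff(cm, names(raw))
  if (length(missing))
    stop("mapped columns absent from file: ", paste(missing, collapse = ", "))
  df <- data.frame(person_id = raw[[cm["person_id"]]],
                   gender = .normalize_gender(raw[[cm["gender"]]]),
                   age = suppressWarnings(as.numeric(raw[[cm["age"]]])),
                   analyte = raw[[cm["analyte"]]],
                   value = suppressWarnings(as.numeric(raw[[cm["value"]]])),
                   date = raw[[cm["date"]]],
                   stringsAsFactors = FALSE)
  parsed_date <- as.Date(df$date, format = "%Y-%m-%d")

  bad_gender <- !(df$gender %in% c("male", "female"))
  bad_age <- !is.finite(df$age) | df$age < age_range[1] |
    df$age > age_range[2] | df$age != floor(df$age)
  bad_value <- !is.finite(df$value)
  bad_date <- is.na(parsed_date)
  bad_id <- is.na(df$person_id) | df$person_id == ""
  keep <- !(bad_gender | bad_age | bad_value | bad_date | bad_id)

  report <- list(bad_gender = sum(bad_gender), bad_age = sum(bad_age),
                 bad_value = sum(bad_value), bad_date = sum(bad_date),
                 bad_person_id = sum(bad_id), total = sum(!keep))
  if (report$bad_gender > 0)
    warning(report$bad_gender, " row(s) with unknown gender code dropped")
  out <- df[keep, , drop = FALSE]
  out$age <- as.integer(out$age)
  out$date <- as.Date(parsed_date[keep])
  rownames(out) <- NULL
  attr(out, "drop_report") <- report
  out
}

#' Drop report of a table returned by [read_results()]
#' @param table a result table.
#' @return named list of drop counts, or `NULL` if absent.
#' @export
drop_report <- function(table) attr(table, "drop_report")

#' Write a result table to CSV
#'
#' Inverse of [read_results()]; values are written with full precision and
#' dates as ISO-8601.
#' @param table result table.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  out <- table[c("person_id", "gender", "age", "analyte", "value", "date")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove physiologically implausible readings
#'
#' Drops rows whose value is non-positive (concentrations are strictly
#' positive) or exceeds the per-analyte maximum. The upper boundary is
#' inclusive: a value exactly at the threshold is retained.
#'
#' @param table result table.
#' @param thresholds named numeric vector of per-analyte maxima in mg/dl;
#'   defaults to [default_thresholds()].
#' @param on_missing what to do with analytes absent from `thresholds`:
#'   `"keep"` (default, with a warning), `"drop"`, or `"error"`.
#' @return list with elements `table` (retained rows) and `removed_count`.
#' @export
filter_plausible <- function(table, thresholds = default_thresholds(),
                             on_missing = c("keep", "drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (nrow(table) == 0)
    return(list(table = table, removed_count = 0L))
  thr <- unname(thresholds[table$analyte])
  unknown <- is.na(thr)
  if (any(unknown)) {
    msg <- paste("no plausibility threshold for analyte(s):",
                 paste(unique(table$analyte[unknown]), collapse = ", "))
    if (on_missing == "error") stop(msg)
    if (on_missing == "keep") warning(msg, "; rows retained")
  }
  keep <- table$value > 0 &
    (ifelse(unknown, on_missing == "keep", table$value <= thr))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, removed_count = sum(!keep))
}

#' Segment a result table by gender and age
#'
#' Assigns every value to exactly one (gender, age-bin) segment. Segments
#' smaller than `min_n` are flagged unreliable: they stay in the report but
#' are excluded from estimation downstream. The default `min_n = 120`
#' follows the conventional minimum sample size for establishing a
#' reference interval directly.
#'
#' @param table result table (typically a single analyte, already filtered).
#' @param bin_width age bin width in years (>= 1); bins are labeled by their
#'   lower edge.
#' @param min_n minimum number of values for a segment to be reliable.
#' @return list with `segments` (named list, `"gender|age"` -> numeric
#'   values) and `info` (data.frame gender, age, n, reliable).
#' @export
segment_by_gender_age <- function(table, bin_width = 1L, min_n = 120L) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  bin <- (table$age %/% bin_width) * bin_width
  key <- paste(table$gender, bin, sep = "|")
  segments <- split(table$value, key)
  parts <- strsplit(names(segments), "|", fixed = TRUE)
  info <- data.frame(
    gender = vapply(parts, `[`, character(1), 1),
    age = as.integer(vapply(parts, `[`, character(1), 2)),
    n = vapply(segments, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  info$reliable <- info$n >= min_n
  ord <- order(info$gender, info$age)
  list(segments = segments[ord], info = info[ord, , drop = FALSE])
}

#' Join two single-analyte tables into joint records
#'
#' Pairs readings of two distinct analytes taken from the same person on the
#' same date, yielding one joint record per (person_id, date) present in both
#' tables. Duplicate same-day readings of one analyte are resolved by keeping
#' the first row in file order (logged as a message). Unmatched rows are
#' dropped and counted in attribute `"join_report"`.
#'
#' @param a,b result tables, each carrying a single distinct analyte.
#' @return data.frame with columns person_id, gender, age, date and one value
#'   column per analyte named `value_<analyte>`, in the order (a, b).
#' @export
join_analytes <- function(a, b) {
  an_a <- unique(a$analyte); an_b <- unique(b$analyte)
  if (length(an_a) != 1 || length(an_b) != 1)
    stop("each table must carry exactly one analyte")
  if (an_a == an_b) stop("tables must carry distinct analytes")
  dedup <- function(t) {
    k <- paste(t$person_id, t$date, sep = "\r")
    dup <- duplicated(k)
    if (any(dup))
      message(sum(dup), " duplicate (person, date) reading(s) of ",
              t$analyte[1], " dropped; first kept")
    t[!dup, , drop = FALSE]
  }
  a1 <- dedup(a); b1 <- dedup(b)
  m <- merge(a1[c("person_id", "gender", "age", "date", "value")],
             b1[c("person_id", "date", "value")],
             by = c("person_id", "date"), suffixes = c("_a", "_b"))
  out <- data.frame(person_id = m$person_id, gender = m$gender, age = m$age,
                    date = m$date, stringsAsFactors = FALSE)
  out[[paste0("value_", an_a)]] <- m$value_a
  out[[paste0("value_", an_b)]] <- m$value_b
  out <- out[order(out$person_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "join_report") <- list(
    unmatched_a = nrow(a1) - nrow(m), unmatched_b = nrow(b1) - nrow(m),
    analytes = c(an_a, an_b))
  out
}
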