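#' Read wide-format trial data
#'
#' Delimited text with a header row; comma by default, tab accepted
#' (auto-detected from the header line). Empty fields and the token `NA`
#' both parse as missing.
#'
#' @param file path to the delimited file.
#' @param sep field separator; `NULL` (default) auto-detects `,` vs tab.
#' @return data frame of numeric columns.
#' @export
read_trial_data <- function(file, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(file, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(file, header = TRUE, sep = sep, na.strings = c("", "NA"),
                    check.names = FALSE)
}

#' Compute early and late change scores from timepoint columns
#'
#' Expects, for each outcome, the column triple `<v>_baseline`, `<v>_wk10`,
#' `<v>_wk52`, plus a `group` column. Early change is week 10 minus baseline;
#' late change is week 52 minus week 10 (negative = improvement). A missing
#' operand makes the corresponding change score missing.
#'
#' @param table data frame of timepoint columns.
#' @return data frame (`group`, `<v>_early`, `<v>_late`, ...) with attribute
#'   `"tiers"`.
#' @export
compute_change_scores <- function(table) {
  if (!"group" %in% colnames(table)) stop("missing column: group")
  base_cols <- grep("_baseline$", colnames(table), value = TRUE)
  if (!length(base_cols)) stop("no *_baseline columns found")
  vars <- sub("_baseline$", "", base_cols)
  need <- c(paste0(vars, "_wk10"), paste0(vars, "_wk52"))
  absent <- setdiff(need, colnames(table))
  if (length(absent)) stop("malformed timepoint columns, missing: ",
                           paste(absent, collapse = ", "))
  out <- data.frame(group = table$group)
  for (v in vars) {
    out[[paste0(v, "_early")]] <- table[[paste0(v, "_wk10")]] - table[[paste0(v, "_baseline")]]
    out[[paste0(v, "_late")]] <- table[[paste0(v, "_wk52")]] - table[[paste0(v, "_wk10")]]
  }
  attr(out, "tiers") <- variable_tiers(colnames(out))
  out
}

#' Drop participants with mostly missing analysis variables
#'
#' Removes rows whose fraction of missing cells across the analysis columns
#' strictly exceeds `fraction` (default one half, i.e. missing in more than
#' 50 percent of the variables). Idempotent.
#'
#' @param data data frame of analysis variables.
#' @param fraction exclusion threshold in (0, 1).
#' @return list with `data` (retained rows) and `excluded` (row count dropped).
#' @export
exclude_high_missingness <- function(data, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  frac_missing <- rowMeans(is.na(data))
  drop <- frac_missing > fraction
  out <- data[!drop, , drop = FALSE]
  attr(out, "tiers") <- attr(data, "tiers")
  list(data = out, excluded = sum(drop))
}

#' Invert a 0-10 sleep item
#'
#' The raw item is scored so that 10 means no problem; analysis uses the
#' inverted score where 0 means no problem and 10 means sleep is impossible
#' because of pain.
#'
#' @param raw numeric in [0, 10].
#' @return `10 - raw`.
#' @export
invert_sleep <- function(raw) {
  if (any(raw < 0 | raw > 10, na.rm = TRUE)) stop("raw sleep score outside [0, 10]")
  10 - raw
}

#' Sum the three fear-avoidance items
#'
#' Each item is scored 0-10; the summed score is 0-30. Errors on
#' out-of-range items.
#'
#' @param item1,item2,item3 numeric vectors in [0, 10].
#' @return numeric vector in [0, 30].
#' @export
sum_fear_items <- function(item1, item2, item3) {
  items <- cbind(item1, item2, item3)
  if (any(items < 0 | items > 10, na.rm = TRUE)) stop("fear item outside [0, 10]")
  item1 + item2 + item3
}
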